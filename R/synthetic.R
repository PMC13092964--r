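# Random balanced food-web generator. The generator emulates the statistical
# structure the balance analysis assumes: row-stochastic Dirichlet diets over
# lower-positioned prey, P/Q ratios in the 0.1-0.3 band typical of balanced
# coastal models, and prey ecotrophic efficiencies inside (0, 0.95], so that
# every generated web balances on the first pass.

#' Specification for a random balanced food web
#'
#' @param n_producers,n_consumers,n_detritus Group counts (producers and
#'   detritus at least 1).
#' @param connectance Probability that a consumer links to each admissible
#'   lower-positioned consumer, in (0, 1).
#' @param pq_range Sampling range for P/Q = (P/B)/(Q/B).
#' @param ee_range Target range for prey ecotrophic efficiencies.
#' @param detritivory Probability that a consumer also feeds on detritus.
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return An object of class `synthetic_web_spec`.
#' @export
synthetic_web_spec <- function(n_producers = 2, n_consumers = 6,
                               n_detritus = 1, connectance = 0.3,
                               pq_range = c(0.1, 0.3),
                               ee_range = c(0.05, 0.95),
                               detritivory = 0.5, seed = 1L) {
  stopifnot(n_producers >= 1, n_detritus >= 1, n_consumers >= 0,
            connectance > 0, connectance < 1,
            length(pq_range) == 2, all(pq_range > 0), all(pq_range < 1),
            diff(pq_range) >= 0,
            length(ee_range) == 2, all(ee_range > 0), all(ee_range <= 0.95),
            diff(ee_range) >= 0,
            detritivory >= 0, detritivory <= 1)
  structure(list(n_producers = n_producers, n_consumers = n_consumers,
                 n_detritus = n_detritus, connectance = connectance,
                 pq_range = pq_range, ee_range = ee_range,
                 detritivory = detritivory, seed = as.integer(seed)),
            class = "synthetic_web_spec")
}

rdirichlet1 <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

#' Generate a random balanced food web
#'
#' Groups are ordered by intended trophic position (producers, then consumers
#' bottom-up, then detritus). Each consumer draws prey from lower-positioned
#' groups (every consumer keeps at least one basal food source, and every
#' producer is grazed by someone), diet fractions from a uniform Dirichlet,
#' Q/B from a uniform range and P/B as `Q/B * P/Q`. Biomasses are then
#' assigned top-down so that each preyed-upon group's implied EE equals a
#' draw from `ee_range`; apex consumers (no predators) receive a small
#' fishery yield `Y = B * PB * EE_draw` so their EE is also inside the range.
#' The returned model leaves EE unspecified: running [solve_balance()]
#' recovers exactly the drawn efficiencies.
#'
#' @param spec A [synthetic_web_spec()].
#' @return A `food_web_model` that passes [validate_model()] and balances
#'   with all living EE in (0, 0.95].
#' @export
generate_web <- function(spec) {
  stopifnot(inherits(spec, "synthetic_web_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  np <- spec$n_producers; nc <- spec$n_consumers; nd <- spec$n_detritus
  n <- np + nc + nd
  name <- c(sprintf("producer_%d", seq_len(np)),
            if (nc) sprintf("consumer_%d", seq_len(nc)),
            sprintf("detritus_%d", seq_len(nd)))
  role <- c(rep("producer", np), rep("consumer", nc), rep("detritus", nd))
  idx_p <- seq_len(np)
  idx_c <- if (nc) np + seq_len(nc) else integer(0)
  idx_d <- np + nc + seq_len(nd)

  # prey sets ----------------------------------------------------------
  prey <- vector("list", n)
  for (k in seq_along(idx_c)) {
    j <- idx_c[k]
    cand_c <- idx_c[seq_len(k - 1)]
    sel <- cand_c[stats::runif(length(cand_c)) < spec$connectance]
    basal <- idx_p[stats::runif(np) < 0.7]
    if (stats::runif(1) < spec$detritivory)
      basal <- c(basal, idx_d[sample.int(nd, 1)])
    if (!length(basal)) basal <- idx_p[sample.int(np, 1)]
    prey[[j]] <- sort(unique(c(basal, sel)))
  }
  if (nc) {
    grazed <- unique(unlist(prey))
    for (p in setdiff(idx_p, grazed)) {
      j <- idx_c[sample.int(length(idx_c), 1)]
      prey[[j]] <- sort(unique(c(prey[[j]], p)))
    }
  }

  diet <- matrix(0, n, n)
  for (j in idx_c) diet[j, prey[[j]]] <- rdirichlet1(length(prey[[j]]))

  # rates --------------------------------------------------------------
  QB <- rep(NA_real_, n)
  PB <- rep(NA_real_, n)
  QB[idx_c] <- stats::runif(nc, 4, 25)
  PB[idx_c] <- QB[idx_c] * stats::runif(nc, spec$pq_range[1], spec$pq_range[2])
  PB[idx_p] <- stats::runif(np, 30, 150)
  GS <- ifelse(role == "consumer", 0.2, 0)
  ee_draw <- stats::runif(n, spec$ee_range[1], spec$ee_range[2])

  # biomass top-down, with a guard on detritus depletion ----------------
  B <- rep(NA_real_, n)
  Y <- rep(0, n)
  for (pass in 1:5) {
    for (k in rev(seq_along(idx_c))) {
      j <- idx_c[k]
      preds <- idx_c[idx_c > j]
      m2 <- sum(B[preds] * QB[preds] * diet[preds, j])
      if (m2 > 0) {
        B[j] <- m2 / (PB[j] * ee_draw[j])
        Y[j] <- 0
      } else {
        B[j] <- stats::runif(1, 0.1, 2)
        Y[j] <- B[j] * PB[j] * ee_draw[j]
      }
    }
    for (p in idx_p) {
      m2 <- sum(B[idx_c] * QB[idx_c] * diet[idx_c, p])
      B[p] <- if (m2 > 0) m2 / (PB[p] * ee_draw[p]) else 1
    }
    B[idx_d] <- stats::runif(nd, 50, 200)
    if (!nc) break
    # implied detritus EE; if the pool would be over-consumed, shift diet
    # away from detritus and redo the biomass assignment
    Q <- ifelse(role == "consumer", B * QB, 0)
    P <- ifelse(role == "detritus", 0, B * PB)
    M2 <- as.numeric(t(diet) %*% Q)
    FD <- Q * GS + P * (1 - pmin(ifelse(P > 0, M2 / P, 0), 1))
    inflow <- sum(FD[role != "detritus"])
    det_cons <- sum(M2[idx_d])
    if (inflow <= 0 || det_cons / inflow <= 0.95) break
    scale <- 0.9 * 0.95 * inflow / det_cons
    for (j in idx_c) {
      dshare <- sum(diet[j, idx_d])
      if (dshare == 0) next
      diet[j, idx_d] <- diet[j, idx_d] * scale
      rest <- sum(diet[j, -idx_d])
      if (rest > 0) {
        diet[j, -idx_d] <- diet[j, -idx_d] * (1 - dshare * scale) / rest
      } else {
        diet[j, idx_p[1]] <- 1 - dshare * scale
      }
    }
  }

  g <- data.frame(name = name, role = role, B = B, PB = PB, QB = QB,
                  EE = NA_real_, Y = Y, BA = 0, E = 0, GS = GS)
  g$PB[idx_d] <- NA
  food_web_model(g, diet)
}
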