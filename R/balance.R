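# Mass-balance engine.
#
# Master equation, one per living group i:
#   B_i * (P/B)_i * EE_i = sum_j B_j * (Q/B)_j * DC_ij + Y_i + BA_i + E_i
# with DC_ij the fraction of prey i in the diet of predator j. At most one of
# {B, PB, QB, EE} may be missing per living group. Missing B's couple through
# predation and are solved as one exact linear system; missing EE, PB, QB are
# then back-computed from each group's own equation.

#' Solve the mass balance of a food-web model
#'
#' Estimates the missing parameter of every living group so the master
#' equation holds exactly, computes flow accounts, and derives detritus-pool
#' ecotrophic efficiency and accumulation.
#'
#' @param model A `food_web_model` that passes [validate_model()].
#' @param rebalance If `TRUE`, when some estimated EE exceeds 1, a greedy
#'   adjustment is attempted: the offending prey's biomass is scaled upward in
#'   1\% steps (capped at +10\%) until its EE drops to 1 or the cap is hit.
#'   Off by default; every adjustment is reported in the `adjustments` field.
#' @return An object of class `balanced_web`: a list with
#'   \describe{
#'     \item{model}{the input model with every living-group parameter filled.}
#'     \item{accounts}{flow accounts data frame (see [compute_flows()]), with
#'       detritus rows carrying the detritus EE and surplus.}
#'     \item{balanced}{`TRUE` when all estimated EE are <= 1 (within 1e-9).}
#'     \item{ee_violations}{names of groups with EE > 1, if any. The model is
#'       returned annotated rather than rejected, so the offending inputs can
#'       be inspected and adjusted.}
#'     \item{adjustments}{log of rebalancer steps (empty unless used).}
#'   }
#' @examples
#' b <- solve_balance(toy_chain_model())
#' b$model$groups$EE   # producer EE = 0.2, herbivore EE = 0 (no predators)
#' @export
solve_balance <- function(model, rebalance = FALSE) {
  stopifnot(inherits(model, "food_web_model"))
  diag <- validate_model(model)
  if (length(diag))
    stop("model fails validation:\n  ", paste(diag, collapse = "\n  "))

  filled <- fill_parameters(model)
  adjustments <- character(0)
  if (rebalance) {
    for (step in 1:10) {
      bad <- which(is_living(filled) & !is.na(filled$groups$EE) &
                     filled$groups$EE > 1 + 1e-9 & !is.na(filled$groups$B))
      if (!length(bad)) break
      for (i in bad) {
        old <- model$groups$B[i]
        cur <- filled$groups$B[i]
        if (is.na(old) || cur >= old * 1.1 - 1e-12) next
        newB <- min(old * 1.1, cur * 1.01)
        filled$groups$B[i] <- newB
        adjustments <- c(adjustments, sprintf(
          "step %d: %s biomass %.6g -> %.6g (+%.1f%% of input)",
          step, filled$groups$name[i], cur, newB, 100 * (newB / old - 1)))
      }
      refit <- filled
      refit$groups$EE[is_living(refit) & is.na(model$groups$EE)] <- NA
      filled <- fill_parameters(refit)
    }
  }

  accounts <- compute_flows(filled)
  viol <- accounts$group[!is.na(accounts$EE) & accounts$EE > 1 + 1e-9]
  structure(list(model = filled, accounts = accounts,
                 balanced = length(viol) == 0,
                 ee_violations = viol, adjustments = adjustments),
            class = "balanced_web")
}

#' @export
print.balanced_web <- function(x, ...) {
  cat(sprintf("balanced_web: %d groups, %s\n", nrow(x$model$groups),
              if (x$balanced) "balanced (all EE <= 1)"
              else paste("NOT balanced; EE > 1 for:",
                         paste(x$ee_violations, collapse = ", "))))
  print(utils::head(x$accounts, 20))
  invisible(x)
}

# Fill the (at most one) missing parameter per living group.
fill_parameters <- function(model) {
  g <- model$groups
  n <- nrow(g)
  DC <- dc_matrix(model)           # DC[prey, predator]
  living <- is_living(model)
  cons <- is_consumer(model)

  # Demand on prey i from predators with known B and QB; unknown-B predators
  # enter the linear system below.
  known_BQ <- ifelse(cons & !is.na(g$B) & !is.na(g$QB), g$B * g$QB, 0)
  unknown_B <- which(living & is.na(g$B))

  if (length(unknown_B)) {
    for (i in unknown_B)
      if (is.na(g$PB[i]) || is.na(g$EE[i]) || (cons[i] && is.na(g$QB[i])))
        stop("structurally underdetermined: group '", g$name[i],
             "' has unknown B together with another unknown parameter")
    # Predators with unknown QB cannot prey on unknown-B groups.
    badQ <- which(cons & is.na(g$QB))
    for (j in badQ)
      if (any(DC[unknown_B, j] > 0))
        stop("structurally underdetermined: predator '", g$name[j],
             "' has unknown Q/B and preys on a group with unknown B")
    m <- length(unknown_B)
    A <- matrix(0, m, m)
    rhs <- numeric(m)
    for (k in seq_len(m)) {
      i <- unknown_B[k]
      A[k, k] <- g$PB[i] * g$EE[i]
      for (l in seq_len(m)) {
        j <- unknown_B[l]
        if (cons[j]) A[k, l] <- A[k, l] - g$QB[j] * DC[i, j]
      }
      rhs[k] <- g$Y[i] + g$BA[i] + g$E[i] + sum(known_BQ * DC[i, ])
    }
    sol <- tryCatch(solve(A, rhs), error = function(e)
      stop("structurally underdetermined: singular biomass system (",
           conditionMessage(e), ")"))
    if (any(!is.finite(sol) | sol < 0))
      stop("biomass solution infeasible (negative or non-finite B) for: ",
           paste(g$name[unknown_B[!is.finite(sol) | sol < 0]], collapse = ", "))
    g$B[unknown_B] <- sol
  }

  # Unknown Q/B first (it changes the predation term every other group sees).
  # QB enters the group's own equation only through cannibalism.
  demand_at <- function() {
    BQ <- ifelse(cons, g$B * ifelse(is.na(g$QB), 0, g$QB), 0)
    as.numeric(DC[, cons, drop = FALSE] %*% BQ[cons]) + g$Y + g$BA + g$E
  }
  for (i in which(cons & is.na(g$QB))) {
    if (DC[i, i] <= 0)
      stop("structurally underdetermined: unknown Q/B for '", g$name[i],
           "' without cannibalism")
    other <- demand_at()[i]  # excludes i's own (unknown) consumption
    qb <- (g$B[i] * g$PB[i] * g$EE[i] - other) / (g$B[i] * DC[i, i])
    if (!is.finite(qb) || qb < 0)
      stop("infeasible Q/B back-computed for '", g$name[i], "'")
    g$QB[i] <- qb
  }

  demand <- demand_at()
  for (i in which(living)) {
    if (is.na(g$EE[i])) {
      prod_i <- g$B[i] * g$PB[i]
      g$EE[i] <- if (prod_i > 0) demand[i] / prod_i else 0
    } else if (is.na(g$PB[i])) {
      if (g$EE[i] <= 0 || g$B[i] <= 0)
        stop("cannot back-compute P/B for '", g$name[i], "' (zero B or EE)")
      g$PB[i] <- demand[i] / (g$B[i] * g$EE[i])
    }
  }
  model$groups <- g
  model
}

#' Derive flow accounts from a fully parameterised model
#'
#' @param model A `food_web_model` with all living-group parameters known
#'   (e.g. the `model` element of [solve_balance()]).
#' @return A data frame of class `flow_accounts`, one row per group:
#'   \describe{
#'     \item{Q}{consumption `B*QB` (0 for producers/detritus).}
#'     \item{P}{production `B*PB` (NA for detritus).}
#'     \item{M2}{predation mortality flow on the group.}
#'     \item{R}{respiration `Q*(1-GS) - P` for consumers, 0 for producers.}
#'     \item{FD}{flow to detritus `Q*GS + P*(1-EE)`.}
#'     \item{EX}{export: `Y` plus positive net migration; for detritus rows,
#'       the pool surplus (inflow minus consumption).}
#'     \item{EE}{ecotrophic efficiency; for detritus rows the derived value
#'       consumption/inflow.}
#'   }
#'   Detritus inflow totals are attached as attribute `detritus_inflow`.
#' @export
compute_flows <- function(model) {
  stopifnot(inherits(model, "food_web_model"))
  g <- model$groups
  living <- is_living(model)
  cons <- is_consumer(model)
  if (any(living & (is.na(g$B) | is.na(g$PB) | is.na(g$EE))) ||
      any(cons & is.na(g$QB)))
    stop("compute_flows requires a fully parameterised model")

  DC <- dc_matrix(model)
  Q <- ifelse(cons, g$B * g$QB, 0)
  P <- ifelse(living, g$B * g$PB, NA_real_)
  M2 <- as.numeric(DC %*% Q)
  R <- ifelse(cons, Q * (1 - g$GS) - P, 0)
  R[!living] <- 0
  if (any(cons & R < -1e-9)) {
    i <- which(cons & R < -1e-9)[1]
    stop(sprintf(
      "negative respiration for '%s': P/Q = %.3f exceeds 1 - GS = %.3f",
      g$name[i], g$PB[i] / g$QB[i], 1 - g$GS[i]))
  }
  R <- pmax(R, 0)
  FD <- ifelse(living, Q * g$GS + P * (1 - pmin(g$EE, 1)), 0)
  EX <- ifelse(living, g$Y + pmax(g$E, 0), 0)
  EE <- g$EE

  det <- which(is_detritus(model))
  inflow <- setNames(numeric(length(det)), g$name[det])
  for (k in seq_along(det)) {
    d <- det[k]
    fate <- model$detritus_fate[, g$name[d]]
    inflow[k] <- sum(FD[living] * fate)
    EE[d] <- if (inflow[k] > 0) M2[d] / inflow[k] else 0
    EX[d] <- max(inflow[k] - M2[d], 0)   # surplus leaves/accumulates
  }

  out <- data.frame(group = g$name, role = g$role, Q = Q, P = P, M2 = M2,
                    R = R, FD = FD, EX = EX, Y = g$Y, BA = g$BA, E = g$E,
                    EE = EE, stringsAsFactors = FALSE)
  attr(out, "detritus_inflow") <- inflow
  class(out) <- c("flow_accounts", class(out))
  out
}

#' Impose a fishing mortality on one group
#'
#' Returns a copy of the model with the group's fishery yield set to
#' `Y = F * B` and its EE cleared for re-estimation; re-balancing the copy is
#' the sensitivity run.
#'
#' @param model A `food_web_model`; the group's biomass must be known.
#' @param group Group name.
#' @param F Instantaneous fishing mortality (year^-1), `>= 0`.
#' @return A modified `food_web_model`.
#' @seealso [fishing_sensitivity()] for the percentage-change wrapper.
#' @export
apply_fishing_mortality <- function(model, group, F) {
  stopifnot(inherits(model, "food_web_model"))
  i <- match(group, model$groups$name)
  if (is.na(i)) stop("unknown group: ", group)
  if (!is.finite(F) || F < 0) stop("F must be a non-negative mortality rate")
  if (is.na(model$groups$B[i]))
    stop("biomass of '", group, "' must be known to impose F")
  model$groups$Y[i] <- F * model$groups$B[i]
  if (F > 0) model$groups$EE[i] <- NA_real_
  model
}

#' Fishing-mortality sensitivity of network indicators
#'
#' Re-balances and re-analyses the model for each hypothetical fishing
#' mortality and reports the percentage change of every scalar network
#' indicator against the F = 0 baseline.
#'
#' @param model A `food_web_model` ready to balance.
#' @param group Group receiving the fishing mortality.
#' @param F Numeric vector of mortalities (year^-1).
#' @param max_level Passed to [analyze_network()].
#' @return A data frame: one row per indicator x F, with baseline value,
#'   perturbed value and percentage change.
#' @export
fishing_sensitivity <- function(model, group, F, max_level = 8) {
  base <- analyze_network(solve_balance(model), max_level = max_level)
  base_idx <- unlist(base$indices)
  out <- list()
  for (f in F) {
    pert <- apply_fishing_mortality(model, group, f)
    rep_f <- analyze_network(solve_balance(pert), max_level = max_level)
    idx <- unlist(rep_f$indices)
    pct <- ifelse(base_idx == 0, ifelse(idx == 0, 0, NA),
                  100 * (idx - base_idx) / abs(base_idx))
    out[[length(out) + 1]] <- data.frame(
      F = f, indicator = names(base_idx), baseline = base_idx,
      value = idx, pct_change = pct, row.names = NULL)
  }
  do.call(rbind, out)
}
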