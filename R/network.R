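# Ecological network analysis: trophic levels, system-level indices, Finn's
# cycling, the Lindeman spine and the mixed trophic impact matrix.

#' Fractional trophic levels
#'
#' Producers, detritus and imports sit at TL = 1; each consumer sits at 1 plus
#' the diet-weighted mean TL of its prey. The defining linear system
#' `TL = 1 + DC' TL` is solved exactly.
#'
#' @param model A `food_web_model` (consumer diet rows summing to 1).
#' @return Named numeric vector of trophic levels.
#' @examples
#' trophic_levels(toy_chain_model())   # producer 1, herbivore 2, detritus 1
#' @export
trophic_levels <- function(model) {
  stopifnot(inherits(model, "food_web_model"))
  g <- model$groups
  n <- nrow(g)
  cons <- is_consumer(model)
  TL <- setNames(rep(1, n), g$name)
  if (!any(cons)) return(TL)
  D <- model$diet[, seq_len(n), drop = FALSE]    # predator rows x prey cols
  Dcc <- D[cons, cons, drop = FALSE]
  # import fraction contributes at TL 1, like basal prey
  basal <- 1 + as.numeric(D[cons, !cons, drop = FALSE] %*% rep(1, sum(!cons))) +
    model$diet[cons, "import"]
  A <- diag(sum(cons)) - Dcc
  tl_c <- tryCatch(solve(A, basal), error = function(e)
    stop("singular trophic-level system (mutual-consumption loop with no ",
         "basal diet fraction): ", conditionMessage(e)))
  TL[cons] <- tl_c
  TL
}

# Flow matrix among compartments: flows[i, j] = flow from i to j
# (predation B_j QB_j DC_ij; flows to detritus via detritus_fate).
flow_matrix <- function(model, accounts) {
  g <- model$groups
  n <- nrow(g)
  cons <- is_consumer(model)
  DC <- dc_matrix(model)
  fl <- matrix(0, n, n, dimnames = list(g$name, g$name))
  fl[, cons] <- DC[, cons, drop = FALSE] %*% diag(accounts$Q[cons], sum(cons))
  det <- which(is_detritus(model))
  liv <- which(is_living(model))
  for (d in det)
    fl[liv, d] <- fl[liv, d] + accounts$FD[liv] * model$detritus_fate[, g$name[d]]
  fl
}

# Per-compartment throughput: consumption for consumers, production for
# producers, total inflow for detritus. Balanced compartments have equal
# in- and outflow, so summing these equals total system throughput.
compartment_throughput <- function(model, accounts) {
  t_j <- ifelse(is_consumer(model), accounts$Q,
                ifelse(is_producer(model), accounts$P, 0))
  det <- is_detritus(model)
  t_j[det] <- attr(accounts, "detritus_inflow")[model$groups$name[det]]
  setNames(t_j, model$groups$name)
}

#' System-level network indices
#'
#' @param accounts Flow accounts from [compute_flows()].
#' @param model The matching `food_web_model`.
#' @param link_threshold Diet fractions above this count as links for the
#'   connectance index.
#' @return Named list: `TST` (total system throughput, the sum of all
#'   consumption, exports, respiration and flows to detritus), `TPP` (total
#'   primary production), `TR` (total respiration), `TPP_over_TR`, `CI`
#'   (connectance: realised living-to-living diet links over S_living^2),
#'   `SOI` (system omnivory: consumption-log-weighted mean of per-consumer
#'   omnivory, the diet-weighted variance of prey TL), and `FML` (Finn's mean
#'   path length `TST / (exports + respiration)`).
#' @export
system_indices <- function(accounts, model, link_threshold = 1e-6) {
  g <- model$groups
  cons <- is_consumer(model)
  liv <- is_living(model)
  TST <- sum(accounts$Q) + sum(accounts$EX) + sum(accounts$R) +
    sum(accounts$FD[liv])
  TPP <- sum(accounts$P[is_producer(model)])
  TR <- sum(accounts$R)
  n <- nrow(g)
  DC <- dc_matrix(model)
  links <- sum(DC[liv, cons & liv, drop = FALSE] > link_threshold)
  CI <- links / sum(liv)^2

  TL <- trophic_levels(model)
  OI <- vapply(which(cons), function(j) {
    w <- DC[, j]
    sum(w * (TL - (TL[j] - 1))^2)
  }, numeric(1))
  wts <- pmax(log(accounts$Q[cons]), 0)
  SOI <- if (!length(OI)) 0
         else if (sum(wts) > 0) sum(OI * wts) / sum(wts) else mean(OI)

  diss <- sum(accounts$EX) + TR
  if (diss <= 0) stop("FML undefined: system has no exports or respiration")
  list(TST = TST, TPP = TPP, TR = TR, TPP_over_TR = TPP / TR,
       CI = CI, SOI = SOI, FML = TST / diss)
}

#' Finn's cycling index
#'
#' Builds the dimensionless input-structure matrix `G` (`G[i,j]` = fraction of
#' compartment j's inflow arriving from i), inverts `I - G`, and measures the
#' recycled share of throughput from the diagonal of the inverse:
#' `FCI = 100 * sum_j T_j (n_jj - 1) / n_jj / TST`.
#' Imports are excluded from cycling; cannibalism counts as a cycle.
#'
#' @inheritParams system_indices
#' @return List with `FCI` (percent) and `cycled` (recycled throughput,
#'   t km^-2 year^-1).
#' @export
finn_cycling <- function(accounts, model) {
  fl <- flow_matrix(model, accounts)
  t_j <- compartment_throughput(model, accounts)
  n <- length(t_j)
  G <- matrix(0, n, n, dimnames = dimnames(fl))
  pos <- t_j > 0
  G[, pos] <- sweep(fl[, pos, drop = FALSE], 2, t_j[pos], "/")
  N <- tryCatch(solve(diag(n) - G), error = function(e)
    stop("cycle mass not dissipated: I - G is singular (",
         conditionMessage(e), ")"))
  njj <- diag(N)
  cycled <- sum(t_j[pos] * (njj[pos] - 1) / njj[pos])
  liv <- is_living(model)
  TST <- sum(accounts$Q) + sum(accounts$EX) + sum(accounts$R) +
    sum(accounts$FD[liv])
  list(FCI = 100 * cycled / TST, cycled = cycled)
}

# Fraction of each group's throughput originating from detritus (vs primary
# producers), solved exactly from the diet structure.
detritus_origin <- function(model) {
  g <- model$groups
  n <- nrow(g)
  cons <- is_consumer(model)
  O <- setNames(as.numeric(is_detritus(model)), g$name)
  if (!any(cons)) return(O)
  D <- model$diet[, seq_len(n), drop = FALSE]
  Dcc <- D[cons, cons, drop = FALSE]
  b <- as.numeric(D[cons, !cons, drop = FALSE] %*% O[!cons])
  O[cons] <- solve(diag(sum(cons)) - Dcc, b)
  O
}

#' Lindeman spine: flows and transfer efficiencies by discrete trophic level
#'
#' Apportions each group's throughput onto integer trophic levels by the
#' fractional composition of its diet paths (flow entering a consumer at level
#' k came from prey acting at level k - 1), separately for producer-origin and
#' detritus-origin chains. Per level k >= 2 the transfer efficiency is the
#' flow predated up to level k + 1 plus exports and catches at k, over the
#' throughput at k.
#'
#' @inheritParams system_indices
#' @param max_level Highest discrete level retained (longer paths are
#'   truncated and the level composition renormalised).
#' @return List with
#'   \describe{
#'     \item{spine}{data frame per level: throughput, flow passed up,
#'       export+catch, and percentage TE for producer-origin, detritus-origin and
#'       combined flows.}
#'     \item{level_fractions}{group x level apportionment matrix.}
#'     \item{detritus_origin_fraction}{detritus share of consumer throughput.}
#'     \item{te_producer, te_detritus, te_total}{geometric-mean transfer
#'       efficiency (percent) over levels II-IV for each flow origin.}
#'     \item{te_total_weighted}{variant: geometric mean over levels II-IV
#'       weighted by the flow transferred at each level.}
#'   }
#' @export
lindeman_spine <- function(accounts, model, max_level = 8) {
  g <- model$groups
  n <- nrow(g)
  cons <- is_consumer(model)
  basal <- !cons
  DC <- dc_matrix(model)
  t_j <- compartment_throughput(model, accounts)

  seed <- function(which_basal) {
    A <- matrix(0, n, max_level, dimnames = list(g$name, NULL))
    A[which_basal, 1] <- 1
    for (k in 2:max_level)
      A[cons, k] <- as.numeric(t(DC[, cons, drop = FALSE]) %*% A[, k - 1])
    A
  }
  Ap <- seed(is_producer(model))
  Ad <- seed(is_detritus(model))
  # renormalise jointly: truncation beyond max_level drops the same share of
  # both origins proportionally
  tot <- rowSums(Ap + Ad)
  tot[tot == 0] <- 1
  Ap <- Ap / tot
  Ad <- Ad / tot

  per_level <- function(A) {
    thr <- as.numeric(t(A) %*% t_j)
    up <- as.numeric(t(A) %*% accounts$M2)
    ex <- as.numeric(t(A) %*% accounts$EX)
    te <- ifelse(thr > 0, 100 * (up + ex) / thr, NA_real_)
    list(thr = thr, up = up, ex = ex, te = te)
  }
  p <- per_level(Ap); d <- per_level(Ad); a <- per_level(Ap + Ad)

  spine <- data.frame(
    level = seq_len(max_level),
    throughput = a$thr, passed_up = a$up, export_catch = a$ex,
    throughput_producer = p$thr, throughput_detritus = d$thr,
    TE_producer = p$te, TE_detritus = d$te, TE_all = a$te)

  geo <- function(te, w = NULL) {
    k <- 2:min(4, max_level)
    v <- te[k]
    if (is.null(w)) w <- rep(1, length(k)) else w <- w[k]
    ok <- is.finite(v) & v > 0 & w > 0
    if (!any(ok)) return(NA_real_)
    exp(sum(w[ok] * log(v[ok])) / sum(w[ok]))
  }
  O <- detritus_origin(model)
  qcons <- accounts$Q[cons]
  det_frac <- if (sum(qcons) > 0) sum(qcons * O[cons]) / sum(qcons) else 0

  list(spine = spine,
       level_fractions = Ap + Ad,
       detritus_origin_fraction = det_frac,
       te_producer = geo(p$te), te_detritus = geo(d$te),
       te_total = geo(a$te),
       te_total_weighted = geo(a$te, w = a$up + a$ex))
}

#' Mixed trophic impact matrix
#'
#' Direct impacts `d[i, j]` of group i on group j combine the positive
#' prey-to-predator term (i's share of j's diet) and the negative
#' predator-to-prey term (j's share of total use of i, predation plus catch).
#' Total (direct + indirect) impacts are `M = (I - d)^-1 - I`.
#'
#' @inheritParams system_indices
#' @return List with `direct` and `total` (the MTI matrix), rows = impacting
#'   group, columns = impacted group.
#' @export
mixed_trophic_impact <- function(accounts, model) {
  g <- model$groups
  n <- nrow(g)
  cons <- is_consumer(model)
  DC <- dc_matrix(model)
  # prey share of predator's diet: DC[i, j]
  pos <- DC
  pos[, !cons] <- 0
  # predator share of total use of its prey (predation + catch)
  use <- accounts$M2 + accounts$Y
  host <- matrix(0, n, n, dimnames = list(g$name, g$name))
  for (i in seq_len(n)) if (use[i] > 0)
    host[i, ] <- accounts$Q * DC[i, ] / use[i]
  d <- pos - t(host)
  M <- tryCatch(solve(diag(n) - d) - diag(n), error = function(e)
    stop("I - d is singular; mixed trophic impacts undefined (",
         conditionMessage(e), ")"))
  dimnames(M) <- dimnames(d)
  list(direct = d, total = M)
}

#' Full network analysis of a balanced model
#'
#' Convenience wrapper producing the complete report: trophic levels, scalar
#' indices, cycling, the Lindeman spine and the MTI matrix.
#'
#' @param balanced A `balanced_web` from [solve_balance()] (or a fully
#'   parameterised `food_web_model`).
#' @param max_level Highest discrete trophic level for the spine.
#' @return An object of class `network_report`: list with `TL`, `indices`
#'   (TST, TPP, TR, TPP_over_TR, CI, SOI, FCI, FML, te_total, te_producer,
#'   te_detritus, detritus_origin_fraction), `spine`, `MTI`, `accounts`.
#' @export
analyze_network <- function(balanced, max_level = 8) {
  if (inherits(balanced, "balanced_web")) {
    model <- balanced$model
    accounts <- balanced$accounts
  } else if (inherits(balanced, "food_web_model")) {
    model <- balanced
    accounts <- compute_flows(model)
  } else stop("expected a balanced_web or food_web_model")

  TL <- trophic_levels(model)
  idx <- system_indices(accounts, model)
  fc <- finn_cycling(accounts, model)
  sp <- lindeman_spine(accounts, model, max_level = max_level)
  mti <- mixed_trophic_impact(accounts, model)
  indices <- c(idx, list(FCI = fc$FCI, cycled_throughput = fc$cycled,
                         te_total = sp$te_total,
                         te_total_weighted = sp$te_total_weighted,
                         te_producer = sp$te_producer,
                         te_detritus = sp$te_detritus,
                         detritus_origin_fraction = sp$detritus_origin_fraction))
  structure(list(TL = TL, indices = indices, spine = sp$spine,
                 level_fractions = sp$level_fractions,
                 MTI = mti$total, MTI_direct = mti$direct,
                 accounts = accounts),
            class = "network_report")
}

#' @export
print.network_report <- function(x, ...) {
  cat("network_report\n")
  cat(sprintf("  TL range: %.2f - %.2f\n", min(x$TL), max(x$TL)))
  idx <- x$indices
  cat(sprintf("  TST = %.2f, TPP = %.2f, TPP/TR = %.3f\n",
              idx$TST, idx$TPP, idx$TPP_over_TR))
  cat(sprintf("  CI = %.3f, SOI = %.3f, FCI = %.2f%%, FML = %.2f\n",
              idx$CI, idx$SOI, idx$FCI, idx$FML))
  cat(sprintf("  mean TE (II-IV): %.2f%% (producer %.2f%%, detritus %.2f%%)\n",
              idx$te_total, idx$te_producer, idx$te_detritus))
  invisible(x)
}
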