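#' Construct a mass-balance food-web model
#'
#' Bundles the per-group parameter table, the diet-composition matrix and the
#' detritus-fate matrix into a validated `food_web_model` object, the input of
#' [solve_balance()].
#'
#' @param groups A data frame with one row per functional group, in model
#'   order, and columns:
#'   \describe{
#'     \item{name}{unique group label.}
#'     \item{role}{one of `"producer"`, `"consumer"`, `"detritus"`.}
#'     \item{B}{biomass (t km^-2), or `NA` if to be estimated.}
#'     \item{PB}{production/biomass ratio (year^-1); `NA` allowed for living
#'       groups, absent for detritus.}
#'     \item{QB}{consumption/biomass ratio (year^-1); consumers only.}
#'     \item{EE}{ecotrophic efficiency in (0, 1], or `NA` if to be estimated.
#'       For detritus EE is always an output and any input is ignored.}
#'     \item{Y}{fishery yield (t km^-2 year^-1), default 0.}
#'     \item{BA}{biomass accumulation (t km^-2 year^-1), default 0.}
#'     \item{E}{net migration (t km^-2 year^-1, positive = emigration loss),
#'       default 0.}
#'     \item{GS}{unassimilated fraction of consumption, default 0.2 for
#'       consumers, 0 otherwise.}
#'   }
#'   Missing optional columns are filled with their defaults.
#' @param diet Numeric matrix, predator rows by prey columns, in group order;
#'   an optional extra last column named `"import"` holds the diet fraction
#'   taken from outside the system. Consumer rows must sum to 1 within `1e-6`
#'   (they are renormalised to machine precision); producer and detritus rows
#'   must be all zero.
#' @param detritus_fate Numeric matrix (living groups x detritus groups) giving
#'   the fraction of each living group's non-predation losses routed to each
#'   detritus pool; rows must sum to 1. Default: everything to the single
#'   detritus group.
#'
#' @return An object of class `food_web_model`.
#' @seealso [validate_model()], [solve_balance()], [read_model()]
#' @examples
#' m <- toy_chain_model()
#' m
#' @export
food_web_model <- function(groups, diet, detritus_fate = NULL) {
  stopifnot(is.data.frame(groups))
  required <- c("name", "role")
  if (!all(required %in% names(groups)))
    stop("groups table must have 'name' and 'role' columns")
  groups$name <- as.character(groups$name)
  groups$role <- as.character(groups$role)

  bad_role <- setdiff(unique(groups$role), c("producer", "consumer", "detritus"))
  if (length(bad_role))
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  if (anyDuplicated(groups$name))
    stop("duplicate group names: ",
         paste(unique(groups$name[duplicated(groups$name)]), collapse = ", "))
  if (!any(groups$role == "producer")) stop("model needs at least one producer")
  if (!any(groups$role == "detritus")) stop("model needs at least one detritus group")

  n <- nrow(groups)
  num_cols <- c("B", "PB", "QB", "EE", "Y", "BA", "E", "GS")
  for (cl in num_cols) {
    if (!cl %in% names(groups)) groups[[cl]] <- NA_real_
    groups[[cl]] <- as.numeric(groups[[cl]])
  }
  groups$Y[is.na(groups$Y)] <- 0
  groups$BA[is.na(groups$BA)] <- 0
  groups$E[is.na(groups$E)] <- 0
  groups$GS[is.na(groups$GS)] <- ifelse(groups$role[is.na(groups$GS)] == "consumer", 0.2, 0)
  groups$GS[groups$role != "consumer"] <- 0
  # detritus has no PB/QB/EE inputs; producers have no QB
  groups$QB[groups$role != "consumer"] <- NA_real_
  groups$PB[groups$role == "detritus"] <- NA_real_
  groups$EE[groups$role == "detritus"] <- NA_real_

  diet <- as.matrix(diet)
  has_import <- ncol(diet) == n + 1
  if (!has_import && ncol(diet) != n)
    stop("diet matrix must have one column per prey group (plus optional import column)")
  if (nrow(diet) != n)
    stop("diet matrix must have one row per predator group")
  if (!has_import) diet <- cbind(diet, import = 0)
  storage.mode(diet) <- "double"
  dimnames(diet) <- list(groups$name, c(groups$name, "import"))
  if (any(!is.finite(diet)) || any(diet < 0) || any(diet > 1 + 1e-6))
    stop("diet entries must be finite fractions in [0, 1]")

  cons <- groups$role == "consumer"
  rs <- rowSums(diet)
  if (any(cons & rs == 0))
    stop("consumer with no diet: ",
         paste(groups$name[cons & rs == 0], collapse = ", "))
  bad <- cons & abs(rs - 1) > 1e-6
  if (any(bad))
    stop("consumer diet row sum outside [1-1e-6, 1+1e-6]: ",
         paste(groups$name[bad], collapse = ", "))
  diet[cons, ] <- diet[cons, , drop = FALSE] / rs[cons]
  diet <- pmin(pmax(diet, 0), 1)
  dim(diet) <- c(n, n + 1)
  dimnames(diet) <- list(groups$name, c(groups$name, "import"))
  if (any(!cons & rs > 0))
    stop("producer/detritus groups must have all-zero diet rows: ",
         paste(groups$name[!cons & rs > 0], collapse = ", "))

  det <- groups$role == "detritus"
  n_liv <- sum(!det)
  if (is.null(detritus_fate)) {
    detritus_fate <- matrix(1 / sum(det), n_liv, sum(det))
  }
  detritus_fate <- as.matrix(detritus_fate)
  storage.mode(detritus_fate) <- "double"
  if (nrow(detritus_fate) != n_liv || ncol(detritus_fate) != sum(det))
    stop("detritus_fate must be (living groups) x (detritus groups)")
  if (any(abs(rowSums(detritus_fate) - 1) > 1e-9))
    stop("detritus_fate rows must sum to 1")
  dimnames(detritus_fate) <- list(groups$name[!det], groups$name[det])

  structure(list(groups = groups, diet = diet, detritus_fate = detritus_fate),
            class = "food_web_model")
}

#' @export
print.food_web_model <- function(x, ...) {
  g <- x$groups
  cat(sprintf("food_web_model: %d groups (%d producers, %d consumers, %d detritus)\n",
              nrow(g), sum(g$role == "producer"), sum(g$role == "consumer"),
              sum(g$role == "detritus")))
  miss <- vapply(seq_len(nrow(g)), function(i) {
    sum(is.na(unlist(g[i, c("B", "PB", "QB", "EE")]))) -
      (g$role[i] != "consumer") - 2 * (g$role[i] == "detritus")
  }, numeric(1))
  cat(sprintf("parameters to estimate: %d\n", sum(pmax(miss, 0))))
  print(utils::head(g[, c("name", "role", "B", "PB", "QB", "EE", "Y")], 20))
  invisible(x)
}

# role helpers ----------------------------------------------------------

is_producer <- function(model) model$groups$role == "producer"
is_consumer <- function(model) model$groups$role == "consumer"
is_detritus <- function(model) model$groups$role == "detritus"
is_living   <- function(model) model$groups$role != "detritus"

#' Diet composition as a prey-by-predator matrix
#'
#' Returns `DC` with `DC[i, j]` the fraction of prey `i` in the diet of
#' predator `j` (the orientation used in the master equation), excluding the
#' import column.
#'
#' @param model A `food_web_model`.
#' @return An n x n numeric matrix.
#' @keywords internal
dc_matrix <- function(model) {
  n <- nrow(model$groups)
  t(model$diet[, seq_len(n), drop = FALSE])
}

#' Validate a food-web model against the mass-balance input rules
#'
#' Checks that every living group carries enough parameters for the balance
#' solver (at least three of B, P/B, Q/B, EE, with Q/B counted as given for
#' producers) and that all inputs lie in their admissible ranges. Structural
#' problems (dimensions, roles, diet row sums) are caught earlier, at
#' construction.
#'
#' @param model A `food_web_model`.
#' @return A character vector of diagnostics; empty when the model is ready to
#'   balance.
#' @examples
#' validate_model(toy_chain_model())   # character(0)
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "food_web_model"))
  g <- model$groups
  out <- character(0)
  note <- function(grp, rule) sprintf("%s: %s", grp, rule)

  for (i in seq_len(nrow(g))) {
    if (g$role[i] == "detritus") {
      if (is.na(g$B[i]) || g$B[i] < 0)
        out <- c(out, note(g$name[i], "detritus biomass must be given and >= 0"))
      next
    }
    known <- c(B = !is.na(g$B[i]), PB = !is.na(g$PB[i]),
               QB = !is.na(g$QB[i]) || g$role[i] == "producer",
               EE = !is.na(g$EE[i]))
    if (sum(known) < 3)
      out <- c(out, note(g$name[i],
        sprintf("underdetermined: only %d of B, P/B, Q/B, EE specified", sum(known))))
    if (!is.na(g$EE[i]) && (g$EE[i] <= 0 || g$EE[i] > 1))
      out <- c(out, note(g$name[i], sprintf("EE outside (0,1]: %g", g$EE[i])))
    for (cl in c("B", "PB", "QB", "Y")) {
      v <- g[[cl]][i]
      if (!is.na(v) && v < 0)
        out <- c(out, note(g$name[i], sprintf("%s must be >= 0, got %g", cl, v)))
    }
    if (g$GS[i] < 0 || g$GS[i] >= 1)
      out <- c(out, note(g$name[i], sprintf("GS outside [0,1): %g", g$GS[i])))
    if (!is.na(g$PB[i]) && !is.na(g$QB[i]) && g$role[i] == "consumer" &&
        g$QB[i] > 0 && g$PB[i] / g$QB[i] > 1 - g$GS[i])
      out <- c(out, note(g$name[i],
        sprintf("P/Q = %.3f exceeds 1 - GS = %.3f (implies negative respiration)",
                g$PB[i] / g$QB[i], 1 - g$GS[i])))
  }
  out
}

#' Minimal three-group model (producer, herbivore, detritus)
#'
#' A convenience toy used in examples and tests: one producer grazed by one
#' herbivore, one detritus pool; herbivore EE left for the solver.
#'
#' @param producer_ee If non-`NULL`, fixes the producer EE and leaves its
#'   biomass to be estimated instead.
#' @return A `food_web_model` with 3 groups.
#' @export
toy_chain_model <- function(producer_ee = NULL) {
  g <- data.frame(
    name = c("producer", "herbivore", "detritus"),
    role = c("producer", "consumer", "detritus"),
    B  = c(10, 1, 5),
    PB = c(10, 2, NA),
    QB = c(NA, 10, NA),
    EE = NA_real_
  )
  if (!is.null(producer_ee)) {
    g$EE[1] <- producer_ee
    g$B[1] <- NA
  }
  diet <- matrix(0, 3, 3)
  diet[2, 1] <- 1
  food_web_model(g, diet)
}
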