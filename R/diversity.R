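# Community diversity and dominance statistics for species x station counts.
# All indices use natural logarithms.

#' Species-by-station abundance table
#'
#' @param counts Numeric matrix or data frame of non-negative counts, rows =
#'   species (rownames required), columns = stations.
#' @param strata Optional character vector mapping each station to a stratum
#'   (transect, tidal zone, ...); names or order must match the columns.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(counts, strata = NULL) {
  m <- as.matrix(counts)
  if (is.null(rownames(m))) stop("species rownames are required")
  if (anyDuplicated(rownames(m))) stop("species names must be unique")
  if (any(!is.finite(m)) || any(m < 0)) stop("counts must be non-negative")
  if (sum(m) <= 0) stop("table must contain at least one positive count")
  if (!is.null(strata)) {
    if (length(strata) != ncol(m))
      stop("strata must map every station")
    strata <- setNames(as.character(strata), colnames(m))
  }
  structure(list(counts = m, strata = strata), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d species x %d stations, N = %d\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

as_counts <- function(x) {
  if (inherits(x, "abundance_table")) rowSums(x$counts) else as.numeric(x)
}

#' Shannon-Wiener diversity index
#'
#' `H' = -sum p_i ln p_i` over species with positive counts.
#'
#' @param counts Per-species totals (numeric vector or `abundance_table`).
#' @return H' (nats).
#' @export
shannon <- function(counts) {
  n <- as_counts(counts)
  if (any(n < 0)) stop("counts must be non-negative")
  n <- n[n > 0]
  if (!length(n)) stop("all counts are zero")
  p <- n / sum(n)
  -sum(p * log(p))
}

#' Margalef species richness index
#'
#' `d = (S - 1) / ln N`.
#'
#' @inheritParams shannon
#' @return d. With a single species, 0 by convention; errors when N < 2.
#' @export
margalef <- function(counts) {
  n <- as_counts(counts)
  S <- sum(n > 0)
  N <- sum(n)
  if (N < 2) stop("Margalef index needs N >= 2")
  (S - 1) / log(N)
}

#' Pielou species evenness index
#'
#' `J' = H' / ln S`, in (0, 1].
#'
#' @inheritParams shannon
#' @return J'. Errors when fewer than 2 species are present.
#' @export
pielou <- function(counts) {
  n <- as_counts(counts)
  S <- sum(n > 0)
  if (S < 2) stop("Pielou evenness needs S >= 2")
  shannon(n) / log(S)
}

#' McNaughton dominance index and dominant-species set
#'
#' `Y_i = (n_i / N) * f_i`, with `n_i` the species total over all stations,
#' `N` the grand total and `f_i` the fraction of stations occupied. Species
#' with `Y` strictly above the threshold are flagged dominant.
#'
#' @param table An [abundance_table()].
#' @param threshold Dominance cut-off (default 0.02); ties are non-dominant.
#' @return Data frame per species: `n`, `f`, `Y`, `dominant`, sorted by
#'   decreasing `Y`.
#' @export
mcnaughton_dominance <- function(table, threshold = 0.02) {
  stopifnot(inherits(table, "abundance_table"))
  m <- table$counts
  N <- sum(m)
  n_i <- rowSums(m)
  f_i <- rowSums(m > 0) / ncol(m)
  Y <- (n_i / N) * f_i
  out <- data.frame(species = rownames(m), n = n_i, f = f_i, Y = Y,
                    dominant = Y > threshold, row.names = NULL)
  out[order(-out$Y), ]
}

#' Per-stratum diversity summary
#'
#' Pools stations by stratum and computes S, N, H', d, J' and the dominant
#' species count for each. Strata whose pooled total is zero are flagged and
#' their indices left `NA`.
#'
#' @param table An [abundance_table()] (with `strata`, unless given here).
#' @param strata Optional stratum vector overriding the one in `table`.
#' @param threshold Dominance threshold within each stratum.
#' @return Data frame, one row per stratum.
#' @export
stratified_summary <- function(table, strata = NULL, threshold = 0.02) {
  stopifnot(inherits(table, "abundance_table"))
  strata <- strata %||% table$strata
  if (is.null(strata)) strata <- colnames(table$counts)
  if (length(strata) != ncol(table$counts))
    stop("strata must map every station")
  out <- lapply(unique(strata), function(s) {
    sub <- table$counts[, strata == s, drop = FALSE]
    n <- rowSums(sub)
    N <- sum(n); S <- sum(n > 0)
    if (N == 0)
      return(data.frame(stratum = s, S = 0L, N = 0L, H = NA_real_,
                        d = NA_real_, J = NA_real_, n_dominant = NA_integer_,
                        empty = TRUE))
    dom <- mcnaughton_dominance(
      abundance_table(sub[n > 0, , drop = FALSE]), threshold)
    data.frame(
      stratum = s, S = S, N = N,
      H = shannon(n),
      d = if (N >= 2) margalef(n) else NA_real_,
      J = if (S >= 2) pielou(n) else NA_real_,
      n_dominant = sum(dom$dominant), empty = FALSE)
  })
  do.call(rbind, out)
}
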