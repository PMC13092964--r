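# Readers/writers for model definitions and result tables.
# Delimited layout: a model directory holds groups.csv (one row per group),
# diet.csv (predator rows x prey columns, optional import column) and an
# optional detritus_fate.csv. The structured-config alternative is a single
# YAML file with the same content.

#' Read a food-web model definition
#'
#' @param path For `format = "tables"` a directory containing `groups.csv` and
#'   `diet.csv` (and optionally `detritus_fate.csv`); for `format = "config"` a
#'   single YAML file with `groups`, `diet` and optional `detritus_fate`
#'   entries.
#' @param format Input layout, `"tables"` (default) or `"config"`.
#' @return A validated [food_web_model()].
#' @details Empty cells in `groups.csv` encode "parameter to be estimated".
#'   Consumer diet rows are renormalised only when they deviate from 1 by at
#'   most `1e-6`; larger deviations are an error.
#' @seealso [write_model()]
#' @export
read_model <- function(path, format = c("tables", "config")) {
  format <- match.arg(format)
  if (format == "tables") {
    gf <- file.path(path, "groups.csv")
    df <- file.path(path, "diet.csv")
    if (!file.exists(gf) || !file.exists(df))
      stop("model directory must contain groups.csv and diet.csv: ", path)
    groups <- utils::read.csv(gf, stringsAsFactors = FALSE)
    dd <- utils::read.csv(df, stringsAsFactors = FALSE, check.names = FALSE)
    diet <- as.matrix(dd[, -1, drop = FALSE])
    rownames(diet) <- dd[[1]]
    prey_names <- colnames(diet)
    want <- groups$name
    if (!identical(rownames(diet), want) ||
        !identical(prey_names[seq_along(want)], want))
      stop("diet.csv rows/columns must match groups.csv names and order")
    fate <- NULL
    ff <- file.path(path, "detritus_fate.csv")
    if (file.exists(ff)) {
      fd <- utils::read.csv(ff, stringsAsFactors = FALSE, check.names = FALSE)
      fate <- as.matrix(fd[, -1, drop = FALSE])
      rownames(fate) <- fd[[1]]
    }
    food_web_model(groups, diet, fate)
  } else {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$groups) || is.null(cfg$diet))
      stop("config must contain 'groups' and 'diet'")
    groups <- do.call(rbind, lapply(cfg$groups, function(g)
      data.frame(name = g$name, role = g$role,
                 B = g$B %||% NA, PB = g$PB %||% NA, QB = g$QB %||% NA,
                 EE = g$EE %||% NA, Y = g$Y %||% 0, BA = g$BA %||% 0,
                 E = g$E %||% 0, GS = g$GS %||% NA)))
    diet <- do.call(rbind, cfg$diet)
    fate <- if (!is.null(cfg$detritus_fate)) do.call(rbind, cfg$detritus_fate)
    food_web_model(groups, diet, fate)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x, digits = NA) {
  out <- if (is.na(digits)) sprintf("%.17g", x) else sprintf("%.*g", digits, x)
  out[is.na(x)] <- ""
  out
}

write_num_csv <- function(df, file, digits = NA) {
  for (cl in names(df))
    if (is.numeric(df[[cl]])) df[[cl]] <- fmt_num(df[[cl]], digits)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
}

#' Write a food-web model definition to a directory
#'
#' Emits `groups.csv`, `diet.csv` and `detritus_fate.csv` with full `%.17g`
#' precision so that [read_model()] reproduces the model bit-identically.
#'
#' @param model A `food_web_model`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "food_web_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_num_csv(model$groups, file.path(path, "groups.csv"))
  dd <- data.frame(predator = rownames(model$diet), check.names = FALSE)
  dd <- cbind(dd, as.data.frame(model$diet, check.names = FALSE))
  write_num_csv(dd, file.path(path, "diet.csv"))
  fd <- data.frame(group = rownames(model$detritus_fate), check.names = FALSE)
  fd <- cbind(fd, as.data.frame(model$detritus_fate, check.names = FALSE))
  write_num_csv(fd, file.path(path, "detritus_fate.csv"))
  invisible(path)
}

#' Write analysis report tables
#'
#' Emits delimited tables mirroring the standard mass-balance output layout:
#' `basic_estimates.csv` (per-group TL, B, P/B, Q/B, EE, P/Q),
#' `flows.csv` (per-group flow accounts), `transfer_efficiency.csv`
#' (Lindeman spine by discrete trophic level), `summary_statistics.csv`
#' (system-level indices) and `mti.csv` (mixed trophic impact matrix).
#'
#' @param model A balanced `food_web_model` (all parameters filled).
#' @param accounts The [compute_flows()] table for `model`.
#' @param report A [network_report] from [analyze_network()].
#' @param path Output directory (created if absent).
#' @param digits Significant digits for printing; `NA` (default) writes full
#'   `%.17g` precision so re-reading reproduces every value bit-identically.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(model, accounts, report, path, digits = NA) {
  stopifnot(inherits(model, "food_web_model"))
  if (is.null(report) || !inherits(report, "network_report"))
    stop("'report' must be a network_report (run analyze_network first)")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- model$groups
  basic <- data.frame(
    group = g$name, role = g$role, TL = report$TL,
    B = g$B, PB = g$PB, QB = g$QB,
    EE = accounts$EE[match(g$name, accounts$group)],
    PQ = ifelse(is_consumer(model), g$PB / g$QB, NA_real_))
  files <- file.path(path, c("basic_estimates.csv", "flows.csv",
                             "transfer_efficiency.csv",
                             "summary_statistics.csv", "mti.csv"))
  write_num_csv(basic, files[1], digits)
  write_num_csv(accounts[, setdiff(names(accounts), "EE_detritus")], files[2], digits)
  write_num_csv(report$spine, files[3], digits)
  idx <- report$indices
  write_num_csv(data.frame(statistic = names(idx), value = unlist(idx)),
                files[4], digits)
  mti <- data.frame(group = rownames(report$MTI), check.names = FALSE)
  mti <- cbind(mti, as.data.frame(report$MTI, check.names = FALSE))
  write_num_csv(mti, files[5], digits)
  invisible(files)
}
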