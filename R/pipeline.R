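# Pipeline driver: validate -> balance -> flows -> network analysis
# (-> sensitivity), with stage-tagged errors and a parameter log on stderr.
# Table outputs go to files only, keeping stdout machine-parsable.

#' Run the full analysis pipeline from a configuration
#'
#' @param config A list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{model}{one of `list(source = "fixture")`,
#'       `list(source = "dir", path = ...)` (read with [read_model()]) or
#'       `list(source = "synthetic", spec = list(...))` (passed to
#'       [synthetic_web_spec()]).}
#'     \item{analyses}{character subset of
#'       `c("validate", "balance", "network", "sensitivity")`; default all
#'       but sensitivity. `"validate"` alone gives a validation-only run.}
#'     \item{sensitivity}{`list(group = ..., F = c(...))`, required when the
#'       sensitivity analysis is requested.}
#'     \item{out}{output directory for report tables (optional).}
#'     \item{seed}{seed forwarded to the synthetic generator / diet
#'       reconstruction (default 1).}
#'     \item{max_level, gs_default, rebalance}{optional engine settings.}
#'   }
#' @param verbose Log defaulted parameters and stage progress to stderr.
#' @return A list with the outputs of each executed stage: `diagnostics`,
#'   `balanced`, `report`, `sensitivity`, and `files` when `out` was given.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  analyses <- config$analyses %||% c("validate", "balance", "network")
  log <- function(...) if (verbose) message("[reefweb] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  mc <- config$model %||% list(source = "fixture")
  model <- stage("read_model", {
    src <- mc$source %||% "fixture"
    switch(src,
      fixture = {
        log("model: built-in Chudao fixture (reconstructed diet, seed %d)", seed)
        core_fixture(seed = seed)$model
      },
      dir = read_model(mc$path, format = mc$format %||% "tables"),
      synthetic = {
        sp <- do.call(synthetic_web_spec,
                      c(mc$spec %||% list(), list(seed = seed)))
        log("model: synthetic web (%d groups, seed %d)",
            sp$n_producers + sp$n_consumers + sp$n_detritus, seed)
        generate_web(sp)
      },
      stop("unknown model source: ", src))
  })
  if (!is.null(config$gs_default)) {
    cons <- is_consumer(model)
    model$groups$GS[cons] <- config$gs_default
    log("GS default overridden to %g for all consumers", config$gs_default)
  } else {
    log("GS defaults: %s", paste(unique(model$groups$GS[is_consumer(model)]),
                                 collapse = ", "))
  }

  out <- list(model = model)
  if ("validate" %in% analyses) {
    out$diagnostics <- stage("validate_model", validate_model(model))
    log("validation: %d diagnostic(s)", length(out$diagnostics))
    if (length(out$diagnostics))
      stage("validate_model",
            stop(paste(out$diagnostics, collapse = "; ")))
  }
  if (any(c("balance", "network", "sensitivity") %in% analyses)) {
    out$balanced <- stage("solve_balance",
                          solve_balance(model,
                                        rebalance = isTRUE(config$rebalance)))
    log("balance: %s", if (out$balanced$balanced) "all EE <= 1"
        else paste("EE > 1 for", paste(out$balanced$ee_violations,
                                       collapse = ", ")))
  }
  if (any(c("network", "sensitivity") %in% analyses)) {
    max_level <- config$max_level %||% 8
    log("network analysis: max discrete level %d, CI denominator S_living^2, link threshold 1e-6",
        max_level)
    out$report <- stage("analyze_network",
                        analyze_network(out$balanced, max_level = max_level))
  }
  if ("sensitivity" %in% analyses) {
    sc <- config$sensitivity
    if (is.null(sc$group) || is.null(sc$F))
      stop("stage 'sensitivity' failed: config$sensitivity needs 'group' and 'F'")
    log("sensitivity: group '%s', F = %s", sc$group,
        paste(sc$F, collapse = ", "))
    out$sensitivity <- stage("sensitivity",
                             fishing_sensitivity(model, sc$group,
                                                 unlist(sc$F),
                                                 max_level = config$max_level %||% 8))
  }
  if (!is.null(config$out) && !is.null(out$report)) {
    out$files <- stage("write_report", {
      f <- write_report(out$balanced$model, out$balanced$accounts,
                        out$report, config$out,
                        digits = config$digits %||% NA)
      if (!is.null(out$sensitivity)) {
        sf <- file.path(config$out, "sensitivity.csv")
        write_num_csv(out$sensitivity, sf, config$digits %||% NA)
        f <- c(f, sf)
      }
      f
    })
    log("wrote %d table(s) to %s", length(out$files), config$out)
  }
  invisible(out)
}
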