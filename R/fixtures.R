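# Built-in example data: the 17-group Chudao oyster reef (Sanggou Bay) model
# inputs and the accompanying plankton and reef-fauna survey tables, shipped
# as plain-text files under inst/extdata. The published model's diet matrix
# is not public, so the model fixture pairs the published per-group
# parameters with a SYNTHETIC diet matrix rebuilt by
# reconstruct_diet_matrix(); reference output values are carried as metadata
# for calibration reporting, never as ground truth for the diet.

fixture_path <- function(file) {
  system.file("extdata", file, package = "reefweb", mustWork = TRUE)
}

.fixture_cache <- new.env(parent = emptyenv())

#' The Chudao oyster reef 17-group model fixture
#'
#' Builds the food-web model from the published per-group inputs (biomass,
#' P/B, Q/B; fishery yield, accumulation and migration all zero; detritus
#' biomass 130 t km^-2), leaving EE to be estimated by [solve_balance()].
#' The diet matrix is reconstructed from the published trophic-level and EE
#' columns and is a synthetic calibration artefact, not survey data.
#'
#' @param diet `"reconstructed"` (default) attaches the optimised diet
#'   matrix; `"none"` returns only the group table (no `food_web_model`).
#' @param seed Seed passed to [reconstruct_diet_matrix()] (result is cached
#'   per seed within the session).
#' @return A list with
#'   \describe{
#'     \item{model}{the `food_web_model` (NULL when `diet = "none"`).}
#'     \item{groups}{the published group-parameter table, including the
#'       reference `TL_ref` and `EE_ref` columns.}
#'     \item{reference}{published system-level values for calibration
#'       reporting: TST, TPP, TPP/TR, CI, SOI, FCI, FML, transfer
#'       efficiencies and the detritus flow share.}
#'     \item{reconstruction}{the [reconstruct_diet_matrix()] result.}
#'   }
#' @export
core_fixture <- function(diet = c("reconstructed", "none"), seed = 1L) {
  diet <- match.arg(diet)
  raw <- utils::read.csv(fixture_path("chudao_groups.csv"),
                         stringsAsFactors = FALSE)
  g <- data.frame(name = raw$name, role = raw$role, B = raw$B, PB = raw$PB,
                  QB = raw$QB, EE = NA_real_, Y = 0, BA = 0, E = 0,
                  GS = ifelse(raw$role == "consumer", 0.2, 0))
  reference <- list(
    TL = setNames(raw$TL_ref, raw$name),
    EE = setNames(raw$EE_ref, raw$name),
    TL_range = c(1.00, 3.73),
    TST = 36752.52, TPP = 10849.86, TPP_over_TR = 1.02,
    CI = 0.37, SOI = 0.22, FCI = 14.69, FML = 3.39,
    TE_producer = c(II = 12.55, III = 4.48, IV = 1.27),
    TE_detritus = c(II = 13.39, III = 4.12, IV = 1.46),
    TE_all = c(II = 12.86, III = 4.34, IV = 1.34),
    te_total = 4.21, te_total_producer = 4.15, te_total_detritus = 4.31,
    detritus_origin_fraction = 0.37)

  if (diet == "none")
    return(list(model = NULL, groups = raw, reference = reference,
                reconstruction = NULL))

  key <- paste0("core_diet_", seed)
  rec <- .fixture_cache[[key]]
  if (is.null(rec)) {
    rec <- reconstruct_diet_matrix(g, tl_target = raw$TL_ref,
                                   ee_target = raw$EE_ref, seed = seed)
    .fixture_cache[[key]] <- rec
  }
  model <- food_web_model(g, rec$diet)
  list(model = model, groups = raw, reference = reference,
       reconstruction = rec)
}

#' Plankton survey counts (species x transect)
#'
#' Species composition and abundance of zooplankton and phytoplankton pooled
#' by transect (A, B, C) from the May 2024 Chudao survey.
#'
#' @param category `"zooplankton"`, `"phytoplankton"` or `"all"`.
#' @return An [abundance_table()]; for `"all"`, the species of both
#'   categories stacked.
#' @export
plankton_fixture <- function(category = c("zooplankton", "phytoplankton", "all")) {
  category <- match.arg(category)
  raw <- utils::read.csv(fixture_path("plankton_counts.csv"),
                         stringsAsFactors = FALSE)
  if (category != "all") raw <- raw[raw$category == category, ]
  m <- as.matrix(raw[, c("A", "B", "C")])
  rownames(m) <- raw$species
  abundance_table(m)
}

#' Reef-dwelling fauna checklist
#'
#' The 30-species, five-phylum inventory of sedentary reef-dwelling animals
#' recorded on the Chudao oyster reefs.
#'
#' @return Data frame with columns `phylum` and `species`.
#' @export
reef_checklist_fixture <- function() {
  utils::read.csv(fixture_path("reef_checklist.csv"), stringsAsFactors = FALSE)
}
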