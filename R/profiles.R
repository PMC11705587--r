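#' Population expression profiles
#'
#' A population profile describes one cell population for the synthetic
#' generator: a categorical expression level per panel marker, mean
#' autofluorescence (AF) abundance per AF endmember, forward/side scatter
#' distribution and viability (fraction of live cells).
#'
#' Expression levels map onto abundance decades: `neg` is background,
#' `low`, `pos` and `hi` sit at 10x, 100x and 1000x background.  These
#' decades mirror the dynamic range of typical surface markers and keep
#' positive/negative strata separable at the generator's default noise.
#'
#' @param name population identifier.
#' @param marker_levels named character vector, one of
#'   `c("neg","low","pos","hi")` per panel marker.
#' @param af_weights named non-negative numeric vector: mean AF abundance
#'   per AF endmember at the reference side scatter (50,000); the
#'   realized per-event AF abundance scales linearly with SSC-A.
#' @param scatter list with `fsc_mean`, `fsc_sd`, `ssc_mean`, `ssc_sd`
#'   (arbitrary scatter units; SDs must be positive).
#' @param viability fraction of live cells in \[0, 1\].
#' @return An object of class `population_profile`.
#' @seealso [default_lung_profiles()]
#' @export
population_profile <- function(name, marker_levels, af_weights = numeric(),
                               scatter = list(fsc_mean = 7e4, fsc_sd = 9e3,
                                              ssc_mean = 4e4, ssc_sd = 8e3),
                               viability = 0.95) {
  lv <- c("neg", "low", "pos", "hi")
  if (!all(marker_levels %in% lv))
    stop("marker levels must be one of ", paste(lv, collapse = "/"))
  if (length(af_weights) && any(af_weights < 0))
    stop("af_weights must be >= 0")
  stopifnot(scatter$fsc_sd > 0, scatter$ssc_sd > 0,
            viability >= 0, viability <= 1)
  structure(list(name = name, marker_levels = marker_levels,
                 af_weights = af_weights, scatter = scatter,
                 viability = viability),
            class = "population_profile")
}

#' @export
print.population_profile <- function(x, ...) {
  on <- x$marker_levels[x$marker_levels != "neg"]
  cat("<population_profile> ", x$name, ": ",
      paste0(names(on), ":", on, collapse = " "), "\n", sep = "")
  invisible(x)
}

## abundance multipliers of the four expression levels
level_means <- function(background = 1) {
  c(neg = 1, low = 10, pos = 100, hi = 1000) * background
}

#' Names of the three synthetic lung AF endmembers
#'
#' A dim lymphoid component (`"AF-lym"`), a mid-scatter myeloid
#' component (`"AF-mye"`), and the bright alveolar-macrophage component
#' (`"AF-amo"`, autofluorescent across all lasers).
#'
#' @return Character vector of length 3.
#' @export
default_af_names <- function() c("AF-lym", "AF-mye", "AF-amo")

#' Default murine lung population profiles
#'
#' The 17 target immune populations of the lung gating hierarchy with
#' marker levels consistent with the full decision path: neutrophils
#' (Ly6G+), inflammatory (Ly6C+) and resident (CD11c+) monocytes,
#' eosinophils (CD11b+ MHCII-), cDC1 (CD103+CD11b-), cDC2 (CD11b+CD103-),
#' pDC (CD11c+Ly6C+), alveolar (CD64+CD11c+) and interstitial
#' (CD64+CD11b+) macrophages, B cells (CD19+), T helper (CD4+), regulatory
#' T cells (CD4+CD25+CD127low), cytotoxic T cells (CD8+), NK
#' (CD335+CD127-), ILC1 (CD335+CD127+), ILC2 (CD25+) and ILC3
#' (CD25-KLRG-1-).
#'
#' The alveolar macrophage carries by far the highest weight on the
#' AF endmember `"AF-amo"` (it is autofluorescent across all detectors),
#' cDC2 a moderate `"AF-amo"` weight, and the `"AF-lym"`/`"AF-mye"`
#' components are spread across several populations.
#'
#' @param panel a [panel_config()]; profiles cover every panel marker.
#' @return Named list of 17 [population_profile()]s.
#' @export
default_lung_profiles <- function(panel = default_lung_panel()) {
  markers <- panel$entries$marker
  af <- default_af_names()

  base_levels <- function(...) {
    lv <- stats::setNames(rep("neg", length(markers)), markers)
    ov <- c(...)
    lv[names(ov)] <- ov
    lv
  }
  sc <- function(f, fs, s, ss)
    list(fsc_mean = f, fsc_sd = fs, ssc_mean = s, ssc_sd = ss)
  afw <- function(lym = 0, mye = 0, amo = 0)
    stats::setNames(c(lym, mye, amo), af)

  pr <- list(
    population_profile("Neutrophil",
      base_levels(CD45 = "pos", Ly6G = "hi", CD11b = "pos", CD24 = "pos",
                  CD62L = "low", Ly6C = "low", `PD-L1` = "low"),
      afw(mye = 150), sc(9e4, 1.2e4, 7e4, 1.2e4)),
    population_profile("Inflammatory monocyte",
      base_levels(CD45 = "pos", CD11b = "pos", Ly6C = "pos",
                  CX3CR1 = "pos", CD62L = "low"),
      afw(mye = 80), sc(7.5e4, 1e4, 3e4, 5e3)),
    population_profile("Resident monocyte",
      base_levels(CD45 = "pos", CD11b = "pos", CD11c = "pos",
                  CX3CR1 = "low", MHCII = "low"),
      afw(mye = 80), sc(7.5e4, 1e4, 3e4, 5e3)),
    population_profile("Eosinophil",
      base_levels(CD45 = "pos", CD11b = "pos", CD24 = "pos"),
      afw(mye = 300), sc(9.5e4, 1.2e4, 1.3e5, 1.8e4)),
    population_profile("cDC1",
      base_levels(CD45 = "pos", CD11c = "pos", CD103 = "pos",
                  CD24 = "pos", MHCII = "hi"),
      afw(lym = 40, mye = 60), sc(9.5e4, 1.2e4, 1e5, 1e4)),
    population_profile("cDC2",
      base_levels(CD45 = "pos", CD11c = "pos", CD11b = "pos",
                  CD24 = "pos", MHCII = "hi"),
      afw(lym = 40, mye = 60, amo = 150), sc(9.5e4, 1.2e4, 1e5, 1e4)),
    population_profile("pDC",
      base_levels(CD45 = "pos", CD11c = "pos", Ly6C = "pos", MHCII = "low"),
      afw(mye = 40), sc(7e4, 9e3, 1e5, 1e4)),
    population_profile("Alveolar macrophage",
      base_levels(CD45 = "pos", CD64 = "pos", CD11c = "pos", CD11b = "low",
                  CD206 = "pos", `F4/80` = "pos", MHCII = "low"),
      afw(amo = 800), sc(1.6e5, 2e4, 1.7e5, 2.2e4)),
    population_profile("Interstitial macrophage",
      base_levels(CD45 = "pos", CD64 = "pos", CD11b = "pos",
                  CX3CR1 = "pos", `F4/80` = "pos", MHCII = "pos"),
      afw(mye = 250), sc(1.2e5, 1.5e4, 1.15e5, 1.4e4)),
    population_profile("B cell",
      base_levels(CD45 = "pos", CD19 = "pos", MHCII = "pos", CD62L = "pos"),
      afw(lym = 120), sc(6.5e4, 8e3, 3.5e4, 7e3)),
    population_profile("T helper",
      base_levels(CD45 = "pos", CD3 = "pos", CD4 = "pos", CD127 = "pos",
                  CD62L = "pos", CD44 = "low"),
      afw(lym = 120), sc(6.2e4, 8e3, 3.2e4, 6e3)),
    population_profile("Treg",
      base_levels(CD45 = "pos", CD3 = "pos", CD4 = "pos", CD25 = "pos",
                  CD127 = "low", CD44 = "pos", CD62L = "pos",
                  `CTLA-4` = "low"),
      afw(lym = 120), sc(6.2e4, 8e3, 3.2e4, 6e3)),
    population_profile("Cytotoxic T",
      base_levels(CD45 = "pos", CD3 = "pos", CD8 = "pos", CD127 = "pos",
                  CD44 = "pos", `KLRG-1` = "low", `PD-1` = "low"),
      afw(lym = 120), sc(6.2e4, 8e3, 3.2e4, 6e3)),
    population_profile("NK",
      base_levels(CD45 = "pos", CD335 = "pos", CD122 = "pos",
                  CD11b = "low", `KLRG-1` = "pos"),
      afw(lym = 120), sc(6.8e4, 9e3, 3.8e4, 7e3)),
    population_profile("ILC1",
      base_levels(CD45 = "pos", CD335 = "pos", CD127 = "pos",
                  CD122 = "low"),
      afw(lym = 120), sc(6.5e4, 8e3, 3.5e4, 7e3)),
    population_profile("ILC2",
      base_levels(CD45 = "pos", CD127 = "pos", CD25 = "pos",
                  `KLRG-1` = "pos"),
      afw(lym = 120), sc(6.5e4, 8e3, 3.5e4, 7e3)),
    population_profile("ILC3",
      base_levels(CD45 = "pos", CD127 = "pos"),
      afw(lym = 120), sc(6.5e4, 8e3, 3.5e4, 7e3)))

  stats::setNames(pr, vapply(pr, function(p) p$name, character(1)))
}
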