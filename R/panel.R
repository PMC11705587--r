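#' Panel configuration: marker to fluorochrome map
#'
#' A panel is the ordered list of (marker, fluorochrome) pairs plus the
#' name of the viability channel and, once autofluorescence (AF) selection
#' has run, the AF identifiers that are carried as virtual fluorochromes.
#'
#' @param entries data.frame with character columns `marker` and
#'   `fluorochrome`; fluorochrome names must be unique.
#' @param viability_channel fluorochrome name of the viability dye.
#' @param af_names character vector of AF signature identifiers included
#'   as virtual fluorochromes (empty before AF selection).
#' @return An object of class `panel_config`.
#' @seealso [default_lung_panel()]
#' @export
panel_config <- function(entries, viability_channel, af_names = character()) {
  stopifnot(is.data.frame(entries),
            all(c("marker", "fluorochrome") %in% colnames(entries)))
  if (anyDuplicated(entries$fluorochrome))
    stop("fluorochrome names must be unique")
  if (anyDuplicated(entries$marker))
    stop("marker names must be unique")
  if (!viability_channel %in% entries$fluorochrome)
    stop("viability_channel must be one of the panel fluorochromes")
  structure(list(entries = entries[, c("marker", "fluorochrome")],
                 viability_channel = viability_channel,
                 af_names = af_names),
            class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat("<panel_config> ", nrow(x$entries), " fluorochromes (viability: ",
      x$viability_channel, ")", sep = "")
  if (length(x$af_names))
    cat(" + ", length(x$af_names), " AF endmembers", sep = "")
  cat("\n")
  invisible(x)
}

#' The default 27-fluorochrome murine lung panel
#'
#' 26 surface antibodies plus one viability dye, covering the lineage
#' markers needed to resolve the 17 target lung immune populations and the
#' maturation/checkpoint markers used for sub-states.  Marker names follow
#' CD nomenclature; fluorochrome names follow the commercial dye names.
#'
#' @return A [panel_config()] with 27 entries.
#' @export
default_lung_panel <- function() {
  entries <- data.frame(
    marker = c("CD62L", "CD103", "CD11c", "CD335", "CD44",
               "F4/80", "CD4", "CD8", "CD127", "CD206",
               "PD-L1", "Ly6C", "CD64", "CD45", "CD19",
               "CTLA-4", "CD24", "CD25", "CX3CR1", "KLRG-1",
               "CD11b", "CD122", "PD-1", "MHCII", "Ly6G",
               "CD3", "Viability"),
    fluorochrome = c("BUV395", "BUV563", "BUV661", "BUV737", "BUV805",
                     "BV421", "PacificBlue", "SparkViolet538", "BV605", "BV650",
                     "BV711", "BV785", "FITC", "SparkBlue550", "BB700",
                     "PE", "PE-Dazzle594", "PE-Cy5", "PE-Fire700", "PE-Cy7",
                     "PE-Fire810", "APC", "AF647", "AF700", "APC-Cy7",
                     "APC-Fire810", "ZombieUV"),
    stringsAsFactors = FALSE)
  panel_config(entries, viability_channel = "ZombieUV")
}

## fluorochrome of a marker (and the reverse), from a panel_config
marker_to_fluor <- function(panel, markers) {
  idx <- match(markers, panel$entries$marker)
  if (anyNA(idx)) stop("unknown marker(s): ",
                       paste(markers[is.na(idx)], collapse = ", "))
  panel$entries$fluorochrome[idx]
}

fluor_to_marker <- function(panel, fluors) {
  idx <- match(fluors, panel$entries$fluorochrome)
  if (anyNA(idx)) stop("unknown fluorochrome(s): ",
                       paste(fluors[is.na(idx)], collapse = ", "))
  panel$entries$marker[idx]
}
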