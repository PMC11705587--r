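#' Detector layout of a full-spectrum cytometer
#'
#' A detector layout is an ordered set of lasers, each carrying a fixed
#' number of fluorescence detectors.  The shipped default is the 5-laser,
#' 64-detector configuration (UV 16, Violet 16, Blue 14, Yellow-Green 10,
#' Red 8) common on full-spectrum instruments.  Detector names are the
#' laser prefix followed by the 1-based detector index ("UV1" .. "R8");
#' their order is fixed and shared by every table in the package.
#'
#' @param lasers named integer vector: detector count per laser, in
#'   acquisition order.
#' @return An object of class `detector_layout` with elements `lasers`
#'   (named integer vector), `detectors` (character vector of detector
#'   names) and `n` (total detector count).
#' @examples
#' lay <- detector_layout()
#' lay$n            # 64
#' head(lay$detectors)
#' @export
detector_layout <- function(lasers = c(UV = 16L, V = 16L, B = 14L, YG = 10L, R = 8L)) {
  if (is.null(names(lasers)) || any(!nzchar(names(lasers))))
    stop("lasers must be a named vector")
  counts <- as.integer(lasers)
  if (any(is.na(counts)) || any(counts < 1L))
    stop("laser detector counts must be positive integers")
  names(counts) <- names(lasers)
  detectors <- unlist(lapply(names(counts),
                             function(l) paste0(l, seq_len(counts[[l]]))),
                      use.names = FALSE)
  if (anyDuplicated(detectors)) stop("duplicate detector names in layout")
  structure(list(lasers = counts, detectors = detectors, n = length(detectors)),
            class = "detector_layout")
}

#' @export
print.detector_layout <- function(x, ...) {
  cat("<detector_layout> ", x$n, " detectors / ",
      length(x$lasers), " lasers: ",
      paste0(names(x$lasers), ":", x$lasers, collapse = " "), "\n", sep = "")
  invisible(x)
}

## laser membership of each detector, in layout order
laser_of <- function(layout) rep(names(layout$lasers), layout$lasers)

## names of the scatter channels carried alongside the detectors
scatter_channels <- function() c("FSC-A", "SSC-A", "FSC-H")
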