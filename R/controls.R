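#' Extract an endmember signature from a single-stain control
#'
#' Positive events are the top `positive_fraction` of the control by its
#' brightest detector; the signature is the per-detector median of the
#' positive events minus the median of the unstained sample, clamped at
#' zero and unit-normalized.  The pre-normalization maximum is retained
#' as `peak_intensity` for brightness comparisons.
#'
#' @param control an [event_table()] with at least 100 events.
#' @param unstained an [event_table()] (background reference).
#' @param positive_fraction fraction in (0, 0.5\] selected as positive.
#' @param name signature identifier (defaults to the control's first
#'   truth abundance column, if any).
#' @return A unit-norm [spectral_signature()]; all-zero (with a warning)
#'   when the control does not differ from the unstained reference.
#' @export
extract_signature <- function(control, unstained, positive_fraction = 0.2,
                              name = NULL) {
  if (nrow(control$raw) < 100)
    stop("insufficient data: control has fewer than 100 events")
  if (positive_fraction <= 0 || positive_fraction > 0.5)
    stop("positive_fraction must be in (0, 0.5]")
  name <- name %||% colnames(control$truth_abundances)[1] %||% "extracted"
  bright <- which.max(colMeans(control$raw))
  npos <- max(1L, round(nrow(control$raw) * positive_fraction))
  pos <- order(control$raw[, bright], decreasing = TRUE)[seq_len(npos)]
  med_pos <- col_medians(control$raw[pos, , drop = FALSE])
  med_bg <- col_medians(unstained$raw)
  v <- pmax(med_pos - med_bg, 0)
  ## degenerate control: the positive events' brightest detector does not
  ## rise above the background's own noise floor
  if (med_pos[bright] <= stats::quantile(unstained$raw[, bright], 0.95,
                                         names = FALSE)) {
    warning("control is indistinguishable from the unstained reference; ",
            "returning an all-zero signature for ", name)
    v[] <- 0
  }
  normalize_signature(v, "unit", name = name, layout = control$layout)
}

#' Carrier-matched background events of a single-stain control
#'
#' The dimmest `fraction` of a control's events (by its brightest
#' detector) form an unstained sample of the same carrier — the correct
#' background reference for [extract_signature()], since bead controls
#' carry no cellular autofluorescence while cell controls do.
#'
#' @param control an [event_table()].
#' @param fraction fraction of dim events to keep.
#' @return An [event_table()] of the background events.
#' @export
control_blank <- function(control, fraction = 0.3) {
  bright <- which.max(colMeans(control$raw))
  n <- nrow(control$raw)
  k <- max(1L, floor(n * fraction))
  idx <- order(control$raw[, bright])[seq_len(k)]
  subset_events(control, idx)
}

#' Stain index of a positive/negative pair
#'
#' `(median(positive) - median(negative)) / (2 * robust SD(negative))`,
#' with the robust SD taken as 1.4826 x the median absolute deviation.
#' Invariant to adding a common constant to both vectors; scales as `1/k`
#' when the negative spread scales by `k` at fixed medians.
#'
#' @param positive,negative numeric vectors (>= 10 values each).
#' @return A real number; `Inf` with a warning when the negative spread
#'   is zero.
#' @export
stain_index <- function(positive, negative) {
  if (length(positive) < 10 || length(negative) < 10)
    stop("stain_index needs at least 10 values per group")
  s <- robust_sd(negative)
  d <- stats::median(positive) - stats::median(negative)
  if (s == 0) {
    warning("negative population has zero robust SD; stain index is Inf")
    return(Inf)
  }
  d / (2 * s)
}

## split a control's events into stained-positive / negative by the
## abundance of its own fluorochrome (midpoint of the quartiles)
.control_split <- function(a) {
  thr <- mean(stats::quantile(a, c(0.25, 0.75), names = FALSE))
  a > thr
}

#' Spillover-spreading matrix of unmixed single-stain controls
#'
#' Entry (f, g), f != g, is the robust SD of endmember-g abundances among
#' f-positive events minus that among f-negative events, floored at zero
#' (the spillover-spreading convention, evaluated at the unmixed
#' abundance level).  The diagonal is zero.
#'
#' @param unmixed_controls named list (fluorochrome -> [unmix()] result),
#'   every control unmixed against the same full endmember matrix.
#' @param fluors fluorochrome names (defaults to the list names).
#' @return A square numeric matrix with zero diagonal.
#' @export
spread_matrix <- function(unmixed_controls, fluors = names(unmixed_controls)) {
  missing <- setdiff(fluors, names(unmixed_controls))
  if (length(missing))
    stop("missing unmixed control(s) for: ", paste(missing, collapse = ", "))
  S <- matrix(0, length(fluors), length(fluors),
              dimnames = list(fluors, fluors))
  for (f in fluors) {
    ab <- unmixed_controls[[f]]$abundances
    pos <- .control_split(ab[, f])
    if (!any(pos) || all(pos)) next
    for (g in setdiff(fluors, f))
      S[f, g] <- max(0, robust_sd(ab[pos, g]) - robust_sd(ab[!pos, g]))
  }
  S
}

#' Panel QC report for one unmixing carrier
#'
#' Unmixes every single-stain control against the supplied endmember
#' matrix, computes the per-fluorochrome stain index (brightest-detector
#' intensities, positive versus negative events) and the spillover
#' [spread_matrix()].
#'
#' @param controls named list of single-stain [event_table()]s.
#' @param m an endmember matrix from [build_mixing_matrix()].
#' @param carrier label recorded in the report (`"beads"` or `"cells"`).
#' @return An object of class `qc_report`: `stain_indices`, `spread`,
#'   `carrier`, `notes`.
#' @export
qc_report <- function(controls, m, carrier = "beads") {
  fluors <- names(controls)
  notes <- character()
  unmixed <- lapply(controls, unmix, m = m)
  si <- vapply(fluors, function(f) {
    raw <- controls[[f]]$raw
    bright <- which.max(colMeans(raw))
    pos <- .control_split(unmixed[[f]]$abundances[, f])
    if (!any(pos) || all(pos)) return(NA_real_)
    stain_index(raw[pos, bright], raw[!pos, bright])
  }, numeric(1))
  structure(list(stain_indices = si,
                 spread = spread_matrix(unmixed, fluors),
                 carrier = carrier, notes = notes),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> carrier=", x$carrier, "; ", length(x$stain_indices),
      " fluorochromes; total spread=",
      format(sum(x$spread), digits = 4),
      "; median stain index=",
      format(stats::median(x$stain_indices, na.rm = TRUE), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Choose the unmixing carrier per fluorochrome
#'
#' For each fluorochrome the carrier whose matrix yields the lower total
#' spread contribution (row sum of the spreading matrix) wins; ties are
#' broken by the higher stain index.  Both metric values are logged.
#'
#' @param bead_qc,cell_qc [qc_report()]s covering the same fluorochromes.
#' @param tie_tol relative spread difference treated as a tie.
#' @return A data.frame with one row per fluorochrome: the chosen
#'   carrier and both spread/stain-index values.
#' @export
choose_carrier <- function(bead_qc, cell_qc, tie_tol = 0.02) {
  fb <- names(bead_qc$stain_indices)
  fc <- names(cell_qc$stain_indices)
  if (!setequal(fb, fc))
    stop("carrier reports cover different fluorochromes")
  res <- data.frame(fluorochrome = fb,
                    spread_beads = rowSums(bead_qc$spread)[fb],
                    spread_cells = rowSums(cell_qc$spread)[fb],
                    stain_beads = bead_qc$stain_indices[fb],
                    stain_cells = cell_qc$stain_indices[fb],
                    row.names = NULL)
  scale <- pmax(res$spread_beads, res$spread_cells, 1e-12)
  tie <- abs(res$spread_beads - res$spread_cells) / scale <= tie_tol
  res$carrier <- ifelse(res$spread_beads <= res$spread_cells, "beads", "cells")
  res$carrier[tie] <- ifelse(res$stain_cells[tie] > res$stain_beads[tie],
                             "cells", "beads")
  res
}
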