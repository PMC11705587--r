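#' Assemble the endmember (mixing) matrix
#'
#' Stacks unit-normalized fluorochrome signatures and, optionally, the
#' selected autofluorescence signatures into the detector x endmember
#' mixing matrix.  Duplicate names are a structural error; near-collinear
#' column pairs (similarity > `collinearity_tol`) and rank deficiency are
#' rejected with a diagnostic naming the offending pair.
#'
#' @param panel_signatures list of fluorochrome [spectral_signature()]s.
#' @param af_set optional [af_select()] result (or plain list of AF
#'   signatures) appended as additional columns.
#' @param collinearity_tol similarity above which two columns are
#'   declared collinear.
#' @return An object of class `endmember_matrix`: numeric matrix
#'   (detectors x endmembers, unit-norm columns) with a `provenance`
#'   attribute tagging each column `"panel"` or `"af"`.
#' @export
build_mixing_matrix <- function(panel_signatures, af_set = NULL,
                                collinearity_tol = 0.999) {
  af_sigs <- if (inherits(af_set, "af_selection")) af_set$signatures
             else af_set %||% list()
  sigs <- c(panel_signatures, af_sigs)
  nm <- vapply(sigs, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate endmember names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  M <- signature_columns(sigs)
  colnames(M) <- nm
  sim <- similarity_matrix(sigs)$values
  up <- which(upper.tri(sim) & sim > collinearity_tol, arr.ind = TRUE)
  if (nrow(up))
    stop("near-collinear endmember pair: ",
         nm[up[1, 1]], " ~ ", nm[up[1, 2]],
         " (similarity ", format(sim[up[1, , drop = FALSE]], digits = 6), ")")
  if (qr(M)$rank < ncol(M))
    stop("endmember matrix is rank deficient")
  structure(M, provenance = rep(c("panel", "af"),
                                c(length(panel_signatures), length(af_sigs))),
            class = c("endmember_matrix", "matrix", "array"))
}

#' @export
print.endmember_matrix <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<endmember_matrix> ", nrow(x), " detectors x ", ncol(x),
      " endmembers (", sum(prov == "panel"), " panel + ",
      sum(prov == "af"), " AF)\n", sep = "")
  invisible(x)
}

.events_raw <- function(events) {
  if (inherits(events, "event_table")) events$raw else as.matrix(events)
}

#' Per-event linear spectral unmixing
#'
#' Solves, for every event, the least-squares problem
#' `raw ~ M %*% abundance` over the endmember matrix `M` via a QR
#' decomposition.  Ordinary least squares (`method = "ols"`) is the
#' default; `method = "wls"` weights detectors by the reciprocal of the
#' supplied per-detector variances (an infinite variance removes that
#' detector from the fit).  Abundances are signed — negatives are
#' preserved, matching the convention of spectral acquisition software.
#'
#' @param events an [event_table()] (or bare events x detectors matrix).
#' @param m an [build_mixing_matrix()] result (or detector x endmember
#'   matrix of full column rank).
#' @param method `"ols"` or `"wls"`.
#' @param variances per-detector variances for `"wls"` (strictly
#'   positive; `Inf` allowed).
#' @return An object of class `unmix_result` with elements `abundances`
#'   (events x endmembers), `residual_rms` (per event), `method` and
#'   `endmember_names`.  Methods: `print`, `summary`, `coef`, `fitted`.
#' @examples
#' lay3 <- detector_layout(c(A = 3L))
#' m <- diag(3); rownames(m) <- lay3$detectors; colnames(m) <- c("a","b","c")
#' unmix(matrix(c(2, 3, 5), 1), m)$abundances   # 2 3 5
#' @export
unmix <- function(events, m, method = c("ols", "wls"), variances = NULL) {
  method <- match.arg(method)
  raw <- .events_raw(events)
  M <- unclass(m)
  if (ncol(raw) != nrow(M))
    stop("events have ", ncol(raw), " detectors; matrix expects ", nrow(M))
  Y <- t(raw)                                   # detectors x events
  if (method == "wls") {
    if (is.null(variances)) stop("wls needs per-detector variances")
    if (length(variances) != nrow(M))
      stop("variances length must equal the detector count")
    if (any(variances <= 0)) stop("variances must be strictly positive")
    w <- sqrt(1 / variances)                    # Inf variance -> weight 0
    keep <- w > 0
    M <- M * w
    Y <- Y * w
    M <- M[keep, , drop = FALSE]
    Y <- Y[keep, , drop = FALSE]
  }
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) stop("endmember matrix is rank deficient")
  A <- t(qr.coef(qrM, Y))                       # events x endmembers
  colnames(A) <- colnames(m)
  res <- qr.resid(qrM, Y)
  structure(list(abundances = A,
                 residual_rms = sqrt(colMeans(res^2)),
                 method = method,
                 endmember_names = colnames(m)),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat("<unmix_result> ", nrow(x$abundances), " events x ",
      ncol(x$abundances), " endmembers (", x$method,
      "); median residual RMS = ",
      format(stats::median(x$residual_rms), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.unmix_result <- function(object, ...) {
  s <- t(apply(object$abundances, 2, function(a)
    c(median = stats::median(a), mad = robust_sd(a),
      min = min(a), max = max(a))))
  cat("Unmixing (", object$method, "), ", nrow(object$abundances),
      " events\n", sep = "")
  print(round(s, 3))
  invisible(s)
}

#' @export
coef.unmix_result <- function(object, ...) object$abundances

#' Fitted detector signal of an unmixing result
#' @param object an [unmix()] result.
#' @param m the endmember matrix used for the fit.
#' @param ... unused.
#' @export
fitted.unmix_result <- function(object, m, ...) {
  object$abundances %*% t(unclass(m))
}

## mean absolute abundance over the panel (non-AF) columns: the
## background-bias objective used for AF selection and comparison
.background_bias <- function(ab, fluor_cols) {
  mean(abs(ab[, fluor_cols, drop = FALSE]))
}

#' Compare multi-AF versus single-AF unmixing
#'
#' Unmixes the same events with the multi-AF and the single-AF endmember
#' matrices and reports, per fluorochrome channel, the background bias
#' (mean absolute abundance among truth-negative events) and spread
#' (robust SD of the same) under both, together with the laser group of
#' each channel's emission peak.
#'
#' @param events an [event_table()] with truth abundances.
#' @param m_multi endmember matrix with the selected AF set.
#' @param m_single endmember matrix with exactly one whole-sample AF
#'   column; must share the fluorochrome columns of `m_multi`.
#' @param negative_cut truth abundance below which an event counts as
#'   negative for a channel.
#' @return A data.frame (class `af_comparison`) with one row per
#'   fluorochrome: `laser`, `bias_single`, `bias_multi`, `spread_single`,
#'   `spread_multi` and the bias `ratio` (multi/single).
#' @export
af_comparison_report <- function(events, m_multi, m_single,
                                 negative_cut = 5) {
  fl_multi <- colnames(m_multi)[attr(m_multi, "provenance") == "panel"]
  fl_single <- colnames(m_single)[attr(m_single, "provenance") == "panel"]
  if (!identical(fl_multi, fl_single))
    stop("matrices do not share their fluorochrome columns")
  if (is.null(events$truth_abundances))
    stop("events must carry truth abundances")
  um <- unmix(events, m_multi)
  us <- unmix(events, m_single)
  layout <- events$layout
  lasers <- laser_of(layout)
  out <- do.call(rbind, lapply(fl_multi, function(f) {
    negidx <- events$truth_abundances[, f] < negative_cut
    ## channels positive on every population have no negative stratum
    if (sum(negidx) < 30) return(NULL)
    am <- um$abundances[negidx, f]
    as <- us$abundances[negidx, f]
    data.frame(fluorochrome = f,
               laser = lasers[which.max(unclass(m_multi)[, f])],
               bias_single = mean(abs(as)), bias_multi = mean(abs(am)),
               spread_single = robust_sd(as), spread_multi = robust_sd(am))
  }))
  out$ratio <- out$bias_multi / pmax(out$bias_single, 1e-12)
  class(out) <- c("af_comparison", "data.frame")
  out
}

#' @export
print.af_comparison <- function(x, ...) {
  cat("<af_comparison> ", nrow(x), " fluorochrome channels; median ",
      "multi/single background-bias ratio = ",
      format(stats::median(x$ratio), digits = 4), "\n", sep = "")
  print.data.frame(cbind(x[, c("fluorochrome", "laser")],
                         round(x[, c("bias_single", "bias_multi", "ratio")], 4)))
  invisible(x)
}
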