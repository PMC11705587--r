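#' Spectral signatures and their similarity machinery
#'
#' A spectral signature is one endmember's (fluorochrome or
#' autofluorescence component) intensity profile across the detectors of a
#' [detector_layout()].  Signatures are stored non-negative together with a
#' normalization tag and the pre-normalization peak intensity, which is
#' retained for brightness comparisons.
#'
#' @param values numeric vector of non-negative detector intensities, one
#'   per detector of `layout`.
#' @param name identifier of the signature.
#' @param normalization one of `"unit"` (Euclidean norm 1, the default used
#'   for similarity computation and unmixing), `"peak"` (maximum 1, used
#'   for plotting/export) or `"raw"`.
#' @param peak_intensity pre-normalization maximum; computed from `values`
#'   when missing.
#' @param layout a [detector_layout()].
#' @return An object of class `spectral_signature`.
#' @seealso [normalize_signature()], [similarity_index()]
#' @export
spectral_signature <- function(values, name = "signature",
                               normalization = c("unit", "peak", "raw"),
                               peak_intensity = NULL,
                               layout = detector_layout()) {
  normalization <- match.arg(normalization)
  values <- as.numeric(values)
  if (length(values) != layout$n)
    stop("signature length ", length(values),
         " does not match layout with ", layout$n, " detectors")
  if (all(is.na(values))) stop("all-NA signature values")
  if (any(values < 0, na.rm = TRUE)) stop("signature values must be >= 0")
  names(values) <- layout$detectors
  structure(list(name = name, values = values, normalization = normalization,
                 peak_intensity = peak_intensity %||% max(values, 0),
                 layout = layout),
            class = "spectral_signature")
}

#' @export
print.spectral_signature <- function(x, ...) {
  pk <- which.max(x$values)
  cat("<spectral_signature> ", x$name, ": ", length(x$values),
      " detectors, peak at ", names(x$values)[pk],
      ", normalization=", x$normalization,
      ", peak_intensity=", format(x$peak_intensity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.spectral_signature <- function(x, ..., type = "h", lwd = 2,
                                    col = "steelblue") {
  graphics::plot(seq_along(x$values), x$values, type = type, lwd = lwd,
                 col = col, xaxt = "n", xlab = "detector",
                 ylab = "intensity", main = x$name, ...)
  graphics::axis(1, at = seq_along(x$values), labels = names(x$values),
                 las = 2, cex.axis = 0.5)
  invisible(x)
}

#' Normalize a raw spectrum into a spectral signature
#'
#' Negative entries (background over-subtraction) are clamped to zero
#' before normalization.  Peak mode divides by the maximum, unit mode by
#' the Euclidean norm; the pre-normalization maximum is recorded as
#' `peak_intensity`.  An all-zero spectrum is returned unchanged with
#' `peak_intensity = 0` (no division by zero).
#'
#' @param raw numeric vector of detector intensities (may contain
#'   negatives, which are clamped).
#' @param mode normalization tag, `"unit"`, `"peak"` or `"raw"`.
#' @param name signature identifier.
#' @param layout a [detector_layout()].
#' @return A [spectral_signature()].
#' @examples
#' lay4 <- detector_layout(c(A = 4L))
#' s <- normalize_signature(c(0, 2, 4, 2), mode = "peak", layout = lay4)
#' s$values          # 0 0.5 1 0.5
#' s$peak_intensity  # 4
#' @export
normalize_signature <- function(raw, mode = c("unit", "peak", "raw"),
                                name = "signature",
                                layout = detector_layout()) {
  mode <- match.arg(mode)
  raw <- as.numeric(raw)
  if (length(raw) != layout$n)
    stop("raw length ", length(raw), " does not match layout with ",
         layout$n, " detectors")
  if (all(is.na(raw))) stop("all-NaN/NA input spectrum")
  raw[is.na(raw)] <- 0
  v <- pmax(raw, 0)
  pk <- max(v)
  den <- switch(mode,
                unit = sqrt(sum(v^2)),
                peak = pk,
                raw  = 1)
  if (den > 0) v <- v / den
  spectral_signature(v, name = name, normalization = mode,
                     peak_intensity = pk, layout = layout)
}

sig_values <- function(x) {
  if (inherits(x, "spectral_signature")) x$values else as.numeric(x)
}

#' Similarity index of two emission spectra
#'
#' Cosine similarity of the non-negative spectra: zero indicates no
#' spectral overlap (disjoint detector support), one denotes identical
#' (proportional) spectra.  Invariant to positive scaling of either
#' argument; returns 0 if either spectrum is all-zero.
#'
#' @param a,b spectral signatures (or bare non-negative numeric vectors of
#'   equal length).
#' @return A number in \[0, 1\].
#' @examples
#' lay3 <- detector_layout(c(A = 3L))
#' s1 <- normalize_signature(c(1, 2, 3), layout = lay3)
#' s2 <- normalize_signature(c(2, 4, 6), layout = lay3)
#' similarity_index(s1, s2)  # 1: proportional spectra
#' @export
similarity_index <- function(a, b) {
  va <- pmax(sig_values(a), 0)
  vb <- pmax(sig_values(b), 0)
  if (length(va) != length(vb))
    stop("signatures have different detector layouts (lengths ",
         length(va), " vs ", length(vb), ")")
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  min(1, max(0, sum(va * vb) / (na * nb)))
}

#' Pairwise similarity matrix of a signature set
#'
#' Element (i, j) is [similarity_index()] of signatures i and j; the
#' matrix is symmetric with unit diagonal and entries in \[0, 1\].
#'
#' @param signatures non-empty list of [spectral_signature()]s on a shared
#'   layout.
#' @return An object of class `similarity_matrix`: list with `names` and
#'   the square numeric `values` matrix.
#' @export
similarity_matrix <- function(signatures) {
  if (length(signatures) == 0) stop("empty signature list")
  nm <- vapply(signatures, function(s)
    if (inherits(s, "spectral_signature")) s$name else "", character(1))
  if (any(!nzchar(nm))) nm <- paste0("S", seq_along(signatures))
  V <- vapply(signatures, sig_values, numeric(length(sig_values(signatures[[1]]))))
  V <- pmax(V, 0)                       # detectors x signatures
  nrm <- sqrt(colSums(V^2))
  k <- ncol(V)
  M <- matrix(0, k, k, dimnames = list(nm, nm))
  nz <- nrm > 0
  if (any(nz)) {
    U <- sweep(V[, nz, drop = FALSE], 2, nrm[nz], "/")
    M[nz, nz] <- crossprod(U)
  }
  M <- pmin(pmax(M, 0), 1)
  diag(M) <- 1
  M <- (M + t(M)) / 2
  structure(list(names = nm, values = M), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> ", length(x$names), " signatures\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' @export
as.matrix.similarity_matrix <- function(x, ...) x$values

#' @export
plot.similarity_matrix <- function(x, ...) {
  k <- length(x$names)
  graphics::image(seq_len(k), seq_len(k), t(x$values[k:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, at = seq_len(k), labels = x$names, las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(k), labels = rev(x$names), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Complexity index of a signature set
#'
#' Scalar summary (>= 1) of how entangled a set of endmember spectra is,
#' defined as the 2-norm condition number of the unit-norm column-stacked
#' signature matrix.  Because the similarity matrix of unit-norm spectra is
#' their Gram matrix, the condition number is the square root of the ratio
#' of its extreme eigenvalues.  Orthogonal spectra give 1; a set containing
#' two proportional signatures is rank deficient and reports `Inf`.
#'
#' @param m a [similarity_matrix()] (or a list of signatures, which is
#'   converted first).
#' @return A number >= 1, possibly `Inf`.
#' @export
complexity_index <- function(m) {
  if (!inherits(m, "similarity_matrix")) m <- similarity_matrix(m)
  ev <- eigen(m$values, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  lo <- min(ev); hi <- max(ev)
  if (lo <= hi * 1e-12) return(Inf)
  sqrt(hi / lo)
}

#' Read or write signature tables as CSV
#'
#' One row per signature; columns are `name`, `peak_intensity`, then the
#' detector names in layout order.
#'
#' @param signatures list of [spectral_signature()]s.
#' @param path file path.
#' @param layout a [detector_layout()] (for reading).
#' @return `write_signatures()` returns `path` invisibly;
#'   `read_signatures()` returns a list of signatures.
#' @export
write_signatures <- function(signatures, path) {
  V <- t(vapply(signatures, sig_values,
                numeric(length(sig_values(signatures[[1]])))))
  df <- data.frame(
    name = vapply(signatures, function(s) s$name, character(1)),
    peak_intensity = vapply(signatures, function(s) s$peak_intensity, numeric(1)),
    V, check.names = FALSE)
  colnames(df)[-(1:2)] <- names(signatures[[1]]$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path, layout = detector_layout()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(layout$detectors %in% colnames(df)))
    stop("signature CSV is missing detector columns for this layout")
  lapply(seq_len(nrow(df)), function(i)
    spectral_signature(as.numeric(df[i, layout$detectors]),
                       name = df$name[i],
                       normalization = "raw",
                       peak_intensity = df$peak_intensity[i],
                       layout = layout))
}

#' @rdname write_signatures
#' @param m a [similarity_matrix()].
#' @export
write_similarity <- function(m, path) {
  utils::write.csv(data.frame(name = m$names, m$values, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
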