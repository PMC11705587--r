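#' Dissect an unstained sample into candidate AF signatures
#'
#' Partitions the FSC-A x SSC-A scatter plane into a quantile grid
#' (default 7 FSC columns x 5 SSC rows = 35 bins) and takes the median
#' spectrum of each bin, clamped non-negative, as one autofluorescence
#' candidate.  Quantile edges keep the bins populated for any scatter
#' distribution; every event is assigned to exactly one bin.  Candidates
#' are labelled `"AF1"` .. in bin order (SSC rows within FSC columns).
#'
#' @param unstained an [event_table()].
#' @param grid integer pair `(fsc_cols, ssc_rows)`.
#' @return List of `af_candidate` objects, each with `id`, `bin` (the
#'   FSC/SSC intervals), `signature` (unit-norm), `event_count` and
#'   `mean_total_intensity`; empty bins (possible with heavily tied
#'   scatter values) carry `event_count = 0` and are flagged for
#'   exclusion.
#' @export
af_dissect <- function(unstained, grid = c(7, 5)) {
  n <- nrow(unstained$raw)
  if (n < 2) stop("insufficient data: need at least 2 events to dissect")
  nbins <- grid[1] * grid[2]
  if (n < nbins)
    warning("fewer events (", n, ") than grid bins (", nbins, ")")
  fsc <- unstained$scatter[["FSC-A"]]
  ssc <- unstained$scatter[["SSC-A"]]
  fedges <- unique(stats::quantile(fsc, seq(0, 1, length.out = grid[1] + 1),
                                   names = FALSE))
  sedges <- unique(stats::quantile(ssc, seq(0, 1, length.out = grid[2] + 1),
                                   names = FALSE))
  fbin <- findInterval(fsc, fedges, rightmost.closed = TRUE, all.inside = TRUE)
  sbin <- findInterval(ssc, sedges, rightmost.closed = TRUE, all.inside = TRUE)
  out <- vector("list", nbins)
  k <- 0L
  for (i in seq_len(grid[1])) for (j in seq_len(grid[2])) {
    k <- k + 1L
    idx <- which(fbin == min(i, length(fedges) - 1L) &
                   sbin == min(j, length(sedges) - 1L))
    ## duplicated quantile edges collapse bins; later duplicates are empty
    if (i > length(fedges) - 1L || j > length(sedges) - 1L) idx <- integer()
    sig <- if (length(idx)) {
      normalize_signature(col_medians(unstained$raw[idx, , drop = FALSE]),
                          "unit", name = paste0("AF", k),
                          layout = unstained$layout)
    } else {
      normalize_signature(rep(0, unstained$layout$n), "unit",
                          name = paste0("AF", k), layout = unstained$layout)
    }
    out[[k]] <- structure(
      list(id = paste0("AF", k),
           bin = list(fsc = c(fedges[min(i, length(fedges) - 1L)],
                              fedges[min(i + 1L, length(fedges))]),
                      ssc = c(sedges[min(j, length(sedges) - 1L)],
                              sedges[min(j + 1L, length(sedges))])),
           signature = sig,
           event_count = length(idx),
           mean_total_intensity = if (length(idx))
             mean(rowSums(unstained$raw[idx, , drop = FALSE])) else 0),
      class = "af_candidate")
  }
  out
}

#' @export
print.af_candidate <- function(x, ...) {
  cat("<af_candidate> ", x$id, ": ", x$event_count, " events, mean total ",
      "intensity ", format(x$mean_total_intensity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Prune near-duplicate AF candidates
#'
#' Greedy pass over the candidates sorted by descending mean total
#' intensity: a candidate is kept iff its similarity to every
#' already-kept candidate is below `threshold` — when two signatures are
#' very similar, the one with the lower spectral intensity is excluded.
#' Empty-bin candidates are dropped first.  The output is independent of
#' the input order and its pairwise similarities are all below
#' `threshold`.
#'
#' @param candidates list of `af_candidate` objects from [af_dissect()].
#' @param threshold similarity threshold in (0, 1\].
#' @return The surviving candidates, brightest first.
#' @export
af_prune <- function(candidates, threshold = 0.98) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  candidates <- Filter(function(c) c$event_count > 0, candidates)
  ord <- order(vapply(candidates, function(c) c$mean_total_intensity,
                      numeric(1)),
               vapply(candidates, function(c) c$id, character(1)),
               decreasing = TRUE)
  candidates <- candidates[ord]
  kept <- list()
  for (c in candidates) {
    dup <- any(vapply(kept, function(k)
      similarity_index(c$signature, k$signature) >= threshold, logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- c
  }
  kept
}

#' Greedy forward selection of AF endmembers
#'
#' Starting from the fluorochrome-only endmember matrix, repeatedly adds
#' the candidate whose inclusion most reduces the background bias — the
#' mean absolute unmixed fluorochrome abundance over the unstained
#' events — and stops when the relative improvement falls below `tol` or
#' `max_af` signatures have been taken.  The full trace of objective
#' values and keep/reject decisions is recorded.
#'
#' @param candidates pruned `af_candidate` list.
#' @param fluor_endmembers list of fluorochrome [spectral_signature()]s.
#' @param unstained an [event_table()].
#' @param max_af maximum number of AF signatures to select.
#' @param tol minimum relative objective improvement to keep adding.
#' @return An object of class `af_selection`: `members` (candidate ids),
#'   `signatures`, `objective` (final value) and `trace` (data.frame of
#'   step, candidate, objective, kept).
#' @export
af_select <- function(candidates, fluor_endmembers, unstained,
                      max_af = 12, tol = 0.05) {
  if (nrow(unstained$raw) == 0) stop("unstained sample is empty")
  trace <- data.frame(step = integer(), candidate = character(),
                      objective = numeric(), kept = logical(),
                      stringsAsFactors = FALSE)
  if (!length(candidates))
    return(structure(list(members = character(), signatures = list(),
                          objective = NA_real_, trace = trace,
                          note = "no candidates supplied"),
                     class = "af_selection"))
  Ef <- signature_columns(fluor_endmembers)
  nf <- ncol(Ef)
  Y <- t(unstained$raw)
  obj_for <- function(af_cols) {
    M <- if (length(af_cols)) cbind(Ef, af_cols) else Ef
    qrM <- qr(M)
    if (qrM$rank < ncol(M)) return(Inf)
    A <- qr.coef(qrM, Y)                 # endmembers x events
    mean(abs(A[seq_len(nf), , drop = FALSE]))
  }
  pool <- candidates
  chosen <- list()
  cur_cols <- NULL
  cur_obj <- obj_for(NULL)
  step <- 0L
  while (length(chosen) < max_af && length(pool)) {
    step <- step + 1L
    objs <- vapply(pool, function(c) {
      col <- matrix(sig_values(c$signature), ncol = 1,
                    dimnames = list(NULL, c$id))
      obj_for(cbind(cur_cols, col))
    }, numeric(1))
    best <- which.min(objs)
    rel <- (cur_obj - objs[best]) / max(cur_obj, .Machine$double.eps)
    kept <- is.finite(objs[best]) && rel >= tol
    trace <- rbind(trace, data.frame(step = step,
                                     candidate = pool[[best]]$id,
                                     objective = objs[best],
                                     kept = kept))
    if (!kept) break
    cur_cols <- cbind(cur_cols,
                      matrix(sig_values(pool[[best]]$signature), ncol = 1,
                             dimnames = list(NULL, pool[[best]]$id)))
    cur_obj <- objs[best]
    chosen[[length(chosen) + 1L]] <- pool[[best]]
    pool <- pool[-best]
  }
  structure(list(members = vapply(chosen, function(c) c$id, character(1)),
                 signatures = lapply(chosen, function(c) c$signature),
                 objective = cur_obj, trace = trace),
            class = "af_selection")
}

#' @export
print.af_selection <- function(x, ...) {
  cat("<af_selection> ", length(x$members), " AF signature(s)", sep = "")
  if (length(x$members))
    cat(": ", paste(x$members, collapse = ", "), sep = "")
  cat(" (final background bias ", format(x$objective, digits = 4), ")\n",
      sep = "")
  invisible(x)
}
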