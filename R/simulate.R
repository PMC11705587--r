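#' Noise model of the synthetic acquisition
#'
#' Detector noise is modelled as Gaussian with variance
#' `shot_coefficient * mean signal` (the Gaussian limit of Poisson shot
#' noise) plus an additive electronic component with standard deviation
#' `electronic_sd` (a scalar, or one value per detector for
#' heteroscedastic electronics).  Biological variation in expression is a
#' log-normal multiplier with coefficient of variation `abundance_cv`.
#' Setting all three to zero yields exactly deterministic signals.
#'
#' @param shot_coefficient non-negative real; detector variance per unit
#'   of mean signal.
#' @param electronic_sd non-negative real (or vector, one per detector).
#' @param abundance_cv non-negative coefficient of variation of per-event
#'   expression.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(shot_coefficient = 0.02, electronic_sd = 0.5,
                        abundance_cv = 0.25) {
  stopifnot(shot_coefficient >= 0, all(electronic_sd >= 0),
            abundance_cv >= 0)
  structure(list(shot_coefficient = shot_coefficient,
                 electronic_sd = electronic_sd,
                 abundance_cv = abundance_cv),
            class = "noise_model")
}

#' Event-level cytometry table
#'
#' Raw detector intensities plus scatter channels per event, with
#' optional ground-truth population labels and endmember abundances from
#' the generator.
#'
#' @param raw numeric matrix, events x detectors, non-negative; columns
#'   named by detector.
#' @param scatter data.frame with columns `FSC-A`, `SSC-A`, `FSC-H`
#'   (convention: `FSC-H <= FSC-A`, doublets inflate the area term).
#' @param truth_labels optional character vector of population names.
#' @param truth_abundances optional events x endmembers matrix.
#' @param alive optional logical vector (live/dead ground truth).
#' @param seed integer recorded for reproducibility.
#' @param layout a [detector_layout()].
#' @return An object of class `event_table`.
#' @export
event_table <- function(raw, scatter, truth_labels = NULL,
                        truth_abundances = NULL, alive = NULL,
                        seed = NA_integer_, layout = detector_layout()) {
  raw <- as.matrix(raw)
  if (ncol(raw) != layout$n)
    stop("raw has ", ncol(raw), " detector columns; layout expects ", layout$n)
  colnames(raw) <- layout$detectors
  n <- nrow(raw)
  stopifnot(is.data.frame(scatter), nrow(scatter) == n,
            all(scatter_channels() %in% colnames(scatter)))
  if (!is.null(truth_labels) && length(truth_labels) != n)
    stop("truth_labels length mismatch")
  if (!is.null(truth_abundances) && nrow(truth_abundances) != n)
    stop("truth_abundances row mismatch")
  if (!is.null(alive) && length(alive) != n)
    stop("alive length mismatch")
  structure(list(raw = raw, scatter = scatter, truth_labels = truth_labels,
                 truth_abundances = truth_abundances, alive = alive,
                 seed = seed, layout = layout),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> ", nrow(x$raw), " events x ", ncol(x$raw),
      " detectors (+", paste(scatter_channels(), collapse = "/"), ")",
      sep = "")
  if (!is.null(x$truth_labels))
    cat("; ", length(unique(x$truth_labels)), " truth populations", sep = "")
  cat("; seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$raw)

## subset an event table by event index
subset_events <- function(x, idx) {
  event_table(x$raw[idx, , drop = FALSE], x$scatter[idx, , drop = FALSE],
              truth_labels = x$truth_labels[idx],
              truth_abundances = if (!is.null(x$truth_abundances))
                x$truth_abundances[idx, , drop = FALSE],
              alive = x$alive[idx], seed = x$seed, layout = x$layout)
}

## one skewed emission peak inside a laser block: Gaussian rise, wider
## red-shifted tail
.peak_shape <- function(size, peak, sig_l, sig_r) {
  o <- seq_len(size) - peak
  ifelse(o <= 0, exp(-o^2 / (2 * sig_l^2)), exp(-o^2 / (2 * sig_r^2)))
}

## draw one fluorochrome spectrum with a given dominant global detector
.draw_fluor_spectrum <- function(dominant, layout) {
  blocks <- split(seq_len(layout$n), rep(seq_along(layout$lasers), layout$lasers))
  home <- which(vapply(blocks, function(b) dominant %in% b, logical(1)))
  v <- numeric(layout$n)
  sig_l <- stats::runif(1, 0.8, 1.5)
  sig_r <- stats::runif(1, 1.5, 3.5)
  hsize <- length(blocks[[home]])
  hpeak <- dominant - blocks[[home]][1] + 1
  rel <- if (hsize > 1) (hpeak - 1) / (hsize - 1) else 0
  for (b in seq_along(blocks)) {
    size <- length(blocks[[b]])
    if (b == home) {
      v[blocks[[b]]] <- .peak_shape(size, hpeak, sig_l, sig_r)
    } else {
      cross <- stats::runif(1, 0.02, 0.45)
      peak <- round(rel * (size - 1)) + 1
      v[blocks[[b]]] <- cross * .peak_shape(size, peak, sig_l, sig_r)
    }
  }
  v
}

## draw one broad multi-laser autofluorescence spectrum
.draw_af_spectrum <- function(layout) {
  x <- seq_len(layout$n)
  v <- rep(0.05, layout$n)
  for (m in seq_len(sample(2:3, 1))) {
    ctr <- stats::runif(1, 1, layout$n)
    wid <- stats::runif(1, 6, 18)
    amp <- stats::runif(1, 0.5, 1)
    v <- v + amp * exp(-(x - ctr)^2 / (2 * wid^2))
  }
  v
}

#' Generate synthetic endmember spectra
#'
#' Fluorochrome spectra are smooth, per-laser unimodal peaks with a
#' distinct dominant detector each and laser-dependent cross-excitation;
#' autofluorescence (AF) spectra are broad humps spanning several lasers.
#' Spectra are redrawn until all pairwise fluorochrome similarities are
#' below `max_similarity` (AF spectra are held below 0.90 among
#' themselves; AF-fluorochrome overlap is unrestricted, as it is in real
#' tissue).  Deterministic given `seed`.
#'
#' @param n_fluorochromes number of fluorochrome endmembers (>= 1).
#' @param n_af number of AF endmembers (>= 0).
#' @param layout a [detector_layout()].
#' @param seed integer seed.
#' @param names,af_names optional identifier vectors.
#' @param max_similarity pairwise similarity cap enforced by redrawing.
#' @param max_tries redraw budget per spectrum before a capacity error.
#' @return Named list of `n_fluorochromes + n_af` unit-norm
#'   [spectral_signature()]s (fluorochromes first).
#' @export
make_endmember_spectra <- function(n_fluorochromes, n_af = 0,
                                   layout = detector_layout(), seed = 1,
                                   names = NULL, af_names = NULL,
                                   max_similarity = 0.95, max_tries = 400) {
  stopifnot(n_fluorochromes >= 1, n_af >= 0)
  if (n_fluorochromes > layout$n)
    stop("cannot place ", n_fluorochromes, " distinct emission peaks in a ",
         layout$n, "-detector layout")
  if (is.null(names)) names <- sprintf("FL%02d", seq_len(n_fluorochromes))
  if (is.null(af_names))
    af_names <- if (n_af > 0) paste0("AF-", letters[seq_len(n_af)]) else character()
  stopifnot(length(names) == n_fluorochromes, length(af_names) == n_af)

  with_seed(seed, {
    ## evenly spread dominant detectors with jitter, kept distinct
    dom <- round(seq(2, layout$n - 1, length.out = n_fluorochromes))
    dom <- dom + sample(c(-1L, 0L, 1L), n_fluorochromes, replace = TRUE)
    dom <- pmin(pmax(dom, 1L), layout$n)
    while (anyDuplicated(dom))
      dom[duplicated(dom)] <- sample(setdiff(seq_len(layout$n), dom),
                                     sum(duplicated(dom)))
    vals <- vector("list", n_fluorochromes)
    for (i in seq_len(n_fluorochromes)) {
      tries <- 0L
      repeat {
        cand <- .draw_fluor_spectrum(dom[i], layout)
        ok <- TRUE
        for (j in seq_len(i - 1L))
          if (similarity_index(cand, vals[[j]]) >= max_similarity) {
            ok <- FALSE; break
          }
        if (ok) break
        tries <- tries + 1L
        if (tries > max_tries)
          stop("capacity error: cannot place ", n_fluorochromes,
               " spectra with pairwise similarity < ", max_similarity)
        if (tries %% 50L == 0L) {          # shift the peak as a last resort
          free <- setdiff(seq_len(layout$n), dom)
          if (length(free)) dom[i] <- sample(free, 1L)
        }
      }
      vals[[i]] <- cand
    }
    afv <- vector("list", n_af)
    for (i in seq_len(n_af)) {
      tries <- 0L
      repeat {
        cand <- .draw_af_spectrum(layout)
        ok <- all(vapply(afv[seq_len(i - 1L)],
                         function(p) similarity_index(cand, p) < 0.90,
                         logical(1)))
        if (ok) break
        tries <- tries + 1L
        if (tries > max_tries)
          stop("capacity error: cannot draw ", n_af, " distinct AF spectra")
      }
      afv[[i]] <- cand
    }
    bright <- stats::rlnorm(n_fluorochromes + n_af, log(5e4), 0.5)
    out <- c(
      lapply(seq_len(n_fluorochromes), function(i) {
        s <- normalize_signature(vals[[i]], "unit", name = names[i],
                                 layout = layout)
        s$peak_intensity <- bright[i]
        s
      }),
      lapply(seq_len(n_af), function(i) {
        s <- normalize_signature(afv[[i]], "unit", name = af_names[i],
                                 layout = layout)
        s$peak_intensity <- bright[n_fluorochromes + i]
        s
      }))
    stats::setNames(out, c(names, af_names))
  })
}

## endmember list -> detectors x endmembers matrix of unit-norm columns
signature_columns <- function(signatures, layout = NULL) {
  layout <- layout %||% signatures[[1]]$layout
  V <- vapply(signatures, function(s) {
    v <- sig_values(s)
    n <- sqrt(sum(v^2))
    if (n > 0) v / n else v
  }, numeric(layout$n))
  rownames(V) <- layout$detectors
  colnames(V) <- vapply(signatures, function(s)
    if (inherits(s, "spectral_signature")) s$name else "", character(1))
  V
}

## draw per-event abundance matrix for one stratum of events
.abundances_for <- function(profile, markers, panel, n, noise, background) {
  lm <- level_means(background)
  A <- matrix(0, n, length(markers),
              dimnames = list(NULL, marker_to_fluor(panel, markers)))
  for (k in seq_along(markers)) {
    mu <- lm[[profile$marker_levels[[markers[k]]]]]
    A[, k] <- rlnorm_mean_cv(n, mu, noise$abundance_cv)
  }
  A
}

## add detector noise to a non-negative mean-signal matrix
.add_detector_noise <- function(mean_raw, noise) {
  elec <- noise$electronic_sd
  if (length(elec) == 1L) elec <- rep(elec, ncol(mean_raw))
  if (noise$shot_coefficient == 0 && all(elec == 0)) return(mean_raw)
  sd <- sqrt(noise$shot_coefficient * pmax(mean_raw, 0) +
               matrix(elec^2, nrow(mean_raw), ncol(mean_raw), byrow = TRUE))
  pmax(mean_raw + stats::rnorm(length(mean_raw)) * sd, 0)
}

## reference side scatter for the AF/SSC linear link
.SSC_REF <- 5e4

## truncated normal draws (+- k sigma): scatter strata are bounded, so
## quantile-derived scatter gates can sit in true gaps between strata
.rtrunc_norm <- function(n, mean, sd, k = 2.5) {
  z <- pmin(pmax(stats::rnorm(n), -k), k)
  pmax(mean + sd * z, 1)
}

#' Simulate a fully stained multi-population sample
#'
#' Per event: a population is drawn from `weights`; each fluorochrome
#' abundance is a level-dependent log-normal draw (neg/low/pos/hi at 1,
#' 10, 100, 1000 times background); AF abundance is the profile's AF
#' weight scaled linearly by the event's SSC-A (so scatter-based AF
#' dissection is meaningful); the raw signal is `endmembers x abundance`
#' plus shot and electronic noise.  A `1 - viability` fraction of each
#' population is marked dead and given a bright viability-dye signal.
#' Doublets inflate FSC-A relative to FSC-H.  Truth labels and abundances
#' are stored; the result is deterministic given `seed`.
#'
#' @param profiles list of [population_profile()]s.
#' @param endmembers named list of [spectral_signature()]s covering every
#'   panel fluorochrome and every AF name used by the profiles.
#' @param panel a [panel_config()].
#' @param n number of events.
#' @param weights mixing proportions (default equal), summing to 1.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param background background abundance of the `neg` level.
#' @param doublet_rate fraction of events with doublet scatter.
#' @return An [event_table()] with truth labels, truth abundances and the
#'   live/dead flag.
#' @export
simulate_sample <- function(profiles, endmembers, panel = default_lung_panel(),
                            n = 20000, weights = NULL,
                            noise = noise_model(), seed = 1,
                            background = 1, doublet_rate = 0.01) {
  stopifnot(n >= 1)
  np <- length(profiles)
  if (is.null(weights)) weights <- rep(1 / np, np)
  if (length(weights) != np)
    stop("weights length ", length(weights), " does not match ",
         np, " profiles")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")

  markers <- panel$entries$marker
  fluors <- panel$entries$fluorochrome
  af_names <- unique(unlist(lapply(profiles, function(p) names(p$af_weights))))
  af_names <- af_names[!is.na(af_names)]
  missing <- setdiff(c(fluors, af_names), names(endmembers))
  if (length(missing))
    stop("endmembers missing for: ", paste(missing, collapse = ", "))
  layout <- endmembers[[1]]$layout
  E <- signature_columns(endmembers[c(fluors, af_names)], layout)

  with_seed(seed, {
    pop <- sample(np, n, replace = TRUE, prob = weights)
    pnames <- vapply(profiles, function(p) p$name, character(1))
    A <- matrix(0, n, length(c(fluors, af_names)),
                dimnames = list(NULL, c(fluors, af_names)))
    fsc <- ssc <- numeric(n)
    alive <- logical(n)
    for (k in seq_len(np)) {
      idx <- which(pop == k)
      if (!length(idx)) next
      p <- profiles[[k]]
      A[idx, fluors] <- .abundances_for(p, markers, panel, length(idx),
                                        noise, background)
      fsc[idx] <- .rtrunc_norm(length(idx), p$scatter$fsc_mean,
                               p$scatter$fsc_sd)
      ssc[idx] <- .rtrunc_norm(length(idx), p$scatter$ssc_mean,
                               p$scatter$ssc_sd)
      alive[idx] <- stats::runif(length(idx)) < p$viability
      for (a in af_names) {
        w <- if (a %in% names(p$af_weights)) p$af_weights[[a]] else 0
        if (w > 0)
          A[idx, a] <- rlnorm_mean_cv(length(idx), w, noise$abundance_cv) *
            ssc[idx] / .SSC_REF
      }
    }
    ## dead cells take up the viability dye
    viab <- panel$viability_channel
    if (any(!alive))
      A[!alive, viab] <- rlnorm_mean_cv(sum(!alive),
                                        level_means(background)[["hi"]],
                                        noise$abundance_cv)
    ## scatter height: singlets have FSC-H ~ FSC-A; doublets inflate area
    ratio <- pmin(.rtrunc_norm(n, 0.97, 0.015), 1)
    if (doublet_rate > 0) {
      dbl <- stats::runif(n) < doublet_rate
      ratio[dbl] <- pmin(.rtrunc_norm(sum(dbl), 0.55, 0.04), 1)
      fsc[dbl] <- fsc[dbl] * 1.8
    }
    fsch <- fsc * ratio
    raw <- .add_detector_noise(A %*% t(E), noise)
    event_table(raw,
                data.frame(`FSC-A` = fsc, `SSC-A` = ssc, `FSC-H` = fsch,
                           check.names = FALSE),
                truth_labels = unname(pnames[pop]), truth_abundances = A,
                alive = alive, seed = seed, layout = layout)
  })
}

#' Simulate an unstained sample
#'
#' As [simulate_sample()] but with every fluorochrome abundance at zero:
#' the signal is autofluorescence plus noise only.  High-AF populations
#' carry high side scatter by construction, so the scatter-based AF
#' dissection has structure to find.
#'
#' @inheritParams simulate_sample
#' @param af_endmembers named list of AF [spectral_signature()]s (may be
#'   empty for the AF-free edge case).
#' @return An [event_table()]; truth abundances cover the AF endmembers.
#' @export
simulate_unstained <- function(profiles, af_endmembers,
                               noise = noise_model(), n = 5000, seed = 1,
                               layout = detector_layout()) {
  stopifnot(n >= 1)
  np <- length(profiles)
  af_names <- names(af_endmembers) %||% character()
  if (length(af_endmembers)) layout <- af_endmembers[[1]]$layout
  E <- if (length(af_endmembers))
    signature_columns(af_endmembers, layout) else
    matrix(0, layout$n, 0)

  with_seed(seed, {
    pop <- sample(np, n, replace = TRUE)
    pnames <- vapply(profiles, function(p) p$name, character(1))
    A <- matrix(0, n, length(af_names), dimnames = list(NULL, af_names))
    fsc <- ssc <- numeric(n)
    for (k in seq_len(np)) {
      idx <- which(pop == k)
      if (!length(idx)) next
      p <- profiles[[k]]
      fsc[idx] <- .rtrunc_norm(length(idx), p$scatter$fsc_mean,
                               p$scatter$fsc_sd)
      ssc[idx] <- .rtrunc_norm(length(idx), p$scatter$ssc_mean,
                               p$scatter$ssc_sd)
      for (a in af_names) {
        w <- if (a %in% names(p$af_weights)) p$af_weights[[a]] else 0
        if (w > 0)
          A[idx, a] <- rlnorm_mean_cv(length(idx), w, noise$abundance_cv) *
            ssc[idx] / .SSC_REF
      }
    }
    mean_raw <- if (ncol(A)) A %*% t(E) else matrix(0, n, layout$n)
    raw <- .add_detector_noise(mean_raw, noise)
    fsch <- fsc * pmin(.rtrunc_norm(n, 0.97, 0.015), 1)
    event_table(raw,
                data.frame(`FSC-A` = fsc, `SSC-A` = ssc, `FSC-H` = fsch,
                           check.names = FALSE),
                truth_labels = unname(pnames[pop]), truth_abundances = A,
                alive = rep(TRUE, n), seed = seed, layout = layout)
  })
}

#' Perturb a signature's spectral shape
#'
#' Multiplies the spectrum by a smooth random curve of the given relative
#' strength (a low-order cosine expansion), renormalizes, and returns the
#' perturbed signature.  Used to emulate fluorochromes whose emission
#' differs on cells versus beads.
#'
#' @param sig a [spectral_signature()].
#' @param strength relative perturbation amplitude.
#' @param seed integer seed (deterministic perturbation).
#' @return A unit-norm [spectral_signature()].
#' @export
perturb_signature <- function(sig, strength = 0.15, seed = 1) {
  with_seed(seed, {
    x <- seq(0, 1, length.out = length(sig$values))
    curve <- numeric(length(x))
    for (h in 1:3)
      curve <- curve + stats::rnorm(1) * cos(pi * h * x + stats::runif(1, 0, pi))
    curve <- curve / max(abs(curve))
    v <- pmax(sig$values * (1 + strength * curve), 0)
    out <- normalize_signature(v, "unit", name = sig$name, layout = sig$layout)
    out$peak_intensity <- sig$peak_intensity
    out
  })
}

#' Default fluorochromes whose on-cell spectra differ from beads
#'
#' @return Character vector of channel names.
#' @export
default_perturbed_channels <- function() c("PE-Fire810", "APC", "AF700")

#' On-cell variants of a set of endmember spectra
#'
#' Returns the endmember list with the designated channels replaced by
#' their cell-perturbed spectra, emulating conjugates whose emission
#' changes when bound to cells instead of beads.
#'
#' @param endmembers named list of [spectral_signature()]s.
#' @param perturbed channel names to perturb.
#' @param strength perturbation amplitude.
#' @param seed integer seed.
#' @return Named list of signatures.
#' @export
cell_spectra <- function(endmembers,
                         perturbed = default_perturbed_channels(),
                         strength = 0.15, seed = 101) {
  perturbed <- intersect(perturbed, names(endmembers))
  for (i in seq_along(perturbed)) {
    f <- perturbed[i]
    endmembers[[f]] <- perturb_signature(endmembers[[f]], strength,
                                         seed = sub_seed(seed, i))
  }
  endmembers
}

#' Simulate single-stain unmixing controls
#'
#' One control sample per panel fluorochrome, each containing a bright
#' positive population (`positive_fraction` of events) and a negative
#' population.  With `carrier = "cells"` the designated channels use
#' their cell-perturbed spectra and every event carries autofluorescence
#' background; `carrier = "beads"` uses unperturbed spectra and no AF.
#'
#' @inheritParams simulate_sample
#' @param carrier `"beads"` or `"cells"`.
#' @param n_events events per control.
#' @param positive_fraction fraction of stained-positive events.
#' @param positive_mean mean abundance of the positive population.
#' @param perturbed channels perturbed on cells.
#' @param perturb_seed seed of the on-cell spectral shift; this is dye
#'   chemistry, not acquisition noise, so it defaults to the same fixed
#'   value everywhere — a simulated biological sample built from
#'   [cell_spectra()] with the default seed carries exactly the spectra
#'   the cell-carrier controls see.
#' @param af_endmembers AF signatures for the cell-carrier background.
#' @param af_weight mean AF abundance on cells.
#' @return Named list (one [event_table()] per fluorochrome); each table
#'   carries the spectrum actually used in attribute `"true_signature"`.
#' @export
simulate_single_stain_controls <- function(panel, endmembers,
                                           carrier = c("beads", "cells"),
                                           noise = noise_model(), seed = 1,
                                           n_events = 2000,
                                           positive_fraction = 0.5,
                                           positive_mean = 500,
                                           perturbed = default_perturbed_channels(),
                                           perturb_seed = 101,
                                           af_endmembers = NULL,
                                           af_weight = 30) {
  carrier <- match.arg(carrier)
  fluors <- panel$entries$fluorochrome
  missing <- setdiff(fluors, names(endmembers))
  if (length(missing))
    stop("no endmember for fluorochrome(s): ", paste(missing, collapse = ", "))
  layout <- endmembers[[1]]$layout
  use <- endmembers[fluors]
  if (carrier == "cells")
    use <- cell_spectra(use, perturbed = perturbed, seed = perturb_seed)
  afE <- if (carrier == "cells" && length(af_endmembers))
    signature_columns(af_endmembers, layout) else NULL

  out <- vector("list", length(fluors))
  names(out) <- fluors
  for (i in seq_along(fluors)) {
    f <- fluors[i]
    sig <- use[[f]]
    out[[f]] <- with_seed(sub_seed(seed, i), {
      npos <- max(1L, round(n_events * positive_fraction))
      a <- c(rlnorm_mean_cv(npos, positive_mean, noise$abundance_cv),
             rep(0, n_events - npos))
      mean_raw <- outer(a, sig$values)
      if (!is.null(afE)) {
        af_a <- rlnorm_mean_cv(n_events, af_weight, noise$abundance_cv)
        mean_raw <- mean_raw + outer(af_a, rowMeans(afE))
      }
      raw <- .add_detector_noise(mean_raw, noise)
      fsc <- if (carrier == "beads") pmax(stats::rnorm(n_events, 4e4, 2e3), 1)
             else pmax(stats::rnorm(n_events, 7e4, 9e3), 1)
      ssc <- if (carrier == "beads") pmax(stats::rnorm(n_events, 3e4, 2e3), 1)
             else pmax(stats::rnorm(n_events, 5e4, 9e3), 1)
      tab <- event_table(raw,
                         data.frame(`FSC-A` = fsc, `SSC-A` = ssc,
                                    `FSC-H` = fsc * 0.97, check.names = FALSE),
                         truth_labels = rep(c("positive", "negative"),
                                            c(npos, n_events - npos)),
                         truth_abundances = matrix(a, ncol = 1,
                                                   dimnames = list(NULL, f)),
                         alive = rep(TRUE, n_events),
                         seed = sub_seed(seed, i), layout = layout)
      attr(tab, "true_signature") <- sig
      tab
    })
  }
  out
}
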