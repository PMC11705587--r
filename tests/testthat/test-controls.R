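test_that("extract_signature recovers planted endmembers from beads", {
  endm <- fx_endmembers()
  some <- c("BUV395", "FITC", "PE", "APC", "ZombieUV")
  for (sd in c(1, 2)) {
    beads <- simulate_single_stain_controls(fx_panel(), endm[fx_fluors()],
                                            "beads", seed = sd,
                                            n_events = 800)
    for (f in some) {
      sig <- extract_signature(beads[[f]], control_blank(beads[[f]]),
                               name = f)
      expect_gte(similarity_index(sig, endm[[f]]), 0.999)
    }
  }
})

test_that("extract_signature is stable in the positive fraction", {
  endm <- fx_endmembers()
  beads <- simulate_single_stain_controls(fx_panel(), endm[fx_fluors()],
                                          "beads", seed = 5, n_events = 800)
  blank <- control_blank(beads[["PE-Cy5"]])
  a <- extract_signature(beads[["PE-Cy5"]], blank, positive_fraction = 0.5)
  b <- extract_signature(beads[["PE-Cy5"]], blank, positive_fraction = 0.2)
  expect_gte(similarity_index(a, b), 0.99)
})

test_that("extract_signature flags degenerate and undersized input", {
  endm <- fx_endmembers()
  beads <- simulate_single_stain_controls(fx_panel(), endm[fx_fluors()],
                                          "beads", seed = 6, n_events = 400)
  ctl <- beads[["FITC"]]
  ## a control identical to its background yields an all-zero signature
  blank <- control_blank(ctl, fraction = 0.4)
  expect_warning(sig <- extract_signature(blank, blank),
                 "indistinguishable")
  expect_equal(max(sig$values), 0)
  tiny <- lungspectral:::subset_events(ctl, 1:50)
  expect_error(extract_signature(tiny, blank), "insufficient")
  expect_error(extract_signature(ctl, blank, positive_fraction = 0.9),
               "positive_fraction")
})

test_that("stain index follows its defining formula and invariances", {
  set.seed(8)
  pos <- rnorm(500, 1000, 80)
  neg <- rnorm(500, 100, 50)
  ## oracle: direct formula with robust estimators
  oracle <- (median(pos) - median(neg)) / (2 * mad(neg))
  expect_equal(stain_index(pos, neg), oracle, tolerance = 1e-12)
  ## same distribution -> index near zero
  expect_lt(abs(stain_index(neg, neg)), 1e-12)
  ## adding a common constant changes nothing
  expect_equal(stain_index(pos + 123, neg + 123), oracle,
               tolerance = 1e-10)
  ## scaling the negative spread by k at fixed medians scales index by 1/k
  neg_wide <- median(neg) + 2 * (neg - median(neg))
  expect_equal(stain_index(pos, neg_wide), oracle / 2, tolerance = 1e-10)
  expect_warning(si <- stain_index(pos, rep(5, 20)), "zero robust SD")
  expect_identical(si, Inf)
  expect_error(stain_index(pos[1:5], neg), "at least 10")
})

test_that("spread matrix is zero without noise and grows with shot noise", {
  ## 5-endmember toy panel with one spectrally close pair
  lay <- detector_layout(c(A = 12L))
  base <- list(c(5, 3, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0),
               c(4.5, 3.4, 1.2, 0.2, 0, 0, 0, 0, 0, 0, 0, 0),  # close to #1
               c(0, 0, 0, 5, 3, 1, 0, 0, 0, 0, 0, 0),
               c(0, 0, 0, 0, 0, 0, 5, 3, 1, 0, 0, 0),
               c(0, 0, 0, 0, 0, 0, 0, 0, 0, 5, 3, 1))
  sigs <- lapply(seq_along(base), function(i)
    normalize_signature(base[[i]], "unit", name = paste0("F", i),
                        layout = lay))
  names(sigs) <- paste0("F", 1:5)
  sim <- similarity_matrix(sigs)$values
  expect_gt(sim["F1", "F2"], 0.8)
  m <- build_mixing_matrix(sigs)

  make_controls <- function(shot, seed) {
    lapply(stats::setNames(1:5, names(sigs)), function(i) {
      with_seed <- lungspectral:::with_seed
      with_seed(seed + i, {
        a <- c(rlnorm(300, log(500), 0.2), rep(0, 300))
        mean_raw <- outer(a, sigs[[i]]$values)
        noise_sd <- sqrt(shot * pmax(mean_raw, 0) + 0.25)
        raw <- pmax(mean_raw + rnorm(length(mean_raw)) * noise_sd, 0)
        unmix(raw, m)
      })
    })
  }
  ## zero noise: all spread entries vanish
  un0 <- lapply(stats::setNames(1:5, names(sigs)), function(i) {
    a <- c(rep(500, 300), rep(0, 300))
    unmix(outer(a, sigs[[i]]$values), m)
  })
  S0 <- spread_matrix(un0)
  expect_equal(max(abs(S0)), 0, tolerance = 1e-8)
  expect_equal(unname(diag(S0)), rep(0, 5))

  ## raising the shot coefficient raises total spread on paired seeds
  S_lo <- spread_matrix(make_controls(0.05, seed = 11))
  S_hi <- spread_matrix(make_controls(0.5, seed = 11))
  expect_gt(sum(S_hi), sum(S_lo))

  ## the spectrally close pair dominates the off-diagonal spread
  off <- S_hi; diag(off) <- 0
  top <- which(off == max(off), arr.ind = TRUE)[1, ]
  expect_setequal(rownames(off)[top], c("F1", "F2"))

  expect_error(spread_matrix(un0, fluors = c("F1", "F9")), "missing")
})

test_that("carrier choice follows spread with a stain-index tie break", {
  mk_qc <- function(spread_total, stain, carrier) {
    k <- length(spread_total)
    S <- diag(0, k); S[, 1] <- 0
    for (i in seq_len(k)) S[i, (i %% k) + 1] <- spread_total[i]
    dimnames(S) <- list(names(spread_total), names(spread_total))
    structure(list(stain_indices = stain, spread = S, carrier = carrier,
                   notes = character()), class = "qc_report")
  }
  fl <- c(A = 0.1, B = 0.5, C = 0.3)
  bead <- mk_qc(fl, c(A = 5, B = 5, C = 2), "beads")
  cell <- mk_qc(c(A = 0.5, B = 0.1, C = 0.3), c(A = 4, B = 6, C = 9),
                "cells")
  cc <- choose_carrier(bead, cell)
  expect_equal(cc$carrier[cc$fluorochrome == "A"], "beads")
  expect_equal(cc$carrier[cc$fluorochrome == "B"], "cells")
  ## equal spread: the higher stain index wins
  expect_equal(cc$carrier[cc$fluorochrome == "C"], "cells")
  bad <- mk_qc(c(A = 1, Z = 1), c(A = 1, Z = 1), "cells")
  expect_error(choose_carrier(bead, bad), "different fluorochromes")
})

test_that("cells are chosen for channels whose on-cell spectra shift", {
  endm <- fx_endmembers()
  fl <- fx_fluors()
  af <- endm[default_af_names()]
  beads <- simulate_single_stain_controls(fx_panel(), endm[fl], "beads",
                                          seed = 21, n_events = 800)
  cells <- simulate_single_stain_controls(fx_panel(), endm[fl], "cells",
                                          seed = 22, n_events = 800,
                                          af_endmembers = af)
  bead_sigs <- lapply(stats::setNames(fl, fl), function(f)
    extract_signature(beads[[f]], control_blank(beads[[f]]), name = f))
  cell_sigs <- lapply(stats::setNames(fl, fl), function(f)
    extract_signature(cells[[f]], control_blank(cells[[f]]), name = f))
  cc <- choose_carrier(
    qc_report(cells, build_mixing_matrix(bead_sigs), "beads"),
    qc_report(cells, build_mixing_matrix(cell_sigs), "cells"))
  for (f in default_perturbed_channels())
    expect_equal(cc$carrier[cc$fluorochrome == f], "cells")
  ## most unperturbed channels keep beads
  expect_gt(sum(cc$carrier == "beads"), 20)
})
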