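test_that("dissection partitions the scatter plane into 35 candidates", {
  af <- fx_endmembers()[default_af_names()]
  un <- simulate_unstained(fx_profiles(), af, n = 4000, seed = 17)
  cand <- af_dissect(un, grid = c(7, 5))
  expect_length(cand, 35)
  expect_equal(vapply(cand, `[[`, "", "id"), paste0("AF", 1:35))
  ## partition: bin counts sum to the number of events
  expect_equal(sum(vapply(cand, `[[`, 0L, "event_count")), 4000)
  ## deterministic re-run
  cand2 <- af_dissect(un, grid = c(7, 5))
  expect_identical(lapply(cand, function(c) c$signature$values),
                   lapply(cand2, function(c) c$signature$values))
  expect_error(af_dissect(lungspectral:::subset_events(un, 1)), "insufficient")
})

test_that("a 2x2 grid on well-separated clusters recovers each cluster", {
  af <- fx_endmembers()[default_af_names()]
  ## four scatter clusters, each carrying one pure AF mixture
  pr <- list(
    population_profile("c1", stats::setNames("neg", "CD45"),
                       c("AF-lym" = 200, "AF-mye" = 0, "AF-amo" = 0),
                       list(fsc_mean = 3e4, fsc_sd = 2e3,
                            ssc_mean = 3e4, ssc_sd = 2e3)),
    population_profile("c2", stats::setNames("neg", "CD45"),
                       c("AF-lym" = 0, "AF-mye" = 200, "AF-amo" = 0),
                       list(fsc_mean = 3e4, fsc_sd = 2e3,
                            ssc_mean = 1.5e5, ssc_sd = 2e3)),
    population_profile("c3", stats::setNames("neg", "CD45"),
                       c("AF-lym" = 0, "AF-mye" = 0, "AF-amo" = 200),
                       list(fsc_mean = 1.5e5, fsc_sd = 2e3,
                            ssc_mean = 3e4, ssc_sd = 2e3)),
    population_profile("c4", stats::setNames("neg", "CD45"),
                       c("AF-lym" = 100, "AF-mye" = 100, "AF-amo" = 0),
                       list(fsc_mean = 1.5e5, fsc_sd = 2e3,
                            ssc_mean = 1.5e5, ssc_sd = 2e3)))
  un <- simulate_unstained(pr, af, n = 4000, seed = 19)
  cand <- af_dissect(un, grid = c(2, 2))
  expect_length(cand, 4)
  ## oracle: each cluster's truth mixture spectrum
  E <- vapply(af, function(s) s$values / sqrt(sum(s$values^2)), numeric(64))
  for (cl in pr) {
    idx <- un$truth_labels == cl$name
    mixture <- E %*% colMeans(un$truth_abundances[idx, , drop = FALSE])
    best <- max(vapply(cand, function(c)
      similarity_index(c$signature, mixture), numeric(1)))
    expect_gte(best, 0.99)
  }
})

test_that("pruning keeps the brighter of near-duplicates, order-free", {
  af <- fx_endmembers()[default_af_names()]
  mk_cand <- function(id, sig, intensity, count = 100)
    structure(list(id = id, bin = NULL, signature = sig,
                   event_count = count, mean_total_intensity = intensity),
              class = "af_candidate")
  a5 <- mk_cand("bright", af[[1]], 5)
  a3 <- mk_cand("dim", af[[1]], 3)
  kept <- af_prune(list(a3, a5), threshold = 0.98)
  expect_equal(vapply(kept, `[[`, "", "id"), "bright")

  ## threshold 1.0 with no exactly proportional pairs keeps everything
  cand3 <- list(mk_cand("x", af[[1]], 3), mk_cand("y", af[[2]], 2),
                mk_cand("z", af[[3]], 1))
  expect_length(af_prune(cand3, threshold = 1.0), 3)

  ## empty bins are dropped first
  empty <- mk_cand("void", af[[2]], 0, count = 0)
  expect_length(af_prune(list(a5, empty), 0.98), 1)

  ## input order does not matter
  k1 <- af_prune(cand3, 0.9)
  k2 <- af_prune(rev(cand3), 0.9)
  expect_identical(vapply(k1, `[[`, "", "id"), vapply(k2, `[[`, "", "id"))
})

test_that("12 planted shapes survive pruning of 35 noisy candidates", {
  lay <- detector_layout()
  shapes <- make_endmember_spectra(1, 12, seed = 31)[-1]
  set.seed(99)
  cand <- lapply(1:35, function(k) {
    base <- shapes[[((k - 1) %% 12) + 1]]
    v <- pmax(base$values + rnorm(64, 0, 0.002), 0)
    structure(list(id = paste0("AF", k), bin = NULL,
                   signature = normalize_signature(v, "unit",
                                                   name = paste0("AF", k),
                                                   layout = lay),
                   event_count = 50,
                   mean_total_intensity = runif(1, 1, 10)),
              class = "af_candidate")
  })
  kept <- af_prune(cand, threshold = 0.98)
  expect_length(kept, 12)
  ## survivors are pairwise below the threshold
  sims <- similarity_matrix(lapply(kept, `[[`, "signature"))$values
  diag(sims) <- 0
  expect_lt(max(sims), 0.98)
})

test_that("greedy selection recovers the planted AF endmembers", {
  endm <- fx_endmembers()
  af <- endm[default_af_names()]
  fluor <- endm[fx_fluors()]
  un <- simulate_unstained(fx_profiles(), af, n = 4000, seed = 23)
  sel <- af_select(af_prune(af_dissect(un), 0.98), fluor, un)
  expect_length(sel$members, 3)
  best <- vapply(sel$signatures, function(s)
    which.max(vapply(af, similarity_index, numeric(1), b = s)), 0L)
  expect_length(unique(best), 3)
  for (s in sel$signatures)
    expect_gte(max(vapply(af, similarity_index, numeric(1), b = s)), 0.98)
  ## the greedy objective decreases along the kept trace
  kept_obj <- sel$trace$objective[sel$trace$kept]
  expect_true(all(diff(kept_obj) < 0))
})

test_that("selection degenerates gracefully", {
  endm <- fx_endmembers()
  af1 <- endm[default_af_names()[3]]
  fluor <- endm[fx_fluors()]
  ## single planted AF -> exactly one selected
  pr1 <- lapply(fx_profiles(), function(p) {
    p$af_weights <- c("AF-amo" = unname(p$af_weights["AF-amo"]) + 50)
    p
  })
  un1 <- simulate_unstained(pr1, af1, n = 3000, seed = 29)
  sel1 <- af_select(af_prune(af_dissect(un1), 0.98), fluor, un1)
  expect_length(sel1$members, 1)
  expect_gte(similarity_index(sel1$signatures[[1]], af1[[1]]), 0.98)

  ## AF-free sample -> empty selection
  pr0 <- lapply(fx_profiles(), function(p) {
    p$af_weights[] <- 0
    p
  })
  un0 <- simulate_unstained(pr0, af1, n = 3000, seed = 30)
  sel0 <- af_select(af_prune(af_dissect(un0), 0.98), fluor, un0)
  expect_length(sel0$members, 0)

  ## no candidates -> empty set with an explanatory trace
  selN <- af_select(list(), fluor, un1)
  expect_length(selN$members, 0)
  expect_match(selN$note, "no candidates")
})
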