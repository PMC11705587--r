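test_that("the lung gate tree has the published structure", {
  tree <- build_lung_gate_tree()
  targets <- gate_targets(tree)
  expect_length(targets, 17)
  expect_setequal(targets, names(fx_profiles()))

  ## 18 antibodies drive the lineage hierarchy, beyond the viability dye,
  ## the CD206/CX3CR1 alternatives and the CD44/CD62L memory markers
  lineage <- gate_markers(tree, exclude = c("Viability", "CD206", "CX3CR1",
                                            "CD44", "CD62L"))
  expect_length(lineage, 18)

  ## path from the Treg gate back to the root
  nodes <- tree$nodes
  names(nodes) <- vapply(nodes, `[[`, "", "name")
  path <- character()
  at <- "treg"
  while (!is.na(at)) {
    path <- c(at, path)
    at <- nodes[[at]]$parent
  }
  expect_equal(path, c("root", "nondebris", "singlets", "live",
                       "leukocytes", "nonneut", "lymphoid", "tcell",
                       "thelper", "treg"))

  ## round-trip through JSON
  p <- withr::local_tempfile(fileext = ".json")
  write_gate_tree(tree, p)
  back <- read_gate_tree(p)
  expect_equal(vapply(back$nodes, `[[`, "", "name"),
               vapply(tree$nodes, `[[`, "", "name"))
  expect_setequal(gate_targets(back), targets)
})

test_that("derived thresholds separate the generator's expression levels", {
  run <- fx_standard_run()
  thr <- run$tree$thresholds
  ## every marker threshold sits strictly between the low and pos decades
  for (ref in c("CD3", "CD19", "CD4", "CD8", "CD64", "CD24", "CD25",
                "CD335", "Ly6C", "CD11b", "CD11c")) {
    expect_gt(thr[[ref]], 10)   # above the "low" level mean
    expect_lt(thr[[ref]], 100)  # below the "pos" level mean
  }
  ## re-derivation on the same reference is identical
  tree2 <- derive_thresholds(build_lung_gate_tree(), run$unmixed,
                             run$sample, fx_profiles(), fx_panel())
  expect_identical(run$tree$thresholds, tree2$thresholds)
})

test_that("identical negative and positive distributions are unresolvable", {
  run <- fx_standard_run()
  ## degenerate profiles: CD3 at the same level everywhere
  pr <- lapply(fx_profiles(), function(p) {
    p$marker_levels["CD3"] <- if (p$marker_levels[["CD3"]] == "pos")
      "pos" else "pos"
    p
  })
  ## half the populations declared negative, but values identical
  pr[1:8] <- lapply(pr[1:8], function(p) {
    p$marker_levels["CD3"] <- "neg"
    p
  })
  mk <- run$unmixed
  ## overwrite the CD3 channel with one shared distribution
  fluor <- lungspectral:::marker_to_fluor(fx_panel(), "CD3")
  mk$abundances[, fluor] <- rnorm(nrow(mk$abundances), 50, 5)
  expect_warning(
    tr <- derive_thresholds(build_lung_gate_tree(), mk, run$sample,
                            pr, fx_panel()),
    "unresolved")
  expect_equal(unname(attr(tr, "flags")["CD3"]), "unresolved")
  expect_error(apply_gates(mk, run$sample, tr, fx_panel()),
               "unresolved")
})

test_that("canonical phenotypes descend to their populations", {
  run <- fx_standard_run()
  tree <- run$tree
  panel <- fx_panel()
  lm <- lungspectral:::level_means()
  mk_event <- function(levels) {
    ab <- matrix(lm[["neg"]], 1, 27,
                 dimnames = list(NULL, panel$entries$fluorochrome))
    for (m in names(levels))
      ab[, lungspectral:::marker_to_fluor(panel, m)] <- lm[[levels[[m]]]]
    sc <- data.frame(`FSC-A` = 7e4, `SSC-A` = 9e4, `FSC-H` = 6.9e4,
                     check.names = FALSE)
    list(ab = ab, sc = sc)
  }
  gate_one <- function(levels, ssc = 9e4) {
    e <- mk_event(levels)
    e$sc[["SSC-A"]] <- ssc
    res <- structure(list(abundances = e$ab), class = "unmix_result")
    ev <- list(scatter = e$sc)
    apply_gates(res, ev, tree, panel)$labels
  }
  expect_equal(gate_one(c(CD45 = "pos", Ly6G = "hi")), "Neutrophil")
  expect_equal(gate_one(c(CD45 = "pos", CD3 = "pos", CD4 = "pos",
                          CD25 = "pos", CD127 = "low")), "Treg")
  expect_equal(gate_one(c(CD45 = "pos", CD3 = "pos", CD8 = "pos")),
               "Cytotoxic T")
  expect_equal(gate_one(c(CD45 = "pos", CD64 = "pos", CD11c = "pos"),
                        ssc = 1.6e5), "Alveolar macrophage")
  expect_equal(gate_one(c(CD45 = "pos", CD11b = "pos", Ly6C = "pos"),
                        ssc = 3e4), "Inflammatory monocyte")
})

test_that("gating on the standard sample is accurate and conservative", {
  run <- fx_standard_run()
  rec <- run$recovery
  expect_gte(rec$accuracy, 0.9)
  ## every truth population's plurality label is itself
  cm <- table(run$sample$truth_labels, run$gates$labels)
  for (p in rownames(cm))
    expect_equal(colnames(cm)[which.max(cm[p, ])], p)

  ## frequency conservation: parent count = sum of non-parallel children
  ## + its unassigned bucket (events in the parent but in no child)
  f <- run$gates$frequency
  member <- run$gates$membership
  kids <- split(seq_len(nrow(f)), f$parent)[!is.na(f$parent)]
  for (parent in names(kids)) {
    k <- kids[[parent]]
    k <- k[!f$parallel[k]]
    if (!length(k)) next
    child_union <- rowSums(member[, f$gate[k], drop = FALSE]) > 0
    expect_equal(sum(member[, parent]),
                 sum(child_union) + sum(member[, parent] & !child_union))
    expect_lte(sum(f$count[k]), sum(member[, parent]))
    expect_lte(sum(f$freq_of_parent[k]), 100 + 1e-9)
  }
})

test_that("gating is invariant under joint monotone channel transforms", {
  run <- fx_standard_run()
  tree <- run$tree
  um2 <- run$unmixed
  fluor <- lungspectral:::marker_to_fluor(fx_panel(), "CD3")
  g <- function(x) sign(x) * abs(x)^3
  um2$abundances[, fluor] <- g(um2$abundances[, fluor])
  tree2 <- tree
  tree2$thresholds["CD3"] <- g(tree$thresholds[["CD3"]])
  l1 <- run$gates$labels
  l2 <- apply_gates(um2, run$sample, tree2, fx_panel())$labels
  expect_identical(l1, l2)
})

test_that("gating is order independent over events", {
  run <- fx_standard_run()
  set.seed(1)
  idx <- sample(nrow(run$sample$raw), 2000)
  um_s <- run$unmixed
  um_s$abundances <- um_s$abundances[idx, ]
  ev_s <- lungspectral:::subset_events(run$sample, idx)
  l <- apply_gates(um_s, ev_s, run$tree, fx_panel())$labels
  expect_identical(l, run$gates$labels[idx])
})

test_that("noise-free gating recovery is exact", {
  pr <- lapply(fx_profiles(), function(p) { p$viability <- 1; p })
  st <- simulate_sample(pr, fx_endmembers(), fx_panel(), n = 4000,
                        seed = 5, noise = noise_model(0, 0, 0),
                        doublet_rate = 0)
  um <- unmix(st, fx_mixing_matrix())
  tree <- suppressWarnings(
    derive_thresholds(build_lung_gate_tree(), um, st, pr, fx_panel()))
  gr <- apply_gates(um, st, tree, fx_panel())
  expect_equal(evaluate_recovery(st$truth_labels, gr$labels)$accuracy, 1)
})

test_that("recovery evaluation matches analytic baselines", {
  truth <- rep(c("a", "b", "c"), c(500, 300, 200))
  expect_equal(evaluate_recovery(truth, truth)$accuracy, 1)
  ## random permutation: expected accuracy is sum of squared frequencies
  set.seed(77)
  acc <- replicate(200, evaluate_recovery(truth, sample(truth))$accuracy)
  baseline <- sum((c(500, 300, 200) / 1000)^2)
  expect_equal(mean(acc), baseline, tolerance = 0.02)
  expect_warning(evaluate_recovery(c("a", "b"), c("x", "y")), "disjoint")
  expect_error(evaluate_recovery(c("a"), c("a", "b")), "lengths")
})
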