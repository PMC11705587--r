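test_that("mixing matrix assembly checks names, counts and collinearity", {
  endm <- fx_endmembers()
  m <- fx_mixing_matrix()
  expect_equal(ncol(m), 30)
  expect_equal(sum(attr(m, "provenance") == "panel"), 27)
  expect_equal(sum(attr(m, "provenance") == "af"), 3)
  ## unit-norm columns
  expect_equal(unname(sqrt(colSums(unclass(m)^2))), rep(1, 30))

  only <- build_mixing_matrix(endm[fx_fluors()])
  expect_equal(ncol(only), 27)

  dup <- endm[[1]]
  expect_error(build_mixing_matrix(list(dup, dup)), "duplicate")
  near <- endm[[1]]
  near$name <- "copy"
  expect_error(build_mixing_matrix(list(endm[[1]], near)), "collinear")
})

test_that("OLS unmixing solves toy and zero-noise systems exactly", {
  lay3 <- lay_n(3)
  m <- diag(3)
  rownames(m) <- lay3$detectors; colnames(m) <- c("a", "b", "c")
  r <- unmix(matrix(c(2, 3, 5), 1), m)
  expect_equal(unname(r$abundances[1, ]), c(2, 3, 5))
  expect_equal(unname(r$residual_rms), 0)

  st <- simulate_sample(fx_profiles(), fx_endmembers(), fx_panel(),
                        n = 200, noise = noise_model(0, 0, 0), seed = 4,
                        doublet_rate = 0)
  um <- unmix(st, fx_mixing_matrix())
  expect_lt(max(abs(um$abundances - st$truth_abundances)), 1e-8)
})

test_that("OLS equals the explicit pseudo-inverse oracle", {
  set.seed(12)
  for (i in 1:10) {
    M <- matrix(runif(64 * 30), 64, 30)
    colnames(M) <- paste0("E", 1:30)
    Y <- matrix(rnorm(64 * 40), 40, 64)
    r <- unmix(Y, M)
    ## oracle: pinv via solve of the normal equations
    oracle <- Y %*% M %*% solve(crossprod(M))
    expect_equal(unname(r$abundances), unname(oracle), tolerance = 1e-10)
    ## residuals orthogonal to the column space (normal equations)
    res <- Y - r$abundances %*% t(M)
    rel <- max(abs(res %*% M)) / max(abs(Y %*% M))
    expect_lt(rel, 1e-8)
  }
})

test_that("unmixing is equivariant under endmember rescaling", {
  set.seed(13)
  M <- matrix(runif(16 * 4), 16, 4)
  colnames(M) <- paste0("E", 1:4)
  Y <- matrix(rnorm(16 * 5), 5, 16)
  a1 <- unmix(Y, M)$abundances
  M2 <- M
  M2[, 2] <- M2[, 2] * 3
  a2 <- unmix(Y, M2)$abundances
  expect_equal(a2[, 2] * 3, a1[, 2], tolerance = 1e-10)
  expect_equal(a2[, -2], a1[, -2], tolerance = 1e-10)
})

test_that("WLS reduces to OLS, drops Inf-variance detectors, beats OLS
           under heteroscedastic noise", {
  set.seed(14)
  M <- matrix(runif(16 * 4), 16, 4)
  colnames(M) <- paste0("E", 1:4)
  Y <- matrix(rnorm(16 * 30), 30, 16)
  expect_equal(unmix(Y, M, "wls", variances = rep(2, 16))$abundances,
               unmix(Y, M)$abundances, tolerance = 1e-10)
  expect_error(unmix(Y, M, "wls"), "variances")
  expect_error(unmix(Y, M, "wls", variances = rep(0, 16)),
               "strictly positive")

  ## infinite variance on a detector = OLS on the reduced layout
  v <- rep(1, 16); v[3] <- Inf
  a_inf <- unmix(Y, M, "wls", variances = v)$abundances
  a_red <- t(qr.coef(qr(M[-3, ]), t(Y[, -3])))
  expect_equal(unname(a_inf), unname(a_red), tolerance = 1e-10)

  ## paired simulations: WLS has lower abundance RMSE than OLS
  sds <- c(rep(0.1, 8), rep(3, 8))
  rmse_w <- rmse_o <- numeric(50)
  for (s in 1:50) {
    set.seed(100 + s)
    A <- matrix(rexp(4 * 50), 50, 4)
    Yn <- A %*% t(M) + matrix(rnorm(50 * 16), 50, 16) %*% diag(sds)
    rmse_o[s] <- sqrt(mean((unmix(Yn, M)$abundances - A)^2))
    rmse_w[s] <- sqrt(mean((unmix(Yn, M, "wls",
                                  variances = sds^2)$abundances - A)^2))
  }
  expect_lt(mean(rmse_w), mean(rmse_o))
})

test_that("three AF endmembers beat a single whole-sample AF signature", {
  endm <- fx_endmembers()
  af <- endm[default_af_names()]
  m_multi <- fx_mixing_matrix()
  st <- simulate_sample(fx_profiles(), endm, fx_panel(), n = 8000,
                        seed = 37)
  un <- simulate_unstained(fx_profiles(), af, n = 3000, seed = 38)
  whole <- normalize_signature(colMeans(un$raw), "unit", name = "AFwhole")
  m_single <- build_mixing_matrix(endm[fx_fluors()], list(whole))
  rep <- af_comparison_report(st, m_multi, m_single)
  expect_gte(mean(rep$ratio < 1), 0.9)
  expect_lt(median(rep$ratio), 1)
  ## a sample with one true AF source: both configurations agree
  pr1 <- lapply(fx_profiles(), function(p) {
    p$af_weights[c("AF-lym", "AF-mye")] <- 0
    p
  })
  st1 <- simulate_sample(pr1, endm, fx_panel(), n = 4000, seed = 39)
  un1 <- simulate_unstained(pr1, af["AF-amo"], n = 3000, seed = 40)
  whole1 <- normalize_signature(colMeans(un1$raw), "unit", name = "AFwhole")
  m_multi1 <- build_mixing_matrix(endm[fx_fluors()], af["AF-amo"])
  m_single1 <- build_mixing_matrix(endm[fx_fluors()], list(whole1))
  rep1 <- af_comparison_report(st1, m_multi1, m_single1)
  expect_equal(median(rep1$ratio), 1, tolerance = 0.15)
})

test_that("unmix result methods expose coefficients and fits", {
  st <- simulate_sample(fx_profiles(), fx_endmembers(), fx_panel(),
                        n = 100, seed = 2)
  um <- unmix(st, fx_mixing_matrix())
  expect_identical(coef(um), um$abundances)
  fit <- fitted(um, fx_mixing_matrix())
  expect_equal(dim(fit), dim(st$raw))
  expect_output(print(um), "unmix_result")
  expect_error(unmix(st$raw[, 1:10], fx_mixing_matrix()), "detectors")
})
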