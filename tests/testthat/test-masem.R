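test_that("stage-1 matrix pooling reproduces the published pooled cells", {
  tab <- pa_resilience_studies()
  neg <- pool_matrix(tab, "negative")
  expect_lt(abs(neg$r_xm - 0.273), 0.005)
  expect_lt(abs(neg$r_xy - (-0.256)), 0.005)
  expect_lt(abs(neg$r_my - (-0.319)), 0.005)
  expect_equal(neg$k, 7L)

  # the positive stratum's published cells came from a different (joint)
  # pooling scheme and an ambiguous k; hold only to a loose tolerance
  pos <- pool_matrix(tab, "positive")
  expect_lt(abs(pos$r_xm - 0.263), 0.02)
  expect_lt(abs(pos$r_xy - 0.27), 0.02)
  expect_lt(abs(pos$r_my - 0.453), 0.02)

  # harmonic mean of stratum sizes
  strat <- subset_by_polarity(tab, "negative")
  expect_equal(neg$n_harmonic, nrow(strat) / sum(1 / strat$n))
})

test_that("single-study stratum returns that study's matrix", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  toy_coding_csv(tmp, "Solo 2024,120,SWB,positive,0.3,0.25,0.5,,")
  pm <- pool_matrix(read_coding_table(tmp), "positive")
  expect_equal(c(pm$r_xm, pm$r_xy, pm$r_my), c(0.3, 0.25, 0.5))
  expect_equal(pm$n_harmonic, 120)
})

test_that("non-positive-definite pooled matrices are rejected by name", {
  expect_error(pooled_matrix(0.9, -0.9, 0.9, n = 100),
               "not positive definite")
  tmp <- withr::local_tempfile(fileext = ".csv")
  toy_coding_csv(tmp, "Bad 2024,120,SWB,positive,0.9,-0.9,0.9,,")
  expect_error(pool_matrix(read_coding_table(tmp), "positive"),
               "0.900.*-0.900")
  # collinearity guard: a unit correlation never builds a matrix
  expect_error(pooled_matrix(1, 0.2, 0.3, n = 100))
})

test_that("saturated mediation closed forms on the published matrices", {
  pms <- published_pooled_matrices()

  pos <- fit_mediation(pms$positive)
  expect_equal(pos$a, 0.263, tolerance = 1e-12)
  expect_equal(pos$b, 0.4103752, tolerance = 1e-6)
  expect_equal(pos$c, 0.1620713, tolerance = 1e-6)
  expect_equal(pos$ab, 0.1079287, tolerance = 1e-6)
  expect_equal(pos$d, 0.27, tolerance = 1e-12)
  expect_equal(pos$proportion, 39.97359, tolerance = 1e-4)

  negm <- fit_mediation(pms$negative)
  expect_equal(negm$a, 0.273, tolerance = 1e-12)
  expect_equal(negm$b, -0.2691732, tolerance = 1e-6)
  expect_equal(negm$c, -0.1825157, tolerance = 1e-6)
  expect_equal(negm$ab, -0.0734843, tolerance = 1e-6)
  expect_equal(negm$d, -0.256, tolerance = 1e-12)
  expect_equal(negm$proportion, 28.70480, tolerance = 1e-4)
})

test_that("independence and saturated-model identities", {
  zero <- fit_mediation(pooled_matrix(0, 0, 0, n = 500))
  expect_equal(c(zero$a, zero$b, zero$c, zero$ab, zero$d), rep(0, 5))
  expect_true(is.na(zero$proportion))

  set.seed(31)
  for (i in 1:25) {
    rho <- random_pd_triple()
    m <- suppressWarnings(
      fit_mediation(pooled_matrix(rho[["xm"]], rho[["xy"]], rho[["my"]],
                                  n = 300)))
    expect_equal(m$d, m$ab + m$c, tolerance = 1e-12)
    expect_equal(m$d, rho[["xy"]], tolerance = 1e-12)  # total = input r_xy
  }
})

test_that("saturated fit block is trivially perfect", {
  pms <- published_pooled_matrices()
  for (m in list(fit_mediation(pms$positive),
                 fit_mediation(pms$negative),
                 fit_mediation(pms$positive, method = "ml"))) {
    expect_lt(abs(m$fit$chi2), 1e-6)
    expect_identical(m$fit$df, 0L)
    expect_equal(m$fit$cfi, 1)
    expect_equal(m$fit$tli, 1)
    expect_equal(m$fit$rmsea, 0)
  }
})

test_that("maximum-likelihood fit agrees with closed forms to 1e-8", {
  set.seed(41)
  for (i in 1:100) {
    rho <- random_pd_triple()
    pm <- pooled_matrix(rho[["xm"]], rho[["xy"]], rho[["my"]], n = 500)
    cf <- suppressWarnings(fit_mediation(pm))
    ml <- suppressWarnings(fit_mediation(pm, method = "ml"))
    expect_lt(abs(ml$a - cf$a), 1e-8)
    expect_lt(abs(ml$b - cf$b), 1e-8)
    expect_lt(abs(ml$c - cf$c), 1e-8)
  }
})

test_that("Monte-Carlo intervals: determinism, ordering, convergence", {
  pm <- published_pooled_matrices()$positive
  ci1 <- mediation_ci(pm, "monte_carlo", reps = 2e4, seed = 99)
  ci2 <- mediation_ci(pm, "monte_carlo", reps = 2e4, seed = 99)
  expect_identical(ci1, ci2)
  for (p in c("a", "b", "c", "ab")) expect_lt(ci1[[p]][1], ci1[[p]][2])

  # doubling replications barely moves the endpoints (convergence)
  ci4 <- mediation_ci(pm, "monte_carlo", reps = 4e4, seed = 100)
  expect_lt(max(abs(ci4$ab - ci1$ab)), 0.005)

  expect_error(mediation_ci(pm, "monte_carlo", reps = 2e4), "seed")
  expect_error(mediation_ci(pm, "monte_carlo", reps = 100, seed = 1),
               ">= 1000")
})

test_that("delta-method and Monte-Carlo intervals corroborate each other", {
  pms <- published_pooled_matrices()
  for (pm in pms) {
    mc <- mediation_ci(pm, "monte_carlo", reps = 1e5, seed = 7)
    de <- mediation_ci(pm, "delta")
    for (p in c("a", "b", "c", "ab")) {
      width <- diff(mc[[p]])
      expect_lt(max(abs(de[[p]] - mc[[p]])), 0.15 * width)
    }
  }
})

test_that("near-null matrix with tiny cell variances straddles zero", {
  pm <- pooled_matrix(0.001, 0.001, 0.001, n = 5000,
                      se_z = c(xm = 0.01, xy = 0.01, my = 0.01))
  ci <- mediation_ci(pm, "monte_carlo", reps = 1e4, seed = 3)
  expect_lt(ci$ab[1], 0)
  expect_gt(ci$ab[2], 0)
})

test_that("proportion mediated is sign-safe with guarded edge cases", {
  expect_equal(proportion_mediated(0.108, 0.269), 40.14870, tolerance = 1e-4)
  expect_equal(proportion_mediated(-0.074, -0.256), 28.90625, tolerance = 1e-4)
  expect_equal(proportion_mediated(0, 0.3), 0)
  expect_error(proportion_mediated(0.1, 0), "undefined")
  expect_warning(proportion_mediated(0.4, 0.3), "inconsistent")
})

test_that("model syntax echo names both structural equations", {
  m <- fit_mediation(published_pooled_matrices()$positive)
  txt <- model_syntax(m)
  expect_true(any(grepl("Re ~", txt)))
  expect_true(any(grepl("MH ~", txt)))
  expect_true(any(grepl("indirect", txt)))
})
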