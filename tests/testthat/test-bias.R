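test_that("fail-safe N: null case, threshold, monotonicity", {
  null_set <- toy_effects(rep(0, 5), rep(0.1, 5))
  fs <- fail_safe_n(null_set)
  expect_equal(fs$n_fs, 0L)
  expect_equal(fs$threshold, 35L)

  # monotone non-decreasing in |sum of deviates| at fixed k
  scales <- c(0.5, 1, 2, 4)
  nfs <- vapply(scales, function(s)
    fail_safe_n(toy_effects(s * c(0.2, 0.3, 0.25), rep(0.01, 3)))$n_fs, 0L)
  expect_true(all(diff(nfs) >= 0))
})

test_that("fail-safe N on the packaged negative stratum matches the record", {
  tab <- pa_resilience_studies()
  neg <- subset_by_polarity(tab, "negative")
  expect_equal(fail_safe_n(effects_from_table(neg, "re_mh"))$n_fs, 1480L)
  expect_equal(fail_safe_n(effects_from_table(neg, "pa_mh"))$n_fs, 875L)
})

test_that("fail-safe N agrees with metafor's Rosenthal version", {
  skip_if_not_installed("metafor")
  tab <- pa_resilience_studies()
  neg <- subset_by_polarity(tab, "negative")
  for (rel in c("pa_mh", "re_mh")) {
    eff <- effects_from_table(neg, rel)
    ours <- fail_safe_n(eff)
    # metafor's alpha is one-tailed; 0.025 matches our two-tailed 0.05
    ref <- metafor::fsn(x = eff$z, vi = eff$v, type = "Rosenthal",
                        alpha = 0.025)
    expect_equal(ours$n_fs, ref$fsnum)
  }
})

test_that("funnel data: one point per study, symmetric guides", {
  eff <- toy_effects(c(0.05, 0.1, 0.15), c(0.02, 0.01, 0.02))
  pooled <- pool_random(eff)
  fd <- funnel_data(eff, pooled)
  expect_equal(nrow(fd$points), 3L)
  expect_equal(fd$points$z, eff$z)
  # guides are centred on the pooled z and widen with se
  mid <- (fd$guides$lower + fd$guides$upper) / 2
  expect_equal(mid, rep(pooled$z_pooled, nrow(fd$guides)))
  expect_true(all(diff(fd$guides$upper - fd$guides$lower) > 0))
  # a symmetric toy set yields points symmetric about its centre
  sym <- toy_effects(0.1 + c(-0.05, 0, 0.05), rep(0.01, 3))
  fs <- funnel_data(sym, pool_random(sym))
  expect_equal(mean(fs$points$z), 0.1)
})

test_that("negative-stratum funnel: all resilience effects left of zero", {
  tab <- pa_resilience_studies()
  eff <- effects_from_table(subset_by_polarity(tab, "negative"), "re_mh")
  fd <- funnel_data(eff, pool_random(eff))
  expect_equal(nrow(fd$points), 7L)
  expect_true(all(fd$points$z < 0))
})

test_that("trim-and-fill leaves a symmetric funnel untouched", {
  # 5 mirrored pairs + centre, variances growing outward
  offs <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  sym <- toy_effects(c(0.5, 0.5 + offs, 0.5 - offs),
                     c(0.005, rep(c(0.01, 0.02, 0.05, 0.1, 0.2), 2)))
  tf <- trim_and_fill(sym)
  expect_equal(tf$k0, 0L)
  expect_equal(nrow(tf$imputed), 0L)
  expect_equal(tf$adjusted$r, pool_random(sym)$r)
})

test_that("trim-and-fill recovers deleted studies and refills symmetrically", {
  fx <- tf_deletion_fixture()
  expect_equal(trim_and_fill(fx$full)$k0, 0L)

  tf <- trim_and_fill(fx$deleted)
  expect_equal(tf$k0, 3L)
  expect_equal(tf$side, "left")
  expect_equal(nrow(tf$imputed), 3L)

  # filled set symmetric: each imputed effect mirrors a trimmed one about
  # the trimmed-set centre, so pairwise midpoints coincide to 1e-9
  trimmed <- sort(fx$deleted$z, decreasing = TRUE)[1:3]
  mids <- (sort(tf$imputed$z) + sort(trimmed, decreasing = FALSE)[3:1]) / 2
  expect_equal(max(mids) - min(mids), 0, tolerance = 1e-9)

  # the adjusted estimate moves toward the full symmetric set's pooled value
  full_r <- pool_random(fx$full)$r
  unadj_r <- pool_random(fx$deleted)$r
  expect_lt(abs(tf$adjusted$r - full_r), abs(unadj_r - full_r))
  expect_lt(abs(tf$adjusted$r - full_r), 0.02)

  # idempotence: filling the filled set finds nothing more
  filled <- effect_table(c(fx$deleted$study_id, tf$imputed$study_id),
                         c(fx$deleted$z, tf$imputed$z),
                         c(fx$deleted$v, tf$imputed$v))
  expect_equal(trim_and_fill(filled)$k0, 0L)
})

test_that("trim-and-fill L0 rank statistic matches a hand computation", {
  fx <- tf_deletion_fixture()
  # first iteration by direct arithmetic: centre on the DL-pooled estimate,
  # rank absolute centred effects, signed-rank sum over the positive side
  eff <- fx$deleted
  b <- pool_random(eff)$z_pooled
  d <- sort(eff$z) - b
  rk <- rank(abs(d), ties.method = "first")
  Tn <- sum(rk[d > 0])
  k <- nrow(eff)
  L0 <- (4 * Tn - k * (k + 1)) / (2 * k - 1)
  expect_gte(round(L0), 1)  # asymmetry visible already at iteration one
  expect_equal(trim_and_fill(eff)$k0, 3L)
})

test_that("trim-and-fill matches metafor on the deletion fixture", {
  skip_if_not_installed("metafor")
  fx <- tf_deletion_fixture()
  ref <- metafor::trimfill(
    metafor::rma(yi = fx$deleted$z, vi = fx$deleted$v, method = "DL"),
    side = "left")
  tf <- trim_and_fill(fx$deleted)
  expect_equal(tf$k0, ref$k0)
  expect_equal(tf$adjusted$z_pooled, as.numeric(ref$b), tolerance = 1e-10)
})

test_that("trim-and-fill warns and returns k0 = 0 below 3 studies", {
  two <- toy_effects(c(0.2, 0.5), c(0.02, 0.05))
  expect_warning(tf <- trim_and_fill(two), "at least 3")
  expect_equal(tf$k0, 0L)
  expect_equal(tf$adjusted$r, pool_random(two)$r)
})
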