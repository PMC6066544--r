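test_that("CV is scale-free and guards its domain", {
  expect_equal(coefficient_of_variation(rep(3, 10)), 0)
  set.seed(101)
  x <- rlnorm(50)
  expect_equal(coefficient_of_variation(7.3 * x),
               coefficient_of_variation(x), tolerance = 1e-14)
  expect_error(coefficient_of_variation(c(-5, 1)), "non-positive")
  expect_error(coefficient_of_variation(2), "at least 2")
})

test_that("Feltz-Miller is null on identical samples and scale invariant", {
  set.seed(102)
  x <- rlnorm(66)
  fm <- feltz_miller_test(list(x, x))
  expect_equal(fm$statistic, 0)
  expect_equal(fm$p_value, 1)
  expect_equal(fm$df, 1L)

  y <- rlnorm(40, 0.5, 0.4)
  fm1 <- feltz_miller_test(list(x, y))
  fm2 <- feltz_miller_test(list(3 * x, 0.2 * y))
  expect_equal(fm2$statistic, fm1$statistic, tolerance = 1e-12)
  # symmetric under reordering
  fm3 <- feltz_miller_test(list(y, x))
  expect_equal(fm3$statistic, fm1$statistic, tolerance = 1e-12)
})

test_that("Feltz-Miller separates very different CVs, calibrated vs a simulated null", {
  set.seed(103)
  # CVs ~0.1 vs ~0.8 at n = 50: statistic far into the tail
  a <- rnorm(50, 10, 1)
  b <- rnorm(50, 1.25, 1)
  b <- b[b > 0][1:40]
  fm <- feltz_miller_test(list(a, b))
  expect_lt(fm$p_value, 0.01)

  # simulation oracle: the observed statistic should exceed the null's
  # 99th percentile when generated under equal CVs it does not
  null_stats <- replicate(300, {
    g1 <- rlnorm(50, 0, 0.3)
    g2 <- rlnorm(50, 0, 0.3)
    feltz_miller_test(list(g1, g2))$statistic
  })
  expect_gt(fm$statistic, quantile(null_stats, 0.99))
  # and the null statistics are consistent with chi-square(1)
  ks <- suppressWarnings(ks.test(null_stats, pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("Bartlett flags pure rescaling while CV comparison does not", {
  set.seed(104)
  x <- rlnorm(100, 1, 0.4)
  # same data on two scales: Bartlett trivially significant...
  bt <- bartlett_k2(list(x, x / 2))
  expect_lt(bt$p_value, 0.001)
  # ...whereas the scale-free CV comparison sees identical dispersion
  fm <- feltz_miller_test(list(x, x / 2))
  expect_equal(fm$statistic, 0, tolerance = 1e-12)

  expect_equal(bartlett_k2(list(x, x))$statistic, 0, tolerance = 1e-12)
  expect_error(bartlett_k2(list(x, rep(1, 10))), "zero-variance")
})

test_that("Bartlett's null calibration holds for equal-variance groups", {
  set.seed(105)
  pvals <- replicate(200, {
    bartlett_k2(list(rnorm(50), rnorm(50)))$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("morphometric normalization creates a labeled hybrid column", {
  df <- data.frame(environment = rep(c("A", "B"), 5),
                   speed = c(10, 12, 9, 14, 11, 13, 10, 12, 9, 15),
                   femur = rep(2, 10))
  pt <- make_pt(df, domains = c("behavioral", "morphometric"),
                timescales = c("fast", "slow"))
  out <- normalize_by_morphometric(pt, "speed", "femur")
  expect_equal(out$speed_per_femur, df$speed / 2)
  meta <- trait_meta(out)
  expect_identical(meta$domain[meta$trait == "speed_per_femur"], "hybrid")
  # constant size: ratio perfectly correlated with the raw trait
  expect_equal(cor(out$speed, out$speed_per_femur), 1)

  df$femur[1] <- -1
  expect_error(normalize_by_morphometric(make_pt(
    df, domains = c("behavioral", "morphometric"),
    timescales = c("fast", "slow")), "speed", "femur"),
    "strictly positive")
})

test_that("normalizing by an anomalously phase-linked size trait destroys the speed signal", {
  # gregarious both faster and longer-femured: speed/femur equalizes phases
  hits <- 0L
  for (i in 1:25) {
    pop <- simulate_phase_population(
      phase_pop_config(femur_ratio = 1.6, seed = 2000 + i))
    pop <- normalize_by_morphometric(pop, "average_speed",
                                     "hind_femur_length")
    y <- as.integer(pop$environment == "gregarious")
    d_raw <- abs(somers_dxy(pop$average_speed, y))
    d_norm <- abs(somers_dxy(pop$average_speed_per_hind_femur_length, y))
    hits <- hits + (d_raw > d_norm)
  }
  expect_gte(hits, 23L)
})

test_that("correlation wrapper reports scope, statistics and guards", {
  set.seed(106)
  x <- rnorm(30)
  y <- exp(x)  # strictly increasing transform
  sp <- correlate_traits(x, y, method = "spearman",
                         scope = "across-groups")
  expect_equal(sp$coefficient, 1)
  expect_identical(sp$scope, "across-groups")
  # Spearman reports the S statistic (0 for perfect positive rank agreement)
  expect_equal(sp$statistic, 0)

  # Pearson on ranks equals Spearman (no ties)
  z <- rnorm(30)
  pe <- correlate_traits(rank(x), rank(z), method = "pearson",
                         scope = "within-group")
  sp2 <- correlate_traits(x, z, method = "spearman",
                          scope = "within-group")
  expect_equal(pe$coefficient, sp2$coefficient, tolerance = 1e-12)
  expect_equal(pe$df, 28L)

  expect_error(correlate_traits(rep(1, 10), rnorm(10)), "constant")
  expect_error(correlate_traits(1:2, 2:3), "at least 3")
})
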