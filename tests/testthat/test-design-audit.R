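test_that("EPV arithmetic and verdicts follow the limiting group", {
  a <- events_per_variable(15, 51, 13)
  expect_equal(a$limiting_n, 15)
  expect_equal(a$epv, 15 / 13, tolerance = 1e-12)
  expect_lt(a$epv, 2)
  expect_identical(a$verdict, "fail")

  b <- events_per_variable(15, 51, 5)
  expect_equal(b$epv, 3)
  expect_identical(b$verdict, "warn")

  expect_identical(events_per_variable(200, 300, 10)$verdict, "pass")
  expect_equal(events_per_variable(7, 100, 7)$epv, 1)
  expect_error(events_per_variable(15, 51, 0), "positive")
  expect_error(events_per_variable(0, 51, 3), "non-empty")
})

test_that("minimum sample sizes follow the EPV rule of thumb", {
  expect_equal(min_sample_size(13), 15 * 14)
  expect_equal(min_sample_size(13, with_strain_interactions = TRUE), 15 * 28)
  for (k in 1:20) {
    expect_equal(min_sample_size(k, with_strain_interactions = TRUE),
                 2 * min_sample_size(k))
  }
  expect_equal(min_sample_size(5, epv_floor = 10), 60)
})

test_that("strain comparison counts coefficients and orders likelihoods", {
  k <- 3
  tab <- simulate_strain_dataset(n_per_strain = 240, k = k, seed = 111)
  mc <- strain_generalization_compare(
    tab, lr_model_spec(paste0("x", 1:k), event_level = "gregarious"))
  expect_equal(mc$lrt_df, k + 1)
  expect_gte(mc$lrt_statistic, 0)
  expect_equal(mc$lrt_statistic, 2 * (mc$loglik_1 - mc$loglik_2),
               tolerance = 1e-10)
  expect_equal(mc$aic_1, -2 * mc$loglik_1 + 2 * (2 * k + 2),
               tolerance = 1e-10)
  expect_equal(mc$aic_2, -2 * mc$loglik_2 + 2 * (k + 1), tolerance = 1e-10)
})

test_that("null strain simulations favor pooling; an injected effect is detected", {
  k <- 3
  # under the null, most replicates recommend the pooled model
  rec <- character(20)
  pvals <- numeric(20)
  for (i in 1:20) {
    tab <- simulate_strain_dataset(n_per_strain = 240, k = k,
                                   seed = 300 + i)
    mc <- strain_generalization_compare(
      tab, lr_model_spec(paste0("x", 1:k), event_level = "gregarious"))
    rec[i] <- mc$recommendation
    pvals[i] <- mc$lrt_p
  }
  expect_gte(mean(rec == "pooled-model"), 0.8)

  # a sign-flipped x1 in strain B: crossed model wins decisively
  tab2 <- simulate_strain_dataset(n_per_strain = 240, k = k,
                                  delta = c(0, -1.6, 0, 0), seed = 112)
  mc2 <- strain_generalization_compare(
    tab2, lr_model_spec(paste0("x", 1:k), event_level = "gregarious"))
  expect_lt(mc2$aic_1, mc2$aic_2)
  expect_lt(mc2$lrt_p, 0.01)
  expect_identical(mc2$recommendation, "strain-specific")
})

test_that("underpowered designs are never read as evidence for pooling", {
  k <- 3
  tab <- simulate_strain_dataset(n_per_strain = 14, k = k, seed = 113)
  mc <- tryCatch(
    strain_generalization_compare(
      tab, lr_model_spec(paste0("x", 1:k), event_level = "gregarious")),
    error = identity)
  # tiny cells either separate (classed error) or come back "underpowered"
  if (inherits(mc, "error")) {
    expect_s3_class(mc, "phaseaudit_separation")
  } else {
    expect_identical(mc$recommendation, "underpowered")
  }
})

test_that("empty phase-by-strain cells are rejected", {
  tab <- simulate_strain_dataset(n_per_strain = 100, seed = 114)
  df <- as.data.frame(tab)
  df <- df[!(df$strain == "B" & df$environment == "solitarious"), ]
  pt <- make_pt(df)
  expect_error(strain_generalization_compare(
    pt, lr_model_spec(c("x1", "x2", "x3"), event_level = "gregarious")),
    "empty phase-by-strain")
})

test_that("the model audit assembles warnings for a deficient hybrid model", {
  pop <- simulate_phase_population(phase_pop_config(femur_ratio = 1.6,
                                                    seed = 120))
  spec <- lr_model_spec(traits(pop), event_level = "gregarious",
                        standardize = TRUE)
  rep <- audit_model(pop, spec,
                     audit_config(bootstrap_B = 60, seed = 2,
                                  claim = "non-morphometric"))
  codes <- rep$warnings$code
  expect_true("W_HYBRID_DOMAIN" %in% codes)
  expect_true("W_EPV_FAIL" %in% codes)
  expect_true(any(c("W_SEPARATION", "W_QUASI_SEPARATION") %in% codes))
  expect_true("W_NOT_NONMORPHOMETRIC" %in% codes)
  expect_true("W_COLLINEAR" %in% codes)
  expect_true("W_SIGN_REDUNDANT" %in% codes)
  # a separated fit is never validated as if it were accurate
  if (rep$separation$flagged) {
    expect_null(rep$validation)
    expect_true("W_VALIDATION_SKIPPED" %in% codes)
  }
})

test_that("a well-powered clean model audits quietly", {
  pop <- simulate_latent_axis(latent_sim_config(seed = 121))
  spec <- lr_model_spec(c("t1", "t2"), event_level = "B")
  rep <- audit_model(pop, spec, audit_config(bootstrap_B = 60, seed = 4))
  expect_false(any(c("W_SEPARATION", "W_EPV_FAIL", "W_HYBRID_DOMAIN") %in%
                     rep$warnings$code))
  expect_identical(rep$design$verdict, "pass")
  expect_lt(abs(rep$validation$dxy_apparent - rep$validation$dxy_corrected),
            0.03)
})

test_that("audit reports are deterministic given table, spec and config", {
  pop <- simulate_phase_population(phase_pop_config(seed = 122))
  spec <- lr_model_spec(c("average_speed", "erratic_movement"),
                        event_level = "gregarious")
  cfg <- audit_config(bootstrap_B = 40, seed = 5)
  r1 <- audit_model(pop, spec, cfg)
  r2 <- audit_model(pop, spec, cfg)
  r1$collinearity <- r2$collinearity <- NULL  # environments differ on closures
  expect_equal(r1, r2)
})
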