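test_that("latent-axis simulation honors its boundary contracts", {
  # no trait effects: assignment is a fair coin
  cfg0 <- latent_sim_config(N = 2000, beta1 = 0, beta2 = 0, seed = 131)
  pop0 <- simulate_latent_axis(cfg0)
  frac_b <- mean(pop0$environment == "B")
  expect_lt(abs(frac_b - 0.5), 3 * sqrt(0.25 / 2000))

  # zero noise: deterministic boundary at the true latent axis
  cfg_det <- latent_sim_config(N = 500, noise_scale = 0, seed = 132)
  pop_det <- simulate_latent_axis(cfg_det)
  expect_identical(pop_det$environment,
                   ifelse(2.5 * pop_det$t1 + 5 * pop_det$t2 > 0, "B", "A"))

  # reproducibility
  expect_identical(as.data.frame(simulate_latent_axis(cfg0)),
                   as.data.frame(simulate_latent_axis(cfg0)))
})

test_that("fits on the latent simulation recover the generating coefficients", {
  pop <- simulate_latent_axis(latent_sim_config(seed = 133))
  fit <- fit_logistic(pop, lr_model_spec(c("t1", "t2"), event_level = "B"))
  b <- coef(fit)
  se <- fit$standard_errors
  expect_lt(abs(b[["(Intercept)"]] - 0), 3 * se[["(Intercept)"]])
  expect_lt(abs(b[["t1"]] - 2.5), 3 * se[["t1"]])
  expect_lt(abs(b[["t2"]] - 5) , 3 * se[["t2"]])

  # estimated probability is non-decreasing along the true latent direction
  grid <- data.frame(t1 = 2.5 * seq(-0.2, 0.2, length.out = 41),
                     t2 = 5 * seq(-0.2, 0.2, length.out = 41))
  p <- predict_prob(fit, grid)
  expect_true(all(diff(p) > 0))
})

test_that("phase population has the study shape with planted pathologies", {
  pop <- simulate_phase_population(phase_pop_config(femur_ratio = 1.6,
                                                    seed = 134))
  expect_equal(sum(pop$environment == "solitarious"), 15)
  expect_equal(sum(pop$environment == "gregarious"), 51)
  expect_equal(length(traits(pop)), 13)

  expect_gt(abs(cor(pop$average_speed, pop$average_acceleration)), 0.999)
  expect_identical(pop$final_choice,
                   ifelse(pop$last_coordinate >= 0, 1, -1))

  greg <- pop$environment == "gregarious"
  expect_gt(mean(pop$hind_femur_length[greg]),
            mean(pop$hind_femur_length[!greg]))  # the anomaly scenario

  expect_error(phase_pop_config(collinear_pair = list(
    base = "average_speed", derived = "average_acceleration", r = 1.2)),
    "infeasible")
})

test_that("crowding moves fast traits but never slow ones", {
  cfg0 <- phase_pop_config(n_solitarious = 120, n_gregarious = 2,
                           crowding_hours = 0, collinear_pair = NULL,
                           sign_redundant_pair = NULL, seed = 135)
  cfg24 <- phase_pop_config(n_solitarious = 120, n_gregarious = 2,
                            crowding_hours = 24, collinear_pair = NULL,
                            sign_redundant_pair = NULL, seed = 135)
  p0 <- simulate_phase_population(cfg0)
  p24 <- simulate_phase_population(cfg24)
  sol0 <- p0[p0$environment == "solitarious", ]
  sol24 <- p24[p24$environment == "solitarious", ]

  # slow morphometrics: statistically identical between cohorts
  for (tr in c("hind_femur_length", "pronotum_length", "head_width")) {
    ks <- suppressWarnings(ks.test(sol0[[tr]], sol24[[tr]]))
    expect_gt(ks$p.value, 0.01)
  }
  # fast behaviors at 24 h: shifted, and within the gregarious distribution
  ks_fast <- suppressWarnings(ks.test(sol0$average_speed,
                                      sol24$average_speed))
  expect_lt(ks_fast$p.value, 1e-6)
  panel <- default_trait_panel()
  gm <- panel$greg_mean[panel$name == "average_speed"]
  expect_lt(abs(mean(sol24$average_speed) - gm), 0.2)

  # a hybrid behavioral+morphometric model spreads its predictions for the
  # crowded cohort across the probability range instead of concentrating
  train <- simulate_phase_population(phase_pop_config(
    n_solitarious = 60, n_gregarious = 60, collinear_pair = NULL,
    sign_redundant_pair = NULL, seed = 136))
  spec <- lr_model_spec(c("average_speed", "hind_femur_length"),
                        event_level = "gregarious")
  fit <- fit_logistic(train, spec)
  p_crowded <- suppressWarnings(predict_prob(fit, sol24))
  expect_gt(diff(range(p_crowded)), 0.5)
})

test_that("crowding response is monotone and saturating", {
  means <- vapply(c(0, 2, 4, 8, 24, 96), function(h) {
    pop <- simulate_phase_population(phase_pop_config(
      n_solitarious = 400, n_gregarious = 2, crowding_hours = h,
      collinear_pair = NULL, sign_redundant_pair = NULL, seed = 137))
    mean(pop$average_speed[pop$environment == "solitarious"])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # half-time 4 h: the 4 h cohort sits near the midpoint of the response
  panel <- default_trait_panel()
  sm <- panel$sol_mean[panel$name == "average_speed"]
  gm <- panel$greg_mean[panel$name == "average_speed"]
  expect_lt(abs(means[3] - (sm + gm) / 2), 0.1)
})

test_that("the fixture suite is deterministic and manifest-complete", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_suite(d1, seed = 555)
  m2 <- write_fixture_suite(d2, seed = 555)
  expect_setequal(names(m1),
                  c("latent_axis", "phase_population_anomaly",
                    "strain_null", "strain_effect"))
  for (nm in names(m1)) {
    expect_identical(readLines(file.path(d1, m1[[nm]]$data)),
                     readLines(file.path(d2, m2[[nm]]$data)))
    expect_true(!is.null(m1[[nm]]$seed))
  }
  anomaly <- read_phenotype_table(
    file.path(d1, "phase_population_anomaly.csv"),
    file.path(d1, "phase_population_anomaly_traits.yaml"))
  expect_equal(table(anomaly$environment)[["solitarious"]], 15)
  expect_equal(table(anomaly$environment)[["gregarious"]], 51)
})
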