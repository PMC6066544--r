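test_that("intercept-only fit on balanced outcomes gives log-odds one half", {
  pt <- make_pt(data.frame(environment = rep(c("A", "B"), each = 5),
                           t1 = rnorm(10)))
  fit <- fit_logistic(pt, lr_model_spec(character(0), event_level = "B"))
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-8)
  expect_equal(fit$fitted_probabilities, rep(0.5, 10), tolerance = 1e-8)
  expect_true(is.na(fit$epv))
})

test_that("saturated binary-predictor fit equals the 2x2 log odds ratio", {
  # cells: x=0 -> 2 events / 8 non-events; x=1 -> 7 events / 3 non-events
  x <- c(rep(0, 10), rep(1, 10))
  y <- c(rep(1, 2), rep(0, 8), rep(1, 7), rep(0, 3))
  fit <- fit_logistic(pt_xy(x, y), lr_model_spec("x", event_level = "B"))
  expect_equal(unname(coef(fit)[1]), log(2 / 8), tolerance = 1e-7)
  expect_equal(unname(coef(fit)[2]), log((7 / 3) / (2 / 8)),
               tolerance = 1e-7)
  # brute-force likelihood grid around the closed form confirms the optimum
  grid <- seq(-0.5, 0.5, by = 0.01)
  X <- cbind(1, x)
  nll_at <- vapply(grid, function(d) {
    nll_logistic(coef(fit) + c(0, d), X, y)
  }, numeric(1))
  expect_equal(grid[which.min(nll_at)], 0, tolerance = 1e-9)
})

test_that("IRLS matches glm and a derivative-free oracle on clean data", {
  set.seed(21)
  for (rep_i in 1:5) {
    n <- sample(60:200, 1)
    p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    beta <- rnorm(p + 1, 0, 0.8)
    y <- rbinom(n, 1, plogis(drop(cbind(1, X) %*% beta)))
    if (min(sum(y), sum(1 - y)) < p + 3) next
    df <- data.frame(environment = ifelse(y == 1, "B", "A"), X)
    pt <- make_pt(df)
    fit <- fit_logistic(pt, lr_model_spec(colnames(X), event_level = "B"))
    if (fit$separation$flagged) next

    g <- suppressWarnings(
      glm(y ~ X, family = binomial, control = list(epsilon = 1e-12)))
    expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-6)
    expect_equal(unname(fit$standard_errors),
                 unname(summary(g)$coefficients[, 2]), tolerance = 1e-4)

    oracle <- fit_logistic_oracle(cbind(1, X), y)
    expect_equal(unname(coef(fit)), oracle, tolerance = 1e-4)

    # score equations hold at the optimum
    score <- drop(crossprod(cbind(1, X), y - fit$fitted_probabilities))
    expect_lt(max(abs(score)), 1e-5)
  }
})

test_that("events per variable uses the limiting group", {
  set.seed(31)
  x <- c(rnorm(15, 1), rnorm(51))
  y <- c(rep(1, 15), rep(0, 51))
  fit <- fit_logistic(pt_xy(x, y), lr_model_spec("x", event_level = "B"))
  expect_equal(fit$epv, 15)
  expect_equal(fit$n_event, 15)
  expect_equal(fit$n_nonevent, 51)
})

test_that("degenerate designs raise informative errors", {
  set.seed(41)
  df <- data.frame(environment = rep(c("A", "B"), 10),
                   t1 = rnorm(20))
  df$t2 <- 2 * df$t1                    # aliased with t1
  pt <- make_pt(df)
  err <- tryCatch(fit_logistic(pt, lr_model_spec(c("t1", "t2"), event_level = "B")),
                  error = identity)
  expect_s3_class(err, "phaseaudit_singular")
  expect_match(conditionMessage(err), "t2")  # later-listed term blamed

  single <- make_pt(data.frame(environment = rep("A", 10), t1 = rnorm(10)))
  expect_error(fit_logistic(single, lr_model_spec("t1")), "2 observed levels")
})

test_that("unspecified event level defaults alphabetically last, with warning", {
  set.seed(51)
  pt <- make_pt(data.frame(environment = rep(c("gregarious", "solitarious"),
                                             each = 20),
                           t1 = rnorm(40)))
  expect_warning(fit <- fit_logistic(pt, lr_model_spec("t1")),
                 "alphabetically last")
  expect_identical(fit$event_level, "solitarious")
})

test_that("rows with missing modeled values are dropped and counted", {
  set.seed(61)
  df <- data.frame(environment = rep(c("A", "B"), each = 10),
                   t1 = rnorm(20))
  df$t1[3] <- NA
  pt <- make_pt(df)
  expect_message(fit <- fit_logistic(pt, lr_model_spec("t1",
                                                       event_level = "B")),
                 "1 row")
  expect_equal(fit$n_dropped, 1L)
  expect_equal(length(fit$y), 19L)
})

test_that("predict_prob reproduces training probabilities bit for bit", {
  pop <- simulate_latent_axis(latent_sim_config(N = 150, seed = 7))
  for (std in c(FALSE, TRUE)) {
    fit <- fit_logistic(pop, lr_model_spec(c("t1", "t2"), event_level = "B",
                                           standardize = std))
    expect_identical(predict_prob(fit, pop), fit$fitted_probabilities)
  }
})

test_that("predict_prob honors the logit geometry and its contracts", {
  pop <- simulate_latent_axis(latent_sim_config(N = 150, seed = 8))
  fit <- fit_logistic(pop, lr_model_spec(c("t1", "t2"), event_level = "B"))

  # a phenotype on the fitted decision line has probability exactly 1/2
  b <- coef(fit)
  t1_star <- 0.1
  t2_star <- -(b[["(Intercept)"]] + b[["t1"]] * t1_star) / b[["t2"]]
  on_line <- data.frame(t1 = t1_star, t2 = t2_star)
  expect_equal(unname(predict_prob(fit, on_line)), 0.5, tolerance = 1e-12)

  # all-zero coefficients give probability 1/2 everywhere
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_equal(unname(predict_prob(fit0, pop)), rep(0.5, nrow(pop)))

  expect_error(predict_prob(fit, data.frame(t1 = 1)), "t2")

  # separated fits clip and warn
  sep_fit <- fit_logistic(pt_xy(c(-2, -1, 1, 2), c(0, 0, 1, 1)),
                          lr_model_spec("x", event_level = "B"))
  expect_warning(p <- predict_prob(sep_fit, data.frame(x = c(-50, 50))),
                 "separation")
  expect_true(all(p >= 1e-12 & p <= 1 - 1e-12))
})

test_that("latent axis slope is the coefficient ratio with an orthogonal iso-line", {
  fit <- fit_logistic(simulate_latent_axis(latent_sim_config(N = 400,
                                                             seed = 9)),
                      lr_model_spec(c("t1", "t2"), event_level = "B"))
  fake <- fit
  fake$coefficients <- c("(Intercept)" = 0, t1 = 1, t2 = 1)
  expect_equal(as.numeric(latent_axis_slope(fake, "t1", "t2")), 1)

  sl <- latent_axis_slope(fit, "t1", "t2")
  expect_equal(as.numeric(sl),
               coef(fit)[["t2"]] / coef(fit)[["t1"]])
  iso <- attr(sl, "iso_direction")
  expect_equal(sum(iso * coef(fit)[c("t1", "t2")]), 0, tolerance = 1e-12)

  fake$coefficients[["t1"]] <- 0
  expect_error(latent_axis_slope(fake, "t1", "t2"), "undefined")
  expect_error(latent_axis_slope(fit, "t1", "nope"), "no coefficient")
})
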