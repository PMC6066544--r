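# Shared fixture builders and independent oracles for the test suite.

# A minimal phenotype table around given trait columns.
make_pt <- function(df, domains = NULL, timescales = NULL,
                    environment_col = "environment") {
  trait_cols <- setdiff(names(df), c(environment_col, "strain", "stadium"))
  if (is.null(domains)) domains <- rep("behavioral", length(trait_cols))
  if (is.null(timescales)) timescales <- rep("fast", length(trait_cols))
  phenotype_table(df,
                  data.frame(trait = trait_cols, domain = domains,
                             timescale = timescales,
                             stringsAsFactors = FALSE),
                  environment_col = environment_col,
                  strain_col = if ("strain" %in% names(df)) "strain")
}

# Two-group table from a single numeric predictor and 0/1 labels.
pt_xy <- function(x, y) {
  make_pt(data.frame(environment = ifelse(y == 1, "B", "A"), x = x))
}

# Brute-force Somers' Dxy: enumerate every event/non-event pair.
dxy_bruteforce <- function(pred, y) {
  pe <- pred[y == 1]
  pn <- pred[y == 0]
  conc <- disc <- 0
  for (a in pe) {
    conc <- conc + sum(a > pn)
    disc <- disc + sum(a < pn)
  }
  (conc - disc) / (length(pe) * length(pn))
}

# Negative log-likelihood of a binary logistic model, for the
# derivative-free optimization oracle.
nll_logistic <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(log1p(exp(-(2 * y - 1) * eta)))
}

# Derivative-free ML fit (Nelder-Mead), independent of the IRLS path.
fit_logistic_oracle <- function(X, y) {
  start <- rep(0, ncol(X))
  opt <- stats::optim(start, nll_logistic, X = X, y = y,
                      method = "Nelder-Mead",
                      control = list(maxit = 50000, reltol = 1e-14))
  opt$par
}

# Random instances with ground-truth separability by construction:
# separable ones get labels from a random hyperplane with a guaranteed
# margin; non-separable ones contain an identical point with both labels.
random_separability_instance <- function(n, p, separable, margin = 0.3) {
  X <- matrix(stats::rnorm(n * p), n, p)
  if (separable) {
    repeat {
      w <- stats::rnorm(p + 1)
      eta <- drop(cbind(1, X) %*% w)
      keep <- abs(eta) > margin
      if (sum(keep) >= max(6, p + 2) &&
          length(unique(eta[keep] > 0)) == 2L) break
    }
    X <- X[keep, , drop = FALSE]
    y <- as.integer(drop(cbind(1, X) %*% w) > 0)
  } else {
    y <- stats::rbinom(n, 1, 0.5)
    X <- rbind(X, X[1, ], X[1, ])
    y <- c(y, 0L, 1L)
  }
  colnames(X) <- paste0("x", seq_len(p))
  list(X = X, y = y)
}

# Ten weak standard-normal predictors at the 15-vs-51 study shape.
weak_predictor_panel <- function(k = 10, effect = 0.3) {
  data.frame(name = paste0("w", seq_len(k)), domain = "behavioral",
             timescale = "fast", sol_mean = 0, sol_sd = 1,
             greg_mean = effect, greg_sd = 1, stringsAsFactors = FALSE)
}

low_epv_population <- function(seed) {
  simulate_phase_population(phase_pop_config(
    traits = weak_predictor_panel(), collinear_pair = NULL,
    sign_redundant_pair = NULL, seed = seed))
}
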