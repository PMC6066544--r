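#' Configuration for the latent-axis simulation
#'
#' Two uncorrelated uniform traits and a latent variable
#' `y' = beta0 + beta1 * t1 + beta2 * t2 + eps` with logistic noise;
#' environment B is assigned where `y' > 0`, A otherwise. With the default
#' coefficients (0, 2.5, 5) the true latent axis has slope 2 over t1 and the
#' data-generating model is exactly the logistic regression
#' `logit(P(E = B)) = 2.5 t1 + 5 t2`.
#'
#' @param N Number of individuals.
#' @param beta0,beta1,beta2 Latent-model coefficients.
#' @param trait_low,trait_high Uniform sampling bounds for both traits.
#' @param noise_scale Scale of the logistic noise (0 gives the deterministic
#'   boundary `E = B` iff the linear predictor is positive).
#' @param seed Optional integer seed.
#' @return A list of class `latent_sim_config`.
#' @export
latent_sim_config <- function(N = 800L, beta0 = 0, beta1 = 2.5, beta2 = 5,
                              trait_low = -0.5, trait_high = 0.5,
                              noise_scale = 1, seed = NULL) {
  stopifnot(N >= 1, trait_low < trait_high, noise_scale >= 0)
  structure(list(N = as.integer(N), beta0 = beta0, beta1 = beta1,
                 beta2 = beta2, trait_low = trait_low,
                 trait_high = trait_high, noise_scale = noise_scale,
                 seed = seed),
            class = "latent_sim_config")
}

#' Simulate two-environment data from a latent axis
#'
#' Logistic noise is drawn by inverse-CDF transform of uniform draws
#' (`qlogis(runif(N))`) so the stream is reproducible from a single seed.
#'
#' @param config A [latent_sim_config()].
#' @return A [phenotype_table()] with traits `t1`, `t2` and environment
#'   labels `A`/`B`; the generating config is attached as attribute
#'   `"sim_config"`.
#' @export
#' @examples
#' pop <- simulate_latent_axis(latent_sim_config(N = 100, seed = 7))
#' table(pop$environment)
simulate_latent_axis <- function(config = latent_sim_config()) {
  stopifnot(inherits(config, "latent_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  t1 <- stats::runif(config$N, config$trait_low, config$trait_high)
  t2 <- stats::runif(config$N, config$trait_low, config$trait_high)
  eps <- if (config$noise_scale > 0) {
    config$noise_scale * stats::qlogis(stats::runif(config$N))
  } else {
    numeric(config$N)
  }
  y_latent <- config$beta0 + config$beta1 * t1 + config$beta2 * t2 + eps
  env <- ifelse(y_latent > 0, "B", "A")
  out <- phenotype_table(
    data.frame(environment = env, t1 = t1, t2 = t2,
               stringsAsFactors = FALSE),
    data.frame(trait = c("t1", "t2"), domain = "behavioral",
               timescale = "fast", stringsAsFactors = FALSE))
  attr(out, "sim_config") <- config
  out
}

#' Default locust-like trait panel
#'
#' Thirteen candidate predictors shaped like a final-instar nymph assay:
#' fast behavioral traits (speeds, movement pattern, arena position) whose
#' distributions shift within hours of crowding, and slow morphometric
#' traits (femur, pronotum, head) fixed within a stadium. Two of the 13 are
#' derived, not drawn: `average_acceleration` is generated collinear with
#' `average_speed`, and `final_choice` encodes the sign of
#' `last_coordinate`. Values are synthetic shape-alikes of the named assay
#' variables, not calibrated measurements.
#'
#' @return A data.frame with columns `name`, `domain`, `timescale`,
#'   `sol_mean`, `sol_sd`, `greg_mean`, `greg_sd`.
#' @export
default_trait_panel <- function() {
  tr <- function(name, domain, timescale, sm, ss, gm, gs) {
    data.frame(name = name, domain = domain, timescale = timescale,
               sol_mean = sm, sol_sd = ss, greg_mean = gm, greg_sd = gs,
               stringsAsFactors = FALSE)
  }
  rbind(
    tr("average_speed", "behavioral", "fast", 1.00, 0.45, 1.60, 0.55),
    tr("erratic_movement", "behavioral", "fast", 0.30, 0.15, 0.55, 0.20),
    tr("stop_ratio", "behavioral", "fast", 0.55, 0.15, 0.35, 0.12),
    tr("turn_ratio", "behavioral", "fast", 0.40, 0.12, 0.45, 0.12),
    tr("time_moving", "behavioral", "fast", 120, 60, 300, 90),
    tr("distance_covered", "behavioral", "fast", 150, 70, 420, 130),
    tr("attraction_index", "behavioral", "fast", -0.40, 0.35, 0.45, 0.35),
    tr("last_coordinate", "behavioral", "fast", -0.25, 0.45, 0.30, 0.45),
    tr("hind_femur_length", "morphometric", "slow", 11.0, 0.8, NA, 1.0),
    tr("pronotum_length", "morphometric", "slow", 4.8, 0.35, 5.1, 0.35),
    tr("head_width", "morphometric", "slow", 3.4, 0.25, 3.7, 0.25))
}

#' Configuration for the two-phase population generator
#'
#' Emulates the structure of a crowding-assay dataset: a small solitarious
#' and a larger gregarious cohort, fast behavioral traits that converge
#' toward gregarious values within hours of crowding (exponential
#' saturation, default half-time 4 h), slow morphometric traits fixed at
#' natal-phase values, an optional near-perfectly collinear trait pair, an
#' optional sign-redundant pair, and a configurable gregarious/solitarious
#' femur-length ratio (0.9 matches the usual shorter gregarious femur;
#' 1.6 reproduces the anomalous longer-legged gregarious cohort that makes
#' size-normalization of speed destroy its phase signal).
#'
#' @param n_solitarious,n_gregarious Cohort sizes.
#' @param traits Trait panel as in [default_trait_panel()].
#' @param crowding_hours Hours of crowding experienced by the solitarious
#'   cohort (scalar or one value per solitarious individual); drives fast
#'   traits toward gregarious values, leaves slow traits untouched.
#' @param crowding_half_time Half-time (h) of the saturating crowding
#'   response.
#' @param femur_ratio Gregarious/solitarious mean `hind_femur_length`.
#' @param collinear_pair `list(base =, derived =, r =)` or `NULL`.
#' @param sign_redundant_pair `list(base =, derived =)` or `NULL`.
#' @param seed Optional integer seed.
#' @return A list of class `phase_pop_config`.
#' @export
phase_pop_config <- function(n_solitarious = 15L, n_gregarious = 51L,
                             traits = default_trait_panel(),
                             crowding_hours = 0, crowding_half_time = 4,
                             femur_ratio = 0.9,
                             collinear_pair = list(
                               base = "average_speed",
                               derived = "average_acceleration",
                               r = 0.9998),
                             sign_redundant_pair = list(
                               base = "last_coordinate",
                               derived = "final_choice"),
                             seed = NULL) {
  stopifnot(n_solitarious >= 2, n_gregarious >= 2,
            all(traits$sol_sd > 0), all(traits$greg_sd > 0, na.rm = TRUE),
            crowding_half_time > 0, femur_ratio > 0,
            all(crowding_hours >= 0))
  if (!is.null(collinear_pair) &&
      (collinear_pair$r <= 0 || collinear_pair$r > 1)) {
    stop("infeasible collinearity target: r must be in (0, 1]",
         call. = FALSE)
  }
  structure(list(n_solitarious = as.integer(n_solitarious),
                 n_gregarious = as.integer(n_gregarious), traits = traits,
                 crowding_hours = crowding_hours,
                 crowding_half_time = crowding_half_time,
                 femur_ratio = femur_ratio, collinear_pair = collinear_pair,
                 sign_redundant_pair = sign_redundant_pair, seed = seed),
            class = "phase_pop_config")
}

#' Simulate a two-phase locust-like population
#'
#' Individuals are drawn per natal phase from the trait panel. For the
#' solitarious cohort, each fast behavioral trait is interpolated from its
#' solitarious toward its gregarious distribution by the saturating
#' crowding response `f(h) = 1 - 2^(-h / half_time)`; slow traits stay at
#' natal-phase values regardless of crowding — the decoupling of behavioral
#' and morphological phase state. Environment labels record the *natal*
#' phase, so a 24 h-crowded solitarious individual behaves gregariously but
#' is labeled (and built) solitarious.
#'
#' @param config A [phase_pop_config()].
#' @return A [phenotype_table()] with environment labels
#'   `solitarious`/`gregarious` and columns `crowding_hours` plus all panel
#'   and derived traits; the config is attached as attribute `"sim_config"`.
#' @export
simulate_phase_population <- function(config = phase_pop_config()) {
  stopifnot(inherits(config, "phase_pop_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  panel <- config$traits
  if ("hind_femur_length" %in% panel$name) {
    ii <- match("hind_femur_length", panel$name)
    panel$greg_mean[ii] <- panel$sol_mean[ii] * config$femur_ratio
  }
  if (anyNA(panel$greg_mean) || anyNA(panel$greg_sd)) {
    stop("trait panel has unresolved gregarious parameters", call. = FALSE)
  }

  n_sol <- config$n_solitarious
  n_greg <- config$n_gregarious
  h <- rep_len(config$crowding_hours, n_sol)
  f <- 1 - 2^(-h / config$crowding_half_time)

  cols <- list(
    environment = c(rep("solitarious", n_sol), rep("gregarious", n_greg)),
    crowding_hours = c(h, rep(NA_real_, n_greg)))
  for (ii in seq_len(nrow(panel))) {
    fast <- panel$timescale[ii] == "fast"
    mix <- if (fast) f else rep(0, n_sol)
    sol_mean <- panel$sol_mean[ii] + mix * (panel$greg_mean[ii] -
                                              panel$sol_mean[ii])
    sol_sd <- panel$sol_sd[ii] + mix * (panel$greg_sd[ii] - panel$sol_sd[ii])
    cols[[panel$name[ii]]] <- c(
      stats::rnorm(n_sol, sol_mean, sol_sd),
      stats::rnorm(n_greg, panel$greg_mean[ii], panel$greg_sd[ii]))
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE)

  meta <- data.frame(trait = panel$name, domain = panel$domain,
                     timescale = panel$timescale, stringsAsFactors = FALSE)

  cp <- config$collinear_pair
  if (!is.null(cp)) {
    base <- df[[cp$base]]
    if (is.null(base)) stop("collinear base trait '", cp$base, "' missing",
                            call. = FALSE)
    # derived = 0.8 * base + Gaussian jitter, jitter variance solved from
    # the target correlation: r^2 = var(a b) / (var(a b) + s^2)
    a <- 0.8
    s2 <- (a^2 * stats::var(base)) * (1 / cp$r^2 - 1)
    df[[cp$derived]] <- a * base + stats::rnorm(nrow(df), 0, sqrt(s2))
    ib <- match(cp$base, meta$trait)
    meta <- rbind(meta, data.frame(trait = cp$derived,
                                   domain = meta$domain[ib],
                                   timescale = meta$timescale[ib],
                                   stringsAsFactors = FALSE))
  }
  sp <- config$sign_redundant_pair
  if (!is.null(sp)) {
    base <- df[[sp$base]]
    if (is.null(base)) stop("sign-redundancy base trait '", sp$base,
                            "' missing", call. = FALSE)
    df[[sp$derived]] <- ifelse(base >= 0, 1, -1)
    ib <- match(sp$base, meta$trait)
    meta <- rbind(meta, data.frame(trait = sp$derived,
                                   domain = meta$domain[ib],
                                   timescale = meta$timescale[ib],
                                   stringsAsFactors = FALSE))
  }

  out <- phenotype_table(df, meta)
  attr(out, "sim_config") <- config
  out
}

#' Simulate a two-strain dataset from a known logistic model
#'
#' Standard-normal predictors `x1 ... xk`, a balanced two-level strain
#' factor, and phase labels drawn from `logit(P(gregarious)) = X beta`
#' within strain A and `X (beta + delta)` within strain B. With
#' `delta = 0` the pooled model is correct (the null of the
#' strain-generalization comparison); a nonzero `delta` (e.g. a
#' sign-flipped coefficient) makes the crossed model necessary.
#'
#' @param n_per_strain Individuals per strain.
#' @param k Number of predictors.
#' @param beta Coefficients `c(intercept, b1 ... bk)` in strain A.
#' @param delta Coefficient offsets for strain B, same length as `beta`.
#' @param seed Optional integer seed.
#' @return A [phenotype_table()] with a `strain` column.
#' @export
simulate_strain_dataset <- function(n_per_strain = 240L, k = 3L,
                                    beta = c(0, rep(0.8, k)),
                                    delta = rep(0, k + 1L), seed = NULL) {
  stopifnot(k >= 1, length(beta) == k + 1L, length(delta) == k + 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * n_per_strain
  strain <- rep(c("A", "B"), each = n_per_strain)
  X <- matrix(stats::rnorm(n * k), n, k,
              dimnames = list(NULL, paste0("x", seq_len(k))))
  b <- rbind(A = beta, B = beta + delta)
  eta <- b[strain, 1L] + rowSums(X * b[strain, -1L, drop = FALSE])
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  df <- data.frame(environment = ifelse(y == 1L, "gregarious", "solitarious"),
                   strain = strain, X, stringsAsFactors = FALSE)
  phenotype_table(df,
                  data.frame(trait = colnames(X), domain = "behavioral",
                             timescale = "fast", stringsAsFactors = FALSE),
                  strain_col = "strain")
}

#' Write the canonical synthetic fixture suite
#'
#' Emits, as plain CSV with YAML trait-metadata sidecars: the latent-axis
#' table; a 15 + 51 two-phase table with the anomalous femur ratio,
#' collinear pair and sign-redundant pair; and a strain-effect and a
#' no-strain-effect table. A `manifest.json` records every file with the
#' seed and config that generated it, so the suite is byte-reproducible.
#'
#' @param outdir Writable output directory (created if needed).
#' @param seed Base integer seed; fixture i uses `seed + i - 1`.
#' @return The manifest, invisibly (list of per-fixture entries).
#' @export
write_fixture_suite <- function(outdir, seed = 20260101L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  emit <- function(name, table, config_desc, fixture_seed) {
    data_file <- file.path(outdir, paste0(name, ".csv"))
    meta_file <- file.path(outdir, paste0(name, "_traits.yaml"))
    write_phenotype_table(table, data_file, meta_file)
    manifest[[name]] <<- list(data = basename(data_file),
                              meta = basename(meta_file),
                              n = nrow(table), seed = fixture_seed,
                              config = config_desc)
  }

  emit("latent_axis",
       simulate_latent_axis(latent_sim_config(seed = seed)),
       list(generator = "simulate_latent_axis", N = 800,
            beta = c(0, 2.5, 5)), seed)
  emit("phase_population_anomaly",
       simulate_phase_population(
         phase_pop_config(femur_ratio = 1.6, seed = seed + 1L)),
       list(generator = "simulate_phase_population", n_solitarious = 15,
            n_gregarious = 51, femur_ratio = 1.6), seed + 1L)
  emit("strain_null",
       simulate_strain_dataset(seed = seed + 2L),
       list(generator = "simulate_strain_dataset", delta = "none"),
       seed + 2L)
  emit("strain_effect",
       simulate_strain_dataset(delta = c(0, -1.6, 0, 0), seed = seed + 3L),
       list(generator = "simulate_strain_dataset",
            delta = c(0, -1.6, 0, 0)), seed + 3L)

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
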