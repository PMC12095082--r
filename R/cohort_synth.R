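# Synthetic growth cohort with known timing structure.
#
# Each child belongs to one of three timing types. A type is a smooth BMI
# template on [0.25, 16] years; a child's curve is the template composed with
# an individual random warping of normalized time (phase noise), scaled by a
# multiplicative amplitude factor, and observed as height/weight pairs at
# jittered visit ages with measurement error. Height follows a single
# monotone template shared by all types, so all cluster signal lives in the
# timing of BMI.

#' Default per-type BMI template parameters
#'
#' Three timing types: Type 1 is the textbook trajectory (infancy peak near
#' 0.75 y, adiposity rebound, pubertal rise); Type 2 adds a mid-childhood
#' bump (peaking near 5 years) with an earlier pubertal rise, giving
#' trajectories with two or three peaks and an early, short BMI decrease;
#' Type 3 is a later-maturing two-peak variant, with a secondary bump near
#' 11 years and a pubertal rise three years later than Type 1's.
#'
#' Template form (BMI in kg/m^2, age t in years):
#' `c0 + a_inf*exp(-((t-p_inf)/s_inf)^2) + a_mid*exp(-((t-p_mid)/s_mid)^2) +
#'  a_pub/(1+exp(-(t-p_pub)/s_pub))`.
#'
#' @return Named list of three parameter lists (`type1`, `type2`, `type3`).
#' @export
default_cluster_params <- function() {
  base <- list(c0 = 13, a_inf = 4, p_inf = 0.75, s_inf = 0.6,
               a_mid = 0, p_mid = 6.5, s_mid = 1.5,
               a_pub = 5, p_pub = 11.5, s_pub = 1.5)
  type2 <- modifyList(base, list(a_mid = 2.5, p_mid = 5, s_mid = 0.8,
                                 p_pub = 10.5))
  type3 <- modifyList(base, list(a_mid = 2.5, p_mid = 11, s_mid = 0.8,
                                 p_pub = 14.5))
  list(type1 = base, type2 = type2, type3 = type3)
}

#' Evaluate a BMI template
#'
#' @param params Named list with elements `c0`, `a_inf`, `p_inf`, `s_inf`,
#'   `a_mid`, `p_mid`, `s_mid`, `a_pub`, `p_pub`, `s_pub` (see
#'   [default_cluster_params()]). Missing Gaussian-bump fields default to an
#'   absent bump (`a_mid = 0`).
#' @param ages Ages in years, all within `[0.25, 16]`.
#' @return BMI values (kg/m^2) at `ages`.
#' @export
make_template_bmi <- function(params, ages) {
  stopifnot(is.numeric(ages), length(ages) >= 1)
  if (any(ages < AGE_MIN - 1e-9) || any(ages > AGE_MAX + 1e-9)) {
    stop("ages must lie within [", AGE_MIN, ", ", AGE_MAX, "] years")
  }
  p <- params
  defaults <- list(a_mid = 0, p_mid = 6.5, s_mid = 1.5)
  for (nm in names(defaults)) if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
  need <- c("c0", "a_inf", "p_inf", "s_inf", "a_pub", "p_pub", "s_pub")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing template parameters: ", paste(miss, collapse = ", "))
  p$c0 +
    p$a_inf * exp(-((ages - p$p_inf) / p$s_inf)^2) +
    p$a_mid * exp(-((ages - p$p_mid) / p$s_mid)^2) +
    p$a_pub / (1 + exp(-(ages - p$p_pub) / p$s_pub))
}

# Monotone height template in cm, shared by all timing types.
height_template <- function(ages) {
  50 + 110 * (1 - exp(-ages / 2.8)) + 20 / (1 + exp(-(ages - 12) / 1.2))
}

#' Sample a random warping function
#'
#' Draws a boundary-fixed, strictly increasing reparameterization of `[0, 1]`
#' as `gamma(t) = int_0^t exp(w(s)) ds / int_0^1 exp(w(s)) ds`, where `w` is
#' a finite Fourier sine series with mean-zero Gaussian coefficients of
#' standard deviation `warp_strength`. `warp_strength = 0` gives the identity.
#'
#' @param warp_strength Nonnegative; sd of the log-rate sine coefficients.
#' @param seed Optional integer; if supplied, the RNG is seeded so the draw
#'   is reproducible. `NULL` uses (and advances) the current RNG stream.
#' @param n_points Number of discretization points (>= 3).
#' @param n_terms Number of sine terms in `w` (default 2: maturational
#'   tempo varies smoothly, as shift-and-stretch-like distortions, so only
#'   low-frequency warps are drawn).
#' @return A `warping_function`: list with uniform `t` and values `gamma`.
#' @export
sample_warping <- function(warp_strength, seed = NULL, n_points = 101,
                           n_terms = 2) {
  if (warp_strength < 0) stop("warp_strength must be nonnegative")
  if (n_points < 3) stop("n_points must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, 1, length.out = n_points)
  if (warp_strength == 0) {
    return(warping_function(t, t))
  }
  coefs <- rnorm(n_terms, mean = 0, sd = warp_strength)
  w <- rep(0, n_points)
  for (k in seq_len(n_terms)) w <- w + coefs[k] * sin(pi * k * t)
  rate <- exp(w)
  cum <- cumsum(c(0, (rate[-1] + rate[-n_points]) / 2)) / (n_points - 1)
  gamma <- cum / cum[n_points]
  gamma[1] <- 0
  gamma[n_points] <- 1
  warping_function(t, gamma)
}

#' Construct a warping function object
#'
#' @param t Uniform abscissa in `[0, 1]`.
#' @param gamma Values in `[0, 1]`, nondecreasing, `gamma[1] = 0`,
#'   `gamma[n] = 1`.
#' @return Object of class `warping_function`.
#' @export
warping_function <- function(t, gamma) {
  stopifnot(length(t) == length(gamma))
  if (abs(gamma[1]) > 1e-10 || abs(gamma[length(gamma)] - 1) > 1e-10) {
    stop("gamma must satisfy gamma(0) = 0 and gamma(1) = 1")
  }
  if (any(diff(gamma) < -1e-12)) stop("gamma must be nondecreasing")
  structure(list(t = t, gamma = gamma), class = "warping_function")
}

# Evaluate a warping function at arbitrary t by linear interpolation.
eval_warping <- function(warp, t) {
  approx(warp$t, warp$gamma, xout = t, rule = 2)$y
}

#' Simulation configuration
#'
#' Assembles and validates the configuration for [simulate_cohort()].
#' Defaults describe a cohort of 60 children (20 per timing type) with
#' moderate phase noise and realistic clinic-record measurement error:
#' visits dense in infancy and every year at school age, first visit before
#' 6 months and follow-up to 16 years, so all children pass the selection
#' criteria by construction.
#'
#' @param n_per_cluster Children per timing type (>= 1).
#' @param cluster_params List of per-type template parameter lists.
#' @param warp_strength Phase-noise level (sd of warp log-rate coefficients).
#' @param amplitude_sd Sd of the per-child log multiplicative BMI scale.
#' @param height_noise_sd Measurement noise on height, cm.
#' @param weight_noise_sd Measurement noise on weight, kg.
#' @param visit_schedule Ordered visit ages in years; first < 0.5, last >= 16.
#' @param visit_jitter_sd Sd of Gaussian jitter on visit ages, years.
#' @param seed Integer RNG seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_cluster = 20,
                       cluster_params = default_cluster_params(),
                       warp_strength = 0.3,
                       amplitude_sd = 0.05,
                       height_noise_sd = 0.5,
                       weight_noise_sd = 0.3,
                       visit_schedule = c(0.3, 0.5, 0.75, 1, 1.25, 1.5, 2, 3,
                                          4, 5, 6, 7, 8, 9, 10, 11, 12, 13,
                                          14, 15, 16),
                       visit_jitter_sd = 0.05,
                       seed = 1L) {
  cfg <- list(n_per_cluster = as.integer(n_per_cluster),
              cluster_params = cluster_params,
              warp_strength = warp_strength,
              amplitude_sd = amplitude_sd,
              height_noise_sd = height_noise_sd,
              weight_noise_sd = weight_noise_sd,
              visit_schedule = visit_schedule,
              visit_jitter_sd = visit_jitter_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_per_cluster < 1) stop("n_per_cluster must be >= 1")
  if (cfg$warp_strength < 0) stop("warp_strength must be nonnegative")
  if (cfg$amplitude_sd < 0) stop("amplitude_sd must be nonnegative")
  if (cfg$height_noise_sd < 0 || cfg$weight_noise_sd < 0) {
    stop("measurement noise sds must be nonnegative")
  }
  vs <- cfg$visit_schedule
  if (any(diff(vs) <= 0)) stop("visit_schedule must be strictly increasing")
  if (vs[1] >= 0.5) stop("first visit must be before 6 months (age < 0.5 y)")
  if (vs[length(vs)] < 16) stop("last visit must be at age 16 y or later")
  if (length(cfg$cluster_params) < 1) stop("at least one cluster template needed")
  invisible(cfg)
}

#' Simulate a synthetic growth cohort
#'
#' For each child: the type template is composed with an individual random
#' warp of normalized time and scaled by `exp(N(0, amplitude_sd))`; height
#' follows the shared monotone template; weight is derived as
#' `BMI * (height/100)^2`; both are recorded at jittered visit ages with
#' Gaussian measurement noise. Jittered ages are clamped so every child
#' still has a first visit before 6 months and follow-up to 16 years.
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_cohort`: list with `records` (long
#'   data.frame: child_id, sex, age_years, height_cm, weight_kg),
#'   `true_labels` (named integer vector), `true_warps` (list of
#'   `warping_function`), and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_types <- length(config$cluster_params)
  n <- config$n_per_cluster * n_types
  ids <- sprintf("C%03d", seq_len(n))
  labels <- rep(seq_len(n_types), each = config$n_per_cluster)
  sexes <- rep(c("F", "M"), length.out = n)

  records <- vector("list", n)
  warps <- vector("list", n)
  for (i in seq_len(n)) {
    warps[[i]] <- sample_warping(config$warp_strength, seed = NULL,
                                 n_points = 101)
    amp <- exp(rnorm(1, 0, config$amplitude_sd))
    ages <- config$visit_schedule +
      rnorm(length(config$visit_schedule), 0, config$visit_jitter_sd)
    ages <- pmin(pmax(ages, AGE_MIN), AGE_MAX)
    ages[1] <- min(ages[1], 0.49)
    ages[length(ages)] <- AGE_MAX
    ages <- sort(unique(ages))

    warped_age <- denormalize_age(eval_warping(warps[[i]], normalize_age(ages)))
    bmi <- amp * make_template_bmi(config$cluster_params[[labels[i]]],
                                   warped_age)
    h <- height_template(ages)
    w <- bmi * (h / 100)^2
    h_obs <- h + rnorm(length(ages), 0, config$height_noise_sd)
    w_obs <- w + rnorm(length(ages), 0, config$weight_noise_sd)
    records[[i]] <- data.frame(child_id = ids[i], sex = sexes[i],
                               age_years = ages, height_cm = h_obs,
                               weight_kg = w_obs,
                               stringsAsFactors = FALSE)
  }
  structure(list(records = do.call(rbind, c(records, make.row.names = FALSE)),
                 true_labels = setNames(labels, ids),
                 true_warps = setNames(warps, ids),
                 config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `measurements.csv` (child_id, sex, age_years, height_cm, weight_kg)
#' and `truth.csv` (child_id, true_label) into `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mfile <- file.path(dir, "measurements.csv")
  tfile <- file.path(dir, "truth.csv")
  write.csv(cohort$records, mfile, row.names = FALSE)
  write.csv(data.frame(child_id = names(cohort$true_labels),
                       true_label = unname(cohort$true_labels)),
            tfile, row.names = FALSE)
  invisible(c(measurements = mfile, truth = tfile))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic growth cohort:", length(x$true_labels), "children,",
      length(unique(x$true_labels)), "timing types,",
      nrow(x$records), "visit records\n")
  invisible(x)
}
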