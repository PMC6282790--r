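# Seeded simulators with known ground truth for every pipeline input:
# retention-time tables and chromatograms under the reciprocal-linear binding
# law k' = k'0 / (1 + K_AM * C_M), and compound tables under the logit-linear
# %HIA model.

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Default concentration levels: 6 total-surfactant levels spanning 5-17 mM,
# converted to micellar concentration with the 0.0046 M mixture CMC.
default_cm_levels <- function() {
  total_mM <- seq(5, 17, length.out = 6)
  micellar_concentration(total_mM / 1000, 0.0046)
}

#' Specify a retention simulation
#'
#' Ground-truth parameters for simulating retention times of one compound
#' under the binding law `k' = k'0 / (1 + K_AM * C_M)`. Retention-time noise
#' is multiplicative with coefficient of variation `rt_noise_cv`, reflecting
#' proportional chromatographic variability. Negative `k_am` simulates an
#' antibinding solute (retention increasing with micellar concentration),
#' valid while `k_am * C_M > -1`.
#'
#' Defaults mirror the reference experiment shape: 6 concentration levels
#' spanning 5-17 mM total surfactant (converted with the 0.0046 M mixture
#' CMC), 3 replicates per level, dead time 1.5 min.
#'
#' @param drug Compound label.
#' @param k_prime_0 Retention factor at C_M = 0 (> 0).
#' @param k_am Association constant (M^-1); negative for antibinding.
#' @param t0 Dead time (min, > 0).
#' @param cm_levels Micellar concentrations (M, >= 0).
#' @param replicates Injections per level (>= 1).
#' @param rt_noise_cv CV of multiplicative retention-time noise (>= 0).
#' @param seed Integer seed.
#' @return A `retention_sim_spec`.
#' @export
retention_sim_spec <- function(drug = "sim", k_prime_0 = 10, k_am = 40,
                               t0 = 1.5, cm_levels = default_cm_levels(),
                               replicates = 3L, rt_noise_cv = 0.01,
                               seed = 1L) {
  stopifnot(k_prime_0 > 0, t0 > 0, replicates >= 1L, rt_noise_cv >= 0,
            length(cm_levels) >= 1L, all(cm_levels >= 0))
  structure(list(drug = as.character(drug), k_prime_0 = k_prime_0,
                 k_am = k_am, t0 = t0, cm_levels = as.numeric(cm_levels),
                 replicates = as.integer(replicates),
                 rt_noise_cv = rt_noise_cv, seed = as.integer(seed)),
            class = "retention_sim_spec")
}

#' Simulate a retention-time table
#'
#' For each micellar concentration level and replicate, the retention time is
#' `t0 * (1 + k'0 / (1 + k_am * C_M)) * (1 + eps)` with
#' `eps ~ Normal(0, rt_noise_cv)`. Deterministic for a fixed seed.
#'
#' @param spec A [retention_sim_spec()].
#' @return data.frame with columns `drug`, `cm`, `replicate`,
#'   `retention_time_min`, plus attributes `t0` and `seed`.
#' @export
#' @examples
#' tab <- simulate_retention_table(retention_sim_spec(rt_noise_cv = 0))
simulate_retention_table <- function(spec) {
  stopifnot(inherits(spec, "retention_sim_spec"))
  if (any(spec$k_am * spec$cm_levels <= -1))
    stop("non-physical spec: k_am * C_M <= -1 at some level", call. = FALSE)
  k <- spec$k_prime_0 / (1 + spec$k_am * spec$cm_levels)
  rt_true <- spec$t0 * (1 + k)
  n <- length(spec$cm_levels) * spec$replicates
  eps <- with_seed(spec$seed, stats::rnorm(n, 0, spec$rt_noise_cv))
  out <- data.frame(
    drug = spec$drug,
    cm = rep(spec$cm_levels, each = spec$replicates),
    replicate = rep(seq_len(spec$replicates), times = length(spec$cm_levels)),
    retention_time_min = rep(rt_true, each = spec$replicates) * (1 + eps))
  attr(out, "t0") <- spec$t0
  attr(out, "seed") <- spec$seed
  out
}

#' Specify a chromatogram simulation
#'
#' Extends [retention_sim_spec()] with trace-shape parameters: Gaussian
#' analyte peak, optional solvent-front peak at the dead time, linear baseline
#' drift and additive Gaussian detector noise.
#'
#' @param retention A [retention_sim_spec()].
#' @param peak_width_sd Gaussian peak SD (min).
#' @param peak_height Analyte peak height (detector units).
#' @param baseline_noise_sd Additive noise SD.
#' @param baseline_drift_slope Baseline drift (units/min).
#' @param sampling_interval Sample spacing (min, > 0).
#' @param duration Trace length (min); must exceed the largest expected
#'   retention time plus 3 peak widths.
#' @param solvent_front Add an unretained-tracer peak at t0?
#' @return A `chromatogram_sim_spec`.
#' @export
chromatogram_sim_spec <- function(retention = retention_sim_spec(),
                                  peak_width_sd = 0.08, peak_height = 1,
                                  baseline_noise_sd = 0,
                                  baseline_drift_slope = 0,
                                  sampling_interval = 0.01, duration = NULL,
                                  solvent_front = TRUE) {
  stopifnot(inherits(retention, "retention_sim_spec"),
            peak_width_sd > 0, peak_height > 0, sampling_interval > 0)
  if (any(retention$k_am * retention$cm_levels <= -1))
    stop("non-physical spec: k_am * C_M <= -1 at some level", call. = FALSE)
  rt_max <- max(retention$t0 * (1 + retention$k_prime_0 /
                                  (1 + retention$k_am * retention$cm_levels)),
                retention$t0 * (1 + retention$k_prime_0))
  if (is.null(duration)) duration <- rt_max * 1.2 + 3 * peak_width_sd
  if (duration <= rt_max + 3 * peak_width_sd)
    stop("duration too short for the expected retention times", call. = FALSE)
  structure(list(retention = retention, peak_width_sd = peak_width_sd,
                 peak_height = peak_height,
                 baseline_noise_sd = baseline_noise_sd,
                 baseline_drift_slope = baseline_drift_slope,
                 sampling_interval = sampling_interval, duration = duration,
                 solvent_front = solvent_front),
            class = "chromatogram_sim_spec")
}

#' Simulate a chromatogram at one micellar concentration
#'
#' Places a Gaussian analyte peak at the (noise-perturbed) retention time
#' implied by the binding law, optionally a solvent-front Gaussian at the dead
#' time, adds linear baseline drift and additive detector noise. Seeded via
#' the spec's seed combined with the level index so traces at different
#' levels are independent but reproducible.
#'
#' @param spec A [chromatogram_sim_spec()].
#' @param level Micellar concentration C_M (M) for this injection.
#' @return A [chromatogram()]; the true analyte retention time is attached as
#'   attribute `rt_true`.
#' @export
simulate_chromatogram <- function(spec, level) {
  stopifnot(inherits(spec, "chromatogram_sim_spec"))
  ret <- spec$retention
  level <- as.numeric(level)
  if (ret$k_am * level <= -1)
    stop("non-physical level: k_am * C_M <= -1", call. = FALSE)
  k <- ret$k_prime_0 / (1 + ret$k_am * level)
  rt_true <- ret$t0 * (1 + k)
  seed_here <- ret$seed + round(1e6 * level) %% 1000L
  tt <- seq(0, spec$duration, by = spec$sampling_interval)
  draws <- with_seed(seed_here, list(
    eps = stats::rnorm(1, 0, ret$rt_noise_cv),
    noise = stats::rnorm(length(tt), 0, spec$baseline_noise_sd)))
  rt <- rt_true * (1 + draws$eps)
  sig <- spec$peak_height * exp(-(tt - rt)^2 / (2 * spec$peak_width_sd^2))
  if (spec$solvent_front)
    sig <- sig + 0.5 * spec$peak_height *
      exp(-(tt - ret$t0)^2 / (2 * spec$peak_width_sd^2))
  sig <- sig + spec$baseline_drift_slope * tt + draws$noise[seq_along(tt)]
  ch <- chromatogram(tt, sig, drug = ret$drug,
                     total_surfactant_M = level + 0.0046)
  attr(ch, "rt_true") <- rt
  ch
}

#' Specify a compound-table simulation
#'
#' Ground truth for simulating compound tables under the logit-linear model
#' `logit(%HIA) = b0 + b1 * log_pmw + b2 * psa + Normal(0, noise_sd)`.
#' Defaults use the reference model's coefficients, predictor ranges covering
#' the reference compounds, and noise at the scale of the reference residual
#' standard error (0.247 logit units).
#'
#' @param n_compounds Number of compounds (>= 5).
#' @param beta Length-3 vector: intercept, log Pmw coefficient, PSA
#'   coefficient.
#' @param log_pmw_range,psa_range Uniform sampling ranges for the predictors.
#' @param noise_sd Residual SD in logit units (>= 0).
#' @param validation_fraction Fraction of records flagged `validation`.
#' @param seed Integer seed.
#' @return A `compound_sim_spec`.
#' @export
compound_sim_spec <- function(n_compounds = 50L,
                              beta = c(4.103, -0.939, -0.02218),
                              log_pmw_range = c(0.9, 3.0),
                              psa_range = c(37, 89),
                              noise_sd = 0.247,
                              validation_fraction = 0,
                              seed = 1L) {
  stopifnot(n_compounds >= 5L, length(beta) == 3L, noise_sd >= 0,
            length(log_pmw_range) == 2L, log_pmw_range[1] < log_pmw_range[2],
            length(psa_range) == 2L, psa_range[1] < psa_range[2],
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(n_compounds = as.integer(n_compounds), beta = beta,
                 log_pmw_range = log_pmw_range, psa_range = psa_range,
                 noise_sd = noise_sd,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "compound_sim_spec")
}

#' Simulate a compound table from the logit-linear model
#'
#' Draws predictors uniformly from the spec ranges, computes the logit with
#' additive Gaussian noise and back-transforms to %HIA. Records whose %HIA
#' equals 0 or 100 at double precision are redrawn so every record has a
#' finite logit. A `validation_fraction` of records is flagged
#' `role = "validation"`; the rest are `train`.
#'
#' @param spec A [compound_sim_spec()].
#' @return data.frame with columns `name`, `log_pmw`, `psa`, `hia_percent`,
#'   `role`; attribute `seed`.
#' @export
simulate_compound_table <- function(spec) {
  stopifnot(inherits(spec, "compound_sim_spec"))
  n <- spec$n_compounds
  out <- with_seed(spec$seed, {
    draw <- function(m) {
      lp <- stats::runif(m, spec$log_pmw_range[1], spec$log_pmw_range[2])
      ps <- stats::runif(m, spec$psa_range[1], spec$psa_range[2])
      L <- spec$beta[1] + spec$beta[2] * lp + spec$beta[3] * ps +
        stats::rnorm(m, 0, spec$noise_sd)
      data.frame(log_pmw = lp, psa = ps, hia_percent = inverse_logit_hia(L))
    }
    tab <- draw(n)
    for (i in 1:100) {           # redraw boundary-rounded records
      bad <- tab$hia_percent <= 0 | tab$hia_percent >= 100
      if (!any(bad)) break
      tab[bad, ] <- draw(sum(bad))
    }
    n_val <- floor(spec$validation_fraction * n)
    role <- rep("train", n)
    if (n_val > 0) role[sample.int(n, n_val)] <- "validation"
    cbind(data.frame(name = sprintf("compound_%03d", seq_len(n))), tab,
          data.frame(role = role))
  })
  attr(out, "seed") <- spec$seed
  out
}
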