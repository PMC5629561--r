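#' Simulation configuration
#'
#' Validated parameter set for [simulate_dataset()]. Defaults emulate a
#' tumor-cohort RNA-seq study: 479 samples, transformed (log2) expression
#' drawn around 8 with spread 2 (an RSEM/TPM-like scale), PSI drawn from a
#' Beta(2, 2) (broad, boundary-avoiding inclusion levels), unit Gaussian
#' noise on the transformed target, and 2 percent missing cells.
#'
#' Each target gene is wired to one TF and one *designated* splicing event;
#' its transformed expression follows the interaction model with that
#' event's transformed PSI. `frac_modulated` is the fraction of all
#' (pair x event) triplets generated with a non-zero interaction
#' coefficient; modulated triplets are placed on designated slots, so
#' `frac_modulated * n_pairs * n_events` must not exceed the number of
#' targets.
#'
#' @param n_samples Number of samples (>= 10).
#' @param n_tfs,n_targets_per_tf,n_events Scan dimensions.
#' @param frac_modulated Fraction of triplets with `beta3 != 0`.
#' @param beta3_effect Interaction coefficient of modulated triplets.
#' @param beta0_range,beta1_range,beta2_range Uniform ranges for the
#'   per-target intercept, TF effect and modulator effect.
#' @param noise_sd Gaussian noise sd on the transformed target scale (> 0
#'   unless exactly 0 for noise-free checks).
#' @param psi_alpha,psi_beta Beta-distribution shapes for PSI.
#' @param expr_mean_log,expr_sd_log Normal parameters of transformed TF
#'   expression.
#' @param missing_rate Fraction of cells set missing in the written
#'   matrices.
#' @param seed Integer seed; every draw flows from it.
#' @return A validated `"sim_config"` list.
#' @export
sim_config <- function(n_samples = 479, n_tfs = 5, n_targets_per_tf = 20,
                       n_events = 4, frac_modulated = 0.1, beta3_effect = 1,
                       beta0_range = c(1, 3), beta1_range = c(0.2, 0.8),
                       beta2_range = c(-0.5, 0.5), noise_sd = 1,
                       psi_alpha = 2, psi_beta = 2,
                       expr_mean_log = 8, expr_sd_log = 2,
                       missing_rate = 0.02, seed = 1) {
  cfg <- list(n_samples = n_samples, n_tfs = n_tfs,
              n_targets_per_tf = n_targets_per_tf, n_events = n_events,
              frac_modulated = frac_modulated, beta3_effect = beta3_effect,
              beta0_range = beta0_range, beta1_range = beta1_range,
              beta2_range = beta2_range, noise_sd = noise_sd,
              psi_alpha = psi_alpha, psi_beta = psi_beta,
              expr_mean_log = expr_mean_log, expr_sd_log = expr_sd_log,
              missing_rate = missing_rate, seed = seed)
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop(sprintf("invalid config field '%s': %s", field, msg),
                          call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(n_samples) && n_samples >= 10, "n_samples", "need >= 10")
  for (f in c("n_tfs", "n_targets_per_tf", "n_events"))
    chk(num1(cfg[[f]]) && cfg[[f]] >= 1, f, "need a positive count")
  chk(num1(frac_modulated) && frac_modulated >= 0 && frac_modulated <= 1,
      "frac_modulated", "need a fraction in [0, 1]")
  chk(num1(beta3_effect), "beta3_effect", "need a finite number")
  for (f in c("beta0_range", "beta1_range", "beta2_range"))
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 2L &&
          cfg[[f]][1L] <= cfg[[f]][2L], f, "need a length-2 interval")
  chk(num1(noise_sd) && noise_sd >= 0, "noise_sd", "need >= 0")
  chk(num1(psi_alpha) && psi_alpha > 0, "psi_alpha", "need > 0")
  chk(num1(psi_beta) && psi_beta > 0, "psi_beta", "need > 0")
  chk(num1(expr_sd_log) && expr_sd_log > 0, "expr_sd_log", "need > 0")
  chk(num1(expr_mean_log), "expr_mean_log", "need a finite number")
  chk(num1(missing_rate) && missing_rate >= 0 && missing_rate < 1,
      "missing_rate", "need a fraction in [0, 1)")
  chk(num1(seed) && seed == round(seed), "seed", "need an integer")
  n_mod <- round(frac_modulated * n_tfs * n_targets_per_tf * n_events)
  chk(n_mod <= n_tfs * n_targets_per_tf, "frac_modulated",
      sprintf("%d modulated triplets exceed the %d available targets (one designated event per target)",
              n_mod, n_tfs * n_targets_per_tf))
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic expression / PSI / pair dataset with ground truth
#'
#' Transformed TF expression is drawn Normal, PSI is drawn Beta, and each
#' target's transformed expression follows the interaction model against its
#' TF and its designated event's clamped-and-transformed PSI, plus Gaussian
#' noise. Expression matrices are returned on the raw scale via the exact
#' inverse `2^x - 1` of the pipeline's `log2(x + 1)` transform (values in the
#' extreme negative tail are clamped to 0 to keep expression non-negative);
#' PSI stays on its natural scale. Ground-truth coefficients are therefore
#' defined on the transformed scale used in fitting. The output is fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()] object.
#' @return List with `expression` (raw matrix), `psi` (matrix with
#'   `"event_gene"` attribute), `pairs` (tf/target data frame), `truth`
#'   (one row per pair x event triplet: `designated`, `modulated`,
#'   `beta0..beta3`) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_samples
  n_targets <- cfg$n_tfs * cfg$n_targets_per_tf
  samples <- sprintf("S%04d", seq_len(ns))
  tfs <- sprintf("TF%03d", seq_len(cfg$n_tfs))
  targets <- sprintf("TG%04d", seq_len(n_targets))
  events <- sprintf("EV%03d", seq_len(cfg$n_events))
  hosts <- sprintf("MD%03d", seq_len(cfg$n_events))

  x_t <- matrix(stats::rnorm(cfg$n_tfs * ns, cfg$expr_mean_log,
                             cfg$expr_sd_log),
                cfg$n_tfs, ns, dimnames = list(tfs, samples))
  psi <- matrix(stats::rbeta(cfg$n_events * ns, cfg$psi_alpha, cfg$psi_beta),
                cfg$n_events, ns, dimnames = list(events, samples))
  m_t <- transform_psi(clamp_psi(psi))

  tf_of <- rep(seq_len(cfg$n_tfs), each = cfg$n_targets_per_tf)
  ev_of <- rep_len(seq_len(cfg$n_events), n_targets)
  b0 <- stats::runif(n_targets, cfg$beta0_range[1L], cfg$beta0_range[2L])
  b1 <- stats::runif(n_targets, cfg$beta1_range[1L], cfg$beta1_range[2L])
  b2 <- stats::runif(n_targets, cfg$beta2_range[1L], cfg$beta2_range[2L])
  n_mod <- round(cfg$frac_modulated * n_targets * cfg$n_events)
  modulated <- sort(sample.int(n_targets, n_mod))
  b3 <- numeric(n_targets)
  b3[modulated] <- cfg$beta3_effect

  y_t <- matrix(0, n_targets, ns, dimnames = list(targets, samples))
  for (i in seq_len(n_targets)) {
    xv <- x_t[tf_of[i], ]
    mv <- m_t[ev_of[i], ]
    y_t[i, ] <- b0[i] + b1[i] * xv + b2[i] * mv + b3[i] * xv * mv +
      stats::rnorm(ns, 0, cfg$noise_sd)
  }

  expr <- pmax(2^rbind(x_t, y_t) - 1, 0)
  if (cfg$missing_rate > 0) {
    expr[stats::runif(length(expr)) < cfg$missing_rate] <- NA_real_
    psi_na <- stats::runif(length(psi)) < cfg$missing_rate
    psi[psi_na] <- NA_real_
  }
  attr(psi, "event_gene") <- stats::setNames(hosts, events)

  pairs <- data.frame(tf = tfs[tf_of], target = targets,
                      stringsAsFactors = FALSE)
  truth <- expand.grid(event = events, target = targets,
                       stringsAsFactors = FALSE)[, c("target", "event")]
  ti <- match(truth$target, targets)
  truth$tf <- tfs[tf_of[ti]]
  truth$designated <- truth$event == events[ev_of[ti]]
  truth$beta0 <- ifelse(truth$designated, b0[ti], NA_real_)
  truth$beta1 <- ifelse(truth$designated, b1[ti], NA_real_)
  truth$beta2 <- ifelse(truth$designated, b2[ti], NA_real_)
  truth$beta3 <- ifelse(truth$designated, b3[ti], 0)
  truth$modulated <- truth$designated & ti %in% modulated
  truth <- truth[, c("target", "tf", "event", "designated", "modulated",
                     "beta0", "beta1", "beta2", "beta3")]

  list(expression = expr, psi = psi, pairs = pairs, truth = truth,
       config = cfg)
}

#' Simulate a single analysis-ready triplet
#'
#' Lightweight generator for statistical checks: draws transformed TF
#' expression and PSI, forms the transformed modulator variable, and builds
#' the target from the interaction model with coefficients `beta` and noise
#' `noise_sd`. Returns the triplet directly on the transformed (fitting)
#' scale, bypassing file I/O and preprocessing.
#'
#' @param n Samples.
#' @param beta Length-4 coefficient vector (intercept, TF, modulator,
#'   interaction).
#' @param noise_sd Gaussian noise sd (0 allowed for exact-recovery checks).
#' @param psi_alpha,psi_beta,expr_mean_log,expr_sd_log As in [sim_config()].
#' @param seed Optional integer seed.
#' @return List with `tv` (a `"triplet_vectors"`-shaped list) and the raw
#'   named `psi_raw` vector.
#' @export
simulate_triplet <- function(n, beta = c(2, 0.5, -0.3, 1), noise_sd = 1,
                             psi_alpha = 2, psi_beta = 2,
                             expr_mean_log = 8, expr_sd_log = 2,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n))
  x <- stats::rnorm(n, expr_mean_log, expr_sd_log)
  psi <- stats::rbeta(n, psi_alpha, psi_beta)
  m <- transform_psi(clamp_psi(psi))
  y <- beta[1L] + beta[2L] * x + beta[3L] * m + beta[4L] * x * m +
    stats::rnorm(n, 0, noise_sd)
  list(tv = structure(list(sample_ids = ids, x_tf = x, y_target = y,
                           x_m = m, n = as.integer(n)),
                      class = "triplet_vectors"),
       psi_raw = stats::setNames(psi, ids))
}

# x, y with the EXACT sample correlation r (Gram-Schmidt construction).
exact_cor_pair <- function(n, r) {
  stopifnot(n >= 3L)
  x <- stats::rnorm(n)
  z <- stats::rnorm(n)
  xc <- (x - mean(x)) / stats::sd(x)
  zc <- z - mean(z)
  zc <- zc - xc * sum(zc * xc) / sum(xc * xc)
  zc <- zc / stats::sd(zc)
  list(x = xc, y = r * xc + sqrt(1 - r^2) * zc)
}

#' Simulate one triplet with a planted mode-of-action transition
#'
#' Builds a PSI vector split into distinct low and high halves and a
#' (TF, target) expression pair whose *sample* Pearson correlation within the
#' bottom- and top-`fraction` PSI groups equals exactly `r_low` / `r_high`.
#' Planting the empirical correlation (rather than a noisy draw around it)
#' makes the intended correlation state deterministic: a planted `Non-sig`
#' side has r = 0 hence p = 1, and a planted `|r| = effect` side is
#' significant for any reasonable group size. Default correlations per
#' transition label: `+` is `+effect`, `-` is `-effect`, `Non-sig` is 0;
#' for same-sign (Repress) transitions the high group gets `0.375 * effect`
#' of the same sign, a reduced-magnitude correlation.
#'
#' @param kind A transition label from [moa_transitions()], e.g.
#'   `"Non-sig->+"`.
#' @param n Total samples (the groups hold `floor(fraction * n)` each).
#' @param effect Planted correlation magnitude in (0, 1).
#' @param seed Optional integer seed.
#' @param fraction Group fraction (as in [split_by_psi()]).
#' @param r_low,r_high Optional explicit group correlations overriding the
#'   label-derived defaults.
#' @return List with `tv` (transformed triplet vectors), `psi_raw`, `kind`,
#'   `r_low`, `r_high`, `sign` (`"positive"` iff the correlation rises),
#'   `beta3` (a sign-carrying proxy, `r_high - r_low`) and `expected`
#'   (planted `state_low`, `state_high`, `transition`, `category`,
#'   `reduced`).
#' @export
simulate_transition_triplet <- function(kind, n = 400, effect = 0.8,
                                        seed = NULL, fraction = 0.30,
                                        r_low = NULL, r_high = NULL) {
  stopifnot(kind %in% moa_transitions(), effect > 0, effect < 1, n >= 10)
  if (!is.null(seed)) set.seed(seed)
  states <- strsplit(kind, "->", fixed = TRUE)[[1L]]
  state_r <- function(s) switch(s, "+" = effect, "-" = -effect, "Non-sig" = 0)
  if (is.null(r_low)) r_low <- state_r(states[1L])
  if (is.null(r_high)) {
    r_high <- state_r(states[2L])
    if (states[1L] == states[2L] && states[1L] != "Non-sig")
      r_high <- 0.375 * r_high            # same-sign: reduced magnitude
  }

  ids <- sprintf("S%04d", seq_len(n))
  n_lo_half <- floor(n / 2)
  psi <- c(stats::runif(n_lo_half, 0.05, 0.30),
           stats::runif(n - n_lo_half, 0.70, 0.95))
  names(psi) <- ids
  k <- floor(fraction * n)
  ord <- order(psi, ids, method = "radix")
  idx_low <- ord[seq_len(k)]
  idx_high <- ord[seq.int(n - k + 1L, n)]
  idx_mid <- setdiff(seq_len(n), c(idx_low, idx_high))

  x <- numeric(n)
  y <- numeric(n)
  fill <- function(idx, r) {
    p <- exact_cor_pair(length(idx), r)
    x[idx] <<- 8 + 2 * p$x
    y[idx] <<- 8 + 2 * p$y
  }
  fill(idx_low, r_low)
  fill(idx_high, r_high)
  if (length(idx_mid) >= 3L) fill(idx_mid, (r_low + r_high) / 2)

  expected_category <- call_category(states[1L], states[2L])
  list(tv = structure(list(sample_ids = ids, x_tf = x, y_target = y,
                           x_m = transform_psi(clamp_psi(psi)),
                           n = as.integer(n)),
                      class = "triplet_vectors"),
       psi_raw = psi, kind = kind, r_low = r_low, r_high = r_high,
       sign = if (r_high > r_low) "positive" else "negative",
       beta3 = r_high - r_low,
       expected = list(state_low = states[1L], state_high = states[2L],
                       transition = kind, category = expected_category,
                       reduced = if (expected_category == "Repress")
                         abs(r_high) < abs(r_low) else NA))
}
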