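#' Configuration for a synthetic cohort
#'
#' Bundles the study-design constants of the emulated cohort: three groups
#' (FLE patients, healthy controls, posterior-cortex-epilepsy patients) with
#' sample sizes 19/19/20, BOLD-like series of 200 time points, and the
#' planted effect structure — an FLE-selective action-verb comprehension
#' deficit, a reduced bilateral-ATR fractional anisotropy, a reduced
#' M1-to-left-parietal coupling, and a positive within-FLE latent correlation
#' between neural integrity and action-verb scores.
#'
#' Effect sizes are in Cohen's d units on the pooled-SD scale of the feature
#' they act on. `rho_neuro_behavior` is the target product-moment correlation
#' between ATR FA and the AT-verb score inside the FLE group; the generator
#' splits it symmetrically between the two loadings on a shared latent
#' integrity factor and corrects analytically for the binomial noise of the
#' 20-item questionnaires.
#'
#' @param n_fle,n_ctl,n_pce Group sizes (each >= 2).
#' @param n_timepoints Time points per BOLD-like series (>= 8).
#' @param tr_seconds Sampling interval of the series, seconds.
#' @param d_behavior Planted FLE AT-verb deficit, Cohen's d.
#' @param d_atr Planted FLE ATR-FA reduction, Cohen's d.
#' @param delta_coupling Planted reduction of the M1-to-left-parietal
#'   variance-share coupling in FLE (subtracted from the baseline 0.55).
#' @param rho_neuro_behavior Planted within-FLE latent correlation between
#'   neural integrity and AT-verb score, in \[0, 1).
#' @param noise_sd Residual scale multiplier for the FA measurement noise.
#' @param seed Integer RNG seed; identical seeds give bitwise-identical
#'   cohorts.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_fle = 19, n_ctl = 19, n_pce = 20,
                          n_timepoints = 200, tr_seconds = 2,
                          d_behavior = 0.9, d_atr = 0.8,
                          delta_coupling = 0.15, rho_neuro_behavior = 0.75,
                          noise_sd = 1, seed = 1L) {
  if (any(c(n_fle, n_ctl, n_pce) < 2)) stop("all group counts must be >= 2")
  if (n_timepoints < 8) stop("'n_timepoints' must be >= 8")
  es <- c(d_behavior, d_atr, delta_coupling)
  if (!all(is.finite(es))) stop("effect sizes must be finite")
  if (!is.finite(rho_neuro_behavior) || rho_neuro_behavior < 0 ||
      rho_neuro_behavior >= 1)
    stop("'rho_neuro_behavior' must lie in [0, 1)")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  structure(
    list(n_fle = as.integer(n_fle), n_ctl = as.integer(n_ctl),
         n_pce = as.integer(n_pce), n_timepoints = as.integer(n_timepoints),
         tr_seconds = tr_seconds, d_behavior = d_behavior, d_atr = d_atr,
         delta_coupling = delta_coupling,
         rho_neuro_behavior = rho_neuro_behavior, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

## ---- fixed design constants of the generator ------------------------------

.SYN <- list(
  q0 = qlogis(0.75),      # baseline item log-odds (controls score ~15/20)
  sig_a = 0.35,           # between-subject ability SD, logit scale
  n_items = 20L,          # items per condition
  fa_sd = 0.04,           # FA measurement SD (unitless FA)
  fa_mu = c(Fmin = 0.45, ATR = 0.42, CING = 0.48, SLF = 0.46, ILF = 0.47,
            CST = 0.55, Fmaj = 0.52, UNC = 0.44, CING.hipp = 0.40,
            IFOF = 0.47),
  ar_phi = 0.3,           # AR(1) coefficient of the latent network signals
  load_seed = 0.70,       # seed-parcel variance share on its network latent
  load_target = 0.55,     # target-parcel baseline variance share
  load_global = 0.05,     # global-signal variance share, all parcels
  k_w = 0.12,             # integrity modulation of planted-target coupling
  k_cm = 0.10             # integrity modulation of M1 seed loading
)

#' Tract, parcel, and network vocabularies of the synthetic cohort
#'
#' `tract_names()` returns the 10 JHU-atlas white-matter tract labels used in
#' the FA tables. `default_networks()` returns the seed parcels of the motor
#' (MN), multimodal-semantic (SemN), and visual (VN) resting-state networks;
#' `default_targets()` the fixed target-parcel set of the seed analysis. The
#' parcel names are symbolic stand-ins for the study's seed coordinates.
#'
#' @return Character vector (`tract_names`, `default_targets`) or named list
#'   of character vectors (`default_networks`).
#' @export
tract_names <- function() names(.SYN$fa_mu)

#' @rdname tract_names
#' @export
default_networks <- function() {
  list(MN = c("M1-L", "M1-R"), SemN = c("ATL-L", "ATL-R"),
       VN = c("V1-L", "V1-R"))
}

#' @rdname tract_names
#' @export
default_targets <- function() {
  c("ParOp-L", "SMG-L", "AG-L", "pMTG-L", "OccSup-L", "OccLat-R")
}

## ---- analytic calibration of the behavioral model -------------------------

# Mean and variance of a 20-item binomial score whose item log-odds is
# eta0 + s_lat * Z, Z ~ N(0,1); dense-grid Gauss quadrature.
.score_moments <- function(eta0, s_lat) {
  z <- seq(-6, 6, length.out = 801)
  w <- dnorm(z); w <- w / sum(w)
  p <- plogis(eta0 + s_lat * z)
  m <- .SYN$n_items * sum(w * p)
  v <- sum(w * .SYN$n_items * p * (1 - p)) +
    .SYN$n_items^2 * (sum(w * p^2) - sum(w * p)^2)
  c(m = m, v = v)
}

# Correlation between the score and the integrity factor f when the item
# log-odds is q0 + b*f + abil, abil ~ N(0, sig_a).
.score_factor_cor <- function(b, shift = 0) {
  z <- seq(-6, 6, length.out = 401)
  w <- dnorm(z); w <- w / sum(w)
  # conditional mean score given f = z, integrating over ability
  mf <- vapply(z, function(f) {
    .score_moments(.SYN$q0 - shift + b * f, .SYN$sig_a)[["m"]]
  }, 0)
  covf <- sum(w * z * mf) - sum(w * z) * sum(w * mf)
  vtot <- .score_moments(.SYN$q0 - shift, sqrt(.SYN$sig_a^2 + b^2))[["v"]]
  covf / sqrt(vtot)
}

# Generator calibration: loadings and logit shift implied by a config.
# The planted correlation rho is split symmetrically: both the FA and the
# score load sqrt(rho) on the latent factor, with the behavioral loading b
# solved so that the *observed* score-factor correlation (attenuated by
# binomial item noise) equals sqrt(rho). The FLE AT-verb logit shift is
# solved so that the planted group difference equals d_behavior pooled-SD
# units despite the logistic nonlinearity.
.cal_cache <- new.env(parent = emptyenv())

.behavior_calibration <- function(config) {
  key <- paste(config$d_behavior, config$rho_neuro_behavior)
  hit <- .cal_cache[[key]]
  if (!is.null(hit)) return(hit)
  rho <- config$rho_neuro_behavior
  b <- 0
  a_fa <- 0
  if (rho > 0) {
    # the binomial item noise caps the attainable score-factor correlation;
    # split rho symmetrically when sqrt(rho) is attainable, otherwise load
    # the (nearly noiseless) FA side more heavily
    target <- sqrt(rho)
    b_max <- 3
    r_max <- .score_factor_cor(b_max)
    if (target <= r_max) {
      b <- uniroot(function(b) .score_factor_cor(b) - target,
                   c(1e-4, b_max), tol = 1e-6)$root
      a_fa <- target
    } else {
      b <- b_max
      a_fa <- min(rho / r_max, 0.999)
    }
  }
  delta <- 0
  if (config$d_behavior != 0) {
    m0 <- .score_moments(.SYN$q0, .SYN$sig_a)
    s_fle <- sqrt(.SYN$sig_a^2 + b^2)
    f <- function(delta) {
      mf <- .score_moments(.SYN$q0 - delta, s_fle)
      (m0[["m"]] - mf[["m"]]) / sqrt((m0[["v"]] + mf[["v"]]) / 2) -
        config$d_behavior
    }
    delta <- uniroot(f, c(-6, 6), tol = 1e-6, extendInt = "upX")$root
  }
  .cal_cache[[key]] <- list(b = b, delta = delta, a_fa = a_fa)
  .cal_cache[[key]]
}

## ---- low-level draws -------------------------------------------------------

.group_labels <- function(config) {
  rep(c("FLE", "CTL", "PCE"), c(config$n_fle, config$n_ctl, config$n_pce))
}

.subject_ids <- function(groups) {
  sprintf("S%02d_%s", seq_along(groups), groups)
}

# stationary unit-variance AR(1)
.ar1 <- function(n, phi = .SYN$ar_phi) {
  e <- rnorm(n)
  as.numeric(stats::filter(e, phi, method = "recursive")) * sqrt(1 - phi^2)
}

.draw_behavior <- function(config, groups, f, cal) {
  n <- length(groups)
  abil <- rnorm(n, 0, .SYN$sig_a)
  eta_base <- .SYN$q0 + abil
  fle <- groups == "FLE"
  draw <- function(eta) rbinom(n, .SYN$n_items, plogis(eta))
  at_verb <- draw(eta_base + fle * (cal$b * f - cal$delta))
  data.frame(subject_id = .subject_ids(groups),
             at_verb = at_verb, at_circ = draw(eta_base),
             nt_verb = draw(eta_base), nt_circ = draw(eta_base),
             stringsAsFactors = FALSE)
}

.draw_fa <- function(config, groups, f, cal) {
  n <- length(groups)
  s <- .SYN$fa_sd * config$noise_sd
  fle <- groups == "FLE"
  a <- cal$a_fa
  fa <- sapply(tract_names(), function(tr) {
    base <- .SYN$fa_mu[[tr]] + s * rnorm(n)
    if (tr == "ATR") {
      shifted <- .SYN$fa_mu[[tr]] - config$d_atr * s +
        s * (a * f + sqrt(1 - a^2) * rnorm(n))
      base[fle] <- shifted[fle]
    }
    base
  })
  fa <- pmin(pmax(fa, 0), 1)
  cbind(data.frame(subject_id = .subject_ids(groups),
                   stringsAsFactors = FALSE),
        as.data.frame(fa))
}

.draw_covariates <- function(groups) {
  n <- length(groups)
  cov <- data.frame(
    moca = pmin(pmax(round(rnorm(n, 26, 2)), 0), 30),
    ifs = pmin(pmax(round(rnorm(n, 25, 2.5) * 2) / 2, 0), 30)
  )
  sub <- c("moca_visuospatial", "moca_attention", "moca_language",
           "moca_abstraction", "moca_recall",
           "ifs_motor_prog", "ifs_conflict", "ifs_inhibition",
           "ifs_proverbs", "ifs_working_mem")
  for (s in sub) cov[[s]] <- pmin(pmax(round(rnorm(n, 4, 1)), 0), 5)
  cov
}

# One subject's region x time matrix: seeds and targets load on network
# latents plus a weak global signal; couplings are variance shares.
.draw_timeseries_one <- function(n_tp, w_planted, cm_m1) {
  lat <- list(m = .ar1(n_tp), sem = .ar1(n_tp), vis = .ar1(n_tp),
              g = .ar1(n_tp))
  lg <- .SYN$load_global
  mk <- function(latent, l) {
    sqrt(l) * latent + sqrt(lg) * lat$g + sqrt(1 - l - lg) * rnorm(n_tp)
  }
  ls <- .SYN$load_seed; lt <- .SYN$load_target
  rows <- rbind(
    "M1-L" = mk(lat$m, cm_m1), "M1-R" = mk(lat$m, cm_m1),
    "ATL-L" = mk(lat$sem, ls), "ATL-R" = mk(lat$sem, ls),
    "V1-L" = mk(lat$vis, ls), "V1-R" = mk(lat$vis, ls),
    "ParOp-L" = mk(lat$m, w_planted), "SMG-L" = mk(lat$m, w_planted),
    "AG-L" = mk(lat$sem, lt), "pMTG-L" = mk(lat$sem, lt),
    "OccSup-L" = mk(lat$vis, lt), "OccLat-R" = mk(lat$vis, lt)
  )
  rows
}

.draw_timeseries <- function(config, groups, f) {
  n <- length(groups)
  fle <- groups == "FLE"
  rho <- config$rho_neuro_behavior
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  w <- rep(.SYN$load_target, n)
  w[fle] <- clip(.SYN$load_target - config$delta_coupling +
                   .SYN$k_w * rho * f[fle], 0.05, 0.90)
  cm <- rep(.SYN$load_seed, n)
  cm[fle] <- clip(.SYN$load_seed + .SYN$k_cm * rho * f[fle], 0.05, 0.90)
  ts <- vector("list", n)
  for (i in seq_len(n)) {
    m <- .draw_timeseries_one(config$n_timepoints, w[i], cm[i])
    attr(m, "tr_seconds") <- config$tr_seconds
    ts[[i]] <- m
  }
  names(ts) <- .subject_ids(groups)
  list(series = ts, w = w, cm = cm)
}

## ---- public generators -----------------------------------------------------

#' Generate a synthetic multimodal cohort
#'
#' Draws a full cohort carrying the planted effect structure described in
#' [cohort_config()]: FLE subjects share a latent integrity factor that
#' simultaneously lowers their AT-verb comprehension scores, their ATR
#' fractional anisotropy, and their M1-to-left-parietal coupling, which
#' induces the planted within-FLE correlations between those measures.
#' Controls and PCE subjects are drawn from the null model; neutral-text
#' scores and non-ATR tracts carry no group effect anywhere.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `"flemark_cohort"`: a list with `subjects`
#'   (id, group, covariates and cognitive subtests), `timeseries` (named list
#'   of region x time matrices), `fa` (subject x 10-tract FA table),
#'   `behavior` (subject x 4 condition scores), and `truth` (the planted
#'   parameters, latent factor values, and calibrated loadings).
#' @export
#' @examples
#' coh <- gen_cohort(cohort_config(n_timepoints = 40, seed = 7))
#' coh
gen_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- .group_labels(config)
  n <- length(groups)
  f <- rnorm(n)
  cal <- .behavior_calibration(config)
  behavior <- .draw_behavior(config, groups, f, cal)
  fa <- .draw_fa(config, groups, f, cal)
  ts <- .draw_timeseries(config, groups, f)
  subjects <- cbind(
    data.frame(subject_id = .subject_ids(groups), group = groups,
               stringsAsFactors = FALSE),
    .draw_covariates(groups)
  )
  structure(
    list(subjects = subjects, timeseries = ts$series, fa = fa,
         behavior = behavior,
         truth = list(config = config, f = f, calibration = cal,
                      coupling = ts$w, seed_loading = ts$cm)),
    class = "flemark_cohort"
  )
}

#' @export
print.flemark_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat("Synthetic multimodal cohort\n")
  cat(sprintf("  subjects: %d (%s)\n", nrow(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  series: %d parcels x %d time points (TR %.1f s)\n",
              nrow(x$timeseries[[1]]), ncol(x$timeseries[[1]]),
              attr(x$timeseries[[1]], "tr_seconds")))
  cfg <- x$truth$config
  cat(sprintf(
    "  planted: d_behavior=%.2f d_atr=%.2f delta_coupling=%.2f rho=%.2f\n",
    cfg$d_behavior, cfg$d_atr, cfg$delta_coupling, cfg$rho_neuro_behavior))
  invisible(x)
}

#' Generate one pair of coupled series
#'
#' Test-bench generator for the dependence estimator. In `"linear"` mode the
#' second series is `coupling * x` plus Gaussian noise; in `"nonlinear-even"`
#' mode it is `coupling * (x^2 - 1)` plus noise, an even coupling with
#' near-zero linear correlation but clear copula dependence.
#'
#' @param n_timepoints Series length (>= 8).
#' @param coupling Coupling strength in \[0, 1\].
#' @param mode `"linear"` or `"nonlinear-even"`.
#' @param noise_sd Additive noise SD on the second series.
#' @param seed Optional integer seed.
#' @return A 2 x n matrix with rows `x` and `y`.
#' @export
gen_coupled_series <- function(n_timepoints, coupling,
                               mode = c("linear", "nonlinear-even"),
                               noise_sd = 1, seed = NULL) {
  mode <- match.arg(mode)
  if (n_timepoints < 8) stop("'n_timepoints' must be >= 8")
  if (!is.finite(coupling) || coupling < 0 || coupling > 1)
    stop("'coupling' must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  x <- .ar1(n_timepoints)
  y <- switch(mode,
    "linear" = coupling * x + noise_sd * rnorm(n_timepoints),
    "nonlinear-even" = coupling * (x^2 - 1) + noise_sd * rnorm(n_timepoints)
  )
  rbind(x = x, y = y)
}

#' Generate the tract-FA table of a synthetic cohort
#'
#' Standalone draw of the subject x 10-tract fractional anisotropy table:
#' the FLE ATR mean is shifted down by `d_atr` measurement-SD units and tied
#' to the latent integrity factor; every other tract and group is null.
#' Values are clipped to \[0, 1\].
#'
#' @param config A [cohort_config()] object.
#' @return A data frame with `subject_id`, `group`, and the 10 tract columns.
#' @export
gen_fa <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- .group_labels(config)
  f <- rnorm(length(groups))
  cal <- .behavior_calibration(config)
  out <- .draw_fa(config, groups, f, cal)
  cbind(out[1], group = groups, out[-1])
}

#' Generate the condition-score table of a synthetic cohort
#'
#' Standalone draw of the behavioral table. Scores are sums of 20 Bernoulli
#' items per condition with a logistic link on subject ability, so the
#' questionnaire granularity (integers in 0..20) is respected; only the
#' FLE x AT-verb cell carries the planted deficit.
#'
#' @param config A [cohort_config()] object.
#' @return A data frame with `subject_id`, `group`, `at_verb`, `at_circ`,
#'   `nt_verb`, `nt_circ`.
#' @export
gen_behavior <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- .group_labels(config)
  f <- rnorm(length(groups))
  cal <- .behavior_calibration(config)
  out <- .draw_behavior(config, groups, f, cal)
  cbind(out[1], group = groups, out[-1])
}
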