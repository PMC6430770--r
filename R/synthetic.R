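#' Default synthetic "true" flux vector (labeled synthetic)
#'
#' A feasible flux vector qualitatively matching a normoxic regime: oxidative
#' IDH3 dominant, small bidirectional IDH2, small net-reductive cytosolic
#' IDH1, bidirectional mitochondria-cytosol citrate exchange. Values are
#' synthetic round numbers chosen for the simulator, not measurements.
#' @return A [flux_vector] (mM/h).
#' @export
synthetic_true_fluxes <- function() {
  flux_vector(
    v_CS = 0.50, v_CIT_F = 0.15, v_CIT_B = 0.08,
    v_IDH1_R = 0.03, v_IDH1_O = 0.01,
    v_IDH2_R = 0.07, v_IDH2_O = 0.10,
    v_IDH3_R = 0.05, v_IDH3_O = 0.45,
    v_AcCoA = 0.09
  )
}

#' Configuration of a synthetic spatial-fluxomics study
#'
#' Defines the hidden truth (fluxes, forcing kinetics, pools), the
#' contamination and noise model, and the sampling design of a simulated
#' isotope-tracing experiment.
#'
#' @param true_fluxes A [flux_vector]; default [synthetic_true_fluxes()].
#' @param forcing_params Named list of `c(A =, k =)` for the saturating-
#'   exponential forcings `A * (1 - exp(-k t))`: `akg5_mito`, `akg5_cyto`,
#'   `mal_mito` (plateau dimensionless, rate 1/min).
#' @param pools Named numeric `c(cit_mito =, cit_cyto =)`, citrate pool sizes
#'   in mM (whole-cell-volume basis).
#' @param pool_fractions Named list per metabolite of true deconvoluted
#'   relative pool fractions `c(mito =, cyto =)` summing to 1.
#' @param contamination A [contamination_model].
#' @param noise_cv Relative (CV) Gaussian noise on pool-size measurements.
#' @param noise_sd_mid Absolute Gaussian noise sd per MID fraction and
#'   replicate.
#' @param n_replicates Biological replicates (default 3).
#' @param sample_times Sampling times in minutes.
#' @param variant `"WT"` or `"SDHKO"`.
#' @param abundance_13C Natural 13C abundance applied in the forward
#'   direction to simulated fraction MIDs (0 to disable).
#' @param seed Integer seed.
#' @export
synthetic_config <- function(true_fluxes = synthetic_true_fluxes(),
                             forcing_params = list(
                               akg5_mito = c(A = 0.80, k = 0.20),
                               akg5_cyto = c(A = 0.70, k = 0.12),
                               mal_mito = c(A = 0.50, k = 0.10)),
                             pools = c(cit_mito = 0.35, cit_cyto = 0.90),
                             pool_fractions = list(
                               citrate = c(mito = 0.30, cyto = 0.70),
                               akg = c(mito = 0.50, cyto = 0.50),
                               malate = c(mito = 0.40, cyto = 0.60)),
                             contamination = contamination_model(),
                             noise_cv = 0.10,
                             noise_sd_mid = 0.005,
                             n_replicates = 3L,
                             sample_times = c(2, 5, 10, 20, 30, 60, 180),
                             variant = c("WT", "SDHKO"),
                             abundance_13C = 0,
                             seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(all(vapply(forcing_params, function(x)
    x[["A"]] >= 0 && x[["A"]] <= 1 && x[["k"]] >= 0, logical(1))))
  stopifnot(all(pools > 0), noise_cv >= 0, noise_sd_mid >= 0,
            n_replicates >= 1, all(sample_times > 0))
  v <- flux_vector(true_fluxes)   # re-validates Eqs. 1-3
  structure(list(true_fluxes = v, forcing_params = forcing_params,
                 pools = pools, pool_fractions = pool_fractions,
                 contamination = contamination, noise_cv = noise_cv,
                 noise_sd_mid = noise_sd_mid,
                 n_replicates = as.integer(n_replicates),
                 sample_times = sample_times, variant = variant,
                 abundance_13C = abundance_13C, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' True forcing curves of a synthetic study
#'
#' The true forcings are the saturating-exponential curves
#' `A * (1 - exp(-k t))` of the configuration (handled exactly by the ODE
#' propagator).
#'
#' @param cfg A [synthetic_config].
#' @param pwl If `TRUE`, return piecewise-linear interpolants through the
#'   curves at the sampling times instead.
#' @return A [forcing_set].
#' @export
generate_forcings <- function(cfg, pwl = FALSE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  one <- function(par) {
    if (pwl) {
      forcing_points(cfg$sample_times,
                     par[["A"]] * (1 - exp(-par[["k"]] * cfg$sample_times)))
    } else {
      forcing_exponential(par[["A"]], par[["k"]])
    }
  }
  forcing_set(akg5_mito = one(cfg$forcing_params$akg5_mito),
              akg5_cyto = one(cfg$forcing_params$akg5_cyto),
              mal_mito = one(cfg$forcing_params$mal_mito))
}

#' Model configuration matching a synthetic study's truth
#'
#' @param cfg A [synthetic_config].
#' @param ratio_bounds Thermodynamic ratio bounds for the fit; the default
#'   brackets the true reductive:oxidative ratios of `cfg$true_fluxes` with
#'   +/-50% slack (a stand-in for bounds derived from Gibbs-energy data).
#' @export
synthetic_model_config <- function(cfg, ratio_bounds = NULL) {
  v <- cfg$true_fluxes
  if (is.null(ratio_bounds)) {
    rb <- function(k) {
      r <- unname(v[paste0("v_", k, "_R")] / max(v[paste0("v_", k, "_O")], 1e-9))
      c(0.5 * r, 1.5 * r)
    }
    ratio_bounds <- list(IDH1 = rb("IDH1"), IDH2 = rb("IDH2"), IDH3 = rb("IDH3"))
  }
  model_config(variant = cfg$variant,
               u_cit_mito = unname(cfg$pools["cit_mito"]),
               u_cit_cyto = unname(cfg$pools["cit_cyto"]),
               fit_times = cfg$sample_times,
               ratio_bounds = ratio_bounds)
}

# Forward mixing of true compartment signals into fraction-level observables:
# the inverse of the deconvolution closed forms. True deconvoluted relative
# pools P'_m, P'_c give per-marker-unit signals X_m = P'_m/(1+beta),
# X_c = P'_c/(1+alpha); measured fractions mix as P_m = X_m + alpha*X_c,
# P_c = X_c + beta*X_m (and component-wise for per-isotopomer pools).
mix_fractions <- function(p_mito_true, p_cyto_true, cm) {
  xm <- p_mito_true / (1 + cm$beta)
  xc <- p_cyto_true / (1 + cm$alpha)
  c(p_mito = xm + cm$alpha * xc, p_cyto = xc + cm$beta * xm)
}

mix_mids <- function(mid_mito_true, mid_cyto_true, p_mito_true, p_cyto_true, cm) {
  qm <- mid_fractions(mid_mito_true) * p_mito_true / (1 + cm$beta)
  qc <- mid_fractions(mid_cyto_true) * p_cyto_true / (1 + cm$alpha)
  fm <- qm + cm$alpha * qc
  fc <- qc + cm$beta * qm
  list(mid_mito = fm / sum(fm), mid_cyto = fc / sum(fc))
}

# carbons per metabolite in the simulated tables
synthetic_n_carbons <- c(citrate = 6L, akg = 5L, malate = 4L)

#' Generate a complete synthetic spatial-fluxomics dataset
#'
#' Integrates the labeling ODEs under the true fluxes, assembles true
#' compartment MID time courses for citrate, alpha-ketoglutarate and malate,
#' mixes them into contaminated mitochondrial/cytosolic fraction measurements
#' (optionally convolved with natural 13C abundance), and adds replicate
#' Gaussian noise. The hidden truth is returned alongside the observables.
#'
#' @param cfg A [synthetic_config].
#' @return List with `truth` (true fluxes, forcings, compartment MIDs and
#'   pool fractions), `pools` (data.frame in the `pools.csv` schema) and
#'   `mids` (data.frame in the `mids.csv` schema).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  f <- generate_forcings(cfg)
  mcfg <- synthetic_model_config(cfg)
  traj <- simulate_labeling(cfg$true_fluxes, mcfg, f, cfg$sample_times)
  iso_low <- attr(traj, "iso_low")
  j_low <- if (cfg$variant == "WT") 4L else 3L
  tt <- cfg$sample_times
  nt <- length(tt)

  # true compartment MIDs per metabolite and time (labeled mass in the tracked
  # isotopomers, remainder unlabeled)
  true_mid <- function(metab, t_idx, comp) {
    n <- synthetic_n_carbons[[metab]]
    fr <- numeric(n + 1L)
    if (metab == "citrate") {
      low <- traj[t_idx, paste0(comp, "_low")]
      m5 <- traj[t_idx, paste0(comp, "_m5")]
      fr[j_low + 1L] <- low
      fr[6L] <- fr[6L] + m5          # m+5 slot
      fr[1L] <- 1 - low - m5
    } else if (metab == "akg") {
      x <- if (comp == "mito") f$akg5_mito$fun(tt[t_idx]) else f$akg5_cyto$fun(tt[t_idx])
      fr[6L] <- x                    # m+5 of a 5-carbon metabolite
      fr[1L] <- 1 - x
    } else {
      x <- if (comp == "mito") f$mal_mito$fun(tt[t_idx]) else
        0.8 * f$mal_mito$fun(tt[t_idx])   # cytosolic malate lags mito
      fr[j_low + 1L] <- x
      fr[1L] <- 1 - x
    }
    fr
  }

  na_C <- lapply(synthetic_n_carbons, function(n)
    if (cfg$abundance_13C > 0) na_correction_matrix(n, cfg$abundance_13C) else NULL)

  pools_rows <- list()
  mids_rows <- list()
  truth_mids <- list()
  max_n <- max(synthetic_n_carbons)
  for (metab in names(synthetic_n_carbons)) {
    n <- synthetic_n_carbons[[metab]]
    pf <- cfg$pool_fractions[[metab]]
    mixed_p <- mix_fractions(pf[["mito"]], pf[["cyto"]], cfg$contamination)
    # pool measurements with replicate noise
    for (fr_name in c("mito_fraction", "cyto_fraction")) {
      true_val <- if (fr_name == "mito_fraction") mixed_p[["p_mito"]] else mixed_p[["p_cyto"]]
      reps <- numeric(cfg$n_replicates)
      for (r in seq_len(cfg$n_replicates)) {
        x <- -1
        while (x < 0) x <- true_val * (1 + stats::rnorm(1, 0, cfg$noise_cv))
        reps[r] <- x
      }
      pools_rows[[length(pools_rows) + 1L]] <- data.frame(
        metabolite = metab, fraction = fr_name,
        value = mean(reps),
        sd = if (cfg$n_replicates > 1L) stats::sd(reps) else 0,
        n_replicates = cfg$n_replicates, units = "relative")
    }
    for (ti in seq_len(nt)) {
      im_true <- true_mid(metab, ti, "mito")
      ic_true <- true_mid(metab, ti, "cyto")
      truth_mids[[paste(metab, tt[ti], sep = "_")]] <-
        list(mito = im_true, cyto = ic_true)
      mx <- mix_mids(im_true, ic_true, pf[["mito"]], pf[["cyto"]],
                     cfg$contamination)
      for (fr_name in c("mito_fraction", "cyto_fraction")) {
        base <- if (fr_name == "mito_fraction") mx$mid_mito else mx$mid_cyto
        if (!is.null(na_C[[metab]])) base <- as.numeric(na_C[[metab]] %*% base)
        reps <- matrix(NA_real_, cfg$n_replicates, n + 1L)
        for (r in seq_len(cfg$n_replicates)) {
          x <- pmin(pmax(base + stats::rnorm(n + 1L, 0, cfg$noise_sd_mid), 0), 1)
          reps[r, ] <- x / sum(x)
        }
        mval <- colMeans(reps)
        msd <- if (cfg$n_replicates > 1L) apply(reps, 2, stats::sd) else
          rep(0, n + 1L)
        row <- as.list(c(metab = metab, fr = fr_name, t = tt[ti]))
        m_cols <- stats::setNames(c(mval, rep(NA_real_, max_n - n)),
                                  paste0("m", 0:max_n))
        sd_cols <- stats::setNames(c(msd, rep(NA_real_, max_n - n)),
                                   paste0("sd_m", 0:max_n))
        mids_rows[[length(mids_rows) + 1L]] <- data.frame(
          metabolite = metab, compartment_or_fraction = fr_name,
          time_min = tt[ti], as.list(m_cols), as.list(sd_cols))
      }
    }
  }
  list(
    truth = list(fluxes = cfg$true_fluxes, forcings = f, model_config = mcfg,
                 trajectories = traj, iso_low = iso_low,
                 pool_fractions = cfg$pool_fractions, mids = truth_mids,
                 seed = cfg$seed, variant = cfg$variant),
    pools = do.call(rbind, pools_rows),
    mids = do.call(rbind, mids_rows)
  )
}

#' Fit a synthetic study end to end
#'
#' Convenience driver for parameter-recovery and coverage experiments:
#' generates a synthetic dataset, deconvolves the fraction-level citrate,
#' alpha-ketoglutarate and malate MIDs (deterministic closed form), assembles
#' the labeling dataset (residual sd = the empirical replicate sd of the
#' measured fractions, floored by `sigma_floor` in the objective) and the
#' smoothed forcing curves, and runs [fit_fluxes()] (optionally followed by
#' [profile_ci()] for selected fluxes). The deconvolved alpha-ketoglutarate
#' and malate series are smoothed by [fit_forcing_curve()] before entering
#' the ODEs as forcings.
#'
#' @param cfg A [synthetic_config].
#' @param n_starts Random multi-starts for the fit (the true flux vector is
#'   *not* used to initialize).
#' @param profile Character vector of fluxes to profile (default none).
#' @param ratio_bounds Optional override of the thermodynamic ratio bounds.
#' @return The [fit_fluxes()] result, with `ci` attached when profiling, and
#'   the generating truth under `$truth`.
#' @export
fit_synthetic_study <- function(cfg, n_starts = 5L, profile = character(0),
                                ratio_bounds = NULL) {
  ds <- generate_dataset(cfg)
  cm <- cfg$contamination
  mcfg <- synthetic_model_config(cfg, ratio_bounds)
  tt <- cfg$sample_times
  mids <- ds$mids
  attr(mids, "m_cols") <- paste0("m", 0:max(synthetic_n_carbons))
  attr(mids, "sd_cols") <- paste0("sd_m", 0:max(synthetic_n_carbons))
  pools <- ds$pools
  pool_of <- function(metab, frac) {
    pools$value[pools$metabolite == metab & pools$fraction == frac]
  }
  sd_of <- function(metab, frac) {
    pools$sd[pools$metabolite == metab & pools$fraction == frac]
  }
  # deconvolved series with Monte-Carlo error propagation (measurement noise
  # of the MIDs plus pool-size and contamination-parameter uncertainty)
  dec_series <- function(metab, slot, mc = FALSE) {
    pm <- pool_of(metab, "mito_fraction"); pc <- pool_of(metab, "cyto_fraction")
    out <- matrix(NA_real_, length(tt), 4)  # mito val, cyto val, mito sd, cyto sd
    for (i in seq_along(tt)) {
      rm_ <- mid_row(mids, metab, "mito_fraction", tt[i])
      rc_ <- mid_row(mids, metab, "cyto_fraction", tt[i])
      if (cfg$abundance_13C > 0) {
        rm_$fractions <- correct_natural_abundance(rm_$fractions, cfg$abundance_13C)
        rc_$fractions <- correct_natural_abundance(rc_$fractions, cfg$abundance_13C)
      }
      if (mc) {
        dm <- deconvolve_mid_mc(rm_$fractions, rc_$fractions, pm, pc,
                                sd_mid_mito = rm_$sds, sd_mid_cyto = rc_$sds,
                                sd_pools = c(sd_of(metab, "mito_fraction"),
                                             sd_of(metab, "cyto_fraction")),
                                cm = cm, n_draws = 500L,
                                seed = cfg$seed + 37L * i)
        out[i, ] <- c(dm$mid_mito$fractions[slot + 1L],
                      dm$mid_cyto$fractions[slot + 1L],
                      dm$sd_mito[slot + 1L], dm$sd_cyto[slot + 1L])
      } else {
        dm <- deconvolve_mid(rm_$fractions, rc_$fractions, pm, pc, cm,
                             neg_tol = 0.05)
        out[i, ] <- c(dm$mid_mito$fractions[slot + 1L],
                      dm$mid_cyto$fractions[slot + 1L],
                      rm_$sds[slot + 1L], rc_$sds[slot + 1L])
      }
    }
    out
  }
  j_low <- if (cfg$variant == "WT") 4L else 3L
  cit_low <- dec_series("citrate", j_low, mc = TRUE)
  cit_m5 <- dec_series("citrate", 5L, mc = TRUE)
  akg5 <- dec_series("akg", 5L)
  mal <- dec_series("malate", j_low)
  data <- labeling_dataset(
    tt,
    X = cbind(mito_low = cit_low[, 1], cyto_low = cit_low[, 2],
              mito_m5 = cit_m5[, 1], cyto_m5 = cit_m5[, 2]),
    SD = cbind(cit_low[, 3], cit_low[, 4], cit_m5[, 3], cit_m5[, 4]),
    iso_low = paste0("m", j_low))
  f <- forcing_set(akg5_mito = fit_forcing_curve(tt, akg5[, 1]),
                   akg5_cyto = fit_forcing_curve(tt, akg5[, 2]),
                   mal_mito = fit_forcing_curve(tt, mal[, 1]))
  fit <- fit_fluxes(data, mcfg, f, n_starts = n_starts, seed = cfg$seed)
  if (length(profile)) fit <- fit_profile_cis(fit, fluxes = profile)
  fit$truth <- ds$truth
  fit
}
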