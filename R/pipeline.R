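#' Assemble a run configuration
#'
#' A single list (readable from JSON via [read_run_config()]) governs a whole
#' run: input table paths, contamination and thermodynamic blocks, model
#' block, Monte-Carlo sizes, and the seed.
#'
#' @param pools_csv,mids_csv Paths to the input tables.
#' @param contamination List `alpha`, `beta`, `sd`.
#' @param thermo List of reaction blocks, each with `name`, `dg0_prime`,
#'   `dg0_sd`, `temperature` (optional) and `quotient_terms` (list of lists
#'   with `species`, `coeff`, `value`, `sd`, `dist`, `lo`, `hi`).
#' @param model List: `variant`, `u_cit_mito`, `u_cit_cyto`, `fit_times`,
#'   `sigma_floor`, `flux_upper_bound`, and the metabolite names carrying the
#'   citrate (`cit_metabolite`), alpha-ketoglutarate (`akg_metabolite`) and
#'   malate (`mal_metabolite`) series.
#' @param fit List: `n_starts`, `profile_fluxes` (character vector or NULL).
#' @param mc List: `n_draws_pools`, `n_draws_mids`, `n_draws_thermo`.
#' @param abundance_13C Natural abundance used for MID correction (0 skips).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @export
run_config <- function(pools_csv, mids_csv,
                       contamination = list(alpha = 0.13, beta = 0.11, sd = 0.03),
                       thermo = list(),
                       model = list(),
                       fit = list(n_starts = 50L, profile_fluxes = NULL),
                       mc = list(n_draws_pools = 10000L, n_draws_mids = 1000L,
                                 n_draws_thermo = 10000L),
                       abundance_13C = 0.0107,
                       seed = 1L,
                       out_dir = "results") {
  for (p in c(pools_csv, mids_csv)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  if (is.null(seed)) stop("a seed is required in the run configuration")
  structure(list(pools_csv = pools_csv, mids_csv = mids_csv,
                 contamination = contamination, thermo = thermo, model = model,
                 fit = fit, mc = mc, abundance_13C = abundance_13C,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with the [run_config()] fields.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  do.call(run_config, cfg)
}

thermo_spec_from_block <- function(block) {
  qts <- lapply(block$quotient_terms, function(q) {
    quotient_term(q$species, q$coeff,
                  value = q$value %||% NA_real_,
                  sd = q$sd %||% 0,
                  dist = q$dist %||% "normal",
                  lo = q$lo %||% NA_real_, hi = q$hi %||% NA_real_)
  })
  thermo_reaction_spec(block$name, block$dg0_prime, block$dg0_sd %||% 0,
                       quotient_terms = qts,
                       temperature = block$temperature %||% 310.15)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full spatial-fluxomics pipeline
#'
#' Executes, in order: natural-abundance correction of all fraction MIDs,
#' Monte-Carlo deconvolution of pool sizes and MID time courses, thermodynamic
#' ratio bounds for the IDH isozymes, constrained flux fitting, and (when
#' requested) profile-likelihood confidence intervals. Writes
#' `pools_deconvolved.csv`, `mids_deconvolved.csv`, `thermo_results.csv`,
#' `fluxes.json`, `fit_trajectories.csv` and `manifest.json` under
#' `cfg$out_dir`. Any stage failure aborts with the stage name; outputs
#' written before the failure are left in place.
#'
#' @param cfg A [run_config].
#' @return Invisible list with the deconvolved tables, thermo results and the
#'   fit.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cm <- contamination_model(cfg$contamination$alpha, cfg$contamination$beta,
                            cfg$contamination$sd)
  md <- cfg$model
  pools <- run_stage("read", read_pools_csv(cfg$pools_csv))
  mids <- run_stage("read", read_mids_csv(cfg$mids_csv))
  m_cols <- attr(mids, "m_cols"); sd_cols <- attr(mids, "sd_cols")
  message(sprintf("[read] %d pool rows, %d MID rows", nrow(pools), nrow(mids)))

  mids_corr <- run_stage("natural_abundance", {
    out <- mids
    if (cfg$abundance_13C > 0) {
      for (i in seq_len(nrow(out))) {
        x <- as.numeric(out[i, m_cols]); ok <- !is.na(x)
        out[i, m_cols][ok] <- correct_natural_abundance(x[ok], cfg$abundance_13C)
      }
    }
    out
  })

  dec <- run_stage("deconvolution", {
    pool_rows <- list(); mid_rows <- list(); dpools <- list()
    for (metab in unique(mids_corr$metabolite)) {
      pm_row <- pools[pools$metabolite == metab & pools$fraction == "mito_fraction", ]
      pc_row <- pools[pools$metabolite == metab & pools$fraction == "cyto_fraction", ]
      if (nrow(pm_row) != 1L || nrow(pc_row) != 1L) {
        stop("need one mito_fraction and one cyto_fraction pool row for ", metab)
      }
      dp <- deconvolve_pools_mc(pm_row$value, pc_row$value,
                                sds = c(pm_row$sd, pc_row$sd), cm = cm,
                                n_draws = cfg$mc$n_draws_pools,
                                seed = cfg$seed)
      dpools[[metab]] <- dp
      pool_rows[[metab]] <- data.frame(
        metabolite = metab,
        p_mito = dp$p_mito_clipped, p_cyto = dp$p_cyto_clipped,
        sd_mito = dp$sd_mito, sd_cyto = dp$sd_cyto,
        alpha = cm$alpha, beta = cm$beta,
        seed = cfg$seed, n_draws = cfg$mc$n_draws_pools)
      for (t in sort(unique(mids_corr$time_min[mids_corr$metabolite == metab]))) {
        rm_ <- mid_row(mids_corr, metab, "mito_fraction", t)
        rc_ <- mid_row(mids_corr, metab, "cyto_fraction", t)
        dm <- deconvolve_mid_mc(rm_$fractions, rc_$fractions,
                                pm_row$value, pc_row$value,
                                sd_mid_mito = rm_$sds, sd_mid_cyto = rc_$sds,
                                sd_pools = c(pm_row$sd, pc_row$sd), cm = cm,
                                n_draws = cfg$mc$n_draws_mids, seed = cfg$seed)
        n <- length(rm_$fractions) - 1L
        max_n <- length(m_cols) - 1L
        pad <- function(x) c(x, rep(NA_real_, max_n - n))
        for (comp in c("mito", "cyto")) {
          fr <- if (comp == "mito") dm$mid_mito$fractions else dm$mid_cyto$fractions
          sdv <- if (comp == "mito") dm$sd_mito else dm$sd_cyto
          row <- data.frame(metabolite = metab, compartment_or_fraction = comp,
                            time_min = t,
                            as.list(stats::setNames(pad(fr), m_cols)),
                            as.list(stats::setNames(pad(sdv), sd_cols)),
                            alpha = cm$alpha, beta = cm$beta,
                            seed = cfg$seed, n_draws = cfg$mc$n_draws_mids)
          mid_rows[[length(mid_rows) + 1L]] <- row
        }
      }
    }
    list(pools = do.call(rbind, pool_rows), mids = do.call(rbind, mid_rows),
         dpools = dpools)
  })
  write_pools_csv(dec$pools, file.path(cfg$out_dir, "pools_deconvolved.csv"))
  write_mids_csv(dec$mids, file.path(cfg$out_dir, "mids_deconvolved.csv"))
  message(sprintf("[deconvolution] %d metabolites deconvolved", nrow(dec$pools)))

  thermo_res <- run_stage("thermo", {
    if (!length(cfg$thermo)) NULL else {
      rows <- lapply(cfg$thermo, function(block) {
        spec <- thermo_spec_from_block(block)
        tr <- gibbs_mc(spec, n_draws = cfg$mc$n_draws_thermo, seed = cfg$seed)
        data.frame(name = tr$name, dg_mean = tr$dg_mean, dg_sd = tr$dg_sd,
                   b = unname(tr$b_ratio), sigma_b = unname(tr$b_sd),
                   lower = unname(tr$lower), upper = unname(tr$upper))
      })
      do.call(rbind, rows)
    }
  })
  if (!is.null(thermo_res)) {
    utils::write.csv(thermo_res, file.path(cfg$out_dir, "thermo_results.csv"),
                     row.names = FALSE)
    message(sprintf("[thermo] bounds for %d reactions", nrow(thermo_res)))
  }

  fit <- run_stage("fit", {
    variant <- md$variant %||% "WT"
    j_low <- if (variant == "WT") 4L else 3L
    cit <- md$cit_metabolite %||% "citrate"
    akg <- md$akg_metabolite %||% "akg"
    mal <- md$mal_metabolite %||% "malate"
    dm <- dec$mids
    attr(dm, "m_cols") <- m_cols; attr(dm, "sd_cols") <- sd_cols
    times <- sort(unique(dm$time_min[dm$metabolite == cit]))
    fit_times <- md$fit_times %||% times
    if (!all(fit_times %in% times)) {
      stop("fit times missing from deconvolved citrate series")
    }
    get_series <- function(metab, comp, slot) {
      vapply(times, function(t) {
        r <- mid_row(dm, metab, comp, t)
        if (length(r$fractions) < slot + 1L) {
          stop("metabolite ", metab, " lacks the m+", slot,
               " isotopomer required by variant ", variant)
        }
        r$fractions[slot + 1L]
      }, numeric(1))
    }
    get_sds <- function(metab, comp, slot) {
      vapply(times, function(t) mid_row(dm, metab, comp, t)$sds[slot + 1L],
             numeric(1))
    }
    X <- cbind(mito_low = get_series(cit, "mito", j_low),
               cyto_low = get_series(cit, "cyto", j_low),
               mito_m5 = get_series(cit, "mito", 5L),
               cyto_m5 = get_series(cit, "cyto", 5L))
    SD <- cbind(get_sds(cit, "mito", j_low), get_sds(cit, "cyto", j_low),
                get_sds(cit, "mito", 5L), get_sds(cit, "cyto", 5L))
    data <- labeling_dataset(times, X, SD,
                             iso_low = paste0("m", j_low))
    mal_series <- get_series(mal, "mito", j_low)
    if (variant == "SDHKO" && all(mal_series < 1e-9)) {
      stop("SDHKO variant requires a nonzero malate m+3 series")
    }
    f <- forcing_set(
      akg5_mito = forcing_points(times, get_series(akg, "mito", 5L)),
      akg5_cyto = forcing_points(times, get_series(akg, "cyto", 5L)),
      mal_mito = forcing_points(times, mal_series))
    rb <- if (!is.null(thermo_res)) {
      stats::setNames(lapply(c("IDH1", "IDH2", "IDH3"), function(k) {
        r <- thermo_res[thermo_res$name == k, ]
        if (nrow(r) == 1L) c(r$lower, r$upper) else c(0, Inf)
      }), c("IDH1", "IDH2", "IDH3"))
    } else md$ratio_bounds %||% list(IDH1 = c(0, Inf), IDH2 = c(0, Inf),
                                     IDH3 = c(0, Inf))
    mcfg <- model_config(variant = variant,
                         u_cit_mito = md$u_cit_mito,
                         u_cit_cyto = md$u_cit_cyto,
                         fit_times = fit_times,
                         sigma_floor = md$sigma_floor %||% 0.002,
                         flux_upper_bound = md$flux_upper_bound %||% 5,
                         ratio_bounds = rb)
    fit <- fit_fluxes(data, mcfg, f, n_starts = cfg$fit$n_starts %||% 50L,
                      seed = cfg$seed)
    prof <- cfg$fit$profile_fluxes
    if (!is.null(prof) && length(prof)) {
      fit <- fit_profile_cis(fit, fluxes = prof)
    }
    fit
  })
  message(sprintf("[fit] SSR = %.4g, %d/%d starts converged",
                  fit$ssr, fit$n_converged, fit$n_starts))

  run_stage("write", {
    traj <- as.data.frame(fit$trajectories)
    utils::write.csv(traj, file.path(cfg$out_dir, "fit_trajectories.csv"),
                     row.names = FALSE)
    flux_out <- list(
      fluxes = as.list(unclass(fit$best)),
      ssr = fit$ssr,
      n_starts = fit$n_starts, n_converged = fit$n_converged,
      starts = fit$starts,
      ci = if (!is.null(fit$ci)) {
        stats::setNames(lapply(rownames(fit$ci), function(r)
          list(lower = fit$ci[r, "lower"], upper = fit$ci[r, "upper"])),
          rownames(fit$ci))
      } else NULL)
    jsonlite::write_json(flux_out, file.path(cfg$out_dir, "fluxes.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_path <- file.path(cfg$out_dir, "run_config.json")
    jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    manifest <- list(
      config_md5 = unname(tools::md5sum(cfg_path)),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("spatialflux")),
      r_version = R.version.string,
      outputs = c("pools_deconvolved.csv", "mids_deconvolved.csv",
                  if (!is.null(thermo_res)) "thermo_results.csv",
                  "fluxes.json", "fit_trajectories.csv"))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(list(pools_deconvolved = dec$pools, mids_deconvolved = dec$mids,
                 thermo = thermo_res, fit = fit))
}
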