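#' Chi-square threshold for 95% profile-likelihood intervals (1 d.f.)
#' @export
chisq95_1df <- 3.841459

#' Profile-likelihood confidence interval for one flux
#'
#' Walks the named flux away from its maximum-likelihood estimate in steps of
#' 5% of the MLE (5% of `v_CS` when the MLE sits at zero), re-optimizing all
#' other fluxes at each step with the walked flux pinned by an equality
#' constraint. Each bound is the first crossing of `SSR_min + 3.841459`
#' (the 95% quantile of the chi-square distribution with one degree of
#' freedom), linearly interpolated between the bracketing steps. If the
#' profile dips back under the threshold after a crossing, the widest
#' crossing is reported and the interval is flagged non-monotone. When the
#' constraints pin the flux so tightly that no step is feasible in either
#' direction, a zero-width interval is returned with the `degenerate` flag.
#'
#' @param fit A [fit_fluxes()] result.
#' @param flux_name One of [flux_names].
#' @param data,cfg,f Dataset, configuration and forcings (defaults: those
#'   stored in `fit`).
#' @param step_frac Step size as a fraction of the MLE (default 0.05).
#' @param max_steps Cap on steps per direction (default 80).
#' @param threshold SSR increase defining the bound (default [chisq95_1df]).
#' @return Numeric `c(lower, upper)` in mM/h with attributes `flags`
#'   (character vector, possibly empty) and `profile` (data.frame of walked
#'   values and SSRs).
#' @export
profile_ci <- function(fit, flux_name, data = fit$data, cfg = fit$cfg,
                       f = fit$forcings, step_frac = 0.05, max_steps = 80L,
                       threshold = chisq95_1df) {
  stopifnot(inherits(fit, "kfp_fit"))
  flux_name <- match.arg(flux_name, flux_names)
  mle <- unname(unclass(fit$best)[flux_name])
  ssr0 <- fit$ssr
  step <- step_frac * mle
  if (step < 1e-8) step <- step_frac * unname(unclass(fit$best)["v_CS"])
  if (step < 1e-8) step <- step_frac * cfg$flux_upper_bound / 100
  target <- ssr0 + threshold
  flags <- character(0)
  prof_all <- data.frame(value = mle, ssr = ssr0)

  walk <- function(dir) {
    bound <- mle
    prev_val <- mle; prev_ssr <- ssr0
    warm <- list(fit$best)
    crossing <- NA_real_
    k <- 0L
    while (k < max_steps) {
      k <- k + 1L
      val <- mle + dir * k * step
      if (val < 0) val <- 0
      if (val > cfg$flux_upper_bound) val <- cfg$flux_upper_bound
      refit <- tryCatch(
        fit_fluxes(data, cfg, f, n_starts = 0L, seed = fit$seed,
                   init = warm, pin = list(name = flux_name, value = val),
                   maxit = 200),
        error = function(e) NULL)
      if (is.null(refit)) {
        # constraint boundary reached before the likelihood bound
        bound <- prev_val
        if (is.na(crossing)) flags <<- union(flags, "constraint_limited")
        break
      }
      ssr_k <- refit$ssr
      prof_all <<- rbind(prof_all, data.frame(value = val, ssr = ssr_k))
      if (ssr_k < ssr0 - 1e-6) flags <<- union(flags, "nonmonotone")
      if (ssr_k >= target) {
        crossing <- prev_val + (val - prev_val) *
          (target - prev_ssr) / (ssr_k - prev_ssr)
        bound <- crossing
        break
      }
      warm <- list(refit$best)
      prev_val <- val; prev_ssr <- ssr_k
      if (val <= 0 || val >= cfg$flux_upper_bound) {
        bound <- val
        flags <<- union(flags, "bound_at_box")
        break
      }
      bound <- val
    }
    if (k >= max_steps && is.na(crossing)) flags <<- union(flags, "max_steps")
    bound
  }

  # degenerate case: neither direction admits a feasible step
  probe <- function(val) {
    !is.null(tryCatch(
      fit_fluxes(data, cfg, f, n_starts = 0L, seed = fit$seed,
                 init = list(fit$best),
                 pin = list(name = flux_name, value = val), maxit = 5),
      error = function(e) NULL))
  }
  if (!probe(mle + step) && !probe(max(mle - step, 0))) {
    out <- c(lower = mle, upper = mle)
    attr(out, "flags") <- "degenerate"
    attr(out, "profile") <- prof_all
    return(out)
  }

  upper <- walk(+1)
  lower <- walk(-1)
  out <- c(lower = min(lower, mle), upper = max(upper, mle))
  attr(out, "flags") <- flags
  attr(out, "profile") <- prof_all[order(prof_all$value), ]
  out
}

#' Profile-likelihood intervals for several fluxes
#'
#' @param fit A [fit_fluxes()] result.
#' @param fluxes Character vector of flux names (default: all ten).
#' @param ... Passed to [profile_ci()].
#' @return The fit with a `ci` matrix (rows = fluxes, columns `lower`,
#'   `upper`) and a `ci_flags` list attached.
#' @export
fit_profile_cis <- function(fit, fluxes = flux_names, ...) {
  ci <- matrix(NA_real_, length(fluxes), 2,
               dimnames = list(fluxes, c("lower", "upper")))
  flags <- vector("list", length(fluxes)); names(flags) <- fluxes
  for (fl in fluxes) {
    res <- profile_ci(fit, fl, ...)
    ci[fl, ] <- res
    flags[[fl]] <- attr(res, "flags")
  }
  fit$ci <- ci
  fit$ci_flags <- flags
  fit
}
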