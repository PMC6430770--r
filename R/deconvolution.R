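#' Cross-contamination model for rapid fractionation
#'
#' `alpha` is the relative abundance of the cytosolic marker detected in the
#' mitochondrial fraction (out of that in the cytosolic fraction); `beta` the
#' mitochondrial marker detected in the cytosolic fraction. Defaults are the
#' marker-based purity estimates for rapid differential centrifugation of
#' HeLa cells (alpha = 0.13, beta = 0.11, sd = 0.03).
#'
#' @param alpha,beta Contamination fractions in `[0, 1)` with `alpha*beta < 1`.
#' @param sd Gaussian standard deviation applied to both parameters in
#'   Monte-Carlo error propagation.
#' @export
contamination_model <- function(alpha = 0.13, beta = 0.11, sd = 0.03) {
  stopifnot(alpha >= 0, alpha < 1, beta >= 0, beta < 1, sd >= 0)
  if (alpha * beta >= 1) stop("alpha * beta must be < 1")
  structure(list(alpha = alpha, beta = beta, sd = sd),
            class = "contamination_model")
}

#' Deconvolve fraction-level pool sizes into compartment pool sizes
#'
#' The measured pool sizes mix the true per-marker-unit compartment signals
#' `X_m`, `X_c` as `P_c = X_c + beta*X_m`, `P_m = alpha*X_c + X_m`. Solving
#' and re-attributing each compartment's contaminating share gives the closed
#' forms
#' `P'_c = (P_c - beta*P_m) * (1 + alpha) / (1 - alpha*beta)` and
#' `P'_m = (P_m - alpha*P_c) * (1 + beta) / (1 - alpha*beta)`,
#' which conserve `P'_m + P'_c = P_m + P_c` exactly.
#'
#' @param p_mito,p_cyto Measured pool sizes in the mitochondrial and cytosolic
#'   fractions (nonnegative; relative or absolute units).
#' @param cm A [contamination_model].
#' @return List of class `"deconvolved_pools"` with raw deconvoluted values
#'   `p_mito`, `p_cyto`, clipped-at-zero companions `p_mito_clipped`,
#'   `p_cyto_clipped`, the per-marker-unit intermediates `x_mito`, `x_cyto`,
#'   and the logical flag `negative` (TRUE when clipping changed a value, in
#'   which case a warning is raised).
#' @export
deconvolve_pools <- function(p_mito, p_cyto, cm = contamination_model()) {
  stopifnot(inherits(cm, "contamination_model"), p_mito >= 0, p_cyto >= 0)
  a <- cm$alpha; b <- cm$beta
  den <- 1 - a * b
  if (den <= 0) stop("alpha * beta must be < 1")
  x_m <- (p_mito - a * p_cyto) / den
  x_c <- (p_cyto - b * p_mito) / den
  pm <- x_m * (1 + b)
  pc <- x_c * (1 + a)
  neg <- (pm < 0) || (pc < 0)
  if (neg) warning("negative deconvoluted pool size; clipped companion set to 0")
  structure(
    list(p_mito = pm, p_cyto = pc,
         p_mito_clipped = max(pm, 0), p_cyto_clipped = max(pc, 0),
         x_mito = x_m, x_cyto = x_c,
         sd_mito = 0, sd_cyto = 0, negative = neg),
    class = "deconvolved_pools"
  )
}

#' Monte-Carlo pool-size deconvolution with Gaussian error propagation
#'
#' Draws `(P_m, P_c, alpha, beta)` from independent Gaussians centred on the
#' measurements, rejects unphysical draws (negative pools or contamination,
#' `alpha*beta >= 1`), applies [deconvolve_pools()] to each draw, and reports
#' the mean and standard deviation of the deconvoluted values.
#'
#' @inheritParams deconvolve_pools
#' @param sds Length-2 numeric: sd of `p_mito` and of `p_cyto`.
#' @param n_draws Number of Monte-Carlo draws (>= 100; default 10000).
#' @param seed Integer seed; required for reproducibility.
#' @return A `"deconvolved_pools"` list whose `p_mito`/`p_cyto` are MC means
#'   and whose `sd_mito`/`sd_cyto` are MC standard deviations.
#' @export
deconvolve_pools_mc <- function(p_mito, p_cyto, sds, cm = contamination_model(),
                                n_draws = 10000L, seed) {
  stopifnot(n_draws >= 100L, length(sds) == 2L, all(sds >= 0))
  if (missing(seed)) stop("a seed is required for Monte-Carlo deconvolution")
  if (all(sds == 0) && cm$sd == 0) {
    out <- deconvolve_pools(p_mito, p_cyto, cm)
    return(out)
  }
  rng <- local({ set.seed(seed); NULL })
  draw_trunc <- function(n, mean, sd, lower = 0) {
    if (sd == 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    bad <- x < lower
    tries <- 0L
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
      bad <- x < lower
      tries <- tries + 1L
      if (tries > 1000L) stop("rejection rate too high when truncating draws")
    }
    x
  }
  pm <- draw_trunc(n_draws, p_mito, sds[1])
  pc <- draw_trunc(n_draws, p_cyto, sds[2])
  al <- draw_trunc(n_draws, cm$alpha, cm$sd)
  be <- draw_trunc(n_draws, cm$beta, cm$sd)
  bad <- al * be >= 1 | al >= 1 | be >= 1
  n_rej <- sum(bad)
  tries <- 0L
  while (any(bad)) {
    al[bad] <- draw_trunc(sum(bad), cm$alpha, cm$sd)
    be[bad] <- draw_trunc(sum(bad), cm$beta, cm$sd)
    bad <- al * be >= 1 | al >= 1 | be >= 1
    n_rej <- n_rej + sum(bad)
    tries <- tries + 1L
    if (tries > 1000L || n_rej > 0.5 * n_draws) {
      stop("rejection rate above 50% in contamination draws")
    }
  }
  den <- 1 - al * be
  xm <- (pm - al * pc) / den
  xc <- (pc - be * pm) / den
  dpm <- xm * (1 + be)
  dpc <- xc * (1 + al)
  structure(
    list(p_mito = mean(dpm), p_cyto = mean(dpc),
         p_mito_clipped = max(mean(dpm), 0), p_cyto_clipped = max(mean(dpc), 0),
         x_mito = mean(xm), x_cyto = mean(xc),
         sd_mito = stats::sd(dpm), sd_cyto = stats::sd(dpc),
         negative = mean(dpm) < 0 || mean(dpc) < 0,
         n_draws = n_draws, seed = seed),
    class = "deconvolved_pools"
  )
}

#' Deconvolve fraction-level MIDs into compartment MIDs
#'
#' Each mass-isotopomer's fraction-level pool size (`I_m[j] * P_m`,
#' `I_c[j] * P_c`) obeys the same two-source mixing model as total pool sizes,
#' so the pool closed forms are applied component-wise. Small negative
#' components (down to `-neg_tol` of the compartment total) are clipped to
#' zero and each compartment MID is renormalized; larger negatives indicate
#' inconsistent inputs and raise an error.
#'
#' @param mid_mito,mid_cyto Fraction-level MIDs ([mid] or numeric vectors of
#'   equal length).
#' @param p_mito,p_cyto Measured (pre-deconvolution) relative pool sizes of
#'   the metabolite in the two fractions.
#' @param cm A [contamination_model].
#' @param neg_tol Tolerated negative mass per component, as a fraction of the
#'   compartment's total deconvoluted pool (default 0.01).
#' @return List with elements `mid_mito` and `mid_cyto` (valid MIDs) and
#'   `pools`, the [deconvolve_pools()] result for the totals.
#' @export
deconvolve_mid <- function(mid_mito, mid_cyto, p_mito, p_cyto,
                           cm = contamination_model(), neg_tol = 0.01) {
  im <- mid_fractions(mid_mito)
  ic <- mid_fractions(mid_cyto)
  if (length(im) != length(ic)) stop("fraction MIDs must have equal length")
  stopifnot(p_mito >= 0, p_cyto >= 0)
  a <- cm$alpha; b <- cm$beta
  den <- 1 - a * b
  qm <- im * p_mito   # per-isotopomer pool sizes in the mitochondrial fraction
  qc <- ic * p_cyto
  dm <- (qm - a * qc) * (1 + b) / den
  dc <- (qc - b * qm) * (1 + a) / den
  clip_norm <- function(x, label) {
    tot <- sum(x)
    if (tot <= 0) stop("deconvoluted ", label, " MID has nonpositive total")
    if (any(x < -neg_tol * tot)) {
      stop(sprintf("deconvoluted %s MID component %.4g below -%g of total",
                   label, min(x), neg_tol))
    }
    x <- pmax(x, 0)
    x / sum(x)
  }
  nm_m <- if (is_mid(mid_mito)) mid_mito$metabolite else "metabolite"
  list(
    mid_mito = mid(nm_m, clip_norm(dm, "mitochondrial")),
    mid_cyto = mid(nm_m, clip_norm(dc, "cytosolic")),
    pools = deconvolve_pools(p_mito, p_cyto, cm)
  )
}

#' Monte-Carlo MID deconvolution with Gaussian error propagation
#'
#' Propagates measurement uncertainty of the fraction MIDs, the pool sizes and
#' the contamination parameters through [deconvolve_mid()]: each draw perturbs
#' every input with independent Gaussian noise (MID fractions truncated to
#' `[0, 1]` and renormalized; pools and contamination truncated at 0), and the
#' per-isotopomer mean and sd of the deconvoluted MIDs are returned.
#'
#' @inheritParams deconvolve_mid
#' @param sd_mid_mito,sd_mid_cyto Per-isotopomer measurement SDs (vectors
#'   matching the MIDs; scalars are recycled).
#' @param sd_pools Length-2 sd of `(p_mito, p_cyto)`.
#' @param n_draws Number of draws (default 2000).
#' @param seed Integer seed.
#' @return List with `mid_mito`, `mid_cyto` (mean MIDs), `sd_mito`, `sd_cyto`
#'   (per-isotopomer SDs).
#' @export
deconvolve_mid_mc <- function(mid_mito, mid_cyto, p_mito, p_cyto,
                              sd_mid_mito = 0, sd_mid_cyto = 0,
                              sd_pools = c(0, 0), cm = contamination_model(),
                              n_draws = 2000L, seed, neg_tol = 0.05) {
  if (missing(seed)) stop("a seed is required for Monte-Carlo deconvolution")
  im <- mid_fractions(mid_mito); ic <- mid_fractions(mid_cyto)
  k <- length(im)
  sd_mid_mito <- rep_len(sd_mid_mito, k)
  sd_mid_cyto <- rep_len(sd_mid_cyto, k)
  set.seed(seed)
  n <- n_draws
  # draws: n x k MID perturbations (truncated to [0,1], renormalized)
  IM <- pmin(pmax(matrix(im, n, k, byrow = TRUE) +
                    matrix(stats::rnorm(n * k, 0, sd_mid_mito), n, k,
                           byrow = TRUE), 0), 1)
  IC <- pmin(pmax(matrix(ic, n, k, byrow = TRUE) +
                    matrix(stats::rnorm(n * k, 0, sd_mid_cyto), n, k,
                           byrow = TRUE), 0), 1)
  IM <- IM / rowSums(IM)
  IC <- IC / rowSums(IC)
  pm <- pmax(stats::rnorm(n, p_mito, sd_pools[1]), 1e-12)
  pc <- pmax(stats::rnorm(n, p_cyto, sd_pools[2]), 1e-12)
  al <- pmax(stats::rnorm(n, cm$alpha, cm$sd), 0)
  be <- pmax(stats::rnorm(n, cm$beta, cm$sd), 0)
  ok <- al < 1 & be < 1 & al * be < 1 & is.finite(rowSums(IM)) &
    is.finite(rowSums(IC))
  den <- 1 - al * be
  QM <- IM * pm
  QC <- IC * pc
  DM <- (QM - al * QC) * (1 + be) / den
  DC <- (QC - be * QM) * (1 + al) / den
  tm <- rowSums(DM); tc <- rowSums(DC)
  ok <- ok & tm > 0 & tc > 0 &
    apply(DM, 1, min) > -neg_tol * tm & apply(DC, 1, min) > -neg_tol * tc
  if (mean(ok) < 0.5) stop("rejection rate above 50% in MID deconvolution draws")
  DM <- pmax(DM[ok, , drop = FALSE], 0); DM <- DM / rowSums(DM)
  DC <- pmax(DC[ok, , drop = FALSE], 0); DC <- DC / rowSums(DC)
  nm <- if (is_mid(mid_mito)) mid_mito$metabolite else "metabolite"
  list(
    mid_mito = mid(nm, colMeans(DM)),
    mid_cyto = mid(nm, colMeans(DC)),
    sd_mito = apply(DM, 2, stats::sd),
    sd_cyto = apply(DC, 2, stats::sd),
    n_used = sum(ok)
  )
}
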