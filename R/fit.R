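#' Measured citrate labeling dataset for flux fitting
#'
#' @param times Timepoints in minutes (strictly increasing).
#' @param X Matrix `length(times) x 4` of measured fractional labeling with
#'   columns `mito_low`, `cyto_low`, `mito_m5`, `cyto_m5` (the lower tracked
#'   isotopomer is citrate m+4 for WT, m+3 for SDH-KO).
#' @param SD Matrix of matching per-point measurement SDs (>= 0).
#' @param iso_low `"m4"` or `"m3"` (documentation of the tracked isotopomer).
#' @export
labeling_dataset <- function(times, X, SD, iso_low = "m4") {
  X <- as.matrix(X); SD <- as.matrix(SD)
  stopifnot(!is.unsorted(times, strictly = TRUE),
            nrow(X) == length(times), ncol(X) == 4L,
            all(dim(SD) == dim(X)),
            all(X >= -1e-9), all(X <= 1 + 1e-9), all(SD >= 0))
  colnames(X) <- colnames(SD) <- c("mito_low", "cyto_low", "mito_m5", "cyto_m5")
  structure(list(times = times, X = pmin(pmax(X, 0), 1), SD = SD,
                 iso_low = iso_low),
            class = "labeling_dataset")
}

#' Variance-weighted sum of squared residuals
#'
#' `sum(((X - Y) / max(SD, sigma_floor))^2)` over all fit times, both tracked
#' isotopomers and both compartments, where `Y` is the simulated labeling for
#' flux vector `v`.
#'
#' @param v A [flux_vector] (or named numeric satisfying the constraints).
#' @param data A [labeling_dataset] covering `cfg$fit_times`.
#' @param cfg A [model_config].
#' @param f A [forcing_set].
#' @return Nonnegative scalar SSR.
#' @export
objective_ssr <- function(v, data, cfg, f) {
  stopifnot(inherits(data, "labeling_dataset"))
  idx <- match(cfg$fit_times, data$times)
  if (anyNA(idx)) {
    stop("dataset is missing fit times: ",
         paste(cfg$fit_times[is.na(idx)], collapse = ", "))
  }
  Y <- simulate_labeling(v, cfg, f, cfg$fit_times)[, -1, drop = FALSE]
  R <- (data$X[idx, , drop = FALSE] - Y) /
    pmax(data$SD[idx, , drop = FALSE], cfg$sigma_floor)
  sum(R * R)
}

# Tolerant objective for the optimizer: no feasibility validation (the
# barrier method may probe slightly infeasible points during line search);
# non-finite or structurally impossible trajectories yield +Inf.
objective_ssr_raw <- function(v, data, cfg, f, idx, exact_ok = TRUE) {
  sys <- kfp_system(v, cfg)
  Y <- if (exact_ok) {
    eg <- eig2x2(sys$A)
    if (is.null(eg)) return(Inf)
    if (identical(f$mal_mito$type, "exp") &&
        identical(f$akg5_mito$type, "exp") &&
        identical(f$akg5_cyto$type, "exp")) {
      sim_analytic_exp(sys, f, cfg$fit_times, eg)
    } else {
      tryCatch(sim_analytic(sys, f, cfg$fit_times), error = function(e) NULL)
    }
  } else {
    tryCatch(sim_lsoda(sys, f, cfg$fit_times), error = function(e) NULL)
  }
  if (is.null(Y) || !all(is.finite(Y))) return(Inf)
  R <- (data$X[idx, , drop = FALSE] - Y) /
    pmax(data$SD[idx, , drop = FALSE], cfg$sigma_floor)
  sum(R * R)
}

# --- linear constraint machinery -------------------------------------------

# Equality rows (Aeq v = 0): mitochondrial and cytosolic citrate balance.
kfp_equality_matrix <- function() {
  Aeq <- matrix(0, 2, 10, dimnames = list(c("mito", "cyto"), flux_names))
  Aeq["mito", c("v_CS", "v_CIT_B", "v_IDH2_R", "v_IDH3_R")] <- 1
  Aeq["mito", c("v_CIT_F", "v_IDH2_O", "v_IDH3_O")] <- -1
  Aeq["cyto", c("v_CIT_F", "v_IDH1_R")] <- 1
  Aeq["cyto", c("v_CIT_B", "v_IDH1_O", "v_AcCoA")] <- -1
  Aeq
}

# Inequality rows in constrOptim convention: U v >= c.
# Nonnegativity, upper bounds, and the thermodynamic wedges
# lower_k * v_IDHk_O <= v_IDHk_R <= upper_k * v_IDHk_O.
kfp_inequality_matrix <- function(cfg) {
  ub <- cfg$flux_upper_bound
  U <- rbind(diag(10), -diag(10))
  cc <- c(rep(0, 10), rep(-ub, 10))
  rn <- c(paste0("nonneg_", flux_names), paste0("ub_", flux_names))
  for (k in c("IDH1", "IDH2", "IDH3")) {
    rb <- cfg$ratio_bounds[[k]]
    iR <- match(paste0("v_", k, "_R"), flux_names)
    iO <- match(paste0("v_", k, "_O"), flux_names)
    lo_row <- rep(0, 10); lo_row[iR] <- 1; lo_row[iO] <- -rb[1]
    U <- rbind(U, lo_row); cc <- c(cc, 0); rn <- c(rn, paste0("ratio_lo_", k))
    if (is.finite(rb[2])) {
      hi_row <- rep(0, 10); hi_row[iR] <- -1; hi_row[iO] <- rb[2]
      U <- rbind(U, hi_row); cc <- c(cc, 0); rn <- c(rn, paste0("ratio_hi_", k))
    }
  }
  dimnames(U) <- list(rn, flux_names)
  list(U = U, c = cc)
}

# Nullspace parameterization v = v0 + N z of {Aeq v = beq}.
nullspace_param <- function(Aeq, beq) {
  sv <- svd(Aeq, nu = nrow(Aeq), nv = ncol(Aeq))
  r <- sum(sv$d > 1e-10 * max(sv$d))
  N <- sv$v[, seq.int(r + 1L, ncol(Aeq)), drop = FALSE]
  v0 <- as.numeric(sv$v[, 1:r, drop = FALSE] %*%
                     ((t(sv$u[, 1:r, drop = FALSE]) %*% beq) / sv$d[1:r]))
  list(v0 = v0, N = N, rank = r)
}

# Smooth hinge-penalty phase-1: push z toward a point with all inequality
# margins >= delta. Returns NULL if no strictly feasible point is found.
phase1_start <- function(z0, Uz, cz, delta) {
  pen <- function(z) {
    m <- as.numeric(Uz %*% z) - cz
    d <- pmax(delta - m, 0)
    sum(d * d)
  }
  gpen <- function(z) {
    m <- as.numeric(Uz %*% z) - cz
    d <- pmax(delta - m, 0)
    as.numeric(-2 * crossprod(Uz, d))
  }
  if (pen(z0) == 0) return(list(par = z0, feasible = TRUE))
  o <- stats::optim(z0, pen, gpen, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-14))
  m <- as.numeric(Uz %*% o$par) - cz
  list(par = o$par, feasible = all(m > 0))
}

# Phase-1 with a decreasing margin ladder: thin but nonempty feasible wedges
# (nearly irreversible reactions give ratio bands of width ~1e-5 and below)
# only admit tiny interior margins.
feasible_z <- function(z0, Uz, cz, delta) {
  for (d in c(delta, delta * 1e-2, delta * 1e-4, delta * 1e-6)) {
    r <- phase1_start(z0, Uz, cz, d)
    if (r$feasible) return(r$par)
    z0 <- r$par
  }
  NULL
}

# Solve one constrained minimization from a strictly feasible z start.
solve_start <- function(z0, fobj, Uz, cz, maxit = 300) {
  fz <- function(z) fobj(z)
  gz <- function(z) {
    f0 <- fobj(z)
    h <- pmax(1e-7, 1e-7 * abs(z))
    g <- numeric(length(z))
    for (i in seq_along(z)) {
      zp <- z; zp[i] <- zp[i] + h[i]
      fp <- fobj(zp)
      if (!is.finite(fp)) {           # boundary: fall back to backward diff
        zm <- z; zm[i] <- zm[i] - h[i]
        fp <- f0; f0i <- fobj(zm)
        g[i] <- (fp - f0i) / h[i]
      } else {
        g[i] <- (fp - f0) / h[i]
      }
    }
    g
  }
  tryCatch(
    stats::constrOptim(z0, fz, gz, ui = Uz, ci = cz, mu = 1e-6,
                       method = "BFGS",
                       outer.iterations = 12, outer.eps = 1e-7,
                       control = list(maxit = maxit, reltol = 1e-10)),
    error = function(e) NULL)
}

# Random strictly feasible starting flux vectors (z-space).
random_feasible_z <- function(n, np, Uz, cz, ub, delta, max_tries = 60L) {
  d <- ncol(Uz)
  out <- vector("list", n)
  got <- 0L
  tries <- 0L
  while (got < n && tries < max_tries * n) {
    tries <- tries + 1L
    # mix start magnitudes across scales so small-flux regimes are reachable
    scale <- exp(stats::runif(1, log(0.02), log(0.3)))
    z0 <- stats::rnorm(d, 0, ub * scale)
    z <- feasible_z(z0, Uz, cz, delta)
    if (!is.null(z)) {
      got <- got + 1L
      out[[got]] <- z
    }
  }
  if (got == 0L) stop("no feasible start found; check ratio bounds and upper bounds")
  out[seq_len(got)]
}

#' Fit the compartmentalized citrate fluxes by constrained maximum likelihood
#'
#' Minimizes [objective_ssr()] over the ten nonnegative fluxes subject to the
#' two citrate mass-balance equalities and the thermodynamic ratio wedges.
#' The equalities are eliminated exactly by a nullspace reparameterization;
#' the remaining linear inequalities are handled by a logarithmic-barrier
#' BFGS (`stats::constrOptim`) run from multiple random strictly feasible
#' starts (plus optional user-supplied warm starts).
#'
#' @param data A [labeling_dataset].
#' @param cfg A [model_config] (carries the thermodynamic `ratio_bounds`).
#' @param f A [forcing_set].
#' @param n_starts Number of random multi-starts (default 50).
#' @param seed Integer seed for the random starts.
#' @param init Optional list of flux vectors used as additional warm starts.
#' @param pin Optional named list `list(name =, value =)` fixing one flux by
#'   an extra equality (used by profile likelihood).
#' @param maxit BFGS iteration cap per barrier stage.
#' @return Object of class `"kfp_fit"`: `best` ([flux_vector]), `ssr`,
#'   `n_starts`, `n_converged`, `starts` (per-start SSR table),
#'   `trajectories` (fitted curves at `cfg$fit_times`), plus the constraint
#'   bookkeeping needed by [profile_ci()].
#' @export
fit_fluxes <- function(data, cfg, f, n_starts = 50L, seed = 1L, init = NULL,
                       pin = NULL, maxit = 300) {
  stopifnot(n_starts >= 0L || length(init) > 0L)
  for (k in c("IDH1", "IDH2", "IDH3")) {
    rb <- cfg$ratio_bounds[[k]]
    if (rb[1] > rb[2]) stop("infeasible ratio bounds for ", k)
  }
  Aeq <- kfp_equality_matrix()
  beq <- c(0, 0)
  if (!is.null(pin)) {
    row <- rep(0, 10); row[match(pin$name, flux_names)] <- 1
    Aeq <- rbind(Aeq, pin = row)
    beq <- c(beq, pin$value)
  }
  np <- nullspace_param(Aeq, beq)
  ineq <- kfp_inequality_matrix(cfg)
  Uz <- ineq$U %*% np$N
  cz <- ineq$c - as.numeric(ineq$U %*% np$v0)
  # drop constraint rows that do not involve the free directions
  keep <- rowSums(abs(Uz)) > 1e-12
  if (any(!keep & cz > 1e-9)) stop("constraints infeasible for pinned flux")
  Uz <- Uz[keep, , drop = FALSE]; czk <- cz[keep]
  to_v <- function(z) as.numeric(np$v0 + np$N %*% z)
  idx <- match(cfg$fit_times, data$times)
  if (anyNA(idx)) {
    stop("dataset is missing fit times: ",
         paste(cfg$fit_times[is.na(idx)], collapse = ", "))
  }
  exact_ok <- all(vapply(f, function(x) identical(x$type, "pwl") ||
                           identical(x$type, "exp"), logical(1)))
  fobj <- function(z) {
    v <- stats::setNames(to_v(z), flux_names)
    objective_ssr_raw(v, data, cfg, f, idx, exact_ok = exact_ok)
  }
  delta <- 1e-4 * cfg$flux_upper_bound
  set.seed(seed)
  starts <- if (n_starts > 0L) {
    random_feasible_z(n_starts, np, Uz, czk, cfg$flux_upper_bound, delta)
  } else list()
  if (!is.null(init)) {
    for (vi in init) {
      z0 <- as.numeric(crossprod(np$N, unclass(vi)[flux_names] - np$v0))
      z <- feasible_z(z0, Uz, czk, delta / 10)
      if (!is.null(z)) starts <- c(starts, list(z))
    }
  }
  if (length(starts) == 0L) stop("no feasible start found")
  fits <- lapply(starts, solve_start, fobj = fobj, Uz = Uz, cz = czk,
                 maxit = maxit)
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all optimization starts failed to converge")
  vals <- vapply(fits[ok], `[[`, numeric(1), "value")
  conv <- vapply(fits[ok], function(x) x$convergence == 0, logical(1))
  best_i <- which.min(vals)
  zb <- fits[ok][[best_i]]$par
  vb <- stats::setNames(pmax(to_v(zb), 0), flux_names)
  # polish roundoff so the reported vector satisfies the invariants exactly
  vb_feas <- tryCatch(flux_vector(vb, tol = 1e-5), error = function(e) vb)
  traj <- simulate_labeling(stats::setNames(to_v(zb), flux_names), cfg, f,
                            cfg$fit_times)
  structure(
    list(best = vb_feas, ssr = vals[best_i],
         n_starts = length(starts), n_converged = sum(conv),
         starts = data.frame(start = seq_along(vals), ssr = vals,
                             converged = conv),
         trajectories = traj,
         z_best = zb, pin = pin,
         data = data, cfg = cfg, forcings = f, seed = seed),
    class = "kfp_fit"
  )
}

#' @export
print.kfp_fit <- function(x, ...) {
  cat(sprintf("<kfp_fit> SSR = %.4g (%d/%d starts converged)\n",
              x$ssr, x$n_converged, x$n_starts))
  print(round(unclass(x$best), 4))
  if (!is.null(x$ci)) {
    cat("95% profile-likelihood intervals (mM/h):\n")
    print(round(x$ci, 4))
  }
  invisible(x)
}
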