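#' Names of the ten fluxes of the compartmentalized citrate model
#'
#' Citrate synthase (`v_CS`), mitochondria-to-cytosol citrate transport and
#' its reverse (`v_CIT_F`, `v_CIT_B`), oxidative (`_O`) and reductive (`_R`)
#' directions of the three IDH isozymes, and cytosolic acetyl-CoA demand
#' (`v_AcCoA`). All in mM/h.
#' @export
flux_names <- c("v_CS", "v_CIT_F", "v_CIT_B",
                "v_IDH1_R", "v_IDH1_O",
                "v_IDH2_R", "v_IDH2_O",
                "v_IDH3_R", "v_IDH3_O",
                "v_AcCoA")

#' Mass-balance residuals of a flux vector
#'
#' Mitochondrial citrate balance:
#' `v_CS + v_CIT_B + v_IDH2_R + v_IDH3_R - (v_CIT_F + v_IDH2_O + v_IDH3_O)`;
#' cytosolic citrate balance:
#' `v_CIT_F + v_IDH1_R - (v_CIT_B + v_IDH1_O + v_AcCoA)`.
#'
#' @param v Named numeric vector over [flux_names].
#' @return Length-2 numeric `c(mito, cyto)` of balance residuals (mM/h).
#' @export
mass_balance_residuals <- function(v) {
  c(mito = unname(v["v_CS"] + v["v_CIT_B"] + v["v_IDH2_R"] + v["v_IDH3_R"] -
                    (v["v_CIT_F"] + v["v_IDH2_O"] + v["v_IDH3_O"])),
    cyto = unname(v["v_CIT_F"] + v["v_IDH1_R"] -
                    (v["v_CIT_B"] + v["v_IDH1_O"] + v["v_AcCoA"])))
}

#' Construct and validate a flux vector
#'
#' @param ... Either a single named numeric vector over [flux_names], or the
#'   ten fluxes as named arguments (mM/h).
#' @param tol Relative tolerance for the two mass-balance equalities.
#' @return Named numeric vector of class `"flux_vector"`.
#' @export
flux_vector <- function(..., tol = 1e-6) {
  args <- list(...)
  v <- if (length(args) == 1L && is.numeric(args[[1]]) && length(args[[1]]) == 10L) {
    args[[1]]
  } else {
    unlist(args)
  }
  if (!all(flux_names %in% names(v))) {
    stop("flux vector must name all of: ", paste(flux_names, collapse = ", "))
  }
  v <- v[flux_names]
  if (any(v < -tol * max(1, max(abs(v))))) stop("fluxes must be nonnegative")
  v <- pmax(v, 0)
  res <- mass_balance_residuals(v)
  if (any(abs(res) > tol * max(1, sum(abs(v))))) {
    stop(sprintf("mass balance violated (mito %.3g, cyto %.3g)", res[1], res[2]))
  }
  structure(v, class = c("flux_vector", "numeric"))
}

#' Forcing curve from measured labeling points
#'
#' Piecewise-linear interpolant through measured fractional-labeling points,
#' anchored at (0, 0) and held constant after the last point.
#'
#' @param times Measurement times in minutes (strictly increasing, > 0 unless
#'   a 0 point is supplied explicitly).
#' @param values Fractional labeling in `[0, 1]` at `times`.
#' @return Object of class `"forcing"` with fields `times`, `values`, `fun`,
#'   and `type = "pwl"` (handled exactly by the segment-wise ODE propagator).
#' @export
forcing_points <- function(times, values) {
  stopifnot(length(times) == length(values), all(diff(times) > 0),
            all(values >= -1e-9), all(values <= 1 + 1e-9))
  values <- pmin(pmax(values, 0), 1)
  if (times[1] > 0) { times <- c(0, times); values <- c(0, values) }
  f <- stats::approxfun(times, values, rule = 2)
  structure(list(times = times, values = values, fun = f, type = "pwl"),
            class = "forcing")
}

#' Constant forcing curve
#'
#' Mathematical device (e.g. steady-state analysis); bypasses the requirement
#' that forcings start unlabeled.
#' @param value Constant fractional labeling in `[0, 1]`.
#' @export
forcing_constant <- function(value) {
  stopifnot(value >= 0, value <= 1)
  structure(list(times = 0, values = value,
                 fun = function(t) rep(value, length(t)), type = "pwl"),
            class = "forcing")
}

#' Saturating-exponential forcing curve
#'
#' `A * (1 - exp(-k t))`: 0 at t = 0, plateau `A` as t grows. Handled exactly
#' by the segment-wise ODE propagator (the forced response of each eigenmode
#' has a closed form for exponential inputs).
#'
#' @param A Plateau in `[0, 1]`.
#' @param k Rate constant in 1/min (>= 0).
#' @export
forcing_exponential <- function(A, k) {
  stopifnot(A >= 0, A <= 1, k >= 0)
  structure(list(times = NULL, values = NULL, A = A, k = k,
                 fun = function(t) A * (1 - exp(-k * t)), type = "exp"),
            class = "forcing")
}

#' Bundle the three forcing curves of the citrate model
#'
#' @param akg5_mito,akg5_cyto Mitochondrial and cytosolic alpha-ketoglutarate
#'   m+5 labeling curves ([forcing_points()] etc.).
#' @param mal_mito Mitochondrial malate labeling curve for the oxidatively
#'   produced citrate isotopomer: malate m+4 for the WT variant, m+3 for the
#'   SDH-KO variant.
#' @export
forcing_set <- function(akg5_mito, akg5_cyto, mal_mito) {
  fs <- list(akg5_mito = akg5_mito, akg5_cyto = akg5_cyto, mal_mito = mal_mito)
  stopifnot(all(vapply(fs, inherits, logical(1), "forcing")))
  structure(fs, class = "forcing_set")
}

#' Configuration of the kinetic flux-profiling model
#'
#' @param variant `"WT"` (track citrate m+4 and m+5) or `"SDHKO"` (citrate
#'   m+3 and m+5; malate m+3 replaces m+4 as the oxidative source).
#' @param u_cit_mito,u_cit_cyto Citrate pool sizes in mitochondria and cytosol
#'   (mM, whole-cell-volume basis; > 0).
#' @param fit_times Labeling timepoints (minutes) entering the objective;
#'   default `c(2, 5, 10, 20, 30, 60, 180)`.
#' @param sigma_floor Minimum residual sd (absolute MID fraction) guarding
#'   against near-zero replicate SDs; default 0.002.
#' @param flux_upper_bound Upper bound on every flux (mM/h); default 5.
#' @param ratio_bounds Named list `IDH1`, `IDH2`, `IDH3`, each `c(lower,
#'   upper)` bounding the reductive:oxidative flux ratio (from
#'   [idh_ratio_bounds()]).
#' @export
model_config <- function(variant = c("WT", "SDHKO"),
                         u_cit_mito, u_cit_cyto,
                         fit_times = c(2, 5, 10, 20, 30, 60, 180),
                         sigma_floor = 0.002,
                         flux_upper_bound = 5,
                         ratio_bounds = list(IDH1 = c(0, Inf),
                                             IDH2 = c(0, Inf),
                                             IDH3 = c(0, Inf))) {
  variant <- match.arg(variant)
  stopifnot(u_cit_mito > 0, u_cit_cyto > 0, all(fit_times > 0),
            !is.unsorted(fit_times, strictly = TRUE),
            sigma_floor > 0, flux_upper_bound > 0)
  stopifnot(all(c("IDH1", "IDH2", "IDH3") %in% names(ratio_bounds)))
  for (k in c("IDH1", "IDH2", "IDH3")) {
    rb <- ratio_bounds[[k]]
    if (length(rb) != 2L || rb[1] < 0 || rb[1] > rb[2]) {
      stop("infeasible ratio bounds for ", k, " (need 0 <= lower <= upper)")
    }
  }
  structure(list(variant = variant, u_cit_mito = u_cit_mito,
                 u_cit_cyto = u_cit_cyto, fit_times = fit_times,
                 sigma_floor = sigma_floor,
                 flux_upper_bound = flux_upper_bound,
                 ratio_bounds = ratio_bounds),
            class = "model_config")
}

# System matrix and forcing coefficients of the tracked-isotopomer ODEs.
# Both tracked isotopomers share the 2x2 matrix
#   d/dt [Y_mito; Y_cyto] = A [Y_mito; Y_cyto] + g(t),
# with A = [[-(v_CS+v_IDH2_R+v_IDH3_R+v_CIT_B)/u_M, v_CIT_B/u_M],
#           [v_CIT_F/u_C, -(v_CIT_F+v_IDH1_R)/u_C]]
# (fluxes in mM/min). The lower isotopomer (m+4 WT, m+3 SDH-KO) is forced by
# v_CS * X_mal in mitochondria; m+5 by (v_IDH2_R+v_IDH3_R) * X_akg5^M there
# and v_IDH1_R * X_akg5^C in cytosol.
kfp_system <- function(v, cfg) {
  w <- unclass(v) / 60   # mM/h -> mM/min
  dM <- w["v_CS"] + w["v_IDH2_R"] + w["v_IDH3_R"] + w["v_CIT_B"]
  dC <- w["v_CIT_F"] + w["v_IDH1_R"]
  A <- matrix(c(-dM / cfg$u_cit_mito, w["v_CIT_B"] / cfg$u_cit_mito,
                w["v_CIT_F"] / cfg$u_cit_cyto, -dC / cfg$u_cit_cyto),
              2, 2, byrow = TRUE)
  list(
    A = A,
    # forcing coefficient per (system, compartment): g(t) = c_m * x_m(t) / u_M etc.
    low = list(cm = unname(w["v_CS"]) / cfg$u_cit_mito, cc = 0),
    high = list(cm = unname(w["v_IDH2_R"] + w["v_IDH3_R"]) / cfg$u_cit_mito,
                cc = unname(w["v_IDH1_R"]) / cfg$u_cit_cyto)
  )
}

# Closed-form eigendecomposition of the 2x2 system matrix. The sign structure
# (nonnegative off-diagonal, nonpositive diagonal) guarantees real
# eigenvalues; returns NULL when the matrix is (near-)defective.
eig2x2 <- function(A) {
  tr <- A[1, 1] + A[2, 2]
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  disc <- tr * tr - 4 * det
  if (!is.finite(disc) || disc < 0) return(NULL)
  sq <- sqrt(disc)
  lam <- c((tr + sq) / 2, (tr - sq) / 2)
  if (abs(lam[1] - lam[2]) < 1e-12) return(NULL)
  V <- if (abs(A[1, 2]) >= abs(A[2, 1])) {
    matrix(c(A[1, 2], lam[1] - A[1, 1], A[1, 2], lam[2] - A[1, 1]), 2, 2)
  } else {
    matrix(c(lam[1] - A[2, 2], A[2, 1], lam[2] - A[2, 2], A[2, 1]), 2, 2)
  }
  dV <- V[1, 1] * V[2, 2] - V[1, 2] * V[2, 1]
  if (!is.finite(dV) || abs(dV) < 1e-300) return(NULL)
  Vinv <- matrix(c(V[2, 2], -V[2, 1], -V[1, 2], V[1, 1]), 2, 2) / dV
  list(lambda = lam, V = V, Vinv = Vinv)
}

# Closed-form eigenmode integrals over one segment of length delta:
#   int_0^delta exp(lambda (delta - s)) * 1 ds          (seg_i1)
#   int_0^delta exp(lambda (delta - s)) * s ds          (seg_i2)
#   int_0^delta exp(lambda (delta - s)) * exp(-k s) ds  (seg_iexp)
# with series guards for small exponents.
seg_i1 <- function(lam, delta) {
  ld <- lam * delta
  ifelse(abs(ld) > 1e-6, (exp(ld) - 1) / lam,
         delta * (1 + ld / 2 + ld^2 / 6))
}
seg_i2 <- function(lam, delta) {
  ld <- lam * delta
  ifelse(abs(ld) > 1e-6, (exp(ld) - 1 - ld) / lam^2,
         delta^2 * (0.5 + ld / 6 + ld^2 / 24))
}
seg_iexp <- function(lam, k, delta) {
  x <- (lam + k) * delta
  ifelse(abs(x) > 1e-6,
         exp(lam * delta) * (1 - exp(-x)) / (lam + k),
         exp(lam * delta) * delta * (1 - x / 2 + x^2 / 6))
}

# Exact propagation of dY/dt = A Y + g(t) over one segment on which every
# forcing channel is either linear in t (piecewise-linear curves) or of the
# form c0 + c1 exp(-k t) (saturating exponentials): eigendecompose A (real
# eigenvalues are guaranteed by the sign structure) and integrate the forced
# response of each eigenmode in closed form. Y0 is 2 x m (one column per
# isotopomer system sharing A); P, Q are the constant and slope parts; exps
# is a list of (col, row, amp, k) exponential terms local to the segment.
propagate_segment <- function(eg, Y0, delta, P, Q, exps) {
  lam <- eg$lambda
  E <- exp(lam * delta)
  W1 <- E * (eg$Vinv %*% Y0) +
    seg_i1(lam, delta) * (eg$Vinv %*% P) +
    seg_i2(lam, delta) * (eg$Vinv %*% Q)
  for (tm in exps) {
    W1[, tm$col] <- W1[, tm$col] +
      seg_iexp(lam, tm$k, delta) * (tm$amp * eg$Vinv[, tm$row])
  }
  eg$V %*% W1
}

#' Simulate tracked citrate isotopomer labeling kinetics
#'
#' Integrates the four linear ODEs for the two tracked citrate mass
#' isotopomers in mitochondria and cytosol, starting unlabeled, driven by the
#' alpha-ketoglutarate and malate forcing curves. Piecewise-linear and
#' saturating-exponential forcings use an exact segment-wise eigenmode
#' propagator; other forcing functions fall back to `deSolve::lsoda`.
#'
#' @param v A [flux_vector] (mass balance is re-checked).
#' @param cfg A [model_config].
#' @param f A [forcing_set].
#' @param t_eval Output times in minutes (>= 0).
#' @param method `"auto"` (exact propagation when all forcings are piecewise
#'   linear or exponential), `"analytic"`, or `"lsoda"`.
#' @return Matrix with one row per `t_eval` and columns `time`, `mito_low`,
#'   `cyto_low`, `mito_m5`, `cyto_m5`; attribute `iso_low` names the lower
#'   tracked isotopomer (`"m4"` for WT, `"m3"` for SDH-KO).
#' @export
simulate_labeling <- function(v, cfg, f, t_eval,
                              method = c("auto", "analytic", "lsoda")) {
  method <- match.arg(method)
  stopifnot(inherits(cfg, "model_config"), inherits(f, "forcing_set"),
            all(t_eval >= 0))
  res <- mass_balance_residuals(v)
  if (any(abs(res) > 1e-6 * max(1, sum(abs(v))))) {
    stop("flux vector violates mass balance beyond tolerance")
  }
  if (any(unclass(v) < -1e-9)) stop("fluxes must be nonnegative")
  sys <- kfp_system(v, cfg)
  exact_ok <- all(vapply(f, function(x) identical(x$type, "pwl") ||
                           identical(x$type, "exp"), logical(1)))
  if (method == "auto") method <- if (exact_ok) "analytic" else "lsoda"
  if (method == "analytic" && !exact_ok) {
    stop("analytic propagation requires piecewise-linear or exponential forcings")
  }
  ord <- order(t_eval)
  te <- t_eval[ord]
  out <- if (method == "analytic") {
    sim_analytic(sys, f, te)
  } else {
    sim_lsoda(sys, f, te)
  }
  out <- out[order(ord), , drop = FALSE]
  out <- cbind(time = t_eval, out)
  # guard against tiny numerical under/overshoot
  out[, -1] <- pmin(pmax(out[, -1], 0), 1)
  colnames(out) <- c("time", "mito_low", "cyto_low", "mito_m5", "cyto_m5")
  attr(out, "iso_low") <- if (cfg$variant == "WT") "m4" else "m3"
  out
}

sim_analytic <- function(sys, f, te) {
  eg <- eig2x2(sys$A)
  if (is.null(eg)) {
    # complex or (near-)defective matrix: delegate to the adaptive integrator
    return(sim_lsoda(sys, f, te))
  }
  if (identical(f$mal_mito$type, "exp") && identical(f$akg5_mito$type, "exp") &&
      identical(f$akg5_cyto$type, "exp")) {
    return(sim_analytic_exp(sys, f, te, eg))
  }
  # forcing channels: (system column, matrix row, coefficient, curve)
  channels <- list(
    list(col = 1L, row = 1L, coeff = sys$low$cm, f = f$mal_mito),
    list(col = 2L, row = 1L, coeff = sys$high$cm, f = f$akg5_mito),
    list(col = 2L, row = 2L, coeff = sys$high$cc, f = f$akg5_cyto))
  pwl_times <- unlist(lapply(f, function(x)
    if (identical(x$type, "pwl")) x$times else NULL))
  brk <- sort(unique(c(0, pwl_times, te)))
  brk <- brk[brk <= max(te)]
  Y <- matrix(0, 2, 2)   # columns: low, high
  out <- matrix(NA_real_, length(te), 4)
  ti <- 1L
  while (ti <= length(te) && te[ti] <= 0) {
    out[ti, ] <- c(Y[, 1], Y[, 2]); ti <- ti + 1L
  }
  for (s in seq_len(length(brk) - 1L)) {
    t0 <- brk[s]; t1 <- brk[s + 1L]
    if (t1 <= t0) next
    delta <- t1 - t0
    P <- matrix(0, 2, 2); Q <- matrix(0, 2, 2)
    exps <- list()
    for (ch in channels) {
      if (ch$coeff == 0) next
      if (identical(ch$f$type, "exp")) {
        # c * A (1 - e^{-k t}) = c A - c A e^{-k t0} e^{-k s}
        P[ch$row, ch$col] <- P[ch$row, ch$col] + ch$coeff * ch$f$A
        exps[[length(exps) + 1L]] <- list(
          col = ch$col, row = ch$row,
          amp = -ch$coeff * ch$f$A * exp(-ch$f$k * t0), k = ch$f$k)
      } else {
        v0 <- ch$f$fun(t0); v1 <- ch$f$fun(t1)
        P[ch$row, ch$col] <- P[ch$row, ch$col] + ch$coeff * v0
        Q[ch$row, ch$col] <- Q[ch$row, ch$col] + ch$coeff * (v1 - v0) / delta
      }
    }
    Y <- propagate_segment(eg, Y, delta, P, Q, exps)
    while (ti <= length(te) && abs(te[ti] - t1) < 1e-12) {
      out[ti, ] <- c(Y[, 1], Y[, 2]); ti <- ti + 1L
    }
  }
  out
}

# Global closed-form solution when every forcing is a saturating exponential
# A (1 - e^{-k t}): each eigenmode w' = lam w + p + sum_j c_j e^{-k_j t},
# w(0) = 0, solves to
#   w(t) = p (e^{lam t} - 1) / lam + sum_j c_j (e^{-k_j t} - e^{lam t}) / (-k_j - lam)
# with the resonance limit c_j t e^{lam t} as k_j -> -lam and p t as lam -> 0.
sim_analytic_exp <- function(sys, f, te, eg) {
  lam <- eg$lambda
  Vinv <- eg$Vinv
  nt <- length(te)
  E1 <- exp(lam[1] * te); E2 <- exp(lam[2] * te)
  b1 <- if (abs(lam[1]) > 1e-12) (E1 - 1) / lam[1] else te
  b2 <- if (abs(lam[2]) > 1e-12) (E2 - 1) / lam[2] else te
  # mode response to one forcing channel coeff * A (1 - e^{-k t}) hitting row r
  mode_resp <- function(coeff, A, k, r, m, Em, bm) {
    if (coeff == 0 || A == 0) return(0)
    p <- coeff * A * Vinv[m, r]
    amp <- -p
    den <- -k - lam[m]
    p * bm + (if (abs(den) > 1e-10) amp * (exp(-k * te) - Em) / den
              else amp * te * Em)
  }
  # low system: mal_mito on row 1
  w1_low <- mode_resp(sys$low$cm, f$mal_mito$A, f$mal_mito$k, 1L, 1L, E1, b1)
  w2_low <- mode_resp(sys$low$cm, f$mal_mito$A, f$mal_mito$k, 1L, 2L, E2, b2)
  # high system: akg5_mito on row 1, akg5_cyto on row 2
  w1_high <- mode_resp(sys$high$cm, f$akg5_mito$A, f$akg5_mito$k, 1L, 1L, E1, b1) +
    mode_resp(sys$high$cc, f$akg5_cyto$A, f$akg5_cyto$k, 2L, 1L, E1, b1)
  w2_high <- mode_resp(sys$high$cm, f$akg5_mito$A, f$akg5_mito$k, 1L, 2L, E2, b2) +
    mode_resp(sys$high$cc, f$akg5_cyto$A, f$akg5_cyto$k, 2L, 2L, E2, b2)
  V <- eg$V
  cbind(V[1, 1] * w1_low + V[1, 2] * w2_low,
        V[2, 1] * w1_low + V[2, 2] * w2_low,
        V[1, 1] * w1_high + V[1, 2] * w2_high,
        V[2, 1] * w1_high + V[2, 2] * w2_high)
}

sim_lsoda <- function(sys, f, te) {
  deriv <- function(t, y, parms) {
    gl <- c(sys$low$cm * f$mal_mito$fun(t), sys$low$cc)
    gh <- c(sys$high$cm * f$akg5_mito$fun(t),
            sys$high$cc * f$akg5_cyto$fun(t))
    dy_low <- sys$A %*% y[1:2] + gl
    dy_high <- sys$A %*% y[3:4] + gh
    list(c(dy_low, dy_high))
  }
  times <- sort(unique(c(0, te)))
  sol <- deSolve::lsoda(y = c(0, 0, 0, 0), times = times, func = deriv,
                        parms = NULL, rtol = 1e-9, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0) stop("ODE integration failed")
  sol[match(te, sol[, 1]), 2:5, drop = FALSE]
}

#' Fit a saturating-exponential curve to measured forcing points
#'
#' Least-squares fit of `A * (1 - exp(-k t))` to fractional-labeling
#' measurements, used to smooth noisy upstream (alpha-ketoglutarate, malate)
#' labeling time courses before they enter the ODEs as forcings.
#'
#' @param times Measurement times (minutes, > 0).
#' @param values Measured fractional labeling at `times`.
#' @return A [forcing_exponential()] forcing with the fitted `A`, `k`.
#' @export
fit_forcing_curve <- function(times, values) {
  stopifnot(length(times) == length(values), all(times > 0))
  values <- pmin(pmax(values, 0), 1)
  if (all(values < 1e-9)) return(forcing_exponential(0, 1))
  A0 <- max(values)
  # initial rate from the earliest point at half plateau or more
  half <- which(values >= A0 / 2)[1]
  k0 <- if (is.finite(half)) log(2) / max(times[half], 1e-3) else 1 / max(times)
  obj <- function(th) sum((th[1] * (1 - exp(-th[2] * times)) - values)^2)
  o <- stats::optim(c(min(A0, 1), k0), obj, method = "L-BFGS-B",
                    lower = c(0, 1e-6), upper = c(1, 100),
                    control = list(factr = 1e3, maxit = 500))
  forcing_exponential(o$par[1], o$par[2])
}
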