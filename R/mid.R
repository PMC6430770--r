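#' Mass-isotopomer distribution (MID)
#'
#' A MID holds the fractional abundances of a metabolite pool carrying
#' 0..n labeled carbons (m+0, m+1, ..., m+n). Fractions are nonnegative and
#' sum to one; the constructor renormalizes small deviations.
#'
#' @param metabolite Metabolite identifier (character scalar).
#' @param fractions Numeric vector of length `n_carbons + 1` with the m+0..m+n
#'   fractional abundances.
#' @param normalize_tol Largest tolerated deviation of `sum(fractions)` from 1
#'   before a warning is issued (the vector is renormalized either way).
#' @return An object of class `"mid"`.
#' @export
mid <- function(metabolite, fractions, normalize_tol = 0.05) {
  stopifnot(is.character(metabolite), length(metabolite) == 1L)
  fractions <- as.numeric(fractions)
  if (length(fractions) < 1L || anyNA(fractions)) {
    stop("MID fractions must be a non-empty numeric vector without NAs")
  }
  if (any(fractions < -1e-9)) {
    stop("MID fractions must be nonnegative (got ", min(fractions), ")")
  }
  fractions <- pmax(fractions, 0)
  s <- sum(fractions)
  if (s <= 0) stop("MID fractions sum to zero; cannot normalize")
  if (abs(s - 1) > normalize_tol) {
    warning(sprintf("MID for %s sums to %.4f; renormalizing", metabolite, s))
  }
  fractions <- fractions / s
  structure(
    list(metabolite = metabolite,
         n_carbons = length(fractions) - 1L,
         fractions = fractions),
    class = "mid"
  )
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("<mid> %s (%d carbons)\n", x$metabolite, x$n_carbons))
  lbl <- paste0("m+", seq_along(x$fractions) - 1L)
  print(stats::setNames(round(x$fractions, 6), lbl))
  invisible(x)
}

#' @export
is_mid <- function(x) inherits(x, "mid")

#' Extract the fraction vector from a MID or plain numeric vector
#' @param x A [mid] or numeric vector.
#' @return Numeric vector of isotopomer fractions.
#' @export
mid_fractions <- function(x) if (is_mid(x)) x$fractions else as.numeric(x)

#' Natural-abundance convolution matrix
#'
#' Matrix `C` with `C[i+1, j+1]` the probability of observing `i` total heavy
#' carbons in a molecule with `j` tracer-labeled carbons, when each of the
#' `n - j` remaining carbons is independently 13C with probability
#' `abundance_13C` (binomial model; tracer carbons are assumed fully labeled).
#'
#' @param n_carbons Number of carbon atoms in the metabolite.
#' @param abundance_13C Natural 13C abundance (default 0.0107).
#' @return `(n+1) x (n+1)` lower-triangular matrix mapping a tracer MID to the
#'   observed MID by `observed = C %*% tracer`.
#' @export
na_correction_matrix <- function(n_carbons, abundance_13C = 0.0107) {
  stopifnot(n_carbons >= 0, abundance_13C >= 0, abundance_13C < 0.5)
  n <- n_carbons
  C <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    k <- j:n   # observable totals given j labeled carbons
    C[k + 1L, j + 1L] <- stats::dbinom(k - j, n - j, abundance_13C)
  }
  C
}

#' Correct a measured MID for natural 13C abundance
#'
#' Finds the tracer-labeling MID that best explains the observed MID under the
#' binomial natural-abundance model, by nonnegative least squares against the
#' forward convolution matrix [na_correction_matrix()]. The unconstrained
#' solution is inspected first: a component below -0.01 signals data
#' inconsistent with the model and raises an error.
#'
#' @param raw Observed MID (a [mid] or plain numeric vector of fractions).
#' @param abundance_13C Natural 13C abundance; default 0.0107.
#' @return A corrected [mid] (plain numeric in, plain numeric out).
#' @export
correct_natural_abundance <- function(raw, abundance_13C = 0.0107) {
  stopifnot(abundance_13C >= 0, abundance_13C < 0.5)
  fr <- mid_fractions(raw)
  n <- length(fr) - 1L
  if (abundance_13C == 0) return(raw)
  C <- na_correction_matrix(n, abundance_13C)
  exact <- solve(C, fr)
  if (any(exact < -0.01)) {
    stop(sprintf(
      "natural-abundance correction failed: component %.4f < -0.01 suggests an invalid input MID",
      min(exact)))
  }
  x <- if (any(exact < 0)) pracma::lsqnonneg(C, fr)$x else exact
  x <- pmax(x, 0)
  x <- x / sum(x)
  if (is_mid(raw)) mid(raw$metabolite, x) else x
}

#' Isotope-ratio pair for pool-size quantification
#'
#' Holds the labeled-to-unlabeled intensity ratio of a metabolite in the
#' internal-standard-only extract (`R1`) and in a subcellular fraction mixed
#' with the same standard (`R2`), at a given standard:fraction dilution.
#'
#' @param R1,R2 Positive intensity ratios.
#' @param dilution Dilution label, e.g. `"1:1"`, `"1:5"`, `"1:10"`.
#' @export
isotope_ratio_pair <- function(R1, R2, dilution = "1:1") {
  stopifnot(is.numeric(R1), is.numeric(R2), length(R1) == 1L, length(R2) == 1L)
  if (!(R1 > 0) || !(R2 > 0)) stop("isotope ratios R1 and R2 must be positive")
  structure(list(R1 = R1, R2 = R2, dilution = as.character(dilution)),
            class = "isotope_ratio_pair")
}

#' Relative pool size from an isotope-ratio pair
#'
#' The fraction of the whole-cell pool present in the analyzed subcellular
#' fraction, computed as `(1 - R2/R1) / (R2 + R2/R1)`. Values below zero
#' (possible when `R2 > R1` through noise) are clipped to 0 with a warning.
#'
#' @param pair An [isotope_ratio_pair], or a positive number `R1` when `R2`
#'   is supplied separately.
#' @param R2 Optional second ratio when `pair` is given as `R1`.
#' @return Dimensionless pool fraction in `[0, 1]`-ish range (can exceed 1 for
#'   concentrated fractions; never negative).
#' @export
isotope_ratio_pool_fraction <- function(pair, R2 = NULL) {
  if (inherits(pair, "isotope_ratio_pair")) {
    R1 <- pair$R1; R2 <- pair$R2
  } else {
    R1 <- pair
    if (is.null(R2)) stop("supply an isotope_ratio_pair or both R1 and R2")
  }
  if (any(R1 <= 0) || any(R2 <= 0)) stop("isotope ratios must be positive")
  val <- (1 - R2 / R1) / (R2 + R2 / R1)
  if (any(val < 0)) {
    warning("negative pool fraction (R2 > R1); clipping to 0")
    val <- pmax(val, 0)
  }
  val
}

#' Pool-size measurement
#'
#' @param metabolite Metabolite identifier.
#' @param fraction One of `"mito_fraction"`, `"cyto_fraction"`, `"whole_cell"`.
#' @param value Relative pool size (fraction of the whole-cell pool) or an
#'   absolute amount in mM, per `units`.
#' @param sd Standard deviation, same units as `value`.
#' @param n_replicates Number of replicates behind the estimate.
#' @param units `"relative"` or `"mM"`.
#' @param selection Optional note on how the value was selected (e.g. the
#'   dilution chosen by [combine_dilutions()]).
#' @export
pool_measurement <- function(metabolite, fraction, value, sd = 0,
                             n_replicates = 1L, units = "relative",
                             selection = NA_character_) {
  fraction <- match.arg(fraction, c("mito_fraction", "cyto_fraction", "whole_cell"))
  stopifnot(value >= 0, sd >= 0, n_replicates >= 1)
  structure(
    list(metabolite = metabolite, fraction = fraction, value = value, sd = sd,
         n_replicates = as.integer(n_replicates), units = units,
         selection = selection),
    class = "pool_measurement"
  )
}

#' Combine pool-size estimates across internal-standard dilutions
#'
#' Each dilution yields its own isotope-ratio pair; the estimate is taken from
#' the pair whose `R2` lies closest to 1, where the labeled and unlabeled
#' signals are best matched and the ratio measurement has the best dynamic
#' range. The spread (sd) across all pairs' estimates is reported alongside.
#'
#' @param pairs List of [isotope_ratio_pair] objects (at least one).
#' @param metabolite,fraction Passed through to the returned measurement.
#' @return A [pool_measurement]; its `selection` field records the dilution
#'   used.
#' @export
combine_dilutions <- function(pairs, metabolite = "metabolite",
                              fraction = "mito_fraction") {
  if (length(pairs) < 1L) stop("combine_dilutions needs at least one pair")
  stopifnot(all(vapply(pairs, inherits, logical(1), "isotope_ratio_pair")))
  est <- vapply(pairs, isotope_ratio_pool_fraction, numeric(1))
  r2 <- vapply(pairs, `[[`, numeric(1), "R2")
  best <- which.min(abs(r2 - 1))
  spread <- if (length(est) > 1L) stats::sd(est) else 0
  pool_measurement(metabolite, fraction, value = est[best], sd = spread,
                   n_replicates = length(pairs),
                   selection = pairs[[best]]$dilution)
}
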