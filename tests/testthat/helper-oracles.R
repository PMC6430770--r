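# Independent oracles used across the suite. These deliberately avoid the
# package's solution paths: brute-force time stepping, direct linear solves,
# and forward convolutions.

# Explicit-Euler integration of the four tracked-isotopomer ODEs.
euler_sim <- function(v, cfg, f, te, dt = 0.001) {
  w <- unclass(v) / 60
  uM <- cfg$u_cit_mito; uC <- cfg$u_cit_cyto
  dM <- unname(w["v_CS"] + w["v_IDH2_R"] + w["v_IDH3_R"] + w["v_CIT_B"])
  dC <- unname(w["v_CIT_F"] + w["v_IDH1_R"])
  cs <- unname(w["v_CS"]); cb <- unname(w["v_CIT_B"])
  cf <- unname(w["v_CIT_F"]); i1r <- unname(w["v_IDH1_R"])
  i23r <- unname(w["v_IDH2_R"] + w["v_IDH3_R"])
  n <- round(max(te) / dt)
  tgrid <- (0:n) * dt
  mal <- f$mal_mito$fun(tgrid)
  akm <- f$akg5_mito$fun(tgrid)
  akc <- f$akg5_cyto$fun(tgrid)
  y <- c(0, 0, 0, 0)  # mito_low, cyto_low, mito_m5, cyto_m5
  out <- matrix(NA_real_, length(te), 4)
  ie <- round(te / dt) + 1L
  hit <- match(1L, ie)
  if (!is.na(hit)) out[hit, ] <- y
  for (s in 1:n) {
    dy1 <- (cs * mal[s] + cb * y[2] - dM * y[1]) / uM
    dy2 <- (cf * y[1] - dC * y[2]) / uC
    dy3 <- (i23r * akm[s] + cb * y[4] - dM * y[3]) / uM
    dy4 <- (cf * y[3] + i1r * akc[s] - dC * y[4]) / uC
    y <- y + dt * c(dy1, dy2, dy3, dy4)
    hits <- which(ie == s + 1L)
    for (h in hits) out[h, ] <- y
  }
  colnames(out) <- c("mito_low", "cyto_low", "mito_m5", "cyto_m5")
  out
}

# Direct 2x2 linear solve of the contamination mixing model, then
# re-attribution of each compartment's contaminating share.
solve_deconv <- function(p_mito, p_cyto, alpha, beta) {
  M <- matrix(c(alpha, 1, 1, beta), 2, 2)  # rows: P_m, P_c; cols: X_c, X_m
  x <- solve(M, c(p_mito, p_cyto))
  c(p_mito = x[2] * (1 + beta), p_cyto = x[1] * (1 + alpha))
}

# Random feasible flux vector (mass balances satisfied, all nonnegative).
random_flux <- function() {
  repeat {
    v <- c(v_CS = runif(1, 0.1, 1), v_CIT_F = runif(1, 0.05, 0.5),
           v_CIT_B = runif(1, 0.01, 0.3),
           v_IDH1_R = runif(1, 0, 0.2), v_IDH1_O = runif(1, 0, 0.1),
           v_IDH2_R = runif(1, 0, 0.3), v_IDH2_O = runif(1, 0, 0.5),
           v_IDH3_R = runif(1, 0, 0.2), v_IDH3_O = NA, v_AcCoA = NA)
    v["v_IDH3_O"] <- v["v_CS"] + v["v_CIT_B"] + v["v_IDH2_R"] +
      v["v_IDH3_R"] - v["v_CIT_F"] - v["v_IDH2_O"]
    v["v_AcCoA"] <- v["v_CIT_F"] + v["v_IDH1_R"] - v["v_CIT_B"] -
      v["v_IDH1_O"]
    if (all(v >= 0)) return(flux_vector(v))
  }
}

# Small default model configuration for simulation tests.
test_model_config <- function(...) {
  model_config(u_cit_mito = 0.35, u_cit_cyto = 0.9, ...)
}

test_forcings <- function() {
  forcing_set(akg5_mito = forcing_exponential(0.8, 0.2),
              akg5_cyto = forcing_exponential(0.7, 0.12),
              mal_mito = forcing_exponential(0.5, 0.1))
}
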