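# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive - brute-force grids, closed-form textbook formulas,
# exhaustive enumeration - and share no code path with the package
# implementation they check.

# Brute-force (E, z0) fit of the sphere Hertz model on a baseline-corrected
# curve: scans a z0 grid, profiles the prefactor by naive least squares over
# the deep indentation window and returns the grid minimiser.
oracle_hertz_grid <- function(curve, z0_grid, q = 0.4, nu = 0.5) {
  R_m <- curve$probe$radius * 1e-6
  best <- NULL
  for (z0 in z0_grid) {
    delta <- (z0 - curve$z) - curve$deflection
    delta[delta < 0] <- 0
    dmax <- max(delta)
    sel <- delta > 0 & delta >= (1 - q) * dmax
    if (sum(sel) < 8) next
    x <- delta[sel]^1.5
    C <- sum(curve$force[sel] * x) / sum(x * x)
    sse <- sum((curve$force[sel] - C * x)^2)
    if (is.null(best) || sse < best$sse) best <- list(z0 = z0, C = C, sse = sse)
  }
  # E in Pa from the prefactor in pN/nm^1.5
  C_si <- best$C * 1e-12 / (1e-9)^1.5
  list(E = 0.75 * (1 - nu^2) * C_si / sqrt(R_m), z0 = best$z0)
}

# Closed-form weighted linear regression of y on x (textbook normal
# equations with weighted means), for checking the brush log-linear
# initialiser.
oracle_wls <- function(x, y, w) {
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}

# Exhaustive hypergeometric upper tail: enumerate every possible draw of
# size b from a universe of size u, of which the first a elements are
# "set A", and count draws sharing at least k elements with A.
oracle_hyper_enum <- function(u, a, b, k) {
  draws <- utils::combn(u, b)
  hits <- colSums(draws <= a)
  mean(hits >= k)
}

# Quick builders -------------------------------------------------------

clean_curve <- function(seed = 1, ...) {
  over <- list(...)
  cc <- utils::modifyList(list(noise_sd = 0, baseline_offset = 0,
                               baseline_slope = 0), over)
  simulate_curve(sim_config(seed = seed, curve = cc))
}

toy_gene_table <- function() {
  data.frame(
    gene_id = paste0("g", 1:5),
    log2fc = c(log2(2.0), log2(1.6), log2(1.4), log2(3.0), -log2(2.5)),
    padj = c(0.05, 0.10, 0.01, 0.50, 0.20),
    stringsAsFactors = FALSE)
}
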