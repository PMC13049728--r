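#' Simulation configuration with planted ground truth
#'
#' Bundles the parameters of every synthetic generator. Defaults emulate the
#' acquisition conditions of a colloidal-probe glycocalyx experiment on
#' endothelial cells: sphere radius 1.25 um, spring constant 0.02 N/m,
#' 500 pN force setpoint, 36.2 C, 7 x 7 force-map grids at 1.5 um step,
#' hourly scratch imaging. Any field can be overridden per call; with `seed`
#' set, every generator is byte-reproducible.
#'
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param curve,map,image,scratch,genes Named lists overriding the default
#'   parameter blocks (see the package vignette for the full field list).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = NULL, curve = list(), map = list(),
                       image = list(), scratch = list(), genes = list()) {
  defaults <- list(
    curve = list(E = 2000, nu = 0.5, L = 300, N = 1e14, z0 = 500,
                 noise_sd = 3, baseline_offset = 5, baseline_slope = 0.005,
                 n_points = 512, z_range = 2000, F_max = 500,
                 probe = "sphere", radius = 1.25, theta = 17.5,
                 k = 0.02, T = 309.35, brush = TRUE, rigid = FALSE,
                 substrate_depth = NULL, substrate_E = 2e6,
                 delta_max = NULL),
    map = list(grid = c(7L, 7L), step = 1.5,
               E_central = 2000, E_periphery = 2000,
               L_central = 300, L_periphery = 300, N = 1e14,
               cyto_factor = NULL, probe = "sphere",
               noise_sd = 3, n_points = 256, z_range = 800,
               delta_max = 220, cell_axes = c(0.45, 0.40)),
    image = list(n_cells = 3, dim = c(96L, 96L), background = 10,
                 totals = c(50000, 80000, 120000), cell_radius = 10,
                 noise_sd = 0, gain = 1),
    scratch = list(dim = c(100L, 200L), gap_width = 100L,
                   rate_pct_per_h = 10, times = 0:9),
    genes = list(n_genes = 4000, frac_deg = 0.2, effect_z = c(3, 6),
                 se_log2fc = 0.25, contrast_cor = 0.8,
                 target_size = 1200, target_enrichment = 1,
                 n_proteins = 200, n_changed = 20, protein_shift = log2(1.5),
                 protein_sd = 0.19, n_rep = 3))
  cfg <- list(seed = seed,
              curve = utils::modifyList(defaults$curve, curve),
              map = utils::modifyList(defaults$map, map),
              image = utils::modifyList(defaults$image, image),
              scratch = utils::modifyList(defaults$scratch, scratch),
              genes = utils::modifyList(defaults$genes, genes))
  structure(cfg, class = "sim_config")
}

maybe_seed <- function(cfg) if (!is.null(cfg$seed)) set.seed(cfg$seed)

# total tip-sample force (pN) as a function of the gap g (nm, negative =
# indentation), for a given curve parameter block
sim_force_of_gap <- function(g, cc) {
  h <- pmax(g, 0)
  delta <- pmax(-g, 0)
  E_eff <- if (isTRUE(cc$rigid)) 1e6 else cc$E
  f <- if (cc$probe == "sphere") {
    hertz_sphere_force(E_eff, cc$nu, cc$radius, delta)
  } else {
    sneddon_pyramid_force(E_eff, cc$nu, cc$theta, delta)
  }
  if (!is.null(cc$substrate_depth)) {
    over <- pmax(delta - cc$substrate_depth, 0)
    f <- f + if (cc$probe == "sphere")
      hertz_sphere_force(cc$substrate_E, cc$nu, cc$radius, over)
    else sneddon_pyramid_force(cc$substrate_E, cc$nu, cc$theta, over)
  }
  if (isTRUE(cc$brush))
    f <- f + brush_force(cc$L, cc$N, cc$radius, cc$T, h)
  f
}

#' Simulate one force-distance approach curve
#'
#' Generates a calibrated approach curve under the additive two-component
#' model: brush force at the tip-sample gap plus Hertz/Sneddon contact force
#' at the indentation, with an affine baseline artifact and i.i.d. Gaussian
#' force noise. The curve is sampled uniformly in the tip-sample gap and the
#' piezo height recovered through the exact force balance
#' z = z0 + g - F(g)/k, so the planted indentation and separation
#' bookkeeping is exact; the ramp is truncated where the noise-free force
#' reaches the `F_max` setpoint (500 pN by default), as an instrument would
#' stop the approach.
#'
#' @param cfg A [sim_config()]; fields under `cfg$curve` apply.
#' @return A list with `curve` (a [force_curve()]) and `truth`
#'   (E, nu, L, N, z0, and the per-sample noise-free `gap`).
#' @export
simulate_curve <- function(cfg = sim_config()) {
  maybe_seed(cfg)
  simulate_curve_raw(cfg$curve)
}

simulate_curve_raw <- function(cc, position = NULL) {
  stopifnot(cc$n_points >= 16L, cc$z_range > 0)
  f_at_contact <- sim_force_of_gap(0, cc)
  if (f_at_contact >= cc$F_max) {
    delta_max <- 0
  } else {
    delta_max <- stats::uniroot(function(d) sim_force_of_gap(-d, cc) - cc$F_max,
                                c(0, 5000), extendInt = "upX",
                                tol = 1e-10)$root
  }
  # an indentation-controlled ramp (constant indentation range maintained
  # across the map) stops at delta_max even below the force setpoint
  if (!is.null(cc$delta_max)) delta_max <- min(delta_max, cc$delta_max)
  g <- seq(cc$z_range, -delta_max, length.out = cc$n_points)
  f_true <- sim_force_of_gap(g, cc)
  k <- cc$k * 1000 # pN/nm
  z <- cc$z0 + g - f_true / k
  f_obs <- f_true + cc$baseline_offset + cc$baseline_slope * z
  if (cc$noise_sd > 0) f_obs <- f_obs + rnorm(length(g), 0, cc$noise_sd)
  probe <- if (cc$probe == "sphere") probe_geometry("sphere", radius = cc$radius)
           else probe_geometry("pyramid", face_half_angle = cc$theta)
  curve <- force_curve(z, deflection = f_obs / k, segment = "approach",
                       position = position, temperature = cc$T, probe = probe,
                       calibration = cantilever_calibration(cc$k))
  list(curve = curve,
       truth = list(E = if (isTRUE(cc$rigid)) Inf else cc$E, nu = cc$nu,
                    L = if (isTRUE(cc$brush)) cc$L else NA_real_,
                    N = if (isTRUE(cc$brush)) cc$N else NA_real_,
                    z0 = cc$z0, gap = g, force_true = f_true))
}

#' Simulate a force map with a planted cell phantom
#'
#' Lays an elliptical cell mask over the grid, assigns distinct planted
#' (E, L) to the central region (the inner half of the cell area around the
#' centroid) versus the periphery, and simulates one approach curve per
#' in-cell pixel. In cytochalasin mode (`cyto_factor` set) all planted E
#' values are scaled by the factor, emulating actin depolymerisation.
#'
#' @param cfg A [sim_config()]; fields under `cfg$map` apply, and per-curve
#'   acquisition settings are inherited from `cfg$curve`.
#' @return A list with `curves` (row-major list of per-pixel curve/truth or
#'   `NULL` outside the cell), `header` ([map_header()]), `cell_mask`,
#'   `central_mask` (logical matrices) and `truth` (planted E/L matrices).
#' @export
simulate_map <- function(cfg = sim_config()) {
  maybe_seed(cfg)
  mc <- cfg$map
  nr <- mc$grid[1]; nc <- mc$grid[2]
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ell <- ((rows - ctr[1]) / (mc$cell_axes[2] * nr))^2 +
         ((cols - ctr[2]) / (mc$cell_axes[1] * nc))^2
  cell_mask <- ell <= 1
  central_mask <- central_region(cell_mask, area_fraction = 0.5)
  fac <- if (is.null(mc$cyto_factor)) 1 else mc$cyto_factor
  E_map <- matrix(NA_real_, nr, nc); L_map <- matrix(NA_real_, nr, nc)
  E_map[cell_mask] <- mc$E_periphery * fac
  E_map[central_mask] <- mc$E_central * fac
  L_map[cell_mask] <- mc$L_periphery
  L_map[central_mask] <- mc$L_central
  cc <- cfg$curve
  cc$probe <- mc$probe
  cc$noise_sd <- mc$noise_sd
  cc$n_points <- mc$n_points
  cc$z_range <- mc$z_range
  cc$N <- mc$N
  if (mc$probe == "pyramid") {
    cc$brush <- FALSE
    cc$delta_max <- mc$delta_max
  }
  curves <- vector("list", nr * nc)
  dim(curves) <- c(nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!cell_mask[i, j]) next
    cc$E <- E_map[i, j]
    if (isTRUE(cc$brush)) cc$L <- L_map[i, j]
    pos <- c((j - 1) * mc$step, (i - 1) * mc$step)
    curves[[i, j]] <- simulate_curve_raw(cc, position = pos)
  }
  list(curves = curves,
       header = map_header(grid_shape = c(nr, nc), step = mc$step),
       cell_mask = cell_mask, central_mask = central_mask,
       truth = list(E = E_map, L = L_map))
}

#' Simulate a fluorescence image with planted per-cell totals
#'
#' Draws `n_cells` disc-shaped cells with planted integrated signal over a
#' flat background, optionally with Gaussian noise, and builds the matching
#' ROI set (the cell discs as labelled ROIs, image corners as background
#' ROIs).
#'
#' @param cfg A [sim_config()]; fields under `cfg$image` apply.
#' @return A list with `rois` (a [roi_set()]) and `truth` (per-cell planted
#'   totals, in the same intensity units scaled by `gain`).
#' @export
simulate_fluor_image <- function(cfg = sim_config()) {
  maybe_seed(cfg)
  ic <- cfg$image
  nr <- ic$dim[1]; nc <- ic$dim[2]
  stopifnot(ic$n_cells <= length(ic$totals))
  img <- matrix(ic$background, nr, nc)
  labels <- matrix(0L, nr, nc)
  # cells spaced on a horizontal line
  cx <- round(seq(0.2, 0.8, length.out = ic$n_cells) * nc)
  cy <- rep(round(nr / 2), ic$n_cells)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  totals <- numeric(ic$n_cells)
  for (cidx in seq_len(ic$n_cells)) {
    disc <- (rows - cy[cidx])^2 + (cols - cx[cidx])^2 <= ic$cell_radius^2
    img[disc] <- img[disc] + ic$totals[cidx] / sum(disc)
    labels[disc] <- cidx
    totals[cidx] <- ic$totals[cidx]
  }
  if (ic$noise_sd > 0) img <- img + rnorm(length(img), 0, ic$noise_sd)
  img <- img * ic$gain
  m <- max(4L, ic$cell_radius %/% 2)
  corner <- function(ri, ci) {
    msk <- matrix(FALSE, nr, nc); msk[ri, ci] <- TRUE; msk
  }
  bg <- list(corner(1:m, 1:m), corner(1:m, (nc - m + 1):nc),
             corner((nr - m + 1):nr, 1:m))
  list(rois = roi_set(img, labels, bg), truth = list(totals = totals * ic$gain))
}

#' Simulate a scratch-assay closure series
#'
#' A vertical cell-free stripe closing symmetrically at a constant rate
#' (percent of the initial open area per hour), producing nested open-area
#' masks on the configured time grid.
#'
#' @param cfg A [sim_config()]; fields under `cfg$scratch` apply.
#' @return A list with `series` (a [scratch_series()]) and `truth`
#'   (`rate_pct_per_h`, initial area `A0`).
#' @export
simulate_scratch <- function(cfg = sim_config()) {
  maybe_seed(cfg)
  sc <- cfg$scratch
  nr <- sc$dim[1]; nc <- sc$dim[2]
  w0 <- sc$gap_width
  stopifnot(w0 >= 1, w0 <= nc)
  mid <- (nc + 1) / 2
  masks <- lapply(sc$times, function(t) {
    w <- w0 * max(0, 1 - sc$rate_pct_per_h * t / 100)
    msk <- matrix(FALSE, nr, nc)
    if (w > 0) {
      half <- w / 2
      cols <- which(abs(seq_len(nc) - mid) < half)
      msk[, cols] <- TRUE
    }
    msk
  })
  list(series = scratch_series(sc$times, masks),
       truth = list(rate_pct_per_h = sc$rate_pct_per_h, A0 = sum(masks[[1]])))
}

#' Simulate a gene table with planted differential expression
#'
#' Per gene, a latent z-score (0 for null genes, a planted effect for true
#' DEGs, correlated between the two contrasts) is observed with unit
#' Gaussian noise; the observed log2 fold change is `se_log2fc` times the
#' observed z, the two-sided normal p-value is taken from the same z, and
#' p-values are Benjamini-Hochberg adjusted - so effect sizes and
#' significance are internally consistent. A putative-target list is drawn
#' with configurable enrichment odds toward the true DEGs
#' (`target_enrichment = 1` gives a null, independent list). Protein-mode
#' fields additionally provide replicate log2 intensity matrices for
#' [protein_ttest()].
#'
#' @param cfg A [sim_config()]; fields under `cfg$genes` apply.
#' @return A list with `table` (data.frame: `gene_id`, `log2fc_mac`,
#'   `padj_mac`, `log2fc_bac`, `padj_bac`, `measure`), `universe`,
#'   `targets` (character vector), `proteins` (list of two intensity
#'   matrices plus ids) and `truth` (planted DEG and changed-protein ids).
#' @export
simulate_gene_table <- function(cfg = sim_config()) {
  maybe_seed(cfg)
  gc <- cfg$genes
  n <- gc$n_genes
  ids <- sprintf("G%05d", seq_len(n))
  is_deg <- runif(n) < gc$frac_deg
  sign_ <- sample(c(-1, 1), n, replace = TRUE)
  mu <- ifelse(is_deg, sign_ * runif(n, gc$effect_z[1], gc$effect_z[2]), 0)
  rho <- gc$contrast_cor
  mu_mac <- mu
  mu_bac <- rho * mu + ifelse(is_deg, sqrt(1 - rho^2) * rnorm(n), 0)
  z_mac <- mu_mac + rnorm(n)
  z_bac <- mu_bac + rnorm(n)
  p_mac <- 2 * stats::pnorm(-abs(z_mac))
  p_bac <- 2 * stats::pnorm(-abs(z_bac))
  tab <- data.frame(gene_id = ids,
                    log2fc_mac = gc$se_log2fc * z_mac,
                    padj_mac = p.adjust(p_mac, "BH"),
                    log2fc_bac = gc$se_log2fc * z_bac,
                    padj_bac = p.adjust(p_bac, "BH"),
                    measure = "rna", stringsAsFactors = FALSE)
  w <- ifelse(is_deg, gc$target_enrichment, 1)
  targets <- sample(ids, min(gc$target_size, n), prob = w)
  np <- gc$n_proteins
  pid <- sprintf("P%04d", seq_len(np))
  changed <- seq_len(gc$n_changed)
  shift <- ifelse(seq_len(np) %in% changed,
                  sample(c(-1, 1), np, replace = TRUE) * gc$protein_shift, 0)
  base <- rnorm(np, 25, 2)
  A <- matrix(rnorm(np * gc$n_rep, base, gc$protein_sd), np, gc$n_rep)
  B <- matrix(rnorm(np * gc$n_rep, base + shift, gc$protein_sd), np, gc$n_rep)
  list(table = tab, universe = ids, targets = targets,
       proteins = list(ids = pid, control = A, mutant = B),
       truth = list(deg = ids[is_deg], changed_proteins = pid[changed]))
}
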