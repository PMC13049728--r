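#' Hertz force for a spherical indenter
#'
#' Closed-form sphere-on-halfspace contact force
#' F = (4/3) E / (1 - nu^2) sqrt(R) delta^(3/2), returned in pN.
#'
#' @param E Apparent Young's modulus, Pa.
#' @param poisson Poisson ratio nu; 0.5 (incompressible) by default.
#' @param R Probe radius, um.
#' @param delta Indentation, nm; must be non-negative (vectorised).
#' @return Force, pN; zero at zero indentation, increasing and convex in
#'   `delta`, linear in `E`.
#' @examples
#' hertz_sphere_force(1000, 0.5, 1.25, 100)  # ~62.9 pN
#' @export
hertz_sphere_force <- function(E, poisson = 0.5, R = 1.25, delta) {
  if (any(delta < 0)) stop("indentation delta must be non-negative")
  if (R <= 0) stop("probe radius must be positive")
  (4 / 3) * E / (1 - poisson^2) * sqrt(R * .UM) * (delta * .NM)^1.5 / .PN
}

#' Sneddon force for a pyramidal indenter
#'
#' Four-sided-pyramid contact force
#' F = E / (1 - nu^2) (tan(theta) / sqrt(2)) delta^2 in pN, with `theta` the
#' face half-angle. The alternative conical front factor (2/pi) tan(theta)
#' is selectable for comparison with vendor software conventions.
#'
#' @param E Apparent Young's modulus, Pa.
#' @param poisson Poisson ratio.
#' @param theta Face half-angle, degrees, strictly between 0 and 90.
#' @param delta Indentation, nm (vectorised, non-negative).
#' @param front_factor `"pyramid"` (default) or `"cone"`.
#' @return Force, pN; quadratic in `delta`.
#' @examples
#' sneddon_pyramid_force(1000, 0.5, 20, 200)  # ~13.7 pN
#' @export
sneddon_pyramid_force <- function(E, poisson = 0.5, theta, delta,
                                  front_factor = c("pyramid", "cone")) {
  front_factor <- match.arg(front_factor)
  if (theta <= 0 || theta >= 90)
    stop("face half-angle theta must lie strictly between 0 and 90 degrees")
  if (any(delta < 0)) stop("indentation delta must be non-negative")
  tt <- tan(theta * pi / 180)
  ff <- if (front_factor == "pyramid") tt / sqrt(2) else (2 / pi) * tt
  E / (1 - poisson^2) * ff * (delta * .NM)^2 / .PN
}

# indentation shape function in nm units: delta^p with the geometry's power
hertz_power <- function(probe) if (probe$kind == "sphere") 1.5 else 2

# convert fitted prefactor C (pN per nm^p) to E (Pa) for the given geometry
prefactor_to_E <- function(C, probe, poisson, front_factor = "pyramid") {
  if (probe$kind == "sphere") {
    # C_SI = C * 1e-12 / (1e-9)^1.5 ; E = 0.75 (1-nu^2) C_SI / sqrt(R)
    0.75 * (1 - poisson^2) * (C * .PN / .NM^1.5) / sqrt(probe$radius * .UM)
  } else {
    tt <- tan(probe$face_half_angle * pi / 180)
    ff <- if (front_factor == "pyramid") tt / sqrt(2) else (2 / pi) * tt
    (1 - poisson^2) * (C * .PN / .NM^2) / ff
  }
}

#' Estimate the contact point of an approach curve
#'
#' Scans candidate contact points over the sampled piezo grid, fitting a
#' piecewise model: zero force on the non-contact side and a power-law rise
#' (exponent set by the probe geometry) past contact, with the indentation
#' corrected for cantilever deflection. The candidate minimising the total
#' squared residual is returned; the half-width of the near-optimal
#' candidate region serves as the uncertainty.
#'
#' When a long-range repulsive layer (a glycocalyx brush) is present, the
#' scan is biased toward the far side by up to roughly the brush decay
#' length; the `brush_suspected` flag marks curves whose force is well above
#' the noise floor far before the estimated contact.
#'
#' @param curve A baseline-corrected approach [force_curve()].
#' @param candidates Optional numeric vector of candidate `z0` values, nm;
#'   defaults to the sampled grid away from the curve edges.
#' @param force_cut Only samples with force at most
#'   `max(force_cut, 10 x noise RMS)` pN enter the scan, keeping the
#'   estimator in the soft contact-onset regime: deep-indentation features
#'   (a stiff-substrate upturn, the force setpoint) would otherwise
#'   dominate the squared residual and can themselves mimic a power-law
#'   onset. Default 100 pN, well below a typical 500 pN setpoint.
#' @return An object of class `contact_point`: list with `z0` (nm),
#'   `method`, `uncertainty` (nm), `noise_rms` (pN) and `brush_suspected`.
#' @export
estimate_contact_point <- function(curve, candidates = NULL, force_cut = 100) {
  require_baseline(curve)
  if (curve$segment != "approach") stop("contact estimation needs an approach segment")
  z <- curve$z; f <- curve$force; d <- curve$deflection
  rms <- attr(curve, "baseline_rms")
  if (is.null(rms)) rms <- sd(f[seq_len(max(8L, length(f) %/% 5))])
  if (max(f) < max(5 * rms, 1e-3))
    stop("no contact detected: maximal force below 5x baseline noise")
  p <- hertz_power(curve$probe)
  n <- length(z)
  if (is.null(candidates)) {
    lo <- max(9L, ceiling(0.02 * n))
    candidates <- z[seq(lo, n - 8L)]
  }
  keep <- f <= max(force_cut, 10 * rms)
  if (sum(keep) < 24L) keep <- rep(TRUE, n)
  zs <- z[keep]; fs <- f[keep]; ds <- d[keep]
  sse <- vapply(candidates, function(z0c) {
    delta <- pmax(0, (z0c - zs) - ds)
    x <- delta^p
    sxx <- sum(x * x)
    a <- if (sxx > 0) max(0, sum(fs * x) / sxx) else 0
    sum((fs - a * x)^2)
  }, numeric(1))
  i <- which.min(sse)
  thr <- min(sse) + 0.05 * (median(sse) - min(sse))
  near <- candidates[sse <= thr]
  unc <- (max(near) - min(near)) / 2
  # force well above noise just outside the estimated contact flags a
  # long-range (brush) component; the samples nearest to contact are the
  # informative ones (the curve is stored far-to-near)
  far <- which(z > candidates[i] + 5 * median(abs(diff(z))))
  nearest_far <- utils::tail(far, 64L)
  brush_suspected <- length(far) >= 8 &&
    median(f[nearest_far]) > 5 * max(rms, 1e-3)
  structure(list(z0 = candidates[i], method = "piecewise_fit",
                 uncertainty = unc, noise_rms = rms,
                 brush_suspected = brush_suspected),
            class = "contact_point")
}

#' @export
print.contact_point <- function(x, ...) {
  cat(sprintf("Contact point: z0 = %.2f nm (+/- %.2f nm, %s)%s\n",
              x$z0, x$uncertainty, x$method,
              if (isTRUE(x$brush_suspected)) "; long-range brush suspected" else ""))
  invisible(x)
}

#' Indentation window policy for Hertz fitting
#'
#' Two policies are supported. `"deep"` keeps the top fraction `q` of the
#' indentation range (delta >= (1 - q) max delta), the regime where a
#' compressed glycocalyx no longer perturbs the elastic response. `"cap"`
#' keeps 0 < delta <= `cap_nm`, the constant-indentation-range policy used
#' for pyramidal mapping to avoid stiff-substrate contributions (cap
#' 200 nm, about 10% of the cell height).
#'
#' @param type `"deep"` or `"cap"`.
#' @param q Deep-window fraction in (0, 1); default 0.4.
#' @param cap_nm Indentation cap, nm; default 200.
#' @return A window-policy list consumed by [fit_hertz()].
#' @export
hertz_window <- function(type = c("deep", "cap"), q = 0.4, cap_nm = 200) {
  type <- match.arg(type)
  if (type == "deep" && !(q > 0 && q < 1)) stop("q must lie in (0,1)")
  if (type == "cap" && cap_nm <= 0) stop("cap_nm must be positive")
  list(type = type, q = q, cap_nm = cap_nm)
}

window_select <- function(delta, window) {
  pos <- delta > 0
  if (window$type == "deep") {
    dmax <- if (any(pos)) max(delta[pos]) else 0
    pos & delta >= (1 - window$q) * dmax
  } else {
    pos & delta <= window$cap_nm
  }
}

# linear LS of f on [delta^p (, 1)]; returns list(C, F0, sse, fitted)
hertz_ls <- function(f, delta, p, offset) {
  x <- delta^p
  X <- if (offset) cbind(x, 1) else cbind(x)
  fit <- lm.fit(X, f)
  cf <- fit$coefficients
  list(C = unname(cf[1]), F0 = if (offset) unname(cf[2]) else 0,
       sse = sum(fit$residuals^2), fitted = f - fit$residuals)
}

#' Fit the Hertz/Sneddon model to an approach curve
#'
#' Least-squares fit of the contact force law over an indentation window,
#' with the prefactor (hence E) linear in the model and the contact point
#' optionally re-optimised within a bracket around its scan estimate --
#' contact-point error is the dominant bias on E, so refinement is on by
#' default. Poisson's ratio is fixed (0.5 unless overridden). With
#' `offset = TRUE` an additive force constant is co-fitted, which absorbs
#' the saturated brush force underneath deep indentation.
#'
#' @param curve A baseline-corrected approach [force_curve()].
#' @param geometry A [probe_geometry()]; defaults to the curve's probe.
#' @param window A [hertz_window()] policy. Default: deep fraction 0.4 for
#'   spheres, 200 nm cap for pyramids.
#' @param poisson Poisson ratio, fixed during the fit.
#' @param z0 Contact point, nm; estimated by [estimate_contact_point()]
#'   when `NULL`.
#' @param refine_z0 Re-optimise `z0` by 1-D minimisation within
#'   `z0_bracket` of the estimate. Default `TRUE`.
#' @param z0_bracket Half-width of the refinement bracket, nm; default
#'   `max(3 * uncertainty, 20 nm)`.
#' @param offset Co-fit an additive force offset (pN). Default `FALSE`.
#' @param front_factor Pyramid front-factor convention, see
#'   [sneddon_pyramid_force()].
#' @return An object of class `hertz_fit` with elements `E` (Pa), `poisson`,
#'   `z0` (nm), `F0` (pN), `prefactor` (pN/nm^p), `power`, `fit_window`
#'   (delta range, nm), `residual_rms` (pN), `n_points`, `converged`,
#'   `geometry` and the windowed data for the method functions.
#' @examples
#' sim <- simulate_curve(sim_config(seed = 1, curve = list(noise_sd = 0,
#'   brush = FALSE)))
#' fit <- fit_hertz(correct_baseline(sim$curve))
#' coef(fit)["E"]
#' @export
fit_hertz <- function(curve, geometry = curve$probe, window = NULL,
                      poisson = 0.5, z0 = NULL, refine_z0 = TRUE,
                      z0_bracket = NULL, offset = FALSE,
                      front_factor = c("pyramid", "cone")) {
  require_baseline(curve)
  front_factor <- match.arg(front_factor)
  if (is.null(window))
    window <- if (geometry$kind == "sphere") hertz_window("deep")
              else hertz_window("cap")
  p <- hertz_power(geometry)
  z <- curve$z; f <- curve$force; d <- curve$deflection
  if (is.null(z0)) {
    cp <- estimate_contact_point(curve)
    z0 <- cp$z0
    if (is.null(z0_bracket)) z0_bracket <- max(3 * cp$uncertainty, 20)
  }
  if (is.null(z0_bracket)) z0_bracket <- 20
  big <- sum(f^2) + 1 # finite sentinel for infeasible windows
  # deep-policy refinement objective; the non-contact side stays out of it
  # because a glycocalyx brush legitimately loads that side
  obj <- function(z0c) {
    delta <- pmax(0, (z0c - z) - d)
    sel <- window_select(delta, window)
    if (sum(sel) < 8L) return(big)
    hertz_ls(f[sel], delta[sel], p, offset)$sse
  }
  if (window$type == "cap") {
    # The windowed objective is not comparable across candidate contact
    # points: shifting z0 moves samples across the cap boundary, so
    # candidates that push signal out of the window always look better.
    # The point set is therefore frozen at the scan estimate - everything
    # at apparent indentation <= cap, including the non-contact side,
    # which a sharp mapping tip should read as zero force - and z0 is
    # refined by the piecewise zero/power-law fit on that fixed set.
    # Points beyond the cap (potentially substrate-contaminated) never
    # enter.
    delta0 <- pmax(0, (z0 - z) - d)
    fixed <- delta0 <= window$cap_nm
    zf <- z[fixed]; ff <- f[fixed]; df_ <- d[fixed]
    obj <- function(z0c) {
      dl <- pmax(0, (z0c - zf) - df_)
      pos <- dl > 0
      if (sum(pos) < 8L) return(big)
      x <- dl[pos]^p
      a <- max(0, sum(ff[pos] * x) / sum(x * x))
      sum((ff[pos] - a * x)^2) + sum(ff[!pos]^2)
    }
  }
  converged <- TRUE
  if (refine_z0) {
    # coarse grid then local polish: the objective can be multimodal
    # (e.g. a stiff-substrate upturn), so a bare golden-section search
    # over the whole bracket is not safe
    lo <- max(min(z), z0 - z0_bracket); hi <- min(max(z), z0 + z0_bracket)
    grid <- seq(lo, hi, length.out = 81L)
    vals <- vapply(grid, obj, numeric(1))
    if (all(vals >= big)) {
      converged <- FALSE
    } else {
      j <- which.min(vals)
      op <- optimize(obj, c(grid[max(1L, j - 1L)], grid[min(81L, j + 1L)]),
                     tol = 1e-4)
      z0 <- if (op$objective <= vals[j]) op$minimum else grid[j]
    }
  }
  delta <- pmax(0, (z0 - z) - d)
  sel <- window_select(delta, window)
  if (sum(sel) < 8L)
    stop("fewer than 8 points in the indentation window; cannot fit")
  ls <- hertz_ls(f[sel], delta[sel], p, offset)
  if (!is.finite(ls$C) || ls$C <= 0) converged <- FALSE
  E <- prefactor_to_E(max(ls$C, .Machine$double.eps), geometry, poisson,
                      front_factor)
  structure(list(E = E, poisson = poisson, z0 = z0, F0 = ls$F0,
                 prefactor = ls$C, power = p,
                 fit_window = range(delta[sel]),
                 residual_rms = sqrt(ls$sse / sum(sel)),
                 n_points = sum(sel), converged = converged,
                 geometry = geometry, front_factor = front_factor,
                 offset = offset,
                 data = list(z = z[sel], force = f[sel], delta = delta[sel])),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("Hertz-%s fit: E = %.4g Pa (nu = %.2f, z0 = %.2f nm)\n",
              if (x$geometry$kind == "sphere") "sphere" else "Sneddon pyramid",
              x$E, x$poisson, x$z0))
  cat(sprintf("  window delta = [%.1f, %.1f] nm, %d points, residual RMS %.3g pN%s\n",
              x$fit_window[1], x$fit_window[2], x$n_points, x$residual_rms,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.hertz_fit <- function(object, ...) {
  c(E = object$E, z0 = object$z0, F0 = object$F0)
}

#' Predicted contact force of a Hertz fit
#'
#' @param object A `hertz_fit`.
#' @param delta Indentations, nm; defaults to the fitted window points.
#' @param ... Unused.
#' @return Predicted force, pN (excluding the fitted offset unless the fit
#'   used one).
#' @export
predict.hertz_fit <- function(object, delta = object$data$delta, ...) {
  object$prefactor * delta^object$power + object$F0
}

#' @export
residuals.hertz_fit <- function(object, ...) {
  object$data$force - predict(object)
}
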