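#' Fit every pixel of a force map
#'
#' Runs the per-curve analysis over a grid of approach curves: the full
#' two-regime decomposition for spherical probes (E and L per pixel) or the
#' capped Sneddon fit for pyramidal mapping probes (E only). Failed pixels
#' are kept with their flags rather than dropped, so aggregation can skip
#' them explicitly.
#'
#' @param curves A row x col list-matrix of curves (entries may be
#'   [force_curve()] objects, `list(curve = ...)` as returned by
#'   [simulate_map()], or `NULL` for off-cell pixels).
#' @param header A [map_header()]; defaults to the curve grid shape.
#' @param cell_mask,central_mask Logical matrices matching the grid;
#'   `central_mask` defaults to the inner 50%-area region of `cell_mask`
#'   (see [central_region()]), and `cell_mask` to all non-`NULL` pixels.
#' @param mode `"decompose"` (sphere, E + L) or `"hertz"` (pyramid cap
#'   window, E only).
#' @param config A [decompose_config()] (decompose mode).
#' @param window A [hertz_window()] (hertz mode); default 200 nm cap.
#' @return An object of class `force_map`: list with `header`, `pixels`
#'   (list-matrix of fits or `NULL`), `cell_mask`, `central_mask`.
#' @export
fit_map <- function(curves, header = NULL, cell_mask = NULL,
                    central_mask = NULL, mode = c("decompose", "hertz"),
                    config = decompose_config(), window = hertz_window("cap")) {
  mode <- match.arg(mode)
  stopifnot(is.list(curves), length(dim(curves)) == 2L)
  nr <- nrow(curves); nc <- ncol(curves)
  if (is.null(header)) header <- map_header(grid_shape = c(nr, nc))
  if (is.null(cell_mask))
    cell_mask <- matrix(!vapply(curves, is.null, logical(1)), nr, nc)
  if (is.null(central_mask)) central_mask <- central_region(cell_mask, 0.5)
  stopifnot(identical(dim(cell_mask), c(nr, nc)),
            identical(dim(central_mask), c(nr, nc)))
  if (any(central_mask & !cell_mask))
    stop("central_mask must be a subset of cell_mask")
  pixels <- vector("list", nr * nc)
  dim(pixels) <- c(nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    entry <- curves[[i, j]]
    if (is.null(entry) || !cell_mask[i, j]) next
    curve <- if (inherits(entry, "force_curve")) entry else entry$curve
    pixels[[i, j]] <- if (mode == "decompose") {
      decompose_curve(curve, config = config)
    } else {
      tryCatch({
        cc <- correct_baseline(curve, config$baseline_fraction)
        fit_hertz(cc, window = window, poisson = config$poisson)
      }, error = function(e) structure(list(error = conditionMessage(e)),
                                       class = "failed_fit"))
    }
  }
  structure(list(header = header, pixels = pixels, cell_mask = cell_mask,
                 central_mask = central_mask, mode = mode),
            class = "force_map")
}

#' @export
print.force_map <- function(x, ...) {
  print(x$header)
  cat(sprintf("  %d in-cell pixels (%d central), mode = %s\n",
              sum(x$cell_mask), sum(x$central_mask), x$mode))
  invisible(x)
}

#' Central region of a cell mask
#'
#' A reproducible, parameter-light proxy for the perinuclear region: the
#' in-mask pixels closest to the mask centroid, covering the given fraction
#' of the mask area (ties broken by row-major order, so the result is
#' deterministic).
#'
#' @param cell_mask Logical matrix.
#' @param area_fraction Fraction of the mask area to keep, default 0.5.
#' @return Logical matrix, a subset of `cell_mask`.
#' @export
central_region <- function(cell_mask, area_fraction = 0.5) {
  stopifnot(is.matrix(cell_mask), area_fraction > 0, area_fraction <= 1)
  idx <- which(cell_mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(cell_mask), ncol(cell_mask))
  if (nrow(idx) == 0L) return(out)
  ctr <- colMeans(idx)
  d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
  keep <- order(d2, idx[, 1], idx[, 2])[seq_len(max(1L, round(area_fraction * nrow(idx))))]
  out[idx[keep, , drop = FALSE]] <- TRUE
  out
}

# per-pixel (E, L, valid) extraction shared by the summaries
pixel_values <- function(map) {
  vals <- lapply(map$pixels, function(px) {
    if (is.null(px)) return(c(NA, NA, FALSE))
    if (inherits(px, "failed_fit")) return(c(NA, NA, FALSE))
    if (inherits(px, "curve_decomposition")) {
      bad <- any(c("no_contact", "hertz_nonconverged") %in% px$quality_flags)
      E <- if (is.null(px$hertz)) NA_real_ else px$hertz$E
      L <- if (px$brush_detected && !is.na(px$brush$L)) px$brush$L else NA_real_
      return(c(E, L, !bad && is.finite(E)))
    }
    if (inherits(px, "hertz_fit"))
      return(c(px$E, NA_real_, px$converged && is.finite(px$E)))
    c(NA, NA, FALSE)
  })
  E <- matrix(vapply(vals, `[`, numeric(1), 1L), nrow(map$pixels), ncol(map$pixels))
  L <- matrix(vapply(vals, `[`, numeric(1), 2L), nrow(map$pixels), ncol(map$pixels))
  valid <- matrix(as.logical(vapply(vals, `[`, numeric(1), 3L)),
                  nrow(map$pixels), ncol(map$pixels))
  list(E = E, L = L, valid = valid)
}

#' Summarise a force map per cell and region
#'
#' Aggregates valid pixel fits (median by default, robust to occasional fit
#' failures) separately over the whole cell mask and its central region.
#' A region with fewer than `min_valid` valid pixels is reported absent
#' (`NA`) with the reason recorded. Invariant under pixel traversal order.
#'
#' @param map A [fit_map()] result.
#' @param aggregation `"median"` or `"mean"`.
#' @param cell_id Identifier carried into the summary.
#' @param min_valid Minimum valid pixels per reported region, default 4.
#' @return An object of class `cell_summary`: `E_whole`, `E_central`,
#'   `L_whole`, `L_central` (Pa / nm), `n_valid`, `n_valid_central`,
#'   `aggregation`, `reasons`.
#' @export
summarize_cell <- function(map, aggregation = c("median", "mean"),
                           cell_id = NA_character_, min_valid = 4L) {
  stopifnot(inherits(map, "force_map"))
  aggregation <- match.arg(aggregation)
  agg <- if (aggregation == "median") function(x) median(x) else function(x) mean(x)
  px <- pixel_values(map)
  reasons <- character()
  region_value <- function(values, mask, what, region) {
    v <- values[mask & px$valid & is.finite(values)]
    if (sum(mask) == 0L) {
      reasons <<- c(reasons, sprintf("%s_%s: empty mask", what, region))
      return(NA_real_)
    }
    if (length(v) < min_valid) {
      reasons <<- c(reasons, sprintf("%s_%s: only %d valid pixels", what,
                                     region, length(v)))
      return(NA_real_)
    }
    agg(v)
  }
  out <- list(cell_id = cell_id,
              E_whole = region_value(px$E, map$cell_mask, "E", "whole"),
              E_central = region_value(px$E, map$central_mask, "E", "central"),
              L_whole = region_value(px$L, map$cell_mask, "L", "whole"),
              L_central = region_value(px$L, map$central_mask, "L", "central"),
              n_valid = sum(px$valid & map$cell_mask),
              n_valid_central = sum(px$valid & map$central_mask),
              aggregation = aggregation, reasons = reasons)
  structure(out, class = "cell_summary")
}

#' @export
print.cell_summary <- function(x, ...) {
  cat(sprintf("Cell summary (%s over %d valid pixels):\n", x$aggregation,
              x$n_valid))
  cat(sprintf("  E: whole %.4g Pa, central %.4g Pa\n", x$E_whole, x$E_central))
  cat(sprintf("  L: whole %.4g nm, central %.4g nm\n", x$L_whole, x$L_central))
  if (length(x$reasons)) cat("  absent:", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Percent reduction between paired summaries
#'
#' Intra-cell (or intra-line) relative drop of a summary field after a
#' treatment, e.g. the elastic modulus after cytochalasin D:
#' 100 (before - after) / before, positive when the value decreased.
#'
#' @param before,after Matched [summarize_cell()] results, or plain numbers.
#' @param field Summary field to compare, default `"E_whole"`.
#' @return Percentage reduction (scalar).
#' @examples
#' percent_reduction(10000, 4000)  # 60
#' @export
percent_reduction <- function(before, after, field = "E_whole") {
  b <- if (inherits(before, "cell_summary")) before[[field]] else before
  a <- if (inherits(after, "cell_summary")) after[[field]] else after
  if (is.null(b) || is.na(b) || is.null(a) || is.na(a))
    stop("both summaries must report '", field, "'")
  if (b <= 0) stop("'before' value must be positive")
  100 * (b - a) / b
}

#' Compare groups of per-cell summaries
#'
#' Reporting plumbing around the standard tests used for per-cell AFM
#' summaries: Kruskal-Wallis rank test across two or more groups, or the
#' unpaired two-sample t-test (exactly two groups).
#'
#' @param x Numeric values, or a list of [summarize_cell()] results (then
#'   `field` selects the value).
#' @param groups Group labels, same length as `x`.
#' @param test `"kruskal"` or `"t"`.
#' @param field Summary field when `x` is a list of summaries.
#' @return An object of class `group_comparison`: `statistic`, `p_value`,
#'   `medians`, `n`, `test`.
#' @export
compare_groups <- function(x, groups, test = c("kruskal", "t"),
                           field = "E_whole") {
  test <- match.arg(test)
  if (is.list(x) && length(x) && inherits(x[[1]], "cell_summary"))
    x <- vapply(x, function(s) s[[field]], numeric(1))
  groups <- factor(groups)
  stopifnot(length(x) == length(groups))
  ok <- is.finite(x)
  x <- x[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 3L)) stop("need at least 3 observations per group")
  if (test == "kruskal") {
    ht <- kruskal.test(x, groups)
  } else {
    if (nlevels(groups) != 2L) stop("t-test requires exactly 2 groups")
    ht <- t.test(x ~ groups)
  }
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 medians = tapply(x, groups, median),
                 n = as.vector(table(groups)), test = test, htest = ht),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.3g\n",
              if (x$test == "kruskal") "Kruskal-Wallis" else "Unpaired t",
              x$statistic, x$p_value))
  cat("  group medians:",
      paste(sprintf("%s = %.4g", names(x$medians), x$medians), collapse = ", "),
      "\n")
  invisible(x)
}
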