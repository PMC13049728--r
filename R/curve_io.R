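#' Read force curves from disk
#'
#' Curve files are plain tab-separated tables with `#`-prefixed `key: value`
#' header lines carrying the metadata (probe, spring constant, temperature,
#' segment, map position) and columns `z` (piezo height, nm) plus `d`
#' (deflection, nm) and/or `f` (force, pN). A force map is a directory of
#' such files together with a `manifest.txt` of `key: value` lines
#' (`rows`, `cols`, `step_um`, `origin_x_um`, `origin_y_um`, and one
#' `curve: <file>` line per map pixel).
#'
#' @param path A curve file or a map directory.
#' @return A list of [force_curve()] objects. For a map directory the list
#'   carries the parsed header as attribute `map_header`.
#' @seealso [write_curves()]
#' @export
read_curves <- function(path) {
  if (dir.exists(path)) {
    manifest <- file.path(path, "manifest.txt")
    if (!file.exists(manifest))
      stop("map directory has no manifest.txt: ", path)
    kv <- parse_kv_lines(readLines(manifest))
    files <- kv$values[kv$keys == "curve"]
    if (length(files) == 0L) stop("manifest lists no curves: ", manifest)
    header <- map_header(
      grid_shape = c(as.integer(kv1(kv, "rows")), as.integer(kv1(kv, "cols"))),
      step = as.numeric(kv1(kv, "step_um")),
      origin = c(as.numeric(kv1(kv, "origin_x_um")),
                 as.numeric(kv1(kv, "origin_y_um"))))
    curves <- lapply(file.path(path, files), read_curve_file)
    attr(curves, "map_header") <- header
    return(curves)
  }
  if (!file.exists(path)) stop("no such file: ", path)
  list(read_curve_file(path))
}

#' Write force curves to disk
#'
#' Inverse of [read_curves()]: writes each curve as a headered TSV. With a
#' `map_header` attribute (or argument) on the list, writes a map directory
#' with a manifest; otherwise `path` must name a single file and `curves`
#' have length one.
#'
#' @param curves A list of [force_curve()] objects.
#' @param path Output file (single curve) or directory (map).
#' @param map_header Optional [map_header()] forcing directory layout.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path, map_header = attr(curves, "map_header")) {
  if (inherits(curves, "force_curve")) curves <- list(curves)
  if (is.null(map_header)) {
    if (length(curves) != 1L)
      stop("writing several curves to one file requires a map_header; ",
           "use a directory layout")
    write_curve_file(curves[[1]], path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- sprintf("curve_%04d.tsv", seq_along(curves))
    for (i in seq_along(curves)) {
      write_curve_file(curves[[i]], file.path(path, files[i]))
    }
    hdr <- c(sprintf("rows: %d", map_header$grid_shape[1]),
             sprintf("cols: %d", map_header$grid_shape[2]),
             sprintf("step_um: %.10g", map_header$step),
             sprintf("origin_x_um: %.10g", map_header$origin[1]),
             sprintf("origin_y_um: %.10g", map_header$origin[2]),
             sprintf("curve: %s", files))
    writeLines(hdr, file.path(path, "manifest.txt"))
  }
  invisible(path)
}

#' Force-map grid header
#'
#' @param grid_shape `(rows, cols)`, both at least 1. Typical maps are
#'   7 x 7 or 16 x 16 points.
#' @param step Grid step, um (about 1.5 um, comparable to the probe
#'   diameter).
#' @param origin `(x, y)` of the grid origin, um.
#' @return An object of class `map_header`.
#' @export
map_header <- function(grid_shape = c(16L, 16L), step = 1.5, origin = c(0, 0)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L))
    stop("grid_shape must be two positive integers (rows, cols)")
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a positive grid spacing in um")
  structure(list(grid_shape = grid_shape, step = step,
                 origin = as.numeric(origin)),
            class = "map_header")
}

#' @export
print.map_header <- function(x, ...) {
  cat(sprintf("Force map grid: %d x %d points, step %.3g um, origin (%.3g, %.3g) um\n",
              x$grid_shape[1], x$grid_shape[2], x$step,
              x$origin[1], x$origin[2]))
  invisible(x)
}

parse_kv_lines <- function(lines) {
  lines <- sub("^#\\s*", "", trimws(lines))
  lines <- lines[nzchar(lines)]
  m <- regexpr(":", lines, fixed = TRUE)
  if (any(m < 0)) stop("malformed header line (expected 'key: value'): ",
                       lines[which(m < 0)[1]])
  list(keys = trimws(substr(lines, 1, m - 1)),
       values = trimws(substr(lines, m + 1, nchar(lines))))
}

kv1 <- function(kv, key) {
  v <- kv$values[kv$keys == key]
  if (length(v) != 1L) stop("header must define '", key, "' exactly once")
  v
}

read_curve_file <- function(file) {
  lines <- readLines(file)
  is_hdr <- startsWith(lines, "#")
  kv <- parse_kv_lines(lines[is_hdr])
  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("curve file has no data rows: ", file)
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t")
  if (!("z" %in% names(tab)))
    stop("curve file lacks a 'z' column: ", file)
  if (!any(c("d", "f") %in% names(tab)))
    stop("curve file needs a 'd' (deflection) or 'f' (force) column: ", file)
  probe_kind <- kv1(kv, "probe")
  probe <- if (probe_kind == "sphere") {
    probe_geometry("sphere", radius = as.numeric(kv1(kv, "radius_um")))
  } else {
    probe_geometry("pyramid",
                   face_half_angle = as.numeric(kv1(kv, "half_angle_deg")))
  }
  pos <- NULL
  if ("pos_x_um" %in% kv$keys)
    pos <- c(as.numeric(kv1(kv, "pos_x_um")), as.numeric(kv1(kv, "pos_y_um")))
  cal <- cantilever_calibration(as.numeric(kv1(kv, "k_N_per_m")))
  args <- list(piezo_height = tab$z, segment = kv1(kv, "segment"),
               position = pos, temperature = as.numeric(kv1(kv, "T_K")),
               probe = probe, calibration = cal)
  # prefer the raw deflection channel; force is re-derived via F = k d
  if ("d" %in% names(tab)) args$deflection <- tab$d else args$force <- tab$f
  curve <- tryCatch(do.call(force_curve, args),
                    error = function(e) stop("malformed curve in ", file, ": ",
                                             conditionMessage(e), call. = FALSE))
  if ("baseline_corrected" %in% kv$keys)
    curve$baseline_corrected <- identical(kv1(kv, "baseline_corrected"), "TRUE")
  curve
}

write_curve_file <- function(curve, file) {
  stopifnot(inherits(curve, "force_curve"))
  hdr <- c(sprintf("# probe: %s", curve$probe$kind),
           if (curve$probe$kind == "sphere")
             sprintf("# radius_um: %.10g", curve$probe$radius)
           else sprintf("# half_angle_deg: %.10g", curve$probe$face_half_angle),
           sprintf("# k_N_per_m: %.10g", curve$calibration$spring_constant),
           sprintf("# T_K: %.10g", curve$temperature),
           sprintf("# segment: %s", curve$segment),
           sprintf("# baseline_corrected: %s", isTRUE(curve$baseline_corrected)),
           if (!is.null(curve$position))
             c(sprintf("# pos_x_um: %.10g", curve$position[1]),
               sprintf("# pos_y_um: %.10g", curve$position[2])))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  tab <- data.frame(z = curve$z, d = curve$deflection)
  writeLines("z\td", con)
  writeLines(sprintf("%.12g\t%.12g", tab$z, tab$d), con)
  invisible(file)
}
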