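#' Fluorescence image with ROIs
#'
#' @param image Numeric intensity matrix (arbitrary units).
#' @param cell_rois Integer label matrix of the same shape; 0 = outside,
#'   positive labels identify cell ROIs.
#' @param background_rois List of logical matrices of the same shape;
#'   background masks must not overlap any cell ROI.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(image, cell_rois, background_rois) {
  stopifnot(is.matrix(image), is.matrix(cell_rois),
            identical(dim(image), dim(cell_rois)))
  if (!is.list(background_rois)) background_rois <- list(background_rois)
  for (bg in background_rois) {
    stopifnot(is.matrix(bg), identical(dim(bg), dim(image)))
    if (any(bg & cell_rois > 0))
      stop("background ROIs must be disjoint from cell ROIs")
  }
  structure(list(image = image, cell_rois = cell_rois,
                 background_rois = background_rois),
            class = "roi_set")
}

#' Corrected total cell fluorescence
#'
#' Per cell ROI, computes the integrated density (sum of pixel
#' intensities), the ROI area in pixels and the background-corrected total
#' CTCF = Integrated Density - Area x Mean background fluorescence.
#' The background mean is taken over all background ROIs pooled
#' (`background = "pooled"`, the default) or as the mean of per-ROI means
#' (`"per_roi"`). CTCF is exactly invariant under a uniform additive
#' intensity offset and scales linearly with multiplicative gain; it may
#' legitimately be negative for ROIs dimmer than the background.
#'
#' @param rois A [roi_set()].
#' @param background `"pooled"` or `"per_roi"`.
#' @return A data frame (class `ctcf_result`) with one row per cell ROI:
#'   `roi_id`, `integrated_density`, `area`, `background_mean`, `ctcf`.
#' @examples
#' img <- matrix(10, 20, 20); img[5:8, 5:8] <- 35
#' lab <- matrix(0L, 20, 20); lab[5:8, 5:8] <- 1L
#' bg <- matrix(FALSE, 20, 20); bg[15:18, 15:18] <- TRUE
#' ctcf(roi_set(img, lab, bg))  # ctcf = 16 * 25 = 400
#' @export
ctcf <- function(rois, background = c("pooled", "per_roi")) {
  stopifnot(inherits(rois, "roi_set"))
  background <- match.arg(background)
  labels <- sort(unique(rois$cell_rois[rois$cell_rois > 0]))
  if (length(labels) == 0L) stop("no cell ROI present")
  if (length(rois$background_rois) == 0L) stop("no background ROI present")
  bg_counts <- vapply(rois$background_rois, sum, numeric(1))
  if (any(bg_counts == 0))
    stop("empty background ROI: #", which(bg_counts == 0)[1])
  bg_means <- vapply(rois$background_rois,
                     function(m) mean(rois$image[m]), numeric(1))
  bg_mean <- if (background == "pooled") {
    sum(bg_means * bg_counts) / sum(bg_counts)
  } else mean(bg_means)
  rows <- lapply(labels, function(lab) {
    m <- rois$cell_rois == lab
    area <- sum(m)
    if (area == 0L) stop("empty cell ROI: ", lab)
    id <- sum(rois$image[m])
    data.frame(roi_id = lab, integrated_density = id, area = area,
               background_mean = bg_mean, ctcf = id - area * bg_mean)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ctcf_result", "data.frame")
  out
}

#' Segment the cell-free wound area of a scratch frame
#'
#' Texture-based wound detection: the cell lawn is locally rough while the
#' cell-free gap is flat, so the local intensity variance over a square
#' window separates the two. The variance image is thresholded with Otsu's
#' method, the low-texture mask is cleaned by morphological opening and
#' closing, and the largest connected low-texture component of sufficient
#' area is returned as the wound. Deterministic given the configuration and
#' invariant under a uniform intensity offset.
#'
#' @param image Single-channel numeric matrix (phase or fluorescence).
#' @param window Local-variance window side, px; default 15.
#' @param min_area Minimum wound area, px; default 0.5% of the frame.
#' @param brush_size Morphological structuring-element diameter, px.
#' @param contrast_min Minimum ratio of mean local variance between the
#'   textured and the low-texture class; below it the frame is considered
#'   uniformly textured (wound closed) and an empty mask is returned. An
#'   Otsu split always produces two classes, so this guard is what rejects
#'   frames with no real wound. Default 4.
#' @return Logical matrix marking the wound (cell-free) area; empty, with a
#'   warning, when no low-texture component reaches `min_area` or the
#'   texture contrast is below `contrast_min`.
#' @export
segment_wound <- function(image, window = 15, min_area = NULL,
                          brush_size = 5, contrast_min = 4) {
  stopifnot(is.matrix(image))
  if (is.null(min_area)) min_area <- ceiling(0.005 * length(image))
  box <- matrix(1 / window^2, window, window)
  m1 <- EBImage::filter2(image, box, boundary = "replicate")
  m2 <- EBImage::filter2(image^2, box, boundary = "replicate")
  v <- pmax(m2 - m1^2, 0)
  rng <- range(v)
  if (diff(rng) <= .Machine$double.eps * max(1, rng[2])) {
    # uniform texture everywhere: either all lawn or all wound; treat a
    # globally flat frame as all wound only if it is flat at pixel level
    if (stats::sd(image) == 0) return(matrix(TRUE, nrow(image), ncol(image)))
    warning("no low-texture component found; returning empty mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  vn <- (v - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(vn), range = c(0, 1))
  low <- vn < thr
  if (mean(v[!low]) < contrast_min * max(mean(v[low]), .Machine$double.eps)) {
    warning("texture contrast below contrast_min; no wound detected, ",
            "returning empty mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  kern <- EBImage::makeBrush(brush_size, shape = "disc")
  low <- EBImage::closing(EBImage::opening(low, kern), kern)
  lab <- EBImage::bwlabel(low)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0L || max(sizes) < min_area) {
    warning("no low-texture component of at least ", min_area,
            " px; returning empty mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  mask <- lab == which.max(sizes)
  matrix(as.logical(mask), nrow(image), ncol(image))
}

#' Scratch-assay time series
#'
#' @param times Acquisition times, hours; strictly increasing, starting
#'   at 0.
#' @param open_masks List of logical matrices (the cell-free area per
#'   frame), all of the same shape, one per time point.
#' @return An object of class `scratch_series`.
#' @export
scratch_series <- function(times, open_masks) {
  times <- as.numeric(times)
  stopifnot(length(times) == length(open_masks), length(times) >= 1L)
  if (times[1] != 0) stop("first time point must be 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  shp <- dim(open_masks[[1]])
  for (m in open_masks)
    stopifnot(is.matrix(m), is.logical(m), identical(dim(m), shp))
  structure(list(times = times, open_masks = open_masks),
            class = "scratch_series")
}

#' Gap closure over a scratch series
#'
#' closure(t) = 100 (A0 - A_t) / A0, with A the open (cell-free) area per
#' frame; closure at time zero is 0 by construction. A warning is issued
#' when the open masks are not nested (closure would not be monotone).
#'
#' @param series A [scratch_series()].
#' @return Data frame with `time_h`, `open_area_px`, `closure_pct`.
#' @examples
#' m0 <- matrix(TRUE, 100, 100); m1 <- m0; m1[, 51:100] <- FALSE
#' gap_closure(scratch_series(c(0, 9), list(m0, m1)))
#' @export
gap_closure <- function(series) {
  stopifnot(inherits(series, "scratch_series"))
  A <- vapply(series$open_masks, sum, numeric(1))
  if (A[1] == 0) stop("initial open area is zero; no gap to close")
  nested <- all(vapply(seq_along(A)[-1], function(i) {
    !any(series$open_masks[[i]] & !series$open_masks[[i - 1]])
  }, logical(1)))
  if (!nested)
    warning("open masks are not nested; closure is not guaranteed monotone")
  data.frame(time_h = series$times, open_area_px = A,
             closure_pct = 100 * (A[1] - A) / A[1])
}

#' Read a single- or multi-page TIFF as matrices
#'
#' @param path TIFF file.
#' @return A numeric matrix, or a list of matrices for multi-page files.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, all = TRUE)
  imgs <- lapply(img, function(x) if (length(dim(x)) == 3L) x[, , 1] else x)
  if (length(imgs) == 1L) imgs[[1]] else imgs
}

#' Write matrices to a (multi-page) TIFF
#'
#' Intensities are rescaled to [0, 1] jointly across pages, as required by
#' the TIFF writer; masks (logical) are written as 0/1.
#'
#' @param images A matrix or list of matrices.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  images <- lapply(images, function(m) {
    m <- m * 1.0
    m
  })
  hi <- max(vapply(images, max, numeric(1)), 1)
  lo <- min(vapply(images, min, numeric(1)), 0)
  images <- lapply(images, function(m) (m - lo) / (hi - lo))
  tiff::writeTIFF(images, path, bits.per.sample = 16L)
  invisible(path)
}
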