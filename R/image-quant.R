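#' Convert an image to single-channel 8-bit greyscale
#'
#' Multi-channel input is collapsed with ITU-R 601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B), rounded to the nearest integer and clipped
#' to \[0, 255\]; single-channel input passes through unchanged (after
#' rounding/clipping). Values are expected on the 0--255 scale.
#'
#' @param img Matrix (grey) or `h x w x 3` array (RGB), values 0--255.
#' @return Integer matrix, 0--255.
#' @examples
#' to_greyscale_8bit(array(c(100, 150, 200), c(1, 1, 3)))  # 141
#' @export
to_greyscale_8bit <- function(img) {
  if (is.matrix(img)) {
    g <- img
  } else if (is.array(img) && length(dim(img)) == 3) {
    ch <- dim(img)[3]
    if (ch == 1) {
      g <- img[, , 1, drop = FALSE]
    } else if (ch == 3) {
      g <- 0.299 * img[, , 1, drop = FALSE] +
        0.587 * img[, , 2, drop = FALSE] +
        0.114 * img[, , 3, drop = FALSE]
    } else {
      stop("unsupported channel count: ", ch, " (expected 1 or 3)",
           call. = FALSE)
    }
    g <- matrix(g, dim(img)[1], dim(img)[2])
  } else {
    stop("`img` must be a matrix or h x w x channels array", call. = FALSE)
  }
  matrix(as.integer(pmin(255, pmax(0, round(g)))), nrow(g))
}

# Integer offsets of the disk neighbourhood of given radius (ImageJ-style
# rank-filter kernel): all (dr, dc) with dr^2 + dc^2 <= radius^2. Always an
# odd count (symmetric pairs plus the centre).
disk_offsets <- function(radius) {
  d <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  d[d$dr^2 + d$dc^2 <= radius^2, ]
}

# Symmetric (reflect-with-border) padding of a matrix by r on each side.
pad_reflect <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(r:1, 1:h, h:(h - r + 1))
  ci <- c(r:1, 1:w, w:(w - r + 1))
  m[ri, ci, drop = FALSE]
}

#' Disk-neighbourhood median filter
#'
#' Replaces each pixel by the median over the disk of the given radius
#' centred on it (the neighbourhood shape ImageJ uses for its rank
#' filters). Image borders are handled by reflecting the image across the
#' edge, border pixel included. The disk always holds an odd number of
#' pixels, so the median is an exact order statistic and the output stays
#' 8-bit.
#'
#' The filter runs as a per-pixel binary search over the 256 grey levels on
#' stacked shifted copies of the image, so cost grows with
#' `log2(256) * |disk|` full-frame operations rather than with a per-pixel
#' sort.
#'
#' @param grey Integer matrix, 0--255.
#' @param radius Disk radius in pixels (integer >= 1; default 2, a
#'   13-pixel neighbourhood).
#' @return Filtered integer matrix of the same dimensions.
#' @export
median_smooth <- function(grey, radius = 2) {
  if (!is.matrix(grey)) stop("`grey` must be a matrix", call. = FALSE)
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1) {
    stop("`radius` must be an integer >= 1", call. = FALSE)
  }
  if (min(dim(grey)) <= radius) {
    stop("image smaller than filter radius", call. = FALSE)
  }
  off <- disk_offsets(radius)
  h <- nrow(grey); w <- ncol(grey)
  p <- pad_reflect(grey, radius)
  shifts <- lapply(seq_len(nrow(off)), function(i) {
    p[(1 + radius + off$dr[i]):(h + radius + off$dr[i]),
      (1 + radius + off$dc[i]):(w + radius + off$dc[i]), drop = FALSE]
  })
  k <- (nrow(off) + 1) / 2  # exact median rank (odd neighbourhood)
  lo <- matrix(0L, h, w); hi <- matrix(255L, h, w)
  while (any(lo < hi)) {
    mid <- (lo + hi) %/% 2L
    cnt <- Reduce(`+`, lapply(shifts, function(s) s <= mid))
    ge <- cnt >= k
    hi[ge] <- mid[ge]
    lo[!ge] <- mid[!ge] + 1L
  }
  matrix(as.integer(lo), h, w)
}

#' Otsu threshold over region-of-interest pixels
#'
#' Computes the 256-bin grey-level histogram of the ROI pixels only and
#' picks the threshold `t` maximising the between-class variance of the
#' split `< t` versus `>= t`. Ties (plateaus of equal variance, as in a
#' perfectly two-valued image) resolve to the plateau midpoint. Pixels
#' strictly below the returned threshold count as dark.
#'
#' @param grey Integer matrix, 0--255.
#' @param roi Logical matrix of identical dimensions (`NULL` = whole image).
#' @return Integer threshold in 1--255.
#' @export
otsu_threshold <- function(grey, roi = NULL) {
  v <- roi_values(grey, roi)
  if (length(unique(v)) < 2) {
    stop("degenerate histogram; no threshold (constant ROI intensity)",
         call. = FALSE)
  }
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                      # P(value <= t-1), index t = 1..256
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  t_cand <- 1:255
  w0 <- omega[t_cand]
  sigma_b <- (mu_t * w0 - mu[t_cand])^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  as.integer(round(mean(range(t_cand[best]))))
}

roi_values <- function(grey, roi) {
  if (is.null(roi)) return(as.integer(grey))
  if (!identical(dim(grey), dim(roi))) {
    stop("ROI mask dimensions do not match image", call. = FALSE)
  }
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  as.integer(grey[roi])
}

#' Mark dark pixels by thresholding
#'
#' Applies a fixed threshold, or — the deterministic stand-in for the
#' manual "adjust until the pixels cover the cells" step — the Otsu
#' threshold computed within the ROI. Pixels strictly below the threshold
#' are dark.
#'
#' @param grey Integer matrix, 0--255.
#' @param roi Logical ROI mask (`NULL` = whole image).
#' @param threshold Fixed integer threshold, or `NULL` for Otsu.
#' @return List with `mask` (logical matrix, dark pixels, full frame) and
#'   `threshold` (the value used).
#' @export
threshold_dark <- function(grey, roi = NULL, threshold = NULL) {
  t_used <- if (is.null(threshold)) otsu_threshold(grey, roi)
            else as.integer(threshold)
  list(mask = grey < t_used, threshold = t_used)
}

#' Percent of the ROI covered by dark pixels
#'
#' @param binary Logical matrix of dark pixels.
#' @param roi Logical ROI mask of identical dimensions.
#' @param threshold_used Optional threshold to record in the result.
#' @return A `cover_result` list: `percent_dark` (0--100),
#'   `threshold_used`, `n_dark_pixels`, `n_roi_pixels`.
#' @export
percent_cover <- function(binary, roi, threshold_used = NA_integer_) {
  if (!identical(dim(binary), dim(roi))) {
    stop("mask dimensions do not match ROI", call. = FALSE)
  }
  n_roi <- sum(roi)
  if (n_roi == 0) stop("empty ROI", call. = FALSE)
  n_dark <- sum(binary & roi)
  structure(
    list(percent_dark = 100 * n_dark / n_roi,
         threshold_used = threshold_used,
         n_dark_pixels = n_dark, n_roi_pixels = n_roi),
    class = "cover_result"
  )
}

#' @export
print.cover_result <- function(x, ...) {
  cat(sprintf("Percent dark cover: %.2f%% (%d / %d ROI pixels, threshold %s)\n",
              x$percent_dark, x$n_dark_pixels, x$n_roi_pixels,
              x$threshold_used))
  invisible(x)
}

#' Quantify percent dark cover of a segment image
#'
#' The full measurement recipe: greyscale conversion, disk median filter
#' (default 2-pixel radius), dark-pixel thresholding (Otsu within the ROI
#' unless a fixed threshold is supplied), percent cover of the ROI.
#'
#' @param image A `segment_image` (from [render_segment_image()]), or a
#'   pixel matrix / RGB array.
#' @param roi Logical ROI mask; taken from the `segment_image` when omitted.
#' @param median_radius Median filter radius in pixels (default 2).
#' @param threshold Fixed threshold override, or `NULL` for Otsu.
#' @param keep_intermediates If `TRUE`, attach the greyscale, filtered and
#'   binary intermediates to the result for audit.
#' @return A `cover_result`; with `keep_intermediates`, also
#'   `$intermediates`.
#' @export
quantify_image <- function(image, roi = NULL, median_radius = 2,
                           threshold = NULL, keep_intermediates = FALSE) {
  if (inherits(image, "segment_image")) {
    roi <- roi %||% image$roi
    image <- image$pixels
  }
  if (is.null(roi)) stop("an ROI mask is required", call. = FALSE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  grey <- step("greyscale", to_greyscale_8bit(image))
  smoothed <- step("median", median_smooth(grey, median_radius))
  th <- step("threshold", threshold_dark(smoothed, roi, threshold))
  res <- step("cover", percent_cover(th$mask, roi, th$threshold))
  if (keep_intermediates) {
    res$intermediates <- list(grey = grey, smoothed = smoothed,
                              binary = th$mask)
  }
  res
}
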