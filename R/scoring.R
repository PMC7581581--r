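#' Stage counts for a graded specimen
#'
#' Bundles the per-stage chromatophore counts of one specimen observation.
#' Each chromatophore is graded on the ordinal dispersion scale 1 (small,
#' fully concentrated pigment) to 5 (large, fully dilated pigment); `n1` to
#' `n5` count the cells at each stage and `Tc` is their total.
#'
#' @param n1,n2,n3,n4,n5 Non-negative integer counts of chromatophores graded
#'   at stages 1 to 5.
#' @return An object of class `stage_counts`: a named integer vector
#'   `c(n1, ..., n5)` with attribute `Tc`.
#' @examples
#' stage_counts(2, 4, 6, 4, 4)
#' @export
stage_counts <- function(n1, n2, n3, n4, n5) {
  n <- c(n1 = n1, n2 = n2, n3 = n3, n4 = n4, n5 = n5)
  if (length(n) != 5L || anyNA(n)) {
    stop("stage counts must be five non-missing numbers", call. = FALSE)
  }
  if (any(n < 0) || any(n != round(n))) {
    stop("stage counts must be non-negative integers", call. = FALSE)
  }
  n <- as.integer(round(n))
  names(n) <- paste0("n", 1:5)
  structure(n, Tc = sum(n), class = "stage_counts")
}

#' @export
print.stage_counts <- function(x, ...) {
  cat("Stage counts (1 = concentrated ... 5 = dispersed):\n")
  print(unclass(x)[1:5])
  cat("Tc =", attr(x, "Tc"), "\n")
  invisible(x)
}

#' Chromatophore coefficient
#'
#' Scores the overall pigment dispersion of one specimen from its per-stage
#' chromatophore counts. Every graded cell contributes its stage (1--5)
#' weighted by 20 and standardised by the total count `Tc`, so the score is
#' 20 times the mean stage:
#' \deqn{C = \sum_{k=1}^{5} \frac{n_k}{T_c} \times 20 \times k}
#' It ranges from 20 (all cells fully concentrated; animal very light) to
#' 100 (all cells fully dilated; animal very dark), and is invariant to the
#' number of cells a segment happens to carry.
#'
#' @param counts A [stage_counts()] object, a numeric vector of five counts
#'   `(n1, ..., n5)`, or a data frame with columns `n1` to `n5`.
#' @return For a single count vector, a `coefficient_result`: a list with
#'   `value` (the score), `per_stage_contributions` (the five weighted
#'   terms summing to `value`) and `Tc`. For a data frame, a numeric vector
#'   of scores, one per row.
#' @examples
#' chromatophore_coefficient(stage_counts(2, 4, 6, 4, 4))$value  # 64
#' chromatophore_coefficient(c(0, 0, 0, 0, 20))$value            # 100
#' @export
chromatophore_coefficient <- function(counts) {
  if (is.data.frame(counts)) {
    cols <- paste0("n", 1:5)
    missing_cols <- setdiff(cols, names(counts))
    if (length(missing_cols)) {
      stop("count table lacks column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    }
    m <- as.matrix(counts[cols])
    tc <- rowSums(m)
    if (any(tc < 1)) {
      stop("no chromatophores graded (Tc = 0) in row(s) ",
           paste(which(tc < 1), collapse = ", "), call. = FALSE)
    }
    return(as.numeric(m %*% (20 * (1:5)) / tc))
  }
  n <- as.numeric(unclass(counts))[1:5]
  if (anyNA(n) || any(n < 0)) {
    stop("stage counts must be five non-negative numbers", call. = FALSE)
  }
  tc <- sum(n)
  if (tc < 1) stop("no chromatophores graded (Tc = 0)", call. = FALSE)
  contrib <- (n / tc) * 20 * (1:5)
  names(contrib) <- paste0("stage", 1:5)
  structure(
    list(value = sum(contrib), per_stage_contributions = contrib, Tc = tc),
    class = "coefficient_result"
  )
}

#' @export
print.coefficient_result <- function(x, ...) {
  cat(sprintf("Chromatophore coefficient: %.1f (Tc = %d)\n", x$value,
              as.integer(x$Tc)))
  invisible(x)
}

#' Add a coefficient column to a specimen table
#'
#' Convenience wrapper computing [chromatophore_coefficient()] row-wise over
#' a specimen table carrying `n1..n5` columns.
#'
#' @param table Data frame with columns `n1` to `n5`.
#' @return The table with a numeric `coefficient` column appended.
#' @export
add_coefficient <- function(table) {
  table$coefficient <- chromatophore_coefficient(table)
  table
}

#' Stage area bins implied by the renderer's radius map
#'
#' The synthetic renderer draws a stage-`k` chromatophore as a disk of
#' radius `radius_base + radius_per_stage * k` pixels. Inverting that map,
#' a connected component of area `A` is graded by the nearest expected disk
#' area; bin edges are midpoints between consecutive expected areas.
#'
#' @param radius_base,radius_per_stage Radius map parameters in pixels.
#' @return Numeric vector of four increasing area cut values (pixels^2);
#'   components below the first cut are stage 1, above the last stage 5.
#' @export
stage_area_bins <- function(radius_base = 2, radius_per_stage = 1.5) {
  areas <- pi * (radius_base + radius_per_stage * (1:5))^2
  (areas[-5] + areas[-1]) / 2
}

#' Grade segmented chromatophores by component area
#'
#' Automates the human 1--5 grading step for synthetic end-to-end runs:
#' connected components of the thresholded dark mask are extracted and each
#' is assigned a dispersion stage from its pixel area via
#' [stage_area_bins()]. Touching chromatophores merge into one component and
#' are graded by their combined area; when any component exceeds the largest
#' single-cell bin noticeably (area > 1.5x the expected stage-5 area) a
#' merge warning is emitted so downstream users can flag the observation.
#'
#' @param binary Logical or 0/1 matrix marking dark (chromatophore) pixels.
#' @param radius_base,radius_per_stage Radius map of the renderer that
#'   produced (or is assumed to approximate) the imaged cells.
#' @param min_area Components smaller than this many pixels are discarded as
#'   noise specks (default 4).
#' @return A [stage_counts()] object. Zero components yield counts of zero,
#'   which downstream scoring rejects with a `Tc = 0` error.
#' @export
grade_chromatophores <- function(binary, radius_base = 2,
                                 radius_per_stage = 1.5, min_area = 4) {
  if (!is.matrix(binary)) stop("`binary` must be a matrix", call. = FALSE)
  lab <- EBImage::bwlabel(matrix(as.numeric(binary != 0), nrow(binary)))
  areas <- tabulate(as.integer(lab[lab > 0]))
  areas <- areas[areas >= min_area]
  bins <- stage_area_bins(radius_base, radius_per_stage)
  stage5_area <- pi * (radius_base + radius_per_stage * 5)^2
  if (any(areas > 1.5 * stage5_area)) {
    warning(sum(areas > 1.5 * stage5_area),
            " component(s) larger than any single-cell area; ",
            "touching cells graded by combined area", call. = FALSE)
  }
  stage <- findInterval(areas, bins) + 1L
  cnt <- tabulate(stage, nbins = 5L)
  stage_counts(cnt[1], cnt[2], cnt[3], cnt[4], cnt[5])
}
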