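#' Rendering parameters for synthetic segment images
#'
#' Geometry and photometry of the synthetic 2nd abdominal segment: a bright
#' elliptical region of interest (ROI) on a neutral canvas, onto which
#' chromatophores are drawn as dark disks. All coordinates are 0-based,
#' row-major, origin at the top-left pixel.
#'
#' @param canvas `(height, width)` in pixels, each >= 64.
#' @param roi_center Ellipse centre `(row, col)`; default canvas centre.
#' @param roi_semiaxes Ellipse semi-axes `(rows, cols)` in pixels; default
#'   scales with the canvas (28% of height, 42% of width).
#' @param background_intensity Grey level of the unpigmented cuticle
#'   (0--255; default 230, a bright segment).
#' @param background_noise_sd Gaussian sensor/texture noise SD in grey
#'   levels (default 5; set 0 for noise-free renders).
#' @param radius_base,radius_per_stage Disk radius map: a stage-`k` cell has
#'   radius `radius_base + radius_per_stage * k` pixels.
#' @param intensity_drop Grey-level drop at a chromatophore core (default
#'   160, i.e. cores near 70 on a 230 background).
#' @param seed Integer seed for placement and noise.
#' @return A `render_params` list.
#' @export
render_params <- function(canvas = c(512L, 512L), roi_center = NULL,
                          roi_semiaxes = NULL, background_intensity = 230,
                          background_noise_sd = 5, radius_base = 2,
                          radius_per_stage = 1.5, intensity_drop = 160,
                          seed = 1L) {
  canvas <- as.integer(canvas)
  if (length(canvas) != 2 || any(canvas < 64)) {
    stop("`canvas` must be (height, width) with both >= 64", call. = FALSE)
  }
  if (background_intensity < 0 || background_intensity > 255) {
    stop("`background_intensity` must lie in [0, 255]", call. = FALSE)
  }
  roi_center <- roi_center %||% (canvas - 1) / 2
  roi_semiaxes <- roi_semiaxes %||% c(0.28, 0.42) * canvas
  structure(
    list(canvas = canvas, roi_center = roi_center,
         roi_semiaxes = roi_semiaxes,
         background_intensity = background_intensity,
         background_noise_sd = background_noise_sd,
         radius_base = radius_base, radius_per_stage = radius_per_stage,
         intensity_drop = intensity_drop, seed = as.integer(seed)),
    class = "render_params"
  )
}

#' Elliptical ROI mask for given render parameters
#'
#' @param params A [render_params()].
#' @return Logical matrix of canvas dimensions, `TRUE` inside the ellipse.
#' @export
roi_mask <- function(params) {
  h <- params$canvas[1]; w <- params$canvas[2]
  rr <- matrix(0:(h - 1), h, w)
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ((rr - params$roi_center[1]) / params$roi_semiaxes[1])^2 +
    ((cc - params$roi_center[2]) / params$roi_semiaxes[2])^2 <= 1
}

#' Sample ground-truth chromatophore placements
#'
#' Places one disk per graded cell uniformly inside the elliptical ROI (via
#' the unit-disk map, so density is uniform in area), with radius set by the
#' stage-radius map.
#'
#' @param counts A [stage_counts()] object or vector of five counts.
#' @param params A [render_params()].
#' @param seed Optional integer seed.
#' @return A data frame of truths: `row`, `col` (0-based centre), `stage`,
#'   `radius`, `intensity_drop`.
#' @export
sample_chromatophore_truths <- function(counts, params, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            sample_chromatophore_truths(counts, params)))
  }
  n <- as.numeric(unclass(counts))[1:5]
  stages <- rep(1:5, times = n)
  k <- length(stages)
  theta <- stats::runif(k, 0, 2 * pi)
  rad <- sqrt(stats::runif(k))
  data.frame(
    row = params$roi_center[1] + rad * sin(theta) * params$roi_semiaxes[1],
    col = params$roi_center[2] + rad * cos(theta) * params$roi_semiaxes[2],
    stage = stages,
    radius = params$radius_base + params$radius_per_stage * stages,
    intensity_drop = rep(params$intensity_drop, k)
  )
}

#' Render a synthetic segment image from ground-truth chromatophores
#'
#' Draws each chromatophore as a radially decaying dark disk: the full
#' `intensity_drop` applies out to `radius - 1` pixels from the centre, then
#' falls linearly to zero at `radius + 1` (a narrow soft edge). Overlapping
#' cells combine by taking the deepest drop. Outside the ROI the canvas
#' keeps a slightly darker surround so the segment outline is visible;
#' Gaussian noise is added everywhere and the result quantised to 8-bit.
#'
#' @param truths Data frame as from [sample_chromatophore_truths()]; may
#'   have zero rows. All centres must lie inside the ROI.
#' @param params A [render_params()].
#' @param seed Optional integer seed (noise only; placement is in `truths`).
#' @return A `segment_image` list: `pixels` (integer matrix, 0--255),
#'   `roi` (logical mask), `truths`, and `truth_dark_mask` — the pixels
#'   whose drawn drop reaches at least half `intensity_drop`, the ground
#'   truth for percent-cover checks.
#' @export
render_segment_image <- function(truths, params, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            render_segment_image(truths, params)))
  }
  stopifnot(inherits(params, "render_params"))
  h <- params$canvas[1]; w <- params$canvas[2]
  roi <- roi_mask(params)
  if (nrow(truths) > 0) {
    inside <- ((truths$row - params$roi_center[1]) /
                 params$roi_semiaxes[1])^2 +
      ((truths$col - params$roi_center[2]) / params$roi_semiaxes[2])^2 <= 1
    if (!all(inside)) {
      stop("chromatophore centre(s) outside the ROI: row(s) ",
           paste(which(!inside), collapse = ", "), call. = FALSE)
    }
  }
  drop <- matrix(0, h, w)
  for (i in seq_len(nrow(truths))) {
    r0 <- truths$row[i]; c0 <- truths$col[i]
    rad <- truths$radius[i]; d <- truths$intensity_drop[i]
    rows <- max(0, floor(r0 - rad - 1)):min(h - 1, ceiling(r0 + rad + 1))
    cols <- max(0, floor(c0 - rad - 1)):min(w - 1, ceiling(c0 + rad + 1))
    dist <- sqrt(outer((rows - r0)^2, (cols - c0)^2, `+`))
    prof <- d * pmin(1, pmax(0, (rad + 1 - dist) / 2))
    idx <- cbind(rep(rows, times = length(cols)) + 1,
                 rep(cols, each = length(rows)) + 1)
    drop[idx] <- pmax(drop[idx], as.vector(prof))
  }
  base <- ifelse(roi, params$background_intensity,
                 max(0, params$background_intensity - 60))
  img <- base - drop
  if (params$background_noise_sd > 0) {
    img <- img + stats::rnorm(h * w, 0, params$background_noise_sd)
  }
  pixels <- matrix(as.integer(pmin(255, pmax(0, round(img)))), h, w)
  structure(
    list(pixels = pixels, roi = roi, truths = truths,
         truth_dark_mask = drop >= params$intensity_drop / 2 & roi),
    class = "segment_image"
  )
}

#' @export
print.segment_image <- function(x, ...) {
  cat(sprintf("Synthetic segment image %dx%d, %d chromatophores, %.1f%% ROI truth cover\n",
              nrow(x$pixels), ncol(x$pixels), nrow(x$truths),
              100 * sum(x$truth_dark_mask) / sum(x$roi)))
  invisible(x)
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generator: expands the design, draws stage counts under the
#' effect model, and (optionally) renders one ground-truthed segment image
#' per observation. With `dir` set, images, masks and truth lists are
#' written to disk (8-bit greyscale PNG + binary mask PNG + JSON truths) and
#' the specimen table to `specimen_table.csv`; otherwise images are kept
#' in-memory. Everything is reproducible from `design$seed`.
#'
#' @param design A [cohort_design()].
#' @param model An [effect_model()].
#' @param params A [render_params()], or `NULL` to skip rendering (tables
#'   only — much faster when images are not needed).
#' @param dir Output directory, or `NULL` for an in-memory bundle.
#' @return A `cohort_bundle` list: `table` (observation rows with counts,
#'   `Tc` and ground-truth `coefficient`), `images` (list of
#'   `segment_image` or of file paths when written), `design`, `model`,
#'   `params`.
#' @export
generate_cohort <- function(design, model = effect_model(),
                            params = render_params(), dir = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  withr::with_seed(design$seed, {
    tab <- sample_design(design)
    tab <- sample_stage_counts(tab, model)
    tab$coefficient <- chromatophore_coefficient(tab)
    tab$observation_id <- sprintf("%s_%s_%s", tab$specimen_id,
                                  tab$exposure_time, tab$background)
    images <- NULL
    if (!is.null(params)) {
      images <- vector("list", nrow(tab))
      names(images) <- tab$observation_id
      for (i in seq_len(nrow(tab))) {
        tr <- sample_chromatophore_truths(
          as.numeric(tab[i, paste0("n", 1:5)]), params)
        img <- render_segment_image(tr, params)
        if (is.null(dir)) {
          images[[i]] <- img
        } else {
          images[[i]] <- write_segment_image(img, dir,
                                             tab$observation_id[i])
        }
      }
    }
    bundle <- structure(
      list(table = tab, images = images, design = design, model = model,
           params = params),
      class = "cohort_bundle"
    )
    if (!is.null(dir)) {
      write_specimen_table(tab, file.path(dir, "specimen_table.csv"))
    }
    bundle
  })
}

# Write one rendered observation to <dir>/<id>.png (+ mask, truths); returns
# the image path. Pixels and masks are 8-bit greyscale PNG; truth JSON keeps
# 0-based row/col coordinates (origin top-left).
write_segment_image <- function(img, dir, id) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(id, ".png"))
  ok <- try({
    png::writePNG(img$pixels / 255, path)
    png::writePNG(matrix(as.numeric(img$roi), nrow(img$roi)),
                  file.path(dir, paste0(id, "_roi.png")))
    jsonlite::write_json(img$truths, file.path(dir, paste0(id, "_truths.json")),
                         digits = 8)
  }, silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("failed writing image bundle for '", id, "' under ", dir, ": ",
         attr(ok, "condition")$message, call. = FALSE)
  }
  path
}

#' Read an 8-bit greyscale image and optional ROI mask
#'
#' PNG pixels are returned as an integer matrix on the 0--255 scale;
#' multi-channel files are collapsed with [to_greyscale_8bit()].
#'
#' @param path Image file (PNG).
#' @param roi_path Optional mask PNG (nonzero = inside ROI).
#' @return A list with `pixels` and `roi` (logical matrix or `NULL`).
#' @export
read_image_8bit <- function(path, roi_path = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) {
    px <- to_greyscale_8bit(px * 255)
  } else {
    px <- matrix(as.integer(round(px * 255)), nrow(px))
  }
  roi <- NULL
  if (!is.null(roi_path)) {
    if (!file.exists(roi_path)) {
      stop("ROI mask file not found: ", roi_path, call. = FALSE)
    }
    m <- png::readPNG(roi_path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    roi <- m > 0.5
  }
  list(pixels = px, roi = roi)
}
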