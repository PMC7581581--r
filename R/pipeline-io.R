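#' Create a blinding key for observation identifiers
#'
#' Assigns each observation a random integer label 1..N (a permutation), so
#' the person grading the images cannot infer treatment group from the file
#' name. Labels are zero-padded to uniform width.
#'
#' @param ids Character vector of unique observation identifiers.
#' @param seed Integer seed for the permutation.
#' @return A `blinding_key` tibble: `original_id`, `blinded_label`, with
#'   attributes `seed` and `created`.
#' @export
blinding_key <- function(ids, seed = 1L) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("observation ids must be unique", call. = FALSE)
  }
  n <- length(ids)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  key <- tibble::tibble(
    original_id = ids,
    blinded_label = sprintf(paste0("%0", nchar(n), "d"), perm)
  )
  attr(key, "seed") <- as.integer(seed)
  attr(key, "created") <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  class(key) <- c("blinding_key", class(key))
  key
}

#' Blind image files by copying under random numeric names
#'
#' Copies (never moves) each image to `out_dir` under its blinded label,
#' and writes the key as CSV to `key_path` — which must not sit inside
#' `out_dir`, so the blinded set can be handed over without the key.
#'
#' @param paths Image files; observation ids default to the file names
#'   without extension.
#' @param out_dir Directory receiving the blinded copies.
#' @param key_path CSV path for the key (outside `out_dir`).
#' @param seed Integer seed.
#' @param ids Optional explicit observation ids (same length as `paths`).
#' @return The blinding key (invisibly), with a `blinded_path` column.
#' @export
blind_images <- function(paths, out_dir, key_path, seed = 1L, ids = NULL) {
  if (!all(file.exists(paths))) {
    stop("missing image file(s): ",
         paste(utils::head(paths[!file.exists(paths)], 3), collapse = ", "),
         call. = FALSE)
  }
  ids <- ids %||% sub("\\.[^.]+$", "", basename(paths))
  key <- blinding_key(ids, seed)
  norm_out <- normalizePath(out_dir, mustWork = FALSE)
  norm_key <- normalizePath(dirname(key_path), mustWork = FALSE)
  if (startsWith(paste0(norm_key, "/"), paste0(norm_out, "/"))) {
    stop("the blinding key must not live inside the blinded image directory",
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ext <- sub("^.*(\\.[^.]+)$", "\\1", basename(paths))
  key$blinded_path <- file.path(out_dir, paste0(key$blinded_label, ext))
  ok <- file.copy(paths, key$blinded_path, overwrite = TRUE)
  if (!all(ok)) stop("failed to copy ", sum(!ok), " file(s)", call. = FALSE)
  utils::write.csv(as.data.frame(key), key_path, row.names = FALSE)
  invisible(key)
}

#' Recover original identifiers from blinded labels
#'
#' @param key A blinding key (or path to its CSV).
#' @param labels Blinded labels to look up.
#' @return Character vector of original ids.
#' @export
unblind <- function(key, labels) {
  if (is.character(key) && length(key) == 1) {
    key <- utils::read.csv(key, colClasses = "character")
  }
  idx <- match(as.character(labels), key$blinded_label)
  if (anyNA(idx)) {
    stop("unknown blinded label(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  key$original_id[idx]
}

specimen_table_required <- c("specimen_id", "trial", "concentration_ng_per_L",
                             "exposure_time", "background",
                             paste0("n", 1:5), "Tc")

#' Read / write the specimen observation table
#'
#' CSV schema: `specimen_id, trial, concentration_ng_per_L, exposure_time,
#' background, n1..n5, Tc` plus any measurement columns (`coefficient`,
#' `percent_dark`, ...). Stage counts must be non-negative integers with
#' `Tc` equal to their sum; violations name the offending column.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_specimen_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_specimen_table(tab)
}

#' @rdname read_specimen_table
#' @param table Table to write.
#' @export
write_specimen_table <- function(table, path) {
  validate_specimen_table(as.data.frame(table))
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

validate_specimen_table <- function(tab) {
  miss <- setdiff(specimen_table_required, names(tab))
  if (length(miss)) {
    stop("specimen table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c(paste0("n", 1:5), "Tc")) {
    v <- tab[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != round(v))) {
      stop("column `", col, "` must hold non-negative integers",
           call. = FALSE)
    }
  }
  if (any(rowSums(tab[paste0("n", 1:5)]) != tab$Tc)) {
    stop("column `Tc` must equal n1 + ... + n5", call. = FALSE)
  }
  tab$exposure_time <- factor(tab$exposure_time,
                              levels = unique(tab$exposure_time))
  tab$background <- factor(tab$background,
                           levels = intersect(c("white", "black"),
                                              unique(tab$background)))
  tibble::as_tibble(tab)
}

#' Run configuration for an end-to-end assay analysis
#'
#' Bundles every knob of a run so an analysis can be replayed from one
#' file: the cohort design, effect model and render parameters of the
#' generator, the quantification settings, and the statistics options.
#'
#' @param design A [cohort_design()].
#' @param model An [effect_model()].
#' @param params A [render_params()] or `NULL` to skip image rendering.
#' @param median_radius Median filter radius (pixels).
#' @param threshold Fixed threshold override or `NULL` for Otsu.
#' @param alpha Significance level for post-hoc selection.
#' @param out_dir Output directory for the results bundle.
#' @param blind Whether to write a blinded copy of the rendered images
#'   (with the key outside the blinded directory).
#' @return A `run_config` list.
#' @export
run_config <- function(design = cohort_design(), model = effect_model(),
                       params = render_params(), median_radius = 2,
                       threshold = NULL, alpha = 0.05,
                       out_dir = tempfile("chromassay_run_"),
                       blind = FALSE) {
  structure(
    list(design = design, model = model, params = params,
         median_radius = median_radius, threshold = threshold,
         alpha = alpha, out_dir = out_dir, blind = blind),
    class = "run_config"
  )
}

#' Read a run configuration from JSON or YAML
#'
#' The file mirrors [run_config()]: top-level keys `design`, `model`,
#' `params` (each a mapping of the respective constructor arguments, all
#' optional), plus `median_radius`, `threshold`, `alpha`, `out_dir`,
#' `blind`. `params: null` disables rendering.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the `yaml` package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  args <- list(
    design = do.call(cohort_design, as.list(raw$design %||% list())),
    model = do.call(effect_model, as.list(raw$model %||% list()))
  )
  if ("params" %in% names(raw) && is.null(raw$params)) {
    args["params"] <- list(NULL)  # explicit null disables rendering
  } else {
    args$params <- do.call(render_params, as.list(raw$params %||% list()))
  }
  for (k in c("median_radius", "threshold", "alpha", "out_dir", "blind")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  do.call(run_config, args)
}

#' Run the full assay pipeline
#'
#' Generate a synthetic cohort, render and quantify the segment images,
#' grade the thresholded cells, optionally write a blinded image copy, run
#' the statistical battery, and write a results bundle
#' (`specimen_table.csv`, `anova_<response>.csv`, `posthoc_*.csv`,
#' `results.json`) under `config$out_dir`. Each stage logs its parameters;
#' failures abort with the stage name attached.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage logging.
#' @return An `assay_results` object (invisibly) with the cohort bundle
#'   attached as attribute `bundle`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[chromassay] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  say("generate: seed ", config$design$seed, ", ",
      length(config$design$trials), " trial(s), ",
      length(config$design$concentrations), " dose level(s)")
  bundle <- stage("generate",
                  generate_cohort(config$design, config$model, config$params))
  tab <- bundle$table

  if (!is.null(config$params)) {
    say("quantify: median radius ", config$median_radius, ", threshold ",
        if (is.null(config$threshold)) "Otsu-in-ROI" else config$threshold)
    qs <- stage("quantify", lapply(bundle$images, function(img)
      quantify_image(img, median_radius = config$median_radius,
                     threshold = config$threshold)))
    tab$percent_dark <- vapply(qs, `[[`, numeric(1), "percent_dark")
    tab$threshold_used <- vapply(qs, `[[`, numeric(1), "threshold_used")

    say("score: grading thresholded components by area")
    graded <- stage("score", lapply(bundle$images, function(img) {
      th <- threshold_dark(median_smooth(img$pixels, config$median_radius),
                           img$roi)
      suppressWarnings(grade_chromatophores(th$mask & img$roi,
                                            config$params$radius_base,
                                            config$params$radius_per_stage))
    }))
    gm <- t(vapply(graded, function(g) unclass(g)[1:5], integer(5)))
    colnames(gm) <- paste0("graded_n", 1:5)
    tab <- cbind(tab, as.data.frame(gm))

    if (isTRUE(config$blind)) {
      say("blind: writing blinded image copies")
      img_dir <- file.path(out_dir, "images")
      stage("blind", {
        if (!dir.exists(img_dir)) dir.create(img_dir, recursive = TRUE)
        paths <- vapply(names(bundle$images), function(id)
          write_segment_image(bundle$images[[id]], img_dir, id),
          character(1))
        blind_images(paths, file.path(out_dir, "blinded_images"),
                     file.path(out_dir, "blinding_key.csv"),
                     seed = config$design$seed)
      })
    }
  }

  say("analyze: repeated-measures battery (alpha = ", config$alpha, ")")
  results <- stage("analyze", analyze_dataset(tab, alpha = config$alpha))

  say("write: results bundle under ", out_dir)
  stage("write", {
    write_specimen_table(tab, file.path(out_dir, "specimen_table.csv"))
    write_results(results, out_dir)
  })
  attr(results, "bundle") <- bundle
  attr(results, "table") <- tibble::as_tibble(tab)
  invisible(results)
}

#' Write an analysis results bundle
#'
#' ANOVA and post-hoc tables as CSV plus a single `results.json` holding
#' the full structure (numbers unrounded).
#'
#' @param results An `assay_results` from [analyze_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (resp in intersect(c("coefficient", "percent_dark"), names(results))) {
    utils::write.csv(as.data.frame(results[[resp]]$anova),
                     file.path(dir, paste0("anova_", resp, ".csv")),
                     row.names = FALSE)
    for (f in names(results[[resp]]$posthoc)) {
      utils::write.csv(as.data.frame(results[[resp]]$posthoc[[f]]),
                       file.path(dir, paste0("posthoc_", resp, "_", f, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(unclass_deep(results),
                       file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read back a results bundle
#'
#' @param dir Directory written by [write_results()].
#' @return The parsed `results.json` structure.
#' @export
read_results <- function(dir) {
  path <- file.path(dir, "results.json")
  if (!file.exists(path)) stop("no results.json under ", dir, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# strip S3 classes recursively so jsonlite serialises plainly
unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.data.frame(x)) {
    as.data.frame(x)
  } else {
    x
  }
}
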