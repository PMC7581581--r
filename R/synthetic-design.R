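#' Cohort design for a background-adaptation exposure experiment
#'
#' Describes the factorial layout of a trial series: each specimen belongs
#' to one trial and one nominal dose group, and is observed at every
#' exposure time on both a white and a black substrate (backgrounds are the
#' repeated measure, recorded white first, then black).
#'
#' @param trials Vector of trial labels (default trials 1--3).
#' @param concentrations Nominal doses in ng/L (default 0, 10, 100, 1000;
#'   0 is the control).
#' @param exposure_times Ordered exposure-time labels; default
#'   `c("1h", "1d", "1wk")`.
#' @param backgrounds Exactly two substrate labels, white then black.
#' @param replicates_per_treatment Specimens per trial x dose cell; a single
#'   positive integer or one per trial.
#' @param seed Integer seed governing all randomness downstream of this
#'   design.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(trials = 1:3,
                          concentrations = c(0, 10, 100, 1000),
                          exposure_times = c("1h", "1d", "1wk"),
                          backgrounds = c("white", "black"),
                          replicates_per_treatment = 15,
                          seed = 1L) {
  if (length(trials) < 1 || anyDuplicated(trials)) {
    stop("`trials` must be a non-empty vector of unique labels", call. = FALSE)
  }
  if (length(concentrations) < 1 || anyDuplicated(concentrations)) {
    stop("`concentrations` must be non-empty and unique", call. = FALSE)
  }
  if (length(exposure_times) < 1 || anyDuplicated(exposure_times)) {
    stop("`exposure_times` must be non-empty and unique", call. = FALSE)
  }
  if (length(backgrounds) != 2 || anyDuplicated(backgrounds)) {
    stop("`backgrounds` must be exactly two distinct labels (white, black)",
         call. = FALSE)
  }
  reps <- rep_len(as.integer(replicates_per_treatment), length(trials))
  if (any(is.na(reps)) || any(reps < 1)) {
    stop("`replicates_per_treatment` must be >= 1", call. = FALSE)
  }
  structure(
    list(trials = trials, concentrations = concentrations,
         exposure_times = exposure_times, backgrounds = backgrounds,
         replicates_per_treatment = reps, seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' Expand a cohort design into an observation table
#'
#' One row per specimen x exposure time x background, with stable specimen
#' identifiers so the repeated measures of one animal can be re-linked.
#' Row order is deterministic (specimen, then time, then white before
#' black); the design itself involves no randomness.
#'
#' @param design A [cohort_design()].
#' @return A tibble with columns `specimen_id`, `trial`,
#'   `concentration_ng_per_L`, `exposure_time`, `background`.
#' @examples
#' d <- cohort_design(trials = 2, replicates_per_treatment = 15)
#' nrow(sample_design(d))  # 60 specimens x 3 times x 2 backgrounds = 360
#' @export
sample_design <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  spec <- do.call(rbind, lapply(seq_along(design$trials), function(i) {
    expand.grid(
      replicate = seq_len(design$replicates_per_treatment[i]),
      concentration_ng_per_L = design$concentrations,
      trial = design$trials[i],
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
  }))
  spec$specimen_id <- sprintf("S%04d", seq_len(nrow(spec)))
  obs <- merge(
    spec[c("specimen_id", "trial", "concentration_ng_per_L")],
    expand.grid(specimen_id = spec$specimen_id,
                exposure_time = design$exposure_times,
                background = design$backgrounds,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    by = "specimen_id"
  )
  obs$exposure_time <- factor(obs$exposure_time, levels = design$exposure_times)
  obs$background <- factor(obs$background, levels = design$backgrounds)
  obs <- obs[order(obs$specimen_id, obs$exposure_time, obs$background), ]
  rownames(obs) <- NULL
  tibble::as_tibble(obs[, c("specimen_id", "trial", "concentration_ng_per_L",
                            "exposure_time", "background")])
}
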