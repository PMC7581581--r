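#' Latent ordered-category model for chromatophore dispersion
#'
#' Generator of synthetic stage grades. Every observation carries a latent
#' dispersion level
#' `L = mu0 + beta_background + beta_time + beta_trial + beta_concentration
#'  + specimen effect + observation noise`;
#' each chromatophore adds its own latent noise and is graded
#' `stage = 1 + #(cutpoints below L + cell noise)`, an ordered-probit style
#' mapping onto the 1--5 dispersion scale. With all betas and SDs zero every
#' cell lands in the same stage.
#'
#' `mu0` and `beta_background` default to an analytic calibration: `mu0` is
#' solved so the population mean coefficient on a white background equals
#' `target_white_coefficient`, and `beta_background` so the black-background
#' mean sits `background_shift_pct` percent higher — the ~20% darkening a
#' background-adaptation assay is built to detect.
#'
#' @param mu0 Baseline latent dispersion (white background, reference levels
#'   of the other factors). `NULL` (default) triggers the calibration above.
#' @param beta_background Additive latent shift on the black background;
#'   `NULL` (default) calibrates it to `background_shift_pct`.
#' @param beta_time,beta_trial,beta_concentration Named numeric vectors of
#'   additive latent shifts per factor level; levels absent from the vector
#'   shift by 0. Defaults: all zero (null effects).
#' @param sigma_specimen SD of the specimen-level random effect (shared by
#'   all observations of one animal; this is what makes white/black
#'   observations paired).
#' @param sigma_obs SD of per-observation noise.
#' @param sigma_cell SD of per-cell latent noise.
#' @param cutpoints Four strictly increasing thresholds mapping latent level
#'   to the 5 stages.
#' @param lambda_count Mean chromatophore count per segment; per-specimen
#'   counts are Poisson(`lambda_count`) truncated at >= 10.
#' @param target_white_coefficient,background_shift_pct Calibration targets
#'   used when `mu0` / `beta_background` are `NULL`.
#' @return An `effect_model` list with all parameters resolved.
#' @examples
#' m <- effect_model()
#' round(c(m$mu0, m$beta_background), 3)
#' @export
effect_model <- function(mu0 = NULL, beta_background = NULL,
                         beta_time = NULL, beta_trial = NULL,
                         beta_concentration = NULL,
                         sigma_specimen = 0.3, sigma_obs = 0.15,
                         sigma_cell = 0.6,
                         cutpoints = c(-1.5, -0.5, 0.5, 1.5),
                         lambda_count = 40,
                         target_white_coefficient = 45,
                         background_shift_pct = 20) {
  if (length(cutpoints) != 4 || any(diff(cutpoints) <= 0)) {
    stop("`cutpoints` must be four strictly increasing values", call. = FALSE)
  }
  sds <- c(sigma_specimen, sigma_obs, sigma_cell)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (lambda_count <= 0) stop("`lambda_count` must be > 0", call. = FALSE)

  # population SD of (latent + cell noise), over which the marginal mean
  # stage is computed
  sigma_pop <- sqrt(sigma_specimen^2 + sigma_obs^2 + sigma_cell^2)
  if (is.null(mu0)) {
    mu0 <- latent_for_mean_stage(target_white_coefficient / 20,
                                 cutpoints, sigma_pop)
  }
  if (is.null(beta_background)) {
    target_black <- target_white_coefficient *
      (1 + background_shift_pct / 100)
    beta_background <- latent_for_mean_stage(target_black / 20,
                                             cutpoints, sigma_pop) - mu0
  }
  structure(
    list(mu0 = mu0, beta_background = beta_background,
         beta_time = beta_time %||% numeric(),
         beta_trial = beta_trial %||% numeric(),
         beta_concentration = beta_concentration %||% numeric(),
         sigma_specimen = sigma_specimen, sigma_obs = sigma_obs,
         sigma_cell = sigma_cell, cutpoints = cutpoints,
         lambda_count = lambda_count,
         background_shift_pct = background_shift_pct),
    class = "effect_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected mean stage at a latent level
#'
#' Marginal mean of the graded stage for cells whose combined latent spread
#' around `mu` has SD `sigma`: `1 + sum_k pnorm((mu - tau_k)/sigma)`.
#'
#' @param mu Latent mean (vectorised).
#' @param cutpoints Four increasing thresholds.
#' @param sigma Total latent SD (> 0, or 0 for the degenerate step map).
#' @return Expected stage in \[1, 5\].
#' @export
expected_mean_stage <- function(mu, cutpoints, sigma) {
  if (sigma == 0) {
    return(1 + vapply(mu, function(m) sum(cutpoints < m), numeric(1)))
  }
  1 + vapply(mu, function(m) sum(stats::pnorm((m - cutpoints) / sigma)),
             numeric(1))
}

# Invert expected_mean_stage for calibration (monotone in mu).
latent_for_mean_stage <- function(target_stage, cutpoints, sigma) {
  if (target_stage <= 1 || target_stage >= 5) {
    stop("calibration target mean stage must lie strictly in (1, 5)",
         call. = FALSE)
  }
  lo <- min(cutpoints) - 10 * max(sigma, 1)
  hi <- max(cutpoints) + 10 * max(sigma, 1)
  stats::uniroot(function(m) expected_mean_stage(m, cutpoints, sigma) -
                   target_stage,
                 c(lo, hi), tol = 1e-10)$root
}

beta_lookup <- function(beta, level) {
  if (!length(beta)) return(rep(0, length(level)))
  lev <- as.character(level)
  unknown <- setdiff(unique(lev), names(beta))
  if (length(unknown)) {
    stop("covariate level(s) not present in effect model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  as.numeric(beta[lev])
}

#' Latent dispersion mean per observation row
#'
#' Fixed-effect part of the latent level for each row of a design table
#' (no random effects or noise).
#'
#' @param covariates Data frame with columns `background`, `exposure_time`,
#'   `trial`, `concentration_ng_per_L`.
#' @param model An [effect_model()].
#' @return Numeric vector of latent means.
#' @export
latent_mean <- function(covariates, model) {
  stopifnot(inherits(model, "effect_model"))
  bg <- as.character(covariates$background)
  if (!all(bg %in% c("white", "black"))) {
    stop("`background` must be 'white' or 'black'", call. = FALSE)
  }
  model$mu0 +
    ifelse(bg == "black", model$beta_background, 0) +
    beta_lookup(model$beta_time, covariates$exposure_time) +
    beta_lookup(model$beta_trial, covariates$trial) +
    beta_lookup(model$beta_concentration, covariates$concentration_ng_per_L)
}

#' Sample stage counts for an observation table
#'
#' Draws, for every row of a design table, the per-stage chromatophore
#' counts implied by the latent model: a per-specimen cell count
#' `N ~ Poisson(lambda_count)` truncated at >= 10 (constant across an
#' animal's repeated observations), a specimen random effect shared across
#' rows with the same `specimen_id`, per-row observation noise, and
#' multinomial cell grades with ordered-probit probabilities.
#'
#' Randomness is drawn from the current RNG stream; pass `seed` to make the
#' call self-contained and leave the global stream untouched.
#'
#' @param covariates Design table as produced by [sample_design()].
#' @param model An [effect_model()].
#' @param seed Optional integer seed.
#' @return The input table with columns `n1..n5`, `Tc` and the latent
#'   diagnostic column `latent` appended.
#' @export
sample_stage_counts <- function(covariates, model, seed = NULL) {
  stopifnot(inherits(model, "effect_model"))
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            sample_stage_counts(covariates, model)))
  }
  ids <- unique(covariates$specimen_id)
  mu_fixed <- latent_mean(covariates, model)

  # specimen-level draws, keyed by id
  n_cells <- rtrunc_pois(length(ids), model$lambda_count, min = 10)
  u_spec <- stats::rnorm(length(ids), 0, model$sigma_specimen)
  names(n_cells) <- names(u_spec) <- ids

  latent <- mu_fixed + u_spec[covariates$specimen_id] +
    stats::rnorm(nrow(covariates), 0, model$sigma_obs)
  counts <- t(vapply(seq_len(nrow(covariates)), function(i) {
    draw_stage_histogram(n_cells[[covariates$specimen_id[i]]],
                         latent[i], model$cutpoints, model$sigma_cell)
  }, integer(5)))
  colnames(counts) <- paste0("n", 1:5)
  out <- cbind(covariates, as.data.frame(counts))
  out$Tc <- rowSums(counts)
  out$latent <- latent
  tibble::as_tibble(out)
}

# Poisson truncated from below: resample until >= min.
rtrunc_pois <- function(n, lambda, min) {
  x <- stats::rpois(n, lambda)
  while (any(low <- x < min)) x[low] <- stats::rpois(sum(low), lambda)
  x
}

# Multinomial draw of N cell grades at latent level L; equivalent to N iid
# cells with stage = 1 + #(cutpoints below L + cell noise).
draw_stage_histogram <- function(n, latent, cutpoints, sigma_cell) {
  if (sigma_cell == 0) {
    stage <- 1L + sum(cutpoints < latent)
    out <- integer(5)
    out[stage] <- as.integer(n)
    return(out)
  }
  cum <- stats::pnorm((cutpoints - latent) / sigma_cell)
  p <- diff(c(0, cum, 1))
  as.integer(stats::rmultinom(1, n, p))
}
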