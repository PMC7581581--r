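#' Natural-log transform with optional offset
#'
#' Both assay responses are log-transformed before ANOVA to meet normality
#' assumptions. Coefficients are bounded below by 20, so no offset is
#' needed; percent dark cover can be exactly 0, so a +1 offset is the
#' default there.
#'
#' @param values Numeric vector.
#' @param offset Added before taking the log (default 0).
#' @return `log(values + offset)`.
#' @export
log_transform <- function(values, offset = 0) {
  shifted <- values + offset
  bad <- which(!is.na(shifted) & shifted <= 0)
  if (length(bad)) {
    stop("log transform undefined for observation(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (value + offset <= 0)", call. = FALSE)
  }
  log(shifted)
}

#' Greenhouse-Geisser sphericity epsilon
#'
#' Box's epsilon estimated from the covariance matrix of the within-subject
#' responses: with `S~` the doubly-centred covariance,
#' `eps = tr(S~)^2 / ((k - 1) * sum(S~^2))`, clamped to
#' `[1/(k - 1), 1]`. Equals 1 exactly when sphericity holds — in particular
#' for any two-level within factor.
#'
#' @param within_covariance Square covariance matrix (k x k) of the within
#'   responses, or a subjects-by-conditions data matrix from which it is
#'   estimated.
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
greenhouse_geisser_epsilon <- function(within_covariance) {
  s <- as.matrix(within_covariance)
  if (nrow(s) != ncol(s)) {
    if (nrow(s) > ncol(s)) s <- stats::cov(s)
    else stop("`within_covariance` must be square (or subjects x conditions)",
              call. = FALSE)
  }
  k <- nrow(s)
  if (k < 2) stop("need at least two within-subject levels", call. = FALSE)
  cent <- diag(k) - 1 / k
  sd_c <- cent %*% s %*% cent
  eps <- sum(diag(sd_c))^2 / ((k - 1) * sum(sd_c^2))
  min(1, max(1 / (k - 1), eps))
}

#' Partial eta squared
#'
#' Effect size `SS_effect / (SS_effect + SS_error)`, where the error sum of
#' squares is the one from the stratum in which the effect is tested.
#'
#' @param ss_effect,ss_error Non-negative sums of squares.
#' @return Value in `[0, 1]`.
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  if (any(ss_effect < 0) || any(ss_error < 0)) {
    stop("sums of squares must be >= 0", call. = FALSE)
  }
  if (any(ss_effect + ss_error == 0)) {
    stop("SS_effect and SS_error cannot both be zero", call. = FALSE)
  }
  ss_effect / (ss_effect + ss_error)
}

#' Mixed-design repeated-measures ANOVA
#'
#' Fits the assay's core model: one two-level within-subject factor (the
#' background each animal was photographed on) crossed with between-subject
#' fixed factors, Type-III sums of squares on possibly unbalanced designs,
#' Greenhouse-Geisser adjustment of within-subject tests, and partial eta
#' squared per effect. The between-subject model fit and Type-III
#' decomposition are delegated to \pkg{car}'s multivariate
#' repeated-measures machinery; this function owns the data reshaping,
#' validation and the assembled table.
#'
#' @param data Long-format data frame: one row per subject x within level.
#' @param dv Name of the response column.
#' @param within Name of the within-subject factor column (2+ levels; every
#'   subject must have every level exactly once).
#' @param between Character vector of between-subject factor columns (may
#'   be empty). Factors with a single observed level are dropped with a
#'   message.
#' @param subject Name of the subject identifier column.
#' @return An `anova_table` tibble with columns `effect`, `ss`, `df`, `ms`,
#'   `f`, `p`, `within` (logical), `gg_epsilon`, `p_gg` (within effects;
#'   between effects carry epsilon `NA` and `p_gg = p`), and
#'   `partial_eta_sq`.
#' @export
mixed_anova <- function(data, dv, within = "background",
                        between = c("concentration_ng_per_L", "trial",
                                    "exposure_time"),
                        subject = "specimen_id") {
  data <- as.data.frame(data)
  need <- c(dv, within, subject, between)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("column(s) missing from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  wlev <- levels(factor(data[[within]]))
  k <- length(wlev)
  if (k < 2) stop("within factor needs >= 2 levels", call. = FALSE)

  # wide reshape; every subject must carry every within level exactly once
  counts <- table(data[[subject]], data[[within]])
  bad <- rownames(counts)[apply(counts != 1, 1, any)]
  if (length(bad)) {
    stop("subject(s) without exactly one observation per within level: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  wide <- stats::reshape(
    data[c(subject, between, within, dv)],
    idvar = c(subject, between), timevar = within, direction = "wide"
  )
  ycols <- paste(dv, wlev, sep = ".")
  y <- as.matrix(wide[ycols])

  between <- between[vapply(between, function(b)
    length(unique(wide[[b]])) > 1, logical(1))]
  for (b in between) {
    wide[[b]] <- factor(wide[[b]])
    stats::contrasts(wide[[b]]) <- stats::contr.sum(nlevels(wide[[b]]))
  }
  rhs <- if (length(between)) paste(between, collapse = " * ") else "1"
  mod <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = wide)
  idata <- data.frame(W = factor(wlev, levels = wlev))
  names(idata) <- within
  stats::contrasts(idata[[within]]) <- stats::contr.sum(k)
  fit <- tryCatch(
    car::Anova(mod, idata = idata,
               idesign = stats::as.formula(paste("~", within)), type = 3),
    error = function(e) stop("singular or deficient design: ",
                             conditionMessage(e), call. = FALSE)
  )
  s <- summary(fit, multivariate = FALSE)
  ut <- s$univariate.tests
  eff <- rownames(ut)
  keep <- eff != "(Intercept)"
  is_within <- grepl(within, eff, fixed = TRUE)

  # GG adjustments exist only for within effects with > 1 numerator df;
  # for a 2-level within factor sphericity is trivial and epsilon is 1.
  gg_eps <- rep(NA_real_, length(eff))
  p_gg <- ut[, "Pr(>F)"]
  gg_eps[is_within] <- 1
  adj <- s$pval.adjustments
  if (!is.null(adj) && nrow(adj)) {
    ok <- rownames(adj)[!is.na(adj[, "GG eps"])]
    gg_eps[match(ok, eff)] <- adj[ok, "GG eps"]
    p_gg[match(ok, eff)] <- adj[ok, "Pr(>F[GG])"]
  }
  out <- tibble::tibble(
    effect = gsub("`", "", eff, fixed = TRUE),
    ss = unname(ut[, "Sum Sq"]),
    df = unname(ut[, "num Df"]),
    df_error = unname(ut[, "den Df"]),
    ms = unname(ut[, "Sum Sq"] / ut[, "num Df"]),
    f = unname(ut[, "F value"]),
    p = unname(ut[, "Pr(>F)"]),
    within = is_within,
    gg_epsilon = unname(gg_eps),
    p_gg = unname(p_gg),
    partial_eta_sq = unname(
      partial_eta_squared(ut[, "Sum Sq"], ut[, "Error SS"]))
  )[keep, ]
  class(out) <- c("anova_table", class(out))
  out
}

#' Bonferroni-adjusted pairwise comparisons of marginal means
#'
#' All level pairs of one factor compared by two-sided t tests on the
#' pooled one-way error (pooled SD over all levels, df = N - k), with the
#' Bonferroni family equal to the number of pairs. Raw p values are kept so
#' other adjustments can be cross-checked.
#'
#' @param data Data frame (typically one row per subject, e.g. responses
#'   averaged over the repeated measure).
#' @param factor_name Column holding the grouping factor (>= 2 levels, each
#'   with >= 2 observations).
#' @param response Column holding the response.
#' @return A `pairwise_table` tibble: `level_a`, `level_b`, `mean_diff`
#'   (a - b), `t`, `df`, `p_raw`, `p_bonferroni`, `m` (family size).
#' @export
pairwise_posthoc <- function(data, factor_name, response) {
  g <- factor(data[[factor_name]])
  y <- data[[response]]
  ok <- stats::complete.cases(g, y)
  g <- droplevels(g[ok]); y <- y[ok]
  lev <- levels(g)
  kk <- length(lev)
  if (kk < 2) stop("factor needs >= 2 levels", call. = FALSE)
  n <- tabulate(g)
  if (any(n < 2)) {
    stop("level(s) with < 2 observations: ",
         paste(lev[n < 2], collapse = ", "), call. = FALSE)
  }
  means <- tapply(y, g, mean)
  ss_within <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df_err <- length(y) - kk
  s2 <- ss_within / df_err
  pairs <- utils::combn(kk, 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(s2 * (1 / n[a] + 1 / n[b]))
    tt <- (means[a] - means[b]) / se
    p <- 2 * stats::pt(-abs(tt), df_err)
    tibble::tibble(level_a = lev[a], level_b = lev[b],
                   mean_diff = unname(means[a] - means[b]),
                   t = unname(tt), df = df_err, p_raw = unname(p),
                   p_bonferroni = min(1, m * unname(p)), m = m)
  })
  out <- do.call(rbind, res)
  class(out) <- c("pairwise_table", class(out))
  out
}

#' Pearson correlation with R squared
#'
#' Product-moment correlation with the two-sided t-based p value and the
#' squared coefficient, the pairing used to compare the human-graded
#' coefficient against the image-derived percent cover.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A `correlation_result` list: `r`, `p`, `r_squared`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(
    list(r = unname(ct$estimate), p = ct$p.value,
         r_squared = unname(ct$estimate)^2, n = length(x)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (R^2 = %.4f, p = %.3g, n = %d)\n",
              x$r, x$r_squared, x$p, x$n))
  invisible(x)
}

#' Run the full statistical battery on a specimen table
#'
#' For each available response (`coefficient`, `percent_dark`): natural-log
#' transform, mixed repeated-measures ANOVA with background as the repeated
#' measure, Bonferroni pairwise post hocs for every significant
#' between-subject main effect, and per-trial-removed subset refits (the
#' sequential-removal check on interactions). When both responses are
#' present, their Pearson correlation is computed overall and per trial.
#'
#' Because each animal is photographed at every exposure time, the ANOVA
#' unit is the specimen x exposure-time observation pair (white, black);
#' exposure time is treated as a fixed between-unit factor.
#'
#' @param table Specimen table with design columns and at least one of
#'   `coefficient` / `percent_dark`.
#' @param alpha Significance threshold used to pick post-hoc factors
#'   (default 0.05).
#' @param offsets Named log offsets per response.
#' @return An `assay_results` list: per response an `anova`, `posthoc`
#'   (list per factor) and `trial_removed` (list of anova tables), plus
#'   `correlation` (overall and per trial) when both responses exist.
#' @export
analyze_dataset <- function(table,
                            alpha = 0.05,
                            offsets = c(coefficient = 0, percent_dark = 1)) {
  table <- as.data.frame(table)
  responses <- intersect(c("coefficient", "percent_dark"), names(table))
  if (!length(responses)) {
    stop("table has neither `coefficient` nor `percent_dark`", call. = FALSE)
  }
  table$unit_id <- paste(table$specimen_id, table$exposure_time, sep = "@")
  between <- intersect(c("concentration_ng_per_L", "trial", "exposure_time"),
                       names(table))
  results <- list()
  for (resp in responses) {
    d <- table
    lcol <- paste0("log_", resp)
    d[[lcol]] <- log_transform(d[[resp]], offset = unname(offsets[resp]))
    aov_tab <- mixed_anova(d, dv = lcol, within = "background",
                           between = between, subject = "unit_id")
    main_between <- aov_tab[!aov_tab$within & aov_tab$effect %in% between, ]
    sig <- main_between$effect[main_between$p < alpha]
    agg <- stats::aggregate(d[[lcol]],
                            by = d[c("unit_id", between)], FUN = mean)
    names(agg)[ncol(agg)] <- lcol
    posthoc <- lapply(sig, function(f) pairwise_posthoc(agg, f, lcol))
    names(posthoc) <- sig
    trials <- unique(d$trial)
    trial_removed <- NULL
    if (length(trials) > 1) {
      trial_removed <- lapply(trials, function(tr) {
        mixed_anova(d[d$trial != tr, ], dv = lcol, within = "background",
                    between = between, subject = "unit_id")
      })
      names(trial_removed) <- paste0("without_trial_", trials)
    }
    results[[resp]] <- list(anova = aov_tab, posthoc = posthoc,
                            trial_removed = trial_removed)
  }
  if (all(c("coefficient", "percent_dark") %in% responses)) {
    per_trial <- lapply(split(table, table$trial), function(d)
      pearson_correlation(d$coefficient, d$percent_dark))
    results$correlation <- list(
      overall = pearson_correlation(table$coefficient, table$percent_dark),
      per_trial = per_trial
    )
  }
  results$alpha <- alpha
  class(results) <- "assay_results"
  results
}
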