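#' Subject-level noise variance
#'
#' A subject's precision is a single number per map: the vertex noise
#' variances \eqn{\sigma_v^2} averaged over the m vertices of the map,
#' \eqn{\sigma_s^2 = \frac{1}{m}\sum_v \sigma_v^2}. Because each subject gets
#' one value, the subject's weight is the same for every eccentricity bin
#' and every model parameter.
#'
#' @param sigma_v2 vector of per-vertex variances (>= 1 values).
#' @return \eqn{\sigma_s^2}.
#' @export
subject_precision <- function(sigma_v2) {
  if (!length(sigma_v2)) stop("no vertices: subject variance undefined")
  mean(sigma_v2)
}

#' Precision-weighted mean across subjects
#'
#' Inverse-variance weighting: \eqn{\bar{x} = \sum_s x_s/\sigma_s^2 \big/
#' \sum_s 1/\sigma_s^2}. Noisier subjects contribute less but are never
#' discarded. Invariant to a common rescaling of all variances; always lies
#' within the range of the inputs.
#'
#' @param values per-subject estimates.
#' @param precision_var per-subject variances \eqn{\sigma_s^2}, > 0.
#' @return Scalar weighted mean.
#' @export
precision_weighted_mean <- function(values, precision_var) {
  if (!length(values)) stop("empty input")
  stopifnot(length(values) == length(precision_var), all(precision_var > 0))
  sum(values / precision_var) / sum(1 / precision_var)
}

#' Bootstrapped 68% confidence interval of the precision-weighted mean
#'
#' Resamples subjects with replacement, recomputes the precision-weighted
#' mean on each replicate (each resampled subject keeps its own weight), and
#' returns the 16th-84th percentile interval. Reproducible under `seed`.
#'
#' @inheritParams precision_weighted_mean
#' @param n_boot number of bootstrap replicates (default 10000; fewer than
#'   100 triggers a warning).
#' @param seed RNG seed.
#' @return list of class `cohort_summary`: `mean`, `ci68` (low, high),
#'   `n_subjects`, `n_boot`, `seed`.
#' @export
bootstrap_ci68 <- function(values, precision_var, n_boot = 10000, seed = 0L) {
  if (length(values) < 2) stop("need >= 2 subjects to bootstrap")
  if (n_boot < 100) warning("n_boot < 100: confidence interval is unstable")
  n <- length(values)
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    apply(idx, 1, function(i) precision_weighted_mean(values[i],
                                                      precision_var[i]))
  })
  ci <- unname(stats::quantile(boots, c(0.16, 0.84), type = 7))
  structure(list(mean = precision_weighted_mean(values, precision_var),
                 ci68 = ci, n_subjects = n, n_boot = n_boot,
                 seed = as.integer(seed)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("mean %.4g, 68%% CI [%.4g, %.4g] (n = %d, %d bootstraps)\n",
              x$mean, x$ci68[1], x$ci68[2], x$n_subjects, x$n_boot))
  invisible(x)
}

#' Aggregate per-subject 2D model fits into a cohort table
#'
#' For each parameter of the 9-parameter model, computes the
#' precision-weighted mean and bootstrapped 68% CI across subjects, using
#' each subject's single map-level variance as the weight for all 9
#' parameters.
#'
#' @param fits list of per-subject `sfp_fit` objects (or bare `sfp_params`).
#' @param precision_var per-subject \eqn{\sigma_s^2}; if `NULL`, taken from
#'   each fit's stored vertex variances via [subject_precision()].
#' @param n_boot,seed passed to [bootstrap_ci68()].
#' @return data.frame: `parameter`, `mean`, `ci_low`, `ci_high`,
#'   `n_subjects`, `n_boot`, `seed`.
#' @export
aggregate_params <- function(fits, precision_var = NULL, n_boot = 10000,
                             seed = 0L) {
  par_of <- function(f) if (inherits(f, "sfp_fit")) f$params else f
  if (is.null(precision_var))
    precision_var <- vapply(fits, function(f) subject_precision(f$sigma_v2),
                            numeric(1))
  pnames <- c("sigma", "slope", "intercept", "p1", "p2", "p3", "p4",
              "A1", "A2")
  rows <- lapply(seq_along(pnames), function(j) {
    vals <- vapply(fits, function(f) par_of(f)[[pnames[j]]], numeric(1))
    cs <- bootstrap_ci68(vals, precision_var, n_boot = n_boot,
                         seed = derive_seed(seed, j))
    data.frame(parameter = pnames[j], mean = cs$mean, ci_low = cs$ci68[1],
               ci_high = cs$ci68[2], n_subjects = cs$n_subjects,
               n_boot = n_boot, seed = as.integer(seed))
  })
  do.call(rbind, rows)
}

#' Within-subject parameter differences between ROIs
#'
#' Computes subject-wise differences of one model parameter between pairs of
#' visual areas (V2-V1, V3-V2, V3-V1 by default), then the precision-weighted
#' mean and bootstrap CI of those differences. The weight for a difference is
#' the sum of the subject's two ROI variances (the variance of a difference
#' of independent estimates). Subjects missing either ROI of a contrast are
#' dropped from that contrast with a warning.
#'
#' @param fit_table data.frame with columns `subject_id`, `roi`, `value`
#'   (the parameter estimate) and `precision_var` (\eqn{\sigma_s^2} of that
#'   subject/ROI).
#' @param contrasts list of 2-vectors `c(roi_a, roi_b)`; each contrast is
#'   `roi_a - roi_b`.
#' @param n_boot,seed passed to [bootstrap_ci68()].
#' @return list with `differences` (per-subject long data.frame) and
#'   `summary` (one row per contrast: mean, ci_low, ci_high, n_subjects).
#' @export
roi_differences <- function(fit_table,
                            contrasts = list(c("V2", "V1"), c("V3", "V2"),
                                             c("V3", "V1")),
                            n_boot = 10000, seed = 0L) {
  stopifnot(all(c("subject_id", "roi", "value", "precision_var") %in%
                  names(fit_table)))
  diffs <- list(); summ <- list()
  for (ci in seq_along(contrasts)) {
    a <- contrasts[[ci]][1]; b <- contrasts[[ci]][2]
    ta <- fit_table[fit_table$roi == a, ]
    tb <- fit_table[fit_table$roi == b, ]
    common <- intersect(ta$subject_id, tb$subject_id)
    missing <- setdiff(union(ta$subject_id, tb$subject_id), common)
    if (length(missing))
      warning(sprintf("contrast %s-%s: dropping subject(s) %s (missing ROI)",
                      a, b, paste(missing, collapse = ", ")))
    if (length(common) < 2) stop("need >= 2 subjects with both ROIs")
    ia <- match(common, ta$subject_id); ib <- match(common, tb$subject_id)
    d <- ta$value[ia] - tb$value[ib]
    pv <- ta$precision_var[ia] + tb$precision_var[ib]
    cs <- bootstrap_ci68(d, pv, n_boot = n_boot, seed = derive_seed(seed, ci))
    diffs[[ci]] <- data.frame(contrast = paste0(a, "-", b),
                              subject_id = common, difference = d,
                              precision_var = pv)
    summ[[ci]] <- data.frame(contrast = paste0(a, "-", b), mean = cs$mean,
                             ci_low = cs$ci68[1], ci_high = cs$ci68[2],
                             n_subjects = length(common))
  }
  list(differences = do.call(rbind, diffs), summary = do.call(rbind, summ))
}
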