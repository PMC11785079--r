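#' Configuration for synthetic cohort generation
#'
#' Defines the study conditions a simulated cohort emulates: an NSD-like
#' design by default (8 subjects, pRF layouts over 0.5-4.2 deg eccentricity,
#' 28 stimulus classes x 8 trials), with trial-level Gaussian noise that is
#' heteroscedastic across vertices so that vertex and subject precisions are
#' meaningful. A Broderick-like variant uses `ecc_range_deg = c(1, 12)`.
#'
#' @param n_vertices vertices per subject per ROI.
#' @param ecc_range_deg eccentricity range of the pRF layout (degrees).
#' @param true_params named list of [sfp_params()] per ROI (names are ROI
#'   labels), or a single `sfp_params` for a one-ROI cohort (labelled V1).
#' @param noise_sd_scale trial noise SD as a fraction of each vertex's mean
#'   (absolute) noiseless response; 0.5 emulates realistic single-trial SNR.
#' @param noise_heterogeneity SD of the log-normal spread of per-vertex
#'   noise levels (0 = homoscedastic across vertices).
#' @param n_trials trials per stimulus class.
#' @param n_subjects subjects in the cohort.
#' @param between_subject_sd named numeric vector of SDs for jittering
#'   generating parameters across subjects (names among the 9 parameter
#'   names); empty/NULL for a shared truth.
#' @param frac_negative fraction of vertices generated with sign-flipped
#'   (negative) mean response, to exercise the exclusion rules.
#' @param seed master seed; per-subject streams are derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_vertices = 1000, ecc_range_deg = c(0.5, 4.2),
                       true_params = list(V1 = nsd_params("V1")),
                       noise_sd_scale = 0.5, noise_heterogeneity = 0.5,
                       n_trials = 8, n_subjects = 8,
                       between_subject_sd = NULL, frac_negative = 0.02,
                       seed = 0L) {
  if (inherits(true_params, "sfp_params")) true_params <- list(V1 = true_params)
  stopifnot(n_vertices >= 1, n_trials >= 2, n_subjects >= 1,
            noise_sd_scale >= 0, noise_heterogeneity >= 0,
            frac_negative >= 0, frac_negative < 1,
            length(ecc_range_deg) == 2, all(ecc_range_deg > 0),
            all(ecc_range_deg < 90),
            ecc_range_deg[1] < ecc_range_deg[2])
  stopifnot(length(names(true_params)) == length(true_params))
  structure(list(n_vertices = n_vertices, ecc_range_deg = ecc_range_deg,
                 true_params = true_params, noise_sd_scale = noise_sd_scale,
                 noise_heterogeneity = noise_heterogeneity,
                 n_trials = n_trials, n_subjects = n_subjects,
                 between_subject_sd = between_subject_sd,
                 frac_negative = frac_negative, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pRF layout
#'
#' Eccentricities are drawn log-uniformly over the range (denser foveally,
#' mimicking cortical magnification), polar angles uniformly on `[0, 2pi)`,
#' and pRF size grows affinely with eccentricity
#' (`size = 0.1 + 0.2 * ecc` by default, loosely following published V1-V3
#' trends; the size only feeds the eccentricity filtering rule).
#'
#' @param n number of vertices.
#' @param ecc_range_deg eccentricity range (degrees), within (0, 90).
#' @param seed RNG seed.
#' @param size_intercept,size_slope pRF size model coefficients.
#' @return data.frame: `vertex_id`, `ecc_deg`, `angle_rad`, `prf_size_deg`.
#' @export
simulate_prf_layout <- function(n, ecc_range_deg = c(0.5, 4.2), seed = 0L,
                                size_intercept = 0.1, size_slope = 0.2) {
  stopifnot(all(ecc_range_deg > 0), all(ecc_range_deg < 90))
  if (n == 0)
    return(data.frame(vertex_id = integer(0), ecc_deg = numeric(0),
                      angle_rad = numeric(0), prf_size_deg = numeric(0)))
  with_seed(seed, {
    ecc <- exp(stats::runif(n, log(ecc_range_deg[1]), log(ecc_range_deg[2])))
    ang <- stats::runif(n, 0, 2 * pi)
    data.frame(vertex_id = seq_len(n), ecc_deg = ecc, angle_rad = ang,
               prf_size_deg = size_intercept + size_slope * ecc)
  })
}

# jitter a parameter set by per-parameter Gaussian SDs (names subset of the 9)
jitter_params <- function(params, sd_vec) {
  if (is.null(sd_vec) || !length(sd_vec)) return(params)
  vals <- unclass(params)
  for (nm in names(sd_vec)) {
    stopifnot(nm %in% names(vals))
    vals[[nm]] <- vals[[nm]] + stats::rnorm(1, 0, sd_vec[[nm]])
  }
  # keep jittered values inside the validity region
  vals$sigma <- max(vals$sigma, 1e-3)
  vals$slope <- max(vals$slope, 0)
  vals$intercept <- max(vals$intercept, 1e-3)
  do.call(sfp_params, vals)
}

#' Simulate one subject's vertex data
#'
#' For each vertex and each catalog class, the noiseless beta is the 2D-model
#' prediction at the vertex's pRF center (local period and orientation from
#' the catalog's frequency vectors). Trials add independent Gaussian noise
#' whose SD is drawn once per vertex: `noise_sd_scale` times the vertex's
#' mean absolute noiseless response, times a log-normal heterogeneity factor.
#' A `frac_negative` fraction of vertices get a sign-flipped gain (negative
#' mean responders, excluded later by the filtering rules). Bit-identical
#' regeneration is guaranteed given (config, subject_index).
#'
#' @param config a [sim_config()].
#' @param subject_index 1-based subject number (selects the RNG stream and
#'   the per-subject parameter jitter).
#' @param catalog stimulus catalog; default the 28-class NSD set.
#' @return list of class `synthetic_subject`: `subject_id`, `vertices`
#'   (per-ROI row-bound data.frame with `roi` column), `betas` (long table
#'   `vertex_id, class_id, trial, beta`), `truth` (named list of generating
#'   `sfp_params` per ROI), `noise_sd` (per-vertex trial SD),
#'   `sigma_v2` (per-vertex variance over all catalog classes), and
#'   `subject_precision`.
#' @export
simulate_subject <- function(config, subject_index, catalog = make_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  sseed <- derive_seed(config$seed, subject_index)
  with_seed(sseed, {
    rois <- names(config$true_params)
    all_v <- list(); all_b <- list(); truth <- list()
    vid0 <- 0L
    for (roi in rois) {
      truth[[roi]] <- jitter_params(config$true_params[[roi]],
                                    config$between_subject_sd)
      lay <- simulate_prf_layout(config$n_vertices, config$ecc_range_deg,
                                 seed = derive_seed(sseed, match(roi, rois)))
      lay$vertex_id <- lay$vertex_id + vid0
      vid0 <- vid0 + nrow(lay)
      des <- build_design(lay$ecc_deg, lay$angle_rad, catalog)
      clean <- predict_matrix(truth[[roi]], des)
      flip <- stats::runif(nrow(lay)) < config$frac_negative
      clean[flip, ] <- -clean[flip, ]
      base_sd <- config$noise_sd_scale * rowMeans(abs(clean))
      het <- exp(stats::rnorm(nrow(lay), 0, config$noise_heterogeneity))
      noise_sd <- base_sd * het
      n <- nrow(lay); k <- ncol(clean); tr <- config$n_trials
      noise <- array(stats::rnorm(n * k * tr, 0, rep(noise_sd, k * tr)),
                     dim = c(n, k, tr))
      trials <- array(rep(clean, tr), dim = c(n, k, tr)) + noise
      lay$roi <- roi
      all_v[[roi]] <- lay
      all_b[[roi]] <- data.frame(
        vertex_id = rep(lay$vertex_id, times = k * tr),
        class_id = rep(rep(catalog$class_id, each = n), times = tr),
        trial = rep(seq_len(tr), each = n * k),
        beta = as.vector(trials))
      lay$noise_sd <- noise_sd
      all_v[[roi]] <- lay
    }
    vertices <- do.call(rbind, all_v)
    betas <- do.call(rbind, all_b)
    rownames(vertices) <- rownames(betas) <- NULL
    tabs <- beta_tables(vertices$vertex_id, betas, catalog)
    sigma_v2 <- rowMeans(tabs$var)
    structure(list(subject_id = sprintf("sub-%02d", subject_index),
                   vertices = vertices, betas = betas, truth = truth,
                   noise_sd = vertices$noise_sd, sigma_v2 = sigma_v2,
                   subject_precision = subject_precision(sigma_v2)),
              class = "synthetic_subject")
  })
}

#' Simulate a cohort of subjects
#'
#' @param config a [sim_config()].
#' @param catalog stimulus catalog.
#' @return list of [simulate_subject()] results, length `n_subjects`.
#' @export
simulate_cohort <- function(config, catalog = make_catalog()) {
  lapply(seq_len(config$n_subjects),
         function(i) simulate_subject(config, i, catalog))
}

#' Write / read a subject's vertex and beta tables
#'
#' The on-disk schema shared by the generator and the fitter (and the one to
#' which real exports should be adapted): per subject, a vertex CSV
#' (`vertex_id, roi, ecc_deg, angle_rad, prf_size_deg`), a beta CSV
#' (`vertex_id, class_id, trial, beta`), and a truth JSON per ROI when the
#' subject is synthetic.
#'
#' @param subject a `synthetic_subject`.
#' @param dir output directory.
#' @return Invisibly, the file paths written.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vfile <- file.path(dir, paste0(subject$subject_id, "_vertices.csv"))
  bfile <- file.path(dir, paste0(subject$subject_id, "_betas.csv"))
  # doubles are written as %.17g so the CSVs round-trip bit-exactly
  fmt17 <- function(df) {
    for (j in seq_along(df))
      if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    df
  }
  data.table::fwrite(fmt17(subject$vertices[, c("vertex_id", "roi", "ecc_deg",
                                                "angle_rad",
                                                "prf_size_deg")]),
                     vfile, quote = FALSE)
  data.table::fwrite(fmt17(subject$betas), bfile, quote = FALSE)
  paths <- c(vfile, bfile)
  if (!is.null(subject$truth)) {
    for (roi in names(subject$truth)) {
      tfile <- file.path(dir, sprintf("%s_%s_truth.json",
                                      subject$subject_id, roi))
      write_params(subject$truth[[roi]], tfile)
      paths <- c(paths, tfile)
    }
  }
  invisible(paths)
}

#' @rdname write_subject
#' @param subject_id subject label, e.g. `"sub-01"`.
#' @export
read_subject <- function(dir, subject_id) {
  vfile <- file.path(dir, paste0(subject_id, "_vertices.csv"))
  bfile <- file.path(dir, paste0(subject_id, "_betas.csv"))
  if (!file.exists(vfile) || !file.exists(bfile))
    stop("missing subject files for ", subject_id, " in ", dir)
  list(subject_id = subject_id,
       vertices = as.data.frame(data.table::fread(vfile)),
       betas = as.data.frame(data.table::fread(bfile)))
}
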