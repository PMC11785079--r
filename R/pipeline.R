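#' Vertex exclusion rules
#'
#' Configuration for the three printed exclusion rules applied before
#' fitting: (i) vertices whose mean response across the relevant stimulus
#' classes is negative (24 primary classes for the 1D pathway, all 28 for
#' the 2D pathway); (ii) vertices whose pRF center lies within the largest
#' anti-aliasing mask (eccentricity below `max_mask_radius_deg`); and, for
#' the 2D pathway only, (iii) vertices whose pRF center is more than one pRF
#' size outside the stimulus extent radius. Boundary cases keep the vertex
#' (inclusive comparisons).
#'
#' @param max_mask_radius_deg largest anti-aliasing mask radius (degrees).
#' @param stimulus_extent_radius_deg stimulus extent radius (degrees).
#' @param exclude_negative_mean apply rule (i).
#' @param prf_size_rule apply rule (iii) (2D mode only).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(max_mask_radius_deg = 0.5,
                          stimulus_extent_radius_deg = 4.2,
                          exclude_negative_mean = TRUE,
                          prf_size_rule = TRUE) {
  stopifnot(max_mask_radius_deg > 0, stimulus_extent_radius_deg > 0)
  structure(list(max_mask_radius_deg = max_mask_radius_deg,
                 stimulus_extent_radius_deg = stimulus_extent_radius_deg,
                 exclude_negative_mean = exclude_negative_mean,
                 prf_size_rule = prf_size_rule),
            class = "filter_config")
}

#' Apply the vertex exclusion rules
#'
#' @param vertices data.frame with `vertex_id`, `ecc_deg`, `prf_size_deg`.
#' @param betas long beta table.
#' @param catalog stimulus catalog.
#' @param config a [filter_config()].
#' @param mode `"1d"` (negative-mean rule over the 24 primary classes; no
#'   pRF-size rule) or `"2d"` (all 28 classes; pRF-size rule active).
#' @return list: `kept` (surviving vertex data.frame) and `log` (data.frame
#'   of per-rule exclusion counts; counts sum to input minus kept because
#'   each dropped vertex is attributed to the first rule it violates, in the
#'   order negative-mean, mask-radius, extent).
#' @export
filter_vertices <- function(vertices, betas, catalog = make_catalog(),
                            config = filter_config(),
                            mode = c("2d", "1d")) {
  mode <- match.arg(mode)
  cls <- if (mode == "1d") {
    catalog$class_id[catalog$shape != "mixture"]
  } else catalog$class_id
  dt <- data.table::as.data.table(betas)
  dt <- dt[dt$class_id %in% cls, ]
  mb <- dt[, list(mean_beta = mean(beta)), by = "vertex_id"]
  mean_beta <- mb$mean_beta[match(vertices$vertex_id, mb$vertex_id)]

  drop_reason <- rep(NA_character_, nrow(vertices))
  if (config$exclude_negative_mean)
    drop_reason[is.na(drop_reason) & mean_beta < 0] <- "negative_mean"
  drop_reason[is.na(drop_reason) &
                vertices$ecc_deg < config$max_mask_radius_deg] <- "mask_radius"
  if (mode == "2d" && config$prf_size_rule)
    drop_reason[is.na(drop_reason) &
                  vertices$ecc_deg > config$stimulus_extent_radius_deg +
                    vertices$prf_size_deg] <- "outside_extent"

  kept <- vertices[is.na(drop_reason), , drop = FALSE]
  log <- data.frame(rule = c("negative_mean", "mask_radius",
                             "outside_extent"),
                    n_excluded = c(sum(drop_reason == "negative_mean",
                                       na.rm = TRUE),
                                   sum(drop_reason == "mask_radius",
                                       na.rm = TRUE),
                                   sum(drop_reason == "outside_extent",
                                       na.rm = TRUE)))
  log <- rbind(log, data.frame(rule = "kept", n_excluded = nrow(kept)))
  list(kept = kept, log = log)
}

#' Run configuration for the end-to-end driver
#'
#' A run is reproducible from its configuration alone: it names the input
#' directory, subjects, ROIs, bin edges, optimizer and bootstrap settings,
#' and seeds. Serializable to YAML via [write_run_config()].
#'
#' @param data_dir directory of per-subject vertex/beta CSVs (the
#'   [write_subject()] schema).
#' @param subjects character vector of subject ids (e.g. `"sub-01"`).
#' @param rois ROI labels to fit.
#' @param bin_edges eccentricity bin edges for the 1D pathway.
#' @param opt an [opt_config()].
#' @param filter a [filter_config()].
#' @param n_boot bootstrap replicates for cohort CIs.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(data_dir, subjects, rois = "V1",
                       bin_edges = seq(0.5, 4, by = 0.5),
                       opt = opt_config(), filter = filter_config(),
                       n_boot = 10000, seed = 0L, out_dir = tempfile("sfrun")) {
  structure(list(data_dir = data_dir, subjects = subjects, rois = rois,
                 bin_edges = bin_edges, opt = opt, filter = filter,
                 n_boot = n_boot, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$opt <- do.call(opt_config, raw$opt)
  raw$filter <- do.call(filter_config, raw$filter)
  do.call(run_config, raw)
}

#' Run the full map-fitting pipeline over a cohort
#'
#' The end-to-end driver: for each subject and ROI it applies the exclusion
#' rules, fits the 1D pathway (eccentricity-binned tuning curves plus the
#' preferred-period-vs-eccentricity line) and the 2D 9-parameter map model,
#' then aggregates the 2D parameters across subjects with precision-weighted
#' means and bootstrapped 68% CIs, and (for multiple ROIs) computes
#' within-subject ROI differences of bandwidth. All outputs are written
#' under `config$out_dir` and returned; a rerun with the same configuration
#' and inputs reproduces them bit-identically. Input tables are never
#' modified.
#'
#' @param config a [run_config()].
#' @param catalog stimulus catalog.
#' @return list: `cohort` (per-ROI parameter summary data.frame),
#'   `fits` (nested per-subject/ROI `sfp_fit`s), `lines` (1D period-line
#'   fits), `bin_curves` (1D per-bin tuning parameters),
#'   `roi_diffs` (bandwidth contrasts, or NULL), `exclusions`, `log`
#'   (character vector, one line per stage).
#' @export
run_replication <- function(config, catalog = make_catalog()) {
  stopifnot(inherits(config, "run_config"))
  for (s in config$subjects) {
    vf <- file.path(config$data_dir, paste0(s, "_vertices.csv"))
    bf <- file.path(config$data_dir, paste0(s, "_betas.csv"))
    if (!file.exists(vf) || !file.exists(bf))
      stop("missing input files for subject ", s)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    message(line)
  }
  fits <- list(); lines <- list(); curves <- list(); excl <- list()
  fit_rows <- list()
  for (s in config$subjects) {
    dat <- read_subject(config$data_dir, s)
    for (roi in config$rois) {
      vx <- dat$vertices[dat$vertices$roi == roi, , drop = FALSE]
      say("[%s %s] %d vertices loaded", s, roi, nrow(vx))

      f1 <- filter_vertices(vx, dat$betas, catalog, config$filter, "1d")
      bd <- bin_vertices(f1$kept, dat$betas, catalog, config$bin_edges)
      bc <- fit_tuning_bins(bd)
      bc$subject_id <- s; bc$roi <- roi
      ln <- fit_period_line(bc)
      curves[[paste(s, roi)]] <- bc
      lines[[paste(s, roi)]] <- data.frame(subject_id = s, roi = roi,
                                           slope = ln$slope,
                                           intercept = ln$intercept)
      say("[%s %s] 1d: %d bins, period line slope %.3f intercept %.3f",
          s, roi, nrow(bc), ln$slope, ln$intercept)

      f2 <- filter_vertices(vx, dat$betas, catalog, config$filter, "2d")
      el <- f2$log; el$subject_id <- s; el$roi <- roi; el$mode <- "2d"
      excl[[paste(s, roi)]] <- el
      fit <- fit_2d_model(f2$kept, dat$betas, catalog,
                          config = config$opt,
                          seed = derive_seed(config$seed, match(s,
                            config$subjects)))
      fits[[s]][[roi]] <- fit
      write_fit(fit, file.path(config$out_dir,
                               sprintf("%s_%s_fit.json", s, roi)))
      say("[%s %s] 2d: %d vertices, %d iters, loss %.4g, converged %s",
          s, roi, fit$n_vertices_used, fit$n_iter, fit$final_loss,
          fit$converged)
      pv <- subject_precision(fit$sigma_v2)
      for (pn in c("sigma", "slope", "intercept", "p1", "p2", "p3", "p4",
                   "A1", "A2"))
        fit_rows[[length(fit_rows) + 1]] <-
          data.frame(subject_id = s, roi = roi, parameter = pn,
                     value = fit$params[[pn]], precision_var = pv)
    }
  }
  fit_table <- do.call(rbind, fit_rows)

  cohort <- list()
  for (roi in config$rois) {
    roi_fits <- lapply(config$subjects, function(s) fits[[s]][[roi]])
    tab <- aggregate_params(roi_fits, n_boot = config$n_boot,
                            seed = derive_seed(config$seed,
                                               1000 + match(roi, config$rois)))
    tab$roi <- roi
    cohort[[roi]] <- tab
  }
  cohort <- do.call(rbind, cohort)
  rownames(cohort) <- NULL

  roi_diffs <- NULL
  if (length(config$rois) > 1) {
    st <- fit_table[fit_table$parameter == "sigma", ]
    pairs <- utils::combn(config$rois, 2, simplify = FALSE)
    contrasts <- lapply(pairs, function(p) c(p[2], p[1]))
    roi_diffs <- roi_differences(st, contrasts, n_boot = config$n_boot,
                                 seed = derive_seed(config$seed, 2000))
    say("roi differences (sigma): %s",
        paste(sprintf("%s %.3f", roi_diffs$summary$contrast,
                      roi_diffs$summary$mean), collapse = "; "))
  }

  exclusions <- do.call(rbind, excl); rownames(exclusions) <- NULL
  utils::write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(exclusions, file.path(config$out_dir, "exclusions.csv"),
                   row.names = FALSE)
  write_run_config(config, file.path(config$out_dir, "run_config.yaml"))
  manifest <- list(package = "sfmaps",
                   version = as.character(utils::packageVersion("sfmaps")),
                   seed = config$seed, subjects = config$subjects,
                   rois = config$rois, n_boot = config$n_boot)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log, file.path(config$out_dir, "run_log.txt"))

  list(cohort = cohort, fits = fits,
       lines = do.call(rbind, lines),
       bin_curves = do.call(rbind, curves),
       roi_diffs = roi_diffs, exclusions = exclusions, log = log)
}
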