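test_that("vertex variance averages per-class sample variances", {
  b <- matrix(5, nrow = 3, ncol = 4)
  expect_equal(vertex_variance(b), 0)
  b2 <- rbind(c(0, 2), c(1, 3))
  expect_equal(vertex_variance(b2), 2)          # ddof = 1 per class, mean
  expect_equal(vertex_variance(b2 + 10), 2)     # shift invariance
  expect_equal(vertex_variance(b2, classes_used = 1), 2)
  b3 <- rbind(c(0, 2), c(1, NA))
  expect_error(vertex_variance(b3), "insufficient trials")
})

test_that("normalized loss is scale-invariant and matches hand values", {
  beta <- c(3, -1, 2, 0.5)
  expect_equal(normalized_loss(beta, 7.3 * beta, 0.8), 0)
  pred <- c(1, 2, 0, -1)
  expect_equal(normalized_loss(2.7 * beta, pred, 0.8),
               normalized_loss(beta, pred, 0.8), tolerance = 1e-12)
  # orthonormal vectors over n = 28 classes: (1/28) * 2
  e1 <- c(1, rep(0, 27)); e2 <- c(0, 1, rep(0, 26))
  expect_equal(normalized_loss(e1, e2, 1), 2 / 28)
  expect_error(normalized_loss(rep(0, 4), pred, 1), "zero-norm")
})

test_that("vectorized map loss equals the loop-based scalar oracle", {
  set.seed(11)
  lay <- simulate_prf_layout(5, c(0.5, 4.2), seed = 12)
  des <- sfmaps:::build_design(lay$ecc_deg, lay$angle_rad, nsd_catalog)
  params <- sfp_params(sigma = 2.1, slope = 0.13, intercept = 0.2,
                       p1 = 0.05, p2 = -0.02, p3 = 0.03, p4 = -0.01,
                       A1 = 0.04, A2 = -0.02)
  pred <- sfmaps:::predict_matrix(params, des)
  beta <- pred + matrix(rnorm(5 * 28, 0, 0.2), 5, 28)
  s2 <- runif(5, 0.2, 1.5)
  u <- sfmaps:::params_to_internal(params)
  X <- beta / sqrt(rowSums(beta^2))
  vec <- sfmaps:::map_loss_grad(u, des, X, 1 / s2, grad = FALSE)$loss
  expect_equal(vec, loop_map_loss(beta, pred, s2), tolerance = 1e-10)
  # and the same loop total from per-vertex normalized_loss calls
  per_vertex <- sapply(1:5, function(v)
    normalized_loss(beta[v, ], pred[v, ], s2[v]))
  expect_equal(vec, mean(per_vertex), tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(21)
  lay <- simulate_prf_layout(20, c(0.5, 4.2), seed = 22)
  des <- sfmaps:::build_design(lay$ecc_deg, lay$angle_rad, nsd_catalog)
  pred <- sfmaps:::predict_matrix(nsd_params("V1"), des)
  beta <- pred + matrix(rnorm(20 * 28, 0, 0.15), 20, 28)
  X <- beta / sqrt(rowSums(beta^2))
  w <- runif(20, 0.5, 2)
  u <- sfmaps:::params_to_internal(
    sfp_params(sigma = 1.9, slope = 0.11, intercept = 0.27, p1 = 0.03,
               p2 = -0.01, p3 = 0.02, p4 = -0.02, A1 = 0.02, A2 = -0.01))
  g <- sfmaps:::map_loss_grad(u, des, X, w)$grad
  num <- sapply(1:9, function(j) {
    h <- 1e-6
    up <- u; up[j] <- up[j] + h
    um <- u; um[j] <- um[j] - h
    (sfmaps:::map_loss_grad(up, des, X, w, grad = FALSE)$loss -
       sfmaps:::map_loss_grad(um, des, X, w, grad = FALSE)$loss) / (2 * h)
  })
  expect_equal(g, num, tolerance = 1e-5)
})

test_that("the 2D fit recovers generating parameters from noiseless data", {
  cfg <- sim_config(n_vertices = 200, noise_sd_scale = 0,
                    noise_heterogeneity = 0, frac_negative = 0, seed = 3)
  s <- simulate_subject(cfg, 1)
  fit <- fit_2d_model(s$vertices, s$betas)
  truth <- as.numeric(nsd_params("V1"))
  expect_true(all(abs(as.numeric(fit$params) - truth) < 1e-2))
  # loss at the truth is the global minimum (0) and beats the default init
  des <- sfmaps:::build_design(s$vertices$ecc_deg, s$vertices$angle_rad,
                               nsd_catalog)
  tabs <- sfmaps:::beta_tables(s$vertices$vertex_id, s$betas, nsd_catalog)
  X <- tabs$mean / sqrt(rowSums(tabs$mean^2))
  w <- rep(1, nrow(X))
  at_truth <- sfmaps:::map_loss_grad(
    sfmaps:::params_to_internal(nsd_params("V1")), des, X, w,
    grad = FALSE)$loss
  at_init <- sfmaps:::map_loss_grad(
    sfmaps:::params_to_internal(sfp_params(2, 0.1, 0.3)), des, X, w,
    grad = FALSE)$loss
  expect_lt(at_truth, 1e-12)
  expect_lte(at_truth, at_init)
  # loss trace decreases overall
  tr <- fit$loss_trace
  expect_lt(tr[length(tr)], tr[1])
})

test_that("null orientation effects are identified as null", {
  cfg <- sim_config(n_vertices = 600, noise_sd_scale = 0.3,
                    true_params = list(V1 = sfp_params(sigma = 2.2,
                                                       slope = 0.14,
                                                       intercept = 0.18)),
                    frac_negative = 0, seed = 5)
  s <- simulate_subject(cfg, 1)
  fit <- fit_2d_model(s$vertices, s$betas)
  est <- fit$params
  expect_true(all(abs(c(est$p1, est$p2, est$p3, est$p4, est$A1, est$A2))
                  < 0.01))
})

test_that("precision weighting reduces the influence of noisy vertices", {
  # two vertex groups generated from different parameter sets; when the
  # contaminant group is noisier, the fit moves toward the clean group
  set.seed(31)
  clean_p <- sfp_params(sigma = 2.2, slope = 0.14, intercept = 0.18)
  contam_p <- sfp_params(sigma = 2.2, slope = 0.30, intercept = 0.35)
  lay <- simulate_prf_layout(120, c(0.5, 4.2), seed = 32)
  des <- sfmaps:::build_design(lay$ecc_deg, lay$angle_rad, nsd_catalog)
  grp <- rep(c("clean", "contam"), each = 60)
  mu <- rbind(sfmaps:::predict_matrix(clean_p, des)[1:60, ],
              sfmaps:::predict_matrix(contam_p, des)[61:120, ])
  make_betas <- function(contam_sd) {
    sds <- ifelse(grp == "clean", 0.05, contam_sd)
    do.call(rbind, lapply(1:8, function(tr)
      data.frame(vertex_id = lay$vertex_id,
                 class_id = rep(nsd_catalog$class_id, each = 120),
                 trial = tr,
                 beta = as.vector(mu) + rnorm(120 * 28, 0, rep(sds, 28)))))
  }
  cfgo <- opt_config(min_vertices = 10)
  fit_lo <- fit_2d_model(lay, make_betas(0.05), config = cfgo)
  fit_hi <- fit_2d_model(lay, make_betas(1.5), config = cfgo)
  d_lo <- abs(fit_lo$params$slope - clean_p$slope)
  d_hi <- abs(fit_hi$params$slope - clean_p$slope)
  expect_lt(d_hi, d_lo)
})

test_that("recovery errors stay within the published between-subject intervals", {
  # 20 independent noisy subjects (trial noise SD = 0.5 x mean response);
  # the median absolute recovery error of each parameter with a published
  # +/- must fall inside that interval
  errs <- sapply(1:20, function(i) {
    cfg <- sim_config(n_vertices = 150, n_subjects = 1, seed = 300 + i)
    s <- simulate_subject(cfg, 1)
    kept <- filter_vertices(s$vertices, s$betas, mode = "2d")$kept
    fit <- fit_2d_model(kept, s$betas, config = opt_config(min_vertices = 30))
    abs(as.numeric(fit$params) - as.numeric(nsd_params("V1")))
  })
  mae <- apply(errs, 1, median)
  names(mae) <- c("sigma", "slope", "intercept", "p1", "p2", "p3", "p4",
                  "A1", "A2")
  expect_lt(mae["sigma"], 0.1)
  expect_lt(mae["slope"], 0.01)
  expect_lt(mae["p1"], 0.04)
  expect_lt(mae["p2"], 0.01)
  expect_lt(mae["A1"], 0.01)
})

test_that("eccentricity binning follows the half-open convention", {
  vx <- data.frame(vertex_id = 1:3, ecc_deg = c(1.0, 2.2, 3.9))
  betas <- expand.grid(vertex_id = 1:3, class_id = nsd_catalog$class_id,
                       trial = 1:2)
  betas$beta <- ifelse(betas$vertex_id == 1, 1, 3)
  bd <- bin_vertices(vx, betas, nsd_catalog)
  expect_equal(sort(unique(bd$bin_center_deg)),
               seq(0.75, 3.75, by = 0.5))            # 7 bins
  expect_equal(length(unique(bd$freq_level)), 6)
  # vertex at 1.0 goes to [1.0, 1.5), not [0.5, 1.0)
  expect_equal(unique(bd$mean_beta[bd$bin_center_deg == 1.25 &
                                     bd$n_vertices > 0]), 1)
  expect_true(all(bd$n_vertices[bd$bin_center_deg == 0.75] == 0))
  # mixtures excluded: bin means come only from the 24 primary classes
  expect_equal(unique(bd$mean_beta[bd$bin_center_deg == 2.25]), 3)
  # toy averaging: two vertices with responses 1 and 3 average to 2
  vx2 <- data.frame(vertex_id = 1:2, ecc_deg = c(2.1, 2.3))
  b2 <- expand.grid(vertex_id = 1:2, class_id = nsd_catalog$class_id,
                    trial = 1:2)
  b2$beta <- ifelse(b2$vertex_id == 1, 1, 3)
  bd2 <- bin_vertices(vx2, b2, nsd_catalog)
  expect_equal(unique(bd2$mean_beta[bd2$n_vertices == 2]), 2)
})

test_that("1D tuning fit recovers generating parameters and separates gain", {
  periods <- 2 * pi * 2.25 / c(6, 11, 20, 37, 69, 128)
  resp <- log_gaussian_response(periods, 1, 0.9, 2.2)
  f <- fit_tuning_1d(periods, resp)
  expect_equal(f$gain_A, 1, tolerance = 1e-3)
  expect_equal(f$p_peak_dpc, 0.9, tolerance = 1e-3)
  expect_equal(f$sigma_oct, 2.2, tolerance = 1e-3)
  # doubling responses doubles the gain only
  f2 <- fit_tuning_1d(periods, 2 * resp)
  expect_equal(f2$gain_A, 2 * f$gain_A, tolerance = 1e-3)
  expect_equal(f2$p_peak_dpc, f$p_peak_dpc, tolerance = 1e-3)
  expect_equal(f2$sigma_oct, f$sigma_oct, tolerance = 1e-3)
  # responses symmetric in log2 period peak at the axis of symmetry
  psym <- 0.7 * 2^seq(-2, 2, by = 1)
  rsym <- c(0.2, 0.6, 1, 0.6, 0.2)
  fs <- fit_tuning_1d(psym, rsym)
  expect_equal(fs$p_peak_dpc, 0.7, tolerance = 1e-6)
  expect_error(fit_tuning_1d(c(1, 2), c(1, 1)), "3 distinct")
})

test_that("period-line fit is exact on affine data", {
  bc <- data.frame(bin_center_deg = c(1, 2, 3),
                   p_peak_dpc = c(0.3, 0.44, 0.58))
  ln <- fit_period_line(bc)
  expect_equal(ln$slope, 0.14, tolerance = 1e-12)
  expect_equal(ln$intercept, 0.16, tolerance = 1e-12)
  flat <- data.frame(bin_center_deg = 1:4, p_peak_dpc = rep(0.5, 4))
  expect_equal(fit_period_line(flat)$slope, 0, tolerance = 1e-12)
  expect_error(fit_period_line(bc[1, , drop = FALSE]), ">= 2 bins")
})

test_that("1D per-bin periods agree with the generating 2D affine law", {
  cfg <- sim_config(n_vertices = 600, noise_sd_scale = 0.2,
                    true_params = list(V1 = sfp_params(sigma = 2.2,
                                                       slope = 0.14,
                                                       intercept = 0.18)),
                    frac_negative = 0, seed = 9)
  s <- simulate_subject(cfg, 1)
  f1 <- filter_vertices(s$vertices, s$betas, nsd_catalog, mode = "1d")
  bd <- bin_vertices(f1$kept, s$betas, nsd_catalog)
  bc <- fit_tuning_bins(bd)
  expected <- 0.14 * bc$bin_center_deg + 0.18
  expect_true(all(abs(bc$p_peak_dpc / expected - 1) < 0.05))
})
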