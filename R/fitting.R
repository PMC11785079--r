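#' Vertex noise variance from repeated trials
#'
#' The noise variance of a vertex, \eqn{\sigma_v^2}, is the sample variance
#' of its beta weights across repeated trials, computed separately within
#' each stimulus class (8 nominal trials per class; ragged counts >= 2 are
#' allowed, e.g. after dropping consecutive repeats) and then averaged over
#' the classes in use: the 24 primary classes for the 1D pathway, all 28 for
#' the 2D loss. Sample variance uses the n-1 denominator.
#'
#' @param betas numeric matrix, classes x trials (NA for absent trials).
#' @param classes_used integer indices of the rows to average over; default
#'   all rows.
#' @return \eqn{\sigma_v^2} (squared percent signal).
#' @export
vertex_variance <- function(betas, classes_used = seq_len(nrow(betas))) {
  betas <- as.matrix(betas)
  sub <- betas[classes_used, , drop = FALSE]
  ntr <- rowSums(!is.na(sub))
  if (any(ntr < 2))
    stop("insufficient trials: every used class needs >= 2 trials")
  mean(apply(sub, 1, stats::var, na.rm = TRUE))
}

#' Precision-weighted, L2-normalized loss for one vertex
#'
#' The per-vertex loss of the 2D map fit: both the observed and predicted
#' 28-vectors are L2-normalized (so only response *pattern*, not overall
#' scale, is fit) and the mean squared difference is weighted by the vertex
#' precision \eqn{1/\sigma_v^2},
#' \deqn{L_v = \frac{1}{\sigma_v^2}\frac{1}{n}\sum_i
#'   \left(\frac{\beta_{iv}}{\|\beta_v\|_2} -
#'         \frac{\hat\beta_{iv}}{\|\hat\beta_v\|_2}\right)^2.}
#'
#' @param beta_v observed beta weights (one value per class, trial means).
#' @param beta_hat_v model predictions, same length.
#' @param variance_v vertex noise variance \eqn{\sigma_v^2}, > 0.
#' @return Scalar loss, >= 0; invariant to positive rescaling of either
#'   argument.
#' @export
normalized_loss <- function(beta_v, beta_hat_v, variance_v) {
  stopifnot(length(beta_v) == length(beta_hat_v), variance_v > 0)
  nb <- sqrt(sum(beta_v^2))
  nh <- sqrt(sum(beta_hat_v^2))
  if (nb == 0 || nh == 0)
    stop("degenerate vertex: zero-norm response vector")
  mean((beta_v / nb - beta_hat_v / nh)^2) / variance_v
}

#' Optimizer configuration for the 2D map fit
#'
#' @param lr Adam learning rate.
#' @param max_iter maximum iterations.
#' @param tol relative-loss-change convergence tolerance.
#' @param patience iterations over which the relative change is measured.
#' @param min_vertices minimum number of vertices required to fit.
#' @return A list of class `sfp_opt_config`.
#' @export
opt_config <- function(lr = 1e-3, max_iter = 20000, tol = 1e-7,
                       patience = 100, min_vertices = 50) {
  structure(list(lr = lr, max_iter = max_iter, tol = tol,
                 patience = patience, min_vertices = min_vertices),
            class = "sfp_opt_config")
}

# --- internal: parameter transforms ---------------------------------------
# Unconstrained internal coordinates mapped to the constrained region:
# sigma, slope, intercept through softplus (slope >= 0 plus intercept > 0
# keeps slope*ecc + intercept > 0 for all ecc >= 0); the period modulations
# through q -> q / (1 + sum|q|), which keeps |p1|+...+|p4| < 1, and likewise
# for (A1, A2).

internal_to_params <- function(u) {
  q <- u[4:7]; s4 <- sum(abs(q))
  qa <- u[8:9]; s2 <- sum(abs(qa))
  p <- q / (1 + s4)
  A <- qa / (1 + s2)
  sfp_params(sigma = softplus(u[1]), slope = softplus(u[2]),
             intercept = softplus(u[3]),
             p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4],
             A1 = A[1], A2 = A[2])
}

params_to_internal <- function(params) {
  p <- c(params$p1, params$p2, params$p3, params$p4)
  s4 <- sum(abs(p))
  if (s4 >= 1) stop("sum |p_i| must be < 1")
  q <- p / (1 - s4)
  A <- c(params$A1, params$A2)
  s2 <- sum(abs(A))
  if (s2 >= 1) stop("|A1| + |A2| must be < 1")
  qa <- A / (1 - s2)
  c(softplus_inv(params$sigma), softplus_inv(max(params$slope, 1e-6)),
    softplus_inv(params$intercept), q, qa)
}

# Jacobian of p = q/(1+sum|q|) wrt q (k x k)
ratio_jacobian <- function(q) {
  s <- sum(abs(q))
  k <- length(q)
  diag(k) / (1 + s) - outer(q, sign(q)) / (1 + s)^2
}

# --- internal: design matrices for a set of vertices ----------------------
# Local stimulus values at each vertex's pRF center for each catalog class:
# log2 local period, cos(2 theta_l), cos(4 theta_l), and the relative-angle
# cosines (constant per class since theta_l - theta_v = atan2(wa, wr)).
build_design <- function(ecc_deg, angle_rad, catalog) {
  if (any(ecc_deg <= 0)) stop("vertex eccentricity must be > 0 for fitting")
  n <- length(ecc_deg)
  base <- catalog$base_frequency
  rel <- atan2(catalog$omega_a, catalog$omega_r)       # theta_l - theta_v
  theta_l <- outer(angle_rad, rel, `+`)                # n x k
  period <- outer(2 * pi * ecc_deg, base, `/`)         # deg/cycle
  list(n = n, k = nrow(catalog),
       ecc = ecc_deg,
       log2_period = log2(period),
       C1 = cos(2 * theta_l), C2 = cos(4 * theta_l),
       C3 = matrix(cos(2 * rel), n, length(rel), byrow = TRUE),
       C4 = matrix(cos(4 * rel), n, length(rel), byrow = TRUE))
}

# predicted beta matrix (n x k) under params for a design
predict_matrix <- function(params, des) {
  M <- 1 + params$p1 * des$C1 + params$p2 * des$C2 +
    params$p3 * des$C3 + params$p4 * des$C4
  B <- params$slope * des$ecc + params$intercept
  log2_pv <- log2(B) + log2(M)
  G <- 1 + params$A1 * des$C1 + params$A2 * des$C2
  d <- des$log2_period - log2_pv
  G * exp(-d^2 / (2 * params$sigma^2))
}

# --- internal: loss + analytic gradient in internal coordinates -----------
# X: row-L2-normalized observed beta matrix (n x k); w: 1/sigma_v^2
map_loss_grad <- function(u, des, X, w, grad = TRUE) {
  params <- internal_to_params(u)
  sg <- params$sigma; a <- params$slope; b <- params$intercept
  B <- a * des$ecc + b
  M <- 1 + params$p1 * des$C1 + params$p2 * des$C2 +
    params$p3 * des$C3 + params$p4 * des$C4
  G <- 1 + params$A1 * des$C1 + params$A2 * des$C2
  d <- des$log2_period - (log(B) + log(M)) * log2e
  E <- exp(-d^2 / (2 * sg^2))
  Y <- G * E
  ny <- sqrt(rowSums(Y^2))
  U <- Y / ny
  res <- X - U
  m <- des$n; k <- des$k
  loss <- mean(w * rowSums(res^2) / k)
  if (!grad) return(list(loss = loss, params = params))

  # dL/dY through the row normalization: for each vertex,
  # g = -(2 w / (m k ny)) * (res - U * (U . res))
  udotres <- rowSums(U * res)
  g <- -(2 * w / (m * k * ny)) * (res - U * udotres)

  T_ <- g * Y * d / sg^2          # shared factor for period-path gradients
  rowT <- rowSums(T_)
  grad_sigma <- sum(g * Y * d^2) / sg^3
  grad_a <- sum(rowT * des$ecc / (B * log(2)))
  grad_b <- sum(rowT / (B * log(2)))
  grad_p <- c(sum(T_ * des$C1 / (M * log(2))),
              sum(T_ * des$C2 / (M * log(2))),
              sum(T_ * des$C3 / (M * log(2))),
              sum(T_ * des$C4 / (M * log(2))))
  grad_A <- c(sum(g * des$C1 * E), sum(g * des$C2 * E))

  # chain through the reparameterization
  gu <- numeric(9)
  gu[1] <- grad_sigma * sigmoid(u[1])
  gu[2] <- grad_a * sigmoid(u[2])
  gu[3] <- grad_b * sigmoid(u[3])
  gu[4:7] <- as.numeric(grad_p %*% ratio_jacobian(u[4:7]))
  gu[8:9] <- as.numeric(grad_A %*% ratio_jacobian(u[8:9]))
  list(loss = loss, grad = gu, params = params)
}

# --- internal: summarize a long beta table into matrices ------------------
# betas: data.frame(vertex_id, class_id, trial, beta); returns trial-mean
# matrix (vertices x classes, catalog order) and per-class trial variances.
beta_tables <- function(vertex_ids, betas, catalog) {
  dt <- data.table::as.data.table(betas)
  dt <- dt[dt$vertex_id %in% vertex_ids & dt$class_id %in% catalog$class_id, ]
  agg <- dt[, list(mu = mean(beta), v = stats::var(beta), ntr = .N),
            by = c("vertex_id", "class_id")]
  if (any(agg$ntr < 2))
    stop("insufficient trials: every (vertex, class) needs >= 2 trials")
  mu <- data.table::dcast(agg, vertex_id ~ class_id, value.var = "mu")
  vv <- data.table::dcast(agg, vertex_id ~ class_id, value.var = "v")
  ord <- match(vertex_ids, mu$vertex_id)
  if (any(is.na(ord))) stop("betas missing for some vertices")
  cls <- as.character(catalog$class_id)
  if (!all(cls %in% names(mu))) stop("betas missing for some catalog classes")
  list(mean = as.matrix(mu[ord, cls, with = FALSE]),
       var = as.matrix(vv[ord, cls, with = FALSE]))
}

#' Fit the 9-parameter 2D model to all vertices of a map
#'
#' Minimizes the mean over vertices of the precision-weighted, L2-normalized
#' loss ([normalized_loss()]) with the Adam first-order gradient method on
#' analytically differentiated, reparameterized (positivity-respecting)
#' internal coordinates. The whole map is fit at once: a single bandwidth and
#' one affine eccentricity dependence shared by every vertex. Local stimulus
#' period and orientation are evaluated at each vertex's pRF center from the
#' stimulus catalog. Deterministic given (data, init, config).
#'
#' @param vertices data.frame with columns `vertex_id`, `ecc_deg`,
#'   `angle_rad` (plus anything else, ignored). Vertices should already be
#'   filtered (see [filter_vertices()]).
#' @param betas long data.frame (`vertex_id`, `class_id`, `trial`, `beta`).
#' @param catalog stimulus catalog, default [make_catalog()] (all 28 classes
#'   enter the loss and the vertex variance).
#' @param init initial parameters ([sfp_params()]); defaults near published
#'   group values with orientation terms 0.
#' @param config an [opt_config()].
#' @param seed recorded in the result for provenance (the fit itself is
#'   deterministic).
#' @return An object of class `sfp_fit`: `params` (sfp_params),
#'   `final_loss`, `loss_trace`, `n_vertices_used`, `n_iter`, `seed`,
#'   `converged`, and `sigma_v2` (per-vertex variances, for precision
#'   weighting downstream).
#' @export
fit_2d_model <- function(vertices, betas, catalog = make_catalog(),
                         init = sfp_params(sigma = 2, slope = 0.1,
                                           intercept = 0.3),
                         config = opt_config(), seed = 0L) {
  stopifnot(inherits(config, "sfp_opt_config"))
  if (nrow(vertices) < config$min_vertices)
    stop(sprintf("need >= %d vertices to fit (got %d)",
                 config$min_vertices, nrow(vertices)))
  tabs <- beta_tables(vertices$vertex_id, betas, catalog)
  sigma_v2 <- rowMeans(tabs$var)
  # noiseless (zero-variance) vertices carry effectively infinite precision;
  # floor the variance so the weights stay finite (Adam is invariant to the
  # overall loss scale, so an all-noiseless map fits identically to uniform
  # weighting)
  sigma_v2 <- pmax(sigma_v2, 1e-12)
  norms <- sqrt(rowSums(tabs$mean^2))
  if (any(norms == 0)) stop("degenerate vertex: zero-norm response vector")
  X <- tabs$mean / norms
  w <- 1 / sigma_v2
  des <- build_design(vertices$ecc_deg, vertices$angle_rad, catalog)

  u <- params_to_internal(init)
  mom <- numeric(9); vel <- numeric(9)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(config$max_iter)
  converged <- FALSE
  it <- 0
  for (it in seq_len(config$max_iter)) {
    lg <- map_loss_grad(u, des, X, w)
    trace[it] <- lg$loss
    mom <- b1 * mom + (1 - b1) * lg$grad
    vel <- b2 * vel + (1 - b2) * lg$grad^2
    mhat <- mom / (1 - b1^it)
    vhat <- vel / (1 - b2^it)
    u <- u - config$lr * mhat / (sqrt(vhat) + eps)
    if (it > config$patience) {
      prev <- trace[it - config$patience]
      if (abs(prev - trace[it]) / max(abs(prev), 1e-12) < config$tol) {
        converged <- TRUE
        break
      }
    }
  }
  final <- map_loss_grad(u, des, X, w, grad = FALSE)
  structure(list(params = final$params, final_loss = final$loss,
                 loss_trace = trace[seq_len(it)],
                 n_vertices_used = nrow(vertices), n_iter = it,
                 seed = as.integer(seed), converged = converged,
                 sigma_v2 = sigma_v2),
            class = "sfp_fit")
}

#' @export
print.sfp_fit <- function(x, ...) {
  cat(sprintf("<sfp_fit: %d vertices, %d iterations, loss %.4g, %s>\n",
              x$n_vertices_used, x$n_iter, x$final_loss,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' Write a fitted model and its fit report
#'
#' Writes the parameter JSON (interchange key set `sigma, slope, intercept,
#' p1..p4, A1, A2`) and a sidecar report (`loss`, `n_vertices`, `seed`,
#' `iterations`, `converged`).
#'
#' @param fit an `sfp_fit`.
#' @param path path of the parameter JSON; the report goes to
#'   `<path>` with suffix `_report.json`.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "sfp_fit"))
  write_params(fit$params, path)
  report <- list(loss = fit$final_loss, n_vertices = fit$n_vertices_used,
                 seed = fit$seed, iterations = fit$n_iter,
                 converged = fit$converged)
  jsonlite::write_json(report, sub("\\.json$", "_report.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Eccentricity-binned mean responses by base frequency
#'
#' The 1D pathway averages responses over trials, over the vertices inside
#' each eccentricity bin, and over the four primary stimulus shapes (annuli,
#' pinwheels, forward/reverse spirals) at each of the six base-frequency
#' levels; mixture classes are excluded. Bins are half-open `[left, right)`
#' except the last, which is closed. The local spatial period attributed to
#' each (bin, level) cell is evaluated at the bin center using the geometric
#' mean of the four shapes' base frequencies at that level (the integer
#' constraint on angular frequency makes the levels match only
#' approximately).
#'
#' @param vertices data.frame with `vertex_id`, `ecc_deg`.
#' @param betas long beta table (`vertex_id`, `class_id`, `trial`, `beta`).
#' @param catalog stimulus catalog ([make_catalog()]).
#' @param bin_edges strictly increasing bin edges in degrees; default the
#'   0.5-degree steps from 0.5 to 4 used for the NSD eccentricity range.
#' @return data.frame with one row per (bin, frequency level):
#'   `bin_center_deg`, `freq_level`, `base_frequency` (geometric mean),
#'   `period_dpc` (at bin center), `mean_beta`, `n_vertices`. Empty bins are
#'   reported with `n_vertices = 0` and NA responses.
#' @export
bin_vertices <- function(vertices, betas, catalog,
                         bin_edges = seq(0.5, 4, by = 0.5)) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  primary <- catalog[catalog$shape != "mixture", ]
  # frequency level = rank of base frequency within each shape
  lev <- stats::ave(primary$base_frequency, primary$shape,
                    FUN = function(b) rank(b))
  level_map <- data.frame(class_id = primary$class_id, freq_level = lev)
  gm_base <- tapply(primary$base_frequency, lev,
                    function(b) exp(mean(log(b))))

  dt <- data.table::as.data.table(betas)
  dt <- dt[dt$class_id %in% primary$class_id, ]
  dt <- merge(dt, data.table::as.data.table(level_map), by = "class_id")
  vx <- data.table::as.data.table(vertices[, c("vertex_id", "ecc_deg")])
  dt <- merge(dt, vx, by = "vertex_id")
  # half-open [left, right), last bin closed
  dt$bin <- findInterval(dt$ecc_deg, bin_edges, rightmost.closed = TRUE)
  dt <- dt[dt$bin >= 1 & dt$bin < length(bin_edges), ]
  # average over trials per (vertex, class), then over vertices and shapes
  per_vc <- dt[, list(mu = mean(beta)),
               by = c("bin", "freq_level", "vertex_id", "class_id")]
  cell <- per_vc[, list(mean_beta = mean(mu),
                        n_vertices = length(unique(vertex_id))),
                 by = c("bin", "freq_level")]

  centers <- (bin_edges[-length(bin_edges)] + bin_edges[-1]) / 2
  grid <- expand.grid(bin = seq_along(centers),
                      freq_level = sort(unique(level_map$freq_level)))
  out <- merge(grid, as.data.frame(cell), by = c("bin", "freq_level"),
               all.x = TRUE)
  out$n_vertices[is.na(out$n_vertices)] <- 0L
  out$bin_center_deg <- centers[out$bin]
  out$base_frequency <- as.numeric(gm_base[as.character(out$freq_level)])
  out$period_dpc <- 2 * pi * out$bin_center_deg / out$base_frequency
  out[order(out$bin, out$freq_level),
      c("bin", "bin_center_deg", "freq_level", "base_frequency",
        "period_dpc", "mean_beta", "n_vertices")]
}

#' Fit a 1D log-Gaussian tuning curve to one eccentricity bin
#'
#' Least-squares fit of gain, preferred period and octave bandwidth to the
#' (period, mean response) points of one bin, with period and bandwidth kept
#' positive by optimizing in log coordinates (BFGS).
#'
#' @param period_dpc local spatial periods (deg/cycle) of the data points.
#' @param response mean responses (percent signal).
#' @return list with `gain_A`, `p_peak_dpc`, `sigma_oct`, `fwhm_oct`, `sse`,
#'   `converged`, `flagged` (TRUE for degenerate/near-constant data).
#' @export
fit_tuning_1d <- function(period_dpc, response) {
  ok <- is.finite(period_dpc) & is.finite(response)
  period_dpc <- period_dpc[ok]; response <- response[ok]
  if (length(unique(period_dpc)) < 3)
    stop("need >= 3 distinct periods to fit a tuning curve")
  flagged <- stats::sd(response) < 1e-12
  i0 <- which.max(response)
  par0 <- c(log(max(response[i0], 1e-3)), log(period_dpc[i0]), log(2))
  sse <- function(par) {
    pred <- exp(par[1]) *
      exp(-(log2(period_dpc) - par[2] / log(2))^2 / (2 * exp(2 * par[3])))
    sum((response - pred)^2)
  }
  opt <- stats::optim(par0, sse, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(gain_A = exp(opt$par[1]), p_peak_dpc = exp(opt$par[2]),
       sigma_oct = exp(opt$par[3]),
       fwhm_oct = fwhm_octaves(exp(opt$par[3])),
       sse = opt$value, converged = opt$convergence == 0, flagged = flagged)
}

#' Fit tuning curves for every eccentricity bin
#'
#' @param bin_data output of [bin_vertices()].
#' @param min_levels minimum distinct frequency levels with data per bin.
#' @return data.frame, one row per non-empty bin: `bin_center_deg`,
#'   `gain_A`, `p_peak_dpc`, `sigma_oct`, `fwhm_oct`, `n_vertices`,
#'   `flagged`.
#' @export
fit_tuning_bins <- function(bin_data, min_levels = 3) {
  out <- list()
  for (b in sort(unique(bin_data$bin))) {
    sub <- bin_data[bin_data$bin == b & bin_data$n_vertices > 0 &
                      is.finite(bin_data$mean_beta), ]
    if (nrow(sub) < min_levels) next
    f <- fit_tuning_1d(sub$period_dpc, sub$mean_beta)
    out[[length(out) + 1]] <- data.frame(
      bin = b, bin_center_deg = sub$bin_center_deg[1], gain_A = f$gain_A,
      p_peak_dpc = f$p_peak_dpc, sigma_oct = f$sigma_oct,
      fwhm_oct = f$fwhm_oct, n_vertices = max(sub$n_vertices),
      flagged = f$flagged)
  }
  if (!length(out)) stop("no bins with enough data to fit")
  do.call(rbind, out)
}

#' Line fit of preferred period against eccentricity
#'
#' Ordinary least squares of per-bin preferred period on bin-center
#' eccentricity, summarizing how spatial period grows across the map.
#'
#' @param bin_curves output of [fit_tuning_bins()] (needs `bin_center_deg`
#'   and `p_peak_dpc`).
#' @return list with `slope` (deg/cycle per deg) and `intercept`
#'   (deg/cycle).
#' @export
fit_period_line <- function(bin_curves) {
  if (nrow(bin_curves) < 2) stop("need >= 2 bins for a line fit")
  co <- stats::coef(stats::lm(p_peak_dpc ~ bin_center_deg, data = bin_curves))
  list(slope = unname(co[2]), intercept = unname(co[1]))
}
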