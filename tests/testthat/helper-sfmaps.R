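# shared fixtures and independent oracles, built in code

nsd_catalog <- make_catalog()

# scalar, loop-based re-implementation of the per-vertex normalized loss,
# written directly from the definition; independent of the vectorized path
loop_map_loss <- function(beta_mat, pred_mat, sigma_v2) {
  m <- nrow(beta_mat)
  total <- 0
  for (v in seq_len(m)) {
    b <- beta_mat[v, ]
    p <- pred_mat[v, ]
    nb <- sqrt(sum(b * b))
    np <- sqrt(sum(p * p))
    acc <- 0
    for (i in seq_along(b))
      acc <- acc + (b[i] / nb - p[i] / np)^2
    total <- total + acc / (length(b) * sigma_v2[v])
  }
  total / m
}

# small noisy subject for fitting tests (kept cheap; seeds fixed)
small_subject <- function(n_vertices = 150, noise = 0.5, seed = 7,
                          params = nsd_params("V1"), frac_negative = 0.02) {
  cfg <- sim_config(n_vertices = n_vertices, noise_sd_scale = noise,
                    true_params = list(V1 = params),
                    frac_negative = frac_negative, seed = seed)
  simulate_subject(cfg, 1)
}

# hand-built toy vertex table exercising each exclusion rule once
toy_filter_fixture <- function() {
  vertices <- data.frame(
    vertex_id = 1:5,
    roi = "V1",
    ecc_deg = c(2.0, 0.3, 5.0, 1.0, 4.5),
    angle_rad = 0,
    prf_size_deg = c(0.5, 0.2, 0.5, 0.3, 0.5))
  grid <- expand.grid(vertex_id = 1:5, class_id = nsd_catalog$class_id,
                      trial = 1:2)
  grid$beta <- 1
  grid$beta[grid$vertex_id == 1] <- -1   # all-negative responder
  list(vertices = vertices, betas = grid)
}
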