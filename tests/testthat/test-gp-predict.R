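test_that("a constant voxel predicts the constant everywhere", {
  sch <- make_scheme(12, 1500, seed = 1)
  vox <- voxel_signal(rep(42, sch$n_dwi), sch)
  hy <- gp_hyper("spherical", lam = 2, a = 1.2, sigma2 = 0.3)
  q <- gp_queries(rbind(c(0, 0, 1), c(1, 1, 1) / sqrt(3)), 1500)
  expect_equal(as.numeric(predict_mean(vox, hy, q)), c(42, 42))
})

test_that("noise-free conditioning passes exactly through the training points", {
  sch <- make_scheme(25, 2000, seed = 2)
  vox <- simulate_voxel(list(fiber_population(c(1, 0, 1) / sqrt(2), 0.6)),
                        0.8e-3, 1000, sch)
  hy <- gp_hyper("spherical", lam = stats::var(vox$values), a = 1.23, sigma2 = 0)
  q <- gp_queries(sch$directions[sch$dwi_index, ], 2000)
  pred <- predict_mean(vox, hy, q)
  expect_equal(as.numeric(pred), vox$values, tolerance = 1e-8)
  v <- suppressWarnings(predict_variance(vox, hy, q))
  expect_true(all(v < 1e-6 * hy$lam))
})

test_that("predictive mean and variance match direct MVN conditioning", {
  set.seed(42)
  for (rep in 1:20) {
    multi <- rep %% 2 == 0
    sch <- if (multi) rand_scheme(c(4, 4), c(1500, 3000)) else rand_scheme(8, 2000)
    hy <- rand_hyper(sch, sample(c("spherical", "exponential"), 1))
    y <- rnorm(sch$n_dwi)
    qdirs <- random_directions_helper(3)
    qb <- sample(sch$shell_bvalues, 3, replace = TRUE)
    vox <- voxel_signal(y, sch)
    ydem <- y - vox$shell_means[sch$shell_ids[sch$dwi_index]]
    oracle <- mvn_conditioning_oracle(sch, hy, ydem, qdirs, qb)
    q <- gp_queries(qdirs, qb)
    m <- as.numeric(predict_mean(vox, hy, q)) -
      restore_means_helper(vox, qb)
    v <- predict_variance(vox, hy, q)
    expect_equal(m, oracle$mean, tolerance = 1e-8)
    expect_equal(v, oracle$var, tolerance = 1e-8)
    expect_true(all(v >= 0 & v <= hy$lam + 1e-12))
  }
})

test_that("predictions are axially symmetric and rotation equivariant", {
  set.seed(9)
  sch <- rand_scheme(c(6, 6), c(1500, 3000))
  hy <- rand_hyper(sch)
  vox <- voxel_signal(rnorm(sch$n_dwi, sd = 2), sch)
  g <- random_directions_helper(4)
  m_pos <- predict_mean(vox, hy, gp_queries(g, 1500))
  m_neg <- predict_mean(vox, hy, gp_queries(-g, 1500))
  expect_identical(as.numeric(m_pos), as.numeric(m_neg))

  # joint rotation of training + query directions leaves predictions unchanged
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); ang <- runif(1, 0, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  sch_rot <- sch
  sch_rot$directions <- sch$directions %*% t(R)
  vox_rot <- voxel_signal(vox$values, sch_rot)
  m_rot <- predict_mean(vox_rot, hy, gp_queries(g %*% t(R), 1500))
  expect_equal(as.numeric(m_rot), as.numeric(m_pos), tolerance = 1e-8)
})

test_that("prediction is linear in the training values", {
  set.seed(10)
  sch <- rand_scheme(10, 1500)
  hy <- rand_hyper(sch)
  y1 <- rnorm(sch$n_dwi); y2 <- rnorm(sch$n_dwi)
  q <- gp_queries(random_directions_helper(5), 1500)
  p1 <- as.numeric(predict_mean(voxel_signal(y1, sch), hy, q))
  p2 <- as.numeric(predict_mean(voxel_signal(y2, sch), hy, q))
  p12 <- as.numeric(predict_mean(voxel_signal(2 * y1 + 3 * y2, sch), hy, q))
  expect_equal(p12, 2 * p1 + 3 * p2, tolerance = 1e-10)
})

test_that("predictive variance ignores the observed values", {
  set.seed(11)
  sch <- rand_scheme(9, 1500)
  hy <- rand_hyper(sch)
  q <- gp_queries(random_directions_helper(3), 1500)
  v1 <- predict_variance(voxel_signal(rnorm(sch$n_dwi), sch), hy, q)
  v2 <- predict_variance(voxel_signal(rnorm(sch$n_dwi, 100, 30), sch), hy, q)
  expect_identical(v1, v2)
})

test_that("query validation rejects bad b-values and length mismatches", {
  sch <- make_scheme(6, 1500, seed = 3)
  vox <- voxel_signal(rnorm(6), sch)
  hy <- gp_hyper("spherical", 1, 1, sigma2 = 0.1)
  expect_error(gp_queries(c(0, 0, 1), 0), class = "dwigp_invalid_input")
  expect_error(gp_queries(rbind(c(0, 0, 1), c(1, 0, 0)), c(1500, 1500, 1500)),
               class = "dwigp_invalid_input")
  # off-shell queries are allowed but flagged
  p <- predict_mean(vox, hy, gp_queries(c(0, 0, 1), 900))
  expect_true(attr(p, "extrapolated"))
})

test_that("volume prediction: interpolation equals the reduced-system prediction", {
  sch <- make_scheme(15, 1500, n_b0 = 1, seed = 4)
  ph <- make_phantom(6, c("wm1", "gm"), sch, noise_spec("gaussian", 10),
                     seed = 8)
  target <- 5   # a DWI volume (volume 1 is b0)
  pred <- predict_volume(ph$volumes, sch, gp_hyper("spherical", 5000, 1.23,
                                                   sigma2 = 100),
                         target, mode = "interpolation", mask = ph$mask)
  # manual reduced-system prediction for one voxel
  vpos <- which(ph$mask, arr.ind = TRUE)[3, ]
  yfull <- ph$volumes[vpos[1], vpos[2], vpos[3], ]
  tgt_dwi <- match(target, sch$dwi_index)
  sub <- scheme_subset(sch, setdiff(seq_len(sch$n_dwi), tgt_dwi))
  vox <- voxel_signal(yfull[sch$dwi_index][-tgt_dwi], sub)
  manual <- predict_mean(vox, gp_hyper("spherical", 5000, 1.23, sigma2 = 100),
                         gp_queries(sch$directions[target, ], sch$bvalues[target]))
  expect_equal(pred[vpos[1], vpos[2], vpos[3]], as.numeric(manual),
               tolerance = 1e-10)
  expect_true(is.na(pred[which(!ph$mask)[1]]))
  expect_error(predict_volume(ph$volumes, sch, gp_hyper("spherical", 1, 1,
                                                        sigma2 = 0.1),
                              1, mode = "smoothing"),
               class = "dwigp_invalid_input")  # b0 target
})

test_that("smoothing with sigma2 = 0 reproduces GP-consistent noise-free data", {
  sch <- make_scheme(12, 1500, n_b0 = 1, seed = 6)
  hy0 <- gp_hyper("spherical", lam = 4, a = 1.3, sigma2 = 1e-10)
  f <- sample_prior(sch, hy0, n_draws = 4, seed = 21, mean = 50)
  vols <- array(0, dim = c(2, 2, 1, length(sch$bvalues)))
  for (v in 1:4) {   # voxel v carries prior draw v; b0 volumes get a constant
    xy <- arrayInd(v, c(2, 2, 1))
    vols[xy[1], xy[2], 1, sch$dwi_index] <- f[v, ]
    vols[xy[1], xy[2], 1, sch$is_b0] <- 60
  }
  pred <- predict_volume(vols, sch, hy0, target_index = 5, mode = "smoothing")
  for (v in 1:4) {
    xy <- arrayInd(v, c(2, 2, 1))
    expect_equal(pred[xy[1], xy[2], 1], vols[xy[1], xy[2], 1, 5],
                 tolerance = 1e-6)
  }
})

test_that("GP interpolation beats the log-linear tensor fit on crossing fibres", {
  sch <- make_scheme(40, 3000, n_b0 = 1, seed = 12, method = "repulsion")
  ph <- make_phantom(10, "wm3_crossing", sch, noise_spec("gaussian", 15),
                     seed = 13, s0 = 1000)
  hy <- gp_hyper("spherical", lam = 4000, a = 1.23, sigma2 = 15^2)
  targets <- sch$dwi_index[c(4, 17, 30)]
  err_gp <- err_tensor <- c()
  for (tg in targets) {
    pred <- predict_volume(ph$volumes, sch, hy, tg, mode = "interpolation",
                           mask = ph$mask)
    vox_idx <- which(ph$mask)
    truth_mat <- matrix(ph$truth, prod(dim(ph$truth)[1:3]),
                        dim(ph$truth)[4])
    obs_mat <- matrix(ph$volumes, prod(dim(ph$volumes)[1:3]),
                      dim(ph$volumes)[4])
    err_gp <- c(err_gp, pred[vox_idx] - truth_mat[vox_idx, tg])
    t_pred <- vapply(vox_idx, function(v)
      tensor_predict_loo(obs_mat[v, ], sch, tg), numeric(1))
    err_tensor <- c(err_tensor, t_pred - truth_mat[vox_idx, tg])
  }
  expect_lt(sqrt(mean(err_gp^2)), sqrt(mean(err_tensor^2)))
})

test_that("prior draws are reproducible, zero-mean and K-distributed", {
  sch <- make_scheme(c(6, 6), c(1500, 3000), seed = 14)
  hy <- gp_hyper("spherical", lam = 3, a = 1.2, ell = 1, sigma2 = c(0.1, 0.1))
  d1 <- sample_prior(sch, hy, 5, seed = 99)
  d2 <- sample_prior(sch, hy, 5, seed = 99)
  expect_identical(d1, d2)
  expect_error(sample_prior(sch, hy, 0), class = "dwigp_invalid_input")

  draws <- sample_prior(sch, hy, 10000, seed = 100)
  expect_true(all(abs(colMeans(draws)) < 4 * sqrt(hy$lam / 10000)))
})

test_that("subsampling a shell degrades gracefully and support helps", {
  sch <- make_scheme(c(60, 60), c(3000, 5000), n_b0 = 1, seed = 15,
                     method = "repulsion")
  vox_nf <- make_phantom(1, "wm2_crossing", sch, noise_spec("none"), seed = 16)
  y <- vox_nf$volumes[1, 1, 1, ]
  noisy <- add_noise(as.numeric(y), noise_spec("gaussian", 5, seed = 17))
  vox <- voxel_signal(noisy, sch)
  hy <- gp_hyper("spherical", lam = stats::var(vox$values), a = 1.23, ell = 1,
                 sigma2 = c(25, 25))
  truth <- y[sch$dwi_index][sch$shell_ids[sch$dwi_index] == 2]
  res <- shell_subsample_experiment(vox, hy, target_shell = 2,
                                    n_points_list = c(10, 30, 60),
                                    support_shells = 1, truth = truth)
  expect_named(res, c("n_points", "support", "rmse"))
  expect_equal(nrow(res), 6)
  for (s in unique(res$support)) {
    r <- res$rmse[res$support == s][order(res$n_points[res$support == s])]
    expect_true(all(diff(r) < 5))   # non-increasing within noise
  }
  expect_error(shell_subsample_experiment(vox, hy, 2, 1000, 1),
               class = "dwigp_invalid_input")
})
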