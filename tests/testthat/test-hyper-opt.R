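test_that("log marginal likelihood matches closed forms and the explicit-inverse oracle", {
  # K_y = I: pick lam C + sigma2 I = I via well-separated directions, tiny a
  sch <- gradient_scheme(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                               c(1, 1, 1) / sqrt(3)), rep(1500, 4))
  k <- assemble_K(sch, gp_hyper("spherical", lam = 0.5, a = 1e-3, sigma2 = 0.5))
  expect_equal(k$K_y, diag(4))
  expect_equal(log_marginal_likelihood(rep(0, 4), k), -2 * log(2 * pi))

  # n = 1: the scalar Gaussian log density
  sch1 <- gradient_scheme(rbind(c(0, 0, 1)), 1500)
  k1 <- assemble_K(sch1, gp_hyper("spherical", lam = 2, a = 1, sigma2 = 0.5))
  y1 <- 0.7
  expect_equal(log_marginal_likelihood(y1, k1),
               dnorm(y1, 0, sqrt(2.5), log = TRUE))

  # random instances vs direct evaluation with explicit inverse/determinant
  set.seed(21)
  for (rep in 1:5) {
    sch5 <- rand_scheme(5, 1500)
    hy <- rand_hyper(sch5)
    k5 <- assemble_K(sch5, hy)
    y <- rnorm(5)
    direct <- -0.5 * t(y) %*% solve(k5$K_y) %*% y -
      0.5 * log(det(k5$K_y)) - 2.5 * log(2 * pi)
    expect_equal(log_marginal_likelihood(y, k5), as.numeric(direct),
                 tolerance = 1e-10)
  }
  expect_error(log_marginal_likelihood(rnorm(3), k5),
               class = "dwigp_invalid_input")
})

test_that("summed objective adds per-voxel criteria and is order invariant", {
  set.seed(22)
  sch <- rand_scheme(10, 1500)
  hy <- gp_hyper("spherical", lam = 2, a = 1.1, sigma2 = 0.3)
  beta <- hyper_to_vector(hy)
  Y <- matrix(rnorm(30), 10, 3)
  spec <- objective_spec(Y, sch)
  single <- vapply(1:3, function(j)
    summed_objective(objective_spec(Y[, j, drop = FALSE], sch), beta),
    numeric(1))
  expect_equal(summed_objective(spec, beta), sum(single), tolerance = 1e-10)
  # identical voxels: V times the single-voxel value
  specV <- objective_spec(Y[, c(1, 1, 1, 1)], sch)
  expect_equal(summed_objective(specV, beta), 4 * single[1], tolerance = 1e-10)
  # voxel order is irrelevant
  expect_equal(summed_objective(objective_spec(Y[, 3:1], sch), beta),
               summed_objective(spec, beta))
  # invalid beta is optimiser-safe
  expect_identical(summed_objective(spec, c(1e6, 1e6, 1e6)), -Inf)
})

test_that("closed-form LOO equals hand algebra on a symmetric 2-point system", {
  sch <- gradient_scheme(rbind(c(1, 0, 0), c(0, 1, 0)), c(1500, 1500))
  # theta = pi/2; spherical a = 2: C = 1 - 3*(pi/2)/4 + (pi/2)^3/16
  a <- 2; lam <- 3; s2 <- 0.5
  co <- lam * (1 - 3 * (pi / 2) / (2 * a) + (pi / 2)^3 / (2 * a^3))
  k <- assemble_K(sch, gp_hyper("spherical", lam, a, sigma2 = s2))
  y <- c(1.2, -0.4)
  # leaving out point i, the GP predicts co/(lam+s2) * y_other with variance
  # lam - co^2/(lam+s2) (+ s2 observation noise)
  mu <- co / (lam + s2) * rev(y)
  v <- lam - co^2 / (lam + s2) + s2
  res <- loo_criteria(y, k)
  expect_equal(res$cv, mean((y - mu)^2), tolerance = 1e-12)
  expect_equal(res$gpp, mean(dnorm(y, mu, sqrt(v), log = TRUE)),
               tolerance = 1e-12)
})

test_that("closed-form LOO equals the naive refit-per-point oracle", {
  set.seed(23)
  for (rep in 1:6) {
    multi <- rep > 3
    sch <- if (multi) rand_scheme(c(4, 4), c(1500, 3000)) else rand_scheme(7, 1500)
    hy <- rand_hyper(sch, sample(c("spherical", "exponential"), 1))
    y <- rnorm(sch$n_dwi)
    k <- assemble_K(sch, hy)
    res <- loo_criteria(y, k)
    oracle <- naive_loo_oracle(sch, hy, y)
    expect_equal(res$cv, oracle$cv, tolerance = 1e-8)
    expect_equal(res$gpp, oracle$gpp, tolerance = 1e-8)
  }
})

test_that("fitting is deterministic and keeps a non-decreasing best trace", {
  set.seed(24)
  sch <- make_scheme(20, 1500, seed = 31)
  hy0 <- gp_hyper("spherical", lam = 4, a = 1.2, sigma2 = 0.4)
  Y <- gp_consistent_voxels(sch, hy0, 30, seed = 32, noise_sd = sqrt(0.4))
  spec <- objective_spec(Y, sch)
  f1 <- fit_hyperparameters(spec, restarts = 2, seed = 77)
  f2 <- fit_hyperparameters(spec, restarts = 2, seed = 77)
  expect_identical(f1$hyper, f2$hyper)
  expect_identical(f1$objective_value, f2$objective_value)
  expect_true(all(diff(f1$trace) >= 0))
  expect_equal(f1$objective_value,
               summed_objective(spec, hyper_to_vector(f1$hyper)))
  expect_true(f1$converged)
})

test_that("fitted scales are equivariant under rescaling of the data", {
  set.seed(25)
  sch <- make_scheme(24, 1500, seed = 41)
  hy0 <- gp_hyper("spherical", lam = 4, a = 1.0, sigma2 = 0.4)
  Y <- gp_consistent_voxels(sch, hy0, 40, seed = 42, noise_sd = sqrt(0.4))
  f1 <- fit_hyperparameters(objective_spec(Y, sch), seed = 1)
  s <- 3
  f2 <- fit_hyperparameters(objective_spec(s * Y, sch), seed = 1)
  expect_equal(f2$hyper$lam, s^2 * f1$hyper$lam, tolerance = 0.02)
  expect_equal(f2$hyper$sigma2, s^2 * f1$hyper$sigma2, tolerance = 0.02)
  expect_equal(f2$hyper$a, f1$hyper$a, tolerance = 0.02)
})

test_that("the likelihood surface is unimodal along axes near a recovered optimum", {
  set.seed(26)
  sch <- make_scheme(30, 1500, seed = 51)
  hy0 <- gp_hyper("spherical", lam = 4, a = 1.2, sigma2 = 0.4)
  Y <- gp_consistent_voxels(sch, hy0, 50, seed = 52, noise_sd = sqrt(0.4))
  spec <- objective_spec(Y, sch)
  fit <- fit_hyperparameters(spec, seed = 2)
  b0 <- hyper_to_vector(fit$hyper)
  for (kdim in 1:3) {
    grid <- seq(-1, 1, length.out = 9)
    vals <- vapply(grid, function(d) {
      b <- b0; b[kdim] <- b[kdim] + d
      summed_objective(spec, b)
    }, numeric(1))
    pk <- which.max(vals)
    expect_true(all(diff(vals[seq_len(pk)]) >= 0))
    expect_true(all(diff(vals[pk:length(vals)]) <= 0))
  }
})

test_that("CV and GPP criteria also recover sensible hyperparameters", {
  set.seed(27)
  sch <- make_scheme(24, 1500, seed = 61)
  hy0 <- gp_hyper("spherical", lam = 4, a = 1.1, sigma2 = 0.4)
  Y <- gp_consistent_voxels(sch, hy0, 40, seed = 62, noise_sd = sqrt(0.4))
  for (crit in c("cv", "gpp")) {
    fit <- fit_hyperparameters(objective_spec(Y, sch, criterion = crit),
                               seed = 3)
    expect_true(fit$converged)
    expect_gt(fit$hyper$a, 0.4)          # in the right region
    expect_lt(abs(log(fit$hyper$lam / 4)), log(3))
  }
})

test_that("jointly fitted hyperparameters model both tissue classes adequately", {
  sch <- make_scheme(32, 3000, n_b0 = 1, seed = 71, method = "repulsion")
  ph_wm <- make_phantom(15, "wm3_crossing", sch, noise_spec("gaussian", 10),
                        seed = 72)
  ph_gm <- make_phantom(15, "gm", sch, noise_spec("gaussian", 10), seed = 73)
  Yw <- t(matrix(ph_wm$volumes, 16, length(sch$bvalues))[1:15, sch$dwi_index])
  Yg <- t(matrix(ph_gm$volumes, 16, length(sch$bvalues))[1:15, sch$dwi_index])
  fit_w <- fit_hyperparameters(objective_spec(Yw, sch), seed = 4)
  fit_g <- fit_hyperparameters(objective_spec(Yg, sch), seed = 4)
  fit_j <- fit_hyperparameters(objective_spec(cbind(Yw, Yg), sch), seed = 4)

  loo_rmse <- function(Y, hyper) {
    k <- assemble_K(sch, hyper)
    spec <- objective_spec(Y, sch)
    mean(vapply(seq_len(ncol(Y)), function(j)
      sqrt(loo_criteria(spec$Ydem[, j], k)$cv), numeric(1)))
  }
  # joint hyperparameters degrade LOO RMSE by < 50% vs class-specific fits
  expect_lt(loo_rmse(Yw, fit_j$hyper), 1.5 * loo_rmse(Yw, fit_w$hyper))
  expect_lt(loo_rmse(Yg, fit_j$hyper), 1.5 * loo_rmse(Yg, fit_g$hyper))
})

test_that("LOO predictions on densely sampled phantom data explain everything but the noise", {
  # needs HCP-density angular sampling (300 directions) so that the GP can
  # capture the fibre structure and the LOO residual approaches the noise floor
  sigma <- 12
  sch <- make_scheme(300, 2000, n_b0 = 1, seed = 81)
  ph <- make_phantom(8, c("wm1", "wm2_crossing"), sch,
                     noise_spec("gaussian", sigma), seed = 82)
  Y <- t(matrix(ph$volumes, prod(dim(ph$volumes)[1:3]),
                length(sch$bvalues))[which(ph$mask), sch$dwi_index])
  spec <- objective_spec(Y, sch)
  fit <- fit_hyperparameters(spec, seed = 5)
  k <- assemble_K(sch, fit$hyper)
  rmse <- sqrt(mean(vapply(seq_len(ncol(Y)), function(j)
    loo_criteria(spec$Ydem[, j], k)$cv, numeric(1))))
  expect_lt(abs(rmse - sigma) / sigma, 0.2)
})
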