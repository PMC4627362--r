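# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately use explicit inverses / naive refitting rather than
# the package's factorised code paths.

# random acquisition scheme with the given shell sizes
rand_scheme <- function(n_per_shell, shell_bvalues = 1500 * seq_along(n_per_shell),
                        n_b0 = 1) {
  make_scheme(n_per_shell, shell_bvalues, n_b0 = n_b0, seed = NULL,
              method = "random")
}

rand_hyper <- function(scheme, model = "spherical",
                       multishell = scheme$n_shells > 1) {
  gp_hyper(model,
           lam = runif(1, 0.5, 5),
           a = runif(1, 0.5, 2),
           ell = if (multishell) runif(1, 0.5, 2) else NULL,
           sigma2 = runif(scheme$n_shells, 0.05, 0.5))
}

# Element-by-element kernel assembly straight from the covariance formulas.
brute_force_K <- function(scheme, hyper) {
  idx <- scheme$dwi_index
  n <- length(idx)
  K <- matrix(0, n, n)
  cf <- if (hyper$model == "spherical") spherical_cov else exponential_cov
  for (i in seq_len(n)) for (j in seq_len(n)) {
    th <- if (i == j) 0 else
      acos(min(1, abs(sum(scheme$directions[idx[i], ] *
                          scheme$directions[idx[j], ]))))
    k <- hyper$lam * cf(th, hyper$a)
    if (hyper$multishell) {
      bi <- scheme$shell_bvalues[scheme$shell_ids[idx[i]]]
      bj <- scheme$shell_bvalues[scheme$shell_ids[idx[j]]]
      k <- k * exp(-(log(bi) - log(bj))^2 / (2 * hyper$ell^2))
    }
    K[i, j] <- k
  }
  K
}

# Direct MVN conditioning with explicit inverses: mean and variance of f*
# given demeaned y, for query (dirs, b).
mvn_conditioning_oracle <- function(scheme, hyper, y_demeaned, qdirs, qb) {
  K <- brute_force_K(scheme, hyper)
  sid <- scheme$shell_ids[scheme$dwi_index]
  Ky <- K + diag(hyper$sigma2[sid], nrow(K))
  if (is.null(dim(qdirs))) qdirs <- matrix(qdirs, nrow = 1)
  cf <- if (hyper$model == "spherical") spherical_cov else exponential_cov
  m <- nrow(qdirs)
  ks <- matrix(0, m, nrow(K))
  for (i in seq_len(m)) for (j in seq_len(nrow(K))) {
    th <- acos(min(1, abs(sum(qdirs[i, ] *
                              scheme$directions[scheme$dwi_index[j], ]))))
    k <- hyper$lam * cf(th, hyper$a)
    if (hyper$multishell) {
      bj <- scheme$shell_bvalues[sid[j]]
      k <- k * exp(-(log(qb[i]) - log(bj))^2 / (2 * hyper$ell^2))
    }
    ks[i, j] <- k
  }
  Kinv <- solve(Ky)
  list(mean = as.numeric(ks %*% Kinv %*% y_demeaned),
       var = hyper$lam - diag(ks %*% Kinv %*% t(ks)))
}

# Naive leave-one-out: refit the GP without point i and predict it, for all i.
naive_loo_oracle <- function(scheme, hyper, y_demeaned) {
  n <- length(y_demeaned)
  mu <- numeric(n)
  v <- numeric(n)
  for (i in seq_len(n)) {
    sub <- scheme_subset(scheme, setdiff(seq_len(n), i))
    hy <- if (hyper$n_shells == sub$n_shells) hyper else {
      keep <- vapply(sub$shell_bvalues, function(b)
        which.min(abs(scheme$shell_bvalues - b)), integer(1))
      gp_hyper(hyper$model, hyper$lam, hyper$a, hyper$ell, hyper$sigma2[keep])
    }
    or <- mvn_conditioning_oracle(sub, hy, y_demeaned[-i],
                                  scheme$directions[scheme$dwi_index[i], ],
                                  scheme$bvalues[scheme$dwi_index[i]])
    mu[i] <- or$mean
    v[i] <- or$var + hyper$sigma2[scheme$shell_ids[scheme$dwi_index[i]]]
  }
  resid <- y_demeaned - mu
  list(mu = mu, var = v, cv = mean(resid^2),
       gpp = mean(-0.5 * log(2 * pi * v) - 0.5 * resid^2 / v))
}

# Log-linear least-squares single-tensor fit (the classical DTI estimator):
# log S = log S0 - b g' D g, solved by ordinary least squares.
tensor_design <- function(scheme) {
  g <- scheme$directions
  b <- scheme$bvalues
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

tensor_predict_loo <- function(full_values, scheme, target_index) {
  X <- tensor_design(scheme)
  keep <- setdiff(seq_along(full_values), target_index)
  pos <- full_values[keep] > 0
  beta <- qr.solve(X[keep, ][pos, , drop = FALSE], log(full_values[keep][pos]))
  exp(as.numeric(X[target_index, , drop = FALSE] %*% beta))
}

# voxel whose signal is an actual GP draw plus gaussian noise
gp_consistent_voxels <- function(scheme, hyper, n_voxels, seed,
                                 noise_sd = sqrt(hyper$sigma2[1]), mean = 0) {
  f <- sample_prior(scheme, gp_hyper(hyper$model, hyper$lam, hyper$a,
                                     hyper$ell, rep(1e-12, hyper$n_shells)),
                    n_draws = n_voxels, seed = seed, mean = mean)
  noise <- with_seed_helper(seed + 1, matrix(rnorm(length(f), sd = noise_sd),
                                             nrow(f), ncol(f)))
  t(f + noise)   # n_dwi x n_voxels
}

random_directions_helper <- function(n) {
  g <- matrix(rnorm(3 * n), n, 3)
  g / sqrt(rowSums(g^2))
}

# shell mean restored by predict_mean at query b-values lying on shells
restore_means_helper <- function(vox, qb) {
  vapply(qb, function(b)
    vox$shell_means[which.min(abs(vox$scheme$shell_bvalues - b))], numeric(1))
}

with_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
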