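#' Query points for GP prediction
#'
#' @param directions m x 3 matrix (or single vector) of unit query
#'   directions.
#' @param bvalues positive b-value per query (a scalar is recycled).
#' @return A `gp_queries` object (normalised direction matrix + b-values).
#' @export
gp_queries <- function(directions, bvalues) {
  if (is.null(dim(directions))) directions <- matrix(directions, nrow = 1)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop_invalid_input("query directions must have 3 columns")
  bvalues <- as.numeric(bvalues)
  if (length(bvalues) == 1L) bvalues <- rep(bvalues, nrow(directions))
  if (length(bvalues) != nrow(directions)) {
    stop_invalid_input(sprintf(
      "query directions (%d) and bvalues (%d) must have equal length",
      nrow(directions), length(bvalues)))
  }
  if (any(!is.finite(bvalues)) || any(bvalues <= 0)) {
    stop_invalid_input("query b-values must be positive (b0 queries are not GP queries)")
  }
  directions <- to_unit_matrix(directions, "query directions", 1e-6)
  structure(list(directions = directions, bvalues = bvalues),
            class = "gp_queries")
}

as_gp_queries <- function(queries) {
  if (inherits(queries, "gp_queries")) return(queries)
  if (is.list(queries) && !is.null(queries$directions)) {
    return(gp_queries(queries$directions, queries$bvalues))
  }
  stop_invalid_input("queries must be a gp_queries object or a list with directions and bvalues")
}

# Mean signal to restore at a query b-value: the matching training shell's
# mean if the query b lies within the scheme's clustering tolerance of a
# shell, otherwise linear interpolation of the shell means on the log-b axis
# (constant beyond the range), flagged as extrapolated.
restore_means <- function(voxel, query_b) {
  scheme <- voxel$scheme
  m <- length(query_b)
  means <- numeric(m)
  extrap <- logical(m)
  for (i in seq_len(m)) {
    d <- abs(scheme$shell_bvalues - query_b[i])
    j <- which.min(d)
    if (d[j] <= scheme$shell_tol) {
      means[i] <- voxel$shell_means[j]
    } else {
      extrap[i] <- TRUE
      if (scheme$n_shells == 1L) {
        means[i] <- voxel$shell_means[1]
      } else {
        means[i] <- stats::approx(log(scheme$shell_bvalues), voxel$shell_means,
                                  xout = log(query_b[i]), rule = 2)$y
      }
    }
  }
  list(means = means, extrapolated = extrap)
}

#' GP predictive mean of the diffusion signal
#'
#' Conditions the Gaussian process on a voxel's measurements and evaluates
#' the predictive mean at arbitrary (direction, b-value) query points:
#' `f_hat(x*) = k(x*, x)' (K + Sigma_noise)^-1 (f - f_bar) + f_bar`, where
#' the per-shell mean `f_bar` is removed before conditioning and the queried
#' shell's mean restored afterwards. The prediction is linear in the
#' training values. Queries at b-values away from every training shell are
#' permitted but flagged (attribute `extrapolated`), with the restored mean
#' interpolated linearly in log-b.
#'
#' @param voxel a [voxel_signal()].
#' @param hyper a [gp_hyper()] (ignored if `kernel` is supplied).
#' @param queries a [gp_queries()] (or list with `directions`, `bvalues`).
#' @param kernel optional pre-assembled [assemble_K()] kernel for the
#'   voxel's scheme, to reuse one factorisation across many voxels.
#' @return Numeric vector of predicted signals, one per query, with a
#'   logical attribute `extrapolated` marking off-shell b-value queries.
#' @export
predict_mean <- function(voxel, hyper, queries, kernel = NULL) {
  stopifnot(inherits(voxel, "voxel_signal"))
  queries <- as_gp_queries(queries)
  kernel <- kernel %||% assemble_K(voxel$scheme, hyper)
  y <- demeaned_values(voxel)
  if (length(y) != nrow(kernel$K)) {
    stop_invalid_input("voxel length does not match kernel dimension")
  }
  Ks <- kernel_cross(kernel, queries$directions, queries$bvalues)
  alpha <- kernel_solve(kernel, y)
  rm_ <- restore_means(voxel, queries$bvalues)
  out <- as.numeric(Ks %*% alpha) + rm_$means
  attr(out, "extrapolated") <- rm_$extrapolated
  out
}

#' GP predictive variance of the diffusion signal
#'
#' `Var[f_hat(x*)] = k(x*, x*) - k(x*, x)' (K + Sigma_noise)^-1 k(x, x*)`.
#' The variance depends only on the acquisition geometry and the
#' hyperparameters, not on the observed values, and is bounded above by the
#' prior variance `lam`. Tiny negative values from floating-point
#' cancellation (within `1e-9 * lam`) are clamped to zero with a warning;
#' larger negativity raises a conditioning error.
#'
#' @inheritParams predict_mean
#' @return Numeric vector of predictive variances (signal units squared).
#' @export
predict_variance <- function(voxel, hyper, queries, kernel = NULL) {
  stopifnot(inherits(voxel, "voxel_signal"))
  queries <- as_gp_queries(queries)
  kernel <- kernel %||% assemble_K(voxel$scheme, hyper)
  hyper <- kernel$hyper
  Ks <- kernel_cross(kernel, queries$directions, queries$bvalues)
  W <- kernel_whiten(kernel, t(Ks))
  v <- hyper$lam - colSums(W^2)
  neg <- v < 0
  if (any(neg)) {
    if (min(v) < -1e-9 * hyper$lam) {
      stop_conditioning(sprintf(
        "predictive variance is negative beyond tolerance (min %.6g)", min(v)))
    }
    warning("small negative predictive variances clamped to zero")
    v[neg] <- 0
  }
  v
}

#' Predict a whole diffusion-weighted volume
#'
#' Predicts the signal of one non-b0 volume in every (masked) voxel of a 4D
#' data set at that volume's (direction, b-value), either keeping the
#' observed volume in the training set (`mode = "smoothing"`: GP smoothing
#' on the sphere) or leaving it out (`mode = "interpolation"`). The kernel
#' factorisation and prediction weights are computed once and shared across
#' voxels, so per-voxel work is a single inner product.
#'
#' @param volumes 4D array (x, y, z, volume) aligned to `scheme`.
#' @param scheme the acquisition's [gradient_scheme()].
#' @param hyper a [gp_hyper()].
#' @param target_index index of the volume to predict (in full scheme
#'   numbering, including b0 volumes); must not be a b0 volume.
#' @param mode `"smoothing"` (observed volume included) or
#'   `"interpolation"` (excluded).
#' @param mask optional 3D logical array; voxels outside are returned as NA.
#' @return 3D array of predicted signal.
#' @export
predict_volume <- function(volumes, scheme, hyper, target_index,
                           mode = c("smoothing", "interpolation"),
                           mask = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "gradient_scheme"))
  dims <- dim(volumes)
  if (length(dims) != 4L) stop_invalid_input("volumes must be a 4D array")
  if (dims[4] != length(scheme$bvalues)) {
    stop_invalid_input(sprintf(
      "volumes has %d volumes but scheme describes %d", dims[4],
      length(scheme$bvalues)))
  }
  if (target_index < 1 || target_index > dims[4]) {
    stop_invalid_input("target_index out of range")
  }
  if (scheme$is_b0[target_index]) {
    stop_invalid_input("target volume is a b0 volume; the GP predicts diffusion-weighted volumes only")
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), dims[1:3])) {
      stop_format("mask shape does not match the spatial dimensions of the data")
    }
    mask <- array(as.logical(mask), dims[1:3])
  } else {
    mask <- array(TRUE, dims[1:3])
  }

  target_dwi <- match(target_index, scheme$dwi_index)
  keep <- if (mode == "interpolation") setdiff(seq_len(scheme$n_dwi), target_dwi)
          else seq_len(scheme$n_dwi)
  sub <- scheme_subset(scheme, keep)
  kernel <- assemble_K(sub, hyper)
  query <- gp_queries(scheme$directions[target_index, ],
                      scheme$bvalues[target_index])
  ks <- kernel_cross(kernel, query$directions, query$bvalues)
  w <- as.numeric(kernel_solve(kernel, as.numeric(ks)))

  # flatten masked voxels into a matrix (n_train x n_voxels)
  vol_mat <- matrix(volumes, prod(dims[1:3]), dims[4])
  vox <- which(as.vector(mask))
  Y <- t(vol_mat[vox, scheme$dwi_index[keep], drop = FALSE])

  sid <- sub$shell_ids[sub$dwi_index]
  shell_f <- factor(sid, levels = seq_len(sub$n_shells))
  counts <- as.numeric(table(shell_f))
  shell_sums <- rowsum(Y, shell_f)                    # n_shells x n_voxels
  shell_means <- shell_sums / counts
  Ydem <- Y - shell_means[sid, , drop = FALSE]

  # which shell of the reduced scheme does the target b-value belong to
  d <- abs(sub$shell_bvalues - scheme$bvalues[target_index])
  j <- which.min(d)
  if (d[j] <= sub$shell_tol) {
    restore <- shell_means[j, ]
  } else if (sub$n_shells == 1L) {
    restore <- shell_means[1, ]
  } else {
    lb <- log(sub$shell_bvalues)
    xq <- log(scheme$bvalues[target_index])
    restore <- apply(shell_means, 2, function(mm)
      stats::approx(lb, mm, xout = xq, rule = 2)$y)
  }

  pred_flat <- rep(NA_real_, prod(dims[1:3]))
  pred_flat[vox] <- as.numeric(crossprod(Ydem, w)) + restore
  array(pred_flat, dims[1:3])
}

#' Draw prior signal shapes from the GP
#'
#' Samples zero-mean signal vectors from `N(0, K)` over the scheme's non-b0
#' points — the "prior shapes" the covariance model considers plausible
#' before seeing any data. For a multi-shell kernel the draws covary across
#' shells. A relative jitter of `1e-12 * lam` is added to the diagonal
#' before factorising `K` (which, unlike `K_y`, carries no noise term).
#'
#' @param scheme a [gradient_scheme()].
#' @param hyper a [gp_hyper()].
#' @param n_draws number of realisations, `>= 1`.
#' @param seed RNG seed (same seed, same draws); `NULL` uses the current
#'   stream.
#' @param mean optional mean offset added to every draw (scalar or
#'   per-point vector).
#' @return `n_draws` x n matrix of signal vectors.
#' @export
sample_prior <- function(scheme, hyper, n_draws, seed = NULL, mean = 0) {
  if (!is.numeric(n_draws) || length(n_draws) != 1L || n_draws < 1) {
    stop_invalid_input("n_draws must be a positive count")
  }
  n_draws <- as.integer(n_draws)
  kernel <- assemble_K(scheme, hyper)
  K <- kernel$K
  R <- chol(K + diag(1e-12 * hyper$lam, nrow(K)))
  Z <- with_seed(seed, matrix(stats::rnorm(n_draws * nrow(K)), n_draws, nrow(K)))
  draws <- Z %*% R
  sweep(draws, 2, rep_len(mean, ncol(draws)), `+`)
}

#' Shell-subsampling prediction experiment
#'
#' Measures how well a shell can be predicted from only its first few points,
#' with and without a supporting shell: for each subset size, the GP is
#' trained on that many points of the target shell (optionally plus the full
#' data of one supporting shell) and predicts the entire target shell; the
#' RMSE against the (held-out) truth is reported. This quantifies the
#' cross-shell borrowing of the multi-shell kernel — a neighbouring b-value
#' shell should rescue predictions when target-shell data is scarce, and its
#' influence should vanish once the target shell is densely sampled.
#'
#' @param voxel a multi-shell [voxel_signal()].
#' @param hyper a multi-shell [gp_hyper()] matching the voxel's scheme.
#' @param target_shell shell index (into `scheme$shell_bvalues`) to predict.
#' @param n_points_list subset sizes of the target shell to train on; points
#'   are taken in acquisition order.
#' @param support_shells shell indices usable as full-data support; each is
#'   evaluated separately, alongside the unsupported case.
#' @param truth optional noise-free signal at the target shell's points
#'   (defaults to the observed values).
#' @return data.frame with columns `n_points`, `support` ("none" or
#'   "b=<value>"), and `rmse`.
#' @export
shell_subsample_experiment <- function(voxel, hyper, target_shell,
                                       n_points_list, support_shells,
                                       truth = NULL) {
  stopifnot(inherits(voxel, "voxel_signal"))
  scheme <- voxel$scheme
  sid <- scheme$shell_ids[scheme$dwi_index]
  tgt <- which(sid == target_shell)
  if (!length(tgt)) stop_invalid_input("target shell has no points")
  if (max(n_points_list) > length(tgt)) {
    stop_invalid_input(sprintf(
      "requested subset of %d points but target shell has only %d",
      max(n_points_list), length(tgt)))
  }
  truth <- truth %||% voxel$values[tgt]
  if (length(truth) != length(tgt)) {
    stop_invalid_input("truth must have one value per target-shell point")
  }
  query <- gp_queries(scheme$directions[scheme$dwi_index[tgt], , drop = FALSE],
                      scheme$bvalues[scheme$dwi_index[tgt]])
  configs <- c(list(integer(0)), lapply(support_shells, function(s) which(sid == s)))
  labels <- c("none", sprintf("b=%g", scheme$shell_bvalues[support_shells]))

  res <- expand.grid(n_points = n_points_list, support = labels,
                     stringsAsFactors = FALSE)
  res$rmse <- NA_real_
  for (ci in seq_along(configs)) {
    for (np in n_points_list) {
      keep <- sort(c(tgt[seq_len(np)], configs[[ci]]))
      sub_scheme <- scheme_subset(scheme, keep)
      sub_voxel <- voxel_signal(voxel$values[keep], sub_scheme)
      sub_hyper <- reduce_hyper(hyper, scheme, sub_scheme)
      pred <- predict_mean(sub_voxel, sub_hyper, query)
      res$rmse[res$n_points == np & res$support == labels[ci]] <-
        sqrt(mean((pred - truth)^2))
    }
  }
  res
}

# Restrict per-shell noise variances to the shells surviving in a reduced
# scheme (matched by representative b-value).
reduce_hyper <- function(hyper, scheme, sub_scheme) {
  if (hyper$n_shells == sub_scheme$n_shells) return(hyper)
  keep <- vapply(sub_scheme$shell_bvalues, function(b)
    which.min(abs(scheme$shell_bvalues - b)), integer(1))
  gp_hyper(model = hyper$model, lam = hyper$lam, a = hyper$a,
           ell = hyper$ell, sigma2 = hyper$sigma2[keep])
}
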