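#' Objective specification for hyperparameter estimation
#'
#' Bundles a collection of voxels sharing one gradient scheme with the
#' covariance model and fitting criterion. Hyperparameters are shared across
#' voxels: the per-voxel criterion is summed over voxels (equivalently, the
#' likelihoods are multiplied), so one beta serves the whole data set.
#'
#' @param voxels either a numeric matrix with one column per voxel
#'   (`n_dwi` or full-scheme rows, in scheme order), a list of
#'   [voxel_signal()] objects, or a single `voxel_signal`.
#' @param scheme the shared [gradient_scheme()].
#' @param model `"spherical"` or `"exponential"`.
#' @param criterion `"ml"` (log marginal likelihood, maximised), `"cv"`
#'   (mean squared leave-one-out residual, minimised) or `"gpp"` (mean
#'   leave-one-out log predictive density, maximised).
#' @param multishell logical; fit the multi-shell kernel (adds the log-b
#'   length scale `ell`). Defaults to `TRUE` when the scheme has more than
#'   one shell.
#' @return An object of class `objective_spec` holding the demeaned signal
#'   matrix and the model choices.
#' @export
objective_spec <- function(voxels, scheme, model = c("spherical", "exponential"),
                           criterion = c("ml", "cv", "gpp"),
                           multishell = scheme$n_shells > 1L) {
  model <- match.arg(model)
  criterion <- match.arg(criterion)
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (inherits(voxels, "voxel_signal")) voxels <- list(voxels)
  if (is.list(voxels)) {
    Y <- vapply(voxels, function(v) {
      stopifnot(inherits(v, "voxel_signal"))
      v$values
    }, numeric(scheme$n_dwi))
    Y <- matrix(Y, nrow = scheme$n_dwi)
  } else {
    Y <- as.matrix(voxels)
    if (nrow(Y) == length(scheme$bvalues) && nrow(Y) != scheme$n_dwi) {
      Y <- Y[!scheme$is_b0, , drop = FALSE]
    }
    if (nrow(Y) != scheme$n_dwi) {
      stop_invalid_input(sprintf(
        "voxel matrix has %d rows; expected %d DWI rows", nrow(Y), scheme$n_dwi))
    }
  }
  if (ncol(Y) < 1L) stop_invalid_input("at least one voxel is required")
  sid <- scheme$shell_ids[scheme$dwi_index]
  shell_f <- factor(sid, levels = seq_len(scheme$n_shells))
  counts <- as.numeric(table(shell_f))
  shell_means <- rowsum(Y, shell_f) / counts
  structure(list(Y = Y, Ydem = Y - shell_means[sid, , drop = FALSE],
                 shell_means = shell_means, scheme = scheme, model = model,
                 criterion = criterion, multishell = multishell,
                 n_voxels = ncol(Y)),
            class = "objective_spec")
}

spec_digest <- function(spec) {
  c(n = spec$n_voxels, n_dwi = nrow(spec$Y), sum = sum(spec$Y),
    ss = sum(spec$Y^2))
}

#' Log marginal likelihood of one voxel under a GP kernel
#'
#' The type-II (marginal) log likelihood
#' `-1/2 y' K_y^-1 y - 1/2 log|K_y| - (n/2) log 2 pi`, evaluated through the
#' kernel's cached Cholesky factor (no explicit inverse). The additive
#' constant is fixed at `-(n/2) log 2 pi` so that values are proper Gaussian
#' log densities, comparable across n.
#'
#' @param voxel a [voxel_signal()] (demeaned per shell internally) or an
#'   already-demeaned numeric vector used as `y` directly.
#' @param kernel an [assemble_K()] kernel matching the voxel's scheme.
#' @return Scalar log marginal likelihood (nats).
#' @export
log_marginal_likelihood <- function(voxel, kernel) {
  stopifnot(inherits(kernel, "gp_kernel"))
  y <- demeaned_values(voxel)
  n <- nrow(kernel$K)
  if (length(y) != n) {
    stop_invalid_input(sprintf(
      "signal length %d does not match kernel dimension %d", length(y), n))
  }
  z <- kernel_whiten(kernel, y)
  -0.5 * sum(z^2) - 0.5 * kernel$log_det - 0.5 * n * log(2 * pi)
}

# Vectorised criteria over a demeaned matrix (n x V); one factorisation.
criterion_values <- function(Ydem, kernel, criterion) {
  n <- nrow(kernel$K)
  if (criterion == "ml") {
    Z <- kernel_whiten(kernel, Ydem)
    return(-0.5 * colSums(Z^2) - 0.5 * kernel$log_det - 0.5 * n * log(2 * pi))
  }
  Kinv <- chol2inv(kernel$R)
  d <- diag(Kinv)
  if (any(d <= 0)) {
    stop_conditioning("leave-one-out predictive variance is non-positive")
  }
  A <- Kinv %*% Ydem
  resid <- A / d            # y_i - LOO mean_i
  if (criterion == "cv") {
    colMeans(resid^2)
  } else {                  # gpp: mean LOO log predictive density
    v <- 1 / d
    colMeans(-0.5 * log(2 * pi * v) - 0.5 * resid^2 / v)
  }
}

#' Summed objective over voxels at an unconstrained parameter vector
#'
#' Maps `beta` (log-parameters) to hyperparameters, assembles the kernel
#' once, and sums the per-voxel criterion over all voxels in the spec. The
#' value is oriented for maximisation: for the `"cv"` criterion the negative
#' summed score is returned. Non-finite values (e.g. a kernel that cannot be
#' factorised at this beta) yield `-Inf`, which Nelder--Mead treats as an
#' ordinary bad point.
#'
#' @param spec an [objective_spec()].
#' @param beta unconstrained parameter vector (see [hyper_to_vector()]).
#' @return Scalar objective (maximise).
#' @export
summed_objective <- function(spec, beta) {
  stopifnot(inherits(spec, "objective_spec"))
  hyper <- tryCatch(
    vector_to_hyper(beta, spec$model, spec$scheme$n_shells, spec$multishell),
    dwigp_invalid_hyper = function(e) NULL)
  if (is.null(hyper)) return(-Inf)
  kernel <- tryCatch(
    suppressWarnings(assemble_K(spec$scheme, hyper)),
    dwigp_error = function(e) NULL, error = function(e) NULL)
  if (is.null(kernel)) return(-Inf)
  vals <- tryCatch(criterion_values(spec$Ydem, kernel, spec$criterion),
                   dwigp_error = function(e) NULL)
  if (is.null(vals) || any(!is.finite(vals))) return(-Inf)
  s <- sum(vals)
  if (spec$criterion == "cv") -s else s
}

#' Leave-one-out criteria for one voxel
#'
#' Closed-form leave-one-out predictions from the factorised full system:
#' with `Kinv = K_y^-1` and `alpha = Kinv y`, the LOO residual for point i is
#' `alpha_i / Kinv_ii` and the LOO predictive variance is `1 / Kinv_ii` —
#' no refitting per point. CV is the mean squared LOO residual (smaller is
#' better); GPP is the mean LOO log predictive density (larger is better).
#'
#' @inheritParams log_marginal_likelihood
#' @return List with elements `cv` and `gpp`.
#' @export
loo_criteria <- function(voxel, kernel) {
  stopifnot(inherits(kernel, "gp_kernel"))
  y <- demeaned_values(voxel)
  if (length(y) != nrow(kernel$K)) {
    stop_invalid_input("signal length does not match kernel dimension")
  }
  Y <- matrix(y, ncol = 1)
  list(cv = as.numeric(criterion_values(Y, kernel, "cv")),
       gpp = as.numeric(criterion_values(Y, kernel, "gpp")))
}

#' Fit GP hyperparameters by criterion maximisation
#'
#' Maximises the summed objective over the unconstrained log-parameters with
#' the Nelder--Mead simplex (robust to the multimodal multi-shell surface),
#' optionally from multiple randomly perturbed starts. Positive parameters
#' are represented as exponentials of unconstrained coordinates, so negative
#' scales or variances cannot occur.
#'
#' Default initialisation: `a = 1` rad, `lam` = pooled variance of the
#' demeaned signals, `sigma2 = 0.1 * lam` per shell, `ell = 1`. Restarts
#' beyond the first multiply the initial positive parameters by seeded
#' log-normal factors. Convergence uses `stats::optim`'s Nelder--Mead with a
#' relative objective tolerance of 1e-8 and at most `200 * d` iterations.
#'
#' @param spec an [objective_spec()].
#' @param init a [gp_hyper()] initial value, or `"auto"`.
#' @param restarts number of optimisation starts (best result kept).
#' @param seed RNG seed controlling restart perturbations and voxel
#'   subsampling; the same seed and init give an identical fit.
#' @param max_voxels if the spec holds more voxels, a seeded uniform random
#'   subset of this size is used for fitting (hyperparameters are global, so
#'   a sizeable subset suffices). Default 1000.
#' @return An object of class `gp_fit`: list with `hyper`, `objective_value`,
#'   `n_evaluations`, `converged`, `trace` (running best objective),
#'   `criterion`, `model`, `seed`, `n_voxels_used` and `data_digest`.
#' @export
fit_hyperparameters <- function(spec, init = "auto", restarts = 1L,
                                seed = NULL, max_voxels = 1000L) {
  stopifnot(inherits(spec, "objective_spec"))
  full_digest <- spec_digest(spec)
  fit_spec <- spec
  if (spec$n_voxels > max_voxels) {
    pick <- with_seed(seed, sort(sample.int(spec$n_voxels, max_voxels)))
    fit_spec <- objective_spec(spec$Y[, pick, drop = FALSE], spec$scheme,
                               model = spec$model, criterion = spec$criterion,
                               multishell = spec$multishell)
  }
  if (identical(init, "auto")) {
    lam0 <- mean(apply(fit_spec$Ydem, 2, stats::var))
    if (!is.finite(lam0) || lam0 <= 0) lam0 <- 1
    init <- gp_hyper(model = fit_spec$model, lam = lam0, a = 1.0,
                     ell = if (fit_spec$multishell) 1.0 else NULL,
                     sigma2 = rep(0.1 * lam0, fit_spec$scheme$n_shells))
  }
  stopifnot(inherits(init, "gp_hyper"))
  beta0 <- hyper_to_vector(init)
  d <- length(beta0)

  n_eval <- 0L
  trace_env <- new.env()
  trace_env$best <- -Inf
  trace_env$trace <- numeric(0)
  fn <- function(b) {
    n_eval <<- n_eval + 1L
    v <- summed_objective(fit_spec, b)
    if (is.finite(v) && v > trace_env$best) {
      trace_env$best <- v
      trace_env$trace <- c(trace_env$trace, v)
    }
    v
  }

  starts <- with_seed(seed, lapply(seq_len(restarts), function(r) {
    if (r == 1L) beta0 else beta0 + stats::rnorm(d, sd = 0.5)
  }))
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, fn, method = "Nelder-Mead",
                   control = list(fnscale = -1, maxit = 200L * d,
                                  reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value > best$value) best <- res
  }
  if (is.null(best)) {
    stop_conditioning("all optimisation restarts failed")
  }
  converged <- best$convergence == 0L
  if (!converged) {
    warning("hyperparameter optimisation did not converge; returning best point found")
  }
  hyper <- vector_to_hyper(best$par, fit_spec$model, fit_spec$scheme$n_shells,
                           fit_spec$multishell)
  structure(list(hyper = hyper,
                 objective_value = summed_objective(fit_spec, best$par),
                 n_evaluations = n_eval,
                 converged = converged,
                 trace = trace_env$trace,
                 criterion = fit_spec$criterion,
                 model = fit_spec$model,
                 multishell = fit_spec$multishell,
                 seed = seed,
                 n_voxels_used = fit_spec$n_voxels,
                 data_digest = full_digest),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("gp_fit (%s criterion, %d voxels, %s): objective %.4f%s\n",
              x$criterion, x$n_voxels_used,
              if (x$converged) "converged" else "NOT converged",
              x$objective_value,
              sprintf(" after %d evaluations", x$n_evaluations)))
  print(x$hyper)
  invisible(x)
}
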