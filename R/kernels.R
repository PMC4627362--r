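#' Exponential covariance model on the sphere
#'
#' `C(theta) = exp(-theta / a)` for `0 <= theta <= pi`, the geostatistical
#' "exponential model". `a` is a positive angular length scale (radians)
#' controlling how fast covariance decays with angle.
#'
#' @param theta angle(s) in radians, in `[0, pi]`.
#' @param a angular length scale, `a > 0` (radians).
#' @return Covariance value(s) in `(0, 1]`; equals 1 at `theta = 0`.
#' @export
exponential_cov <- function(theta, a) {
  check_angular_args(theta, a)
  exp(-theta / a)
}

#' Spherical covariance model on the sphere
#'
#' The geostatistical "spherical model"
#' `C(theta) = 1 - 3 theta / (2 a) + theta^3 / (2 a^3)` for `theta <= a` and
#' exactly 0 for `theta > a`. The scale `a` (radians) is the angular distance
#' at which the covariance reaches zero; the function is continuous and
#' non-increasing on `[0, pi]`.
#'
#' @inheritParams exponential_cov
#' @return Covariance value(s) in `[0, 1]`.
#' @examples
#' spherical_cov(0.5, 1.0)   # 0.3125
#' spherical_cov(1.5, 1.23)  # 0: beyond the scale the covariance vanishes
#' @export
spherical_cov <- function(theta, a) {
  check_angular_args(theta, a)
  ifelse(theta > a, 0, 1 - 3 * theta / (2 * a) + theta^3 / (2 * a^3))
}

check_angular_args <- function(theta, a) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    stop_invalid_hyper("angular scale a must be a single positive number")
  }
  if (any(theta < 0 | theta > pi + 1e-12)) {
    stop_invalid_input("theta must lie in [0, pi]")
  }
  invisible(TRUE)
}

#' Cross-shell covariance on log b-value distance
#'
#' Squared-exponential kernel on the log of the b-values,
#' `C_b(b, b') = exp(-(log b - log b')^2 / (2 l^2))`. Using log-b as the
#' distance makes the kernel scale free: the covariance between b = 1500 and
#' 3000 equals that between 3000 and 6000.
#'
#' @param b,b_prime positive b-values (s/mm^2); b = 0 volumes must be
#'   filtered out upstream.
#' @param ell positive length scale on the log-b axis (dimensionless).
#' @return Covariance value(s) in `(0, 1]`; 1 when `b == b_prime`.
#' @export
log_b_cov <- function(b, b_prime, ell) {
  if (!is.numeric(ell) || length(ell) != 1L || !is.finite(ell) || ell <= 0) {
    stop_invalid_hyper("log-b length scale ell must be a single positive number")
  }
  if (any(b <= 0) || any(b_prime <= 0)) {
    stop_invalid_input("b-values must be positive (b0 volumes are excluded upstream)")
  }
  exp(-(log(b) - log(b_prime))^2 / (2 * ell^2))
}

#' Covariance-model hyperparameters
#'
#' The hyperparameter vector of the GP signal model: a signal-variance scale
#' `lam` (lambda, signal units squared), an angular length scale `a`
#' (radians), an optional log-b length scale `ell` for multi-shell models,
#' and one noise variance `sigma2` per shell (signal units squared). A
#' single-shell model has 3 free parameters; an N-shell model has 3 + N.
#'
#' `sigma2 = 0` is accepted (noise-free conditioning, useful for exact
#' interpolation), but such hyperparameters cannot be mapped to the
#' unconstrained log-parameter space used by the optimiser.
#'
#' @param model `"spherical"` or `"exponential"` angular covariance.
#' @param lam signal variance scale, `> 0`.
#' @param a angular length scale in radians, `> 0`.
#' @param ell log-b length scale, `> 0`, or `NULL` for a single-shell model.
#' @param sigma2 numeric vector of per-shell noise variances, each `>= 0`.
#' @return An object of class `gp_hyper`.
#' @export
gp_hyper <- function(model = c("spherical", "exponential"), lam, a,
                     ell = NULL, sigma2) {
  model <- match.arg(model)
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0) {
    stop_invalid_hyper("lam must be a single positive number")
  }
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    stop_invalid_hyper("a must be a single positive number")
  }
  if (!is.null(ell) &&
      (!is.numeric(ell) || length(ell) != 1L || !is.finite(ell) || ell <= 0)) {
    stop_invalid_hyper("ell must be NULL or a single positive number")
  }
  if (!is.numeric(sigma2) || length(sigma2) < 1L || any(!is.finite(sigma2)) ||
      any(sigma2 < 0)) {
    stop_invalid_hyper("sigma2 must be a vector of non-negative noise variances")
  }
  if (is.null(ell) && length(sigma2) != 1L) {
    stop_invalid_hyper("single-shell model (ell = NULL) requires exactly one sigma2")
  }
  structure(list(model = model, lam = lam, a = a, ell = ell,
                 sigma2 = as.numeric(sigma2),
                 n_shells = length(sigma2),
                 multishell = !is.null(ell)),
            class = "gp_hyper")
}

#' @export
print.gp_hyper <- function(x, ...) {
  cat(sprintf("gp_hyper (%s, %s): lam = %.6g, a = %.6g rad%s, sigma2 = %s\n",
              x$model, if (x$multishell) "multi-shell" else "single-shell",
              x$lam, x$a,
              if (x$multishell) sprintf(", ell = %.6g", x$ell) else "",
              paste(signif(x$sigma2, 6), collapse = ", ")))
  invisible(x)
}

#' Map hyperparameters to/from the unconstrained optimisation vector
#'
#' Positive hyperparameters are optimised on the log scale (each parameter p
#' is represented as log p, so that p = exp(u) can never go negative). The
#' vector layout is `(log lam, log a, [log ell], log sigma2_1, ...,
#' log sigma2_N)`. The round trip is lossless for strictly positive
#' hyperparameters.
#'
#' @param hyper a [gp_hyper()] with strictly positive entries.
#' @return `hyper_to_vector`: numeric vector of length 3 (single-shell) or
#'   3 + N (N shells, multi-shell).
#' @export
hyper_to_vector <- function(hyper) {
  stopifnot(inherits(hyper, "gp_hyper"))
  if (any(hyper$sigma2 <= 0)) {
    stop_invalid_hyper("sigma2 = 0 cannot be mapped to the log-parameter space")
  }
  c(log(hyper$lam), log(hyper$a),
    if (hyper$multishell) log(hyper$ell),
    log(hyper$sigma2))
}

#' @rdname hyper_to_vector
#' @param beta unconstrained parameter vector.
#' @param model angular covariance model name.
#' @param n_shells number of shells (number of sigma2 entries).
#' @param multishell logical; whether the vector contains a log ell entry.
#' @export
vector_to_hyper <- function(beta, model, n_shells = 1L,
                            multishell = n_shells > 1L) {
  d <- 2L + as.integer(multishell) + n_shells
  if (length(beta) != d) {
    stop_invalid_input(sprintf(
      "parameter vector has length %d; expected %d for %d shell(s)%s",
      length(beta), d, n_shells, if (multishell) " (multi-shell)" else ""))
  }
  gp_hyper(model = model,
           lam = exp(beta[1]), a = exp(beta[2]),
           ell = if (multishell) exp(beta[3]) else NULL,
           sigma2 = exp(beta[(d - n_shells + 1L):d]))
}

#' Assemble the GP covariance matrix for an acquisition scheme
#'
#' Builds the n x n kernel matrix over the scheme's non-b0 volumes. Each
#' element is `K_ij = lam * C_theta(theta_ij; a) * C_b(b_i, b_j; ell)` with
#' `C_theta` the chosen angular model and `C_b` the log-b kernel (identically
#' 1 within a shell and for single-shell models, so a one-shell multi-shell
#' assembly reduces exactly to the single-shell one). The noisy-data matrix
#' `K_y` adds the per-shell noise variance to the diagonal and is factorised
#' once (Cholesky); the factor and `log|K_y|` are cached for reuse across
#' voxels.
#'
#' If the factorisation fails (e.g. duplicate directions with near-zero
#' noise), a jitter of `1e-10 * mean(diag(K_y))` is added to the diagonal and
#' the factorisation retried once with a warning; a second failure raises a
#' conditioning error reporting the smallest eigenvalue.
#'
#' @param scheme a [gradient_scheme()] with at least one non-b0 volume.
#' @param hyper a [gp_hyper()]; its shell count must match the scheme's.
#' @return An object of class `gp_kernel`: list with `K`, `K_y`, `R` (upper
#'   Cholesky factor of `K_y`), `log_det` (`log|K_y|`), `jitter` (0 if none
#'   was needed), plus the `scheme` and `hyper` used.
#' @export
assemble_K <- function(scheme, hyper) {
  stopifnot(inherits(scheme, "gradient_scheme"), inherits(hyper, "gp_hyper"))
  if (scheme$n_dwi < 1L) {
    stop_invalid_input("scheme contains no non-b0 measurements")
  }
  if (hyper$n_shells != scheme$n_shells) {
    stop_invalid_input(sprintf(
      "hyperparameters have %d shell(s) but scheme has %d",
      hyper$n_shells, scheme$n_shells))
  }
  dirs <- scheme$directions[scheme$dwi_index, , drop = FALSE]
  sid <- scheme$shell_ids[scheme$dwi_index]
  theta <- compute_angles(dirs)
  K <- hyper$lam * angular_cov(theta, hyper)
  if (hyper$multishell) {
    sb <- scheme$shell_bvalues[sid]
    K <- K * log_b_cov(rep(sb, times = length(sb)),
                       rep(sb, each = length(sb)),
                       hyper$ell)
    dim(K) <- c(length(sb), length(sb))
  }
  K_y <- K
  diag(K_y) <- diag(K_y) + hyper$sigma2[sid]

  jitter <- 0
  R <- tryCatch(chol(K_y), error = function(e) NULL)
  if (is.null(R)) {
    jitter <- 1e-10 * mean(diag(K_y))
    warning(sprintf(
      "Cholesky factorisation of K_y failed; retrying with jitter %.3g on the diagonal",
      jitter))
    R <- tryCatch(chol(K_y + diag(jitter, nrow(K_y))), error = function(e) NULL)
    if (is.null(R)) {
      lam_min <- min(eigen(K_y, symmetric = TRUE, only.values = TRUE)$values)
      stop_conditioning(sprintf(
        "K_y is not positive definite even after jitter (smallest eigenvalue %.6g)",
        lam_min))
    }
  }
  structure(list(K = K, K_y = K_y, R = R,
                 log_det = 2 * sum(log(diag(R))),
                 jitter = jitter, scheme = scheme, hyper = hyper),
            class = "gp_kernel")
}

angular_cov <- function(theta, hyper) {
  switch(hyper$model,
         spherical   = spherical_cov(theta, hyper$a),
         exponential = exponential_cov(theta, hyper$a))
}

# Solve K_y x = b through the cached Cholesky factor (t(R) %*% R = K_y).
kernel_solve <- function(kernel, b) {
  backsolve(kernel$R, backsolve(kernel$R, b, transpose = TRUE))
}

# t(R)^{-1} b; colSums of its square give the quadratic forms b' K_y^{-1} b.
kernel_whiten <- function(kernel, b) {
  backsolve(kernel$R, b, transpose = TRUE)
}

# Cross-covariance k(x*, x) between query (direction, b) points and the
# scheme's training points. query_b outside the training shells is allowed;
# the angular part still applies and C_b uses the representative shell
# b-values of the training points.
kernel_cross <- function(kernel, query_dirs, query_b) {
  scheme <- kernel$scheme
  hyper <- kernel$hyper
  dirs <- scheme$directions[scheme$dwi_index, , drop = FALSE]
  Ks <- hyper$lam * angular_cov(compute_angles(query_dirs, dirs), hyper)
  if (hyper$multishell) {
    sb <- scheme$shell_bvalues[scheme$shell_ids[scheme$dwi_index]]
    m <- nrow(Ks)
    Cb <- log_b_cov(rep(query_b, times = length(sb)),
                    rep(sb, each = m), hyper$ell)
    dim(Cb) <- dim(Ks)
    Ks <- Ks * Cb
  }
  Ks
}
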