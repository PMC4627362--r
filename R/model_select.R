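#' Central finite-difference Hessian
#'
#' Second derivatives of a scalar function by central differences with a
#' per-coordinate step `rel_step * max(|x_k|, 1)`; the result is symmetrised
#' as `(H + H')/2`. The default step of 1e-3 balances truncation error
#' against cancellation for objectives that cost one kernel factorisation
#' per call.
#'
#' @param objective function of a numeric vector returning a finite scalar.
#' @param beta_hat point at which to differentiate.
#' @param rel_step relative step size.
#' @return d x d symmetric matrix.
#' @export
finite_difference_hessian <- function(objective, beta_hat, rel_step = 1e-3) {
  d <- length(beta_hat)
  h <- rel_step * pmax(abs(beta_hat), 1)
  f <- function(x, what) {
    v <- objective(x)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_conditioning(sprintf(
        "objective is non-finite at a stencil point perturbing coordinate %s", what))
    }
    v
  }
  f0 <- f(beta_hat, "none")
  H <- matrix(0, d, d)
  for (k in seq_len(d)) {
    ek <- h[k] * (seq_len(d) == k)
    H[k, k] <- (f(beta_hat + ek, k) - 2 * f0 + f(beta_hat - ek, k)) / h[k]^2
    if (k < d) for (l in (k + 1L):d) {
      el <- h[l] * (seq_len(d) == l)
      lbl <- paste(k, l, sep = ",")
      H[k, l] <- (f(beta_hat + ek + el, lbl) - f(beta_hat + ek - el, lbl) -
                  f(beta_hat - ek + el, lbl) + f(beta_hat - ek - el, lbl)) /
                 (4 * h[k] * h[l])
      H[l, k] <- H[k, l]
    }
  }
  (H + t(H)) / 2
}

# Laplace's approximation for log int exp(L(beta)) d beta around a maximum
# beta_hat: L(beta_hat) + (d/2) log 2 pi - 1/2 log |-H|. A flat (improper)
# prior over the unconstrained coordinates is assumed, so the MAP point
# coincides with the maximum-likelihood point.
laplace_from_fn <- function(objective, beta_hat, rel_step = 1e-3) {
  H <- finite_difference_hessian(objective, beta_hat, rel_step)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  valid <- all(ev < 0)
  d <- length(beta_hat)
  log_ev <- if (valid) {
    as.numeric(objective(beta_hat)) + 0.5 * d * log(2 * pi) -
      0.5 * sum(log(-ev))
  } else NA_real_
  list(log_evidence = log_ev, hessian = H, eigenvalues = ev, valid = valid)
}

#' Laplace-approximated log model evidence
#'
#' Approximates the model evidence `p(y | M) = int p(y | beta, M) p(beta) d
#' beta` by Laplace's method: the summed log marginal likelihood `L` (in
#' unconstrained log-parameter coordinates) is maximised at `beta_hat`, its
#' Hessian `H` estimated by central finite differences, and
#' `log p(y|M) ~= L(beta_hat) + (d/2) log 2 pi - 1/2 log|-H|`. A flat
#' improper prior over the unconstrained coordinates is assumed, making the
#' posterior mode coincide with the type-II ML point. If `H` is not negative
#' definite the result is flagged invalid and its eigenvalues reported.
#'
#' @param spec an [objective_spec()] (the evidence always uses the marginal
#'   likelihood, regardless of the spec's fitting criterion).
#' @param fit a [fit_hyperparameters()] result for this spec.
#' @param rel_step finite-difference step (see
#'   [finite_difference_hessian()]).
#' @return An object of class `gp_evidence`: list with `model`,
#'   `log_evidence` (nats; `NA` if flagged invalid), `beta_hat` (the
#'   [gp_hyper()]), `hessian`, `eigenvalues`, `valid`, `n_voxels` and
#'   `data_digest`.
#' @export
laplace_log_evidence <- function(spec, fit, rel_step = 1e-3) {
  stopifnot(inherits(spec, "objective_spec"), inherits(fit, "gp_fit"))
  if (!fit$converged) {
    warning("evidence computed at a non-converged optimum")
  }
  ml_spec <- if (spec$criterion == "ml") spec else
    objective_spec(spec$Y, spec$scheme, model = spec$model, criterion = "ml",
                   multishell = spec$multishell)
  beta_hat <- hyper_to_vector(fit$hyper)
  lp <- laplace_from_fn(function(b) summed_objective(ml_spec, b), beta_hat,
                        rel_step)
  structure(list(model = paste0(fit$model,
                                if (fit$multishell) "-multishell" else ""),
                 log_evidence = lp$log_evidence,
                 beta_hat = fit$hyper,
                 hessian = lp$hessian,
                 eigenvalues = lp$eigenvalues,
                 valid = lp$valid,
                 n_voxels = spec$n_voxels,
                 data_digest = spec_digest(spec)),
            class = "gp_evidence")
}

#' @export
print.gp_evidence <- function(x, ...) {
  cat(sprintf("gp_evidence (%s, %d voxels): log evidence %.4f%s\n",
              x$model, x$n_voxels, x$log_evidence,
              if (!x$valid) "  [INVALID: Hessian not negative definite]" else ""))
  invisible(x)
}

#' Bayes factor between two covariance models
#'
#' `BF = exp(log_evidence_1 - log_evidence_2)`; values above 1 favour the
#' first model. Both evidences must have been computed on the identical
#' voxel set and scheme.
#'
#' @param e1,e2 [laplace_log_evidence()] results.
#' @return Scalar Bayes factor.
#' @export
bayes_factor <- function(e1, e2) {
  stopifnot(inherits(e1, "gp_evidence"), inherits(e2, "gp_evidence"))
  if (!isTRUE(all.equal(e1$data_digest, e2$data_digest))) {
    dwigp_stop("evidences were computed on different voxel sets; Bayes factor is undefined",
               "dwigp_invalid_comparison")
  }
  if (!e1$valid || !e2$valid) {
    warning("Bayes factor involves an evidence flagged invalid")
  }
  exp(e1$log_evidence - e2$log_evidence)
}
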