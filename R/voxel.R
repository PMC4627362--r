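#' A single voxel's diffusion-weighted measurements
#'
#' Pairs one voxel's signal values with the gradient scheme they were
#' acquired under. Only the non-b0 (diffusion-weighted) values enter the GP;
#' if `values` covers the full scheme (including b0 volumes) the b0 entries
#' are split off and kept alongside. Per-shell mean signals are precomputed:
#' the GP models the demeaned signal, the shell mean being subtracted before
#' conditioning and restored on prediction.
#'
#' @param values numeric vector, either of length `scheme$n_dwi` (DWI
#'   volumes only, in scheme order) or of the full scheme length.
#' @param scheme a [gradient_scheme()].
#' @return An object of class `voxel_signal`: list with `values` (non-b0),
#'   `b0_values` (possibly empty), `shell_means` (one per shell) and
#'   `scheme`.
#' @export
voxel_signal <- function(values, scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  values <- as.numeric(values)
  n_all <- length(scheme$bvalues)
  if (length(values) == n_all && n_all != scheme$n_dwi) {
    b0_values <- values[scheme$is_b0]
    values <- values[!scheme$is_b0]
  } else if (length(values) == scheme$n_dwi) {
    b0_values <- numeric(0)
  } else {
    stop_invalid_input(sprintf(
      "values has length %d; expected %d (DWI only) or %d (full scheme)",
      length(values), scheme$n_dwi, n_all))
  }
  if (any(!is.finite(values))) stop_invalid_input("signal values must be finite")
  sid <- scheme$shell_ids[scheme$dwi_index]
  shell_means <- as.numeric(tapply(values, factor(sid, levels = seq_len(scheme$n_shells)),
                                   mean))
  structure(list(values = values, b0_values = b0_values,
                 shell_means = shell_means, scheme = scheme),
            class = "voxel_signal")
}

# Demeaned signal vector (per-shell mean removed), used by conditioning and
# marginal likelihood. Accepts a voxel_signal or an already-demeaned numeric
# vector (returned as is).
demeaned_values <- function(voxel, scheme = NULL) {
  if (inherits(voxel, "voxel_signal")) {
    sid <- voxel$scheme$shell_ids[voxel$scheme$dwi_index]
    voxel$values - voxel$shell_means[sid]
  } else {
    as.numeric(voxel)
  }
}

#' @export
print.voxel_signal <- function(x, ...) {
  cat(sprintf("voxel_signal: %d DWI values (+%d b0), shell means %s\n",
              length(x$values), length(x$b0_values),
              paste(signif(x$shell_means, 5), collapse = ", ")))
  invisible(x)
}
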