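#' Gradient scheme: directions, b-values and shell structure
#'
#' Container describing a whole diffusion acquisition: one unit gradient
#' direction and one b-value per volume, with b-values clustered into shells.
#' Volumes with b-value at or below `b0_threshold` are flagged as b=0
#' ("b0") volumes; they carry no directional information and are excluded
#' from all GP training and prediction sets.
#'
#' Shell clustering is tolerance based: sorted non-b0 b-values are split
#' wherever consecutive values differ by more than `shell_tol`, and each
#' cluster is represented by its mean b-value. Scanners jitter nominal
#' b-values slightly, so exact matching would be too strict; the default
#' tolerance of 100 s/mm^2 is far below the separation of nominal shells in
#' typical protocols.
#'
#' @param directions n x 3 matrix (or coercible) of gradient directions.
#'   Rows are normalised to unit length; zero rows are only permitted for b0
#'   volumes.
#' @param bvalues numeric vector of n non-negative b-values (s/mm^2).
#' @param b0_threshold b-values at or below this count as b=0 (s/mm^2).
#' @param shell_tol clustering tolerance for shell assignment (s/mm^2).
#' @param norm_tol warn if a non-b0 direction deviates from unit norm by more
#'   than this before normalisation.
#'
#' @return An object of class `gradient_scheme`: a list with elements
#'   `directions` (n x 3, unit rows for non-b0 volumes), `bvalues`,
#'   `is_b0` (logical), `shell_ids` (integer per volume, `NA` for b0),
#'   `shell_bvalues` (strictly increasing representative b-value per shell),
#'   `n_shells`, `n_dwi` (number of non-b0 volumes), `dwi_index`
#'   (indices of the non-b0 volumes), `b0_threshold` and `shell_tol`.
#' @examples
#' sch <- gradient_scheme(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                        c(0, 1500, 1500))
#' sch$n_shells      # 1
#' sch$shell_bvalues # 1500
#' @export
gradient_scheme <- function(directions, bvalues, b0_threshold = 50,
                            shell_tol = 100, norm_tol = 1e-3) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) {
    stop_invalid_input("directions must have 3 columns (x, y, z)")
  }
  storage.mode(directions) <- "double"
  dimnames(directions) <- NULL
  bvalues <- as.numeric(bvalues)
  n <- nrow(directions)
  if (length(bvalues) != n) {
    stop_invalid_input(sprintf(
      "directions (%d rows) and bvalues (%d) must have equal length", n,
      length(bvalues)))
  }
  if (any(!is.finite(bvalues)) || any(bvalues < 0)) {
    stop_invalid_input("bvalues must be finite and non-negative")
  }
  is_b0 <- bvalues <= b0_threshold

  norms <- sqrt(rowSums(directions^2))
  bad <- which(!is_b0 & norms == 0)
  if (length(bad)) {
    stop_format(sprintf(
      "zero gradient vector at volume %d with b = %g > b0 threshold %g",
      bad[1], bvalues[bad[1]], b0_threshold))
  }
  off <- which(!is_b0 & abs(norms - 1) > norm_tol)
  if (length(off)) {
    warning(sprintf(
      "%d gradient vector(s) deviate from unit norm by more than %g (max %.3g); normalising",
      length(off), norm_tol, max(abs(norms[off] - 1))))
  }
  nz <- !is_b0
  directions[nz, ] <- directions[nz, , drop = FALSE] / norms[nz]
  directions[is_b0 & norms > 0, ] <-
    directions[is_b0 & norms > 0, , drop = FALSE] / norms[is_b0 & norms > 0]

  # shell clustering on the non-b0 b-values
  b_dwi <- bvalues[!is_b0]
  if (length(b_dwi) == 0L) {
    shell_bvalues <- numeric(0)
    shell_ids <- rep(NA_integer_, n)
  } else {
    ub <- sort(unique(b_dwi))
    breaks <- which(diff(ub) > shell_tol)
    grp <- rep(seq_len(length(breaks) + 1L), diff(c(0L, breaks, length(ub))))
    shell_bvalues <- as.numeric(tapply(ub, grp, mean))
    shell_of_b <- grp[match(b_dwi, ub)]
    shell_ids <- rep(NA_integer_, n)
    shell_ids[!is_b0] <- shell_of_b
  }

  structure(list(
    directions = directions,
    bvalues = bvalues,
    is_b0 = is_b0,
    shell_ids = shell_ids,
    shell_bvalues = shell_bvalues,
    n_shells = length(shell_bvalues),
    n_dwi = sum(!is_b0),
    dwi_index = which(!is_b0),
    b0_threshold = b0_threshold,
    shell_tol = shell_tol
  ), class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf(
    "gradient_scheme: %d volumes (%d b0), %d shell(s) at b = %s s/mm^2\n",
    length(x$bvalues), sum(x$is_b0), x$n_shells,
    paste(signif(x$shell_bvalues, 5), collapse = ", ")))
  invisible(x)
}

#' Restrict a gradient scheme to a subset of its non-b0 volumes
#'
#' @param scheme a [gradient_scheme()].
#' @param dwi_keep indices into the non-b0 (DWI) volumes, i.e. into
#'   `1:scheme$n_dwi`, to keep. b0 volumes are dropped.
#' @return A new `gradient_scheme` containing only the selected DWI volumes.
#' @export
scheme_subset <- function(scheme, dwi_keep) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  dwi_keep <- as.integer(dwi_keep)
  if (any(dwi_keep < 1L | dwi_keep > scheme$n_dwi)) {
    stop_invalid_input("dwi_keep out of range of the scheme's DWI volumes")
  }
  full <- scheme$dwi_index[dwi_keep]
  gradient_scheme(scheme$directions[full, , drop = FALSE],
                  scheme$bvalues[full],
                  b0_threshold = scheme$b0_threshold,
                  shell_tol = scheme$shell_tol)
}

#' Axially symmetric angles between gradient directions
#'
#' The diffusion signal along g equals the signal along -g, so distance on
#' the sphere is measured between axes, not vectors: each direction is
#' extended in the negative direction and the smaller of the two crossing
#' angles is taken, `theta = arccos(|g . g'|)`. Dot products are clipped to
#' \eqn{[-1, 1]} before `acos` to guard against rounding.
#'
#' @param G n x 3 matrix of unit vectors (a single vector is accepted).
#' @param G_prime m x 3 matrix of unit vectors; defaults to `G`.
#' @param tol unit-norm tolerance.
#' @return n x m matrix of angles in `[0, pi/2]` (radians); symmetric with a
#'   zero diagonal when `G_prime` is `G`.
#' @examples
#' compute_angles(c(1, 0, 0), c(0, 1, 0))   # pi/2
#' compute_angles(c(1, 0, 0), c(-1, 0, 0))  # 0: antipodal = identical
#' @export
compute_angles <- function(G, G_prime = G, tol = 1e-6) {
  same <- missing(G_prime) || identical(G, G_prime)
  G <- to_unit_matrix(G, "G", tol)
  G_prime <- if (same) G else to_unit_matrix(G_prime, "G_prime", tol)
  d <- if (same) abs(tcrossprod(G)) else abs(tcrossprod(G, G_prime))
  d[d > 1] <- 1
  th <- acos(d)
  # identical sets: zero diagonal exactly (self-angle is 0 by definition,
  # not up to the rounding of the dot product)
  if (same) diag(th) <- 0
  th
}

to_unit_matrix <- function(G, name, tol) {
  if (is.null(dim(G))) G <- matrix(G, nrow = 1)
  G <- as.matrix(G)
  if (ncol(G) != 3L) stop_invalid_input(sprintf("%s must have 3 columns", name))
  norms <- sqrt(rowSums(G^2))
  bad <- which(abs(norms - 1) > tol)
  if (length(bad)) {
    stop_invalid_input(sprintf(
      "%s row %d is not unit length (norm %.8g, tolerance %g)",
      name, bad[1], norms[bad[1]], tol))
  }
  G / norms
}
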