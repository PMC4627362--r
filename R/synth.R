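#' One fibre population of a multi-tensor voxel
#'
#' An axially symmetric diffusion tensor: diffusivity `axial` along
#' `orientation` and `radial` perpendicular to it, occupying a volume
#' fraction of the voxel. Fractions across a voxel's populations must sum to
#' at most 1; the remainder is an isotropic compartment. Defaults are
#' textbook human white-matter magnitudes.
#'
#' @param orientation 3-vector, normalised internally.
#' @param volume_fraction in `[0, 1]`.
#' @param axial_diffusivity,radial_diffusivity mm^2/s, with
#'   `axial >= radial >= 0`.
#' @return An object of class `fiber_population`.
#' @export
fiber_population <- function(orientation, volume_fraction,
                             axial_diffusivity = 1.7e-3,
                             radial_diffusivity = 0.2e-3) {
  orientation <- as.numeric(orientation)
  if (length(orientation) != 3L || sum(orientation^2) == 0) {
    stop_invalid_input("orientation must be a non-zero 3-vector")
  }
  if (volume_fraction < 0 || volume_fraction > 1) {
    stop_invalid_input("volume_fraction must lie in [0, 1]")
  }
  if (radial_diffusivity < 0 || axial_diffusivity < radial_diffusivity) {
    stop_invalid_input("diffusivities must satisfy axial >= radial >= 0")
  }
  structure(list(orientation = orientation / sqrt(sum(orientation^2)),
                 volume_fraction = volume_fraction,
                 axial_diffusivity = axial_diffusivity,
                 radial_diffusivity = radial_diffusivity),
            class = "fiber_population")
}

#' Measurement-noise specification
#'
#' @param kind `"gaussian"` (additive `N(0, sigma^2)`), `"rician"`
#'   (magnitude of a complex Gaussian perturbation, as in magnitude MR data)
#'   or `"none"`.
#' @param sigma noise standard deviation in signal units, `>= 0`.
#' @param seed RNG seed; the same seed reproduces the noise exactly.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("gaussian", "rician", "none"), sigma = 0,
                       seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) {
    stop_invalid_input("noise sigma must be a single non-negative number")
  }
  structure(list(kind = kind, sigma = sigma, seed = seed),
            class = "noise_spec")
}

#' Generate a synthetic gradient scheme
#'
#' Builds a multi-shell acquisition with `n_per_shell[s]` directions on each
#' shell and `n_b0` b=0 volumes (placed first). Directions are either drawn
#' uniformly on the sphere (`method = "random"`) or spread by iterative
#' electrostatic repulsion of antipodally symmetrised points
#' (`method = "repulsion"`), which maximises the minimum pairwise axial
#' angle — the layout used by real diffusion protocols.
#'
#' @param n_per_shell integer count of directions per shell.
#' @param shell_bvalues distinct positive nominal b-values (s/mm^2), one per
#'   shell.
#' @param n_b0 number of b=0 volumes.
#' @param seed RNG seed (same seed, identical scheme).
#' @param method `"random"` or `"repulsion"`.
#' @return A [gradient_scheme()].
#' @export
make_scheme <- function(n_per_shell, shell_bvalues, n_b0 = 1, seed = NULL,
                        method = c("random", "repulsion")) {
  method <- match.arg(method)
  if (length(shell_bvalues) < 1L) stop_invalid_input("at least one shell is required")
  if (length(n_per_shell) == 1L) {
    n_per_shell <- rep(n_per_shell, length(shell_bvalues))
  }
  if (length(n_per_shell) != length(shell_bvalues)) {
    stop_invalid_input("n_per_shell and shell_bvalues must have equal length")
  }
  if (any(n_per_shell < 1)) stop_invalid_input("each shell needs at least one direction")
  if (any(shell_bvalues <= 0) || anyDuplicated(shell_bvalues)) {
    stop_invalid_input("shell b-values must be positive and distinct")
  }
  if (n_b0 < 0) stop_invalid_input("n_b0 must be non-negative")
  ord <- order(shell_bvalues)
  shell_bvalues <- shell_bvalues[ord]
  n_per_shell <- n_per_shell[ord]
  dirs <- with_seed(seed, {
    lapply(n_per_shell, function(n) {
      switch(method,
             random = random_directions(n),
             repulsion = repulsion_directions(n))
    })
  })
  directions <- rbind(matrix(0, n_b0, 3), do.call(rbind, dirs))
  bvalues <- c(rep(0, n_b0), rep(shell_bvalues, n_per_shell))
  gradient_scheme(directions, bvalues)
}

random_directions <- function(n) {
  g <- matrix(stats::rnorm(3 * n), n, 3)
  g / sqrt(rowSums(g^2))
}

# Electrostatic repulsion between axes: each point repels every other point
# and its antipode with an inverse-square force; points take small tangent
# steps until the configuration settles.
repulsion_directions <- function(n, n_iter = 400, step0 = 0.1) {
  p <- random_directions(n)
  if (n == 1L) return(p)
  for (it in seq_len(n_iter)) {
    F <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      dminus <- sweep(p[-i, , drop = FALSE], 2, p[i, ], function(x, y) y - x)
      dplus <- sweep(p[-i, , drop = FALSE], 2, p[i, ], `+`)
      rm3 <- pmax(rowSums(dminus^2), 1e-12)^1.5
      rp3 <- pmax(rowSums(dplus^2), 1e-12)^1.5
      F[i, ] <- colSums(dminus / rm3) + colSums(dplus / rp3)
    }
    # project onto the tangent plane; cap the step so near-coincident pairs
    # (unbounded force) cannot overshoot
    F <- F - p * rowSums(F * p)
    fmax <- max(sqrt(rowSums(F^2)), 1e-12)
    step <- step0 * exp(-4 * (it - 1) / n_iter)
    p <- p + (step / fmax) * F
    p <- p / sqrt(rowSums(p^2))
  }
  p
}

#' Noise-free multi-tensor diffusion signal for one voxel
#'
#' `S(g, b) = s0 * (sum_i f_i exp(-b g' D_i g) + f_iso exp(-b d_iso))` with
#' `D_i` the axially symmetric tensor of fibre population i and `f_iso = 1 -
#' sum f_i` the isotropic remainder. The signal is axially symmetric in `g`
#' by construction and equals `s0` exactly at b = 0.
#'
#' @param fibers list of [fiber_population()] objects (possibly empty for a
#'   purely isotropic voxel).
#' @param iso_diffusivity diffusivity of the isotropic compartment (mm^2/s).
#' @param s0 non-diffusion-weighted signal, `> 0`.
#' @param scheme a [gradient_scheme()].
#' @return A [voxel_signal()] carrying the noise-free signal of every volume
#'   in the scheme (b0 volumes included, stored as `b0_values`).
#' @export
simulate_voxel <- function(fibers, iso_diffusivity = 3.0e-3, s0 = 1000,
                           scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (inherits(fibers, "fiber_population")) fibers <- list(fibers)
  if (!is.numeric(s0) || s0 <= 0) stop_invalid_input("s0 must be positive")
  fsum <- sum(vapply(fibers, function(f) f$volume_fraction, numeric(1)))
  if (fsum > 1 + 1e-12) {
    stop_invalid_input(sprintf("fibre volume fractions sum to %.4g > 1", fsum))
  }
  f_iso <- 1 - fsum
  b <- scheme$bvalues
  g <- scheme$directions
  S <- f_iso * exp(-b * iso_diffusivity)
  for (f in fibers) {
    proj2 <- as.numeric(g %*% f$orientation)^2
    adc <- f$radial_diffusivity +
      (f$axial_diffusivity - f$radial_diffusivity) * proj2
    S <- S + f$volume_fraction * exp(-b * adc)
  }
  voxel_signal(s0 * S, scheme)
}

#' Add measurement noise to a voxel signal
#'
#' Gaussian noise adds `N(0, sigma^2)` to each measurement; Rician noise
#' returns `sqrt((S + e1)^2 + e2^2)` with independent `e ~ N(0, sigma^2)`,
#' the magnitude-MR noise model (strictly non-negative, biased upward at low
#' SNR). Deterministic given the spec's seed; `kind = "none"` or
#' `sigma = 0` is the identity.
#'
#' @param voxel a [voxel_signal()] or plain numeric vector.
#' @param noise a [noise_spec()].
#' @return Same type as `voxel`, with noise applied (b0 values included).
#' @export
add_noise <- function(voxel, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  vs <- inherits(voxel, "voxel_signal")
  x <- if (vs) c(voxel$b0_values, voxel$values) else as.numeric(voxel)
  if (noise$kind == "none" || noise$sigma == 0) {
    return(voxel)
  }
  y <- with_seed(noise$seed, {
    if (noise$kind == "gaussian") {
      x + stats::rnorm(length(x), sd = noise$sigma)
    } else {
      sqrt((x + stats::rnorm(length(x), sd = noise$sigma))^2 +
             stats::rnorm(length(x), sd = noise$sigma)^2)
    }
  })
  if (!vs) return(y)
  nb0 <- length(voxel$b0_values)
  out <- voxel
  out$b0_values <- y[seq_len(nb0)]
  out$values <- y[(nb0 + 1L):length(y)]
  sid <- out$scheme$shell_ids[out$scheme$dwi_index]
  out$shell_means <- as.numeric(tapply(
    out$values, factor(sid, levels = seq_len(out$scheme$n_shells)), mean))
  out
}

# canonical tissue classes for the phantom; diffusivities in mm^2/s
phantom_class_params <- function(class) {
  ax <- 1.7e-3; rad <- 0.2e-3
  switch(class,
    wm1 = list(fibers = list(fiber_population(c(0, 0, 1), 0.8, ax, rad)),
               iso = 0.8e-3),
    wm2_crossing = list(fibers = list(
      fiber_population(c(1, 0, 0), 0.45, ax, rad),
      fiber_population(c(0, 1, 0), 0.45, ax, rad)), iso = 0.8e-3),
    wm3_crossing = list(fibers = list(
      fiber_population(c(1, 0, 0), 0.3, ax, rad),
      fiber_population(c(0, 1, 0), 0.3, ax, rad),
      fiber_population(c(0, 0, 1), 0.3, ax, rad)), iso = 0.8e-3),
    gm = list(fibers = list(), iso = 0.8e-3),
    csf = list(fibers = list(), iso = 3.0e-3),
    stop_invalid_input(sprintf("unknown phantom class '%s'", class)))
}

# Small random 3D rotation (angle ~ |N(0, jitter_sd^2)| about a random axis).
random_rotation <- function(jitter_sd) {
  ang <- stats::rnorm(1, sd = jitter_sd)
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' Synthetic multi-tissue diffusion phantom
#'
#' Simulates a small 4D data set containing voxels of canonical tissue
#' classes: `wm1` (single fibre, f = 0.8), `wm2_crossing` (two orthogonal
#' fibres, f = 0.45 each), `wm3_crossing` (three orthogonal fibres, f = 0.3
#' each), `gm` (isotropic, 0.8e-3 mm^2/s) and `csf` (isotropic, 3.0e-3
#' mm^2/s). Fibre orientations are jittered per voxel by a small random
#' rotation (sd `orient_jitter` radians); noise is applied per the noise
#' spec. Voxels are laid out on an x-y grid (z = 1); the noise-free signal
#' is returned alongside for validation.
#'
#' @param n_voxels_per_class count per class (scalar or one per class).
#' @param classes subset of the canonical class names.
#' @param scheme a [gradient_scheme()].
#' @param noise a [noise_spec()] (its seed is ignored; `seed` rules).
#' @param seed RNG seed for orientations and noise.
#' @param s0 non-diffusion-weighted signal level.
#' @param orient_jitter per-voxel orientation jitter (radians, sd).
#' @return List with `volumes` (4D array nx x ny x 1 x n_volumes), `truth`
#'   (noise-free 4D array), `labels` (3D character array, `""` for padding),
#'   `mask` (3D logical), and `scheme`.
#' @export
make_phantom <- function(n_voxels_per_class, classes = c("wm1", "wm2_crossing",
                                                         "wm3_crossing", "gm", "csf"),
                         scheme, noise = noise_spec("rician", 0), seed = NULL,
                         s0 = 1000, orient_jitter = 0.1) {
  stopifnot(inherits(scheme, "gradient_scheme"), inherits(noise, "noise_spec"))
  if (length(classes) < 1L) stop_invalid_input("classes must be non-empty")
  n_voxels_per_class <- rep_len(n_voxels_per_class, length(classes))
  labels_vec <- rep(classes, n_voxels_per_class)
  n_vox <- length(labels_vec)
  n_vol <- length(scheme$bvalues)

  with_seed(seed, {
    truth_mat <- matrix(0, n_vox, n_vol)
    for (v in seq_len(n_vox)) {
      par <- phantom_class_params(labels_vec[v])
      Rm <- random_rotation(orient_jitter)
      fibers <- lapply(par$fibers, function(f) {
        f$orientation <- as.numeric(Rm %*% f$orientation)
        f
      })
      vs <- simulate_voxel(fibers, iso_diffusivity = par$iso, s0 = s0,
                           scheme = scheme)
      full <- numeric(n_vol)
      full[scheme$is_b0] <- vs$b0_values
      full[!scheme$is_b0] <- vs$values
      truth_mat[v, ] <- full
    }
    noisy_mat <- truth_mat
    if (noise$kind != "none" && noise$sigma > 0) {
      spec2 <- noise_spec(noise$kind, noise$sigma, seed = NULL)
      noisy_mat <- matrix(add_noise(as.numeric(truth_mat), spec2),
                          n_vox, n_vol)
    }

    nx <- ceiling(sqrt(n_vox))
    ny <- ceiling(n_vox / nx)
    pad <- nx * ny - n_vox
    to4d <- function(m) {
      m <- rbind(m, matrix(0, pad, n_vol))
      array(m, dim = c(nx, ny, 1, n_vol))
    }
    labels <- array(c(labels_vec, rep("", pad)), dim = c(nx, ny, 1))
    mask <- array(c(rep(TRUE, n_vox), rep(FALSE, pad)), dim = c(nx, ny, 1))
    list(volumes = to4d(noisy_mat), truth = to4d(truth_mat),
         labels = labels, mask = mask, scheme = scheme)
  })
}
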