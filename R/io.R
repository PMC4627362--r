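#' Read an FSL-style gradient table
#'
#' The FSL dialect stores b-values as one whitespace-separated row and
#' gradient vectors as three rows (x, y and z components, one column per
#' volume). Vectors are normalised (with a warning if a norm deviates from 1
#' by more than 1e-3); zero vectors are allowed only for volumes at or below
#' the b0 threshold; shell clustering follows [gradient_scheme()].
#'
#' @param bvals_path,bvecs_path paths to the two text files.
#' @param b0_threshold,shell_tol passed to [gradient_scheme()].
#' @return A [gradient_scheme()].
#' @export
read_gradient_table <- function(bvals_path, bvecs_path, b0_threshold = 50,
                                shell_tol = 100) {
  if (!file.exists(bvals_path)) stop_format(sprintf("bvals file not found: %s", bvals_path))
  if (!file.exists(bvecs_path)) stop_format(sprintf("bvecs file not found: %s", bvecs_path))
  bvals <- tryCatch(scan(bvals_path, quiet = TRUE),
                    error = function(e) stop_format(sprintf(
                      "cannot parse bvals file %s: %s", bvals_path, conditionMessage(e))))
  bv <- tryCatch(as.matrix(utils::read.table(bvecs_path)),
                 error = function(e) stop_format(sprintf(
                   "cannot parse bvecs file %s: %s", bvecs_path, conditionMessage(e))))
  if (nrow(bv) != 3L) {
    stop_format(sprintf("bvecs must have 3 rows (x, y, z); found %d", nrow(bv)))
  }
  if (ncol(bv) != length(bvals)) {
    stop_format(sprintf(
      "bvals lists %d volumes but bvecs has %d columns", length(bvals), ncol(bv)))
  }
  gradient_scheme(t(bv), bvals, b0_threshold = b0_threshold,
                  shell_tol = shell_tol)
}

#' Write an FSL-style gradient table
#'
#' @param scheme a [gradient_scheme()].
#' @param bvals_path,bvecs_path output paths.
#' @export
write_gradient_table <- function(scheme, bvals_path, bvecs_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  writeLines(paste(format(scheme$bvalues, trim = TRUE, scientific = FALSE),
                   collapse = " "), bvals_path)
  rows <- apply(t(scheme$directions), 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " "))
  writeLines(rows, bvecs_path)
}

#' Read / write 4D diffusion volumes (NIfTI)
#'
#' `read_volumes` loads a 4D NIfTI file (and an optional 3D mask) and
#' returns a plain array plus provenance; `write_volumes` writes an array,
#' copying spatial metadata from a reference image when given. Gradient
#' directions are interpreted in the image coordinate frame as stored; no
#' reorientation through the NIfTI affine is attempted (sign flips are
#' irrelevant under axial symmetry; axis permutations are the caller's
#' responsibility).
#'
#' @param path NIfTI file (.nii or .nii.gz) with 4 dimensions.
#' @param mask_path optional 3D mask NIfTI; non-zero voxels are in-mask.
#' @return `read_volumes`: list with `volumes` (4D array), `mask` (3D
#'   logical array or `NULL`), `image` (the RNifti object, for reuse as a
#'   write reference) and `provenance` (paths).
#' @export
read_volumes <- function(path, mask_path = NULL) {
  if (!file.exists(path)) stop_format(sprintf("NIfTI file not found: %s", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) {
    stop_format(sprintf("expected a 4D NIfTI volume; %s has %d dimension(s)",
                        path, length(dim(arr))))
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path)) stop_format(sprintf("mask file not found: %s", mask_path))
    marr <- as.array(RNifti::readNifti(mask_path))
    if (length(dim(marr)) > 3L && all(dim(marr)[-(1:3)] == 1L)) {
      marr <- array(marr, dim(marr)[1:3])
    }
    # NIfTI readers drop trailing singleton dimensions; restore them
    if (length(dim(marr)) < 3L) {
      marr <- array(marr, c(dim(marr), rep(1L, 3L - length(dim(marr)))))
    }
    if (!identical(dim(marr)[1:3], dim(arr)[1:3]) || length(dim(marr)) != 3L) {
      stop_format(sprintf(
        "mask dimensions (%s) do not match data spatial dimensions (%s)",
        paste(dim(marr), collapse = "x"), paste(dim(arr)[1:3], collapse = "x")))
    }
    mask <- marr != 0
  }
  list(volumes = arr, mask = mask, image = img,
       provenance = list(path = path, mask_path = mask_path))
}

#' @rdname read_volumes
#' @param array array to write.
#' @param reference optional image (from `read_volumes()$image`) whose
#'   spatial metadata is copied.
#' @export
write_volumes <- function(array, path, reference = NULL) {
  img <- if (!is.null(reference)) {
    RNifti::asNifti(array, reference = reference)
  } else {
    RNifti::asNifti(array)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Bundle volumes, gradient scheme and mask with consistency checks
#'
#' @param volumes 4D array.
#' @param scheme a [gradient_scheme()]; its length must equal the number of
#'   volumes.
#' @param mask optional 3D logical array matching the spatial dimensions.
#' @param provenance free-form list of source paths / parse notes.
#' @return An object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(volumes, scheme, mask = NULL, provenance = list()) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  dims <- dim(volumes)
  if (length(dims) != 4L) stop_invalid_input("volumes must be a 4D array")
  if (dims[4] != length(scheme$bvalues)) {
    stop_invalid_input(sprintf(
      "data has %d volumes but the gradient table lists %d",
      dims[4], length(scheme$bvalues)))
  }
  if (!is.null(mask) && !identical(dim(mask)[1:3], dims[1:3])) {
    stop_format("mask shape does not match the data's spatial dimensions")
  }
  structure(list(volumes = volumes, scheme = scheme, mask = mask,
                 provenance = provenance),
            class = "dataset_bundle")
}

#' Plain-text key-value configuration files
#'
#' One `key = value` pair per line; blank lines and lines starting with `#`
#' are ignored. Values that parse fully as numbers become numeric vectors
#' (comma-separated lists supported); everything else stays character.
#' `write_config` serialises with 15 significant digits so that parse ->
#' serialise -> parse is the identity.
#'
#' @param path file path.
#' @return `read_config`: a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop_format(sprintf("config line without '=': %s", ln))
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (length(parts) && !any(is.na(num))) num else parts
  }
  out
}

#' @rdname read_config
#' @param config named list of scalars or vectors.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    vs <- if (is.numeric(v)) format(v, digits = 15, trim = TRUE,
                                    scientific = FALSE) else as.character(v)
    sprintf("%s = %s", k, paste(vs, collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write hyperparameter files (JSON)
#'
#' The on-disk format has keys `model`, `multishell`, `lambda`, `a`, `ell`
#' (absent for single-shell), `sigma2` (list), plus `criterion` and `seed`
#' when written from a fit.
#'
#' @param fit a [gp_hyper()] or [fit_hyperparameters()] result.
#' @param path file path.
#' @export
write_hyper <- function(fit, path) {
  if (inherits(fit, "gp_fit")) {
    hyper <- fit$hyper
    extra <- list(criterion = fit$criterion, seed = fit$seed,
                  objective_value = fit$objective_value,
                  converged = fit$converged)
  } else {
    stopifnot(inherits(fit, "gp_hyper"))
    hyper <- fit
    extra <- list()
  }
  obj <- c(list(model = hyper$model, multishell = hyper$multishell,
                lambda = hyper$lam, a = hyper$a),
           if (hyper$multishell) list(ell = hyper$ell),
           list(sigma2 = as.list(hyper$sigma2)), extra)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 12,
                              pretty = TRUE, null = "null"), path)
  invisible(path)
}

#' @rdname write_hyper
#' @return `read_hyper`: a [gp_hyper()].
#' @export
read_hyper <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("hyperparameter file not found: %s", path))
  obj <- jsonlite::fromJSON(path)
  gp_hyper(model = obj$model, lam = obj$lambda, a = obj$a,
           ell = if (isTRUE(obj$multishell)) obj$ell else NULL,
           sigma2 = unlist(obj$sigma2))
}
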