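## Bespoke BOLD preprocessing stages applied before the dual regression:
## mean WM/CSF nuisance regression, discrete-cosine high-pass filtering and
## Gaussian spatial smoothing. Each stage is a pure, exactly linear function.

#' Regress mean white-matter and CSF signals out of a BOLD series
#'
#' Extracts the mean time course over the (eroded, subject-specific) WM and
#' CSF masks and replaces every voxel time course by its least-squares
#' residual against `[1, mean WM, mean CSF]`. Degenerate (constant or
#' duplicated) nuisance regressors are dropped with a warning.
#'
#' @param bold a [bold4d()].
#' @param wm_mask,csf_mask non-empty logical 3D arrays on the BOLD grid.
#' @return a [bold4d()] whose voxel time courses are orthogonal to the
#'   retained regressors.
#' @export
regress_nuisance <- function(bold, wm_mask, csf_mask) {
  stopifnot(inherits(bold, "bold4d"))
  wm_mask <- as_mask(wm_mask, bold$grid, "wm_mask")
  csf_mask <- as_mask(csf_mask, bold$grid, "csf_mask")
  if (!any(wm_mask)) stop("WM mask is empty", call. = FALSE)
  if (!any(csf_mask)) stop("CSF mask is empty", call. = FALSE)
  y <- bold_matrix(bold)                       # T x V
  x <- cbind(intercept = 1,
             wm = rowMeans(y[, as.logical(wm_mask), drop = FALSE]),
             csf = rowMeans(y[, as.logical(csf_mask), drop = FALSE]))
  keep <- c(TRUE, vapply(2:3, function(j) pop_sd(x[, j]) > 1e-12, TRUE))
  if (!all(keep)) {
    warning("dropping degenerate nuisance regressor(s): ",
            paste(colnames(x)[!keep], collapse = ", "), call. = FALSE)
    x <- x[, keep, drop = FALSE]
  }
  qx <- qr(x)
  resid <- y - x %*% qr.coef(qx, y)
  bold4d(array(t(resid), dim = dim(bold$data)), bold$grid, bold$tr,
         bold$subject_id)
}

#' High-pass filter a BOLD series by discrete-cosine projection
#'
#' Removes slow drifts by projecting out the DC component and every
#' discrete-cosine basis function with frequency below `cutoff_hz`
#' (f_j = j / (2 T TR)). The operation is deterministic, exactly linear and
#' idempotent; the output is mean-free.
#'
#' @param bold a [bold4d()].
#' @param cutoff_hz cut-off frequency in Hz (default 0.005); must be positive
#'   and below the Nyquist frequency `1 / (2 TR)`.
#' @return the filtered [bold4d()].
#' @export
highpass_filter <- function(bold, cutoff_hz = 0.005) {
  stopifnot(inherits(bold, "bold4d"))
  stop_if_not_scalar_number(cutoff_hz, "cutoff_hz")
  if (cutoff_hz <= 0) stop("`cutoff_hz` must be > 0", call. = FALSE)
  nyquist <- 1 / (2 * bold$tr)
  if (cutoff_hz >= nyquist)
    stop(sprintf("`cutoff_hz` (%.4g Hz) must be below Nyquist (%.4g Hz)",
                 cutoff_hz, nyquist), call. = FALSE)
  tt <- n_volumes(bold)
  y <- bold_matrix(bold)                       # T x V
  y <- sweep(y, 2L, colMeans(y), "-")          # DC removal, always
  freqs <- seq_len(tt - 1L) / (2 * tt * bold$tr)
  j <- which(freqs < cutoff_hz)
  if (length(j)) {
    # orthonormal DCT-II basis columns below the cut-off
    tgrid <- seq_len(tt) - 0.5
    basis <- sqrt(2 / tt) * cos(outer(tgrid, j) * pi / tt)
    y <- y - basis %*% crossprod(basis, y)
  }
  bold4d(array(t(y), dim = dim(bold$data)), bold$grid, bold$tr,
         bold$subject_id)
}

#' Gaussian spatial smoothing of a 3D volume or 4D BOLD series
#'
#' Separable 3D Gaussian convolution with sigma = FWHM / (2 sqrt(2 ln 2)) per
#' axis, expressed in mm and divided by the voxel size. Boundaries are handled
#' by reflection, which preserves the global mean on small grids. Sequential
#' smooths combine as the root-sum-of-squares of their FWHMs (6 mm twice gives
#' an effective ~8.49 mm).
#'
#' @param x a [bold4d()], a [molecular_template()] or a 3D array.
#' @param fwhm_mm full width at half maximum in mm (>= 0; 0 is the identity).
#' @param grid required [volume_grid()] when `x` is a bare array.
#' @return the smoothed object, same type as the input.
#' @export
gaussian_smooth <- function(x, fwhm_mm = 6, grid = NULL) {
  stop_if_not_scalar_number(fwhm_mm, "fwhm_mm")
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(x)
  if (inherits(x, "bold4d")) {
    ops <- smoothing_operators(x$grid, fwhm_mm)
    out <- x$data
    for (t in seq_len(dim(out)[4]))
      out[, , , t] <- smooth3_apply(out[, , , t], ops)
    return(bold4d(out, x$grid, x$tr, x$subject_id))
  }
  if (inherits(x, "molecular_template")) {
    ops <- smoothing_operators(x$grid, fwhm_mm)
    data <- smooth3_apply(x$data, ops)
    data[!x$valid_mask] <- 0
    return(molecular_template(
      x$system_name, data, x$grid, valid_mask = x$valid_mask,
      reference_region = x$reference_region, reference_mask = x$reference_mask,
      provenance = c(x$provenance, sprintf("gaussian_smooth(%g mm)", fwhm_mm))))
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    if (is.null(grid)) grid <- volume_grid(dim(x), 1)
    ops <- smoothing_operators(grid, fwhm_mm)
    return(smooth3_apply(x, ops))
  }
  stop("`x` must be a bold4d, a molecular_template or a 3D array",
       call. = FALSE)
}

# Per-axis dense convolution matrices (reflective boundary), rows sum to 1.
smoothing_operators <- function(grid, fwhm_mm) {
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / grid$voxel_size
  lapply(1:3, function(ax) {
    n <- grid$shape[ax]
    s <- sigma_vox[ax]
    if (s < 1e-8) return(diag(n))
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    op <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- i + (-r:r)
      # reflect indices across the boundaries (period 2n, mirrored)
      idx <- abs(idx - 1) %% (2 * n)
      idx <- ifelse(idx >= n, 2 * n - 1 - idx, idx) + 1L
      for (m in seq_along(idx)) op[i, idx[m]] <- op[i, idx[m]] + k[m]
    }
    op
  })
}

smooth3_apply <- function(vol, ops) {
  d <- dim(vol)
  # axis 1
  m <- matrix(vol, d[1], d[2] * d[3])
  m <- ops[[1]] %*% m
  vol <- array(m, d)
  # axis 2
  p <- aperm(vol, c(2, 1, 3))
  m <- ops[[2]] %*% matrix(p, d[2], d[1] * d[3])
  vol <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  # axis 3
  p <- aperm(vol, c(3, 1, 2))
  m <- ops[[3]] %*% matrix(p, d[3], d[1] * d[2])
  aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Run the default preprocessing chain on one subject
#'
#' Smooth (6 mm) -> WM/CSF nuisance regression -> 0.005 Hz high-pass ->
#' smooth (6 mm), the stage order used before the dual regression; each stage
#' can be toggled or re-parameterized.
#'
#' @param bold a [bold4d()].
#' @param wm_mask,csf_mask logical 3D arrays (skipped if `NULL`).
#' @param fwhm_mm smoothing FWHM per pass, mm; `0` disables a pass.
#' @param cutoff_hz high-pass cut-off, Hz; `NULL` disables.
#' @return the preprocessed [bold4d()].
#' @export
preprocess_bold <- function(bold, wm_mask = NULL, csf_mask = NULL,
                            fwhm_mm = 6, cutoff_hz = 0.005) {
  out <- gaussian_smooth(bold, fwhm_mm)
  if (!is.null(wm_mask) && !is.null(csf_mask))
    out <- regress_nuisance(out, wm_mask, csf_mask)
  if (!is.null(cutoff_hz)) out <- highpass_filter(out, cutoff_hz)
  gaussian_smooth(out, fwhm_mm)
}
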