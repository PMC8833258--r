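## Synthetic molecular templates and subject BOLD series with known ground
## truth. Templates are smoothed, rectified Gaussian random fields: smoothing
## gives receptor-atlas-like spatial structure, rectification guarantees
## non-negativity with a genuine zero-density region, and a shared latent
## field tunes the pairwise overlap.

DEFAULT_SYSTEMS <- c("DAT", "NET", "SERT", "MOR")
# quantification reference region per default system (occipital for the
# SPECT/PET monoamine transporter and opioid maps, cerebellum for SERT)
DEFAULT_REF_REGIONS <- c(DAT = "occipital", NET = "occipital",
                         SERT = "cerebellum", MOR = "occipital")

#' Generate synthetic molecular density templates
#'
#' Produces `K` smooth non-negative density fields emulating transporter /
#' receptor atlases. Each field is a Gaussian random field (white noise
#' smoothed at `smoothness_mm` FWHM) mixed with a shared latent field so the
#' expected pairwise correlation before rectification equals `overlap`, then
#' shifted and rectified at its 30th percentile (guaranteeing a zero-density
#' region) and scaled to a maximum of 1. Each template carries a designated
#' reference-region sub-mask (a corner block, a different corner per system)
#' so reference masking can be exercised downstream.
#'
#' @param K number of systems (>= 1). Default names DAT, NET, SERT, MOR for
#'   K <= 4, then SYS5, ...
#' @param grid a [volume_grid()].
#' @param smoothness_mm FWHM of the field-generating smoothing kernel, mm.
#' @param overlap target pairwise spatial correlation in \[0, 1).
#' @param seed RNG seed; identical seed gives bit-identical templates.
#' @param system_names optional K labels.
#' @return list of K [molecular_template()] with `reference_mask` set.
#' @export
make_templates <- function(K, grid, smoothness_mm = 8, overlap = 0.3,
                           seed = 1, system_names = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  K <- as.integer(K)
  if (K < 1L) stop("`K` must be >= 1", call. = FALSE)
  stop_if_not_scalar_number(smoothness_mm, "smoothness_mm")
  if (smoothness_mm <= 0) stop("`smoothness_mm` must be > 0", call. = FALSE)
  if (overlap < 0 || overlap >= 1)
    stop("`overlap` must be in [0, 1)", call. = FALSE)
  if (n_voxels(grid) < 100L * K)
    stop(sprintf(
      "grid with %d voxels cannot support K = %d templates at the requested overlap (need >= %d voxels)",
      n_voxels(grid), K, 100L * K), call. = FALSE)
  if (is.null(system_names)) {
    system_names <- c(DEFAULT_SYSTEMS, paste0("SYS", seq_len(max(0, K - 4)) + 4))[seq_len(K)]
  }
  if (length(system_names) != K)
    stop("`system_names` must have K entries", call. = FALSE)
  ops <- smoothing_operators(grid, smoothness_mm)
  with_seed(seed, {
    # latent smooth fields: one shared + K own, orthogonalized across fields
    # so the pre-rectification pairwise correlation is exactly `overlap`
    # (smoothing leaves few effective degrees of freedom on desk-scale grids,
    # so raw sample correlations would otherwise wander far from the target)
    latent <- vapply(seq_len(K + 1L), function(i)
      as.vector(smooth3_apply(array(stats::rnorm(n_voxels(grid)),
                                    dim = grid$shape), ops)),
      numeric(n_voxels(grid)))
    latent <- demean_cols(latent)
    latent <- qr.Q(qr(latent)) * sqrt(n_voxels(grid))  # orthonormal, unit SD
    shared <- latent[, 1L]
    lapply(seq_len(K), function(k) {
      raw <- sqrt(overlap) * shared + sqrt(1 - overlap) * latent[, k + 1L]
      raw <- pmax(raw - stats::quantile(raw, 0.3), 0)
      dim(raw) <- grid$shape
      raw <- raw / max(raw)
      ref <- corner_block(grid, k)
      nm <- system_names[k]
      molecular_template(
        nm, raw, grid,
        reference_region = NA_character_,
        reference_mask = ref,
        provenance = sprintf(
          "make_templates(K=%d, smoothness_mm=%g, overlap=%g, seed=%s)",
          K, smoothness_mm, overlap, format(seed))
      )
    })
  })
}

#' Default reference-region label for a system name
#'
#' `"cerebellum"` for SERT, `"occipital"` for DAT, NET and MOR, `"ref"`
#' otherwise.
#' @param system_name label.
#' @return character scalar.
#' @export
default_reference_region <- function(system_name) {
  out <- unname(DEFAULT_REF_REGIONS[system_name])
  out[is.na(out)] <- "ref"
  out
}

# A block occupying ~1/4 of each axis, in corner (k mod 8); stands in for a
# quantification reference region.
corner_block <- function(grid, k) {
  s <- grid$shape
  len <- pmax(1L, s %/% 4L)
  bits <- c(k %% 2L, (k %/% 2L) %% 2L, (k %/% 4L) %% 2L)
  ref <- array(FALSE, dim = s)
  rng <- lapply(1:3, function(ax) {
    if (bits[ax] == 0L) seq_len(len[ax]) else (s[ax] - len[ax] + 1L):s[ax]
  })
  ref[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  ref
}

#' Synthesize one subject's 4D BOLD series from templates and system series
#'
#' Implements the generative model inverted by the dual regression: the
#' signal at voxel v and time t is `sum_k D_k(v) s_k(t)` plus white Gaussian
#' noise of standard deviation `noise_sd` (optionally spatially smoothed).
#' An optional per-system voxelwise `gain` multiplies template k's
#' contribution — this is how group FC effects are planted.
#'
#' @param templates list of K [molecular_template()] on one grid.
#' @param series T x K numeric matrix of system time courses.
#' @param noise_sd noise standard deviation (>= 0).
#' @param seed RNG seed (`NULL`: use current stream).
#' @param smooth_fwhm_mm optional spatial smoothing of the noise field, mm.
#' @param gain optional list of K 3D arrays (or a single array recycled)
#'   multiplying each template voxelwise; default all-ones.
#' @param tr repetition time, s.
#' @param subject_id label.
#' @return a [bold4d()].
#' @export
make_subject_bold <- function(templates, series, noise_sd = 1, seed = NULL,
                              smooth_fwhm_mm = 0, gain = NULL, tr = 2.5,
                              subject_id = "sub-01") {
  if (inherits(templates, "molecular_template")) templates <- list(templates)
  grid <- templates[[1]]$grid
  templates <- check_template_set(templates, grid)
  series <- as.matrix(series)
  if (!all(is.finite(series))) stop("`series` must be finite", call. = FALSE)
  k <- length(templates)
  if (ncol(series) != k)
    stop(sprintf("`series` has %d columns but there are %d templates",
                 ncol(series), k), call. = FALSE)
  tt <- nrow(series)
  if (tt < 2L) stop("need at least 2 time points", call. = FALSE)
  stop_if_not_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  d <- vapply(templates, function(tpl) as.vector(tpl$data),
              numeric(n_voxels(grid)))
  if (!is.null(gain)) {
    if (is.array(gain) || is.numeric(gain)) gain <- rep(list(gain), k)
    if (length(gain) != k)
      stop("`gain` must supply one field per template", call. = FALSE)
    for (kk in seq_len(k))
      d[, kk] <- d[, kk] * as.vector(as_vol(gain[[kk]], grid, "gain"))
  }
  signal <- d %*% t(series)                    # V x T
  out <- with_seed(seed, {
    if (noise_sd > 0) {
      eps <- matrix(stats::rnorm(length(signal), sd = noise_sd),
                    nrow = nrow(signal))
      if (smooth_fwhm_mm > 0) {
        ops <- smoothing_operators(grid, smooth_fwhm_mm)
        for (t in seq_len(tt)) {
          v <- eps[, t]; dim(v) <- grid$shape
          eps[, t] <- smooth3_apply(v, ops)
        }
      }
      signal + eps
    } else signal
  })
  bold4d(array(out, dim = c(grid$shape, tt)), grid, tr, subject_id)
}
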