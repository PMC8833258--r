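## The two-step dual regression at the heart of the package. Step 1 regresses
## each BOLD volume across voxels on the K molecular density templates to
## obtain the dominant fluctuation of each system's network; step 2 regresses
## each voxel's time course on those (standardized) fluctuations to obtain K
## subject-level enriched-FC maps.

#' Step 1: spatial regression of BOLD volumes on molecular templates
#'
#' For every time point, the masked BOLD volume is fitted across voxels by
#' least squares on the K template densities. Data and design are demeaned
#' across voxels within the mask before fitting, so regions of high density
#' dominate each system's recovered fluctuation. Solved by QR; a design
#' condition number above `kappa_max` aborts with the offending systems named.
#'
#' @param bold a [bold4d()].
#' @param templates list of [molecular_template()] on the BOLD grid.
#' @param mask an [build_analysis_mask()] result, or a logical 3D array; its
#'   voxel count must exceed K.
#' @param kappa_max condition-number failure threshold (default `1e8`).
#' @return a [system_series()] (T x K, not yet standardized) with attributes
#'   `kappa` (design condition number) and `n_mask_voxels`.
#' @export
fit_spatial_glm <- function(bold, templates, mask = NULL, kappa_max = 1e8) {
  stopifnot(inherits(bold, "bold4d"))
  templates <- check_template_set(templates, bold$grid)
  k <- length(templates)
  if (is.null(mask)) mask <- build_analysis_mask(templates)
  m <- if (inherits(mask, "analysis_mask")) mask$mask
       else as_mask(mask, bold$grid, "mask")
  nm <- sum(m)
  if (nm <= k)
    stop("analysis mask must contain more voxels than templates", call. = FALSE)
  design <- vapply(templates, function(tpl) tpl$data[m], numeric(nm))
  design <- demean_cols(design)
  y <- t(bold_matrix(bold, m))                  # voxels x T
  y <- demean_cols(y)
  qx <- qr(design)
  if (qx$rank < k) {
    dep <- vapply(templates, `[[`, "", "system_name")[-qx$pivot[seq_len(qx$rank)]]
    stop("template design is rank deficient; collinear system(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  kappa <- design_condition(design)
  if (kappa > kappa_max)
    stop(sprintf(
      "template design is ill-conditioned (kappa = %.3g > %.3g); systems: %s",
      kappa, kappa_max,
      paste(vapply(templates, `[[`, "", "system_name"), collapse = ", ")),
      call. = FALSE)
  coefs <- t(qr.coef(qx, y))                    # T x K
  out <- system_series(coefs,
                       vapply(templates, `[[`, "", "system_name"))
  attr(out, "kappa") <- kappa
  attr(out, "n_mask_voxels") <- nm
  out
}

design_condition <- function(x) {
  sv <- svd(x, nu = 0, nv = 0)$d
  if (min(sv) <= 0) Inf else max(sv) / min(sv)
}

check_template_set <- function(templates, grid) {
  if (inherits(templates, "molecular_template")) templates <- list(templates)
  if (!length(templates)) stop("need at least one template", call. = FALSE)
  stopifnot(all(vapply(templates, inherits, TRUE, "molecular_template")))
  for (tpl in templates)
    if (!same_grid(tpl$grid, grid))
      stop("template grid does not match the BOLD grid", call. = FALSE)
  templates
}

#' Standardize step-1 time series to zero mean and unit standard deviation
#'
#' Mirrors the demean + unit-SD design normalization applied to the temporal
#' design matrix before step 2. The population SD convention (divide by T) is
#' used and documented.
#'
#' @param series a [system_series()] or T x K matrix.
#' @return a standardized [system_series()] with `demeaned` and `unit_sd` set.
#' @export
standardize_series <- function(series) {
  s <- if (inherits(series, "system_series")) series$series else as.matrix(series)
  nms <- if (inherits(series, "system_series")) series$system_names
         else colnames(as.matrix(series))
  sds <- apply(s, 2L, pop_sd)
  if (any(sds < 1e-12)) {
    bad <- if (is.null(nms)) paste0("column ", which(sds < 1e-12))
           else nms[sds < 1e-12]
    stop("constant series cannot be standardized: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- sweep(sweep(s, 2L, colMeans(s), "-"), 2L, sds, "/")
  system_series(out, nms, demeaned = TRUE, unit_sd = TRUE)
}

#' Step 2: temporal regression of voxel time courses on system fluctuations
#'
#' For every voxel in `brain_mask`, the demeaned time course is fitted by
#' multivariate least squares on the K standardized system series, yielding K
#' beta maps of molecular-enriched FC. Voxels excluded from step 1 (e.g.
#' reference regions) are deliberately included here — BOLD is measured
#' everywhere — and may show positive or negative coupling. Zero-variance
#' voxels get beta 0 and are flagged.
#'
#' @param bold a [bold4d()].
#' @param series a standardized [system_series()] with T rows.
#' @param brain_mask logical 3D array (default: whole grid).
#' @return an [fc_maps()] on the `"beta"` scale.
#' @export
fit_temporal_glm <- function(bold, series, brain_mask = NULL) {
  stopifnot(inherits(bold, "bold4d"), inherits(series, "system_series"))
  if (!series$demeaned || !series$unit_sd)
    stop("`series` must be standardized first (see standardize_series())",
         call. = FALSE)
  x <- series$series
  tt <- n_volumes(bold)
  if (nrow(x) != tt)
    stop("series length does not match the BOLD series", call. = FALSE)
  k <- ncol(x)
  if (tt <= k) stop("need more volumes than regressors", call. = FALSE)
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = bold$grid$shape)
  brain_mask <- as_mask(brain_mask, bold$grid, "brain_mask")
  y <- bold_matrix(bold, brain_mask)            # T x V
  y <- sweep(y, 2L, colMeans(y), "-")
  zero_var <- apply(y, 2L, function(col) pop_sd(col) < 1e-12)
  beta <- qr.coef(qr(x), y)                     # K x V
  beta[, zero_var] <- 0
  maps <- vector("list", k)
  names(maps) <- series$system_names
  zv <- array(FALSE, dim = bold$grid$shape)
  zv[brain_mask] <- zero_var
  for (kk in seq_len(k)) {
    m <- array(0, dim = bold$grid$shape)
    m[brain_mask] <- beta[kk, ]
    maps[[kk]] <- m
  }
  fc_maps(maps, bold$grid, scale = "beta", subject_id = bold$subject_id,
          brain_mask = brain_mask, zero_variance_mask = zv)
}

#' Convert beta maps to across-voxel z-score maps
#'
#' Each subject map is standardized across the voxels of its brain mask
#' ((beta - mean) / SD, population SD), the display scale conventionally used
#' for enriched-FC networks. A per-map zero across-voxel variance is an error.
#'
#' @param maps an [fc_maps()] on the `"beta"` scale.
#' @return an [fc_maps()] on the `"z"` scale.
#' @export
to_zscore_maps <- function(maps) {
  stopifnot(inherits(maps, "fc_maps"))
  if (maps$scale != "beta")
    stop("`maps` must be on the beta scale", call. = FALSE)
  m <- maps$brain_mask
  out <- lapply(maps$maps, function(b) {
    v <- b[m]
    s <- pop_sd(v)
    if (s < 1e-12)
      stop("map has zero across-voxel variance; z-scale undefined",
           call. = FALSE)
    z <- b
    z[m] <- (v - mean(v)) / s
    z[!m] <- 0
    z
  })
  fc_maps(out, maps$grid, scale = "z", subject_id = maps$subject_id,
          brain_mask = m, zero_variance_mask = maps$zero_variance_mask)
}

#' Run the full two-step dual regression for one subject
#'
#' Composition `fit_spatial_glm()` -> `standardize_series()` ->
#' `fit_temporal_glm()` (-> `to_zscore_maps()` if `zscore = TRUE`). A
#' per-subject log (mask sizes, design condition number, zero-variance voxel
#' count) is attached as attribute `"log"`, and the standardized step-1 series
#' as attribute `"series"`.
#'
#' @param bold a [bold4d()].
#' @param templates list of [molecular_template()].
#' @param mask step-1 analysis mask (see [fit_spatial_glm()]); defaults to the
#'   intersection of the templates' valid masks.
#' @param brain_mask step-2 voxel set (default: whole grid).
#' @param zscore convert the beta maps to the z scale? Default `FALSE`.
#' @param kappa_max condition-number failure threshold for step 1.
#' @return an [fc_maps()].
#' @export
run_react <- function(bold, templates, mask = NULL, brain_mask = NULL,
                      zscore = FALSE, kappa_max = 1e8) {
  series <- fit_spatial_glm(bold, templates, mask, kappa_max = kappa_max)
  std <- standardize_series(series)
  maps <- fit_temporal_glm(bold, std, brain_mask)
  if (zscore) maps <- to_zscore_maps(maps)
  attr(maps, "series") <- std
  attr(maps, "log") <- list(
    subject_id = bold$subject_id,
    n_mask_voxels = attr(series, "n_mask_voxels"),
    kappa = attr(series, "kappa"),
    n_zero_variance = sum(maps$zero_variance_mask),
    zscore = zscore
  )
  maps
}
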