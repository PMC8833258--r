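## Core data containers: molecular templates, 4D BOLD series, step-1 time
## series and step-2 enriched-FC maps. Plain S3 lists over base arrays; grids
## carry the spatial metadata a NIfTI header would.

#' Molecular density template for one neurotransmitter system
#'
#' A 3D non-negative density field (e.g. a group-average DAT, NET, SERT or
#' mu-opioid receptor map) together with its validity mask. The valid mask is
#' the voxel set where density was quantifiable: grey matter minus the
#' radioligand's reference region (occipital cortex for DAT/NET/MOR,
#' cerebellum for SERT). Outside the valid mask the data are zero.
#'
#' @param system_name label, e.g. `"SERT"`.
#' @param data 3D numeric array on `grid`.
#' @param grid a [volume_grid()].
#' @param valid_mask logical 3D array; defaults to `data != 0 | TRUE` (all
#'   voxels valid).
#' @param reference_region label of the excluded quantification reference
#'   region, or `NA` if none has been masked out yet.
#' @param reference_mask optional logical 3D array marking that region (used by
#'   the synthetic generator so downstream masking can be exercised).
#' @param provenance character vector of operations applied, newest last.
#' @return an object of class `molecular_template`.
#' @export
molecular_template <- function(system_name, data, grid, valid_mask = NULL,
                               reference_region = NA_character_,
                               reference_mask = NULL,
                               provenance = character()) {
  data <- as_vol(data, grid, "data")
  if (is.null(valid_mask)) valid_mask <- array(TRUE, dim = grid$shape)
  valid_mask <- as_mask(valid_mask, grid, "valid_mask")
  if (!any(valid_mask)) stop("`valid_mask` must be non-empty", call. = FALSE)
  if (any(!is.finite(data))) stop("template data must be finite", call. = FALSE)
  data[!valid_mask] <- 0
  if (!is.null(reference_mask))
    reference_mask <- as_mask(reference_mask, grid, "reference_mask")
  structure(
    list(system_name = as.character(system_name), data = data, grid = grid,
         valid_mask = valid_mask, reference_region = reference_region,
         reference_mask = reference_mask, provenance = provenance),
    class = "molecular_template"
  )
}

#' @export
print.molecular_template <- function(x, ...) {
  cat(sprintf(
    "<molecular_template> %s on %s | %d valid voxels | ref region: %s\n",
    x$system_name, format(x$grid), sum(x$valid_mask),
    ifelse(is.na(x$reference_region), "(none)", x$reference_region)
  ))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' One subject's 4D BOLD series
#'
#' @param data 4D numeric array, three spatial axes then time.
#' @param grid a [volume_grid()] matching the spatial axes.
#' @param tr repetition time in seconds (> 0).
#' @param subject_id label.
#' @return an object of class `bold4d`.
#' @export
bold4d <- function(data, grid, tr, subject_id = "sub-01") {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)", call. = FALSE)
  if (!identical(dim(data)[1:3], grid$shape))
    stop("spatial dimensions of `data` do not match `grid`", call. = FALSE)
  if (dim(data)[4] < 2L) stop("need at least 2 volumes", call. = FALSE)
  if (!all(is.finite(data))) stop("BOLD data must be finite", call. = FALSE)
  stop_if_not_scalar_number(tr, "tr")
  if (tr <= 0) stop("`tr` must be > 0", call. = FALSE)
  structure(
    list(data = data, grid = grid, tr = as.double(tr),
         subject_id = as.character(subject_id)),
    class = "bold4d"
  )
}

#' @export
print.bold4d <- function(x, ...) {
  cat(sprintf("<bold4d> %s: %s, T = %d volumes, TR = %g s\n",
              x$subject_id, format(x$grid), dim(x$data)[4], x$tr))
  invisible(x)
}

n_volumes <- function(bold) dim(bold$data)[4]

# T x V matrix view of a bold4d restricted to `mask` (logical 3D or NULL).
bold_matrix <- function(bold, mask = NULL) {
  v <- matrix(bold$data, nrow = n_voxels(bold$grid), ncol = n_volumes(bold))
  if (!is.null(mask)) v <- v[as.logical(mask), , drop = FALSE]
  t(v)
}

#' Subject-level dominant BOLD fluctuations, one column per molecular system
#'
#' The T x K output of the first (spatial) regression step: at each time point
#' the masked BOLD volume is regressed across voxels on the K density
#' templates, so column k tracks the dominant fluctuation of system k's
#' functional network.
#'
#' @param series T x K numeric matrix.
#' @param system_names K labels.
#' @param demeaned,unit_sd logical flags recording the standardization state.
#' @return an object of class `system_series`.
#' @export
system_series <- function(series, system_names = colnames(series),
                          demeaned = FALSE, unit_sd = FALSE) {
  series <- as.matrix(series)
  if (is.null(system_names)) system_names <- paste0("sys", seq_len(ncol(series)))
  if (length(system_names) != ncol(series))
    stop("`system_names` must have one entry per column", call. = FALSE)
  if (!all(is.finite(series))) stop("series must be finite", call. = FALSE)
  colnames(series) <- system_names
  structure(
    list(series = series, system_names = as.character(system_names),
         demeaned = isTRUE(demeaned), unit_sd = isTRUE(unit_sd)),
    class = "system_series"
  )
}

#' @export
print.system_series <- function(x, ...) {
  cat(sprintf("<system_series> T = %d, K = %d (%s)%s\n",
              nrow(x$series), ncol(x$series),
              paste(x$system_names, collapse = ", "),
              if (x$demeaned && x$unit_sd) " [standardized]" else ""))
  invisible(x)
}

#' Molecular-enriched functional connectivity maps for one subject
#'
#' The K per-subject 3D maps from the second (temporal) regression step; map k
#' holds, per voxel, the regression weight of that voxel's time course on
#' system k's dominant fluctuation ("beta" scale) or its across-voxel z-scored
#' version ("z" scale).
#'
#' @param maps named list of K 3D arrays on `grid`.
#' @param grid a [volume_grid()].
#' @param scale `"beta"` or `"z"`.
#' @param subject_id label.
#' @param brain_mask logical 3D array over which the maps were estimated.
#' @param zero_variance_mask optional logical 3D array flagging voxels whose
#'   time course had zero variance (betas forced to 0 there).
#' @return an object of class `fc_maps`.
#' @export
fc_maps <- function(maps, grid, scale = c("beta", "z"), subject_id = "sub-01",
                    brain_mask = NULL, zero_variance_mask = NULL) {
  scale <- match.arg(scale)
  if (!length(maps)) stop("need at least one map", call. = FALSE)
  if (is.null(names(maps))) names(maps) <- paste0("sys", seq_along(maps))
  maps <- lapply(maps, as_vol, grid = grid, name = "map")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = grid$shape)
  brain_mask <- as_mask(brain_mask, grid, "brain_mask")
  for (m in maps)
    if (any(!is.finite(m[brain_mask])))
      stop("maps must be finite inside the brain mask", call. = FALSE)
  structure(
    list(maps = maps, grid = grid, scale = scale,
         subject_id = as.character(subject_id), brain_mask = brain_mask,
         zero_variance_mask = zero_variance_mask),
    class = "fc_maps"
  )
}

#' @export
print.fc_maps <- function(x, ...) {
  cat(sprintf("<fc_maps> %s: %d system map(s) [%s scale] on %s\n",
              x$subject_id, length(x$maps), x$scale, format(x$grid)))
  invisible(x)
}

## coercion helpers -----------------------------------------------------------

as_vol <- function(x, grid, name) {
  if (is.null(dim(x)) && length(x) == n_voxels(grid)) dim(x) <- grid$shape
  if (!is.array(x) || !identical(dim(x), grid$shape))
    stop(sprintf("`%s` must be a 3D array matching the grid (%s)",
                 name, paste(grid$shape, collapse = "x")), call. = FALSE)
  storage.mode(x) <- "double"
  x
}

as_mask <- function(x, grid, name) {
  if (is.null(dim(x)) && length(x) == n_voxels(grid)) dim(x) <- grid$shape
  if (!is.array(x) || !identical(dim(x), grid$shape))
    stop(sprintf("`%s` must be a 3D array matching the grid", name),
         call. = FALSE)
  if (is.numeric(x)) x <- x >= 0.5  # probabilistic masks threshold at 0.5
  if (!is.logical(x)) stop(sprintf("`%s` must be logical or numeric", name),
                           call. = FALSE)
  x[is.na(x)] <- FALSE
  x
}
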