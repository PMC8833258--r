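## Template preparation: turn raw molecular density images into
## analysis-ready templates (grey-matter masking, reference-region exclusion,
## min-max normalization, resampling, analysis-mask construction).

#' Exclude a radioligand's quantification reference region from a template
#'
#' PET/SPECT density maps are quantified against a reference region (occipital
#' cortex for DAT, NET and the mu-opioid receptor; cerebellum for SERT) where
#' target density cannot be measured; those voxels are removed from the
#' template's valid mask and zeroed before the spatial regression. They are
#' still analysed in the temporal (step-2) regression, where BOLD is measured
#' everywhere.
#'
#' @param template a [molecular_template()].
#' @param region_mask logical 3D array on the template grid (empty allowed:
#'   identity).
#' @param region_name label recorded as provenance, e.g. `"occipital"`.
#' @return the masked [molecular_template()].
#' @export
mask_reference_region <- function(template, region_mask,
                                  region_name = "reference") {
  stopifnot(inherits(template, "molecular_template"))
  region_mask <- as_mask(region_mask, template$grid, "region_mask")
  keep <- template$valid_mask & !region_mask
  if (!any(keep))
    stop("reference region covers every valid voxel", call. = FALSE)
  data <- template$data
  data[!keep] <- 0
  molecular_template(
    template$system_name, data, template$grid, valid_mask = keep,
    reference_region = region_name, reference_mask = region_mask,
    provenance = c(template$provenance,
                   sprintf("mask_reference_region(%s)", region_name))
  )
}

#' Min-max normalize a template to [0, 1] over its valid mask
#'
#' Linear (affine) rescaling of the valid voxel values so the minimum maps to
#' 0 and the maximum to 1; ranks and relative spacing of the original
#' intensity distribution are preserved.
#'
#' @param template a [molecular_template()].
#' @return the normalized [molecular_template()].
#' @export
minmax_normalize <- function(template) {
  stopifnot(inherits(template, "molecular_template"))
  v <- template$data[template$valid_mask]
  rng <- range(v)
  if (diff(rng) == 0)
    stop("template is constant over its valid mask; scale undefined",
         call. = FALSE)
  data <- template$data
  data[template$valid_mask] <- (v - rng[1]) / diff(rng)
  data[!template$valid_mask] <- 0
  out <- molecular_template(
    template$system_name, data, template$grid,
    valid_mask = template$valid_mask,
    reference_region = template$reference_region,
    reference_mask = template$reference_mask,
    provenance = c(template$provenance, "minmax_normalize")
  )
  out
}

#' Restrict a template to a grey-matter mask
#'
#' @param template a [molecular_template()].
#' @param gm_mask logical or probabilistic (threshold 0.5) 3D array.
#' @return the masked [molecular_template()].
#' @export
apply_gm_mask <- function(template, gm_mask) {
  stopifnot(inherits(template, "molecular_template"))
  gm_mask <- as_mask(gm_mask, template$grid, "gm_mask")
  keep <- template$valid_mask & gm_mask
  if (!any(keep))
    stop("grey-matter mask is disjoint from the template's valid voxels",
         call. = FALSE)
  data <- template$data
  data[!keep] <- 0
  molecular_template(
    template$system_name, data, template$grid, valid_mask = keep,
    reference_region = template$reference_region,
    reference_mask = template$reference_mask,
    provenance = c(template$provenance, "apply_gm_mask")
  )
}

#' Resample a template onto a target grid
#'
#' Density values are interpolated trilinearly (or by nearest neighbour for
#' `order = 0`) through the source and target affines; the valid mask is
#' resampled by nearest neighbour and re-binarized. Target voxels falling
#' outside the source support are 0 / invalid.
#'
#' @param template a [molecular_template()].
#' @param grid target [volume_grid()].
#' @param order interpolation order: 0 (nearest) or 1 (trilinear, default).
#' @return the resampled [molecular_template()].
#' @export
resample_to_grid <- function(template, grid, order = 1L) {
  stopifnot(inherits(template, "molecular_template"),
            inherits(grid, "volume_grid"))
  if (!order %in% c(0L, 1L)) stop("`order` must be 0 or 1", call. = FALSE)
  if (same_grid(template$grid, grid)) return(template)
  # target voxel centres in source voxel coordinates
  src <- world_to_voxel(template$grid, voxel_to_world(grid, grid_voxel_coords(grid)))
  data <- interp3(template$data, src, order = order)
  vm <- interp3(template$valid_mask + 0, src, order = 0L) >= 0.5
  dim(data) <- grid$shape
  dim(vm) <- grid$shape
  if (!any(vm))
    stop("resampled valid mask is empty: grids do not overlap", call. = FALSE)
  data[!vm] <- 0
  rm_new <- NULL
  if (!is.null(template$reference_mask)) {
    rm_new <- interp3(template$reference_mask + 0, src, order = 0L) >= 0.5
    dim(rm_new) <- grid$shape
  }
  molecular_template(
    template$system_name, data, grid, valid_mask = vm,
    reference_region = template$reference_region, reference_mask = rm_new,
    provenance = c(template$provenance,
                   sprintf("resample_to_grid(order=%d)", order))
  )
}

# Trilinear / nearest interpolation of a 3D array at 0-based coordinates
# (n x 3). Coordinates outside the array return 0.
interp3 <- function(vol, coords, order = 1L) {
  d <- dim(vol)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  if (order == 0L) {
    i <- round(x); j <- round(y); k <- round(z)
    ok <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 & k >= 0 & k <= d[3] - 1
    out <- numeric(nrow(coords))
    idx <- 1 + i[ok] + d[1] * (j[ok] + d[2] * k[ok])
    out[ok] <- vol[idx]
    return(out)
  }
  ok <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 & z >= 0 & z <= d[3] - 1
  out <- numeric(nrow(coords))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  z0 <- pmin(floor(z), d[3] - 2)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  at <- function(i, j, k) vol[1 + i + d[1] * (j + d[2] * k)]
  out[ok] <-
    at(x0,     y0,     z0)     * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x0 + 1, y0,     z0)     * fx       * (1 - fy) * (1 - fz) +
    at(x0,     y0 + 1, z0)     * (1 - fx) * fy       * (1 - fz) +
    at(x0 + 1, y0 + 1, z0)     * fx       * fy       * (1 - fz) +
    at(x0,     y0,     z0 + 1) * (1 - fx) * (1 - fy) * fz +
    at(x0 + 1, y0,     z0 + 1) * fx       * (1 - fy) * fz +
    at(x0,     y0 + 1, z0 + 1) * (1 - fx) * fy       * fz +
    at(x0 + 1, y0 + 1, z0 + 1) * fx       * fy       * fz
  out
}

#' Build the binarized analysis mask from a set of templates
#'
#' Step 1 of the dual regression fits one multivariate model with K spatial
#' regressors over a common voxel set, so the default mask is the intersection
#' of all templates' valid masks; the union is also returned for step-2
#' reporting, together with each system's own mask (a per-system mode is
#' available when fitting each system in its own support is preferred).
#'
#' @param templates list of [molecular_template()] on one grid.
#' @return an object of class `analysis_mask` with elements `mask`
#'   (intersection), `union_mask`, `per_system` (named list) and `n_voxels`.
#' @export
build_analysis_mask <- function(templates) {
  if (!length(templates)) stop("need at least one template", call. = FALSE)
  stopifnot(all(vapply(templates, inherits, TRUE, "molecular_template")))
  grid <- templates[[1]]$grid
  for (tpl in templates)
    if (!same_grid(tpl$grid, grid))
      stop("all templates must share one grid", call. = FALSE)
  per <- lapply(templates, `[[`, "valid_mask")
  names(per) <- vapply(templates, `[[`, "", "system_name")
  inter <- Reduce(`&`, per)
  uni <- Reduce(`|`, per)
  if (!any(inter))
    stop("intersection of template valid masks is empty", call. = FALSE)
  if (sum(inter) <= length(templates))
    stop("analysis mask has fewer voxels than regressors", call. = FALSE)
  structure(
    list(mask = inter, union_mask = uni, per_system = per,
         n_voxels = sum(inter), grid = grid),
    class = "analysis_mask"
  )
}

#' @export
print.analysis_mask <- function(x, ...) {
  cat(sprintf(
    "<analysis_mask> intersection: %d voxels, union: %d voxels, %d system(s)\n",
    x$n_voxels, sum(x$union_mask), length(x$per_system)))
  invisible(x)
}
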