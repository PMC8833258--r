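## Nonparametric group inference on subject-level FC maps: voxelwise t / F
## statistics with nuisance covariates, Freedman-Lane residual permutation,
## and family-wise-error control through the permutation null distribution of
## the maximum cluster size.

#' Stack one system's maps across subjects into an n x V matrix
#'
#' @param maps_list list of [fc_maps()], one per subject, on one grid.
#' @param system system name (or index) to extract.
#' @param mask logical 3D array restricting the voxel set (default: the first
#'   subject's brain mask).
#' @return n x V numeric matrix with subject ids as row names; the mask is
#'   attached as attribute `"mask"`.
#' @export
stack_system_maps <- function(maps_list, system = 1L, mask = NULL) {
  stopifnot(length(maps_list) >= 1L,
            all(vapply(maps_list, inherits, TRUE, "fc_maps")))
  grid <- maps_list[[1]]$grid
  if (is.null(mask)) mask <- maps_list[[1]]$brain_mask
  mask <- as_mask(mask, grid, "mask")
  y <- t(vapply(maps_list, function(m) {
    mm <- if (is.character(system)) m$maps[[system]] else m$maps[[system]]
    mm[mask]
  }, numeric(sum(mask))))
  rownames(y) <- vapply(maps_list, `[[`, "", "subject_id")
  attr(y, "mask") <- mask
  y
}

# Voxelwise t statistics for contrast `cvec` in the model Y = X B + E.
# Y: n x V, X: n x p. Returns list(t = length-V, df).
glm_tmap <- function(y, x, cvec) {
  n <- nrow(x); p <- ncol(x)
  qx <- qr(x)
  if (qx$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  b <- qr.coef(qx, y)                                    # p x V
  rss <- colSums((y - x %*% b)^2)
  df <- n - p
  xtxi_c <- drop(crossprod(cvec, chol2inv(qr.R(qx))) %*% cvec)
  se <- sqrt(pmax(rss, 0) / df * xtxi_c)
  tval <- drop(crossprod(cvec, b)) / se
  tval[se == 0] <- 0
  list(t = tval, df = df)
}

# Voxelwise partial F for dropping `effect_cols` from X. Returns
# list(f, df1, df2).
glm_fmap <- function(y, x, effect_cols) {
  n <- nrow(x); p <- ncol(x)
  q <- length(effect_cols)
  qx <- qr(x)
  if (qx$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  rss_full <- colSums(qr.resid(qx, y)^2)
  qz <- qr(x[, -effect_cols, drop = FALSE])
  rss_red <- colSums(qr.resid(qz, y)^2)
  df2 <- n - p
  fval <- ((rss_red - rss_full) / q) / (rss_full / df2)
  fval[rss_full <= 0] <- 0
  list(f = pmax(fval, 0), df1 = q, df2 = df2)
}

# Freedman-Lane permutation scaffolding: residualize Y against the nuisance
# columns Z, keep the fitted nuisance part to add back under each relabelling.
freedman_lane_parts <- function(y, x, effect_cols) {
  z <- x[, -effect_cols, drop = FALSE]
  if (ncol(z) == 0L) return(list(resid = y, fitted = 0 * y))
  qz <- qr(z)
  fitted <- z %*% qr.coef(qz, y)
  list(resid = y - fitted, fitted = fitted)
}

# Permutation index matrix (n_perm x n). Exhaustive two-group mode builds one
# representative row permutation per distinct group relabelling (identity
# first).
build_permutations <- function(n, n_perm, seed, exhaustive, group = NULL) {
  if (exhaustive) {
    if (is.null(group)) stop("exhaustive mode needs the group coding",
                             call. = FALSE)
    g <- as.integer(factor(group))
    if (length(unique(g)) != 2L)
      stop("exhaustive enumeration implemented for two groups", call. = FALSE)
    a_pos <- which(g == 1L)
    subsets <- utils::combn(n, length(a_pos))
    perms <- t(apply(subsets, 2L, function(s) {
      perm <- integer(n)
      perm[a_pos] <- s                      # new rows taking group-A slots
      perm[-a_pos] <- setdiff(seq_len(n), s)
      perm
    }))
    # put the identity first for readability
    id_row <- which(apply(perms, 1L, identical, y = seq_len(n)))
    if (length(id_row)) perms <- perms[c(id_row, setdiff(seq_len(nrow(perms)), id_row)), ]
    return(perms)
  }
  with_seed(seed, t(vapply(seq_len(n_perm), function(i) sample.int(n),
                           integer(n))))
}

perm_cluster_engine <- function(y, mask, x, effect_cols, stat_fun, thr,
                                connectivity, n_perm, seed, exhaustive,
                                group = NULL) {
  n <- nrow(y)
  d <- dim(mask)
  off <- connectivity_offsets(as.integer(connectivity))
  to_map <- function(v) { m <- array(-Inf, dim = d); m[mask] <- v; m }

  obs_stat <- stat_fun(y)
  obs_map <- to_map(obs_stat)
  cs <- label_clusters(obs_map, thr, connectivity)

  fl <- freedman_lane_parts(y, x, effect_cols)
  perms <- build_permutations(n, n_perm, seed, exhaustive, group)
  null_max <- integer(nrow(perms))
  for (i in seq_len(nrow(perms))) {
    ystar <- fl$resid[perms[i, ], , drop = FALSE] + fl$fitted
    null_max[i] <- max_cluster_size(to_map(stat_fun(ystar)), thr, off)
  }
  if (nrow(cs$clusters)) {
    cs$clusters$p_fwe <- if (exhaustive) {
      # exact enumeration: the identity relabelling is part of the null set
      vapply(cs$clusters$size,
             function(s) mean(null_max >= s), numeric(1))
    } else {
      vapply(cs$clusters$size,
             function(s) (1 + sum(null_max >= s)) / (1 + length(null_max)),
             numeric(1))
    }
  } else {
    cs$clusters$p_fwe <- numeric(0)
  }
  stat_map <- array(0, dim = d)
  stat_map[mask] <- obs_stat
  structure(
    list(stat_map = stat_map, mask = mask, cf_threshold = thr,
         clusters = cs$clusters, label_map = cs$label_map,
         null_max_sizes = null_max, n_perm = nrow(perms),
         connectivity = as.integer(connectivity),
         exhaustive = exhaustive, seed = seed),
    class = "cluster_inference"
  )
}

#' @export
print.cluster_inference <- function(x, ...) {
  cat(sprintf(
    "<cluster_inference> cf threshold = %.3f, %d permutation(s)%s, %d cluster(s)\n",
    x$cf_threshold, x$n_perm, if (x$exhaustive) " (exhaustive)" else "",
    nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Permutation two-sample t-test with max-cluster-size FWE correction
#'
#' Fits the voxelwise model `Y ~ design`, thresholds the one-sided contrast
#' t-map at the cluster-forming threshold, and assigns each suprathreshold
#' cluster an FWE-corrected p-value against the permutation null distribution
#' of the maximum cluster size across the image. Nuisance covariates (design
#' columns with zero contrast weight) are respected by Freedman-Lane
#' permutation: reduced-model residuals are permuted and the nuisance fit
#' added back before refitting the full model. For random permutations
#' `p_fwe = (1 + #\{null >= observed\}) / (1 + n_perm)`; in exhaustive mode
#' the exact enumeration proportion (identity included) is reported.
#'
#' @param y n x V matrix of subject map values (see [stack_system_maps()]).
#' @param mask logical 3D array mapping the V columns back into the volume.
#' @param design n x p numeric design matrix (include the intercept).
#' @param contrast length-p contrast vector; its non-zero entries define the
#'   effect columns, the rest are nuisance. One-sided: clusters are formed
#'   where `t > cf_threshold`.
#' @param n_perm number of random permutations (default 5000; < 100 warns).
#' @param cft_p one-sided p-value defining the default cluster-forming
#'   threshold via the t distribution's null quantile (default 0.01).
#' @param cf_threshold explicit statistic threshold overriding `cft_p`.
#' @param connectivity 6, 18 or 26 (default).
#' @param seed RNG seed for the permutation stream.
#' @param exhaustive enumerate all distinct two-group relabellings instead of
#'   sampling (requires an intercept + binary group + no further effect
#'   structure beyond nuisance columns).
#' @return a `cluster_inference` object.
#' @export
permutation_ttest_clusters <- function(y, mask, design, contrast,
                                       n_perm = 5000, cft_p = 0.01,
                                       cf_threshold = NULL,
                                       connectivity = 26L, seed = 1,
                                       exhaustive = FALSE) {
  y <- as.matrix(y)
  design <- as.matrix(design)
  mask <- as_mask(mask, volume_grid(dim(mask), 1), "mask")
  n <- nrow(y); p <- ncol(design)
  if (nrow(design) != n) stop("design/map row mismatch", call. = FALSE)
  if (length(contrast) != p)
    stop("contrast length must equal the number of design columns",
         call. = FALSE)
  effect_cols <- which(contrast != 0)
  if (!length(effect_cols)) stop("contrast is all zero", call. = FALSE)
  grp <- design[, effect_cols[1]]
  if (length(unique(grp)) == 2L && min(table(grp)) < 2L)
    stop("fewer than 2 subjects per group", call. = FALSE)
  if (!exhaustive && n_perm < 100)
    warning("n_perm < 100 gives a very coarse FWE p-value", call. = FALSE)
  df <- n - p
  if (df < 1L) stop("no residual degrees of freedom", call. = FALSE)
  thr <- if (is.null(cf_threshold)) stats::qt(1 - cft_p, df) else cf_threshold
  stat_fun <- function(yy) glm_tmap(yy, design, contrast)$t
  perm_cluster_engine(y, mask, design, effect_cols, stat_fun, thr,
                      connectivity, n_perm, seed, exhaustive, group = grp)
}

#' Permutation 2x2 interaction ANCOVA with max-cluster-size FWE correction
#'
#' Builds the design `[1, A, B, A:B, covariates]` with effect-coded factors
#' (+/- 1/2), computes the voxelwise partial F for the interaction column,
#' and runs the same Freedman-Lane max-cluster-size machinery as
#' [permutation_ttest_clusters()] (nuisance = everything but the
#' interaction).
#'
#' @param y n x V matrix of subject map values.
#' @param mask logical 3D array mapping columns into the volume.
#' @param factor_a,factor_b two-level factors (e.g. treatment arm, responder
#'   status); all four cells must be non-empty.
#' @param covariates optional n x c numeric matrix (e.g. age, gender).
#' @param n_perm,cft_p,cf_threshold,connectivity,seed as in
#'   [permutation_ttest_clusters()]; the default threshold is the
#'   `1 - cft_p` quantile of the null F(1, n - p) distribution.
#' @return a `cluster_inference` object.
#' @export
permutation_interaction_f <- function(y, mask, factor_a, factor_b,
                                      covariates = NULL, n_perm = 5000,
                                      cft_p = 0.01, cf_threshold = NULL,
                                      connectivity = 26L, seed = 1) {
  y <- as.matrix(y)
  a <- as.integer(factor(factor_a)); b <- as.integer(factor(factor_b))
  if (length(unique(a)) != 2L || length(unique(b)) != 2L)
    stop("both factors must have exactly two levels", call. = FALSE)
  if (any(table(factor_a, factor_b) == 0L))
    stop("all four factor cells must be non-empty", call. = FALSE)
  ac <- a - 1.5; bc <- b - 1.5                  # effect coding +/- 0.5
  design <- cbind(intercept = 1, a = ac, b = bc, ab = ac * bc)
  if (!is.null(covariates)) design <- cbind(design, as.matrix(covariates))
  mask <- as_mask(mask, volume_grid(dim(mask), 1), "mask")
  n <- nrow(y); p <- ncol(design)
  df2 <- n - p
  if (df2 < 1L) stop("no residual degrees of freedom", call. = FALSE)
  thr <- if (is.null(cf_threshold)) stats::qf(1 - cft_p, 1, df2)
         else cf_threshold
  effect_cols <- 4L
  stat_fun <- function(yy) glm_fmap(yy, design, effect_cols)$f
  perm_cluster_engine(y, mask, design, effect_cols, stat_fun, thr,
                      connectivity, n_perm, seed, exhaustive = FALSE)
}

#' Bonferroni adjustment across molecular systems and contrasts
#'
#' `p_adj = min(1, m * p)`; used to correct cluster FWE p-values across the
#' family of K systems x contrasts tested.
#'
#' @param p_values numeric vector in (0, 1].
#' @param m family size (>= 1); defaults to `length(p_values)`.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  pmin(1, m * p_values)
}

#' Extract per-subject mean FC over significant clusters
#'
#' The subject-level summary used for hypothesis-driven follow-up: the mean
#' map value over a cluster mask, optionally averaged across several cluster
#' masks when they cover overlapping anatomy and a single pooled value is
#' wanted.
#'
#' @param maps_list list of [fc_maps()], or an n x V matrix with attribute
#'   `"mask"` (as returned by [stack_system_maps()]).
#' @param cluster_mask logical 3D array, or a list of them.
#' @param system system selector when `maps_list` is a list of maps.
#' @param average_clusters average the per-cluster means into one column?
#' @return data.frame with `subject_id`, one `mean_fc_<i>` column per cluster
#'   mask, and `mean_fc` (the across-cluster average).
#' @export
extract_cluster_means <- function(maps_list, cluster_mask, system = 1L,
                                  average_clusters = TRUE) {
  if (is.matrix(maps_list)) {
    y <- maps_list
    mask <- attr(y, "mask")
    if (is.null(mask)) stop("matrix input needs a \"mask\" attribute",
                            call. = FALSE)
    ids <- rownames(y)
    grid <- volume_grid(dim(mask), 1)
  } else {
    grid <- maps_list[[1]]$grid
    mask <- array(TRUE, dim = grid$shape)
    y <- stack_system_maps(maps_list, system, mask)
    ids <- rownames(y)
  }
  if (is.null(ids)) ids <- sprintf("sub-%02d", seq_len(nrow(y)))
  if (!is.list(cluster_mask)) cluster_mask <- list(cluster_mask)
  cols <- lapply(cluster_mask, function(cm) {
    cm <- as_mask(cm, grid, "cluster_mask")
    sel <- which(cm[mask])
    if (!length(sel)) {
      if (!any(cm)) stop("cluster mask is empty", call. = FALSE)
      stop("cluster mask lies outside the analysed voxel set", call. = FALSE)
    }
    rowMeans(y[, sel, drop = FALSE])
  })
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (i in seq_along(cols)) out[[paste0("mean_fc_", i)]] <- cols[[i]]
  if (average_clusters)
    out$mean_fc <- rowMeans(as.matrix(as.data.frame(cols)))
  out
}
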