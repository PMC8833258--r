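## Connected-component labelling of suprathreshold voxels in a 3D statistic
## map. Pure-R breadth-first flood fill over the suprathreshold set: under a
## permutation null only a small fraction of voxels exceed the
## cluster-forming threshold, so compiled code buys nothing here.

connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

#' Label suprathreshold clusters of a 3D statistic map
#'
#' Connected components of `{voxel : stat > cf_threshold}` (strict
#' inequality) under 6-, 18- or 26-neighbour connectivity. Peak coordinates
#' are reported 0-based, mirroring the voxel-coordinate convention of
#' neuroimaging cluster tables.
#'
#' @param stat_map 3D numeric array.
#' @param cf_threshold finite cluster-forming threshold.
#' @param connectivity 6, 18 or 26 (default).
#' @return object of class `cluster_set`: list with `clusters` (data.frame:
#'   label, size, peak_stat, peak_x/y/z 0-based), `label_map` (integer 3D
#'   array, 0 = background) and `n_clusters`. Labels are ordered by
#'   decreasing size (ties: discovery order).
#' @export
label_clusters <- function(stat_map, cf_threshold, connectivity = 26L) {
  if (!is.array(stat_map) || length(dim(stat_map)) != 3L)
    stop("`stat_map` must be a 3D array", call. = FALSE)
  stop_if_not_scalar_number(cf_threshold, "cf_threshold")
  off <- connectivity_offsets(as.integer(connectivity))
  d <- dim(stat_map)
  supra <- which(stat_map > cf_threshold)
  lab <- array(0L, dim = d)
  if (length(supra)) {
    in_set <- array(FALSE, dim = d)
    in_set[supra] <- TRUE
    nxt <- 0L
    for (s in supra) {
      if (lab[s] != 0L) next
      nxt <- nxt + 1L
      frontier <- s
      lab[s] <- nxt
      while (length(frontier)) {
        # expand the whole frontier at once
        i0 <- (frontier - 1L) %% d[1]
        j0 <- ((frontier - 1L) %/% d[1]) %% d[2]
        k0 <- (frontier - 1L) %/% (d[1] * d[2])
        ni <- rep(i0, each = nrow(off)) + off[, 1]
        nj <- rep(j0, each = nrow(off)) + off[, 2]
        nk <- rep(k0, each = nrow(off)) + off[, 3]
        ok <- ni >= 0 & ni < d[1] & nj >= 0 & nj < d[2] & nk >= 0 & nk < d[3]
        cand <- unique(1L + ni[ok] + d[1] * (nj[ok] + d[2] * nk[ok]))
        cand <- cand[in_set[cand] & lab[cand] == 0L]
        lab[cand] <- nxt
        frontier <- cand
      }
    }
  }
  build_cluster_set(stat_map, lab)
}

build_cluster_set <- function(stat_map, lab) {
  nlab <- max(lab)
  if (nlab == 0L) {
    clusters <- data.frame(label = integer(), size = integer(),
                           peak_stat = numeric(), peak_x = integer(),
                           peak_y = integer(), peak_z = integer())
  } else {
    d <- dim(stat_map)
    rows <- lapply(seq_len(nlab), function(l) {
      idx <- which(lab == l)
      pk <- idx[which.max(stat_map[idx])]
      data.frame(
        label = l, size = length(idx), peak_stat = stat_map[pk],
        peak_x = (pk - 1L) %% d[1],
        peak_y = ((pk - 1L) %/% d[1]) %% d[2],
        peak_z = (pk - 1L) %/% (d[1] * d[2])
      )
    })
    clusters <- do.call(rbind, rows)
    ord <- order(-clusters$size, clusters$label)
    clusters <- clusters[ord, , drop = FALSE]
    relab <- integer(nlab)
    relab[clusters$label] <- seq_len(nlab)
    lab[lab > 0L] <- relab[lab[lab > 0L]]
    clusters$label <- seq_len(nlab)
    rownames(clusters) <- NULL
  }
  structure(list(clusters = clusters, label_map = lab, n_clusters = nlab),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s)\n", x$n_clusters))
  if (x$n_clusters) print(x$clusters)
  invisible(x)
}

# Max cluster size of {stat > thr}; cheap path for the permutation null.
max_cluster_size <- function(stat_map, cf_threshold, off) {
  d <- dim(stat_map)
  supra <- which(stat_map > cf_threshold)
  if (!length(supra)) return(0L)
  in_set <- array(FALSE, dim = d)
  in_set[supra] <- TRUE
  seen <- array(FALSE, dim = d)
  best <- 0L
  for (s in supra) {
    if (seen[s]) next
    size <- 1L
    seen[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      i0 <- (frontier - 1L) %% d[1]
      j0 <- ((frontier - 1L) %/% d[1]) %% d[2]
      k0 <- (frontier - 1L) %/% (d[1] * d[2])
      ni <- rep(i0, each = nrow(off)) + off[, 1]
      nj <- rep(j0, each = nrow(off)) + off[, 2]
      nk <- rep(k0, each = nrow(off)) + off[, 3]
      ok <- ni >= 0 & ni < d[1] & nj >= 0 & nj < d[2] & nk >= 0 & nk < d[3]
      cand <- unique(1L + ni[ok] + d[1] * (nj[ok] + d[2] * nk[ok]))
      cand <- cand[in_set[cand] & !seen[cand]]
      seen[cand] <- TRUE
      size <- size + length(cand)
      frontier <- cand
    }
    best <- max(best, size)
  }
  best
}
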