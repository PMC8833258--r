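test_that("label_clusters: trivial cases, connectivity semantics, flood-fill
           oracle", {
  d <- c(6, 6, 6)
  # all sub-threshold: zero clusters
  expect_equal(label_clusters(array(0, dim = d), 1)$n_clusters, 0L)

  # two voxels touching only at a corner: one cluster under 26, two under 6
  m <- array(0, dim = d)
  m[2, 2, 2] <- 5; m[3, 3, 3] <- 5
  expect_equal(label_clusters(m, 1, 26)$n_clusters, 1L)
  expect_equal(label_clusters(m, 1, 6)$n_clusters, 2L)
  # edge-touching voxels merge under 18 but not 6
  m2 <- array(0, dim = d)
  m2[2, 2, 2] <- 5; m2[3, 3, 2] <- 5
  expect_equal(label_clusters(m2, 1, 18)$n_clusters, 1L)
  expect_equal(label_clusters(m2, 1, 6)$n_clusters, 2L)

  # peak bookkeeping: 0-based voxel coordinates of the maximum
  cl <- label_clusters(m, 1, 26)$clusters
  expect_equal(cl$size, 2L)
  expect_true(all(cl[, c("peak_x", "peak_y", "peak_z")] == 1))

  # random binary maps against the independent flood-fill oracle, all
  # connectivities
  set.seed(30)
  for (conn in c(6L, 18L, 26L)) {
    stat <- array(rnorm(12^3), dim = c(12, 12, 12))
    got <- label_clusters(stat, 0.8, conn)
    oracle <- floodfill_oracle(stat > 0.8, conn)
    # same partition: compare sorted component sizes and total coverage
    expect_equal(sort(got$clusters$size),
                 sort(unname(as.vector(table(oracle[oracle > 0])))))
    expect_equal(got$label_map > 0, oracle > 0)
    # voxels sharing a package label share an oracle label
    for (l in seq_len(got$n_clusters)) {
      expect_equal(length(unique(oracle[got$label_map == l])), 1L)
    }
  }
})

test_that("cluster size is monotone non-increasing in the threshold", {
  set.seed(31)
  stat <- gaussian_smooth(array(rnorm(10^3), dim = c(10, 10, 10)), 4,
                          grid = tiny_grid(10))
  thrs <- quantile(stat, c(0.8, 0.9, 0.95))
  sizes <- vapply(thrs, function(th) {
    cl <- label_clusters(stat, th)
    if (cl$n_clusters) max(cl$clusters$size) else 0L
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("permutation_ttest_clusters: null identity, determinism,
           Freedman-Lane with covariates", {
  set.seed(32)
  msk <- array(TRUE, dim = c(8, 8, 8))
  n <- 12
  y <- matrix(rnorm(n * 512), n, 512)
  y[7:12, ] <- y[1:6, ]                          # two literally equal groups
  grp <- rep(0:1, each = 6)
  x <- cbind(1, grp)
  res <- permutation_ttest_clusters(y, msk, x, c(0, 1), n_perm = 120,
                                    seed = 2)
  expect_lt(max(abs(res$stat_map)), 1e-6)
  expect_equal(nrow(res$clusters), 0L)

  # seeded determinism of the null distribution and p-values
  y2 <- matrix(rnorm(n * 512), n, 512)
  r1 <- permutation_ttest_clusters(y2, msk, x, c(0, 1), n_perm = 150,
                                   seed = 5)
  r2 <- permutation_ttest_clusters(y2, msk, x, c(0, 1), n_perm = 150,
                                   seed = 5)
  expect_identical(r1$null_max_sizes, r2$null_max_sizes)
  expect_identical(r1$clusters, r2$clusters)

  # observed t-map equals a per-voxel lm fit, with covariates present
  age <- rnorm(n, 57, 7); gender <- rbinom(n, 1, 0.5)
  xc <- cbind(1, grp, age, gender)
  rc <- permutation_ttest_clusters(y2, msk, xc, c(0, 1, 0, 0), n_perm = 120,
                                   seed = 1)
  idx <- c(1, 100, 500)
  for (v in idx) {
    fit <- summary(lm(y2[, v] ~ grp + age + gender))
    expect_equal(rc$stat_map[which(msk)[v]],
                 unname(fit$coefficients["grp", "t value"]),
                 tolerance = 1e-10)
  }

  # p_fwe convention (1 + #{null >= obs}) / (1 + n_perm)
  if (nrow(rc$clusters)) {
    s0 <- rc$clusters$size[1]
    expect_equal(rc$clusters$p_fwe[1],
                 (1 + sum(rc$null_max_sizes >= s0)) / (1 + rc$n_perm))
  }

  expect_error(permutation_ttest_clusters(y2[c(1, 2, 7), ], msk,
                                          x[c(1, 2, 7), ], c(0, 1),
                                          n_perm = 100),
               "fewer than 2")
  expect_warning(permutation_ttest_clusters(y2, msk, x, c(0, 1), n_perm = 50,
                                            seed = 1), "coarse")
})

test_that("exhaustive two-group enumeration matches an independent
           enumeration oracle", {
  set.seed(33)
  d <- c(6, 6, 6); v <- prod(d)
  msk <- array(TRUE, dim = d)
  grp <- rep(0:1, each = 3)
  x <- cbind(1, grp)
  y <- matrix(rnorm(6 * v), 6, v)
  y[4:6, 1:40] <- y[4:6, 1:40] + 2.5             # planted difference
  thr <- qt(0.99, 4)
  res <- permutation_ttest_clusters(y, msk, x, c(0, 1), cf_threshold = thr,
                                    exhaustive = TRUE)
  expect_equal(res$n_perm, choose(6, 3))

  # oracle: enumerate the 20 relabellings directly with normal-equations t
  tmap_for <- function(labels) {
    xx <- cbind(1, labels)
    b <- ols_oracle(xx, y)
    rss <- colSums((y - xx %*% b)^2)
    se <- sqrt(rss / 4 * solve(t(xx) %*% xx)[2, 2])
    b[2, ] / se
  }
  combs <- combn(6, 3)
  null_sizes <- apply(combs, 2, function(s) {
    labels <- rep(0, 6); labels[s] <- 1
    tm <- array(-Inf, dim = d); tm[msk] <- tmap_for(labels)
    lab <- floodfill_oracle(tm > thr, 26)
    if (max(lab) == 0) 0L else max(table(lab[lab > 0]))
  })
  expect_equal(sort(as.integer(res$null_max_sizes)),
               sort(as.integer(null_sizes)))
  # p-values equal the exact enumeration proportion for every cluster
  for (i in seq_len(nrow(res$clusters))) {
    expect_equal(res$clusters$p_fwe[i],
                 mean(null_sizes >= res$clusters$size[i]))
  }
})

test_that("permutation_interaction_f: additive null, planted effect,
           factor-swap symmetry", {
  set.seed(34)
  d <- c(8, 8, 8); v <- prod(d)
  msk <- array(TRUE, dim = d)
  n_cell <- 5
  a <- rep(c("placebo", "duloxetine"), each = 2 * n_cell)
  b <- rep(rep(c("R", "NR"), each = n_cell), 2)
  age <- rnorm(4 * n_cell, 57, 7); gender <- rbinom(4 * n_cell, 1, 0.5)

  # purely additive data: interaction F small, no significant clusters
  y_add <- matrix(rnorm(4 * n_cell * v), ncol = v) +
    outer(as.numeric(factor(a)), rep(0.8, v)) +
    outer(as.numeric(factor(b)), rep(-0.5, v))
  r_add <- permutation_interaction_f(y_add, msk, a, b,
                                     covariates = cbind(age, gender),
                                     n_perm = 150, seed = 3)
  expect_true(all(r_add$clusters$p_fwe > 0.05) || nrow(r_add$clusters) == 0)

  # crossed effect inside a known region is detected there
  region <- 1:60
  y_x <- matrix(rnorm(4 * n_cell * v), ncol = v)
  delta <- ifelse(b == "R", 1, -1) * ifelse(a == "duloxetine", 1, -1) * 1.8
  y_x[, region] <- y_x[, region] + delta
  r_x <- permutation_interaction_f(y_x, msk, a, b,
                                   covariates = cbind(age, gender),
                                   n_perm = 200, seed = 4)
  expect_gt(nrow(r_x$clusters), 0)
  top <- r_x$clusters[which.min(r_x$clusters$p_fwe), ]
  expect_lt(top$p_fwe, 0.05)
  hit <- which(r_x$label_map == top$label)
  expect_gt(length(intersect(hit, which(msk)[region])), 0)

  # swapping the factor labels leaves the F-map unchanged
  r_sw <- permutation_interaction_f(y_x, msk, b, a,
                                    covariates = cbind(age, gender),
                                    n_perm = 10, seed = 4)
  expect_equal(r_sw$stat_map, r_x$stat_map, tolerance = 1e-10)

  # empty cell fails
  expect_error(permutation_interaction_f(y_x[1:10, ], msk, a[1:10],
                                         rep("R", 10), n_perm = 10),
               "two levels|non-empty")
})

test_that("bonferroni_adjust and extract_cluster_means", {
  # 4 maps x 2 contrasts family: 0.012 -> 0.096 (not significant at 0.05)
  expect_equal(bonferroni_adjust(0.012, 8), 0.096)
  expect_equal(bonferroni_adjust(0.002, 8), 0.016)
  expect_equal(bonferroni_adjust(0.9, 8), 1.0)
  expect_error(bonferroni_adjust(0, 8), "0, 1")
  expect_error(bonferroni_adjust(1.2, 8), "0, 1")

  # cluster means: constant map, single voxel, arithmetic oracle
  tpl <- bump_template(6)
  g <- tpl$grid
  set.seed(35)
  mk <- function(val) fc_maps(list(DAT = array(val, dim = g$shape)), g,
                              subject_id = paste0("s", round(mean(val), 3)))
  cmask <- array(FALSE, dim = g$shape); cmask[2:3, 2:3, 2] <- TRUE
  maps <- list(mk(2.5), mk(array(rnorm(216), dim = g$shape)))
  got <- extract_cluster_means(maps, cmask, system = "DAT")
  expect_equal(got$mean_fc[1], 2.5)
  expect_equal(got$mean_fc[2], sum(maps[[2]]$maps$DAT[cmask]) / sum(cmask))

  single <- array(FALSE, dim = g$shape); single[4, 4, 4] <- TRUE
  got1 <- extract_cluster_means(maps, single)
  expect_equal(got1$mean_fc[2], maps[[2]]$maps$DAT[4, 4, 4])

  # several clusters averaged into one pooled column
  got2 <- extract_cluster_means(maps, list(cmask, single))
  expect_equal(got2$mean_fc, (got2$mean_fc_1 + got2$mean_fc_2) / 2)

  expect_error(extract_cluster_means(maps, array(FALSE, dim = g$shape)),
               "empty")
})
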