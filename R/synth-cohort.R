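## Cohort-level synthesis: many subjects' BOLD series with a group-localized
## FC effect of known size and location, a covariate table, and clinical
## outcomes (VAS) coupled to the ground-truth FC with configurable strength.

#' Specification of a synthetic cohort
#'
#' Describes the stated world a synthetic cohort is drawn from: group sizes,
#' series length and TR, noise level, where/how strongly a group FC effect is
#' planted, covariate distributions and the FC-to-analgesia coupling.
#'
#' The planted effect multiplies the effect system's template-driven signal
#' component by `1 + effect_size * effect_pattern[group]` inside
#' `effect_mask`, which shifts the step-2 FC weights (not the mean signal) —
#' the quantity the dual regression estimates. A per-subject lognormal-free
#' Gaussian jitter of SD `subject_sd` on the amplification makes the
#' ground-truth FC score vary between subjects within a group, which is what
#' the clinical coupling acts on.
#'
#' @param n_per_group named integer vector of subjects per group (each >= 2),
#'   e.g. `c(HC = 10, OA = 10)` or
#'   `c(placebo_R = 5, placebo_NR = 5, duloxetine_R = 5, duloxetine_NR = 5)`.
#' @param T_volumes volumes per subject (>= 2 K). Default 150.
#' @param tr repetition time, s. Default 2.5.
#' @param noise_sd BOLD noise SD. Default 1.
#' @param effect_size dimensionless scaling of the planted FC difference (in
#'   template-amplitude units; 0 disables).
#' @param effect_system system (name or index) whose FC is shifted. Default 1.
#' @param effect_pattern named numeric vector of per-group multipliers of
#'   `effect_size` (groups absent default to 0), e.g. `c(OA = 1)` or a crossed
#'   `c(duloxetine_R = 1, placebo_R = -1)`.
#' @param effect_n_voxels size of the auto-chosen effect region (highest
#'   density voxels of the effect system). Default 100.
#' @param subject_sd per-subject SD of the amplification jitter. Default 0.25.
#' @param age_mean,age_sd Gaussian age distribution, years. Defaults 57, 7.
#' @param vas_coupling percent-analgesia points per SD of ground-truth FC.
#'   Default 15.
#' @param vas_intercept mean percent analgesia. Default 20 (the responder
#'   threshold, so both labels occur).
#' @param vas_noise_sd residual SD of percent analgesia. Default 10.
#' @param seed master RNG seed; per-subject child seeds are derived by fixed
#'   arithmetic.
#' @return an object of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(n_per_group = c(HC = 10, OA = 10),
                              T_volumes = 150, tr = 2.5, noise_sd = 1,
                              effect_size = 0, effect_system = 1L,
                              effect_pattern = NULL, effect_n_voxels = 100L,
                              subject_sd = 0.25, age_mean = 57, age_sd = 7,
                              vas_coupling = 15, vas_intercept = 20,
                              vas_noise_sd = 10, seed = 1) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("`n_per_group` must be a named vector", call. = FALSE)
  n_per_group <- vapply(n_per_group, as.integer, 1L)
  if (any(n_per_group < 2L))
    stop("each group needs at least 2 subjects", call. = FALSE)
  if (tr <= 0) stop("`tr` must be > 0", call. = FALSE)
  if (is.null(effect_pattern)) {
    effect_pattern <- stats::setNames(numeric(length(n_per_group)),
                                      names(n_per_group))
    if (length(n_per_group) >= 2L) effect_pattern[2L] <- 1
  }
  if (!is.finite(effect_size))
    stop("`effect_size` must be finite", call. = FALSE)
  structure(
    list(n_per_group = n_per_group, T_volumes = as.integer(T_volumes),
         tr = tr, noise_sd = noise_sd, effect_size = effect_size,
         effect_system = effect_system, effect_pattern = effect_pattern,
         effect_n_voxels = as.integer(effect_n_voxels),
         subject_sd = subject_sd, age_mean = age_mean, age_sd = age_sd,
         vas_coupling = vas_coupling, vas_intercept = vas_intercept,
         vas_noise_sd = vas_noise_sd, seed = seed),
    class = "synth_cohort_spec"
  )
}

#' @export
print.synth_cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<synth_cohort_spec> %s | T = %d, TR = %g s | noise_sd = %g | effect_size = %g\n",
    paste(sprintf("%s:%d", names(x$n_per_group), x$n_per_group), collapse = " "),
    x$T_volumes, x$tr, x$noise_sd, x$effect_size))
  invisible(x)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-subject system time series (unit-variance white Gaussian), builds
#' each subject's BOLD series as the template-weighted mixture plus noise via
#' [make_subject_bold()], plants the group FC effect of `spec`, and returns
#' the covariate table plus a full ground-truth record.
#'
#' @param spec a [synth_cohort_spec()].
#' @param templates list of [molecular_template()] (e.g. [make_templates()]).
#' @param effect_mask optional logical 3D array overriding the auto-chosen
#'   effect region; must be non-empty.
#' @return list with elements `bolds` (list of [bold4d()]), `table`
#'   (data.frame: subject_id, group, arm, age, gender), `ground_truth` (list:
#'   true_templates, true_series, effect_mask, effect_size, effect_system,
#'   noise_sd, seed, subject_gain, fc_score) and `spec`.
#' @export
make_cohort <- function(spec, templates, effect_mask = NULL) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  if (inherits(templates, "molecular_template")) templates <- list(templates)
  grid <- templates[[1]]$grid
  templates <- check_template_set(templates, grid)
  k <- length(templates)
  if (spec$T_volumes < 2L * k)
    stop("T_volumes must be at least 2 K", call. = FALSE)
  sys_idx <- if (is.character(spec$effect_system))
    match(spec$effect_system, vapply(templates, `[[`, "", "system_name"))
  else as.integer(spec$effect_system)
  if (is.na(sys_idx) || sys_idx < 1L || sys_idx > k)
    stop("`effect_system` does not name a template", call. = FALSE)
  if (is.null(effect_mask)) {
    tpl <- templates[[sys_idx]]
    nv <- min(spec$effect_n_voxels, sum(tpl$valid_mask))
    thr <- sort(tpl$data[tpl$valid_mask], decreasing = TRUE)[nv]
    effect_mask <- tpl$valid_mask & tpl$data >= thr
  } else {
    effect_mask <- as_mask(effect_mask, grid, "effect_mask")
  }
  if (!any(effect_mask)) stop("`effect_mask` is empty", call. = FALSE)

  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)
  ids <- sprintf("sub-%02d", seq_len(n))
  pattern <- spec$effect_pattern
  mult <- ifelse(groups %in% names(pattern), pattern[groups], 0)

  covar <- with_seed(spec$seed, data.frame(
    subject_id = ids,
    group = groups,
    arm = derive_arm(groups),
    age = round(stats::rnorm(n, spec$age_mean, spec$age_sd), 1),
    gender = stats::rbinom(n, 1L, 0.5),
    stringsAsFactors = FALSE
  ))

  bolds <- vector("list", n)
  names(bolds) <- ids
  true_series <- vector("list", n)
  gain_field <- array(0, dim = grid$shape)
  gain_field[effect_mask] <- 1
  subject_gain <- numeric(n)
  for (i in seq_len(n)) {
    cs <- child_seed(spec$seed, i)
    sub <- with_seed(cs, {
      s <- matrix(stats::rnorm(spec$T_volumes * k), ncol = k)
      g_i <- 1 + spec$effect_size * mult[i] +
        stats::rnorm(1L, 0, spec$subject_sd)
      list(series = s, gain = g_i)
    })
    subject_gain[i] <- sub$gain
    true_series[[i]] <- sub$series
    gains <- rep(list(array(1, dim = grid$shape)), k)
    gains[[sys_idx]] <- 1 + (sub$gain - 1) * gain_field
    bolds[[i]] <- make_subject_bold(
      templates, sub$series, noise_sd = spec$noise_sd,
      seed = child_seed(spec$seed, i + n), gain = gains, tr = spec$tr,
      subject_id = ids[i])
  }
  mean_density <- mean(templates[[sys_idx]]$data[effect_mask])
  list(
    bolds = bolds,
    table = covar,
    ground_truth = list(
      true_templates = lapply(templates, `[[`, "data"),
      system_names = vapply(templates, `[[`, "", "system_name"),
      true_series = true_series,
      effect_mask = effect_mask,
      effect_size = spec$effect_size,
      effect_system = sys_idx,
      noise_sd = spec$noise_sd,
      seed = spec$seed,
      subject_gain = subject_gain,
      fc_score = mean_density * subject_gain
    ),
    spec = spec
  )
}

derive_arm <- function(groups) {
  arm <- rep("none", length(groups))
  arm[grepl("placebo", groups, ignore.case = TRUE)] <- "placebo"
  arm[grepl("duloxetine|drug", groups, ignore.case = TRUE)] <- "duloxetine"
  arm
}

#' Simulate clinical outcomes (VAS) coupled to ground-truth FC
#'
#' Percent analgesia is `vas_intercept + vas_coupling * z(FC score) + noise`,
#' where the FC score is the subject's ground-truth template-mixture amplitude
#' in the effect mask (the quantity step 2 of the dual regression estimates).
#' Baseline VAS is drawn on (0, 10] and measured three times (the
#' triple-baseline design used to damp regression to the mean); the average is
#' the working baseline and the post-treatment VAS is derived from the percent
#' analgesia, clipped to the scale. `pct_analgesia` is recomputed from the
#' emitted baseline/post pair so the table is self-consistent.
#'
#' @param cohort a [make_cohort()] result.
#' @param spec a [synth_cohort_spec()]; defaults to `cohort$spec`.
#' @param seed RNG seed; defaults to `spec$seed + 1` (fixed offset from the
#'   master seed).
#' @return `cohort$table` extended with `vas_baseline_1..3`, `vas_baseline`,
#'   `vas_post`, `pct_analgesia` and `responder` (20% rule).
#' @export
make_clinical_outcomes <- function(cohort, spec = cohort$spec, seed = NULL) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  if (!is.finite(spec$vas_coupling))
    stop("`vas_coupling` must be finite", call. = FALSE)
  if (is.null(seed)) seed <- child_seed(spec$seed, 999983L)
  fc <- cohort$ground_truth$fc_score
  n <- length(fc)
  zfc <- if (stats::sd(fc) > 1e-12) (fc - mean(fc)) / stats::sd(fc)
         else rep(0, n)
  out <- with_seed(seed, {
    base <- pmin(pmax(stats::rnorm(n, 6, 1.5), 0.5), 10)
    reps <- vapply(1:3, function(j)
      pmin(pmax(base + stats::rnorm(n, 0, 0.3), 0.1), 10), numeric(n))
    pct <- spec$vas_intercept + spec$vas_coupling * zfc +
      stats::rnorm(n, 0, spec$vas_noise_sd)
    list(reps = reps, pct = pct)
  })
  baseline <- rowMeans(out$reps)
  post <- pmin(pmax(baseline * (1 - out$pct / 100), 0), 10)
  tab <- cohort$table
  tab$vas_baseline_1 <- out$reps[, 1]
  tab$vas_baseline_2 <- out$reps[, 2]
  tab$vas_baseline_3 <- out$reps[, 3]
  tab$vas_baseline <- baseline
  tab$vas_post <- post
  tab$pct_analgesia <- 100 * (baseline - post) / baseline
  tab$responder <- tab$pct_analgesia >= 20
  tab
}

#' Write a cohort to disk in a BIDS-like layout
#'
#' Subjects go to `sub-XX/func/sub-XX_bold.rds`, templates to
#' `templates/<system>.rds`, covariates to `participants.tsv` and the ground
#' truth to `ground_truth.rds` (volumes are serialized as RDS because no
#' NIfTI writer is available in this toolchain; the spatial metadata travels
#' in the `volume_grid`).
#'
#' @param cohort a [make_cohort()] result.
#' @param templates the template list used to build it.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, templates, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in cohort$bolds) {
    sd <- file.path(dir, b$subject_id, "func")
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    saveRDS(b, file.path(sd, paste0(b$subject_id, "_bold.rds")))
  }
  td <- file.path(dir, "templates")
  dir.create(td, showWarnings = FALSE)
  for (tpl in templates)
    saveRDS(tpl, file.path(td, paste0(tpl$system_name, ".rds")))
  utils::write.table(cohort$table, file.path(dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  saveRDS(cohort$ground_truth, file.path(dir, "ground_truth.rds"))
  invisible(dir)
}
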