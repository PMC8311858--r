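# Planted-structure synthetic cohorts.
#
# The generator emulates the statistical skeleton the analysis assumes:
# block-structured ROI correlations over a planted bilateral partition, one
# target node whose between-module correlation scales with dementia
# severity, and an active-arm-only reduction of that coupling at the post
# timepoint. Everything downstream (thresholding, reference clustering,
# participation coefficients, the statistical battery) can then be validated
# against known ground truth.

#' Specify a synthetic cohort design
#'
#' Collects every planted parameter of the generator in one object. The
#' defaults encode the study conditions the pipeline targets: 76 nodes in 7
#' bilateral modules, 19 healthy controls scanned once, 16 patients per
#' treatment arm scanned pre and post, 210 time points per scan, and a
#' target node (`LIFG_tri`) whose between-module correlation increases by
#' `severity_slope` per unit of a 0-15 severity score and drops by
#' `treatment_effect` after treatment in the active arm only.
#'
#' @param node_table Node table; defaults to the packaged 76-node set.
#' @param partition Planted partition; defaults to the packaged seven-module
#'   reference organization.
#' @param within_r,between_r Target Pearson correlation inside and across
#'   planted modules; both in (-1, 1) with `within_r > between_r`.
#' @param target_node Label of the perturbed node.
#' @param severity_slope Added between-module correlation per severity unit
#'   for the target node.
#' @param treatment_effect Mean reduction of the target node's
#'   between-module correlation at post-treatment, active arm only.
#' @param effect_sd Between-subject SD of the realized post-treatment change
#'   in the target node's between-module correlation (both arms; the sham
#'   arm drifts around zero). Gives the cohort subject-level variability so
#'   brain-behavior relationships are estimable.
#' @param n_hc Healthy controls (single scan each).
#' @param n_per_group Patients per treatment arm (scanned pre and post).
#' @param t_len Time points per scan.
#' @param t_len_alt,alt_fraction Optional second scan length and the
#'   fraction of subjects acquired at it, emulating a cohort pooled across
#'   two acquisition protocols (210 and 156 time points); `alt_fraction = 0`
#'   disables mixing.
#' @param severity_range Severity scores are drawn uniformly from this range
#'   on a 0.5 grid (clinical dementia rating style).
#' @param bump_cap Upper cap on the realized between-module elevation of
#'   the target node (deterministic severity part plus sampled subject
#'   variability); keeps sampled covariances inside the region where PSD
#'   repair stays within `max_psd_drift`.
#' @param max_psd_drift Bound on how far positive-semi-definite repair may
#'   move any covariance entry before generation errors out.
#' @param seed Integer base seed; per-subject substreams are derived from it
#'   so adding a subject never changes another subject's data.
#' @return A `conn_design` list, validated.
#' @export
cohort_design <- function(node_table = default_node_table(),
                          partition = reference_partition(node_table),
                          within_r = 0.5,
                          between_r = 0.1,
                          target_node = "LIFG_tri",
                          severity_slope = 0.02,
                          treatment_effect = 0.15,
                          effect_sd = 0.05,
                          n_hc = 19,
                          n_per_group = 16,
                          t_len = 210,
                          t_len_alt = NULL,
                          alt_fraction = 0,
                          severity_range = c(1, 15),
                          bump_cap = 0.32,
                          max_psd_drift = 0.05,
                          seed = 1L) {
  design <- structure(list(
    node_table = validate_node_table(node_table),
    partition = validate_partition(partition),
    within_r = within_r,
    between_r = between_r,
    target_node = target_node,
    severity_slope = severity_slope,
    treatment_effect = treatment_effect,
    effect_sd = effect_sd,
    n_hc = as.integer(n_hc),
    n_per_group = as.integer(n_per_group),
    t_len = as.integer(t_len),
    t_len_alt = if (is.null(t_len_alt)) NULL else as.integer(t_len_alt),
    alt_fraction = alt_fraction,
    severity_range = severity_range,
    bump_cap = bump_cap,
    max_psd_drift = max_psd_drift,
    seed = as.integer(seed)
  ), class = "conn_design")
  validate_design(design)
}

validate_design <- function(design) {
  if (abs(design$within_r) >= 1 || abs(design$between_r) >= 1) {
    abort("invalid design: |within_r| and |between_r| must be < 1")
  }
  if (design$within_r <= design$between_r) {
    abort("invalid design: within_r must exceed between_r for modular structure")
  }
  if (!design$target_node %in% design$node_table$label) {
    abort(sprintf("invalid design: target node '%s' is not in the node table",
                  design$target_node))
  }
  if (design$n_hc < 0 || design$n_per_group < 0) {
    abort("invalid design: group sizes must be non-negative")
  }
  if (design$t_len < 2) abort("invalid design: t_len must be at least 2")
  design
}

#' @export
print.conn_design <- function(x, ...) {
  cat("<conn_design>\n")
  cat(sprintf("  %d nodes, %d planted modules, target %s\n",
              nrow(x$node_table), n_modules(x$partition), x$target_node))
  cat(sprintf("  within_r %.2f / between_r %.2f; severity slope %.3f; treatment effect %.3f\n",
              x$within_r, x$between_r, x$severity_slope, x$treatment_effect))
  cat(sprintf("  %d HC (single scan), %d per arm (pre/post), T = %d, seed %d\n",
              x$n_hc, x$n_per_group, x$t_len, x$seed))
  invisible(x)
}

#' Build the planted node-by-node covariance for one scan
#'
#' Constructs the two-level block correlation matrix (unit diagonal,
#' `within_r` inside planted modules, `between_r` across), adds the target
#' node's severity-scaled between-module elevation, subtracts the treatment
#' effect when `timepoint = "post"` and `arm = "active"`, and repairs the
#' result to the nearest positive semi-definite matrix if the perturbation
#' broke it. Repair clips negative eigenvalues, re-symmetrizes and rescales
#' to unit diagonal; it errors if any entry would move by more than
#' `design$max_psd_drift`.
#'
#' @param design A [cohort_design()].
#' @param severity Severity score (0-15 scale) of the scanned subject.
#' @param timepoint `"pre"`, `"post"` or `"single"`.
#' @param arm `"active"`, `"sham"` or `"none"`.
#' @param treatment_effect Realized reduction for this subject; defaults to
#'   the design's planted mean effect.
#' @return A symmetric unit-diagonal covariance matrix with node labels as
#'   dimnames.
#' @export
build_block_covariance <- function(design, severity = 0,
                                   timepoint = "single", arm = "none",
                                   treatment_effect = design$treatment_effect) {
  design <- validate_design(design)
  memb <- partition_membership(design$partition)
  n <- length(memb)
  same <- outer(memb, memb, "==")
  cov <- ifelse(same, design$within_r, design$between_r)

  target <- match(design$target_node, design$node_table$label)
  bump <- design$severity_slope * severity
  if (identical(timepoint, "post") && identical(arm, "active")) {
    bump <- bump - treatment_effect
  }
  other_module <- memb != memb[target]
  cov[target, other_module] <- cov[target, other_module] + bump
  cov[other_module, target] <- cov[other_module, target] + bump
  diag(cov) <- 1
  cov <- pmin(pmax(cov, -0.999), 0.999)
  diag(cov) <- 1

  rep <- repair_psd(cov, max_drift = design$max_psd_drift)
  out <- rep$cov
  attr(out, "chol") <- rep$chol
  dimnames(out) <- list(design$node_table$label, design$node_table$label)
  out
}

#' Sample one ROI-by-time matrix from a covariance
#'
#' Draws `t_len` independent time points from a zero-mean multivariate
#' normal with the given covariance. Bit-reproducible under a fixed seed.
#'
#' @param cov Positive semi-definite covariance matrix (rows/cols = ROIs).
#' @param t_len Number of time points (at least 2).
#' @param seed Integer seed.
#' @return An ROI-by-time numeric matrix (`nrow(cov)` x `t_len`), with the
#'   covariance's row names as ROI names.
#' @export
simulate_timeseries <- function(cov, t_len, seed) {
  if (t_len < 2) abort("t_len must be at least 2")
  ch <- attr(cov, "chol")
  if (is.null(ch)) {
    ch <- tryCatch(chol(cov), error = function(e) {
      abort("covariance must be positive semi-definite")
    })
  }
  set.seed(as.integer(seed))
  n <- nrow(cov)
  z <- matrix(rnorm(n * t_len), nrow = n, ncol = t_len)
  x <- crossprod(ch, z)
  rownames(x) <- rownames(cov)
  x
}

# Deterministic per-subject seed substream. Subject index is global within
# the cohort layout (HC first, then patients), so adding subjects at the end
# never perturbs earlier subjects' draws.
.subject_seed <- function(base_seed, subject_index) {
  as.integer(base_seed) + 7919L * as.integer(subject_index)
}

#' Simulate a full longitudinal cohort
#'
#' Generates one scan per healthy control and pre + post scans per patient,
#' together with a covariate table (age, gender, education years, severity,
#' in-scanner motion, behavioral gain) and a ground-truth record of every
#' planted parameter, for recovery tests.
#'
#' Patient severities are uniform on the design's severity range (0.5
#' grid); each patient's realized post-pre change in the target node's
#' between-module correlation is drawn around `-treatment_effect` (active)
#' or `0` (sham) with SD `effect_sd`, and behavioral gain is generated so
#' that larger planted reductions yield larger gains in the active arm.
#'
#' @param design A [cohort_design()].
#' @return A `conn_cohort` list with elements `timeseries` (named list of
#'   ROI-by-time matrices, names `<subject>_<timepoint>`), `covariates`
#'   (tibble), `truth` (list of planted parameters incl. per-subject
#'   realized effects), and the `design`.
#' @export
simulate_cohort <- function(design) {
  design <- validate_design(design)
  nt <- design$node_table

  subjects <- list()
  idx <- 0L
  add_subject <- function(id, cohort, arm) {
    idx <<- idx + 1L
    subjects[[length(subjects) + 1L]] <<- list(
      subject_id = id, cohort = cohort, arm = arm, index = idx)
  }
  if (design$n_hc > 0) {
    for (i in seq_len(design$n_hc)) {
      add_subject(sprintf("HC%02d", i), "HC", "none")
    }
  }
  if (design$n_per_group > 0) {
    for (i in seq_len(design$n_per_group)) {
      add_subject(sprintf("P%02d", i), "PPA", "active")
    }
    for (i in seq_len(design$n_per_group)) {
      add_subject(sprintf("P%02d", design$n_per_group + i), "PPA", "sham")
    }
  }

  sev_grid <- seq(design$severity_range[1], design$severity_range[2], by = 0.5)
  ts <- list()
  cov_rows <- list()
  truth_subj <- list()

  # The covariance depends on the scan only through the target node's net
  # between-module bump, so scans sharing a bump share one matrix (and its
  # Cholesky factor). Large null simulations collapse to a single build.
  cov_cache <- new.env(parent = emptyenv())
  cached_cov <- function(severity, timepoint, arm, treatment_effect) {
    bump <- design$severity_slope * severity -
      (if (identical(timepoint, "post")) treatment_effect else 0)
    # Sampled per-subject variability must not push the planted matrix
    # outside the repairable PSD region; the realized bump is capped.
    bump <- min(bump, design$bump_cap)
    key <- sprintf("%.12g", bump)
    if (is.null(cov_cache[[key]])) {
      cov_cache[[key]] <- build_block_covariance(
        design, severity = 0, timepoint = "post", arm = "active",
        treatment_effect = -bump)
    }
    cov_cache[[key]]
  }

  for (s in subjects) {
    s_seed <- .subject_seed(design$seed, s$index)
    set.seed(s_seed)
    age <- round(rnorm(1, mean = 68, sd = 7), 1)
    gender <- sample(c("F", "M"), 1)
    education <- round(rnorm(1, mean = 16, sd = 2.5), 1)
    motion <- round(exp(rnorm(1, mean = log(0.08), sd = 0.4)), 4)
    is_alt <- design$alt_fraction > 0 && !is.null(design$t_len_alt) &&
      runif(1) < design$alt_fraction
    t_len <- if (is_alt) design$t_len_alt else design$t_len

    if (s$cohort == "HC") {
      severity <- 0
      delta <- 0
      gain <- NA_real_
      cov_mat <- cached_cov(0, "single", "none", 0)
      key <- paste0(s$subject_id, "_single")
      ts[[key]] <- simulate_timeseries(cov_mat, t_len, seed = s_seed + 1L)
      cov_rows[[length(cov_rows) + 1L]] <- list(
        subject_id = s$subject_id, cohort = "HC", arm = "none",
        timepoint = "single", age = age, gender = gender,
        education = education, severity = 0, motion_rms = motion,
        behavior_gain = NA_real_)
    } else {
      severity <- sample(sev_grid, 1)
      mean_delta <- if (s$arm == "active") -design$treatment_effect else 0
      delta <- rnorm(1, mean = mean_delta, sd = design$effect_sd)
      # Behavioral gain: larger planted reductions pay off in the active
      # arm; the sham arm's drift correlates positively with gain. Severity
      # costs improvement. Free parameters, not calibrated to real data.
      slope <- if (s$arm == "active") -250 else 250
      gain <- 55 - 1.5 * severity + slope * (delta - mean_delta) +
        (if (s$arm == "active") 25 else 0) + rnorm(1, sd = 8)
      gain <- round(pmin(pmax(gain, 0), 100), 1)

      cov_pre <- cached_cov(severity, "pre", s$arm, 0)
      # `delta` is the realized post-pre change for this subject (applies in
      # both arms; sham drifts around zero), so the post covariance adds it
      # on top of the severity bump regardless of arm.
      cov_post <- cached_cov(severity, "post", s$arm, -delta)
      ts[[paste0(s$subject_id, "_pre")]] <-
        simulate_timeseries(cov_pre, t_len, seed = s_seed + 1L)
      ts[[paste0(s$subject_id, "_post")]] <-
        simulate_timeseries(cov_post, t_len, seed = s_seed + 2L)
      for (tp in c("pre", "post")) {
        cov_rows[[length(cov_rows) + 1L]] <- list(
          subject_id = s$subject_id, cohort = "PPA", arm = s$arm,
          timepoint = tp, age = age, gender = gender,
          education = education, severity = severity, motion_rms = motion,
          behavior_gain = gain)
      }
    }
    truth_subj[[length(truth_subj) + 1L]] <- list(
      subject_id = s$subject_id, cohort = s$cohort, arm = s$arm,
      severity = severity, realized_delta = delta, t_len = t_len)
  }

  structure(list(
    timeseries = ts,
    covariates = bind_rows(lapply(cov_rows, as_tibble)),
    truth = list(
      partition = design$partition,
      within_r = design$within_r,
      between_r = design$between_r,
      target_node = design$target_node,
      severity_slope = design$severity_slope,
      treatment_effect = design$treatment_effect,
      effect_sd = design$effect_sd,
      seed = design$seed,
      subjects = bind_rows(lapply(truth_subj, as_tibble))
    ),
    design = design
  ), class = "conn_cohort")
}

#' @export
print.conn_cohort <- function(x, ...) {
  cv <- x$covariates
  cat("<conn_cohort>\n")
  cat(sprintf("  %d scans: %d HC, %d active-arm, %d sham-arm subjects\n",
              length(x$timeseries),
              dplyr::n_distinct(cv$subject_id[cv$cohort == "HC"]),
              dplyr::n_distinct(cv$subject_id[cv$arm == "active"]),
              dplyr::n_distinct(cv$subject_id[cv$arm == "sham"])))
  invisible(x)
}
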