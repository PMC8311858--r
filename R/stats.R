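# The statistical battery: pre-treatment group and severity regressions,
# treatment-arm change model, paired/independent t tests, brain-behavior
# interaction model, and BH-FDR correction for per-module families.
#
# Factor coding is fixed for reproducibility: gender reference F, treatment
# arm reference sham, cohort reference HC.

new_conn_stat <- function(model_id, terms, n, df_residual = NA_real_,
                          fits = list(), extra = list()) {
  structure(list(model_id = model_id, terms = terms, n = n,
                 df_residual = df_residual, fits = fits, extra = extra),
            class = "conn_stat")
}

#' @export
print.conn_stat <- function(x, ...) {
  cat(sprintf("<conn_stat: %s> n = %d\n", x$model_id, x$n))
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.conn_stat <- function(x, ...) x$terms

#' @exportS3Method generics::glance
glance.conn_stat <- function(x, ...) {
  tibble(model_id = x$model_id, n = x$n, df.residual = x$df_residual)
}

# Coefficient table of an lm fit as a tidy tibble; non-finite statistics
# (degenerate fits) are kept and flagged rather than erroring.
lm_terms <- function(fit, model = NULL) {
  sm <- summary(fit)
  ct <- sm$coefficients
  out <- tibble(
    term = rownames(ct),
    estimate = unname(ct[, "Estimate"]),
    std.error = unname(ct[, "Std. Error"]),
    statistic = unname(ct[, "t value"]),
    p.value = unname(ct[, "Pr(>|t|)"]),
    df = fit$df.residual
  )
  aliased <- names(which(is.na(coef(fit))))
  if (length(aliased) > 0) {
    abort(paste0("collinear (rank-deficient) design; aliased term(s): ",
                 paste(aliased, collapse = ", ")))
  }
  if (!is.null(model)) out <- mutate(out, model = model, .before = 1)
  mutate(out, degenerate = !is.finite(.data$statistic))
}

.code_factors <- function(df) {
  if ("gender" %in% names(df)) df$gender <- factor(df$gender, levels = c("F", "M"))
  if ("arm" %in% names(df)) df$arm <- factor(df$arm, levels = c("sham", "active"))
  if ("cohort" %in% names(df)) df$cohort <- factor(df$cohort, levels = c("HC", "PPA"))
  df
}

.check_covariates <- function(df, fields) {
  for (f in fields) {
    bad <- df$subject_id[is.na(df[[f]])]
    if (length(bad) > 0) {
      abort(sprintf("missing covariate '%s' for subject(s): %s",
                    f, paste(bad, collapse = ", ")))
    }
  }
  df
}

# One PC value per subject at the pre/single timepoint for one node,
# joined with that timepoint's covariate row.
.pretreatment_frame <- function(metrics, covariates, node) {
  metrics |>
    filter(.data$node == !!node, .data$timepoint %in% c("pre", "single")) |>
    left_join(covariates, by = c("subject_id", "timepoint")) |>
    .code_factors()
}

#' Pre-treatment regressions: group contrast and severity association
#'
#' Two linear regressions on one PC value per subject at the pre-treatment
#' (patients) or single (controls) timepoint: (a) `pc ~ cohort + age +
#' education + gender + motion_rms` over controls and patients together,
#' giving the patient-vs-control contrast, and (b) `pc ~ severity + age +
#' education + gender + motion_rms` over patients only, giving the
#' severity association. Both are ordinary `lm` fits.
#'
#' @param metrics Long metrics tibble from [compute_node_metrics()].
#' @param covariates Covariate tibble (see [simulate_cohort()]).
#' @param node Node label to analyze.
#' @return A `conn_stat`; `tidy()` lists terms of both fits under
#'   `model = "group"` and `model = "severity"`.
#' @export
pretreatment_model <- function(metrics, covariates, node = "LIFG_tri") {
  df <- .pretreatment_frame(metrics, covariates, node)
  .check_covariates(df, c("age", "education", "gender", "motion_rms"))

  fit_group <- lm(pc ~ cohort + age + education + gender + motion_rms,
                  data = df)
  ppa <- filter(df, .data$cohort == "PPA")
  .check_covariates(ppa, "severity")
  if (nrow(ppa) == 0) abort("no patients at the pre timepoint")
  fit_sev <- lm(pc ~ severity + age + education + gender + motion_rms,
                data = ppa)

  terms <- bind_rows(lm_terms(fit_group, "group"),
                     lm_terms(fit_sev, "severity"))
  new_conn_stat("pretreatment", terms, n = nrow(df),
                df_residual = fit_group$df.residual,
                fits = list(group = fit_group, severity = fit_sev))
}

# Post-minus-pre change per patient for one node and metric column.
.delta_frame <- function(metrics, covariates, node, value = "pc") {
  pat <- covariates |>
    filter(.data$cohort == "PPA") |>
    dplyr::distinct(.data$subject_id, .data$arm, .data$age, .data$gender,
                    .data$education, .data$severity, .data$motion_rms,
                    .data$behavior_gain)
  m <- metrics |>
    filter(.data$node == !!node, .data$timepoint %in% c("pre", "post")) |>
    select("subject_id", "timepoint", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = dplyr::all_of(value))
  missing <- m$subject_id[!stats::complete.cases(m[c("pre", "post")])]
  missing <- union(missing,
                   setdiff(pat$subject_id, m$subject_id))
  if (length(missing) > 0) {
    abort(paste0("subject(s) missing a timepoint: ",
                 paste(missing, collapse = ", ")))
  }
  m |>
    mutate(delta = .data$post - .data$pre) |>
    dplyr::inner_join(pat, by = "subject_id") |>
    .code_factors()
}

#' Treatment-arm model of pre-to-post change
#'
#' Fits `delta ~ arm + severity + age + education + gender + motion_rms`
#' where `delta` is each patient's post-minus-pre value of the metric
#' (participation coefficient by default). The treatment-arm term is the
#' headline contrast: does the active arm change differently from sham?
#'
#' @inheritParams pretreatment_model
#' @param value Metric column to difference (`"pc"`, `"between_count"`, ...).
#' @return A `conn_stat` with the arm contrast among its terms; the delta
#'   frame is kept in `$extra$data`.
#' @export
change_model <- function(metrics, covariates, node = "LIFG_tri", value = "pc") {
  df <- .delta_frame(metrics, covariates, node, value)
  .check_covariates(df, c("severity", "age", "education", "gender", "motion_rms"))
  fit <- lm(delta ~ arm + severity + age + education + gender + motion_rms,
            data = df)
  new_conn_stat(paste0("change_", value), lm_terms(fit), n = nrow(df),
                df_residual = fit$df.residual, fits = list(change = fit),
                extra = list(data = df))
}

#' Paired t test on pre vs post values
#'
#' Classical two-sided paired t test of `post - pre`. If all within-pair
#' differences are identical (zero variance) the t statistic is returned as
#' signed infinity (or 0 when the common difference is 0) with a
#' `degenerate` flag rather than an error.
#'
#' @param pre,post Equal-length matched numeric vectors.
#' @return A `conn_stat` with one term `post - pre`.
#' @export
paired_change_test <- function(pre, post) {
  if (length(pre) != length(post)) abort("pre and post must be matched vectors")
  if (length(pre) < 2) abort("need at least 2 pairs")
  d <- post - pre
  if (sd(d) == 0) {
    stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    terms <- tibble(term = "post - pre", estimate = mean(d),
                    std.error = 0, statistic = stat,
                    p.value = if (mean(d) == 0) 1 else 0,
                    df = length(d) - 1, degenerate = !is.finite(stat))
    return(new_conn_stat("paired_t", terms, n = length(d),
                         df_residual = length(d) - 1))
  }
  ht <- t.test(d)
  terms <- tibble(term = "post - pre", estimate = unname(ht$estimate),
                  std.error = unname(ht$stderr),
                  statistic = unname(ht$statistic),
                  p.value = ht$p.value, df = unname(ht$parameter),
                  degenerate = FALSE)
  new_conn_stat("paired_t", terms, n = length(d),
                df_residual = unname(ht$parameter))
}

#' Independent-samples t test between two groups
#'
#' Two-sided t test of `mean(a) - mean(b)`. Pooled-variance (Student) by
#' default so the degrees of freedom are `n1 + n2 - 2`, matching the
#' df-reporting convention of group-vs-control comparisons; Welch's
#' correction is available behind `welch = TRUE`.
#'
#' @param a,b Numeric vectors, each of length at least 2.
#' @param welch Use Welch's unequal-variance test instead of pooled.
#' @return A `conn_stat` with one term `a - b`.
#' @export
independent_group_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 values per group")
  if (sd(a) == 0 && sd(b) == 0) {
    est <- mean(a) - mean(b)
    stat <- if (est == 0) 0 else sign(est) * Inf
    terms <- tibble(term = "a - b", estimate = est, std.error = 0,
                    statistic = stat, p.value = if (est == 0) 1 else 0,
                    df = length(a) + length(b) - 2, degenerate = !is.finite(stat))
    return(new_conn_stat("independent_t", terms, n = length(a) + length(b),
                         df_residual = length(a) + length(b) - 2))
  }
  ht <- t.test(a, b, var.equal = !welch)
  terms <- tibble(term = "a - b",
                  estimate = unname(ht$estimate[1] - ht$estimate[2]),
                  std.error = unname(ht$stderr),
                  statistic = unname(ht$statistic),
                  p.value = ht$p.value, df = unname(ht$parameter),
                  degenerate = FALSE)
  new_conn_stat("independent_t", terms, n = length(a) + length(b),
                df_residual = unname(ht$parameter))
}

#' Brain-behavior interaction model
#'
#' Fits `behavior_gain ~ delta * arm + severity + age + education + gender`
#' over patients, where `delta` is the post-minus-pre change of the metric.
#' The `delta:arm` interaction asks whether the relationship between neural
#' change and behavioral improvement differs between arms; per-arm simple
#' slopes are reported as Pearson correlations in `$extra$simple_slopes`.
#'
#' @inheritParams change_model
#' @param behavior Optional replacement for the covariate table's
#'   `behavior_gain` column (percent of maximal gain, 0-100), e.g. gains
#'   simulated under a known slope; a named vector or a tibble with
#'   `subject_id` and `behavior_gain`.
#' @return A `conn_stat`.
#' @export
brain_behavior_model <- function(metrics, covariates, node = "LIFG_tri",
                                 value = "pc", behavior = NULL) {
  df <- .delta_frame(metrics, covariates, node, value)
  if (!is.null(behavior)) {
    if (is.data.frame(behavior)) {
      df <- df |> select(-"behavior_gain") |>
        left_join(behavior, by = "subject_id")
    } else {
      df$behavior_gain <- unname(behavior[df$subject_id])
    }
  }
  .check_covariates(df, c("behavior_gain", "severity", "age", "education",
                          "gender"))
  fit <- lm(behavior_gain ~ delta * arm + severity + age + education + gender,
            data = df)
  slopes <- df |>
    group_by(.data$arm) |>
    summarise(
      r = if (sd(.data$delta) == 0 || sd(.data$behavior_gain) == 0) 0 else
        cor(.data$delta, .data$behavior_gain),
      p = if (sd(.data$delta) == 0 || sd(.data$behavior_gain) == 0) 1 else
        cor.test(.data$delta, .data$behavior_gain)$p.value,
      n = dplyr::n(), .groups = "drop")
  new_conn_stat(paste0("brain_behavior_", value), lm_terms(fit), n = nrow(df),
                df_residual = fit$df.residual, fits = list(interaction = fit),
                extra = list(simple_slopes = slopes, data = df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate, with
#' monotonicity enforced; output order matches input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05))
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must all lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Per-module between-module connectivity comparisons with FDR
#'
#' For each module other than the target node's own, compares the target's
#' mean connection count into that module (i) patients-pre vs controls,
#' (ii) patients-post vs controls (independent t, pooled), and (iii) pre vs
#' post within the chosen arm (paired t). p-values are BH-adjusted within
#' each comparison family (one family = one comparison across modules).
#'
#' @param module_counts Long tibble from [compute_module_counts()].
#' @param covariates Covariate tibble.
#' @param arm Patient arm to test (default `"active"`).
#' @param welch Use Welch tests for the group comparisons.
#' @return Tibble: `module`, `module_name`, `comparison`, `estimate`,
#'   `statistic`, `df`, `p.value`, `p.adjusted`.
#' @export
per_module_tests <- function(module_counts, covariates, arm = "active",
                             welch = FALSE) {
  subj_arm <- covariates |>
    dplyr::distinct(.data$subject_id, .data$cohort, .data$arm)
  df <- left_join(module_counts, subj_arm, by = "subject_id")
  target_module <- unique(df$module[df$within])
  mods <- df |>
    filter(!.data$within) |>
    dplyr::distinct(.data$module,
                    module_name = if ("module_name" %in% names(df))
                      .data$module_name else paste0("module_", .data$module))

  purrr::pmap_dfr(mods, function(module, module_name) {
    mc <- filter(df, .data$module == !!module)
    hc <- mc$count[mc$cohort == "HC" & mc$timepoint == "single"]
    pre <- mc |> filter(.data$arm == !!arm, .data$timepoint == "pre") |>
      arrange(.data$subject_id)
    post <- mc |> filter(.data$arm == !!arm, .data$timepoint == "post") |>
      arrange(.data$subject_id)
    res <- list(
      pre_vs_hc = independent_group_test(pre$count, hc, welch = welch),
      post_vs_hc = independent_group_test(post$count, hc, welch = welch),
      post_vs_pre = paired_change_test(pre$count, post$count)
    )
    purrr::imap_dfr(res, function(st, nm) {
      tidy(st) |>
        mutate(module = module, module_name = module_name,
               comparison = nm, .before = 1) |>
        select("module", "module_name", "comparison", "estimate",
               "statistic", "df", "p.value")
    })
  }) |>
    group_by(.data$comparison) |>
    mutate(p.adjusted = bh_fdr(.data$p.value)) |>
    ungroup() |>
    arrange(.data$comparison, .data$module)
}
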