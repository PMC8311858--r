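# Statistical battery.

# Construct a metrics + covariates pair with fully controlled values.
make_stats_fixture <- function(n_hc = 8, n_act = 8, n_sham = 8, seed = 1,
                               pc_fun = NULL) {
  set.seed(seed)
  subj <- c(sprintf("HC%02d", seq_len(n_hc)),
            sprintf("P%02d", seq_len(n_act + n_sham)))
  cohort <- c(rep("HC", n_hc), rep("PPA", n_act + n_sham))
  arm <- c(rep("none", n_hc), rep("active", n_act), rep("sham", n_sham))
  severity <- c(rep(0, n_hc), sample(seq(1, 15, 0.5), n_act + n_sham, TRUE))
  base <- tibble::tibble(
    subject_id = subj, cohort = cohort, arm = arm,
    age = round(rnorm(length(subj), 68, 6), 1),
    gender = sample(c("F", "M"), length(subj), TRUE),
    education = round(rnorm(length(subj), 16, 2), 1),
    severity = severity,
    motion_rms = round(runif(length(subj), 0.03, 0.15), 4),
    behavior_gain = round(runif(length(subj), 20, 90), 1)
  )
  base$behavior_gain[base$cohort == "HC"] <- NA_real_
  covariates <- dplyr::bind_rows(
    dplyr::mutate(base[base$cohort == "HC", ], timepoint = "single"),
    dplyr::mutate(base[base$cohort == "PPA", ], timepoint = "pre"),
    dplyr::mutate(base[base$cohort == "PPA", ], timepoint = "post")
  )
  if (is.null(pc_fun)) {
    pc_fun <- function(cv) 0.5 + 0.01 * cv$severity + rnorm(nrow(cv), 0, 0.02)
  }
  metrics <- covariates |>
    dplyr::mutate(node = "LIFG_tri", pc = pc_fun(covariates),
                  within_count = 10, between_count = 5, mean_degree = 15) |>
    dplyr::select(subject_id, timepoint, node, pc, within_count,
                  between_count, mean_degree)
  list(metrics = metrics, covariates = covariates)
}

test_that("pretreatment model recovers a constructed severity slope", {
  fx <- make_stats_fixture(seed = 3)
  st <- pretreatment_model(fx$metrics, fx$covariates)
  sev <- dplyr::filter(tidy(st), model == "severity", term == "severity")
  expect_equal(sev$estimate, 0.01, tolerance = 0.35)
  expect_lt(sev$p.value, 1e-4)
  # matches a direct lm fit on the same frame
  df <- fx$metrics |>
    dplyr::filter(timepoint %in% c("pre", "single")) |>
    dplyr::left_join(fx$covariates, by = c("subject_id", "timepoint")) |>
    dplyr::filter(cohort == "PPA") |>
    dplyr::mutate(gender = factor(gender, c("F", "M")))
  ref <- lm(pc ~ severity + age + education + gender + motion_rms, data = df)
  expect_equal(sev$estimate, unname(coef(ref)["severity"]), tolerance = 1e-12)
  expect_equal(st$n, 24)

  # glance/tidy interface
  expect_s3_class(tidy(st), "tbl_df")
  expect_equal(glance(st)$model_id, "pretreatment")
})

test_that("missing covariates and rank deficiency raise informative errors", {
  fx <- make_stats_fixture(seed = 4)
  cv <- fx$covariates
  cv$age[cv$subject_id == "P03"] <- NA
  expect_error(pretreatment_model(fx$metrics, cv), "age.*P03")
  cv2 <- fx$covariates
  cv2$education <- cv2$age  # exact collinearity
  expect_error(pretreatment_model(fx$metrics, cv2), "collinear")
})

test_that("change model recovers a constructed arm effect and validates pairing", {
  fx <- make_stats_fixture(seed = 5, pc_fun = function(cv) {
    0.5 + ifelse(cv$timepoint == "post" & cv$arm == "active", -0.1, 0) +
      rnorm(nrow(cv), 0, 0.01)
  })
  st <- change_model(fx$metrics, fx$covariates)
  armt <- dplyr::filter(tidy(st), term == "armactive")
  expect_lt(armt$p.value, 1e-6)
  expect_equal(armt$estimate, -0.1, tolerance = 0.05)

  # arm reference level is sham: intercept-only sham change near zero
  expect_equal(st$model_id, "change_pc")

  m2 <- fx$metrics[!(fx$metrics$subject_id == "P02" &
                       fx$metrics$timepoint == "post"), ]
  expect_error(change_model(m2, fx$covariates), "missing a timepoint.*P02")
})

test_that("post identical to pre collapses the change model to zero", {
  fx <- make_stats_fixture(seed = 6, pc_fun = function(cv) 0.4 + 0.01 * cv$severity)
  st <- change_model(fx$metrics, fx$covariates)
  expect_true(all(abs(dplyr::filter(tidy(st), term != "(Intercept)")$estimate) < 1e-12))
  expect_true(all(st$extra$data$delta == 0))
})

test_that("paired t matches the closed form on a printed pair set", {
  # textbook-style matched sample
  pre <- c(12.9, 13.5, 12.8, 15.6, 17.2, 19.2, 12.6, 15.3, 14.4, 11.3)
  post <- c(12.7, 13.6, 12.0, 15.2, 16.8, 20.0, 12.0, 15.9, 16.0, 11.1)
  st <- paired_change_test(pre, post)
  d <- post - pre
  t_closed <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(tidy(st)$statistic, t_closed, tolerance = 1e-12)
  expect_equal(tidy(st)$df, length(d) - 1)
  expect_equal(tidy(st)$p.value,
               2 * pt(abs(t_closed), df = 9, lower.tail = FALSE),
               tolerance = 1e-12)

  # degenerate cases
  expect_equal(tidy(paired_change_test(pre, pre))$statistic, 0)
  expect_equal(tidy(paired_change_test(pre, pre))$p.value, 1)
  inf_case <- paired_change_test(c(1, 2, 3), c(2, 3, 4))
  expect_true(is.infinite(tidy(inf_case)$statistic))
  expect_true(tidy(inf_case)$degenerate)
  expect_error(paired_change_test(1:3, 1:4), "matched")
})

test_that("independent t uses pooled variance df, Welch behind a flag", {
  set.seed(7)
  a <- rnorm(16, 0.5, 0.1)
  b <- rnorm(19, 0.45, 0.1)
  st <- independent_group_test(a, b)
  expect_equal(tidy(st)$df, 33)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(tidy(st)$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tidy(st)$p.value, ref$p.value, tolerance = 1e-12)

  stw <- independent_group_test(a, b, welch = TRUE)
  refw <- t.test(a, b)
  expect_equal(tidy(stw)$df, unname(refw$parameter))
  expect_error(independent_group_test(a, numeric(1)), "at least 2")
})

test_that("brain-behavior interaction recovers opposite-slope arms", {
  fx <- make_stats_fixture(seed = 8, n_act = 12, n_sham = 12, pc_fun = function(cv) {
    0.5 + ifelse(cv$timepoint == "post", rnorm(nrow(cv), 0, 0.05), 0)
  })
  # gains built from the actual deltas: -b for active, +b for sham
  deltas <- fx$metrics |>
    dplyr::filter(node == "LIFG_tri") |>
    tidyr::pivot_wider(id_cols = subject_id, names_from = timepoint,
                       values_from = pc) |>
    dplyr::filter(!is.na(pre) & !is.na(post)) |>
    dplyr::mutate(delta = post - pre)
  arm_of <- fx$covariates$arm[match(deltas$subject_id,
                                    fx$covariates$subject_id)]
  b <- 300
  gain <- 50 + ifelse(arm_of == "active", -b, b) * deltas$delta +
    rnorm(nrow(deltas), 0, 3)
  names(gain) <- deltas$subject_id

  st <- brain_behavior_model(fx$metrics, fx$covariates, behavior = gain)
  inter <- dplyr::filter(tidy(st), term == "delta:armactive")
  expect_lt(inter$p.value, 1e-6)
  expect_lt(inter$estimate, 0)
  slopes <- st$extra$simple_slopes
  expect_lt(slopes$r[slopes$arm == "active"], 0)
  expect_gt(slopes$r[slopes$arm == "sham"], 0)

  # constant gains: zero slopes, flagged not crashed
  st0 <- suppressWarnings(  # lm warns on the exactly constant response
    brain_behavior_model(fx$metrics, fx$covariates,
                         behavior = setNames(rep(50, length(gain)),
                                             names(gain))))
  expect_equal(st0$extra$simple_slopes$r, c(0, 0))
  expect_true(all(abs(dplyr::filter(tidy(st0), term != "(Intercept)")$estimate) < 1e-9))
})

test_that("BH adjustment matches the hand-computed step-up procedure", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))

  # hand application of p * m / rank with cumulative minimum
  p <- c(0.002, 0.3, 0.04, 0.011, 0.9)
  m <- length(p)
  ord <- order(p)
  stepup <- p[ord] * m / seq_len(m)
  stepup <- rev(cummin(rev(stepup)))
  expected <- numeric(m); expected[ord] <- pmin(stepup, 1)
  expect_equal(bh_fdr(p), expected, tolerance = 1e-12)

  # order-preserving, monotone, adjusted >= raw on random vectors
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    adj <- bh_fdr(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # same ranking
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("per-module tests adjust within comparison families", {
  coh <- small_cohort(seed = 15, n_hc = 5, n_per_group = 5, t_len = 60)
  part <- reference_partition()
  mc <- compute_module_counts(coh$timeseries, part, "LIFG_tri")
  res <- per_module_tests(mc, coh$covariates)
  # 6 non-target modules x 3 comparisons
  expect_equal(nrow(res), 18)
  expect_setequal(unique(res$comparison),
                  c("pre_vs_hc", "post_vs_hc", "post_vs_pre"))
  expect_true(all(res$p.adjusted >= res$p.value - 1e-15))
  for (cmp in unique(res$comparison)) {
    sub <- res[res$comparison == cmp, ]
    expect_equal(sub$p.adjusted, bh_fdr(sub$p.value), tolerance = 1e-12)
  }
})
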