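test_that("mann_whitney_u matches its exact definition", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)  # 2 * 1/20 over the C(6,3) rank assignments
  expect_equal(mw$method, "exact")

  expect_warning(mw2 <- mann_whitney_u(c(2, 2, 2), c(2, 2, 2)), "identical")
  expect_equal(mw2$p, 1)

  # exact path equals full enumeration on tie-free n = 8 vs 8
  set.seed(1)
  a <- rnorm(8); b <- rnorm(8, 0.5)
  expect_equal(mann_whitney_u(a, b)$p, mw_enum_p(a, b), tolerance = 1e-12)

  # U (and hence exact p) invariant under strictly monotone transforms
  expect_equal(mann_whitney_u(exp(a), exp(b))$U, mann_whitney_u(a, b)$U)
  expect_equal(mann_whitney_u(a^3, b^3)$U, mann_whitney_u(a, b)$U)

  # ties or large n fall back to the corrected normal approximation
  mwt <- mann_whitney_u(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_equal(mwt$method, "normal")
  expect_true(mwt$p >= 0 && mwt$p <= 1)
  mwl <- mann_whitney_u(rnorm(12), rnorm(12))
  expect_equal(mwl$method, "normal")

  expect_error(mann_whitney_u(numeric(0), 1), class = "ek_invalid_input")
})

test_that("between-subjects two-way ANOVA reproduces hand-computed sums of squares", {
  # 2 x 2, n = 3 per cell; cell means 2, 5, 4, 9
  d <- data.frame(
    group = rep(c("a1", "a1", "a2", "a2"), each = 3),
    level = rep(c("b1", "b2", "b1", "b2"), each = 3),
    value = c(1, 2, 3, 4, 5, 6, 3, 4, 5, 8, 9, 10))
  fit <- two_way_anova(d, response = "value", between = "group",
                       within = "level", design = "between")
  tab <- fit$table
  # hand arithmetic: SS_A = 27, SS_B = 48, SS_AB = 3, SS_err = 8, df_err = 8
  expect_equal(tab$ss, c(27, 48, 3))
  expect_equal(tab$df1, c(1, 1, 1))
  expect_equal(tab$df2, c(8, 8, 8))
  expect_equal(tab$F, c(27, 48, 3))
  expect_equal(tab$p, pf(c(27, 48, 3), 1, 8, lower.tail = FALSE))
  # SS conservation
  ss_tot <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(tab$ss) + fit$context$ms_error * fit$context$df_error,
               ss_tot, tolerance = 1e-8)
})

test_that("mixed ANOVA matches first-principles stratum arithmetic", {
  d <- data.frame(
    subject_id = rep(paste0("s", 1:6), each = 2),
    group = rep(c("g1", "g2"), each = 6),
    level = rep(c("t1", "t2"), 6),
    value = c(1, 2.1, 2, 2.8, 3, 4.2, 5, 7.1, 6, 8.3, 7, 8.8))
  fit <- two_way_anova(d, response = "value", between = "group",
                       within = "level", subject = "subject_id",
                       design = "mixed")
  # independent arithmetic from cell/marginal means
  gm <- mean(d$value)
  subj_means <- tapply(d$value, d$subject_id, mean)
  grp_of <- tapply(d$group, d$subject_id, `[`, 1)
  grp_means <- tapply(d$value, d$group, mean)
  lev_means <- tapply(d$value, d$level, mean)
  cell_means <- tapply(d$value, list(d$group, d$level), mean)
  ss_between_subj <- 2 * sum((subj_means - gm)^2)
  ss_A <- 2 * 3 * sum((grp_means - gm)^2)
  ss_subj_within <- ss_between_subj - ss_A
  ss_B <- 6 * sum((lev_means - gm)^2)
  ss_AB <- 3 * sum((sweep(sweep(cell_means, 1, grp_means), 2, lev_means) + gm)^2)
  ss_tot <- sum((d$value - gm)^2)
  ss_resid <- ss_tot - ss_between_subj - ss_B - ss_AB
  tab <- fit$table
  expect_equal(tab$ss, c(ss_A, ss_B, ss_AB), tolerance = 1e-10)
  expect_equal(tab$df1, c(1, 1, 1))
  expect_equal(tab$df2, c(4, 4, 4))
  expect_equal(tab$F[1], (ss_A / 1) / (ss_subj_within / 4))
  expect_equal(tab$F[2], (ss_B / 1) / (ss_resid / 4))
  expect_equal(tab$F[3], (ss_AB / 1) / (ss_resid / 4))

  # identical groups: zero group effect
  d2 <- d
  d2$value[d2$group == "g2"] <- d2$value[d2$group == "g1"]
  fit2 <- two_way_anova(d2, response = "value", between = "group",
                        within = "level", subject = "subject_id",
                        design = "mixed")
  expect_equal(fit2$table$F[1], 0, tolerance = 1e-12)
  expect_equal(fit2$table$p[1], 1, tolerance = 1e-12)

  # grand-mean shift leaves every F unchanged
  d3 <- d
  d3$value <- d3$value + 100
  fit3 <- two_way_anova(d3, response = "value", between = "group",
                        within = "level", subject = "subject_id",
                        design = "mixed")
  expect_equal(fit3$table$F, fit$table$F, tolerance = 1e-10)

  # incomplete within-subject rows are rejected, naming the subject
  d4 <- d[-2, ]
  err <- tryCatch(
    two_way_anova(d4, response = "value", between = "group",
                  within = "level", subject = "subject_id", design = "mixed"),
    ek_invalid_input = function(e) e)
  expect_s3_class(err, "ek_invalid_input")
  expect_true(any(grepl("s1", conditionMessage(err))))
})

test_that("Tukey post hoc behaves like a studentized-range adjustment", {
  set.seed(2)
  # 3 groups x 2 levels, one group shifted by >= 5 SD
  d <- data.frame(
    subject_id = rep(paste0("s", 1:12), each = 2),
    group = rep(c("a", "b", "c"), each = 8),
    level = rep(c("t1", "t2"), 12),
    value = rnorm(24, sd = 1))
  d$value[d$group == "c"] <- d$value[d$group == "c"] + 8
  fit <- two_way_anova(d, response = "value", between = "group",
                       within = "level", subject = "subject_id",
                       design = "mixed")
  ph <- tukey_posthoc(fit)
  involves_c <- grepl("(^|\\s)c\\.", ph$contrast)
  same_group_c <- grepl("c\\..* - c\\.", ph$contrast)
  expect_true(all(ph$p_adj[involves_c & !same_group_c] < 0.05))
  expect_true(all(ph$p_adj[!involves_c] > 0.05))

  # equal cell means: adjusted p ~ 1
  deq <- data.frame(
    subject_id = rep(paste0("s", 1:6), each = 2),
    group = rep(c("g1", "g2"), each = 6),
    level = rep(c("t1", "t2"), 6),
    value = c(1, 2, 2, 1, 1.5, 1.5, 1, 2, 2, 1, 1.5, 1.5))
  feq <- two_way_anova(deq, response = "value", between = "group",
                       within = "level", subject = "subject_id",
                       design = "mixed")
  pheq <- tukey_posthoc(feq, pairs = list(c("g1.t1", "g2.t1")))
  expect_gt(pheq$p_adj, 0.99)

  # adjusted p is never below the raw pairwise t p
  for (i in seq_len(nrow(ph))) {
    se <- sqrt(fit$context$ms_error / 2 * (1 / 4 + 1 / 4))
    p_raw <- 2 * pt(-abs(ph$estimate[i]) / (se * sqrt(2)),
                    fit$context$df_error)
    expect_gte(ph$p_adj[i] + 1e-12, p_raw)
  }
})

test_that("Sidak adjustment is the closed form and the identity at m = 1", {
  expect_equal(sidak_posthoc(0.05, m = 1)$p_adj, 0.05)
  expect_equal(sidak_posthoc(0.01, m = 2)$p_adj, 1 - 0.99^2)
  expect_equal(sidak_posthoc(1, m = 3)$p_adj, 1)
  ph <- sidak_posthoc(c(x = 0.02, y = 0.5), m = 4)
  expect_equal(ph$p_adj, 1 - (1 - c(0.02, 0.5))^4)
  expect_equal(ph$contrast, c("x", "y"))
  expect_error(sidak_posthoc(0.5, m = 0), class = "ek_invalid_input")
})

test_that("compare_cohort runs the design-appropriate tests and excludes degenerates", {
  mk_summaries <- function(shift_acc = 0) {
    set.seed(10)
    n <- 8
    rbind(
      data.frame(subject_id = paste0("c", 1:n), group = "control",
                 distance_cm = rnorm(n, 2000, 200),
                 eff_vel_cm_s = rnorm(n, 17, 1),
                 mean_acc_cm_s2 = rnorm(n, 80, 8),
                 stops = rpois(n, 140),
                 dist_per_stop_cm = rnorm(n, 15, 2), degenerate = FALSE),
      data.frame(subject_id = paste0("v", 1:n), group = "treated",
                 distance_cm = rnorm(n, 2000, 200),
                 eff_vel_cm_s = rnorm(n, 17, 1),
                 mean_acc_cm_s2 = rnorm(n, 80 + shift_acc, 8),
                 stops = rpois(n, 140),
                 dist_per_stop_cm = rnorm(n, 15, 2), degenerate = FALSE))
  }
  sm <- mk_summaries(shift_acc = 60)
  cmp <- compare_cohort(sm, design = "totals")
  expect_true(cmp$results$significant[cmp$results$statistic == "mean_acc_cm_s2"])
  expect_equal(nrow(cmp$results), 5)

  # degenerate exclusion is logged
  sm2 <- sm
  sm2$degenerate[3] <- TRUE
  cmp2 <- compare_cohort(sm2, design = "totals")
  expect_equal(cmp2$exclusions, sm$subject_id[3])
  expect_equal(cmp2$results$n_1[1], 7)

  # single group input errors
  expect_error(compare_cohort(sm[sm$group == "control", ], design = "totals"),
               class = "ek_invalid_input")
  # a group emptied by exclusions errors
  sm3 <- sm
  sm3$degenerate[sm3$group == "treated"] <- TRUE
  expect_error(compare_cohort(sm3, design = "totals"),
               class = "ek_invalid_input")

  # areas design: mixed ANOVA + Sidak contrasts
  set.seed(11)
  ar <- expand.grid(subject_id = c(paste0("c", 1:6), paste0("v", 1:6)),
                    area = c("social", "non_social"),
                    stringsAsFactors = FALSE)
  ar$group <- ifelse(grepl("^c", ar$subject_id), "control", "treated")
  ar$mean_acc_cm_s2 <- rnorm(nrow(ar), 100, 5) +
    ifelse(ar$group == "control" & ar$area == "social", -40, 0)
  ar$degenerate <- FALSE
  cmpa <- compare_cohort(ar, design = "areas",
                         statistics = "mean_acc_cm_s2")
  res <- cmpa$results
  expect_true(res$significant[grepl(":", res$effect)])  # interaction
  ph <- cmpa$posthoc$mean_acc_cm_s2
  expect_equal(attr(ph, "method"), "sidak")
  # the within-control area contrast carries the -40 shift
  expect_true(ph$p_adj[grepl("^control:", ph$contrast)] < 0.05)
  expect_true(ph$p_adj[grepl("^treated:", ph$contrast)] > 0.05)
})

test_that("null cohorts reject near the nominal rate", {
  set.seed(123)
  rej <- mean(replicate(200, {
    mann_whitney_u(rnorm(8), rnorm(8))$p < 0.05
  }))
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.10)
})
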