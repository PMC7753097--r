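test_that("a perfect linear association yields r = 1 and tiny one-tailed p", {
  x <- seq(-1, 1, length.out = 20)
  res <- correlate_tva_alpha(x, 3 * x + 2)
  expect_equal(res$r, 1)
  expect_equal(res$df, 18)
  expect_lt(res$p, 1e-10)
  expect_equal(res$p_bonferroni, min(1, 4 * res$p))
  # the Bonferroni family multiplies the raw one-sided p by 4
  set.seed(9)
  res2 <- correlate_tva_alpha(rnorm(38), rnorm(38))
  expect_equal(res2$p_bonferroni, min(1, 4 * res2$p))
  expect_error(correlate_tva_alpha(rep(1, 10), rnorm(10)),
               class = "tvalpha_degenerate_input")
  expect_error(correlate_tva_alpha(1:2, 2:1), class = "tvalpha_degenerate_input")
})

test_that("mixed-ANOVA degrees of freedom are fixed by the design", {
  dat <- sim_cohort_frame()
  tab <- mixed_anova(dat, dv = "value", subject = "subject",
                     between = "group", within = "block")
  ix <- tab$effect == "group:block"
  expect_equal(tab$df_num[ix], 2)
  expect_equal(tab$df_den[ix], 35)
  expect_equal(tab$df_den[tab$effect == "group"], 35)
  expect_true(all(tab$ges >= 0 & tab$ges <= 1))
  # incomplete designs are refused
  expect_error(mixed_anova(dat[-1, ], dv = "value", subject = "subject",
                           between = "group", within = "block"),
               class = "tvalpha_incomplete_design")
})

test_that("type II sums of squares agree with aov on a balanced design", {
  dat <- sim_cohort_frame(seed = 2, n = c(NVG = 6, NAVG = 6, AVG = 6))
  tab <- mixed_anova(dat, dv = "value", subject = "subject",
                     between = "group", within = "block")
  oracle <- summary(stats::aov(value ~ group * block + Error(subject / block),
                               data = transform(dat, subject = factor(subject))))
  f_between <- oracle[["Error: subject"]][[1]]["group", "F value"]
  f_within <- oracle[["Error: subject:block"]][[1]]
  expect_equal(tab$F[tab$effect == "group"], f_between, tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "block"], f_within["block", "F value"],
               tolerance = 1e-8)
  expect_equal(tab$F[tab$effect == "group:block"],
               f_within["group:block", "F value"], tolerance = 1e-8)
})

test_that("sphericity handling: epsilon near 1 under compound symmetry", {
  set.seed(5)
  n <- 45
  subj_eff <- rnorm(n, 0, 2)
  dat <- expand.grid(subject = sprintf("S%02d", 1:n),
                     w = paste0("w", 1:4), stringsAsFactors = FALSE)
  dat$group <- rep(rep(c("A", "B", "C"), each = 15), 4)
  dat$value <- subj_eff[as.integer(factor(dat$subject))] + rnorm(nrow(dat))
  tab <- mixed_anova(dat, dv = "value", subject = "subject",
                     between = "group", within = "w")
  eps <- tab$epsilon[tab$effect == "w"]
  expect_gt(eps, 0.8)
  expect_lte(eps, 1)
  # with iid noise sphericity holds, so no correction is applied
  expect_false(tab$corrected[tab$effect == "w"])
  # forcing the correction shrinks the degrees of freedom
  tab_f <- mixed_anova(dat, dv = "value", subject = "subject",
                       between = "group", within = "w", sphericity = "always")
  expect_lt(tab_f$df_num[tab_f$effect == "w"], 3)
  expect_true(tab_f$corrected[tab_f$effect == "w"])
})

test_that("difference values are antisymmetric block contrasts", {
  tab <- data.frame(subject = c("S1", "S2"), group = c("NVG", "AVG"),
                    C_block1 = c(40, 35), C_block2 = c(46, 50),
                    alpha_block1 = c(0.05, 0.02), alpha_block2 = c(0.06, 0.12))
  d <- difference_values(tab)
  expect_equal(d$d_param, c(6, 15))
  expect_equal(d$d_alpha, c(0.01, 0.1))
  swapped <- tab
  names(swapped)[3:6] <- c("C_block2", "C_block1", "alpha_block2", "alpha_block1")
  d2 <- difference_values(swapped)
  expect_equal(d2$d_param, -d$d_param)
  expect_equal(d2$d_alpha, -d$d_alpha)
  same <- tab; same$C_block2 <- same$C_block1; same$alpha_block2 <- same$alpha_block1
  expect_equal(difference_values(same)$d_param, c(0, 0))
  expect_error(difference_values(tab[, -3]), class = "tvalpha_incomplete_data")
})

test_that("Cook's screening flags planted leverage points only", {
  set.seed(22)
  n <- c(NVG = 13, NAVG = 14, AVG = 9)
  diff <- data.frame(subject = sprintf("S%02d", 1:36),
                     group = rep(names(n), n),
                     d_alpha = rnorm(36, 0, 0.03),
                     d_param = rnorm(36, 2, 2), stringsAsFactors = FALSE)
  clean <- cooks_screen(diff)
  expect_length(clean$excluded, 0)
  planted <- diff
  planted$d_alpha[1] <- 0.4
  planted$d_param[1] <- -40
  scr <- cooks_screen(planted)
  expect_true("S01" %in% scr$excluded)
  expect_length(cooks_screen(planted, threshold = Inf)$excluded, 0)
})

test_that("the dummy regression reproduces per-group least squares", {
  set.seed(12)
  n <- c(NVG = 12, NAVG = 13, AVG = 9)
  diff <- data.frame(subject = sprintf("S%02d", 1:34),
                     group = rep(names(n), n),
                     d_alpha = rnorm(34, 0, 0.05), stringsAsFactors = FALSE)
  slopes <- c(NVG = -30, NAVG = -5, AVG = 160)
  inters <- c(NVG = -1.5, NAVG = 2.5, AVG = -5)
  diff$d_param <- inters[diff$group] + slopes[diff$group] * diff$d_alpha +
    rnorm(34, 0, 1.5)
  res <- dummy_regression(diff)
  for (g in names(n)) {
    sub <- diff[diff$group == g, ]
    ind <- stats::lm(d_param ~ d_alpha, data = sub)
    ln <- res$group_lines[res$group_lines$group == g, ]
    expect_equal(ln$intercept, unname(coef(ind)[1]), tolerance = 1e-8)
    expect_equal(ln$slope, unname(coef(ind)[2]), tolerance = 1e-8)
  }
  # whole-model F equals the R-squared identity with df (5, n - 6)
  expect_equal(res$df, c(5, 28))
  expect_equal(res$F, (res$r_squared / 5) / ((1 - res$r_squared) / 28),
               tolerance = 1e-10)
})

test_that("a shared line across groups gives unit R2 and zero group terms", {
  diff <- data.frame(subject = sprintf("S%02d", 1:12),
                     group = rep(c("NVG", "NAVG", "AVG"), each = 4),
                     d_alpha = rep(c(-0.1, 0, 0.1, 0.2), 3),
                     stringsAsFactors = FALSE)
  diff$d_param <- 2 * diff$d_alpha
  # exact fit: summary() warns about the perfect R-squared
  res <- suppressWarnings(dummy_regression(diff))
  expect_equal(unname(res$coefficients["beta1"]), 2, tolerance = 1e-10)
  expect_equal(unname(res$coefficients[c("alpha", "beta2", "beta3",
                                         "beta4", "beta5")]),
               rep(0, 5), tolerance = 1e-8)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  tiny <- diff[diff$group != "AVG", ]
  expect_error(dummy_regression(rbind(tiny, diff[9, ])),
               class = "tvalpha_singular_design")
})

test_that("assumption checks are advisory and handle degenerate cells", {
  set.seed(13)
  values <- rnorm(36)
  groups <- rep(c("NVG", "NAVG", "AVG"), each = 12)
  rep_checks <- assumption_checks(values, groups)
  expect_equal(nrow(rep_checks), 4)
  expect_true(all(rep_checks$p[!is.na(rep_checks$p)] >= 0))
  const <- assumption_checks(rep(1, 9), rep(c("A", "B", "C"), each = 3))
  expect_true(all(is.na(const$p)))
})
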