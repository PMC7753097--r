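#' One-tailed Pearson correlation with Bonferroni adjustment
#'
#' Tests for a positive association between a per-subject alpha ratio and
#' a TVA parameter (the study's directional hypothesis: stronger
#' post-stimulus alpha attenuation goes along with faster processing).
#' Four such tests form the family, so the Bonferroni-adjusted p-value
#' multiplies by `m = 4` by default.
#'
#' @param x,y paired per-subject values (at least 3 pairs).
#' @param alternative passed to [stats::cor.test()]; `"greater"` encodes
#'   the expected positive direction.
#' @param m Bonferroni family size.
#' @return list: `r`, `r_squared`, `df`, `t`, `p`, `p_bonferroni`, `n`,
#'   `alternative`.
#' @export
correlate_tva_alpha <- function(x, y, alternative = "greater", m = 4) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_tvalpha("need at least 3 pairs", "tvalpha_degenerate_input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_tvalpha("zero variance in one of the variables",
                 "tvalpha_degenerate_input")
  }
  ct <- stats::cor.test(x, y, alternative = alternative, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       df = unname(ct$parameter), t = unname(ct$statistic),
       p = ct$p.value, p_bonferroni = min(1, m * ct$p.value),
       n = length(x), alternative = alternative)
}

#' Mixed ANOVA with type II sums of squares
#'
#' Between-subjects factor crossed with one or two within-subject
#' factors, computed on type II sums of squares (the design has unequal
#' group sizes). For every within effect with more than one numerator
#' degree of freedom, Mauchly's sphericity test is run and, when it
#' rejects at `alpha`, the Greenhouse-Geisser correction is applied to
#' the degrees of freedom and p-value (Huynh-Feldt available via
#' `correction`). Effect sizes are generalized eta squared in the
#' observed-measure formulation: the effect's SS over the effect's SS
#' plus the summed error SS of all strata.
#'
#' @param data long-format data frame.
#' @param dv,subject,between column names (strings).
#' @param within character vector of one or two within-factor column
#'   names.
#' @param correction `"greenhouse-geisser"` (default), `"huynh-feldt"`,
#'   or `"none"`; applied only when Mauchly rejects (or always/never via
#'   `sphericity`).
#' @param sphericity `"mauchly"` (apply correction on violation),
#'   `"always"`, or `"never"`.
#' @param alpha significance level of Mauchly's test.
#' @return object of class `anova_table`: a data frame with one row per
#'   effect (`effect`, `df_num`, `df_den`, `epsilon`, `F`, `p`, `ges`,
#'   `mauchly_p`, `corrected`).
#' @export
mixed_anova <- function(data, dv, subject, between, within,
                        correction = c("greenhouse-geisser", "huynh-feldt", "none"),
                        sphericity = c("mauchly", "always", "never"),
                        alpha = 0.05) {
  correction <- match.arg(correction)
  sphericity <- match.arg(sphericity)
  stopifnot(all(c(dv, subject, between, within) %in% names(data)))
  data[[subject]] <- factor(data[[subject]])
  data[[between]] <- factor(data[[between]])
  for (w in within) data[[w]] <- factor(data[[w]])

  # wide response matrix: one column per within-cell, ordered so the
  # within design matches idata
  idata <- rev(expand.grid(rev(lapply(within, function(w) levels(data[[w]]))),
                           stringsAsFactors = TRUE))
  names(idata) <- within
  cellkey <- interaction(lapply(within, function(w) data[[w]]), drop = FALSE,
                         lex.order = TRUE)
  targetkey <- interaction(idata, drop = FALSE, lex.order = TRUE)
  subj_levels <- levels(data[[subject]])
  Y <- matrix(NA_real_, length(subj_levels), nrow(idata))
  grp <- rep(NA_character_, length(subj_levels))
  for (i in seq_along(subj_levels)) {
    rows <- data[data[[subject]] == subj_levels[i], ]
    if (nrow(rows) != nrow(idata) || anyNA(rows[[dv]])) {
      stop_tvalpha(sprintf("subject %s has incomplete within cells",
                           subj_levels[i]), "tvalpha_incomplete_design")
    }
    Y[i, ] <- rows[[dv]][match(targetkey, cellkey[data[[subject]] == subj_levels[i]])]
    grp[i] <- as.character(rows[[between]][1])
  }
  if (anyNA(Y)) stop_tvalpha("missing within cells", "tvalpha_incomplete_design")
  grp <- factor(grp, levels = levels(data[[between]]))
  if (any(table(grp) < 2)) {
    stop_tvalpha("need at least 2 subjects per group", "tvalpha_incomplete_design")
  }
  mlm <- stats::lm(Y ~ grp)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = "II")
  # car warns when the Huynh-Feldt epsilon exceeds 1 and clips it; expected
  s <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  uni <- s$univariate.tests
  effects <- rownames(uni)
  keep <- effects != "(Intercept)"

  # generalized eta squared: unique error strata are keyed by the
  # within-part of the effect
  within_part <- vapply(effects, function(e) {
    parts <- strsplit(e, ":", fixed = TRUE)[[1]]
    paste(parts[parts != "grp"], collapse = ":")
  }, character(1))
  err_by_stratum <- tapply(uni[, "Error SS"], within_part, function(v) v[1])
  ss_err_total <- sum(err_by_stratum)

  mauchly <- s$sphericity.tests
  adj <- s$pval.adjustments
  eps_col <- if (correction == "huynh-feldt") "HF eps" else "GG eps"

  out <- data.frame(effect = character(0), df_num = numeric(0),
                    df_den = numeric(0), epsilon = numeric(0),
                    F = numeric(0), p = numeric(0), ges = numeric(0),
                    mauchly_p = numeric(0), corrected = logical(0),
                    stringsAsFactors = FALSE)
  for (e in effects[keep]) {
    df1 <- uni[e, "num Df"]; df2 <- uni[e, "den Df"]
    Fv <- uni[e, "F value"]; pv <- uni[e, "Pr(>F)"]
    eps <- NA_real_; mp <- NA_real_; corrected <- FALSE
    if (df1 > 1 && !is.null(adj) && e %in% rownames(adj)) {
      eps <- unname(adj[e, eps_col])
      wp <- within_part[match(e, effects)]
      mrow <- match(wp, rownames(mauchly))
      mp <- if (!is.na(mrow)) unname(mauchly[mrow, "p-value"]) else NA_real_
      do_corr <- switch(sphericity,
                        mauchly = !is.na(mp) && mp < alpha,
                        always = TRUE, never = FALSE)
      if (do_corr && correction != "none") {
        df1 <- df1 * eps; df2 <- df2 * eps
        pv <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
        corrected <- TRUE
      }
    }
    ges <- uni[e, "Sum Sq"] / (uni[e, "Sum Sq"] + ss_err_total)
    out <- rbind(out, data.frame(
      effect = gsub("grp", between, e, fixed = TRUE), df_num = df1,
      df_den = df2, epsilon = eps, F = Fv, p = pv, ges = ges,
      mauchly_p = mp, corrected = corrected, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$df_num <- round(y$df_num, 2); y$df_den <- round(y$df_den, 2)
  y$epsilon <- round(y$epsilon, 2); y$F <- round(y$F, 2)
  y$p <- signif(y$p, 3); y$ges <- round(y$ges, 3)
  print(y[, c("effect", "df_num", "df_den", "epsilon", "F", "p", "ges")],
        row.names = FALSE)
  invisible(x)
}

#' Block-2 minus block-1 difference values
#'
#' Collapses a subject-level table to the change scores entering the
#' dummy-coded regression: the TVA parameter difference (criterion) and
#' the per-block mean medium-alpha-ratio difference (predictor).
#'
#' @param table data frame with columns `subject`, `group`, the
#'   parameter per block (`<param>_block1`, `<param>_block2`) and the
#'   alpha ratio per block (`alpha_block1`, `alpha_block2`).
#' @param param prefix of the parameter columns (default `"C"`).
#' @return data frame: `subject`, `group`, `d_param`, `d_alpha`.
#' @export
difference_values <- function(table, param = "C") {
  cols <- c(paste0(param, "_block1"), paste0(param, "_block2"),
            "alpha_block1", "alpha_block2")
  if (!all(cols %in% names(table))) {
    stop_tvalpha(paste0("missing block columns: ",
                        paste(setdiff(cols, names(table)), collapse = ", ")),
                 "tvalpha_incomplete_data")
  }
  if (anyNA(table[, cols])) {
    stop_tvalpha("missing block values", "tvalpha_incomplete_data")
  }
  data.frame(subject = table$subject, group = table$group,
             d_param = table[[cols[2]]] - table[[cols[1]]],
             d_alpha = table$alpha_block2 - table$alpha_block1,
             stringsAsFactors = FALSE)
}

#' Cook's-distance outlier screen for the difference regression
#'
#' Fits the dummy-coded interaction model and removes subjects whose
#' Cook's distance exceeds the threshold (default `4/n`), as a screening
#' step before the reported fit.
#'
#' @param diff data frame from [difference_values()].
#' @param threshold exclusion threshold; `Inf` disables screening.
#' @return list: `retained` (screened data frame), `excluded` (subject
#'   ids), `distances` (named Cook's distances), `threshold`.
#' @export
cooks_screen <- function(diff, threshold = 4 / nrow(diff)) {
  fit <- stats::lm(d_param ~ d_alpha * group, data = dummy_frame(diff))
  cd <- stats::cooks.distance(fit)
  names(cd) <- diff$subject
  out <- cd > threshold
  if (all(out)) stop_tvalpha("screen excluded every subject",
                             "tvalpha_degenerate_screen")
  list(retained = diff[!out, , drop = FALSE],
       excluded = diff$subject[out],
       distances = cd, threshold = threshold)
}

dummy_frame <- function(diff) {
  lv <- intersect(c("NVG", "NAVG", "AVG"), unique(diff$group))
  diff$group <- factor(diff$group, levels = lv)
  diff
}

#' Dummy-coded difference regression
#'
#' Ordinary least squares of the TVA-parameter change on the alpha-ratio
#' change with group dummies (non-video gamers as reference):
#' `Y = a + b1*X + b2*D_NAVG + b3*D_AVG + b4*X*D_NAVG + b5*X*D_AVG`.
#' The per-group lines are recoverable as intercept `a + b2` (or `b3`)
#' and slope `b1 + b4` (or `b5`). Only the whole-model F is meant for
#' inference; individual coefficients are descriptive.
#'
#' @param diff data frame from [difference_values()] (after screening).
#' @return object of class `diff_regression`: `coefficients` (named
#'   a/b1..b5), `r_squared`, `F`, `df`, `p`, `group_lines` (per-group
#'   intercept/slope), `n`, and the underlying `lm` fit.
#' @export
dummy_regression <- function(diff) {
  diff <- dummy_frame(diff)
  if (any(table(diff$group) < 2)) {
    stop_tvalpha("need at least 2 subjects per group", "tvalpha_singular_design")
  }
  fit <- stats::lm(d_param ~ d_alpha * group, data = diff)
  if (any(is.na(stats::coef(fit)))) {
    stop_tvalpha("rank-deficient design", "tvalpha_singular_design")
  }
  sm <- summary(fit)
  co <- stats::coef(fit)
  groups <- levels(diff$group)
  lines <- do.call(rbind, lapply(groups, function(g) {
    int <- co[["(Intercept)"]] +
      if (g == groups[1]) 0 else co[[paste0("group", g)]]
    slp <- co[["d_alpha"]] +
      if (g == groups[1]) 0 else co[[paste0("d_alpha:group", g)]]
    data.frame(group = g, intercept = int, slope = slp,
               stringsAsFactors = FALSE)
  }))
  fstat <- sm$fstatistic
  structure(list(
    coefficients = stats::setNames(co, c("alpha", "beta1", "beta2", "beta3",
                                         "beta4", "beta5")[seq_along(co)]),
    r_squared = sm$r.squared,
    F = unname(fstat[1]), df = unname(fstat[2:3]),
    p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    group_lines = lines, n = nrow(diff), fit = fit),
    class = "diff_regression")
}

#' @export
print.diff_regression <- function(x, ...) {
  cat(sprintf("Difference regression: R^2 = %.2f, F(%d, %d) = %.2f, p = %.4g (n = %d)\n",
              x$r_squared, x$df[1], x$df[2], x$F, x$p, x$n))
  for (i in seq_len(nrow(x$group_lines))) {
    cat(sprintf("  %s: Y = %.2f %+.2f * X\n", x$group_lines$group[i],
                x$group_lines$intercept[i], x$group_lines$slope[i]))
  }
  invisible(x)
}

#' Advisory normality and variance-homogeneity checks
#'
#' Shapiro-Wilk per group and Levene's test across groups. The checks
#' are advisory: the pipeline reports them but never blocks on them
#' (ANOVA is robust to the normality violations typical of these data).
#'
#' @param values numeric vector of observations.
#' @param groups grouping factor of the same length.
#' @return data frame with one row per check: `check`, `group`,
#'   `statistic`, `p` (`NA` for degenerate cells).
#' @export
assumption_checks <- function(values, groups) {
  groups <- factor(groups)
  rows <- lapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (length(v) < 3 || stats::sd(v) == 0) {
      return(data.frame(check = "shapiro_wilk", group = g,
                        statistic = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    sw <- stats::shapiro.test(v)
    data.frame(check = "shapiro_wilk", group = g,
               statistic = unname(sw$statistic), p = sw$p.value,
               stringsAsFactors = FALSE)
  })
  lev <- if (nlevels(groups) >= 2 && stats::sd(values) > 0) {
    lt <- car::leveneTest(values ~ groups)
    data.frame(check = "levene", group = "all",
               statistic = lt[1, "F value"], p = lt[1, "Pr(>F)"],
               stringsAsFactors = FALSE)
  } else {
    data.frame(check = "levene", group = "all", statistic = NA_real_,
               p = NA_real_, stringsAsFactors = FALSE)
  }
  rbind(do.call(rbind, rows), lev)
}
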