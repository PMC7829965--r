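#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum test with midrank ties. `U` is the smaller of the two group
#' statistics. The exact two-tailed p (doubled lower tail of the exact U
#' distribution, capped at 1) is used when the combined sample size is at
#' most `exact_limit` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b numeric vectors of per-subject values (n >= 1 each).
#' @param exact_limit largest `length(a) + length(b)` for the exact path
#'   (default 16).
#' @return list with `U`, `p`, `method` ("exact" or "normal"), `U_a`, `U_b`,
#'   `n_a`, `n_b`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(a, b, exact_limit = 16) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L || anyNA(c(a, b)) ||
      !all(is.finite(c(a, b)))) {
    ek_stop("both samples must be non-empty and finite", "ek_invalid_input")
  }
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  u <- min(u_a, u_b)
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  if (length(ties) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(list(U = u, p = 1, method = "degenerate",
                U_a = u_a, U_b = u_b, n_a = n_a, n_b = n_b))
  }
  if (!has_ties && n <= exact_limit) {
    p <- min(1, 2 * stats::pwilcox(u, n_a, n_b))
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      warning("zero variance after tie correction; p = 1")
      return(list(U = u, p = 1, method = "degenerate",
                  U_a = u_a, U_b = u_b, n_a = n_a, n_b = n_b))
    }
    z <- (u - mu + 0.5) / sqrt(sigma2)  # continuity correction toward mean
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal"
  }
  list(U = u, p = p, method = method, U_a = u_a, U_b = u_b,
       n_a = n_a, n_b = n_b)
}

#' Two-way ANOVA (mixed or between-subjects)
#'
#' `design = "mixed"` fits the standard mixed model with one
#' between-subjects factor (`between`, e.g. treatment group) and one
#' within-subjects factor (`within`, e.g. minute or social area): the
#' between effect is tested against subjects-within-groups, the within and
#' interaction effects against the within-by-subject residual. Every
#' subject must have exactly one observation per within level (missing
#' cells are an error naming the offending subjects).
#'
#' `design = "between"` fits a fully between-subjects two-factor layout
#' with type-III sums of squares (sum-to-zero contrasts), appropriate for
#' unbalanced group sizes.
#'
#' @param data long-format data.frame.
#' @param response,between,within,subject column names in `data`.
#' @param design `"mixed"` or `"between"`.
#' @return `ek_anova`: list with `table` (effect, df1, df2, ss, F, p),
#'   `design`, and a `context` used by [tukey_posthoc()] (cell means and
#'   sizes, error mean squares and df).
#' @export
two_way_anova <- function(data, response = "value", between = "group",
                          within = "level", subject = "subject_id",
                          design = c("mixed", "between")) {
  design <- match.arg(design)
  for (col in c(response, between, within,
                if (design == "mixed") subject)) {
    if (!col %in% names(data)) {
      ek_stop(sprintf("column '%s' not in data", col), "ek_invalid_input")
    }
  }
  y <- data[[response]]
  if (anyNA(y) || !all(is.finite(y))) {
    ek_stop("response contains missing/non-finite values", "ek_invalid_input")
  }
  A <- factor(data[[between]])
  B <- factor(data[[within]])
  if (nlevels(A) < 2L || nlevels(B) < 2L) {
    ek_stop("both factors need >= 2 levels", "ek_invalid_input")
  }
  if (design == "mixed") {
    S <- factor(data[[subject]])
    tab <- table(S, B)
    bad <- rownames(tab)[apply(tab, 1, function(r) any(r != 1L))]
    if (length(bad) > 0L) {
      ek_stop(sprintf("within design needs one observation per subject per level; offending subjects: %s",
                      paste(bad, collapse = ", ")),
              "ek_invalid_input", data = list(subjects = bad))
    }
    d <- data.frame(y = y, A = A, B = B, S = S)
    fit <- stats::aov(y ~ A * B + Error(S / B), data = d)
    sm <- summary(fit)
    # between stratum: A against subjects-within-groups
    st1 <- sm[["Error: S"]][[1]]
    st2 <- sm[["Error: S:B"]][[1]]
    row_of <- function(st, name) which(trimws(rownames(st)) == name)
    tabout <- data.frame(
      effect = c(between, within, paste0(between, ":", within)),
      df1 = c(st1[row_of(st1, "A"), "Df"],
              st2[row_of(st2, "B"), "Df"],
              st2[row_of(st2, "A:B"), "Df"]),
      df2 = c(st1[row_of(st1, "Residuals"), "Df"],
              st2[row_of(st2, "Residuals"), "Df"],
              st2[row_of(st2, "Residuals"), "Df"]),
      ss = c(st1[row_of(st1, "A"), "Sum Sq"],
             st2[row_of(st2, "B"), "Sum Sq"],
             st2[row_of(st2, "A:B"), "Sum Sq"]),
      F = c(st1[row_of(st1, "A"), "F value"],
            st2[row_of(st2, "B"), "F value"],
            st2[row_of(st2, "A:B"), "F value"]),
      p = c(st1[row_of(st1, "A"), "Pr(>F)"],
            st2[row_of(st2, "B"), "Pr(>F)"],
            st2[row_of(st2, "A:B"), "Pr(>F)"]),
      stringsAsFactors = FALSE)
    ms_within <- st2[row_of(st2, "Residuals"), "Mean Sq"]
    df_within <- st2[row_of(st2, "Residuals"), "Df"]
    ms_between <- st1[row_of(st1, "Residuals"), "Mean Sq"]
    df_between <- st1[row_of(st1, "Residuals"), "Df"]
    context <- list(
      cells = stats::aggregate(y ~ A + B, d, mean),
      cell_n = stats::aggregate(y ~ A + B, d, length),
      ms_error = ms_within, df_error = df_within,
      ms_error_between = ms_between, df_error_between = df_between,
      data = d)
  } else {
    d <- data.frame(y = y, A = A, B = B)
    contrasts(d$A) <- stats::contr.sum(nlevels(A))
    contrasts(d$B) <- stats::contr.sum(nlevels(B))
    mm <- stats::model.matrix(~ A * B, d)
    asg <- attr(mm, "assign")  # 0 intercept, 1 A, 2 B, 3 A:B
    fit_full <- stats::lm.fit(mm, d$y)
    rss_full <- sum(fit_full$residuals^2)
    df_res <- nrow(d) - ncol(mm)
    one <- function(term) {
      keep <- asg != term
      fit_r <- stats::lm.fit(mm[, keep, drop = FALSE], d$y)
      ss <- sum(fit_r$residuals^2) - rss_full
      df1 <- sum(asg == term)
      Fv <- (ss / df1) / (rss_full / df_res)
      c(df1 = df1, ss = ss, F = Fv,
        p = stats::pf(Fv, df1, df_res, lower.tail = FALSE))
    }
    eff <- t(vapply(1:3, one, numeric(4)))
    tabout <- data.frame(
      effect = c(between, within, paste0(between, ":", within)),
      df1 = eff[, "df1"], df2 = df_res, ss = eff[, "ss"],
      F = eff[, "F"], p = eff[, "p"], stringsAsFactors = FALSE)
    context <- list(
      cells = stats::aggregate(y ~ A + B, d, mean),
      cell_n = stats::aggregate(y ~ A + B, d, length),
      ms_error = rss_full / df_res, df_error = df_res,
      data = d)
  }
  structure(list(table = tabout, design = design, context = context,
                 between = between, within = within),
            class = "ek_anova")
}

#' @export
print.ek_anova <- function(x, ...) {
  cat(sprintf("<ek_anova> %s design\n", x$design))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tukey post hoc comparisons of cell means
#'
#' Studentized-range (Tukey-Kramer) adjusted p-values for contrasts among
#' the `between x within` cell means of a fitted [two_way_anova()], using
#' its residual error mean square and df. The family size is the number of
#' cells.
#'
#' @param fit an `ek_anova`.
#' @param pairs list of length-2 character vectors of cell labels
#'   (`"A.B"`, i.e. `<between level>.<within level>`); default: all pairs.
#' @return `ek_posthoc` data.frame with `contrast`, `estimate` (difference
#'   of cell means), `p_adj`; attribute `method = "tukey"`.
#' @export
tukey_posthoc <- function(fit, pairs = NULL) {
  if (!inherits(fit, "ek_anova")) {
    ek_stop("fit must be an ek_anova", "ek_invalid_input")
  }
  cells <- fit$context$cells
  nn <- fit$context$cell_n
  labels <- paste(cells$A, cells$B, sep = ".")
  means <- stats::setNames(cells$y, labels)
  sizes <- stats::setNames(nn$y, paste(nn$A, nn$B, sep = "."))[labels]
  k <- length(means)
  if (is.null(pairs)) {
    pairs <- utils::combn(labels, 2, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% labels)) {
      ek_stop(sprintf("unknown cell label(s): %s (known: %s)",
                      paste(setdiff(pr, labels), collapse = ","),
                      paste(labels, collapse = ",")), "ek_invalid_input")
    }
    est <- means[pr[1]] - means[pr[2]]
    se <- sqrt(fit$context$ms_error / 2 *
                 (1 / sizes[pr[1]] + 1 / sizes[pr[2]]))
    q <- abs(est) / se
    p <- stats::ptukey(q, k, fit$context$df_error, lower.tail = FALSE)
    data.frame(contrast = paste(pr, collapse = " - "),
               estimate = unname(est), p_adj = unname(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- "tukey"
  class(out) <- c("ek_posthoc", "data.frame")
  out
}

#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p_raw)^m`, clipped to [0, 1]. With `m = 1` this is the
#' identity.
#'
#' @param p_raw numeric vector of raw p-values.
#' @param m number of comparisons in the family (default `length(p_raw)`).
#' @return `ek_posthoc` data.frame with `contrast` (names of `p_raw` or
#'   indices), `p_raw`, `p_adj`; attribute `method = "sidak"`.
#' @export
sidak_posthoc <- function(p_raw, m = length(p_raw)) {
  if (m < 1) ek_stop("m must be >= 1", "ek_invalid_input")
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    ek_stop("p_raw must lie in [0, 1]", "ek_invalid_input")
  }
  p_adj <- pmin(1, pmax(0, 1 - (1 - p_raw)^m))
  out <- data.frame(
    contrast = names(p_raw) %||% as.character(seq_along(p_raw)),
    p_raw = as.numeric(p_raw), p_adj = p_adj, stringsAsFactors = FALSE)
  attr(out, "method") <- "sidak"
  class(out) <- c("ek_posthoc", "data.frame")
  out
}

KINEMATIC_STATS <- c("distance_cm", "eff_vel_cm_s", "mean_acc_cm_s2",
                     "stops", "dist_per_stop_cm")

#' Group comparison over a cohort of kinematic summaries
#'
#' Applies the group-comparison strategy of the original analyses:
#' whole-session totals by two-tailed Mann-Whitney U; minute-by-minute
#' profiles by mixed two-way ANOVA (group x minute) with Tukey first-vs-last
#' minute contrasts within group; social/non-social area splits by mixed
#' two-way ANOVA (group x area) with Sidak-adjusted cell contrasts.
#' Degenerate subjects (never moved) are excluded first and logged. No
#' multiplicity correction is applied *across* the five statistics,
#' matching the original analysis; this is noted in the report.
#'
#' @param summaries for `design = "totals"`: per-subject summary rows as
#'   from [summarize_kinematics()]; for `"minutes"`: [bin_by_minute()] rows
#'   (one per subject x minute); for `"areas"`: per-subject per-area rows
#'   as from [per_zone_kinematics()] (column `area` in
#'   `{"social","non_social"}`).
#' @param design `"totals"`, `"minutes"` or `"areas"`.
#' @param statistics which summary columns to compare.
#' @param alpha significance level (default 0.05).
#' @return `ek_comparison`: list with `results` (per-statistic table),
#'   `posthoc` (for ANOVA designs), `exclusions` (subject ids), `design`,
#'   `alpha`, and `note`.
#' @export
compare_cohort <- function(summaries, design = c("totals", "minutes", "areas"),
                           statistics = KINEMATIC_STATS, alpha = 0.05) {
  design <- match.arg(design)
  df <- as.data.frame(summaries)
  if (!"group" %in% names(df)) ek_stop("missing 'group' column", "ek_invalid_input")
  excl <- unique(df$subject_id[df$degenerate %||% FALSE])
  df <- df[!(df$subject_id %in% excl), , drop = FALSE]
  groups <- unique(df$group)
  if (length(groups) < 2L) {
    ek_stop("need at least two groups after exclusions", "ek_invalid_input")
  }
  for (g in groups) {
    if (length(unique(df$subject_id[df$group == g])) < 2L) {
      ek_stop(sprintf("group '%s' has < 2 subjects after exclusions", g),
              "ek_invalid_input")
    }
  }
  results <- NULL
  posthoc <- list()
  if (design == "totals") {
    if (length(groups) != 2L) {
      ek_stop("totals design compares exactly two groups", "ek_invalid_input")
    }
    for (st in statistics) {
      va <- df[[st]][df$group == groups[1]]
      vb <- df[[st]][df$group == groups[2]]
      keep_a <- is.finite(va); keep_b <- is.finite(vb)
      if (sum(keep_a) < 1L || sum(keep_b) < 1L) next
      mw <- mann_whitney_u(va[keep_a], vb[keep_b])
      results <- rbind(results, data.frame(
        statistic = st, U = mw$U, p = mw$p,
        significant = mw$p < alpha, n_1 = mw$n_a, n_2 = mw$n_b,
        method = paste0("mann_whitney_", mw$method),
        stringsAsFactors = FALSE))
    }
  } else {
    level_col <- if (design == "minutes") "minute" else "area"
    if (!level_col %in% names(df)) {
      ek_stop(sprintf("design '%s' needs a '%s' column", design, level_col),
              "ek_invalid_input")
    }
    for (st in statistics) {
      dat <- df[, c("subject_id", "group", level_col, st)]
      names(dat)[4] <- "value"
      if (anyNA(dat$value) || !all(is.finite(dat$value))) next
      fit <- two_way_anova(dat, response = "value", between = "group",
                           within = level_col, design = "mixed")
      tabs <- fit$table
      tabs$statistic <- st
      tabs$significant <- tabs$p < alpha
      results <- rbind(results, tabs)
      if (design == "minutes") {
        levs <- sort(unique(as.numeric(dat[[level_col]])))
        prs <- lapply(groups, function(g) {
          c(paste(g, levs[1], sep = "."),
            paste(g, levs[length(levs)], sep = "."))
        })
        posthoc[[st]] <- tukey_posthoc(fit, pairs = prs)
      } else {
        ph <- area_sidak_contrasts(fit, groups)
        posthoc[[st]] <- ph
      }
    }
  }
  structure(list(results = results, posthoc = posthoc,
                 exclusions = excl, design = design, alpha = alpha,
                 groups = groups,
                 note = "no multiplicity correction across the five kinematic statistics"),
            class = "ek_comparison")
}

# Sidak-adjusted cell contrasts for the group x area design: between-group
# contrast within each area, and social vs non-social within each group.
area_sidak_contrasts <- function(fit, groups) {
  cells <- fit$context$cells
  nn <- fit$context$cell_n
  key <- function(a, b) which(cells$A == a & cells$B == b)
  ms <- fit$context$ms_error; dfe <- fit$context$df_error
  raw <- c(); est <- c(); lab <- c()
  areas <- levels(cells$B)
  for (ar in areas) {
    i <- key(groups[1], ar); j <- key(groups[2], ar)
    e <- cells$y[i] - cells$y[j]
    se <- sqrt(ms * (1 / nn$y[key(groups[1], ar)] +
                       1 / nn$y[key(groups[2], ar)]))
    tt <- e / se
    lab <- c(lab, sprintf("%s vs %s in %s", groups[1], groups[2], ar))
    est <- c(est, e)
    raw <- c(raw, 2 * stats::pt(-abs(tt), dfe))
  }
  for (g in groups) {
    i <- key(g, areas[1]); j <- key(g, areas[2])
    e <- cells$y[i] - cells$y[j]
    se <- sqrt(ms * (1 / nn$y[i] + 1 / nn$y[j]))
    tt <- e / se
    lab <- c(lab, sprintf("%s: %s vs %s", g, areas[1], areas[2]))
    est <- c(est, e)
    raw <- c(raw, 2 * stats::pt(-abs(tt), dfe))
  }
  out <- sidak_posthoc(stats::setNames(raw, lab), m = length(raw))
  out$estimate <- est
  out
}

#' @export
print.ek_comparison <- function(x, ...) {
  cat(sprintf("<ek_comparison> design = %s, alpha = %g\n", x$design, x$alpha))
  if (length(x$exclusions)) {
    cat("excluded (degenerate):", paste(x$exclusions, collapse = ", "), "\n")
  }
  print(x$results, row.names = FALSE, digits = 4)
  invisible(x)
}
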