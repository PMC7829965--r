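default_arena_for <- function(test, config = list()) {
  social_side <- config$social_side %||% "left"
  switch(test,
         OFT = make_open_field(),
         `3C_habituation` = make_three_chamber(social_side = social_side),
         `3C_social` = make_three_chamber(social_side = social_side),
         EPM = make_epm(),
         ek_stop(sprintf("unknown test type '%s'", test), "ek_invalid_config"))
}

#' Read a cohort manifest CSV
#'
#' Columns: `subject_id`, `group`, `test` (one of OFT, 3C_habituation,
#' 3C_social, EPM), `path` (trajectory CSV). (subject_id, test) pairs must
#' be unique.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "test", "path")
  if (!all(need %in% names(df))) {
    ek_stop(sprintf("manifest needs columns %s", paste(need, collapse = ",")),
            "ek_invalid_input")
  }
  if (anyDuplicated(df[, c("subject_id", "test")])) {
    ek_stop("(subject_id, test) pairs must be unique", "ek_invalid_input")
  }
  df
}

#' Run the full analysis pipeline over a cohort
#'
#' For every manifest row the trajectory is loaded and summarized
#' (whole-session five statistics, minute-by-minute profile, zone
#' occupancy; for the three-chamber social stage additionally social
#' preference and the social/non-social kinematic ratios). Per test, group
#' statistics are computed: totals by Mann-Whitney, minute profiles by
#' mixed ANOVA + Tukey. Degenerate subjects are excluded from group
#' statistics and logged; unreadable inputs are recorded as failures and
#' the run continues. Output is deterministic given inputs and config.
#'
#' @param manifest data.frame (see [read_manifest()]) or a CSV path.
#' @param config list (or YAML path): `epsilon_cm` (default 0.3), `bin_s`
#'   (60), `alpha` (0.05), `social_side` ("left").
#' @param out_dir optional; when given, writes `summaries.csv`,
#'   `minutes.csv`, `zones.csv`, `ratios.csv`, `stats.csv` and
#'   `provenance.json` there.
#' @return `ek_run_report`: list with `summaries`, `minutes`, `zones`,
#'   `ratios`, `stats`, `exclusions`, `failures`, `config`.
#' @export
run_pipeline <- function(manifest, config = list(), out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(
    list(epsilon_cm = 0.3, bin_s = 60, alpha = 0.05, social_side = "left"),
    config)
  summaries <- NULL; minutes <- NULL; zones <- NULL; ratios <- NULL
  failures <- NULL
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      if (!file.exists(row$path)) {
        ek_stop(sprintf("input not found: %s", row$path), "ek_invalid_input")
      }
      traj <- read_trajectory(row$path)
      attr(traj, "subject_id") <- row$subject_id
      attr(traj, "group_label") <- row$group
      attr(traj, "test_stage") <- row$test
      arena <- default_arena_for(row$test, config)
      sm <- summarize_kinematics(traj, config$epsilon_cm)
      sm <- cbind(test = row$test, sm)
      mn <- bin_by_minute(traj, config$epsilon_cm, config$bin_s)
      mn <- cbind(test = row$test, mn)
      occ <- zone_occupancy(traj, arena)
      zn <- cbind(test = row$test, subject_id = row$subject_id,
                  group = row$group, occ$roles)
      rt <- NULL
      if (row$test == "3C_social") {
        srr <- social_ratio_report(traj, arena, config$epsilon_cm)
        rt <- cbind(test = row$test, subject_id = row$subject_id,
                    group = row$group, as.data.frame(srr))
        rt$social_preference_pct <- social_preference(traj, arena)
        rt$degenerate <- sm$degenerate
      }
      list(sm = sm, mn = mn, zn = zn, rt = rt)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures, data.frame(
        subject_id = row$subject_id, test = row$test,
        message = conditionMessage(res), stringsAsFactors = FALSE))
      next
    }
    summaries <- rbind(summaries, res$sm)
    minutes <- rbind(minutes, res$mn)
    zones <- rbind(zones, res$zn)
    if (!is.null(res$rt)) ratios <- rbind(ratios, res$rt)
  }
  # group statistics per test
  stats_tab <- NULL
  exclusions <- unique(summaries$subject_id[summaries$degenerate])
  for (tt in unique(summaries$test)) {
    st <- summaries[summaries$test == tt, ]
    grps <- table(st$group[!st$degenerate])
    if (length(grps) < 2L || any(grps < 2L)) next
    cmp <- compare_cohort(st, design = "totals", alpha = config$alpha)
    stats_tab <- rbind(stats_tab,
                       cbind(test = tt, design = "totals", cmp$results))
    mt <- minutes[minutes$test == tt & !(minutes$subject_id %in% exclusions), ]
    n_min <- length(unique(mt$minute))
    complete <- all(table(mt$subject_id) == n_min)
    if (n_min >= 2L && complete) {
      cm <- compare_cohort(mt, design = "minutes", alpha = config$alpha)
      res <- cm$results
      stats_tab <- rbind(stats_tab, data.frame(
        test = tt, design = "minutes", statistic = res$statistic,
        U = NA_real_, p = res$p, significant = res$significant,
        n_1 = res$df1, n_2 = res$df2,
        method = paste0("mixed_anova_", res$effect),
        stringsAsFactors = FALSE))
    }
  }
  report <- structure(
    list(summaries = summaries, minutes = minutes, zones = zones,
         ratios = ratios, stats = stats_tab, exclusions = exclusions,
         failures = failures, config = config,
         version = as.character(utils::packageVersion("ethokinetics"))),
    class = "ek_run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      if (!is.null(df)) utils::write.csv(df, file.path(out_dir, name),
                                         row.names = FALSE)
    }
    wr(summaries, "summaries.csv"); wr(minutes, "minutes.csv")
    wr(zones, "zones.csv"); wr(ratios, "ratios.csv")
    wr(stats_tab, "stats.csv")
    jsonlite::write_json(
      list(config = config, version = report$version,
           exclusions = exclusions,
           failures = if (is.null(failures)) list() else failures),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.ek_run_report <- function(x, ...) {
  cat(sprintf("<ek_run_report> %d subjects, %d excluded, %d failures\n",
              length(unique(x$summaries$subject_id)),
              length(x$exclusions),
              if (is.null(x$failures)) 0L else nrow(x$failures)))
  invisible(x)
}

#' Habituation profile: per-group minute curves and first-vs-last contrasts
#'
#' From minute-binned summaries (as in `report$minutes` or rbind-ed
#' [bin_by_minute()] rows with `group` and `subject_id` columns), computes
#' per-statistic group means and SEM per minute and the Tukey contrast
#' first minute vs last minute within each group (from the mixed
#' group x minute ANOVA).
#'
#' @param minutes data.frame of per-subject per-minute summary rows.
#' @param statistics summary columns to profile.
#' @param alpha significance level.
#' @return list with `curves` (group, minute, statistic, mean, sem, n) and
#'   `contrasts` (statistic, contrast, estimate, p_adj, significant).
#' @export
habituation_profile <- function(minutes, statistics = KINEMATIC_STATS,
                                alpha = 0.05) {
  mt <- as.data.frame(minutes)
  if (length(unique(mt$minute)) < 2L) {
    ek_stop("need at least 2 minute bins", "ek_invalid_input")
  }
  excl <- unique(mt$subject_id[mt$degenerate %||% FALSE])
  mt <- mt[!(mt$subject_id %in% excl), ]
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  curves <- NULL; contrasts <- NULL
  groups <- unique(mt$group)
  levs <- sort(unique(as.numeric(mt$minute)))
  for (st in statistics) {
    dat <- mt[, c("subject_id", "group", "minute", st)]
    names(dat)[4] <- "value"
    if (anyNA(dat$value) || !all(is.finite(dat$value))) next
    agg_m <- stats::aggregate(value ~ group + minute, dat, mean)
    agg_s <- stats::aggregate(value ~ group + minute, dat, sem)
    agg_n <- stats::aggregate(value ~ group + minute, dat, length)
    curves <- rbind(curves, data.frame(
      statistic = st, group = agg_m$group, minute = agg_m$minute,
      mean = agg_m$value, sem = agg_s$value, n = agg_n$value,
      stringsAsFactors = FALSE))
    # first-vs-last contrasts need the group x minute ANOVA context
    if (length(groups) < 2L) next
    fit <- two_way_anova(dat, response = "value", between = "group",
                         within = "minute", design = "mixed")
    prs <- lapply(groups, function(g) {
      c(paste(g, levs[1], sep = "."), paste(g, levs[length(levs)], sep = "."))
    })
    ph <- tukey_posthoc(fit, pairs = prs)
    contrasts <- rbind(contrasts, data.frame(
      statistic = st, contrast = ph$contrast, estimate = ph$estimate,
      p_adj = ph$p_adj, significant = ph$p_adj < alpha,
      stringsAsFactors = FALSE))
  }
  list(curves = curves, contrasts = contrasts)
}

#' Read an arena config YAML
#'
#' Either a preset (`preset: open_field|three_chamber|epm` plus the
#' constructor's arguments) or an explicit spec (`name`, `bounds_cm`,
#' `zones:` list of maps with zone_id, x0, y0, x1, y1, role).
#'
#' @param path YAML file.
#' @return `ek_arena`.
#' @export
read_arena_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset)) {
    fn <- switch(cfg$preset,
                 open_field = make_open_field,
                 three_chamber = make_three_chamber,
                 epm = make_epm,
                 ek_stop(sprintf("unknown preset '%s'", cfg$preset),
                         "ek_invalid_config"))
    return(do.call(fn, cfg[setdiff(names(cfg), "preset")]))
  }
  zones <- do.call(rbind, lapply(cfg$zones, as.data.frame))
  arena_spec(cfg$name, unlist(cfg$bounds_cm), zones)
}
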