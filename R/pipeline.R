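#' Analyze a trajectory table
#'
#' Full per-cell analysis of a tracks table: spindle frames from the two
#' pole trajectories, per-pair kinematics, the per-pair event table
#' (polar/aligned classification, plate crossing, congression velocity,
#' 30-min success), the per-cell summary (alignment success percentage,
#' misalignment category and maximum chromosome spread at the last frame)
#' and the polar-count timeline. Cells that fail a precondition (e.g. a
#' degenerate spindle) are skipped with a logged reason, never silently
#' dropped.
#'
#' @param tracks Tracks tibble (schema of [read_tracks_csv()]); an
#'   optional `condition` column is carried through.
#' @param thresholds A [congression_thresholds()].
#' @param max_gap,eps_pole Gap-filling and spindle-degeneracy policy, see
#'   [spindle_frames()].
#' @param t_ref Reference time (minutes) for initial polar status and the
#'   success window; a single value or a named vector per cell.
#' @param mode `"2d"` drops the z column (projections); `"3d"` keeps it.
#' @return List of tibbles: `kinematics`, `events`, `cells`, `timeline`,
#'   `skipped`.
#' @export
analyze_tracks <- function(tracks, thresholds = congression_thresholds(),
                           max_gap = 2, eps_pole = 1, t_ref = 0,
                           mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  if (nrow(tracks) == 0) stop("no cells in the input", call. = FALSE)
  tracks <- as.data.frame(tracks)   # fast base subsetting in the loops
  if (is.null(tracks$z_um)) tracks$z_um <- 0
  if (mode == "2d") tracks$z_um <- 0
  has_cond <- "condition" %in% names(tracks)
  kin_out <- list(); ev_out <- list(); cell_out <- list(); tl_out <- list()
  skipped <- list()
  for (cell in unique(tracks$cell_id)) {
    tc <- tracks[tracks$cell_id == cell, ]
    cond <- if (has_cond) tc$condition[1] else NA_character_
    tref_cell <- if (length(t_ref) > 1) t_ref[[cell]] else t_ref
    res <- tryCatch({
      poles <- tc[tc$object_type == "pole", ]
      pa <- poles[poles$object_id == sort(unique(poles$object_id))[1], ]
      pb <- poles[poles$object_id == sort(unique(poles$object_id))[2], ]
      if (nrow(pa) == 0 || nrow(pb) == 0)
        stop("cell has fewer than two pole tracks")
      frames <- spindle_frames(pa, pb, eps_pole = eps_pole, max_gap = max_gap)
      kts <- tc[tc$object_type == "kinetochore", ]
      pair_ids <- unique(kts$pair_id)
      kin_list <- list()
      for (pid in pair_ids) {
        s1 <- kts[kts$pair_id == pid & kts$sister == 1, ]
        s2 <- kts[kts$pair_id == pid & kts$sister == 2, ]
        kin <- pair_kinematics(s1, s2, frames, max_gap = max_gap)
        kin_list[[pid]] <- kin
      }
      ev <- pair_event_table(kin_list, pair_ids, thresholds, tref_cell)
      ev$cell_id <- cell; ev$condition <- cond
      pct <- if (any(ev$polar_initial))
        100 * mean(ev$success_30min[ev$polar_initial]) else NA_real_
      last_frame <- max(vapply(kin_list, function(k) max(k$frame), numeric(1)))
      at_last <- lapply(kin_list, function(k) k[k$frame == last_frame, ])
      d_last <- vapply(at_last, function(r) if (nrow(r)) r$d_plane else
        NA_real_, numeric(1))
      centers <- do.call(rbind, lapply(at_last, function(r)
        if (nrow(r)) c(r$cx, r$cy, r$cz) else NULL))
      spread <- if (!is.null(centers) && nrow(centers) >= 2)
        max_chromosome_spread(centers) else NA_real_
      tl <- polar_counts_timeline(kin_list, thresholds,
                                  t_end = max(frames$t_min, na.rm = TRUE))
      tl$cell_id <- cell; tl$condition <- cond
      kin_long <- do.call(rbind, lapply(pair_ids, function(pid) {
        k <- kin_list[[pid]]; k$cell_id <- cell; k$pair_id <- pid; k
      }))
      list(kin = kin_long, ev = ev,
           cell = tibble::tibble(
             cell_id = cell, condition = cond,
             n_pairs = length(pair_ids),
             n_polar_initial = sum(ev$polar_initial),
             pct_aligned_30min = pct,
             misalignment_category = misalignment_category(d_last, thresholds),
             max_spread_um = spread),
           tl = tl)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("skipping cell ", cell, ": ", conditionMessage(res))
      skipped[[cell]] <- tibble::tibble(cell_id = cell,
                                        reason = conditionMessage(res))
    } else {
      kin_out[[cell]] <- res$kin; ev_out[[cell]] <- res$ev
      cell_out[[cell]] <- res$cell; tl_out[[cell]] <- res$tl
    }
  }
  if (length(cell_out) == 0) stop("no cells could be analyzed", call. = FALSE)
  list(kinematics = do.call(rbind, kin_out),
       events = do.call(rbind, ev_out),
       cells = do.call(rbind, cell_out),
       timeline = do.call(rbind, tl_out),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         tibble::tibble(cell_id = character(), reason = character()))
}

#' Run the analysis on a tracks CSV and write result tables
#'
#' Thin orchestration around [analyze_tracks()]: reads the tracks CSV,
#' writes `kinematics.csv`, `events.csv`, `cells.csv`, `timeline.csv` and
#' a `manifest.json` recording the configuration hash, seed and package
#' version, so every output is traceable.
#'
#' @param tracks_csv Input path.
#' @param out_dir Output directory (created if missing).
#' @param thresholds,max_gap,eps_pole,t_ref,mode Passed to
#'   [analyze_tracks()].
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return The [analyze_tracks()] result, invisibly.
#' @export
run_analyze <- function(tracks_csv, out_dir,
                        thresholds = congression_thresholds(),
                        max_gap = 2, eps_pole = 1, t_ref = 0, mode = "2d",
                        seed = NA_integer_) {
  tracks <- read_tracks_csv(tracks_csv)
  res <- analyze_tracks(tracks, thresholds, max_gap, eps_pole, t_ref, mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(res$kinematics, file.path(out_dir, "kinematics.csv"))
  readr::write_csv(res$events, file.path(out_dir, "events.csv"))
  readr::write_csv(res$cells, file.path(out_dir, "cells.csv"))
  readr::write_csv(res$timeline, file.path(out_dir, "timeline.csv"))
  cfg <- list(thresholds = unclass(thresholds), max_gap = max_gap,
              eps_pole = eps_pole, t_ref = t_ref, mode = mode)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(config = cfg, config_md5 = unname(tools::md5sum(tf)),
                   seed = seed,
                   package_version =
                     as.character(utils::packageVersion("congressr")),
                   n_cells = nrow(res$cells),
                   n_skipped = nrow(res$skipped))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Statistical report over analysis outputs
#'
#' Applies the study's statistical plan to the event and cell tables:
#' congression velocities compared across conditions by one-way ANOVA with
#' Tukey HSD, 30-min alignment success compared by pairwise two-proportion
#' z-tests with a chi-square test of overall independence, and (when an
#' intensity-loss table is supplied) an OLS regression of mean congression
#' speed on checkpoint-signal loss.
#'
#' @param events Event table from [analyze_tracks()] (needs `condition`).
#' @param loss_speed Optional tibble with columns `speed` and `loss` for
#'   the regression.
#' @return Tibble: `test`, `comparison`, `statistic`, `df`, `p`, `p_adj`,
#'   `stars`.
#' @export
run_stats <- function(events, loss_speed = NULL) {
  if (!"condition" %in% names(events) || all(is.na(events$condition)))
    stop("events table has no condition labels", call. = FALSE)
  conds <- unique(events$condition)
  if (length(conds) < 2)
    stop("need at least two conditions; found: ",
         paste(conds, collapse = ", "), call. = FALSE)
  rows <- list()
  add <- function(test, comparison, statistic, df, p, p_adj = NA_real_) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      test = test, comparison = comparison, statistic = statistic,
      df = df, p = p, p_adj = p_adj,
      stars = significance_stars(if (is.na(p_adj)) p else p_adj))
  }
  # velocities: ANOVA + Tukey across conditions
  vsel <- !is.na(events$v_congress_um_per_min)
  if (sum(vsel) > 0 &&
      length(unique(events$condition[vsel])) >= 2 &&
      all(table(events$condition[vsel]) >= 2)) {
    at <- anova_tukey(events$v_congress_um_per_min[vsel],
                      events$condition[vsel])
    add("anova_velocity", "all", at$F, at$df[["between"]], at$p)
    for (i in seq_len(nrow(at$pairwise)))
      add("tukey_velocity", at$pairwise$comparison[i], at$pairwise$diff[i],
          NA_real_, NA_real_, at$pairwise$p_adj[i])
  }
  # success fractions: pairwise z + overall chi-square
  pol <- events[events$polar_initial, ]
  ks <- tapply(pol$success_30min, pol$condition, sum)
  ns <- tapply(pol$success_30min, pol$condition, length)
  cc <- names(ks)[!is.na(ks)]
  if (length(cc) >= 2) {
    tab <- rbind(ks[cc], ns[cc] - ks[cc])
    ok <- tryCatch({
      cs <- chi_square_independence(tab)
      add("chisq_success", "all", cs$chisq, cs$df, cs$p)
      TRUE
    }, error = function(e) FALSE)
    for (i in seq_along(cc)) for (j in seq_along(cc)) if (i < j) {
      zt <- tryCatch(two_proportion_z(ks[cc[i]], ns[cc[i]],
                                      ks[cc[j]], ns[cc[j]]),
                     error = function(e) NULL)
      if (!is.null(zt))
        add("two_proportion_z_success", paste(cc[i], "vs", cc[j]),
            zt$z, NA_real_, zt$p)
    }
  }
  # signal loss vs speed regression
  if (!is.null(loss_speed)) {
    fit <- ols_fit(loss_speed$loss, loss_speed$speed)
    add("ols_speed_vs_loss", "slope", fit$slope, fit$n - 2, fit$p_slope)
  }
  do.call(rbind, rows)
}

#' Write the small packaged demonstration dataset
#'
#' Simulates a compact two-condition experiment (3 cells per condition, 4
#' pairs per cell, 40 min at 1-min frames) and writes the tracks, ground
#' truth and intensity tables to a directory. Used by examples and as a
#' quick smoke fixture.
#'
#' @param dir Output directory.
#' @param seed Master seed.
#' @return `dir`, invisibly.
#' @export
write_fixture_dataset <- function(dir, seed = 1L) {
  cfg <- simulation_config(n_cells = 3, pairs_per_cell = 4, duration = 40,
                           master_seed = seed)
  sim <- simulate_experiment(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tracks_csv(sim$tracks, file.path(dir, "tracks.csv"))
  truth <- sim$truth
  truth$t_init_min[!is.finite(truth$t_init_min)] <- NA_real_
  readr::write_csv(truth, file.path(dir, "truth.csv"))
  readr::write_csv(sim$mad2, file.path(dir, "mad2.csv"))
  invisible(dir)
}
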