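#' Configuration of an end-to-end scoring run
#'
#' Bundles everything a run needs: where the sections come from, the
#' metric settings, the outlier policy, statistics parameters and the
#' output directory.  The seed is always recorded so a run can be
#' reproduced byte for byte.
#'
#' @param input either a directory containing a `manifest.csv` (as
#'   written by [write_sections()]), a manifest CSV path, or a character
#'   vector of PLY/STL paths whose file names follow
#'   `<egg>_<zone>_<id>.ply`; may be `NULL` when sections are passed
#'   in memory.
#' @param output_dir directory for CSV and report output.
#' @param pre_aligned skip the alignment step for data standardized
#'   externally.
#' @param target_faces decimation target (default 5000; meshes already
#'   at or below the target pass through).
#' @param settings a [metric_settings()].
#' @param outlier an [outlier_policy()].
#' @param alpha significance threshold for the pairwise comparisons.
#' @param bootstrap_iterations iterations for [bootstrap_mean_diff()].
#' @param seed integer seed for every stochastic step of the run.
#' @param group_col grouping column for taxon-level comparisons
#'   (default `"specimen_id"`).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = NULL, output_dir = tempfile("eggscore_run_"),
                       pre_aligned = FALSE, target_faces = 5000,
                       settings = metric_settings(),
                       outlier = outlier_policy(), alpha = 0.05,
                       bootstrap_iterations = 1000, seed = 1L,
                       group_col = "specimen_id") {
  structure(list(input = input, output_dir = output_dir,
                 pre_aligned = isTRUE(pre_aligned),
                 target_faces = as.integer(target_faces),
                 settings = settings, outlier = outlier, alpha = alpha,
                 bootstrap_iterations = as.integer(bootstrap_iterations),
                 seed = as.integer(seed), group_col = group_col),
            class = "run_config")
}

# resolve config$input into a list of surface_section objects
.load_sections <- function(config) {
  input <- config$input
  if (is.list(input) && all(vapply(input, inherits, TRUE, "surface_section")))
    return(list(sections = input, failures = character()))
  paths <- NULL
  meta <- NULL
  if (length(input) == 1L && dir.exists(input))
    input <- file.path(input, "manifest.csv")
  if (length(input) == 1L && grepl("\\.csv$", input)) {
    if (!file.exists(input)) stop("manifest not found: ", input, call. = FALSE)
    meta <- read.csv(input, stringsAsFactors = FALSE)
    need <- c("path", "specimen_id", "egg_id", "zone", "section_id")
    if (!all(need %in% names(meta)))
      stop("manifest lacks columns: ",
           paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
    if (is.null(meta$long_axis_azimuth)) meta$long_axis_azimuth <- 90
    if (is.null(meta$section_diameter)) meta$section_diameter <- 10
    paths <- ifelse(file.exists(meta$path), meta$path,
                    file.path(dirname(input), meta$path))
  } else {
    paths <- as.character(input)
    # filename pattern <egg>_<zone>_<id>.ext
    base <- sub("\\.[^.]+$", "", basename(paths))
    parts <- strsplit(base, "_")
    bad <- vapply(parts, length, 0L) < 3L
    if (any(bad))
      stop("file name(s) not matching <egg>_<zone>_<id>: ",
           paste(basename(paths)[bad], collapse = ", "), call. = FALSE)
    meta <- data.frame(
      path = paths,
      specimen_id = vapply(parts, `[[`, "", 1L),
      egg_id = vapply(parts, `[[`, "", 1L),
      zone = suppressWarnings(as.integer(gsub("\\D", "",
                                              vapply(parts, `[[`, "", 2L)))),
      section_id = base,
      long_axis_azimuth = 90, section_diameter = 10,
      stringsAsFactors = FALSE)
  }
  sections <- list()
  failures <- character()
  for (i in seq_along(paths)) {
    s <- tryCatch({
      mesh <- read_mesh(paths[i])
      surface_section(mesh, specimen_id = meta$specimen_id[i],
                      egg_id = meta$egg_id[i], zone = meta$zone[i],
                      long_axis_azimuth = meta$long_axis_azimuth[i],
                      section_diameter = meta$section_diameter[i],
                      section_id = meta$section_id[i])
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("%s: %s", paths[i], conditionMessage(e)))
      NULL
    })
    if (!is.null(s)) sections[[length(sections) + 1L]] <- s
  }
  list(sections = sections, failures = failures)
}

#' Run the scoring stage of the pipeline
#'
#' Ingests sections (from disk or in memory), standardizes each one --
#' alignment to the X-Y plane (unless `pre_aligned`) followed by
#' decimation to `target_faces` -- and computes the three metrics.
#' Per-section failures are logged and the batch continues.  Records are
#' sorted by specimen, egg, zone and section and written as the SCORE
#' CSV together with a run log.
#'
#' @param config a [run_config()]; its `input` may also be a list of
#'   [surface_section()] objects.
#' @return list with `records` (the score data frame), `csv` (path) and
#'   `failures` (character vector of per-section error messages).
#' @export
run_score <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  loaded <- .load_sections(config)
  failures <- loaded$failures
  records <- list()
  for (s in loaded$sections) {
    rec <- tryCatch({
      mesh <- s$mesh
      if (!config$pre_aligned) mesh <- align_to_xy(mesh)
      if (n_faces(mesh) > config$target_faces)
        mesh <- decimate(mesh, config$target_faces)
      s$mesh <- mesh
      score(s, config$settings)
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("%s: %s", s$section_id, conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  if (length(records) == 0L)
    stop("no section could be scored", call. = FALSE)
  records <- do.call(rbind, records)
  ord <- order(records$specimen_id, records$egg_id, records$zone,
               records$section_id, method = "radix")
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  csv <- file.path(config$output_dir, "score.csv")
  write_score_csv(records, csv, config$settings)
  log <- file.path(config$output_dir, "run_score.log")
  con <- file(log, "wb")
  writeLines(c(sprintf("sections scored: %d", nrow(records)),
               sprintf("sections failed: %d", length(failures)),
               failures), con)
  close(con)
  list(records = records, csv = csv, failures = failures)
}

#' Aggregate score records per egg and per zone
#'
#' Applies [iqr_filter()] per egg and per metric, then reports per-egg
#' means and per-zone means and value ranges (zones pooled across the
#' eggs of a specimen, sections equally weighted by default).  Ranges
#' are computed on the retained sections only.
#'
#' @param records score data frame (as from [run_score()]).
#' @param policy an [outlier_policy()].
#' @param egg_weighted if `TRUE`, per-zone means average the per-egg zone
#'   means instead of pooling sections.
#' @return an object of class `aggregate_table`: list of data frames
#'   `per_egg` (egg means plus retained/removed counts per metric) and
#'   `per_zone` (specimen x zone means and ranges).
#' @export
aggregate_scores <- function(records, policy = outlier_policy(),
                             egg_weighted = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  metrics <- c("complexity", "relief", "orientation")

  filt <- records
  for (met in metrics) filt[[paste0(met, "_keep")]] <- TRUE
  for (egg in unique(records$egg_id)) {
    sel <- which(records$egg_id == egg)
    for (met in metrics) {
      v <- records[[met]][sel]
      ok <- !is.na(v)
      if (sum(ok) >= 4L) {
        fr <- iqr_filter(v[ok], policy)
        keep <- ok
        keep[ok] <- v[ok] >= fr$bounds["lower"] & v[ok] <= fr$bounds["upper"]
      } else keep <- ok
      filt[[paste0(met, "_keep")]][sel] <- keep
    }
  }

  per_egg <- do.call(rbind, lapply(split(filt, filt$egg_id), function(d) {
    out <- data.frame(specimen_id = d$specimen_id[1L], egg_id = d$egg_id[1L],
                      n_sections = nrow(d), stringsAsFactors = FALSE)
    for (met in metrics) {
      keep <- d[[paste0(met, "_keep")]]
      out[[paste0(met, "_mean")]] <- mean(d[[met]][keep])
      out[[paste0(met, "_removed")]] <- sum(!keep)
    }
    out
  }))
  rownames(per_egg) <- NULL

  zone_stat <- function(d) {
    out <- data.frame(specimen_id = d$specimen_id[1L], zone = d$zone[1L],
                      stringsAsFactors = FALSE)
    for (met in metrics) {
      keep <- d[[paste0(met, "_keep")]]
      v <- d[[met]][keep]
      if (egg_weighted) {
        mns <- tapply(v, d$egg_id[keep], mean)
        out[[paste0(met, "_mean")]] <- mean(mns)
      } else {
        out[[paste0(met, "_mean")]] <- mean(v)
      }
      out[[paste0(met, "_min")]] <- if (length(v)) min(v) else NA_real_
      out[[paste0(met, "_max")]] <- if (length(v)) max(v) else NA_real_
    }
    out
  }
  per_zone <- do.call(rbind, lapply(
    split(filt, list(filt$specimen_id, filt$zone), drop = TRUE), zone_stat))
  per_zone <- per_zone[order(per_zone$specimen_id, per_zone$zone), ]
  rownames(per_zone) <- NULL

  structure(list(per_egg = per_egg, per_zone = per_zone,
                 policy = policy, records = filt),
            class = "aggregate_table")
}

#' Run the comparison stage of the pipeline
#'
#' Group-level exact KS tests per metric between specimens (taxa),
#' per-egg pairwise matrices with harmonic-mean combination, and
#' bootstrap confidence intervals of the between-group mean differences.
#' Writes the long-format and square-matrix CSVs and a text summary
#' reporting the fractions of significant pairs within and between
#' groups.
#'
#' @param records score data frame.
#' @param config a [run_config()].
#' @return list with `group_ks` (data frame of per-metric group tests,
#'   `NULL` for a single group), `pairwise` (a [pairwise_compare()]
#'   result), `bootstrap` (named list of [bootstrap_mean_diff()] results,
#'   `NULL` unless there are exactly 2 groups), `summary_path` and the
#'   written CSV paths.
#' @export
run_compare <- function(records, config = run_config()) {
  stopifnot(is.data.frame(records))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- c("complexity", "relief", "orientation")
  groups <- unique(records[[config$group_col]])

  group_ks <- NULL
  boot <- NULL
  if (length(groups) < 2L) {
    message("single group: group-level comparison skipped")
  } else {
    combos <- utils::combn(as.character(groups), 2L, simplify = FALSE)
    group_ks <- do.call(rbind, lapply(combos, function(gp) {
      do.call(rbind, lapply(metrics, function(met) {
        va <- records[[met]][records[[config$group_col]] == gp[1L]]
        vb <- records[[met]][records[[config$group_col]] == gp[2L]]
        kt <- ks_exact(va[!is.na(va)], vb[!is.na(vb)])
        data.frame(group_a = gp[1L], group_b = gp[2L], metric = met,
                   D = kt$statistic, p_value = kt$p_value, exact = kt$exact,
                   stringsAsFactors = FALSE)
      }))
    }))
    if (length(groups) == 2L) {
      boot <- lapply(metrics, function(met) {
        va <- records[[met]][records[[config$group_col]] == groups[1L]]
        vb <- records[[met]][records[[config$group_col]] == groups[2L]]
        bootstrap_mean_diff(va[!is.na(va)], vb[!is.na(vb)],
                            iterations = config$bootstrap_iterations,
                            seed = config$seed)
      })
      names(boot) <- metrics
    }
  }

  pm <- pairwise_compare(records, alpha = config$alpha, metrics = metrics)
  paths <- write_pairwise_csv(pm, config$output_dir)
  if (!is.null(group_ks))
    paths <- c(paths, {
      p <- file.path(config$output_dir, "group_ks.csv")
      .write_csv_bytes(group_ks, p)
      p
    })

  # which egg belongs to which group, for the within/cross breakdown
  egg_group <- tapply(records[[config$group_col]], records$egg_id,
                      function(g) as.character(g[1L]))
  comb <- pm$pairs[pm$pairs$metric == "combined", ]
  same <- egg_group[comb$egg_a] == egg_group[comb$egg_b]
  lines <- c(
    sprintf("eggs compared: %d (%d pairs)", length(pm$labels), nrow(comb)),
    sprintf("alpha: %g", pm$alpha),
    sprintf("significant pairs overall: %.1f%%",
            100 * mean(comb$p_value < pm$alpha, na.rm = TRUE)))
  if (any(same))
    lines <- c(lines, sprintf("significant within-group pairs: %.1f%% of %d",
                              100 * mean(comb$p_value[same] < pm$alpha,
                                         na.rm = TRUE), sum(same)))
  if (any(!same))
    lines <- c(lines, sprintf("significant cross-group pairs: %.1f%% of %d",
                              100 * mean(comb$p_value[!same] < pm$alpha,
                                         na.rm = TRUE), sum(!same)))
  if (!is.null(group_ks)) {
    lines <- c(lines, "", "group-level KS tests:",
               sprintf("  %s vs %s [%s]: D = %.4f, p = %.3g",
                       group_ks$group_a, group_ks$group_b, group_ks$metric,
                       group_ks$D, group_ks$p_value))
    hm <- vapply(split(group_ks, paste(group_ks$group_a, "vs",
                                       group_ks$group_b)),
                 function(d) harmonic_mean_p(d$p_value), 0)
    lines <- c(lines, "group-level harmonic mean p-values:",
               sprintf("  %s: %.3g", names(hm), hm))
  }
  if (!is.null(boot)) {
    lines <- c(lines, "", "bootstrap 95% CI of group mean differences:",
               vapply(metrics, function(met) {
                 b <- boot[[met]]
                 sprintf("  %s: %.4f [%.4f, %.4f]", met, b$estimate,
                         b$lower, b$upper)
               }, ""))
  }
  summary_path <- file.path(config$output_dir, "compare_summary.txt")
  con <- file(summary_path, "wb")
  writeLines(lines, con)
  close(con)

  list(group_ks = group_ks, pairwise = pm, bootstrap = boot,
       summary_path = summary_path, paths = paths)
}

#' Run the whole pipeline end to end
#'
#' Scoring ([run_score()]), aggregation ([aggregate_scores()]) and
#' comparison ([run_compare()]) in sequence, with every output written
#' under `config$output_dir`.  Identical configuration and seed produce
#' byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return list with `score`, `aggregate` and `compare` results.
#' @export
run_all <- function(config) {
  sc <- run_score(config)
  agg <- aggregate_scores(sc$records, config$outlier)
  .write_csv_bytes(agg$per_egg, file.path(config$output_dir, "per_egg.csv"))
  .write_csv_bytes(agg$per_zone, file.path(config$output_dir, "per_zone.csv"))
  cmp <- run_compare(sc$records, config)
  list(score = sc, aggregate = agg, compare = cmp)
}
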