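# Pipeline driver: simulate -> (reconstruct) -> segment -> analyze -> stats
# under one seed, with a machine-readable manifest and output validation.

#' Pipeline run configuration
#'
#' @param groups named list; each element a list with `kinematics` (a
#'   [vessel_kinematics()] object, a preset name, or a list of
#'   [vessel_kinematics()] arguments) and `n_recordings`.
#' @param seed master integer seed. Recording seeds are derived as
#'   `seed + 1000 * group_index + recording_index`.
#' @param out_dir output directory.
#' @param path `"image"` renders M-mode images directly (default);
#'   `"spectral"` synthesizes raw interferograms and reconstructs them
#'   (slower, same downstream contract).
#' @param speckle apply speckle noise on the image path.
#' @param write_images also write each recording's M-mode TIFF stack
#'   (`FALSE` by default: stacks are large and traces/reports carry the
#'   analysis).
#' @param cohort optional [cohort_config()] for the survival/climbing
#'   stage; by default a cohort is derived from the groups' kinematics
#'   (first group used as reference).
#' @param system an [ocm_system()].
#' @param geometry a [vessel_geometry()].
#' @param stages character subset of
#'   `c("simulate", "segment", "analyze", "stats")` to run; earlier stages
#'   are always implied by later ones.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(groups, seed = 1L, out_dir = tempfile("flycardia_"),
                            path = c("image", "spectral"), speckle = TRUE,
                            write_images = FALSE, cohort = NULL,
                            system = ocm_system(),
                            geometry = vessel_geometry(),
                            stages = c("simulate", "segment", "analyze",
                                       "stats")) {
  path <- match.arg(path)
  stopifnot(is.list(groups), length(groups) >= 1L,
            !is.null(names(groups)), all(nzchar(names(groups))))
  stages <- match.arg(stages, several.ok = TRUE)
  groups <- lapply(groups, function(g) {
    k <- g$kinematics
    if (is.character(k)) k <- kinematics_preset(k)
    else if (is.list(k) && !inherits(k, "vessel_kinematics"))
      k <- do.call(vessel_kinematics, k)
    stopifnot(inherits(k, "vessel_kinematics"), is_count(g$n_recordings))
    list(kinematics = k, n_recordings = as.integer(g$n_recordings))
  })
  structure(list(groups = groups, seed = as.integer(seed), out_dir = out_dir,
                 path = path, speckle = speckle,
                 write_images = write_images, cohort = cohort,
                 system = system, geometry = geometry, stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: top-level `seed`, `out_dir`,
#' `path`, `speckle`, `write_images`, and a `groups` map whose entries have
#' `n_recordings` and either `preset` or a `kinematics` parameter map.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$groups)) stopf("config must define groups")
  groups <- lapply(y$groups, function(g) {
    kin <- if (!is.null(g$preset)) {
      do.call(kinematics_preset,
              c(list(name = g$preset), g$kinematics))
    } else do.call(vessel_kinematics, g$kinematics)
    list(kinematics = kin, n_recordings = g$n_recordings)
  })
  args <- y[intersect(names(y), c("seed", "out_dir", "path", "speckle",
                                  "write_images"))]
  do.call(pipeline_config, c(list(groups = groups), args))
}

#' Run the full phenotyping pipeline
#'
#' For every recording of every group: simulate the recording (image-level
#' rendering, or spectral synthesis + reconstruction), segment the lumen,
#' calibrate masks to 1 um/pixel, extract and write the area trace, and
#' compute the cardiac report. Group summaries with pairwise Welch tests,
#' a simulated survival/climbing cohort with Kaplan-Meier and log-rank
#' statistics, and a run manifest are written to `config$out_dir`. The run
#' is deterministic for a given configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return The run manifest (also written as `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  run_stats <- "stats" %in% config$stages
  run_analyze <- run_stats || "analyze" %in% config$stages
  run_segment <- run_analyze || "segment" %in% config$stages

  manifest <- list(package = "flycardia",
                   version = as.character(packageVersion("flycardia")),
                   seed = config$seed, path = config$path,
                   speckle = config$speckle, stages = config$stages,
                   recordings = list(), outputs = character(0))
  reports <- list()

  for (gi in seq_along(config$groups)) {
    gname <- names(config$groups)[gi]
    g <- config$groups[[gi]]
    gdir <- file.path(out, gname)
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    for (ri in seq_len(g$n_recordings)) {
      rec_seed <- config$seed + 1000L * gi + ri
      kin <- g$kinematics
      kin$seed <- rec_seed
      rec_id <- sprintf("%s_rec%02d", gname, ri)
      rec <- tryCatch(
        simulate_recording(kin, config),
        error = function(e) stopf("stage 'simulate' failed for %s: %s",
                                  rec_id, conditionMessage(e)))
      files <- character(0)
      if (config$write_images) {
        tif <- file.path(gdir, paste0(rec_id, ".tif"))
        write_mmode(rec$mmode, tif)
        write_ground_truth(rec$truth,
                           file.path(gdir, paste0(rec_id, "_truth.json")))
        files <- c(files, tif)
      }
      entry <- list(id = rec_id, group = gname, seed = rec_seed,
                    n_frames = rec$truth$n_frames, fps = kin$fps)
      if (run_segment) {
        trace <- tryCatch({
          masks <- segment_mmode(rec$mmode)
          masks <- calibrate_resize(masks, 1)
          extract_area_trace(masks)
        }, error = function(e) stopf("stage 'segment' failed for %s: %s",
                                     rec_id, conditionMessage(e)))
        trace_csv <- file.path(gdir, paste0(rec_id, "_trace.csv"))
        write_area_trace(trace, trace_csv)
        files <- c(files, trace_csv)
        entry$trace <- trace_csv
      }
      if (run_analyze) {
        rep <- tryCatch(cardiac_report(trace),
                        error = function(e)
                          stopf("stage 'analyze' failed for %s: %s",
                                rec_id, conditionMessage(e)))
        rep_json <- file.path(gdir, paste0(rec_id, "_report.json"))
        write_cardiac_report(rep, rep_json)
        files <- c(files, rep_json)
        entry$report <- rep_json
        reports[[rec_id]] <- data.frame(
          recording = rec_id, group = gname, hr_hz = rep$hr_hz,
          eda_um2 = rep$eda_um2, esa_um2 = rep$esa_um2,
          fs_percent = rep$fs_percent, ai = rep$ai, n_beats = rep$n_beats)
      }
      manifest$recordings[[rec_id]] <- entry
      manifest$outputs <- c(manifest$outputs, files)
    }
  }

  if (run_analyze && length(reports)) {
    reports_df <- do.call(rbind, c(reports, make.row.names = FALSE))
    rep_csv <- file.path(out, "cardiac_reports.csv")
    write.csv(reports_df, rep_csv, row.names = FALSE)
    manifest$outputs <- c(manifest$outputs, rep_csv)
  }
  if (run_stats) {
    stats_files <- run_stats_stage(config, reports_df, out)
    manifest$outputs <- c(manifest$outputs, stats_files)
  }
  manifest$outputs <- unname(manifest$outputs)
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

# image- or spectral-path simulation of one recording
simulate_recording <- function(kin, config) {
  if (config$path == "image") {
    render_mmode(kin, config$system, config$geometry,
                 speckle = config$speckle)
  } else {
    sp <- simulate_spectral_mmode(kin, config$system, config$geometry)
    fov_ax <- fov_for_area(kin$eda_um2 * 1.05, config$geometry)[["axial"]]
    mm <- reconstruct_mmode(sp$frames, config$system, sp$background,
                            crop_depth_um = 120 + c(-10, fov_ax + 10))
    list(mmode = mm, truth = sp$truth)
  }
}

# group summaries + simulated cohort statistics
run_stats_stage <- function(config, reports_df, out) {
  gs <- group_summary(reports_df)
  sum_csv <- file.path(out, "group_summary.csv")
  write.csv(gs$summary, sum_csv, row.names = FALSE)
  files <- sum_csv
  if (!is.null(gs$tests)) {
    tests_csv <- file.path(out, "group_tests.csv")
    write.csv(gs$tests, tests_csv, row.names = FALSE)
    files <- c(files, tests_csv)
  }
  cohort_cfg <- config$cohort
  if (is.null(cohort_cfg)) {
    groups <- lapply(config$groups, function(g)
      list(eda_um2 = g$kinematics$eda_um2, esa_um2 = g$kinematics$esa_um2,
           rate_hz = g$kinematics$rate_hz, ai = g$kinematics$jitter_cv))
    cohort_cfg <- cohort_config(groups, seed = config$seed + 99L)
  }
  cohort <- simulate_cohort(cohort_cfg)
  write.csv(cohort$survival, file.path(out, "survival.csv"),
            row.names = FALSE)
  write.csv(cohort$climbing, file.path(out, "climbing.csv"),
            row.names = FALSE)
  stats <- list(climbing = climbing_index(cohort$climbing)$summary)
  gn <- unique(cohort$survival$group)
  if (length(gn) >= 2L) {
    pairs <- utils::combn(gn, 2, simplify = FALSE)
    stats$logrank <- lapply(pairs, function(pr) {
      a <- cohort$survival[cohort$survival$group == pr[1], ]
      b <- cohort$survival[cohort$survival$group == pr[2], ]
      lr <- logrank_test(a, b)
      list(group_a = pr[1], group_b = pr[2], chisq = lr$statistic,
           p_value = lr$p_value, stars = signif_stars(lr$p_value))
    })
    stats$lifespan_t <- lapply(pairs, function(pr) {
      a <- cohort$survival$time_days[cohort$survival$group == pr[1]]
      b <- cohort$survival$time_days[cohort$survival$group == pr[2]]
      tt <- welch_t_test(a, b)
      list(group_a = pr[1], group_b = pr[2], t = tt$statistic,
           p_value = tt$p_value)
    })
  }
  stats_json <- file.path(out, "assay_stats.json")
  jsonlite::write_json(stats, stats_json, auto_unbox = TRUE, digits = NA)
  c(files, file.path(out, "survival.csv"), file.path(out, "climbing.csv"),
    stats_json)
}

#' Validate the outputs of a pipeline run
#'
#' Re-reads every output named in the run manifest and checks the
#' contracts that apply to it: files exist; traces have strictly
#' increasing timestamps, non-negative areas, a full frame count and at
#' most 20% invalid frames; reports satisfy `ESA <= EDA`,
#' `0 <= FS < 100`, `AI >= 0`, and HR consistent with
#' `n_beats / duration` to within one beat.
#'
#' @param out_dir directory of a completed [run_pipeline()] run.
#' @return An object of class `validation_summary`: data.frame of
#'   `check`, `target`, `pass`, `detail`, with attribute `pass` (overall).
#' @export
validate_report <- function(out_dir) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stopf("no manifest.json under %s: not a completed run", out_dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  checks <- list()
  add <- function(check, target, pass, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, target = target, pass = pass, detail = detail)
  for (f in unlist(manifest$outputs))
    add("output exists", basename(f), file.exists(f), f)
  for (rec in manifest$recordings) {
    if (!is.null(rec$trace) && file.exists(rec$trace)) {
      tr <- tryCatch(read_area_trace(rec$trace), error = function(e) NULL)
      if (is.null(tr)) {
        add("trace readable", rec$id, FALSE, rec$trace)
      } else {
        add("trace frame count", rec$id, nrow(tr) == rec$n_frames,
            sprintf("%d/%d", nrow(tr), rec$n_frames))
        add("trace time increasing", rec$id, !is.unsorted(tr$time_s,
                                                          strictly = TRUE))
        add("trace areas non-negative", rec$id, all(tr$area_um2 >= 0))
        add("trace valid fraction", rec$id, mean(tr$valid) >= 0.8,
            sprintf("%.1f%% valid", 100 * mean(tr$valid)))
      }
    }
    if (!is.null(rec$report) && file.exists(rec$report)) {
      rp <- jsonlite::read_json(rec$report, simplifyVector = TRUE)
      add("report ESA <= EDA", rec$id, rp$esa_um2 <= rp$eda_um2)
      add("report FS in [0, 100)", rec$id,
          rp$fs_percent >= 0 && rp$fs_percent < 100)
      add("report AI >= 0", rec$id, is.na(rp$ai) || rp$ai >= 0)
      hr_count <- rp$n_beats / rp$duration_s
      add("report HR consistent with beat count", rec$id,
          abs(rp$hr_hz - hr_count) <= 1 / rp$duration_s +
            0.1 * rp$hr_hz,
          sprintf("hr %.3f vs n/T %.3f", rp$hr_hz, hr_count))
    }
  }
  res <- do.call(rbind, checks)
  attr(res, "pass") <- all(res$pass)
  class(res) <- c("validation_summary", "data.frame")
  res
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("<validation_summary> %d checks, %d failed -> %s\n",
              nrow(x), sum(!x$pass),
              if (attr(x, "pass")) "PASS" else "FAIL"))
  if (any(!x$pass)) print(as.data.frame(x[!x$pass, ]))
  invisible(x)
}
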