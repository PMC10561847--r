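#' Read and write pipeline tables
#'
#' Fixed-header CSV interchange for the pipeline's tabular artifacts:
#' onset events (`oscillator_id,onset_time_s`), coherence traces
#' (`time_s,r,psi_rad`), beat grids
#' (`center_s,window_start_s,window_end_s`) and tap logs
#' (`participant_id,stimulus_id,tap_time_s`). Writers emit times with nine
#' decimal places; readers validate the header and report malformed rows
#' by line number.
#'
#' @param path File path.
#' @return `read_onsets()`: a time-sorted data frame of onset events.
#' @name pipeline_io
NULL

check_header <- function(path, expected) {
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  if (length(header) == 0 && file.size(path) == 0)
    stop("empty file: ", path)
  missing <- setdiff(expected, header)
  if (length(missing))
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
}

#' @rdname pipeline_io
#' @export
read_onsets <- function(path) {
  check_header(path, c("oscillator_id", "onset_time_s"))
  tab <- utils::read.csv(path)
  bad <- which(!is.finite(tab$onset_time_s) | tab$onset_time_s < 0)
  if (length(bad)) {
    warning("dropping ", length(bad), " malformed onset row(s) at line(s) ",
            paste(bad + 1L, collapse = ", "))
    tab <- tab[-bad, , drop = FALSE]
  }
  tab <- tab[order(tab$onset_time_s), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' @rdname pipeline_io
#' @param onsets Onset-event data frame (`oscillator_id`, `onset_time_s`).
#' @export
write_onsets <- function(onsets, path) {
  out <- data.frame(oscillator_id = onsets$oscillator_id,
                    onset_time_s = sprintf("%.9f", onsets$onset_time_s))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param trace Coherence-trace data frame (`time_s`, `r`, `psi_rad`).
#' @export
write_trace <- function(trace, path) {
  out <- data.frame(time_s = sprintf("%.9f", trace$time_s),
                    r = sprintf("%.9f", trace$r),
                    psi_rad = sprintf("%.9f", trace$psi_rad))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_trace <- function(path) {
  check_header(path, c("time_s", "r", "psi_rad"))
  utils::read.csv(path)
}

#' @rdname pipeline_io
#' @param grid A `beat_grid`.
#' @export
write_beat_grid <- function(grid, path) {
  w <- grid$windows
  out <- data.frame(center_s = sprintf("%.9f", w$center_s),
                    window_start_s = sprintf("%.9f", w$window_start_s),
                    window_end_s = sprintf("%.9f", w$window_end_s))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tap log into tap trials
#'
#' Groups rows of a `participant_id,stimulus_id,tap_time_s` CSV by
#' participant and stimulus; tap times are sorted, duplicate timestamps
#' within a trial are deduplicated with a warning, and rows with negative
#' times are rejected with their line numbers.
#'
#' @param path Tap-log CSV path.
#' @param base_periods Named numeric vector mapping `stimulus_id` to its
#'   beat period in seconds (required to derive normalized ITIs).
#' @param condition_labels Optional named character vector mapping
#'   `stimulus_id` to coupling condition.
#' @return List of [tap_trial()]s.
#' @export
read_taps <- function(path, base_periods, condition_labels = NULL) {
  check_header(path, c("participant_id", "stimulus_id", "tap_time_s"))
  tab <- utils::read.csv(path, colClasses = c(participant_id = "character",
                                              stimulus_id = "character"))
  if (nrow(tab) == 0L) return(list())
  bad <- which(!is.finite(tab$tap_time_s) | tab$tap_time_s < 0)
  if (length(bad)) {
    warning("rejecting ", length(bad), " row(s) with negative or ",
            "non-numeric times at line(s) ",
            paste(bad + 1L, collapse = ", "))
    tab <- tab[-bad, , drop = FALSE]
  }
  keys <- split(tab, list(tab$participant_id, tab$stimulus_id), drop = TRUE)
  trials <- lapply(keys, function(g) {
    times <- sort(g$tap_time_s)
    if (anyDuplicated(times)) {
      warning("duplicate tap time(s) for ", g$participant_id[1], " x ",
              g$stimulus_id[1], "; keeping one of each")
      times <- unique(times)
    }
    sid <- g$stimulus_id[1]
    if (!sid %in% names(base_periods))
      stop("no base period supplied for stimulus ", sid)
    tap_trial(g$participant_id[1], sid, times, base_periods[[sid]],
              condition_label = if (!is.null(condition_labels) &&
                                    sid %in% names(condition_labels))
                condition_labels[[sid]] else NA_character_)
  })
  unname(trials)
}

#' @rdname read_taps
#' @param trials List of `tap_trial`s to serialize.
#' @param path Output path.
#' @export
write_taps <- function(trials, path) {
  rows <- lapply(trials, function(tr)
    data.frame(participant_id = tr$participant_id,
               stimulus_id = tr$stimulus_id,
               tap_time_s = sprintf("%.9f", tr$tap_times)))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes every stage in order: stimulus generation for the
#' feedback-controlled 40-sequence design, beat-window segmentation,
#' synthetic-cohort tap simulation, per-trial interval metrics, per-condition
#' phase-coherence summaries, k-means phenotyping with semantic labels,
#' group assignment, dense/sparse classification of frequent-tapping
#' trials, and the factorial ITI regression. All artifacts are written as
#' CSV under `out_dir` together with a JSON run manifest recording the
#' seeds and output file hashes.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; every stage's randomness derives from it.
#' @param design Stimulus design data frame (default [exp2_design()]).
#' @param n_regular,n_hybrid,n_fast Cohort sizes.
#' @param write_audio If `TRUE`, also render WAV click tracks (off by
#'   default; audio is an optional artifact).
#' @return Invisibly, a list with `sequences`, `grids`, `trials`,
#'   `points` (labelled trial points), `groups`, `phasors`,
#'   `dense_sparse`, `regression` and `manifest`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, design = exp2_design(),
                         n_regular = 17L, n_hybrid = 24L, n_fast = 9L,
                         write_audio = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  message("[generate] ", nrow(design), " stimulus sequences")
  sequences <- batch_generate(design, seed = seed)
  message("[segment] extracting beat grids")
  grids <- lapply(sequences, segment_sequence)
  message("[simulate-cohort] ", n_regular, "/", n_hybrid, "/", n_fast,
          " Regular/Hybrid/Fast tappers")
  cohort <- simulate_cohort(sequences, grids, n_regular = n_regular,
                            n_hybrid = n_hybrid, n_fast = n_fast,
                            seed = seed)
  message("[analyze] ", length(cohort$trials), " tap trials")
  points <- build_trial_points(cohort$trials, sequences)
  message("[coherence] per-condition phasors")
  phasors <- condition_phasors(cohort$trials, sequences, grids)
  message("[classify] k-means phenotyping")
  model <- fit_clusters(points, k = 5L, seed = seed)
  groups <- assign_groups(model$assignment)
  dense_sparse <- classify_dense_sparse(cohort$trials, model$assignment)
  regression <- tryCatch(
    fit_iti_regression(merge_regression_table(model$assignment, groups,
                                              dense_sparse)),
    error = function(e) {
      warning("ITI regression skipped: ", conditionMessage(e))
      NULL
    })

  tap_path <- file.path(out_dir, "taps.csv")
  write_taps(cohort$trials, tap_path)
  cluster_path <- file.path(out_dir, "clusters.csv")
  utils::write.csv(model$assignment, cluster_path, row.names = FALSE)
  group_path <- file.path(out_dir, "groups.csv")
  utils::write.csv(groups, group_path, row.names = FALSE)
  phasor_path <- file.path(out_dir, "phasors.csv")
  utils::write.csv(phasors, phasor_path, row.names = FALSE)
  ds_path <- file.path(out_dir, "dense_sparse.csv")
  utils::write.csv(dense_sparse, ds_path, row.names = FALSE)
  outputs <- c(tap_path, cluster_path, group_path, phasor_path, ds_path)
  if (!is.null(regression)) {
    reg_path <- file.path(out_dir, "regression.txt")
    utils::capture.output(print(regression$coefficients),
                          cat("R-squared:", regression$r_squared, "\n"),
                          file = reg_path)
    outputs <- c(outputs, reg_path)
  }
  if (write_audio) {
    for (id in names(sequences)) {
      wav <- file.path(out_dir, paste0(id, ".wav"))
      write_wav(render_clicks(sequences[[id]]), wav)
      outputs <- c(outputs, wav)
    }
  }
  manifest <- list(
    seed = seed,
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    design_rows = nrow(design),
    cohort = list(regular = n_regular, hybrid = n_hybrid, fast = n_fast),
    n_trials = length(cohort$trials),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) list(md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message("[done] ", length(outputs), " artifacts in ",
          format(Sys.time() - t0, digits = 3))
  invisible(list(sequences = sequences, grids = grids,
                 trials = cohort$trials, truth = cohort$truth,
                 points = model$assignment, model = model, groups = groups,
                 phasors = phasors, dense_sparse = dense_sparse,
                 regression = regression, manifest = manifest))
}

#' Dense/sparse classification of frequent-tapping trials
#'
#' Applies [dispersion_metric()] to the raw intervals of every trial whose
#' point was labelled cluster 3.
#'
#' @param trials List of `tap_trial`s.
#' @param assignment Labelled trial points (`fit_clusters()$assignment`).
#' @param threshold Dense/sparse split in seconds.
#' @return Data frame `participant_id`, `stimulus_id`, `condition`,
#'   `rms_dispersion`, `label`.
#' @export
classify_dense_sparse <- function(trials, assignment, threshold = 0.1065) {
  key <- paste(assignment$participant_id, assignment$stimulus_id)
  c3 <- assignment$label == 3L
  rows <- list()
  for (tr in trials) {
    k <- paste(tr$participant_id, tr$stimulus_id)
    m <- match(k, key)
    if (is.na(m) || !c3[m] || length(tr$itis) < 3L) next
    dm <- dispersion_metric(tr$itis, threshold = threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = tr$participant_id,
      stimulus_id = tr$stimulus_id,
      condition = assignment$condition[m],
      rms_dispersion = dm$rms_dispersion,
      label = dm$label)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(0), stimulus_id = character(0),
               condition = character(0), rms_dispersion = numeric(0),
               label = character(0))
  rownames(out) <- NULL
  out
}

# join cluster-3 trials with group labels for the factorial regression
merge_regression_table <- function(assignment, groups, dense_sparse) {
  c3 <- assignment[assignment$label == 3L, ]
  if (nrow(c3) == 0L) stop("no cluster-3 trials to regress on")
  c3$group <- groups$group[match(c3$participant_id, groups$participant_id)]
  c3 <- c3[!is.na(c3$group), ]
  data.frame(mean_iti = c3$mean_iti, r = c3$mean_r, tempo = c3$tempo_bpm,
             group = c3$group)
}

#' Read a simulation configuration from YAML
#'
#' Loads a YAML file whose keys mirror the [sim_config()] arguments
#' (`n_oscillators`, `base_tempo`, `freq_sd_fraction`, `coupling_mode`,
#' `k_init`, `r_target`, `k_step`, `dt`, `duration_beats`, `seed`);
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(sim_config)), "")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}
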