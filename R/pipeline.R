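#' Write a trial to a directory of delimited tables
#'
#' One file per rate group — `forces.tsv` (200 Hz), `kinematics.tsv`
#' (50 Hz), `emg.tsv` (2 kHz, if present) — plus `meta.yaml` and, for
#' synthetic trials, `truth.json` with the generating ground truth. All
#' units SI.
#'
#' @param x a `sim_trial` (trial + truth) or bare `trial_timeseries`.
#' @param dir output directory (created if needed).
#' @param digits signif digits used when serializing channels.
#' @return `dir`, invisibly.
#' @export
write_trial <- function(x, dir, digits = 10) {
  trial <- if (inherits(x, "sim_trial")) x$trial else x
  truth <- if (inherits(x, "sim_trial")) x$truth else NULL
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file)
    utils::write.table(signif(as.data.frame(lapply(df, as.numeric)), digits),
                       file.path(dir, file), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  wr(trial$forces, "forces.tsv")
  wr(trial$kinematics, "kinematics.tsv")
  if (!is.null(trial$emg)) wr(trial$emg, "emg.tsv")
  yaml::write_yaml(trial$meta, file.path(dir, "meta.yaml"))
  if (!is.null(truth)) {
    tr <- unclass(truth)
    tr$config <- unclass(tr$config)
    tr$com_series <- NULL              # recoverable from channels; keep light
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a trial written by [write_trial()]
#'
#' @param dir trial directory.
#' @return a `trial_timeseries`; if `truth.json` is present it is attached
#'   as attribute `"truth"`.
#' @export
read_trial <- function(dir) {
  rd <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) return(NULL)
    utils::read.table(path, header = TRUE, sep = "\t")
  }
  forces <- rd("forces.tsv")
  if (is.null(forces)) stopf("read_trial: %s has no forces.tsv", dir)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  out <- structure(list(forces = forces, kinematics = rd("kinematics.tsv"),
                        emg = rd("emg.tsv"), meta = meta),
                   class = "trial_timeseries")
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) attr(out, "truth") <- jsonlite::read_json(tp,
                                                                 simplifyVector = TRUE)
  out
}

#' Run the full analysis pipeline over a cohort manifest
#'
#' The manifest (a YAML file or an equivalent list) names the trials to
#' analyze and the analysis settings:
#'
#' ```yaml
#' analysis: {n_strides: 200, event_method: force, min_steps: 50}
#' trials:
#'   - {participant: P01, condition: steady, speed: normal, path: trials/P01_steady_normal}
#'   - ...
#' ```
#'
#' Each trial is read, analyzed with [analyze_trial()], and its step table
#' and phase-wise fits are written under `out_dir`. Failing trials are
#' quarantined (recorded with their error message) without stopping the
#' run. The group table pools one row per trial; if the manifest spans a
#' complete 2 x 2 (condition x speed) design, [rm_2x2()] summaries are
#' appended to the report.
#'
#' @param manifest path to a YAML manifest, or a list with the same
#'   structure.
#' @param out_dir output directory.
#' @return list with `group_table`, `failures` and the paths written,
#'   invisibly.
#' @export
run_pipeline <- function(manifest, out_dir) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  if (is.null(manifest$trials) || !length(manifest$trials))
    stopf("run_pipeline: manifest lists no trials")
  an_cfg <- manifest$analysis %||% list()
  n_strides <- an_cfg$n_strides %||% NULL
  method <- an_cfg$event_method %||% "force"
  min_steps <- an_cfg$min_steps %||% 50
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "steps"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "fits"), showWarnings = FALSE)

  rows <- NULL; failures <- NULL
  for (tr in manifest$trials) {
    key <- paste(tr$participant, tr$condition, tr$speed, sep = "_")
    res <- tryCatch({
      trial <- read_trial(tr$path)
      an <- analyze_trial(trial, n_strides = n_strides,
                          event_method = method, min_steps = min_steps)
      tab <- step_records_table(an$records)
      utils::write.table(tab, file.path(out_dir, "steps",
                                        paste0(key, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(an$fp_fit$by_phase,
                         file.path(out_dir, "fits", paste0(key, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      row <- data.frame(
        participant = tr$participant, condition = tr$condition,
        speed = tr$speed,
        r2_mid = an$fp_fit$mid$r2, r2_ts = an$fp_fit$ts$r2,
        z_mid = fisher_transform(an$fp_fit$mid$r2),
        z_ts = fisher_transform(an$fp_fit$ts$r2),
        mean_step_width = an$metrics$mean_step_width,
        step_width_variability = an$metrics$step_width_variability,
        stride_frequency = an$metrics$stride_frequency,
        n_steps = an$metrics$n_steps,
        dropped_steps = 2L * (an$fp_fit$n_steps %/% 2) - an$metrics$n_steps)
      if (!is.null(an$muscle_fit)) {
        row$beta_gm <- an$muscle_fit$beta_gm
        row$beta_al <- an$muscle_fit$beta_al
        row$r2_muscle <- an$muscle_fit$r2
      }
      row
    }, error = function(e) {
      failures <<- rbind(failures,
                         data.frame(trial = key, path = tr$path,
                                    error = conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows <- rbind(rows, res)
  }
  if (!is.null(rows))
    utils::write.table(rows, file.path(out_dir, "group_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(failures))
    utils::write.table(failures, file.path(out_dir, "failures.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  report <- c(sprintf("fpcontrol pipeline: %d trials analyzed, %d failed",
                      if (is.null(rows)) 0L else nrow(rows),
                      if (is.null(failures)) 0L else nrow(failures)))
  if (!is.null(rows)) {
    conds <- unique(rows$condition); spds <- unique(rows$speed)
    if (length(conds) == 2 && length(spds) == 2) {
      steady <- intersect(c("steady", conds), conds)[1]
      other <- setdiff(conds, steady)[1]
      for (oc in intersect(c("z_ts", "z_mid", "step_width_variability",
                             "mean_step_width", "stride_frequency"),
                           names(rows))) {
        s <- tryCatch(rm_2x2(rows, oc, c(steady, other),
                             intersect(c("normal", spds), spds)),
                      error = function(e) NULL)
        if (!is.null(s))
          report <- c(report, utils::capture.output(print(s)))
      }
    }
  }
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(list(group_table = rows, failures = failures, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
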