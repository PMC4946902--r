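# Session data layout: trials table, spike-events table, optional neuron
# ground truth. CSV on disk, plain data.frames in memory.

TRIAL_COLUMNS <- c(
  "session_id", "trial_id", "block", "condition", "prior_mean_deg",
  "cue_lines_deg", "cue_centroid_deg", "target_deg", "reach_deg",
  "t_target_on_s", "t_go_s", "t_move_on_s", "reaction_time_s", "peak_speed_cms"
)
SPIKE_COLUMNS <- c("trial_id", "neuron_id", "t_s")

#' Analysis epoch window
#'
#' A half-open time window `[start_ms, end_ms)` with an alignment event. The
#' canonical spike clock is relative to target onset; `move_on`-aligned windows
#' are re-referenced per trial by subtracting `t_move_on - t_target_on`.
#'
#' @param name window label, e.g. `"visual"`, `"delay"`, `"movement"`,
#'   `"baseline"` or a custom label.
#' @param alignment `"target_on"` or `"move_on"`.
#' @param start_ms,end_ms window bounds in milliseconds, `start_ms < end_ms`.
#' @return list of class `epoch_window`.
#' @export
epoch_window <- function(name, alignment, start_ms, end_ms) {
  alignment <- match.arg(alignment, c("target_on", "move_on"))
  if (!is.finite(start_ms) || !is.finite(end_ms) || start_ms >= end_ms) {
    stop("need start_ms < end_ms")
  }
  structure(list(name = name, alignment = alignment,
                 start_ms = start_ms, end_ms = end_ms),
            class = "epoch_window")
}

#' @export
print.epoch_window <- function(x, ...) {
  cat(sprintf("epoch '%s': [%g, %g) ms, aligned to %s\n",
              x$name, x$start_ms, x$end_ms, x$alignment))
  invisible(x)
}

#' Standard analysis epochs
#'
#' The three tuning epochs (visual 50-250 ms and delay 300-700 ms after target
#' onset; movement 0-200 ms after movement onset) plus the pre-target baseline
#' window (-300 to 0 ms).
#'
#' @return named list of [epoch_window()] objects.
#' @export
default_epochs <- function() {
  list(
    visual   = epoch_window("visual", "target_on", 50, 250),
    delay    = epoch_window("delay", "target_on", 300, 700),
    movement = epoch_window("movement", "move_on", 0, 200),
    baseline = epoch_window("baseline", "target_on", -300, 0)
  )
}

#' Assemble a session object
#'
#' Bundles a validated trials table and spike table (plus optional neuron
#' ground truth) into a `reach_session`.
#'
#' @param trials data.frame with the trials-table columns (see
#'   [read_session()]).
#' @param spikes data.frame with columns `trial_id`, `neuron_id`, `t_s` (spike
#'   times in seconds relative to target onset).
#' @param neurons optional neuron ground-truth data.frame.
#' @param rec_span length-2 numeric, recorded span of spike times (seconds
#'   relative to target onset).
#' @return list of class `reach_session`.
#' @export
reach_session <- function(trials, spikes, neurons = NULL, rec_span = NULL) {
  validate_trials(trials)
  if (is.null(rec_span)) rec_span <- attr(spikes, "rec_span")
  validate_spikes(spikes, trials, rec_span)
  structure(list(
    session_id = trials$session_id[1],
    trials = trials, spikes = spikes, neurons = neurons,
    rec_span = rec_span
  ), class = "reach_session")
}

#' @export
print.reach_session <- function(x, ...) {
  cat(sprintf("reach session '%s': %d trials (%d center-out, %d uncertainty), %d spikes, %d neurons\n",
              x$session_id, nrow(x$trials),
              sum(x$trials$block == "center_out"),
              sum(x$trials$block == "uncertainty"),
              nrow(x$spikes),
              length(unique(x$spikes$neuron_id))))
  invisible(x)
}

validate_trials <- function(trials) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols)) {
    stop("trials table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(trials) == 0L) stop("trials table is empty")
  if (anyDuplicated(trials$trial_id)) stop("duplicate trial_id in trials table")
  bad_block <- which(!trials$block %in% c("center_out", "uncertainty"))
  if (length(bad_block)) stop("invalid block at trial row ", bad_block[1])
  bad_cond <- which(!trials$condition %in% c("zero", "low", "high"))
  if (length(bad_cond)) stop("invalid condition at trial row ", bad_cond[1])
  mism <- which((trials$condition == "zero") != (trials$block == "center_out"))
  if (length(mism)) {
    stop("condition 'zero' must coincide with block 'center_out' (trial row ", mism[1], ")")
  }
  for (col in c("prior_mean_deg", "cue_centroid_deg", "target_deg", "reach_deg")) {
    bad <- which(!is.finite(trials[[col]]) | abs(trials[[col]]) > 360)
    if (length(bad)) stop(col, " out of parseable range at trial row ", bad[1])
  }
  bad_t <- which(!(trials$t_target_on_s < trials$t_go_s &
                     trials$t_go_s < trials$t_move_on_s))
  if (length(bad_t)) {
    stop("event times must satisfy t_target_on < t_go < t_move_on (trial row ", bad_t[1], ")")
  }
  # cue centroid must be the circular mean of the cue lines when lines exist
  lines <- parse_cue_lines(trials$cue_lines_deg)
  has_lines <- lengths(lines) > 0
  if (any(has_lines)) {
    for (i in which(has_lines)) {
      m <- circ_mean(lines[[i]])
      if (!is.na(m) && abs(wrap_deg(m - trials$cue_centroid_deg[i])) > 1e-3) {
        stop("cue_centroid_deg does not match circular mean of cue_lines_deg at trial row ", i)
      }
    }
  }
  invisible(TRUE)
}

validate_spikes <- function(spikes, trials, rec_span = NULL) {
  missing_cols <- setdiff(SPIKE_COLUMNS, names(spikes))
  if (length(missing_cols)) {
    stop("spikes table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  orphan <- which(!spikes$trial_id %in% trials$trial_id)
  if (length(orphan)) {
    stop("spike row ", orphan[1], " references unknown trial_id ", spikes$trial_id[orphan[1]])
  }
  if (!is.null(rec_span)) {
    out <- which(spikes$t_s < rec_span[1] | spikes$t_s > rec_span[2])
    if (length(out)) {
      stop("spike row ", out[1], " outside recorded span [",
           rec_span[1], ", ", rec_span[2], "] s")
    }
  }
  invisible(TRUE)
}

parse_cue_lines <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

format_cue_lines <- function(lines) {
  vapply(lines, function(v) paste(formatC(v, digits = 6, format = "g"), collapse = ";"), "")
}

#' Read a session from disk
#'
#' Reads and validates a trials CSV and a spikes CSV (and optionally a neurons
#' CSV with synthetic ground truth). Validation enforces the schema, event-time
#' ordering, the centroid/cue-line consistency, and referential integrity of
#' spike rows; violations are reported with the offending row number.
#'
#' @param trials_path path to `trials.csv`.
#' @param spikes_path path to `spikes.csv`. A first line of the form
#'   `# rec_start_s=<a> rec_end_s=<b>` declares the recorded span.
#' @param neurons_path optional path to `neurons.csv`.
#' @return a [reach_session()] object.
#' @export
read_session <- function(trials_path, spikes_path, neurons_path = NULL) {
  trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE,
                            colClasses = c(cue_lines_deg = "character"))
  first <- readLines(spikes_path, n = 1L)
  rec_span <- NULL
  skip <- 0L
  if (startsWith(first, "#")) {
    m <- regmatches(first, gregexpr("-?[0-9.]+", first))[[1]]
    if (length(m) >= 2) rec_span <- as.numeric(m[1:2])
    skip <- 1L
  }
  spikes <- utils::read.csv(spikes_path, stringsAsFactors = FALSE, skip = skip)
  neurons <- if (!is.null(neurons_path)) {
    utils::read.csv(neurons_path, stringsAsFactors = FALSE)
  }
  reach_session(trials, spikes, neurons, rec_span = rec_span)
}

#' Write a session to disk
#'
#' Writes `trials.csv`, `spikes.csv` (with the recorded span on a comment
#' line) and, when present, `neurons.csv` into `dir`. Output is deterministic:
#' fixed column order, fixed float formatting.
#'
#' @param session a [reach_session()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "reach_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- session$trials[, TRIAL_COLUMNS]
  num <- vapply(tr, is.numeric, TRUE) & names(tr) != "trial_id"
  tr[num] <- lapply(tr[num], function(v) signif(v, 9))
  utils::write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE)
  sp_path <- file.path(dir, "spikes.csv")
  con <- file(sp_path, "w")
  if (!is.null(session$rec_span)) {
    writeLines(sprintf("# rec_start_s=%.9g rec_end_s=%.9g",
                       session$rec_span[1], session$rec_span[2]), con)
  }
  sp <- session$spikes[, SPIKE_COLUMNS]
  sp$t_s <- signif(sp$t_s, 9)
  utils::write.csv(sp, con, row.names = FALSE)
  close(con)
  if (!is.null(session$neurons)) {
    utils::write.csv(session$neurons, file.path(dir, "neurons.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Write result tables with run metadata
#'
#' Writes each named data.frame in `results` as `<name>.csv` under `dir`
#' (deterministic column order, floats at 6 significant digits) and a
#' `results_meta.json` recording the seed, a configuration hash and the
#' package version. Identical inputs produce byte-identical files.
#'
#' @param results named list of data.frames (may contain zero-row tables).
#' @param dir output directory.
#' @param seed integer seed used for the run (recorded in metadata).
#' @param config optional list; hashed into the metadata.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir, seed = NA_integer_, config = NULL) {
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    stop("`results` must be a fully named list of data.frames")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(results)) {
    df <- results[[nm]]
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) signif(v, 6))
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  meta <- list(
    seed = seed,
    config_hash = sprintf("%d", sum(utf8ToInt(as.character(cfg_json)) *
                                      (seq_along(utf8ToInt(as.character(cfg_json))) %% 97 + 1))),
    package_version = as.character(utils::packageVersion("uncertainreach")),
    tables = names(results)
  )
  jsonlite::write_json(meta, file.path(dir, "results_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

# Aligned spike times: seconds relative to the window's alignment event.
aligned_spike_times <- function(spikes, trials, alignment) {
  if (alignment == "target_on") return(spikes$t_s)
  shift <- trials$t_move_on_s - trials$t_target_on_s
  names(shift) <- as.character(trials$trial_id)
  if (any(is.na(shift))) stop("move_on alignment requires t_move_on_s for every trial")
  spikes$t_s - shift[as.character(spikes$trial_id)]
}

# Count spikes per (trial, neuron) in a window. Returns a trials x neurons
# integer matrix including structural zeros.
window_count_matrix <- function(spikes, trials, window, neuron_ids = NULL) {
  stopifnot(inherits(window, "epoch_window"))
  if (is.null(neuron_ids)) neuron_ids <- sort(unique(spikes$neuron_id))
  t_al <- aligned_spike_times(spikes, trials, window$alignment)
  lo <- window$start_ms / 1000
  hi <- window$end_ms / 1000
  keep <- t_al >= lo & t_al < hi
  tf <- factor(spikes$trial_id[keep], levels = trials$trial_id)
  nf <- factor(spikes$neuron_id[keep], levels = neuron_ids)
  m <- table(tf, nf)
  mat <- matrix(as.integer(m), nrow = nrow(trials),
                dimnames = list(as.character(trials$trial_id), neuron_ids))
  mat
}
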