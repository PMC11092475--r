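#' Clustered-sparse task timing parameters
#'
#' The thalamic localizer task presents 9 s of auditory or visual
#' stimulation per trial, flanked by two silent gaps of equal duration, and
#' acquires a short cluster of BOLD volumes at the end of each 12 s trial so
#' that scanner noise never coincides with stimulation.
#'
#' @param tr_seconds repetition time in seconds.
#' @param volumes_per_cluster volumes acquired per trial cluster (default 3).
#' @param stimulation_seconds stimulation duration per trial (default 9).
#' @param trial_total_seconds total trial duration (default 12).
#' @return a `timing_params` list.
#' @export
timing_params <- function(tr_seconds, volumes_per_cluster = 3L,
                          stimulation_seconds = 9,
                          trial_total_seconds = 12) {
  stopifnot(tr_seconds > 0, volumes_per_cluster >= 1,
            stimulation_seconds > 0, trial_total_seconds > 0)
  p <- list(tr_seconds = tr_seconds,
            volumes_per_cluster = as.integer(volumes_per_cluster),
            stimulation_seconds = stimulation_seconds,
            trial_total_seconds = trial_total_seconds)
  class(p) <- "timing_params"
  p
}

#' Trial timing arithmetic
#'
#' The acquisition cluster lasts `volumes_per_cluster * tr_seconds`; the two
#' silent gaps split the remaining trial time equally:
#' `gap = (trial_total - stimulation - cluster) / 2`.
#'
#' @param params a [timing_params].
#' @return list with `gap_seconds` and `cluster_seconds`.
#' @export
compute_trial_timing <- function(params) {
  stopifnot(inherits(params, "timing_params"))
  cluster <- params$volumes_per_cluster * params$tr_seconds
  gap <- (params$trial_total_seconds - params$stimulation_seconds - cluster) / 2
  if (gap < -1e-12)
    stop("timing infeasible: stimulation + acquisition cluster exceed the ",
         "trial duration", call. = FALSE)
  list(gap_seconds = max(gap, 0), cluster_seconds = cluster)
}

#' Build a pseudorandom run schedule
#'
#' One run is a single leading fixation trial followed by 16 stimulus trials
#' (8 auditory, 8 visual) in a seeded pseudorandom order. Every trial,
#' including fixation, ends with an acquisition cluster of
#' `volumes_per_cluster` volume onsets spaced by TR.
#'
#' @param params a [timing_params].
#' @param seed integer seed; the schedule is a pure function of
#'   `(params, seed)`.
#' @param n_each stimulus trials per condition (default 8).
#' @param max_run optional maximum run length of the same condition; NULL
#'   (default) places no constraint.
#' @param lead_in_seconds silence prepended before the first trial
#'   (default 0).
#' @return a `trial_schedule`: data.frame `trials` (onset, duration,
#'   condition), matrix `acquisition_times` (trial x volume-in-cluster),
#'   plus `params` and `seed`.
#' @export
build_run_schedule <- function(params, seed, n_each = 8L, max_run = NULL,
                               lead_in_seconds = 0) {
  stopifnot(inherits(params, "timing_params"))
  timing <- compute_trial_timing(params)
  conds <- rep(c("auditory", "visual"), each = n_each)
  rng <- rng_stream(seed, "schedule")
  repeat {
    order_ <- conds[rand_perm(rng, length(conds))]
    if (is.null(max_run) || max(rle(order_)$lengths) <= max_run) break
  }
  condition <- c("fixation", order_)
  n_trials <- length(condition)
  onset <- lead_in_seconds + (seq_len(n_trials) - 1) * params$trial_total_seconds
  # cluster begins after gap + stimulation + gap
  cluster_start <- onset + params$trial_total_seconds - timing$cluster_seconds
  acq <- outer(cluster_start,
               (seq_len(params$volumes_per_cluster) - 1) * params$tr_seconds,
               "+")
  sched <- list(trials = data.frame(onset = onset,
                                    duration = params$trial_total_seconds,
                                    condition = condition,
                                    stringsAsFactors = FALSE),
                acquisition_times = acq,
                params = params, seed = seed)
  class(sched) <- "trial_schedule"
  sched
}

n_volumes_scheduled <- function(schedule) length(schedule$acquisition_times)

#' Plan the auditory-trial stimulus sequence
#'
#' An auditory trial concatenates nine 900 ms music segments, each followed
#' by 100 ms of silence, sampled without replacement from a segment pool in
#' seeded pseudorandom order.
#'
#' @param pool vector of available segment identifiers (length >= 9).
#' @param seed integer seed.
#' @param n_segments segments per trial (default 9).
#' @return list with `segment_ids`, `segment_seconds` (0.9),
#'   `silence_seconds` (0.1), and `total_seconds`.
#' @export
plan_auditory_trial <- function(pool, seed, n_segments = 9L) {
  if (length(pool) < n_segments)
    stop("segment pool too small: need ", n_segments, ", have ",
         length(pool), call. = FALSE)
  rng <- rng_stream(seed, "auditory")
  ids <- pool[rand_perm(rng, length(pool))[seq_len(n_segments)]]
  list(segment_ids = ids, segment_seconds = 0.9, silence_seconds = 0.1,
       total_seconds = n_segments * (0.9 + 0.1))
}

#' Write / read a run schedule as an events table
#'
#' Writes a BIDS-style events TSV (onset, duration, condition) plus an
#' acquisition-times sidecar TSV (one row per trial, one column per volume
#' in the cluster); `read_events_table` reconstructs the schedule.
#'
#' @param schedule a `trial_schedule`.
#' @param path events TSV path; the sidecar is written next to it with
#'   suffix `.acq.tsv`.
#' @return `path`, invisibly.
#' @export
write_events_table <- function(schedule, path) {
  write_tsv(schedule$trials, path)
  acq <- as.data.frame(schedule$acquisition_times)
  names(acq) <- paste0("volume_", seq_len(ncol(acq)))
  write_tsv(acq, paste0(path, ".acq.tsv"))
  invisible(path)
}

#' @rdname write_events_table
#' @param params the [timing_params] the schedule was built with.
#' @export
read_events_table <- function(path, params) {
  trials <- read_tsv(path)
  acq <- as.matrix(read_tsv(paste0(path, ".acq.tsv")))
  dimnames(acq) <- NULL
  sched <- list(trials = trials, acquisition_times = acq,
                params = params, seed = NA_integer_)
  class(sched) <- "trial_schedule"
  sched
}
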