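#' Construct a two-task delayed match-to-sample dataset
#'
#' A `pm_dataset` bundles trial-resolved binned firing rates for a set of
#' (not necessarily simultaneously recorded) neurons with the trial metadata
#' the analyses need: task (`"perceptual"` or `"memory"`), sample direction,
#' behavioural outcome, delay duration and anatomical position of each neuron.
#' Rates cover the 1,000-ms sample period plus the first 1,200 ms of the
#' delay, binned at `bin_ms` with bin 0 aligned to sample onset; bins are
#' half-open `[t, t + bin_ms)`.
#'
#' @param trials Tibble with columns `trial_id`, `task`, `direction_deg`,
#'   `outcome`, `delay_ms`, `session_id`, `subject_id`.
#' @param neurons Tibble with columns `neuron_id`, `x_mm`, `y_mm`,
#'   `subject_id`.
#' @param rates Named list (one element per neuron, names matching
#'   `neuron_id`) of numeric matrices `[trials x time bins]` of firing rates
#'   in spikes/s, rows in `trials` order.
#' @param direction_set The session's four sample directions in degrees,
#'   mutually separated by multiples of 90 degrees.
#' @param bin_ms Bin width in ms (default 40).
#' @param sample_ms Sample presentation duration in ms (default 1000); the
#'   delay starts at `sample_ms` in both tasks (in the perceptual task the
#'   sample simply stays on screen during its delay).
#' @param provenance Free-form list of metadata (generator seed, ground
#'   truth, ...).
#' @return An object of class `pm_dataset`.
#' @export
pm_dataset <- function(trials, neurons, rates, direction_set,
                       bin_ms = 40L, sample_ms = 1000L, provenance = list()) {
  x <- structure(
    list(
      trials = tibble::as_tibble(trials),
      neurons = tibble::as_tibble(neurons),
      rates = rates,
      direction_set = as.numeric(direction_set),
      bin_ms = as.integer(bin_ms),
      sample_ms = as.integer(sample_ms),
      provenance = provenance
    ),
    class = "pm_dataset"
  )
  validate_pm_dataset(x)
}

#' Validate the internal consistency of a `pm_dataset`
#'
#' Checks the invariants all downstream analyses rely on: exactly two tasks
#' and four directions (eight condition labels), 90-degree direction spacing,
#' delay durations within 1,200-2,000 ms, one rate matrix per neuron with one
#' row per trial, finite non-negative rates, and a common bin count.
#'
#' @param x A `pm_dataset`.
#' @return `x`, invisibly-checked (returned unchanged).
#' @export
validate_pm_dataset <- function(x) {
  stopifnot(inherits(x, "pm_dataset"))
  tr <- x$trials
  need <- c("trial_id", "task", "direction_deg", "outcome", "delay_ms",
            "session_id", "subject_id")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0) {
    stop("trials table is missing columns: ", paste(miss, collapse = ", "))
  }
  bad_task <- setdiff(unique(tr$task), c("perceptual", "memory"))
  if (length(bad_task) > 0) {
    stop("unknown task label(s): ", paste(bad_task, collapse = ", "))
  }
  bad_out <- setdiff(unique(tr$outcome), c("correct", "error"))
  if (length(bad_out) > 0) {
    stop("unknown outcome label(s): ", paste(bad_out, collapse = ", "))
  }
  if (length(x$direction_set) != 4) {
    stop("direction_set must contain exactly 4 directions")
  }
  gaps <- diff(sort(x$direction_set %% 360))
  if (any(abs(gaps - 90) > 1e-8)) {
    stop("the 4 directions must be mutually separated by multiples of 90 degrees")
  }
  if (!all(tr$direction_deg %in% x$direction_set)) {
    stop("trials contain directions outside direction_set")
  }
  if (nrow(tr) > 0) {
    labs <- unique(paste(tr$task, tr$direction_deg))
    if (length(labs) != 8) {
      stop("expected exactly 8 condition labels (2 tasks x 4 directions), found ",
           length(labs))
    }
    if (any(tr$delay_ms < 1200 | tr$delay_ms > 2000)) {
      stop("delay_ms must lie in [1200, 2000]")
    }
  }
  if (!setequal(names(x$rates), x$neurons$neuron_id) ||
      length(x$rates) != nrow(x$neurons)) {
    stop("rates must be a named list with one matrix per neuron_id")
  }
  nb <- unique(vapply(x$rates, ncol, integer(1)))
  if (length(x$rates) > 0 && length(nb) != 1) {
    stop("all neurons must share the same number of time bins")
  }
  for (id in names(x$rates)) {
    m <- x$rates[[id]]
    if (nrow(m) != nrow(tr)) {
      stop("rates for neuron ", id, " have ", nrow(m),
           " rows but the dataset has ", nrow(tr), " trials")
    }
    if (any(!is.finite(m)) || any(m < 0)) {
      stop("rates for neuron ", id, " contain negative or non-finite values")
    }
  }
  x
}

#' @export
print.pm_dataset <- function(x, ...) {
  cat("<pm_dataset> ", nrow(x$neurons), " neurons, ", nrow(x$trials),
      " trials, ", n_bins(x), " bins of ", x$bin_ms, " ms\n", sep = "")
  cat("  directions: ", paste(x$direction_set, collapse = ", "),
      " deg; sample ", x$sample_ms, " ms\n", sep = "")
  invisible(x)
}

n_bins <- function(dataset) {
  if (length(dataset$rates) == 0) return(0L)
  ncol(dataset$rates[[1]])
}

#' Define an analysis time window
#'
#' Windows are half-open `[start_ms, end_ms)` relative to either sample onset
#' or delay onset (the delay starts `sample_ms` after sample onset in both
#' tasks). Boundaries must be multiples of the dataset bin width; windows
#' that do not align to whole bins are rejected rather than truncated.
#'
#' @param start_ms,end_ms Window boundaries in ms, `start_ms < end_ms`.
#' @param reference `"sample_onset"` or `"delay_onset"`.
#' @return A `pm_window` object.
#' @export
pm_window <- function(start_ms, end_ms,
                      reference = c("delay_onset", "sample_onset")) {
  reference <- match.arg(reference)
  if (!(start_ms < end_ms)) stop("start_ms must be < end_ms")
  structure(list(start_ms = start_ms, end_ms = end_ms, reference = reference),
            class = "pm_window")
}

#' Default delay analysis window
#'
#' The first 240 ms of the delay are excluded to avoid residual sensory
#' transients, and only the first 1,200 ms of the (variable-length) delay are
#' analysed, so the default window is 240-1,200 ms after delay onset.
#'
#' @return A `pm_window` spanning `[240, 1200)` ms from delay onset.
#' @export
delay_window <- function() pm_window(240, 1200, "delay_onset")

# Resolve a window to absolute bin indices within the dataset's rate
# matrices. Errors if boundaries are not bin-aligned or extend beyond the
# stored bins.
window_bins <- function(dataset, window) {
  stopifnot(inherits(window, "pm_window"))
  off <- if (window$reference == "delay_onset") dataset$sample_ms else 0
  a <- window$start_ms + off
  b <- window$end_ms + off
  if (a %% dataset$bin_ms != 0 || b %% dataset$bin_ms != 0) {
    stop("window boundaries (", a, ", ", b,
         " ms) are not multiples of bin_ms = ", dataset$bin_ms)
  }
  i0 <- a %/% dataset$bin_ms + 1L
  i1 <- b %/% dataset$bin_ms
  if (i0 < 1 || i1 > n_bins(dataset)) {
    stop("window [", a, ", ", b, ") ms extends beyond the ",
         n_bins(dataset), " stored bins (0-",
         n_bins(dataset) * dataset$bin_ms, " ms)")
  }
  seq.int(i0, i1)
}

#' Mean delay-period firing rate for one neuron and trial
#'
#' Arithmetic mean of the binned rates within a half-open window, by default
#' the 240-1,200 ms delay window.
#'
#' @param dataset A `pm_dataset`.
#' @param neuron_id Neuron identifier.
#' @param trial_id Trial identifier.
#' @param window A [pm_window()]; default [delay_window()].
#' @return Mean firing rate (spikes/s).
#' @export
delay_mean_rate <- function(dataset, neuron_id, trial_id,
                            window = delay_window()) {
  row <- match(trial_id, dataset$trials$trial_id)
  if (is.na(row)) stop("unknown trial_id: ", trial_id)
  m <- dataset$rates[[as.character(neuron_id)]]
  if (is.null(m)) stop("unknown neuron_id: ", neuron_id)
  bins <- tryCatch(window_bins(dataset, window), error = function(e) {
    stop("trial ", trial_id, ": ", conditionMessage(e))
  })
  mean(m[row, bins])
}

#' Delay-mean firing rates for all neurons and trials
#'
#' @inheritParams delay_mean_rate
#' @return Numeric matrix `[trials x neurons]` of window-mean rates, with
#'   neuron ids as column names.
#' @export
delay_mean_matrix <- function(dataset, window = delay_window()) {
  bins <- window_bins(dataset, window)
  out <- vapply(
    dataset$neurons$neuron_id,
    function(id) rowMeans(dataset$rates[[id]][, bins, drop = FALSE]),
    numeric(nrow(dataset$trials))
  )
  out <- matrix(out, nrow = nrow(dataset$trials),
                dimnames = list(NULL, dataset$neurons$neuron_id))
  out
}

#' Group trials by condition labels
#'
#' Partitions the trial list by any combination of task, sample direction and
#' behavioural outcome. Every trial falls in exactly one group and the
#' within-group ordering follows the trial table.
#'
#' @param dataset A `pm_dataset`.
#' @param by Character vector drawn from `"task"`, `"direction"`, `"outcome"`.
#' @return Tibble with one row per group: the grouping columns, `n`, and a
#'   list-column `idx` of trial row indices.
#' @export
pm_group_trials <- function(dataset, by = c("task", "direction")) {
  cols <- c(task = "task", direction = "direction_deg", outcome = "outcome")
  bad <- setdiff(by, names(cols))
  if (length(bad) > 0) stop("unknown grouping key(s): ", paste(bad, collapse = ", "))
  key <- unname(cols[by])
  tr <- dataset$trials
  if (nrow(tr) == 0) {
    return(tibble::tibble(!!!stats::setNames(rep(list(character(0)), length(key)), key),
                          n = integer(0), idx = list()))
  }
  tr$..row <- seq_len(nrow(tr))
  out <- tr |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(n = dplyr::n(), idx = list(.data$..row), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(key)))
  out
}
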