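# Condition-mean high-gamma responses and the baseline-corrected
# local-by-global interaction waveform,
#   L x G = (LDGD - LSGD) - (LDGS - LSGS),
# computed on non-negative power so the interaction sign is interpretable.

#' Per-condition mean power responses
#'
#' Arithmetic mean over unmasked test trials, separately for LSGS, LDGS,
#' LSGD and LDGD.
#'
#' @param epochs A [power_epochs()] object.
#' @return A `condition_means` object: `mean_power` (4 x time matrix with
#'   condition rownames), `n_trials`, `time_ms`.
#' @export
condition_means <- function(epochs) {
  stopifnot(inherits(epochs, "power_epochs"))
  keep <- !epochs$artifact
  m <- matrix(NA_real_, 4, ncol(epochs$power),
              dimnames = list(CONDITION_LEVELS, NULL))
  n <- setNames(integer(4), CONDITION_LEVELS)
  for (cc in CONDITION_LEVELS) {
    rows <- which(keep & epochs$condition == cc)
    if (!length(rows))
      stop("no unmasked trials in condition ", cc)
    n[[cc]] <- length(rows)
    m[cc, ] <- colMeans(epochs$power[rows, , drop = FALSE])
  }
  structure(list(mean_power = m, n_trials = n, time_ms = epochs$time_ms,
                 site = epochs$site),
            class = "condition_means")
}

#' Local-by-global interaction waveform
#'
#' `(LDGD - LSGD) - (LDGS - LSGS)`, baseline-corrected by subtracting the
#' mean over the window preceding the 5th-vowel onset (default
#' `[-600, 0)` ms, half-open).
#'
#' @param means A [condition_means()] object.
#' @param baseline_window Baseline window, ms.
#' @return An `lxg_waveform` object: `values`, `time_ms`,
#'   `baseline_window`, `baseline_mean` (the subtracted constant).
#' @export
lxg_waveform <- function(means, baseline_window = c(-600, 0)) {
  stopifnot(inherits(means, "condition_means"))
  m <- means$mean_power
  raw <- (m["LDGD", ] - m["LSGD", ]) - (m["LDGS", ] - m["LSGS", ])
  in_base <- means$time_ms >= baseline_window[1] &
    means$time_ms < baseline_window[2]
  if (!any(in_base))
    stop("baseline window [", baseline_window[1], ", ", baseline_window[2],
         ") contains no samples of the epoch time axis")
  b <- mean(raw[in_base])
  structure(list(values = raw - b, time_ms = means$time_ms,
                 baseline_window = baseline_window, baseline_mean = b,
                 site = means$site),
            class = "lxg_waveform")
}

#' Write an interaction waveform to TSV
#'
#' Columns `time_ms`, `value`.
#'
#' @param wave An [lxg_waveform()] object.
#' @param path Output path.
#' @export
write_waveform_tsv <- function(wave, path) {
  utils::write.table(data.frame(time_ms = wave$time_ms, value = wave$values),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
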