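# Continuous voltage -> trial-epoched high-gamma power.
#
# Chain: downsample to the 1000 Hz analysis rate, suppress the 60 Hz line
# component, bandpass 70-150 Hz (300th-order FIR, zero-phase), flag artifact
# trials (5 SD rule on the band-filtered voltage), square + 50 ms running
# average to power (uV^2), epoch around the 5th-vowel onset.

#' Continuous multichannel recording container
#'
#' @param samples Numeric matrix, channels x time, in uV.
#' @param fs Sampling rate, Hz.
#' @param channel_names Optional channel labels.
#' @return A `continuous_recording` object.
#' @export
continuous_recording <- function(samples, fs,
                                 channel_names = paste0("ch", seq_len(nrow(samples)))) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), fs > 0,
            length(channel_names) == nrow(samples))
  if (anyNA(samples)) stop("recording contains NaN/NA samples")
  structure(list(samples = samples, fs = fs,
                 channel_names = as.character(channel_names)),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat("<continuous_recording: ", nrow(x$samples), " channel(s), ",
      ncol(x$samples), " samples @ ", x$fs, " Hz (",
      round(ncol(x$samples) / x$fs, 1), " s)>\n", sep = "")
  invisible(x)
}

# Centered running mean with edge truncation (the window shrinks at the
# series edges). Window of w samples spans [i - floor(w/2), i + w - 1 - floor(w/2)].
running_mean <- function(x, w) {
  n <- length(x)
  if (w < 1) stop("smoothing window shorter than 1 sample")
  if (w == 1) return(x)
  half_l <- floor(w / 2)
  half_r <- w - 1L - half_l
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_l)
  hi <- pmin(n, i + half_r)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Apply a per-channel function over a recording, returning a new recording.
map_channels <- function(rec, f) {
  out <- t(apply(rec$samples, 1, f))
  if (nrow(rec$samples) == 1) out <- matrix(out, nrow = 1)
  continuous_recording(out, rec$fs, rec$channel_names)
}

#' Downsample a recording to the analysis rate
#'
#' Anti-alias lowpass (FIR, zero-phase) followed by cubic-spline
#' interpolation onto the uniform target-rate grid. Output length is
#' `round(n * target_fs / fs)`.
#'
#' @param rec A [continuous_recording()].
#' @param target_fs Target rate, Hz (default 1000); upsampling is refused.
#' @return A [continuous_recording()] at `target_fs`.
#' @export
resample_to_analysis_rate <- function(rec, target_fs = 1000) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (target_fs > rec$fs)
    stop("upsampling not supported: recording at ", rec$fs,
         " Hz, target ", target_fs, " Hz")
  if (target_fs == rec$fs) return(rec)
  n <- ncol(rec$samples)
  new_n <- round(n * target_fs / rec$fs)
  # anti-alias at 90% of the target Nyquist
  cutoff <- 0.9 * (target_fs / 2) / (rec$fs / 2)
  h <- signal::fir1(64, cutoff, type = "low")
  t_old <- (seq_len(n) - 1) / rec$fs
  t_new <- (seq_len(new_n) - 1) / target_fs
  out <- map_channels(rec, function(x) {
    xf <- signal::filtfilt(h, x)
    stats::spline(t_old, xf, xout = t_new, method = "fmm")$y
  })
  out$fs <- target_fs
  out
}

#' Suppress power-line noise
#'
#' Least-squares regression of sine/cosine components at the line frequency
#' and its harmonics, fitted and subtracted independently in successive
#' chunks so slow drifts of line amplitude/phase are tracked. Narrowband
#' suppression with broadband preservation: only 2 degrees of freedom per
#' harmonic per chunk are removed.
#'
#' @param rec A [continuous_recording()].
#' @param line_freq Line frequency, Hz (default 60).
#' @param n_harmonics Number of harmonics to remove (those below Nyquist).
#' @param chunk_s Chunk length in seconds for the piecewise fit; longer
#'   chunks absorb less broadband energy (2 degrees of freedom per harmonic
#'   per chunk), shorter chunks track amplitude/phase drift better.
#' @return The denoised recording.
#' @export
remove_line_noise <- function(rec, line_freq = 60, n_harmonics = 1,
                              chunk_s = 30) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (line_freq >= rec$fs / 2) stop("line_freq must be below Nyquist")
  freqs <- line_freq * seq_len(n_harmonics)
  freqs <- freqs[freqs < rec$fs / 2]
  if (!length(freqs)) return(rec)
  n <- ncol(rec$samples)
  chunk_n <- max(round(chunk_s * rec$fs), 2 * rec$fs / line_freq)
  starts <- seq(1, n, by = chunk_n)
  map_channels(rec, function(x) {
    for (s in starts) {
      e <- min(s + chunk_n - 1, n)
      if (e - s + 1 < 4 * length(freqs)) next
      idx <- s:e
      tt <- (idx - 1) / rec$fs
      X <- do.call(cbind, lapply(freqs, function(f)
        cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))))
      beta <- solve(crossprod(X), crossprod(X, x[idx]))
      x[idx] <- x[idx] - drop(X %*% beta)
    }
    x
  })
}

#' Bandpass filter into the high-gamma band
#'
#' 300th-order FIR (Hamming window design), 70-150 Hz passband, applied
#' forward-backward for a zero-phase-equivalent result so cluster onset
#' latencies are not delayed by the filter.
#'
#' @param rec A [continuous_recording()] at 1000 Hz (the filter order is
#'   rate-specific).
#' @param band Passband edges, Hz.
#' @param order FIR filter order.
#' @param zero_phase Forward-backward application (default); set `FALSE` for
#'   a single pass with group-delay compensation.
#' @return The band-filtered recording.
#' @export
bandpass_high_gamma <- function(rec, band = c(70, 150), order = 300,
                                zero_phase = TRUE) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (rec$fs != 1000)
    stop("bandpass_high_gamma expects the 1000 Hz analysis rate (got ",
         rec$fs, " Hz); resample first")
  h <- signal::fir1(order, band / (rec$fs / 2), type = "pass")
  map_channels(rec, function(x) {
    if (zero_phase) {
      signal::filtfilt(h, x)
    } else {
      y <- signal::filter(h, c(x, numeric(order / 2)))
      as.numeric(y)[-(seq_len(order / 2))]
    }
  })
}

# Sample index (1-based) of time t ms at rate fs: floor(t * fs / 1000) + 1.
ms_to_sample <- function(t_ms, fs) floor(t_ms * fs / 1000) + 1L

#' Flag trials containing artifacts
#'
#' The across-block mean and SD of the band-filtered voltage are computed
#' once per site over the full block; a trial is flagged iff any sample in
#' its epoch window deviates from the block mean by more than `k` SD.
#'
#' @param x Band-filtered voltage series for one site (numeric vector).
#' @param events Events data frame ([build_block()]).
#' @param fs Sampling rate of `x`, Hz.
#' @param k SD multiplier (default 5); `Inf` disables flagging.
#' @param window Epoch window in ms relative to the 5th-vowel onset,
#'   half-open `[start, end)`.
#' @return Logical vector, one entry per events row.
#' @export
detect_artifact_trials <- function(x, events, fs, k = 5,
                                   window = c(-600, 800)) {
  if (!length(x)) stop("empty block: no samples to screen")
  m <- mean(x)
  s <- stats::sd(x)
  thr <- k * s
  vapply(seq_len(nrow(events)), function(i) {
    i0 <- ms_to_sample(events$fifth_vowel_onset_ms[i] + window[1], fs)
    i1 <- ms_to_sample(events$fifth_vowel_onset_ms[i] + window[2], fs) - 1L
    i0 <- max(i0, 1L)
    i1 <- min(i1, length(x))
    if (i1 < i0) return(FALSE)
    any(abs(x[i0:i1] - m) > thr)
  }, logical(1))
}

#' High-gamma power envelope
#'
#' Squares the band-filtered voltage and smooths with a centered running
#' average (50 ms default). Output is non-negative power in uV^2.
#'
#' @param x Band-filtered voltage series.
#' @param fs Sampling rate, Hz.
#' @param smooth_ms Running-average window, ms.
#' @return Power series, same length as `x`.
#' @export
power_envelope <- function(x, fs, smooth_ms = 50) {
  w <- round(smooth_ms * fs / 1000)
  if (w < 1) stop("smoothing window of ", smooth_ms,
                  " ms is shorter than one sample at ", fs, " Hz")
  running_mean(x^2, w)
}

#' Trial-epoched power container
#'
#' @param power Trials x time matrix of non-negative power (uV^2).
#' @param time_ms Time axis in ms relative to the 5th-vowel onset.
#' @param condition Per-trial condition labels.
#' @param artifact Per-trial logical artifact mask.
#' @param site Site (channel) name.
#' @param fs Sampling rate of the time axis.
#' @return A `power_epochs` object.
#' @export
power_epochs <- function(power, time_ms, condition, artifact, site = "site",
                         fs = 1000) {
  stopifnot(is.matrix(power), ncol(power) == length(time_ms),
            nrow(power) == length(condition),
            nrow(power) == length(artifact))
  structure(list(power = power, time_ms = as.numeric(time_ms),
                 condition = as.character(condition),
                 artifact = as.logical(artifact),
                 site = site, fs = fs),
            class = "power_epochs")
}

#' @export
print.power_epochs <- function(x, ...) {
  cat("<power_epochs '", x$site, "': ", nrow(x$power), " trials x ",
      ncol(x$power), " samples, ", sum(x$artifact), " masked; ",
      paste(sprintf("%s=%d", CONDITION_LEVELS,
                    vapply(CONDITION_LEVELS,
                           function(cc) sum(x$condition == cc), integer(1))),
            collapse = " "), ">\n", sep = "")
  invisible(x)
}

#' Epoch a power series around the 5th-vowel onsets
#'
#' One row per test trial (habituation trials are excluded); `t = 0` is the
#' 5th-vowel onset. Windows are half-open `[start, end)`.
#'
#' @param power Power series for one site.
#' @param events Events data frame.
#' @param fs Sampling rate, Hz.
#' @param window Epoch window, ms.
#' @param artifact Optional per-events-row artifact mask
#'   ([detect_artifact_trials()]).
#' @param site Site label.
#' @return A [power_epochs()] object.
#' @export
epoch_power <- function(power, events, fs, window = c(-600, 800),
                        artifact = NULL, site = "site") {
  if (is.null(artifact)) artifact <- rep(FALSE, nrow(events))
  stopifnot(length(artifact) == nrow(events))
  test <- which(!events$is_habituation)
  n_samp <- round((window[2] - window[1]) * fs / 1000)
  out <- matrix(NA_real_, length(test), n_samp)
  for (j in seq_along(test)) {
    i <- test[j]
    i0 <- ms_to_sample(events$fifth_vowel_onset_ms[i] + window[1], fs)
    i1 <- i0 + n_samp - 1L
    if (i0 < 1 || i1 > length(power))
      stop("epoch window of trial ", events$trial_index[i],
           " exceeds the recording bounds")
    out[j, ] <- power[i0:i1]
  }
  power_epochs(out,
               time_ms = window[1] + (seq_len(n_samp) - 1) * 1000 / fs,
               condition = events$condition[test],
               artifact = artifact[test], site = site, fs = fs)
}

#' Full preprocessing chain for one site
#'
#' Line-noise removal, high-gamma bandpass, artifact flagging, power
#' envelope, epoching. The recording must already be at the analysis rate
#' (see [resample_to_analysis_rate()]).
#'
#' @param rec A [continuous_recording()] at 1000 Hz.
#' @param events Events data frame.
#' @param channel Channel name or index.
#' @param line_freq,n_harmonics See [remove_line_noise()]; `line_freq = NULL`
#'   skips denoising.
#' @param band,filter_order See [bandpass_high_gamma()].
#' @param artifact_k See [detect_artifact_trials()].
#' @param smooth_ms See [power_envelope()].
#' @param window Epoch window, ms.
#' @return A [power_epochs()] object.
#' @export
preprocess_site <- function(rec, events, channel = 1, line_freq = 60,
                            n_harmonics = 1, band = c(70, 150),
                            filter_order = 300, artifact_k = 5,
                            smooth_ms = 50, window = c(-600, 800)) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (is.character(channel)) channel <- match(channel, rec$channel_names)
  if (is.na(channel) || channel < 1 || channel > nrow(rec$samples))
    stop("unknown channel")
  one <- continuous_recording(rec$samples[channel, , drop = FALSE], rec$fs,
                              rec$channel_names[channel])
  if (!is.null(line_freq))
    one <- remove_line_noise(one, line_freq, n_harmonics)
  filt <- bandpass_high_gamma(one, band = band, order = filter_order)
  xf <- filt$samples[1, ]
  mask <- detect_artifact_trials(xf, events, rec$fs, k = artifact_k,
                                 window = window)
  pw <- power_envelope(xf, rec$fs, smooth_ms = smooth_ms)
  epoch_power(pw, events, rec$fs, window = window, artifact = mask,
              site = rec$channel_names[channel])
}

#' Persist / load a recording as a plain-text container
#'
#' Writes `<prefix>_meta.json` (rate, channel names) and
#' `<prefix>_samples.tsv` (one column per channel). A simple, portable
#' text container for continuous recordings.
#'
#' @param rec A [continuous_recording()].
#' @param prefix Path prefix for the two files.
#' @return `read_recording` returns a [continuous_recording()].
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "continuous_recording"))
  jsonlite::write_json(list(fs = rec$fs, channel_names = rec$channel_names,
                            n_samples = ncol(rec$samples), unit = "uV"),
                       paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  m <- t(rec$samples)
  colnames(m) <- rec$channel_names
  utils::write.table(m, paste0(prefix, "_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  m <- as.matrix(utils::read.delim(paste0(prefix, "_samples.tsv")))
  continuous_recording(t(m), meta$fs, meta$channel_names)
}

#' Persist / load trial-epoched power
#'
#' Writes `<prefix>_power.tsv` (trials x time) and `<prefix>_meta.json`
#' (time axis, conditions, artifact mask, site).
#'
#' @param epochs A [power_epochs()] object.
#' @param prefix Path prefix.
#' @return `read_power_epochs` returns a [power_epochs()] object.
#' @export
write_power_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "power_epochs"))
  jsonlite::write_json(list(time_ms = epochs$time_ms,
                            condition = epochs$condition,
                            artifact = epochs$artifact,
                            site = epochs$site, fs = epochs$fs),
                       paste0(prefix, "_meta.json"), digits = NA,
                       auto_unbox = TRUE)
  utils::write.table(epochs$power, paste0(prefix, "_power.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_power_epochs
#' @export
read_power_epochs <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  pw <- as.matrix(utils::read.delim(paste0(prefix, "_power.tsv"),
                                    header = FALSE))
  dimnames(pw) <- NULL
  power_epochs(pw, meta$time_ms, meta$condition, meta$artifact, meta$site,
               meta$fs)
}
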