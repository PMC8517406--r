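# Synthetic continuous iEEG and behavior with known injected effects.
#
# The generator is the ground-truth-bearing stand-in for raw recordings:
# 1/f background + 60 Hz line noise + vowel-locked high-gamma bursts whose
# 5th-vowel response carries the condition gains and, for the designated
# condition, an additive power increment that creates a local-by-global
# interaction of known sign, onset and amplitude.

#' Per-site effect specification for the simulator
#'
#' Defaults put the gamma-burst amplitude at roughly the band-limited
#' background level (a realistic evoked high-gamma SNR for responsive
#' cortical sites), with modest local- and global-deviance gains, so that
#' ordinary responses stay well inside the 5 SD artifact criterion.
#'
#' @param base_amplitude Gamma-burst amplitude (uV) for the LSGS condition.
#' @param ld_gain,gd_gain Multiplicative amplitude gains applied to the
#'   5th-vowel burst on local-deviant / global-deviant trials.
#' @param interaction_amp Signed power increment (uV^2) added to the smoothed
#'   high-gamma envelope of LDGD trials (if positive) or LSGD trials (if
#'   negative) over the effect window; 0 disables the interaction.
#' @param effect_onset,effect_duration Interaction window relative to the
#'   5th-vowel onset, ms.
#' @param noise_sd Broadband (pink) background SD, uV.
#' @param line_amp 60 Hz line-noise amplitude, uV.
#' @param arousal_scale Named multipliers in `[0, 1]` per arousal state,
#'   applied to the deviance gains (above 1) and the interaction amplitude;
#'   defaults emulate progressive attenuation from awake to unresponsive.
#' @param artifact_rate Fraction of trials receiving a high-amplitude
#'   transient (to exercise artifact rejection); default 0 here, 0.01 in the
#'   bundled demo config.
#' @param name Site label.
#' @return A `site_effect_spec` object.
#' @export
site_effect_spec <- function(base_amplitude = 1, ld_gain = 1.3, gd_gain = 1.2,
                             interaction_amp = 0, effect_onset = 150,
                             effect_duration = 200, noise_sd = 3,
                             line_amp = 2,
                             arousal_scale = c(W = 1, S = 0.4, U = 0.1),
                             artifact_rate = 0, name = "site01") {
  stopifnot(base_amplitude >= 0, effect_duration > 0, noise_sd >= 0,
            all(arousal_scale >= 0 & arousal_scale <= 1),
            all(c("W", "S", "U") %in% names(arousal_scale)))
  structure(list(base_amplitude = base_amplitude, ld_gain = ld_gain,
                 gd_gain = gd_gain, interaction_amp = interaction_amp,
                 effect_onset = effect_onset,
                 effect_duration = effect_duration, noise_sd = noise_sd,
                 line_amp = line_amp, arousal_scale = arousal_scale,
                 artifact_rate = artifact_rate, name = name),
            class = "site_effect_spec")
}

#' Behavioral response specification for the simulator
#'
#' Defaults reflect the double-surprise advantage of the LDGD target over
#' LSGD seen in awake subjects: higher hit probability and the grand median
#' reaction times of 420 ms (LDGD) versus 516 ms (LSGD).
#'
#' @param hit_prob Named hit probabilities for the two target conditions.
#' @param fa_rate Probability of a false-alarm press per non-target trial.
#' @param rt_mean Named mean reaction times, ms.
#' @param rt_sd Reaction-time SD, ms.
#' @param rt_floor Minimum physiologically plausible reaction time, ms.
#' @return A `behavior_spec` object.
#' @export
behavior_spec <- function(hit_prob = c(LSGD = 0.60, LDGD = 0.85),
                          fa_rate = 0.02,
                          rt_mean = c(LSGD = 516, LDGD = 420),
                          rt_sd = 120, rt_floor = 150) {
  stopifnot(all(hit_prob >= 0 & hit_prob <= 1), fa_rate >= 0, fa_rate <= 1,
            all(rt_mean > rt_floor), rt_floor > 0,
            all(c("LSGD", "LDGD") %in% names(hit_prob)),
            all(c("LSGD", "LDGD") %in% names(rt_mean)))
  structure(list(hit_prob = hit_prob, fa_rate = fa_rate, rt_mean = rt_mean,
                 rt_sd = rt_sd, rt_floor = rt_floor),
            class = "behavior_spec")
}

#' Pink (1/f) noise by spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain so power falls as
#' 1/f^exponent, then rescaled to the requested SD.
#'
#' @param n Number of samples.
#' @param sd Target standard deviation.
#' @param exponent Spectral power exponent (default 1).
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, sd = 1, exponent = 1) {
  if (n < 2) return(rnorm(n, 0, sd))
  # pad to a highly composite FFT length, truncate after shaping
  m <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(m)
  spec <- stats::fft(w)
  # frequency index per FFT bin (two-sided); DC removed
  k <- c(0, seq_len(m - 1))
  k <- pmin(k, m - k)
  scale <- c(0, k[-1]^(-exponent / 2))
  x <- Re(stats::fft(spec * scale, inverse = TRUE))[seq_len(n)] / m
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (sd / s)
  x
}

# Raised-cosine (Hann) envelope of length n samples.
hann_env <- function(n) {
  if (n <= 1) return(rep(1, n))
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

# Plateau envelope with raised-cosine ramps (ramp_n samples each side).
plateau_env <- function(n, ramp_n) {
  env <- rep(1, n)
  ramp_n <- min(ramp_n, floor(n / 2))
  if (ramp_n > 0) {
    r <- 0.5 * (1 - cos(pi * (seq_len(ramp_n)) / (ramp_n + 1)))
    env[seq_len(ramp_n)] <- r
    env[n + 1 - seq_len(ramp_n)] <- rev(r)
  }
  env
}

BURST_CARRIER_HZ <- 110   # main vowel-burst carrier, center of 70-150 Hz band
INTERACTION_CARRIER_HZ <- 130  # interaction carrier; the 20 Hz beat against
                               # the 110 Hz carrier is nulled exactly by the
                               # 50 ms running-average window

# Effective per-trial amplitude of the 5th-vowel burst and the interaction
# power increment, after arousal scaling.
effective_site_params <- function(spec, state) {
  sc <- spec$arousal_scale[[state]]
  list(ld_gain = 1 + sc * (spec$ld_gain - 1),
       gd_gain = 1 + sc * (spec$gd_gain - 1),
       interaction_amp = sc * spec$interaction_amp)
}

#' Simulate a continuous multichannel recording for a block schedule
#'
#' Per site, the signal is pink background noise plus a 60 Hz line component
#' plus one gamma-band burst per vowel. Only the 5th-vowel burst is
#' condition-modulated: its amplitude is multiplied by `ld_gain` on
#' local-deviant trials and `gd_gain` on global-deviant trials, and for the
#' interaction-designated condition an additional band-limited component is
#' added whose smoothed power equals `abs(interaction_amp)` over the effect
#' window. All deviance effects are attenuated by `arousal_scale[state]`.
#'
#' @param schedule Events data frame from [build_block()].
#' @param sites List of [site_effect_spec()] objects (or a single one).
#' @param fs Sampling rate, Hz (>= 1000; must exceed twice the 150 Hz band
#'   edge).
#' @param pad_ms Extra signal simulated after the final trial.
#' @param seed Optional integer seed (bit-reproducible output).
#' @return List with `recording` (a [continuous_recording()]), `events`
#'   (the schedule), and `ground_truth` (one entry per site recording every
#'   injected effect: sign, onset, amplitude, artifact trials).
#' @export
simulate_recording <- function(schedule, sites, fs = 1000, pad_ms = 2000,
                               seed = NULL) {
  if (inherits(sites, "site_effect_spec")) sites <- list(sites)
  if (fs < 2 * 150) stop("fs = ", fs, " Hz would alias the 70-150 Hz band")
  if (fs < 1000) stop("fs must be >= 1000 Hz")
  if (nrow(schedule) == 0) stop("empty schedule")
  set_seed_if_given(seed)
  n <- ceiling((max(schedule$onset_ms) + FIFTH_VOWEL_OFFSET_MS +
                  VOWEL_DURATION_MS + pad_ms) * fs / 1000)
  tvec <- (seq_len(n) - 1) / fs
  state <- schedule$arousal_state[1]
  burst_n <- round(VOWEL_DURATION_MS * fs / 1000)
  burst_env <- hann_env(burst_n)
  burst_t <- (seq_len(burst_n) - 1) / fs
  x <- matrix(0, nrow = length(sites), ncol = n)
  gt <- vector("list", length(sites))
  for (s in seq_along(sites)) {
    spec <- sites[[s]]
    eff <- effective_site_params(spec, state)
    sig <- pink_noise(n, sd = spec$noise_sd)
    if (spec$line_amp > 0) {
      phi <- runif(1, 0, 2 * pi)
      sig <- sig + spec$line_amp * sin(2 * pi * 60 * tvec + phi)
    }
    int_n <- round(spec$effect_duration * fs / 1000)
    int_env <- plateau_env(int_n, ramp_n = round(0.02 * fs))
    int_t <- (seq_len(int_n) - 1) / fs
    int_cond <- if (eff$interaction_amp > 0) "LDGD"
                else if (eff$interaction_amp < 0) "LSGD" else NA_character_
    artifact_trials <- integer(0)
    for (i in seq_len(nrow(schedule))) {
      onsets <- vowel_onsets(schedule$onset_ms[i])
      cond <- schedule$condition[i]
      amp5 <- spec$base_amplitude
      if (substr(cond, 1, 2) == "LD") amp5 <- amp5 * eff$ld_gain
      if (substr(cond, 3, 4) == "GD") amp5 <- amp5 * eff$gd_gain
      for (v in 1:5) {
        i0 <- floor(onsets[v] * fs / 1000) + 1
        if (i0 + burst_n - 1 > n) next
        a <- if (v == 5) amp5 else spec$base_amplitude
        idx <- i0:(i0 + burst_n - 1)
        sig[idx] <- sig[idx] + a * burst_env *
          sin(2 * pi * BURST_CARRIER_HZ * (burst_t + onsets[v] / 1000))
      }
      if (!is.na(int_cond) && cond == int_cond) {
        t0 <- onsets[5] + spec$effect_onset
        i0 <- floor(t0 * fs / 1000) + 1
        if (i0 + int_n - 1 <= n) {
          idx <- i0:(i0 + int_n - 1)
          # amplitude sqrt(2*P) yields smoothed power P in the plateau
          sig[idx] <- sig[idx] + sqrt(2 * abs(eff$interaction_amp)) * int_env *
            sin(2 * pi * INTERACTION_CARRIER_HZ * (int_t + t0 / 1000))
        }
      }
      if (spec$artifact_rate > 0 && runif(1) < spec$artifact_rate) {
        art_n <- round(0.010 * fs)
        off <- runif(1, 0, 0.6)
        i0 <- floor((onsets[5] + off * 1000) * fs / 1000) + 1
        if (i0 + art_n - 1 <= n) {
          idx <- i0:(i0 + art_n - 1)
          sig[idx] <- sig[idx] + 30 * max(spec$noise_sd, 0.1) * hann_env(art_n) *
            sin(2 * pi * BURST_CARRIER_HZ * (seq_len(art_n) - 1) / fs)
          artifact_trials <- c(artifact_trials, schedule$trial_index[i])
        }
      }
    }
    x[s, ] <- sig
    gt[[s]] <- list(
      site = spec$name, state = state,
      interaction_sign = if (is.na(int_cond)) "none"
                         else if (int_cond == "LDGD") "positive" else "negative",
      interaction_condition = int_cond,
      interaction_amp = eff$interaction_amp,
      effect_onset_ms = spec$effect_onset,
      effect_duration_ms = spec$effect_duration,
      ld_gain = eff$ld_gain, gd_gain = eff$gd_gain,
      base_amplitude = spec$base_amplitude, noise_sd = spec$noise_sd,
      line_amp = spec$line_amp,
      artifact_trials = artifact_trials
    )
  }
  rec <- continuous_recording(x, fs,
                              vapply(sites, `[[`, character(1), "name"))
  list(recording = rec, events = schedule, ground_truth = gt)
}

#' Simulate button presses for a block
#'
#' Each target (GD) trial is pressed with the condition's hit probability at
#' `5th-vowel onset + max(rt_floor, Normal(rt_mean, rt_sd))`; each non-target
#' trial receives a false-alarm press with probability `fa_rate` at a uniform
#' time within the trial.
#'
#' @param schedule Events data frame from [build_block()].
#' @param spec A [behavior_spec()].
#' @param seed Optional seed.
#' @return The schedule with `press_times_ms` filled in.
#' @export
simulate_behavior <- function(schedule, spec = behavior_spec(), seed = NULL) {
  stopifnot(inherits(spec, "behavior_spec"))
  set_seed_if_given(seed)
  presses <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    if (schedule$is_target[i]) {
      cond <- schedule$condition[i]
      if (runif(1) < spec$hit_prob[[cond]]) {
        rt <- max(spec$rt_floor, rnorm(1, spec$rt_mean[[cond]], spec$rt_sd))
        presses[[i]] <- schedule$fifth_vowel_onset_ms[i] + rt
      } else presses[[i]] <- numeric(0)
    } else {
      if (runif(1) < spec$fa_rate) {
        presses[[i]] <- schedule$onset_ms[i] + runif(1, 0, 1500)
      } else presses[[i]] <- numeric(0)
    }
  }
  schedule$press_times_ms <- format_press_times(presses)
  schedule
}

#' Fast null power epochs for permutation-test calibration
#'
#' Generates trial-wise high-gamma-power-like epochs with no condition
#' effect: each trial is a running-average-smoothed squared white-noise
#' series, reproducing the temporal autocorrelation the 50 ms smoother
#' imposes on real envelopes, without simulating a continuous recording.
#' Trials are exchangeable across the four condition labels by construction,
#' which is exactly the null hypothesis of the cluster permutation test.
#'
#' @param n_per_condition Trials per condition.
#' @param window Epoch window in ms relative to the 5th-vowel onset.
#' @param fs Sampling rate of the epoch time axis.
#' @param smooth_ms Running-average window, ms.
#' @param seed Optional seed.
#' @param site Site label.
#' @return A `power_epochs` object.
#' @export
simulate_null_epochs <- function(n_per_condition = 40, window = c(-600, 800),
                                 fs = 1000, smooth_ms = 50, seed = NULL,
                                 site = "null_site") {
  set_seed_if_given(seed)
  n_trials <- 4L * n_per_condition
  n_samp <- round((window[2] - window[1]) * fs / 1000)
  pw <- matrix(0, n_trials, n_samp)
  for (i in seq_len(n_trials)) {
    pw[i, ] <- running_mean(rnorm(n_samp)^2,
                            max(1L, round(smooth_ms * fs / 1000)))
  }
  power_epochs(pw,
               time_ms = window[1] + (seq_len(n_samp) - 1) * 1000 / fs,
               condition = rep(CONDITION_LEVELS, each = n_per_condition),
               artifact = rep(FALSE, n_trials), site = site, fs = fs)
}

#' Noise floor of the power envelope
#'
#' The standard deviation of the high-gamma power envelope over the
#' pre-stimulus baseline window, pooled across trials and time points: the
#' measurement noise against which injected interaction amplitudes are
#' scaled.
#'
#' @param epochs A [power_epochs()] object.
#' @param baseline_window Window in ms (default `[-600, 0)`).
#' @return Scalar SD, uV^2.
#' @export
power_noise_floor <- function(epochs, baseline_window = c(-600, 0)) {
  cols <- epochs$time_ms >= baseline_window[1] &
    epochs$time_ms < baseline_window[2]
  stats::sd(as.vector(epochs$power[!epochs$artifact, cols]))
}

#' Write the simulator's ground-truth sidecar
#'
#' Records every injected effect (site, sign, onset, amplitude, artifact
#' trials) so parameter-recovery tests can compare analysis output to truth.
#'
#' @param ground_truth The `ground_truth` element of [simulate_recording()].
#' @param path Output JSON path.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
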