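# Scoring of button presses against the schedule, signal-detection metrics
# (hit rate, d-prime), and the nonparametric group tests comparing the two
# target conditions.

#' Score button presses against a block schedule
#'
#' A press counts as a hit when it falls between the 5th-vowel onset of a
#' target trial and the onset of the following trial; a press within a
#' non-target trial's span is a false alarm on that trial. Unpressed targets
#' are misses; unpressed non-targets are correct rejections. Each press is
#' assigned to at most one trial; a press on a target trial before its
#' 5th-vowel onset cannot be a hit and is ignored. Habituation trials are
#' scored like other non-targets.
#'
#' @param events Events data frame with `press_times_ms` filled (see
#'   [simulate_behavior()] or [read_events_tsv()]).
#' @param presses Optional list of numeric press-time vectors (one per
#'   trial) overriding the `press_times_ms` column.
#' @return Data frame of trial outcomes: `trial_index`, `condition`,
#'   `category` (hit / miss / false_alarm / correct_rejection), `rt_ms`
#'   (hits only, else `NA`).
#' @export
score_presses <- function(events, presses = NULL) {
  if (is.null(presses)) presses <- parse_press_times(events$press_times_ms)
  stopifnot(length(presses) == nrow(events))
  all_presses <- unlist(presses)
  if (length(all_presses) && any(all_presses < 0))
    stop("press time before block start")
  n <- nrow(events)
  span_end <- c(events$onset_ms[-1], events$onset_ms[n] + 1500)
  category <- character(n)
  rt <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- sort(presses[[i]])
    p <- p[p >= events$onset_ms[i] & p < span_end[i]]
    if (events$is_target[i]) {
      hits <- p[p > events$fifth_vowel_onset_ms[i]]
      if (length(hits)) {
        category[i] <- "hit"
        rt[i] <- hits[1] - events$fifth_vowel_onset_ms[i]
      } else {
        category[i] <- "miss"
      }
    } else {
      category[i] <- if (length(p)) "false_alarm" else "correct_rejection"
    }
  }
  data.frame(trial_index = events$trial_index, condition = events$condition,
             is_habituation = events$is_habituation,
             category = category, rt_ms = rt, stringsAsFactors = FALSE)
}

#' Signal-detection sensitivity d-prime
#'
#' `d' = Z(hit rate) - Z(false-alarm rate)` with `Z` the standard normal
#' quantile function. Rates of exactly 0 or 1 are replaced by `1/(2n)` and
#' `1 - 1/(2n)` before the transform when `correct_extremes = TRUE`
#' (otherwise an extreme rate yields `NA` with a flag, so blocks without
#' hits can be reported descriptively instead of numerically).
#'
#' @param hit_rate,fa_rate Observed rates in `[0, 1]`.
#' @param n_targets,n_nontargets Trial counts behind the two rates.
#' @param correct_extremes Apply the `1/(2n)` correction (default TRUE).
#' @return d-prime value (`NA` with attribute `undefined = TRUE` when not
#'   computable).
#' @export
dprime <- function(hit_rate, fa_rate, n_targets, n_nontargets,
                   correct_extremes = TRUE) {
  if (n_targets <= 0 || n_nontargets <= 0)
    return(structure(NA_real_, undefined = TRUE))
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  clamp <- function(r, n) {
    if (r <= 0) 1 / (2 * n) else if (r >= 1) 1 - 1 / (2 * n) else r
  }
  if (correct_extremes) {
    hit_rate <- clamp(hit_rate, n_targets)
    fa_rate <- clamp(fa_rate, n_nontargets)
  } else if (hit_rate %in% c(0, 1) || fa_rate %in% c(0, 1)) {
    return(structure(NA_real_, undefined = TRUE))
  }
  qnorm(hit_rate) - qnorm(fa_rate)
}

#' Per-condition behavioral summary for a block
#'
#' Hit rate, d-prime and the reaction-time collection per target condition
#' (LSGD, LDGD). The false-alarm rate is computed over all non-target
#' trials of the block and shared by both conditions' d-prime.
#'
#' @param outcomes Result of [score_presses()].
#' @param block Block label carried into the output.
#' @param correct_extremes See [dprime()].
#' @return A `behavioral_summary` object: data frame `summary` (one row
#'   per condition) and `rts` (named list of hit RTs per condition).
#' @export
behavioral_summary <- function(outcomes, block = 1L,
                               correct_extremes = TRUE) {
  nontarget <- outcomes$category %in% c("false_alarm", "correct_rejection")
  n_nt <- sum(nontarget)
  n_fa <- sum(outcomes$category == "false_alarm")
  fa_rate <- if (n_nt > 0) n_fa / n_nt else NA_real_
  rows <- lapply(c("LSGD", "LDGD"), function(cc) {
    tgt <- outcomes$condition == cc &
      outcomes$category %in% c("hit", "miss")
    n_t <- sum(tgt)
    n_hit <- sum(outcomes$category[tgt] == "hit")
    hr <- if (n_t > 0) n_hit / n_t else NA_real_
    dp <- if (n_t > 0) dprime(hr, fa_rate, n_t, n_nt, correct_extremes)
          else structure(NA_real_, undefined = TRUE)
    data.frame(block = block, condition = cc, n_targets = n_t,
               n_hits = n_hit, hit_rate = hr, n_fa = n_fa,
               n_nontargets = n_nt, fa_rate = fa_rate,
               d_prime = as.numeric(dp),
               d_prime_undefined = isTRUE(attr(dp, "undefined")),
               stringsAsFactors = FALSE)
  })
  rts <- lapply(c(LSGD = "LSGD", LDGD = "LDGD"), function(cc)
    outcomes$rt_ms[outcomes$condition == cc & outcomes$category == "hit"])
  structure(list(summary = do.call(rbind, rows), rts = rts, block = block),
            class = "behavioral_summary")
}

#' Group-level behavioral tests
#'
#' One-tailed Wilcoxon signed-rank tests across subjects for hit rate and
#' d-prime (alternative: LDGD > LSGD), per-subject two-sided Wilcoxon
#' rank-sum tests on hit reaction times, and Benjamini-Hochberg adjustment
#' across the whole reported family.
#'
#' @param hit_lsgd,hit_ldgd Per-subject hit rates (paired vectors).
#' @param d_lsgd,d_ldgd Per-subject d-prime values (paired vectors).
#' @param rts Optional named list, one element per subject, each a list
#'   with numeric `LSGD` and `LDGD` RT vectors.
#' @return A data frame: `test`, `subject`, `statistic`, `p`, `p_adj`,
#'   `note`.
#' @export
group_tests <- function(hit_lsgd, hit_ldgd, d_lsgd, d_ldgd, rts = NULL) {
  stopifnot(length(hit_lsgd) == length(hit_ldgd),
            length(d_lsgd) == length(d_ldgd))
  if (length(hit_lsgd) < 2) stop("need >= 2 subjects for signed-rank tests")
  one_sided <- function(a, b, label) {
    note <- ""
    d <- b - a
    if (all(d == 0)) note <- "all differences tied; exact method degenerate"
    w <- suppressWarnings(
      stats::wilcox.test(b, a, paired = TRUE, alternative = "greater",
                         exact = TRUE))
    data.frame(test = label, subject = NA_character_,
               statistic = unname(w$statistic), p = w$p.value, note = note,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_sided(hit_lsgd, hit_ldgd, "hit_rate_signed_rank"),
               one_sided(d_lsgd, d_ldgd, "d_prime_signed_rank"))
  if (!is.null(rts)) {
    for (subj in names(rts)) {
      a <- rts[[subj]]$LSGD
      b <- rts[[subj]]$LDGD
      if (!length(a) || !length(b)) {
        out <- rbind(out, data.frame(
          test = "rt_rank_sum", subject = subj, statistic = NA_real_,
          p = NA_real_, note = "empty RT sample; skipped",
          stringsAsFactors = FALSE))
        next
      }
      w <- suppressWarnings(stats::wilcox.test(a, b))
      out <- rbind(out, data.frame(
        test = "rt_rank_sum", subject = subj,
        statistic = unname(w$statistic), p = w$p.value, note = "",
        stringsAsFactors = FALSE))
    }
  }
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out[, c("test", "subject", "statistic", "p", "p_adj", "note")]
}
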