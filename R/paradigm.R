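#' @useDynLib lgdint, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif qnorm qt pt quantile median sd var setNames
#' @importFrom utils read.delim write.table
NULL

# Timing constants of the vowel-quintuple paradigm: 100 ms vowels gated with
# 5 ms ramps, 50 ms inter-vowel gaps, so the 5th vowel starts 600 ms after
# trial onset.
VOWEL_DURATION_MS <- 100
VOWEL_RAMP_MS <- 5
INTER_VOWEL_GAP_MS <- 50
FIFTH_VOWEL_OFFSET_MS <- 4L * (VOWEL_DURATION_MS + INTER_VOWEL_GAP_MS)

CONDITION_LEVELS <- c("LSGS", "LDGS", "LSGD", "LDGD")
AROUSAL_STATES <- c("W", "S", "U")

set_seed_if_given <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Construct a vowel quintuple
#'
#' A trial stimulus is five 100 ms vowels (/a/ or /i/) separated by 50 ms
#' gaps. The first four vowels are identical; the fifth either matches them
#' (local standard, LS) or differs (local deviant, LD).
#'
#' @param first Vowel of the first four positions, `"a"` or `"i"`.
#' @param fifth Fifth vowel, `"a"` or `"i"`.
#' @return A `quintuple` object with the vowel string and its local type.
#' @examples
#' quintuple("a", "i")  # /aaaai/, a local deviant
#' @export
quintuple <- function(first, fifth) {
  first <- match.arg(first, c("a", "i"))
  fifth <- match.arg(fifth, c("a", "i"))
  structure(
    list(
      vowels = c(rep(first, 4), fifth),
      vowel_string = paste0(paste(rep(first, 4), collapse = ""), fifth),
      local_type = if (identical(first, fifth)) "LS" else "LD",
      duration_ms = VOWEL_DURATION_MS,
      ramp_ms = VOWEL_RAMP_MS,
      gap_ms = INTER_VOWEL_GAP_MS
    ),
    class = "quintuple"
  )
}

quintuple_from_string <- function(s) {
  stopifnot(nchar(s) == 5)
  ch <- strsplit(s, "")[[1]]
  if (length(unique(ch[1:4])) != 1)
    stop("first four vowels of a quintuple must be identical: ", s)
  quintuple(ch[1], ch[5])
}

#' @export
print.quintuple <- function(x, ...) {
  cat("<quintuple /", x$vowel_string, "/ (", x$local_type, ")>\n", sep = "")
  invisible(x)
}

#' Define one stimulus sequence of the local/global paradigm
#'
#' A sequence establishes one quintuple as the frequent global standard (GS)
#' through a habituation run, then presents GS and the infrequent global
#' deviant (GD) test trials in pseudorandom order. GD trials are the task
#' targets.
#'
#' @param global_standard,global_deviant `quintuple` objects (or 5-character
#'   vowel strings); must differ, and exactly one of the two is a local
#'   standard.
#' @param n_habituation Habituation trials establishing the GS (default 10).
#' @param n_gs_test,n_gd_test Numbers of GS and GD test trials (defaults
#'   72 and 18; the extended variant uses 80 and 20).
#' @return A `sequence_spec` object.
#' @export
sequence_spec <- function(global_standard, global_deviant,
                          n_habituation = 10, n_gs_test = 72, n_gd_test = 18) {
  if (is.character(global_standard)) global_standard <- quintuple_from_string(global_standard)
  if (is.character(global_deviant)) global_deviant <- quintuple_from_string(global_deviant)
  if (identical(global_standard$vowel_string, global_deviant$vowel_string))
    stop("global standard and deviant must be different quintuples")
  if (n_habituation < 0 || n_gs_test <= 0 || n_gd_test < 0)
    stop("invalid sequence spec: counts must be positive (n_gd_test may be 0)")
  structure(
    list(global_standard = global_standard, global_deviant = global_deviant,
         n_habituation = as.integer(n_habituation),
         n_gs_test = as.integer(n_gs_test), n_gd_test = as.integer(n_gd_test)),
    class = "sequence_spec"
  )
}

#' The four canonical sequences of a block
#'
#' Pairs /aaaaa/ with /aaaai/ and /iiiii/ with /iiiia/, each quintuple serving
#' once as global standard and once as global deviant, so that across a block
#' every combination of local (LS/LD) and global (GS/GD) status occurs.
#'
#' @param variant `"standard"` (10 habituation + 72 GS + 18 GD per sequence)
#'   or `"extended"` (10 + 80 + 20).
#' @return List of four `sequence_spec` objects.
#' @export
lgd_sequences <- function(variant = c("standard", "extended")) {
  variant <- match.arg(variant)
  n_gs <- if (variant == "standard") 72L else 80L
  n_gd <- if (variant == "standard") 18L else 20L
  list(
    sequence_spec("aaaaa", "aaaai", 10L, n_gs, n_gd),
    sequence_spec("aaaai", "aaaaa", 10L, n_gs, n_gd),
    sequence_spec("iiiii", "iiiia", 10L, n_gs, n_gd),
    sequence_spec("iiiia", "iiiii", 10L, n_gs, n_gd)
  )
}

#' Label the condition of a quintuple within a sequence
#'
#' The local factor is LS when the 5th vowel equals the first four, LD
#' otherwise; the global factor is GS when the quintuple is the sequence's
#' frequent stimulus, GD when it is the infrequent one.
#'
#' @param q A `quintuple` or vowel string.
#' @param spec The `sequence_spec` the trial belongs to.
#' @return One of `"LSGS"`, `"LDGS"`, `"LSGD"`, `"LDGD"`.
#' @export
label_condition <- function(q, spec) {
  if (is.character(q)) q <- quintuple_from_string(q)
  g <- if (identical(q$vowel_string, spec$global_standard$vowel_string)) "GS"
       else if (identical(q$vowel_string, spec$global_deviant$vowel_string)) "GD"
       else stop("unknown stimulus /", q$vowel_string, "/ for this sequence")
  paste0(q$local_type, g)
}

#' Onsets of the five vowels within a trial
#'
#' @param onset_ms Trial onset (onset of the 1st vowel), ms.
#' @return Numeric vector of 5 vowel onsets: onset + c(0, 150, 300, 450, 600).
#' @export
vowel_onsets <- function(onset_ms) {
  onset_ms + (0:4) * (VOWEL_DURATION_MS + INTER_VOWEL_GAP_MS)
}

# Pseudorandom GS/GD test order. Default constraint: no two GD trials
# adjacent, drawn uniformly over valid arrangements by placing the GD trials
# into distinct gaps between (and around) the GS trials.
pseudorandom_order <- function(n_gs, n_gd, no_adjacent_gd = TRUE) {
  if (n_gd == 0) return(rep("GS", n_gs))
  if (!no_adjacent_gd) {
    return(sample(c(rep("GS", n_gs), rep("GD", n_gd))))
  }
  if (n_gd > n_gs + 1)
    stop("cannot place ", n_gd, " global deviants without adjacency among ",
         n_gs, " standards")
  gaps <- sort(sample.int(n_gs + 1L, n_gd))
  out <- character(n_gs + n_gd)
  pos <- gaps + seq_len(n_gd) - 1L  # account for previously inserted GDs
  out[pos] <- "GD"
  out[out == ""] <- "GS"
  out
}

#' Build the trial list of one sequence
#'
#' Generates habituation trials (all GS), then the GS/GD test trials in
#' pseudorandom order, with onset-to-onset intervals drawn from a Gaussian
#' (mean 1500 ms, SD 10 ms by default).
#'
#' @param spec A `sequence_spec`.
#' @param start_ms Onset of the first trial relative to block start.
#' @param iti_mean,iti_sd Gaussian onset-to-onset interval parameters, ms.
#' @param no_adjacent_gd Forbid adjacent GD test trials (default TRUE).
#' @param seed Optional integer seed for reproducible order/ITIs.
#' @return Data frame of trials: `onset_ms`, `vowel_string`, `condition`,
#'   `is_habituation`, `is_target`, `fifth_vowel_onset_ms`.
#' @export
build_sequence <- function(spec, start_ms = 0, iti_mean = 1500, iti_sd = 10,
                           no_adjacent_gd = TRUE, seed = NULL) {
  stopifnot(inherits(spec, "sequence_spec"))
  set_seed_if_given(seed)
  order <- c(rep("GS", spec$n_habituation),
             pseudorandom_order(spec$n_gs_test, spec$n_gd_test, no_adjacent_gd))
  n <- length(order)
  iti <- rnorm(n - 1, iti_mean, iti_sd)
  onsets <- round(start_ms + c(0, cumsum(iti)))
  q <- ifelse(order == "GS", spec$global_standard$vowel_string,
              spec$global_deviant$vowel_string)
  cond <- vapply(unique(q), function(s) label_condition(s, spec), character(1))
  data.frame(
    onset_ms = onsets,
    vowel_string = q,
    condition = unname(cond[q]),
    is_habituation = seq_len(n) <= spec$n_habituation,
    is_target = order == "GD",
    fifth_vowel_onset_ms = onsets + FIFTH_VOWEL_OFFSET_MS,
    stringsAsFactors = FALSE
  )
}

#' Build a block schedule
#'
#' A block is four sequences presented in randomized order, each preceded by
#' an instruction/gap period. Returns the events table used by every
#' downstream stage.
#'
#' @param specs List of `sequence_spec`s (default [lgd_sequences()]).
#' @param arousal_state One of `"W"` (awake), `"S"` (sedated), `"U"`
#'   (unresponsive); carried as a label, it does not alter the schedule.
#' @param block_index Integer block label.
#' @param start_gap_ms Silent gap before the first trial of each sequence
#'   (stands in for the recorded instruction; default 4000 ms).
#' @param iti_mean,iti_sd,no_adjacent_gd See [build_sequence()].
#' @param randomize_order Randomize sequence order within the block.
#' @param seed Optional seed.
#' @return Data frame with one row per trial: `trial_index`,
#'   `sequence_index`, `block_index`, `onset_ms`, `vowel_string`,
#'   `condition`, `is_habituation`, `is_target`, `fifth_vowel_onset_ms`,
#'   `press_times_ms` (empty; filled by behavior simulation or ingest),
#'   `arousal_state`.
#' @export
build_block <- function(specs = lgd_sequences(), arousal_state = "W",
                        block_index = 1L, start_gap_ms = 4000,
                        iti_mean = 1500, iti_sd = 10, no_adjacent_gd = TRUE,
                        randomize_order = TRUE, seed = NULL) {
  arousal_state <- match.arg(arousal_state, AROUSAL_STATES)
  set_seed_if_given(seed)
  ord <- if (randomize_order) sample(seq_along(specs)) else seq_along(specs)
  t0 <- start_gap_ms
  parts <- vector("list", length(specs))
  for (k in seq_along(ord)) {
    tr <- build_sequence(specs[[ord[k]]], start_ms = t0, iti_mean = iti_mean,
                         iti_sd = iti_sd, no_adjacent_gd = no_adjacent_gd)
    tr$sequence_index <- ord[k]
    parts[[k]] <- tr
    t0 <- tr$onset_ms[nrow(tr)] + iti_mean + start_gap_ms
  }
  ev <- do.call(rbind, parts)
  ev$trial_index <- seq_len(nrow(ev))
  ev$block_index <- as.integer(block_index)
  ev$press_times_ms <- ""
  ev$arousal_state <- arousal_state
  ev[, c("trial_index", "sequence_index", "block_index", "onset_ms",
         "vowel_string", "condition", "is_habituation", "is_target",
         "fifth_vowel_onset_ms", "press_times_ms", "arousal_state")]
}

#' Write / read an events table (BIDS-style TSV)
#'
#' `press_times_ms` holds semicolon-separated press times per trial.
#'
#' @param events Events data frame as returned by [build_block()].
#' @param path File path of the TSV.
#' @return `read_events_tsv` returns the events data frame.
#' @export
write_events_tsv <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("trial_index", "onset_ms", "vowel_string", "condition",
                "is_habituation", "is_target", "fifth_vowel_onset_ms")
  missing <- setdiff(required, names(ev))
  if (length(missing))
    stop("events TSV ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  if (!"press_times_ms" %in% names(ev)) ev$press_times_ms <- ""
  ev$press_times_ms[is.na(ev$press_times_ms)] <- ""
  ev$press_times_ms <- as.character(ev$press_times_ms)
  ev
}

# Parse the semicolon-separated press-time column into a list of numeric
# vectors, one per trial.
parse_press_times <- function(press_times_ms) {
  lapply(strsplit(as.character(press_times_ms), ";", fixed = TRUE),
         function(x) {
           x <- suppressWarnings(as.numeric(x[nzchar(x)]))
           x[!is.na(x)]
         })
}

format_press_times <- function(presses) {
  vapply(presses, function(x) paste(signif(x, 10), collapse = ";"), character(1))
}
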