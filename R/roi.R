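# ROI bookkeeping: electrode tables, hemisphere pooling, prevalence and
# latency summaries across arousal states, and mean T-score time courses.

ROI_GROUP_LEVELS <- c("HGPM", "STP", "STG", "Auditory-related", "Prefrontal",
                      "Other")

# Closed ROI vocabulary -> ROI group. Anything not listed is "Other".
ROI_GROUP_MAP <- c(
  "HGPM" = "HGPM",
  "HGAL" = "STP", "PT" = "STP", "PP" = "STP",
  "Posterior STG" = "STG", "Middle STG" = "STG",
  "Anterior STG" = "Auditory-related", "STSU" = "Auditory-related",
  "STSL" = "Auditory-related", "MTG" = "Auditory-related",
  "SMG" = "Auditory-related", "AG" = "Auditory-related",
  "Posterior insula" = "Auditory-related",
  "IFG" = "Prefrontal", "MFG" = "Prefrontal", "SFG" = "Prefrontal",
  "OG" = "Prefrontal", "TFG" = "Prefrontal", "ACC" = "Prefrontal"
)

#' Map ROI subdivisions to ROI groups
#'
#' @param roi Character vector of ROI labels.
#' @return ROI group labels (`"Other"` for subdivisions outside the
#'   auditory/auditory-related/prefrontal scheme).
#' @export
roi_group <- function(roi) {
  out <- unname(ROI_GROUP_MAP[roi])
  out[is.na(out)] <- "Other"
  out
}

#' Read an electrode table
#'
#' Expected columns: `site`, `hemisphere` (L/R), `x_mni`, `y_mni`, `z_mni`,
#' `roi`; optional `roi_group` (derived from `roi` when absent) and
#' `excluded` (default FALSE; excluded sites never enter summaries).
#'
#' @param path TSV path.
#' @return Electrode data frame.
#' @export
read_electrodes_tsv <- function(path) {
  if (!file.exists(path)) stop("electrodes file not found: ", path)
  el <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("site", "hemisphere", "x_mni", "y_mni", "z_mni", "roi")
  missing <- setdiff(required, names(el))
  if (length(missing))
    stop("electrodes TSV ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  if (!"roi_group" %in% names(el)) el$roi_group <- roi_group(el$roi)
  if (!"excluded" %in% names(el)) el$excluded <- FALSE
  el
}

#' Flip left-hemisphere MNI x coordinates
#'
#' Multiplies `x_mni` by -1 for left-hemisphere sites so both hemispheres
#' pool in right-hemisphere common space. Applied once per table; a flag
#' attribute guards against double application.
#'
#' @param sites Electrode data frame.
#' @return The table with flipped coordinates and attribute
#'   `mni_flipped = TRUE`.
#' @export
flip_left_hemisphere <- function(sites) {
  if (isTRUE(attr(sites, "mni_flipped")))
    stop("left-hemisphere coordinates already flipped for this table")
  left <- sites$hemisphere == "L"
  sites$x_mni[left] <- -sites$x_mni[left]
  attr(sites, "mni_flipped") <- TRUE
  sites
}

#' Prevalence of significant interactions per ROI group and state
#'
#' Prevalence is the percentage of (non-excluded) classified sites in an
#' ROI group exhibiting at least one significant cluster of the given sign
#' in the given arousal state. A site significant for both signs counts
#' once in each sign's row.
#'
#' @param classifications Data frame with columns `site`, `state`,
#'   `positive`, `negative` (e.g. `classification_table(...)$sites`), or a
#'   list of [permutation_test()] results.
#' @param sites Electrode data frame (see [read_electrodes_tsv()]).
#' @param grouping Column of `sites` to aggregate by (default
#'   `"roi_group"`).
#' @return Data frame: `roi_group`, `state`, `sign`, `n_total`,
#'   `n_significant`, `percent` (full precision; see
#'   [format_percent_printed()] for display rounding).
#' @export
prevalence <- function(classifications, sites, grouping = "roi_group") {
  if (!is.data.frame(classifications))
    classifications <- classification_table(classifications)$sites
  unknown <- setdiff(classifications$site, sites$site)
  if (length(unknown))
    stop("classification references unknown site(s): ",
         paste(unknown, collapse = ", "))
  cl <- merge(classifications,
              sites[, c("site", grouping, "excluded")], by = "site")
  cl <- cl[!cl$excluded, , drop = FALSE]
  out <- list()
  for (g in unique(cl[[grouping]])) {
    for (st in unique(cl$state)) {
      sub <- cl[cl[[grouping]] == g & cl$state == st, , drop = FALSE]
      if (!nrow(sub)) next
      for (sgn in c("positive", "negative")) {
        n_sig <- sum(sub[[sgn]])
        out[[length(out) + 1]] <- data.frame(
          roi_group = g, state = st, sign = sgn,
          n_total = nrow(sub), n_significant = n_sig,
          percent = 100 * n_sig / nrow(sub),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Percentage of significant sites
#'
#' @param n_significant,n_total Counts.
#' @return `100 * n_significant / n_total` at full precision.
#' @export
prevalence_percent <- function(n_significant, n_total) {
  100 * n_significant / n_total
}

#' Display rounding for percentages (3 significant figures)
#'
#' Computations keep full precision; this is display-only.
#'
#' @param x Numeric percentages.
#' @return Character vector rounded to 3 significant figures.
#' @export
format_percent_printed <- function(x) {
  vapply(x, function(v) format(signif(v, 3), trim = TRUE), character(1))
}

# Does `computed` agree with the printed string `printed` at its printed
# decimal precision?
agrees_with_printed <- function(computed, printed) {
  printed <- trimws(printed)
  nd <- if (grepl(".", printed, fixed = TRUE))
    nchar(sub("^[^.]*\\.", "", printed)) else 0L
  abs(computed - as.numeric(printed)) <= 0.5 * 10^(-nd) + 1e-9
}

#' Reference regional summary tables
#'
#' `reference_site_counts()` returns the per-subject electrode counts per
#' ROI group (a regression fixture for coverage bookkeeping);
#' `reference_interaction_counts()` returns the per-ROI counts and printed
#' percentages of sites with significant positive/negative interactions per
#' arousal state. In the latter, `inconsistent_cells` flags cells whose
#' printed percentage does not match its own printed counts (transcription
#' of typographic errors in the source table; `-` means none).
#'
#' @return A data frame.
#' @export
reference_site_counts <- function() {
  read.delim(system.file("extdata", "reference_site_counts.tsv",
                         package = "lgdint"), stringsAsFactors = FALSE)
}

#' @rdname reference_site_counts
#' @export
reference_interaction_counts <- function() {
  path <- system.file("extdata", "reference_interaction_counts.tsv",
                      package = "lgdint")
  cls <- c(roi = "character", group = "character", is_group_row = "logical",
           n_total = "integer",
           pos_w_n = "integer", pos_w_pct = "character",
           pos_s_n = "integer", pos_s_pct = "character",
           pos_u_n = "integer", pos_u_pct = "character",
           neg_w_n = "integer", neg_w_pct = "character",
           neg_s_n = "integer", neg_s_pct = "character",
           neg_u_n = "integer", neg_u_pct = "character",
           inconsistent_cells = "character")
  read.delim(path, colClasses = unname(cls), stringsAsFactors = FALSE)
}

#' Check the reference prevalence arithmetic
#'
#' Recomputes every percentage of the reference interaction-count table
#' from its own counts via [prevalence_percent()] and compares to the
#' printed value at printed precision.
#'
#' @return Data frame with one row per (roi, sign, state) cell: `roi`,
#'   `cell`, `n`, `n_total`, `computed`, `printed`, `agrees`,
#'   `flagged_inconsistent`.
#' @export
check_reference_prevalence <- function() {
  tab <- reference_interaction_counts()
  cells <- expand.grid(sign = c("pos", "neg"), state = c("w", "s", "u"),
                       stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    flagged <- strsplit(tab$inconsistent_cells[i], ";")[[1]]
    for (j in seq_len(nrow(cells))) {
      cell <- paste0(cells$sign[j], "_", cells$state[j])
      n <- tab[[paste0(cell, "_n")]][i]
      printed <- tab[[paste0(cell, "_pct")]][i]
      computed <- prevalence_percent(n, tab$n_total[i])
      out[[length(out) + 1]] <- data.frame(
        roi = tab$roi[i], cell = cell, n = n, n_total = tab$n_total[i],
        computed = computed, printed = printed,
        agrees = agrees_with_printed(computed, printed),
        flagged_inconsistent = cell %in% flagged,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Compare interaction onset latencies across ROI groups and states
#'
#' Three comparisons: (1) Kruskal-Wallis across HGPM, STP, STG and
#' auditory-related cortex for positive interactions in the awake state;
#' (2) Wilcoxon rank-sum of awake vs sedated positive-interaction latencies
#' pooled over those four groups; (3) rank-sum of auditory-related vs
#' prefrontal negative-interaction latencies in the awake state.
#' Comparisons with a group of fewer than 2 values are skipped and flagged.
#'
#' @param latencies Data frame with columns `site`, `state`, `sign`,
#'   `roi_group`, `latency_ms`.
#' @return List of test reports, each with `comparison`, `p` (or `NA`),
#'   `statistic`, `skipped`, `reason`.
#' @export
latency_comparisons <- function(latencies) {
  aud_groups <- c("HGPM", "STP", "STG", "Auditory-related")
  res <- list()
  report <- function(comparison, p, statistic, skipped = FALSE,
                     reason = "") {
    list(comparison = comparison, p = p, statistic = statistic,
         skipped = skipped, reason = reason)
  }
  # (1) KW across auditory hierarchy, positive, awake
  sub <- latencies[latencies$sign == "positive" & latencies$state == "W" &
                     latencies$roi_group %in% aud_groups, , drop = FALSE]
  sizes <- table(factor(sub$roi_group, aud_groups))
  if (any(sizes < 2)) {
    res$kw_positive_w <- report("kw_positive_awake", NA_real_, NA_real_,
                                TRUE, paste("group(s) with < 2 latencies:",
                                            paste(names(sizes)[sizes < 2],
                                                  collapse = ", ")))
  } else {
    k <- stats::kruskal.test(sub$latency_ms, factor(sub$roi_group))
    res$kw_positive_w <- report("kw_positive_awake", k$p.value,
                                unname(k$statistic))
  }
  # (2) W vs S, positive, pooled auditory + auditory-related
  w <- latencies$latency_ms[latencies$sign == "positive" &
                              latencies$state == "W" &
                              latencies$roi_group %in% aud_groups]
  s <- latencies$latency_ms[latencies$sign == "positive" &
                              latencies$state == "S" &
                              latencies$roi_group %in% aud_groups]
  if (length(w) < 2 || length(s) < 2) {
    res$ranksum_w_vs_s <- report("ranksum_positive_awake_vs_sedated",
                                 NA_real_, NA_real_, TRUE,
                                 "a state with < 2 latencies")
  } else {
    t2 <- suppressWarnings(stats::wilcox.test(w, s))
    res$ranksum_w_vs_s <- report("ranksum_positive_awake_vs_sedated",
                                 t2$p.value, unname(t2$statistic))
  }
  # (3) auditory-related vs prefrontal, negative, awake
  a <- latencies$latency_ms[latencies$sign == "negative" &
                              latencies$state == "W" &
                              latencies$roi_group == "Auditory-related"]
  p <- latencies$latency_ms[latencies$sign == "negative" &
                              latencies$state == "W" &
                              latencies$roi_group == "Prefrontal"]
  if (length(a) < 2 || length(p) < 2) {
    res$ranksum_negative <- report("ranksum_negative_audrel_vs_prefrontal",
                                   NA_real_, NA_real_, TRUE,
                                   "a group with < 2 latencies")
  } else {
    t3 <- suppressWarnings(stats::wilcox.test(a, p))
    res$ranksum_negative <- report("ranksum_negative_audrel_vs_prefrontal",
                                   t3$p.value, unname(t3$statistic))
  }
  res
}

#' Mean T-score time courses of significant sites
#'
#' For each requested (roi_group, state, sign), the pointwise mean of the
#' observed t series over the sites classified significant for that sign.
#' Empty groups yield no trace and are flagged.
#'
#' @param classifications List of [permutation_test()] results.
#' @param sites Electrode data frame.
#' @return List with `traces` (named list of data frames `time_ms`,
#'   `mean_t`, `n_sites`) and `empty` (character vector of absent
#'   group/state/sign combinations).
#' @export
timecourse_summary <- function(classifications, sites) {
  info <- classification_table(classifications)$sites
  info <- merge(info, sites[, c("site", "roi_group", "excluded")],
                by = "site")
  info <- info[!info$excluded, , drop = FALSE]
  by_site <- setNames(classifications,
                      vapply(classifications, function(cl)
                        paste(cl$site, cl$state), character(1)))
  traces <- list()
  empty <- character(0)
  for (g in unique(info$roi_group)) {
    for (st in unique(info$state)) {
      for (sgn in c("positive", "negative")) {
        sel <- info[info$roi_group == g & info$state == st &
                      info[[sgn]], , drop = FALSE]
        key <- paste(g, st, sgn, sep = "/")
        if (!nrow(sel)) {
          empty <- c(empty, key)
          next
        }
        ts <- lapply(paste(sel$site, sel$state), function(k) by_site[[k]]$t)
        tm <- by_site[[paste(sel$site[1], sel$state[1])]]$time_ms
        traces[[key]] <- data.frame(
          time_ms = tm,
          mean_t = Reduce(`+`, ts) / length(ts),
          n_sites = nrow(sel))
      }
    }
  }
  list(traces = traces, empty = empty)
}

#' Crude MNI-box ROI assigner for synthetic data
#'
#' Assigns ROI groups from coarse coordinate boxes in right-hemisphere
#' common space. This is a synthetic-data convenience only: real ROI
#' assignment requires subject-specific anatomy and physiology and is
#' consumed from the electrode table, never computed here.
#'
#' @param x_mni,y_mni,z_mni MNI coordinates (mm), left hemisphere already
#'   flipped.
#' @return ROI group labels.
#' @export
synthetic_mni_box_roi <- function(x_mni, y_mni, z_mni) {
  n <- length(x_mni)
  out <- rep("Other", n)
  sup_temp <- z_mni > -5 & z_mni < 20 & y_mni > -45 & y_mni < 15 &
    x_mni > 30
  out[sup_temp] <- "STG"
  out[sup_temp & x_mni < 48 & y_mni > -30 & y_mni < -5] <- "STP"
  out[sup_temp & x_mni < 45 & y_mni > -25 & y_mni < -12] <- "HGPM"
  out[z_mni <= -5 & z_mni > -40 & y_mni > -70 & y_mni < 10 &
        x_mni > 35] <- "Auditory-related"
  out[y_mni >= 15 & z_mni > -25] <- "Prefrontal"
  out
}
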