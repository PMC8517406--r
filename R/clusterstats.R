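# Cluster-based permutation test for local-by-global interactions.
#
# Pointwise interaction-contrast t statistics over the 0-800 ms analysis
# window are thresholded at the two-tailed 1% tail of Student's T; maximal
# runs of suprathreshold points form clusters whose statistic is the sum of
# t values. Significance comes from a max-statistic Monte Carlo null built
# by shuffling the four condition labels across trials.

# Interaction contrast t at every time point of a trials x time matrix.
# Pooled within-condition variance over the four groups, df = N - 4.
# labels: integer 1..4 in CONDITION_LEVELS order (LSGS, LDGS, LSGD, LDGD).
contrast_t_matrix <- function(X, labels) {
  ng <- tabulate(labels, 4L)
  df <- sum(ng) - 4L
  inv_sum <- sum(1 / ng)
  sums <- rowsum(X, labels, reorder = TRUE)
  sqs <- rowsum(X^2, labels, reorder = TRUE)
  means <- sums / ng
  sse <- colSums(sqs - sums^2 / ng)
  sp2 <- sse / df
  contrast <- (means[4, ] - means[3, ]) - (means[2, ] - means[1, ])
  se <- sqrt(sp2 * inv_sum)
  t <- ifelse(se > 0, contrast / se,
              ifelse(contrast == 0, 0, sign(contrast) * Inf))
  list(t = t, df = df)
}

condition_labels_int <- function(condition) {
  lab <- match(condition, CONDITION_LEVELS)
  if (anyNA(lab)) stop("unknown condition label(s): ",
                       paste(unique(condition[is.na(lab)]), collapse = ", "))
  lab
}

#' Pointwise interaction t statistics
#'
#' At each time point of the analysis window, the 2x2 interaction contrast
#' `(m_LDGD - m_LSGD) - (m_LDGS - m_LSGS)` divided by its pooled-variance
#' standard error (`s_p * sqrt(sum 1/n_c)`), with `df = N - 4`.
#'
#' @param epochs A [power_epochs()] object.
#' @param window Analysis window in ms, half-open `[start, end)`.
#' @return List with `t`, `df`, `time_ms`, `n_per_condition`.
#' @export
pointwise_t <- function(epochs, window = c(0, 800)) {
  stopifnot(inherits(epochs, "power_epochs"))
  keep <- !epochs$artifact
  cols <- epochs$time_ms >= window[1] & epochs$time_ms < window[2]
  X <- epochs$power[keep, cols, drop = FALSE]
  labels <- condition_labels_int(epochs$condition[keep])
  ng <- tabulate(labels, 4L)
  if (any(ng < 2))
    stop("need >= 2 unmasked trials per condition; got ",
         paste(sprintf("%s=%d", CONDITION_LEVELS, ng), collapse = " "))
  res <- contrast_t_matrix(X, labels)
  list(t = res$t, df = res$df, time_ms = epochs$time_ms[cols],
       n_per_condition = setNames(ng, CONDITION_LEVELS))
}

#' Threshold a t series and form clusters
#'
#' Threshold is the `1 - alpha_cluster/2` quantile of Student's
#' T(`df`) (two-tailed cluster-forming criterion). Maximal runs of
#' consecutive points with `t > +threshold` form positive clusters; runs
#' with `t < -threshold` form negative clusters. The cluster statistic is
#' the sum of t values within the run.
#'
#' @param t Numeric t series.
#' @param df Degrees of freedom.
#' @param alpha_cluster Two-tailed cluster-forming alpha (default 0.01).
#' @param time_ms Time axis of `t`; cluster bounds are reported on it, with
#'   `end_ms` the first time point after the run (half-open).
#' @return Data frame of clusters: `start_ms`, `end_ms`, `sign`, `stat`.
#' @export
threshold_and_cluster <- function(t, df, alpha_cluster = 0.01,
                                  time_ms = seq_along(t) - 1) {
  stopifnot(all(is.finite(t) | is.infinite(t)), length(time_ms) == length(t))
  thr <- qt(1 - alpha_cluster / 2, df)
  step <- if (length(time_ms) > 1) diff(time_ms[1:2]) else 1
  code <- ifelse(t > thr, 1L, ifelse(t < -thr, -1L, 0L))
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values != 0L)
  if (!length(sel))
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      sign = character(0), stat = numeric(0)))
  data.frame(
    start_ms = time_ms[starts[sel]],
    end_ms = time_ms[ends[sel]] + step,
    sign = ifelse(r$values[sel] > 0, "positive", "negative"),
    stat = vapply(sel, function(k)
      sum(t[starts[k]:ends[k]]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Cluster-based permutation test and site classification
#'
#' Condition labels are randomly reassigned to trials (preserving group
#' sizes) `n_perm` times; for each partition the pointwise t series and its
#' clusters are recomputed and the largest absolute cluster statistic is
#' collected (0 when no cluster forms). Each observed cluster's Monte Carlo
#' p-value is `(1 + #(null >= |stat|)) / (n_perm + 1)`. A site exhibits a
#' positive (negative) interaction iff it has at least one significant
#' positive (negative) cluster at `alpha`; the onset latency per sign is the
#' start of the first significant cluster.
#'
#' @param epochs A [power_epochs()] object.
#' @param n_perm Number of random partitions (default 10000).
#' @param seed Optional seed for the permutation stream.
#' @param alpha Cluster significance level (default 0.05).
#' @param alpha_cluster Cluster-forming threshold alpha (default 0.01).
#' @param window Analysis window, ms.
#' @param state Arousal-state label carried into the result.
#' @return A `site_classification` object: `site`, `state`, `clusters`
#'   (with Monte Carlo `p_value`), `positive`, `negative`,
#'   `onset_latency_ms` (named by sign, `NA` when absent), the observed
#'   `t`/`df`/`time_ms`, `n_per_condition`, and `degraded` (TRUE when
#'   `n_perm < 100`).
#' @export
permutation_test <- function(epochs, n_perm = 10000, seed = NULL,
                             alpha = 0.05, alpha_cluster = 0.01,
                             window = c(0, 800), state = "W") {
  stopifnot(inherits(epochs, "power_epochs"))
  set_seed_if_given(seed)
  obs <- pointwise_t(epochs, window = window)
  clusters <- threshold_and_cluster(obs$t, obs$df, alpha_cluster, obs$time_ms)
  degraded <- n_perm < 100
  if (degraded)
    warning("n_perm = ", n_perm, " gives a degraded Monte Carlo resolution")
  keep <- !epochs$artifact
  cols <- epochs$time_ms >= window[1] & epochs$time_ms < window[2]
  X <- epochs$power[keep, cols, drop = FALSE]
  labels <- condition_labels_int(epochs$condition[keep])
  thr <- qt(1 - alpha_cluster / 2, obs$df)
  null_max <- perm_null_max_cluster(X, labels, as.integer(n_perm), thr)
  if (nrow(clusters)) {
    clusters$p_value <- vapply(clusters$stat, function(s)
      (1 + sum(null_max >= abs(s))) / (n_perm + 1), numeric(1))
  } else {
    clusters$p_value <- numeric(0)
  }
  sig <- clusters[clusters$p_value < alpha, , drop = FALSE]
  lat <- c(positive = NA_real_, negative = NA_real_)
  for (sgn in c("positive", "negative")) {
    rows <- sig$sign == sgn
    if (any(rows)) lat[[sgn]] <- min(sig$start_ms[rows])
  }
  structure(list(site = epochs$site, state = state, clusters = clusters,
                 positive = any(sig$sign == "positive"),
                 negative = any(sig$sign == "negative"),
                 onset_latency_ms = lat,
                 t = obs$t, df = obs$df, time_ms = obs$time_ms,
                 n_per_condition = obs$n_per_condition,
                 n_masked = sum(epochs$artifact),
                 n_perm = n_perm, alpha = alpha,
                 alpha_cluster = alpha_cluster, degraded = degraded),
            class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat("<site_classification '", x$site, "' [", x$state, "]: ",
      if (x$positive) "positive " else "",
      if (x$negative) "negative " else "",
      if (!x$positive && !x$negative) "no " else "",
      "interaction; ", nrow(x$clusters), " cluster(s)>\n", sep = "")
  invisible(x)
}

#' Onset latency of the first significant cluster
#'
#' @param classification A [permutation_test()] result.
#' @param sign `"positive"` or `"negative"`.
#' @return Start time (ms) of the earliest significant cluster of that
#'   sign, or `NA` if none.
#' @export
onset_latency <- function(classification, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  classification$onset_latency_ms[[sign]]
}

#' Tabulate site classifications
#'
#' Flattens a list of [permutation_test()] results into one row per site
#' with classification flags and onset latencies, plus a cluster-level
#' table.
#'
#' @param classifications List of `site_classification` objects.
#' @return List with `sites` and `clusters` data frames.
#' @export
classification_table <- function(classifications) {
  sites <- do.call(rbind, lapply(classifications, function(cl) {
    data.frame(site = cl$site, state = cl$state,
               positive = cl$positive, negative = cl$negative,
               onset_positive_ms = cl$onset_latency_ms[["positive"]],
               onset_negative_ms = cl$onset_latency_ms[["negative"]],
               n_masked = cl$n_masked,
               n_clusters = nrow(cl$clusters),
               stringsAsFactors = FALSE)
  }))
  clusters <- do.call(rbind, lapply(classifications, function(cl) {
    if (!nrow(cl$clusters)) return(NULL)
    cbind(data.frame(site = cl$site, state = cl$state,
                     stringsAsFactors = FALSE), cl$clusters)
  }))
  list(sites = sites, clusters = clusters)
}
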