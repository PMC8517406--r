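# Shared helpers: tiny fixture builders and independent oracles used to
# cross-check the implementation paths.

# Build a power_epochs object from a trials x time matrix.
make_epochs <- function(power, condition,
                        time_ms = seq(0, length.out = ncol(power)),
                        artifact = rep(FALSE, nrow(power)),
                        site = "fix") {
  power_epochs(power, time_ms = time_ms, condition = condition,
               artifact = artifact, site = site)
}

# Independent pointwise-t oracle: the interaction coefficient of a
# saturated two-factor linear model (treatment coding) equals the
# difference-of-differences contrast, with pooled-variance SE and df N-4.
lm_contrast_t <- function(y, condition) {
  L <- factor(substr(condition, 1, 2), c("LS", "LD"))
  G <- factor(substr(condition, 3, 4), c("GS", "GD"))
  fit <- summary(lm(y ~ L * G))
  fit$coefficients["LLD:GGD", "t value"]
}

# Brute-force run scanner: clusters as maximal runs of points beyond the
# threshold, found by linear scan.
scan_clusters <- function(t, thr, time_ms = seq_along(t) - 1) {
  out <- data.frame(start = numeric(0), end = numeric(0), stat = numeric(0),
                    sign = character(0))
  i <- 1
  n <- length(t)
  while (i <= n) {
    s <- if (t[i] > thr) 1L else if (t[i] < -thr) -1L else 0L
    if (s == 0L) { i <- i + 1; next }
    j <- i
    while (j < n && (if (s > 0) t[j + 1] > thr else t[j + 1] < -thr)) j <- j + 1
    out <- rbind(out, data.frame(
      start = time_ms[i], end = time_ms[j] + 1, stat = sum(t[i:j]),
      sign = if (s > 0) "positive" else "negative"))
    i <- j + 1
  }
  out
}

# Max |cluster stat| of one labeling, used by the exhaustive oracle.
max_cluster_stat <- function(X, labels_int, thr) {
  cond <- lgdint:::CONDITION_LEVELS[labels_int]
  ep <- make_epochs(X, cond)
  pt <- pointwise_t(ep, window = range(ep$time_ms) + c(0, 1))
  cl <- threshold_and_cluster(pt$t, pt$df, time_ms = pt$time_ms)
  if (!nrow(cl)) 0 else max(abs(cl$stat))
}

# Exhaustive permutation p-values for a 2-trials-per-condition instance:
# enumerate all 8!/(2!^4) = 2520 assignments of the 8 trials to the four
# labels and compare each max cluster statistic to the observed clusters.
exhaustive_cluster_p <- function(X, labels_int) {
  stopifnot(nrow(X) == 8)
  thr <- qt(1 - 0.01 / 2, 4)
  cond <- lgdint:::CONDITION_LEVELS[labels_int]
  ep <- make_epochs(X, cond)
  pt <- pointwise_t(ep, window = range(ep$time_ms) + c(0, 1))
  obs <- threshold_and_cluster(pt$t, pt$df, time_ms = pt$time_ms)
  idx <- 1:8
  partitions <- list()
  for (a in utils::combn(8, 2, simplify = FALSE)) {
    r1 <- setdiff(idx, a)
    for (b in utils::combn(r1, 2, simplify = FALSE)) {
      r2 <- setdiff(r1, b)
      for (d in utils::combn(r2, 2, simplify = FALSE)) {
        lab <- integer(8)
        lab[a] <- 1L; lab[b] <- 2L; lab[d] <- 3L
        lab[setdiff(r2, d)] <- 4L
        partitions[[length(partitions) + 1]] <- lab
      }
    }
  }
  null_max <- vapply(partitions, function(lab) max_cluster_stat(X, lab, thr),
                     numeric(1))
  list(
    clusters = obs,
    n_partitions = length(partitions),
    p_exact = vapply(obs$stat, function(s) mean(null_max >= abs(s)),
                     numeric(1))
  )
}

# Exact one-tailed sign-flip p-value for the signed-rank statistic:
# enumerate all 2^n sign assignments of the ranked |differences|.
exact_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_null <- as.matrix(signs) %*% r
  mean(v_null >= v_obs)
}
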