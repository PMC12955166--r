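# Independent oracles used to cross-check the package implementations.
# These deliberately use naive algorithms (exhaustive enumeration, direct
# accumulation) so they share no code with the functions under test.

# AUC by exhaustive pair counting with half-credit for ties.
oracle_auc_pairs <- function(scores, labels, case_level = "sptb") {
  cases <- scores[labels == case_level]
  ctrls <- scores[labels != case_level]
  tot <- 0
  for (x in cases) for (y in ctrls) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(cases) * length(ctrls))
}

# Trapezoidal area under the empirical ROC curve.
oracle_auc_trapezoid <- function(scores, labels, case_level = "sptb") {
  is_case <- labels == case_level
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- fpr <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    pos <- scores >= cuts[i]
    tpr[i] <- sum(pos & is_case) / sum(is_case)
    fpr[i] <- sum(pos & !is_case) / sum(!is_case)
  }
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mw_exact_p <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    sum(rank(all_v)[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * length(y) / 2
  combs <- utils::combn(length(all_v), n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Two-sided Fisher exact p by enumeration over all tables with fixed margins.
oracle_fisher_enum <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  total <- m + n
  p_of <- function(a) {
    b <- m - a; cc <- k - a; d <- n - k + a
    if (min(b, cc, d) < 0) return(NA_real_)
    exp(lchoose(m, a) + lchoose(n, cc) - lchoose(total, k))
  }
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, p_of, 0)
  p_obs <- p_of(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Log-rank chi-square by direct 2x2-per-event-time hypergeometric sums.
oracle_logrank <- function(time, group) {
  g1 <- unique(group)[1]
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t)
    d1 <- sum(time == t & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# Youden index by exhaustive scan over every observed score as the cutoff
# (plus the all-high and all-low rules).
oracle_best_youden <- function(scores, labels, case_level = "sptb") {
  is_case <- labels == case_level
  best <- -Inf
  for (cut in c(-Inf, sort(unique(scores)), Inf)) {
    high <- scores >= cut
    j <- sum(high & is_case) / sum(is_case) +
      sum(!high & !is_case) / sum(!is_case) - 1
    best <- max(best, j)
  }
  best
}
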