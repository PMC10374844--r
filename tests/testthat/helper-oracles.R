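# Independent oracles used by module and acceptance tests. Each recomputes a
# quantity by direct enumeration or a hand-coded formula, never through the
# package's own code path.

# rank/concordance AUC: P(score_rare > score_abundant) + 0.5 P(equal)
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# exhaustive Youden scan over all midpoint cuts, lower threshold on ties,
# sentinel winners mapped to finite cuts with the same confusion table
youden_scan_oracle <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  j <- vapply(cand, function(t) {
    mean(scores[labels == 1] > t) + mean(scores[labels == 0] <= t) - 1
  }, 0)
  best <- min(cand[j >= max(j) - 1e-12])
  if (best == -Inf) best <- min(scores) - 1
  if (best == Inf) best <- max(scores) + 1
  best
}

# Shapley value by full coalition enumeration of an arbitrary value function
shapley_enum <- function(value, p) {
  phi <- numeric(p)
  subsets <- function(v) {
    if (length(v) == 0) return(list(integer(0)))
    rest <- subsets(v[-1])
    c(rest, lapply(rest, function(s) c(v[1], s)))
  }
  for (i in seq_len(p)) {
    for (S in subsets(setdiff(seq_len(p), i))) {
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      phi[i] <- phi[i] + w * (value(c(S, i)) - value(S))
    }
  }
  phi
}

# brute-force majority-vote rule
vote_oracle <- function(cl, sc) {
  n1 <- sum(cl == 1)
  win <- if (n1 > length(cl) - n1) 1 else if (n1 < length(cl) - n1) 0 else 1
  s <- if (win == 1) max(sc[cl == 1]) else min(sc[cl == 0])
  list(class = win, score = s)
}

# hand-coded rank-sum p: normal approximation with tie correction, no
# continuity correction
ranksum_p_oracle <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  r <- rank(c(x1, x0))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x1, x0))
  n <- n1 + n0
  v <- n1 * n0 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (U - n1 * n0 / 2) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

# base_model_fit with chosen weights/calibration, for closed-form checks
make_fit <- function(weights, intercept = 0, slope = 1, offset = 0) {
  rrsorisk:::new_base_model_fit(
    selected = setNames(weights != 0, names(weights)),
    importances = setNames(rep(1 / length(weights), length(weights)),
                           names(weights)),
    weights = weights, intercept = intercept,
    calibration = c(slope = slope, offset = offset), seed = 1L)
}
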