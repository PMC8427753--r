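# Brute-force oracles kept independent of the implementation paths they check.

# Concordance-probability AUC: all case-control pairs, ties counted 1/2.
concordance_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Textbook Pearson chi-square statistic.
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Nearest point on the midline by dense grid search.
grid_project <- function(t_point, base, apex, step = 1e-4) {
  ts <- seq(-5, 6, by = step)
  d <- apex - base
  pts <- cbind(base[1] + ts * d[1], base[2] + ts * d[2])
  dist2 <- (pts[, 1] - t_point[1])^2 + (pts[, 2] - t_point[2])^2
  pts[which.min(dist2), ]
}

# Linearly weighted kappa expanded cell by cell over the weight matrix.
weighted_kappa_oracle <- function(r1, r2, levels) {
  n <- length(r1)
  w <- 1 - abs(outer(levels, levels, "-")) / (max(levels) - min(levels))
  po <- 0; pe <- 0
  for (i in seq_along(levels)) {
    for (j in seq_along(levels)) {
      obs <- sum(r1 == levels[i] & r2 == levels[j]) / n
      expd <- (sum(r1 == levels[i]) / n) * (sum(r2 == levels[j]) / n)
      po <- po + w[i, j] * obs
      pe <- pe + w[i, j] * expd
    }
  }
  (po - pe) / (1 - pe)
}

make_phantom_cohort <- function(n = 60, seed = 42) {
  set.seed(seed)
  data.frame(patient_id = sprintf("P%03d", 1:n),
             age = runif(n, 40, 90),
             abza_deg = runif(n, 0, 90),
             mrs_90 = sample(0:6, n, replace = TRUE),
             toast = sample(c("LAA", "CE", "other"), n, replace = TRUE),
             mtici_2b3 = runif(n) < 0.8,
             stringsAsFactors = FALSE)
}
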