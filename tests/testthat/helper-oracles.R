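# Independent oracles, deliberately naive: these re-derive the quantities
# the package computes by a different route (enumeration / explicit loops)
# and must never call the implementation under test.

# Exact two-sided McNemar p by enumerating all 2^n discordance assignments:
# under H0 each discordant pair falls on either side with probability 1/2;
# p doubles the tail at or below the observed minimum count.
mcnemar_brute <- function(b, c_) {
  n <- b + c_
  if (n == 0) return(1)
  k_obs <- min(b, c_)
  tail_count <- 0
  for (assign in 0:(2^n - 1)) {
    k <- sum(as.integer(intToBits(assign))[1:n])
    if (k <= k_obs) tail_count <- tail_count + 1
  }
  min(1, 2 * tail_count / 2^n)
}

# Repeated-measures sums of squares by explicit double loops.
rm_anova_brute <- function(y) {
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  ss_cond <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(y[, j]) - grand)^2
  ss_subj <- 0
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(y[i, ]) - grand)^2
  ss_tot <- 0
  for (i in 1:n) for (j in 1:k) ss_tot <- ss_tot + (y[i, j] - grand)^2
  ss_err <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(ss_cond = ss_cond, ss_subj = ss_subj, ss_err = ss_err,
       ss_tot = ss_tot, f = f,
       p = pf(f, k - 1, (k - 1) * (n - 1), lower.tail = FALSE))
}

long_from_matrix <- function(y) {
  data.frame(
    pig = rep(seq_len(nrow(y)), times = ncol(y)),
    cond = rep(seq_len(ncol(y)), each = nrow(y)),
    y = as.vector(y)
  )
}
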