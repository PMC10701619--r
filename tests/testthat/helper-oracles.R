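# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's vectorized code paths: explicit loops, two-pass
# medians, direct rank enumeration.

random_expression <- function(n_genes, n_samples, seed, scale = "log",
                              cohort_id = "FIX") {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_samples, mean = if (scale == "linear") 0
                       else 0), n_genes, n_samples)
  if (scale == "linear") vals <- exp(vals)  # strictly positive
  rownames(vals) <- sprintf("G%03d", seq_len(n_genes))
  colnames(vals) <- sprintf("S%03d", seq_len(n_samples))
  expression_matrix(vals, cohort_id = cohort_id, scale = scale)
}

random_gene_set <- function(expr, size, seed, name = "SET") {
  set.seed(seed)
  gene_set(name, sample(rownames(expr), size))
}

# Midpoint-of-order-statistics median, written out.
naive_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Two-pass fold oracle: per-gene median, then per-cell difference/ratio.
naive_fold <- function(expr) {
  vals <- unclass(expr)
  out <- vals * NA_real_
  for (g in seq_len(nrow(vals))) {
    med <- naive_median(vals[g, ])
    for (s in seq_len(ncol(vals))) {
      out[g, s] <- if (attr(expr, "scale") == "linear")
        log2(vals[g, s] / med) else vals[g, s] - med
    }
  }
  out
}

# Direct evaluation of the activation z-score from raw expression.
naive_activation <- function(expr, members) {
  f <- naive_fold(expr)
  matched <- rownames(f)[rownames(f) %in% members]
  m <- length(matched)
  out <- numeric(ncol(f))
  for (s in seq_len(ncol(f))) {
    prof <- f[, s]
    mu <- sum(prof) / length(prof)
    sdv <- sqrt(sum((prof - mu)^2) / (length(prof) - 1))
    set_mean <- sum(f[matched, s]) / m
    out[s] <- sqrt(m) * (set_mean - mu) / sdv
  }
  names(out) <- colnames(f)
  out
}

# Direct rank-score enumeration for one sample at a time.
naive_rank_score <- function(expr, members) {
  vals <- unclass(expr)
  n <- nrow(vals)
  matched <- rownames(vals)[rownames(vals) %in% members]
  m <- length(matched)
  out <- numeric(ncol(vals))
  for (s in seq_len(ncol(vals))) {
    r <- rank(vals[, s])
    rbar <- mean(r[matched])
    out[s] <- (rbar - (m + 1) / 2) / ((2 * n - m + 1) / 2 - (m + 1) / 2)
  }
  names(out) <- colnames(vals)
  out
}

# Log-rank oracle: per-event-time 2x2 hypergeometric bookkeeping.
naive_logrank <- function(time, event, group) {
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & group == "high")
    n0 <- sum(at_risk & group == "low")
    d1 <- sum(time == t & event == 1 & group == "high")
    d <- sum(time == t & event == 1)
    n <- n1 + n0
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n0 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
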