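# Independent brute-force oracles used to cross-check the implementation.

# Spearman by explicit average ranks then textbook Pearson sums.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(rx)
  sx <- rx - sum(rx) / n
  sy <- ry - sum(ry) / n
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

# BH step-up by the definitional formula: sort, p(i)*m/i, cumulative min
# from the largest rank down, cap at 1, map back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail P(X >= k) by direct enumeration of overlap
# counts with choose().
oracle_hyper_tail <- function(k, set_size, universe_size, query_size) {
  kk <- max(0, k):min(set_size, query_size)
  kk <- kk[query_size - kk <= universe_size - set_size]
  sum(choose(set_size, kk) * choose(universe_size - set_size, query_size - kk)) /
    choose(universe_size, query_size)
}

# Kaplan-Meier product-limit by an explicit loop over distinct event times
# (events precede censorings at ties).
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(et))
  risk <- integer(length(et))
  for (i in seq_along(et)) {
    t <- et[i]
    n_i <- sum(time >= t)
    d_i <- sum(time == t & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
    risk[i] <- n_i
  }
  list(event_times = et, survival = surv, at_risk = risk)
}

# Two-group log-rank chi-square by the O-E/V hypergeometric loop over
# pooled distinct event times.
oracle_logrank <- function(time, event, group) {
  g <- unique(group)
  stopifnot(length(g) == 2)
  et <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in et) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Cosine reversal ranking by an exhaustive loop over drugs.
oracle_reversal <- function(sig_w, library) {
  scores <- c()
  for (drug in names(library)) {
    ov <- intersect(names(library[[drug]]), names(sig_w))
    if (length(ov) == 0) next
    x <- sig_w[ov]; y <- library[[drug]][ov]
    scores[drug] <- -sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
  }
  scores[order(-scores, names(scores))]
}

# Small in-code fixture: a valid two-phenotype study.
make_study <- function(n_genes = 4, n_per = 3, seed = 42, study_id = "T") {
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * 2 * n_per, mean = 8), nrow = n_genes,
                 dimnames = list(paste0("g", seq_len(n_genes)),
                                 paste0("s", seq_len(2 * n_per))))
  expression_study(study_id, vals,
                   rep(c("disease", "control"), each = n_per))
}
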