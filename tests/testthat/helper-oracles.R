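# Independent closed-form oracles used to freeze expected values.
# These are deliberately naive re-derivations, not calls into the package.

# product-limit estimator by direct enumeration (deaths before censorings
# at tied times)
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])
    d_i <- sum(time == ts[i] & event)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# BH step-up from the definition: q_(i) = min_{j >= i} min(1, n p_(j) / j)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n))
    q[i] <- min(1, min(n * ps[i:n] / (i:n)))
  out <- numeric(n)
  out[o] <- q
  out
}

# Kruskal-Wallis H from the rank-sum formula (no tie correction; use on
# tie-free data only)
kw_oracle <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  n <- length(x)
  idx <- rep(seq_along(groups), lengths(groups))
  rs <- tapply(r, idx, sum)
  12 / (n * (n + 1)) * sum(rs^2 / lengths(groups)) - 3 * (n + 1)
}

# one-way ANOVA F from explicit sums of squares
anova_oracle <- function(groups) {
  x <- unlist(groups)
  gm <- mean(x)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 1) - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  k <- length(groups)
  n <- length(x)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# AUC by brute-force pair enumeration, ties scoring one half
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# a null cohort (no planted effects) at moderate size, shared across tests
null_sim <- function(n_genes = 200, n_tumor = 50, n_normal = 20, seed = 5) {
  simulate_cohort(sim_config(
    n_genes = n_genes, n_tumor = n_tumor, n_normal = n_normal,
    frac_dge = 0, frac_surv = 0, frac_clinical = 0, frac_hotspot = 0,
    frac_dependent = 0, seed = seed))
}

survival_records_quiet <- function(clinical) {
  suppressMessages(build_survival_records(clinical))
}
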