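# Independent brute-force oracles used to cross-check the package's
# statistical machinery. These deliberately re-derive each quantity from
# its definition rather than calling the code paths under test.

# Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Holm step-down: running max of p_(i) * (m - i + 1), capped.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, min(1, ps[i] * (m - i + 1)))
    adj[i] <- run
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric pmf and tails by direct enumeration over choose().
hyper_pmf_oracle <- function(j, N, K, n) {
  choose(K, j) * choose(N - K, n - j) / choose(N, n)
}
hyper_tail_ge_oracle <- function(k, N, K, n) {
  js <- k:min(K, n)
  sum(hyper_pmf_oracle(js, N, K, n))
}
hyper_tail_le_oracle <- function(k, N, K, n) {
  js <- max(0, n - (N - K)):k
  sum(hyper_pmf_oracle(js, N, K, n))
}

# Spearman rho from the textbook rank-difference formula (no ties).
spearman_formula_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Cohen's kappa from the explicit 2x2 membership table.
kappa_oracle <- function(set_a, set_b, universe) {
  n11 <- sum(universe %in% set_a & universe %in% set_b)
  n10 <- sum(universe %in% set_a & !(universe %in% set_b))
  n01 <- sum(!(universe %in% set_a) & universe %in% set_b)
  n00 <- sum(!(universe %in% set_a) & !(universe %in% set_b))
  n <- n11 + n10 + n01 + n00
  po <- (n11 + n00) / n
  pe <- ((n11 + n10) * (n11 + n01) + (n01 + n00) * (n10 + n00)) / n^2
  (po - pe) / (1 - pe)
}

# Unidirectional-region rule, written as a literal transcription of the
# definition for a single region.
dmr_rule_oracle <- function(n_probes, n_hyper, n_hypo, min_fraction = 0.25) {
  hyper_ok <- n_hyper >= min_fraction * n_probes
  hypo_ok <- n_hypo >= min_fraction * n_probes
  if (hyper_ok && hypo_ok) return("ambiguous")
  if (hyper_ok) return("hyper")
  if (hypo_ok) return("hypo")
  "none"
}

# All permutations via Heap's algorithm (distinct from the package's
# recursive generator).
heap_permutations <- function(n) {
  out <- matrix(0L, factorial(n), n)
  a <- seq_len(n)
  cnt <- 0L
  emit <- function() {
    cnt <<- cnt + 1L
    out[cnt, ] <<- a
  }
  heap <- function(k) {
    if (k == 1) {
      emit()
      return(invisible())
    }
    for (i in seq_len(k)) {
      heap(k - 1)
      if (i < k) {
        j <- if (k %% 2 == 0) i else 1
        tmp <- a[j]; a[j] <<- a[k]; a[k] <<- tmp
      }
    }
  }
  heap(n)
  out
}

# Adjusted Rand index between two labelings.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n <- length(a)
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
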