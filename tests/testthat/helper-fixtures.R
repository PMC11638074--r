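# Shared fixtures: the chain-notation corpus used across the study
# (controls, homotypic chains, branched/mixed tetramers, variant-tagged
# constructs) and small oracle implementations kept deliberately
# independent of the package internals.

notation_corpus <- c(
  "Ub",
  "Ub-[1]Ub",
  "Ub-[11]Ub",
  "Ub-[48]Ub",
  "Ub-[63]Ub",
  "48Ub3",
  "63Ub3",
  "48Ub4",
  "63Ub4",
  "(Ub)2-[48,63]Ub",
  "(Ub)2-[1,63]Ub",
  "(Ub)2-[11,48]Ub",
  "(Ub)2-[29,48]Ub",
  "(Ub)2-[48,63]Ub-[48]Ub",
  "(Ub)2-[48,63]Ub-[63]Ub",
  "Ub-[48]Ub-[63]Ub-[48]Ub",
  "(Ub{K48R,K63R})2-[48,63]Ub{1-72}",
  "(Ub)2-[48,63]Ub-[48]Ub{AVI}",
  "Ub{15N}"
)

# Brute-force Benjamini-Hochberg step-up, written from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o]
  for (i in seq_len(n)) {
    adj[i] <- min(sorted[i:n] * n / (i:n))
  }
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# All permutations of 1..n (small n), recursively.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# All ordered selections of k out of n distinct indices.
all_selections <- function(n, k) {
  out <- list()
  rec <- function(prefix) {
    if (length(prefix) == k) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (j in setdiff(seq_len(n), prefix)) rec(c(prefix, j))
  }
  rec(integer())
  out
}

# Adjusted Rand index (chance-corrected clustering agreement), from the
# contingency-table formula; used when mclust is unavailable.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    mclust::adjustedRandIndex(a, b)
  } else {
    ari_oracle(a, b)
  }
}
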