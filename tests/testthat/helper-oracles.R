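# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the code paths they check.

# Two-sided Fisher P by exact log-binomial-coefficient arithmetic over the
# full conditional support (no dhyper).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p <- exp(logp)
  obs <- p[match(a, support)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# Brute-force BH step-up straight from the definition:
# q_i = min over j with p_(j) >= p_(i) of p_(j) * m / rank(j).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranks <- match(seq_len(m), o) # rank of each element in sorted order
  vapply(seq_len(m), function(i) {
    js <- which(p[o] >= p[i] - 1e-15)
    min(1, min(p[o][js] * m / js))
  }, numeric(1))
}

# Exhaustive enumeration of nested structures: maximum number of WC/GU
# pairs with a minimum hairpin loop, by explicit recursion over all
# pairings of the last base (no memoization; feasible for length <= 12).
pairs_oracle <- function(seq, min_loop = 3) {
  s <- chartr("Uu", "Tt", toupper(seq))
  s <- strsplit(s, "")[[1]]
  ok <- function(x, y) paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i, j - 1)
    for (k in i:(j - min_loop - 1)) {
      if (!ok(s[k], s[j])) next
      left <- if (k > i) rec(i, k - 1) else 0
      best <- max(best, left + rec(k + 1, j - 1) + 1)
    }
    best
  }
  if (length(s) < 2) return(0) else rec(1, length(s))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
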