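# Shared in-code fixtures and independent oracles.

# Three tiny pathways with a one-edge hierarchy.
tiny_db <- function() {
  pathway_db(list(P1 = c("A", "B", "C"), P2 = c("C", "D"), P3 = c("E", "F")),
             names = c(P1 = "Alpha pathway", P2 = "Beta pathway",
                       P3 = "Gamma pathway"),
             hierarchy = data.frame(parent = "P1", child = "P2",
                                    stringsAsFactors = FALSE))
}

# The nine printed drug-target binding rows for the nephrin-interactions
# worked example (all carry experimental binding values, i.e. level III).
nephrin_binding_records <- function() {
  data.frame(
    drug = c("Bosutinib", "Crizotinib", "Bosutinib", "Bosutinib",
             "Dasatinib", "Sunitinib Malate", "Vandetanib",
             "Idelalisib", "Idelalisib"),
    target = c("CASK", "CASK", "FYN", "FYN", "FYN", "FYN", "FYN",
               "PIK3CA", "PIK3CB"),
    evidence_level = rep("III", 9),
    assay_type = c("KD", "KD", "KD", "IC50", "KD", "KD", "KD",
                   "IC50", "IC50"),
    assay_value_nM = c(830, 140, 11, 1.799999952, 0.79, 520, 360, 820, 562),
    stringsAsFactors = FALSE)
}

# A 22-gene pathway whose member set contains the four targeted kinases /
# scaffolds of the worked example.
nephrin_like_db <- function() {
  genes <- c("CASK", "FYN", "PIK3CA", "PIK3CB",
             sprintf("FILLER%02d", 1:18))
  pathway_db(list(NEPH = genes), names = c(NEPH = "Nephrin-like interactions"))
}

# Independent upper-tail oracle: exhaustive enumeration of hypergeometric
# draw probabilities via binomial coefficients. Returns P(X >= k) (or
# P(X > k)) for k = 0..min(m, K).
hyper_tail_oracle <- function(N, m, K, tail = "ge") {
  x <- 0:min(m, K)
  terms <- choose(K, x) * choose(N - K, m - x) / choose(N, m)
  ge <- rev(cumsum(rev(terms)))
  if (tail == "ge") ge else c(ge[-1], 0)
}

# Independent BY oracle: the step-up formula computed directly.
by_oracle <- function(p) {
  n <- length(p)
  cn <- sum(1 / seq_len(n))
  o <- order(p)
  raw <- pmin(1, p[o] * n / seq_len(n) * cn)
  q_sorted <- rev(cummin(rev(raw)))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Brute-force boolean transitive closure of a parent->child edge list over
# the given node IDs (iterated matrix closure; independent of the package's
# DFS walk).
closure_oracle <- function(edges, ids) {
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(edges) > 0L) {
    A[cbind(match(edges$parent, ids), match(edges$child, ids))] <- TRUE
  }
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R  # R[p, c] TRUE iff p is a transitive ancestor of c
}
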