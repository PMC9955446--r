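# Independent oracle implementations used to cross-check the package.
# These are deliberately written from the definitions, not from package
# internals.

# plug-in Shannon entropy (nats), 0 log 0 = 0
oracle_entropy <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log(v)
  s
}

# brute-force BALD decomposition of a T x C matrix of per-pass rows
oracle_decompose <- function(passes) {
  Tn <- nrow(passes)
  pbar <- colSums(passes) / Tn
  H <- oracle_entropy(pbar)
  A <- mean(vapply(seq_len(Tn), function(t) oracle_entropy(passes[t, ]), 0))
  list(H = H, A = A, MI = H - A)
}

# jackknife-corrected predictive entropy and aleatoric term by explicit
# enumeration of every leave-one-out subset
oracle_jackknife_mi <- function(passes) {
  Tn <- nrow(passes)
  full <- oracle_decompose(passes)
  H_loo <- numeric(Tn); A_loo <- numeric(Tn)
  for (j in seq_len(Tn)) {
    sub <- passes[-j, , drop = FALSE]
    d <- oracle_decompose(sub)
    H_loo[j] <- d$H; A_loo[j] <- d$A
  }
  H_bc <- Tn * full$H - (Tn - 1) * mean(H_loo)
  A_bc <- Tn * full$A - (Tn - 1) * mean(A_loo)
  H_bc - A_bc
}

# AUC as the probability a random positive outscores a random negative,
# ties counted half, over all label pairs
oracle_auc_paircount <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# random points on the C-simplex
random_simplex <- function(n, C) {
  m <- matrix(-log(runif(n * C)), n, C)
  m / rowSums(m)
}
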