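# Independent brute-force oracles. These deliberately avoid the package's
# code paths: Mendelian probabilities come from the Bernoulli transmission
# closed form, tables from explicit loops, BH from the textbook step-up
# formula, and the hypergeometric tail from subset enumeration.

# P(child dosage | parental dosages): each parent transmits a minor allele
# with probability dosage/2, independently.
oracle_mendel <- function(f, m) {
  pf <- f / 2; pm <- m / 2
  c((1 - pf) * (1 - pm), pf * (1 - pm) + (1 - pf) * pm, pf * pm)
}

# Full loop-based recomputation of the corrected/normalized expected field
# (iterative proportional fitting, written as plain loops) and the joint
# table + statistic for one pair. gm/trios as in the package.
oracle_field <- function(gm, trios, tol = 1e-14, max_iter = 1000) {
  g <- gm$genotypes
  tt <- trios$trios
  nt <- nrow(tt); nm <- ncol(g)
  probs <- array(NA_real_, c(nt, nm, 3))
  for (t in seq_len(nt)) for (m in seq_len(nm)) {
    if (!trios$usable[t, m]) next
    probs[t, m, ] <- oracle_mendel(g[tt$father[t], m], g[tt$mother[t], m])
  }
  for (m in seq_len(nm)) {
    use <- which(trios$usable[, m])
    if (!length(use)) next
    obs <- c(0, 0, 0)
    for (t in use) obs[g[tt$child[t], m] + 1] <- obs[g[tt$child[t], m] + 1] + 1
    for (it in seq_len(max_iter)) {
      es <- c(0, 0, 0)
      for (t in use) es <- es + probs[t, m, ]
      fac <- ifelse(es > 0, obs / es, 1)
      for (t in use) {
        v <- probs[t, m, ] * fac
        probs[t, m, ] <- v / sum(v)
      }
      if (max(abs(fac - 1)) < tol) break
    }
  }
  probs
}

oracle_joint <- function(gm, trios, pair, tol = 1e-14) {
  probs <- oracle_field(gm, trios, tol = tol)
  g <- gm$genotypes
  tt <- trios$trios
  a <- pair[1]; b <- pair[2]
  O <- matrix(0, 3, 3); E <- matrix(0, 3, 3)
  n_pair <- 0
  for (t in seq_len(nrow(tt))) {
    if (!(trios$usable[t, a] && trios$usable[t, b])) next
    n_pair <- n_pair + 1
    ca <- g[tt$child[t], a]; cb <- g[tt$child[t], b]
    O[ca + 1, cb + 1] <- O[ca + 1, cb + 1] + 1
    for (j in 1:3) for (k in 1:3)
      E[j, k] <- E[j, k] + probs[t, a, j] * probs[t, b, k]
  }
  list(observed = O, expected = E, n_pair = n_pair)
}

oracle_statistic <- function(O, E) {
  S <- 0
  for (j in 1:3) for (k in 1:3)
    if (E[j, k] > 0) S <- S + (O[j, k] - E[j, k])^2 / E[j, k]
  S
}

# Textbook BH step-up: q_i = min over j with p_(j) >= p_(i) of p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Exact P(|A ∩ B| >= s) for a uniformly random Ka-subset A of a universe of
# size N, against a fixed Kb-subset B, by enumerating all Ka-subsets.
oracle_hyper_tail <- function(N, Ka, Kb, s) {
  if (s <= 0) return(1)
  if (Ka == 0 || Kb == 0) return(0)
  subsets <- utils::combn(N, Ka)
  B <- seq_len(Kb)
  mean(apply(subsets, 2, function(A) length(intersect(A, B)) >= s))
}

# Exhaustive pseudo-offspring support: the child dosages reachable from the
# four transmitted-allele combinations.
oracle_offspring_support <- function(f, m) {
  tf <- if (f == 1) c(0, 1) else rep(f / 2, 2)
  tm <- if (m == 1) c(0, 1) else rep(m / 2, 2)
  sort(unique(as.vector(outer(tf, tm, `+`))))
}
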