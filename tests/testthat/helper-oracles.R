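# Independent oracles used across the suite: exhaustive enumeration of
# internal-node states for parsimony scores, Mk likelihoods and marginals,
# and the permutation distribution of the Wilcoxon U statistic.  These stay
# deliberately brute-force and share no code with the implementation.

# random rooted binary tree with branch lengths, deterministic under seed
random_rooted_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 2)
  tr
}

# all assignments of 0/1 to internal nodes
internal_assignments <- function(n_internal) {
  if (n_internal == 0L) return(matrix(integer(), nrow = 1, ncol = 0))
  as.matrix(expand.grid(rep(list(0:1), n_internal)))
}

# minimum number of state changes over all internal labelings
oracle_parsimony_score <- function(tree, tipstates) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  asg <- internal_assignments(tree$Nnode)
  best <- Inf
  for (i in seq_len(nrow(asg))) {
    st <- integer(nn)
    st[seq_len(ntip)] <- tipstates[tree$tip.label]
    st[(ntip + 1):nn] <- asg[i, ]
    changes <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# full joint enumeration of the two-state chain: likelihood and per-node
# marginal presence probabilities
oracle_mk <- function(tree, tipstates, a, b, prior = "stationary") {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  s <- a + b
  pi1 <- if (s == 0) 0.5 else a / s
  pi0 <- 1 - pi1
  pr_root <- switch(prior, stationary = c(pi0, pi1), flat = c(0.5, 0.5))
  pmat <- function(t) {
    e <- exp(-s * t)
    matrix(c(pi0 + pi1 * e, pi1 * (1 - e),
             pi0 * (1 - e), pi1 + pi0 * e), 2, 2, byrow = TRUE)
  }
  Ps <- lapply(tree$edge.length, pmat)
  asg <- internal_assignments(tree$Nnode)
  tot <- 0
  marg <- numeric(nn)
  for (i in seq_len(nrow(asg))) {
    st <- integer(nn)
    st[seq_len(ntip)] <- tipstates[tree$tip.label]
    st[(ntip + 1):nn] <- asg[i, ]
    p <- pr_root[st[ntip + 1] + 1]
    for (e in seq_len(nrow(tree$edge)))
      p <- p * Ps[[e]][st[tree$edge[e, 1]] + 1, st[tree$edge[e, 2]] + 1]
    tot <- tot + p
    marg <- marg + p * st
  }
  list(lik = tot, marginals = marg / tot)
}

# exact two-sided p for the rank-sum test by enumeration of group labels
oracle_wilcoxon_p <- function(xs, ys) {
  n <- length(xs); m <- length(ys)
  r <- rank(c(xs, ys))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# tiny annotation table shared by several io / assignment tests
tiny_hits <- function() {
  data.frame(
    protein_id = c("P1", "P1", "P2", "P3", "P3", "P3"),
    species_id = c("spA", "spA", "spA", "spB", "spB", "spB"),
    domain_name = c("ubiquitin", "UBA", "ubiquitin", "F-box", "LRR", "LRR"),
    ali_start = c(1L, 90L, 1L, 5L, 60L, 120L),
    ali_end = c(76L, 130L, 76L, 45L, 100L, 160L),
    e_value = c(1e-30, 1e-8, 1e-25, 1e-12, 1e-6, 1e-5),
    stringsAsFactors = FALSE)
}

basic_config <- function() {
  family_config(data.frame(
    family = c("Ub", "F-box", "ThiF", "UQ_con", "zf-RING_2", "JAB"),
    core_domain = c("ubiquitin", "F-box", "ThiF", "UQ_con", "zf-RING_2",
                    "JAB"),
    system = c("Ub", "Ub", "shared", "shared", "Ub", "Ub"),
    role = c("label", "CRL-subunit", "E1", "E2", "E3", "peptidase"),
    refinement = NA_character_, stringsAsFactors = FALSE))
}
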