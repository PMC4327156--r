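# Ancestral gain/loss reconstruction of gene families on a rooted species
# tree: Fitch parsimony (unit-cost Sankoff dynamic programme, multifurcation
# safe, ACCTRAN/DELTRAN mapping), Dollo parsimony (single gain above the
# MRCA of presence leaves, minimal losses below), and an asymmetric binary
# Mk model (continuous-time two-state chain with loss/gain rate ratio fixed
# to a bias, gain rate estimated by maximum likelihood via Felsenstein
# pruning, marginal ancestral states by the up-down algorithm).

# ---- tree helpers ----------------------------------------------------------

#' Node labels for every node of a tree
#'
#' Tips keep their labels; internal nodes use `node.label` where present and
#' non-empty, else `node<index>`.
#'
#' @param tree ape phylo
#' @return character vector indexed by ape node number
#' @export
node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  inner <- if (!is.null(tree$node.label)) tree$node.label
           else character(nnode)
  inner[is.na(inner) | !nzchar(inner)] <-
    paste0("node", (ntip + 1:nnode)[is.na(inner) | !nzchar(inner)])
  lab <- c(tree$tip.label, inner)
  if (anyDuplicated(lab)) stop("node labels not unique after filling")
  lab
}

node_index <- function(tree, label) {
  i <- match(label, node_labels(tree))
  if (is.na(i)) stop("unknown node label: ", label)
  i
}

children_of <- function(tree, node) {
  # ape's edge matrix preserves the Newick child order
  tree$edge[tree$edge[, 1] == node, 2]
}

descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- children_of(tree, node)
  unlist(lapply(kids, descendant_tips, tree = tree))
}

descendant_nodes <- function(tree, node) {
  kids <- children_of(tree, node)
  if (length(kids) == 0L) return(integer())
  c(kids, unlist(lapply(kids, descendant_nodes, tree = tree)))
}

root_of <- function(tree) length(tree$tip.label) + 1L

postorder_edges <- function(tree) {
  ape::reorder.phylo(tree, "postorder")$edge
}

check_tips_in_matrix <- function(tree, pa) {
  missing <- setdiff(tree$tip.label, colnames(pa))
  if (length(missing))
    stop("tree leaves missing from matrix: ", paste(missing, collapse = ", "))
}

# ---- event map -------------------------------------------------------------

new_event_map <- function(tree, presence, gains, losses, score, method) {
  structure(list(tree = tree, presence = presence, gains = gains,
                 losses = losses, score = score, method = method),
            class = "event_map")
}

#' @export
print.event_map <- function(x, ...) {
  cat("event_map (", x$method, "): ", ncol(x$presence), " families, ",
      nrow(x$gains), " gains, ", nrow(x$losses), " losses\n", sep = "")
  invisible(x)
}

event_df <- function() {
  data.frame(node = character(), family = character(),
             stringsAsFactors = FALSE)
}

# ---- Fitch parsimony -------------------------------------------------------

#' Fitch parsimony reconstruction of gene-family gains and losses
#'
#' Unit-cost dynamic programme over the rooted tree (handles multifurcations
#' natively).  Per family the number of mapped state changes equals the
#' Fitch minimum; changes are placed on branches under the chosen
#' resolution: `ACCTRAN` accepts a change as early (rootward) as possible
#' when costs tie, `DELTRAN` delays it.  A root tie (both states equally
#' parsimonious) resolves toward absence by default, biasing against
#' trivially ancestral calls; set `root_tie = "present"` to flip.
#'
#' @param tree rooted ape phylo; leaves must appear in `pa`
#' @param pa presence/absence matrix, rows = families, columns = species
#' @param resolution `"ACCTRAN"` or `"DELTRAN"`
#' @param root_tie `"absent"` or `"present"`
#' @return an `event_map`: per-node presence matrix (nodes x families),
#'   per-branch `gains`/`losses` tables keyed by the branch's child node
#'   label, and the per-family parsimony `score`
#' @export
fitch_reconstruct <- function(tree, pa, resolution = c("ACCTRAN", "DELTRAN"),
                              root_tie = c("absent", "present")) {
  resolution <- match.arg(resolution)
  root_tie <- match.arg(root_tie)
  check_tips_in_matrix(tree, pa)
  labs <- node_labels(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- root_of(tree)
  po <- postorder_edges(tree)
  fams <- rownames(pa)
  presence <- matrix(0L, nrow = nnode, ncol = length(fams),
                     dimnames = list(labs, fams))
  gains <- list(); losses <- list()
  score <- stats::setNames(integer(length(fams)), fams)
  tipstate <- pa[, tree$tip.label, drop = FALSE]
  for (f in seq_along(fams)) {
    # bottom-up: cost[v, s+1] = min changes in subtree of v given state s
    cost <- matrix(0, nrow = nnode, ncol = 2)
    s <- tipstate[f, ]
    cost[seq_len(ntip), 1] <- ifelse(s == 0L, 0, Inf)
    cost[seq_len(ntip), 2] <- ifelse(s == 1L, 0, Inf)
    for (e in seq_len(nrow(po))) {
      p <- po[e, 1]; ch <- po[e, 2]
      cost[p, 1] <- cost[p, 1] + min(cost[ch, 1], cost[ch, 2] + 1)
      cost[p, 2] <- cost[p, 2] + min(cost[ch, 2], cost[ch, 1] + 1)
    }
    score[f] <- min(cost[root, ])
    state <- integer(nnode)
    state[root] <- if (cost[root, 2] < cost[root, 1]) 1L
                   else if (cost[root, 1] < cost[root, 2]) 0L
                   else if (root_tie == "absent") 0L else 1L
    # top-down in preorder (reverse postorder visits parents first)
    for (e in rev(seq_len(nrow(po)))) {
      p <- po[e, 1]; ch <- po[e, 2]
      sp <- state[p]
      stay <- cost[ch, sp + 1]
      move <- cost[ch, 2 - sp] + 1
      state[ch] <- if (stay < move) sp
                   else if (move < stay) 1L - sp
                   else if (resolution == "ACCTRAN") 1L - sp else sp
      if (state[ch] > sp)
        gains[[length(gains) + 1L]] <- c(labs[ch], fams[f])
      else if (state[ch] < sp)
        losses[[length(losses) + 1L]] <- c(labs[ch], fams[f])
    }
    presence[, f] <- state
  }
  as_events <- function(lst) {
    if (length(lst) == 0L) return(event_df())
    m <- do.call(rbind, lst)
    data.frame(node = m[, 1], family = m[, 2], stringsAsFactors = FALSE)
  }
  new_event_map(tree, presence, as_events(gains), as_events(losses), score,
                paste0("fitch/", resolution))
}

# ---- Dollo parsimony -------------------------------------------------------

#' Dollo parsimony reconstruction
#'
#' Each family is allowed a single gain, placed on the branch above the most
#' recent common ancestor of all presence leaves (at the root itself when
#' presence spans the root); losses are placed minimally below it, on the
#' topmost branches whose subtrees contain no presence leaf.
#'
#' @inheritParams fitch_reconstruct
#' @return an `event_map` (one gain per family with any presence)
#' @export
dollo_reconstruct <- function(tree, pa) {
  check_tips_in_matrix(tree, pa)
  labs <- node_labels(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  fams <- rownames(pa)
  presence <- matrix(0L, nrow = nnode, ncol = length(fams),
                     dimnames = list(labs, fams))
  gains <- event_df(); losses <- event_df()
  score <- stats::setNames(integer(length(fams)), fams)
  po <- postorder_edges(tree)
  # has_leaf[v]: does the subtree of v contain a presence leaf?
  for (f in seq_along(fams)) {
    ptips <- match(tree$tip.label[pa[f, tree$tip.label] == 1L],
                   tree$tip.label)
    if (length(ptips) == 0L) next
    has_leaf <- logical(nnode)
    has_leaf[ptips] <- TRUE
    for (e in seq_len(nrow(po)))
      has_leaf[po[e, 1]] <- has_leaf[po[e, 1]] || has_leaf[po[e, 2]]
    mrca <- if (length(ptips) == 1L) ptips
            else ape::getMRCA(tree, ptips)
    inside <- c(mrca, descendant_nodes(tree, mrca))
    state <- logical(nnode)
    state[inside] <- has_leaf[inside]
    presence[, f] <- as.integer(state)
    gains <- rbind(gains, data.frame(node = labs[mrca], family = fams[f],
                                     stringsAsFactors = FALSE))
    # topmost absent branches inside the gain clade are the losses
    for (v in inside) {
      if (!state[v]) next
      for (ch in children_of(tree, v)) {
        if (!state[ch])
          losses <- rbind(losses,
                          data.frame(node = labs[ch], family = fams[f],
                                     stringsAsFactors = FALSE))
      }
    }
    score[f] <- 1L + sum(losses$family == fams[f])
  }
  new_event_map(tree, presence, gains, losses, score, "dollo")
}

# ---- asymmetric Mk likelihood model ---------------------------------------

# transition probabilities of the two-state chain with gain rate a (0 -> 1)
# and loss rate b (1 -> 0) over branch lengths t
mk_pmats <- function(a, b, t) {
  s <- a + b
  if (s == 0) {
    ones <- rep(1, length(t)); zeros <- rep(0, length(t))
    return(list(p00 = ones, p01 = zeros, p10 = zeros, p11 = ones))
  }
  e <- exp(-s * t)
  pi1 <- a / s; pi0 <- b / s
  list(p00 = pi0 + pi1 * e, p01 = pi1 * (1 - e),
       p10 = pi0 * (1 - e), p11 = pi1 + pi0 * e)
}

mk_root_prior <- function(a, b, root_prior) {
  switch(root_prior,
    stationary = if (a + b == 0) c(0.5, 0.5) else c(b, a) / (a + b),
    flat = c(0.5, 0.5),
    fixed_absent = c(1, 0),
    fixed_present = c(0, 1))
}

# pruning pass over all characters at once; states is a (families x species)
# 0/1 matrix.  Returns per-node partial likelihood matrices and the summed
# log-likelihood per character.
mk_prune <- function(tree, states, a, b, root_prior) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nch <- nrow(states)
  po <- postorder_edges(tree)
  elen <- tree$edge.length
  P <- mk_pmats(a, b, elen)
  L0 <- matrix(1, nnode, nch); L1 <- matrix(1, nnode, nch)
  tipstates <- states[, tree$tip.label, drop = FALSE]
  L0[seq_len(ntip), ] <- t(tipstates == 0L) + 0
  L1[seq_len(ntip), ] <- t(tipstates == 1L) + 0
  logscale <- numeric(nch)
  # map postorder edges back to rows of tree$edge to index branch lengths
  eid <- match(paste(po[, 1], po[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1]; ch <- po[e, 2]; k <- eid[e]
    c0 <- P$p00[k] * L0[ch, ] + P$p01[k] * L1[ch, ]
    c1 <- P$p10[k] * L0[ch, ] + P$p11[k] * L1[ch, ]
    L0[p, ] <- L0[p, ] * c0
    L1[p, ] <- L1[p, ] * c1
    # rescale the parent occasionally to avoid underflow
    mx <- pmax(L0[p, ], L1[p, ])
    pos <- mx > 0 & mx < 1e-150
    if (any(pos)) {
      L0[p, pos] <- L0[p, pos] / mx[pos]
      L1[p, pos] <- L1[p, pos] / mx[pos]
      logscale[pos] <- logscale[pos] + log(mx[pos])
    }
  }
  root <- root_of(tree)
  pr <- mk_root_prior(a, b, root_prior)
  lik <- pr[1] * L0[root, ] + pr[2] * L1[root, ]
  list(L0 = L0, L1 = L1, loglik = log(lik) + logscale,
       root_lik = lik, P = P, eid = eid, prior = pr)
}

#' Fit the asymmetric binary Mk model
#'
#' Two-state continuous-time Markov chain on the tree with gain rate
#' \eqn{\alpha} (absent to present) and loss rate \eqn{\beta = r\alpha}
#' where `bias` \eqn{= r} is fixed (default 0.1, i.e. losses ten times
#' slower per unit branch length than gains; flip the ratio by passing
#' `bias > 1`).  The gain rate is estimated by maximizing the Felsenstein
#' pruning likelihood; the root prior defaults to the chain's stationary
#' distribution \eqn{\pi_1 = \alpha/(\alpha+\beta) = 1/(1+r)}.
#' Optimization is a bracketed Brent search on \eqn{\log\alpha}
#' (deterministic, tolerance 1e-8).
#'
#' @param tree rooted ape phylo with branch lengths
#' @param states binary character: a named vector (species -> 0/1), or a
#'   families-x-species 0/1 matrix
#' @param bias fixed loss/gain rate ratio r
#' @param rate_mode `"per_character"` fits one gain rate per matrix row;
#'   `"shared"` fits a single rate maximizing the summed log-likelihood
#' @param root_prior root state prior
#' @param interval search interval for the gain rate
#' @return object of class `mk_fit`: per-character `gain_rate`,
#'   `loss_rate`, `log_likelihood`, plus the tree, data and settings needed
#'   by [mk_ancestral()]
#' @export
mk_fit <- function(tree, states, bias = 0.1,
                   rate_mode = c("per_character", "shared"),
                   root_prior = c("stationary", "flat", "fixed_absent",
                                  "fixed_present"),
                   interval = c(1e-8, 1e3)) {
  rate_mode <- match.arg(rate_mode)
  root_prior <- match.arg(root_prior)
  if (is.null(tree$edge.length))
    stop("mk_fit requires branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (is.vector(states))
    states <- matrix(states, nrow = 1,
                     dimnames = list("char1", names(states)))
  check_tips_in_matrix(tree, states)
  stopifnot(all(states %in% c(0L, 1L)), bias > 0)

  ll_at <- function(loga) {
    a <- exp(loga)
    mk_prune(tree, states, a, bias * a, root_prior)$loglik
  }
  bounds <- log(interval)
  # zero-likelihood regions (conflicting data on zero-length subtrees) give
  # -Inf log-likelihoods; cap the objective so the bracketed search stays
  # finite and quiet
  finite_obj <- function(v) if (is.finite(v)) v else .Machine$double.xmax
  if (rate_mode == "shared") {
    opt <- stats::optimize(function(x) finite_obj(-sum(ll_at(x))), bounds,
                           tol = 1e-9)
    alpha <- rep(exp(opt$minimum), nrow(states))
    ll <- ll_at(opt$minimum)
  } else {
    alpha <- numeric(nrow(states))
    ll <- numeric(nrow(states))
    for (f in seq_len(nrow(states))) {
      row <- states[f, , drop = FALSE]
      g <- function(x) {
        a <- exp(x)
        finite_obj(-mk_prune(tree, row, a, bias * a, root_prior)$loglik)
      }
      opt <- stats::optimize(g, bounds, tol = 1e-9)
      alpha[f] <- exp(opt$minimum)
      ll[f] <- mk_prune(tree, row, alpha[f], bias * alpha[f],
                        root_prior)$loglik
    }
  }
  if (any(!is.finite(ll))) {
    warning("zero likelihood for character(s) ",
            paste(rownames(states)[!is.finite(ll)], collapse = ", "),
            " (conflicting states on a zero-length tree?); ",
            "log-likelihood reported as -Inf")
    alpha[!is.finite(ll)] <- NA_real_
  }
  structure(list(tree = tree, states = states, bias = bias,
                 gain_rate = stats::setNames(alpha, rownames(states)),
                 loss_rate = stats::setNames(bias * alpha, rownames(states)),
                 log_likelihood = stats::setNames(ll, rownames(states)),
                 rate_mode = rate_mode, root_prior = root_prior),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("mk_fit (", x$rate_mode, "): ", nrow(x$states),
      " character(s), bias (loss/gain) = ", x$bias,
      ", total logLik = ", sum(x$log_likelihood), "\n", sep = "")
  invisible(x)
}

#' Marginal ancestral states under a fitted Mk model
#'
#' Standard up-down (outside) pass at the fitted rates: the marginal
#' presence probability of node v is proportional to the product of the
#' likelihood of the data below v and of the data outside v's subtree,
#' conditioned on v's state.  A node is called present when its marginal
#' exceeds 0.5.
#'
#' @param fit mk_fit
#' @return list with `marginals` (nodes x characters matrix of presence
#'   probabilities) and `calls` (binary matrix, 1 iff marginal > 0.5)
#' @export
mk_ancestral <- function(fit) {
  tree <- fit$tree
  states <- fit$states
  labs <- node_labels(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- root_of(tree)
  nch <- nrow(states)
  marg <- matrix(NA_real_, nnode, nch, dimnames = list(labs, rownames(states)))
  po <- postorder_edges(tree)
  for (f in seq_len(nch)) {
    a <- fit$gain_rate[f]
    if (is.na(a)) next
    b <- fit$bias * a
    pr <- mk_prune(tree, states[f, , drop = FALSE], a, b, fit$root_prior)
    P <- pr$P; eid <- pr$eid
    L0 <- pr$L0[, 1]; L1 <- pr$L1[, 1]
    G0 <- numeric(nnode); G1 <- numeric(nnode)
    G0[root] <- pr$prior[1]; G1[root] <- pr$prior[2]
    # preorder: parent outside values are ready before each child is visited
    for (e in rev(seq_len(nrow(po)))) {
      p <- po[e, 1]; ch <- po[e, 2]; k <- eid[e]
      u0 <- G0[p]; u1 <- G1[p]
      for (sib in children_of(tree, p)) {
        if (sib == ch) next
        ks <- match(paste(p, sib), paste(tree$edge[, 1], tree$edge[, 2]))
        u0 <- u0 * (P$p00[ks] * L0[sib] + P$p01[ks] * L1[sib])
        u1 <- u1 * (P$p10[ks] * L0[sib] + P$p11[ks] * L1[sib])
      }
      G0[ch] <- u0 * P$p00[k] + u1 * P$p10[k]
      G1[ch] <- u0 * P$p01[k] + u1 * P$p11[k]
      m <- max(G0[ch], G1[ch])
      if (m > 0 && m < 1e-150) { G0[ch] <- G0[ch] / m; G1[ch] <- G1[ch] / m }
    }
    w1 <- G1 * L1; w0 <- G0 * L0
    tot <- w0 + w1
    marg[tot > 0, f] <- (w1 / tot)[tot > 0]
  }
  list(marginals = marg, calls = (marg > 0.5) + 0L)
}

# ---- event summaries -------------------------------------------------------

#' Summarize gains and losses below a named node
#'
#' Counts families whose gain or loss branch lies strictly within the clade
#' below `node` (the branch into `node` itself is excluded), and reports the
#' reconstructed ancestral toolkit at the node.
#'
#' @param events event_map
#' @param node node label (e.g. `"LECA"`)
#' @return list with `gains_after`, `losses_after`, `present_at_node`
#' @export
summarize_events <- function(events, node) {
  tree <- events$tree
  labs <- node_labels(tree)
  idx <- node_index(tree, node)
  below <- labs[descendant_nodes(tree, idx)]
  list(
    gains_after = sum(events$gains$node %in% below),
    losses_after = sum(events$losses$node %in% below),
    present_at_node = colnames(events$presence)[
      events$presence[node, ] == 1L])
}
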