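# Synthetic-data generator with ground truth: binary gene families evolving
# by a two-state gain/loss chain along a tree, per-species gene counts
# conditional on presence (shifted geometric), and per-family accessory
# architectures with lineage-specific shuffling.  A single integer seed
# governs all draws through a per-family derived stream, so results do not
# depend on iteration order.

fam_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * k) %% 2147483647)
}

#' Simulate binary gene-family characters on a tree
#'
#' Each family's root state is drawn according to `root_presence`
#' (`stationary` uses the chain's equilibrium presence probability
#' `gain_rate / (gain_rate + loss_rate)`); the state then evolves down every
#' branch under the two-state continuous-time chain with the given per-unit
#' branch-length rates.  Leaf states are emitted as a presence/absence
#' matrix; all node states and net per-branch events are recorded as truth.
#'
#' @param tree rooted ape phylo with branch lengths
#' @param n_families number of independent characters
#' @param gain_rate,loss_rate rates >= 0 (0 -> 1 and 1 -> 0)
#' @param root_presence `"stationary"`, `"fixed_absent"` or `"fixed_present"`
#' @param seed integer seed
#' @return list with `pa` (families x species 0/1 matrix) and `truth`
#'   (class `simulated_truth`: per-node states, per-branch `gains`/`losses`,
#'   the rates and settings)
#' @export
simulate_characters <- function(tree, n_families, gain_rate, loss_rate,
                                root_presence = c("stationary",
                                                  "fixed_absent",
                                                  "fixed_present"),
                                seed = 1L) {
  root_presence <- match.arg(root_presence)
  stopifnot(gain_rate >= 0, loss_rate >= 0, n_families >= 1)
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  labs <- node_labels(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- root_of(tree)
  po <- postorder_edges(tree)
  eid <- match(paste(po[, 1], po[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
  P <- mk_pmats(gain_rate, loss_rate, tree$edge.length)
  pi1 <- if (gain_rate + loss_rate == 0) 0.5
         else gain_rate / (gain_rate + loss_rate)
  fams <- paste0("FAM", seq_len(n_families))
  node_states <- matrix(0L, nnode, n_families, dimnames = list(labs, fams))
  gains <- list(); losses <- list()
  for (f in seq_len(n_families)) {
    set.seed(fam_seed(seed, f))
    state <- integer(nnode)
    state[root] <- switch(root_presence,
      stationary = stats::rbinom(1, 1, pi1),
      fixed_absent = 0L, fixed_present = 1L)
    for (e in rev(seq_len(nrow(po)))) {     # preorder: parent before child
      p <- po[e, 1]; ch <- po[e, 2]; k <- eid[e]
      p1 <- if (state[p] == 1L) P$p11[k] else P$p01[k]
      state[ch] <- stats::rbinom(1, 1, p1)
      if (state[ch] > state[p])
        gains[[length(gains) + 1L]] <- c(labs[ch], fams[f])
      else if (state[ch] < state[p])
        losses[[length(losses) + 1L]] <- c(labs[ch], fams[f])
    }
    node_states[, f] <- state
  }
  as_events <- function(lst) {
    if (length(lst) == 0L)
      return(data.frame(node = character(), family = character(),
                        stringsAsFactors = FALSE))
    m <- do.call(rbind, lst)
    data.frame(node = m[, 1], family = m[, 2], stringsAsFactors = FALSE)
  }
  pa <- t(node_states[seq_len(ntip), , drop = FALSE])
  truth <- structure(list(tree = tree, node_states = node_states,
                          gains = as_events(gains), losses = as_events(losses),
                          gain_rate = gain_rate, loss_rate = loss_rate,
                          root_presence = root_presence, seed = seed),
                     class = "simulated_truth")
  list(pa = pa, truth = truth)
}

#' Simulate gene counts conditional on presence
#'
#' Absent cells are 0; present cells are `1 + Geometric` with mean
#' `count_mean - 1`, so the expected present-cell count is `count_mean`
#' (`count_mean = 1` gives every present cell exactly one gene).
#'
#' @param pa presence/absence matrix
#' @param count_mean mean gene count of present cells (>= 1)
#' @param seed integer seed
#' @return integer count matrix of the same shape
#' @export
simulate_counts <- function(pa, count_mean = 3, seed = 1L) {
  if (count_mean < 1) stop("count_mean must be >= 1")
  counts <- matrix(0L, nrow(pa), ncol(pa), dimnames = dimnames(pa))
  prob <- 1 / count_mean
  for (f in seq_len(nrow(pa))) {
    set.seed(fam_seed(seed, f))
    pres <- pa[f, ] == 1L
    counts[f, pres] <- 1L + stats::rgeom(sum(pres), prob)
  }
  counts
}

#' Simulate accessory-domain architectures
#'
#' Each family carries a pool of candidate accessory domains; the ancestral
#' accessory set is drawn at the root (each pool member with probability
#' 1/2) and membership then toggles along each branch with probability
#' `1 - exp(-shuffle_rate * t)` per domain.  For every present
#' (family, species) cell the generator emits proteins (one per gene when a
#' count matrix is given, else one) carrying the family's core domain plus
#' the species' accessory set, as an annotation set writable through
#' [write_annotation_tsv()].
#'
#' @param pa presence/absence matrix (families x species)
#' @param tree the tree the matrix was simulated on
#' @param accessory_pool_size candidate accessory domains per family (>= 1)
#' @param shuffle_rate per-unit-branch-length toggle rate (0 = frozen)
#' @param counts optional count matrix (genes per present cell)
#' @param seed integer seed
#' @return list with `annotations` (annotation_set) and `truth` (class
#'   `simulated_architectures`: per-node logical membership matrices per
#'   family, the core-domain naming, the pool)
#' @export
simulate_architectures <- function(pa, tree, accessory_pool_size = 4,
                                   shuffle_rate = 0.2, counts = NULL,
                                   seed = 1L) {
  stopifnot(accessory_pool_size >= 1, shuffle_rate >= 0)
  labs <- node_labels(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- root_of(tree)
  po <- postorder_edges(tree)
  eid <- match(paste(po[, 1], po[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
  fams <- rownames(pa)
  node_sets <- list()
  rows <- list()
  for (f in seq_along(fams)) {
    fam <- fams[f]
    set.seed(fam_seed(seed, 10000L + f))
    pool <- paste0(fam, "_acc", seq_len(accessory_pool_size))
    member <- matrix(FALSE, nnode, accessory_pool_size,
                     dimnames = list(labs, pool))
    member[root, ] <- stats::runif(accessory_pool_size) < 0.5
    for (e in rev(seq_len(nrow(po)))) {
      p <- po[e, 1]; ch <- po[e, 2]
      t_br <- tree$edge.length[eid[e]]
      flip <- stats::runif(accessory_pool_size) <
        (1 - exp(-shuffle_rate * t_br))
      member[ch, ] <- xor(member[p, ], flip)
    }
    node_sets[[fam]] <- member
    core <- paste0(fam, "_core")
    for (sp in colnames(pa)) {
      if (pa[fam, sp] != 1L) next
      acc <- pool[member[sp, ]]
      ngene <- if (is.null(counts)) 1L else counts[fam, sp]
      for (g in seq_len(ngene)) {
        pid <- paste0(sp, "_", fam, "_g", g)
        doms <- c(core, acc)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = pid, species_id = sp, domain_name = doms,
          ali_start = seq(1L, by = 100L, length.out = length(doms)),
          ali_end = seq(80L, by = 100L, length.out = length(doms)),
          e_value = 1e-10, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else NULL
  truth <- structure(list(tree = tree, node_sets = node_sets,
                          shuffle_rate = shuffle_rate,
                          accessory_pool_size = accessory_pool_size,
                          seed = seed),
                     class = "simulated_architectures")
  list(annotations = annotation_set(hits), truth = truth)
}

#' Family configuration matching a simulated dataset
#'
#' Maps each simulated family to its synthetic core domain
#' (`<family>_core`) so that simulated annotation tables round-trip through
#' [assign_families()] and [build_count_matrix()].
#'
#' @param families character vector of family names (e.g. `rownames(pa)`)
#' @return family_config
#' @export
synthetic_family_config <- function(families) {
  family_config(data.frame(
    family = families, core_domain = paste0(families, "_core"),
    system = "Ub", role = "other", refinement = NA_character_,
    stringsAsFactors = FALSE))
}

#' Compare an inference against simulated truth
#'
#' Generic validation harness.  For an `event_map`: root-state sensitivity
#' and specificity over families, plus branch-event recall and precision on
#' (branch, family, gain/loss) triples.  For an `mk_fit`: the relative
#' error of the fitted gain rate.  For a `domain_network`: the fraction of
#' true ancestral core-accessory edges at a node that were recovered
#' (`edge_recall`).
#'
#' @param truth the matching `simulated_truth` / `simulated_architectures`
#' @param inferred an `event_map`, `mk_fit` or `domain_network`
#' @param ... method-specific arguments (`node` for networks)
#' @return named list of scores
#' @export
recovery_report <- function(truth, inferred, ...) {
  UseMethod("recovery_report", inferred)
}

check_same_tree <- function(truth, tree) {
  if (!setequal(truth$tree$tip.label, tree$tip.label) ||
      truth$tree$Nnode != tree$Nnode)
    stop("truth and inference derive from different trees")
}

#' @export
recovery_report.event_map <- function(truth, inferred, ...) {
  check_same_tree(truth, inferred$tree)
  labs <- node_labels(truth$tree)
  root_lab <- labs[root_of(truth$tree)]
  true_root <- truth$node_states[root_lab, ]
  infer_root <- inferred$presence[root_lab, colnames(truth$node_states)]
  sens <- if (sum(true_root == 1L) == 0) NA_real_
          else mean(infer_root[true_root == 1L] == 1L)
  spec <- if (sum(true_root == 0L) == 0) NA_real_
          else mean(infer_root[true_root == 0L] == 0L)
  ev_key <- function(g, l) c(
    if (nrow(g)) paste("G", g$node, g$family),
    if (nrow(l)) paste("L", l$node, l$family))
  true_ev <- ev_key(truth$gains, truth$losses)
  inf_ev <- ev_key(inferred$gains, inferred$losses)
  list(sensitivity = sens, specificity = spec,
       event_recall = if (length(true_ev) == 0) NA_real_
                      else mean(true_ev %in% inf_ev),
       event_precision = if (length(inf_ev) == 0) NA_real_
                         else mean(inf_ev %in% true_ev))
}

#' @export
recovery_report.mk_fit <- function(truth, inferred, ...) {
  check_same_tree(truth, inferred$tree)
  if (truth$gain_rate <= 0) stop("true gain rate is zero")
  rel <- abs(inferred$gain_rate - truth$gain_rate) / truth$gain_rate
  list(rate_relative_error = unname(rel[1]),
       rate_relative_error_all = rel)
}

#' @export
recovery_report.domain_network <- function(truth, inferred, ..., node,
                                           present_families = NULL) {
  check_same_tree(truth, truth$tree)  # arch truth carries its own tree
  fams <- names(truth$node_sets)
  if (!is.null(present_families)) fams <- intersect(fams, present_families)
  true_edges <- character()
  for (fam in fams) {
    acc <- colnames(truth$node_sets[[fam]])[truth$node_sets[[fam]][node, ]]
    if (length(acc))
      true_edges <- c(true_edges, paste(paste0(fam, "_core"), acc))
  }
  inf_edges <- c(paste(inferred$edges$from, inferred$edges$to),
                 paste(inferred$edges$to, inferred$edges$from))
  list(edge_recall = if (length(true_edges) == 0) NA_real_
                     else mean(true_edges %in% inf_edges),
       n_true_edges = length(true_edges))
}

# ---- fixture trees ---------------------------------------------------------

#' Balanced binary fixture tree
#'
#' @param n_tips number of leaves (a power of two, default 16)
#' @param branch_length length assigned to every branch
#' @return ape phylo with unit branch lengths and labeled internal nodes
#' @export
balanced_tree <- function(n_tips = 16, branch_length = 1) {
  if (bitwAnd(n_tips, n_tips - 1L) != 0L)
    stop("n_tips must be a power of two")
  tr <- ape::stree(n_tips, type = "balanced")
  tr$edge.length <- rep(branch_length, nrow(tr$edge))
  tr$node.label <- paste0("N", n_tips + seq_len(tr$Nnode))
  tr
}

#' Demonstration eukaryote species tree
#'
#' A 14-leaf consensus-style eukaryote topology rooted between Amorphea and
#' Bikonta, with named internal nodes (LECA, Amorphea, Opisthokonta,
#' Holozoa, Metazoa, Eumetazoa, Choanoflagellata, Fungi, Bikonta,
#' Viridiplantae, Embryophyta, Alveolata) and unit branch lengths.  Used by
#' the worked examples.
#'
#' @return ape phylo
#' @export
demo_species_tree <- function() {
  nwk <- paste0(
    "((((((Hsap:1,Nvec:1)Eumetazoa:1,Mlei:1)Metazoa:1,",
    "(Sros:1,Mbre:1)Choanoflagellata:1)Holozoa:1,",
    "(Scer:1,Spom:1)Fungi:1)Opisthokonta:1,Ddis:1)Amorphea:1,",
    "(((Atha:1,Ppat:1)Embryophyta:1,Crei:1)Viridiplantae:1,",
    "(Pfal:1,Tthe:1)Alveolata:1,Ngru:1)Bikonta:1)LECA;")
  read_newick(nwk)
}

#' Demonstration presence/absence matrix
#'
#' Builds the textbook gain pattern on [demo_species_tree()]: every family
#' present in every species, except families listed in `restricted`, which
#' are present only in the leaves of their named clade.  The default
#' restricts SOCS-box to Holozoa and IR1-M to Metazoa, the two families
#' that arose after the last eukaryotic common ancestor.
#'
#' @param tree ape phylo (default [demo_species_tree()])
#' @param families family names (default: the packaged survey)
#' @param restricted named character vector family -> clade node label
#' @return 0/1 matrix, families x species
#' @export
demo_presence_matrix <- function(tree = demo_species_tree(),
                                 families = config_families(
                                   default_family_config()),
                                 restricted = c("SOCS-box" = "Holozoa",
                                                "IR1-M" = "Metazoa")) {
  pa <- matrix(1L, length(families), length(tree$tip.label),
               dimnames = list(families, tree$tip.label))
  for (fam in names(restricted)) {
    if (!fam %in% families) next
    clade <- tree$tip.label[descendant_tips(tree,
                                            node_index(tree, restricted[[fam]]))]
    pa[fam, !colnames(pa) %in% clade] <- 0L
  }
  pa
}
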