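# Ancestral accessory-domain co-occurrence networks.  Edges link core
# domains to the accessory domains found on the same proteins (and core
# domains to each other); an edge is called ancestral at a tree node when
# the co-occurrence is observed both in the earliest-branching child clade
# (first child in Newick order — the user encodes the intended basal
# lineage by child ordering) and in at least one species of the remaining
# clade(s).  Node abundances and edge weights are medians over all species
# of the clade, zeros included, so half-integers can occur.

#' Construct a domain network object
#'
#' @param nodes data.frame with columns `name`, `role` (`core`/`accessory`),
#'   `abundance`
#' @param edges data.frame with columns `from`, `to`, `weight`
#' @return object of class `domain_network` with `density` and
#'   `degree_distribution` filled in
#' @export
domain_network <- function(nodes, edges) {
  stopifnot(all(c("name", "role", "abundance") %in% names(nodes)),
            all(c("from", "to", "weight") %in% names(edges)))
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  if (anyDuplicated(nodes$name)) stop("duplicate node names")
  missing <- setdiff(c(edges$from, edges$to), nodes$name)
  if (length(missing)) stop("edge endpoints missing from nodes: ",
                            paste(missing, collapse = ", "))
  net <- structure(list(nodes = nodes, edges = edges), class = "domain_network")
  met <- network_metrics(net)
  net$density <- met$density
  net$degree_distribution <- met$degree_distribution
  net
}

#' @export
print.domain_network <- function(x, ...) {
  cat("domain_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$role == "core"), "core ),", nrow(x$edges),
      "edges, density", signif(x$density, 4), "\n")
  invisible(x)
}

#' Convert a domain network to igraph
#' @param net domain_network
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Per-species domain co-occurrence table
#'
#' For each protein, every unordered pair of distinct domains with at least
#' one core member contributes one count; pairs of two core domains are
#' core-core edges.  Counts are per species numbers of proteins carrying the
#' pair.
#'
#' @param annotations annotation_set
#' @param config family_config (defines the core domain set)
#' @return data.frame with columns `species_id`, `domain_a`, `domain_b`
#'   (lexicographically ordered), `n_proteins`
#' @export
cooccurrence_table <- function(annotations, config) {
  hits <- annotations$hits
  cores <- unique(config$core_domain)
  empty <- data.frame(species_id = character(), domain_a = character(),
                      domain_b = character(), n_proteins = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  key <- paste(hits$species_id, hits$protein_id, sep = "\r")
  doms_by_protein <- lapply(split(hits$domain_name, key), function(d)
    sort(unique(d)))
  sp_of <- vapply(strsplit(names(doms_by_protein), "\r", fixed = TRUE),
                  `[`, character(1), 1L)
  rows <- list()
  for (i in seq_along(doms_by_protein)) {
    d <- doms_by_protein[[i]]
    if (length(d) < 2L || !any(d %in% cores)) next
    pairs <- utils::combn(d, 2L)
    keep <- pairs[1, ] %in% cores | pairs[2, ] %in% cores
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      species_id = sp_of[i], domain_a = pairs[1, keep],
      domain_b = pairs[2, keep], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  all <- do.call(rbind, rows)
  out <- stats::aggregate(list(n_proteins = rep(1L, nrow(all))),
                          all[, c("species_id", "domain_a", "domain_b")], sum)
  out <- out[order(out$species_id, out$domain_a, out$domain_b), ]
  rownames(out) <- NULL
  out
}

#' Reconstruct the ancestral domain network at a tree node
#'
#' A domain pair is called ancestral at the node iff it is observed (count
#' >= 1) in at least one species of the earliest-branching child clade (the
#' first child in Newick order) *and* in at least one species of the
#' remaining clade(s).  Core-node abundance is the median gene count of that
#' core domain's family over all species of the clade (zeros included);
#' edge weight is the median per-species co-occurrence count over the same
#' species.  Core nodes enter the network when their median abundance is
#' positive or they carry a retained edge; accessory nodes only via
#' retained edges, so every accessory node touches a core.  Reconstruction
#' uses extant species only, making node reconstructions independent; a
#' nested outside-in report is obtained by calling this per node.
#'
#' @param tree rooted ape phylo with labeled internal nodes
#' @param node internal node label
#' @param cooc co-occurrence table from [cooccurrence_table()]
#' @param counts family-by-species gene count matrix
#' @param config family_config (maps core domains to families)
#' @return domain_network
#' @export
reconstruct_ancestral_network <- function(tree, node, cooc, counts, config) {
  idx <- node_index(tree, node)
  ntip <- length(tree$tip.label)
  if (idx <= ntip) stop("node '", node, "' is a leaf")
  kids <- children_of(tree, idx)
  if (length(kids) < 2L) stop("node '", node, "' has fewer than 2 children")
  clade <- tree$tip.label[descendant_tips(tree, idx)]
  basal <- tree$tip.label[descendant_tips(tree, kids[1])]
  others <- setdiff(clade, basal)

  cc <- cooc[cooc$species_id %in% clade, , drop = FALSE]
  pk <- paste(cc$domain_a, cc$domain_b, sep = "\r")
  in_basal <- tapply(cc$species_id %in% basal, pk, any)
  in_other <- tapply(cc$species_id %in% others, pk, any)
  anc_pairs <- names(in_basal)[in_basal & in_other]

  cmap <- core_domain_map(config)
  med_count <- function(dom) {
    fam <- cmap[[dom]]
    v <- if (fam %in% rownames(counts))
      counts[fam, intersect(clade, colnames(counts))] else numeric()
    v <- c(v, rep(0, length(clade) - length(v)))
    stats::median(as.numeric(v))
  }
  edges <- data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (length(anc_pairs)) {
    parts <- strsplit(anc_pairs, "\r", fixed = TRUE)
    weights <- vapply(anc_pairs, function(p) {
      sub <- cc[pk == p, ]
      per <- stats::setNames(rep(0, length(clade)), clade)
      per[sub$species_id] <- sub$n_proteins
      stats::median(per)
    }, numeric(1))
    edges <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                        to = vapply(parts, `[`, character(1), 2L),
                        weight = unname(weights), stringsAsFactors = FALSE)
  }
  cores <- unique(config$core_domain)
  core_nodes <- sort(unique(c(
    cores[vapply(cores, med_count, numeric(1)) > 0],
    intersect(c(edges$from, edges$to), cores))))
  acc_nodes <- sort(setdiff(unique(c(edges$from, edges$to)), cores))
  nodes <- rbind(
    data.frame(name = core_nodes, role = rep("core", length(core_nodes)),
               abundance = vapply(core_nodes, med_count, numeric(1)),
               stringsAsFactors = FALSE),
    data.frame(name = acc_nodes, role = rep("accessory", length(acc_nodes)),
               abundance = rep(NA_real_, length(acc_nodes)),
               stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  domain_network(nodes, edges)
}

#' Density, edge count and degree distribution of a domain network
#'
#' Density is `2E / (N (N - 1))` over all nodes (0 by convention for fewer
#' than two nodes).
#'
#' @param net domain_network
#' @return list with `density`, `edge_count`, `degree_distribution` (named
#'   integer vector: degree -> number of nodes)
#' @export
network_metrics <- function(net) {
  n <- nrow(net$nodes); e <- nrow(net$edges)
  density <- if (n <= 1L) 0 else 2 * e / (n * (n - 1))
  if (n == 0L) {
    dd <- stats::setNames(integer(), character())
  } else {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    deg <- igraph::degree(g)
    tab <- table(deg)
    dd <- stats::setNames(as.integer(tab), names(tab))
  }
  list(density = density, edge_count = e, degree_distribution = dd)
}
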