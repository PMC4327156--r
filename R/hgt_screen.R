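# Reciprocal-similarity screen for horizontal-transfer candidates: take the
# top hits of each query under a forward e-value cutoff, collect the
# reverse-search hits under a (stricter) reverse cutoff, and report the
# domain-of-life composition of each query's reciprocal hits.  No binary
# HGT verdict is issued — the judgment is left to the user.

DOMAINS_OF_LIFE <- c("Eukaryota", "Archaea", "Bacteria", "unknown")

#' Top hits per query
#'
#' Retains, per query, the hits with `e_value <= max_e`, sorted by ascending
#' e-value, then descending bit score, then subject id (deterministic
#' tie-break at rank k), truncated at `k`.  Self-hits (query == subject) are
#' removed.
#'
#' @param hits data.frame of BLAST hits (see [read_blast_tab()])
#' @param k number of hits to keep per query (default 50)
#' @param max_e e-value cutoff (default 1e-5)
#' @return named list query_id -> data.frame of retained hits
#' @export
top_hits <- function(hits, k = 50, max_e = 1e-5) {
  if (nrow(hits) == 0L) return(stats::setNames(list(), character()))
  hits <- hits[hits$e_value <= max_e & hits$query_id != hits$subject_id, ,
               drop = FALSE]
  lapply(split(hits, hits$query_id), function(h) {
    h <- h[order(h$e_value, -h$bit_score, h$subject_id), , drop = FALSE]
    h <- utils::head(h, k)
    rownames(h) <- NULL
    h
  })
}

#' Build the reciprocal similarity network
#'
#' Edges are the forward top-k hits of each query plus the reverse hits
#' passing the (stricter) reverse cutoff.  For every query the composition
#' of its reciprocal (reverse) hits over the domains of life is reported;
#' subjects absent from the taxonomy map are labeled `unknown` with a
#' warning.  Queries with no qualifying reverse hits are flagged.
#'
#' @param forward data.frame of forward-search hits
#' @param reverse data.frame of reverse-search hits (searches seeded by the
#'   forward top hits)
#' @param taxonomy named character vector sequence id -> domain of life
#'   (`Eukaryota`, `Archaea`, `Bacteria`)
#' @param k top hits per query (default 50)
#' @param e_forward forward e-value cutoff (default 1e-5)
#' @param e_reverse reverse e-value cutoff (default 1e-10)
#' @return list of class `reciprocal_network`: `edges` (data.frame with
#'   `query_id`, `subject_id`, `e_value`, `stage` in forward/reverse),
#'   `composition` (data.frame `query_id`, one column per domain of life,
#'   `n_reverse_hits`, `empty`)
#' @export
build_reciprocal_network <- function(forward, reverse, taxonomy,
                                     k = 50, e_forward = 1e-5,
                                     e_reverse = 1e-10) {
  fw <- top_hits(forward, k = k, max_e = e_forward)
  fw_edges <- if (length(fw)) do.call(rbind, fw) else forward[0, ]
  rv <- reverse[reverse$e_value <= e_reverse &
                  reverse$query_id != reverse$subject_id, , drop = FALSE]
  edges <- rbind(
    if (nrow(fw_edges))
      data.frame(query_id = fw_edges$query_id,
                 subject_id = fw_edges$subject_id,
                 e_value = fw_edges$e_value, stage = "forward",
                 stringsAsFactors = FALSE),
    if (nrow(rv))
      data.frame(query_id = rv$query_id, subject_id = rv$subject_id,
                 e_value = rv$e_value, stage = "reverse",
                 stringsAsFactors = FALSE))
  if (is.null(edges))
    edges <- data.frame(query_id = character(), subject_id = character(),
                        e_value = numeric(), stage = character(),
                        stringsAsFactors = FALSE)
  edges <- edges[order(edges$stage, edges$query_id, edges$e_value,
                       edges$subject_id), , drop = FALSE]
  rownames(edges) <- NULL

  queries <- sort(unique(c(names(fw), rv$query_id)))
  tax_of <- function(ids) {
    d <- unname(taxonomy[ids])
    if (any(is.na(d))) {
      warning("subject id(s) missing from taxonomy map, labeled unknown: ",
              paste(utils::head(ids[is.na(d)], 5), collapse = ", "))
      d[is.na(d)] <- "unknown"
    }
    factor(d, levels = DOMAINS_OF_LIFE)
  }
  comp <- lapply(queries, function(q) {
    sub <- rv$subject_id[rv$query_id == q]
    n <- length(sub)
    frac <- if (n == 0L) stats::setNames(rep(NA_real_, 4), DOMAINS_OF_LIFE)
            else table(tax_of(sub)) / n
    data.frame(query_id = q, as.list(frac), n_reverse_hits = n,
               empty = n == 0L, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  composition <- if (length(comp)) do.call(rbind, comp)
    else data.frame(query_id = character(), Eukaryota = numeric(),
                    Archaea = numeric(), Bacteria = numeric(),
                    unknown = numeric(), n_reverse_hits = integer(),
                    empty = logical(), stringsAsFactors = FALSE)
  rownames(composition) <- NULL
  structure(list(edges = edges, composition = composition,
                 k = k, e_forward = e_forward, e_reverse = e_reverse),
            class = "reciprocal_network")
}

#' @export
print.reciprocal_network <- function(x, ...) {
  cat("reciprocal_network:", nrow(x$edges), "edges,",
      nrow(x$composition), "queries (cutoffs:", x$e_forward, "forward,",
      x$e_reverse, "reverse, top", x$k, ")\n")
  invisible(x)
}
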