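# Readers and writers for every external representation the pipeline touches.
# All downstream modules consume the domain objects built here: an
# `annotation_set` (per-species protein domain hits), an ape `phylo` species
# tree, BLAST tabular hit tables, and plain-TSV matrices / networks.
# Coordinates are 1-based inclusive throughout (Pfam convention).

HIT_COLUMNS <- c("protein_id", "species_id", "domain_name",
                 "ali_start", "ali_end", "e_value", "bit_score", "clan")

#' Construct an annotation set
#'
#' An annotation set is the package's representation of a per-species protein
#' domain survey: one row per domain hit, with 1-based inclusive alignment
#' coordinates, plus (optionally) the protein sequences needed for motif-based
#' family refinements.
#'
#' @param hits data.frame with columns `protein_id`, `species_id`,
#'   `domain_name`, `ali_start`, `ali_end`, `e_value` and optionally
#'   `bit_score`, `clan`.
#' @param sequences optional named character vector of amino-acid sequences,
#'   names are protein ids.
#' @return An object of class `annotation_set`: a list with elements `hits`
#'   (the validated, canonically sorted hit table) and `sequences`.
#' @export
annotation_set <- function(hits, sequences = NULL) {
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- empty_hits()
  } else {
    for (col in c("bit_score", "clan")) {
      if (!col %in% names(hits)) hits[[col]] <- NA
    }
    hits <- hits[, HIT_COLUMNS]
    hits$ali_start <- as.integer(hits$ali_start)
    hits$ali_end <- as.integer(hits$ali_end)
    hits$e_value <- as.numeric(hits$e_value)
    hits$bit_score <- as.numeric(hits$bit_score)
    hits$clan <- as.character(hits$clan)
    bad <- hits$ali_start > hits$ali_end | hits$e_value < 0
    if (any(bad)) {
      stop("invalid hits (ali_start > ali_end or e_value < 0) at rows: ",
           paste(which(bad), collapse = ", "))
    }
    # canonical sort makes the object independent of input row order
    hits <- hits[order(hits$species_id, hits$protein_id, hits$ali_start,
                       hits$domain_name, hits$e_value), , drop = FALSE]
    rownames(hits) <- NULL
    dup <- duplicated(hits[, c("species_id", "protein_id", "domain_name",
                               "ali_start", "ali_end")])
    hits <- hits[!dup, , drop = FALSE]
  }
  if (!is.null(sequences)) {
    sequences <- unlist(sequences)
    if (anyDuplicated(names(sequences)))
      stop("duplicate protein ids in sequences")
  }
  structure(list(hits = hits, sequences = sequences),
            class = "annotation_set")
}

empty_hits <- function() {
  data.frame(protein_id = character(), species_id = character(),
             domain_name = character(), ali_start = integer(),
             ali_end = integer(), e_value = numeric(),
             bit_score = numeric(), clan = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.annotation_set <- function(x, ...) {
  sp <- unique(x$hits$species_id)
  cat("annotation_set:", nrow(x$hits), "domain hits,",
      length(unique(x$hits$protein_id)), "proteins,",
      length(sp), "species\n")
  if (!is.null(x$sequences))
    cat("  with", length(x$sequences), "protein sequences\n")
  invisible(x)
}

#' Species represented in an annotation set
#' @param x annotation_set
#' @return character vector of species ids
#' @export
species_ids <- function(x) sort(unique(x$hits$species_id))

#' Merge annotation sets
#' @param ... annotation_set objects
#' @return a single combined annotation_set
#' @export
merge_annotations <- function(...) {
  sets <- list(...)
  hits <- do.call(rbind, lapply(sets, function(s) s$hits))
  seqs <- do.call(c, lapply(sets, function(s) s$sequences))
  annotation_set(hits, seqs)
}

#' Read a protein domain annotation table
#'
#' Parses per-species domain annotation files in either the `pfam_scan.pl`
#' output dialect (whitespace-separated; one file per species, so a
#' `species_id` must be supplied) or a simple six-column TSV dialect carrying
#' its own species column (`protein_id species_id domain_name ali_start
#' ali_end e_value`).  Parsing is permissive-with-report: malformed lines
#' (wrong field count, non-numeric coordinates, start > end, negative
#' e-value) are skipped and reported with their line numbers, never silently
#' dropped.  Hits are not e-value-filtered by default (upstream domain calls
#' are assumed to use the Pfam gathering threshold); pass `max_evalue` to
#' filter.
#'
#' @param path file path.
#' @param dialect `"simple_tsv"` or `"pfam_scan"`.
#' @param species_id species identifier; required for the pfam_scan dialect.
#' @param max_evalue optional numeric; hits with larger e-value are dropped.
#' @return annotation_set
#' @export
read_domain_table <- function(path, dialect = c("simple_tsv", "pfam_scan"),
                              species_id = NULL, max_evalue = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "pfam_scan" && is.null(species_id))
    stop("pfam_scan dialect is one file per species: supply species_id")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    warning("no annotation rows in ", path, "; returning empty set")
    return(annotation_set(NULL))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- integer()
  rows <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    f <- fields[[i]]
    row <- switch(dialect,
      simple_tsv = parse_simple_row(f),
      pfam_scan = parse_pfamscan_row(f, species_id))
    if (is.null(row)) bad <- c(bad, idx[i]) else rows[[i]] <- row
  }
  if (length(bad))
    warning("skipped ", length(bad), " malformed line(s) in ", path,
            " (lines: ", paste(bad, collapse = ", "), ")")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    warning("no parseable annotation rows in ", path)
    return(annotation_set(NULL))
  }
  hits <- do.call(rbind, rows)
  if (!is.null(max_evalue)) hits <- hits[hits$e_value <= max_evalue, ]
  annotation_set(hits)
}

parse_simple_row <- function(f) {
  if (length(f) < 6L) return(NULL)
  s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
  ev <- suppressWarnings(as.numeric(f[6]))
  if (is.na(s) || is.na(e) || is.na(ev) || s > e || ev < 0) return(NULL)
  data.frame(protein_id = f[1], species_id = f[2], domain_name = f[3],
             ali_start = s, ali_end = e, e_value = ev,
             bit_score = NA_real_, clan = NA_character_,
             stringsAsFactors = FALSE)
}

# pfam_scan.pl columns: <seq id> <ali start> <ali end> <env start> <env end>
# <hmm acc> <hmm name> <type> <hmm start> <hmm end> <hmm len> <bit score>
# <E-value> <significance> <clan>.  Only seq id, alignment coordinates, hmm
# name, bit score, e-value and clan are consumed.
parse_pfamscan_row <- function(f, species_id) {
  if (length(f) < 13L) return(NULL)
  s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
  ev <- suppressWarnings(as.numeric(f[13]))
  if (is.na(s) || is.na(e) || is.na(ev) || s > e || ev < 0) return(NULL)
  data.frame(protein_id = f[1], species_id = species_id, domain_name = f[7],
             ali_start = s, ali_end = e, e_value = ev,
             bit_score = suppressWarnings(as.numeric(f[12])),
             clan = if (length(f) >= 15L) f[15] else NA_character_,
             stringsAsFactors = FALSE)
}

#' Read protein sequences from a FASTA file
#'
#' Identifiers are the first whitespace-separated token of each header.
#' Duplicate identifiers are an error; residues outside the 20-letter
#' alphabet other than `X` and `*` trigger a warning but are retained.
#'
#' @param path FASTA file path
#' @return named character vector protein_id -> sequence
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(aa)
  names(seqs) <- ids
  odd <- grepl(paste0("[^", paste(AA20, collapse = ""), "X*]"), seqs)
  if (any(odd))
    warning("non-standard residues (other than X/*) retained in: ",
            paste(ids[odd], collapse = ", "))
  seqs
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read a rooted species tree in Newick format
#'
#' Exactly one tree is allowed per file.  Internal node labels (e.g. `LECA`,
#' `Metazoa`) are kept; the child order of the input string is preserved,
#' which downstream network reconstruction uses as the earliest-branching
#' convention (first child = basal lineage).
#'
#' @param path file path, or a Newick string ending in ";".
#' @return an ape `phylo` object
#' @export
read_newick <- function(path) {
  tr <- if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
        else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick input")
  if (inherits(tr, "multiPhylo")) stop("multiple trees in input; expected one")
  if (any(!nzchar(tr$tip.label))) stop("unlabeled leaves in tree")
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in tree")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch lengths")
  tr
}

#' Read a 12-column BLAST tabular (outfmt 6) hit file
#'
#' @param path file path
#' @return data.frame of hits with standard column names (`query_id`,
#'   `subject_id`, `percent_identity`, ..., `e_value`, `bit_score`)
#' @export
read_blast_tab <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity", "aln_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "e_value", "bit_score")
  empty <- as.data.frame(stats::setNames(
    c(rep(list(character()), 2), rep(list(numeric()), 10)), cols))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    warning("skipped ", sum(nf != 12L), " line(s) without 12 columns (lines: ",
            paste(which(nf != 12L), collapse = ", "), ")")
  fields <- fields[nf == 12L]
  if (length(fields) == 0L) return(empty)
  m <- do.call(rbind, fields)
  out <- data.frame(m[, 1], m[, 2], stringsAsFactors = FALSE)
  for (j in 3:12) out[[j]] <- as.numeric(m[, j])
  names(out) <- cols
  bad <- !stats::complete.cases(out[, c("e_value", "bit_score")]) |
    out$e_value < 0
  if (any(bad)) {
    warning("skipped ", sum(bad), " unparseable/invalid hit row(s)")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write / read a family-by-species matrix as TSV
#'
#' Row names are families, columns species; the round trip is exact.
#'
#' @param m matrix with dimnames
#' @param path output path
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(family = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (all(m == round(m))) storage.mode(m) <- "integer"
  m
}

#' Write a domain network as node and edge TSV tables
#'
#' Produces `<prefix>_nodes.tsv` (name, role, abundance) and
#' `<prefix>_edges.tsv` (from, to, weight).  With `graphml = TRUE` an
#' additional `<prefix>.graphml` is written via igraph.
#'
#' @param net a `domain_network` (see [reconstruct_ancestral_network()])
#' @param prefix path prefix for the output files
#' @param graphml also write GraphML
#' @export
write_network_tsv <- function(net, prefix, graphml = FALSE) {
  utils::write.table(net$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (graphml)
    igraph::write_graph(as_igraph(net), paste0(prefix, ".graphml"),
                        format = "graphml")
  invisible(prefix)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(prefix) {
  nodes <- utils::read.delim(paste0(prefix, "_nodes.tsv"),
                             stringsAsFactors = FALSE)
  edges <- utils::read.delim(paste0(prefix, "_edges.tsv"),
                             stringsAsFactors = FALSE)
  domain_network(nodes, edges)
}

#' Write an annotation set in the simple TSV dialect
#'
#' Emits the six-column dialect read back by
#' `read_domain_table(dialect = "simple_tsv")`; coordinates are 1-based
#' inclusive.
#'
#' @param annotations annotation_set
#' @param path output path
#' @export
write_annotation_tsv <- function(annotations, path) {
  h <- annotations$hits
  utils::write.table(
    data.frame(h$protein_id, h$species_id, h$domain_name, h$ali_start,
               h$ali_end, format(h$e_value)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
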