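# Assignment of proteins to gene families via core domains, with the
# motif-based refinements used for the survey: DCAFs are WD40-only proteins
# carrying a DWD sequence logo, zf-MIZ E3s require PINIT and/or SAP on the
# same protein, and ThiF proteins matching a (configurable) MoeZ/MoeB
# catalytic exclusion motif are discarded as non-E1s.

#' The DWD sequence logo used to identify DCAF substrate receptors
#'
#' Bracket notation for the ten-position motif
#' `[D|E] X X X X [I|L|V] [W|Y] [D] [I|L|V|M] [R|K]`.
#' @export
DWD_LOGO_TEXT <- "[D|E]XXXX[I|L|V][W|Y][D][I|L|V|M][R|K]"

#' Compile a bracket-notation sequence logo
#'
#' A logo is a fixed-length pattern over the 20-letter amino-acid alphabet:
#' each position is either a choice set written `[A|B|...]` or the wildcard
#' `X`.
#'
#' @param text pattern string, e.g. `"[D|E]XXXX[I|L|V][W|Y][D][I|L|V|M][R|K]"`
#' @return object of class `seq_logo`: a list of per-position character
#'   vectors, `NULL` marking a wildcard
#' @export
compile_logo <- function(text) {
  positions <- list()
  i <- 1L
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "X") {
      positions[[length(positions) + 1L]] <- NULL_POS
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced bracket in logo: ", text)
      letters <- strsplit(paste(chars[(i + 1L):(j - 1L)], collapse = ""),
                          "|", fixed = TRUE)[[1]]
      letters <- letters[nzchar(letters)]
      if (length(letters) == 0L) stop("empty choice set in logo: ", text)
      if (!all(letters %in% AA20))
        stop("non-amino-acid letter in logo: ",
             paste(setdiff(letters, AA20), collapse = ", "))
      positions[[length(positions) + 1L]] <- letters
      i <- j + 1L
    } else if (ch %in% AA20) {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in logo: ", text)
    }
  }
  if (length(positions) == 0L) stop("empty logo")
  structure(positions, class = "seq_logo")
}

# sentinel kept distinct from NULL so list() retains the element
NULL_POS <- NA_character_

is_wildcard <- function(pos) length(pos) == 1L && is.na(pos[1])

#' @export
print.seq_logo <- function(x, ...) {
  cat("seq_logo, length", length(x), ":",
      paste(vapply(x, function(p) {
        if (is_wildcard(p)) "X" else paste0("[", paste(p, collapse = "|"), "]")
      }, character(1)), collapse = " "), "\n")
  invisible(x)
}

#' Scan a sequence for logo matches
#'
#' Exact positional matching over the 20-letter alphabet: an `X` in the
#' *sequence* matches only wildcard positions.  Overlapping matches are all
#' reported.
#'
#' @param sequence amino-acid string
#' @param pattern seq_logo from [compile_logo()]
#' @return integer vector of 1-based match start positions (possibly empty)
#' @export
scan_logo <- function(sequence, pattern) {
  stopifnot(inherits(pattern, "seq_logo"), nzchar(sequence))
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(pattern)
  n <- length(chars)
  if (n < L) return(integer())
  starts <- integer()
  for (p in seq_len(n - L + 1L)) {
    ok <- TRUE
    for (k in seq_len(L)) {
      pos <- pattern[[k]]
      if (is_wildcard(pos)) next
      if (!chars[p + k - 1L] %in% pos) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, p)
  }
  starts
}

#' Assign proteins to gene families via their core domains
#'
#' Each protein carrying core domains of k distinct families yields k
#' assignments (the survey is keyed by core domain, so multi-family proteins
#' count once per family).  Refinement rules referenced by the configuration
#' are applied per family:
#' \describe{
#'   \item{`dcaf_dwd`}{keep only proteins composed exclusively of WD40
#'     domains whose sequence matches the DWD logo.}
#'   \item{`zf_miz_pinit_sap`}{keep only proteins that also carry a PINIT
#'     and/or SAP domain.}
#'   \item{`thif_exclusion`}{discard proteins matching any pattern in
#'     `thif_exclusion_patterns` (catalytic MoeZ/MoeB-type motifs that mark
#'     non-E1 ThiF proteins).  The motif set defaults to empty — with a
#'     warning — because no canonical published pattern exists.}
#' }
#'
#' @param annotations annotation_set
#' @param config family_config
#' @param sequences named character vector of protein sequences; required by
#'   the sequence-based refinements (`dcaf_dwd`, `thif_exclusion` with
#'   patterns).  Defaults to the sequences stored in `annotations`.
#' @param thif_exclusion_patterns list of `seq_logo` patterns
#' @return data.frame of class `family_assignments` with one row per
#'   (protein, family): `protein_id`, `species_id`, `family`,
#'   `core_domains`, `accessory_domains`, `architecture` (the sorted set of
#'   distinct domain names on the protein, `;`-separated)
#' @export
assign_families <- function(annotations, config,
                            sequences = annotations$sequences,
                            thif_exclusion_patterns = list()) {
  stopifnot(inherits(annotations, "annotation_set"),
            inherits(config, "family_config"))
  hits <- annotations$hits
  if (nrow(hits) == 0L) return(empty_assignments())
  rules <- stats::setNames(config$refinement, config$family)
  known_rules <- c("dcaf_dwd", "zf_miz_pinit_sap", "thif_exclusion")
  unknown <- setdiff(stats::na.omit(unique(config$refinement)), known_rules)
  if (length(unknown))
    stop("unknown refinement rule(s): ", paste(unknown, collapse = ", "))
  if ("thif_exclusion" %in% rules && length(thif_exclusion_patterns) == 0L)
    warning("ThiF exclusion motif list is empty: no ThiF proteins discarded")
  dwd <- compile_logo(DWD_LOGO_TEXT)
  cmap <- core_domain_map(config)

  key <- paste(hits$species_id, hits$protein_id, sep = "\r")
  doms_by_protein <- split(hits$domain_name, key)
  out <- vector("list", length(doms_by_protein))
  for (i in seq_along(doms_by_protein)) {
    ks <- strsplit(names(doms_by_protein)[i], "\r", fixed = TRUE)[[1]]
    species <- ks[1]; protein <- ks[2]
    doms <- sort(unique(doms_by_protein[[i]]))
    fams <- unique(stats::na.omit(unname(cmap[doms])))
    if (length(fams) == 0L) next
    keep <- vapply(fams, function(fam) {
      rule <- rules[[fam]]
      if (is.na(rule)) return(TRUE)
      switch(rule,
        dcaf_dwd = {
          core <- config$core_domain[config$family == fam]
          if (!all(doms %in% core)) return(FALSE)
          seqv <- get_sequence(sequences, protein, fam)
          length(scan_logo(seqv, dwd)) > 0L
        },
        zf_miz_pinit_sap = any(c("PINIT", "SAP") %in% doms),
        thif_exclusion = {
          if (length(thif_exclusion_patterns) == 0L) return(TRUE)
          seqv <- get_sequence(sequences, protein, fam)
          !any(vapply(thif_exclusion_patterns,
                      function(p) length(scan_logo(seqv, p)) > 0L,
                      logical(1)))
        })
    }, logical(1))
    fams <- fams[keep]
    if (length(fams) == 0L) next
    out[[i]] <- do.call(rbind, lapply(fams, function(fam) {
      core <- intersect(doms, config$core_domain[config$family == fam])
      acc <- setdiff(doms, config$core_domain[config$family == fam])
      data.frame(protein_id = protein, species_id = species, family = fam,
                 core_domains = paste(core, collapse = ";"),
                 accessory_domains = paste(acc, collapse = ";"),
                 architecture = paste(doms, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty_assignments())
  res <- do.call(rbind, out)
  res <- res[order(res$species_id, res$protein_id, res$family), ]
  rownames(res) <- NULL
  class(res) <- c("family_assignments", "data.frame")
  res
}

get_sequence <- function(sequences, protein, fam) {
  if (is.null(sequences) || is.na(match(protein, names(sequences))))
    stop("refinement for family '", fam, "' needs the sequence of protein '",
         protein, "' but none was supplied")
  sequences[[protein]]
}

empty_assignments <- function() {
  res <- data.frame(protein_id = character(), species_id = character(),
                    family = character(), core_domains = character(),
                    accessory_domains = character(),
                    architecture = character(), stringsAsFactors = FALSE)
  class(res) <- c("family_assignments", "data.frame")
  res
}

#' Split ubiquitin-domain usage per species
#'
#' Classifies every protein carrying the ubiquitin label domain as either a
#' pure label protein (`ub_only`: all its domain hits are the label domain —
#' mono- or poly-ubiquitin) or a fusion (`ub_plus_other`: the label plus at
#' least one other domain).
#'
#' @param annotations annotation_set
#' @param config family_config; the row with system `Ub` and role `label`
#'   designates the label core domain
#' @return data.frame with columns `species_id`, `ub_only`, `ub_plus_other`
#' @export
split_ub_usage <- function(annotations, config) {
  lab <- config$core_domain[config$system == "Ub" & config$role == "label"]
  if (length(lab) == 0L) stop("config designates no Ub label domain")
  hits <- annotations$hits
  species <- sort(unique(hits$species_id))
  key <- paste(hits$species_id, hits$protein_id, sep = "\r")
  doms <- split(hits$domain_name, key)
  has_ub <- vapply(doms, function(d) any(d %in% lab), logical(1))
  only_ub <- vapply(doms, function(d) all(d %in% lab), logical(1))
  sp_of <- vapply(strsplit(names(doms), "\r", fixed = TRUE), `[`,
                  character(1), 1L)
  data.frame(
    species_id = species,
    ub_only = vapply(species, function(s)
      sum(has_ub & only_ub & sp_of == s), integer(1)),
    ub_plus_other = vapply(species, function(s)
      sum(has_ub & !only_ub & sp_of == s), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
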