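# Quantitative survey objects: family-by-species gene-count matrices,
# binary presence/absence profiles, domain-architecture inventories, and
# toolkit-completeness calls per signaling system.

#' Build a family-by-species gene count matrix
#'
#' `cell(f, s)` is the number of distinct proteins of species `s` assigned
#' to family `f` (multiple hits of the same core domain on one protein count
#' as one gene).  Families configured but absent everywhere are kept as
#' all-zero rows so matrices align across datasets.
#'
#' @param assignments output of [assign_families()]
#' @param config optional family_config supplying the full family universe
#'   (zero rows); defaults to the families seen in `assignments`
#' @param species optional character vector fixing the column universe
#' @return integer matrix, rows = families, columns = species
#' @export
build_count_matrix <- function(assignments, config = NULL, species = NULL) {
  fams <- if (is.null(config)) sort(unique(assignments$family))
          else config_families(config)
  if (is.null(species)) species <- sort(unique(assignments$species_id))
  m <- matrix(0L, nrow = length(fams), ncol = length(species),
              dimnames = list(fams, species))
  if (nrow(assignments)) {
    a <- assignments[!duplicated(assignments[, c("species_id", "protein_id",
                                                 "family")]), ]
    a <- a[a$family %in% fams & a$species_id %in% species, ]
    tab <- table(factor(a$family, levels = fams),
                 factor(a$species_id, levels = species))
    m[] <- as.integer(tab)
  }
  m
}

#' Threshold a count matrix into presence/absence
#'
#' @param counts count matrix
#' @return integer 0/1 matrix of the same shape (1 iff count >= 1)
#' @export
to_presence_absence <- function(counts) {
  pa <- (counts >= 1L) + 0L
  dimnames(pa) <- dimnames(counts)
  pa
}

#' Domain-architecture inventory
#'
#' An architecture is the set of distinct domain names on a protein
#' (order- and copy-number-insensitive, so tandem repeats collapse).  For
#' every (species, family) the inventory records the distinct architectures
#' with their protein counts; per family it records the accessory-domain
#' set (all domains ever co-occurring with that family's core domains) and
#' its size, the accessory diversity.
#'
#' @param assignments output of [assign_families()]
#' @return object of class `architecture_inventory`: list with
#'   `architectures` (data.frame species_id, family, architecture,
#'   n_proteins), `accessory` (data.frame family, accessory_domains,
#'   diversity)
#' @export
architecture_inventory <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(structure(list(
      architectures = data.frame(species_id = character(),
                                 family = character(),
                                 architecture = character(),
                                 n_proteins = integer()),
      accessory = data.frame(family = character(),
                             accessory_domains = character(),
                             diversity = integer())),
      class = "architecture_inventory"))
  }
  key <- assignments[, c("species_id", "family", "architecture")]
  tab <- stats::aggregate(list(n_proteins = rep(1L, nrow(key))), key, sum)
  tab <- tab[order(tab$species_id, tab$family, tab$architecture), ]
  rownames(tab) <- NULL
  acc <- lapply(split(assignments$accessory_domains, assignments$family),
                function(x) {
                  d <- unlist(strsplit(x, ";", fixed = TRUE))
                  sort(unique(d[nzchar(d)]))
                })
  accessory <- data.frame(
    family = names(acc),
    accessory_domains = vapply(acc, paste, character(1), collapse = ";"),
    diversity = lengths(acc), row.names = NULL, stringsAsFactors = FALSE)
  structure(list(architectures = tab, accessory = accessory),
            class = "architecture_inventory")
}

#' @export
print.architecture_inventory <- function(x, ...) {
  cat("architecture_inventory:", nrow(x$architectures),
      "distinct (species, family, architecture) records;",
      nrow(x$accessory), "families\n")
  invisible(x)
}

#' Per-species architecture count matrix
#'
#' Species-by-architecture matrix of protein counts, the substrate for the
#' architecture-based ordination.
#'
#' @param inventory architecture_inventory
#' @return integer matrix, rows = species, columns = architectures
#'   (`family|architecture` keys)
#' @export
architecture_count_matrix <- function(inventory) {
  a <- inventory$architectures
  key <- paste(a$family, a$architecture, sep = "|")
  species <- sort(unique(a$species_id))
  arch <- sort(unique(key))
  m <- matrix(0L, length(species), length(arch),
              dimnames = list(species, arch))
  for (i in seq_len(nrow(a)))
    m[a$species_id[i], key[i]] <- m[a$species_id[i], key[i]] + a$n_proteins[i]
  m
}

#' Toolkit completeness per species and signaling system
#'
#' A system is complete in a species iff its label, an E1, an E2, at least
#' one E3-role family and at least one peptidase-role family are present;
#' families with system `shared` (e.g. the ThiF E1 and UQ_con E2) count
#' toward every system.  "Complete" has no universal formal definition in
#' the field; requiring all five roles matches the canonical description of
#' the archaeal Ub toolkit and is documented as a convention.
#'
#' @param pa presence/absence matrix (families x species)
#' @param config family_config
#' @param systems systems to evaluate
#' @return data.frame with columns `species_id`, `system`, `complete`,
#'   `missing_roles` (`;`-separated)
#' @export
toolkit_completeness <- function(pa, config,
                                 systems = c("Ub", "SUMO", "Ufm1")) {
  required <- c("label", "E1", "E2", "E3", "peptidase")
  rows <- list()
  for (sys in systems) {
    sub <- config[config$system %in% c(sys, "shared"), ]
    for (role in required)
      if (!role %in% sub$role)
        stop("config defines no ", role, "-role family for system ", sys)
    for (sp in colnames(pa)) {
      present <- rownames(pa)[pa[, sp] == 1L]
      have <- unique(sub$role[sub$family %in% present])
      missing <- setdiff(required, have)
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = sp, system = sys,
        complete = length(missing) == 0L,
        missing_roles = paste(missing, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
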