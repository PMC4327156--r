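# Family configuration: the mapping from surveyed gene families to their
# defining ("core") Pfam domains, signaling system, cascade role and optional
# motif refinement rule.  Shipped as an editable TSV; a YAML layout (one
# entry per family) is also accepted.

CONFIG_SYSTEMS <- c("Ub", "SUMO", "Ufm1", "shared")
CONFIG_ROLES <- c("label", "E1", "E2", "E3", "peptidase", "CRL-subunit", "other")

#' Read a family configuration
#'
#' A family configuration maps each surveyed gene family to one or more core
#' Pfam domains, a signaling system (`Ub`, `SUMO`, `Ufm1`, or `shared` for
#' enzymes such as the E1/E2 that serve all systems), a cascade role and an
#' optional refinement rule id (`dcaf_dwd`, `zf_miz_pinit_sap`,
#' `thif_exclusion`).
#'
#' TSV layout: columns `family`, `core_domain`, `system`, `role`,
#' `refinement`, one row per (family, core domain) pair.  YAML layout: a
#' mapping family -> {core_domains, system, role, refinement}.
#'
#' @param path path to a `.tsv` or `.yaml`/`.yml` file
#' @return data.frame of class `family_config`
#' @export
read_family_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    rows <- lapply(names(y), function(fam) {
      e <- y[[fam]]
      data.frame(family = fam, core_domain = unlist(e$core_domains),
                 system = e$system, role = e$role,
                 refinement = if (is.null(e$refinement)) NA_character_
                              else e$refinement,
                 stringsAsFactors = FALSE)
    })
    cfg <- do.call(rbind, rows)
  } else {
    cfg <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  family_config(cfg)
}

#' @rdname read_family_config
#' @param cfg data.frame with columns family, core_domain, system, role,
#'   refinement
#' @export
family_config <- function(cfg) {
  need <- c("family", "core_domain", "system", "role")
  if (!all(need %in% names(cfg)))
    stop("family config must have columns: ", paste(need, collapse = ", "))
  if (!"refinement" %in% names(cfg)) cfg$refinement <- NA_character_
  cfg$refinement[!nzchar(trimws(ifelse(is.na(cfg$refinement), "",
                                       cfg$refinement)))] <- NA_character_
  if (anyDuplicated(cfg[, c("family", "core_domain")]))
    stop("duplicate (family, core_domain) pairs in config")
  if (!all(cfg$system %in% CONFIG_SYSTEMS))
    stop("unknown system(s): ",
         paste(setdiff(cfg$system, CONFIG_SYSTEMS), collapse = ", "))
  if (!all(cfg$role %in% CONFIG_ROLES))
    stop("unknown role(s): ",
         paste(setdiff(cfg$role, CONFIG_ROLES), collapse = ", "))
  if (any(!nzchar(cfg$core_domain))) stop("family with empty core domain")
  rownames(cfg) <- NULL
  class(cfg) <- c("family_config", "data.frame")
  cfg
}

#' Default family configuration
#'
#' The packaged survey of ubiquitin-like signaling families: labels, E1/E2
#' enzymes, RING/HECT-type and SUMO/Ufm1-specific E3 ligases, Cullin-RING
#' ligase subunits, and delabeling peptidases, each keyed by its defining
#' Pfam domain.
#'
#' @return family_config
#' @export
default_family_config <- function() {
  read_family_config(system.file("extdata", "families.tsv",
                                 package = "domevol", mustWork = TRUE))
}

#' All configured family names
#' @param config family_config
#' @export
config_families <- function(config) unique(config$family)

core_domain_map <- function(config) {
  stats::setNames(config$family, config$core_domain)
}
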