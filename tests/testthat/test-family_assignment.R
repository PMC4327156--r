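test_that("bracket-notation logos compile to the right length and reject junk", {
  logo <- compile_logo(DWD_LOGO_TEXT)
  expect_s3_class(logo, "seq_logo")
  expect_length(logo, 10L)
  expect_length(compile_logo("X"), 1L)
  expect_error(compile_logo("[D|E"), "unbalanced")
  expect_error(compile_logo("[D|1]"), "non-amino-acid")
})

test_that("logo scanning matches the documented DWD examples", {
  dwd <- compile_logo(DWD_LOGO_TEXT)
  expect_equal(scan_logo("DAAAAIWDLR", dwd), 1L)
  expect_equal(scan_logo("EPQRSVYDMK", dwd), 1L)
  expect_equal(scan_logo("DAAAAIWELR", dwd), integer())  # E where D required
  expect_equal(scan_logo("X", compile_logo("X")), 1L)    # wildcard matches X
  expect_equal(scan_logo("XAAAAIWDLR", dwd), integer())  # X never matches a set
})

test_that("logo scanning agrees with a brute-force checker on random sequences", {
  brute_scan <- function(seq, positions) {
    chars <- strsplit(seq, "")[[1]]
    L <- length(positions)
    out <- integer()
    for (p in seq_len(max(0, length(chars) - L + 1))) {
      ok <- TRUE
      for (k in seq_len(L)) {
        allowed <- positions[[k]]
        if (is.null(allowed)) next
        if (!chars[p + k - 1] %in% allowed) ok <- FALSE
      }
      if (ok) out <- c(out, p)
    }
    out
  }
  set.seed(11)
  aa <- c("A", "C", "D", "E", "W", "R")
  pat <- compile_logo("[D|E]X[W|R]")
  pat_brute <- list(c("D", "E"), NULL, c("W", "R"))
  for (i in 1:200) {
    s <- paste(sample(aa, sample(3:12, 1), replace = TRUE), collapse = "")
    expect_identical(scan_logo(s, pat), brute_scan(s, pat_brute))
  }
})

test_that("core domains drive assignment; multi-family proteins count once per family", {
  hits <- rbind(tiny_hits(), data.frame(
    protein_id = "P4", species_id = "spB",
    domain_name = c("F-box", "ubiquitin"),
    ali_start = c(1L, 100L), ali_end = c(40L, 170L), e_value = 1e-9))
  asg <- assign_families(annotation_set(hits), basic_config())
  expect_s3_class(asg, "family_assignments")
  # P3 = F-box + LRR + LRR: one assignment, accessory LRR (set semantics)
  p3 <- asg[asg$protein_id == "P3", ]
  expect_equal(p3$family, "F-box")
  expect_equal(p3$accessory_domains, "LRR")
  # P4 carries core domains of two families -> two assignments
  expect_setequal(asg$family[asg$protein_id == "P4"], c("Ub", "F-box"))
})

test_that("assignment is deterministic and order-insensitive", {
  hits <- tiny_hits()
  a1 <- assign_families(annotation_set(hits), basic_config())
  a2 <- assign_families(annotation_set(hits[sample(nrow(hits)), ]),
                        basic_config())
  expect_identical(a1, a2)
})

test_that("DCAF refinement keeps only WD40-only proteins with a DWD motif", {
  cfg <- family_config(data.frame(
    family = c("DCAF", "F-box"), core_domain = c("WD40", "F-box"),
    system = "Ub", role = "CRL-subunit",
    refinement = c("dcaf_dwd", NA), stringsAsFactors = FALSE))
  hits <- data.frame(
    protein_id = c("W1", "W1", "W2", "W3", "W3"),
    species_id = "spA",
    domain_name = c("WD40", "WD40", "WD40", "WD40", "F-box"),
    ali_start = c(1L, 50L, 1L, 1L, 200L),
    ali_end = c(40L, 90L, 40L, 40L, 240L),
    e_value = 1e-10, stringsAsFactors = FALSE)
  seqs <- c(W1 = "MKDAAAAIWDLRGG",  # DWD logo match at position 3
            W2 = "MKAAAAAAAAAAAA",  # WD40-only but no motif
            W3 = "MKDAAAAIWDLRGG")  # motif but not WD40-only
  asg <- assign_families(annotation_set(hits), cfg, sequences = seqs)
  expect_equal(asg$protein_id[asg$family == "DCAF"], "W1")
  expect_true("W3" %in% asg$protein_id[asg$family == "F-box"])
  expect_error(assign_families(annotation_set(hits), cfg, sequences = NULL),
               "needs the sequence")
})

test_that("zf-MIZ assignments require PINIT and/or SAP on the same protein", {
  cfg <- family_config(data.frame(
    family = "zf-MIZ", core_domain = "zf-MIZ", system = "SUMO", role = "E3",
    refinement = "zf_miz_pinit_sap", stringsAsFactors = FALSE))
  hits <- data.frame(
    protein_id = c("M1", "M1", "M2", "M3", "M3"),
    species_id = "spA",
    domain_name = c("zf-MIZ", "PINIT", "zf-MIZ", "zf-MIZ", "SAP"),
    ali_start = c(1L, 100L, 1L, 1L, 100L),
    ali_end = c(50L, 150L, 50L, 50L, 150L),
    e_value = 1e-10, stringsAsFactors = FALSE)
  asg <- assign_families(annotation_set(hits), cfg)
  expect_setequal(asg$protein_id, c("M1", "M3"))  # M2 lacks PINIT/SAP
})

test_that("ThiF exclusion patterns discard matching proteins, empty list warns", {
  cfg <- family_config(data.frame(
    family = "ThiF", core_domain = "ThiF", system = "shared", role = "E1",
    refinement = "thif_exclusion", stringsAsFactors = FALSE))
  hits <- data.frame(protein_id = c("T1", "T2"), species_id = "spA",
                     domain_name = "ThiF", ali_start = 1L, ali_end = 100L,
                     e_value = 1e-20, stringsAsFactors = FALSE)
  seqs <- c(T1 = "MKCWCWAAA", T2 = "MKAAAAAAA")
  excl <- list(compile_logo("[C][W][C][W]"))
  asg <- assign_families(annotation_set(hits), cfg, sequences = seqs,
                         thif_exclusion_patterns = excl)
  expect_equal(asg$protein_id, "T2")
  expect_warning(
    assign_families(annotation_set(hits), cfg, sequences = seqs),
    "exclusion motif list is empty")
})

test_that("removing a refinement rule never shrinks a family (filter monotonicity)", {
  cfg_ref <- family_config(data.frame(
    family = "DCAF", core_domain = "WD40", system = "Ub",
    role = "CRL-subunit", refinement = "dcaf_dwd", stringsAsFactors = FALSE))
  cfg_raw <- family_config(data.frame(
    family = "DCAF", core_domain = "WD40", system = "Ub",
    role = "CRL-subunit", refinement = NA_character_,
    stringsAsFactors = FALSE))
  set.seed(5)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    hits <- data.frame(protein_id = paste0("W", seq_len(n)),
                       species_id = "spA", domain_name = "WD40",
                       ali_start = 1L, ali_end = 40L, e_value = 1e-8,
                       stringsAsFactors = FALSE)
    seqs <- stats::setNames(vapply(seq_len(n), function(j)
      paste(sample(c("D", "A", "I", "W", "L", "R"), 14, replace = TRUE),
            collapse = ""), character(1)), hits$protein_id)
    with_rule <- assign_families(annotation_set(hits), cfg_ref,
                                 sequences = seqs)
    without <- assign_families(annotation_set(hits), cfg_raw,
                               sequences = seqs)
    expect_lte(nrow(with_rule), nrow(without))
  }
})

test_that("ubiquitin usage split distinguishes pure labels from fusions", {
  hits <- data.frame(
    protein_id = c("U1", "U1", "U1", "U2", "U2", "U3"),
    species_id = "spA",
    domain_name = c("ubiquitin", "ubiquitin", "ubiquitin",  # poly-Ub
                    "ubiquitin", "UBA",                      # fusion
                    "ubiquitin"),                            # mono-Ub
    ali_start = c(1L, 80L, 160L, 1L, 100L, 1L),
    ali_end = c(76L, 155L, 235L, 76L, 140L, 76L),
    e_value = 1e-20, stringsAsFactors = FALSE)
  usage <- split_ub_usage(annotation_set(hits), basic_config())
  expect_equal(usage$ub_only, 2L)        # U1 (poly) + U3 (mono)
  expect_equal(usage$ub_plus_other, 1L)  # U2
})
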