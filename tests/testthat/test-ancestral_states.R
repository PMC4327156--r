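quartet <- function() read_newick("((A:1,B:1)AB:1,(C:1,D:1)CD:1)Root;")

pa_row <- function(...) {
  v <- c(...)
  matrix(v, 1, length(v), dimnames = list("fam", names(v)))
}

test_that("Fitch handles the textbook quartet cases", {
  tr <- quartet()
  em <- fitch_reconstruct(tr, pa_row(A = 1L, B = 1L, C = 1L, D = 1L))
  expect_equal(unname(em$score), 0L)
  expect_equal(em$presence["Root", "fam"], 1L)

  em <- fitch_reconstruct(tr, pa_row(A = 1L, B = 0L, C = 0L, D = 0L))
  expect_equal(unname(em$score), 1L)
  expect_equal(em$presence["Root", "fam"], 0L)
  expect_equal(em$gains$node, "A")
  expect_equal(nrow(em$losses), 0L)
})

test_that("a leaf missing from the matrix is a fatal error naming it", {
  tr <- quartet()
  expect_error(fitch_reconstruct(tr, pa_row(A = 1L, B = 0L, C = 0L)), "D")
})

test_that("Fitch root ties resolve toward absence by default, flippable", {
  tr <- quartet()
  pa <- pa_row(A = 1L, B = 1L, C = 0L, D = 0L)  # root set is {0, 1}
  expect_equal(fitch_reconstruct(tr, pa)$presence["Root", "fam"], 0L)
  expect_equal(fitch_reconstruct(tr, pa,
                                 root_tie = "present")$presence["Root", "fam"],
               1L)
})

test_that("ACCTRAN places tied changes rootward, DELTRAN tipward", {
  # ((A,B),(C,D)) with A and C present: 2 changes either way, but ACCTRAN
  # gains early (internal branch) and loses later, DELTRAN gains at the tips
  tr <- quartet()
  pa <- pa_row(A = 1L, B = 0L, C = 1L, D = 0L)
  acc <- fitch_reconstruct(tr, pa, resolution = "ACCTRAN",
                           root_tie = "present")
  del <- fitch_reconstruct(tr, pa, resolution = "DELTRAN",
                           root_tie = "present")
  expect_equal(unname(acc$score), unname(del$score))
  expect_equal(nrow(acc$gains) + nrow(acc$losses),
               nrow(del$gains) + nrow(del$losses))
  expect_true(all(del$gains$node %in% c("A", "C")))
})

test_that("Fitch change counts equal exhaustive enumeration, including polytomies", {
  set.seed(301)
  for (i in 1:60) {
    nt <- sample(3:6, 1)
    tr <- random_rooted_tree(nt, seed = 9000 + i)
    states <- stats::setNames(sample(0:1, nt, replace = TRUE), tr$tip.label)
    em <- fitch_reconstruct(tr, matrix(states, 1,
                                       dimnames = list("f", names(states))))
    expect_equal(unname(em$score), oracle_parsimony_score(tr, states))
    # mapped events count exactly the parsimony score
    expect_equal(nrow(em$gains) + nrow(em$losses), unname(em$score))
  }
  # polytomy: (A,B,C,D,E)R with 2 present -> 2 gains, not 1
  tr <- read_newick("(A,B,C,D,E)R;")
  em <- fitch_reconstruct(tr, pa_row(A = 1L, B = 1L, C = 0L, D = 0L, E = 0L))
  expect_equal(unname(em$score), 2L)
})

test_that("Fitch agrees with phangorn's parsimony scores on random data", {
  skip_if_not_installed("phangorn")
  set.seed(55)
  for (i in 1:20) {
    tr <- random_rooted_tree(6, seed = 700 + i)
    states <- stats::setNames(sample(0:1, 6, replace = TRUE), tr$tip.label)
    pd <- phangorn::phyDat(matrix(as.character(states), ncol = 1,
                                  dimnames = list(names(states), NULL)),
                           type = "USER", levels = c("0", "1"))
    em <- fitch_reconstruct(tr, matrix(states, 1,
                                       dimnames = list("f", names(states))))
    expect_equal(unname(em$score), phangorn::parsimony(tr, pd))
  }
})

test_that("Dollo places one gain above the MRCA and minimal losses below", {
  tr <- quartet()
  em <- dollo_reconstruct(tr, pa_row(A = 1L, B = 0L, C = 1L, D = 0L))
  expect_equal(em$gains$node, "Root")
  expect_setequal(em$losses$node, c("B", "D"))

  em1 <- dollo_reconstruct(tr, pa_row(A = 1L, B = 0L, C = 0L, D = 0L))
  expect_equal(em1$gains$node, "A")
  expect_equal(nrow(em1$losses), 0L)

  em0 <- dollo_reconstruct(tr, pa_row(A = 0L, B = 0L, C = 0L, D = 0L))
  expect_equal(nrow(em0$gains), 0L)
  expect_equal(nrow(em0$losses), 0L)
})

test_that("Dollo maps exactly one gain per family with any presence", {
  set.seed(77)
  for (i in 1:25) {
    tr <- random_rooted_tree(sample(4:8, 1), seed = 50 + i)
    nf <- 12
    pa <- matrix(rbinom(nf * length(tr$tip.label), 1, 0.5), nf,
                 dimnames = list(paste0("f", 1:nf), tr$tip.label))
    em <- dollo_reconstruct(tr, pa)
    nonzero <- rownames(pa)[rowSums(pa) > 0]
    expect_equal(sort(em$gains$family), sort(nonzero))
    expect_equal(anyDuplicated(em$gains$family), 0L)
  }
})

test_that("the Mk stationary-root analytic case holds at any rate", {
  tr <- read_newick("(A:0.0);")
  fit <- mk_fit(tr, c(A = 1L), bias = 0.1)
  expect_equal(unname(exp(fit$log_likelihood)), 1 / 1.1, tolerance = 1e-12)
})

test_that("pruning likelihood matches exhaustive enumeration", {
  set.seed(303)
  for (i in 1:40) {
    nt <- sample(3:6, 1)
    tr <- random_rooted_tree(nt, seed = 400 + i)
    states <- stats::setNames(sample(0:1, nt, replace = TRUE), tr$tip.label)
    a <- runif(1, 0.02, 3)
    pr <- domevol:::mk_prune(tr, matrix(states, 1,
                                        dimnames = list("f", names(states))),
                             a, 0.1 * a, "stationary")
    oracle <- oracle_mk(tr, states, a, 0.1 * a)
    expect_equal(exp(pr$loglik), oracle$lik, tolerance = 1e-10)
  }
})

test_that("pruning log-likelihood is invariant under leaf reorder and joint rescale", {
  tr <- random_rooted_tree(6, seed = 21)
  states <- stats::setNames(c(1L, 0L, 1L, 1L, 0L, 1L), tr$tip.label)
  m <- matrix(states, 1, dimnames = list("f", names(states)))
  a <- 0.7
  ll1 <- domevol:::mk_prune(tr, m, a, 0.1 * a, "stationary")$loglik
  perm <- sample(6)
  m2 <- m[, perm, drop = FALSE]
  ll2 <- domevol:::mk_prune(tr, m2, a, 0.1 * a, "stationary")$loglik
  expect_equal(ll1, ll2, tolerance = 1e-12)
  # alpha * t jointly rescaled: halve rates, double branch lengths
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 2
  ll3 <- domevol:::mk_prune(tr2, m, a / 2, 0.1 * a / 2, "stationary")$loglik
  expect_equal(ll1, ll3, tolerance = 1e-12)
})

test_that("marginal ancestral states match the enumeration posterior", {
  set.seed(304)
  for (i in 1:25) {
    nt <- sample(3:5, 1)
    tr <- random_rooted_tree(nt, seed = 600 + i)
    states <- stats::setNames(sample(0:1, nt, replace = TRUE), tr$tip.label)
    a <- runif(1, 0.05, 2)
    fit <- structure(list(tree = tr,
                          states = matrix(states, 1,
                                          dimnames = list("f", names(states))),
                          bias = 0.1, gain_rate = c(f = a),
                          loss_rate = c(f = 0.1 * a), log_likelihood = 0,
                          rate_mode = "per_character",
                          root_prior = "stationary"), class = "mk_fit")
    anc <- mk_ancestral(fit)
    oracle <- oracle_mk(tr, states, a, 0.1 * a)
    expect_equal(unname(anc$marginals[, 1]), oracle$marginals,
                 tolerance = 1e-10)
  }
})

test_that("symmetric data under bias 1 give equal marginals on mirror nodes", {
  tr <- read_newick("((A:1,B:1)AB:1,(C:1,D:1)CD:1)Root;")
  fit <- mk_fit(tr, c(A = 1L, B = 0L, C = 0L, D = 1L), bias = 1)
  anc <- mk_ancestral(fit)
  expect_equal(anc$marginals["AB", 1], anc$marginals["CD", 1],
               tolerance = 1e-8)
})

test_that("short branches with uniform presence drive the root marginal to one", {
  tr <- quartet()
  tr$edge.length <- rep(1e-6, nrow(tr$edge))
  fit <- mk_fit(tr, c(A = 1L, B = 1L, C = 1L, D = 1L), bias = 0.1)
  anc <- mk_ancestral(fit)
  expect_gt(anc$marginals["Root", 1], 0.999)
})

test_that("conflicting states on a zero-length tree report -Inf with a warning", {
  tr <- quartet()
  tr$edge.length <- rep(0, nrow(tr$edge))
  expect_warning(
    fit <- mk_fit(tr, c(A = 1L, B = 0L, C = 1L, D = 0L), bias = 0.1),
    "-Inf")
  expect_equal(unname(fit$log_likelihood), -Inf)
})

test_that("event summaries count events strictly below a node", {
  tr <- demo_species_tree()
  pa <- demo_presence_matrix(tr)
  em <- fitch_reconstruct(tr, pa)
  s <- summarize_events(em, "LECA")
  expect_equal(s$gains_after, 2L)
  expect_setequal(setdiff(config_families(default_family_config()),
                          s$present_at_node), c("SOCS-box", "IR1-M"))
  # event-free matrix: no gains anywhere
  pa1 <- pa; pa1[] <- 1L
  em1 <- fitch_reconstruct(tr, pa1)
  expect_equal(summarize_events(em1, "LECA")$gains_after, 0L)
  # single-leaf presence: one gain below that leaf's parent
  pa2 <- pa[1, , drop = FALSE]; pa2[] <- 0L; pa2[, "Hsap"] <- 1L
  em2 <- fitch_reconstruct(tr, pa2)
  expect_equal(summarize_events(em2, "Eumetazoa")$gains_after, 1L)
  expect_error(summarize_events(em2, "NoSuchNode"), "unknown node")
})
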