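# Lineage enrichment (Wilcoxon rank-sum per family), scaled PCA of toolkit
# profiles, and the matched-pairs (Bowker) test of symmetry for aligned
# amino-acid sequence pairs.

#' Two-sample Wilcoxon (Mann-Whitney) rank-sum test
#'
#' The U statistic is computed from midranks.  The p-value is exact —
#' obtained by full enumeration of group assignments over the pooled sample
#' (equivalently the null permutation distribution of U; for tie-free data
#' this reduces to the classical Wilcoxon distribution) — whenever
#' `n * m <= 400`, no tied value spans both groups, and the enumeration is
#' small enough (`choose(n + m, n) <= 2e5`).  Otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' Two-sided throughout.
#'
#' @param xs,ys numeric samples (non-empty)
#' @return list with `u` (U statistic of `xs`), `p_two_sided`, and the
#'   branch taken (`method`: `"exact"` or `"normal"`)
#' @export
wilcoxon_rank_sum <- function(xs, ys) {
  if (length(xs) == 0L || length(ys) == 0L)
    stop("both samples must be non-empty")
  n <- length(xs); m <- length(ys)
  pooled <- c(xs, ys)
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  cross_ties <- length(intersect(unique(xs), unique(ys))) > 0L
  exact_ok <- n * m <= 400 && !cross_ties && choose(n + m, n) <= 2e5
  if (exact_ok) {
    if (!anyDuplicated(pooled)) {
      # tie-free: classical Wilcoxon null distribution
      p <- 2 * min(stats::pwilcox(u, n, m),
                   1 - stats::pwilcox(u - 1, n, m))
    } else {
      # within-group ties: enumerate group assignments over the midranks
      combs <- utils::combn(n + m, n)
      us <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
      p <- 2 * min(mean(us <= u), mean(us >= u))
    }
    p <- min(1, p)
    return(list(u = u, p_two_sided = p, method = "exact"))
  }
  mu <- n * m / 2
  nt <- n + m
  ties <- table(pooled)
  sigma2 <- n * m / 12 * (nt + 1 - sum(ties^3 - ties) / (nt * (nt - 1)))
  if (sigma2 <= 0) return(list(u = u, p_two_sided = 1, method = "normal"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(u = u, p_two_sided = p, method = "normal")
}

#' Scan a count matrix for lineage enrichments and depletions
#'
#' One two-sided Wilcoxon rank-sum test per family comparing gene counts
#' between two disjoint species groups.  Direction (`enriched` means larger
#' in group A) is assigned by comparing group medians only when the test is
#' significant at `alpha`; no multiple-testing correction is applied by
#' default (set `correct = "BH"` for Benjamini-Hochberg).
#'
#' @param counts family-by-species count matrix
#' @param group_a,group_b disjoint character vectors of species ids, each of
#'   size >= 2
#' @param alpha significance threshold (default 0.01)
#' @param correct `"none"` or `"BH"`
#' @return data.frame with one row per family: `family`, `median_a`,
#'   `median_b`, `u_statistic`, `p_value`, `direction`
#' @export
enrichment_scan <- function(counts, group_a, group_b, alpha = 0.01,
                            correct = c("none", "BH")) {
  correct <- match.arg(correct)
  if (length(intersect(group_a, group_b)))
    stop("species groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 species")
  missing <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(missing))
    stop("species missing from matrix: ", paste(missing, collapse = ", "))
  res <- lapply(rownames(counts), function(f) {
    xs <- as.numeric(counts[f, group_a])
    ys <- as.numeric(counts[f, group_b])
    w <- wilcoxon_rank_sum(xs, ys)
    data.frame(family = f, median_a = stats::median(xs),
               median_b = stats::median(ys), u_statistic = w$u,
               p_value = w$p_two_sided, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (correct == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$direction <- ifelse(out$p_value >= alpha | out$median_a == out$median_b,
                          "none",
                          ifelse(out$median_a > out$median_b,
                                 "enriched", "depleted"))
  out
}

#' PCA of species toolkit profiles
#'
#' Columns (families or architectures) are centered and, by default, scaled
#' to unit variance before the spectral decomposition — the survey mixes
#' families with hundreds of genes and families with one or two, so scaling
#' keeps the ordination from being dominated by the large families.
#' Zero-variance columns are dropped with a warning (they cannot be scaled).
#' Loading vectors are oriented so their largest-magnitude entry is
#' positive, which makes signs reproducible across platforms.
#'
#' @param m species-by-variables count matrix (>= 2 rows)
#' @param scale scale columns to unit variance (default TRUE)
#' @return list of class `pca_result`: `scores` (species x components),
#'   `loadings` (variables x components), `variance_fractions`
#' @export
pca_profiles <- function(m, scale = TRUE) {
  if (nrow(m) < 2L) stop("PCA needs at least 2 species (rows)")
  v <- apply(m, 2, stats::var)
  if (scale && any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance column(s): ",
            paste(utils::head(colnames(m)[v == 0], 5), collapse = ", "))
    m <- m[, v > 0, drop = FALSE]
  }
  p <- stats::prcomp(m, center = TRUE, scale. = scale)
  # deterministic sign convention
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(scores = p$x, loadings = p$rotation,
                 variance_fractions = p$sdev^2 / sum(p$sdev^2),
                 center = p$center,
                 scale = if (scale) p$scale else NULL),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  vf <- round(100 * x$variance_fractions[seq_len(min(3,
          length(x$variance_fractions)))], 2)
  cat("pca_result:", nrow(x$scores), "species,", nrow(x$loadings),
      "variables; PC variance %:", paste(vf, collapse = ", "), "...\n")
  invisible(x)
}

#' Matched-pairs (Bowker) test of symmetry
#'
#' Tests whether two aligned amino-acid sequences are consistent with
#' evolution under time-reversible (stationary, symmetric-flow) conditions.
#' With \eqn{n_{ij}} the number of aligned sites showing residue i in the
#' first sequence and j in the second, the statistic is
#' \deqn{S = \sum_{i<j,\; n_{ij}+n_{ji}>0} (n_{ij}-n_{ji})^2/(n_{ij}+n_{ji})}
#' with degrees of freedom the number of contributing unordered pairs, and
#' the p-value from the chi-squared upper tail.  Sites with a gap or an
#' ambiguity character in either sequence are skipped (pairwise deletion).
#' When every off-diagonal count is zero the test is undefined: `df = 0`,
#' `p_value = NA`, `undefined = TRUE`.
#'
#' @param x either a character vector of two aligned equal-length sequences,
#'   or a square substitution count matrix with matching dimnames
#' @param y second aligned sequence when `x` is a single string
#' @return list of class `symmetry_test`: `statistic`, `df`, `p_value`,
#'   `undefined`
#' @export
bowker_symmetry <- function(x, y = NULL) {
  tab <- if (is.matrix(x)) {
    stopifnot(nrow(x) == ncol(x))
    x
  } else {
    seqs <- if (is.null(y)) x else c(x, y)
    stopifnot(length(seqs) == 2L)
    a <- strsplit(toupper(seqs[1]), "")[[1]]
    b <- strsplit(toupper(seqs[2]), "")[[1]]
    if (length(a) != length(b)) stop("sequences are not aligned (lengths differ)")
    ok <- a %in% AA20 & b %in% AA20
    table(factor(a[ok], levels = AA20), factor(b[ok], levels = AA20))
  }
  tab <- as.matrix(tab)
  S <- 0; df <- 0L
  nn <- nrow(tab)
  for (i in seq_len(nn - 1)) {
    for (j in (i + 1):nn) {
      tot <- tab[i, j] + tab[j, i]
      if (tot > 0) {
        S <- S + (tab[i, j] - tab[j, i])^2 / tot
        df <- df + 1L
      }
    }
  }
  undefined <- df == 0L
  p <- if (undefined) NA_real_ else stats::pchisq(S, df, lower.tail = FALSE)
  structure(list(statistic = S, df = df, p_value = p, undefined = undefined),
            class = "symmetry_test")
}

#' @export
print.symmetry_test <- function(x, ...) {
  if (x$undefined)
    cat("matched-pairs symmetry test: undefined (no off-diagonal counts)\n")
  else
    cat("matched-pairs symmetry test: S =", signif(x$statistic, 5),
        ", df =", x$df, ", p =", signif(x$p_value, 4), "\n")
  invisible(x)
}
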