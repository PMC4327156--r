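# domevol

Comparative genomics of domain-defined gene families on a species
phylogeny, built for surveys of the ubiquitin-like (Ub, SUMO, Ufm1)
posttranslational signaling systems but applicable to any core-domain-keyed
gene-family census.

Cells attach small peptide labels to substrates through an E1 → E2 → E3
enzyme cascade and remove them with peptidases; each component family is
identified by a defining Pfam "core" domain.  Given per-species domain
annotation tables and a rooted species tree, `domevol`:

* assigns proteins to families by core domain, with motif refinements
  (the DWD logo for DCAF receptors, PINIT/SAP co-occurrence for zf-MIZ,
  a configurable ThiF/MoeB exclusion);
* builds gene-count and presence/absence matrices, domain-architecture
  inventories, and per-system toolkit-completeness calls;
* reconstructs per-branch gains and losses by Fitch parsimony
  (ACCTRAN/DELTRAN, multifurcation-safe), Dollo parsimony, and an
  asymmetric binary Mk model — gain rate α, loss rate β = rα with the
  bias r fixed (default 0.1), α fitted by maximum likelihood via
  Felsenstein pruning, marginal ancestral states π(node) by the up-down
  pass;
* reconstructs ancestral accessory-domain co-occurrence networks at named
  nodes (a pair is ancestral when observed in the earliest-branching child
  clade and another clade member; node/edge weights are clade-wide
  medians; density = 2E/(N(N−1)));
* runs lineage enrichment scans (two-sided Wilcoxon rank-sum, exact by
  enumeration where feasible), scaled PCA of toolkit profiles, and the
  matched-pairs (Bowker) test of symmetry for aligned sequences;
* screens reciprocal BLAST tabular output for cross-domain-of-life
  similarity (top-50 forward hits at 1e-5, reverse hits at 1e-10,
  per-query composition report);
* simulates all of the above with recorded ground truth for validation.

## Worked example

The packaged 14-species eukaryote fixture encodes the canonical survey
result — every family present on both sides of the unikont–bikont root
except SOCS-box (Holozoa only) and IR1-M (Metazoa only):

```r
library(domevol)
tree <- demo_species_tree()
pa <- demo_presence_matrix(tree)
events <- fitch_reconstruct(tree, pa)
summarize_events(events, "LECA")$gains_after
#> [1] 2
events$gains
#>      node   family
#> 1 Holozoa SOCS-box
#> 2 Metazoa    IR1-M
```

Exactly two families postdate the last eukaryotic common ancestor, gained
on the branches to Holozoa and Metazoa; the other 28 configured families
are part of the reconstructed LECA toolkit.

```r
fit <- mk_fit(tree, pa, bias = 0.1)          # asymmetric Mk, loss/gain = 0.1
anc <- mk_ancestral(fit)                     # per-node presence probabilities
round(anc$marginals["LECA", c("SOCS-box", "HECT")], 4)
#> SOCS-box     HECT
#>    5e-04    1e+00
```

The likelihood model agrees with parsimony: SOCS-box was almost certainly
absent from the LECA while HECT was present.

See the vignette (`vignettes/domain-toolkit-evolution.Rmd`) for the full
model description, parameter semantics and design choices.

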