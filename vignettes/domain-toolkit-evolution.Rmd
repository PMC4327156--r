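---
title: "Tracing ubiquitin-like signaling toolkits across a species phylogeny"
author: "domevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing ubiquitin-like signaling toolkits across a species phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domevol)
```

## The problem

Ubiquitin (Ub), SUMO and Ufm1 are small peptide labels that cells attach to
substrate proteins through a three-enzyme cascade (E1 activase, E2 conjugase,
E3 ligase) and remove again with dedicated peptidases.  Each enzyme family is
recognizable by a defining ("core") Pfam domain, so the composition of a
species' labeling toolkit can be read off its predicted proteome.  Given such
domain annotation tables for many species and a rooted species tree, this
package reconstructs where gene families were gained and lost, what the
ancestral toolkits at named nodes (e.g. the last eukaryotic common ancestor,
LECA) looked like, and how the accessory domains surrounding each core domain
evolved — plus the enrichment, ordination and screening statistics that
accompany such a survey.

The pipeline is organized as:

1. **Ingestion** (`read_domain_table()`, `read_fasta()`, `read_newick()`,
   `read_blast_tab()`): permissive parsers that skip and report malformed
   lines.  Coordinates are 1-based inclusive.  Hits are not e-value-filtered
   at parse time — upstream domain calling is assumed to have used the Pfam
   gathering threshold — but a `max_evalue` flag exists.
2. **Family assignment** (`assign_families()`): a protein belongs to every
   family whose core domain it carries; three motif-based refinements sharpen
   families that a domain alone cannot define (see below).
3. **Profiles** (`build_count_matrix()`, `to_presence_absence()`,
   `architecture_inventory()`, `toolkit_completeness()`).
4. **Ancestral states** (`fitch_reconstruct()`, `dollo_reconstruct()`,
   `mk_fit()`/`mk_ancestral()`).
5. **Ancestral domain networks** (`cooccurrence_table()`,
   `reconstruct_ancestral_network()`, `network_metrics()`).
6. **Comparative statistics** (`enrichment_scan()`, `pca_profiles()`,
   `bowker_symmetry()`), and the **reciprocal-similarity screen**
   (`top_hits()`, `build_reciprocal_network()`).
7. A **simulator** with ground truth (`simulate_characters()` and friends)
   used throughout the test suite.

## Family assignment and its refinements

The survey is keyed by core domains (the shipped `default_family_config()`
covers the Ub/SUMO/Ufm1 labels, the shared ThiF E1 and UQ_con E2, RING-,
HECT- and SUMO/Ufm1-specific E3s, Cullin-RING ligase subunits and the
peptidase families).  A protein with core domains of *k* families yields *k*
assignments: counts are per core domain, so a bifunctional fusion counts once
in each family.  Multiple hits of the same core domain on one protein count
as one gene; copy number matters only for architectures.

Three families need motif refinements:

* **DCAF** substrate receptors are WD40 proteins, but WD40 alone is far too
  promiscuous.  Only proteins composed exclusively of WD40 domains whose
  sequence matches the ten-position DWD logo
  `[D|E] X X X X [I|L|V] [W|Y] [D] [I|L|V|M] [R|K]` are kept.  The logo is
  matched anywhere in the sequence (the position of the motif relative to
  the repeats is not constrained; requiring it inside a repeat would need
  per-repeat coordinates that annotation tables do not reliably carry).
* **zf-MIZ** SUMO E3s are retained only when PINIT and/or SAP domains
  co-occur on the same protein.
* **ThiF** proteins whose catalytic motifs mark them as MoeZ/MoeB-type
  biosynthetic enzymes (no E1 activity) are discarded.  No canonical
  published pattern exists for this exclusion, so the pattern list is a
  user-supplied argument defaulting to empty, with a warning so the default
  is never silent.

Logo matching is exact positional matching over the 20-letter alphabet; an
`X` in a *sequence* is an unknown residue and matches only wildcard
positions, never a choice set.

## Gain/loss reconstruction

Presence/absence profiles (`cell = 1` iff the species has at least one gene
of the family) are reconstructed on the tree three ways.

**Fitch parsimony** is implemented as a unit-cost dynamic programme
(minimum-change; handles multifurcations natively), with ACCTRAN/DELTRAN
branch mapping.  A root tie — both states equally parsimonious — resolves
toward *absence* by default.  This biases against trivial
"everything-was-ancestral" calls; `root_tie = "present"` flips it.

**Dollo parsimony** allows a single gain per family, placed above the MRCA
of all presence leaves, with losses on the topmost presence-free branches
below it.  It encodes the single-origin convention appropriate for complex
gene families.

**Asymmetric Mk** is a two-state continuous-time chain with gain rate
$\alpha$ (0→1) and loss rate $\beta = r\alpha$ (1→0), where the bias $r$ is
fixed — default $r = 0.1$ — and $\alpha$ is estimated by maximizing the
Felsenstein pruning likelihood over branch lengths.  The direction of a
"0.1 bias between gain and loss rates" is ambiguous in prose, so $r$ is an
explicit parameter rather than a hard-coded convention; the default makes
losses ten times slower per unit branch length, and $r > 1$ expresses the
opposite.  The root prior defaults to the chain's stationary distribution
$\pi_1 = \alpha/(\alpha + \beta) = 1/(1+r)$ (the Mesquite-compatible
choice); flat and fixed priors are available.  Optimization is a bracketed
Brent search on $\log\alpha$ over $[10^{-8}, 10^{3}]$ with tolerance
$10^{-9}$ — deterministic, no starting-point sensitivity.  Rates are fitted
per character by default; `rate_mode = "shared"` pools all characters into
one rate, which is what the simulation-recovery analyses use.  Marginal
ancestral states come from the standard up-down pass; a node is called
present when its marginal exceeds 0.5.  Zero-length trees with conflicting
tip states have likelihood zero: the fit reports `-Inf` with a diagnostic
rather than failing.

Both engines are validated against exhaustive enumeration of internal-node
states on trees of up to six leaves (hundreds of seeded random cases,
agreement to $10^{-10}$ relative), and Fitch scores are cross-checked
against phangorn.

### A worked example

The packaged 14-species eukaryote fixture encodes the survey's canonical
result: every family present on both sides of the unikont–bikont root except
SOCS-box (restricted to Holozoa) and IR1-M (restricted to Metazoa).

```{r worked}
tree <- demo_species_tree()
pa <- demo_presence_matrix(tree)
events <- fitch_reconstruct(tree, pa)
summarize_events(events, "LECA")$gains_after
events$gains
```

Two post-LECA gains, on the branches to Holozoa and Metazoa; all other
families are already part of the LECA toolkit.

## Ancestral domain networks

Accessory domains are the other domains co-occurring with a core domain on
one protein.  Per species, every unordered domain pair with at least one
core member counts one per protein carrying it (core–core pairs included).
A pair is called ancestral at a tree node when it is observed in at least
one species of the *earliest-branching child clade* and at least one species
of the remaining clade(s).  Three interpretation choices are deliberate:

* "Earliest-branching lineage" is operationalized as the **first child in
  Newick order**.  At a binary node both children branch simultaneously;
  the phrase presumes a known basal lineage, which the user encodes by
  ordering children in the input tree.
* "Another internal taxon" is read as any clade species outside that first
  child clade.
* Each node is reconstructed from **extant species only**, so node
  reconstructions are independent; an outside-in "nested" report is simply
  obtained by calling the function per node.

Node abundance is the median gene count of the core domain's family over
*all* clade species, zeros included; edge weight is the median per-species
co-occurrence count (protein counts, not distinct architectures).  Medians
over an even number of species use the midpoint, so half-integers occur.
Density is $2E/(N(N-1))$, zero for degenerate graphs.

## Comparative statistics

* **Enrichment**: per family, a two-sided Wilcoxon rank-sum test between two
  species groups.  The p-value is exact (full enumeration of group
  assignments over midranks; the classical Wilcoxon distribution when
  tie-free) whenever $nm \le 400$, no tied value spans both groups, and the
  enumeration is small; otherwise the tie-corrected,
  continuity-corrected normal approximation.  Direction is called by group
  medians only below `alpha` (default 0.01).  No multiple-testing
  correction by default, with an optional Benjamini–Hochberg flag.  Note
  that with three species per group the smallest achievable two-sided exact
  p is 0.1, so very small groups can never be significant at 0.01 — a
  property of the test, not a bug.
* **PCA** (`pca_profiles()`): `prcomp` with centering and unit-variance
  scaling by default, because family sizes span orders of magnitude.
  Zero-variance columns are dropped with a warning.  Each loading vector is
  oriented so its largest-magnitude entry is positive, making signs
  deterministic across platforms.
* **Matched-pairs symmetry test** (`bowker_symmetry()`): for aligned
  sequences, $S = \sum_{i<j} (n_{ij}-n_{ji})^2/(n_{ij}+n_{ji})$ over residue
  pairs with nonzero total, $\chi^2$ upper tail with one degree of freedom
  per contributing pair.  Sites with gaps or non-standard residues in
  either sequence are deleted pairwise; no partial-count schemes.  All
  off-diagonals zero (e.g. identical sequences) makes the test undefined —
  flagged, not an error.

## The reciprocal-similarity screen

`top_hits()` keeps per query the hits passing the forward cutoff
($10^{-5}$ by default), sorted by e-value, then bit score, then subject id
(a deterministic tie-break at rank $k = 50$).  `build_reciprocal_network()`
adds reverse hits under the stricter reverse cutoff ($10^{-10}$) and reports
each query's reciprocal-hit composition across Eukaryota/Archaea/Bacteria.
No binary transfer verdict is issued: whether a composition is "unexpectedly
similar" to a foreign domain of life is a judgment the module leaves to the
analyst, reporting fractions only.

## The simulator and what passing tests mean

`simulate_characters()` evolves each family independently under the same
two-state chain the Mk model fits, from a root state drawn per
`root_presence` (default: the stationary distribution).
`simulate_counts()` layers gene counts on presence as a shifted geometric
with mean `count_mean` (chosen over a negative binomial for its single
parameter; present cells are always $\ge 1$).  `simulate_architectures()`
gives each family an accessory pool whose membership toggles along branches
at `shuffle_rate`, emulating lineage-specific domain shuffling.  One integer
seed drives everything through per-family derived streams, so results are
independent of iteration order.

Default analysis sizes, chosen to exercise the estimators well inside a
laptop's patience: a 16-leaf balanced unit-branch-length tree, 500
characters and 20 replicates for rate recovery (gain rate 0.5, bias 0.1),
500 random small-tree cases for oracle equivalence, and 2,000 replicates of
a 400-site symmetric null for the symmetry test's type-I error.

The simulator matches the *model assumptions* of the analysis, not real
proteomes: families evolve independently, counts are homogeneous across
species, and architectures ignore domain order and copy number.  Passing
recovery tests therefore demonstrates correctness of the inference
machinery, not robustness to model violations (rate heterogeneity across
lineages, annotation noise, isoform inflation) that real surveys face.

Two identifiability caveats are worth stating plainly:

* A loss-free history with several independent gains of the same family is
  generally *not* recoverable by parsimony: when the gained clades cover
  most of the tree, root-presence-plus-loss mappings are equally or more
  parsimonious than the truth.  Exact event-map recovery holds for
  single-origin families (and trivially in the stationary-root loss-free
  regime, where no events occur at all); the tests assert exactly that.
* Fitch root ties are genuinely ambiguous; the absent-by-default policy is
  a documented convention, not an inference.

## Known limitations

* Isoform collapsing is the caller's responsibility: distinct `protein_id`s
  are distinct genes.
* Overlapping hits of the same domain are all retained at parse time;
  family assignment collapses them per gene, architectures per domain set.
* The Mk model is binary — no gene-count (birth–death) dynamics.
* Tree inference, alignment, and running HMMER/BLAST are out of scope;
  the package consumes their outputs.
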