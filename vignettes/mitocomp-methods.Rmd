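---
title: "Compositional bias and gene-order analysis of mitochondrial genomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional bias and gene-order analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

# Scope

`mitocomp` implements the statistics a comparative mitogenomics study runs
between genome annotation and tree inference: composition and strand-skew
profiles, codon usage, breakpoint distances between gene orders, tests of
compositional heterogeneity across taxa, amino-acid recoding schemes that
mitigate that heterogeneity, and sitewise evolutionary rates used to strip
fast-evolving (saturation-prone) alignment columns. Genome annotation itself
(gene finding, tRNA prediction), multiple sequence alignment, and tree
inference are out of scope: annotated GenBank records, FASTA alignments and
Newick trees are inputs.

# Composition and skews

For a nucleotide sequence the package counts A, C, G, T (N and gaps are
excluded) and reports proportions, AT% and the Perna–Kocher strand skews

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C},$$

computed on the plus (deposited) strand for whole genomes and on the coding
strand for genes, which is how the packaged survey tables are laid out. Both
skews lie in $[-1, 1]$; a zero denominator yields `NaN` (an explicit
undefined-skew sentinel) rather than an error. Outputs print proportions and
skews to 3 decimals and percentages to 1 decimal, matching the conventions of
published composition tables; full precision is kept internally.

Clade summaries are unweighted per-genome means. This choice is deliberate:
averaging AT% per genome (rather than pooling bases) is what reproduces the
survey's published clade means from its per-genome rows.

The packaged survey (`load_fixtures()$table2`) stores the printed,
3-decimal proportions. Derived columns (AT%, skews) recomputed from those
rounded inputs can differ from the printed derived values in the last digit
(propagation error up to ~0.0025 on a skew, 0.1 on AT%); every such cell is
flagged in the table's `rounding_note` column, and the test suite asserts
exact agreement wherever no flag is recorded. The two printed composition
tables use different column orders (A,C,G,T vs A,G,C,T); the loader
normalizes both to A,C,G,T.

# Codon usage

Codons are counted over complete triplets of the coding strand under the
invertebrate mitochondrial code (NCBI table 5) by default; the code is
overridable per call because metazoan lineages differ. Complete termination
codons are counted (they form their own family); a trailing incomplete
termination codon — a CDS ending in T or TA that is completed to UAA by
polyadenylation — is excluded from the codon list and flagged on the
feature. Families follow the tRNA classes: one family per amino acid except
leucine (Leu1 = CUN, Leu2 = UUR) and serine (Ser1 = AGN, Ser2 = UCN).

# Gene orders and breakpoint distances

Gene orders are circular, signed token lists over a controlled vocabulary
(13 protein-coding genes, 2 rRNAs, tRNAs by single-letter code with
L1/L2/S1/S2 isoacceptor and W1/W2 duplicate disambiguation). tRNAs are
excluded from distance calculations by default, giving the standard
15-token orders: published breakpoint matrices for these genomes are
restricted to protein-coding plus rRNA genes, and tRNAs rearrange too fast
to be informative at this depth.

An order's adjacency set contains its consecutive signed pairs, including
the closing pair of the circle, canonicalized under
$(x, y) \equiv (-y, -x)$ so that reading direction does not matter. The
breakpoint distance between two orders on the same tokens is the number of
adjacencies of one absent from the other. It is symmetric, zero on
identical orders, invariant under rotation and under full reversal with
sign flip, and each inversion or transposition changes at most 3
adjacencies — the test suite checks all of these, plus exact agreement with
a brute-force double-loop oracle on random order pairs. Conserved blocks
are maximal runs of consecutive shared adjacencies, reported in the first
order's coordinates.

Whether published breakpoint counts treated orientation is not always
stated; for genomes whose genes all lie on one strand (as in the
cheilostomate ectoprocts) signed and unsigned counts coincide, which limits
the risk of the signed convention used here.

# Compositional heterogeneity tests

**Chi-square homogeneity.** The classical contingency-table test: expected
counts are row totals times pooled state frequencies,
$X^2 = \sum (O - E)^2 / E$, df $= (\text{taxa} - 1)(\text{states} - 1)$
(144 for 49 taxa and 4 nucleotides). The test assumes independent rows;
shared ancestry violates that on real alignments, which is why it is
reported alongside the pairwise test below. Its type-I error is calibrated
in the tests on a long-branch star tree, where leaves are effectively
independent draws from the stationary composition.

**Matched-pairs test of symmetry (Bowker).** For two aligned sequences the
divergence matrix $N_{ij}$ counts columns with state $i$ in one and $j$ in
the other. Under stationary, reversible evolution $E[N_{ij}] = E[N_{ji}]$;
the statistic $S = \sum_{i<j} (N_{ij} - N_{ji})^2 / (N_{ij} + N_{ji})$ is
chi-square with df equal to the number of pairs with $N_{ij} + N_{ji} > 0$.
Counting only non-empty pairs (rather than fixing df at $c(c-1)/2$) is the
standard treatment of empty cells and matters for short, sparse inputs such
as concatenated tRNAs. Pairs with no off-diagonal counts are degenerate:
statistic 0, df 0, p 1, flagged. The pairwise summary reports the raw
fraction of pairs with $p < \alpha$ ($\alpha = 0.05$ by default) without a
multiple-testing correction, because published summaries of this kind
report raw fractions.

**Per-taxon deviation and posterior-predictive-style testing.** The
deviation of taxon $t$ is $d_t = \sum_a |f_{t,a} - f_a|$, the sum over the
alphabet of absolute differences between taxon-specific and pooled non-gap
frequencies (bounded by 2); the global statistic is $\max_t d_t$. Observed
statistics are compared with their distribution over alignments simulated
under a homogeneous reference model on a fixed tree: Z scores are
$(d_{obs} - \bar d_{rep}) / s_{rep}$ and one-sided p-values use
$(r + 1)/(n + 1)$ smoothing, which avoids $p = 0$ artifacts from finite
replicate counts. At least 20 replicates are required; fewer give an
unusable replicate standard deviation (degenerate cases, $s = 0$, are
flagged rather than scored).

This is a stand-in for a full posterior predictive test: real posterior
predictive checks draw replicate parameters from an MCMC posterior of a
site-heterogeneous model, which is out of scope here. Published Z scores
from such samplers are therefore not reproducible by this package, and the
tests instead verify self-consistency (uniform-ish p-values under the null)
and power (a planted single-taxon composition shift of total variation 0.2
is detected at $\alpha = 0.05$ with power above 0.8 at 1,000 columns, with
fewer than 10% of null taxa flagged). The power experiment uses 49 taxa —
the scale of the study the package re-implements — because the planted
taxon contaminates the pooled frequencies that null taxa are measured
against; that contamination scales as $1/n_{taxa}$, and at very small taxon
counts it inflates null flagging regardless of implementation.

# Recoding schemes

`recode()` maps residues to group symbols (each group's alphabetically
first member, which is unique across groups), preserving gaps and column
count. The Dayhoff groups (AGPST, C, DENQ, FWY, HKR, ILMV) are packaged.
`find_minmax_bins()` searches for a partition of the alphabet into $k$
bins minimizing the maximum over taxa of the binned chi-square statistic
(taxon binned counts vs pooled binned frequencies). The search is
steepest-descent over single-residue moves from 50 random restarts,
deterministic given the seed, with ties broken towards the
lexicographically smallest partition — determinism matters for
reproducible pipelines, and on alphabets of up to 8 letters the heuristic
provably (by enumeration in the tests) attains the exhaustive optimum. The
p-value attached to a partition uses df $= k - 1$; this convention is
recorded in the result because taxon-wise df adjustments exist in other
software and are not always documented. `select_bin_count()` implements the
min-P rule: the largest $k$ whose minimum per-taxon p-value exceeds 0.05,
i.e. the finest binning under which no taxon rejects homogeneity.

# Sitewise rates and fast-site removal

Likelihoods are computed by Felsenstein pruning under a reversible model
built from a symmetric exchangeability matrix and stationary frequencies,
normalized to one expected substitution per unit branch length. Rate
variation uses equiprobable discrete-gamma categories whose rates are the
category means (not medians), 8 categories by default; category means make
the weighted mean rate exactly 1. Computation is log-space stable via
per-node rescaling, and zero branch lengths are legal. The per-site rate is
the posterior mean
$\hat r_s = \sum_g r_g w_g L_{s,g} / \sum_g w_g L_{s,g}$; a
maximum-posterior-category mode is available behind a flag, since published
"sitewise rates" do not always state which estimator was used. All-gap
columns have undefined rates and are treated as slowest for removal.

`remove_fast_sites()` removes the `round(q * L)` highest-rate columns,
keeping the leftmost of tied columns and preserving survivor order. The
rounding convention is chosen because it reproduces both published
remaining-column counts exactly (12,648 nucleotide columns minus 20% leaves
10,118; 2,729 amino-acid columns minus 10% leaves 2,456).

Model parameters are user-supplied (trees and substitution parameters are
inputs in this workflow); a simple one-dimensional direct search for the
gamma shape on a fixed tree is provided, and empirical amino-acid
exchangeabilities can be read from PAML-format files. No "official"
amino-acid matrix is bundled.

# Synthetic data

The simulators exist so that every stage is testable without downloads, and
their defaults are the study conditions the tests assume.

* `scramble_gene_order()` applies seeded random inversions/transpositions,
  never spanning the full circle (a full-circle operation is a rotation,
  i.e. a no-op on a circular order), and logs every operation; replaying
  the log is byte-identical.
* `simulate_alignment()` evolves sites down a fixed tree by exact
  matrix-exponential transition probabilities (via eigendecomposition of
  the reversible rate matrix), not discretized time steps — exactness of
  the stationary distribution is what makes the type-I calibrations of the
  heterogeneity tests meaningful. Composition breakpoints switch the active
  composition part-way along a branch; the rate matrix is rebuilt from the
  shared exchangeabilities and the new frequencies, and the regime is
  inherited by the descendant subtree. With no breakpoints the process is
  stationary. Per-site rates (gamma-distributed or supplied) are returned
  as simulation truth.
* `simulate_cds()` draws i.i.d. codons from target usage fractions,
  excluding stop codons unless asked.

What the simulators do not emulate: indels (alignments are generated
gapless), tRNA secondary structure, control-region motifs, and
among-lineage rate variation beyond branch lengths. Passing tests on
synthetic data therefore demonstrate the correctness of the statistics, not
that real mitogenome alignments satisfy the tests' assumptions — on real
data the chi-square homogeneity test in particular is anti-conservative
because taxa share phylogeny.

# Problem sizes and numerical choices used by the checks

The packaged checks run at sizes chosen to balance statistical resolution
against runtime: type-I calibrations use 2,000 replicates (300-column,
10-taxon star alignments for the chi-square test; 2,000-column pairs for
the symmetry test), the planted-shift power experiment uses 6 experiments
of 49 taxa x 1,000 columns with 100 replicates each, exhaustive/heuristic
bin comparisons enumerate all partitions of an 8-letter alphabet, and the
pruning engine is checked against brute-force ancestral-state enumeration
on 200 random trees of up to 4 leaves (relative error below 1e-10) plus a
16-taxon rank-correlation recovery of simulated gamma(0.5) rates.

Other numerical conventions: ambiguity characters other than N are rejected
at GenBank parse time (downstream statistics assume the 4-letter alphabet;
N is excluded from counts); protein alignments tolerate X and `*` as
uncounted symbols; duplicated tRNAs get ordinal suffixes while duplicated
protein/rRNA tokens are an error (distance analyses need unique tokens);
and CDS features whose length is not a multiple of 3 are interpreted as
ending in an incomplete termination codon of 1–2 bases.

# Known limitations

* The GenBank reader covers single-record flat files with simple,
  complement and two-segment origin-wrapping join locations — the forms
  that occur in mitogenome deposits — not the full location grammar.
* The posterior-predictive stand-in draws replicates from one fixed
  stationary model rather than a posterior; its Z scores are comparable
  within a run, not with sampler-based published values.
* The minmax bin search is heuristic beyond enumerable alphabet sizes;
  restarts make it reliable in practice but optimality is only guaranteed
  where enumeration is feasible.
* Breakpoint distance is the only rearrangement measure implemented; no
  inversion/transposition scenario reconstruction is attempted.
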