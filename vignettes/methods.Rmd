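---
title: "Methods: chromatin structure, annotation and cross-species conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin structure, annotation and cross-species conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicross)
```

This vignette is the package's account of the statistics it implements:
the models and their assumptions, the parameters that matter, the
numerical conventions adopted where a published description leaves room,
and what the synthetic-data generators can and cannot demonstrate.

## Coordinate conventions

All intervals are 0-based, half-open (BED convention), on a single
reference per analysis. GTF input/output converts to and from 1-based
closed coordinates at the boundary, so interval arithmetic inside the
package is uniform. Transcripts are always stranded; peaks and bins are
unstranded. The TSS of a transcript is its 5' base with respect to
strand, the TTS its 3' base; both are single positions, not intervals.

## Hi-C matrix processing

A `contact_map()` holds a symmetric, non-negative within-chromosome count
matrix at a fixed bin size with a per-bin validity mask. Everything is
per-chromosome; trans-chromosomal contacts are out of scope, and on real
data one would restrict to the largest assembled chromosomes before
calling structure.

**Balancing.** `ice_normalize()` performs iterative proportional fitting:
bins in the lowest 2% of marginal sums (`low_count_frac = 0.02`), plus
all empty bins, are masked; the matrix is repeatedly divided by the outer
product of its normalized marginals until the bias update falls below
`eps = 0.1` in max-norm or `max_iter = 100` sweeps are reached. These
defaults mirror a standard Hi-C processing configuration; for numerical
studies of the fixed point itself the tests tighten `eps` to `1e-4`,
which drives the row-sum coefficient of variation below `1e-3`. The
total unmasked count is preserved, so balancing changes relative, not
absolute, contact intensity. Balancing preserves symmetry and the zero
pattern.

**Distance correction.** Contact counts decay strongly with genomic
distance, which would dominate any bin-bin correlation. Each cell is
therefore standardized against its distance stratum:
\[
\hat K_{ij} = \frac{K_{ij} - \bar K^{d}}{\sigma^{d}},
\qquad d = |i - j|,
\]
with mean and standard deviation taken over all unmasked pairs at
distance \(d\). Two degenerate cases need a convention: a stratum with a
single unmasked pair, and a stratum with zero variance. Both are set to
corrected value 0 — the neutral value of the standardized scale — which
keeps the affected bins usable for the correlation step without
injecting information. The correction is invariant under global
rescaling of the input, so the overall sequencing depth (and the global
scale left free by balancing) cannot influence compartment calls.

**Compartment calling.** `call_compartments()` chains balancing,
distance correction, the bin-by-bin Pearson correlation matrix over
unmasked bins, and a symmetric eigendecomposition of that correlation
matrix; the first eigenvector (largest eigenvalue) defines the
compartment axis, following the classic plaid-pattern argument. The
eigenvector sign is arbitrary, so a rule is needed to decide which sign
group is "A". We compare the mean main-diagonal value of the *balanced*
matrix between the two sign groups and label the larger one A: active
chromatin is more compact locally, enriching the short-range diagonal.
This keeps the assignment annotation-free and consistent across
chromosomes. Bins whose distance-corrected profile is constant carry no
correlation signal and are reported NA, as are masked bins.
`segment_compartments()` converts the per-bin labels to maximal runs,
with NA bins breaking runs, and `replicate_consistency()` reports the
proportion of bins with non-conflicting labels among bins informative in
at least two replicates.

**Directionality index.** For each bin, `A` and `B` are the contact sums
to bins within `window_bp` upstream and downstream, `E = (A+B)/2`, and
\[
DI = \mathrm{sign}(B - A)\left(\frac{(A-E)^2}{E} +
\frac{(B-E)^2}{E}\right),
\]
with DI defined as 0 when `A = B` or `E = 0`. The default window is 2 Mb
(the choice of the original definition); it is configurable, and the
tests use windows matched to the simulated domain size. Bins within one
window of the chromosome edge are flagged, since their up/downstream
sums are truncated asymmetrically.

**Insulation score.** Within a sliding window (default 500 kb, step
10 kb), the score is the proportion of contacts that span the window
midpoint among all contacts with both ends inside the window. It is
computed from the raw binned counts by default, matching the
valid-pairs reading of the statistic (a `use_balanced` flag switches to
balanced counts). Self-pairs (`i = j`) are included in the denominator;
excluding them changes the score by a near-constant factor and none of
the comparisons in this package. Windows truncated by a chromosome end
are not reported rather than rescaled, to avoid edge artifacts: the
profile starts half a window into the chromosome. Low scores mark
insulation; `boundary_scores()` assigns each TAD boundary the score of
the nearest profiled midpoint (ties resolved toward the lower
coordinate), and `insulation_minima()` reports strict local minima.

## Positional transcript classification

Queries are compared to all reference transcripts on the same chromosome
and strand, with class priority known > extension > alternative > novel
(a query identical to one reference and sharing an intron with another
is *known*):

* **known** — exon-intron structure strictly identical;
* **extension** — identical intron chain, with an extreme exon extending
  the reference outward by at least 1 bp on at least one side. We read
  "extends" as containment: the query may not shrink the reference on
  either side. For mono-exonic transcripts this becomes single-exon
  containment with at least 1 bp of strict extension (equality allowed
  on one side);
* **alternative** — shares at least one intron (identical donor and
  acceptor coordinates); only multi-exonic queries can be in this class;
* **novel** — none of the above.

The implementation uses signature lookups (exon chains, intron chains,
individual introns); the test suite checks it against a plain four-rule
oracle on an exhaustive enumeration of all 1-, 2- and 3-exon structures
over a 1 kb window on a 100 bp grid, on both strands.

## Peak genomic domains and promoter integration

Peaks are classified into nine domains, several of which may hold
simultaneously: exonic (≥ 1 bp exon overlap), intronic (totally included
in one intron), tss/tts (peak contains the site), tss1Kb/tss5Kb and
tts1Kb/tts5Kb (peak overlaps the site extended 1 kb / 5 kb on both
sides), and intergenic (no overlap with any gene span extended 5 kb on
each side) — intergenic is by construction exclusive of the rest, and
the site labels are nested (tss ⇒ tss1Kb ⇒ tss5Kb).

The promoter of a transcript is the 1 kb strictly upstream of its TSS —
deliberately asymmetric, following the accumulation of accessibility
immediately upstream of the TSS visible in TSS-centred profiles
(`tss_density_profile()`, which orients windows 5'→3' and also reports
the fraction of peaks within ±1 kb of a TSS). A peak overlapping any
promoter of a gene contributes its full per-sample counts to that gene;
multiple contributing peaks are summed, and a peak serving promoters of
several genes counts for each (such peaks are flagged in an attribute).

Per-gene coupling is the Pearson correlation of
`log10(accessibility + 1e-3)` vs `log10(expression + 1e-3)` over shared
samples. The `1e-3` pseudocount keeps zero values finite on the TPM
scale. At least 3 shared samples are required — a two-point correlation
is always ±1 — and constant vectors give NA. Sample-level clustering
uses `1 − r²` on log10 TPM with complete linkage; squaring makes the
distance indifferent to the sign of the correlation, so it groups
samples by strength of co-variation. Expression quartiles break ties by
feature id so repeated runs partition identically.

## Cross-species procedures

**Best hits, clusters, chaining.** Per query feature, the best hit is
the maximal-score block (ties: smallest target start, then target
chromosome id). Species-tagged best hits are merged on the reference
genome by single linkage on overlapping-or-abutting intervals; a merged
cluster fed by more than one feature of the same species is ambiguous
and excluded from similarity levels, which otherwise count distinct
species. Fragmented projections are re-assembled by
`chain_blocks()`: dynamic programming over the strict-ordering DAG
(collinear on query and target, same strand, no gap penalty) maximizes
total score; a chain is accepted if query coverage ≥ 0.4, total score
≥ 3000 and chained target length ≥ 5000. Block score is defined as
aligned bases, so the score threshold is in base pairs; coverage is
measured on the query and chained length on the target, where the
projected feature lives.

**Syntenic lncRNAs.** A lncRNA is syntenically conserved when (1) it
lies between two orthologous protein-coding genes, (2) it is the only
lncRNA in that gap in every species, and (3) the order and orientation
of the triplet is identical across species. "Between" means the lncRNA
span intersects the open interval between the inner flank boundaries, so
a divergently overlapping lncRNA at zero distance remains eligible.
Because whole-genome orientation is arbitrary, patterns are compared
after orienting each species' triplet by its flank orthology, flipping
order and strands together when needed; the detector is therefore
invariant under coordinate reversal of any one species.

**Compartment conservation.** With per-species observed A-frequencies
\(p_A^{(s)}\) over \(N\) fully-labelled orthologs, the expected number
of all-A genes under independence is \(N\prod_s p_A^{(s)}\) (same for
B), and the headline quantity is the percent excess of the observed
same-type count over the summed expectation. All-A and all-B counts are
each tested with a 1-df χ² goodness-of-fit against the complement,
following the separate-categories phrasing of the procedure; a combined
2-df variant over (all-A, all-B, discordant) is available behind the
`combined` flag. Degenerate frequencies (0 or 1) make the χ² undefined
and are reported NA. A statistical caveat documented by the calibration
test: the expectation uses *plug-in* frequencies estimated from the same
table, which under the null tracks the observation and makes the test
conservative (its type-I rate falls well below the nominal level; the
delta-method variance of the plug-in statistic is roughly a third of
the binomial variance the χ² assumes at these frequencies). The test
therefore understates significance; observed excesses survive it a
fortiori.

**Permutation overlap.** The observed statistic is the number of set-B
intervals overlapping set A by ≥ 1 bp. The null redraws set A uniformly
per chromosome, preserving lengths and allowing self-overlap, and the
empirical p-value uses the add-one rule, so it is never exactly 0 and
its resolution is `1/(n_perm + 1)`. Stratified score comparisons use
two-sided Wilcoxon rank-sum tests within each similarity level.

## Synthetic data: what it emulates, and what it does not

The generators produce the *downstream products* of the assays — binned
contact maps, annotations, peak count tables — never reads or sequence.

`simulate_contact_map()` draws independent Poisson counts around
\[
\lambda_{ij} \propto (1+|i-j|)^{-\alpha}\,
(1 + c\,[\text{same compartment}])\,(1 + t\,[\text{same TAD}]),
\]
with the main diagonal of A bins further inflated by \(1 + a\) so that
the diagonal sign rule is identifiable. The reference conditions — 200
bins of 10 kb, alternating 40-bin compartment blocks, 20-bin TADs,
expected depth \(10^6\) pairs over unique bin pairs, \(\alpha = 1\)
(classic polymer scaling), \(c = 1\), \(t = 0.5\), \(a = 0.5\) — were
fixed once as a plausible single-chromosome caricature and are the
defaults. A 10 kb bin keeps the standard insulation step (10 kb) a
multiple of the bin size; the insulation tests use a 200 kb window
matched to the simulated domain size, since the 500 kb default was
designed for megabase-scale domains and cannot be evaluated within half
a window of a chromosome end. Poisson noise is thinner-tailed than real
Hi-C overdispersion, bins are never unmappable, and the decay has no
genome-specific structure — so recovery rates here bound what identical
settings would achieve on real data from above.

`simulate_multispecies_annotation()` lays out the same ordered coding
genes (1-to-1 orthologs, conserved strands) per species with
species-specific coordinates, plants lncRNA triplets satisfying all
three synteny criteria (one of them divergently overlapping its upstream
flank, the zero-distance case), and adds decoys each violating exactly
one criterion: a second lncRNA in the gap, a lncRNA present in one
species only, or a strand flipped in the second species. Real genomes
add rearrangements, missing orthologs and annotation errors that the
generator does not model; the planted/decoy design tests the decision
boundary of the detector, not robustness to assembly noise.

`simulate_coupled_peaks_expression()` gives every gene one promoter
peak inside the 1 kb upstream window and couples log10 accessibility to
the per-sample log10 expression fluctuation with slope +1, −1 or 0,
plus Gaussian noise (`noise_sd = 0.25` on the log10 scale, 10 samples —
a scale at which coupled genes correlate around ±0.87, leaving room for
the noise to matter without washing out the bimodality). One peak per
gene is a simplification; multi-peak promoters are exercised by explicit
fixtures instead.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed and restores the
caller's RNG state, so generators are pure functions of (parameters,
seed). The test suite runs the full surface at the reference conditions
above, plus: 50-bin matrices for the distance-correction identity
(deviations at machine precision), 500 random fixtures of up to 12
blocks against an exhaustive-subset chaining oracle, an exhaustive
1694-structure classification suite, 1000 replicates of the χ²
calibration at \(10^4\) genes, and 200 replicates of the permutation
null at 199 permutations each. The pipeline wrapper (`run_pipeline()`)
re-runs byte-identically for a fixed configuration; its manifest records
seed, parameters and output checksums. The package's command-line
surface is these exported functions plus `scripts/acceptance.R`; the
stages read and write plain-text formats (GTF, BED, TSV, JSON), so each
can be run standalone on files.

## Known limitations

* Per-chromosome processing only; no trans contacts, no `.hic`/cooler
  binary formats (bins BED + pair counts text is the exchange format).
* TAD calling itself is out of scope: TAD intervals are consumed as
  input (or planted by the simulator), and the package quantifies their
  boundaries.
* Differential expression/accessibility labels and normalized counts
  are inputs; no NB-GLM fitting, normalization, motif scanning or
  coding-potential classification.
* The compartment sign rule assumes the A compartment enriches the
  short-range diagonal; on real data chromosomes with weak plaid
  structure (the known first-PC exceptions) may need manual review.
* The χ² conservation test is conservative under the null (plug-in
  expectation, see above); its p-values are upper bounds in practice.
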