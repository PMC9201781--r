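---
title: "Chloroplast haplotype phylogeography with haplogeo: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chloroplast haplotype phylogeography with haplogeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplogeo)
```

# The study system and what the package computes

`haplogeo` implements the complete computational chain of a range-wide
chloroplast-DNA phylogeography: from aligned cpDNA spacer sequences to
haplotypes and a median-joining network; from site-level haplotype counts to
diversity and differentiation statistics, hierarchical AMOVA, spatially
constrained SAMOVA, PCoA and Mantel isolation-by-distance tests; and from
suitability rasters to niche-overlap tests, migration vectors and
least-cost dispersal corridors.

The packaged worked example is the lacquer tree *Toxicodendron
vernicifluum* in East Asia: 79 sampling sites across China, South Korea and
Japan, five chloroplast haplotypes defined by seven substitutions (one of
them a 96-bp indel coded as a single event) across a 717-bp alignment of the
*trnL* and *trnL-F* spacers. The species shows a sharp east-west
phylogeographic break along the boundary between the middle and low steps of
China's three-step geomorphology: western wild populations are essentially
fixed for haplotype H1 (with rare H2 and H4), eastern populations, Korea and
Japan for H3 (with rare H5). The site table, group labels, and the
network-implied step-distance matrix ship in `inst/extdata/` and load with
`load_fixture()`.

# Sequence handling

**Indel coding.** Maximal gap runs with identical column extent across all
gap-bearing sequences are treated as single mutation events: the run is
replaced by one binary A/T column (`code_indels()`). Runs that overlap with
different extents are ambiguous and raise an error instead of guessing.
Any shared run is coded, minimum length one; the packaged 96-bp indel is one
instance of the general rule. A caveat: substitutions that fall *inside* a
coded run among the ungapped sequences are collapsed away with the run. This
cannot affect the packaged system (the run carries a single event) but is a
known simplification for other data.

**Haplotype collapsing.** Identical sequences share a haplotype; labels are
assigned in order of first appearance, which makes results reproducible and
lets a suitably ordered input reproduce conventional label sets. Columns
containing `N` in any record are masked from both distances and the
segregating-character count — the conservative choice when base calls are
missing.

**Median-joining network.** `median_joining_network()` builds a minimum
spanning network (equal-cost links retained as reticulations), then greedily
adds consensus (median) vectors of linked triplets while they shorten the
total spanning length, and finally prunes median vectors of degree two or
less. Tolerance `epsilon` defaults to 0; ties are broken by (weight,
endpoint label) order. Columns at which all three triplet members differ
keep the first member's state — coded cpDNA columns are effectively binary,
so this limitation is immaterial here, but the function is not a general
quasi-median network builder.

# Diversity and differentiation estimators

Per-site diversity uses Nei's unbiased gene diversity
$H_d = n(1 - \sum_i p_i^2)/(n-1)$ and the all-pairs nucleotide diversity
$\pi = \sum_{i<j} d_{ij} / (\binom{n}{2} L)$, where $d_{ij}$ counts
mutational steps between the haplotypes of individuals $i, j$ and $L$ is
the alignment length. Both conventions were selected because they reproduce
every polymorphic per-site cell of the packaged table at printed precision
(the tests assert all of them); the table's ZAO row includes that site's two
cultivated trees, and the `table1_as_printed` preset reproduces that quirk
without propagating it into the analysis pipeline.

For the Pons & Petit (1996) statistics, sites contribute unweighted (each of
the $K$ sites counts once). Within-site diversity is the mean of the
unbiased per-site values. For total diversity the package uses the
among-site variance form
$$\hat h_T = 1 - \sum_i \bar x_i^2 + \frac{1}{K}\sum_i s_i^2,$$
where $\bar x_i$ is the unweighted mean sample frequency of haplotype $i$
across sites and $s_i^2$ its between-site sample variance. This form arises
from treating sites as a sample from a population of sites: the binomial
within-site corrections cancel exactly against the variance decomposition,
so no harmonic-mean term remains. The distance-weighted (ordered) analogues
replace frequency products with $\pi_{ij}$-weighted products,
$\hat v_T = \sum_{i \ne j} \pi_{ij}(\bar x_i \bar x_j - s_{ij}/K)$, giving
$G_{ST} = 1 - h_S/h_T$ and $N_{ST} = 1 - v_S/v_T$. The variance form — and
not the Nei–Chesser harmonic-mean correction — is the estimator that
reproduces the published totals on both packaged presets, which is why it is
the one implemented.

**Standard errors** are delete-one-site jackknife estimates. The original
papers give closed-form variance estimators; the jackknife was chosen as a
single transparent mechanism covering all six statistics, and on the
packaged data it reproduces the published standard errors to within one or
two units in the last printed digit. SEs are reported, not tested.

**NST-vs-GST permutation test.** The null hypothesis is "haplotype
relatedness carries no information about haplotype distribution", under
which $E[N_{ST}] = E[G_{ST}]$. The default null scheme shuffles the
off-diagonal distance values among haplotype pairs; an alternative
(`scheme = "labels"`) relabels whole rows/columns of the distance matrix.
With five haplotypes the relabeling null has only $5! = 120$ distinct
points and is too coarse to register the packaged system's structure
(its exact tail fraction is 9/120), whereas the distance-shuffle null
matches the published judgement of significance; for three haplotypes the
two schemes coincide, and the tests verify the exact enumeration against an
independent oracle. P-values use the $(1 + \text{hits})/(1 + n)$ convention
so that a sampled p is never zero.

# AMOVA, SAMOVA and ordination

**AMOVA** (`amova()`) partitions squared inter-individual distances across
three levels with the standard unequal-sample-size coefficients. The squared
distance between two individuals is their haplotypes' mutational step count
— the pairwise-difference convention. That convention is a load-bearing
choice: with it, the packaged dataset's sums of squares are reproduced
exactly (413.19 / 4.05 / 7.61), while a 0/1 haplotype metric is off by a
factor of roughly five. Significance uses three permutation schemes:
individuals among sites (F_ST), individuals among sites within groups
(F_SC), whole sites among groups (F_CT).

**SAMOVA** (`samova()`) searches for the K-group partition maximizing F_CT
under geographic contiguity. Contiguity comes from a Delaunay triangulation
of site coordinates (computed directly by circumcircle tests — adequate for
survey-scale site counts — and augmented with nearest-neighbour links if
numerically degenerate configurations disconnect it). Each run grows a
random contiguous K-partition from random seeds, then anneals by moving
boundary sites into adjacent groups under a Metropolis rule. The initial
temperature is calibrated so that a median worsening move from the initial
state is accepted with probability one half; the temperature decays
geometrically (factor 0.9) after each sweep of `n_sites` moves. Groups may
transiently lose contiguity through later moves, as in the original
procedure. The best partition over all runs is returned together with the
per-run trace. On the packaged dataset the K = 2 search recovers the
35-site western / 40-site eastern split in essentially every run, and the
objective is verified in the tests to equal the full AMOVA F_CT to machine
precision.

**Pairwise PhiST, PCoA and Mantel.** `pairwise_phist()` supports two
inter-haplotype distance conventions. The hierarchical AMOVA always uses
step counts, but for the PCoA/Mantel track the default is the 0/1
(frequency-based) convention of the GUI tool used for those analyses in the
original workflow: on the packaged data it puts the first PCoA axis at
94.3% explained variance and the Mantel correlation at r = 0.70, inside the
bands the published values (88.12%, 0.682) imply once the tool's exact
convention is acknowledged as unrecoverable. Negative pairwise estimates
are clamped to zero (they would otherwise break the ordination), identical
monomorphic pairs are defined as zero, and the Mantel test uses the natural
log of great-circle kilometres, one-tailed for positive association — the
isolation-by-distance alternative. PCoA percent variance is computed over
positive eigenvalues only.

**Strict-clock divergence.** `clock_divergence()` reports
$d_{net} = d_{XY} - (\pi_X + \pi_Y)/2$ per site and
$T = d_{net}/(2\mu)$ with $\mu$ defaulting to the angiosperm cpDNA average
of $2 \times 10^{-9}$ substitutions/site/year. Within-clade diversity here
is frequency-based (not the unbiased pairwise form), so identical clades
give exactly zero net divergence. This is a first-order sanity check, not a
replacement for model-based dating; full Bayesian dating is out of scope.

# Niche overlap and landscape connectivity

Schoener's $D = 1 - \frac12\sum|p_a - p_b|$ and Warren's
$I = 1 - \frac12\sum(\sqrt{p_a} - \sqrt{p_b})^2$ are computed after
normalizing each suitability raster over the cells valid in *both* rasters.
The identity test re-partitions the pooled occurrence points, without
replacement, into pseudoreplicate sets of the original sizes, refits the
suitability model, and reports one-tailed p-values for divergence
(observed overlap *below* the null). The suitability model is pluggable;
the built-in Gaussian envelope (per-layer z-scores at the occurrence cells,
suitability $\exp(-\frac12\bar{z^2})$ rescaled to $[0,1]$) is a transparent
stand-in sufficient for testing the randomization machinery — it is not a
Maxent substitute in any inferential sense, and observed overlap values on
real data are model-dependent.

Corridor analysis inverts suitability into friction ($1 - x$), computes
Dijkstra cost fields over the 8-connected cell lattice (step cost = mean
friction of the two cells times 1 or $\sqrt 2$ in cell units; latitude
distortion is ignored at these scales, matching planar GIS practice), and
classes each cell of the two-field corridor surface by the fraction its
cost exceeds the least-cost-path cost. The published class rule
("<1%, <2%, <5%" weighted 5/2/1) overlaps as printed; the package reads it
as disjoint half-open bands $[0,1\%) \to 5$, $[1\%,2\%) \to 2$,
$[2\%,5\%) \to 1$ so that no cell is double-counted, with a `cumulative`
flag for the stacked reading. "Path length" is interpreted as accumulated
cost — the friction construction is cost-based and geometric length is
undefined off the single optimal path. Corridors for all site pairs sharing
a haplotype are summed into the dispersal-network raster; sites are first
thinned to one per grid cell.

# The packaged dataset and its presets

The site table is data, not simulation: per-haplotype wild and cultivated
counts, coordinates (two-decimal degrees), elevations and west/east group
labels for all 79 sites. Cultivated trees in China are excluded from every
analysis (they record historical transplanting); cultivated trees in Japan
and Korea are retained as the only representation of the species there.
Four sites consist only of Chinese cultivated trees and drop out entirely,
leaving the 75-site / 385-tree dataset used for AMOVA, SAMOVA, PCoA and
Mantel.

The differentiation analyses additionally require at least three trees per
site. The general rule (`aggregate_small_sites()`: merge a small site into
its largest 0.625-degree grid-cell mate, then drop what remains below three)
is implemented and tested on constructed cases, but the published 47-site
membership itself is hard-coded as the `paper_permut_sites` preset: the
published exclusion list is authoritative, the table's rounded coordinates
make borderline grid membership unrecoverable, and under any single grid
anchoring the rule disagrees with the published list for one or two
borderline pairs. Because every Japanese and Korean site is fixed for one
haplotype, the differentiation statistics are provably invariant to which
particular Japanese sites were combined — the tests assert this — so the
hard-coding affects bookkeeping, not results. Grid cells are half-open
intervals anchored at 0 degrees; country is parsed as the last
comma-separated token of the locality string.

# Synthetic data: what it emulates and what it does not

The generators (`paper_network_spec()`, `generate_alignment()`,
`generate_sites()`, `generate_landscape()`, `sample_occurrences()`) are pure
functions of their parameters and seed. `generate_alignment()` plants each
branch step at a distinct random column, so collapsing the output recovers
the specified haplotype count, segregating characters and path distances
exactly — the round-trip property the sequence tests rely on.
`generate_sites()` draws multinomial counts from region-specific haplotype
frequencies around two spatial cluster centers; the defaults (ten trees per
site; west: 0.95 H1 / 0.04 H2 / 0.01 H4; east: 0.93 H3 / 0.07 H5) mirror
the near-fixation observed in the packaged table. What the generators do
*not* emulate: recombination-free but non-treelike variation (homoplasy),
sequencing error, spatially autocorrelated sampling effort, and realistic
paleoclimate structure — landscape layers are smooth gradients plus white
noise. Tests passing on synthetic data therefore validate the estimators
and search machinery, not the ecological realism of any particular model
output.

# Numerical choices and degenerate inputs

* Permutation p-values use $(1+\text{hits})/(1+n)$ throughout; seeds are
  explicit arguments, never global state, and the orchestration functions
  derive distinct sub-seeds per stage from one user seed.
* Sites with fewer than two individuals yield `NA` diversity; datasets with
  all sites fixed for one haplotype raise an error from `pons_petit()`
  (differentiation undefined) rather than returning 0/0.
* Dijkstra ties on zero-friction plateaus are broken by insertion order;
  costs, not particular paths, are the contract.
* The annealing objective can in principle stall in a local optimum;
  independent runs are the mitigation, and the packaged analyses use 25-100
  runs. Test and example problem sizes (a 75-site SAMOVA with 25 runs, 100
  identity-test pseudoreplicates on a 20x20-cell landscape, 999-9999
  Mantel permutations) were chosen so the whole suite runs in about a
  minute while leaving each statistic's sampling noise far below its
  assertion tolerance.

# Known limitations

* The MJ builder targets small cpDNA haplotype sets; it is quadratic-plus
  in haplotypes and not meant for hundreds of sequences.
* The Delaunay construction is a direct O(n^3) circumcircle scan — fine for
  survey-scale site counts, wrong tool beyond a few hundred sites.
* The envelope suitability model is intentionally simple; plug in a real
  SDM via the `model` argument of `identity_test()` for substantive niche
  inference.
* Cost surfaces are planar in cell units; geodesic cost distances and
  projection-aware corridors are out of scope.
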