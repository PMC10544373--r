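---
title: "Methods and design of gitmicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of gitmicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gitmicro)
```

`gitmicro` implements the post-assembly analysis layer of multi-kingdom
gastrointestinal-tract (GIT) metagenome studies: genome-level abundance
profiling, community variance statistics, Firmicutes/Bacteroidota (F/B)
trajectory clustering, a genus-by-glycoside-hydrolase correlation screen,
and a four-evidence virus-host interaction network. This vignette records
the models, the tunable parameters, and the design decisions behind each
component, and states precisely what the synthetic-data validation does
and does not demonstrate.

## Abundance model

`tpm_normalize()` converts a genome x sample count table into
transcripts-per-million-style relative abundances:
\[
\mathrm{TPM}(g,s) = 10^6\,
\frac{c_{gs}/L_g}{\sum_j c_{js}/L_j},
\]
with $c_{gs}$ the mapped read count and $L_g$ the genome length in bp.
Whether a study's per-genome "coverage" means read counts or mean depth is
often ambiguous; both are supported (`measure = "counts"` is the default,
`measure = "coverage"` skips the length division because depth is already
a per-base rate). Columns of a non-empty sample sum to $10^6$ by
construction; all-zero samples are preserved as zero with a warning
rather than silently dropped.

`rollup()` sums member-genome abundances into clades from 7-rank
GTDB-style lineages, conserving per-sample totals at every rank. Genomes
missing from the taxonomy are an error by default; an explicit
`unclassified` bucket is available but never silent.

`fb_ratio()` uses the grouped numerator
Firmicutes + Firmicutes_A + Firmicutes_B + Firmicutes_C (i.e. Bacillota
under the split GTDB phyla) over Bacteroidota. A zero denominator yields
`NA` — flagged undefined and excluded downstream — never a silent
infinity.

`rarefy_features()` counts features present (strictly TPM > 100; the
strict inequality is deliberate) in at least one sample of a random
subset, for every subset size, with 100 repetitions by default. The curve
reports mean and standard deviation per size; at the full size the count
is the exact union and the sd is exactly zero. The threshold and
repetition count follow the conventions of genome-catalog rarefaction
analyses in this field.

qPCR support is a two-liner by design: `fit_standard_curve()` is ordinary
least squares of $y = \log_{10}(\text{copies}/\mu l)$ on $x = C_T$ (this
axis convention matters: the slope is in log-copies per cycle), usable
for quantification only when $R^2 > 0.99$;
`copies_from_concentration()` is the exact closed form
$\text{conc} \cdot 10^{-9} \cdot 6.02\times10^{23} / (\text{bp}\cdot660)$.

## Community variance statistics

`bray_curtis()` computes $d(i,j) = \sum_f |x_{fi}-x_{fj}| / \sum_f
(x_{fi}+x_{fj})$, bounded in $[0,1]$ with zero diagonal.

`anosim_test()` implements Clarke's statistic with midranks for ties:
$R = (\bar r_B - \bar r_W) / (n(n-1)/4)$, which keeps $R \in [-1, 1]$.
The permutation p-value uses the add-one rule
$p = (1 + \#\{R^\ast \ge R\})/(1 + B)$, so it is never exactly zero; the
default $B = 999$ makes the smallest reportable p equal 0.001.

`permanova()` Gower-centres the squared distance matrix,
$G = -\tfrac12 J D^{(2)} J$, and partitions $\mathrm{tr}(G)$ with
sequential (Type I) sums of squares in the order the design table gives
the factors — the convention of the standard distance-based
multivariate-ANOVA implementations; reorder the columns to change the
conditioning. Factor sums of squares are computed as differences of
projection traces $\mathrm{tr}(H_k G)$ along the growing QR basis, so
aliased factors are detected exactly (rank does not grow) and reported as
an error; a constant (single-level) factor is a legitimate null term with
zero SS. Per-factor adjusted $R^2$ uses
$1 - (1-R^2)(n-1)/(n-d_f-1)$ with that factor's own df — a marginal
shrinkage that matches how per-covariate explained variance is reported
in community-ecology scans. Permutations act on sample identities (rows
and columns of $D$ jointly), recomputing every factor's pseudo-F.
Sequential factor $R^2$ plus residual $R^2$ sums to one; with Euclidean
distances on one-dimensional data the pseudo-F reduces exactly to the
classical one-way ANOVA F, which the tests verify to $10^{-9}$.

Ordination is deliberately not wrapped: classical principal-coordinates
analysis of a `bray_curtis()` matrix is one call to `stats::cmdscale()`,
and no statistical claim in this package depends on an ordination plot.

## Differential-taxon screen

`lefse_screen()` is a deterministic, single-pass variant of the
LDA-effect-size procedure. Per taxon: a Kruskal-Wallis rank test across
classes (for two classes this is the tie-corrected Wilcoxon rank-sum
test) gates at `alpha`; survivors are scored on unit-variance-scaled
$\log_{10}(\mathrm{TPM}+1)$, where for a single feature the
one-component discriminant axis is the feature itself, so the effect
score is
$\log_{10}(1 + \Delta\bar z \cdot 10^5 / \mathrm{range}(z))$ — the
class-mean separation expressed as a fraction of the observed dynamic
range on the $10^5$ scale the original tool normalises to. A score of 2
therefore means the class means are separated by about 0.1% of the
feature's observed spread. Taxa constant across all samples are excluded
before testing. Two deliberate departures from the original tool: no
30-fold bootstrap subsampling (the screen is deterministic and
order-invariant), and no one-against-all hierarchy (classes are compared
jointly). Validation is accordingly by planted-effect recovery and null
calibration, not by bitwise agreement with the original implementation.

One statistical caveat the tests make explicit: the rank test assumes
independent samples. When class labels ride on a blocking unit (for
example feeding style assigned per subject while each subject contributes
one sample per GIT site), subject-level random structure inflates the
per-sample test — a pseudo-replication property of the design, not of the
implementation. The calibration experiments therefore randomise labels at
the sample level; blocked designs should aggregate to subject level
first.

## F/B trajectory clustering

`trajectory_matrix()` arranges per-sample F/B ratios into a
subjects x ordered-sites matrix (rumen, reticulum, omasum, abomasum,
jejunum, ileum, cecum, colon, rectum) and retains subjects observed at
≥ 7 of 9 sites, mirroring the retention rule of goat GIT trajectory
analyses. `trajectory_cluster()` then applies the standard time-course
preprocessing: subjects with fewer than two observed sites are excluded
with a warning, interior gaps are linearly interpolated (boundary gaps
take the nearest observed value), and each subject is z-scored across
sites so only trajectory *shape* matters. Fuzzy c-means with fuzzifier
$m = 2$ iterates
\[
u_{ik} = \Big(\sum_j (\lVert x_i - v_k\rVert / \lVert x_i -
v_j\rVert)^{2/(m-1)}\Big)^{-1},
\qquad
v_k = \frac{\sum_i u_{ik}^m x_i}{\sum_i u_{ik}^m},
\]
until no centroid moves more than `tol` (default $10^{-6}$). Membership
rows sum to one exactly; a subject sitting on a centroid gets crisp
membership; hard labels break ties toward the lower cluster index so
reports are deterministic. The objective $\sum u^m d^2$ is recorded per
iteration and is non-increasing, which the tests assert, alongside
agreement of the converged state with an independently coded naive
iteration.

## Genus-GH correlation screen

`correlate_genus_gh()` computes Pearson correlations on
$\log_{10}(\mathrm{TPM}+1)$ (a `raw` mode exists because the transform
choice is a convention, not a claim), with the two-sided t-based p-value.
The reported hit gate is $r \ge 0.5$ and $p < 0.05$ on the raw p —
faithful to how such screens are usually gated — while
Benjamini-Hochberg q-values are emitted alongside for transparency.
Per-GH-family correlation is the default; `pool_gh = TRUE` collapses all
families into one pooled GH abundance for the coarser reading of
"correlates with GH category". Zero-variance features are skipped and
logged, never tested. `max_abundance_section()` annotates each genus with
its section of maximal mean abundance among stomach, small intestine,
large intestine and rectum, breaking ties toward the anatomically earlier
section.

## Virus-host evidence channels

**CRISPR detection.** `detect_crispr()` is a CRT-style detector: an exact
seed k-mer (k = 19, the minimum repeat length) recurring at spacings
between min-repeat+min-spacer and max-repeat+max-spacer seeds a
candidate; the seed is extended left and right to the maximal unit shared
by *every* instance; arrays need ≥ 3 repeat copies, repeat length in
[19, 38], spacer lengths in [19, 48], and mutually non-identical spacers
(rejecting plain tandem repeats). Overlapping candidates — one array
seeds from many k-mers, and a seed spanning the array boundary can
produce a shifted sub-array — are resolved by keeping the candidate with
the most repeat copies, then the longest span. One consequence of
extension-based boundary calling: if all spacers happen to share their
first or last base with the flank, the called repeat can absorb one
extra base, shifting every spacer by one; the spacer-matching coverage
rule (> 95%) absorbs this. Coordinates are 0-based half-open throughout.

**Spacer matching.** `match_spacers()` is an exhaustive ungapped scan of
every spacer against every virus, both strands, at C speed — all
placements, including terminal overhangs. A hit needs ≤ 1 substitution
over a span longer than 95% of the spacer; overhanging bases shorten the
span and are not counted as mismatches. Exhaustive search was chosen over
seed-and-extend deliberately: at these problem sizes it is fast enough,
it cannot miss a qualifying placement, and it is definitionally identical
to the naive Hamming oracle the tests compare against. One evidence row
per (virus, host) keeps the best hit (fewest mismatches, then longest
span).

**Homology.** `match_homology()` finds shared exact 11-mers (both
strands), masks words occurring more than 5 times in a genome
(low-complexity/repeat seeds that only inflate the candidate set), groups
seed pairs by alignment diagonal, and evaluates diagonals carrying ≥ 15
seeds spanning ≥ 250 bp — a true > 500 bp segment at > 90% identity
carries on the order of 150 exact 11-mers, so this filter cannot lose
qualifying alignments but removes essentially all random collisions. Each
candidate diagonal is scored base-by-base with +1 per match and
$-\mathrm{id}/(1-\mathrm{id})$ per mismatch, so the maximal-scoring
segment (vectorised Kadane via prefix sums) is positive exactly when its
identity exceeds the threshold; acceptance requires identity > 0.90 over
> 500 bp, keeping the longest alignment per pair. Ungapped alignment is a
deliberate scope decision: the planted validation and the acceptance
semantics concern substitution-level homology, and gapped
blastn-equivalence is not claimed.

**Oligonucleotide composition (d2\*).** `d2star()` counts k-mers
(k = 6) pooled over both strands, estimates expected counts from an
order-2 Markov background fitted to the same strand-pooled sequence
(transition probabilities from 3-mer/2-mer counts), centres
$\tilde X_w = N_w - E_w$, and computes
\[
d_2^\ast = \frac12\left(1 -
\frac{\sum_w \tilde X_w \tilde Y_w / \sqrt{E^X_w E^Y_w}}
{\sqrt{\sum_w \tilde X_w^2/E^X_w}\sqrt{\sum_w \tilde Y_w^2/E^Y_w}}
\right) \in [0, 1],
\]
zero for identical composition and symmetric by construction
(Cauchy-Schwarz bounds the normalised inner product by one). Words with
zero expected count are floored at $10^{-8}$ and logged. The Markov order
matches the generator's composition models; sequences must be long enough
to estimate the background ($\ge 4^r \cdot 10$ bp). Bitwise agreement
with any particular external host-prediction tool is not asserted; what
is asserted (and tested) is agreement to $10^{-10}$ with a naive
enumeration over all $4^6$ words, plus the threshold semantics: per
virus, `predict_kmer_hosts()` ranks hosts ascending and emits at most 5
with score ≤ 0.25, ties broken by lexicographic host id.

**Bin co-membership and integration.** `bin_comembership()` links a
virus to a host when their contigs share a bin; a contig in two bins is
an error because it violates binning semantics. `integrate_evidence()`
collapses evidence to distinct (virus, host) edges with the set of
supporting channels (consensus = set size, so duplicated rows never
inflate it), labels viruses virulent at lifestyle score ≥ 0.5 (or ≥ 50
with `score_scale = 100` for percentage-scaled inputs) and classifies
them specialist (one host) or generalist. `methanogen_screen()` keeps
edges whose host genus is in the methanogen set *and* whose host kingdom
is archaeal — a bacterial genus that merely shares a name cannot slip
through — and reports both the full targeting list and the virulent
subset.

## The synthetic community generator

The generator exists so that every pipeline claim can be checked against
known truth. `generate_genomes()` draws per-genome order-2 Markov
composition models (flat Dirichlet transition rows), which makes genomes
mutually distinguishable by composition — the signal the d2\* channel
needs — while remaining estimable from genomes of ~100 kb. Evidence
channels are planted on *disjoint* virus subsets (default: 25% of viruses
each), so recovered channel sets can be compared to the ledger exactly:

* **crispr** — the host receives an array of 3-6 copies of a random
  28 bp repeat with 32 bp spacers, one of which is a protospacer copied
  from the linked virus with 0 or 1 substitutions. Repeat and spacer
  geometry sit inside the detector's default windows.
* **homology** — a 1000 bp virus segment (shrunk for small virus
  genomes, never below 600 bp) is copied into the host at 95% identity —
  above the 90% acceptance bound, so recovery is unambiguous.
* **kmer** — the virus is sampled from its host's own Markov model.
* **bin** — the virus contig is assigned to the host's bin.

Planted features are placed with a 200 bp exclusion margin so they cannot
overlap. Host taxonomy is scaffolded with near-equal Firmicutes-group and
Bacteroidota genome counts (mirroring the near-parity of these phyla in
large ruminant MAG catalogs), up to four archaeal methanogens carrying
the four methanogen genus names, and two minor phyla.

`generate_abundance()` draws log-normal counts around per-genome base
abundances with fixed site (sd 0.6), geography (sd 0.25) and age
(sd 0.15) loadings on the log10 scale, plus i.i.d. log10 noise
(`noise_sigma`, default 0.5). On top of this, three effects are planted:

* **F/B trajectories.** Each subject belongs to one of two archetypes —
  a flat profile with a sudden jejunum/ileum peak, or a monotone rise
  from rumen to rectum — spanning F/B ratios from about 0.7 to about 8,
  the dynamic range such trajectory clusters exhibit. The trajectory is
  planted at the *community* level: after all per-genome draws, each
  sample's Firmicutes group is rescaled up and Bacteroidota down by a
  common factor so that the realised $\log_{10}$ F/B equals the archetype
  value plus $N(0, \sigma/2)$ sample noise. Per-genome loadings cannot
  control this observable — a log-sum of lognormals is dominated by its
  largest term, so loading-level planting leaves the aggregate ratio at
  the mercy of whichever genome happens to dominate. Planting at the
  observable level is what "planted trajectory" should mean.
  `trajectory_contrast = 0` flattens both archetypes, giving a null
  generator for calibration.
* **Differential genera.** Two genera are scaled by
  `effect_size_differential` (default 10-fold) in one feeding group
  each, with the favoured group recorded as the direction.
* **Genus-GH pairs.** Three genera share a latent factor with one GH
  family each: the family's log10 abundance is
  $\rho z + \sqrt{1-\rho^2}\,\varepsilon$ with $z$ the standardised
  log10 genus abundance, so the planted Pearson correlation is `rho_gh`
  (default 0.8) by construction, and exactly 1 when `rho_gh = 1`.
* A **hindgut genus** is amplified 5x in the large intestine (its random
  site loadings are zeroed — its site structure *is* the planted
  enrichment).

Counts are rounded to integers; metadata rows (subject, site, section,
age, feeding, geography) correspond one-to-one to count columns, and the
truth ledger records every planted link, cluster assignment, effect and
lifestyle label. A fixed seed makes the whole community, including the
written FASTA/TSV/JSON files, byte-reproducible.

**What the generator does not emulate** — and therefore what passing
tests do not show about real data: raw reads, assembly and binning errors
(chimeric bins, contamination), variable genome completeness, sequencing
depth compositionality, phylogenetic correlation among genomes,
overdispersion beyond log-normal noise, and spacer decay or partial
prophage deletion. Recovery rates on this generator demonstrate that the
*computations* are correct and calibrated under known conditions, not
that any particular biological discovery rate is expected in the field.

## Numerical choices and determinism

* All permutation p-values use the add-one rule; defaults are 999
  permutations.
* Fuzzy c-means ties in the hard assignment go to the lower cluster
  index; d2\* host ties go to the lexicographically smaller host id;
  section ties go to the anatomically earlier section.
* The d2\* zero-expectation floor is $10^{-8}$; the Bray-Curtis
  zero/zero pair is defined as distance 0 with a warning; the fuzzy
  c-means convergence tolerance is $10^{-6}$ on centroid movement.
* Every stochastic function takes an explicit seed; `run_pipeline()`
  derives all stage seeds from the single config seed and re-running a
  config reproduces the JSON report byte-for-byte.

## Problem sizes used in validation

The shipped validation works at sizes chosen to exercise every code path
while keeping the full suite fast on a laptop: the default community (20
hosts of 100 kb, 20 viruses of 20 kb, seed 42) for end-to-end link
recovery; 50 replicates of 10 hosts at 50 kb for the composition
channel's top-1 ranking; 24 subjects x 9 sites at noise sd 0.3 for
trajectory recovery; 50-sample subsets for the GH screen; 200 null
replicates for calibration of the differential screen and the
permutation tests; and brute-force oracles (all-positions Hamming scan,
$4^6$-word enumeration, exhaustive subset enumeration for rarefaction,
naive fuzzy c-means) on small instances.

## Known limitations

* The differential screen is a deterministic simplification of the
  original LDA-effect-size tool; it is validated by planted-effect
  recovery and null calibration, not output-for-output equivalence.
* Homology evidence is ungapped and collapsed to the single best
  alignment per pair; multiple loci do not count separately.
* The CRISPR detector approximates the union of the two detectors used
  in practice with one permissive CRT-style pass; degenerate repeats
  below 19 bp or arrays with fewer than 3 copies are out of its design
  range.
* Rank-based tests are applied per sample; blocked designs (repeated
  measures per subject) need aggregation before testing, as the
  calibration section explains.
* UniFrac-style phylogenetically informed distances and covariate-
  constrained (strata) permutations are out of scope.
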