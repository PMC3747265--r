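---
title: "Methods: evaluating 16S primers by short-read information content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating 16S primers by short-read information content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`primereval` evaluates degenerate 16S rRNA primers along four axes —
coverage, phylogenetic signal, OTU richness, taxonomic assignment — by
comparing, for each primer, an in-silico short-read (SR) library against the
nearly-full-length (NFL) library it was cut from. This vignette documents
the models and conventions behind each statistic, the tunable parameters,
what the synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reading was defensible.

# Degenerate matching and coverage

A primer position encoded by an IUPAC code matches a target base iff the
base is in the code's set; an ambiguous base in the *target* (including `N`)
matches nothing and consumes mismatch budget. This is the conservative
behavior of classical probe-matching services. Both the primer and its
reverse complement are scanned; hit positions are always reported as the
leftmost coordinate of the matched window on the reference strand, for both
strands. A consequence worth knowing: reverse-complementing both primer and
target mirrors hit positions but *preserves* strand labels under this
convention.

Coverage uses a strict zero-mismatch budget (a sequence is covered iff at
least one hit exists on either strand of its ungapped sequence); amplicon
extraction uses a tolerant anchor (default 2 mismatches) instead. These are
deliberately two different settings: coverage asks "would the primer bind
exactly?", extraction asks "where is the homologous site?", and a reference
library is typically trimmed at the site even for sequences an exact match
would miss.

# Short-read extraction

The read window spans `read_length` (default 280) *ungapped* bases,
0-based half-open throughout: for a forward primer it starts at the
primer's 5' start and runs 3'-ward; for a reverse primer it ends at the
site's 3'-most reference position and runs 5'-ward. The primer bases are
then removed, so an untruncated read retains `read_length − primer_length`
bases. Reads are reported in reference orientation as the alignment columns
covering the retained bases; the union of per-sequence column sets defines
one shared column space, gap-filled outside each read, so the SR library
remains a valid alignment for downstream tree building. Sequences whose
site cannot be anchored are excluded and logged by default; a
`majority-column` mode instead trims them at the modal start/end columns of
the anchored sequences. Neither behavior is claimed to be what any
particular historical pipeline did — the choice is surfaced as a flag.

# Distances and trees

Pairwise sequence distances are p-distances with pairwise deletion (columns
with a gap or ambiguity in either sequence are skipped), optionally
Jukes–Cantor corrected, `d = −(3/4)·ln(1 − 4p/3)`. Saturation (`p ≥ 0.75`)
raises an error by default and can be capped instead; the cap is used
inside bootstrap resampling, where a resampled replicate may transiently
saturate a pair without invalidating the replicate.

Tree inference is neighbor joining with two determinism guarantees: ties in
the Q criterion are broken on the lexicographically smallest label pair
(merged clusters inherit their smallest member label), and negative
branch-length estimates are clamped to zero with the deficit moved to the
sister edge. Bootstrap supports are fractions (in \[0, 1\]) of
column-resampled replicate trees containing each bipartition of the main
tree. Replicate "tree searches" — the within-library variability axis — are
emulated by building each replicate tree from its own column-resampled
alignment under a derived seed, standing in for the run-to-run variability
of heuristic maximum-likelihood searches; ML inference itself is out of
scope, and externally built trees can be imported as Newick.

On Newick import two support dialects are recognized: numeric internal-node
labels and bracketed branch comments; auto-detection prefers the bracket
form when present. If any support exceeds 1, the whole tree is rescaled by
1/100 — bootstrap percentages and fractions both occur in the wild, and the
weighted Robinson–Foulds arithmetic requires \[0, 1\].

# Comparing trees

**Branch lengths.** Patristic matrices are normalized to a maximum of one
(this cannot change the Pearson correlation, which is scale-invariant, but
puts the through-origin slope and the binned profiles on a common axis).
Every unordered pair of shared sequences contributes one (NFL, SR) tuple.
Reported statistics: Pearson *r*; the slope `b = Σxy/Σx²` of the
least-squares line forced through the origin; and a binned profile with
0.01-wide bins of the reference distance, per-bin mean and sample (n−1)
standard deviation of the SR distances. Single-member bins report `sd = NA`
rather than 0 — the estimator is undefined there. Bins beyond a reference
distance of 0.8 are still computed and emitted but flagged, because so few
pairs fall there that the sd is noise rather than resolving power.

**Superposition (wRMSD).** Both normalized matrices are embedded by
classical (Torgerson) MDS: double-center the squared distances, take the
top-`dims` eigenpairs, scale eigenvectors by the square roots of the
eigenvalues clamped at zero. Axes are sorted by eigenvalue and each axis's
sign is fixed so its largest-magnitude coordinate is positive, making the
embedding — and everything downstream — deterministic. The two point
configurations are then superimposed by weighted orthogonal Procrustes
(translation + rotation/reflection, *no scaling*) and scored as
`wRMSD = sqrt(Σwᵢ‖xᵢ−yᵢ‖²/Σwᵢ)`. Three open choices were closed as
follows: weights default to uniform (nothing in the method's description
forces any other weighting; alternatives can be passed explicitly);
`dims = 3` by default (the smallest dimensionality where superposition has
non-trivial structure; exposed, not hidden); and scaling is omitted because
both matrices are already max-normalized and a scale step would absorb
exactly the branch-length inflation the slope statistic is meant to
measure.

**Topology.** Bipartitions are canonicalized as the side containing the
lexicographically smallest leaf; trivial splits are excluded; in rooted
binary storage the two root children carry the same split and are merged
with preference for the support-labelled node. RF is the size of the
symmetric difference; WRF1 weights unique splits by support (missing
supports default to 1.0, recovering RF exactly); WRF2 adds |s₁ − s₂| over
shared splits, so WRF2 ≥ WRF1 always. Multifurcations are allowed and
simply contribute fewer splits, letting degenerate (star) trees flow
through. When replicate trees exist, pipeline tables report RF/WRF values
averaged over all tree pairs.

**Sliding-window placement.** For each window (default 280 columns) and
each taxon, the taxon is pruned, its window-restricted p-distances to the
remaining taxa computed, and it is re-attached to the edge minimizing the
least-squares disagreement between window distances and tree distances
(attachment point and pendant length are fitted per edge in closed form and
clamped to the feasible range). The statistic is the node distance between
the original and chosen attachment edges (BFS over the edge-adjacency
graph; 0 on the same edge). This is a distance-based surrogate for
likelihood re-insertion: it preserves the statistic's meaning — how far
short-window information displaces a taxon — at desk scale, and is exactly
zero when the window distances are additive on the tree (verified in the
tests with a perfect-character construction). Both the per-taxon matrix and
the per-window mean are emitted, since either summary is defensible.

# OTU clustering

"Average neighbor with a hard cutoff" is read as: agglomerative clustering
with average linkage (cross-pair mean, maintained by the Lance–Williams
update), stopped as soon as the minimum inter-cluster distance exceeds the
cutoff — i.e. the dendrogram cut at exactly the cutoff height, with no
re-thresholding of nearest-neighbor lists. Ties are broken on the
lexicographically smallest member labels, making cluster assignments
invariant to input order. Distances for OTUs default to uncorrected p with
pairwise deletion; mixing distance conventions silently between the
correlation plots and the clustering is a documented historical pitfall, so
the model is a single explicit switch.

# Taxonomic assignment

The classifier is the Wang-style naive Bayes that standard 16S assignment
tools wrap. With N reference sequences, word (8-mer) priors are
`Pᵢ = (n(wᵢ) + 0.5)/(N + 1)` with `n(wᵢ)` the number of sequences
containing the word; genus conditionals over the M sequences of genus G are
`P(wᵢ|G) = (m(wᵢ) + Pᵢ)/(M + 1)`. A query is scored by the sum of log
conditionals over its distinct words; per bootstrap round, ⌊W/8⌋ of its W
words are resampled with replacement and the winning genus recorded.
Confidence at a rank is the percentage of rounds agreeing with the full-set
winner's label at that rank; labels under the cutoff (default 80%) report
as "unclassified". Because agreement at genus implies agreement at every
higher rank, confidences are monotone non-increasing with depth and labels
always nest.

Scoring SR against NFL assignments: reads unclassified in *both* libraries
count as agreements in the inclusive correct-assignment tally (the
inclusive/exclusive row pair only makes structural sense if they enter it);
this convention is explicit and switchable. False positives are reads
classified in SR but not NFL; false negatives the reverse.

# The synthetic world

The generator emulates the architecture the evaluation exploits — not any
particular database. A random binary tree (yule-style random splits with
Gamma(shape 2) branch lengths, or a rescaled coalescent) is evolved under
Jukes–Cantor with per-column rate multipliers from a region map: ten
conserved blocks (relative rate 0.25) alternating with nine variable blocks
(relative rate 4.0) over 1542 columns at approximate E. coli V1–V9
coordinates. The five classical primer sites (338, 518, 799, 926, 1062) are
written verbatim into the root inside conserved blocks, with degenerate
positions resolved uniformly at random — real genomes carry concrete bases;
degeneracy is the matcher's problem, not the template's. Taxonomy is
assigned by cutting the tree at increasing depth thresholds, so every label
induces a connected subtree and ranks nest by construction.

Calibrated defaults, chosen once and frozen:

* **Mean branch length 0.00075** (substitutions/site at relative rate 1).
  The binding constraint is that planted primer sites must survive as exact
  IUPAC matches in ≥ 95% of leaves — the defining property of a universal
  primer site — which bounds the tree depth because one substitution on a
  basal edge destroys the site for a whole clade. At this depth variable
  regions still accumulate roughly ten-fold the conserved divergence.
* **Gamma(shape 2) rather than exponential branch lengths** for the yule
  model: an exponential puts substantial mass on internal edges carrying
  less than one expected substitution over the whole alignment, which no
  method could resolve and which made exact topology recovery (an invariant
  the package tests) fail for reasons unrelated to the code under test.
* **The genus-library generator** (for classifier tests) draws independent
  random ancestors per genus (pairwise p ≈ 0.75) and mutates members at
  0.005/site, keeping intra-genus p-distances comfortably below the stated
  0.03 bound (at 0.01/site the binomial tail crosses it).

What the generator does *not* emulate — and therefore what a green test
does not establish: indels and alignment uncertainty (the alignment is
trivially correct by construction); secondary-structure constraints and
among-site rate variation beyond the two-rate block structure; chimeras and
sequencing error; base-composition bias; and the real covariation between
region identity and taxonomic depth. One visible consequence: in this
two-rate world, whether short reads under- or over-estimate OTU richness
follows mechanically from the read window's average rate relative to the
whole gene, so the "reads underestimate richness" pattern is asserted for
conserved-flanked windows (e.g. 518r), whereas real surveys found it for
every primer — saturation and alignment effects the simulator omits
presumably account for the difference.

# Numerical conventions

Distance and support round-trips are asserted at 1e-9; correlation oracles
at 1e-12; self-comparison wRMSD at 1e-8 (eigen-decomposition noise). Ties
in NJ and clustering are lexicographic; MDS signs are pinned as described;
all randomness flows through a single seed via stable string-hashed child
seeds (kept below 2³¹), so a pipeline run is byte-reproducible. Degenerate
inputs degrade explicitly: an all-identical library yields a star tree with
no supports; zero-variance correlations report NA; single-member bins
report NA standard deviations; an all-zero distance matrix refuses
normalization.

# Known limitations

Neighbor joining is a stand-in for likelihood inference; absolute RF/WRF
magnitudes are not comparable to ML-based runs, only the contrasts between
libraries are meaningful. The sliding-window placement is distance-based,
not likelihood-based. Coverage treats every target ambiguity as a mismatch,
which under-counts coverage on low-quality reference sequences. The
pipeline's runtime scales as O(n³) in taxa through NJ and O(n²L) through
distance computation; it is a desk-scale instrument, not a database-scale
one.
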