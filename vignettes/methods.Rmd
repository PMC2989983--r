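---
title: "Predicting O-linked glycosylation sites with RBF networks and significant amino acid pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting O-linked glycosylation sites with RBF networks and significant amino acid pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycorbf)
```

## The prediction problem

O-linked glycosylation attaches a sugar to the hydroxyl oxygen of a
serine or threonine. Whether a given S/T is modified depends on the
surrounding sequence context and on where the residue sits in the
protein's membrane topology: glycosyltransferases act in the secretory
pathway, so sites inside membrane-spanning (TM) segments are not
enzymatically accessible. `glycorbf` treats site prediction as binary
classification of fixed-length sequence windows, with separate models
for serine and threonine on TM and non-TM proteins (four strata), plus a
hard topology veto for TM proteins.

## Window representation

A candidate site is the center of a window of length 2n + 1 over a
21-symbol alphabet: the 20 amino acids plus one terminal symbol that
pads windows running past either sequence end (and absorbs non-standard
residue codes B, Z, U, O, J, X on input, with a warning). Coordinates
are 1-based throughout; window positions are written relative to the
site, −n..+n with the site at 0.

Each position is encoded as 21 numbers. For an amino acid these are its
20-entry BLOSUM62 substitution row — min–max scaled to [0, 1] over the
whole 20 × 20 matrix, i.e. (s + 4)/15 since BLOSUM62 scores span
[−4, 11] — followed by a 0 in the terminal slot; the terminal symbol is
all zeros with a 1 in the terminal slot. Min–max scaling was chosen as
the simplest normalization that puts all features on the kernel's
[0, 1] scale; any affine rescaling would only change the effective
kernel bandwidth. The matrix itself is taken from Biostrings, the
standard R source for substitution matrices. Distinct windows always
receive distinct vectors because BLOSUM62 rows are distinct.

## The F-score and pair discovery

Feature relevance is measured by the feature-selection F-score (not the
F1 classification measure): for one feature with positive-class values
$x^{(+)}$ and negative-class values $x^{(-)}$,

$$F = \frac{(\bar x^{(+)} - \bar x)^2 + (\bar x^{(-)} - \bar x)^2}
          {s^2_{(+)} + s^2_{(-)}},$$

with $\bar x$ the grand mean and $s^2_{(\pm)}$ the unbiased
within-class variances. The statistic is symmetric in the class labels
and invariant under affine rescaling of the feature. Two conventions
cover degenerate inputs that real data never produce but synthetic data
can: when both within-class variances are zero the score is 0 if the
class means agree (a constant feature) and `Inf` otherwise (a perfectly
separating feature, which sorts ahead of every finite score during
ranking); each class must contribute at least two values, otherwise the
variances do not exist and an error is raised.

Pair discovery follows a three-step procedure:

1. **Anchor selection.** For every relative position p ≠ 0 and residue
   a, the F-score of the binary indicator "window has a at p" is
   computed; a position's score is the maximum over its residues. This
   indicator reading — rather than scoring the BLOSUM-encoded
   dimensions — was adopted because the discovered pairs are themselves
   residue indicators, so anchor and partner live on the same scale.
   The argmax position becomes the anchor; exact ties go to the smaller
   |position|, then to the negative (N-terminal) side, and are logged.
   The anchor residues are the `k_anchor` (default 3) most frequent
   residues at that position among positives.
2. **Pair enumeration.** For each anchor residue and each other
   position, every partner residue with positive-class frequency ≥
   `f_min` (default 0.10) yields a candidate pair scored by the F-score
   of its joint indicator. At each partner position the best two-residue
   merge is additionally kept when it strictly beats both singletons;
   this is what produces "or" partner sets such as (+3T, +9E or +9T).
   Partner sets are capped at two residues. The `k_anchor` and `f_min`
   defaults are pragmatic thresholds for "most frequent": small enough
   to keep enumeration cheap, large enough that implanted signal at
   realistic penetrance passes them.
3. **Forward selection.** Candidates are sorted by descending F-score
   and appended to the feature vector one at a time; after each
   addition, sequence-level cross-validated balanced accuracy is
   recorded, and the shortest prefix attaining the maximum is kept.
   Balanced accuracy is the criterion because site data are heavily
   class-imbalanced and plain accuracy would reward the all-negative
   model; ties toward the shorter prefix keep uninformative candidates
   out (the selection may legitimately be empty, leaving a
   BLOSUM62-only model).

## The RBF network

The classifier is a radial basis function network with Gaussian kernel
$\phi(x, \mu) = \exp(-\lVert x-\mu\rVert^2 / 2\sigma^2)$ — the
2σ² denominator convention is fixed in one place in the code — a fixed
bandwidth σ = 5, and **every** training instance as a center. Each of
the two output nodes (positive, negative) is a linear combination of
the k activations; the weight matrix solves the regularized normal
equations $(\Phi^\top\Phi + \lambda I)W = \Phi^\top Y$ with one-hot
targets. With λ = 0 (the default, honoring the all-centers design) the
system reduces to the square interpolation problem ΦW = Y and the
network reproduces its training labels exactly; the test suite checks
this against a dense linear-solve oracle up to k = 200. There is no
bias node and no output calibration. Fitting is fully deterministic.

Degenerate case: identical training vectors with conflicting labels
make Φ singular at λ = 0; the fit then falls back to λ = 1e−8 with a
warning, never silently. Increasing λ can only increase the training
residual (checked as a property test).

The decision rule — positive iff score_pos − score_neg > threshold,
default 0 — is deliberately exposed: raising the threshold trades
sensitivity for specificity. No class rebalancing is applied; the full
negative set is used.

## Homology reduction

To avoid counting near-duplicate sites twice, fragment sets are
redundancy-reduced before training: for protein pairs whose full
sequences exceed 30% identity in a Smith–Waterman local alignment
(BLOSUM62, gap open 11, gap extend 1 — BL2SEQ protein defaults;
identity = matches / alignment columns, gaps included), fragment pairs
with 100% identical windows collapse to one representative, the one
from the lexicographically smaller protein id. Positives and negatives
are reduced separately. Two caveats are worth knowing. First,
local-alignment identity without a coverage requirement is permissive:
unrelated proteins can reach 100% identity over a few aligned columns,
so the protein-level gate rarely blocks a collapse — the effective
guard is the requirement of a 100% identical window, and the
consequence of over-collapsing is only the loss of one of two exactly
duplicated windows. Second, "the glycosylated sites in the same
position" is read as window-string equality, since equal windows
centered on the sites pin the sites to the same relative position of
the alignment.

By default the reduction is applied inside each training fold, against
that fold's training proteins only, so no information about held-out
proteins leaks into training-set construction; a `global` mode (reduce
once up front) and `none` are also available. Global reduction slightly
shrinks the evaluation set; per-fold is the stricter reading of
"prevent overestimation" and is the default.

## Cross-validation and metrics

Cross-validation is performed at the sequence level: proteins, not
sites, are partitioned into five folds (sizes differing by at most one,
uniformly at random given the seed), and every site of a protein
follows its fold. Confusion counts are pooled (micro-averaged) across
folds before computing precision, sensitivity, specificity, accuracy,
balanced accuracy = (Sn + Sp)/2, and the Matthews correlation
coefficient; pooled counting is used because the per-fold positive
counts are small and integer pooled counts are what a study of this
design reports. MCC with a zero denominator is defined as 0. Report
formatting rounds percentages to one decimal and MCC to two.

The topology veto is a post-hoc filter on predictions: any positive
call whose position lies inside a TM segment is forced negative;
nothing else changes, and negative calls are never flipped positive.
Topology is consumed as an input table (UniProt-style 1-based inclusive
segments labeled L, N, E, C, TM, S, Unknown); the package does not
predict topology.

## The synthetic-data generator

Because the curated training corpus is not shipped, the generator
builds study-shaped data: `n_proteins` sequences (default 60, lengths
150–400) drawn i.i.d. from a background distribution (default uniform
with S and T enriched to 0.10 each so candidate sites are plentiful); a
`fraction_tm` of proteins (default 0.17, roughly the one-in-six TM
share of curated glycoprotein sets) receive 1–3 non-overlapping TM
segments of length 15–25 — a typical membrane-helix span — with the
remaining intervals labeled alternately E and C. Positive sites are
chosen among S/T positions outside TM segments and at least one full
window from the sequence ends, spaced at least 2 × 14 + 1 apart so
implanted flanks never collide; each configured pair is implanted
independently with its penetrance by overwriting the anchor and one
random partner-set member. The default implant is one pair at
penetrance 0.25 — a deliberately weak, realistic motif; validation
scenarios pass explicit configurations (penetrance 0.9–1.0 for
recovery, 0.95 for separability). Exact positive/negative counts can be
requested; everything is deterministic given the seed.

What the generator does *not* emulate: real amino-acid composition
(unless configured), position-dependent composition, correlated flanks,
homologous protein families (sequences are independent, so the
homology-reduction path is exercised mainly by constructed fixtures),
signal peptides, or any glycan chemistry. Passing tests on synthetic
data therefore demonstrate that the machinery recovers signal of a
known planted form at given strength — not that real glycosylation
motifs have that form or strength.

## Validation scenarios and problem sizes

The shipped validation uses three surfaces, sized to run in seconds to
a few minutes: exact recomputation of the derived statistics of a
published-style confusion table (2652 TM candidate sites, reproduced by
a deterministic fixture whose 145 in-TM false positives the veto must
remove exactly); oracle equivalence for the F-score (hand-evaluated
two-point example, 0.125), the alignment identity (an exhaustive
affine-gap dynamic-programming oracle) and the network solve (dense
oracle, k ≤ 200); and parameter recovery (anchor position recovered in
50 replicates of a 25-protein / 40-positive / 400-negative study at
penetrance 0.9; pooled five-fold balanced accuracy on a 100-protein
separable study at penetrance 0.95; near-zero MCC after label
permutation). Forward selection is validated on a constructed fixture
in which one pair separates perfectly and must be selected alone.

## Known limitations

- The homology gate's local-identity permissiveness, discussed above.
- All-centers interpolation scales cubically in training-set size; the
  intended regime is the few-thousand-site scale of curated site
  corpora. Larger corpora would need center subset selection, which is
  deliberately out of scope.
- σ = 5 is tuned to the [0, 1] feature scale and 609-dimensional
  windows; changing the window length or encoding changes the distance
  distribution and may warrant a different bandwidth.
- The topology veto only removes false positives inside TM segments; it
  cannot repair sensitivity, and it is only as good as the supplied
  topology annotation.
- Four independent strata models mean small strata (e.g. few TM serine
  sites) are trained on little data; the generator's exact-count options
  make this regime easy to probe.
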