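---
title: "Methods: HAR calling, feature-incorporated alignment, and template selection for CBMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HAR calling, feature-incorporated alignment, and template selection for CBMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harfia)
```

## The problem

Carbohydrate-binding modules (CBMs) are non-catalytic domains that anchor
polysaccharide-active enzymes onto their substrates. Fewer than 5% of known
CBMs have solved structures, and the pairwise identity between a CBM and its
nearest structural template is typically well below 30%, which is exactly the
regime where conventional homology modeling pipelines mis-align the residues
that matter most: the solvent-exposed aromatic residues (Trp, Tyr, Phe) that
stack against sugar rings, and the polar residues around them that hydrogen-
bond to the ligand.

`harfia` implements the sequence-analysis front end of an automated CBM
modeling procedure: it predicts which aromatic residues are likely
ligand-binding (**HAR calling**), aligns the target to each template with
extra weight on those positions and on confident secondary-structure elements
(**feature-incorporated alignment, FIA**), filters templates with
gap-penalized identity/similarity statistics (**template filter**), and
enumerates single- and double-template model candidates ranked by a pluggable
structure scorer (**model selection**). 3D coordinate generation and
statistical-potential evaluation are delegated to external engines through
the PIR export and the z-score injection table; they are not reimplemented
here.

## HAR calling

A *hydrophilic aromatic residue* (HAR) is an aromatic residue whose
sequence context looks like a binding site. The model is a windowed weighted
sum: for an aromatic at position $i$ with residues $r$,

$$\mathrm{score}(i) = w(r_{i-2}) + w(r_{i-1}) + w(r_{i+1}) + w(r_{i+2}),$$

where $w(\cdot)$ is an integer weight per amino acid derived from the
occurrence counts of residues flanking known ligand-binding aromatics in
curated CBM structure templates (`default_weight_table()`; glycine is the
heaviest at 49, arginine and tryptophan the lightest at 3). The residue is
called an HAR when $\mathrm{score}(i) \ge 97$, the calibrated default
cutoff. Two standard worked motifs: GSWNP scores $49+34+43+8 = 134$ (an
HAR), PTYKA scores $8+34+20+30 = 92$ (not an HAR).

Choices the model itself does not pin down:

* **Aromatic set** = {W, Y, F}. Histidine only ever appears as a flank in
  the weight table and never as an annotated binder, so it is excluded.
* **Terminal aromatics**: flank positions outside the sequence contribute 0.
  This is conservative and keeps scores comparable across positions; a
  terminal aromatic can still be called if its two inner flanks are heavy
  enough.
* **Unknown residues** (`X`) contribute 0 as flanks.
* A **strict mode** (off by default) additionally requires at least one
  polar/small flank on each side, echoing the older flanked-on-both-sides
  definition of an HAR.

As a standalone binding-residue predictor, HAR calling is evaluated with
`evaluate_binding_prediction()`: known binding aromatics are the positive
set, all remaining aromatics the negative set, and the score is swept to
produce a ROC curve (`roc_curve()`, trapezoid AUC). Note the negative set
necessarily contains not-yet-characterized true binders, so the measured
false positive rate is an overestimate and the true positive rate an
underestimate.

## Feature-incorporated alignment

`align_pair()` is a global Needleman–Wunsch/Gotoh alignment with affine gap
penalties over BLOSUM62, with two position-level bonuses:

* `har_bonus` (default +5) when both aligned residues are HAR-flagged;
* `ss_bonus` (default +2) when both residues share a confident helix or
  strand state. Loop–loop columns earn nothing: loops are low-information,
  and the secondary-structure input relabels any helix/strand prediction
  with confidence below 0.5 to loop for the same reason.

The bonus magnitudes are this package's defaults, chosen so that a conserved
HAR pair outweighs a typical single-residue substitution difference
(BLOSUM62 entries for aromatics span 1–11) without overriding a run of
mismatches; both are exposed as parameters and setting them to zero recovers
the plain BLOSUM62 aligner exactly, which is how the dynamic program is
validated against exhaustive enumeration in the test suite.

Numerical conventions:

* Gap run of length $L$ costs $\mathrm{open} + (L-1)\,\mathrm{extend}$,
  defaults 11/1 (the standard BLOSUM62 pairing).
* Alignment is fully global by default (whole CBM domains); a
  `free_end_gaps` flag supports domain-in-protein use.
* Traceback ties break diagonal first, then a gap in the template row, then
  a gap in the target row, so output is deterministic.
* "Similar" aligned pairs are those with a positive BLOSUM62 entry (or
  identical residues), the usual "positives" convention.

## Template filter

For each alignment the filter computes an identity level and a similarity
level,

$$\mathrm{il} = 100\,\frac{\mathrm{ident} - \gamma\,\mathrm{gap}}{N},\qquad
  \mathrm{sl} = 100\,\frac{\mathrm{sim} - \gamma\,\mathrm{gap}}{N},$$

where `gap` counts maximal gap runs in both rows, $\gamma$ (default 1) is
the opening charge, and $N$ is the column count (a minimum-sequence-length
denominator is available as an option). The candidate alignment set is the
union of the top-$k$ by identity level and the top-$k$ by similarity level,
so it always holds between $k$ and $2k$ alignments; $k$ defaults to 5, the
same unit used for top-candidate evaluation downstream. Ranking ties break
by raw alignment score, then template id.

## Model selection

From $n$ filtered alignments, `enumerate_candidates()` builds $n$
single-template candidates plus $\binom{n}{2}$ unordered double-template
candidates ($n + n(n-1)/2$ total; triples are excluded as their modeling
cost grows too quickly for batch runs). Each candidate is scored by a
`scorer(target, candidate)` contract — deterministic, finite, lower is
better — and the minimum-score candidate is selected, ties favoring fewer
templates. Real structure-quality z scores from an external modeling and
evaluation engine can be injected per candidate id; for offline runs
`mock_surface_scorer()` provides a deterministic stand-in that rewards
identity and HAR-on-binding-site coverage:
$1 - 2\,\frac{\mathrm{ident}}{N} - \tfrac12\,\mathrm{cov}$, averaged over
the candidate's alignments. Double-template candidates are exported as
3-entry PIR files after re-projecting both alignments onto the shared
target columns.

## The synthetic benchmark

`generate_benchmark()` emulates the study conditions a curated corpus would
provide, without any downloads:

* **Templates** (default length 100) are random sequences — uniform residue
  background by default, BLOSUM62 background optional — with 2 planted
  5-residue binding motifs per template: an aromatic center flanked by
  residues drawn from {G, N, S, T, D}, so every planted center scores at
  least $4 \times 33 = 132 \ge 97$. Secondary-structure tracks are runs of
  3–8 residues, strand-rich (E 40%, L 45%, H 15%) as in the β-sandwich and
  β-trefoil folds that dominate CBMs.
* **Targets** are mutated template copies: per-position substitutions at the
  requested divergence, geometric indels (p = 0.5, capped at 5), motif
  windows preserved. Divergence 0.5–0.7 lands targets in the sub-30%
  identity regime that makes CBM modeling hard. Tracks are perturbed by
  flipping 10% of states, roughly a 70%-accurate 3-state predictor.
* Everything derives deterministically from one seed, and a truth table maps
  each target to its source template.

What the generator does *not* emulate: real CBM family phylogeny, indel
clustering at loops, compositional bias of real binding clefts, and
correlated errors of real secondary-structure predictors. Passing the
recovery tests therefore demonstrates that the machinery is correct and that
the filter tolerates heavy, unstructured divergence — not a field accuracy
claim for real CBM corpora, which additionally require the curated template
profiles and external modeling engines.

## Validation problem sizes

The test suite validates (sizes are the package's own choices):

* the dynamic program against brute-force enumeration of every global
  affine-gap alignment, 500 random pairs of length ≤ 6 with bonuses off;
* the batch arithmetic on a full-scale synthetic corpus: 817 targets × 93
  templates (length 50) gives exactly 75,981 pairwise alignments;
* the $k \le |CA| \le 2k$ bound on 100 random pools;
* chance-level AUC (0.5 ± 0.05) on 1000 permutation-labeled sites;
* planted-motif recovery: on a 25-template × 2-target benchmark at
  substitution rate 0.7 (seed 11017), 100% of planted HARs are recalled and
  the true source template reaches the candidate set for at least 80% of
  targets at $k = 5$ (the pilot run recovered 50/50).

## Limitations

* Structure building and surface-potential evaluation are contracts, not
  implementations; conclusions about model quality require the external
  engines.
* The bonus weights of the FIA and the exact functional form of the level
  statistics are package-level realizations of the published prose
  description; both are parameterized so alternatives can be swept.
* The HAR weight table is consumed as given; re-deriving it from structure
  data is out of scope.
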