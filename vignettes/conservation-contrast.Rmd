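---
title: "Family-specific conservation contrast and structural tethering: methods"
author: "seqcontrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-specific conservation contrast and structural tethering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcontrast)
```

## The problem

Protein families inside a large superfamily — the ErbB kinases inside the
receptor tyrosine kinases are the motivating case — often owe their
functional divergence to a small set of residues that are nearly invariant
within the family yet strikingly different outside it. `seqcontrast`
identifies such positions from a gapped multiple sequence alignment split
into a *foreground* (the family) and a *background* (the rest of the
superfamily), renders the result as a contrast hierarchical alignment,
maps the positions onto interaction networks in crystal-structure
ensembles, and overlays recurrent somatic mutations.

## The column statistic

Let $w_i$ be per-sequence weights, and for a column let $n$ be the
weighted number of non-gap foreground sequences, $k$ the weighted number
carrying a candidate residue set $S$, and $q$ the weighted background
frequency of $S$ (conditional on non-gap). The divergence score is the
ball-in-urn tail probability
$$
\mathrm{score}(S) \;=\; -\log_{10} P\!\left(X \ge \lfloor k + \tfrac12 \rfloor\right),
\qquad X \sim \mathrm{Binomial}\!\left(\lfloor n + \tfrac12 \rfloor,\; \max(q, q_0)\right),
$$
the chance of drawing at least the observed number of pattern residues
from an urn with the background composition. The tail is evaluated in log
space (`pbinom(..., log.p = TRUE)`), so scores of several hundred are
exact rather than underflowing to infinity; an independent log-space
summation oracle in the test suite confirms agreement to $10^{-9}$
relative error wherever a double-precision summation can resolve the
value at all.

Numerical choices, all recorded in the output metadata:

* **Weighted counts are rounded half-up** to feed the exact binomial
  tail. A continuous alternative via the regularised incomplete beta
  function $I_q(k, n-k+1)$ is available with
  `contrast_config(tail = "beta")`; the two agree at integer counts.
* **Background floor** $q_0 = 1/(2\,N_b^{\mathrm{eff}})$, where
  $N_b^{\mathrm{eff}}$ is the effective (weighted) background count: a
  residue never observed in the background gets a finite, sample-size
  aware urn probability instead of an infinite score.
* **Candidate sets**: every subset of the residues observed in the
  foreground up to `max_set_size` (default 3) is scored exhaustively;
  ties break toward the smaller set, then alphabetically, so results are
  deterministic.
* **Selection**: a column is a pattern position when its best set scores
  at least `score_threshold` (default 10, i.e. $P < 10^{-10}$) and the
  foreground set frequency reaches `min_fore_conservation` (default
  0.6). The rendered histogram height is the score divided by the
  maximum selected score.

Sequence weighting is Henikoff position-based weighting over non-gap
letters, normalised so the maximum weight is 1; the weighting scheme is a
package choice and is stated in every output sidecar. `uniform` is
available as a fallback. Gaps and `X` are counted as missing: profile
frequencies are conditional on non-gap, because the urn statistic
compares residue composition, not indel structure.

Alignment columns are 1-based throughout the R interfaces (the natural R
convention); all *reported* positions go through a reference map, which
adds a signal-peptide offset (default 24) to the reference sequence's
mature residue index — the pre-mature numbering convention used in the
EGFR literature.

## Joint inference of the partition

When the partition is not given, `sample_partition()` alternates (i)
pattern selection given the membership with (ii) Gibbs reassignment of
each sequence, with probability proportional to the product over selected
pattern columns of per-class match likelihoods with additive pseudocount
$\alpha = 0.5$. Two design points matter and were genuinely open:

* **Initialisation.** A random membership gives the pattern-column
  Gibbs step no gradient: with no true contrast, no columns pass the
  threshold and reassignment is uniform. The family signal lives in the
  *co-occurrence* of pattern residues across columns, so the first
  restart is initialised by a spectral split — the sign of the first
  principal component of the centred one-hot residue matrix. On the
  benchmark generator this alone recovers ~95% of memberships; the Gibbs
  sweeps then sharpen it to ~100%. Additional restarts use random
  initialisation.
* **Which state to return.** The sum of selected-column scores grows
  when background sequences that happen to match the pattern are folded
  into the foreground (each match adds roughly $\log_{10}(1/q)$), so
  "best score visited" systematically returns an impurer foreground than
  the converged chain. The sampler therefore returns the converged end
  state of the restart with the highest final joint score; the full sweep
  trace, including any higher-scoring intermediate states, is kept in
  `$trace`.

The contrast is orientation-sensitive (the conserved pattern must be the
foreground), so each restart's first sweep evaluates both labelings and
keeps the better one; agreement with a reference partition should always
be measured label-swap aware (`partition_agreement()`).

**Identifiability caveat.** On a *diverse* single-profile alignment the
sampler can lock onto the carriers of a polymorphic residue: that is a
real, self-consistent pattern-partition of the data (carriers genuinely
share the residue), even though the generative process had no classes.
The `degenerate` flag therefore means "no column ever reached the
selection threshold", not "the generative truth had no classes"; for
near-fixed profiles the two coincide.

## Rendering

`render_cha()` emits equal-width monospaced rows: a five-glyph histogram
ramp (` .:|#`, blank for height 0, then quarters of the height range), a
dot row marking selected columns, the query display sequences, and the
foreground and background consensus rows with weighted residue
frequencies in integer tenths. Digit $d$ covers the band
$[d/10, (d+1)/10)$; the top band is closed, so a frequency of exactly 1.0
renders as `9` — a single-character constraint worth knowing when reading
the output. Effective (weighted) and total sequence counts are printed in
parentheses beside the consensus labels.

## Structural tethering analysis

Structures are read from PDB files (first model, highest-occupancy
altloc, waters/heteroatoms/hydrogens removed). Three detectors operate on
heavy-atom geometry:

* **Hydrogen bonds**: polar (N/O/S) donor-acceptor pairs within 3.5 Å,
  with donor/acceptor roles taken from the chemistry of the standard
  residues (a backbone carbonyl oxygen never donates; a non-proline
  backbone nitrogen donates; atoms of unknown residues are treated
  permissively as both). For backbone amide donors the hydrogen is
  reconstructed in the peptide plane and the N–H···acceptor angle must
  reach 120°; this is what separates the genuine $i \rightarrow i{+}4$
  helical ladder from the $i{+}3$ near-contacts (at ideal helix geometry:
  165° vs 109.5°), which a bare heavy-atom angle criterion cannot do. All
  other donors and all acceptors use an antecedent-vertex-partner angle
  of at least 90° when a unique covalent antecedent exists. Pairs closer
  than two residues in sequence count only when both atoms are
  side-chain atoms.
* **van der Waals contacts**: heavy-atom pairs from distinct residues
  within the sum of element radii (C 1.70, N 1.55, O 1.52, S/P 1.80,
  default 1.70) plus 0.5 Å, at least 2.0 Å apart (excluding covalent
  neighbours), excluding pairs already counted as hydrogen bonds.
* **CH–π**: carbon atoms within 4.5 Å of an aromatic ring centroid
  (Phe/Tyr/His rings and both Trp rings) at an elevation of at least 30°
  from the ring plane — a common literature convention; the thresholds
  are package choices.

All detectors are exactly invariant under rigid motions (verified by
property tests), and interactions are stored with canonically ordered
partners. `ensemble_frequency()` tabulates, per (kind, residue pair), the
fraction of structures showing the interaction; the denominator counts
only structures in which *both* residues are present, so
crystallographically disordered residues reduce the denominator rather
than the frequency, and every missing position is listed in a coverage
report. Frequencies are additionally stratified by user-assigned
active/inactive state labels. Because the geometric thresholds here are
self-chosen, ensemble frequencies on real structures will not numerically
reproduce tables computed with other software's (unpublished) cutoffs;
the bookkeeping, not the thresholds, is the tested contract.

`classify_tethers()` is a deterministic join of selected positions
against a user-supplied region table with the three tether classes of the
ErbB model — N-lobe tether (NLT), active-site tether (AST) and C-lobe
tether (CLT) — plus `none` for unannotated positions. A curated example
annotation for EGFR (pre-mature numbering) ships in `inst/extdata/`.

## Mutation overlay

`read_mutations()` accepts an explicit five-column table or compact
strings (`"L861Q(26)"`); identical changes reported more than once (as
published recurrence tables sometimes do) are summed, which is a stated
package choice, not a reconstruction of the source's bookkeeping.
`overlay_mutations()` joins each mutation to the pattern positions and
annotation and adds a one-sided Fisher exact test on the 2×2 table
(position mutated × position in pattern) over all integer positions of a
stated reference range. The enrichment statistic is an extension beyond a
plain overlap report and is labelled as such in the output. The test
matches exact hypergeometric enumeration to ~$10^{-14}$ absolute over all
tables with margins up to 100 (property-tested).

## Synthetic data: what it emulates, what it does not

`generate_msa()` draws a background residue profile per column from a
symmetric Dirichlet (concentration 0.5 — realistically uneven columns),
plants `n_pattern` foreground-specific columns, inserts gaps i.i.d., and
can append exact duplicate clones to exercise weighting. The defaults
(50 foreground / 200 background sequences, 100 columns, 10 pattern
columns, foreground conservation 0.9 against background frequency 0.05,
gap rate 0.02) are the benchmark study conditions used by the tests and
the acceptance script; they emulate the *shape* of a kinase-superfamily
contrast at roughly 1/10 scale in sequence count. Sequences are i.i.d.
given the profiles: there is no phylogeny, no indel model, no site-rate
heterogeneity. Passing the recovery benchmarks therefore demonstrates the
statistics under profile-level redundancy and noise, not robustness to
deep tree correlation — for real data, the position-based weighting is
the (standard, partial) remedy.

`generate_helix()` builds an ideal poly-alanine backbone by internal
coordinates (φ = −57°, ψ = −47°, standard bond geometry), whose
$i \rightarrow i{+}4$ O···N ladder is the planted hydrogen-bond truth.
`generate_mutation_fixture()` plants an exact 2×2 overlap between a
mutation table and a designated pattern set. All generators are
seed-deterministic and emit standard formats readable by the package's
own readers.

## Problem sizes and runtime

The test suite and acceptance script run the full benchmark: 20 generator
seeds for pattern recovery, 10 seeds for sampler recovery and jackknife
stability, the 1707-point ball-in-urn grid, 8 rigid-motion trials and a
121-table Fisher sweep — a few minutes on one CPU. These sizes were
chosen so that every stochastic claim is averaged over enough replicates
to be stable while keeping a full run interactive.

## Known limitations

* Two classes only; no hierarchical multi-level partitioning and no
  Dirichlet-process prior over partitions.
* The joint score is a sum of per-column tail exponents, not a proper
  marginal likelihood; it is used for ranking states and flagging
  degeneracy, not as a posterior probability.
* Heavy-atom hydrogen-bond criteria cannot adjudicate donor/acceptor
  roles for His tautomers or Ser/Thr/Tyr hydroxyl rotamers; both roles
  are allowed where the chemistry permits.
* Inter-chain interactions are computed only between chains present in
  the file; crystallographic symmetry mates are not generated.
* The alignment is consumed as given: building it (database search,
  profile alignment) is out of scope.
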