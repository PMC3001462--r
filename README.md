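# seqcontrast

Identify the residues that make a protein family different from the rest
of its superfamily — and what those residues do in the structure.

Given a gapped multiple sequence alignment partitioned into a
**foreground** family (e.g. the ErbB/EGFR kinases) and a **background**
superfamily (the other receptor tyrosine kinases), `seqcontrast` scores
every alignment column with a *ball-in-urn* divergence statistic on
Henikoff-weighted residue counts: with `n` weighted non-gap foreground
sequences, `k` of them carrying a candidate residue set `S`, and `q` the
weighted background frequency of `S`,

    score(S) = -log10 P(X >= round(k)),   X ~ Binomial(round(n), max(q, q0)),

i.e. the tail probability of drawing that many pattern residues from an
urn with the background composition (`q0` is a floor of one over twice
the effective background count). The best-scoring residue set per column
is found by exhaustive enumeration up to size 3; columns with score ≥ 10
and foreground conservation ≥ 0.6 are the family's **pattern positions**.

Around that core statistic the package provides:

* **Alignment plumbing** — aligned FASTA / Stockholm I/O, Henikoff
  position-based sequence weighting, weighted column profiles, and
  mapping of alignment columns to reference residue numbers including a
  signal-peptide offset (pre-mature numbering, e.g. EGFR +24).
* **Joint partition inference** — a Gibbs-style sampler
  (`sample_partition()`) that alternates pattern selection with
  membership reassignment, seeded by a spectral split of the residue
  co-occurrence structure, plus jackknife stability checks
  (`jackknife_stability()`) that emulate removing an atypical subfamily.
* **Contrast hierarchical alignment rendering** — monospaced text output
  with a score histogram, pattern dots, query sequences, and
  foreground/background consensus rows with weighted residue frequencies
  in integer tenths (`render_cha()`).
* **Structural tethering analysis** — PDB reading, geometric detection
  of hydrogen bonds (with reconstructed amide hydrogens), van der Waals
  contacts and CH-pi interactions, interaction frequencies across a
  crystal-structure ensemble with active/inactive stratification and
  disorder-aware denominators (`ensemble_frequency()`), and tether-class
  labelling (N-lobe / active-site / C-lobe tether).
* **Mutation overlay** — parsing of recurrent somatic-mutation tables
  (compact `"L861Q(26)"` strings supported), overlap with pattern
  positions, and a one-sided Fisher exact positional enrichment test.
* **Synthetic data with planted truth** — alignments with planted
  pattern columns, ideal helices with a known hydrogen-bond ladder, and
  mutation tables with a designed 2×2 overlap, so the whole pipeline is
  testable offline (`generate_msa()`, `generate_helix()`,
  `generate_mutation_fixture()`).

## Worked example

The numbered scripts under `analysis/` run the full pipeline on the
benchmark synthetic family (50 foreground / 200 background sequences,
100 columns, 10 planted pattern columns at 0.9 foreground conservation
vs 0.05 background frequency) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_alignment.R
Rscript analysis/02_contrast_analysis.R
Rscript analysis/03_render_cha.R
Rscript analysis/04_tether_ensemble.R
Rscript analysis/05_mutation_overlay.R
```

`02_contrast_analysis.R` prints:

```
Selected 10 pattern columns; sensitivity 1.00, false positives 0
Contrast analysis: 100 columns, 10 pattern positions (score >= 10.0, fore conservation >= 0.60)
  top positions: col 59 (37.9), col 68 (35.1), col 39 (33.5), col 1 (33.0), ...
Jackknife stability: removed 13 sequences, Jaccard overlap of selected columns 1.000 (10 -> 10 selected)
Sampler re-derives the partition at 100.0% agreement (label-swap aware)
```

All ten planted columns are recovered with no false positives; removing
a quarter of the foreground leaves the selected set unchanged (Jaccard
1.0); and the sampler re-derives the foreground/background split from
the alignment alone. `03_render_cha.R` shows the rendered contrast
alignment — histogram ramp and dots over the pattern columns, consensus
rows beneath, where e.g. a `9` under a consensus letter means that
residue occurs in ≥ 90% of the weighted foreground:

```
histogram                  |       #       #        #
pattern                    *       *       *        *
fore_001                 YKNTWYQIMFKVASLDCTRGTPEPDQYFCC
...
conserved (28.1, 50)     ETHVRCPMMSKFLHTNHKRMTELQDRWFLH
wt_res_freqs             228121121293223221922231212832
background (126.5, 200)  ETATRCPMELEFKHTNHKAMTYLIDRWKNH
bg_res_freqs             222122122223221221133232322233
```

`05_mutation_overlay.R` overlays the recurrent EGFR kinase-domain
mutations shipped in `inst/extdata/` (COSMIC-derived recurrence counts,
pre-mature numbering) onto the canonical ErbB-specific positions with
their region/tether annotation:

```
Mutation overlay: 37 mutations, 36 at pattern positions; positional enrichment p = 2.81e-17
```

with a per-mutation table (position, recurrence, region, tether class)
written to `results/egfr_mutation_overlay.tsv` — e.g. S768 (C-helix,
N-lobe tether) and L861 (activation loop, C-lobe tether) carry the
highest recurrence counts.

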