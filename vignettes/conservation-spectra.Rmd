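---
title: "Conservation spectra from protein alignments: the PKV and its conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation spectra from protein alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkvtools)
```

## The model

Given a protein MSA of an orthologue set — $N_{sp}$ sequences, columns
indexed by $i$ — the package summarizes each column twice.

**Entropy.** With emergence probabilities $P$ over the residues present
at the column, the raw sum $S_i = \sum P \ln P \le 0$ is reported
together with the Shannon form $H_i = -S_i$ and a display form $-1/S_i$
(a fully conserved column has $S_i = 0$ and maps to the $+\infty$
sentinel). The display form produces deliberately spiky spectra in which
perfectly conserved sites stand out; $H$ is always reported alongside so
either convention can be plotted.

**PKV.** Distinct residues at the column are ranked by abundance; the
rank-$d$ residue (most abundant has $d = 0$) occurs $N_i(d)$ times, and
the diversity $D$ (number of distinct residues, at most 20) bounds
$d \le D - 1$. The statistic is built from the existence-augmented
second moment of this rank spectrum:

$$\varphi_i = 1 + \sum_d d^2\,N_i(d), \qquad
  E[d^2] = \varphi_i / N_{sp}, \qquad
  \Phi_i = \varphi_i / N_{sp}^2, \qquad
  \kappa_i = -\ln \Phi_i .$$

The leading 1 in $\varphi$ scores the existence of the site itself, so
$\varphi = 1$ exactly when the column is fully conserved and
$\kappa$ then attains its global maximum $2 \ln N_{sp}$. Spreading
sequences into minority residues inflates $\varphi$ quadratically in
rank, and $\kappa$ can become negative at maximally diverse columns
(e.g. 8 all-distinct residues give $\varphi = 141$,
$\kappa = -\ln(141/64) \approx -0.79$ for $N_{sp} = 8$). By analogy
with a moment of inertia $I = r^2 M_r$, $\Phi$ weighs residue "mass"
(abundance) by squared rank distance from the most constrained state;
the name *phylogenetic kinetic value* follows that analogy. The
algebraic identity $\kappa_i + \ln\varphi_i = 2\ln N_{sp}$ holds per
column and is asserted in the test suite to $10^{-9}$.

Two interpretive caveats are part of the model, not bugs. First, the
rank-ordered reading of $N_i(d)$ is a design decision: $d$ is the
0-based abundance rank of each distinct residue, which is the only
reading that makes $\sum d^2 N_i(d)$ well defined per column, reduces
to $d = D - 1$ as the maximal difference, and respects
$0 \le d \le 19$. Second, the statistic is *phylogeny-blind*: it sees
the residue frequency vector of a column and nothing about the tree
that generated it. Shared ancestry among close orthologues therefore
inflates apparent conservation equally for $H$ and $\kappa$.

## Conventions and tunable parameters

* **$N_{sp}$ at gapped columns** (`nsp`, default `"global"`): the
  definition normalizes by the total sequence count everywhere, which
  is the default; under it a column where many sequences are gapped but
  the rest agree still scores near the maximum, conflating absence with
  conservation. `nsp = "local"` divides by the column's non-gap count
  instead. Both are exposed so the sensitivity of any called region to
  this ambiguity can be checked directly.
* **Probability denominator** (`p_denominator`, default
  `"effective"`): entropy probabilities are counts over the non-gap
  count, a proper distribution. `"global"` divides by $N_{sp}$, in
  which case probabilities at gapped columns sum below one.
* **Gap handling**: `-` (and `.`, normalized at parse time) is never a
  residue category — the diversity bound of 20 implies gaps are not
  counted. All-gap columns yield flagged `NA` records rather than
  errors, so alignments with ragged termini parse cleanly; they are
  excluded from selectors and argmax computations.
* **Tie-breaking**: ranking is by count descending, then residue
  alphabetically. The tie-break is arbitrary but deterministic — it
  never changes $\varphi$ (which depends on counts only through their
  sorted order) but fixes the reported residue order and makes runs
  reproducible.
* **Nonstandard letters** (B, J, O, U, X, Z): counted as their own
  categories with a warning; `strict = TRUE` rejects them. Silently
  dropping them would distort the $N_{sp}$ accounting.
* **Region calling** (`call_conserved_regions`): either the columns
  attaining the `top_k` largest $\kappa$ or those at/above a $\kappa$
  `quantile`; ties are always included, so `top_k = 1` can return a
  multi-column region. Selected columns merge into maximal runs that
  are consecutive both in reference numbering and in alignment columns
  — an intervening reference-gap column splits a region even though the
  flanking reference positions are numerically adjacent. `min_run`
  (default 1 residue) drops short runs.
* **Coordinates**: 1-based inclusive throughout, matching residue
  nomenclature such as L91; only the BED export converts to 0-based
  half-open.
* **Hydropathy** (`hydropathy`): Kyte–Doolittle scale, unweighted mean
  over an odd window, default 9 residues — the common default of
  protein-scale web tools; the exact window behind published profiles
  of this kind is rarely stated, so it is a flag. Only full windows are
  scored; no boundary values are invented.
* **Molecular weight**: average (not monoisotopic) residue masses plus
  one water, in kDa — the convention matching SDS-PAGE-style figures
  such as a 19 kDa cytosolic protein.

## The synthetic generator

`synthetic_msa_spec()`/`generate_msa()` emulate an orthologue set with
independent columns: each background column draws a residue-frequency
vector from a symmetric Dirichlet over the 20-letter alphabet
(concentration $\alpha$ is the single knob — small $\alpha$ gives
near-conserved columns, large $\alpha$ near-uniform diversity), each
sequence then samples i.i.d. from it, and gaps are injected per cell at
`gap_rate`. Planted blocks are fully conserved single-residue intervals
and never receive gaps, so ground truth stays crisp and planted columns
attain $\kappa = 2\ln N_{sp}$ by construction. Identical specs generate
identical alignments (the seed is part of the spec, and generation does
not disturb the caller's RNG stream).

What this does *not* emulate: phylogenetic correlation between rows,
insertion/deletion structure, partially conserved motifs,
composition bias, and alignment error. Passing the recovery benchmarks
therefore shows that the statistics and the region caller do what their
definitions promise on frequency-model data — not that PKV separates
signal from noise on real, tree-correlated orthologue sets.

`synthetic_omp_standin()` packages one fixed configuration: 30
sequences × 163 gap-free columns — the size class of a small cytosolic
protein such as olfactory marker protein with a few dozen vertebrate
orthologues — with a fully conserved leucine block planted at residues
91–100 (the Ω-loop-like, NES-like span) against a flat-Dirichlet
background. It is a labelled synthetic stand-in for a real downloaded
orthologue alignment: it exercises the full
read → spectrum → map → call-regions workflow and the expectation that
the κ peak falls in the 90–100 span, and nothing about real OMP should
be concluded from it. With the flat background the planted block is the
unique $\kappa$ maximum almost surely (a background column would have
to be monomorphic across all 30 sequences to tie).

## Numerical choices and degenerate inputs

Equality assertions use $10^{-9}$ absolute tolerance; the quantities are
short sums of logs of small integers, so no looser tolerance is needed.
$\varphi$ is integer-valued by construction. The entropy display form
maps $S = 0$ to `Inf` rather than a large constant, so downstream code
must treat conserved columns explicitly. Degenerate inputs are
contracts, not crashes: empty FASTA, ragged alignments, invalid symbols,
out-of-range columns, unknown references, unsorted score tracks,
duplicate or mismatched mutation edits, even windows, and unscored
residues all raise typed messages; all-gap columns and empty region
selections return flagged/empty values.

The quantile selector uses R's default (type 7) sample quantile; with
ties included at the threshold, a quantile matched to a planted fraction
$w/L$ selects exactly the planted columns whenever they strictly
dominate the background.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run 500 random alignments
($N_{sp} \le 12$, length $\le 30$, gap rate $\le 0.2$, with a 5-letter
alphabet on alternate draws to stress tie-breaking) against a literal
brute-force re-evaluation of the definitions, 300 random column
perturbations for the monotonicity properties (merging a minority
residue into the majority never decreases $\kappa$; introducing a new
distinct residue strictly decreases it), and 20 seeded recovery
simulations at $N_{sp} = 10$, length 200, one planted block of width
11, near-uniform background ($\alpha = 50$), scored with the
matched-quantile selector. These sizes give the properties thousands of
column-level cases while keeping a full run in the tens of seconds.

## Limitations

Beyond the generator caveats above: the statistics assume a trustworthy
input alignment (alignment error masquerades as diversity); $\kappa$
under the global-$N_{sp}$ default rewards columns that are mostly gap;
the LIST-S2-style taxonomy-weighted score is supported only as an
imported track, not reimplemented; and the bundled stand-in cannot
substitute for analysis of a real orthologue download, for which
`read_msa()` + `cmd_scan()` on the downloaded FASTA is the intended
path.
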