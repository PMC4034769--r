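---
title: "Inter-protein coevolution: model, scores, and restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-protein coevolution: model, scores, and restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevcomplex)
```

## The problem

Residues that make contact across a protein-protein interface tend to
covary during evolution: a substitution on one side is compensated by a
substitution on the other. Given a deep alignment of *paired* sequences —
each row the concatenation of the protein-A and protein-B sequences from
one genome — a global statistical model can separate such direct couplings
from the indirect correlations that confound local covariance measures.
`coevcomplex` implements the full chain from paired-alignment construction
to calibrated contact scores and distance restraints for complex modeling,
together with structure-based evaluation utilities and synthetic
generators that make the whole pipeline testable.

## Pairing sequences by operon structure

The hard step for inter-protein analysis is deciding *which* A sequence
pairs with *which* B sequence in a genome with paralogs. In prokaryotes,
interacting proteins are frequently co-located in operons, so the package
pairs genes by their intergenic distance: `delta_gene()` counts the
annotated genes between two gene records (proxied by the difference of
serial accession indices, minus one). For two families,
`build_paired_alignment()`:

1. takes, per genome, the candidate (A, B) pair with the smallest
   distance;
2. applies `conserved_pair_test()`: the modal distance must be below 20
   and, together with the second or third most common distance when it
   lies within 1 of the mode (annotation ambiguity), must cover at least
   60% of the genomes;
3. concatenates rows only for genomes whose distance is in the accepted
   set, then removes columns with more than 75% gaps and filters rows to
   at most 90% pairwise identity.

Design choices the data do not dictate: modal ties break toward the
smaller distance (tighter linkage); one row per genome (the minimum-
distance pair); the conservation denominator is the set of genomes
containing both families, the only computable reading when records exist
for just those genomes. Column filtering runs before row filtering so
identities are measured on the retained positions.

## The global model

The sequence model is a 21-state Potts model (20 amino acids plus gap —
gaps carry phylogenetic and structural signal, so they are a state, not
missing data): position-specific fields $v_i$ and pairwise couplings
$w_{ij}$ define

$$p(x_1,\dots,x_{p+q}) \propto
  \exp\Big(\sum_i v_i(x_i) + \sum_{i<j} w_{ij}(x_i, x_j)\Big).$$

The partition function is intractable, so `fit_plm()` maximizes the
regularized *pseudo-likelihood*: the sum over positions of the log
conditional probability of each residue given the rest of its sequence,
each conditional normalized over only 21 states. The objective

$$-\sum_n \omega_n \sum_i \log P(x_i^n \mid x_{-i}^n)
  + \lambda_v \lVert v\rVert_2^2 + \lambda_w \lVert w\rVert_2^2$$

is smooth and convex; with positive penalties the optimum is unique, so
the zero-start L-BFGS-B fit is deterministic and restart-invariant (a
property the tests exercise). Defaults: $\lambda_v = 0.01$ and
$\lambda_w = 0.01\,(L-1)$ with $L = p+q$, scaling the coupling penalty
with the number of pairs competing to explain each position, following
the convention of single-protein coupling analysis. Sequences are
weighted by $\omega_n = 1/(\text{number of rows at} \ge 80\%\ \text{identity})$
by default (`use_weights = FALSE` disables). One unordered pair carries
one 21×21 coupling block; the joint optimization is over all positions at
once rather than per-position regressions with post-hoc symmetrization.
Stopping: projected-gradient tolerance $10^{-5}$, relative-objective
factor $10^{8} \cdot \epsilon$, at most 500 iterations; non-convergence
flags the result rather than erroring.

A caution the tests document: on alignments with strong conservation but
no covariation, the jointly regularized optimum still places some mass on
couplings (spreading logit mass over many small parameters is cheaper in
$L_2$ penalty than concentrating it in fields). This entropic background
is uniform across pairs and is exactly what the average product
correction removes; raw coupling strengths should never be interpreted
without it.

## From couplings to contact scores

- `coupling_strength()`: a pair's 21×21 block is reduced to the
  root-mean-square of its entries, by default over the 20×20 amino-acid
  sub-block (gap couplings largely reflect alignment artifacts; a switch
  restores the full block).
- `block_apc()`: the average product correction
  $s_{ij} - \langle s_{ik}\rangle_k \langle s_{kj}\rangle_k / \langle
  s_{kl}\rangle_{kl}$ with averages restricted per protein: intra-A pairs
  average over A, intra-B over B, and inter pairs take the row average
  over B, the column average over A, and the denominator over the inter
  block. This lets the two families evolve at different rates; for any
  rank-one inter block the correction is exactly zero (tested to
  $10^{-10}$). Intra-block averages include the zero diagonal, the usual
  convention for zero-diagonal coupling matrices. Negative corrected
  values are kept for ranking.
- `normalize_ncs()`: corrected strengths are divided by the mean of the
  top $3L/2$ values over all pairs (a protein of length $L$ has roughly
  $3L/2$ contacts), so `ncs > 1` means stronger-than-typical coupling.
- `gremlin_score()`: the sigmoid
  $1/(1+\exp(-\sigma(x-\mu)))$ with $\mu = m/(N/L+1) + c$ and shipped
  constants $m = 0.47$, $c = 0.96$, $\sigma = 9.77$ (fitted by the
  method's authors on the bacterial 50S ribosomal subunit; refitting them
  requires that dataset and is out of scope). $x = \sqrt{\mathrm{ncs}}$
  for the complex's top-ranked pair and $\sqrt{\mathrm{ncs}}$ scaled by
  the top pair's score otherwise; negative `ncs` is floored at zero
  before the square root. The $\mu$ formula is typeset ambiguously in its
  source; the package defaults to the reading under which deeper
  alignments need lower coupling strength for the same confidence (the
  empirically observed direction), with the alternative
  $\mu = m\,(N/L+1)+c$ available via `mu_form = "linear"`. $N$ is the
  post-filter row count ($N_{\mathrm{eff}}$ optional), $L$ the total
  paired length, for both the depth ratio and the top-$3L/2$ pool; the
  "top pair" is taken over all pairs, consistent with that pool.

`coupling_scores()` assembles everything into one table;
`summed_pair_coupling()` totals inter-protein `ncs` at or above 1.5 as
interaction evidence for the protein pair, and `rank_pairs()` orders
pairs deterministically (score, then indices).

## Distance restraints

`eval_restraint()` implements the sigmoidal form
$\mathrm{weight}/(1+\exp(-\mathrm{slope}\,(d-\mathrm{cutoff}))) +
\mathrm{intercept}$. `build_restraints()` converts the top $3L/2$ inter
pairs (by score) into either centroid-mode Cβ–Cβ restraints (Cα for
glycine) with residue-pair-specific cutoff/slope from an editable table —
shipped flat at 8 Å / 2, since the published per-pair table lives in
third-party supplementary material — or full-atom ambiguous restraints
over all side-chain heavy-atom combinations at cutoff 5.5 Å, slope 4,
scored as the minimum over alternatives. Weights are `-ncs` (attractive)
times a configurable constant. Writers emit a native TSV and
Rosetta-style constraint lines (`AtomPair ... SCALARWEIGHTEDFUNC`;
`AmbiguousConstraint`/`END_AMBIGUOUS` blocks), both covered by
golden-file tests.

## Evaluation against structures

`pair_distances()` tabulates minimal side-chain heavy-atom, Cβ, and Cα
distances per residue pair (missing atoms yield `NA`, never 0);
`protein_pair_in_contact()` applies the Cα-within-12 Å rule ("within"
read as ≤ everywhere); `fnat()` counts native interface contacts
(side-chain minimum < 5 Å) preserved in a model; `interface_rmsd()`
superposes interface Cα atoms (reference residues with any cross-chain Cα
≤ 12 Å — the source never defines its interface set, so the contact rule
is reused) by least-squares rotation and is rigid-motion invariant to
numerical precision. PDB input takes the first model, altloc A, ATOM
records only.

## Synthetic data: what it does and does not emulate

`sample_potts()` Gibbs-samples paired alignments from a known Potts
model with planted state-matching couplings (diagonal 21×21 pattern,
magnitude 0.5–2 detectable); single chain, burn-in $100L$ sweeps,
thinning 10. That approximates independent draws well enough for
rank-based criteria, and the sampler is validated against the exactly
enumerable two-column Boltzmann distribution. `make_genomes()` builds
operon-structured annotations with a planted conserved distance,
non-conserved genomes and paralog decoys at distances drawn from 25–60 —
far above the 20 bound and outside mode±1, i.e. unambiguous distant
paralogs. `make_toy_structure()` lays out two poly-alanine chains with
requested contact distances for evaluation fixtures.

What passing on this synthetic bed shows: the estimator recovers planted
direct couplings (10 planted pairs inside the top 12 inter pairs at
$N = 5000$, $L = 50$ across replicate seeds), the correction and
calibration behave as designed, and pairing is exact when its assumption
(a conserved operon distance) holds. The depth-calibration study spans
$N/L \in \{1, 2, 4\}$ with the planted signal at the strong end of the
detectable range (coupling 2.0): at magnitude 1.0 those depths carry
essentially no signal and every pair correctly scores near zero, which is
calibrated but uninformative; at 2.0 detection power varies across depth
and binned precision tracks the score roughly one to one. What it does not show: performance
under phylogenetic correlation between sequences (rows here are near-
independent draws; real alignments are tree-structured), realistic gap
and indel processes, paralog confusion subtler than distant decoys, or
the adequacy of the shipped sigmoid constants for any particular real
complex. Problem sizes in tests (up to $L = 50$, $N = 5000$, ten
replicate fits; smaller instances for oracle comparisons) were chosen so
the full suite runs on one CPU in minutes while still operating at the
depth ratio $N/L \ge 2$ where contact prediction is reported to become
reliable.

## Numerical notes and degenerate inputs

Identity between rows is matches over columns where neither is a gap,
divided by the count of such columns (0 when none) — insensitive to
shared gap runs. Columns at exactly the 75% gap threshold are retained
("more than"); chain contact at exactly 12.0 Å counts ("within").
Redundancy filtering scans greedily in input order with the query pinned
first, so it is deterministic and order-stable. A zero-mean strength
block makes the correction undefined and errors; an all-gap column set,
an empty family intersection, and a reference without interface contacts
error with diagnostics rather than returning fabricated values. Mode ties
in the distance histogram break toward the smaller distance. Records
with identical accession indices denote the same gene and are rejected
(configurable to distance 0).

## A worked example

```{r example, eval = FALSE}
set.seed(1)
sim <- sample_potts(planted_complex_spec(p = 25, q = 25, n_contacts = 10,
                                         coupling = 1, n_seq = 2000,
                                         seed = 7))
fit <- fit_plm(sim$alignment)
scores <- coupling_scores(fit)
head(rank_pairs(scores, "inter"))
rs <- build_restraints(scores,
                       seq_a = paste(sim$alignment$seqs[1, 1:25],
                                     collapse = ""),
                       seq_b = paste(sim$alignment$seqs[1, 26:50],
                                     collapse = ""),
                       mode = "centroid")
write_rosetta_constraints(rs, tempfile(fileext = ".cst"))
```

## Limitations

The pipeline reads alignments produced by external homology searches; it
does not run them. Docking itself is out of scope — the package emits
restraints and evaluates given models. Eukaryotic genomes, where operon
structure is absent and ortholog resolution is an open problem, are not
supported by the pairing rule. The calibration constants are shipped as
published, not refit.
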