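---
title: "Methods: simulating alignment uncertainty and its effect on phylogenetic inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating alignment uncertainty and its effect on phylogenetic inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msabias)
```

## The question the package addresses

Standard molecular-evolution practice is a two-step process: estimate a
multiple sequence alignment (MSA), then treat its columns as known homologies
and infer trees and branch lengths by maximum likelihood (ML). ML is
statistically consistent *given the correct alignment*; this package provides
the machinery to ask what happens to that guarantee when the alignment itself
is estimated. It simulates sequences under substitution **and** indel
processes on designed trees while recording the true column homologies,
re-aligns the simulated sequences with a self-contained progressive aligner,
runs ML (and parsimony) inference on both alignments, and quantifies the
resulting bias in divergence estimates, polytomy resolution, topology-test
calibration, and long-branch attraction (LBA).

## Simulation model

**Substitution.** Nucleotide data evolve under a general time-reversible
model with exchangeabilities (relative to rAG = 1)
rAC = 0.30, rAG = 1.0, rAT = 0.20, rCG = 0.25, rCT = 1.39, rGT = 0.22 and
frequencies piA = 0.25, piC = 0.26, piG = 0.27, piT = 0.22 — values
representative of mammalian nuclear genes. Amino-acid data evolve under the
WAG empirical matrix, whose exchangeabilities and frequencies ship as a
plain-text table (`inst/extdata/wag.dat`, PAML state order: 19
lower-triangle rows then one frequency line). Rate matrices are scaled so
the expected substitution rate at stationarity is 1; branch lengths are
therefore expected substitutions per site. Among-site rate variation is a
discrete Gamma with shape 1.8 and 4 equal-probability categories whose rates
are the conditional means over quantile intervals (the mean method): for
shape 1.8 the rates are `r paste(round(discretize_gamma(1.8, 4)$rates, 3),
collapse = ", ")`. Transition probabilities come from the symmetric
eigendecomposition of the similarity-transformed rate matrix, which is
numerically stable for reversible models; tiny negative entries from
round-off are clamped and rows renormalized.

**Indels.** Insertions and deletions are modeled as a reversible process:
each occurs at 0.05 times the substitution rate, per site, so a sequence of
length L has insertion rate 0.05·L and deletion rate 0.05·L per unit branch
length. Reading the single stated relative rate as *separate, equal* rates
for insertion and deletion keeps expected sequence length stationary, which
a reversible length process requires. Lengths are drawn from a power-law
(Zipf) distribution with exponent 1.7, truncated at 20 residues (amino
acids) or 60 (nucleotides). Insertion positions are uniform over the L+1
slots (terminal insertions allowed); inserted residues are drawn from the
stationary distribution and receive fresh Gamma categories (sites are
exchangeable under the model); deletions start at a uniform site and are
truncated at the sequence end. Along a branch, indel event times follow a
Gillespie walk and substitutions are applied *exactly* between events via
the matrix exponential, so there is no time-discretization error.

**Root and homology tracking.** The root sequence (408 amino acids or
3 × 408 = 1224 nucleotides by default) is drawn from the stationary
distribution — the process is at stationarity, so nothing downstream
depends on a particular fixed root sequence. Every site carries a unique
homology identifier; insertions allocate fresh identifiers and splice them
into a global ordered column registry next to their anchor site. The true
alignment is read off this registry (columns surviving in no leaf are
dropped), which guarantees two checked identities: each row degaps to its
taxon's unaligned sequence, and the column count equals surviving root
columns plus surviving insertion columns.

## Study trees

Three 8-taxon families, plus supertrees:

* **Balanced tree** — two balanced 4-leaf halves joined by a central
  branch: 13 equal branches (8 external, 4 middle, 1 central "root"
  branch), scaled to a requested total tree length. Used for divergence
  bias; the branch classes drive the quartile summaries.
* **Polytomy tree** — a degree-4 root with four 2-leaf cherries, two short
  (all branches 0.06; root-to-tip 0.12) and two long (0.7; root-to-tip
  1.4). Its three resolutions differ by an internal branch started at 0;
  the one grouping the long cherries is the LBA resolution.
* **Felsenstein-zone tree** — four balanced subtrees (two of depth alpha,
  two of depth beta, all branches within a subtree equal) around one
  internal branch; the generating topology separates the long subtrees.
  The internal branch defaults to alpha, co-varying with the short subtree
  depth, since only the two depth axes are varied in the grid design; it
  is exposed as a parameter. 8 or 32 taxa.
* **Supertrees** — 64 or 512 leaves built by repeatedly attaching extra
  tips at uniformly random points on branches lying on paths between the 8
  core taxa (pendant lengths uniform on 0.05 to 0.5 × the core branch
  length). Subdividing core-path edges preserves the induced core tree
  exactly, which is the embedding contract the tests verify.

## The built-in aligner

A deliberately conventional progressive aligner stands in for external
guide-tree based MSA tools so the pipeline needs no binaries: k-mer
distances (k = 6 nt / 3 aa; one minus the shared-k-mer fraction normalized
by the shorter sequence), a neighbor-joining guide tree (negative branch
lengths clamped; UPGMA available), midpoint-rooted for merge order, and
profile–profile global alignment with affine gaps and "once a gap, always a
gap". Column scores are expected pairwise log-odds,
s(x, y) = 10·log(P(x→y at d = 1)/pi_y), rounded to integers, with profile
columns represented by residue frequency vectors and a separate gap
fraction; gap-versus-residue mass is charged the extension score.

Gap penalties default to open −20, extend −1 on that ×10 score scale. The
open penalty was set so that on gapless data (indel rate 0) the optimal
path is the gapless alignment across divergences up to tree length ≈ 1 for
both alphabets — with a weaker opening cost (e.g. −11) the
frequency-normalized column scores let spurious gap pairs into the optimum
even when no indels occurred, which would confound "alignment error" with
"aligner eccentricity". Because the aligner is a stand-in, its absolute
accuracy is not the point; what matters is that it behaves like the class
of tools it represents: accuracy decays with divergence, its guide tree is
nearly always correct for conserved data, and — the central effect — its
alignments push polytomy resolution toward the LBA tree on divergent
nucleotide data while true alignments stay neutral.

## Inference

ML inference runs on a fixed topology under the same substitution model
family used for simulation, gaps treated as missing data (a gapped site
contributes a partial-likelihood vector of ones; a column with one residue
contributes log pi of it). Frequencies are always taken from observed
counts (floored at 1e-6 and renormalized); branch lengths are always
optimized; the Gamma shape is re-estimated per fit by default, and the GTR
exchangeabilities are re-estimated for nucleotide data ("everything except
frequencies by ML"). Since simulation uses WAG's published frequencies but
inference uses observed counts, the amino-acid fits are effectively "+F" —
the estimated and generating frequencies coincide up to sampling error.
The numerical optimization is delegated to the pruning-based machinery of
phangorn (`pml`/`optim.pml`); the package's own vectorized pruning
implementation computes the log-likelihood and per-site log-likelihoods at
given parameters and is tested against an exhaustive enumeration oracle on
4-taxon toys, against closed forms on pairs, and against phangorn itself
(agreement ~1e-13), so the two routes check each other.

Topology selection fits each candidate and applies the tie rule: all
candidates within 0.01 log-likelihood units of the maximum share weight
equally (weights sum to one per data set). Fitch parsimony (gaps missing)
provides the MP arm. The Shimodaira–Hasegawa test is implemented by RELL:
site log-likelihood vectors are resampled with replacement B = 1000 times
(B is not fixed by the study design; 1000 is standard RELL practice and
ample for decisions at alpha = 0.05), each candidate's replicate scores are
centered by its own replicate mean, and one-sided p-values are exceedance
fractions with ties counted as exceedances — so the ML candidate has p = 1
by construction and can never be rejected.

## Experiments and their defaults

Each driver is a pure function of (config, seed): per-replicate seeds are
derived from the master seed by a counter scheme, both arms of a replicate
share the same simulated data (paired comparisons), and re-runs are
byte-identical. Failed replicates would be excluded and counted; none occur
under the shipped conditions. Defaults follow the study design: 200
replicates, root length 408 aa (nucleotide runs use three times the
amino-acid length), tree-length grid {0.5, 1, 2, 3, 4, 5, 6} (the grid is
not fixed by the design; this covers the plotted range), root-length grid
{102, 204, 408, 816} aa centered on 408, OTU counts {8, 64, 512},
Felsenstein grids alpha in {0.025, ..., 0.25} by 0.025 and beta in
{0.25, ..., 1.375} by 0.125.

## What the tests and acceptance runs compute, at what sizes

The automated suite uses desk-scale problem sizes, chosen as the smallest
that leave the statistical checks well-powered; all are stated here as
package choices:

* tree-length unbiasedness: 50 replicates, nt, tree length 6, root 1224,
  indels on — median inferred length within 3% of 6;
* polytomy neutrality: 100 replicates, aa, root 408, true alignments —
  each resolution within 3 binomial SE of 1/3;
* SH conservatism: same 100 replicates — overall rejection rate at
  alpha = 0.05 is at most 5%;
* parameter recovery: one 100,000-site no-indel nt simulation (rCT and
  shape within 5% of 1.39 and 1.8) and one 50,000-site aa simulation
  (mean long-subtree branch within 5% of 0.7);
* direction of effect: 30 replicates, nt, root 1224 — the builtin-aligner
  arm resolves the polytomy to the LBA tree significantly more often than
  the true-alignment arm (one-sided two-proportion test, alpha = 0.01);
* property suites at toy sizes (enumeration oracles, metric axioms,
  Chapman–Kolmogorov, pulley principle, RELL versus a naive resampler,
  parsimony LBA in the extreme Felsenstein cell).

`scripts/acceptance.R` recomputes the quantitative subset of these from
scratch against the installed package.

## What the generator does and does not emulate

The simulator reproduces the stated generative model exactly:
reversible substitution with discrete-Gamma rates, equal-rate
insertion/deletion with truncated-Zipf lengths, stationary root. It does
**not** emulate several properties of real data: among-lineage rate
variation, selection or site-specific constraint profiles, codon structure,
length-dependent or context-dependent indels, or alignment-column
correlations beyond shared rate categories. Passing tests therefore show
that the two-step inferential machinery behaves as analyzed *under the
generating model*; they do not certify accuracy on real sequences, where
model misspecification compounds the alignment effects studied here.

## Numerical choices and degenerate inputs

* Branch lengths are floored at 1e-8 before optimization; candidate
  resolutions start their new internal branch at 0.
* Optimization convergence follows `phangorn::pml.control` defaults
  (relative log-likelihood tolerance 1e-8).
* Tie-breaking: the tie rule uses epsilon = 0.01 log-likelihood units;
  RELL ties count as exceedances (conservative); the profile DP breaks
  score ties deterministically (match, then gap-in-second, then
  gap-in-first), so alignment is reproducible without a seed.
* A sequence shrinking to length 0 during simulation stops experiencing
  events (its indel rates are length-proportional); with the shipped
  parameters this does not occur.
* All-gap alignment columns are disallowed by the MSA container and
  removed by subalignment extraction.
* The exact published alignment-distance algorithm is not re-derived here;
  the package's `msa_distance` is a documented symmetric-difference
  distance over homology-pair and flank-labeled gap statements ("d_ssp
  style"): 0 iff identical homology statements, sensitive to gap placement,
  invariant to padding columns, and a pseudo-metric — the properties the
  comparison experiments rely on.

## Known limitations

* The built-in aligner is one representative of guide-tree progressive
  methods; consistency-based and phylogeny-aware aligners, which the
  original comparisons show are more robust, are reachable only through
  the external-tool adapter.
* The pure-R pruning implementation is for reference and per-site scores;
  large-scale optimization goes through phangorn's C code. Likelihood
  computations on hundreds of taxa are untested territory (the experiments
  only ever fit 8-taxon subproblems).
* Supertree topologies beyond the exact-embedding contract are arbitrary;
  only the induced core tree is specified by the design.
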