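---
title: "Methods: codon-model selection tests and folding-stability mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-model selection tests and folding-stability mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

selstab implements an inference chain that links positive selection in a
protein-coding gene to a biophysical phenotype, folding stability. It was
built around the canonical example of cetacean myoglobin — a protein whose
muscle concentration rose 10–20 fold in diving mammals while its folding
stability rose by 2–4 kcal/mol — but every stage is generic: any in-frame
coding alignment, tree, and mutation→ΔΔG table can be run through it.

The chain has four stages:

1. **Codon-model selection tests.** Goldman–Yang rate matrices over the 61
   sense codons with F3X4 equilibrium frequencies; maximum-likelihood fits
   of M0 (one ω), free-ratio (ω per branch), the site models
   M1a/M2a/M7/M8/M8fix, branch-site model A (one marked foreground
   branch), and clade model C (two branch types); likelihood-ratio tests
   between the nested pairs; NEB and BEB per-site posteriors of ω > 1.
2. **Ancestral reconstruction.** Dayhoff exchangeabilities with
   discrete-gamma rate variation; branch lengths and the gamma shape are
   optimized by pruning likelihood, then marginal posteriors over the 20
   residues are computed for every internal node and site, and MAP
   ancestor sequences are differenced along branches into substitution
   records (`G129A` notation).
3. **Stability bookkeeping.** FoldX-style TSV tables (site, from, to,
   ddg; replicate rows averaged) joined to branch substitutions;
   per-branch ΔΔG sums; an explicitly labelled surrogate generator for
   testing (not a force field).
4. **Integrative statistics.** pr(ΔΔG < 0 | positively selected), computed
   both directly and via Bayes' rule (they must agree identically);
   two-sample t tests in both variance conventions; apo→holo conversion
   (ΔG_holo = ΔG_apo − 2.7 kcal/mol); stability–abundance correlation.

## The codon model

For codons $i \ne j$ differing at exactly one nucleotide,

$$q_{ij} \propto \pi_j \cdot \kappa^{\mathrm{ts}(i,j)} \cdot
\omega^{\mathrm{ns}(i,j)},$$

zero otherwise; rows sum to zero and the matrix is rescaled so branch
lengths are expected substitutions per codon. $\pi$ is F3X4: the product
of position-specific nucleotide frequencies counted from the data,
renormalized over sense codons, never optimized. Sense codons with zero
counted frequency receive a pseudo-frequency of 1e-10 before
renormalization so the chain stays irreducible on small alignments.

Likelihoods come from Felsenstein pruning with per-node rescaling,
implemented once in compiled code and reused by every model (codon and
amino-acid states, per-class and per-edge rate matrices, gamma-category
length multipliers). Transition probabilities use the spectral
decomposition of the π-symmetrized generator, with tiny negative entries
clamped to zero. The pruning kernel is verified against brute-force
enumeration over internal-node states on small trees, at codon and
amino-acid state spaces, to 1e-8 and better.

### Site-class mixtures

* M1a: classes $(\omega_0 \in (0,1), \omega_1 = 1)$ with proportions
  $(p_0, p_1)$.
* M2a: adds $(\omega_2 > 1, p_2)$.
* M7: $\omega \sim \mathrm{Beta}(p, q)$ discretized into $K = 10$
  equal-probability categories represented by category means (closed form
  via the incomplete beta of shape $p + 1$). $K$ follows the convention
  of the standard software; it is configurable.
* M8: M7 plus an extra class $(p_1, \omega_s \ge 1)$; M8fix pins
  $\omega_s = 1$.
* Branch-site A: four classes in the standard two-proportion layout;
  the foreground branch (exactly one, marked `#1` in Newick or via
  `mark_branch()`) carries $\omega_2$ free or fixed at 1 for the null.
* Clade C: shared $(\omega_0, 1)$ classes plus a divergent class whose ω
  differs between the two branch types (`$1` marks / `mark_clade()`).
  The published analysis labels its clade model only by the clade name;
  the parameter layout printed there matches clade model C, which is what
  is implemented.

### Optimization

Bounded quasi-Newton (`nlminb`) on transformed parameters: log for κ, ω
and branch lengths, logit for proportions and $\omega_0$,
$\log(\omega_s - 1)$ for the M8/branch-site positive class. Multi-start
from dispersed deterministic starting points (default `n_restarts = 5`;
the published workflow likewise re-ran its optimizer from several initial
values), keeping the best log-likelihood. When branch lengths are
co-estimated, a cheap pre-phase first optimizes the model parameters plus
one overall branch-scale factor, then the joint optimization polishes.
Convergence: relative lnL change below 1e-8; estimates within 1e-4 of a
bound are flagged as boundary warnings in the fit object. Alignments with
no variable columns are flagged `unidentifiable` rather than crashing.

Site models default to branch lengths fixed from the M0 fit
(`scan_selection()` wires this automatically), with co-estimation behind
a flag; both modes are supported because both are used in practice and
published site lists are reported to be robust to the choice.

Trees are unrooted internally before codon fits (the models are
time-reversible, and a degree-2 root would leave the two root-adjacent
quantities confounded); branch and clade marks are re-keyed by descendant
tip set so they survive the unrooting.

### LRT conventions

Degrees of freedom are frozen to the printed conventions: M1a vs M2a and
M7 vs M8 use 2; M8fix vs M8 and branch-site A vs its null use 1; M0 vs
free-ratio uses branches − 1; M1a vs clade C uses 3. The df = 1
comparisons sit on a boundary where the plain χ² is conservative; the
plain convention is the default because it reproduces the published
arithmetic. Negative statistics within 0.02 (optimizer noise) clamp to
zero with a warning; anything larger raises, signalling an upstream
optimization failure.

### NEB and BEB

NEB plugs the MLEs in: per-site class posteriors ∝ class proportion ×
per-class site likelihood. BEB integrates the same posterior over a
uniform grid on the mixture parameters — $(p_0, p_1, \omega_0, \omega_2)$
for M2a (proportions gridded on the simplex triangle),
$(p_0, p, q, \omega_s)$ for M8 — weighting each grid point by its data
likelihood, with κ, branch lengths and π held at the MLEs, as in the
standard implementation. Default 10 points per dimension; fewer than 4
is refused, except for the degenerate one-point grid at the MLEs, which
exists as a construction check: it must reproduce NEB exactly, and a test
asserts that it does.

A practical note established on synthetic data: with a planted ω = 5
class, M2a's NEB is conservative here (its positive class tends to small
weight and large ω), while M8's NEB/BEB recover 85–100% of planted sites
at P(ω>1) > 0.5 with false-positive rates below 2% at the 0.95 tier.
The planted-site acceptance check therefore runs on M8; both models are
exposed.

## Ancestral reconstruction

Branch lengths and the gamma shape α (K = 4 equal-probability categories,
category means) are fitted under Dayhoff exchangeabilities — embedded as
a package constant and cross-checked in a test against phangorn's copy —
with model frequencies by default and empirical (+F) frequencies behind a
flag. Reconstruction is marginal (per node, integrating over the other
nodes and the rate categories), matching the usual ML reconstruction
practice; joint-MAP reconstruction is out of scope. Posteriors come from
an inside–outside recursion with per-category log-scale tracking, exact
against enumeration on small trees and invariant to root placement.

MAP ties break to the alphabetically first residue and carry a tie flag.
Tip gaps are missing data; ancestors are always assigned a residue. Each
node–site record also reports the runner-up residue, because ambiguous
sites (posterior 0.5–0.9) are best read together with their alternative
state — in the motivating analysis those ambiguous sites were the ones
whose alternative was the initially mutated residue. Site numbering takes
a configurable integer offset between alignment column and reported
residue number (mature-chain numbering vs alignment coordinates).

Substitutions are emitted per branch in parent→child polarity by
differencing MAP (or observed, at tips) sequences. Note that per-branch
substitution counts along a path can exceed the endpoint difference when
a site reverses (the motivating data contain such reversals at site 129),
so no path-conservation identity is asserted beyond the inequality.

## Stability tables and the surrogate

Tables are TSVs with columns `site`, `from`, `to`, `ddg` (kcal/mol) and
optional `replicate`/`source`; replicate rows (e.g. the recommended five
force-field repeats) are averaged on load. The internal sign convention
is ΔΔG < 0 = stabilizing, everywhere; tables in the opposite convention
are negated on load. Joins default to `require_entry` — a missing X→Y
entry stays missing, is excluded from branch sums, and is counted —
because force-field ΔΔG is not exactly antisymmetric; the
`antisymmetric` policy fills X→Y with −ΔΔG(Y→X) and flags the fill,
motivated by reversal substitutions that occur in real data.

`surrogate_ddg()` is a clearly-labelled testing stand-in, not a
force-field reimplementation: draws from gamma(2, 1.1) − 1 (mean
+1.2 kcal/mol, the field's consensus average effect of a random point
mutation on a globular protein; right-skewed with ~23% stabilizing mass),
plus deterministic offsets for helix-breaker→former replacements in
helix context and hydrophobicity gains at buried sites.

## Integrative statistics

`conditional_prob_stabilizing()` computes pr(ΔΔG<0 | selected site) both
as a direct count ratio and via Bayes' rule and requires exact agreement
— the identity is asserted on every call, and property tests exercise it
on random tables. `two_sample_t()` returns both Welch and pooled
conventions, because published analyses use both; on the in-text pairwise
dN/dS tables (36 cetacean vs 28 primate values) the pooled convention
reproduces the printed 1.33e-16 and Welch gives the same order of
magnitude. The pairwise values are not independent (pairs share species);
the published test ignores this and the reproduction does too, by
design. `apo_to_holo()` subtracts a constant offset, default 2.7
kcal/mol (the measured holo–apo stability gap of horse heart myoglobin,
taken as constant because heme-pocket residues are conserved).
Correlation defaults to Pearson with a t-distributed p on n − 2 df;
Spearman is available.

The bundled phenotype table carries the twelve printed apo-ΔG values
plus the two printed muscle concentrations; the remaining concentrations
behind the published stability–abundance correlation come from scattered
primary references and are deliberately not reconstructed, so the
correlation on real data is not an acceptance target. One printed
internal discrepancy (minke whale −8.7 vs −8.4 kcal/mol in different
sections) is carried as published and flagged in the table.

## The synthetic world

The generators give every stage inputs with the statistical structure the
models assume:

* `simulate_codon_alignment()`: root states from π, per-branch evolution
  by `expm(Q(ω_c) t)`, one ω class per site across the tree (the
  site-model assumption); marked branches can carry their own ω per class
  (branch-site / clade structure). Simulated data contain no stops and
  are bit-reproducible for a seed.
* `simulate_aa_alignment()`: Dayhoff + discretized gamma, with true
  internal-node sequences and per-site rates recorded for scoring.
* `simulate_phenotypes()`: stabilities Gaussian in the plausible apo band
  (mean −6.5, sd 1.5 kcal/mol), concentrations log-normal (median 1.5
  g/100 g, sdlog 0.5, spanning the terrestrial-to-deep-diver range); the
  latent correlation is pre-compensated for log-normal attenuation so the
  realized Pearson correlation between stability magnitude (−ΔG) and
  concentration targets the requested value; |ρ| = 1 switches to an
  exact linear generator.
* Random trees are pure-birth topologies with i.i.d. exponential branch
  lengths. Simulation worlds in tests that need a fixed information
  content normalize the total tree length instead of the per-branch mean,
  because detection power tracks tree length much more than topology.

What the generators do **not** emulate: indels and alignment error,
codon-usage bias beyond F3X4, synonymous rate variation, site-class
switching along the tree, covarion behaviour, and any real energetics in
the surrogate ΔΔG. A green recovery test therefore establishes that the
estimators invert the package's own generative models at realistic sizes
— not that any biological conclusion is reproduced. The published
sequence data themselves are available only by accession download, so the
real-data fits are explicitly out of desk-testable scope; the in-text
numerical inputs that *are* printed (the pairwise dN/dS matrices, the
LRT statistics, the apo stabilities) are bundled and reproduced exactly.

## Numerical choices worth knowing

* Canonical codon order: alphabetical with stops removed — frozen, it
  defines every 61-vector and matrix layout.
* Gap in any codon position ⇒ whole codon missing (flat partial).
* `U` silently maps to `T`.
* Per-node rescaling in the pruning kernel; per-category log-scale
  bookkeeping in the inside–outside recursion (scale factors differ per
  rate category and must be re-applied before mixing categories).
* Deterministic outputs: fits and reports serialize without timestamps;
  identical inputs give byte-identical files. Branch lengths in JSON are
  keyed by the child node's descendant tip set, which is stable across
  edge reorderings.
* Degenerate two-sample t on zero-variance inputs returns the exact
  answer (p = 1 for equal constants, p = 0 otherwise) instead of
  erroring, so constant-group fixtures behave.

## Known limitations

* No analytic gradients: co-estimating many branch lengths on large
  trees is the slow path (a pre-phase mitigates; ~20 s for 12 taxa × 500
  codons on one core).
* BEB at the default 10-points-per-dimension grid over four dimensions is
  computationally heavy on large alignments; tests and the acceptance
  script use coarser grids, which the object records.
* The df = 1 boundary LRTs use the plain χ² convention by default
  (conservative); a mixture-null option is deliberately not the default
  to keep printed-table arithmetic reproducible.
* Branch-level multiple-testing correction across free-ratio branches is
  out of scope, as in the source analysis.
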