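---
title: "Predicting binding ddG from structural interface profiles"
author: "ddgprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting binding ddG from structural interface profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddgprof)
```

## The model

A mutation at a protein-protein interface changes the binding free energy of
the complex (ddG, kcal/mol; positive values destabilize binding). Measuring
ddG experimentally is slow, and physics-based estimates require rebuilding a
full-atom model of every mutant. `ddgprof` instead scores mutations against
the *evolutionary record of analogous interfaces*: if many structurally
similar binding sites in known complexes tolerate an amino acid at the
equivalent position, a mutation to that amino acid is unlikely to be very
destabilizing.

The central object is a position-specific structural profile over the query
interface. Given a set of template interfaces aligned to the query, the
profile score of amino acid $A$ at interface position $p$ is

$$F(p, A) = \sum_{a=1}^{20} g(p, a)\, M(A, a)$$

where $g(p,a)$ is the Henikoff-weighted frequency of residue $a$ among the
aligned template residues at $p$ (exactly redundant aligned interface
sequences are removed first), and $M$ is a substitution matrix (BLOSUM62 by
default) that smooths the sparse observed counts. The predicted
destabilization of mutating position $p$ from the wild type to a mutant
residue is the profile-score difference

$$\Delta\Delta G_{calc} \propto F(p, A_{WT}) - F(p, A_{Mut}),$$

summed over sites for multi-site mutations (the score is strictly additive
by construction; see Limitations).

## Interface similarity metrics

Templates are recruited by structurally aligning candidate interfaces to the
query. An interface residue is any residue with a heavy atom within 4 A of
the partner chain. Three similarity scores are computed from an alignment of
$N_a$ residue pairs with C-alpha distances $d_i$, normalized by the query
interface length $L_Q$:

* **iTM-score** — backbone only:
  $\frac{1}{L_Q}\sum_i \frac{1}{1 + d_i^2/d_0^2}$ with
  $d_0(L_Q) = \max(0.5,\; 1.24\,(L_Q-15)^{1/3} - 1.8)$.
* **Iscore** — adds the per-pair fraction of conserved cross-chain contacts
  $f_i = (c_i/a_i + c_i/b_i)/2$, where $a_i$, $b_i$ count the contacts of
  the template and query residues and $c_i$ those preserved under the
  alignment: $\frac{1}{L_Q}\sum_i \frac{f_i}{1 + d_i^2/d_0^2}$. Term-wise
  $f_i \le 1$, so Iscore never exceeds the iTM-score on the same alignment.
* **PCscore** — adds a physicochemical match indicator $I_i$ over six
  residue classes (K,R / E,D / N,Q,S,T / F,W / C,A,I,L,M,P,V,G / H,Y) with
  a fixed 4 A distance scale:
  $\frac{f_c}{L_Q}\sum_i \frac{1}{1 + 0.25\,(1-I_i) + d_i^2/4^2}$, where
  $f_c$ is the ratio of preserved contacts over all query interface
  contacts.

The alignment itself is a heuristic search: gapless threading seeds (start-,
centre- and end-aligned offsets) in both possible chain pairings, refined by
iterating optimal superposition (Kabsch) with dynamic-programming
re-assignment on the score matrix $S(i,j) = 1/(1 + d_{ij}^2/d_0^2)$ with
zero gap penalty, until the pair set stabilizes (at most 20 rounds). The
alignment maximizing the requested metric wins; ties break toward smaller
RMSD. This reproduces the published score definitions, not any particular
external program's output.

## The adaptive profile

Profile accuracy is bimodal in the similarity cutoff: very strict cutoffs
admit too few sequences for reliable statistics, while very loose ones
dilute the profile with unrelated interfaces. The adaptive profile combines
both regimes: all templates above a strict cutoff (Iscore 0.25 by default)
are always included, and up to $n$ more (default 80) are added in
descending-similarity order until a looser cutoff (0.19) is reached. The
resulting selection always satisfies
strict-set $\subseteq$ adaptive-set $\subseteq$ loose-set. $n$ counts
sequences globally, not per position — the simplest reading of the rule and
the one implemented here.

## The feature set and the forest

For machine-learning combination, each mutation receives 13 profile-derived
features: the three mutant profile scores (strict, loose, adaptive
profiles), plus five quality features for each of the strict and loose
profiles:

1. mean alignment distance at the mutation site (A),
2. mean fraction of preserved contacts at the site,
3. number of templates aligned at the site,
4. Jensen-Shannon divergence (base 2, equal mixture) between the site's
   amino-acid distribution and the BLOSUM62 background frequencies,
5. the Z-score of that divergence across interface sites (0 when the
   across-site spread is zero).

Six sequence features are appended: signed count changes in five
(deliberately overlapping) pharmacophore categories — hydrophobic
(V,I,L,M,F,W,C), aromatic (Y,F,W), charged (R,K,D,E), H-bond acceptors
(D,E,N,H,Q,S,T,Y), donors (R,K,W,N,Q,H,S,T,Y) — and the residue volume
difference (Zamyatnin volumes). External potential scores (e.g. docking or
all-atom energies computed elsewhere) can be appended as optional numeric
columns; `ddgprof` never computes them itself, but `combine_energy_terms()`
implements the standard contract for turning complex/monomer energies into
a ddG.

A random forest (500 trees by default; variables-per-split tuned over
{2, 4, 6, 8, p/3} on an internal 15% testing split) regresses experimental
ddG on these features. Two validation schemes are provided:
repeated k-fold (default 10-fold, 3 repeats; Pearson correlation on pooled
out-of-fold predictions per repeat, summarized as mean +/- sd) and
leave-one-protein-out, which holds out every mutant of the tested complex
and reports the standard error of prediction (read here as the RMS
residual — the usual convention when "standard error of prediction" is
reported without further definition). Leave-one-protein-out is the honest
estimate of cross-protein generalization; on protein-clustered data its
error is expected to exceed (never fall below) the k-fold error.

## Data curation and the template library

Experimental mutation tables follow a simple tab-separated dialect
(`complex_id`, `chain`, `mutations` like `"L45D;K12E"`, `ddg_exp`,
`temperature`). Curation keeps one-sided entries only (all substitutions on
one chain), merges replicate measurements of the same mutation set, and
discards replicates lying more than one standard deviation *above* the
group mean before averaging — the outlier rule is deliberately one-sided,
aimed at spuriously large destabilization values. Curation is idempotent.

Template libraries are built from dimers: larger assemblies are split into
all chain pairs, pairs whose chains do not both contribute at least 10
interface residues are dropped, and a dimer is removed as redundant only if
it shares both >= 70% sequence identity and a complex TM-score >= 0.8 with
an already-kept entry (first-kept wins; the rule is conjunctive). The
complex-level TM-score is approximated in-package: chains are paired by
best sequence identity, matched C-alpha pairs from per-chain global
sequence alignments are superposed with iterative distance trimming, and
the TM-score is normalized by the smaller complex. This is a deliberate
approximation of a full multichain structural alignment, adequate for the
coarse redundancy threshold it serves; near the 0.8 boundary it is less
precise than a dedicated multichain aligner.

## Residue burial classes

Interface residues are classified by relative solvent accessibility in the
isolated chain (rASA) versus the complex (rASA_c), each normalized by
theoretical Gly-X-Gly maxima, with a 25% exposure threshold:

| class    | monomer      | complex      | contact |
|----------|--------------|--------------|---------|
| core     | exposed      | buried       | —       |
| rim      | exposed      | exposed      | yes     |
| surface  | exposed      | exposed      | no      |
| support  | buried       | —            | yes     |
| interior | buried       | —            | no      |

A rASA of exactly 0.25 counts as buried, so the partition is deterministic;
every (rASA, rASA_c, contact) triple receives exactly one class. Note the
"surface" class is *exposed in both states*: the alternative reading
(buried in the monomer but exposed in the complex) is impossible because
complex formation can only bury surface, never expose it — SASA in the
complex never exceeds SASA of the isolated chain.

SASA itself is computed by the Shrake-Rupley method with 960 deterministic
golden-spiral test points per atom, a 1.4 A water probe, and Bondi-type
element radii. 960 points keep the single-sphere closed-form error well
under 1% while remaining fast for toy-scale fixtures.

## What the synthetic generators emulate

All tests run on generated data; nothing is downloaded. Three generators
define the study conditions:

* `make_toy_dimer()` builds two antiparallel extended chains (backbone +
  C-beta, ideal local geometry) posed so a chosen number of residues per
  chain sit within 4 A of the partner. The two chains deliberately differ
  in residue spacing, pleat amplitude and curvature so the interface has no
  chain-swap pseudo-symmetry and the correct chain pairing of an alignment
  is uniquely optimal. A 0.03 A seeded jitter makes different seeds
  produce distinct coordinates without disturbing the contact geometry.
* `make_template_family()` derives templates from the base dimer by grading
  Gaussian coordinate noise from 0 up to a maximum (default 2 A) across
  the family — spanning similarities from 1 down past the loose cutoff —
  applying a random rigid motion (the scores must be invariant to it), and
  resampling interface residue identities from a known per-position
  distribution $\pi(p,\cdot)$.
* The default $\pi$ gives each position a consensus residue and weights the
  others by $\pi(p,a) \propto \exp(0.5\, M(a, a^*_p))$: positions tolerate
  residues chemically similar to their consensus, every residue keeps
  positive probability (so $\log\pi$ is finite), and profile recovery
  against $\log\pi$ is well-posed. The concentration 0.5 was fixed once as
  a realistic middle ground between near-delta conservation and uniform
  tolerance.
* `make_mutation_table()` emits mutation rows whose true ddG is a linear
  function of the sequence features, with configurable replicate and
  high-outlier injection rates for exercising curation, and
  `make_synthetic_feature_table()` produces feature tables with linear
  truth, optional pure-noise columns and protein-specific intercepts for
  probing the cross-validation machinery.

Passing tests on these fixtures demonstrate that the formulas, selection
rules and validation machinery are implemented correctly and that known
ground truth is recovered under controlled noise. They do *not* demonstrate
predictive accuracy on real complexes: the toy geometry has no side chains
beyond C-beta, template diversity is far narrower than a structure
database, and true ddG values in nature are not linear in any small feature
set. Problem sizes in the shipped tests and acceptance script (interfaces
of 20-24 residues, 50-template families, feature tables of 300-500 rows)
were chosen as the smallest sizes at which the statistical properties under
test are stable.

## Numerical choices and edge cases

* $d_0$ floors at 0.5 A so short interfaces keep a positive scale; the
  PCscore uses its fixed 4 A scale regardless of length.
* Scores are normalized by the *query* interface length; with a query and
  template swapped the score changes accordingly (the normalization side is
  configurable nowhere else, and reported alignments always name the
  query).
* Alignments with fewer than 3 pairs are reported with all scores 0 and an
  empty correspondence rather than an error.
* Cross-chain contacts use a 4.5 A heavy-atom distance, slightly looser
  than the 4.0 A interface depth, and are restricted to interface
  residues — so every contact endpoint is an interface residue and a
  self-alignment preserves every contact exactly ($f_i = 1$, Iscore 1).
* Positions no template covers fall back to the raw substitution-matrix
  difference for scoring, with sentinel quality features (distance 10 A,
  contacts 0, counts 0, JS 0, Z 0) so feature vectors stay finite and the
  forest can learn to discount them.
* Henikoff weights are computed over interface columns only (the alignment
  exists only there); gap cells contribute nothing.
* Relative accessibilities above 1 (possible for extended conformations
  against the Gly-X-Gly reference) are clamped to 1 for classification
  only; raw values are reported unchanged.

## Limitations

The profile score is linearly additive over mutation sites; cooperative
effects between simultaneous mutations (e.g. an engineered salt bridge
across the interface) are outside the model, which is also why curation
keeps only one-sided mutation entries. Only dimeric complexes are handled.
The alignment search is heuristic and sequence-order-dependent; permuted
(non-sequential) interface matches are not found. The complex TM-score used
for library redundancy is an approximation, documented above.
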