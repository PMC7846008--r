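---
title: "Soft disorder and interface analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft disorder and interface analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softdis)
```

## The problem

X-ray crystal structures carry two per-residue signals of structural
disorder. *Missing residues* (REMARK 465) are present in the construct but
unmodelled — classical "hard" disorder. *Soft disorder* is a milder signal:
residues whose Cα temperature factor (B-factor) is anomalously high for
their chain, indicating flexibility or a structurally amorphous
conformation that is still modelled. Because B-factors vary strongly with
resolution and refinement protocol, raw values are not comparable between
entries; each chain is therefore reduced to a z-score,

$$ b_i = \frac{B_i - \langle B \rangle}{\sigma}, $$

with the mean and standard deviation taken over all observed Cα B-factors
of that chain. A residue is *soft disordered* at threshold $\theta$ when
$b_i \ge \theta$; $\theta = 1$ is the working default, with 0.5, 2 and 3
available, and a static absolute-B variant is provided for comparison.

The same chain crystallised in different complexes exposes different
interaction interfaces. By grouping near-identical chains into clusters and
mapping every structure's annotations onto one reference sequence, the
package asks how the union of soft-disordered regions (USDR) relates to the
union of interface regions (UIR): whether soft disorder marks the surface
where interfaces are progressively accommodated.

## Per-structure annotation

* **Protein–protein interfaces.** Two residues are in contact when their Cα
  atoms are within 5.0 Å, inclusive. The inclusive comparison is a
  deliberate reading of the cutoff ("≤ 5 Å"); interfaces are computed within
  one entry (the asymmetric unit), and crystal-packing contacts are not
  filtered out.
* **Protein–nucleic-acid interfaces.** A residue binds a DNA/RNA chain when
  its accessible surface area decreases upon adding that chain. ASA is
  computed with a Shrake–Rupley implementation: heavy atoms only, a
  Bondi-style radius table, probe 1.4 Å, and 960 deterministic
  golden-spiral sample points per atom, so results are exactly
  reproducible. Since relative ASA divides by a positive per-residue
  constant, a relative decrease is equivalent to an absolute one; a
  tolerance of 0.1 Å² suppresses floating-point churn. Each nucleic partner
  is assessed separately (protein alone vs. protein plus that partner) and
  the per-partner sets are unioned — assessing the full complex instead
  would attribute occlusion by *protein* partners to the nucleic rule.
* **Missing residues** come from REMARK 465 and are interleaved with
  observed residues by author numbering; SEQRES, when present and
  consistent, supplies the sequence letters. Missing residues carry no
  B-factor, are excluded from $\langle B \rangle$ and $\sigma$, and can
  never be soft disordered.
* A chain is **bound** when it has at least one protein/DNA/RNA partner
  with a detected contact, and **unbound** otherwise.

Zero-variance chains (all B equal) get $b \equiv 0$: with no contrast there
is no evidence of relative flexibility. The population (divisor $N$)
standard deviation is used — the normalization is a descriptive rescaling
of one finite chain, not an inference about a larger population.

## Clustering and mapping

Chains with ≥ 90% sequence identity and ≥ 90% length ratio are grouped.
Identity is the number of identically aligned residues under global
alignment with match = 1, mismatch = 0 and no gap penalty (the scoring of
`pairwise2.globalxx`), divided by the shorter length; combined with the
length-ratio constraint this reproduces "nearly identical" grouping while
leaving the denominator choice — which the grouping criterion does not fix —
explicit. Clustering is greedy and seeded: chains are visited in order of
structure quality (resolution, then R-value, then label) and join the first
cluster whose seed satisfies both thresholds. This is deterministic,
makes the best structure the natural seed, and matches exhaustive
single-linkage whenever family structure is unambiguous (tested against a
brute-force oracle).

The representative is the member with the numerically smallest resolution,
ties broken by R-value, then label; a random-representative mode exists for
sensitivity analysis. "Best resolution or R-value" does not define a
combination rule, so the lexicographic (resolution, then R-value) reading
is fixed here. Every member's flags are transferred onto the representative
sequence through the same global alignment; among co-optimal alignments the
traceback prefers diagonal, then up, then left, which is deterministic and
keeps near-identical sequences on the diagonal. Positions aligned to gaps
are dropped. Non-standard residues (e.g. MSE) read as `X` for identity
purposes but keep their Cα and B-factor.

## Cluster-level regions

With members mapped to reference coordinates:

* **UIR / UMR / USDR(θ)** are at-least-once unions of interface, missing
  and soft sets.
* **IDR** (intrinsic disorder here): positions missing in *every* member
  whose alignment covers them. **DtO** (disorder-to-order): the rest of the
  UMR — missing somewhere, modelled elsewhere. By construction
  `UMR = IDR ⊔ DtO`, and DtO requires at least two members.
* **NDI** — the number of distinct interfaces. Two member interfaces are
  "the same" when their symmetric difference is at most 5% of the reference
  length (1% variant available). The minimal representative group is
  extracted greedily, largest interface first with lexicographic
  tie-breaks. The minimal-group objective is set-cover-like and the
  original procedure is unspecified, so a deterministic greedy is fixed
  here; an alternative (smallest-first) ordering changes the count by at
  most one on the synthetic families in the test suite, which is the
  documented sensitivity.
* **Interface hierarchy.** Distinct interfaces form a DAG: an edge A → B
  when B contains A up to the tolerance (`|A \ B| ≤ tol`) and adds at least
  `tol` material, with the transitive reduction applied. Requiring *at
  least* (rather than strictly more than) `tol` added material is the
  reading consistent with nested ladders whose steps sit exactly at the
  tolerance; for sets that are pairwise NDI-distinct both readings
  coincide. Edges strictly increase interface size, so the graph is acyclic.
* **Connected regions**: single-linkage components of a position set on the
  representative structure at a 6.0 Å Cα cutoff (checked against a
  breadth-first-search oracle). Positions without coordinates in the
  representative are skipped.
* **DtO interface frequencies**: per DtO position, the share of members in
  which it is modelled *and* at an interface, among members in which it is
  modelled, plus the fraction of DtO positions above 1/2.
* **Unbound USDR**: the soft union restricted to unbound members, for
  asking whether disorder seen before binding anticipates later interfaces.

## Scoring

USDR(θ) is scored against UIR per cluster with the usual confusion-matrix
metrics (Sen, Spe, Acc, PPV, and F1 as the harmonic mean of Sen and PPV).
The null model is a uniformly random placement of the same number of
predicted sites, which has closed-form expectations

$$ \mathrm{Sen}_r = r_D,\quad \mathrm{Spe}_r = 1 - r_D,\quad
   \mathrm{PPV}_r = r_I,\quad
   \mathrm{Acc}_r = r_D(2 r_I - 1) + (1 - r_I), $$

with $r_D$, $r_I$ the relative region sizes. Three randomization schemes
provide empirical nulls: per-member segment displacement before the union
(mode 1), uniform resampling of the union (mode 2), and segment-preserving
displacement of the union (mode 3); placements are rejection-sampled with a
10⁴-attempt cap and keep segments non-adjacent so that run lengths are
preserved exactly. Ratios of the form 0/0 (e.g. PPV of an empty prediction)
are reported as `NA` and excluded from medians rather than coerced to 0,
which would bias bins dominated by empty predictions.

Cluster statistics are summarised as binned medians with the standard error
of the mean from within-bin fluctuations. Integer keys (cluster size, NDI)
use doubling bins {1}, {2}, {3,4}, {5–8}, …, the closest reproducible
reading of the histogram binning; keys in [0, 1] (specificity) use 20 even
bins.

## The synthetic generator

Acceptance at the scale of the original study (tens of thousands of
clusters from the full PDB) is not reproducible at desk scale, so
correctness is established on synthetic families whose ground truth is
planted:

* A self-avoiding Cα trace (3.8 Å steps, ≥ 4.0 Å non-consecutive
  separation) shared by all members.
* A nested ladder of planted interfaces $I_1 \subset I_2 \subset \dots$
  (or disjoint patches), realised by partner chains positioned so that
  *exactly* the planted residues satisfy the 5 Å rule (protein partners) or
  lose surface area (DNA partners). Each planted increment exceeds the 5%
  NDI tolerance with a two-residue margin so that the planted count
  survives annotation transfer.
* One unbound member plus one bound member per interface (extras recycle
  the ladder). The member carrying $I_k$ gets +`delta_b` σ (default 3)
  added to the true normalized B at the residues of $I_{k+1} \setminus
  I_k$ — soft disorder anticipating the *next* interface to form, which is
  the hypothesis the pipeline is meant to detect. Raw B-factors are
  `30 + 8·b` Å².
* Missing segments are emitted as REMARK 465 in a configurable fraction of
  members (fraction 1 ⇒ IDR, intermediate ⇒ DtO); defaults plant one of
  each at the N-terminus.
* Members differ by random substitutions at 2% per residue, placed away
  from the planted patches (±2 residues) so the planted ground truth is
  invariant under alignment transfer; identity between members stays above
  the clustering thresholds.

What the generator does **not** emulate: real side-chain packing and
full-atom geometry (protein fixtures are Cα-only), crystal-packing
contacts, biological-assembly symmetry, correlated B-factor structure along
the chain, sequence-dependent disorder propensity, and heterogeneous
cluster sizes with the PDB's long-tailed distribution. Green tests
therefore demonstrate that the machinery is correct and that the planted
statistical structure is recovered — not that real proteins behave this
way.

## Problem sizes and determinism

The test suite and the acceptance script run at deliberately small scale:
clusters of 80–400 residues with up to 17 members, 100 clusters for the
set-algebra checks, 50 fixtures per oracle comparison, 10⁴ Monte-Carlo
draws for the baseline recovery, and NDI ladders up to 16. Every stochastic
operation takes an explicit seed; the pipeline re-run with the same
configuration and seed produces byte-identical reports.

## Known limitations

* mmCIF is not read; very large complexes distributed only as mmCIF are
  out of reach by design.
* Interfaces are computed in the asymmetric unit; no crystal-packing
  discrimination or biological-assembly reconstruction.
* Small-molecule (HETATM ligand) interfaces are deliberately ignored.
* The greedy minimal-group NDI is one deterministic choice among
  order-sensitive variants; counts should be compared across tools only
  with a ±1 allowance.
* External disorder predictors are not run; their per-residue outputs can
  be scored through `read_annotation_flags()` and the metrics machinery.
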