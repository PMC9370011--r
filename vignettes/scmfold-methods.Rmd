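---
title: "Primary-contact scanning with scmfold: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primary-contact scanning with scmfold: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmfold)
```

## The model

Under the sequential collapse model (SCM), folding of proteins longer than
roughly 100 residues is nucleated by an early, specific *non-local* contact
— the primary contact — between two short hydrophobic segments. Whether a
candidate pair of segments can serve as that nucleus is decided by a
three-term free energy, evaluated in the unfolded state:

$$
\Delta G_{\mathrm{cont}} =
\underbrace{-\frac{h_{i,w} + h_{j,w}}{0.45}}_{\text{hydrophobic stabilization}}
\;+\;
\underbrace{\tfrac{3}{2}\,\ln n_{ij}}_{\text{loop-closure entropy}}
\;+\;
\underbrace{1.09 \times 2w}_{\text{side-chain ordering}}
\qquad [kT]
$$

where $h_{i,w}$ is the Fauchère–Pliska hydrophobicity summed over a
$w$-residue window centered at residue $i$, $n_{ij}$ is the center-to-center
sequence separation, 0.45 scale units correspond to one $kT$ (with a stated
margin of about 0.1 $kT$ per conversion), and 1.09 $kT$ per residue is the
entropic cost of ordering the side chains of the $2w$ residues that form the
contact — at the default $w = 5$ this term is the familiar 10.9 $kT$
constant, which the code always derives from the per-residue cost rather
than hard-coding. Negative totals are stabilizing; reports print the
positive magnitude as the contact's *stability*, the sign convention of the
published contact tables.

Only hydrophobicity stabilizes a contact here: hydrogen bonds are weaker,
and disulfides and salt bridges form later along the pathway, so an early
contact formed from the unfolded state is modelled as hydrophobicity-only.

Admissible separations are bounded below by the optimal minimal loop,
$n_{ij} \ge n_{\mathrm{op}} \approx 65$ residues (shorter early loops are
entropically disfavored), and above by the maximum viable primary loop,
about 100 residues; both bounds are inclusive. The minimal fluctuating loop
of later folding phases ($n_{\min} \sim 15$) plays no computational role in
this package and is mentioned only for orientation.

## Tunable parameters

All scan tunables live in `scan_config()`:

| parameter | default | units | meaning |
|---|---|---|---|
| `width` | 5 | residues | contact window per segment; odd widths are centered, width 4 is accepted as a left-anchored special case (the center sits just left of the midpoint). Results are reported to be robust for widths up to 7, with some deviations at 4. |
| `min_separation` | 65 | residues | $n_{\mathrm{op}}$, inclusive lower bound on $n_{ij}$ |
| `max_separation` | 100 | residues | maximum primary loop, inclusive |
| `cutoff_kT` | 3.0 | kT | candidates more than this much less stable than the best are dropped; beyond it populations are an order of magnitude below the dominant channel |
| `sidechain_cost_per_residue` | 1.09 | kT/residue | side-chain ordering cost; the pair constant is $1.09 \times 2w$ |
| `loop_exponent` | 1.5 | — | coefficient of $\ln n_{ij}$ |

The window width default of 5 is taken as a configuration constant: the
geometric argument behind it (chain width ≈ 15.8 Å over a 3.5 Å peptide
bond, truncated to an integer) is rounding-ambiguous, so the package does
not attempt to re-derive it.

The 5-mer window sums come from `hydrophobicity_profile()`; windows are
summed left-to-right per window (not as cumulative-sum differences) so that
identical segments give bitwise-identical sums wherever they occur — this
keeps tie-breaking exactly reproducible.

## Selection of distinct contacts

Sliding a 5-residue window across a hydrophobic patch produces a plateau of
near-identical candidates. `select_primary_contacts()` therefore applies
non-maximum suppression: a candidate survives only if no better-scoring
candidate exists whose N-terminal *and* C-terminal windows both overlap its
own. Candidates sharing a single segment remain distinct contacts — on the
p53 core domain two selected contacts share the VVVPY segment, as the
published contact table also shows for its shared segments. Ranking ties
break deterministically: lower $\Delta G$, then smaller $n_{ij}$, then
smaller N-terminal center, then smaller C-terminal center. Nothing in the
model fixes a tie order; determinism is our requirement so that
byte-identical reports are testable.

Windows that would overhang a terminus are skipped, never padded.
Non-standard residue letters (X, U, B, Z) abort by default; a `"zero"`
policy assigns $h = 0$ with a warning, because silently zeroing letters
would bias $\Delta G$ without a trace.

## Channel populations

Contact stabilities map to relative folding-channel populations by
Boltzmann weighting of the stability magnitudes,
$p_k = e^{s_k} / \sum_m e^{s_m}$ (the maximum is subtracted before
exponentiation for numerical stability). No formula is attached to the
published percentages; this standard weighting is the unique choice that
reproduces all four printed percentages and the merged-channel value, which
is why the package adopts it.

```{r}
pops <- boltzmann_populations(c(8.9, 8.2, 7.8, 7.8))
round(100 * pops$fractions)
```

Confidence shifts are computed one contact at a time: contact $k$'s
stability is raised or lowered by its one-standard-deviation uncertainty
while all others stay nominal, and the signed change of $p_k$ is reported
in percentage points. Joint propagation of all four uncertainties does not
reproduce the published asymmetric intervals; one-at-a-time perturbation
does, which settles the design choice. The uncertainties themselves
(±0.3 kT for the top contact, ±0.4 for the rest on the p53 example) are
user-supplied inputs — the package does not re-derive them, because the
propagation from the ~0.1 kT per-conversion margin is not specified.

Contacts whose stabilities differ by at most `merge_tolerance_kT` are
grouped transitively into one apparent kinetic channel (`merge_channels()`):
equal-stability contacts break up on similar time scales and would not be
resolved as separate channels in a low-resolution kinetic experiment. The
two 7.8 kT contacts of the worked example merge into a ~31% channel. The
package models populations only, not traversal rates.

A deliberate configuration point: on the p53 core domain the population
stage consumes the *published* stabilities (8.9/8.2/7.8/7.8 kT) rather than
re-scanned values. The scan reproduces 8.9, 8.2 and 7.8 for three of the
four published contacts exactly, but scores the published VQLWV–YNYMC pair
at about 5.1 kT, not 7.8 — an irreproducible entry under the stated formula
and scale. The scanner reports what the formula yields (no special-casing,
no hard-coded table value); the pipeline accepts stabilities from either
source so the published populations can be reproduced from the published
energies.

## Interdiction analysis

Each selected contact yields two folding-interdiction designs
(`fitr_pairs()`): either segment may template the folding interdicting
peptide (FIP) while the other is the folding interdiction target region
(FITR). `map_peptide_to_contacts()` assigns an exogenous peptide to every
contact segment it covers as an exact substring (minimum overlap 5 by
default; a mismatch tolerance exists but defaults to 0), reporting both
interdiction modes — competing for the partner segment and masking the
matched segment itself — because which mode dominates is experimentally
open. Polymeric-seed interdiction is recorded as the same assignments with
a `seed` flag; no aggregate structure is modelled.

Two components are explicitly *model extensions* and labelled as such in
reports:

1. **Attachment score.** Intermolecular attachment closes no loop, so the
   score is the contact energy without the loop term:
   $-(h_{\mathrm{pep}} + h_{\mathrm{target}})/0.45 + 1.09 \times 2w$.
   Nothing in the source model quantifies intermolecular binding; this is
   the minimal consistent estimate and is always at least as favorable as
   the corresponding intramolecular contact.
2. **Redistribution.** `redistribute_populations()` scales the blocked
   channel by $1 - \varepsilon$ and reassigns the removed mass to surviving
   channels in proportion to their baseline Boltzmann weights. The
   efficiency $\varepsilon \in [0,1]$ is a free input — no binding
   constants are available to estimate it — and proportional partitioning
   is an assumption; blocked molecules could equally misfold directly. At
   $\varepsilon = 1$ the result coincides with Boltzmann weighting of the
   reduced stability list, a self-consistency the tests verify.

## Synthetic data and verification

`generator_spec()`/`generate_sequence()` produce i.i.d. background
sequences with optional planted segments, deterministic in their own seed
(the caller's RNG state is preserved). Backgrounds are i.i.d. by design —
the scan assumes nothing about local sequence correlation, so Markov
structure would add nothing the scanner is sensitive to. What the generator
does *not* emulate: real amino-acid composition bias, secondary-structure
propensity, or any 3D information. Passing the planted-pair and oracle
tests therefore shows the scanner is algorithmically correct, not that its
predictions are native contacts for arbitrary real proteins — the model's
empirical support comes from the worked example and the literature behind
it.

`oracle_scan()` is an independently coded brute-force path (explicit double
loop, per-residue summation, no shared helpers) used by the test suite to
verify the vectorized scan pair-for-pair on 100 random sequences of length
120–300, alongside planted-pair recovery across 20 seeds on polar
backgrounds and monotonicity checks of the energy in $h$ and $n_{ij}$.
These sizes keep the full suite to a couple of minutes on one CPU while
exercising every admissible-separation regime.

The built-in worked example (`p53_core_fixture()`) is the 204-residue
DNA-binding core domain of human p53, residues 94–297 of the canonical
sequence, carried with a numbering offset of 93 so every reported position
is in full-length p53 numbering. Because the analysis depends on exact
segment identities, the constructor asserts seven documented spans
(AMAIY 159–163, ILTII 251–255, VQLWV 143–147, VVVPY 216–220, YNYMC 234–238,
MFCQL 133–137, PILTIITL 250–257) and the domain length on every call, so a
transcription error in the embedded constant fails loudly rather than
silently shifting a window.

```{r}
fit <- scm_scan(p53_core_fixture())
fit
summary(fit, uncertainties = c(0.3, 0.4, 0.4, 0.4))
```

The scan's own fourth contact (MTEVV–ILTII, ~6.2 kT) sits within the 3 kT
reporting cutoff but more than 2.5 kT below the leader; it illustrates why
the cutoff is a reporting device, not a claim that everything above it is
kinetically relevant.

## Known limitations

- The energy model is hydrophobicity-only by construction; contacts
  stabilized by other interactions are invisible to it.
- Populations are equilibrium weights of nucleation events, not folding
  rates; no kinetic modelling is attempted.
- Native/non-native classification of contacts requires a 3D structure and
  is out of scope; the scan ranks by stability alone.
- The interdiction stage quantifies *which* contacts a peptide can reach
  and what the population bookkeeping implies, not binding affinity or
  aggregation kinetics.
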