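---
title: "Designing orthogonal switchable transcription terminators: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing orthogonal switchable transcription terminators: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swtdesign)
```

## The regulatory element

A switchable transcription terminator (SWT) is an RNA element placed between
a promoter and a reporter gene. Its transcript is, 5' to 3',

```
toehold (40 nt) | stem5 | loop | stem3 | poly-U
```

where `stem3 = revcomp(stem5)`. Left alone, the stem folds into a GC-rich
intrinsic-terminator hairpin followed by the poly-U tract, dissociating RNA
polymerase: the OFF state. A cognate *trigger RNA* — the reverse complement
of the toehold plus the stem 5' arm — nucleates at the single-stranded
toehold and displaces the hairpin by branch migration, letting transcription
continue: the ON state. Because the functional species are transcripts, the
whole package works on the RNA alphabet; DNA input is transcribed on read.

Coordinates are 0-based and half-open throughout, and all sequences are
written 5'→3'.

The historical reference stem-loop (the phage-derived T500 terminator: a
7-bp, all-GC stem with a small loop) is published only in supplementary
material that is not bundled here, so `swt_presets()` ships clearly labelled
*synthetic* stand-ins that reproduce the stated architecture rather than a
guessed sequence.

## Stem design space

The stem accepts substantial redesign: extending the 7-bp all-GC stem to
10 bp while allowing exactly one A-U/U-A pair keeps termination tight but
multiplies the number of admissible duplexes. Counting duplexes as
`choose(L, k) * 2^L` (a G/C or A/U letter choice per position, `k` non-GC
positions),

```{r}
stem_space_size(10, 1) / stem_space_size(7, 0)
```

an 80-fold expansion. We operationalize "90% GC, 10 bp" as *exactly one*
non-GC pair: the count above is exact under that reading, whereas "at most
one" would give 88-fold. The defaults of `design_constraints()` encode this
expanded regime (stem length 10, one non-GC pair); the designer samples a
fresh stem per candidate from this space, which is precisely what the
expansion is for — per-member stems decorrelate the triggers' stem segments
and improve orthogonality.

## The thermodynamic engine

All screening rests on a self-contained nearest-neighbor secondary-structure
model (`energy_model()`):

* Watson-Crick stack free energies at 37 °C are the published Turner-style
  values; G·U wobble stacks are a simplified Turner-style set (bundled as
  plain CSV under `inst/extdata/` with provenance notes).
* Hairpin, bulge and internal loops carry size-only penalties, extrapolated
  logarithmically (`dG(n) = dG(n_max) + 1.75·RT·ln(n/n_max)`) beyond the
  tables; the minimum hairpin loop is 3 nt.
* Multibranch and exterior loops are free; coaxial stacking, dangles and
  terminal-pair penalties are omitted; pseudoknots are excluded; a
  bimolecular complex pays a +4.09 kcal/mol initiation penalty; homodimer
  rotational-symmetry corrections are omitted (designed tubes never rely on
  homodimers).
* Temperature (default 310.15 K) only rescales `RT`; free energies are not
  split into enthalpy and entropy.

These simplifications mean absolute energies will not match a full
Turner-2004 implementation; the toolkit claims orderings and screens, not
calorimetry. Minimum-free-energy folding and McCaskill-style partition
functions for one or two strands are computed in C++ by dynamic programming
with an unambiguous (rightmost-branch) decomposition, so the partition
function counts every structure exactly once. Two-strand ensembles are
restricted to *connected* structures via the identity that a connected
complex has exactly one exterior branch spanning the strand nick — giving
the connected partition function as a product-sum without subtraction (and
hence without catastrophic cancellation). Loops containing the nick are
treated as exterior (zero energy, exempt from the minimum-hairpin rule).

Every recursion is validated against `enumerate_structures()`, an
exhaustive generator (guarded to 20 nt total) that evaluates each structure
with the independent loop-decomposition evaluator `structure_energy()`; an
interval-recursion counter cross-checks the enumeration itself.

### Test tubes

`equilibrium_concentrations()` solves the dilute-solution mass-action
equilibrium over monomers and dimers with association constants
`K = Q_dimer / (Q_a · Q_b)` relative to a 1 M standard state. The solver
uses a damped (geometric-mean) fixed point to approach the solution and a
Newton polish in log-concentration space to reach a relative mass residual
of 1e-12; tube results assert per-strand mass conservation to 1e-9. The
default tube puts each strand at 10 nM with a maximum complex size of 2 —
the screening conditions used for every crosstalk number in the package.

## What "activation" means here

The quantity of interest is the ON state of a switch. The naive
surrogate — the fraction of SWT bound in any duplex with the trigger — is
useless as soon as complementary stretches exceed ~15 bp: at 10 nM any such
duplex saturates to bound fraction 1.0 within double precision, so a
toehold-only trigger (which binds avidly but cannot displace the stem) would
be indistinguishable from a full trigger. `predicted_activation()` therefore
returns the equilibrium fraction of SWT that is *trigger-bound with the
terminator stem displaced*: the bound fraction times the conditional
probability, within the complex ensemble, that no stem5:stem3 pair is formed
(computed from a partition function with those pairs forbidden), plus the
(negligible) open fraction of free monomer. This is the in-silico analogue
of the ON mechanism: toehold-only and stem-only triggers score near zero,
full triggers score near one, and the ordering is robust. The literal bound
fraction remains available via `state = "bound"`.

## The design algorithm

`design_library(n, constraints, seed)` assembles mutually orthogonal
SWT/trigger pairs greedily:

1. **Candidate generation.** A toehold is drawn uniformly at the configured
   length (40 nt) inside the GC window (50-60%) and rejection-sampled until
   it has no predicted secondary structure; a stem arm is drawn from the
   configured stem space. Jointly satisfying the remaining constraints (the
   trigger must be linear; the SWT's own MFE must be the bare terminator
   hairpin with the toehold unpaired) is vanishingly rare for uniform
   random draws — the trigger carries a GC-rich stem complement next to the
   reversed toehold — so candidates are refined by a seeded mutation-repair
   walk: the defect `(-MFE_toehold) + (-MFE_trigger) + (E_hairpin -
   MFE_SWT)` is driven to zero by point mutations at positions involved in
   unwanted pairs, with the GC window and the stem composition held
   invariant. This mirrors how practical nucleic-acid design tools work
   (defect-directed mutation rather than blind rejection) and leaves every
   constraint exactly as stated.
2. **Filtering.** `check_candidate()` re-verifies all constraints,
   including that the complex MFE hybridizes the complete toehold+stem
   target region (the "completely hybridized" target complex).
3. **Greedy acceptance.** A candidate joins the library when its cognate
   activation is ≥ 0.90 and every cross activation against the accepted
   pairs — in both directions — is ≤ 0.05. Trigger-trigger ensemble
   energies below a configurable bound are surfaced as warnings (strong
   inter-trigger binding was an observed failure mode in practice).
   The sampling budget is 10,000 draws per slot; exhaustion raises a design
   error carrying the best partial library.

Everything is driven by the R RNG from a single seed, so a library, its
crosstalk matrix, and its FASTA/CSV/JSON exports are byte-reproducible.
`multi_tube_defect()` reports the concentration fraction allocated to
off-target complexes across the three declared tube categories (individual
constructs; every cognate pair; everything pooled). Homodimer formation in
individual tubes is reported by the defect score but is deliberately not an
acceptance threshold — the acceptance surface is the crosstalk matrix, whose
cognate tubes the homodimers cannot survive (cognate duplexes outcompete
them by tens of kcal/mol).

## Circuits

Circuit layers are matched by *sequence identity* of their signals, not by
name. `compose_cascade()` chains pairs so that layer *i*'s transcript
encodes layer *i+1*'s trigger; `compose_or_gate()` points two converter
switches at a common output trigger. `evaluate_circuit()` propagates a
Boolean threshold (`theta_on = 0.5` by default) over equilibrium
activations — the package deliberately does not simulate transcription
kinetics, which the underlying data do not constrain; `truth_table()`
iterates all input combinations, and `absent_layers` reproduces the
combinatorial knockout experiment (a cascade must go dark when any layer is
removed). `circuit_crosstalk_audit()` pools all circuit species in one tube
and flags non-cognate duplexes above the crosstalk threshold.

## Assay analysis

Plate analysis follows the standard normalization: the batch mean of the
no-template BACKGROUND wells is subtracted from every measurement
(`normalize_fluorescence()`), and the fold change is the normalized ON
replicate mean over the normalized OFF replicate mean, compared with a
Welch's *t*-test (`stats::t.test`, unequal variances). Two documented
choices: background subtraction uses the batch mean of all control wells
(the replicate controls are exchangeable); and a non-positive normalized
OFF mean makes the fold change an explicit error rather than a clamped
value — silent clamping fabricates dynamic range. Whether published fold
changes are replicate-mean ratios or means of replicate ratios is usually
unstated; the replicate-mean ratio is the default and `mean_of_ratios` is
exposed as an option. Endpoint analysis defaults to the 2 h timepoint.

`simulate_plate()` draws `mean × (1 + CV·N(0,1))` per well — multiplicative
noise because plate-reader error scales with signal; this is a fixture
choice, not an instrument claim. The generator emulates programmed ON/OFF
means, a shared background and replicate noise; it does not emulate
time-course kinetics, well position effects, or gain drift, so recovery
tests validate the statistics, not the instrument model. Note the ratio
estimator carries an intrinsic upward bias of roughly `CV_den^2` where
`CV_den` is the relative error of the normalized OFF mean; recovery
fixtures therefore program an OFF state well above background, a regime
where the bias is far below the 2% assertion used in the tests.

## Numerical choices and problem sizes

* Enumeration oracles run at ≤ 20 nt total; the test suite checks DP
  against enumeration on 200+ random monomers and dimers (Q to 1e-6
  relative, MFE exactly).
* Designed-library tests use n = 3 and n = 5 at the default constraints;
  these sizes exercise every code path (greedy rejection, both crosstalk
  directions, warnings) while keeping a full run in minutes on one core.
* MFE ties are resolved by the deterministic traceback order of the dynamic
  program; candidate ties never arise because acceptance is sequential.
* Equilibrium tolerances: 1e-12 solver residual, 1e-9 asserted mass
  conservation, 1e-6 agreement with the two-state closed form.

## Known limitations

* Energies are a simplified Turner-style set: no dangles, no coaxial
  stacks, size-only internal loops. Orderings are reliable; absolute ΔG is
  not guaranteed to match other engines.
* Complexes are capped at two strands; co-transcriptional folding,
  kinetics, and pseudoknots are out of scope.
* Activation is an equilibrium surrogate; it cannot predict fluorescence
  magnitudes or wet-lab fold changes, only orthogonality structure and
  logic-level behavior.
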