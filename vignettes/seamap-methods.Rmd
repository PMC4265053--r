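---
title: "Models and methods: degenerate RBS library design and sequence-expression-activity maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models, the tunable parameters and why their defaults are what they are, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations. It states no empirical result that the
test suite does not itself compute.

## Translation initiation thermodynamics

A bacterial 30S ribosomal subunit binds an mRNA around a start codon; the
total Gibbs free energy change of that binding event is modeled as five
terms,

$$\Delta G_\mathrm{total} = \Delta G_\mathrm{mRNA:rRNA} + \Delta G_\mathrm{start}
 + \Delta G_\mathrm{spacing} + \Delta G_\mathrm{standby} - \Delta G_\mathrm{mRNA},$$

the final (ribosome-bound) state minus the initial (folded mRNA) state. The
initial state's folding energy $\Delta G_\mathrm{mRNA} \le 0$ is subtracted;
in the final state the last nine nucleotides of the 16S rRNA (the
anti-Shine-Dalgarno tail) are hybridized to the mRNA and any mRNA structure
clashing with the hybrid or with the ribosome footprint is kept unfolded.
Translation initiation rate follows a Boltzmann-like law
$r = 2500\,\exp(-0.45\,\Delta G_\mathrm{total})$ on a proportional `au`
scale: 0 kcal/mol maps to 2500 au and physiological sequences span roughly
0.1 to several million au.

Candidate 16S binding sites are enumerated as all 9-nt windows whose aligned
spacing to the start codon lies in $[0, 20]$ nt; each candidate's energy is
its hybridization energy plus the constrained refold of the remaining mRNA
plus the spacing penalty; the minimum-total candidate is selected. Ties are
broken toward the spacing closest to the 5-nt optimum and then the
most-upstream site, so predictions are deterministic. Coordinates are
0-based half-open internally; "aligned spacing" counts the nucleotides
strictly between the 16S pairing window and the start codon.

Parameters of `ribosome_model()`, with defaults and rationale:

* `beta = 0.45` mol/kcal — the apparent Boltzmann constant of the rate law.
* `rate_scale = 2500` — the proportionality constant anchoring the au scale.
* `optimal_spacing = 5` nt; the distortion penalty is quadratic
  (`0.4 (s-5)^2` kcal/mol) on the compressed branch and saturating
  (`6 d^2/(d^2+16)`) on the stretched branch. The penalty's measured shape is
  not reported numerically, so these coefficients are configuration, not
  ground truth; the penalty is zero at the optimum and non-decreasing away
  from it by construction, which is the property the design algorithm
  actually uses.
* `start_codon_energies`: AUG = GUG = −1.19, UUG = −0.37, CUG = 0 kcal/mol.
  Only the ordering (AUG and GUG most negative) is established; values are
  configuration.
* `dG_standby = 0` with a configurable hook — structured-standby-site
  energetics are deliberately out of scope.
* `footprint = 13` nt of coding sequence held unfolded in the bound state.

Two folding engines satisfy one contract (`mfe_fold`, `hybridize`):
`vienna_engine()` shells out to the ViennaRNA suite (`RNAfold -C` with hard
single-stranded constraints; `RNAduplex` for the mRNA/anti-SD duplex), and
`toy_engine()` is a deterministic closed-form stand-in (folding energy
proportional to G+C content outside the constrained region; hybridization
proportional to Watson-Crick matches in the antiparallel alignment).
Algorithmic unit tests run on the toy engine so they test the pipeline's
logic, not nearest-neighbor parameters; the ViennaRNA adapter has its own
contract smoke tests. Swapping engines changes energies but may violate no
postcondition — that is itself a tested property.

## Degenerate libraries and the design objective

A degenerate RBS uses the 16-letter IUPAC alphabet; its variant count is the
product of per-position code cardinalities. T and U are normalized to one
internal RNA alphabet; expansions are deduplicated and lexicographic so
outputs are byte-reproducible; above 10^6 variants (10^4 inside the
optimizer) expansion is refused in favor of seeded uniform sampling, and
subsampled evaluations are flagged.

The targeted rate axis $[r_\mathrm{min}, r_\mathrm{max}]$ is discretized
into $B_\mathrm{total} = \lceil \log_{10}(r_\mathrm{max}/r_\mathrm{min})/W
\rceil$ bins; bin centers sit at $r_\mathrm{min}10^{W(k+1/2)}$ (center
placement is our choice; only the fill window is prescribed), and a bin at
$y$ is filled by a rate in $[y/10^W,\ y\,10^W]$, boundaries inclusive.
Windows are twice the bin width, so adjacent windows overlap and one variant
can fill neighboring bins. The objective is $F = C - 0.02\,N$; the 0.02
weight is a named constant (`variant_penalty`).

The genetic algorithm draws operators at 40% recombination / 15% increase
degeneracy / 15% decrease degeneracy / 15% substitution / 10% unmodified /
5% fresh random, with fitness-proportional parent selection on
$F - \min F + \epsilon$ (the shift is our choice; only proportionality is
prescribed). Within-operator choices (which superset or subset code, which
junction) are uniform among eligible options. The incumbent best individual
is always carried into the next generation, so the best objective is
monotone. Termination: objective at its maximum $1 - 0.02B_\mathrm{total}$,
stagnation (default 50 generations), or an iteration cap (default 500).
Population defaults to 100. Genome-editing mode initializes from the
wild-type RBS and enforces feasibility — all differing positions inside one
contiguous window of at most `max_window` nt — as a hard constraint with
redraw, rather than a penalty, because no penalty weight is prescribed and a
hard constraint guarantees every returned solution is realizable by a single
editing oligo. Zoom mode is a pure re-parameterization (narrower range,
smaller $W$); there is no separate code path.

## The crtEBI kinetic model

The pathway converts the boundary precursors IPP and DMAPP to neurosporene
through Idi, IspA, CrtE, CrtB, and CrtI. Ten overall reversible conversions
are decomposed into reversible elementary steps — substrate binding,
bound-state conversion where applicable, product release — yielding exactly
24 reversible elementary reactions and 48 rate constants, with one mole
balance per enzyme. Prephytoene exists only enzyme-bound (processive CrtB),
which is what keeps the count at 24. This decomposition is pinned by the
reported aggregate counts, not by a species-level diagram; with it the model
has 29 species (9 metabolites, 5 free enzymes, 15 complexes). A printed
count of 24 species cannot be reconciled with 24 elementary reactions and 10
conversions under any standard chain decomposition we could construct; the
network ships with its own species count documented and serialized in
`inst/extdata/crtebi_network.txt`.

Concentrations are de-dimensionalized as ratios to a reference pathway
variant, so a variant is specified entirely by its enzyme concentration
ratios: transcription multiplier times the ratio of its translation rates to
the reference rates (72268, 20496, 203462 au for crtE, crtB, crtI). Idi and
IspA are host enzymes, fixed at ratio 1. The choice of reference
concentrations only rescales apparent parameters; `simulate_pathway()`
exposes that rescaling (`ref_scale`) precisely so the invariance is
testable, and the test suite holds it to 1e-6.

Numerics: lsoda (stiff) with relative tolerance 1e-8 and absolute 1e-10
over a 7-hour batch horizon matching the culture period; the production flux
$r_p$ is end-point neurosporene divided by 7 h, and productivity is
$196\, r_p / r_{p,\mathrm{ref}}$ µg/gDCW/h. Initial conditions: boundary
precursors at the supply level, free enzymes at their total ratios,
everything else at zero. Boundary precursors held constant make the
precursor-supply sweep a single knob (an option for finite pools exists in
the network representation by clearing the boundary flags). The right-hand
side is compiled C driven entirely by the parameter vector (structure,
constants, boundary flags, scales). Halving tolerances changes $r_p$ by well
under 0.1%; enzyme totals are conserved to better than 1e-6 relative.

## Parameter reduction and identification

Of the 48 constants, 10 are eliminated by one detailed-balance relation per
conversion — the reverse constant of each conversion chain's last elementary
reaction is determined by the chain's overall equilibrium constant — and 5
are pinned to configured values (the first substrate-binding forward
constant of each enzyme, taken diffusion-limited at 100 in dimensionless
units). Which constants are eliminated or pinned is configuration
(`reduction_map()`), documented and versioned; changing the map cannot
change the 33-free-parameter contract. Overall equilibrium constants default
to 50 per conversion (forward-favorable, as expected for prenyl
condensations and desaturations); they are configuration, not fit targets.

Identification minimizes the mean relative error between predicted and
measured productivities over the non-reference variants (the reference row
anchors the normalization and carries no residual; the metric is therefore
scale-invariant). The optimizer works in log10 parameter space within
[−4, 4]: a real-coded genetic algorithm followed by a bounded
Levenberg-Marquardt polish of the best individual. Three numerical choices
matter and are deliberate:

* The optimizer's residuals are clipped log prediction ratios
  $\log(\hat p / p)$ rather than raw relative errors: where a poor parameter
  set collapses predictions toward zero, the relative error saturates at 1
  and carries no gradient, while the log residual still points uphill. The
  reported fit metric remains the mean relative error.
* GA individuals are initialized coarse-to-fine: most draws share one
  forward-rate and one reverse-rate log-level across reactions (plus
  per-parameter jitter), the rest are fully random. Elementary rate
  constants within one pathway are far closer to each other in magnitude
  than to the full prior range, and the structured draws let a small budget
  find the right basin; the LM polish then moves all 33 coordinates freely.
* The LM finite-difference step (`epsfcn = 1e-6`) is set above the ODE
  solver's noise floor at the fitting tolerances (rtol 1e-6), without which
  the numerical Jacobian is noise. Fitting simulations also cap solver steps
  so pathological parameter draws fail fast and are penalized rather than
  stalling the fit.

Runs are independently seeded (default ten); per-run best errors and the
cross-run dispersion of the identified log-parameters are reported as a
uniqueness diagnostic. A permuted-productivity refit on the same budget is
the null check: a well-defined model should fit shuffled data far worse, and
the acceptance suite requires at least 3× worse.

## The synthetic-data generator

`generate_variant_dataset()` defines the simulated study conditions: 73
design points (matching the characterized library scale), translation-rate
triples scattered log-uniformly over the characterized per-gene ranges
(crtE 445–72,000; crtB 3–20,000; crtI 97–203,000 au) with the reference
rates included, productivities simulated under a known parameter set,
multiplicative lognormal noise at a chosen CV (0 for the recovery study),
the row closest to the reference rates flagged as reference, and all rows
renormalized through the flux-to-productivity anchor so the reference reads
exactly 196 µg/gDCW/h. The default "true" parameter set is role-structured
(free forward constants 40, free reverse constants 20, bindings pinned at
100, conversion equilibria 50): release steps are appreciably reversible, so
excess enzyme re-captures its product and sequesters intermediates as
complexes — this is what gives the activity landscape interior optima along
each enzyme axis and makes induction response curves rise and then fall.

What the generator does not emulate: measurement-count structure (technical
replicates), growth-condition and media effects, toxicity or burden,
RBS-sequence errors from synthesis bias (sampling of degenerate positions is
uniform), or any mismatch between the fitted network and the data-generating
network. Passing the recovery study therefore shows the estimator is
consistent under the model's own assumptions at the study's scale — not that
the model family is correct for any real pathway.

## Downstream analyses

Flux control coefficients are central finite differences of
$\ln(\mathrm{productivity})$ with respect to $\ln(\mathrm{enzyme\ ratio})$
(default 1% relative step, validated by step-halving) rather than analytic
sensitivities — simpler and network-agnostic. Two batch-model caveats are
measured rather than hidden: in deeply enzyme-limited regimes an enzyme
catalyzing $k$ sequential conversions shows FCC $\approx k$ (the classical
single-step proportional limit, FCC = 1, is recovered on a single-conversion
network, and tested there); and the steady-state summation theorem holds
only as a band here — the suite checks $\sum \mathrm{FCC} \in [0, 1.05]$ at
moderately expressed interior points. Similarly, end-point flux under fully
irreversible kinetics is non-decreasing in each enzyme except for a
percent-level finite-horizon exception at the GGPP dimerization step, where
extra CrtB ends the batch holding more half-loaded complexes; the tests
document both.

The induction model is a Hill function (basal, max, K, n) mapping inducer to
a transcription multiplier — the exact induction model form is
not printed, and a configurable Hill captures the monotone saturating shape.
Evolutionary-landscape sampling draws mutation positions uniformly over the
105 RBS nucleotides and replacement bases uniformly over the three
alternatives (the mutation distribution is unspecified; uniform is the
neutral choice), re-predicts translation rates only for mutated genes with
caching, and reports the productivity-ratio histogram and the fraction of
mutants that decreased productivity. Under the toy engine some substitutions
are exactly rate-neutral (they change neither G+C content in the folded
region nor the matched 16S window), and neutral mutants count as
non-decreasing, which makes the tested ">50% decrease" bound conservative.
`zoom_target()` grid-searches an expanded log-box around the current best
variant and returns the per-gene windows spanned by the top decile of
predictions, formatted for a Zoom-mode design; applied repeatedly it shrinks
or stabilizes.

All downstream outputs carry a hash of the parameter set so tables and plots
are traceable to one identified model.

## Problem sizes used by the test suite

Deliberate desk-scale choices, stated here as the package's own: GA-vs-brute
force comparisons enumerate the full 15^3 degenerate design space of
length-3 sequences against 20 seeded GA runs; the recovery study uses the
73-point noiseless dataset with 3 identification runs (GA population 30,
4 generations, LM capped at 8 iterations) and a 10-variant held-out grid;
landscape histograms use 10^4 samples per mutation count. These sizes keep
every study comfortably reproducible on a single CPU while leaving the
algorithms' asymptotic behavior (more GA budget, more runs, larger samples)
available to users through the exported knobs.

## Known limitations

* The spacing-penalty coefficients and start-codon energies are plausible
  configuration values, not fitted constants; absolute rate predictions
  under the ViennaRNA engine should be read as proportional-scale, not
  calibrated, values.
* The standby-site term defaults to zero; long highly structured 5' UTRs are
  outside the model.
* The kinetic model predicts sequence-dependent productivity changes only —
  no growth feedback, toxicity, media or aeration effects.
* The canonical network's species-level decomposition is pinned by aggregate
  counts (24 reactions / 48 constants / 10 conversions / 5 balances), and
  its 29-species count is documented as deviating from the printed 24.
* Identification recovers a predictive map, not unique parameters: the model
  is sloppy, many parameter sets fit equally well, and the cross-run
  dispersion diagnostic is there to make that visible.
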