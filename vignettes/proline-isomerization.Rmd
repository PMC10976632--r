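---
title: "Coupled proline cis-trans isomerization with bias-potential replica exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled proline cis-trans isomerization with bias-potential replica exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbpremd)
```

## The problem

The peptide bond preceding a proline residue is the only backbone amide
that populates both its trans (omega near 180 degrees) and cis (omega
near 0 degrees) isomers to an appreciable degree. Interconversion
crosses a barrier of roughly 20 kcal/mol and therefore happens on
timescales of seconds to minutes -- far beyond what straightforward
sampling can reach. In peptides with several prolines, such as the
nonapeptide bradykinin (prolines at positions 2, 3 and 7), the cis/trans
states of the residues are moreover *coupled*: the isomerization free
energy of one proline can change by more than 2 kcal/mol depending on
the isomers of the others.

`wbpremd` implements the analysis machinery for studying this coupling
with a Hamiltonian replica-exchange scheme (bias-potential replica
exchange on the omega torsions) and validates every estimator on a
reduced model whose exact answers are known. The package covers:

* the reduced three-dihedral model Hamiltonian and its exact quadrature
  oracle (`model_potential()`, `quadrature_state_probabilities()`,
  `calibrate_model()`);
* the replica ladder, Metropolis Monte Carlo propagation and
  configuration exchanges (`replica_ladder()`, `mc_propagate()`,
  `run_wbp_remd()`);
* histogram reweighting of the biased replica and all free-energy
  estimators (`histogram3d()`, `unbias_density()`,
  `free_energy_table()`, `conditional_dG()`, `block_sem()`);
* sampling diagnostics (`label_states()`, `running_mean_states()`,
  `transition_rate()`, `state_correlation()`);
* structural observables (`noe_violation()`, `detect_hbonds()`,
  `rank_features()`, `cluster_conformations()`).

## The model

Each prolyl peptide bond contributes four dihedral-angle energy terms
(Ca-C-N-Ca, O-C-N-Ca, O-C-N-H, Ca-C-N-H). Under rigid co-rotation of
the planar peptide unit these sit at omega + {0, 180, 180, 0} degrees,
and with multiplicity 2 and phase 180 degrees all four terms coincide,
so the per-bond profile is

$$U_\mathrm{tors}(\omega) = 4\,V_{\chi,2}\,[1 + \cos(2\omega - 180^\circ)],$$

with equal minima of zero at 0 and 180 degrees and a barrier of
$8 V_{\chi,2}$ at $\pm 90^\circ$ -- 20 kcal/mol at the physical force
constant $V_{\chi,2} = 2.5$ kcal/mol. The amplitude convention is fixed
by that barrier height, which is why the package validates
`eval_physical_torsion()` against it exactly.

A real solvated peptide makes the eight cis/trans octant states
(labelled TTT ... CCC over Pro2, Pro3, Pro7) energetically inequivalent.
The reduced model emulates this with a smooth coupling term: each state
$s$ carries an offset $e_s$ weighted by a switching function built from
$\cos^2(\omega/2)$ factors, which partitions unity over the eight states,
is periodic and is ~1 deep inside the corresponding octant. The exact
functional form is immaterial as long as the calibration below
converges; the $\cos^2$ product was chosen as the simplest smooth
partition of the three-torus.

Because the switching function leaks slightly across octant boundaries,
the offsets are *calibrated*: `calibrate_model()` iterates
"offset += free-energy residual" against the midpoint quadrature oracle
(default 120 points per axis; refining the grid changes state
probabilities by less than 1e-6) until the octant free energies match
the targets to better than 0.005 kcal/mol -- twice as tight as the
0.01 kcal/mol contract the recovery tests rely on. The default targets
are the bradykinin reference table chained from reported conditional
isomerization free energies (`bk_state_table()`), which makes the
ground truth of every downstream estimator the reported physics.

Constants: $k_B = 0.0019872$ kcal/(mol K), default temperature 300 K
($k_B T = 0.5962$ kcal/mol), angles in degrees on $[-180, 180)$
throughout.

## Sampling scheme

The replica ladder scales the torsion force constant linearly from 2.5
kcal/mol (replica 1, physical) to 0 (replica 12, free rotation). All
replicas additionally carry a one-fold cosine bias
$\sum_i V_\omega [1 + \cos(\omega_i - 180^\circ)]$ with
$V_\omega = 1$ kcal/mol, which penalizes the otherwise dominant
all-trans state by 2 kcal/mol per residue and balances cis/trans
sampling. Whether the bias magnitude should differ between replicas is
not specified by the scheme; the package uses the same value
everywhere, which is the simplest choice and cancels exactly in
exchange attempts.

Dynamics is Metropolis Monte Carlo rather than molecular dynamics: one
sweep proposes a wrapped-Gaussian move (default sigma = 20 degrees) for
each of the three angles. This sampler is exactly Boltzmann (verified
against the quadrature oracle in the tests) and is entirely adequate
because only equilibrium populations, not kinetics, are analysed.
Exchange attempts between neighbouring replicas occur every 250 sweeps,
alternating even and odd pairs, and swap *configurations* (replica
identity stays with the Hamiltonian). Frames are saved every 10 sweeps.
Observed neighbour acceptance rates for the calibrated bradykinin model
are around 25-95%; they are reported (`tidy()` on the run object) but
not asserted, since they depend on the model.

Replica 1 samples the physical torsion potential plus the bias; it is
the sole analysis input. The un-exchanged single replica stays trapped
in its starting isomer state over any practical run -- the tests
demonstrate both this and the frequent cis/trans transitions that
exchanges deliver.

## Unbiasing and free energies

The replica-1 frames are binned into a $50^3$ histogram over the
three-torus (bin width 7.2 degrees). The biased density is reweighted
bin-by-bin with $\exp[+\beta V_\mathrm{bias}(\text{bin centre})]$ and
renormalized; the additive free-energy constants of the biased and
unbiased ensembles are absorbed by the renormalization. Evaluating the
bias at bin centres rather than bin averages incurs a negligible error
at this bin width (the test suite checks the full round trip against
the quadrature density to a few percent per bin at $10^6$ samples, and
a bin-averaged reference is available via
`density_from_model(supersample = )`).

State probabilities integrate the unbiased density over the eight
$\pm 90^\circ$ octants with composite Simpson's rule on the bin-centre
ordinates. With 50 bins the octant boundaries fall exactly on bin
centres; those shared boundary ordinates serve as endpoints of both
adjacent Simpson ranges (an even split), so the eight integrals
partition the torus and are normalized by their own total -- the
probabilities sum to one exactly. This construction requires the number
of bins to be 2 modulo 4; the default 50 satisfies it, and other values
are rejected with an informative error rather than silently
mis-assigning boundary bins.

Free energies follow by Boltzmann inversion,
$G(\text{state}) = -k_B T \ln P(\text{state})$, shifted so that
G(TTT) = 0. Kinetic and pressure-volume contributions are omitted
throughout (only configurational variables change). Empty octants get
probability 0 and free energy $+\infty$ with a warning -- never a crash
and never silent smoothing; plots cap the infinity for display only.
If the reference state itself is empty the shift falls back to the
lowest sampled state, again with the empty-octant warning.

Projections (`project_density()`) sum over dropped axes times the bin
volume; one-dimensional marginals feed the potential of mean force
(`pmf_1d()`) and the marginal isomerization free energy, and the full
3D density feeds the conditional one:

* marginal: $\Delta G_{c \to t}(i) = -k_B T \ln[P_i(\text{trans half}) /
  P_i(\text{cis half})]$, an ensemble average over the other residues'
  states;
* conditional: the same ratio with the other two residues fixed in
  prescribed octants, i.e. the free-energy difference of the two
  involved octants.

**Sign convention.** $\Delta G_{\mathrm{cis}\to\mathrm{trans}} =
G_\mathrm{trans} - G_\mathrm{cis}$: negative when trans is favored. For
the bradykinin reference table, Pro2 with both others trans gives
$-4.09$ kcal/mol (4.09 kcal/mol must be invested to switch Pro2 to
cis), and Pro7 with Pro2 cis / Pro3 trans gives $+0.89$ kcal/mol -- the
single condition that favors a cis proline. The chaining of the
reference conditionals into the state table pins this convention in a
regression test, including the coupling shifts $\Delta\Delta G$ (e.g.
2.51 kcal/mol for Pro2 when Pro7 switches to cis at Pro3 trans).

The reference table carries a known rounding caveat: the chained CCC
entry is 5.74 vs the directly reported 5.75, and CTC (3.20) was
reported as "about 3.3"; inputs are printed at two decimals, so closure
residuals up to ~0.02 kcal/mol are expected and asserted, not hidden.
A related, unresolved discrepancy in the source data itself -- CTT from
reported state probabilities (~3.67 kcal/mol) vs from the conditional
chain (4.09) -- is left as is: both routes exist in the package and
neither is "corrected". The calibration targets use the conditional
chain, as the reconstruction prescribes.

Statistical errors are 5-subset block errors: the whole analysis is
repeated on five contiguous fifths of the trajectory and the SEM of the
block values, $\mathrm{sd}/\sqrt{5}$, is attached
(`analyze_replica1()`, `block_sem()`). No autocorrelation-time or
multi-replica (WHAM/MBAR) machinery is provided; the scheme unbiases
replica 1 only.

## Diagnostics

`label_states()` implements both labeling conventions: half-width 90
degrees (every frame labeled; used for octant integration, where
replica-1 cis/trans populations are well separated) and the stricter
half-width 45 degrees used to filter state-specific trajectories, which
leaves barrier-top frames unassigned. The running mean of isomerization
states (trans = 1, cis = 0) over 100-frame windows hovers near 0.5 when
sampling is balanced; window edges are truncated rather than dropped
(the windowed-mean definition is silent on edges, and truncation keeps
the series frame-aligned). Transition rates count label changes between
consecutive assigned frames -- by default no transition is scored
across an unassigned gap -- and the labeling half-width for rate
counting defaults to the 90-degree convention with the stricter one a
flag away. Pearson correlations of the binary state series detect
collective switching; values near zero certify that the residues'
isomerizations decorrelate.

## Structural observables

These operate on precomputed geometric time series in long/tidy form
(distances and donor-H-acceptor angles per frame), not on atomistic
trajectories: extracting geometry from coordinates is outside the
tested core.

* NOE violations: $\Delta_{ij} = \langle r_{ij}^{-6}\rangle^{-1/6} -
  d_{ij}^\mathrm{NOE}$ with upper bounds 3.0/3.5/4.0/4.5 A for
  strong/medium/weak/very-weak intensities; positive means violated.
  The inverse-6th-power average is monotone in every frame's distance
  and equals the distance for constant series -- both are asserted.
* Hydrogen bonds: donor-H-acceptor angle >= 135 degrees and
  donor-acceptor distance < 3.0 A (3.5 A as the looser occupancy
  criterion), with per-state occupancy bookkeeping.
* Feature ranking: donor-acceptor distances are scaled as
  $d_\mathrm{scaled} = (d - 1.8\,\mathrm{A})^2$ and ranked by
  impurity-based importance of a random forest classifying the eight
  isomer states (`ranger`, classes weighted inversely to frequency to
  counter imbalance; the weighting choice is ours, the class count is
  the eight states).
* Clustering: hierarchical density-based clustering with minimum
  cluster size 500, run on the top-k ranked features (k = 20 by
  default; neither k nor the remaining clustering parameters are
  prescribed, so they are documented defaults, not asserted constants).
  The implementation is the package's own: core distances to the
  `min_samples`-th neighbour (default 10), mutual-reachability single
  linkage, condensed tree with excess-of-mass cluster selection, and no
  single-cluster solutions -- uniform noise therefore yields zero
  clusters, and sub-threshold blobs are never reported. It holds the
  full distance matrix in memory and is intended for the $10^3$--$10^4$
  frame scale used here.

## What the synthetic data does and does not show

The package generates all of its own inputs. The i.i.d. sampler draws
frames directly from the quadrature-tabulated density (inverse CDF on
the flattened grid with in-bin jitter), isolating estimator correctness
from sampler mixing; the Monte Carlo path then exercises mixing
separately. Geometry fixtures plant hydrogen-bond occupancies exactly
(non-contact frames are kept above 3.8 A so the planted fraction is
recovered under both distance criteria), NOE channels with closed-form
violations, feature matrices with known informative columns, and
well-separated Gaussian blobs for clustering. Every planted quantity is
returned alongside the data, so the tests never need external inputs.

Passing these tests shows that the estimators are correct and that the
replica-exchange machinery recovers known state free energies through
the full simulate-reweight-integrate pipeline. It does *not* show
anything about explicit-solvent peptide dynamics: the reduced model has
no atoms, no solvent and no realistic kinetics. Quantities tied to the
real solvated peptide -- transition rates per nanosecond, biased state
percentages, the Pearson correlations of a particular trajectory,
per-restraint NOE violations of bradykinin ensembles -- are emulated
qualitatively at most and are deliberately not asserted quantitatively.

## Problem sizes and numerical choices

The recovery analyses in the test suite run 12 replicas for
$5 \times 10^5$ sweeps ($5 \times 10^4$ saved frames) and the
acceptance script for $10^7$ sweeps per replica ($10^6$ saved frames);
both complete in seconds to about a minute on a single core thanks to
the compiled sampler. The run length for the acceptance analysis was
chosen from a variance consideration: the rarest octant (CTT,
equilibrium probability ~0.1%, biased ~0.25%) is visited in episodic
bursts whose count -- not the raw frame count -- controls the error of
its log-probability, and of order $10^6$ frames are needed to bring the
3-SEM band of the Pro2 conditional below a few tenths of a kcal/mol.
Tolerances elsewhere follow the propagated statistics (3 standard
errors for sampled quantities, with block SEMs from the run itself) or
the stated contracts (0.01 kcal/mol calibration, 1e-6 quadrature
convergence, exact recovery for planted bookkeeping quantities).
Degenerate inputs fail loudly: empty trajectories, zero-weight
densities, unknown state labels, non-positive temperatures and missing
seeds are all errors, and every stochastic entry point requires an
explicit seed.

## A complete run

```{r pipeline, eval = FALSE}
model <- calibrate_model(bk_state_table())
run <- run_wbp_remd(model, replica_ladder(), n_sweeps = 1e6, seed = 1)
analysis <- analyze_replica1(replica1(run), bias_force_constant = 1)
analysis$fe                    # state probabilities and free energies
analysis$conditionals          # twelve conditional dG values with ddG
autoplot(analysis$fe)          # free-energy bar chart
autoplot(analysis$density)     # projected 2D free-energy surface
```

`run_pipeline()` wraps the same flow behind a YAML-configurable entry
point that writes tab-separated outputs with JSON twins, each stamped
with the package version, a configuration hash and the seed; reruns
with the same seed are bit-identical. A thin command-line wrapper lives
in `inst/cli/wbpremd`.

## Known limitations

* The model is a three-torus caricature: it reproduces state
  thermodynamics by construction, not mechanism, geometry or kinetics.
* Only replica 1 is unbiased; samples in replicas 2-12 are used solely
  for mixing (no multi-ensemble reweighting).
* Error bars are 5-block SEMs; for quantities dominated by a few rare
  episodes they can themselves be noisy (the CTT octant is the
  documented example, with a propagated-SEM fallback when a block is
  empty).
* The clustering implementation is quadratic in memory and time with
  frame count; beyond a few times $10^4$ frames, subsample.
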