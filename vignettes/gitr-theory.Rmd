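---
title: "Rate theory for multi-state self-assembly networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate theory for multi-state self-assembly networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gitr)
```

## The problem

Self-assembling protein systems often support several distinct bound
states — alternative dimer interfaces, ligand-bound and ligand-free
arrangements — connected by transformation paths that pass through
free-energy maxima. Given per-state binding free energies (from MM-PBSA
or experiment) and barrier heights (from steered MD or otherwise), one
wants the relative rates of the competing paths and the time evolution
of the state populations. `gitr` implements a transition-state-theory
treatment of this problem on an arbitrary finite bipartite network of
stable states and transition states.

Three physical assumptions underlie the model:

1. every transformation between two stable states passes through exactly
   one transition state (if two maxima lie on a path, a stable state can
   be inserted between them);
2. transition states are high-energy and low-concentration, so they hold
   no population of their own;
3. inter-state transformation follows first-order kinetics — the
   rate-determining step is the activation of monomers out of a stable
   state, not the multi-monomer aggregation itself.

## The network model

A stable state is declared with its monomer count $\nu_s$ and its
*total* cluster binding free energy (kcal/mol, relative to free
monomers); the engine works throughout with the per-monomer value
$G_s = G^{\mathrm{total}}_s/\nu_s$, the average free energy of a monomer
in that state. The free monomer is the energy zero. Transition states
carry a per-monomer energy $G_t$ directly: they have no cluster size of
their own, and when a barrier is known at cluster level the file format
divides it by the $\nu$ of a named stable state
(`g_total_over_nu_of`). This per-monomer convention for transition
states is an interpretation — nothing in the theory assigns a $\nu$ to a
maximum — so the packaged example is also checked under the alternative
convention (using the cluster value unchanged), which leaves the
dominant-path conclusion intact; see below.

Each link from transition state $t$ to stable state $s$ carries a
dimensionless frequency factor $A_t^s > 0$ correcting for path-specific
dissociation/conformational-activation frequencies. No calibration
recipe exists for these factors, so they default to 1; consequently the
absolute prefactor $k = (k_B T/h)A$ is left as a single user-settable
scale (`k_scale`, default 1) and rates are reported in reduced units.
Every scientific conclusion the solver supports is a rate *ratio*, which
the prefactor cancels out of.

Defaults: $T = 310$ K (physiological / simulation temperature),
$R = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$, so
$RT \approx 0.616$ kcal/mol.

## Rates and time evolution

Outflow from a transition state is barrierless, so it is distributed
over the directly linked stable states by the column-stochastic
**linking-fraction matrix** $Lf_{s,t} = k_t^s / \sum_{s'} k_t^{s'}$,
which reduces to $1/n$ per column when all $A$ are equal. The path rate
between linked $s$ and $t$ at cluster concentrations $C_s$ is

$$R_{s,t} = -k_t^s e^{-(G_t-G_s)/RT} C_s
  + \sum_{s'} Lf_{s,t}\, k_t^{s'} e^{-(G_t-G_{s'})/RT}
    \frac{\nu_{s'}}{\nu_s} C_{s'},$$

negative for net outflow. The $\nu_{s'}/\nu_s$ factor converts cluster
counts between states of different size, so monomers — not clusters —
are the conserved currency. State rates are the row sums
$R_s = \sum_t R_{s,t}$.

The equilibrium monomer distribution follows a Boltzmann weight on the
per-monomer energies, $P_s = e^{-G_s/RT}/Z$, with
$C_s^{eq} = P_s C_0/\nu_s$. Which states enter the partition sum $Z$ is
a *modelling decision*, not something the engine can guess: a product
state that cannot yet form (no drug present, say) must be excluded.
`equilibrium_distribution()` therefore takes the accessible set as an
explicit argument, defaulting to all states only. Substituting the
equilibrium concentrations makes every path rate vanish identically —
this is enforced analytically through the definition of $Lf$, so the
tests assert stationarity at a tight $10^{-10}$ relative tolerance:
residuals there indicate bugs, not numerics. The one-way flux along a
path at equilibrium, $|R|_{s,t} = k_t^s \frac{1}{\nu_s}\frac{1}{Z}
e^{-G_t/RT} C_0$ (monomer form omits $1/\nu_s$), depends only on the
transition-state energy: more stable states are more populated but must
climb correspondingly higher barriers, and the two effects cancel.

Collecting terms gives the linear system $\mathrm{d}\mathbf{C}/\mathrm{d}t
= \mathbf{A}\mathbf{C}$ with

$$A_{sj} = \delta_{sj}\sum_t -k_t^s e^{-(G_t-G_s)/RT}
  + \sum_t \frac{\nu_j}{\nu_s} Lf_{s,t}\, k_t^j e^{-(G_t-G_j)/RT}.$$

Because each $Lf$ column sums to one, $(\nu_1,\dots,\nu_{n_s})$ is a
left null vector of $\mathbf{A}$: total monomer is conserved exactly,
and the same identity is verified numerically on random networks.
`evolve()` uses the eigen-superposition
$\mathbf{C}(t) = \sum_i z_i \xi_i e^{\lambda_i t}$, solving the weights
$z$ from the initial condition.

## Numerical choices

- Boltzmann sums are computed with max-subtraction (log-sum-exp), since
  $e^{-G/RT}$ spans tens of orders of magnitude at 310 K for binding
  energies of a few tens of kcal/mol. Individual factors
  $e^{-(G_t-G_s)/RT}$ are exponentiated directly: for per-monomer
  energies within $\pm 30$ kcal/mol they stay comfortably inside double
  range.
- The eigenbasis condition number is estimated from Frobenius norms of
  $V$ and $V^{-1}$ (valid for complex bases). Above $10^{12}$, or if
  $V$ is numerically singular, `evolve()` silently switches to a dense
  matrix-exponential evaluation with the same contract; the method used
  is recorded on the returned object. Rate matrices of physical
  networks are usually diagonalizable, but nothing guarantees it.
- `dominant_path()` ranks paths by $|R_{s,t}|$ and declares *joint*
  dominance for magnitudes agreeing within a relative $10^{-9}$, rather
  than ordering ties arbitrarily. At equilibrium every one-way flux
  pairs with its reverse, so joint ranks are the norm there.
- Degenerate inputs: transitions with no links, links to undeclared
  states, and zero frequency factors (the encoding for "not linked" is
  omission, not $A=0$) are rejected at validation; negative
  concentrations and negative times error in the operations that
  receive them.

## The packaged PD-L1 example

The worked example encodes the dimerization-mode network of PD-L1 with
the inhibitor BMS-202: S1, the apo dimer seen in the 4Z18-type crystal
interface ($\nu=2$, $-23.63$ kcal/mol total); S2, the more stable apo
dimer sharing the drug-site interface ($-31.15$); S3, the holo sandwich
dimer; T1, three-body separation through free monomers (0 kcal/mol, the
reference); T2, the drug-insertion transition state. Two of the
energies are composed rather than printed anywhere:

- the T2 total, $-31.15 + 20.28 = -10.87$ kcal/mol, where 20.28 is the
  geometric insertion barrier obtained as the PMF endpoint of pulling
  the drug out (33.10) minus the stabilization it provides (12.82);
- the S3 total, $-31.15 - 12.82 = -43.97$ kcal/mol, the S2 energy plus
  the drug stabilization; the fixture documents it as derived.

The drug molecule does not count toward $\nu$ ($\nu_3 = 2$): cluster
size tracks protein monomers only. T2 links only S2 and S3 — the 4Z18
interface is geometrically incompatible with direct drug insertion — so
with equal frequency factors the linking fractions are
$(1/3,1/3,1/3)$ and $(0,1/2,1/2)$.

```{r}
app <- reproduce_application()
```

The drug-insertion path dominates by the factor

```{r}
abs(app$path_rates[["R2t2"]]) / abs(app$path_rates[["R1t1"]])
```

which is essentially the Boltzmann factor of the barrier gap
$e^{-(G_{T2}-G_{T1})/RT}$ times the ratio of linking coefficients
(1/2 vs 1/3) — robust to any common rate prefactor, to $C_0$, and to
the per-monomer vs per-cluster transition-energy convention (the gap is
negative either way).

## Energy bookkeeping

`combine_mmpbsa()` applies the standard single-trajectory MM-PBSA
identities ($\Delta E_{polar} = \Delta E_{ele} + \Delta G_{PB}$,
$\Delta E_{nonpolar} = \Delta E_{vdw} + \Delta G_{SA}$, their sum
$\Delta G_{mmpbsa}$, and $\Delta G_{bind} = \Delta G_{mmpbsa} -
T\Delta S$) on full-precision values; rounding is presentation-only.
Internal-energy terms (bond/angle/torsion) cancel in single-trajectory
binding deltas and are optional metadata. When published tables print
components rounded to two decimals, recombination can differ from the
printed totals by $\sim 0.01$ kcal/mol; the tests assert exactness
where the arithmetic is exact and a $\pm 0.015$ band where printed
rounding propagates. Standard deviations, when supplied, propagate in
quadrature under an independence assumption and are never used in the
kinetics. `nonpolar_solvation()` is the linear SASA model
$\gamma\,\mathrm{SASA} + \beta$ with the common PB/SA defaults
($\gamma = 0.00542$ kcal mol$^{-1}$ Å$^{-2}$, $\beta = 0.92$ kcal/mol);
solving the Poisson–Boltzmann equation and computing SASA from
structures are out of scope — those quantities are consumed as inputs.

## Jarzynski estimation and the synthetic generator

`jarzynski_average()` evaluates $\Delta G = -kT\ln\langle
e^{-W/kT}\rangle$ by log-sum-exp; Jensen's inequality
($\Delta G \le \bar W$) holds by construction and is property-tested.
`staged_pmf()` chains per-stage pointwise averages into a continuous
profile, anchoring each stage at the endpoint of the previous one, and
records which replicate ends closest to the stage average — the
replicate an adaptive steered-MD protocol would seed the next stage
from. Here the flag is metadata only: the package does not run MD.

The synthetic generator `synth_pulling()` is an overdamped Langevin
particle in a quadratic well pulled by a moving harmonic restraint. Its
defaults mirror a typical adaptive protocol — spring 20 kcal
mol$^{-1}$ Å$^{-2}$, speed 2 Å/ns, 20 Å split into 10 stages, 20
replicates per stage — and its exact free-energy profile is the
quadratic $\tfrac12 k_{\mathrm{eff}} \xi^2$ with $k_{\mathrm{eff}} =
k_w k_s/(k_w+k_s)$, returned alongside for oracle use. Each stage
restarts from the analytic equilibrium at the stage boundary. What it
emulates is the estimator's operating regime: dissipative work
distributions whose Jarzynski average recovers the true profile while
the mean work overshoots it. What it does *not* emulate is anything
molecular — no rugged landscape, no orthogonal slow modes, no
pulling-coordinate curvature — so passing tests validate the estimator
arithmetic and its convergence behaviour, not the accuracy of any MD
protocol. Tests run the Gaussian family at $N = 10^2$–$10^6$ (the
largest only in the convergence check, where the closed form
$\mu - \sigma^2/2kT$ must be hit within three standard errors) and the
Langevin generator at a few hundred to a few thousand steps per stage —
sizes chosen to keep the full suite in seconds while leaving the
bias/variance structure visible.

## Trajectory metrics

The metrics operate on in-memory `F × N × 3` arrays read from
multi-model PDB (via `bio3d`) or a plain whitespace xyz table.
Superposition is the standard Kabsch/SVD solution (optionally
mass-weighted), cross-checked in the tests against `bio3d::fit.xyz` and
a brute-force rotation grid. RMSD is mass-weighted by default. RMSF is
computed about the time-mean position (the standard reading; a fixed
reference structure is a documented option), and residue-level RMSF is
the mass-weighted mean of the atomic values, which always lies between
the residue's extremes. The cross-correlation matrix uses full 3-D
scalar products of mean-free displacements; zero-variance atoms produce
flagged `NA` entries rather than silent zeros, and values are clipped
to $[-1,1]$ only within $10^{-12}$.

The hydrogen-bond statistic counts a donor–hydrogen–acceptor triple
when the distance is under 3.5 Å and the D–H···A angle lies strictly
between 120° and 180° (a perfectly linear geometry is excluded by the
strict inequality, a measure-zero case in real data but visible in
constructed fixtures). The distance convention is ambiguous in common
usage; both donor–acceptor (default) and hydrogen–acceptor are
offered. Published occupancy numbers for real systems depend on the
underlying MD trajectories and cannot be reproduced from energies
alone; the package's statistic is validated on constructed geometries.

## Known limitations

- Kinetics are strictly linear: the rate matrix does not update with
  concentrations, and no stochastic (Gillespie-type) simulation is
  provided.
- Absolute rates require a calibration of $k = (k_BT/h)A$ that the
  theory's inputs do not supply; only ratios are meaningful with the
  default scale.
- Network topology and barrier heights are user inputs — nothing is
  inferred from structures.
- Trajectory readers handle plain-text formats only, with no
  periodic-boundary treatment.
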