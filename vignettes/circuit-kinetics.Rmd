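---
title: "Modeling reaction kinetics as transconductor-RC circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling reaction kinetics as transconductor-RC circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kincirc)
```

## The model

`kincirc` expresses a mass-action reaction network as an electronic circuit
and simulates the circuit instead of hand-derived differential equations.
The dictionary is exact, not an analogy:

| circuit quantity | kinetic quantity | unit |
|---|---|---|
| node voltage $V$ | concentration | M |
| current $I$ | reaction flux | M/s |
| transconductor $I = g \prod_j V_j$ | mass-action flux (gain $g$ = rate constant) | M/s |
| resistor $I = V/R$ | first-order loss, $R = 1/k$ | Ohm |
| capacitor $C = 1$ | volume-normalized container | A·s/V |
| adder/subtracter (pool) | mass conservation | M |

With $C = 1$, Kirchhoff's current law at a species node *is* that species'
rate equation: $dV/dt = \sum I_\text{source} - \sum I_\text{sink}$.  A
production-decay node, for instance, obeys
$dP/dt = V_\text{in} k_\text{cat} - P/r$, the charging curve of an RC block.

Conserved totals are never integrated; they are bookkept by **pools** whose
free value is $\text{total} - \sum_i m_i \cdot [\text{bound}_i]$ with signed,
possibly non-integer stoichiometric weights $m_i$.  Because the free value is
computed by exact subtraction at every evaluation, conservation holds to
machine precision by construction, and the "use-it-and-lose-it" negative
feedback of binding reactions is implicit in the wiring.  Two consequences
matter in practice:

* the Michaelis-Menten block subtracts the complex from **both** the enzyme
  and the substrate pool, so it remains correct in the tight-binding
  (Morrison) regime where $E_0 \sim S_0$ and the free-ligand hyperbola fails;
* a substantially negative free value cannot be a rounding artifact — it
  indicates inconsistent parameters, so it is reported, never clamped.

## Quasi-steady state as capacitor removal

Under the quasi-steady-state approximation an enzyme complex equilibrates
instantly: its capacitor is removed and the node becomes *algebraic*, its
current balance constrained to zero.  For the Michaelis-Menten block the
balance is $[E_\text{free}][S_\text{free}] = [ES]\,K_m$: a unity-gain
bimolecular transconductor feeding a resistor $R = 1/K_m$ (with $K_m$ in M —
$K_m = 0.167\ \text{mM}$ maps to $5988\ \Omega$).  Forward gains in QSSA
blocks are fixed at 1 because the balance is normalized by the association
rate; they are deliberately not user-configurable.  The generalized
inhibition block adds EI and ESI nodes with balances
$[E_f][I_f] = [EI] K_i$ and $[EI][S_f] + [ES][I_f] = [ESI](K_{m2} + K_{i2})$;
the four classic mechanisms are parameter specializations (competitive: no
ESI node; uncompetitive: no EI node, removed exactly rather than by a huge
resistance, which avoids ill-conditioning; noncompetitive: $K_{m2}=K_m$,
$K_{i2}=K_i$; mixed: all four independent).

## Compilation and integration

`compile_circuit()` partitions nodes into ODEs (dynamic) and residuals
(algebraic) and precomputes index-based evaluators; pools reduce to an
affine map `free = t0 + A v`.  Integration is *nested*: the stiff solver
(`deSolve::ode`, lsoda, default rtol $10^{-8}$, atol $10^{-12}$ M — chosen
because concentrations span nM to mM) advances the dynamic nodes, and every
right-hand-side evaluation re-solves the algebraic nodes with a damped
Newton iteration warm-started from the previous solution.  The shipped
motifs have at most four algebraic nodes, so the 1-CPU cost stays small.
Numerical choices worth knowing:

* **Convergence is relative flux balance.**  An algebraic node is converged
  when its net current is below $10^{-9}$ times the *gross* current through
  it.  An absolute flux floor was tried and rejected: with sub-nanomolar
  enzyme the currents are $\sim 10^{-13}$ M/s, and any fixed floor loosens
  the solve enough to distort the substrate-exhaustion plateau by ~0.1%.
  A state with all currents zero (e.g. $S_0 = 0$) converges trivially.
* **Initialization.**  The algebraic state at $t = 0$ is solved from an
  all-zeros guess (complexes start empty and equilibrate "instantly").
* **Tie-break.**  When Newton fails on a single-node block, a bounded
  bracketing root-finder takes over on $[0, B]$; this picks the physical
  branch of the conservation-coupled quadratic
  $(S_0 - ES)(E_0 - ES) = ES\,K_m$ (the smaller root, $0 \le ES \le
  \min(E_0, S_0)$) — the larger root violates conservation.
* **Non-negativity.**  Node values are not clamped.  Mass-action systems
  preserve positivity analytically, so negativity beyond
  $10\,(\text{atol} + \text{rtol}\cdot\text{scale})$ triggers a warning (and
  a converged algebraic value below $-10\,\text{atol}$ is an error):
  clamping would hide solver failure.
* **Determinism.**  The solver has no stochastic component; identical
  settings give bitwise-identical trajectories.

## Rate analysis

`rate_curve()` simulates one trajectory per initial substrate concentration
and fits an OLS slope over an automatically chosen window: the earliest 10%
of the span, further capped so substrate consumption stays below a
configurable fraction (default 5%).  The cap matters: reading a slope while
a few percent of substrate disappears biases low-$S_0$ rates downward and
inflates the fitted $K_m$ by a similar factor, so parameter-recovery work in
this package uses a 1% cap.  `lineweaver_burk()` is the classic unweighted
double-reciprocal regression ($Y$-intercept $1/V_\max$, $X$-intercept
$-1/K_m$); weighting schemes are out of scope.
`classify_inhibition()` compares two fits with a 10% relative-change
threshold (arbitrary but exposed as an argument), with the extra
slope-equality test that distinguishes uncompetitive inhibition.

## The synthetic fixture generator

`generate_fixture()` emulates replicate plate-reader assays: multiplicative
Gaussian noise, $x \mapsto x(1+\varepsilon)$,
$\varepsilon \sim N(0, \sigma)$, clamped at zero, with $\sigma \le 0.2$ by
default because experimental replicate scatter in the assays this package
emulates stays below 20% of the mean; recovery studies use $\sigma = 0.05$,
three replicates, and fifty seeds.  The seed is mandatory.  The generator is
deliberately simple: it does not emulate instrument drift, pipetting bias,
path-length or inner-filter effects, or temporally correlated noise.
Passing the recovery tests therefore shows that the analysis pipeline is
unbiased and noise-tolerant under i.i.d. multiplicative noise — not that it
is robust to every failure mode of real plates.

## Module-specific modeling choices

* **TXTL block.**  The promoter DNA acts as the "enzyme" of a
  noncompetitive binding block (polymerase and TetR bind independent
  sites); the polymerase "substrate" is sequestered but never consumed.
  Each actively transcribing DNA-RNAP complex ties up
  $1 + k_{TX} L_m / C_m$ polymerases (one at the promoter plus the
  elongating ones), and each translating mRNA ties up
  $1 + k_{TL} L_p / C_p$ ribosomes.  The repressed ternary complex
  DNA-RNAP-TetR deducts exactly one polymerase: it is bound at the promoter
  but not elongating.  mRNA degradation acts on total mRNA (free plus
  ribosome-bound) through a single decay path; whether ribosome-bound mRNA
  is protected is unknown, and this is the documented assumption.  GFP and
  dark GFP carry no decay (cell-free, first ~4000 s).  TetR is treated as a
  preformed homodimer; monomer-dimer kinetics are out of scope.  $K_{ribo}$
  and the rate constants have no defaults — they are condition-specific
  fitted quantities the user must supply (the bundled netlist carries
  `UNKNOWN` placeholders that are rejected at load time).
* **Reversible Bi-Bi.**  Full mass action, all six nodes dynamic (no QSSA),
  with product-rebinding fluxes $k_{-4}[P][E{\cdot}NADH]$ and
  $k_{-5}[NADH][E_f]$.  Thermodynamic (Haldane) consistency of a
  user-supplied rate set is not enforced.  The bundled dehydrogenase
  netlist ships with `UNKNOWN` rate constants for the same reason as TXTL.
* **Capacitance $\ne 1$.**  Supported (a dynamic node divides its net
  current by $C$) but untested against any published configuration; all
  shipped motifs use $C = 1$.

## Problem sizes and limitations

The test-suite and reproduction runs use 12-point substrate grids, 120–500
output points per trajectory, and 50-seed noise studies; a full run of
everything takes well under a minute on one CPU.  Known limitations: the
nested-Newton DAE strategy is designed for the small algebraic blocks of
these motifs (a network with dozens of coupled QSSA nodes would want an
analytic Jacobian or a true DAE integrator); there is no stochastic
(low-copy-number) simulation; no SBML/CellML interchange; and no automatic
inference of mechanisms from data — the package simulates and analyzes the
mechanisms you specify.
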