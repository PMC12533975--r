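---
title: "Methods: enzyme-constrained and thermodynamic analysis of metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enzyme-constrained and thermodynamic analysis of metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxkit)
```

## Scope and model

fluxkit analyses stoichiometric metabolic models of the kind used for
*Escherichia coli* central metabolism: a matrix $S \in \mathbb{R}^{m\times N}$
of metabolite/reaction stoichiometries, per-reaction flux bounds in
mmol/gDW/h, and a biomass reaction whose flux is read as the specific growth
rate $\mu$ (1/h). All flux analyses assume steady state, $Sv = 0$, with
exchange uptake represented as negative exchange flux. On top of this core
the package layers three kinds of information: a knowledge graph connecting
reactions to enzymes, polypeptides and genes; per-reaction enzyme costs
derived from turnover numbers and protein masses; and standard reaction
Gibbs energies with a covariance describing their estimation uncertainty.

The linear programs behind FBA, parsimonious FBA, production envelopes and
enzyme allocation are solved by a dense bounded-variable two-phase primal
simplex implemented in the package. This is a deliberate choice for the
target scale (tens to a few hundred reactions): solutions are exact basic
optima, behaviour is deterministic, and the test suite can validate the
solver against an exhaustive vertex-enumeration oracle. It is not intended
for genome-scale models.

## Flux analyses

`solve_fba()` maximises (or minimises) the objective over
$\{v : Sv=0,\; l \le v \le u\}$. `solve_pfba()` then fixes the objective at
its optimum (minus a $10^{-9}$ slack) and minimises $\sum_i |v_i|$ by
splitting each flux into nonnegative forward/backward parts; this removes
futile cycles from reported distributions. `production_envelope()`
discretises the achievable range of a target flux into an equally spaced
grid and minimises/maximises growth at each fixed target value; interior
points that become infeasible are recorded as `NA` rather than failing the
grid. `set_condition()` encodes a growth condition the way medium-scale
*E. coli* studies state them: a carbon-uptake bound (10 mmol/gDW/h by
default), oxygen closed for anaerobic runs, and a non-growth-associated
maintenance lower bound (6.86 mmol/gDW/h, the value conventionally inherited
from the genome-scale parent models).

`lump_equivalent_biomass()` compresses the part of an extended network that
lies outside a retained metabolite set into one equivalent biomass reaction:
the lumped set is the biomass reaction plus every reaction touching a
non-retained metabolite, and the lumped stoichiometry is the net
consumption/production of each retained metabolite at a reference flux
distribution, scaled to unit biomass flux. The exact construction used by
the original equivalent-biomass pipelines is not fully specified in public
descriptions; this reading is fixed here because it is the unique choice
that (a) reduces to the original biomass reaction when everything is
retained and (b) preserves the reference solution's growth rate, which the
tests assert.

## Knowledge graph and knockouts

The graph is typed: `catalysis` edges (protein to reaction, `primary` or
`secondary`), `subunit_composition` edges with integer stoichiometry,
`coding` edges (gene to polypeptide), and `regulation`/`modification` edges
that are stored and round-tripped through GML but deliberately excluded
from knockout logic. Catalysis edges with no stated class default to
primary — the conservative choice when evidence of minor activity is
missing. Protein masses are computed recursively from polypeptide masses
(kDa) through the subunit edges.

A reaction's gene-protein-reaction (GPR) rule is the OR over catalysing
proteins of the AND over the protein's required polypeptides, each
polypeptide an OR over its coding genes. Knockout propagation walks the
graph directly (a polypeptide dies when all its coding genes are knocked
out; a protein dies when any required polypeptide dies), which gives a
second, independent route to the same semantics; the tests compare the two
on exhaustive truth tables (up to $2^{10}$ gene states). Disruption
classes follow the fixed precedence complete > full primary > partial
primary > secondary, and `disruption_analysis()` labels each gene of each
essential reaction with its most severe class across conditions.
Essentiality uses a relative threshold (growth below $10^{-6}\times$ wild
type); known false essentials are handled by an exclusion-list argument
rather than hard-coded identifiers. Complex abundances are estimated from
polypeptide counts by non-negative least squares over the subunit
stoichiometry matrix, solved as a quadratic program; rank-deficient cases
are pushed towards the minimum-norm solution by a vanishing ridge.

## Enzyme-constrained models

The enzyme-constrained variant follows the pooled (sMOMENT-style)
construction: each reversible reaction is split into irreversible forward
and backward copies, each enzymatic reaction $i$ consumes a pool
pseudometabolite with stoichiometry equal to its enzyme cost per unit flux

$$a_i = \frac{M_i}{k_{\mathrm{cat},i}\,\sigma}, $$

and a supply pseudoreaction bounded by $e_{\mathrm{tot}}$ (g/gDW) feeds the
pool, enforcing $\sum_i a_i v_i \le e_{\mathrm{tot}}$. Units: $M_i$ in kDa
(numerically g/mmol), $k_\mathrm{cat}$ input in s$^{-1}$ per polypeptide,
converted once to h$^{-1}$ and multiplied by the number of polypeptide
subunits at build time, so $a_i$ lands in g·h/mmol with no hidden factors.
$\sigma$ is a single condition-specific average saturation scalar; the
alternative of per-reaction saturations is intentionally out of scope
(costs stay linear in flux). Transporters without a measured turnover get
the conventional default of 65 s$^{-1}$. Exchanges, biomass, maintenance
and spontaneous reactions carry zero cost. Reaction-specific capacity
bounds (GECKO-style) are not implemented: with a single pool they would not
change the solution space here.

`predict_allocation()` fixes growth at a measured rate and minimises total
enzyme cost; per-enzyme abundances are $a_i v_i$ aggregated per enzyme.
`fit_saturation()` estimates $\sigma$ per condition as the ratio of the
summed predictions (over measured enzymes) to the measured total, which by
construction makes scaled prediction totals match the data.

## Turnover-number adjustment

With the reference flux distributions frozen (minimum-cost allocations at
measured growth, computed with the unadjusted turnover numbers), the
adjustment problem in $\log_{10}$ space is

$$\min_{u \in [u_{\min}, u_{\max}],\, s}
 \sum_{c,i}\bigl(\log_{10}\hat e_{i,c}(u, s_c) - \log_{10} e^{\mathrm{meas}}_{i,c}\bigr)^2
 + \rho \lVert u\rVert_2^2,$$

where $u_i$ is the per-reaction $\log_{10}$ adjustment,
$s_c = \log_{10}\sigma_c$, and
$\hat e_{i,c} = \sum_j a_j 10^{-u_j} v^{\mathrm{ref}}_{j,c} / \sigma_c$.
When every measured enzyme maps to a single reaction the residuals are
affine in $(u, s)$ and the problem is a box-constrained ridge least-squares
solved exactly as a QP — the deterministic special case chosen as the
primary route. Enzymes pooled over several reactions make the log-of-sum
nonlinear; a smooth L-BFGS-B route with analytic gradients covers that
case, and the tests require the two routes to agree where both apply.
Defaults: bounds $\pm 2$ (a hundredfold change at most) and $\rho = 1$,
the value below which further deregularisation buys little accuracy;
zero measured abundances are dropped from the loss (their logarithm is
undefined) with a reported count. Reactions with zero flux in every
reference distribution are structurally unidentifiable and keep $u = 0$.

One direction of the parameter space is flat: adding a constant to all
$u_i$ while subtracting it from every $s_c$ leaves all residuals unchanged
whenever the enzyme/condition incidence graph is connected. The ridge
resolves it towards the minimum-norm representative, and the synthetic
generator draws ground-truth adjustments centred to mean zero so that
"recovery" is a well-posed statement. Leave-one-out cross-validation
refits without one condition and predicts its abundances with the fitted
parameters, obtaining the held-out condition's scaling by total-matching.

## Elementary flux modes, scoring, and saturation FBA

`enumerate_efms()` uses direction splitting followed by double description
with the combinatorial (zero-pattern) adjacency test; futile
forward+backward two-cycles are removed and rays mapped back to signed net
fluxes, normalised to $\max_i |v_i| = 1$. A guard refuses networks above 40
reactions by default — the algorithm is meant for the reduced fixtures this
package targets, not for the millions of modes of a medium-scale network.
`brute_force_efms()` re-derives modes from the definition (all support
subsets with a one-dimensional, sign-feasible restricted null space,
inclusion-minimal), and set equality between the two enumerations is
asserted on every fixture and on randomized networks.

Scored modes carry a biomass yield $v_{BM}/|v_{\mathrm{upt}}|$ and an
achievable growth rate $\mu = f_{\mathrm{enz}} v_{BM} / c_{\mathrm{enz}}$
with $c_{\mathrm{enz}} = \sum_i a_i |v_i|$; both are invariant to the
arbitrary scaling of a mode, so no normalisation convention is needed
beyond the canonical one. $f_{\mathrm{enz}}$ defaults to 0.285 g/gDW, a
proteome fraction representative of aerobic growth on glucose, and is
overridable. Low-oxygen environments are emulated by multiplying the cost
of oxygen-consuming reactions (a configurable list) by a factor, 1000-fold
in the standard scenario.

Saturation FBA keeps every enzyme cost at the fitted condition saturation
except the substrate transporter, whose efficiency follows irreversible
Michaelis–Menten saturation $\sigma_{\mathrm{up}} = c/(K_m + c)$ (default
$K_m$ 0.116 mM for the glucose PTS). Screening external concentrations
traces a Monod-like growth curve; without auxiliary flux bounds each
optimum is an elementary mode (checked by the rank test on its support),
so the yield is piecewise constant with downward jumps at mode switches,
and a positive maintenance bound provably breaks both properties — the
tests assert all three behaviours. Switches are detected on support
signatures (fluxes above $10^{-9}$ of the largest) rather than yield
deltas, which is robust to floating-point noise.

## Probabilistic max–min driving force

Reaction Gibbs energy estimates enter as a mean vector with a covariance
$\Sigma$ (kJ²/mol²) over balanced metabolic reactions only. The covariance
is factored by eigendecomposition, $\Sigma = QQ^\top$, keeping eigenvalues
above $10^{-9}\lambda_{\max}$ (the numerical rank $q$); a significantly
negative eigenvalue is rejected. The probabilistic MDF maximises the
minimum driving force $b$ over realised energies within the
$\alpha$-confidence ellipsoid ($\lVert m\rVert_2^2 \le \chi^2_{q;\alpha}$,
realisation $\bar{\Delta G} + Qm$) and log-concentrations within bounds
(default 1 µM to 10 mM), with $-\mathrm{sign}(v_i)\,\Delta_r G'_i \ge b$
for every nonzero-flux covered reaction. The original formulation writes a
strict inequality; the implementation uses $\ge$, which linear programming
requires and which leaves the optimum unchanged. The single ball
constraint is handled by cutting planes (supporting hyperplanes of the
ball) over the package LP solver; termination at ball violation below
$10^{-9}$ makes the procedure an exact QCP solver for this structure.
Reactions not covered by the parameter set are exempted from sign
constraints with a warning, mirroring incomplete coverage of real
parameter sets. $T$ is fixed at 310.15 K with $R = 8.314$ J/mol/K.

The flux-force efficacy $\eta = \tanh(-\Delta_r G'/(2RT))$ summarises how
far a reaction operates from equilibrium (net over total flux);
$\eta = 0.5$ corresponds to $\Delta_r G' \approx -1.1\,RT \approx -2.8$
kJ/mol at 310.15 K. `group_by_efficacy()` pools reactions carrying at
least 2.5% of the reference uptake flux into low/high groups at
$\eta = 0.5$, with an exclusion list for transport/spontaneous reactions.

## Synthetic data: what it does and does not emulate

The fixture module builds three deterministic toy worlds. The
`respirofermentative` variant is the workhorse: a substrate can be
respired (high ATP yield, oxygen-consuming, enzymatically expensive:
a 300 kDa complex at 15 s$^{-1}$) or fermented (low yield, cheap: 50 kDa
dimer at 150 s$^{-1}$) with byproduct secretion, and biomass drains both
substrate and ATP (100 substrate + 400 ATP per unit growth, giving growth
rates of order 0.1–2.5 h$^{-1}$ and yields of order 0.002–0.005 gDW/mmol).
Stoichiometric coefficients are small integers so brute-force oracles stay
exact; internal bounds are wide so that the enzyme pool, not box bounds,
limits flux. Simulated proteomics computes minimum-cost allocations at
eight growth rates under substrate and oxygen bounds that force both
routes at stoichiometrically determined fluxes, divides by a drawn
condition saturation $\sigma_c \in [0.35, 0.75]$, and applies
$10^{\varepsilon}$ noise with $\varepsilon$ normal in $\log_{10}$. The
default noise scale used in the noisy tests is 0.3 $\log_{10}$ units,
a typical order for proteomics abundance error.

These worlds emulate the structure that the analyses depend on —
mode multiplicity, cost/yield trade-offs, isozyme redundancy, correlated
thermodynamic uncertainty — but not the scale, parameter realism or
measurement idiosyncrasies of real datasets: passing tests demonstrate
correctness of the algorithms under the stated model assumptions, not
predictive accuracy on real proteomes. Problem sizes throughout the test
suite (networks of 5–15 reactions, 8 conditions, grids of ~25
concentrations) were chosen so every oracle can be exhaustive.

## Numerical conventions and limitations

Zero-flux thresholds are $10^{-9}$ relative to the largest flux; LP
feasibility tolerance $10^{-9}$; EFM identity is tested on supports plus
normalised values within $10^{-8}$; mass balance of reported optima is
checked to $10^{-6}$. Ties among primary isozymes with equal abundance
fall back to the lexicographically smaller identifier (documented, so runs
are reproducible). Known limitations: the simplex and the double
description are dense and unsuitable beyond a few hundred reactions; the
kcat fit freezes reference fluxes rather than alternating re-optimisation;
regulation and modification edges carry no semantics yet; and MDF analysis
consumes externally estimated energy means/covariances — estimating them
from compound data is out of scope.
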