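---
title: "The modified Ising model with gene-type spins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The modified Ising model with gene-type spins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isingnet)
```

## The model

Gene regulatory networks are often abstracted as logic models: each gene is
either active (1) or inactive (0), and activity propagates along the
network's edges. `isingnet` treats such a network as a two-state
thermodynamic system in a heat bath. On an undirected simple graph with
adjacency matrix $A_{ij}$, the energy of a configuration
$s \in \{0,1\}^N$ is

$$H = -\tfrac{1}{2}\sum_{i,j} J A_{ij} s_i s_j - h \sum_i s_i,$$

where $J$ is the coupling constant ($J>0$: connected genes prefer to be
active together; $J<0$: they suppress each other), and $h$ is a uniform
external field modelling the cell's exchange with its environment. The
asymmetric 0/1 alphabet is the biologically meaningful difference from the
classical $\pm 1$ Ising model: an inactive gene contributes nothing to any
interaction. The order parameter is the fraction of active genes,
$M = \frac{1}{N}\sum_i s_i \in [0,1]$; the disordered phase sits at
$M = 1/2$, order at $M$ near 0 or 1. Temperature $T$ (with $k_B = 1$,
$\beta = 1/T$) injects stochastic flipping.

The network substrate is the Barabási–Albert (BA) model: $m_0$ initially
unconnected nodes, then one node at a time attaching $m$ distinct edges to
existing nodes with probability proportional to current degree. Because all
degrees are zero at the first growth step, that step needs a rule the
construction itself does not supply; we choose targets uniformly at random
without replacement whenever the total attachment weight is zero, and
$\propto k_i$ afterwards. $m_0$ defaults to $m$ (the common convention),
making the generated edge count exactly $m(N-m_0)$ and the mean degree
$\bar k \approx 2m$. Multi-edges are excluded so that $A_{ij}\in\{0,1\}$.

## Monte Carlo sampling

`run_chain()` performs single-spin-flip MCMC. One step is one attempted
update of one uniformly chosen node — the reading under which the reference
schedule (2×10⁴ equilibration plus 3×10⁴ sampling steps at $N = 5\times
10^3$) amounts to exactly 10 attempted flips per spin. The default kernel
is the heat bath: the chosen node is resampled from its conditional
Boltzmann distribution

$$P(s_i = 1) = \frac{1}{1+e^{-\beta(h + J\sum_j A_{ij} s_j)}},$$

independent of its current state. This is the self-consistent choice here
because its annealed average is precisely the right-hand side of the
central mean-field equation below. A Metropolis kernel
($\min(1, e^{-\beta\Delta E})$) is provided as well; the two kernels
sample the same stationary distribution and the tests compare them against
exact enumeration on small graphs. Updates use random node selection with
replacement (no sweep order is prescribed by the model). $T = 0$ is the
deterministic limit: heat-bath follows the sign of the local field (ties at
probability 1/2), Metropolis accepts only strictly downhill moves.

Chains report the equilibrium mean of $M$ with a standard error from 20
contiguous batch means, a blunt but serviceable guard against the strong
autocorrelation of single-site dynamics sampled every step. Default initial
configurations are all-active for $J>0$ and all-inactive for $J<0$ — the
low-temperature equilibria at $h=0$ — and every chain's random stream is
derived deterministically from a master seed, a realization index and a
control-point index (`derive_seed()`), so whole sweep ensembles reproduce
bit-for-bit.

## Mean-field solution

Replacing neighbour states by the global mean $M$ decouples the model into
independent spins in effective fields $h_i^{\mathrm{eff}} = h + J M k_i$,
giving the self-consistency equation

$$M = \frac{1}{N}\sum_i \frac{1}{1+e^{-\beta(h + J M k_i)}},$$

evaluated on the degree sequence of an actually generated network (not the
idealized continuous degree distribution), which is how a comparison with
MC on the same graphs must be made. `mf_fixed_point()` solves it by damped
iteration $M \leftarrow (1-\lambda)M + \lambda f(M)$, $\lambda = 0.5$,
tolerance $10^{-10}$, cap $10^5$ iterations. Plain iteration 2-cycles when
$f$ is steep (strong antiferromagnetic coupling at very low $T$: the fixed
point sits at $M \sim 10^{-4}$ where $|f'| > 3$), so $\lambda$ is halved
whenever the residual stalls for 50 iterations; with that refinement the
solver converges in a few hundred iterations everywhere we exercise it.
Since $f$ maps $[0,1]$ into $(0,1)$, iterates never leave $[0,1]$. At
$\beta = 0$ every logistic term is exactly $1/2$, so the solver returns
exactly $0.5$.

For $J>0$ at low temperature the equation is bistable: `mf_branch_scan()`
institutionalizes this by solving from the two canonical starts $M=0$ and
$M=1$ at every field value, flagging bistability when the branches differ
by more than 0.5 — a single-start solver would silently pick one branch.
For $T \gg 1$ the Taylor-expanded closed form is
$M \approx \tfrac12 (2+\beta h)/(2 \mp \beta J m)$; the sign key (minus for
ferromagnetic coupling) is fixed by expanding the logistic around $1/2$,
which also makes $M$ increase with $J$ in the ferromagnetic case.

## The mapping to the classical Ising model and the critical field

Substituting $s_i = (s'_i+1)/2$ maps the 0/1 model exactly onto a classical
$\pm1$ model with renormalized coupling $J' = J/4$, local fields
$h'_i = h/2 + (J/4) k_i$, and additive constant
$E_0 = -(J/4)|E| - Nh/2$:

$$H_{0,1}(s) = H_{-1,1}(s') + E_0, \qquad
  Z_{0,1} = e^{-\beta E_0} Z_{-1,1}.$$

The intrinsic local field at $h = 0$ is the fingerprint of the asymmetric
alphabet. The constants are derived from scratch, with the exact energy
identity as the defining requirement:
`verify_mapping()` enumerates all $2^N$ configurations of small graphs and
checks both the energy identity and the partition-function relation to
$10^{-8}$, for ferro- and antiferromagnetic couplings and both field signs.
Only this set of constants is internally consistent: setting the
ensemble-averaged mapped field $h/2 - (J/4)\bar k$ to zero with
$\bar k = 2m$ yields the critical-field law

$$h_c = J m,$$

linear in both the coupling and the attachment parameter
(`critical_field()`), e.g. $h_c = 5$ for $J=1$, $m=5$. A coefficient
$J/2$ in $h'_i$ would both break the energy identity (no constant can
absorb a configuration-dependent residual) and predict $h_c = 2Jm$.

## Protocols

* `temperature_sweep()` / `field_sweep()`: one independent equilibrium
  chain per (realization, control point), fresh BA network per realization,
  20 realizations by default. No state is carried between control values,
  so each point measures the branch pinned by the initial state.
* `hysteresis_loop()`: the one protocol with memory — the final
  configuration at each field seeds the chain at the next, ramping
  $h$ from one end to the other and back (default range $\pm 10$,
  81 points). The enclosed area $|\oint M\,dh|$ (trapezoid rule) is the
  hysteresis signature of the first-order transition and vanishes at high
  temperature.
* `estimate_critical_field()`: the first upward 0.5-crossing of the
  ensemble-mean curve of an ascending field sweep, linearly interpolated
  (exact grid hits returned as-is, ties toward the lower $h$). The model
  never prescribes a numerical read-out for $h_c$; the midpoint of the two
  saturated phases is the natural choice.
* `critical_field_scan()`: measures the activation transition as a
  function of $J$, $m$ or $N$ and pairs it with the analytic line $Jm$.
  Because the system is history-dependent, the estimator must pin one
  branch: sweeps run with antiferromagnetic coupling of magnitude $J$ from
  the all-inactive state, ascending $h$ — the activation branch. (A
  ferromagnetic sweep from the inactive state activates by nucleation just
  below $h = 0$ regardless of $J$, carrying no information about the
  coupling.)

## What the synthetic generator does and does not emulate

All study conditions are generated internally: BA topology with the
reference parameters $N = 5\times10^3$, $m = 5$, $|J| = 1$ (hysteresis
figures use $J = 2$), $T$-grids log-spaced over $[0.1, 100]$, $h$-grids
over $[-10, 10]$, ensembles of 20 realizations. BA graphs share the heavy
degree tail of real interactomes but none of their directionality, edge
signs, modularity or degree correlations; passing tests demonstrate the
statistical mechanics on the abstraction, not biological fidelity. The
edge-list/GraphML readers let any measured connectivity be substituted for
the generator.

## Numerical choices, degenerate inputs, reduced test scales

* Energies in the enumeration oracle are shifted by their minimum before
  exponentiation; $\log Z$ stays finite when $Z$ overflows. The oracle is
  capped at $N \le 20$ (a test instrument, not a production path).
* The tail-exponent estimate is the continuous maximum-likelihood estimator
  above $k_\min = m$ with the standard half-integer shift for integer
  data; it is omitted for $N < 100$ or degenerate degree sequences
  (e.g. regular rings).
* Trailing isolated nodes survive edge-list round-trips via a `# nodes:`
  header; self-loops and malformed lines are rejected with line numbers.
* Unit and end-to-end tests run MC at reduced scales: graphs of 8–12
  nodes against the exact oracle (10⁶-step chains), and $N = 500$ with 5
  realizations for the phase-transition, hysteresis and
  critical-field-trend checks — ample statistics for the threshold
  properties they assert. The package defaults remain the full reference
  scale.

## Known limitations

* The annealed mean-field curve tracks ferromagnetic MC within a few
  hundredths of $M$ across the whole temperature range, but for
  antiferromagnetic coupling below $T \approx 1$ it underestimates $M$:
  at $h = 0$ every set of active genes with no two adjacent costs zero
  energy, and the dynamics drift into this massively degenerate
  independent-set manifold ($M \approx 0.2$ on BA graphs) that the
  decoupling approximation cannot see. For the same reason the
  antiferromagnetic field sweep saturates only gradually: genes on hubs
  with more than $h/|J|$ active neighbours stay off, so $M$ at
  $h = Jm + 3$ plateaus around 0.8 rather than reaching 1 until $h$
  exceeds the largest hub degree.
* For $J = 2$ the deactivation branch of the hysteresis loop is metastable
  down to $-Jm = -10$, the edge of the reference field range; its
  0.5-crossing can fall outside the scanned window, which is why loop
  width (the region where the branches disagree macroscopically) is the
  robust separation measure.
* Directed, weighted or per-edge heterogeneous couplings, per-node input
  fields, cluster MC algorithms and finite-size-scaling analyses are out
  of scope.
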