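# isingnet

Monte Carlo simulation and mean-field analysis of the **modified Ising
model with gene-type spins** on Barabási–Albert scale-free networks.

## The problem

Logic models of gene regulation describe each gene as active (1) or
inactive (0). Treating such a network as a two-state thermodynamic system
in a heat bath lets the machinery of statistical physics — phase
transitions, critical fields, hysteresis — speak to questions like why a
cell switches abruptly between global activity states. The asymmetry of
the biological alphabet matters: unlike a classical ±1 spin, an inactive
gene contributes nothing to any interaction. `isingnet` is for
computational/systems biologists and statistical-physics practitioners who
want a tested, reproducible implementation of this asymmetric model:
simulator, analytic solver and exact small-graph oracles in one package.

## The model

On an undirected simple graph with adjacency matrix `A_ij` (by default a
Barabási–Albert network: `m0 = m` unconnected seed nodes, then
preferential attachment of `m` edges per new node),

```
H = -(1/2) Σ_ij J A_ij s_i s_j - h Σ_i s_i,      s_i ∈ {0, 1}
```

with coupling `J`, external field `h`, temperature `T` (`k_B = 1`). The
order parameter `M = (1/N) Σ_i s_i` is the fraction of active genes.
Key results the package implements and verifies:

* **Heat-bath / Metropolis MCMC** (compiled kernel): one step = one
  attempted update of a uniformly chosen node; the reference schedule
  (2·10⁴ + 3·10⁴ steps at N = 5·10³) gives exactly 10 attempted flips per
  spin.
* **Central mean-field equation**
  `M = (1/N) Σ_i [1 + exp(-β(h + J M k_i))]^-1`, solved by damped
  fixed-point iteration on the degree sequence of a generated network;
  two canonical starts (M = 0, 1) expose the bistable window of the
  first-order transition.
* **Critical field** `h_c = J·m`, linear in both parameters.
* **Exact mapping** onto the classical ±1 Ising model:
  `J' = J/4`, `h'_i = h/2 + (J/4) k_i`, `E0 = -(J/4)|E| - N h/2`, with
  `H_gene(s) = H_classical(s') + E0` and `Z_gene = e^{-βE0} Z_classical`,
  verified by enumeration over all 2^N configurations of small graphs.

## Worked example

```r
library(isingnet)

net <- ba_network(n_nodes = 500, m = 5, seed = 1)
net
#> <ising_network> 500 nodes, 2475 edges, mean degree 9.900
#>   Barabasi-Albert: m = 5, m0 = 5
degree_statistics(net)
#> mean degree 9.900, max degree 91
#> tail exponent gamma = 2.718 (MLE, k_min = 5, n = 500)
```

2475 edges is exactly `m (N - m0) = 5 × 495`; the mean degree is close to
`2m = 10` and the degree tail has the scale-free exponent between 2 and 3.

```r
run_chain(net, model_params(J = 1, h = 0, T = 2), chain_schedule(seed = 42))
#> <chain_result> N = 500, heat_bath kernel, J = 1, h = 0, T = 2
#>   mean M = 0.9615 (se 0.0012), acceptance 0.074, 30000 samples
mf_fixed_point(net$degree, J = 1, h = 0, T = 2, start_M = 1)
#> <mf_solution> M = 0.96028905 (start 1, J = 1, h = 0, T = 2): converged after 35 iterations, residual 7.18e-12
```

At `T = 2` the ferromagnetic network is still strongly ordered
(96% of genes active); the Monte Carlo estimate and the mean-field
solution agree to ~0.001.

```r
critical_field(J = 1, m = 5)
#> [1] 5
verify_mapping(ba_network(10, m = 2, seed = 3), model_params(J = 1, h = 0.7, T = 1))
#> <mapping_report> 1024 configurations: max |H_gene - H_classical - E0| = 1.78e-15, |1 - Z ratio| = 0 (E0 = -7.5, J' = 0.25)

sw <- field_sweep(seq(-1, 8, by = 1), J = -1, T = 0.1, n_nodes = 500, m = 5,
                  n_realizations = 5, master_seed = 7, init = "inactive")
estimate_critical_field(sw)
#> [1] 1.722536
```

The mapping identity holds to machine precision. The antiferromagnetic
activation sweep turns on gradually (hub genes with more than `h/|J|`
active neighbours stay off), so its 0.5-crossing sits below the mean-field
line `J·m = 5` — the mean-field calculation overestimates the dependence
on `J` and `m`, as the Monte Carlo critical-field scans
(`critical_field_scan()`) show systematically.

## Command line

A thin Rscript front-end ships in `inst/cli/isingnet`:

```sh
Rscript inst/cli/isingnet sweep-temperature --J 1 --h 0 --seed 42 --out runs/T-sweep
Rscript inst/cli/isingnet verify-oracle --nodes 8 --m 2 --J 1 --h 0.7 --T 1 --out runs/oracle
Rscript inst/cli/isingnet scan-hc --vary J --values 0.5,1,2 --out runs/hc
```

Every run writes tidy CSVs plus a `manifest.json` of the fully resolved
configuration; `run_from_manifest()` reproduces the outputs byte-for-byte.

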