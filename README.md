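# spreadrank

Which nodes of a contact network would seed the largest epidemics? Degree
centrality and the k-shell decomposition are the standard first answers, but
both assign the same value to many nodes, so large groups of nodes cannot be
ranked against each other at all. `spreadrank` implements a high-resolution
ranking family built on top of the k-shell decomposition, together with the
simulation machinery needed to validate any node-ranking method against
actual spreading dynamics. It is aimed at researchers in network
epidemiology and network science who need to rank spreaders on undirected,
unweighted contact networks supplied as plain-text edge lists.

## The method

The k-shell decomposition peels a network inwards: shell k is removed by
repeated *simultaneous sweeps* of all remaining nodes with degree ≤ k. The
package records, for every node i, both its shell value k_s(i) and the sweep
(stage) p(i) at which it fell; with q(k) sweeps in shell k, the **improved
k-shell index** is

    k_s*(i) = k_s(i) + p(i) / (max_k q(k) + 1)

so nodes peeled later — closer to the core — outrank earlier nodes of the
same shell, while the integer part stays the plain shell value. Adding the
degree gives the **DK index**, DK(i) = k(i) + k_s*(i), which combines local
and global structure and resolves ties that degree, shell, and even their
plain sum cannot.

Treating DK(i) as a mass in a truncated gravity law yields the **DK-based
gravity model (DKGM)**:

    DKGM(i) = Σ_{j ≠ i, d(i,j) ≤ R}  DK(i) · DK(j) / d(i,j)²

with hop distance d and truncation radius R (heuristically R* ≈ ⟨d⟩/2; on
small-world networks R = 2 or 3). The same engine with degree mass is the
local gravity model (LGM) and with shell mass at R = 3 is gravity centrality
(GC). The benchmark suite also provides degree, k-shell, H-index,
betweenness and closeness centralities.

Ground truth comes from a discrete-time SIR simulator (infection
probability β per contact, recovery after one infectious step): the
influence F(i) of node i is the mean final recovered fraction over many
outbreaks seeded at i, typically run at the epidemic threshold
β_c ≈ ⟨k⟩/(⟨k²⟩ − ⟨k⟩). Methods are scored by Kendall's tau against F
(tied pairs counted as neither concordant nor discordant) and by the
monotonicity M_r = [1 − Σ N_t(N_t − 1)/(N(N − 1))]² of their score vector,
which is 1 when every node gets a distinct score.

## Worked example

The package ships a 9-node network whose 2-shell peels in two stages, the
minimal setting where the staged index earns its keep:

```r
library(spreadrank)
net <- toy_network()
round(dkgm(net, radius = 2), 2)
#>      1      2      3      4      5      6      7      8      9
#>  20.61 116.44 143.08 228.56 210.22 210.22 289.58  30.53  30.53

evaluate_methods(net, methods = c("dc", "ks", "dkgm"),
                 beta = "auto", radius = 2,
                 realizations = 1000, rng_seed = 7)
#>   method    tau monotonicity   beta n
#> 1     dc 0.8056       0.6489 0.3824 9
#> 2     ks 0.7222       0.5216 0.3824 9
#> 3   dkgm 0.9444       0.8920 0.3824 9
```

Node 7 ranks first (it sits in the innermost shell with the highest degree);
nodes 2 and 3 — tied under degree, shell, and degree+shell — are separated
because node 3 is peeled one stage later. In the evaluation table, `beta` is
the resolved epidemic threshold 26/68, `tau` the rank agreement with the
simulated influence, and `monotonicity` the fraction-of-unique-ranks
resolution measure: DKGM is both the most accurate and the best resolved of
the three.

A command-line interface is installed as `exec/spreadrank` with subcommands
`stats`, `rank`, `sir`, `evaluate` and `synth`, e.g.

```sh
Rscript exec/spreadrank rank inst/extdata/toy.edges --method dkgm --radius 2
```

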