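# heatpass

Heat-kernel diffusion and exemplar message passing ("heat passing") for
weighted networks, with applications to community detection, protein-family
sorting from similarity matrices, and conformational-state discovery for
projection images.

## The problem

Given noisy pairwise relationships — network edges, sequence similarity
scores, image distances — a scientist usually wants three things at once:
a **ranking** of items against a query, a low-dimensional **embedding**
for inspection, and a **clustering** whose number of groups is not assumed
in advance.  `heatpass` derives all three from one object, the spectral
heat kernel of the graph

    H_t(i,j) = sum_k exp(-lambda_k t) phi_k(i) phi_k(j) = [exp(-t L_N)]_ij,

where `lambda_k`, `phi_k` are eigenpairs of the normalized Laplacian
`L_N = D^{-1/2}(D - W)D^{-1/2}`.  `H_t(i,j)` is the heat reaching node `j`
after time `t` when a unit of heat is applied at `i`; it pools evidence
over *all* paths, which is what makes it robust to individual noisy edges.

* Heat distance `D_t(i,j) = H_t(i,i) + H_t(j,j) - 2 H_t(i,j)` ranks nodes.
* Heat coordinates `(e^{-lambda_k t/2} phi_k(i))_k` embed them (squared
  Euclidean distances reproduce `D_t`).
* **Heat passing** finds cluster exemplars ("heat centers") and members
  ("heat sinks") by exchanging heat-absorption and heat-emission messages,
  initialized from each node's average temperature
  `Temp_t(i) = sum_{j != i} H_t(i,j)`.  The number of clusters emerges
  from the optimization of the net similarity
  `sum_i H_t(i, g_i)` under the constraint that exemplars select
  themselves.

For cryo-EM style projection images the package also implements the
common-line image distance (polar Fourier transform, best-matching line
pair) and a two-state phantom simulator, so the whole pipeline runs
without any external data.

## Worked example: the karate-club split

```r
library(heatpass)
g <- karate_graph()
print(g)
#> weighted_graph: 34 nodes, 78 edges, total weight 78

res <- heat_pass_graph(g, t = 4)   # defaults: normalized Laplacian,
print(res)                         # mean-temperature preference
#> heat_clustering: 2 center(s): 1, 34
#>   objective = 2.424301 ; iterations = 108 ; converged = TRUE
```

Two heat centers emerge — member 1 (the instructor) and member 34 (the
president), the two leaders the club actually split behind.  Their
average temperatures are the largest in the network (1.59 and 1.61; next
highest 1.35), which is why they are preferred as centers.  Comparing the
partition with the factions observed after the real-life split:

```r
pred <- ifelse(res$assignment == "1", "1", "34")
names(pred)[pred != karate_factions()]
#> [1] "9"
accuracy_index(res$assignment, karate_factions())
#> [1] 0.9705882
```

The single disagreement is member 9 — the famous borderline case who
sided with the instructor for personal reasons (a black-belt exam)
despite sitting structurally in the president's faction, which is where
the diffusion geometry places him.

## Command line

```sh
./exec/heatpass cluster --input inst/extdata/karate.tsv \
    --output clusters.tsv --report report.json
./exec/heatpass rank  --input inst/extdata/karate.tsv --query 1 --output rank.tsv
./exec/heatpass embed --input inst/extdata/karate.tsv --dim 3 --output coords.tsv
./exec/heatpass simulate phantoms --seed 7 --n-per-state 10 --snr 0.5 \
    --out-prefix sim
./exec/heatpass em-distance --stack sim_images.mrc --out dist.csv
./exec/heatpass cluster --input dist.csv --format distance --output img_clusters.tsv
./exec/heatpass evaluate --pred img_clusters.tsv --truth sim_truth.tsv
```

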