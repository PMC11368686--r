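# spatialcontrast

Reconstruct spatial relationships in dissociated single-cell RNA-seq (SC)
data from a spatial transcriptomics (ST) reference, by contrastive
representation learning.

Single-cell RNA-seq profiles the transcriptome but loses cell positions;
spatial platforms keep positions but trade off gene coverage or resolution.
`spatialcontrast` trains a multilayer-perceptron encoder on an ST reference
so that physically proximate cells obtain similar latent representations,
then applies it to SC queries to recover: nearest neighbors in
representation space, 2-D pseudo-space coordinates (metric MDS), assignment
of each query cell to a reference coordinate with an entropy-based
confidence score, and per-gene contributions to the spatial representation.
It is aimed at anyone who wants neighborhood-level spatial context — e.g.
for cell–cell communication or co-localization analyses — for cells that
were sequenced without it.

## The model

Training batches pair each anchor cell with one of its *k* spatial nearest
neighbors in the reference (*k* = 80 for single-cell-resolution, 20 for
spot-resolution platforms); the other batch members act as negatives. On
the L2-normalized outputs of a projection head, the infoNCE loss

```
L_q = -log( exp(q·k₊/τ) / Σᵢ exp(q·kᵢ/τ) ),   τ = 0.05
```

pulls positives together and pushes negatives apart (SGD, momentum 0.9,
weight decay 5e-4, cosine-decayed learning rate from 0.1). The projection
head is discarded after training; inference uses the encoder output, where
higher cosine similarity means shorter spatial distance. Everything —
network, backprop, optimizer — is implemented in base-R matrix algebra and
verified against finite differences and a brute-force loss oracle.

## Worked example

```r
library(spatialcontrast)

# a synthetic 5-zone tissue: 800 cells, 100 genes, smooth spatial
# gradients plus non-spatial cell-state factors and gaussian noise
ds  <- generate_spatial_dataset(sim_config(seed = 7))
ref <- spatial_dataset(log_normalize(ds$profile), ds$coords, ds$platform)

fit <- spatialcontrast(ref, model_config(epochs = 300, seed = 7))
fit
#> spatialcontrast model
#>   input genes:  100
#>   encoder:      400 -> 512 (batch norm + leaky ReLU)
#>   projector:    256 -> 128 (training only)
#>   reference:    800 cells [single_cell]
#>   epochs:       300; final loss 2.2512

# an independent replicate of the same tissue, positions withheld
q   <- make_query(ds, seed = 99)
qln <- log_normalize(q$profile)

nb    <- predict(fit, qln, type = "neighbors", k = 20)
hit20 <- neighbor_hit(nb, q$true_coords, 20)
hit20
#>    k20
#> 3.2375
```

A uniformly random predictor would recover `20^2/799 = 0.50` true
neighbors on average, so the trained encoder finds ~6.5x more. Continuing:

```r
jsd <- neighborhood_jsd(nb, q$true_coords, q$profile$cell_types, k = 20)
mean(jsd$per_cell)
#> [1] 0.1577909      # vs ~0.58 when locations are shuffled

mapped <- predict(fit, qln, type = "mapping")   # SC -> ST coordinates
head(mapped, 3)
#>      cell_id st_index     st_id         x         y confidence
#> 1 query_0001      583 cell_0583 0.9493306 0.4461057 0.09167304
#> 2 query_0002      594 cell_0594 0.4820199 0.9949016 0.03566513
#> 3 query_0003      651 cell_0651 0.2698861 0.7739455 0.05163811
```

`mean hit` counts true spatial k-nearest neighbors recovered among the
predicted k; `JSD` is the Jensen–Shannon distance between predicted and
true neighborhood cell-type compositions (0 = identical, √ln2 ≈ 0.83 =
disjoint); the mapping data frame gives each query cell's assigned
reference location and a confidence in [0, 1] (1 = unambiguous, 0 = most
ambiguous cell in the batch).

The same workflow is available from a shell via the installed script:

```sh
spatialcontrast simulate --n-cells 800 --seed 7 --query --out sim/
spatialcontrast train --st sim/reference.csv --epochs 300 --seed 7 --out run/
spatialcontrast map --checkpoint run/checkpoint.json --sc sim/query.csv --out map/
spatialcontrast evaluate --pred-neighbors map/neighbors.tsv \
    --truth sim/query_truth.csv --out eval/
```

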