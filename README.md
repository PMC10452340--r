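# graphSaliency

Channel-weighted gradient saliency for graph classifiers of cell-line drug
response.

## What this is for

Drug-response classifiers built on molecular networks take a cell-line–drug
instance as a graph: genes on a shared protein–protein interaction (PPI)
topology, each node carrying a few data channels — gene expression, a
kinase flag, drug binding affinity, a disease-association score — and
predict whether the drug is effective. This package explains such
predictions at the node level, for people who want to know *which kinases*
a model relied on, per prediction and per cancer type.

The attribution method is gradient saliency adapted to multi-channel
graphs. With pre-softmax class score `S_c`, node features `X` and fixed
adjacency, the per-node per-channel signal is

    W[i,k] = | dS_c / dX[i,k] |        (N x K)

Because molecular channels live on incomparable scales, the channel
dimension is not collapsed with a max (the image-style baseline, also
provided) but reweighted: the Gram matrix `G = W'W` summarizes channel
correlation, its column means `V` measure aggregate channel strength, and
each channel gets an inverse-document-frequency-style weight

    t_k = ln( (K*eps + sum_l v_l^r) / (eps + v_k^r) ),   r = 2, eps = 1e-8

so dominant channels are down-weighted and the final node map is the
matrix product `M = W T` (dimensions N×1 = N×K · K×1).

Around the method the package ships everything needed to study it end to
end at desk scale: a reference attention-propagation classifier
(embedding → GAT-style attention blocks → Set2Set readout → fully
connected head) with exact analytic gradients, a synthetic planted-driver
cohort generator over a scale-free PPI-like topology, leave-one-tissue-out
cross-validation with rank-based ROC/AUC, per-cancer-type importance
aggregation, and planted-driver recovery metrics.

## Worked example

```r
library(graphSaliency)

co    <- generateCohort(syntheticConfig(seed = 1))   # 5 tissues x 30 graphs
model <- trainModel(co$graphs,
                    modelConfig(embed_dim = 16, n_blocks = 2,
                                set2set_steps = 2, fc_layers = 16,
                                learning_rate = 1e-2, epochs = 200,
                                seed = 1))

predictGraph(model, co$graphs[[2]])
#> $class_scores    9.13 -9.32
#> $class_probs     1.00  9.72e-09
#> $predicted_class 0

explainGraph(model, co$graphs[[2]])
#> SaliencyExplanation: 60 nodes, 4 channels (class 0)
#>   channel weights: expression=1.435, kinase_flag=3.904,
#>                    binding_affinity=0.3846, disease_assoc=2.796
#>   top nodes: GENE034 (79.76), GENE055 (37.93), GENE002 (2.652), ...
```

The class scores say this graph is confidently predicted ineffective; the
channel weights show binding affinity carried the largest share of the
gradient energy (and is therefore down-weighted most), and the saliency
map concentrates on a handful of nodes. Aggregating over the graphs of
each tissue that the model predicts responsive, restricted to kinases:

```r
rep <- cohortImportance(model, co$graphs, kinaseIds = co$truth$kinaseIds)
topRanked(rep, 5)
#>   group rank node_id     score
#>  breast    1 GENE055 0.4274816
#>  breast    2 GENE049 0.3504485
#>  breast    3 GENE044 0.3410373
#>  breast    4 GENE020 0.2291152
#>  breast    5 GENE003 0.1259070
#>  ...

driverRecovery(rep, co$truth, 5)
#>           group precision recall
#>          breast       0.6      1
#>       digestive       0.6      1
#>       excretory       0.6      1
#>  haematopoietic       0.6      1
#>     respiratory       0.6      1
```

The three kinases planted as breast drivers (`GENE044`, `GENE049`,
`GENE055`) occupy the top three breast ranks; recall 1 in every tissue
means all planted drivers sit inside the top 5 of 12 kinases (precision@5
is capped at 3/5 = 0.6 with three drivers).

A thin command-line front end with subcommands `simulate`, `train`,
`explain`, `evaluate`, `report` lives in `inst/scripts/graphsal`; data
interchange is headered TSV (`edges.tsv`, `nodes.tsv`, `labels.tsv`),
configs are YAML/JSON, models serialize to JSON.

See the vignette (`vignettes/channel-weighted-saliency.Rmd`) for the
model, the generator's assumptions, and the reasoning behind the design
choices.

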