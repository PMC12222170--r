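# gtmaloc

Multi-label prediction of **miRNA subcellular localization** from
multi-source biological networks.

MicroRNAs function where they reside — exported in exosomes and
microvesicles, retained in the nucleus or nucleolus, docked at
mitochondria — and a single miRNA may occupy several compartments at
once.  `gtmaloc` predicts, for each miRNA, a probability for each of
seven compartments (cytoplasm, nucleus, nucleolus, mitochondrion,
exosome, microvesicle, extracellular vesicle) by integrating five
miRNA-centric networks:

1. **Sequence similarity** — Smith–Waterman local alignment, normalized
   as `SW(i,j) = sp(i,j) / sqrt(sp(i,i) sp(j,j))`; kept weighted.
2. **Functional similarity** — disease-DAG semantics (depth-discounted
   ancestor contributions `C(d_t,d_i) = a / Depth(d_t,d_i)`, semantic
   values, best-match-average over miRNA disease sets) fused with the
   Gaussian interaction profile kernel,
   `FS* = λ FS + (1−λ) GIP` (λ = 0.5), thresholded at `FS* > 0.6` into
   the functional adjacency.
3. **miRNA–mRNA**, **miRNA–drug**, **miRNA–disease** bipartite
   association networks.

Each feature network is embedded with **node2vec** (64-d sequence, 128-d
associations), refined by a **graph transformer** — masked multi-head
attention with Pre-LN over the functional adjacency, trained
unsupervised on the edge-reconstruction loss
`−Σ_{E+} log σ(hᵢᵀhⱼ) − Σ_{E−} log(1 − σ(hᵢᵀhⱼ))` — and the four
per-source tables are fused per miRNA by transformer-style **multi-head
attention** (4 tokens → scaled dot-product attention → FFN → flatten)
into a 7-way sigmoid classification head (positive call when the
probability strictly exceeds 0.5).

A planted-group **synthetic data generator** ships with the package, so
the full pipeline is trainable, testable and reproducible with no
external database; loaders for the standard formats (FASTA, TSV edge
lists, child→parent DAG TSV, labels CSV) accept real curated data in the
same shapes.

## Worked example

```r
library(gtmaloc)

model <- planted_model(n_mirna = 120, n_disease = 30, n_drug = 20,
                       n_mrna = 60, seed = 11)
ds <- generate_dataset(model)        # in-memory bundle; add out_dir= to write files
cfg <- gtmaloc_config("fast")        # reduced-size training preset
feats <- gtmaloc_features(ds, cfg)   # networks -> node2vec -> graph transformer
cv <- cross_validate(feats, k = 5, seed = 11)
cv
#> 5-fold cross-validation (seq+mrna+drug+disease)
#>      cytoplasm nucleus nucleolus mitochondrion exosome microvesicle
#> AUC     0.9593  0.9860    0.9697        0.9568  0.9543       0.9866
#> AUPR    0.9630  0.9919    0.9762        0.9379  0.9741       0.9938
#>      extracellular_vesicle
#> AUC                 0.9697
#> AUPR                0.9762
#> macro AUC 0.9689 | macro AUPR 0.9733
```

The per-class rows are fold-averaged AUC / AUPR for each compartment;
the macro numbers are their unweighted means.  Values near 1 say the
pipeline recovered the planted group structure linking all five networks
to the labels; a label-permuted control sits at chance (≈ 0.5).

Fitting and ranking directly:

```r
fit <- gtmaloc(feats$tokens, ds$labels, config = cfg)   # fusion classifier
pred <- predict(fit, feats$tokens)                      # probabilities + calls
top_k_per_compartment(pred, k = 3)$exosome
#> [1] "miR-0051" "miR-0098" "miR-0111"
```

`run_ablation()` re-evaluates with one component removed (a source
network, the graph transformer, or the attention fusion);
`head_count_study()` sweeps the attention head count on shared folds.

A command-line front end wraps the same functions:

```sh
gtmaloc simulate --seed 3 --out data/
gtmaloc evaluate --data data/ --out results/ --folds 5 --seed 3 --fast
gtmaloc --help
```

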