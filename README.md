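# jsnmf

Joint symmetric non-negative matrix factorization for clustering
multi-subject weighted networks into shared modules, with module-quality
indices and a module-based feature-selection + classification pipeline.

## What problem this solves

In resting-state fMRI studies every subject contributes one functional
brain network: a symmetric matrix of (thresholded, non-negative) Pearson
correlations between regions of interest. Individual edges vary between
subjects, but the modular organization — which regions belong together —
is largely shared. Two questions follow:

1. **What are the shared modules?** Find one partition of the nodes that
   fits *all* subject networks at once, not a partition of one subject or
   of a blurred average.
2. **Are modules better feature masks than whole networks?** For
   case/control classification (e.g. autism spectrum disorder vs typical
   development), are edge-weight features restricted to one module — such
   as the default mode network — more discriminative than the full
   ~N²/2-dimensional edge vector?

The package answers (1) with a joint factorization: every view
A⁽ᵛ⁾ is approximated as **H S⁽ᵛ⁾ Hᵀ**, where H ≥ 0 is one shared N×K
module-indicator matrix and S⁽ᵛ⁾ ≥ 0 is a per-subject K×K matrix
absorbing subject-specific module expression. The objective is

```
O = Σᵥ ‖A⁽ᵛ⁾ − H S⁽ᵛ⁾ Hᵀ‖²_F + 4α Σₖ ‖hₖ‖₁ ,  H ≥ 0, S⁽ᵛ⁾ ≥ 0
```

minimized by alternating the closed-form solve
S⁽ᵛ⁾ = (HᵀH)⁻¹HᵀA⁽ᵛ⁾H(HᵀH)⁻¹ (clipped at 0) with the multiplicative
update H ← H ⊙ (Σᵥ A⁽ᵛ⁾HS⁽ᵛ⁾) ⊘ (Σᵥ HS⁽ᵛ⁾HᵀHS⁽ᵛ⁾ + αE). Nodes are
assigned to modules by the row-wise argmax of the column-normalized H.
For (2) it provides leave-one-out evaluation of seven classifier families
with the ROC/AUC conventions matched to score type (margin sweeps for
SVMs, unit-interval sweeps for probabilistic classifiers), plus RFE and
binary-PSO feature-selection wrappers.

Everything is exercisable end to end on synthetic data: generators plant
a known module structure in multi-view networks and a module-localized
group effect in labeled cohorts, so recovery and the module-vs-whole
claim can be tested without any imaging data.

## Worked example

Three small example networks (16 nodes, two planted modules) ship with
the package:

```r
library(jsnmf)

paths <- system.file("extdata", paste0("example_view_", 1:3, ".tsv"),
                     package = "jsnmf")
views <- lapply(paths, read_network, format = "dense")
set   <- multiview_set(lapply(views, preprocess_fbn, threshold = 0.35))
set
#> multiview_set: 3 views over 16 nodes

fits <- jsnmf_restarts(set, jsnmf_config(K = 2, alpha = 1, seed = 1),
                       runs = 5)
best <- select_representative_run(lapply(fits, `[[`, "partition"))
fit  <- fits[[best]]
fit
#> jsnmf_fit: N=16, K=2, 500 iterations (iteration cap), objective 70.4693 -> 22.478

p <- fit$partition; names(p) <- set$node_ids
p
#> partition: 16 nodes in 2 modules (sizes: 8, 8)

q <- module_quality(average_network(set), p)
sprintf("modularity %.4f | conductance %.4f | coverage %.4f",
        q$modularity, q$conductance, q$coverage)
#> "modularity 0.4803 | conductance 0.9804 | coverage 0.9804"
```

The partition splits the 16 nodes into the two planted 8-node modules.
Modularity 0.48 means 48 percentage points more intra-module weight than
expected under the degree-preserving null; conductance/coverage ≈ 0.98
mean almost all surviving edge weight is intra-module. Matching a module
against a reference node list (how one pins an anatomical system like the
default mode network onto the data-driven partition):

```r
ref <- readLines(system.file("extdata", "example_reference_nodes.txt",
                             package = "jsnmf"))
match_module_to_reference(p, ref)
#> $module
#> [1] 1
#> $overlap
#> [1] 1
```

For a labeled cohort, `compare_feature_scopes()` runs the LOOCV AUC
comparison between module-restricted and whole-network edge features,
and `run_pipeline()` chains every stage (preprocess → joint clustering on
the control group → representative run → quality indices → module
matching → feature extraction → classification) into one reproducible
artifact directory. A command-line front end over the same functions is
installed at `system.file("cli", "jsnmf-cli.R", package = "jsnmf")` with
subcommands `simulate`, `preprocess`, `cluster`, `metrics`,
`match-module`, `extract`, `classify` and `run`.

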