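# multigrank

Multiple-graph regularized ranking for protein domain retrieval.

## The problem

Given a query protein domain described by a fixed-length structural feature
vector (such as a 32-dimensional tableau descriptor), retrieval means
returning the database domains most likely to share the query's fold, ranked
by relevance. Classical pairwise methods score each database domain by its
direct similarity to the query and ignore the global geometry of the
database. Graph-regularized ranking instead propagates the query's relevance
signal over a K-nearest-neighbor graph of the database, exploiting the
manifold structure of the domain distribution — but its performance is
sensitive to the choice of graph model and parameters, for which there is no
general rule.

`multigrank` addresses the model-selection problem by *combining* graphs. A
pool of M candidate K-NN graphs is built under five edge-weighting schemes
(Gaussian kernel at several bandwidths, dot product, cosine, Jaccard,
Tanimoto), and the composite Laplacian is a convex combination
`L = Σ_m μ_m L_m` with weights `μ` on the probability simplex, learned from
the database's fold labels.

## The model

**Single-graph ranking (G-Rank).** The score vector `f` minimizes

    (f − y)ᵀ U (f − y) + α fᵀ L f

where `y` is the 0/1 relevance vector, `U` selects the entries of `y` that
are known (on-line, only the query's own), `L = D − W` is the graph
Laplacian, and `α` trades smoothness against fidelity. The minimizer solves
the linear system `(U + αL) f = U y`.

**Off-line weight learning.** With all database labels known, every domain
serves as a query at once (`U = I`, relevance matrix `Y` from label
equality), and the joint objective

    Tr((F−Y)ᵀ(F−Y)) + α Σ_m μ_m Tr(Fᵀ L_m F) + β‖μ‖²,   μ ∈ simplex

is minimized by alternating two exact convex steps: a closed-form solve
`F = (I + α Σ_m μ_m L_m)⁻¹ Y` and a simplex-constrained quadratic program in
`μ` (solved exactly by projection onto the simplex). The objective is
provably non-increasing at every half-step. The `β‖μ‖²` term discourages
collapse onto a single graph.

**On-line ranking.** A new query is attached incrementally to each pre-built
graph (only N new edge weights per graph), the extended Laplacians are
combined with the learned `μ`, and the system above is solved with
`y = (1, 0, …, 0)`. Database domains are returned in descending score order.

Retrieval quality is evaluated with ROC / recall–precision curves swept over
every list length, and the AUC, at fold, superfamily or family relevance
levels.

## Worked example

```r
library(multigrank)

# a fold-structured synthetic database: 6 folds x 10 domains, 32 features
db    <- generate_synthetic_database(n_folds = 6, domains_per_fold = 10,
                                     dim = 32, separation = 6, noise_sd = 1,
                                     seed = 7)
specs <- default_graph_specs(db, k = 5)        # M = 8 candidate graphs
pool  <- build_graph_pool(db, specs)
w     <- learn_graph_weights(laplacian_pool(pool), db$labels, alpha = 0.01)
print(w)
#> graph_weights: M=8, 4 iteration(s) (converged), alpha=0.01, beta=1.083
#>   gaussian(k=5, sigma=4.68667, sigma_scale=0.5) mu = 1.0000
#>   gaussian(k=5, sigma=9.37335, sigma_scale=1) mu = 0.0000
#>   ...
```

The learner put all weight on the sharpest Gaussian graph — on this
database it is the candidate whose edges best respect fold boundaries
(smallest label-smoothness penalty `e_m = Tr(FᵀL_mF)`).

```r
query  <- generate_synthetic_queries(db, 1, seed = 8)[[1]]
ranked <- rank_query(db, query, pool, w, top = 5)
print(ranked)
#> ranked_list: 5 domains
#>  rank    id     score
#>     1 d0032 0.9999642
#>     2 d0041 0.9999612
#>     3 d0027 0.9999609
#>     4 d0009 0.9999591
#>     5 d0025 0.9999578
```

The top hit d0032 shares the query's fold (F04). Averaging over a query
set gives the usual retrieval summary, here against the pairwise baseline:

```r
queries <- generate_synthetic_queries(db, 10, seed = 8)
mean_auc(queries, db, function(db, q) rank_query(db, q, pool, w))$mean
#> [1] 0.9422042
mean_auc(queries, db, function(db, q) pairwise_rank(db, q, "cosine"))$mean
#> [1] 0.8894345
```

The full benchmark (N = 200, 10 folds, 40 queries, M = 8) compares
multi-graph ranking with every single-graph ranker and the pairwise
baseline:

```r
run_benchmark(seed = 1)
#> multigrank_benchmark: N=200 (10 folds), 40 queries, M=8, seed=1
#>                                                 method mean_auc sd_auc
#>                                            MultiG-Rank   0.9669 0.0552
#>  G-Rank[gaussian(k=5, sigma=4.90438, sigma_scale=0.5)]   0.9669 0.0552
#>    ...
#>                                   G-Rank[jaccard(k=5)]   0.9556 0.0699
#>                                       Pairwise[cosine]   0.9114 0.0665
```

Multi-graph ranking matches the best candidate graph — without knowing in
advance which one it is — and clearly beats the pairwise baseline.

## Command-line interface

A thin Rscript wrapper over the same functions lives at
`inst/cli/multigrank.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "multigrank.R", package = "multigrank"))')
Rscript $CLI learn-weights --features db.tsv --config pool.yaml --out mu.json
Rscript $CLI rank --features db.tsv --query query.tsv --config pool.yaml \
                  --weights mu.json --top 50 --out ranked.tsv
Rscript $CLI evaluate --features db.tsv --queries queries.tsv \
                  --ranked-dir runs/ --level fold --out metrics.csv
Rscript $CLI benchmark --seed 1 --out-dir bench/
```

`pool.yaml` declares the candidate graphs (`- {model: gaussian, k: 5,
sigma_scale: 1}` …); `mu.json` records the learned weights together with a
hash of the spec list, so ranking refuses a mismatched pool. Exit codes: 0
success, 2 input error, 3 numerical error. Feature tables are TSV/CSV with
columns `id`, `label` (optionally `fold`, `superfamily`, `family`) and
`f1..fd`; a small synthetic fixture ships in `inst/extdata/`.

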