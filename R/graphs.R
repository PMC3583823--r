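#' Specify a K-nearest-neighbor graph
#'
#' Five edge-weighting models are supported. Neighbors are found by the
#' comparison rule each model states: `gaussian` and `dot_product` compare
#' squared Euclidean distance; `cosine`, `jaccard` and `tanimoto` compare
#' their own similarity.
#'
#' @param model one of `"gaussian"`, `"dot_product"`, `"cosine"`,
#'   `"jaccard"`, `"tanimoto"`.
#' @param k number of nearest neighbors (must be `< N` at build time).
#' @param sigma Gaussian kernel bandwidth (`gaussian` only; > 0).
#' @param sigma_scale alternative to `sigma`: bandwidth as a multiple of the
#'   median pairwise Euclidean distance of the database, resolved when the
#'   graph is built.
#' @return an object of class `graph_spec`.
#' @export
graph_spec <- function(model = c("gaussian", "dot_product", "cosine",
                                 "jaccard", "tanimoto"),
                       k, sigma = NULL, sigma_scale = NULL) {
  model <- match.arg(model)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) mg_stop_input("k must be a positive integer")
  if (model == "gaussian") {
    if (is.null(sigma) && is.null(sigma_scale))
      mg_stop_input("gaussian model needs sigma or sigma_scale")
    if (!is.null(sigma) && sigma <= 0) mg_stop_input("sigma must be > 0")
    if (!is.null(sigma_scale) && sigma_scale <= 0)
      mg_stop_input("sigma_scale must be > 0")
  } else {
    sigma <- NULL; sigma_scale <- NULL
  }
  structure(list(model = model, k = k, sigma = sigma,
                 sigma_scale = sigma_scale),
            class = "graph_spec")
}

#' @export
print.graph_spec <- function(x, ...) {
  cat(spec_label(x), "\n"); invisible(x)
}

spec_label <- function(spec) {
  s <- sprintf("%s(k=%d", spec$model, spec$k)
  if (!is.null(spec$sigma)) s <- sprintf("%s, sigma=%.6g", s, spec$sigma)
  if (!is.null(spec$sigma_scale))
    s <- sprintf("%s, sigma_scale=%g", s, spec$sigma_scale)
  paste0(s, ")")
}

# Neighbor-comparison rule for each weighting model.
model_affinity <- function(model) {
  switch(model,
         gaussian = "sq_euclidean", dot_product = "sq_euclidean",
         cosine = "cosine", jaccard = "jaccard", tanimoto = "tanimoto",
         mg_stop_input("unknown model: ", model))
}

affinity_is_distance <- function(affinity) affinity == "sq_euclidean"

# Full pairwise affinity matrix (N x N). `ids` only used in error messages.
affinity_matrix <- function(X, affinity, ids = NULL) {
  G <- tcrossprod(X)
  ss <- diag(G)
  switch(affinity,
    sq_euclidean = {
      A <- outer(ss, ss, "+") - 2 * G
      A[A < 0] <- 0  # guard tiny negative round-off
      A
    },
    cosine = {
      nrm <- sqrt(ss)
      check_nonzero_norm(nrm, ids, "cosine")
      G / outer(nrm, nrm)
    },
    tanimoto = {
      check_nonzero_norm(sqrt(ss), ids, "tanimoto")
      G / (outer(ss, ss, "+") - G)
    },
    jaccard = {
      if (min(X) < 0)
        mg_stop_input("jaccard affinity requires nonnegative features")
      s <- rowSums(X)
      man <- as.matrix(stats::dist(X, method = "manhattan"))
      num <- (outer(s, s, "+") - man) / 2
      den <- (outer(s, s, "+") + man) / 2
      A <- num / den
      A[den == 0] <- 0  # both vectors all-zero
      A
    },
    mg_stop_input("unknown affinity: ", affinity))
}

check_nonzero_norm <- function(nrm, ids, what) {
  z <- which(nrm == 0)
  if (length(z)) {
    nm <- if (is.null(ids)) paste(z, collapse = ", ")
          else paste(ids[z], collapse = ", ")
    mg_stop_input(what, " weighting is undefined for zero-norm vector(s): ", nm)
  }
}

# Affinity of one vector x against all rows of X.
affinity_vector <- function(x, X, affinity, id = "query", ids = NULL) {
  g <- drop(X %*% x)
  ssx <- sum(x * x)
  ss <- rowSums(X * X)
  switch(affinity,
    sq_euclidean = pmax(ss + ssx - 2 * g, 0),
    cosine = {
      if (ssx == 0) mg_stop_input("cosine weighting is undefined for zero-norm vector: ", id)
      check_nonzero_norm(sqrt(ss), ids, "cosine")
      g / (sqrt(ss) * sqrt(ssx))
    },
    tanimoto = {
      if (ssx == 0) mg_stop_input("tanimoto weighting is undefined for zero-norm vector: ", id)
      check_nonzero_norm(sqrt(ss), ids, "tanimoto")
      g / (ss + ssx - g)
    },
    jaccard = {
      if (min(x) < 0 || min(X) < 0)
        mg_stop_input("jaccard affinity requires nonnegative features")
      man <- colSums(abs(t(X) - x))
      s <- rowSums(X)
      num <- (s + sum(x) - man) / 2
      den <- (s + sum(x) + man) / 2
      a <- num / den
      a[den == 0] <- 0
      a
    },
    mg_stop_input("unknown affinity: ", affinity))
}

#' K-nearest-neighbor index sets
#'
#' For each domain, the `k` nearest others under the given comparison rule
#' (`sq_euclidean`: the `k` smallest distances; similarities: the `k`
#' largest), excluding the domain itself. Ties are broken deterministically
#' by affinity, then by lower index.
#'
#' @param db a `domain_database`.
#' @param k number of neighbors, `1 <= k < N`.
#' @param affinity `"sq_euclidean"`, `"cosine"`, `"jaccard"` or
#'   `"tanimoto"`.
#' @return list with `neighbors` (list of length-`k` integer vectors) and
#'   `kth` (numeric vector of each domain's k-th best affinity value, used
#'   for incremental query insertion).
#' @export
knn_neighbors <- function(db, k, affinity = c("sq_euclidean", "cosine",
                                              "jaccard", "tanimoto")) {
  affinity <- match.arg(affinity)
  n <- n_domains(db)
  k <- as.integer(k)
  if (k >= n) mg_stop_input("k = ", k, " must be smaller than N = ", n)
  if (k < 1L) mg_stop_input("k must be >= 1")
  A <- affinity_matrix(db$features, affinity, db$ids)
  dist_like <- affinity_is_distance(affinity)
  neighbors <- vector("list", n)
  kth <- numeric(n)
  idx <- seq_len(n)
  for (i in idx) {
    a <- A[i, ]
    cand <- idx[-i]
    v <- a[-i]
    ord <- if (dist_like) order(v, cand, method = "radix")
           else order(-v, cand, method = "radix")
    sel <- ord[seq_len(k)]
    neighbors[[i]] <- cand[sel]
    kth[i] <- v[sel[k]]
  }
  list(neighbors = neighbors, kth = kth, affinity = affinity)
}

#' Build a weighted K-nearest-neighbor graph
#'
#' Edges follow the union rule: `(i, j)` is an edge when `j` is among `i`'s
#' `k` nearest neighbors or vice versa. Edge weights use the model formula:
#' Gaussian `exp(-||xi-xj||^2 / (2 sigma^2))`, dot product `xi'xj`, cosine
#' `xi'xj/(||xi|| ||xj||)`, Jaccard `sum(min)/sum(max)`, Tanimoto
#' `xi'xj/(||xi||^2+||xj||^2-xi'xj)`. Negative weights (possible for dot
#' product, cosine and Tanimoto on signed features) are clamped to zero,
#' with a message, because Laplacian regularization assumes nonnegative
#' weights.
#'
#' @param db a `domain_database`.
#' @param spec a `graph_spec`; a `sigma_scale` is resolved here against the
#'   median pairwise Euclidean distance of `db`.
#' @return an object of class `domain_graph`: fields `spec` (with resolved
#'   `sigma`), `W` (symmetric nonnegative matrix, zero diagonal),
#'   `neighbors`, `kth`, `affinity`, `ids`.
#' @export
build_graph <- function(db, spec) {
  if (!inherits(spec, "graph_spec")) mg_stop_input("spec must be a graph_spec")
  spec <- resolve_sigma(spec, db)
  affinity <- model_affinity(spec$model)
  nn <- knn_neighbors(db, spec$k, affinity)
  n <- n_domains(db)
  E <- matrix(FALSE, n, n)
  for (i in seq_len(n)) E[i, nn$neighbors[[i]]] <- TRUE
  E <- E | t(E)
  W <- edge_weights(db$features, spec, db$ids)
  dimnames(W) <- NULL
  W[!E] <- 0
  diag(W) <- 0
  neg <- W < 0
  if (any(neg)) {
    message("build_graph: clamped ", sum(neg) / 2, " negative ", spec$model,
            " edge weight(s) to 0")
    W[neg] <- 0
  }
  structure(list(spec = spec, W = W, neighbors = nn$neighbors, kth = nn$kth,
                 affinity = affinity, ids = db$ids),
            class = "domain_graph")
}

resolve_sigma <- function(spec, db) {
  if (spec$model == "gaussian" && is.null(spec$sigma)) {
    med <- stats::median(stats::dist(db$features))
    if (med <= 0)
      mg_stop_input("cannot resolve sigma_scale: median pairwise distance is 0")
    spec$sigma <- spec$sigma_scale * med
  }
  spec
}

# Full dense weight matrix under the model formula (before edge masking).
edge_weights <- function(X, spec, ids = NULL) {
  switch(spec$model,
    gaussian = exp(-affinity_matrix(X, "sq_euclidean", ids) / (2 * spec$sigma^2)),
    dot_product = tcrossprod(X),
    cosine = affinity_matrix(X, "cosine", ids),
    jaccard = affinity_matrix(X, "jaccard", ids),
    tanimoto = affinity_matrix(X, "tanimoto", ids))
}

# Model weight between one vector and the rows of X.
edge_weights_vector <- function(x, X, spec, id = "query", ids = NULL) {
  switch(spec$model,
    gaussian = exp(-affinity_vector(x, X, "sq_euclidean") / (2 * spec$sigma^2)),
    dot_product = drop(X %*% x),
    cosine = affinity_vector(x, X, "cosine", id, ids),
    jaccard = affinity_vector(x, X, "jaccard", id, ids),
    tanimoto = affinity_vector(x, X, "tanimoto", id, ids))
}

#' Graph Laplacian `L = D - W`
#'
#' @param g a `domain_graph`, or a symmetric nonnegative weight matrix.
#' @return the Laplacian matrix: symmetric, positive semi-definite, rows
#'   summing to zero.
#' @export
graph_laplacian <- function(g) {
  W <- if (inherits(g, "domain_graph")) g$W else as.matrix(g)
  if (!isSymmetric(unname(W), tol = 1e-12))
    mg_stop_internal("weight matrix is not symmetric")
  L <- -W
  diag(L) <- diag(L) + rowSums(W)
  L
}

#' Build a pool of graphs / Laplacians
#'
#' `build_graph_pool()` builds and keeps the weighted graphs (needed for
#' incremental query extension); `build_pool()` returns the corresponding
#' Laplacian pool used by the off-line weight learner.
#'
#' @param db a `domain_database`.
#' @param specs list of `graph_spec` objects (length `M >= 1`); order is
#'   preserved. Duplicate specs are allowed (and noted).
#' @return `build_graph_pool()`: an object of class `graph_pool` (fields
#'   `graphs`, `specs`, `n`); `build_pool()`: class `laplacian_pool`
#'   (fields `laplacians`, `specs`).
#' @export
build_graph_pool <- function(db, specs) {
  if (inherits(specs, "graph_spec")) specs <- list(specs)
  if (!length(specs)) mg_stop_input("need at least one graph_spec")
  labs <- vapply(specs, spec_label, "")
  if (anyDuplicated(labs))
    message("build_graph_pool: pool contains duplicate specs: ",
            paste(unique(labs[duplicated(labs)]), collapse = "; "))
  graphs <- lapply(specs, function(s) build_graph(db, s))
  structure(list(graphs = graphs,
                 specs = lapply(graphs, `[[`, "spec"),
                 n = n_domains(db)),
            class = "graph_pool")
}

#' @rdname build_graph_pool
#' @export
build_pool <- function(db, specs) {
  laplacian_pool(build_graph_pool(db, specs))
}

#' @rdname build_graph_pool
#' @param pool a `graph_pool`.
#' @export
laplacian_pool <- function(pool) {
  if (!inherits(pool, "graph_pool")) mg_stop_input("pool must be a graph_pool")
  structure(list(laplacians = lapply(pool$graphs, graph_laplacian),
                 specs = pool$specs),
            class = "laplacian_pool")
}

#' @export
print.laplacian_pool <- function(x, ...) {
  cat(sprintf("laplacian_pool: M=%d graphs over N=%d domains\n",
              length(x$laplacians), nrow(x$laplacians[[1L]])))
  for (s in x$specs) cat("  -", spec_label(s), "\n")
  invisible(x)
}

#' Default candidate graph pool
#'
#' Gaussian graphs at bandwidths `sigma_scales` times the median pairwise
#' distance, plus dot-product, cosine and Tanimoto graphs, plus a Jaccard
#' graph when all features are nonnegative -- each at every `k`. With one
#' `k` and four bandwidth scales this yields `M = 8` candidates on
#' nonnegative data.
#'
#' @param db a `domain_database`.
#' @param k neighbor counts (vector allowed).
#' @param sigma_scales Gaussian bandwidth multiples of the median pairwise
#'   distance.
#' @return list of `graph_spec` objects.
#' @export
default_graph_specs <- function(db, k = 5L, sigma_scales = c(0.5, 1, 2, 4)) {
  specs <- list()
  for (kk in k) {
    for (s in sigma_scales)
      specs <- c(specs, list(graph_spec("gaussian", kk, sigma_scale = s)))
    specs <- c(specs, list(graph_spec("dot_product", kk),
                           graph_spec("cosine", kk),
                           graph_spec("tanimoto", kk)))
    if (min(db$features) >= 0)
      specs <- c(specs, list(graph_spec("jaccard", kk)))
  }
  specs
}

#' Extend a database graph with a query node
#'
#' Adds the query as node 1 of an `(N+1)`-node graph. Database-internal
#' edges and weights are frozen (pre-computed off-line); only query--database
#' weights are added. A query--j edge exists when j is among the query's `k`
#' nearest database domains, or the query beats j's current k-th neighbor
#' (ties resolve in the query's favor, consistent with the lower-index
#' tie-break).
#'
#' @param g a `domain_graph` built on `db`.
#' @param db the `domain_database` the graph was built on.
#' @param query a `domain_query` with matching dimension.
#' @return an `(N+1) x (N+1)` weight matrix of class `extended_graph`
#'   (row/column 1 is the query; rows 2..N+1 reproduce `g$W` exactly).
#' @export
extend_graph <- function(g, db, query) {
  if (!inherits(g, "domain_graph")) mg_stop_input("g must be a domain_graph")
  check_query_dim(db, query)
  n <- n_domains(db)
  a <- affinity_vector(query$features, db$features, g$affinity,
                       id = query$id, ids = db$ids)
  dist_like <- affinity_is_distance(g$affinity)
  ord <- if (dist_like) order(a, seq_len(n), method = "radix")
         else order(-a, seq_len(n), method = "radix")
  in_Nq <- logical(n)
  in_Nq[ord[seq_len(g$spec$k)]] <- TRUE
  # query (index 0, lowest) enters j's neighbor set on ties with j's k-th
  q_in_Nj <- if (dist_like) a <= g$kth else a >= g$kth
  edge <- in_Nq | q_in_Nj
  w <- unname(edge_weights_vector(query$features, db$features, g$spec,
                                  id = query$id, ids = db$ids))
  w[!edge] <- 0
  w[w < 0] <- 0
  W <- matrix(0, n + 1L, n + 1L)
  W[2:(n + 1L), 2:(n + 1L)] <- g$W
  W[1L, 2:(n + 1L)] <- w
  W[2:(n + 1L), 1L] <- w
  structure(W, class = c("extended_graph", "matrix", "array"),
            query_id = query$id, ids = c(query$id, db$ids))
}
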