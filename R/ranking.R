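#' Relevance specification for graph-regularized ranking
#'
#' The relevance vector `y` is 1 for domains known to be relevant and 0
#' otherwise; `known` marks the entries whose relevance is actually known
#' (the diagonal of the selection matrix `U`). In the on-line setting only
#' the query itself is known relevant.
#'
#' @param y 0/1 numeric vector.
#' @param known logical vector, same length; at least one `TRUE`.
#' @return object of class `relevance_spec`.
#' @export
relevance_spec <- function(y, known) {
  y <- as.numeric(y)
  known <- as.logical(known)
  if (length(y) != length(known))
    mg_stop_input("y and known differ in length")
  if (!any(known)) mg_stop_input("at least one relevance entry must be known")
  if (!all(y %in% c(0, 1))) mg_stop_input("y must be 0/1")
  structure(list(y = y, known = known), class = "relevance_spec")
}

#' Ranker configuration
#'
#' @param alpha trade-off of the graph-smoothness penalty against fidelity
#'   to the known relevance (> 0). Default 0.01.
#' @param ridge small nonnegative diagonal regularizer guarding the case
#'   where a graph component contains no known-relevance node (there the
#'   unregularized system is singular). Default `1e-8`.
#' @return object of class `ranker_config`.
#' @export
ranker_config <- function(alpha = 0.01, ridge = 1e-8) {
  if (alpha <= 0) mg_stop_input("alpha must be > 0")
  if (ridge < 0) mg_stop_input("ridge must be >= 0")
  structure(list(alpha = alpha, ridge = ridge), class = "ranker_config")
}

#' Convex combination of a Laplacian pool
#'
#' Computes `L = sum_m mu_m L_m`; a convex combination of symmetric PSD
#' Laplacians is itself a symmetric PSD Laplacian.
#'
#' @param pool a `laplacian_pool` or a plain list of Laplacian matrices.
#' @param mu weight vector on the probability simplex (`sum(mu) = 1`,
#'   `mu >= 0`, checked to `1e-8`).
#' @return combined Laplacian matrix.
#' @export
combine_laplacians <- function(pool, mu) {
  Ls <- if (inherits(pool, "laplacian_pool")) pool$laplacians else pool
  mu <- as_mu(mu, length(Ls))
  L <- mu[1L] * Ls[[1L]]
  for (m in seq_along(Ls)[-1L]) if (mu[m] != 0) L <- L + mu[m] * Ls[[m]]
  L
}

as_mu <- function(mu, m) {
  if (inherits(mu, "graph_weights")) mu <- mu$mu
  mu <- as.numeric(mu)
  if (length(mu) != m)
    mg_stop_input("mu has length ", length(mu), " but the pool has M = ", m)
  if (any(mu < -1e-8) || abs(sum(mu) - 1) > 1e-8)
    mg_stop_input("mu must lie on the probability simplex (sum 1, nonnegative)")
  pmax(mu, 0)
}

#' Solve the graph-regularized ranking system (G-Rank)
#'
#' Minimizes `(f - y)' U (f - y) + alpha f' L f`, whose stationarity
#' condition is the linear system `(U + alpha L) f = U y`. The system is
#' solved by Cholesky factorization (never an explicit inverse), with an
#' optional ridge on the diagonal; the residual is checked to
#' `1e-8 * max(1, ||Uy||_inf)`.
#'
#' @param L graph Laplacian (`n x n`).
#' @param rel a `relevance_spec` of length `n`.
#' @param cfg a `ranker_config`.
#' @return numeric score vector `f` of length `n`.
#' @export
grank_solve <- function(L, rel, cfg = ranker_config()) {
  n <- nrow(L)
  if (length(rel$y) != n)
    mg_stop_input("relevance length ", length(rel$y), " != n = ", n)
  u <- as.numeric(rel$known)
  A <- cfg$alpha * L
  diag(A) <- diag(A) + u + cfg$ridge
  b <- u * rel$y
  R <- tryCatch(chol(A), error = function(e) {
    if (cfg$ridge == 0)
      mg_stop_solver("ranking system is singular (a graph component may ",
                     "contain no known-relevance node); retry with ridge > 0")
    mg_stop_solver("Cholesky factorization failed: ", conditionMessage(e))
  })
  f <- backsolve(R, backsolve(R, b, transpose = TRUE))
  res <- max(abs(A %*% f - b))
  if (res > 1e-8 * max(1, max(abs(b))))
    mg_stop_solver("ranking solve residual ", format(res),
                   " exceeds tolerance; system is ill-conditioned, ",
                   "increase ridge")
  drop(f)
}

# Eq-style objective of the single-query problem, for optimality audits.
grank_objective <- function(f, L, rel, alpha) {
  u <- as.numeric(rel$known)
  sum(u * (f - rel$y)^2) + alpha * drop(crossprod(f, L %*% f))
}

#' Rank database domains against a query (on-line MultiG-Rank)
#'
#' Extends each candidate graph with the query node, combines the extended
#' Laplacians with the learned weights `mu`, sets the relevance vector to
#' `y = (1, 0, ..., 0)` with only the query entry known
#' (`U = diag(1, 0, ..., 0)`), solves the regularized system, and returns
#' the database domains sorted by descending score (the query itself is
#' excluded unless `include_self = TRUE`).
#'
#' @param db a `domain_database`.
#' @param query a `domain_query`.
#' @param pool a `graph_pool` from [build_graph_pool()], or a list of
#'   `graph_spec`s (graphs are then built on the fly).
#' @param mu graph-combination weights (`graph_weights` or numeric simplex
#'   vector matching the pool). With a single graph use `mu = 1`.
#' @param cfg a `ranker_config`.
#' @param top optional: keep only the best `top` domains.
#' @param include_self keep the query row in the output (debugging aid).
#' @param rebuild_full rebuild each `(N+1)`-node graph from scratch instead
#'   of extending the frozen database graph (exactness checks).
#' @return a `ranked_list`.
#' @export
rank_query <- function(db, query, pool, mu, cfg = ranker_config(),
                       top = NULL, include_self = FALSE,
                       rebuild_full = FALSE) {
  if (!inherits(pool, "graph_pool")) pool <- build_graph_pool(db, pool)
  check_query_dim(db, query)
  Ls <- extended_laplacians(db, query, pool, rebuild_full)
  L <- combine_laplacians(Ls, as_mu(mu, length(Ls)))
  n <- n_domains(db)
  rel <- relevance_spec(c(1, rep(0, n)), c(TRUE, rep(FALSE, n)))
  f <- grank_solve(L, rel, cfg)
  ids <- db$ids
  scores <- f[-1L]
  if (include_self) { ids <- c(query$id, ids); scores <- f }
  out <- ranked_list(ids, scores)
  if (!is.null(top)) {
    out <- out[seq_len(min(top, nrow(out))), , drop = FALSE]
    class(out) <- c("ranked_list", "data.frame")
  }
  out
}

# Extended (N+1)-node Laplacians for every graph in the pool.
extended_laplacians <- function(db, query, pool, rebuild_full = FALSE) {
  if (rebuild_full) {
    ext_db <- domain_database(c(query$id, db$ids),
                              rbind(query$features, db$features),
                              c("query", db$labels))
    lapply(pool$specs, function(s) graph_laplacian(build_graph(ext_db, s)))
  } else {
    lapply(pool$graphs, function(g)
      graph_laplacian(unclass(extend_graph(g, db, query))))
  }
}

#' Pairwise similarity baseline ranking
#'
#' Scores each database domain by its direct similarity to the query and
#' sorts descending -- the classical pairwise comparison baseline that
#' ignores the database's manifold structure.
#'
#' @param db a `domain_database`.
#' @param query a `domain_query`.
#' @param similarity `"cosine"`, `"tanimoto"`, `"jaccard"`, or
#'   `"neg_euclidean"` (negated Euclidean distance, so larger is closer).
#' @return a `ranked_list`.
#' @export
pairwise_rank <- function(db, query,
                          similarity = c("cosine", "tanimoto", "jaccard",
                                         "neg_euclidean")) {
  similarity <- match.arg(similarity)
  check_query_dim(db, query)
  s <- if (similarity == "neg_euclidean")
    -sqrt(affinity_vector(query$features, db$features, "sq_euclidean"))
  else
    affinity_vector(query$features, db$features, similarity,
                    id = query$id, ids = db$ids)
  ranked_list(db$ids, s)
}
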