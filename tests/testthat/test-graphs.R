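test_that("knn neighbor sets follow forced geometry and bounds", {
  db <- domain_database(c("a", "b", "c"),
                        matrix(c(0, 1, 10), ncol = 1), c("x", "x", "x"))
  nn <- knn_neighbors(db, 1, "sq_euclidean")
  expect_equal(nn$neighbors, list(2L, 1L, 2L))

  # k = N-1 gives everyone else
  nn2 <- knn_neighbors(db, 2, "sq_euclidean")
  expect_equal(lapply(nn2$neighbors, sort), list(2:3, c(1L, 3L), 1:2))

  expect_error(knn_neighbors(db, 3, "sq_euclidean"), "smaller than N")
  neg <- domain_database(c("a", "b", "c"), matrix(c(-1, 1, 2), ncol = 1),
                         c("x", "x", "x"))
  expect_error(knn_neighbors(neg, 1, "jaccard"), "nonnegative")
})

test_that("knn matches an exhaustive-sort oracle for every affinity", {
  db <- random_db(20, 5, seed = 42)
  for (aff in c("sq_euclidean", "cosine", "jaccard", "tanimoto")) {
    nn <- knn_neighbors(db, 3, aff)
    A <- multigrank:::affinity_matrix(db$features, aff, db$ids)
    for (i in 1:20) {
      others <- setdiff(1:20, i)
      v <- A[i, others]
      ord <- if (aff == "sq_euclidean") order(v, others) else order(-v, others)
      expect_equal(nn$neighbors[[i]], others[ord][1:3],
                   info = paste(aff, "row", i))
    }
  }
})

test_that("edge weight formulas give their closed-form values", {
  # identical points: gaussian 1, jaccard 1, tanimoto 1
  X <- rbind(c(0.3, 0.7), c(0.3, 0.7), c(5, 5))
  db <- domain_database(c("p", "q", "far"), X, c("x", "x", "y"))
  for (model in c("gaussian", "jaccard", "tanimoto")) {
    spec <- if (model == "gaussian") graph_spec("gaussian", 1, sigma = 2)
            else graph_spec(model, 1)
    g <- build_graph(db, spec)
    expect_equal(g$W[1, 2], 1, info = model)
    expect_equal(g$W[2, 1], 1, info = model)
  }
  # orthogonal vectors under cosine weight 0
  db2 <- domain_database(c("a", "b"), rbind(c(1, 0), c(0, 1)), c("x", "y"))
  g2 <- build_graph(db2, graph_spec("cosine", 1))
  expect_equal(g2$W[1, 2], 0)
  # dot-product weight equals the inner product on edges
  g3 <- build_graph(db, graph_spec("dot_product", 1))
  expect_equal(g3$W[1, 2], sum(X[1, ] * X[2, ]))
  # gaussian explicit formula
  g4 <- build_graph(db, graph_spec("gaussian", 2, sigma = 1.5))
  expect_equal(g4$W[1, 3], exp(-sum((X[1, ] - X[3, ])^2) / (2 * 1.5^2)))
})

test_that("all weighting schemes give symmetric nonnegative zero-diagonal W", {
  db <- random_db(15, 4, seed = 7)
  models <- c("gaussian", "dot_product", "cosine", "jaccard", "tanimoto")
  for (model in models) {
    spec <- if (model == "gaussian") graph_spec("gaussian", 4, sigma = 0.5)
            else graph_spec(model, 4)
    g <- build_graph(db, spec)
    expect_true(isSymmetric(unname(g$W)), info = model)
    expect_true(all(diag(g$W) == 0), info = model)
    expect_gte(min(g$W), 0)
    # nonzero entries only on the union-rule edge set
    E <- matrix(FALSE, 15, 15)
    for (i in 1:15) E[i, g$neighbors[[i]]] <- TRUE
    E <- E | t(E)
    expect_true(all(g$W[!E] == 0), info = model)
  }
})

test_that("negative dot-product weights are clamped to zero with a message", {
  set.seed(21)
  X <- matrix(rnorm(20 * 3), 20, 3)   # signed features
  db <- domain_database(sprintf("s%02d", 1:20), X, rep("x", 20))
  expect_message(g <- build_graph(db, graph_spec("dot_product", 5)),
                 "clamped")
  expect_gte(min(g$W), 0)
})

test_that("zero-norm vectors are rejected by cosine/tanimoto, naming the id", {
  db <- domain_database(c("ok", "null", "ok2"),
                        rbind(c(1, 1), c(0, 0), c(2, 1)), rep("x", 3))
  expect_error(build_graph(db, graph_spec("cosine", 1)), "null")
  expect_error(build_graph(db, graph_spec("tanimoto", 1)), "null")
})

test_that("gaussian weights decrease monotonically with distance", {
  x0 <- rep(0, 3)
  dists <- seq(0.5, 5, by = 0.5)
  X <- rbind(x0, t(sapply(dists, function(d) c(d, 0, 0))))
  db <- domain_database(sprintf("g%02d", 1:11), X, rep("x", 11))
  g <- build_graph(db, graph_spec("gaussian", 10, sigma = 1))
  w <- g$W[1, -1]
  expect_true(all(diff(w) < 0))
})

test_that("laplacian satisfies L = D - W, zero row sums, PSD, quadratic form", {
  W <- matrix(c(0, 1, 1, 0), 2)
  L <- graph_laplacian(W)
  expect_equal(L, matrix(c(1, -1, -1, 1), 2))

  set.seed(5)
  for (s in 1:5) {
    g <- random_graph(n = 10, d = 4, k = 3, seed = s)
    L <- graph_laplacian(g)
    expect_equal(max(abs(L %*% rep(1, 10))), 0, tolerance = 1e-12)
    expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
    for (r in 1:20) {
      f <- rnorm(10)
      expect_equal(drop(crossprod(f, L %*% f)), quadform_oracle(f, g$W),
                   tolerance = 1e-10)
    }
  }
  expect_error(graph_laplacian(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("pools preserve order and M, and flag duplicate specs", {
  db <- random_db(12, 3, seed = 2)
  specs <- list(graph_spec("gaussian", 3, sigma = 1), graph_spec("cosine", 4))
  pool <- build_pool(db, specs)
  expect_s3_class(pool, "laplacian_pool")
  expect_length(pool$laplacians, 2L)
  expect_equal(pool$specs[[2]]$model, "cosine")
  expect_equal(pool$laplacians[[1]],
               graph_laplacian(build_graph(db, specs[[1]])))

  one <- build_pool(db, list(graph_spec("tanimoto", 2)))
  expect_length(one$laplacians, 1L)

  expect_message(dup <- build_pool(db, list(graph_spec("cosine", 3),
                                            graph_spec("cosine", 3))),
                 "duplicate")
  expect_identical(dup$laplacians[[1]], dup$laplacians[[2]])
})

test_that("default pool spans the five models with a bandwidth grid", {
  db <- random_db(20, 4, seed = 3)  # nonnegative features
  specs <- default_graph_specs(db, k = 5)
  expect_length(specs, 8L)
  expect_setequal(unique(vapply(specs, `[[`, "", "model")),
                  c("gaussian", "dot_product", "cosine", "tanimoto", "jaccard"))
  pool <- build_pool(db, specs)
  for (L in pool$laplacians)
    expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  # signed features drop jaccard
  dbn <- domain_database(c("a", "b", "c"), rbind(c(-1, 2), c(1, 1), c(2, -3)),
                         rep("x", 3))
  expect_length(default_graph_specs(dbn, k = 1), 7L)
})

test_that("query extension freezes the database block and adds query edges", {
  db <- random_db(12, 4, seed = 8)
  g <- build_graph(db, graph_spec("gaussian", 3, sigma = 1))
  # query identical to database point 5: edge weight 1 if the edge exists
  q <- domain_query("q", db$features[5, ])
  W <- extend_graph(g, db, q)
  expect_equal(dim(W), c(13L, 13L))
  expect_identical(unclass(W)[2:13, 2:13], g$W)   # bit-exact restriction
  expect_equal(W[1, 6], 1)                        # duplicate point, gaussian
  expect_true(isSymmetric(unname(unclass(W))))
  expect_error(extend_graph(g, db, domain_query("bad", c(1, 2))), "dimension")
})

test_that("extension agrees with a from-scratch rebuild when the query is
           outside every database K-NN set", {
  # database points cluster tightly in the positive orthant (mutual cosine
  # and jaccard are high, mutual distances small); each query below is
  # provably worse than any internal k-th neighbor under its affinity, so
  # it cannot displace an internal K-NN relation and the incremental
  # extension must equal the full (N+1)-point rebuild
  set.seed(13)
  X <- matrix(0.8 + 0.2 * runif(30), 10, 3)
  db <- domain_database(sprintf("t%02d", 1:10), X, rep("x", 10))
  queries <- list(
    gaussian = domain_query("q0", X[1, ] + 10),      # far in distance
    cosine   = domain_query("q0", c(1, 1e-6, 1e-6)), # off the data direction
    tanimoto = domain_query("q0", rep(1e-6, 3)),     # near-zero norm
    jaccard  = domain_query("q0", rep(1e-6, 3))
  )
  for (model in names(queries)) {
    spec <- if (model == "gaussian") graph_spec("gaussian", 3, sigma = 5)
            else graph_spec(model, 3)
    g <- build_graph(db, spec)
    q <- queries[[model]]
    W_inc <- unclass(extend_graph(g, db, q))
    full <- domain_database(c("q0", db$ids), rbind(q$features, db$features),
                            rep("x", 11))
    W_full <- build_graph(full, spec)$W
    # same edge pattern, weights equal to absolute float round-off
    expect_identical(W_inc > 0, W_full > 0, info = model)
    expect_lt(max(abs(W_inc - W_full)), 1e-12)
  }
})
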