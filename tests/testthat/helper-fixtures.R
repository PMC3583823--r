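# Shared fixture builders. All randomness is seeded per call site.

# Small labeled database with explicit features.
tiny_db <- function() {
  domain_database(
    ids = c("d1", "d2", "d3", "d4"),
    features = rbind(c(1, 0), c(0.9, 0.1), c(0, 1), c(0.1, 0.9)),
    labels = c("a", "a", "b", "b")
  )
}

# Random nonnegative database: n domains, d features, uniform labels.
random_db <- function(n, d, n_labels = 2, seed = 1) {
  set.seed(seed)
  domain_database(
    ids = sprintf("r%03d", seq_len(n)),
    features = matrix(runif(n * d), n, d),
    labels = sample(letters[seq_len(n_labels)], n, replace = TRUE)
  )
}

# Random K-NN weighted graph on random points.
random_graph <- function(n = 10, d = 4, k = 3, seed = 1,
                         model = "gaussian") {
  db <- random_db(n, d, seed = seed)
  spec <- if (model == "gaussian") graph_spec("gaussian", k, sigma = 1)
          else graph_spec(model, k)
  build_graph(db, spec)
}

# Independent dense solve oracle (LU via solve(), distinct from the
# package's Cholesky path).
dense_solve_oracle <- function(A, b) solve(A, b)

# Brute-force quadratic form 0.5 * sum_ij (f_i - f_j)^2 W_ij.
quadform_oracle <- function(f, W) {
  n <- length(f)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    s <- s + (f[i] - f[j])^2 * W[i, j]
  s / 2
}

# Grid search over the simplex for the mu-subproblem (M = 2 only needs a
# 1-D grid; larger M uses recursive enumeration at the given step).
qp_grid_oracle <- function(e, alpha, beta, step = 1e-4) {
  M <- length(e)
  obj <- function(mu) alpha * sum(e * mu) + beta * sum(mu^2)
  if (M == 1) return(1)
  grid <- seq(0, 1, by = step)
  if (M == 2) {
    vals <- alpha * (e[1] * grid + e[2] * (1 - grid)) +
      beta * (grid^2 + (1 - grid)^2)
    best <- grid[which.min(vals)]
    return(c(best, 1 - best))
  }
  # M = 3 or 4: coarse recursive grid (used only with step >= 0.01)
  best <- NULL; best_val <- Inf
  rec <- function(prefix, remaining, budget) {
    if (remaining == 1) {
      mu <- c(prefix, budget)
      v <- obj(mu)
      if (v < best_val) { best_val <<- v; best <<- mu }
      return(invisible())
    }
    for (g in grid[grid <= budget + 1e-12])
      rec(c(prefix, g), remaining - 1, budget - g)
  }
  rec(numeric(0), M, 1)
  best
}

# Pool of simple Laplacians for learning tests.
toy_pool <- function(db, models = c("gaussian", "cosine"), k = 3) {
  specs <- lapply(models, function(m)
    if (m == "gaussian") graph_spec("gaussian", k, sigma_scale = 1)
    else graph_spec(m, k))
  build_pool(db, specs)
}
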