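#' Relevance matrix from category labels
#'
#' `Y[i, q] = 1` when domains `i` and `q` share a label, else 0. Used as the
#' fixed ground truth of the off-line weight-learning problem, where every
#' database domain serves as a query in turn and all labels are known.
#'
#' @param labels character vector of `N >= 2` category labels.
#' @return `N x N` symmetric 0/1 matrix with unit diagonal.
#' @export
relevance_matrix <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L) mg_stop_input("need at least 2 labels")
  Y <- outer(labels, labels, "==") * 1
  dimnames(Y) <- NULL
  Y
}

#' Closed-form update of the ranking-score matrix
#'
#' With the graph weights fixed, the score matrix solves
#' `(I + alpha * sum_m mu_m L_m) F = Y`; the system matrix is identity plus
#' PSD, hence positive definite, and is solved for all columns with a
#' single Cholesky factorization.
#'
#' @param pool a `laplacian_pool` (or list of Laplacians).
#' @param mu simplex weight vector.
#' @param Y relevance matrix.
#' @param alpha smoothness trade-off (> 0).
#' @return score matrix `F`, same shape as `Y`.
#' @export
update_F <- function(pool, mu, Y, alpha) {
  Ls <- if (inherits(pool, "laplacian_pool")) pool$laplacians else pool
  mu <- as_mu(mu, length(Ls))
  A <- alpha * combine_laplacians(Ls, mu)
  diag(A) <- diag(A) + 1
  R <- chol(A)
  F <- backsolve(R, backsolve(R, Y, transpose = TRUE))
  res <- max(abs(A %*% F - Y))
  if (res > 1e-8 * max(1, max(abs(Y))))
    mg_stop_solver("score-matrix solve residual ", format(res),
                   " exceeds tolerance")
  F
}

#' Exact simplex-constrained quadratic program for graph weights
#'
#' Minimizes `alpha * e'mu + beta * ||mu||^2` subject to `sum(mu) = 1`,
#' `mu >= 0`. Completing the square shows the minimizer is the Euclidean
#' projection of `v = -alpha * e / (2 * beta)` onto the probability
#' simplex, computed exactly by the sort-based water-filling algorithm.
#' The KKT conditions are verified before returning.
#'
#' @param e length-`M` vector of smoothness terms `e_m = Tr(F' L_m F)`.
#' @param alpha smoothness trade-off (> 0).
#' @param beta l2 regularizer on `mu` (> 0; keeps the problem strictly
#'   convex and discourages collapse onto a single graph).
#' @return the unique minimizer `mu` on the simplex.
#' @export
qp_simplex_solve <- function(e, alpha, beta) {
  e <- as.numeric(e)
  if (!length(e)) mg_stop_input("e must have length >= 1")
  if (beta <= 0)
    mg_stop_input("beta must be > 0 (the objective is strictly convex only then)")
  if (alpha <= 0) mg_stop_input("alpha must be > 0")
  mu <- project_simplex(-alpha * e / (2 * beta))
  # KKT: lambda = 2*beta*mu_m + alpha*e_m on the active set; >= lambda off it
  g <- 2 * beta * mu + alpha * e
  active <- mu > 0
  lambda <- min(g[active])
  if (max(g[active]) - lambda > 1e-7 * max(1, abs(lambda)) ||
      any(g[!active] < lambda - 1e-7 * max(1, abs(lambda))))
    mg_stop_internal("simplex QP KKT check failed")
  mu
}

# Euclidean projection onto {mu : sum(mu) = 1, mu >= 0} (sort-based, exact).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  j <- seq_along(v)
  rho <- max(j[u + (1 - css) / j > 0])
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Full learning objective
#'
#' `Tr((F-Y)'(F-Y)) + alpha * sum_m mu_m Tr(F' L_m F) + beta * ||mu||^2` --
#' the quantity the alternating optimization decreases at every half-step.
#'
#' @param F score matrix.
#' @param Y relevance matrix.
#' @param pool a `laplacian_pool` (or list of Laplacians).
#' @param mu simplex weight vector.
#' @param alpha,beta trade-off parameters.
#' @return scalar objective value.
#' @export
multig_objective <- function(F, Y, pool, mu, alpha, beta) {
  Ls <- if (inherits(pool, "laplacian_pool")) pool$laplacians else pool
  mu <- as_mu(mu, length(Ls))
  e <- smoothness_terms(F, Ls)
  sum((F - Y)^2) + alpha * sum(mu * e) + beta * sum(mu^2)
}

# e_m = Tr(F' L_m F), computed without forming F' L F.
smoothness_terms <- function(F, Ls) {
  vapply(Ls, function(L) sum(F * (L %*% F)), 0)
}

#' Learn graph-combination weights off-line
#'
#' Alternating minimization of [multig_objective()]: the score matrix `F`
#' is updated in closed form ([update_F()]), then the weights `mu` by the
#' exact simplex QP ([qp_simplex_solve()]). Both subproblems are convex and
#' solved exactly, so the objective is non-increasing at every half-step
#' (this is asserted; a violation beyond `1e-8` relative is an internal
#' error). The loop is deterministic.
#'
#' @param pool a `laplacian_pool` built on the database.
#' @param labels the database's category labels (defines the relevance
#'   matrix).
#' @param alpha smoothness trade-off (> 0). Default 0.01.
#' @param beta l2 penalty on `mu`; `"auto"` (default) sets
#'   `0.01 * alpha * mean(|e|)` from the first iteration's smoothness
#'   terms.
#' @param max_iter maximum number of alternating iterations `T`.
#' @param tol early-stop threshold on the relative objective change between
#'   full iterations.
#' @return object of class `graph_weights`: fields `mu`, `history` (data
#'   frame of per-half-step objective values), `alpha`, `beta`,
#'   `iterations`, `converged`, `e` (final smoothness terms).
#' @export
learn_graph_weights <- function(pool, labels, alpha = 0.01, beta = "auto",
                                max_iter = 20L, tol = 1e-6) {
  Ls <- if (inherits(pool, "laplacian_pool")) pool$laplacians else pool
  M <- length(Ls)
  n <- nrow(Ls[[1L]])
  if (length(labels) != n)
    mg_stop_input("labels length ", length(labels),
                  " does not match pool dimension ", n)
  if (alpha <= 0) mg_stop_input("alpha must be > 0")
  if (max_iter < 1L) mg_stop_input("max_iter must be >= 1")
  Y <- relevance_matrix(labels)
  mu <- rep(1 / M, M)
  auto_beta <- identical(beta, "auto")
  if (!auto_beta && beta <= 0) mg_stop_input("beta must be > 0 (or \"auto\")")
  hist_iter <- integer(0); hist_step <- character(0); hist_obj <- numeric(0)
  prev_obj <- Inf
  last_full <- NA_real_
  converged <- FALSE
  iterations <- 0L
  for (t in seq_len(max_iter)) {
    F <- update_F(Ls, mu, Y, alpha)
    e <- smoothness_terms(F, Ls)
    if (auto_beta) { beta <- 0.01 * alpha * mean(abs(e)); auto_beta <- FALSE
                     if (beta <= 0) beta <- .Machine$double.eps }
    obj_f <- sum((F - Y)^2) + alpha * sum(mu * e) + beta * sum(mu^2)
    check_monotone(prev_obj, obj_f)
    hist_iter <- c(hist_iter, t); hist_step <- c(hist_step, "F")
    hist_obj <- c(hist_obj, obj_f)
    mu <- qp_simplex_solve(e, alpha, beta)
    obj_mu <- sum((F - Y)^2) + alpha * sum(mu * e) + beta * sum(mu^2)
    check_monotone(obj_f, obj_mu)
    hist_iter <- c(hist_iter, t); hist_step <- c(hist_step, "mu")
    hist_obj <- c(hist_obj, obj_mu)
    prev_obj <- obj_mu
    iterations <- t
    if (!is.na(last_full) &&
        abs(last_full - obj_mu) <= tol * max(abs(obj_mu), .Machine$double.xmin)) {
      converged <- TRUE
      last_full <- obj_mu
      break
    }
    last_full <- obj_mu
  }
  mu[mu < 0] <- 0
  if (abs(sum(mu) - 1) > 1e-8)
    mg_stop_internal("learned mu left the simplex")
  structure(list(mu = mu, history = data.frame(iter = hist_iter,
                                               step = hist_step,
                                               objective = hist_obj,
                                               stringsAsFactors = FALSE),
                 alpha = alpha, beta = beta, iterations = iterations,
                 converged = converged, e = e,
                 specs = if (inherits(pool, "laplacian_pool")) pool$specs),
            class = "graph_weights")
}

check_monotone <- function(before, after) {
  if (after > before + 1e-8 * max(1, abs(before)))
    mg_stop_internal("objective increased from ", format(before), " to ",
                     format(after))
  invisible(TRUE)
}

#' @export
print.graph_weights <- function(x, ...) {
  cat(sprintf("graph_weights: M=%d, %d iteration(s)%s, alpha=%g, beta=%.4g\n",
              length(x$mu), x$iterations,
              if (x$converged) " (converged)" else "", x$alpha, x$beta))
  lab <- if (!is.null(x$specs)) vapply(x$specs, spec_label, "")
         else paste0("graph ", seq_along(x$mu))
  for (m in seq_along(x$mu)) cat(sprintf("  %-32s mu = %.4f\n", lab[m], x$mu[m]))
  invisible(x)
}
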