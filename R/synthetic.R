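#' Generate a synthetic fold-structured domain database
#'
#' Emulates the cluster structure of a protein fold classification: each fold
#' is a Gaussian cluster around a fold centroid, with expected pairwise
#' centroid distance equal to `separation`. Centroids are drawn i.i.d.
#' `N(0, separation^2/(2*dim))` per coordinate, so
#' `E||c_a - c_b||^2 = separation^2`; members are the centroid plus
#' `N(0, noise_sd^2)` noise. With `separation = 0` the geometry carries no
#' label information.
#'
#' When `nonnegative = TRUE` the whole feature matrix is shifted by its
#' global minimum so that all values are `>= 0` (a rigid translation:
#' Euclidean geometry is preserved), which makes Jaccard/Tanimoto weighting
#' well defined.
#'
#' With `hierarchy = TRUE` each fold is split into 2 superfamilies of 2
#' families each, as nested sub-clusters at 1/3 and 1/9 of the fold
#' separation, and a fold/superfamily/family hierarchy is attached.
#'
#' @param n_folds number of folds (>= 2).
#' @param domains_per_fold a single count or a vector of length `n_folds`.
#' @param dim feature dimension.
#' @param separation expected distance between fold centroids (>= 0).
#' @param noise_sd within-fold standard deviation per coordinate (> 0).
#' @param nonnegative shift features to be nonnegative (default `TRUE`).
#' @param seed integer seed; the result is fully reproducible from it.
#' @param hierarchy attach a 3-level label hierarchy (default `FALSE`).
#' @return a `domain_database`; fold centroids and generator settings are
#'   kept in `attr(db, "generator")` so matching queries can be drawn later.
#' @export
generate_synthetic_database <- function(n_folds, domains_per_fold, dim = 32L,
                                        separation = 6, noise_sd = 1,
                                        nonnegative = TRUE, seed = 1L,
                                        hierarchy = FALSE) {
  if (n_folds < 2L) mg_stop_input("n_folds must be >= 2")
  if (separation < 0) mg_stop_input("separation must be >= 0")
  if (noise_sd <= 0) mg_stop_input("noise_sd must be > 0")
  if (length(domains_per_fold) == 1L)
    domains_per_fold <- rep(as.integer(domains_per_fold), n_folds)
  if (length(domains_per_fold) != n_folds)
    mg_stop_input("domains_per_fold has length ", length(domains_per_fold),
                  " but n_folds = ", n_folds)
  if (any(domains_per_fold < 1L))
    mg_stop_input("every fold needs at least one domain")

  with_seed(seed, {
    fold_names <- sprintf("F%02d", seq_len(n_folds))
    centroids <- matrix(stats::rnorm(n_folds * dim, sd = separation / sqrt(2 * dim)),
                        n_folds, dim, dimnames = list(fold_names, NULL))
    sub_centroids <- NULL
    if (hierarchy) {
      # 4 family centroids per fold, nested 2 superfamilies x 2 families
      sub_centroids <- lapply(seq_len(n_folds), function(a) {
        sf <- matrix(stats::rnorm(2 * dim, sd = separation / 3 / sqrt(2 * dim)),
                     2, dim)
        fam <- lapply(1:2, function(s)
          sweep(matrix(stats::rnorm(2 * dim, sd = separation / 9 / sqrt(2 * dim)),
                       2, dim), 2L, centroids[a, ] + sf[s, ], "+"))
        do.call(rbind, fam)  # rows: s1f1, s1f2, s2f1, s2f2
      })
    }
    n <- sum(domains_per_fold)
    feats <- matrix(NA_real_, n, dim)
    labels <- character(n)
    hier <- if (hierarchy)
      data.frame(fold = character(n), superfamily = character(n),
                 family = character(n), stringsAsFactors = FALSE)
    row <- 0L
    for (a in seq_len(n_folds)) {
      for (j in seq_len(domains_per_fold[a])) {
        row <- row + 1L
        labels[row] <- fold_names[a]
        if (hierarchy) {
          fam_idx <- ((j - 1L) %% 4L) + 1L   # cycle families within the fold
          mu <- sub_centroids[[a]][fam_idx, ]
          sfam <- (fam_idx - 1L) %/% 2L + 1L
          fam <- (fam_idx - 1L) %% 2L + 1L
          hier$fold[row] <- fold_names[a]
          hier$superfamily[row] <- sprintf("%s.S%d", fold_names[a], sfam)
          hier$family[row] <- sprintf("%s.S%d.A%d", fold_names[a], sfam, fam)
        } else {
          mu <- centroids[a, ]
        }
        feats[row, ] <- mu + stats::rnorm(dim, sd = noise_sd)
      }
    }
    shift <- 0
    if (nonnegative && min(feats) < 0) {
      shift <- -min(feats)
      feats <- feats + shift
    }
    ids <- sprintf("d%04d", seq_len(n))
    db <- domain_database(ids, feats, labels, hierarchy = hier)
    attr(db, "generator") <- list(
      centroids = centroids, sub_centroids = sub_centroids, shift = shift,
      noise_sd = noise_sd, separation = separation, dim = dim, seed = seed,
      hierarchy = hierarchy, fold_names = fold_names)
    db
  })
}

#' Draw query domains matching a synthetic database
#'
#' Queries are fresh draws from the fold clusters of a database produced by
#' [generate_synthetic_database()] (same centroids, same noise, same
#' nonnegativity shift), so every query has at least one relevant domain in
#' the database -- mirroring how retrieval query sets are constructed.
#'
#' @param db a synthetic `domain_database`.
#' @param n_queries number of queries to draw.
#' @param seed integer seed.
#' @return list of `domain_query` objects with true labels attached.
#' @export
generate_synthetic_queries <- function(db, n_queries, seed = 1L) {
  gen <- attr(db, "generator")
  if (is.null(gen))
    mg_stop_input("db was not produced by generate_synthetic_database()")
  with_seed(seed, {
    folds <- sample(seq_len(nrow(gen$centroids)), n_queries, replace = TRUE)
    lapply(seq_len(n_queries), function(i) {
      a <- folds[i]
      if (gen$hierarchy) {
        fam_idx <- sample.int(4L, 1L)
        mu <- gen$sub_centroids[[a]][fam_idx, ]
        sfam <- (fam_idx - 1L) %/% 2L + 1L
        fam <- (fam_idx - 1L) %% 2L + 1L
        hier <- c(fold = gen$fold_names[a],
                  superfamily = sprintf("%s.S%d", gen$fold_names[a], sfam),
                  family = sprintf("%s.S%d.A%d", gen$fold_names[a], sfam, fam))
      } else {
        mu <- gen$centroids[a, ]
        hier <- NULL
      }
      x <- mu + stats::rnorm(gen$dim, sd = gen$noise_sd) + gen$shift
      if (gen$shift > 0) x <- pmax(x, 0)
      domain_query(sprintf("q%03d", i), x, label = gen$fold_names[a],
                   hierarchy = hier)
    })
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    mg_stop_input("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
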