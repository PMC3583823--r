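#' Construct a protein domain database
#'
#' A `domain_database` holds `N` protein domains, each represented by a
#' fixed-length numeric feature vector (e.g. a 32-dimensional tableau
#' descriptor of secondary-structure geometry) and a category label
#' (typically a SCOP fold identifier). An optional three-level label
#' hierarchy (fold, superfamily, family) supports evaluation at coarser or
#' finer relevance levels.
#'
#' @param ids character vector of unique domain identifiers.
#' @param features numeric matrix, one row per domain (`N x d`, `d >= 1`).
#' @param labels character vector of `N` non-empty category labels.
#' @param hierarchy optional data frame with columns `fold`, `superfamily`,
#'   `family` (one row per domain); when present, `fold` must agree with
#'   `labels`.
#' @return an object of class `domain_database` with fields `ids`,
#'   `features`, `labels`, `hierarchy`.
#' @examples
#' db <- domain_database(c("d1", "d2"), rbind(c(0, 1), c(1, 0)), c("a", "b"))
#' @export
domain_database <- function(ids, features, labels, hierarchy = NULL) {
  ids <- as.character(ids)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.character(labels)
  db <- structure(
    list(ids = ids, features = features, labels = labels, hierarchy = hierarchy),
    class = "domain_database"
  )
  validate_domain_database(db)
}

validate_domain_database <- function(db) {
  n <- nrow(db$features)
  if (n < 2L)
    mg_stop_input("a domain database needs at least 2 domains, got ", n)
  if (ncol(db$features) < 1L)
    mg_stop_input("feature dimension must be >= 1")
  if (length(db$ids) != n || length(db$labels) != n)
    mg_stop_input("ids (", length(db$ids), "), labels (", length(db$labels),
                  ") and feature rows (", n, ") must all have the same length")
  dup <- db$ids[duplicated(db$ids)]
  if (length(dup))
    mg_stop_input("duplicate domain id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(db$features) || any(!is.finite(db$features)))
    mg_stop_input("features must be finite numbers")
  if (anyNA(db$labels) || any(!nzchar(db$labels)))
    mg_stop_input("labels must be non-empty strings")
  if (!is.null(db$hierarchy)) {
    h <- db$hierarchy
    need <- c("fold", "superfamily", "family")
    if (!is.data.frame(h) || !all(need %in% names(h)))
      mg_stop_input("hierarchy must be a data frame with columns ",
                    paste(need, collapse = ", "))
    if (nrow(h) != n)
      mg_stop_input("hierarchy has ", nrow(h), " rows, expected ", n)
    for (col in need) {
      v <- as.character(h[[col]])
      if (anyNA(v) || any(!nzchar(v)))
        mg_stop_input("hierarchy column '", col, "' has missing entries")
      h[[col]] <- v
    }
    if (!identical(h$fold, db$labels))
      mg_stop_input("hierarchy 'fold' column must agree with labels")
    db$hierarchy <- h
  }
  rownames(db$features) <- db$ids
  db
}

#' @export
print.domain_database <- function(x, ...) {
  cat(sprintf("domain_database: %d domains, %d features, %d labels%s\n",
              nrow(x$features), ncol(x$features), length(unique(x$labels)),
              if (is.null(x$hierarchy)) "" else " (3-level hierarchy)"))
  invisible(x)
}

#' Number of domains and feature dimension
#' @param db a `domain_database`.
#' @return integer count.
#' @export
n_domains <- function(db) nrow(db$features)

#' @rdname n_domains
#' @export
n_features <- function(db) ncol(db$features)

#' Labels of a database at a hierarchy level
#'
#' @param db a `domain_database`.
#' @param level one of `"fold"`, `"superfamily"`, `"family"`. `"fold"` falls
#'   back to `db$labels` when no hierarchy is attached.
#' @return named character vector (names are domain ids).
#' @export
labels_at_level <- function(db, level = c("fold", "superfamily", "family")) {
  level <- match.arg(level)
  lab <- if (level == "fold" && is.null(db$hierarchy)) db$labels
         else if (!is.null(db$hierarchy)) db$hierarchy[[level]]
         else mg_stop_input("database has no label hierarchy; only level='fold' is available")
  stats::setNames(lab, db$ids)
}

#' Construct a query domain
#'
#' @param id query identifier (need not occur in any database).
#' @param features numeric feature vector.
#' @param label optional true category label, used only for evaluation.
#' @param hierarchy optional named character vector with entries `fold`,
#'   `superfamily`, `family`.
#' @return an object of class `domain_query`.
#' @export
domain_query <- function(id, features, label = NULL, hierarchy = NULL) {
  features <- as.numeric(features)
  if (length(features) < 1L || anyNA(features))
    mg_stop_input("query '", id, "' has an invalid feature vector")
  structure(list(id = as.character(id), features = features,
                 label = if (is.null(label)) NULL else as.character(label),
                 hierarchy = hierarchy),
            class = "domain_query")
}

query_label_at_level <- function(query, level = "fold") {
  if (level == "fold" && !is.null(query$label)) return(query$label)
  if (!is.null(query$hierarchy) && level %in% names(query$hierarchy))
    return(unname(query$hierarchy[[level]]))
  if (level == "fold")
    mg_stop_input("query '", query$id, "' carries no label")
  mg_stop_input("query '", query$id, "' carries no ", level, " label")
}

check_query_dim <- function(db, query) {
  if (length(query$features) != n_features(db))
    mg_stop_input("query '", query$id, "' has dimension ",
                  length(query$features), " but the database has ",
                  n_features(db))
  invisible(TRUE)
}

#' Construct a ranked retrieval list
#'
#' Scores are sorted in descending order; ties are broken by ascending id
#' (deterministic across platforms). The tie-break rule is recorded as an
#' attribute.
#'
#' @param ids character vector of domain ids.
#' @param scores numeric ranking scores, same length as `ids`.
#' @return a data frame of class `ranked_list` with columns `rank`, `id`,
#'   `score`, ordered by decreasing score.
#' @export
ranked_list <- function(ids, scores) {
  ids <- as.character(ids)
  scores <- as.numeric(scores)
  if (length(ids) != length(scores))
    mg_stop_input("ids and scores differ in length")
  if (anyDuplicated(ids))
    mg_stop_input("ranked list has duplicate ids")
  ord <- order(-scores, ids, method = "radix")
  out <- data.frame(rank = seq_along(ids), id = ids[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranked_list", "data.frame"),
            tie_break = "score descending, then id ascending")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("ranked_list: %d domains\n", nrow(x)))
  print.data.frame(utils::head(x, 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("... %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Read a feature table into a domain database
#'
#' The file must have a header row naming columns `id`, `label`, and feature
#' columns `f1 ... fd`; optional `fold`, `superfamily`, `family` columns
#' attach a label hierarchy (in which case `fold` must equal `label`).
#'
#' @param path path to a delimited text file.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return a validated `domain_database`; row order is preserved.
#' @export
read_feature_table <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  if (!file.exists(path))
    mg_stop_input("file not found: ", path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(nf) < 2L)
    mg_stop_input("feature table ", path, " has no data rows")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    mg_stop_input("row ", bad - 1L, " of ", path, " has ", nf[bad],
                  " fields while the header has ", nf[1L],
                  ": ragged feature rows")
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  cols <- names(tab)
  if (!all(c("id", "label") %in% cols))
    mg_stop_input(path, " must contain 'id' and 'label' columns")
  fcols <- grep("^f[0-9]+$", cols, value = TRUE)
  if (!length(fcols))
    mg_stop_input(path, " contains no feature columns (expected f1..fd)")
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  feats <- matrix(NA_real_, nrow(tab), length(fcols),
                  dimnames = list(NULL, fcols))
  for (j in seq_along(fcols)) {
    v <- suppressWarnings(as.numeric(tab[[fcols[j]]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      mg_stop_input("non-numeric feature value '", tab[[fcols[j]]][bad],
                    "' at row ", bad, ", column ", fcols[j], " of ", path)
    }
    feats[, j] <- v
  }
  hier <- NULL
  if (all(c("fold", "superfamily", "family") %in% cols))
    hier <- data.frame(fold = tab$fold, superfamily = tab$superfamily,
                       family = tab$family, stringsAsFactors = FALSE)
  domain_database(tab$id, feats, tab$label, hierarchy = hier)
}

#' Write a domain database as a feature table
#'
#' Inverse of [read_feature_table()]; numeric values are written with 17
#' significant digits so that read-write-read is an identity.
#'
#' @param db a `domain_database`.
#' @param path output path.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(db, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  d <- n_features(db)
  header <- c("id", "label",
              if (!is.null(db$hierarchy)) c("fold", "superfamily", "family"),
              paste0("f", seq_len(d)))
  fmt <- apply(db$features, 1L, function(r) paste(sprintf("%.17g", r), collapse = sep))
  rows <- if (is.null(db$hierarchy)) {
    paste(db$ids, db$labels, fmt, sep = sep)
  } else {
    paste(db$ids, db$labels, db$hierarchy$fold, db$hierarchy$superfamily,
          db$hierarchy$family, fmt, sep = sep)
  }
  writeLines(c(paste(header, collapse = sep), rows), path)
  invisible(path)
}

#' Read query domains from a feature table
#'
#' Same format as [read_feature_table()], but rows are returned as a list of
#' [domain_query()] objects and a single row is allowed.
#'
#' @inheritParams read_feature_table
#' @return list of `domain_query` objects.
#' @export
read_query_table <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  if (!file.exists(path)) mg_stop_input("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(tab), value = TRUE)
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  if (!length(fcols) || !"id" %in% names(tab))
    mg_stop_input(path, " must contain 'id' and feature columns f1..fd")
  has_hier <- all(c("fold", "superfamily", "family") %in% names(tab))
  lapply(seq_len(nrow(tab)), function(i) {
    v <- suppressWarnings(as.numeric(unlist(tab[i, fcols], use.names = FALSE)))
    if (anyNA(v))
      mg_stop_input("non-numeric feature value at query row ", i, " of ", path)
    domain_query(tab$id[i], v,
                 label = if ("label" %in% names(tab)) tab$label[i] else NULL,
                 hierarchy = if (has_hier)
                   c(fold = tab$fold[i], superfamily = tab$superfamily[i],
                     family = tab$family[i]) else NULL)
  })
}

#' Write a ranked list as TSV
#'
#' Columns `rank` (1-based), `id`, `score`; scores carry 17 significant
#' digits so a write-then-read round trip reproduces them bit-exactly.
#'
#' @param ranked a `ranked_list`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(ranked, path) {
  if (!inherits(ranked, "ranked_list"))
    mg_stop_input("'ranked' must be a ranked_list")
  lines <- c("rank\tid\tscore",
             if (nrow(ranked))
               sprintf("%d\t%s\t%.17g", ranked$rank, ranked$id, ranked$score))
  tryCatch(writeLines(lines, path),
           error = function(e) mg_stop_input("cannot write ", path, ": ",
                                             conditionMessage(e)))
  invisible(path)
}

#' @rdname write_ranked_list
#' @return `read_ranked_list()` returns the `ranked_list` stored at `path`.
#' @export
read_ranked_list <- function(path) {
  if (!file.exists(path)) mg_stop_input("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("integer", "character", "numeric"),
                           stringsAsFactors = FALSE)
  ranked_list(tab$id, tab$score)
}
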