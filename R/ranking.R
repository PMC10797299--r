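#' Random-forest Mean Decrease Gini importance of regions
#'
#' Trains a random-forest classifier (bootstrap sampling, Gini split
#' criterion) on a mice-by-regions feature table with two class labels and
#' returns, per region, the Mean Decrease Gini: the total Gini impurity
#' decrease attributed to splits on that region, averaged over trees. A
#' larger value means the region discriminates the two groups better.
#'
#' Determinism and invariances: rows are sorted canonically (by mouse id)
#' and the class coding is fixed by first occurrence in that order, so for
#' a given `seed` the result is invariant to row permutations and to
#' renaming the two classes. A table with no informative split anywhere
#' (all features constant) yields all-zero importances.
#'
#' @param features a `feature_table` (see [as_feature_table()]), or a list
#'   with elements `x` (numeric matrix) and `labels`.
#' @param n_trees number of trees (default 500, the randomForest
#'   convention).
#' @param seed RNG seed for the forest.
#' @param mtry candidate features per split (default
#'   `floor(sqrt(#regions))`).
#' @return Named numeric vector of Mean Decrease Gini per region, with the
#'   forest's out-of-bag error rate in `attr(, "oob_error")` (reported for
#'   diagnostics only; with a handful of mice per class it is far too
#'   noisy to select models on).
#' @examples
#' ft <- list(x = cbind(sep = rep(c(0, 3), each = 4),
#'                      noise = rnorm(8)),
#'            labels = rep(c("a", "b"), each = 4))
#' gini_importance(ft, n_trees = 101, seed = 1)
#' @export
gini_importance <- function(features, n_trees = 500, seed = 1L,
                            mtry = NULL) {
  x <- as.matrix(features$x)
  labels <- as.character(features$labels)
  if (length(unique(labels)) < 2)
    stop("need two classes to rank regions", call. = FALSE)
  if (min(table(labels)) < 2)
    stop("need at least 2 mice per class", call. = FALSE)
  if (anyNA(x)) stop("feature table has missing values", call. = FALSE)

  ord <- order(rownames(x) %||% seq_len(nrow(x)))
  x <- x[ord, , drop = FALSE]
  labels <- labels[ord]
  # class coding by first occurrence after the canonical row sort: renaming
  # a class then changes nothing in the fitted forest
  y <- factor(match(labels, unique(labels)), levels = c(1L, 2L))

  zero <- stats::setNames(rep(0, ncol(x)), colnames(x))
  informative <- apply(x, 2, function(v) diff(range(v)) > 0)
  if (!any(informative)) {
    attr(zero, "oob_error") <- NA_real_
    return(zero)
  }

  p <- ncol(x)
  fit <- with_seed(seed,
    randomForest::randomForest(x, y, ntree = n_trees,
                               mtry = mtry %||% max(1, floor(sqrt(p)))))
  imp <- randomForest::importance(fit, type = 2)[, "MeanDecreaseGini"]
  out <- zero
  out[names(imp)] <- imp
  attr(out, "oob_error") <- unname(fit$err.rate[n_trees, "OOB"])
  out
}

#' Composite discriminative-region ranking across three indexes
#'
#' Integrates the Mean Decrease Gini rankings obtained for each output
#' index (arborization per neuron, axon density, density fraction): a
#' region's `frequency` is the number of indexes in which it falls in the
#' top `top_k` by Gini, and `mean_gini` is the arithmetic mean of its Gini
#' across all indexes. Regions are reported sorted by frequency, then mean
#' Gini, descending. Ties at the top-k boundary are broken by a stable
#' sort on (Gini descending, region name ascending), recorded in the
#' result.
#'
#' @param gini_tables list of named Gini vectors (one per index, e.g. from
#'   [gini_importance()]) over a shared region vocabulary.
#' @param top_k top-list size per index (default 10).
#' @return A `ranking_result` data.frame with `region`, `frequency`,
#'   `mean_gini`, sorted as above; parameters in
#'   `attr(, "parameters")`.
#' @export
composite_ranking <- function(gini_tables, top_k = 10L) {
  stopifnot(is.list(gini_tables), length(gini_tables) >= 1)
  vocab <- sort(names(gini_tables[[1]]))
  for (g in gini_tables)
    if (!identical(sort(names(g)), vocab))
      stop("Gini tables span different region vocabularies", call. = FALSE)
  top_sets <- lapply(gini_tables, function(g) {
    ord <- order(-g[vocab], vocab)   # Gini desc, name asc (tie break)
    vocab[ord][seq_len(min(top_k, length(vocab)))]
  })
  freq <- vapply(vocab, function(r)
    sum(vapply(top_sets, function(s) r %in% s, logical(1))), numeric(1))
  mean_gini <- rowMeans(vapply(gini_tables, function(g) g[vocab],
                               numeric(length(vocab))))
  out <- data.frame(region = vocab, frequency = freq,
                    mean_gini = unname(mean_gini),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, -out$mean_gini, out$region), ]
  rownames(out) <- NULL
  structure(out, class = c("ranking_result", "data.frame"),
            parameters = list(top_k = top_k,
                              n_indexes = length(gini_tables),
                              tie_break = "gini desc, region name asc"))
}

#' @export
print.ranking_result <- function(x, ...) {
  p <- attr(x, "parameters")
  cat(sprintf("Composite region ranking (%d indexes, top_k = %d)\n",
              p$n_indexes, p$top_k))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more regions\n")
  invisible(x)
}

#' Seed-stability of the composite top-ranked region
#'
#' Re-runs the full per-index Gini ranking and the composite integration
#' across `n_seeds` forest seeds and reports how often each region comes
#' out top-ranked — a necessary diagnostic when each forest is trained on
#' only a handful of mice.
#'
#' @param features list of `feature_table`s, one per index.
#' @param n_seeds number of seeds (at least 2).
#' @param seed base seed; run s uses `derive_seed(seed, s)`.
#' @param n_trees,top_k passed to [gini_importance()] and
#'   [composite_ranking()].
#' @return Named numeric vector: per-region fraction of seeds in which the
#'   region ranked first.
#' @export
rank_stability <- function(features, n_seeds, seed = 1L,
                           n_trees = 500, top_k = 10L) {
  if (n_seeds < 2) stop("n_seeds must be at least 2", call. = FALSE)
  tops <- vapply(seq_len(n_seeds), function(s) {
    gt <- lapply(seq_along(features), function(i)
      gini_importance(features[[i]], n_trees = n_trees,
                      seed = derive_seed(seed, 10L * s + i)))
    composite_ranking(gt, top_k = top_k)$region[1]
  }, character(1))
  vocab <- sort(colnames(as.matrix(features[[1]]$x)))
  tab <- table(factor(tops, levels = vocab))
  stats::setNames(as.numeric(tab) / n_seeds, vocab)
}
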