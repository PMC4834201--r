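# Unsupervised random-forest proximity.
#
# The similarity between two compounds is the fraction of trees, in a
# two-class forest separating the real bioactivity matrix (class 1) from a
# synthetic marginal-resampled copy (class 2), in which both compounds land
# in the same terminal node. The synthetic class preserves each assay's
# univariate distribution but destroys the between-assay dependency
# structure, so the forest's splits track that structure and co-terminal
# compounds share correlated bioactivity.

#' Proximity configuration
#'
#' @param n_trees number of trees. The headline analyses in the field use
#'   10,000; smaller forests are adequate for moderate n and are the default
#'   here for tractability.
#' @param mtry features tried per split; default `floor(sqrt(p))`, resolved
#'   at fit time when NULL.
#' @param min_leaf minimum terminal-node size (default 1: trees grown to
#'   purity, the classic proximity setting).
#' @param missing_strategy `"median-impute"` or `"indicator-augment"`; see
#'   [resolve_missing()].
#' @param oob_only if TRUE, a compound pair's proximity is counted only over
#'   trees where both compounds are out-of-bag, normalized by that tree
#'   count.
#' @param seed integer master seed; per-run sub-seeds are derived from it.
#' @return a `proximity_config` list.
#' @export
proximity_config <- function(n_trees = 500, mtry = NULL, min_leaf = 1,
                             missing_strategy = c("median-impute",
                                                  "indicator-augment"),
                             oob_only = FALSE, seed = 1L) {
  missing_strategy <- match.arg(missing_strategy)
  stopifnot(n_trees >= 1, min_leaf >= 1)
  if (!is.null(mtry)) stopifnot(mtry >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_leaf = as.integer(min_leaf),
                 missing_strategy = missing_strategy,
                 oob_only = isTRUE(oob_only), seed = as.integer(seed)),
            class = "proximity_config")
}

#' Resolve missing bioactivity values
#'
#' `median-impute` replaces each missing cell with its assay's median over
#' observed cells. `indicator-augment` does the same and additionally appends
#' one 0/1 column per assay marking where data were missing, letting trees
#' split on missingness itself.
#'
#' @param values numeric activity matrix with `NA` for missing cells.
#' @param strategy imputation strategy.
#' @return complete numeric matrix (n x p, or n x 2p for indicator-augment).
#' @export
resolve_missing <- function(values,
                            strategy = c("median-impute", "indicator-augment")) {
  strategy <- match.arg(strategy)
  all_na <- colSums(!is.na(values)) == 0
  if (any(all_na)) {
    stop(sprintf("assay '%s' has no observed values",
                 colnames(values)[which(all_na)[1]]), call. = FALSE)
  }
  miss <- is.na(values)
  med <- apply(values, 2, stats::median, na.rm = TRUE)
  imputed <- values
  for (j in which(colSums(miss) > 0)) imputed[miss[, j], j] <- med[j]
  if (strategy == "indicator-augment") {
    ind <- miss + 0
    colnames(ind) <- paste0(colnames(values), "_missing")
    imputed <- cbind(imputed, ind)
  }
  imputed
}

#' Generate the synthetic second class
#'
#' Each column of the synthetic matrix is an independent resample, with
#' replacement, of the corresponding original column: marginal distributions
#' are preserved while the joint dependency structure is destroyed.
#'
#' @param values complete numeric matrix (run [resolve_missing()] first).
#' @param seed RNG seed.
#' @return matrix of identical shape; rownames prefixed `"synthetic_"`.
#' @export
generate_synthetic_class <- function(values, seed = NULL) {
  if (anyNA(values)) {
    stop("matrix contains missing values; resolve_missing() first", call. = FALSE)
  }
  n <- nrow(values)
  synth <- with_seed(seed, {
    apply(values, 2, function(col) sample(col, n, replace = TRUE))
  })
  dimnames(synth) <- list(paste0("synthetic_", seq_len(n)), colnames(values))
  synth
}

#' Fit the two-class forest and record terminal nodes
#'
#' Stacks original (class 1) over synthetic (class 2) rows, trains a
#' CART-style bootstrap ensemble with Gini splits and `mtry` candidate
#' features per split, then drops every ORIGINAL compound down every tree —
#' regardless of bootstrap membership — and records its terminal leaf.
#'
#' @param values complete numeric matrix of the original compounds.
#' @param config a [proximity_config()].
#' @return a `terminal_assignment`: integer matrix (n compounds x n_trees) of
#'   per-tree leaf identifiers, comparable within a tree only. If
#'   `config$oob_only`, attribute `"oob"` holds the matching out-of-bag
#'   indicator matrix.
#' @export
fit_unsupervised_forest <- function(values, config = proximity_config()) {
  if (nrow(values) < 2) stop("need at least 2 compounds", call. = FALSE)
  if (anyNA(values)) stop("matrix contains missing values", call. = FALSE)
  synth <- generate_synthetic_class(values, seed = derive_seed(config$seed, 1L))
  stacked <- rbind(values, synth)
  df <- as.data.frame(stacked)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.class <- factor(rep(c("real", "synthetic"), each = nrow(values)))
  mtry <- config$mtry %||% max(1L, floor(sqrt(ncol(values))))
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = config$n_trees, mtry = min(mtry, ncol(values)),
    min.node.size = config$min_leaf,
    keep.inbag = config$oob_only,
    seed = derive_seed(config$seed, 2L), num.threads = 1,
    verbose = FALSE
  )
  orig <- df[seq_len(nrow(values)), names(df) != ".class", drop = FALSE]
  assign <- stats::predict(fit, data = orig, type = "terminalNodes",
                           num.threads = 1)$predictions
  rownames(assign) <- rownames(values)
  if (config$oob_only) {
    inbag <- matrix(unlist(fit$inbag.counts), ncol = config$n_trees)
    attr(assign, "oob") <- inbag[seq_len(nrow(values)), , drop = FALSE] == 0
  }
  class(assign) <- c("terminal_assignment", class(assign))
  assign
}

#' Proximity matrix from terminal-node assignments
#'
#' `P[i, j]` is the number of trees in which compounds i and j share a
#' terminal node, divided by the number of trees (or, with an `oob` mask, by
#' the number of trees where both are out-of-bag). The diagonal is exactly 1
#' under all-cases counting.
#'
#' @param assign a `terminal_assignment` matrix (compounds x trees).
#' @return symmetric numeric matrix in `[0, 1]` with unit diagonal and
#'   compound dimnames.
#' @export
proximity_from_assignments <- function(assign) {
  n <- nrow(assign)
  n_trees <- ncol(assign)
  oob <- attr(assign, "oob")
  counts <- matrix(0, n, n)
  if (is.null(oob)) {
    for (t in seq_len(n_trees)) {
      leaf <- assign[, t]
      counts <- counts + outer(leaf, leaf, "==")
    }
    P <- counts / n_trees
  } else {
    denom <- matrix(0, n, n)
    for (t in seq_len(n_trees)) {
      both <- outer(oob[, t], oob[, t], "&")
      leaf <- assign[, t]
      counts <- counts + (outer(leaf, leaf, "==") & both)
      denom <- denom + both
    }
    P <- ifelse(denom > 0, counts / denom, 0)
  }
  diag(P) <- 1
  dimnames(P) <- list(rownames(assign), rownames(assign))
  P
}

#' Compute the unsupervised random-forest proximity matrix
#'
#' End-to-end composition: resolve missing cells, generate the synthetic
#' class, fit the two-class forest, count co-terminal-node events and
#' normalize by tree count. Rows are canonicalised to sorted compound-id
#' order before fitting and the result is mapped back to the input order, so
#' the matrix is invariant to input row permutation under a fixed seed.
#'
#' @param values numeric activity matrix (missing cells as `NA`) with
#'   compound rownames.
#' @param config a [proximity_config()].
#' @return symmetric unit-diagonal proximity matrix aligned to the input
#'   compound order.
#' @export
compute_rf_proximity <- function(values, config = proximity_config()) {
  values <- validate_activity_matrix(values)
  ord <- order(rownames(values))
  canon <- values[ord, , drop = FALSE]
  complete <- resolve_missing(canon, config$missing_strategy)
  assign <- fit_unsupervised_forest(complete, config)
  P <- proximity_from_assignments(assign)
  P[rownames(values), rownames(values)]
}
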