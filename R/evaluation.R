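# Model assessment: balanced sampling of unbalanced endpoints, leave-one-out
# evaluation with sensitivity / specificity / balanced accuracy, permutation
# significance against a label-shuffling null, and full-factorial parameter
# sweeps over (k, tau, mode).

#' Balance an unbalanced endpoint by down-sampling the majority class
#'
#' Keeps every compound of the minority class plus an equal-size uniform
#' sample, without replacement, of the majority class. In vivo endpoints are
#' frequently dominated by one outcome; evaluating on the balanced subset
#' keeps sensitivity and specificity on equal footing.
#'
#' @param labels named POSITIVE/NEGATIVE/UNKNOWN vector.
#' @param seed RNG seed for the majority-class draw.
#' @return character vector of retained compound ids, in input order, with
#'   exactly `min(n_pos, n_neg)` of each class.
#' @export
balance_dataset <- function(labels, seed = NULL) {
  pos <- names(labels)[labels == "POSITIVE"]
  neg <- names(labels)[labels == "NEGATIVE"]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("balancing requires at least one POSITIVE and one NEGATIVE label",
         call. = FALSE)
  }
  n_keep <- min(length(pos), length(neg))
  keep <- with_seed(seed, {
    c(sample(pos, n_keep), sample(neg, n_keep))
  })
  names(labels)[names(labels) %in% keep]
}

confusion_metrics <- function(truth, pred_pos) {
  tp <- sum(truth == 1 & pred_pos)
  fn <- sum(truth == 1 & !pred_pos)
  tn <- sum(truth == 0 & !pred_pos)
  fp <- sum(truth == 0 & pred_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
       sensitivity = sens, specificity = spec,
       balanced_accuracy = mean(c(sens, spec)))
}

#' Leave-one-out evaluation of read-across predictions
#'
#' Predicts every labeled compound from its nearest tested neighbors with its
#' own label withheld from the pool, tallies the confusion matrix over
#' evaluable predictions, and reports sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)` and their mean, the balanced accuracy. Non-evaluable
#' compounds (no eligible neighbors, or zero total weight) are counted
#' separately, never silently dropped.
#'
#' @param P proximity matrix.
#' @param S structural similarity matrix (St.BaBRA only).
#' @param labels named endpoint vector; needs at least one POSITIVE and one
#'   NEGATIVE.
#' @param config a [read_across_config()].
#' @param ids optional subset of compounds to evaluate (e.g. the output of
#'   [balance_dataset()]); labeled compounds outside the subset still serve
#'   as neighbors only if retained in `labels`.
#' @param seed echoed into the report for provenance.
#' @return a `babra_report` list: `confusion`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `n_evaluated`, `n_non_evaluable`, `config`, `seed`.
#' @export
loo_evaluate <- function(P, S = NULL, labels, config = read_across_config(),
                         ids = NULL, seed = NULL) {
  labeled <- names(labels)[labels != "UNKNOWN"]
  labeled <- intersect(rownames(P), labeled)
  if (!is.null(ids)) labeled <- intersect(labeled, ids)
  counts <- label_counts(labels[labeled])
  if (any(counts == 0)) {
    stop("evaluation requires both POSITIVE and NEGATIVE labeled compounds",
         call. = FALSE)
  }
  preds <- predict_all(P, S, labels, config, ids = labeled)
  # leakage guard: a compound must never appear among its own neighbors
  nb <- attr(preds, "neighbors")
  leaks <- vapply(labeled, function(id) id %in% nb[[id]]$id, logical(1))
  stopifnot(!any(leaks))
  eval_ok <- preds$call != "NON_EVALUABLE"
  if (!any(eval_ok)) stop("no evaluable predictions", call. = FALSE)
  truth <- label_to_numeric(labels[preds$compound_id[eval_ok]])
  m <- confusion_metrics(truth, preds$call[eval_ok] == "POSITIVE")
  stopifnot(isTRUE(all.equal(m$balanced_accuracy,
                             mean(c(m$sensitivity, m$specificity)))))
  structure(list(
    confusion = m$confusion,
    sensitivity = m$sensitivity,
    specificity = m$specificity,
    balanced_accuracy = m$balanced_accuracy,
    p_value = NULL,
    n_evaluated = sum(eval_ok),
    n_non_evaluable = sum(!eval_ok),
    config = unclass(config),
    seed = seed
  ), class = "babra_report")
}

#' @export
print.babra_report <- function(x, ...) {
  cat("Read-across evaluation (", x$config$mode, ", k=", x$config$k,
      ", tau=", x$config$min_weight, ")\n", sep = "")
  cat(sprintf("  tp=%d fp=%d tn=%d fn=%d (non-evaluable: %d)\n",
              x$confusion["tp"], x$confusion["fp"], x$confusion["tn"],
              x$confusion["fn"], x$n_non_evaluable))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  balanced accuracy %.3f\n",
              x$sensitivity, x$specificity, x$balanced_accuracy))
  if (!is.null(x$p_value)) cat(sprintf("  permutation p-value %.4g\n", x$p_value))
  invisible(x)
}

# Neighbor sets depend on labels only through WHICH compounds are labeled,
# never on the label values, so under label permutation (within the labeled
# set) the selected neighbors and their weights are fixed. Predictions for
# any label assignment then reduce to a row-normalized weight-matrix product,
# which is what makes many-permutation significance cheap. Equivalence with
# a full re-run is unit-tested.
prediction_weight_matrix <- function(P, S, labels, config, ids) {
  nb <- lapply(ids, function(id) select_neighbors(id, P, S, labels, config))
  labeled <- names(labels)[labels != "UNKNOWN"]
  W <- matrix(0, length(ids), length(labeled),
              dimnames = list(ids, labeled))
  for (i in seq_along(ids)) {
    d <- nb[[i]]
    if (nrow(d) == 0) next
    W[i, d$id] <- if (config$mode == "babra") d$P else d$P + d$S
  }
  W
}

ba_from_weights <- function(W, a, truth, cutoff) {
  denom <- rowSums(W)
  ok <- denom > 0
  a_pred <- as.vector(W[ok, , drop = FALSE] %*% a) / denom[ok]
  m <- confusion_metrics(truth[ok], a_pred >= cutoff)
  m$balanced_accuracy
}

#' Permutation significance of the observed balanced accuracy
#'
#' Shuffles endpoint labels over the labeled compounds, keeping the neighbor
#' structure fixed, and compares the observed balanced accuracy with the
#' permutation distribution: `p = (1 + #{BA_perm >= BA_obs}) / (1 + n_perm)`.
#'
#' @inheritParams loo_evaluate
#' @param n_perm number of label permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @return list with `p_value`, `observed_ba`, `perm_ba` (vector of length
#'   `n_perm`), `n_perm` and `seed`.
#' @export
permutation_significance <- function(P, S = NULL, labels,
                                     config = read_across_config(),
                                     n_perm = 9999, seed = NULL, ids = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  labeled <- intersect(rownames(P), names(labels)[labels != "UNKNOWN"])
  if (!is.null(ids)) eval_ids <- intersect(labeled, ids) else eval_ids <- labeled
  W <- prediction_weight_matrix(P, S, labels, config, eval_ids)
  a <- label_to_numeric(labels[colnames(W)])
  truth <- label_to_numeric(labels[eval_ids])
  observed <- ba_from_weights(W, a, truth, config$call_cutoff)
  perm_ba <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(a))
      a_p <- a[idx]
      truth_p <- a_p[match(eval_ids, colnames(W))]
      ba_from_weights(W, a_p, truth_p, config$call_cutoff)
    }, numeric(1))
  })
  list(p_value = (1 + sum(perm_ba >= observed)) / (1 + n_perm),
       observed_ba = observed, perm_ba = perm_ba,
       n_perm = as.integer(n_perm), seed = seed)
}

#' Exact binomial significance cross-check
#'
#' On a balanced dataset a chance predictor is correct with probability 0.5;
#' this tests the observed number of correct calls against that null with a
#' one-sided exact binomial test. Provided as an independent cross-check of
#' the permutation p-value.
#'
#' @param report a `babra_report`.
#' @return one-sided binomial p-value.
#' @export
binomial_significance <- function(report) {
  correct <- report$confusion["tp"] + report$confusion["tn"]
  total <- sum(report$confusion)
  stats::binom.test(correct, total, p = 0.5, alternative = "greater")$p.value
}

#' Full-factorial parameter sweep
#'
#' Runs [loo_evaluate()] for every combination of neighborhood size `k`,
#' similarity threshold `tau` and prediction mode, and selects the cell with
#' the highest balanced accuracy; ties prefer smaller `k`, then larger `tau`
#' (the simpler, more conservative model).
#'
#' @inheritParams loo_evaluate
#' @param k_grid,tau_grid numeric grids (duplicates removed).
#' @param modes subset of `c("babra", "stbabra")`.
#' @param call_cutoff binarization threshold shared across cells.
#' @return a `babra_sweep` list: `grid` (one data.frame row per cell with
#'   metrics), `selected` (the winning row), `reports` (full reports).
#' @export
parameter_sweep <- function(P, S = NULL, labels, k_grid = 1:10, tau_grid = 0,
                            modes = "babra", call_cutoff = 0.5, ids = NULL,
                            seed = NULL) {
  k_grid <- sort(unique(as.integer(k_grid)))
  tau_grid <- sort(unique(tau_grid))
  modes <- unique(match.arg(tolower(modes), c("babra", "stbabra"),
                            several.ok = TRUE))
  if (length(k_grid) == 0 || length(tau_grid) == 0 || length(modes) == 0) {
    stop("sweep grids must be non-empty", call. = FALSE)
  }
  cells <- expand.grid(k = k_grid, tau = tau_grid, mode = modes,
                       stringsAsFactors = FALSE)
  reports <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- read_across_config(k = cells$k[i], min_weight = cells$tau[i],
                              mode = cells$mode[i], call_cutoff = call_cutoff)
    reports[[i]] <- loo_evaluate(P, S, labels, cfg, ids = ids, seed = seed)
  }
  grid <- cbind(cells, data.frame(
    sensitivity = vapply(reports, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(reports, `[[`, numeric(1), "specificity"),
    balanced_accuracy = vapply(reports, `[[`, numeric(1), "balanced_accuracy"),
    n_non_evaluable = vapply(reports, `[[`, numeric(1), "n_non_evaluable")
  ))
  sel <- order(-grid$balanced_accuracy, grid$k, -grid$tau)[1]
  structure(list(grid = grid, selected = grid[sel, , drop = FALSE],
                 reports = reports, seed = seed),
            class = "babra_sweep")
}

#' @export
print.babra_sweep <- function(x, ...) {
  cat("Parameter sweep over", nrow(x$grid), "cells\n")
  cat("Selected:\n")
  print(x$selected, row.names = FALSE)
  invisible(x)
}
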