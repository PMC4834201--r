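# The read-across prediction engine: weighted kNN over similarity space.
#
# BaBRA weights neighbors by bioactivity proximity P alone:
#   A_pred = sum(P_i * A_i) / sum(P_i)
# St.BaBRA adds Tanimoto structural similarity S:
#   A_pred = (sum(P_i * A_i) + sum(S_i * A_i)) / (sum(P_i) + sum(S_i))
# where A_i is the binary in vivo outcome (1/0) of neighbor i.

#' Read-across configuration
#'
#' @param k number of nearest neighbors (>= 1).
#' @param min_weight eligibility threshold tau in `[0, 1]` applied to the
#'   ranking weight before the top-k cut.
#' @param mode `"babra"` (bioactivity proximity only) or `"stbabra"`
#'   (proximity plus structural similarity).
#' @param call_cutoff binarization threshold on `a_pred`; predictions at or
#'   above it are called POSITIVE (inclusive boundary).
#' @param rank_by in St.BaBRA mode, rank candidates by the `"combined"`
#'   weight `P + S` (default; matches the weights in the prediction
#'   denominator) or by `"proximity"` alone. Ignored in BaBRA mode.
#' @return a `read_across_config` list.
#' @export
read_across_config <- function(k = 5, min_weight = 0,
                               mode = c("babra", "stbabra"),
                               call_cutoff = 0.5,
                               rank_by = c("combined", "proximity")) {
  mode <- match.arg(tolower(mode), c("babra", "stbabra"))
  rank_by <- match.arg(rank_by)
  stopifnot(k >= 1, min_weight >= 0, min_weight <= 1,
            call_cutoff > 0, call_cutoff < 1)
  structure(list(k = as.integer(k), min_weight = min_weight, mode = mode,
                 call_cutoff = call_cutoff, rank_by = rank_by),
            class = "read_across_config")
}

label_to_numeric <- function(labels) {
  ifelse(labels == "POSITIVE", 1L, ifelse(labels == "NEGATIVE", 0L, NA_integer_))
}

#' Select the k nearest tested neighbors for a query compound
#'
#' Candidates are all compounds other than the query with a known endpoint
#' label and ranking weight at least `min_weight`; the top k by weight are
#' kept, ties broken by ascending compound id. Fewer than k survivors (down
#' to zero) is allowed.
#'
#' @param query compound id.
#' @param P proximity matrix.
#' @param S structural similarity matrix (required for St.BaBRA).
#' @param labels named POSITIVE/NEGATIVE/UNKNOWN vector.
#' @param config a [read_across_config()].
#' @return data.frame with columns `id`, `P`, `S`, `A` (1/0), `weight`,
#'   at most `k` rows, in rank order.
#' @export
select_neighbors <- function(query, P, S = NULL, labels,
                             config = read_across_config()) {
  if (!query %in% rownames(P)) {
    stop(sprintf("query '%s' not in proximity matrix", query), call. = FALSE)
  }
  if (config$mode == "stbabra" && is.null(S)) {
    stop("St.BaBRA mode requires a structural similarity matrix", call. = FALSE)
  }
  labeled <- names(labels)[labels != "UNKNOWN"]
  cand <- setdiff(intersect(labeled, rownames(P)), query)
  if (!is.null(S)) cand <- intersect(cand, rownames(S))
  p <- P[query, cand]
  s <- if (is.null(S)) rep(0, length(cand)) else S[query, cand]
  w <- if (config$mode == "stbabra" && config$rank_by == "combined") p + s else p
  keep <- w >= config$min_weight
  cand <- cand[keep]; p <- p[keep]; s <- s[keep]; w <- w[keep]
  ord <- order(-w, cand)
  take <- utils::head(ord, config$k)
  data.frame(id = cand[take], P = unname(p[take]), S = unname(s[take]),
             A = label_to_numeric(unname(labels[cand[take]])),
             weight = unname(w[take]), stringsAsFactors = FALSE)
}

#' Predicted activity from bioactivity proximity alone (BaBRA)
#'
#' Proximity-weighted mean of neighbor outcomes:
#' `sum(P_i * A_i) / sum(P_i)`.
#'
#' @param neighbors data.frame from [select_neighbors()].
#' @return `a_pred` in `[0, 1]`, or `NA` (non-evaluable) for an empty
#'   neighbor list or all-zero proximity weights.
#' @export
predict_babra <- function(neighbors) {
  if (nrow(neighbors) == 0 || sum(neighbors$P) <= 0) return(NA_real_)
  sum(neighbors$P * neighbors$A) / sum(neighbors$P)
}

#' Predicted activity with structural enrichment (St.BaBRA)
#'
#' `(sum(P_i * A_i) + sum(S_i * A_i)) / (sum(P_i) + sum(S_i))`; reduces
#' exactly to [predict_babra()] when all `S_i` are zero.
#'
#' @inheritParams predict_babra
#' @return `a_pred` in `[0, 1]`, or `NA` when the denominator is zero.
#' @export
predict_stbabra <- function(neighbors) {
  denom <- sum(neighbors$P) + sum(neighbors$S)
  if (nrow(neighbors) == 0 || denom <= 0) return(NA_real_)
  (sum(neighbors$P * neighbors$A) + sum(neighbors$S * neighbors$A)) / denom
}

#' Predict the endpoint for every compound in the pool
#'
#' Each compound — labeled or not — is predicted from its nearest tested
#' neighbors; a compound's own label is never used for its own prediction
#' (leave-one-out by construction), so read-across can both fill data gaps
#' and be evaluated against known outcomes.
#'
#' @param P proximity matrix.
#' @param S structural similarity matrix (St.BaBRA only).
#' @param labels named endpoint vector.
#' @param config a [read_across_config()].
#' @param ids compounds to predict; default all rows of `P`.
#' @return a `babra_predictions` data.frame (`compound_id`, `a_pred`,
#'   `call` in POSITIVE/NEGATIVE/NON_EVALUABLE) with the per-compound
#'   neighbor tables in attribute `"neighbors"`.
#' @export
predict_all <- function(P, S = NULL, labels, config = read_across_config(),
                        ids = rownames(P)) {
  nb <- lapply(ids, function(id) select_neighbors(id, P, S, labels, config))
  names(nb) <- ids
  a_pred <- vapply(nb, function(d) {
    if (config$mode == "babra") predict_babra(d) else predict_stbabra(d)
  }, numeric(1))
  call <- ifelse(is.na(a_pred), "NON_EVALUABLE",
                 ifelse(a_pred >= config$call_cutoff, "POSITIVE", "NEGATIVE"))
  out <- data.frame(compound_id = ids, a_pred = unname(a_pred),
                    call = unname(call), stringsAsFactors = FALSE)
  attr(out, "neighbors") <- nb
  attr(out, "config") <- config
  class(out) <- c("babra_predictions", "data.frame")
  out
}
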