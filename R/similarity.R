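# Structural similarity (Tanimoto on fingerprint bit-vectors) and masked
# similarity on sparse trinary bioprofiles, plus the side-by-side
# chemical-vs-biological nearest-neighbor report.

#' Tanimoto similarity of two fingerprint bit-vectors
#'
#' `|a AND b| / |a OR b|`. By convention two all-zero fingerprints have
#' similarity 0 (never NaN), so downstream weighted sums stay finite.
#'
#' @param a,b equal-length 0/1 vectors.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("fingerprints differ in length", call. = FALSE)
  }
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Pairwise Tanimoto structural-similarity matrix
#'
#' @param fp 0/1 fingerprint matrix with compound rownames (see
#'   [read_fingerprints()]).
#' @return symmetric numeric matrix in `[0, 1]`; diagonal 1 for any
#'   non-empty fingerprint, 0 for an all-zero one (with a warning).
#' @export
structural_similarity_matrix <- function(fp) {
  fp <- validate_fingerprints(fp)
  storage.mode(fp) <- "double"
  inter <- tcrossprod(fp)               # |a AND b|
  ones <- rowSums(fp)
  un <- outer(ones, ones, "+") - inter  # |a OR b|
  S <- ifelse(un > 0, inter / un, 0)
  if (any(ones == 0)) {
    warning(sprintf("all-zero fingerprint(s): %s (similarity 0 by convention)",
                    paste(rownames(fp)[ones == 0], collapse = ", ")),
            call. = FALSE)
  }
  dimnames(S) <- list(rownames(fp), rownames(fp))
  S
}

#' Masked similarity of two trinary bioprofiles
#'
#' Agreement is the fraction of assays, among those observed in both
#' profiles, with identical active/inactive calls. Pairs whose observed
#' overlap falls below `min_overlap` are flagged non-evaluable rather than
#' scored on too little evidence.
#'
#' @param a,b trinary rows in `{1, 0, NA}` over the same assay panel.
#' @param min_overlap minimum mutually observed assays (default 4).
#' @return list with `overlap`, `agreement` (NA when non-evaluable) and
#'   `evaluable`.
#' @export
trinary_profile_similarity <- function(a, b, min_overlap = 4) {
  if (length(a) != length(b)) stop("profiles differ in assay panel", call. = FALSE)
  both <- !is.na(a) & !is.na(b)
  overlap <- sum(both)
  if (overlap < min_overlap) {
    return(list(overlap = overlap, agreement = NA_real_, evaluable = FALSE))
  }
  list(overlap = overlap,
       agreement = sum(a[both] == b[both]) / overlap,
       evaluable = TRUE)
}

#' Chemical vs biological nearest-neighbor comparison
#'
#' For a query compound, ranks the analog pool by structural (Tanimoto)
#' similarity and, separately, by trinary-bioprofile agreement, and reports
#' the top-m of each side by side with the analogs' endpoint labels. On
#' datasets with activity cliffs the biological neighbors carry endpoint
#' values closer to the query's than the chemical neighbors do.
#'
#' @param query compound id present in all artifacts.
#' @param S structural similarity matrix.
#' @param profiles trinary profile matrix (`{1, 0, NA}`).
#' @param labels endpoint labels (named POSITIVE/NEGATIVE/UNKNOWN vector).
#' @param m neighbors reported per side (default 3); if fewer analogs are
#'   evaluable the list is truncated with a message.
#' @param min_overlap passed to [trinary_profile_similarity()].
#' @return data.frame with columns `rank`, `chemical_id`,
#'   `chemical_similarity`, `chemical_label`, `biological_id`,
#'   `biological_agreement`, `biological_overlap`, `biological_label`;
#'   attribute `"query_label"` carries the query's own endpoint value.
#' @export
neighbor_comparison_report <- function(query, S, profiles, labels, m = 3,
                                       min_overlap = 4) {
  if (!query %in% rownames(S)) {
    stop(sprintf("query '%s' lacks a fingerprint-based similarity entry", query),
         call. = FALSE)
  }
  if (!query %in% rownames(profiles)) {
    stop(sprintf("query '%s' lacks a bioprofile", query), call. = FALSE)
  }
  pool <- intersect(rownames(S), rownames(profiles))
  pool <- setdiff(pool, query)
  if (length(pool) == 0) stop("empty analog pool", call. = FALSE)

  chem <- S[query, pool]
  chem_ord <- pool[order(-chem, pool)]

  prof <- vapply(pool, function(id) {
    r <- trinary_profile_similarity(profiles[query, ], profiles[id, ],
                                    min_overlap = min_overlap)
    c(agreement = if (r$evaluable) r$agreement else NA_real_,
      overlap = as.numeric(r$overlap))
  }, c(agreement = 0, overlap = 0))
  evaluable <- pool[!is.na(prof["agreement", ])]
  bio_ord <- evaluable[order(-prof["agreement", evaluable], evaluable)]

  m_eff <- min(m, length(chem_ord), max(length(bio_ord), 1L))
  if (length(bio_ord) < m || length(chem_ord) < m) {
    message(sprintf("neighbor report truncated to %d of %d requested", m_eff, m))
  }
  lab <- function(ids) unname(labels[ids])
  top_c <- chem_ord[seq_len(m_eff)]
  top_b <- bio_ord[seq_len(min(m_eff, length(bio_ord)))]
  length(top_b) <- m_eff  # pad with NA when the evaluable pool is short
  out <- data.frame(
    rank = seq_len(m_eff),
    chemical_id = top_c,
    chemical_similarity = unname(chem[top_c]),
    chemical_label = lab(top_c),
    biological_id = top_b,
    biological_agreement = unname(prof["agreement", ])[match(top_b, pool)],
    biological_overlap = unname(prof["overlap", ])[match(top_b, pool)],
    biological_label = lab(top_b),
    stringsAsFactors = FALSE
  )
  attr(out, "query_label") <- unname(labels[query])
  out
}
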