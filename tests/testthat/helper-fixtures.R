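# Shared fixture builders; everything is generated in code at test time.

random_activity <- function(n = 10, p = 5, missing_rate = 0.1, seed = 1) {
  set.seed(seed)
  M <- matrix(round(stats::runif(n * p, -2, 2), 6), n, p,
              dimnames = list(sprintf("C%03d", seq_len(n)),
                              sprintf("A%02d", seq_len(p))))
  if (missing_rate > 0) M[stats::runif(n * p) < missing_rate] <- NA
  M
}

random_fingerprints <- function(n = 10, L = 32, density = 0.4, seed = 1) {
  set.seed(seed)
  fp <- matrix(stats::rbinom(n * L, 1, density), n, L,
               dimnames = list(sprintf("C%03d", seq_len(n)), NULL))
  storage.mode(fp) <- "integer"
  fp
}

make_labels <- function(ids, pos_frac = 0.5, seed = 1) {
  set.seed(seed)
  stats::setNames(
    ifelse(stats::runif(length(ids)) < pos_frac, "POSITIVE", "NEGATIVE"), ids)
}

# neighbor table in the shape select_neighbors() returns
neighbor_df <- function(P, S, A, ids = NULL) {
  ids <- ids %||% sprintf("N%d", seq_along(P))
  data.frame(id = ids, P = P, S = S, A = A, weight = P + S,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
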