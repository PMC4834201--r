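# Tabular I/O for all artifacts: activity matrices, fingerprints, endpoint
# labels, trinary bioprofiles, square similarity matrices, predictions and
# evaluation reports. All cross-artifact operations align by compound id,
# never by row position. Floats are serialized with 12 significant digits so
# write-then-read round-trips are stable.

FLOAT_DIGITS <- 12L

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else formatC(v, digits = FLOAT_DIGITS, format = "g")
  }, character(1))
  out
}

read_delim_chr <- function(path, sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.table(path, sep = sep, header = FALSE, colClasses = "character",
                    quote = "\"", comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = NULL,
                    blank.lines.skip = TRUE)
}

#' Read a compound-by-assay bioactivity matrix
#'
#' Parses a delimited text file whose first row holds assay ids and first
#' column holds compound ids. Cells may be binary hit-calls or continuous
#' potencies; empty cells or a sentinel token denote missing assay data and
#' become `NA` in the returned matrix.
#'
#' @param path path to a CSV/TSV file.
#' @param sep field delimiter (default comma).
#' @param missing_tokens character vector of tokens treated as missing, in
#'   addition to the empty string. Default `"NA"`.
#' @return numeric matrix with compound ids as rownames and assay ids as
#'   colnames; missing cells are `NA`.
#' @export
read_activity_matrix <- function(path, sep = ",", missing_tokens = "NA") {
  raw <- read_delim_chr(path, sep)
  if (nrow(raw) < 2 || ncol(raw) < 2) {
    stop("activity matrix needs at least one compound row and one assay column",
         call. = FALSE)
  }
  assay_ids <- as.character(raw[1, -1])
  compound_ids <- as.character(raw[-1, 1])
  check_unique_ids(compound_ids, "compound")
  check_unique_ids(assay_ids, "assay")
  cells <- as.matrix(raw[-1, -1, drop = FALSE])
  dimnames(cells) <- list(compound_ids, assay_ids)
  is_missing <- cells %in% c("", missing_tokens)
  dim(is_missing) <- dim(cells)
  vals <- suppressWarnings(as.numeric(cells))
  dim(vals) <- dim(cells)
  bad <- which(is.na(vals) & !is_missing, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell '%s' at compound '%s', assay '%s'",
                 cells[bad[1, 1], bad[1, 2]],
                 compound_ids[bad[1, 1]], assay_ids[bad[1, 2]]),
         call. = FALSE)
  }
  vals[is_missing] <- NA_real_
  dimnames(vals) <- list(compound_ids, assay_ids)
  validate_activity_matrix(vals)
}

#' Validate a bioactivity matrix
#'
#' Checks unique row/column ids, minimum dimensions, and finiteness of all
#' observed cells.
#'
#' @param values numeric matrix with compound rownames and assay colnames;
#'   `NA` marks missing cells.
#' @return the validated matrix, invisibly classed as input for pipelines.
#' @export
validate_activity_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("activity matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("activity matrix must carry compound rownames and assay colnames",
         call. = FALSE)
  }
  if (nrow(values) < 2) stop("need at least 2 compounds", call. = FALSE)
  if (ncol(values) < 1) stop("need at least 1 assay", call. = FALSE)
  check_unique_ids(rownames(values), "compound")
  check_unique_ids(colnames(values), "assay")
  obs <- values[!is.na(values)]
  if (any(!is.finite(obs))) {
    stop("non-finite value in observed cells", call. = FALSE)
  }
  values
}

#' Write a bioactivity (or any id-labelled numeric) matrix
#'
#' @param values numeric matrix with rownames/colnames; `NA` written as "NA".
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_activity_matrix <- function(values, path, sep = ",") {
  header <- paste(c("compound_id", colnames(values)), collapse = sep)
  rows <- vapply(seq_len(nrow(values)), function(i) {
    paste(c(rownames(values)[i], fmt_num(values[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read or write a square similarity matrix (proximity or Tanimoto)
#'
#' Same layout as an activity matrix, with identical row and column ids.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return numeric square matrix with matching dimnames.
#' @export
read_similarity_matrix <- function(path, sep = ",") {
  M <- read_activity_matrix(path, sep = sep)
  if (nrow(M) != ncol(M) || !identical(rownames(M), colnames(M))) {
    stop("similarity matrix must be square with matching row/column ids",
         call. = FALSE)
  }
  M
}

#' @rdname read_similarity_matrix
#' @param values square numeric matrix.
#' @export
write_similarity_matrix <- function(values, path, sep = ",") {
  write_activity_matrix(values, path, sep = sep)
}

#' Read compound fingerprints
#'
#' Two formats are supported. `bitstring-csv`: each row is
#' `id<sep>0101...` with equal-length bit strings. `smiles-list`: each line is
#' `id<whitespace>SMILES`; a caller-supplied `fingerprinter` callback maps
#' each SMILES string to a fixed-length 0/1 vector.
#'
#' @param path input file.
#' @param format `"bitstring-csv"` or `"smiles-list"`.
#' @param fingerprinter for `smiles-list`, a `function(smiles) -> 0/1 vector`.
#' @param permissive if TRUE, records whose SMILES the fingerprinter rejects
#'   (by erroring or returning NULL) are skipped with a warning instead of
#'   aborting the read.
#' @param sep delimiter for `bitstring-csv`.
#' @return integer 0/1 matrix, one row per compound, with compound rownames;
#'   for `smiles-list` input the SMILES strings are kept in attribute
#'   `"smiles"`.
#' @export
read_fingerprints <- function(path, format = c("bitstring-csv", "smiles-list"),
                              fingerprinter = NULL, permissive = FALSE,
                              sep = ",") {
  format <- match.arg(format)
  if (format == "bitstring-csv") {
    raw <- read_delim_chr(path, sep)
    if (ncol(raw) != 2) stop("bitstring-csv must have exactly 2 columns", call. = FALSE)
    ids <- as.character(raw[[1]])
    bits <- as.character(raw[[2]])
    check_unique_ids(ids, "compound")
    lens <- nchar(bits)
    if (length(unique(lens)) > 1) {
      off <- ids[lens != lens[1]][1]
      stop(sprintf("ragged fingerprint length for compound '%s'", off), call. = FALSE)
    }
    if (any(grepl("[^01]", bits))) {
      off <- ids[grepl("[^01]", bits)][1]
      stop(sprintf("non-binary fingerprint character for compound '%s'", off),
           call. = FALSE)
    }
    fp <- t(vapply(strsplit(bits, ""), function(b) as.integer(b),
                   integer(lens[1])))
    rownames(fp) <- ids
    return(validate_fingerprints(fp))
  }
  # smiles-list
  if (is.null(fingerprinter)) {
    stop("smiles-list format requires a fingerprinter callback", call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  ids <- vapply(parts, `[`, character(1), 1)
  smiles <- vapply(parts, function(p) paste(p[-1], collapse = " "), character(1))
  check_unique_ids(ids, "compound")
  fps <- vector("list", length(ids))
  keep <- rep(TRUE, length(ids))
  for (i in seq_along(ids)) {
    res <- tryCatch(fingerprinter(smiles[i]), error = function(e) NULL)
    if (is.null(res)) {
      if (!permissive) {
        stop(sprintf("unparsable structure for compound '%s': %s",
                     ids[i], smiles[i]), call. = FALSE)
      }
      warning(sprintf("skipping compound '%s' (unparsable structure)", ids[i]),
              call. = FALSE)
      keep[i] <- FALSE
    } else {
      fps[[i]] <- as.integer(res)
    }
  }
  fps <- fps[keep]
  ids <- ids[keep]
  smiles <- smiles[keep]
  if (length(fps) == 0) stop("no parsable structures in file", call. = FALSE)
  L <- length(fps[[1]])
  ragged <- which(vapply(fps, length, integer(1)) != L)
  if (length(ragged) > 0) {
    stop(sprintf("fingerprinter returned ragged lengths (compound '%s')",
                 ids[ragged[1]]), call. = FALSE)
  }
  fp <- do.call(rbind, fps)
  rownames(fp) <- ids
  attr(fp, "smiles") <- stats::setNames(smiles, ids)
  validate_fingerprints(fp)
}

validate_fingerprints <- function(fp) {
  if (!is.matrix(fp) || is.null(rownames(fp))) {
    stop("fingerprints must be a matrix with compound rownames", call. = FALSE)
  }
  if (ncol(fp) < 1) stop("fingerprint length must be >= 1", call. = FALSE)
  check_unique_ids(rownames(fp), "compound")
  if (!all(fp %in% c(0L, 1L))) stop("fingerprint bits must be 0/1", call. = FALSE)
  storage.mode(fp) <- "integer"
  fp
}

#' @rdname read_fingerprints
#' @param fp 0/1 fingerprint matrix with compound rownames.
#' @export
write_fingerprints <- function(fp, path, sep = ",") {
  rows <- vapply(seq_len(nrow(fp)), function(i) {
    paste(rownames(fp)[i], paste(fp[i, ], collapse = ""), sep = sep)
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

LABEL_TOKENS <- stats::setNames(
  c("POSITIVE", "POSITIVE", "POSITIVE",
    "NEGATIVE", "NEGATIVE", "NEGATIVE",
    "UNKNOWN", "UNKNOWN", "UNKNOWN"),
  c("1", "positive", "pos", "0", "negative", "neg", "", "na", "unknown")
)

#' Read per-compound binary in vivo endpoint labels
#'
#' Accepts `1/0/positive/negative` (case-insensitive); empty, `NA` or
#' `unknown` map to UNKNOWN. A `compound_id,label` header row is optional.
#'
#' @param path CSV file with columns compound id and label.
#' @param sep field delimiter.
#' @return named character vector over compounds with values
#'   `"POSITIVE"`, `"NEGATIVE"` or `"UNKNOWN"`.
#' @export
read_labels <- function(path, sep = ",") {
  raw <- read_delim_chr(path, sep)
  if (ncol(raw) == 1) {
    # a trailing empty field (UNKNOWN label) may be dropped by the parser
    raw <- cbind(raw, V2 = "")
  }
  if (ncol(raw) != 2) stop("label file must have 2 columns", call. = FALSE)
  if (tolower(raw[1, 1]) %in% c("compound_id", "id")) raw <- raw[-1, , drop = FALSE]
  ids <- as.character(raw[[1]])
  check_unique_ids(ids, "compound")
  tok <- tolower(trimws(as.character(raw[[2]])))
  idx <- match(tok, names(LABEL_TOKENS))  # match() handles the "" token
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("unknown label token '%s' for compound '%s' (row %d)",
                 raw[bad, 2], ids[bad], bad), call. = FALSE)
  }
  stats::setNames(unname(LABEL_TOKENS[idx]), ids)
}

#' @rdname read_labels
#' @param labels named character vector of POSITIVE/NEGATIVE/UNKNOWN.
#' @export
write_labels <- function(labels, path, sep = ",") {
  tok <- c(POSITIVE = "1", NEGATIVE = "0", UNKNOWN = "")[labels]
  writeLines(c(paste("compound_id", "label", sep = sep),
               paste(names(labels), tok, sep = sep)), path)
  invisible(path)
}

# number of POSITIVE/NEGATIVE labels; used by evaluation preconditions
label_counts <- function(labels) {
  c(pos = sum(labels == "POSITIVE"), neg = sum(labels == "NEGATIVE"))
}

TRINARY_TOKENS <- stats::setNames(
  c(1L, 1L, 0L, 0L, NA_integer_, NA_integer_, NA_integer_),
  c("1", "active", "0", "inactive", "", "na", "nodata")
)

#' Read or write a sparse trinary bioprofile matrix
#'
#' Cells are active (`1`), inactive (`0`) or no-data (empty/`NA`). The file
#' layout matches [read_activity_matrix()]: assay ids in the first row,
#' compound ids in the first column.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return integer matrix in `{1, 0, NA}` with compound rownames and assay
#'   colnames (`NA` = no data).
#' @export
read_trinary_profiles <- function(path, sep = ",") {
  raw <- read_delim_chr(path, sep)
  assay_ids <- as.character(raw[1, -1])
  compound_ids <- as.character(raw[-1, 1])
  check_unique_ids(compound_ids, "compound")
  check_unique_ids(assay_ids, "assay")
  cells <- as.matrix(raw[-1, -1, drop = FALSE])
  cells[] <- tolower(trimws(cells))
  idx <- match(cells, names(TRINARY_TOKENS))  # match() handles the "" token
  dim(idx) <- dim(cells)
  bad <- which(is.na(idx) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid trinary call '%s' at compound '%s', assay '%s'",
                 cells[bad[1, 1], bad[1, 2]],
                 compound_ids[bad[1, 1]], assay_ids[bad[1, 2]]), call. = FALSE)
  }
  calls <- TRINARY_TOKENS[idx]
  dim(calls) <- dim(cells)
  dimnames(calls) <- list(compound_ids, assay_ids)
  calls
}

#' @rdname read_trinary_profiles
#' @param calls integer matrix in `{1, 0, NA}` with dimnames.
#' @export
write_trinary_profiles <- function(calls, path, sep = ",") {
  chr <- ifelse(is.na(calls), "", as.character(calls))
  header <- paste(c("compound_id", colnames(calls)), collapse = sep)
  rows <- vapply(seq_len(nrow(calls)), function(i) {
    paste(c(rownames(calls)[i], chr[i, ]), collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write or read read-across predictions
#'
#' One CSV row per predicted compound: `compound_id`, `a_pred`, `call`, and
#' the selected neighbors encoded as `id:P:S:A` triples separated by `;`.
#'
#' @param predictions a `babra_predictions` object from [predict_all()].
#' @param path output file.
#' @export
write_predictions <- function(predictions, path) {
  nb <- attr(predictions, "neighbors")
  enc <- vapply(predictions$compound_id, function(id) {
    d <- nb[[id]]
    if (is.null(d) || nrow(d) == 0) return("")
    paste(sprintf("%s:%s:%s:%d", d$id, fmt_num(d$P), fmt_num(d$S), d$A),
          collapse = ";")
  }, character(1))
  lines <- c(
    "compound_id,a_pred,call,neighbors",
    sprintf("%s,%s,%s,%s", predictions$compound_id,
            ifelse(is.na(predictions$a_pred), "", fmt_num(predictions$a_pred)),
            predictions$call, enc)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_predictions
#' @return for `read_predictions`, a data.frame with one row per compound and
#'   a `neighbors` attribute (list of per-compound neighbor data.frames).
#' @export
read_predictions <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  out <- data.frame(
    compound_id = raw$compound_id,
    a_pred = suppressWarnings(as.numeric(raw$a_pred)),
    call = raw$call,
    stringsAsFactors = FALSE
  )
  nb <- lapply(raw$neighbors, function(s) {
    if (!nzchar(s)) {
      return(data.frame(id = character(), P = numeric(), S = numeric(),
                        A = integer(), stringsAsFactors = FALSE))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(
      id = vapply(parts, `[`, character(1), 1),
      P = as.numeric(vapply(parts, `[`, character(1), 2)),
      S = as.numeric(vapply(parts, `[`, character(1), 3)),
      A = as.integer(vapply(parts, `[`, character(1), 4)),
      stringsAsFactors = FALSE
    )
  })
  names(nb) <- out$compound_id
  attr(out, "neighbors") <- nb
  class(out) <- c("babra_predictions", "data.frame")
  out
}

#' Write or read an evaluation report as JSON
#'
#' The JSON carries confusion counts, metrics, the significance estimate,
#' counts of non-evaluable compounds, the configuration echo and the seed.
#'
#' @param report a `babra_report` from [loo_evaluate()].
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$confusion <- as.list(out$confusion)  # keep tp/fp/tn/fn keys in JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$confusion <- unlist(rep$confusion)
  class(rep) <- "babra_report"
  rep
}
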