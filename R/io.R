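# Domain data model and readers/writers for the external text formats:
# interaction tables, compound tables, target FASTA, similarity matrices
# and prediction-region tables.

#' Construct an interaction table
#'
#' An interaction table holds measured compound-target binding affinities
#' in pKd/pKi units (-log10 molar).  It is a plain `data.frame` with
#' columns `compound_id`, `target_id` and `affinity`, carrying class
#' `interaction_table`.
#'
#' @param compound_id,target_id Character vectors of entity identifiers.
#' @param affinity Numeric vector of binding affinities (pKd/pKi).
#' @return An `interaction_table`.
#' @export
interaction_table <- function(compound_id, target_id, affinity) {
  compound_id <- as.character(compound_id)
  target_id <- as.character(target_id)
  affinity <- as.numeric(affinity)
  n <- length(affinity)
  if (length(compound_id) != n || length(target_id) != n) {
    stop("compound_id, target_id and affinity must have equal length",
         call. = FALSE)
  }
  if (n && any(!is.finite(affinity))) {
    stop("all affinities must be finite; offending rows: ",
         paste(utils::head(which(!is.finite(affinity)), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (n && (any(!nzchar(compound_id)) || any(!nzchar(target_id)))) {
    stop("compound and target ids must be non-empty strings", call. = FALSE)
  }
  out <- data.frame(compound_id = compound_id, target_id = target_id,
                    affinity = affinity, stringsAsFactors = FALSE)
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Read an interaction table from delimited text
#'
#' The delimiter (comma or tab) is auto-detected from the header line.
#' Rows whose affinity does not parse as a finite number are rejected with
#' their row index reported.  Duplicate (compound, target) pairs are kept
#' as-is; call [aggregate_duplicates()] to merge them.
#'
#' @param path Path to a delimited text file with a header.
#' @param column_map Named character vector mapping the canonical names
#'   `compound_id`, `target_id`, `affinity` to the file's column names.
#' @return An [interaction_table()].
#' @export
read_interaction_table <- function(path,
                                   column_map = c(compound_id = "compound_id",
                                                  target_id = "target_id",
                                                  affinity = "affinity")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  needed <- c("compound_id", "target_id", "affinity")
  if (is.null(names(column_map))) names(column_map) <- needed
  missing_cols <- setdiff(column_map[needed], colnames(raw))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("empty interaction table: ", path, call. = FALSE)
  aff <- suppressWarnings(as.numeric(raw[[column_map[["affinity"]]]]))
  bad <- which(!is.finite(aff))
  if (length(bad)) {
    stop("non-numeric affinity in ", path, " at data row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  interaction_table(raw[[column_map[["compound_id"]]]],
                    raw[[column_map[["target_id"]]]],
                    aff)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Merge duplicate interaction measurements
#'
#' Collapses repeated measurements of the same (compound, target) pair to
#' a single record.  The default aggregator is the arithmetic mean, the
#' least-surprising reconciliation when Kd- and Ki-derived values coexist
#' for a pair.  Output rows are sorted by compound id then target id, so
#' the operation is deterministic and idempotent.
#'
#' @param table An [interaction_table()].
#' @param fun Aggregation function applied to duplicate affinities.
#' @return An [interaction_table()] with one record per pair.
#' @export
aggregate_duplicates <- function(table, fun = mean) {
  stopifnot(inherits(table, "interaction_table"))
  key <- pair_key(table$compound_id, table$target_id)
  agg <- tapply(table$affinity, key, fun)
  first <- !duplicated(key)
  ord_tbl <- table[first, , drop = FALSE]
  ord_tbl$affinity <- as.numeric(agg[pair_key(ord_tbl$compound_id,
                                              ord_tbl$target_id)])
  ord <- order(ord_tbl$compound_id, ord_tbl$target_id)
  out <- interaction_table(ord_tbl$compound_id[ord], ord_tbl$target_id[ord],
                           ord_tbl$affinity[ord])
  out
}

#' Write an interaction table as delimited text
#'
#' @param table An [interaction_table()].
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(table, path, sep = "\t") {
  stopifnot(inherits(table, "interaction_table"))
  utils::write.table(
    data.frame(compound_id = table$compound_id,
               target_id = table$target_id,
               affinity = fmt6(table$affinity)),
    path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein target sequences from FASTA
#'
#' The target id is the first whitespace-delimited token of the header;
#' sequences are uppercased and line wrapping is joined.  Characters
#' outside the 20-letter amino-acid alphabet plus X are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A `target_set`: a named character vector of sequences.
#' @export
read_targets_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  target_set(seqs)
}

#' Construct a target set
#'
#' @param sequences Named character vector: names are target ids, values
#'   are amino-acid sequences over the 20-letter alphabet plus X.
#' @return A `target_set`.
#' @export
target_set <- function(sequences) {
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every target sequence must be named by a non-empty id",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate target id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sequences <- toupper(as.character(sequences))
  names(sequences) <- ids
  if (any(!nzchar(sequences))) {
    stop("empty sequence for target(s): ",
         paste(ids[!nzchar(sequences)], collapse = ", "), call. = FALSE)
  }
  ok <- grepl(paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$"),
              sequences)
  if (any(!ok)) {
    stop("illegal characters in sequence(s): ",
         paste(ids[!ok], collapse = ", "), call. = FALSE)
  }
  structure(sequences, class = "target_set")
}

#' @export
`[.target_set` <- function(x, i) {
  target_set(unclass(x)[i])
}

#' Construct a compound set
#'
#' @param ids Character vector of compound ids (unique, non-empty).
#' @param fingerprints Optional binary matrix (rows = compounds) of
#'   fingerprint bits; row order matches `ids`.
#' @param smiles Optional character vector of SMILES strings.
#' @return A `compound_set` list with elements `ids`, `fingerprints`,
#'   `smiles`.
#' @export
compound_set <- function(ids, fingerprints = NULL, smiles = NULL) {
  ids <- as.character(ids)
  if (any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop("compound ids must be unique non-empty strings", call. = FALSE)
  }
  if (!is.null(fingerprints)) {
    fingerprints <- as.matrix(fingerprints)
    if (nrow(fingerprints) != length(ids)) {
      stop("fingerprint matrix must have one row per compound",
           call. = FALSE)
    }
    if (!all(fingerprints %in% c(0, 1))) {
      stop("fingerprints must be binary", call. = FALSE)
    }
    storage.mode(fingerprints) <- "integer"
    rownames(fingerprints) <- ids
  }
  if (!is.null(smiles)) {
    smiles <- as.character(smiles)
    if (length(smiles) != length(ids)) {
      stop("smiles must align with ids", call. = FALSE)
    }
    names(smiles) <- ids
  }
  structure(list(ids = ids, fingerprints = fingerprints, smiles = smiles),
            class = "compound_set")
}

#' Read a compound table (id + SMILES or fingerprint bitstring)
#'
#' Expects delimited text with a header containing an `id` column and
#' either a `smiles` column or a `fingerprint` column of 0/1 bitstrings.
#'
#' @param path Path to a delimited text file.
#' @return A [compound_set()].
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE)
  if (!"id" %in% colnames(raw)) {
    stop("compound table must have an 'id' column", call. = FALSE)
  }
  fp <- NULL
  if ("fingerprint" %in% colnames(raw)) {
    bits <- strsplit(raw$fingerprint, "")
    len <- unique(lengths(bits))
    if (length(len) != 1L) {
      stop("all fingerprint bitstrings must have equal length",
           call. = FALSE)
    }
    fp <- do.call(rbind, lapply(bits, as.integer))
  }
  compound_set(raw$id, fingerprints = fp,
               smiles = if ("smiles" %in% colnames(raw)) raw$smiles)
}

#' Construct (and validate) a similarity matrix
#'
#' A similarity matrix is a dense symmetric matrix of pairwise
#' similarities in \[0, 1\] with unit diagonal, with entity ids as
#' dimnames.  Asymmetries beyond 1e-9 and off-range entries are rejected.
#'
#' @param values Square numeric matrix.
#' @param ids Entity ids (defaults to the matrix rownames).
#' @return A `similarity_matrix`.
#' @export
similarity_matrix <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("similarity matrix must be square", call. = FALSE)
  }
  if (is.null(ids) || length(ids) != nrow(values)) {
    stop("similarity matrix needs one id per row", call. = FALSE)
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate entity ids", call. = FALSE)
  dimnames(values) <- list(ids, ids)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    stop("similarity values must be finite and in [0, 1]", call. = FALSE)
  }
  if (max(abs(values - t(values))) > 1e-9) {
    stop("similarity matrix asymmetric beyond 1e-9", call. = FALSE)
  }
  if (any(abs(diag(values) - 1) > 1e-9)) {
    stop("similarity matrix diagonal must be 1", call. = FALSE)
  }
  diag(values) <- 1
  structure(values, class = c("similarity_matrix", "matrix", "array"))
}

#' Read a similarity matrix from delimited text
#'
#' First row and first column carry the entity ids.
#'
#' @param path Path to a square delimited text file.
#' @return A [similarity_matrix()].
#' @export
read_similarity_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE)
  similarity_matrix(as.matrix(raw))
}

#' Write a similarity matrix as delimited text
#'
#' @param m A [similarity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(m, path) {
  stopifnot(inherits(m, "similarity_matrix"))
  df <- data.frame(id = rownames(m),
                   format(unclass(m), digits = 17, scientific = FALSE,
                          trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Prediction-region table serialization ------------------------------------

fmt6 <- function(x) {
  out <- ifelse(is.na(x), "", formatC(x, format = "f", digits = 6))
  out
}

#' Write prediction regions to delimited text
#'
#' One row per (pair, confidence level).  Abstained rows carry empty
#' `alpha`, `lower` and `upper` fields.  Floats are serialized at six
#' decimal places.
#'
#' @param regions A `prediction_regions` data frame as returned by
#'   [predict.dad_model()] or [predict.icp_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(regions, path) {
  if (NROW(regions) == 0L) stop("no regions to write", call. = FALSE)
  cols <- c("compound_id", "target_id", "y_pred", "confidence", "alpha",
            "lower", "upper", "abstained", "n_calibration")
  stopifnot(all(cols %in% colnames(regions)))
  out <- data.frame(
    compound_id = regions$compound_id,
    target_id = regions$target_id,
    y_pred = fmt6(regions$y_pred),
    confidence = fmt6(regions$confidence),
    alpha = fmt6(ifelse(regions$abstained, NA_real_, regions$alpha)),
    lower = fmt6(ifelse(regions$abstained, NA_real_, regions$lower)),
    upper = fmt6(ifelse(regions$abstained, NA_real_, regions$upper)),
    abstained = tolower(as.character(regions$abstained)),
    n_calibration = regions$n_calibration,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a prediction-region table
#'
#' @param path Path written by [write_predictions()].
#' @return A `prediction_regions` data frame.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  num <- function(x) suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
  out <- data.frame(
    compound_id = raw$compound_id,
    target_id = raw$target_id,
    y_pred = num(raw$y_pred),
    confidence = num(raw$confidence),
    alpha = num(raw$alpha),
    lower = num(raw$lower),
    upper = num(raw$upper),
    abstained = raw$abstained == "true",
    n_calibration = as.integer(raw$n_calibration),
    stringsAsFactors = FALSE)
  class(out) <- c("prediction_regions", "data.frame")
  out
}
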