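#' Derive a child RNG seed from a master seed and stage labels
#'
#' Child seeds are a stable 31-bit hash of the master seed plus one or more
#' stage labels, so different pipeline stages never share a random stream and
#' the same master seed always reproduces the same run.
#'
#' @param master integer master seed.
#' @param ... stage labels (coerced to character).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "walks", "expr")
derive_seed <- function(master, ...) {
  parts <- vapply(list(master, ...), function(x) paste(format(x), collapse = ","),
                  character(1))
  bytes <- utf8ToInt(paste(parts, collapse = "|"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

# stable content hash (hex string) used in run manifests; FNV-1a over the
# serialized object, no external digest dependency
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

.assert <- function(ok, msg, ...) if (!isTRUE(ok)) stop(sprintf(msg, ...), call. = FALSE)

.is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)

# Matrices are carried patients x features with rownames = patient ids,
# colnames = feature ids and a "source_tag" attribute.
.check_omics <- function(m, what = "omics matrix") {
  .assert(is.matrix(m) && is.numeric(m), "%s must be a numeric matrix", what)
  .assert(!is.null(rownames(m)) && !is.null(colnames(m)),
          "%s must carry patient ids (rownames) and feature ids (colnames)", what)
  .assert(!anyDuplicated(rownames(m)), "%s has duplicate patient ids", what)
  .assert(!anyDuplicated(colnames(m)), "%s has duplicate feature ids", what)
  invisible(m)
}

#' Write an omics matrix in the package TSV dialect
#'
#' Features are rows and patients are columns; the header row holds patient
#' ids and the first column (`feature_id`) holds feature ids.
#'
#' @param m numeric matrix, patients x features, with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_omics_tsv <- function(m, path) {
  .check_omics(m)
  df <- data.frame(feature_id = colnames(m), t(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an omics matrix written by [write_omics_tsv()]
#'
#' @param path TSV file (features as rows, patients as columns).
#' @param source_tag optional label attached as the matrix `source_tag`
#'   attribute.
#' @return numeric matrix, patients x features.
#' @export
read_omics_tsv <- function(path, source_tag = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(df) >= 2, "omics TSV needs a feature_id column plus >=1 patient")
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(vals) <- as.character(df[[1]])
  rownames(vals) <- colnames(df)[-1]
  storage.mode(vals) <- "double"
  if (!is.null(source_tag)) attr(vals, "source_tag") <- source_tag
  vals
}

#' Write a clinical endpoint table
#'
#' Patients are rows; each endpoint is a 0/1 column.
#'
#' @param clinical 0/1 matrix or data.frame, patients x endpoints, with
#'   patient ids as rownames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clinical_tsv <- function(clinical, path) {
  clinical <- as.matrix(clinical)
  .assert(all(clinical %in% c(0, 1)), "clinical endpoints must be 0/1")
  df <- data.frame(patient_id = rownames(clinical), clinical, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical endpoint table written by [write_clinical_tsv()]
#'
#' @param path TSV file.
#' @return integer 0/1 matrix, patients x endpoints.
#' @export
read_clinical_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  .assert(all(m %in% c(0L, 1L)), "clinical endpoints must be 0/1")
  m
}

#' Write a feature matrix as TSV with a family comment line
#'
#' @param m patients x features matrix with a `family` attribute.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fam <- attr(m, "family")
  if (!is.null(fam)) writeLines(sprintf("# family: %s", fam), con)
  df <- data.frame(patient_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features_tsv()]
#' @param path TSV file.
#' @return patients x features numeric matrix (family comment restored as
#'   attribute when present).
#' @export
read_features_tsv <- function(path) {
  first <- readLines(path, n = 1)
  fam <- if (startsWith(first, "# family:")) trimws(sub("# family:", "", first)) else NULL
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (!is.null(fam)) attr(m, "family") <- fam
  m
}
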