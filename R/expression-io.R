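#' Read an expression matrix from tab-separated text
#'
#' Expects a header row of condition names and a first column of gene
#' identifiers; all remaining cells numeric.  Gene and condition identifiers
#' must be unique.  Rows containing missing or non-numeric values are either
#' rejected (default) or dropped with a message.
#'
#' @param path path to a TSV file.
#' @param missing_policy `"reject"` (error on any missing value) or
#'   `"drop_rows"` (remove offending rows, reporting how many).
#' @return A numeric matrix, genes in rows (rownames), conditions in
#'   columns (colnames).
#' @seealso [write_expression_matrix()]
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' write_expression_matrix(m, tf)
#' read_expression_matrix(tf)
#' @export
read_expression_matrix <- function(path, missing_policy = c("reject", "drop_rows")) {
  missing_policy <- match.arg(missing_policy)
  # cells come in as text; base as.numeric() is correctly rounded, so a
  # matrix written at full precision reads back bit-for-bit
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = character())
  if (ncol(df) < 3) stop("expression matrix needs at least 2 condition columns", call. = FALSE)
  genes <- as.character(df[[1]])
  conds <- colnames(df)[-1]
  if (anyDuplicated(genes)) stop("duplicated gene identifiers in matrix", call. = FALSE)
  if (anyDuplicated(conds)) stop("duplicated condition identifiers in matrix", call. = FALSE)
  m <- suppressWarnings(apply(as.matrix(df[-1]), 2, as.numeric))
  dimnames(m) <- list(genes, conds)
  bad <- !is.finite(m)
  if (any(bad)) {
    if (missing_policy == "reject") {
      stop("matrix contains missing or non-numeric values; use missing_policy = 'drop_rows' to drop them",
           call. = FALSE)
    }
    drop <- rowSums(bad) > 0
    message(sum(drop), " row(s) with missing values dropped")
    m <- m[!drop, , drop = FALSE]
  }
  validate_expression_matrix(m)
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression_matrix()]; doubles are written in shortest
#' round-trip representation so write-then-read preserves values exactly.
#'
#' @param mat numeric matrix with gene rownames and condition colnames.
#' @param path output path.
#' @param id_column header name for the gene-identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, id_column = "gene") {
  mat <- validate_expression_matrix(mat)
  # %.17g guarantees read-back reproduces each double bit-for-bit
  chr <- matrix(sprintf("%.17g", mat), nrow(mat), ncol(mat),
                dimnames = dimnames(mat))
  df <- tibble::as_tibble(chr, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(!!id_column := rownames(mat)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks shape (>= 2 x 2), unique dimnames and finiteness; returns the
#' matrix (with synthesized dimnames if absent).
#'
#' @param mat numeric matrix.
#' @return the validated matrix.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("degenerate expression matrix: need at least 2 genes and 2 conditions", call. = FALSE)
  }
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  if (anyDuplicated(rownames(mat))) stop("duplicated gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(mat))) stop("duplicated condition identifiers", call. = FALSE)
  if (!all(is.finite(mat))) stop("expression matrix contains non-finite values", call. = FALSE)
  mat
}
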