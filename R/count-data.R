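#' Detected-gene count vector
#'
#' A `count_vector` holds the result of an RNA-seq experiment as the vector of
#' per-gene tag counts `y = (y_1, ..., y_g)`, keeping only detected genes
#' (`y_i >= 1`). It carries the sequencing depth `N = sum(y)` and the number of
#' detected genes `g = length(y)`. Counts are stored as doubles internally so
#' that `N` may exceed the 32-bit integer range (deep samples reach hundreds
#' of millions of tags) while remaining exact (doubles represent integers
#' exactly up to 2^53).
#'
#' @param counts integer-valued vector of tag counts, all `>= 1`.
#' @param gene_ids optional character vector of unique gene identifiers, one
#'   per count; autogenerated (`"g1"`, `"g2"`, ...) when omitted.
#'
#' @return An object of class `"count_vector"`: a list with elements
#'   `gene_ids`, `counts`, `N` (total tags) and `g` (detected genes).
#' @examples
#' cv <- count_vector(c(2, 3, 1))
#' cv$N  # 6
#' cv$g  # 3
#' @export
count_vector <- function(counts, gene_ids = NULL) {
  counts <- as.double(counts)
  if (length(counts) == 0L)
    stop("count_vector: at least one detected gene is required")
  if (anyNA(counts) || any(counts < 1) || any(counts != floor(counts)))
    stop("count_vector: counts must be integers >= 1 (undetected genes must not appear)")
  if (is.null(gene_ids))
    gene_ids <- paste0("g", seq_along(counts))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != length(counts))
    stop("count_vector: gene_ids and counts lengths differ")
  if (anyDuplicated(gene_ids))
    stop("count_vector: duplicate gene identifiers")
  structure(
    list(gene_ids = gene_ids, counts = counts,
         N = sum(counts), g = length(counts)),
    class = "count_vector"
  )
}

#' @export
print.count_vector <- function(x, ...) {
  cat("Count vector: g =", format(x$g, big.mark = ",", scientific = FALSE),
      "detected genes, N =", format(x$N, big.mark = ",", scientific = FALSE),
      "tags\n")
  invisible(x)
}

#' Gene-by-library expression count matrix
#'
#' Validates a genes x libraries matrix of raw (non-negative integer) tag
#' counts. Rows with all-zero counts are retained: a gene may be undetected in
#' one library yet present in another, and per-library versus total-library
#' comparisons need the full row set.
#'
#' @param counts numeric matrix (genes x libraries) of non-negative integers.
#' @param gene_ids unique gene identifiers (defaults to rownames).
#' @param libraries library names (defaults to colnames).
#' @return An object of class `"expression_matrix"`: a list with `gene_ids`,
#'   `libraries` and the integer-valued `counts` matrix.
#' @export
expression_matrix <- function(counts, gene_ids = rownames(counts),
                              libraries = colnames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(counts)))
  if (is.null(libraries)) libraries <- paste0("lib", seq_len(ncol(counts)))
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("expression_matrix: counts must be non-negative integers (raw tag counts, not normalized values)")
  if (length(gene_ids) != nrow(counts))
    stop("expression_matrix: gene_ids length must equal number of rows")
  if (length(libraries) != ncol(counts))
    stop("expression_matrix: libraries length must equal number of columns")
  if (anyDuplicated(gene_ids))
    stop("expression_matrix: duplicate gene identifiers")
  dimnames(counts) <- list(gene_ids, libraries)
  structure(
    list(gene_ids = as.character(gene_ids),
         libraries = as.character(libraries),
         counts = counts),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$counts), "genes x",
      ncol(x$counts), "libraries\n")
  invisible(x)
}

#' Read a delimited gene count table
#'
#' Reads a text count table with a mandatory header row: first column gene
#' identifiers, remaining columns raw integer tag counts, one column per
#' library. The delimiter is auto-detected from the file extension
#' (`.csv` = comma, anything else = tab) unless given explicitly. Normalized
#' (non-integer) data are rejected: the estimators operate on raw counts only.
#'
#' @param path path to the count table.
#' @param sep field delimiter; `NULL` (default) auto-detects from extension.
#' @return An [expression_matrix()].
#' @seealso [collapse_libraries()], [library_counts()]
#' @export
read_count_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("read_count_table: file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("read_count_table: no data rows in ", path)
  if (ncol(df) < 2L)
    stop("read_count_table: need a gene-id column plus at least one count column")
  gene_ids <- df[[1L]]
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1L]
    stop("read_count_table: duplicate gene id '", dup, "'")
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) & !is.na(raw))
  if (length(bad)) {
    row <- ((bad[1L] - 1L) %% nrow(raw)) + 1L
    stop("read_count_table: malformed count '", raw[bad[1L]],
         "' at data line ", row)
  }
  if (anyNA(num)) stop("read_count_table: missing count values")
  nonint <- which(num != floor(num))
  if (length(nonint)) {
    row <- ((nonint[1L] - 1L) %% nrow(num)) + 1L
    stop("read_count_table: non-integer count '", raw[nonint[1L]],
         "' at data line ", row,
         "; raw tag counts are required (normalized data cannot be used)")
  }
  if (any(num < 0)) stop("read_count_table: negative counts are not allowed")
  expression_matrix(num, gene_ids = gene_ids, libraries = colnames(df)[-1L])
}

#' Collapse all libraries of an accession into a total library
#'
#' Sums tag counts across libraries gene by gene (`y_i_total = sum_j y_ij`),
#' giving the "total library" of the accession: the sample holding every gene
#' detected anywhere in the experiment. Genes with zero total count are
#' dropped ("detected" means at least one tag).
#'
#' @param mat an [expression_matrix()].
#' @return A [count_vector()] of per-gene totals.
#' @examples
#' m <- expression_matrix(cbind(a = c(2, 0), b = c(0, 3)))
#' collapse_libraries(m)$N  # 5
#' @export
collapse_libraries <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  tot <- rowSums(mat$counts)
  keep <- tot > 0
  if (!any(keep)) stop("collapse_libraries: no detected genes in any library")
  count_vector(tot[keep], gene_ids = mat$gene_ids[keep])
}

#' Extract a single library as a count vector
#'
#' @param mat an [expression_matrix()].
#' @param library_name name of the library (column) to extract.
#' @return A [count_vector()] of that library's positive counts.
#' @export
library_counts <- function(mat, library_name) {
  stopifnot(inherits(mat, "expression_matrix"))
  j <- match(library_name, mat$libraries)
  if (is.na(j))
    stop("library_counts: unknown library '", library_name, "'")
  y <- mat$counts[, j]
  keep <- y > 0
  if (!any(keep))
    stop("library_counts: library '", library_name, "' has no detected genes")
  count_vector(y[keep], gene_ids = mat$gene_ids[keep])
}
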