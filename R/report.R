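#' Write a table of richness estimates to a delimited file
#'
#' One row per estimate with columns `sample`, `N`, `g`, `f0_hat`, `se`,
#' `ci_lower`, `ci_upper`, `pct_missing`, `estimator`, `flags`. Depth and
#' gene counts are integers; `f0_hat`, `se` and the CI bounds are rounded to
#' the nearest integer (they count genes) and `pct_missing` to `digits`
#' decimals. Degenerate estimates carry the flag `"degenerate"` and an empty
#' value.
#'
#' @param estimates a single [richness_estimate()] or a list of them.
#' @param destination output file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param sample_names optional character vector naming each estimate's
#'   sample; recycled from `"sample1"`, ... when omitted.
#' @param digits decimal places for `pct_missing`.
#' @return Invisibly, the data frame written.
#' @export
write_report <- function(estimates, destination, format = c("tsv", "csv"),
                         sample_names = NULL, digits = 2) {
  format <- match.arg(format)
  if (inherits(estimates, "richness_estimate")) estimates <- list(estimates)
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, TRUE, "richness_estimate")))
  if (is.null(sample_names))
    sample_names <- paste0("sample", seq_along(estimates))
  num <- function(x) vapply(estimates, function(e) as.double(e[[x]]), 0)
  df <- data.frame(
    sample = sample_names,
    N = round(num("N")),
    g = round(num("g")),
    f0_hat = round(num("f0_hat")),
    se = round(num("se")),
    ci_lower = round(num("ci_lower")),
    ci_upper = round(num("ci_upper")),
    pct_missing = round(num("pct_missing"), digits),
    estimator = vapply(estimates, function(e) e$estimator, ""),
    flags = vapply(estimates, function(e)
      if (e$degenerate) "degenerate" else "", ""),
    stringsAsFactors = FALSE
  )
  sep <- if (format == "csv") "," else "\t"
  tryCatch(
    suppressWarnings(utils::write.table(df, destination, sep = sep,
                                        quote = FALSE, row.names = FALSE)),
    error = function(e) stop("write_report: cannot write to '",
                             destination, "': ", conditionMessage(e))
  )
  invisible(df)
}

#' Write a count table to a delimited file
#'
#' Inverse of [read_count_table()]: gene-id first column, one column per
#' library, header row. Round-trips the integer matrix exactly.
#'
#' @param mat an [expression_matrix()] or a [count_vector()] (written as a
#'   single-library table).
#' @param destination output file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return Invisibly, `destination`.
#' @export
write_count_table <- function(mat, destination, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (inherits(mat, "count_vector"))
    mat <- expression_matrix(matrix(mat$counts, ncol = 1,
                                    dimnames = list(mat$gene_ids, "total")))
  stopifnot(inherits(mat, "expression_matrix"))
  df <- data.frame(gene = mat$gene_ids,
                   format(mat$counts, scientific = FALSE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("gene", mat$libraries)
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(df, destination, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(destination)
}
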