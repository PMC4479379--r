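#' Frequency-of-frequencies spectrum
#'
#' The spectrum `f_r` counts how many genes were observed exactly `r` times in
#' a sample: `f_1` is the number of singletons, `f_2` the number of doubletons,
#' and so on. It is the sufficient statistic for every richness estimator in
#' this package. `f_0` — the number of expressed genes observed zero times —
#' is the estimand, never a field. The spectrum is stored sparsely (only
#' `r` with `f_r > 0`) and the maximum `r` is unbounded.
#'
#' @param r integer vector of tag-count values (`>= 1`).
#' @param f integer vector of frequencies-of-frequencies, same length as `r`.
#' @return An object of class `"freq_spectrum"`: a list with sorted vectors
#'   `r` and `f` (entries with `f_r = 0` removed), the depth `N = sum(r * f)`
#'   and the detected-gene count `g = sum(f)`.
#' @examples
#' sp <- freq_spectrum(r = c(1, 2, 3), f = c(2, 1, 2))
#' sp$N  # 10
#' sp$g  # 5
#' @export
freq_spectrum <- function(r, f) {
  r <- as.double(r); f <- as.double(f)
  if (length(r) != length(f)) stop("freq_spectrum: r and f lengths differ")
  if (anyNA(r) || anyNA(f)) stop("freq_spectrum: missing values")
  if (any(r < 1) || any(r != floor(r))) stop("freq_spectrum: r must be integers >= 1")
  if (any(f < 0) || any(f != floor(f))) stop("freq_spectrum: f must be integers >= 0")
  if (anyDuplicated(r)) stop("freq_spectrum: duplicate r values")
  keep <- f > 0
  r <- r[keep]; f <- f[keep]
  o <- order(r)
  r <- r[o]; f <- f[o]
  g <- sum(f)
  if (g == 0) stop("freq_spectrum: empty spectrum (no detected genes)")
  structure(list(r = r, f = f, N = sum(r * f), g = g),
            class = "freq_spectrum")
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat("Frequency spectrum: g =", format(x$g, big.mark = ",", scientific = FALSE),
      "genes, N =", format(x$N, big.mark = ",", scientific = FALSE), "tags\n")
  cat("  f1..f6:", paste0("f", 1:6, "=", spectrum_f(x, 1:6), collapse = " "), "\n")
  invisible(x)
}

#' Look up f_r values in a spectrum
#'
#' Absent keys mean `f_r = 0`.
#'
#' @param spec a [freq_spectrum()].
#' @param r integer vector of tag-count values.
#' @return Numeric vector of `f_r` values (0 where absent).
#' @export
spectrum_f <- function(spec, r) {
  stopifnot(inherits(spec, "freq_spectrum"))
  i <- match(r, spec$r)
  out <- ifelse(is.na(i), 0, spec$f[i])
  as.double(out)
}

#' Build the frequency spectrum of a count vector
#'
#' Tallies `f_r = #\{i : y_i = r\}`. By construction
#' `sum(r * f_r) = N` and `sum(f_r) = g`.
#'
#' @param cv a [count_vector()], or a bare vector of positive integer counts.
#' @return A [freq_spectrum()].
#' @examples
#' spectrum_from_counts(c(1, 1, 2, 3, 3))  # f1=2, f2=1, f3=2
#' @export
spectrum_from_counts <- function(cv) {
  if (!inherits(cv, "count_vector")) cv <- count_vector(cv)
  tb <- table(cv$counts)
  freq_spectrum(r = as.double(names(tb)), f = as.double(tb))
}

#' Is a sample complete?
#'
#' A sample is operationally complete when it has no singletons (`f_1 = 0`):
#' every detected gene is supported by at least two tags, the standard
#' stopping rule for with-replacement class sampling. Complete samples serve
#' as known-truth references for estimator evaluation.
#'
#' @param spec a [freq_spectrum()] or [count_vector()].
#' @return `TRUE` iff `f_1 = 0`.
#' @export
is_complete <- function(spec) {
  if (inherits(spec, "count_vector")) spec <- spectrum_from_counts(spec)
  stopifnot(inherits(spec, "freq_spectrum"))
  spectrum_f(spec, 1) == 0
}

#' Read a bare frequency spectrum from a two-column file
#'
#' Input mode for data already reduced to a spectrum: a delimited text file
#' with header and two columns, `r` and `f_r`.
#'
#' @param path file path.
#' @param sep delimiter; auto-detected from extension when `NULL`.
#' @return A [freq_spectrum()].
#' @export
read_spectrum <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("read_spectrum: file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(df) < 2L) stop("read_spectrum: need columns r and f_r")
  freq_spectrum(r = df[[1L]], f = df[[2L]])
}
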