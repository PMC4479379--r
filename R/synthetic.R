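## Known-truth synthetic transcriptomes. A population fixes the true number
## of expressed genes G and a relative-abundance vector p; samples drawn from
## it have a known number of missing genes, so estimators can be scored
## against truth without any external data.

#' Create a synthetic transcriptome population
#'
#' Draws `G` relative abundances from an abundance model and normalizes them
#' to probabilities. The heavy-tailed models (`"lognormal"`, `"pareto"`)
#' emulate real transcriptomes, where a few transcripts are very abundant and
#' most are rare; `"uniform"` is a degenerate benchmark; `"from_counts"`
#' turns an observed count vector into a population via `p_i = y_i / N`,
#' the maximum-likelihood abundances of a sample accepted as complete.
#'
#' @param G true number of expressed genes (`>= 1`). Ignored for
#'   `"from_counts"`, where `G` is the number of genes in `counts`.
#' @param model `"lognormal"`, `"pareto"`, `"uniform"` or `"from_counts"`.
#' @param meanlog,sdlog log-normal parameters (model `"lognormal"`).
#' @param alpha,xmin Pareto shape (`> 0`) and scale (`> 0`) (model `"pareto"`).
#' @param counts a [count_vector()] (model `"from_counts"`).
#' @param seed optional integer seed; the draw is deterministic given it.
#' @return An object of class `"synthetic_population"`: list with `G`, the
#'   probability vector `p` (all `p_i > 0`, summing to 1), `model` and the
#'   model parameters.
#' @examples
#' pop <- make_population(10, "uniform")
#' pop$p  # all 0.1
#' @export
make_population <- function(G, model = c("lognormal", "pareto", "uniform", "from_counts"),
                            meanlog = 0, sdlog = 1.5, alpha = 1.2, xmin = 1,
                            counts = NULL, seed = NULL) {
  model <- match.arg(model)
  if (model != "from_counts") {
    if (length(G) != 1L || G < 1 || G != floor(G))
      stop("make_population: G must be an integer >= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  ab <- switch(model,
    lognormal = {
      if (sdlog < 0) stop("make_population: sdlog must be >= 0")
      stats::rlnorm(G, meanlog = meanlog, sdlog = sdlog)
    },
    pareto = {
      if (alpha <= 0 || xmin <= 0)
        stop("make_population: alpha and xmin must be positive")
      # inverse-CDF draw: x = xmin * U^(-1/alpha)
      xmin * stats::runif(G)^(-1 / alpha)
    },
    uniform = rep(1, G),
    from_counts = {
      if (!inherits(counts, "count_vector"))
        stop("make_population: model 'from_counts' requires a count_vector")
      counts$counts
    }
  )
  p <- ab / sum(ab)
  params <- switch(model,
    lognormal = list(meanlog = meanlog, sdlog = sdlog),
    pareto = list(alpha = alpha, xmin = xmin),
    list()
  )
  structure(list(G = length(p), p = p, model = model, params = params,
                 seed = seed),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("Synthetic population:", x$model, "model, G =",
      format(x$G, big.mark = ","), "genes\n")
  invisible(x)
}

#' Draw a sequencing sample from a synthetic population
#'
#' Sampling with replacement from a conceptually infinite pool of molecules:
#' either one multinomial draw of exactly `N` tags, or independent Poisson
#' counts with rates `N * p_i` (total random with expectation `N`). Genes
#' drawn zero times are excluded from the returned count vector, and the
#' realized number of missing genes `true_f0 = G - g` is returned alongside.
#'
#' @param pop a [make_population()] object.
#' @param N target depth in tags (`>= 1`).
#' @param distribution `"multinomial"` or `"poisson"`.
#' @param seed optional integer seed.
#' @return List with elements `sample` (a [count_vector()] over gene ids
#'   `"g1"..."gG"`) and `true_f0`.
#' @export
draw_sample <- function(pop, N, distribution = c("multinomial", "poisson"),
                        seed = NULL) {
  stopifnot(inherits(pop, "synthetic_population"))
  distribution <- match.arg(distribution)
  if (length(N) != 1L || N < 1) stop("draw_sample: N must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  y <- if (distribution == "multinomial") {
    drop(stats::rmultinom(1, size = N, prob = pop$p))
  } else {
    stats::rpois(pop$G, lambda = N * pop$p)
  }
  keep <- y > 0
  if (!any(keep))
    return(list(sample = NULL, true_f0 = pop$G))
  list(sample = count_vector(y[keep], gene_ids = paste0("g", which(keep))),
       true_f0 = pop$G - sum(keep))
}

#' Build a complete reference sample from a population
#'
#' Draws samples of doubling depth starting at `target_N` until one satisfies
#' the completeness criterion (`f1 = 0` and every gene detected), mirroring
#' how a real complete accession is identified. The returned sample is the
#' known-truth reference for the selection harness: its `g` equals the
#' population's `G`.
#'
#' @param pop a [make_population()] object.
#' @param target_N starting depth.
#' @param seed optional integer seed.
#' @param max_doublings cap on the number of depth doublings before giving up.
#' @return A complete [count_vector()].
#' @export
make_complete_reference <- function(pop, target_N = 2e6, seed = NULL,
                                    max_doublings = 12L) {
  stopifnot(inherits(pop, "synthetic_population"))
  if (!is.null(seed)) set.seed(seed)
  N <- target_N
  last_f1 <- NA
  for (k in 0:max_doublings) {
    dr <- draw_sample(pop, N, "multinomial")
    if (!is.null(dr$sample)) {
      sp <- spectrum_from_counts(dr$sample)
      last_f1 <- spectrum_f(sp, 1)
      if (last_f1 == 0 && dr$sample$g == pop$G) return(dr$sample)
    }
    N <- N * 2
  }
  stop("make_complete_reference: completeness not reached after ",
       max_doublings, " doublings (last f1 = ", last_f1,
       "); increase target_N or the cap")
}
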