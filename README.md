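# genemiss — how many expressed genes did your RNA-seq sample miss?

An RNA-seq experiment reports tag counts for the `g` genes it detected, but
an unknown number of expressed genes, `f0`, received zero tags because the
sequencing depth `N` was finite. The true number of expressed genes is
`G = g + f0`. Treating "not detected" as "not expressed" — the implicit
assumption of standard pipelines — is unsafe exactly for the genes that
matter most, the weakly expressed ones (transcription factors and other
regulators). This is the classic unseen-species problem of ecology, carried
over to transcriptomics: tags are draws with replacement from an effectively
infinite pool of molecules, genes are species.

`genemiss` estimates `f0` non-parametrically from the sample's
**frequency-of-frequencies spectrum** `f_r` (the number of genes observed
exactly `r` times; `f1` = singletons, `f2` = doubletons), which is the
sufficient statistic for all of its estimators. It is intended for anyone
planning or interpreting bulk or single-cell RNA-seq depth: how complete is
my gene catalogue, and how much more sequencing buys a given gain?

## Estimators

* **h6, the harmonic estimator of degree 6** — the recommended estimator:

  h6 = (6/10) · f1² / H(f2, …, f6),  H(f2, …, f6) = 5 / Σ<sub>r=2..6</sub>(1/f<sub>r</sub>)

  It exploits the fact that at RNA-seq depths (10⁵–10⁹ tags) the higher-order
  frequencies f3…f6 are almost always positive and carry information about
  `f0` that singleton/doubleton-only estimators ignore. It is the member of
  the Pythagorean-mean candidate family u·f1²/c(f2…f_r) (arithmetic,
  geometric or harmonic mean `c`, degrees 3–10) selected by bootstrap scoring
  against known truth; the whole family is available via
  `pythagorean_family()`.
* **Chao1** f1²/(2·f2), bias-corrected **Chao2** f1(f1−1)/(2(f2+1)),
  **iChao1** (adds f3, f4), and the **Medial** estimator f1(f1−1)/(f2+1) —
  the classical closed forms, for comparison.
* `estimate_se_bias_ci()` attaches a parametric-bootstrap standard error
  se = √((1/B)·Σ(f̂0ᵢ − f0ᵢ)²) and an approximate 95 % interval
  f̂0 ± 1.96·se (clamped at 0; percentile option available).
* `extra_sample_h6()` / `extra_sample_chao()` give the extra depth needed to
  observe a proportion ψ of the estimated missing genes, e.g.
  m′<sub>ψ</sub> = N·(h6/f1)·ln(h6/(Ĝ(1−ψ))), valid when
  h6/(Ĝ(1−ψ)) > 1.
* `run_selection_harness()` and `compare_extra_sample_estimators()` score any
  set of estimators against known truth on a complete reference sample
  (one with `f1 = 0`), by parametric bootstrap over a range of depths.
* `make_population()` / `draw_sample()` / `make_complete_reference()` build
  known-truth synthetic transcriptomes (log-normal, Pareto, uniform, or the
  empirical distribution of a real count table).

## Worked example

A known-truth transcriptome with G = 5000 genes and log-normal abundances,
sampled at 100,000 tags:

```r
library(genemiss)

pop <- make_population(G = 5000, model = "lognormal", sdlog = 1.5, seed = 20)
s   <- draw_sample(pop, N = 1e5, seed = 1)
s$sample
#> Count vector: g = 4,503 detected genes, N = 100,000 tags
s$true_f0
#> [1] 497

est <- estimate_se_bias_ci(s$sample, "h6", bootstrap_config(B = 500, seed = 2))
est
#> h6 estimate of undetected genes: f0_hat = 550.12 (g = 4,503, 10.9% of G_hat missing)
#>   se = 95.26, 95% CI [363.40, 736.84]
```

The sample missed 497 genes; h6 estimates 550 ± 95 and its 95 % interval
covers the truth. How much more sequencing to observe 95 % of them?

```r
sp <- spectrum_from_counts(s$sample)
extra_sample_h6(sp, est$f0_hat, psi = 0.95)
#> Extra sample (h6, psi = 0.95): 85,439 additional tags
```

Real data enter the same way, from a delimited count table (genes × library
columns of raw integer tag counts):

```r
mat <- read_count_table("counts.tsv")
cv  <- collapse_libraries(mat)       # the accession's "total library"
h6(spectrum_from_counts(cv))
```

or from the shell:

```sh
exec/genemiss estimate counts.tsv --estimator all --bootstrap 1000 --out report.tsv
exec/genemiss extrasample counts.tsv --psi 0.95
exec/genemiss simulate --G 5000 --model lognormal --sdlog 1.5 --N 2e6 --out synth.tsv
```

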