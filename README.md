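# decaypro

Genome-wide **relative RNA half-life estimation** from matched PRO-seq and
RNA-seq experiments, with a structural equation model (SEM) linking
transcript features to transcription and stability, and a U1/PAS hidden
Markov model scoring promoter-proximal sequence stability.

## The scientific problem

RNA abundance is set by two opposing rates: synthesis and decay. Metabolic
labeling assays measure decay directly but are laborious and perturbative.
`decaypro` instead exploits a steady-state argument on two routinely
collected assays:

- **PRO-seq** maps transcriptionally engaged polymerase; gene-body read
  density is proportional to the synthesis rate β.
- **RNA-seq** measures steady-state abundance M.

At steady state the decay flux balances synthesis, `β = α·M`, where α is the
per-molecule decay rate. Hence `M/β = 1/α ∝ half-life`, and with
length-and-depth-normalized measurements (TPM) the unit-less ratio

```
T½^PR = RNA-seq TPM / PRO-seq TPM
```

is proportional to the RNA half-life — comparable *across genes within an
experiment*, up to one unknown proportionality constant. TUs with no signal
on either axis are excluded (never mapped to 0 or ∞), and the default
filters keep TUs with PRO-seq > 10 TPM and RNA-seq > 1 TPM (strict
inequalities).

Downstream, the package asks *why* half-lives differ:

- a **linear-Gaussian SEM** on the natural-log scale,
  `b = Xλ + ε_b`, `t½ = Xμ + ε_t`, `m = b + t½`, observed through replicate
  log TPMs `p_j = b + ε_p`, `r_j = m + ε_r`. The λ path measures a feature's
  effect on transcription, the μ path its effect on half-life, estimated
  jointly by maximum likelihood (coefficients profiled out by GLS, the four
  variance components optimized with L-BFGS-B; SEs from the observed
  information).
- a **U1/PAS HMM** over the first kilobase past the TSS: transcripts whose
  first motif hit is a polyadenylation signal (PAS) with no upstream U1
  5′-splice site are flagged unstable; the **sequence stability index
  (SSI)** is one minus the posterior probability of that "PAS-first"
  macro-state.
- supporting modules: annotation ingest (GTF/BED12), k-mer enrichment,
  expression-matched cohort comparison (greedy nearest-neighbour matching,
  KS tests with bootstrap eCDF bands), TSS-anchored meta-profiles, and a
  fully seeded synthetic-data generator with planted ground truth.

## Worked example

Everything below is runnable as-is; numbers are the actual output.

```r
library(decaypro)

# 1. simulate a 300-TU cohort with known ground truth
sim <- simulate_tus(300, seed = 42)
ex  <- simulate_expression(sim$tus, matrix(1, 300, 1), lambda = 3, mu = 1,
                           sigmas = c(0.5, 0.4, 0, 0), depth = 2e5,
                           mode = "counts", seed = 43)

# 2. quantify both assays and estimate relative half-lives
q  <- quantify(sim$tus, ex$pro_reads, ex$rna_reads, pro_len = "body")
hl <- half_life_table(q)
ok <- hl$passed_filters
sum(ok)
#> [1] 300
cor(hl$t_half_pr[ok], ex$truth$half_life[ok], method = "spearman")
#> [1] 0.986
head(hl[ok, c("tu_id", "t_half_pr", "log2_t_half")], 3)
#>   tu_id t_half_pr log2_t_half
#>  TU0001 0.5228466 -0.93554046
#>  TU0002 0.9815551 -0.02685885
#>  TU0003 1.2117321  0.27707078
```

Fitting the SEM to replicate observations recovers the generative
coefficients λ = (2, 0.5, −0.3), μ = (1, 0, 0.4), with the null μ for `gc`
correctly non-significant:

```r
set.seed(1)
n <- 1500
X <- cbind(`(intercept)` = 1, gc = rnorm(n), len = rnorm(n))
gen <- sem_model(lambda = c(2, 0.5, -0.3), mu = c(1, 0, 0.4),
                 sigma_b = 0.5, sigma_t = 0.4, sigma_p = 0.2, sigma_r = 0.2)
d <- sem_simulate(gen, X, J_p = 2, J_r = 2)
fit <- sem_fit(sem_observations(X, d$p, d$r), standardize = FALSE)
sem_fit_table(fit)
#>      feature lambda se_lambda z_lambda p_lambda stars_lambda      mu se_mu z_mu p_mu stars_mu
#>  (intercept)   2.00     0.014      147  0.0e+00          ***  0.9937 0.011 86.6 0.00      ***
#>           gc   0.52     0.013       39  0.0e+00          *** -0.0067 0.011 -0.6 0.55
#>          len  -0.29     0.013      -22 1.5e-111          ***  0.4138 0.011 37.6 0.00      ***
```

The SSI separates motif arrangements as designed — a U1 site upstream of a
PAS shields the transcript, an unshielded PAS marks it unstable:

```r
set.seed(2)
bg  <- paste(sample(c("A","C","G","T"), 1000, TRUE), collapse = "")
pas <- paste0(substr(bg, 1, 100), "AATAAA", substr(bg, 107, 1000))
u1  <- paste0(substr(pas, 1, 40), "CAGGTAAGT", substr(pas, 50, 1000))
round(ssi(c(background = bg, pas_only = pas, u1_then_pas = u1)), 3)
#>  background    pas_only u1_then_pas
#>       0.360       0.134       0.953
```

## Command-line interface

`exec/decaypro` wraps the exported functions as subcommands
(`quantify`, `halflife`, `sem`, `features`, `kmers`, `ssi`, `match`,
`compare`, `metaprofile`, `simulate`), reading standard formats (GTF/BED12
annotations, BED6 reads, FASTA, bedGraph) and writing tab-separated tables
with a provenance header:

```sh
decaypro simulate --n 200 --seed 1 --out-dir sim/
decaypro quantify --annotations sim/tus.bed \
    --pro sim/pro_rep1.bed,sim/pro_rep2.bed \
    --rna sim/rna_rep1.bed,sim/rna_rep2.bed -o counts.tsv
decaypro halflife --counts counts.tsv -o halflife.tsv
```

## Reproduction

- Unit, property and acceptance tests:
  `Rscript -e 'testthat::test_dir("tests/testthat", package = "decaypro", load_package = "installed")'`
  (the acceptance criteria live in `tests/testthat/test-acceptance.R`,
  one `test_that()` block each).
- Acceptance summary (flat JSON of the key computed quantities):
  `Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`
- The methods vignette source is `vignettes/decaypro-methods.Rmd`.

All simulations are pure functions of their seed; the test suite and the
acceptance script run offline in a few minutes on one CPU.
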