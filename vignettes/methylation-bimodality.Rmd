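---
title: "Separating true CpG methylation bimodality from sequencing-depth artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating true CpG methylation bimodality from sequencing-depth artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylKL)
```

## The problem

Whole-genome bisulfite sequencing reports, for every covered CpG cytosine, a
methylated read count $M_i$ and a total depth $T_i$; the per-site methylation
level is the beta value $\beta_i = M_i / T_i$. Across a mammalian methylome
the distribution of $\beta$ is famously bimodal, with peaks at 0
(constitutively unmethylated) and 1 (constitutively methylated).

Part of that bimodality, however, is an arithmetic artifact. A site covered
by $T$ reads can only produce $\beta \in \{0, 1/T, \dots, 1\}$, and *every*
depth can produce 0 and 1 while only some depths can produce, say, $1/4$.
When many low-depth sites are pooled, simple counting piles excess mass onto
the endpoints even if the underlying biology were completely random.
methylKL quantifies how much endpoint mass is *genuinely* in excess of this
depth artifact.

## The model

Let $N$ sites have depths $\{T_i\}$ and counts $\{M_i\}$. The package
computes:

* the **observed distribution** $r_{obs}(\beta) = \frac{1}{N}\sum_i
  \delta(\beta - \beta_i)$, held over *exact reduced fractions* — a $1/2$
  from depth 2 and a $2/4$ from depth 4 are the same support point;
* the **depth-matched binomial null**: with $p$ the mean of the $\beta_i$,
  each site's count is replaced by a Binomial$(T_i, p)$ variable, giving the
  closed-form mixture
  $r_{ran}(\beta) = \frac{1}{N}\sum_i \sum_{n=0}^{T_i}
  \binom{T_i}{n} p^n (1-p)^{T_i - n}\, \delta(n/T_i - \beta)$,
  computed analytically (never sampled);
* deviation statistics in bits: the full Kullback–Leibler divergence
  $\mathrm{KL} = \sum_\beta r_{obs}\log_2 (r_{obs}/r_{ran})$ over the
  observed support, its single endpoint terms $\mathrm{KL}(0)$ and
  $\mathrm{KL}(1)$, and the direct differences
  $d(e) = r_{obs}(e) - r_{ran}(e)$.

$\mathrm{KL}(0)$ measures *methylation variation* — how strongly sites
conserve the fully unmethylated state beyond what depth alone explains — and
$\mathrm{KL}(1)$ the analogous *demethylation variation*. As single terms
they are signed; only the full divergence obeys the Gibbs inequality
$\mathrm{KL} \ge 0$.

```{r toy}
toy <- methyl_sites("chrT", c(3L, 4L, 7L), c("+", "-", "+"),
                    c(2L, 0L, 2L), c(2L, 2L, 4L))
summarize_divergence(toy)
```

The null mass at the endpoints, $r_{ran}(0) = r_{ran}(1) = 0.1875$, already
explains a substantial part of the observed $1/3$; the residual excess is
what $\mathrm{KL}(0) \approx 0.2767$ bits reports.

## Flanking-sequence context

The two strands of a CpG are biologically distinct substrates: each carries
its own cytosine with its own 5' neighbor. methylKL therefore never pools
strands. Every strand-cytosine is annotated with its tetranucleotide
N5-C-G-N3 read 5'→3' on its own strand (16 classes), or the trinucleotide
N5-C-G (4 classes); the minus-strand context is the reverse complement of
the shared 4-base reference window. In context-stratified runs, $p$ is
estimated **within each context class** — it is the average methylation
level of that tetranucleotide — while whole-sample runs estimate one global
$p$; report metadata records which scope was used.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 1 | minimum depth at read time; 1 means "covered at all", no cutoff — low-depth sites are exactly what the null corrects for |
| `p_mode` | `per_site` | $p$ as the arithmetic mean of $\beta_i$; `pooled` ($\sum M/\sum T$) is a depth-weighted diagnostic only |
| `mode` | `tetra` | 16 tetranucleotide classes; `tri` merges over the 3' base |
| `depths` | none | optional per-depth strata (e.g. 4, 6, 8): endpoint KL grows with depth because the null endpoint mass $(1-p)^T$ shrinks faster than genuine endpoint biology |
| `lambda` | 9 | simulator depth model $T = 1 + \mathrm{Poisson}(\lambda)$, i.e. mean 10× coverage |

## What the synthetic generator emulates — and what it does not

`simulate_reference()` builds a CpG-free random background and plants
Binomial$(L, \rho)$ CpG dinucleotides at even offsets with uniform flanks,
so the CpG count is exact, planted CpGs never overlap or touch a boundary,
and all 16 contexts occur at comparable frequency. `simulate_methylome()`
then draws, per strand-cytosine in coordinate order: a true level $\beta^*$
from the context's two-component Beta mixture, a depth, and
$M \sim \mathrm{Binomial}(T, \beta^*)$. Draws are vectorized per variable
(all $\beta^*$, then all $T$, then all $M$) and fully determined by one
seed.

The default truth mixtures encode the conserved/variable contrast as a pure
concentration difference: contexts with G or C before the CpG use
$w = 0.5$, $\mathrm{Beta}(0.3, 6)$ and $\mathrm{Beta}(6, 0.3)$
(endpoint-concentrated), contexts with A or T use $\mathrm{Beta}(1, 3)$ and
$\mathrm{Beta}(3, 1)$ (flatter). Both classes have true mean exactly 0.5, so
any KL ordering recovered by the pipeline reflects variability, not level.

The generator does **not** emulate bisulfite conversion failure, mapping
bias, SNP-induced miscalls, CpG islands or other spatial clustering, or
read-level correlation. A green simulation test therefore establishes that
the statistics behave correctly *given* binomial sampling over a reference
with known contexts — not that any particular biological sample will show a
particular ordering.

## Numerical choices and degenerate inputs

* Support points are exact reduced integer fractions; equal values merge
  across depths. No floating-point binning exists in the core.
* $0 \log 0 = 0$: absent observed mass contributes nothing; an endpoint with
  $r_{obs}(e) = 0$ yields $\mathrm{KL}(e) = 0$ rather than an error.
* $0^0 = 1$ in the binomial pmf, so $p \in \{0, 1\}$ gives point-mass nulls.
* A site set whose mean methylation is exactly 0 or 1 has no usable null:
  `summarize_divergence()` raises an error naming the context. Stratified
  drivers convert that into a warning and omit the group (a whole-sample
  degenerate $p$ still aborts a CLI run), because small context classes of
  uniformly (un)methylated sites are routine in real data and should not
  kill a 16-class report.
* The full KL is summed over the observed support; null support points never
  observed contribute nothing.
* Zero-mass support points are dropped, so "support" always means "values
  with positive probability".
* Monte-Carlo sampling of the null exists purely as a validation oracle; the
  analytic mixture is always the primary path. The package's Monte-Carlo
  agreement checks use 3–3.5 standard errors *per support point* and are
  therefore run on small-depth profiles (few support points, all with large
  expected counts), keeping the family-wise chance-failure probability
  negligible; with many support points such an "everywhere within 3 SE"
  assertion would fail for any correct sampler.

## Known limitations

* No beta-binomial/overdispersed null, no smoothing, no significance tests:
  the statistics are descriptive point values.
* Readers assume well-formed single-genome coordinates; no BAM/CRAM input or
  methylation calling.
* Context is always taken from the reference, never from per-read sequence,
  so reference/sample SNPs at flanking bases are invisible.
* Promoter or PMD analyses are whatever BED file the user supplies; the
  package makes no claim about how such regions should be defined.
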