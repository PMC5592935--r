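---
title: "Finding conditions for optimal genomic prediction by steepest ascent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding conditions for optimal genomic prediction by steepest ascent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpascent)
```

## The problem

Genomic prediction (GP) trains a model on genotyped and phenotyped lines
and predicts phenotypes of lines with genotypes only. How accurate a GP
method is depends on the training population size, marker density, the
number of QTL, the genetic architecture (in particular the share of
genetic variance due to epistasis) and heritability. A full factorial
sweep over these factors explodes combinatorially; `gpascent` instead
treats mean prediction accuracy as a *response surface* over the design
factors and uses the steepest-ascent response-surface method (RSM) to
locate the factor combination that maximizes a chosen response — for
example the accuracy advantage of a kernel method over an additive
linear model, which is of interest as a computational diagnostic for
epistatic architectures — while evaluating a small fraction of the grid.

The package simulates everything it analyses, so the "experiments" are
cheap, reproducible, and fully controlled.

## The simulator

**Genomes and genotypes.** A doubled-haploid (DH) population is fully
homozygous, so each marker is coded $-1/+1$ (Cockerham scaling). The
genome has 10 chromosomes of equal genetic length (default 1 Morgan)
with markers equally spaced within chromosomes; when the marker count is
not a multiple of the chromosome count the remainder is spread over the
first chromosomes (a strict mode rejects such configurations instead).
Each line is one recombinant gamete, doubled — distributionally
identical to simulating an F1 meiosis and doubling, but cheaper. Codes
along a chromosome form a two-state Markov chain: the first marker is
$\pm 1$ with probability $\tfrac12$ and adjacent markers recombine with
the Haldane frequency $r(d) = (1 - e^{-2d})/2$ at the inter-marker
distance $d$. The map function and chromosome length are not dictated by
the study design, so we chose Haldane on a 1-Morgan chromosome: it is
the standard choice and has a closed form that the test suite uses as an
independent oracle for the simulated recombination frequencies.

**Traits.** Phenotypes follow

$$\mathbf{y} = \mu + X_a\,a + X_e\,\mathit{epi} + \boldsymbol\epsilon,$$

where $X_a$ holds the codes at the $q$ QTL (placed at marker loci,
evenly spaced by default), and $X_e$ holds additive-by-additive products
of *paired neighboring QTL*. We pair QTL disjointly — $(1,2), (3,4),
\dots$, giving $\lfloor q/2 \rfloor$ product columns — because a DH
population admits only A$\times$A two-locus terms and disjoint pairing
keeps the covariance between the additive and epistatic sums small. A
sliding "chain" pairing ($q-1$ overlapping pairs) is available via
`pairing = "chain"`; in our experiments it changes prediction
accuracies very little.

All QTL share one additive scalar $a$ and all pairs one epistatic
scalar $\mathit{epi}$. Writing $V_a$, $V_{epi}$ and
$\mathrm{Cov}$ for the empirical (co)variances of the additive and
epistatic row sums, the genetic variance is

$$V_G = a^2 V_a + \mathit{epi}^2 V_{epi} + 2\,a\,\mathit{epi}\,\mathrm{Cov}.$$

Given a target epistatic share $t$ the scalars are solved as
$a = \sqrt{(1-t)/V_a}$, $\mathit{epi} = \sqrt{t/V_{epi}}$, which
normalizes $a^2V_a + \mathit{epi}^2V_{epi} = 1$ with the epistatic part
exactly $t$. The share definition deliberately excludes the covariance
cross-term (which the disjoint pairing keeps near zero); the error
variance uses the full $V_G$ including the cross-term:
$V_e = V_G\,(1-h)/h$, so broad-sense heritability equals $h$ by
construction and $h = 1$ gives noiseless phenotypes. $\mu$ defaults to 0
since Pearson accuracy is translation-invariant, and
$\boldsymbol\epsilon$ is normal, the conventional reading of a mean-zero
error term.

## Prediction methods and accuracy

**Ridge-regression BLUP** solves $\mathbf{y} = \mathbf{1}\mu + Z
\mathbf{u} + \mathbf{e}$ with i.i.d. random marker effects; the
shrinkage $\lambda = \hat\sigma_e^2/\hat\sigma_u^2$ is estimated by REML
through a spectral decomposition of the centered marker cross-product
(the smaller of $Z_c'Z_c$ and $Z_cZ_c'$ is decomposed, so cost scales
with $\min(n, m)$). $\lambda$ is floored at $10^{-8}$ so that a
vanishing error variance (e.g. $h = 1$ additive traits) remains
solvable. A fixed-$\lambda$ mode exists and is verified in the tests
against a direct matrix-inversion ridge solution.

**Support-vector regression** is $\epsilon$-insensitive SVR with a
radial-basis kernel (via `e1071`), defaults cost $= 1$,
$\gamma = 1/m$, $\epsilon = 0.1$ — the defaults of the common R
implementation. Inputs are not rescaled: codes are already on a common
$\pm1$ scale, and the variance normalization above puts phenotypes on a
unit genetic-variance scale so the $\epsilon$ tube has a stable meaning.

**Accuracy** is the Pearson correlation between held-out phenotypes
(not genetic values) and predictions. Replication follows the two-level
scheme: independent genotype/phenotype data sets, and within each data
set independent random 80/20 train/test splits (not rotation folds);
the package default is $20 \times 25 = 500$ replicates per design
point. BLUP and SVR always consume identical splits, so the
SVM$-$BLUP difference is computed replicate-wise on shared data. A
degenerate replicate (zero-variance predictions, e.g. BLUP on a purely
epistatic noiseless trait) is recorded as accuracy 0 and flagged, which
keeps averages total.

## Designs, first-order fits, steepest ascent

Factors are coded so the low design level is $-1$ and the high level
$+1$; the base is $(\text{low}+\text{high})/2$ and the half-range
$(\text{high}-\text{low})/2$. Two-level full factorials ($2^p$ runs,
lexicographic order) and regular half fractions defined by a generator
word (e.g. $I = -ABCDE$ keeps the 16 runs whose five-column product is
$-1$) are supported, with the alias structure derived by word
multiplication with squares cancelled ($C \cdot ABC = AB$). The default
five-factor starting region is progeny 200/1000, markers 100/400, QTL
10/100, epistatic share 0.2/0.5, heritability 0.2/0.5, with operability
regions (the attainable ranges) of positive integers for counts and
$[0,1]$ for the two fractions.

A first-order model $\hat y = b_0 + \sum_i b_i x_i$ is fit by OLS on
the coded runs; on orthogonal designs each slope equals half the
difference of high/low response means, and the tests require the two
computations to agree to $10^{-12}$. `first_order_fit()` also accepts a
plain coefficient vector, so previously reported fits can drive the
ascent stage directly.

The ascent turns the fit into a path:

* **basis**: the factor with the largest $|b_i|$ (overridable);
* **coded steps**: the basis moves by a researcher-chosen natural step
  (default 0.25, natural for fraction-type factors) divided by its
  half-range, *carrying the sign of its coefficient* — maximizing a
  response with a negative epistasis slope steps epistasis downward;
  every other factor moves by $(b_i/b_{basis})$ times the basis coded
  step;
* **increments**: $\Delta_i = \text{half-range}_i \times
  \text{coded step}_i$;
* **coordinates**: $\text{base} + k\Delta$, accumulated from the base
  (not from previously rounded coordinates), with counts rounded to
  whole numbers, fractions to two decimals, and every value clamped to
  its operability region — the epistatic share and heritability pin at
  1 once the path crosses the boundary.

### Rounding conventions

Published path tables round increments inconsistently if read as a
fixed decimal rule (91.2 is shown as 91 but $-4.35$ as $-4.4$). The
package's `compat = TRUE` mode rounds each increment to **two
significant figures but never finer than whole units**, rounding half
away from zero; this single rule reproduces every increment and every
coordinate of the reference path tables, and the arithmetic tests pin
it down exactly. The default (`compat = FALSE`) keeps full precision,
which is what a new analysis should use; the coded steps themselves can
be rounded to a chosen number of decimals via `digits` to mirror
printed tables.

`run_ascent()` iterates design $\to$ fit $\to$ path $\to$ re-center:
the region (half-ranges preserved) is relocated onto the best path
point, clamped to operability, and the loop stops when the best
response stops improving by more than a configurable margin, when all
slopes vanish, or at an iteration cap. The stopping rule is our
design choice — the procedure's narrative description ("repeat until
the optimum is reached") leaves it open. The audit trail records every
design, fit and path so a run can be replayed.

## The full surface and the yield demonstration

`enumerate_grid()` builds the full $3 \times 3 \times 3 \times 5
\times 3 = 405$-combination factor grid and `evaluate_grid()` attaches
replicated accuracies; `summarize_surface()` reports the maximum, the
argmax, threshold-exceedance fractions (the histogram bin width
defaults to 0.05) for user-chosen thresholds. A deterministic
two-factor demonstration surface,

$$\text{yield} = 110 + \cos^2(0.25\,d) + \sin^2(0.15\,T) +
0.0024375\,d\,T,$$

(arguments in radians — the only reading under which the yield maximum
falls at a temperature between 73 and 74 °F) is included for
illustrating RSM without simulation noise; its grid argmax at 0.01
resolution is $T = 73.39$, $d = 1.59$, and an L-BFGS-B optimizer agrees
to two decimals.

## Numerical and replication choices

* Stochastic acceptance checks run at 100 replicates per design point
  (20 data sets $\times$ 5 splits), the package's chosen problem size
  for verification; the full default remains $20 \times 25$.
* Seeds are hierarchical: a master seed spawns labelled substreams
  (genotypes / QTL / phenotypes / splits, per data set), so changing
  predictor settings never perturbs the simulation streams, and any
  single replicate can be replayed from the logged seed.
* REML optimizes the profile likelihood over $\log\lambda \in
  [\log 10^{-8}, \log 10^{10}]$ with Brent search.
* Degenerate inputs are first-class: constant training phenotypes fall
  back to mean prediction with a warning (BLUP) or a flagged constant
  prediction (SVR); zero-variance predictions score accuracy 0 with a
  degeneracy flag; a singular first-order design names its collinear
  columns.

## What the simulator does and does not emulate

The generator reproduces the study conditions: equal-length
chromosomes, equally spaced markers, no missing data, QTL at marker
loci, scalar effects shared across QTL, and exact broad-sense
heritability by construction. It does **not** emulate allele-frequency
spectra of real breeding populations, linkage phases from pedigree
structure, dominance, higher-order epistasis, genotype-by-environment
interaction, or missing genotypes. Passing tests therefore certify the
method's behavior under this idealized architecture, not performance
on real data.

## Known limitations and divergences

* With the stated SVR defaults, the kernel method learns
  intermediate-complexity epistatic traits (tens of interacting pairs,
  thousands of training lines) well; consequently the maximal
  SVM$-$BLUP difference over the surface, and accuracies at mid-path
  coordinates, can exceed historically reported values whose SVM
  configuration is not fully documented. The endpoints — additive
  accuracies, BLUP's collapse to zero under pure epistasis, and the
  near-perfect SVR accuracy at the final path coordinate — reproduce.
* A purely additive, well-specified trait at large $n$ pushes BLUP
  accuracy toward its theoretical ceiling $\sqrt{h}$
  ($\approx 0.894$ at $h = 0.8$), which is worth keeping in mind when
  comparing against reported surface maxima.
* Second-order models, central-composite designs and ridge analysis
  (the usual follow-on once ascent reaches the optimum's neighborhood)
  are out of scope; `fit_first_order()` is deliberately first-order
  only.
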