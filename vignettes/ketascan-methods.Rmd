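---
title: "ketascan: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ketascan: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ketascan` analyses genetic stock-identification (GSI) baseline data for
chum salmon and similar high gene-flow species: it estimates neutral
population structure from microsatellite allele frequencies and then asks
which SNP loci deviate from that structure — the signature of natural or
hatchery-induced selection, confounded in GSI panels by the SNP discovery
process. This vignette documents the statistical machinery, the synthetic
data generator that stands in for the real baselines, and the design
decisions a maintainer would want to know about.

## The estimator: bias-corrected Nei–Chesser G_ST

Pairwise F_ST between populations is estimated with the Nei & Chesser
(1983) moment estimator, which corrects the naive heterozygosity-based
G_ST for finite sample size. For two populations with allele-frequency
vectors $p_1, p_2$ and sample sizes $n_1, n_2$ diploid individuals, with
$\tilde n = 2/(1/n_1 + 1/n_2)$ the harmonic mean,
$h_S = 1 - \tfrac12\sum_k (p_{1k}^2 + p_{2k}^2)$ and
$h_T = 1 - \sum_k \bar p_k^2$:

$$\hat H_S = \frac{\tilde n}{\tilde n - 1}\Bigl(h_S - \frac{\hat H_O}{2\tilde n}\Bigr),
\qquad
\hat H_T = h_T + \frac{\hat H_S}{2\tilde n} - \frac{\hat H_O}{4\tilde n},
\qquad
G_{ST} = \frac{\hat H_T - \hat H_S}{\hat H_T}.$$

Three conventions matter:

* **Observed heterozygosity.** Frequency-only data carry no $\hat H_O$, so
  by default it is replaced by its Hardy–Weinberg expectation $h_S$
  (`ho_mode = "hwe"`). Datasets built from genotypes via
  `genotypes_to_frequencies()` carry the true observed heterozygosity and
  can use `ho_mode = "observed"`.
* **Multilocus combination.** Loci are combined as a ratio of sums,
  $\sum_l(\hat H_{T,l} - \hat H_{S,l})/\sum_l \hat H_{T,l}$, the standard
  multilocus practice; the unstable mean of per-locus ratios is exposed as
  `combine = "mean_of_ratios"` for sensitivity checks only.
* **Negative estimates** (sampling noise around zero differentiation after
  bias correction) are reported as-is. They are clamped to zero only where
  an algorithm requires dissimilarities — MDS, NJ, and the connectivity
  threshold — and each clamp is counted and warned about. Truncating at
  the estimation stage would bias the MDS geometry.

Pairs sharing no usable locus, or with $\sum\hat H_T = 0$, are flagged
undefined, never silently zero. Loci and pairs with missing frequency
vectors are handled pairwise-complete (the provenance of absent
combinations in public frequency tables is rarely documented, so the
package makes the convention explicit).

For haploid (mtDNA-like) loci the sample-size unit is the haplotype: with
harmonic-mean gene copies $g$, $\hat H_S = g/(g-1)\,h_S$ and
$\hat H_T = h_T + \hat H_S/g$.

## Structure inference

Classical MDS (principal coordinates) is applied to the F_ST matrix used
directly as a distance matrix — no square-root or linearizing transform —
because that is the convention in the GSI literature this package
follows. Axis $k$ is the $k$-th eigenvector of the double-centred squared
distance matrix scaled by $\sqrt{\lambda_k}$; axes with numerically
non-positive eigenvalues get all-zero coordinates. Explained variation is
the cumulative contribution ratio with negative eigenvalues zeroed:

$$C_k = \sum_{j \le k} \max(\lambda_j, 0) \Big/ \sum_j \max(\lambda_j, 0).$$

Eigenvector signs are arbitrary, so each axis is oriented with its
largest-magnitude population positive; downstream regressions and tests
then see reproducible axes. The number of retained axes `k` defaults to 2
(the two axes the selection scan regresses on); more can be retained for
exploration.

Neighbor joining uses the Saitou–Nei agglomeration (via `ape::nj`), which
is exact on additive matrices; small negative branch lengths, routine on
noisy F_ST matrices, are clamped to zero with a warning. TreeMix graph
fitting is external, established software; the package only provides the
AIC bookkeeping, $\mathrm{AIC} = -2\log\hat L + 2s$ with $s = 3$ per
migration event (edge, branch length, weight), for comparing externally
fitted models.

## Diversity, spectra, connectivity

Expected heterozygosity is $H_e = 1 - \sum_k p_k^2$ per population ×
locus, averaged over usable loci. Allele-frequency spectra are computed
per region from region-mean frequencies per locus — the only well-defined
pooling when only frequencies are available — folded by default because
SNP reference alleles are arbitrary. Binning follows the histogram
convention (right-closed bins, first bin closed at zero).

The connectivity graph links pairs with multilocus $F_{ST}$ strictly below
a threshold (default 0.01). Under Wright's island model
$F_{ST} \approx 1/(4N_em + 1)$, so each edge is annotated with
$4N_em = 1/F_{ST} - 1$; the default threshold corresponds to ~99 migrants
per generation. Map colouring uses the min–max standardized value mapped
to RGB $(v_0, 0, 1 - v_0)$, i.e. blue for the lowest and red for the
highest value of $H_e$ or allele frequency — the verbal orientation
("blue to red for lowest and highest") is taken as authoritative and
applied uniformly to both quantities.

## The selection scan

SNP sampling sites are matched to microsatellite sites by case-insensitive
exact name first, then by nearest haversine great-circle distance
(radius 6371 km), ties broken by the lexicographically smallest candidate
id. Each locus $i$ is then fit by ordinary least squares:

$$p_{ji} = \beta_{0i} + \beta_{1i}\,\mathrm{mds1}_j +
  \beta_{2i}\,\mathrm{mds2}_j + \varepsilon_{ji},
  \qquad \varepsilon \sim N(0, \sigma^2),$$

on the raw (signed) MDS coordinates of the matched populations. The
linear model on raw frequencies is deliberate — it is the form used in
the GSI selection-scan literature — and its bounded-response violations
are accepted as such; the synthetic generator (below) plants effects on
the logit scale precisely so that recovery tests exercise the mismatch a
real analysis would face. An `covariates = "absolute"` switch fits
$|\mathrm{mds}|$ covariates instead, since published coefficient tables
are sometimes labelled that way; reported tables always show
$|\hat\beta|$ regardless.

Per-coefficient p-values ($t$-tests on $J - 3$ df) are Benjamini–Hochberg
adjusted across loci **within each coefficient family** (all $\beta_1$
p-values together, all $\beta_2$ together), matching the separate q-value
columns such analyses report; a pooled family is available as
`bh_family = "pooled"`. Loci are ranked by $|\beta_2|$ — the focal-region
axis — and the outlier set is the top `top_k` ranked loci with
$q(\beta_2)$ below the cut (default 0.05). Multi-allelic loci enter
through one focal allele, by default the second-most-frequent allele
overall (for the simulated mtDNA-like locus the pipeline designates its
major allele, which the catalogue lists second). Duplicate covariate rows
(several SNP sites matched to one microsatellite site) are kept as-is.

PCA of the population × locus focal-allele frequency matrix
(column-centred, unscaled — frequencies share a scale) serves as the
model-free confirmation of the scan.

## The synthetic study design

The generator emulates the statistical structure of the real baselines so
that every downstream stage can be tested without network access.

* `simulate_structure()` places $J$ populations along a one-dimensional
  coastline mapped to plausible North Pacific coordinates, partitioned
  into seven contiguous regions; the first ("Japan/Korea") is the focal
  region, by default 10% of populations. Two standardized latent axes are
  planted: `a1`, the coastline cline, and `a2`, the focal-divergence
  contrast. Because the focal block sits at one end of the coastline, the
  raw focal indicator is correlated with the cline ($\rho \approx -0.5$),
  which would make the two planted axes unidentifiable by any orthogonal
  axis pair (no rotation can correlate above $\sqrt{1-\rho^2}$ with
  both); `a2` is therefore orthogonalized against `a1` before
  standardization. Outside the focal region `a2` is consequently small
  rather than exactly zero.
* `simulate_msat_frequencies()` uses a Balding–Nichols-style hierarchy:
  symmetric-Dirichlet ancestral frequencies (concentration solved from
  the target heterozygosity via $E[H_e] = 1 - (a+1)/(Aa+1)$), a log-scale
  tilt of each population's mean frequencies along `a1`/`a2`, Dirichlet
  drift with concentration $(1-F)/F$, and multinomial sampling of
  $2n$ gene copies. The tilt scales and $F$ are tied to `target_fst`
  ($s \propto \sqrt{t}$, $F \propto t$), so the no-differentiation limit
  is exact and realized differentiation is monotone in the target. The
  proportionality constants were calibrated once against the package's
  own NC83 estimator at the default configuration
  ($J = 60$, 10 loci, 15 alleles, $n = 50$): cline tilt $3.5\sqrt t$,
  focal tilt $2.4\sqrt t$, drift $0.5t$, splitting the target roughly
  evenly between structure and drift; a fourth constant compensates the
  heterozygosity lost to the tilt. At the defaults this yields mean
  pairwise G_ST ≈ 0.014–0.019 and mean $H_e \approx 0.89$. The
  compensation saturates near the $1 - 1/A$ equifrequency ceiling, so
  very high $H_e$ targets combined with small samples or strong
  differentiation raise an informative infeasibility error.
* `simulate_snp_dataset()` inverts the scan's regression model as a
  generator: $\mathrm{logit}(p_{ji}) = \mathrm{logit}(p_{0i}) + b_{1i}a_{1j}
  + b_{2i}a_{2j}$, neutral effects $N(0, 0.3^2)$, outlier
  $|b_2| \sim U(\text{effect\_scale}, 2\,\text{effect\_scale})$ with
  default scale 3 (no quantitative effect sizes are published for the
  real outliers; 3 logit units makes outliers separable from the neutral
  tail by construction while leaving detection non-trivial under
  sampling noise). Ancestral frequencies are Beta(0.6, 0.6), giving the
  moderate panel-level SNP heterozygosity (~0.27) characteristic of GSI
  SNP baselines. Genotypes are Binomial(2, p) per individual
  (Hardy–Weinberg). The `focal-discovery` ascertainment mode redraws any
  locus whose discovery-region minor-allele frequency falls below 0.05,
  reproducing the mechanism by which a regionally focused SNP panel
  inflates diversity in its discovery region and depletes its rare-allele
  spectrum.
* `simulate_mtdna_locus()` plants a haploid multi-allelic locus whose
  major allele is nearly fixed (0.98) outside the focal region and drops
  to ~0.21 (jitter sd 0.11) inside it.

What the generator does **not** emulate: linkage disequilibrium between
loci, coalescent genealogies, temporal sampling, null alleles and
genotyping error, and within-region isolation-by-distance beyond the
smooth cline. Passing recovery tests therefore demonstrate that the
estimators and the scan do what they claim under the planted model — not
that real baselines satisfy that model.

## Numerical conventions and degenerate inputs

* Frequency vectors must sum to 1 within $10^{-6}$ on input (renormalized;
  larger deviations are errors naming the population × locus) and within
  $10^{-9}$ internally; renormalization is skipped when the sum is within
  $10^{-12}$ so that file round-trips are byte-stable at 15 significant
  digits.
* An all-zero genepop genotype is missing; a half-called genotype is
  conservatively treated as fully missing.
* Longitudes are normalized to $(-180, 180]$ so antimeridian-spanning
  distances (Russia vs Alaska) are correct; latitude bounds are enforced.
* A locus fixed for the same allele in both populations contributes
  nothing to either G_ST sum; a constant-frequency locus in the scan gets
  zero slopes and p-values of 1; loci missing in more than half the
  matched populations are excluded with a warning.
* MDS eigenvalues within $10^{-12}$ (relative) of zero are treated as
  zero; NJ tie-breaks follow `ape::nj`'s deterministic scan order.
* All simulation draws flow from one seeded generator per function;
  `run_pipeline()` derives per-stage sub-seeds deterministically from the
  base seed, so stage outputs are reproducible independently.

## Problem sizes

The default configuration — 60 populations, 10 microsatellite loci,
55 SNPs, one mtDNA-like locus, 50 individuals per population — was chosen
as the desk scale at which every stage (1,770 population pairs, 56
regressions) completes in seconds while leaving Monte-Carlo recovery
checks (20 replicate designs) comfortable. The published baselines this
emulates are an order of magnitude larger (hundreds of sites, tens of
thousands of fish); nothing in the implementation is specific to the desk
scale, and the pipeline accepts real frequency tables and genepop files
of that size through `config$inputs`.

## Command-line surface

The package's functions are the primary interface; `inst/cli/ketascan.R`
is a thin wrapper running `run_pipeline()` from a shell
(`--config`, `--out`, `--seed`). Individual stages are scriptable through
the exported functions and the documented file formats (genepop,
long-format frequency CSV, location TSV, square F_ST CSV, newick), so
external tools can be interposed between stages.
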