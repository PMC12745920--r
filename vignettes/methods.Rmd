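---
title: "Inferring pre-LGM divergence from joint site frequency spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring pre-LGM divergence from joint site frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refugia)
```

## The question and the model

Temperate forest understorey plants survived Pleistocene glacials in
refugia. If today's geo-genetic groups descend from *separate* refugia,
their divergence must predate the Last Glacial Maximum (~21 ka); if a group
was founded post-glacially from another, divergence is young and carries a
founder signature. `refugia` frames this as competitive model fitting of
two-population diffusion models to the joint site frequency spectrum
(JSFS) of unlinked biallelic SNPs.

Throughout, sizes are relative to the ancestral reference size $N_{ref}$,
times $\tau$ are in units of $2N_{ref}$ generations, and migration rates
are $M_{ij} = 2N_{ref} m_{ij}$ (the rate at which population $i$ receives
migrants from population $j$). The allele-frequency density
$\phi(x, y, \tau)$ obeys

$$\partial_\tau \phi =
  \tfrac12 \partial_x^2\!\left[\tfrac{x(1-x)}{\nu_1}\phi\right] +
  \tfrac12 \partial_y^2\!\left[\tfrac{y(1-y)}{\nu_2}\phi\right]
  - \partial_x\!\left[M_{12}(y-x)\,\phi\right]
  - \partial_y\!\left[M_{21}(x-y)\,\phi\right],$$

with mutation influx $\theta/2$ at the lowest non-zero frequency of either
population ($\theta = 4N_{ref}\mu L$; the engine works per unit $\theta$,
the likelihood recovers the scale analytically). Expected spectrum entries
are binomial-sampling integrals of $\phi$:
$E[S_{ij}] = \theta\iint \binom{n_1}{i}x^i(1-x)^{n_1-i}
\binom{n_2}{j}y^j(1-y)^{n_2-j}\,\phi\,dx\,dy.$

### The nine divergence scenarios

Three **vicariance** models split the ancestor into constant fractions $s$
and $1-s$: `vic_no_mig`, `vic_anc_sym_mig` (symmetric migration $M$ during
the first epoch $T_1$, isolation for $T_2$), and
`vic_sec_contact_sym_mig` (isolation first, migration during $T_2$). Six
**founder-event** models keep the source at $1-s$ while the founded deme
grows exponentially from $s$ to $\nu_2$ over the *total* divergence time
($\nu_2(\tau) = s\,(\nu_2/s)^{\tau/T_{tot}}$, continuous across epochs):
`founder_nomig`, `founder_sym`, `founder_asym`, `founder_anc_sym_mig`,
`founder_sec_contact_sym`, `founder_sec_contact_asym`. Free-parameter
counts are 2, 4, 4, 3, 4, 5, 5, 5, 6; founder models are fitted in both
orientations because the source and founded roles are a hypothesis.

## Numerical engine

The density is integrated on a frequency grid that is uniform in a warped
coordinate, $x(u) = u - a\sin(2\pi u)/2\pi$ with $a = 0.9$, crowding nodes
near $x \in \{0, 1\}$ where $\phi \sim \theta/x$ is steep. Each time step
applies operator splitting: an implicit (tridiagonal) finite-volume sweep
along each axis, with that axis's migration advection included implicitly.
The implicit systems' LU factors are reused across steps within
constant-size epochs. The default step is $10^{-3}$ (in $2N_{ref}$
generations) and spectra are computed on grids of 40, 50 and 60 nodes and
quadratically extrapolated to zero spacing entry by entry; negative
extrapolation residues are clipped at 0.

Degenerate boundaries need care. The scheme is flux-conservative with
zero boundary flux, so density lost or fixed in one population pools at
the boundary nodes; this pooled mass is real signal for the
"absent/fixed in one population" spectrum entries. Two interface rules
keep its exchange with the interior honest:

* advection pointing **off** a boundary (migration re-importing an allele
  that one population lost): the local steady profile is the integrable
  power law $x^{\kappa-1}$, $\kappa = 2\nu a$ with $a$ the advection speed
  at the boundary; the advective weighting of the boundary interface is
  chosen so the discrete zero-flux state reproduces the cell-averaged mass
  of that profile (a Chang--Cooper-style exactness condition);
* advection pointing **toward** a boundary (immigrant dilution of a
  private allele): the interface is upwinded on the interior node, because
  the pooled delta sits at the boundary node itself where the advection
  speed vanishes; coupling it centrally over-absorbs young alleles.

The second rule matters: without it the singleton and private-allele
entries under migration are biased low by 10--20%.

### Validation against an independent oracle

`simulate_coalescent_jsfs()` is a structured-coalescent simulator (written
independently of the engine; exponential size trajectories handled by exact
inversion of the integrated coalescence intensity) whose mean
branch-length spectrum estimates the same quantity. The acceptance suite
checks, for all nine models at three parameter sets each, that the engine
agrees entrywise within 3 Monte-Carlo standard errors of a $10^5$-genealogy
oracle run, and that closed forms hold: the isolated equilibrium population
($E[S_i] = \theta\nu/i$, within 1% at $n = 10$) and the $\tau = 0$ limit
($E[S_{ij}] = \theta\binom{n_1}{i}\binom{n_2}{j}/\binom{n_1+n_2}{i+j}(i+j)$).

## Likelihood, search, and model selection

For unlinked sites the entries are independent Poisson counts, giving the
composite log-likelihood with analytic scale
$\hat\theta = \sum D / \sum M$ -- the Poisson formulation of the
multinomial likelihood. The search perturbs the incumbent best parameters
multiplicatively by $2^{U(-f, +f)}$ and refines with Nelder--Mead in log
space, over staged rounds; the full-scale default schedule is folds
(3,2,2,1), reps (60,70,70,80), maxiters (10,10,10,15). Box bounds default
to $s \in [0.01, 0.99]$, sizes $[10^{-3}, 100]$, $M \in [10^{-4}, 20]$
(the positive floor keeps log-space search defined; $M$ at the floor is
operationally "no migration"), $T \in [10^{-3}, 15]$. Ranking uses
$AIC = 2k - 2\ell$ and Akaike weights
$\omega_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$.

## Goodness of fit, times, and the pre-LGM test

`goodness_of_fit()` draws 100 Poisson datasets from
$\hat\theta\,M$ and records their log-likelihoods and Pearson
$\chi^2 = \sum (D-E)^2/E$ (log10 copies stored, convenient for display);
the empirical statistics are flagged against the central 95% of the
simulated distributions. By default simulated datasets are *evaluated* at
the fitted parameters -- the cheap variant, and the exchangeable one, so
its coverage is exactly calibrated. `refit = TRUE` re-optimises each
simulated dataset from the fitted parameters with a reduced schedule; this
is what yields percentile CIs for $s$ and the $T$s and a distribution of
divergence times. Both modes are provided because bootstrap-CI protocols
in this literature imply re-estimation while the coverage check does not
need it.

One behaviour of real pipelines is worth knowing: hypergeometric
projection of partially genotyped sites *averages* fractional
contributions into each entry, so an observed projected spectrum is
smoother than a Poisson draw from its own expectation. Against a Poisson
bootstrap its log-likelihood can then sit *above* the simulated
distribution -- an "outside (too good)" flag that signals the sub-Poisson
noise of projection, not a poor fit. The chi-squared statistic makes this
visible (empirical value well below the cell count).

Times convert to years via $N_{ref} = \hat\theta/(4\mu L)$ and
$\mathrm{years} = T \cdot 2N_{ref} \cdot g$, with defaults
$\mu = 7\times10^{-9}$ substitutions/site/generation (the Arabidopsis
estimate commonly borrowed for herbaceous taxa) and $g = 10$ y (weakly
clonal) or $20$ y (strongly clonal). $L$, the surveyed sequence length
behind the retained SNPs, is deliberately a required input: it multiplies
every absolute time and a SNP matrix does not determine it.

The pre-LGM test applies the one-sided Wilcoxon signed-rank test
(`stats::wilcox.test`, exact for $n \le 25$ without ties) to the simulated
times against a null location of 20 ka, reporting $p$, the Hodges--Lehmann
pseudomedian (median of Walsh averages), the signed-rank CI, and the
fraction of simulations younger than the null.

## Synthetic data: what it emulates, and what not

`simulate_genotype_dataset()` draws unlinked variant sites from the
scenario's expected JSFS (conditioned on being variant in the full
sample), scatters derived alleles over haplotypes, and dresses genotypes
with read depth $\mathcal{N}(25, 6^2)$ rounded and floored, quality
$GQ = \min(99, 4\,DP + \varepsilon)$ (a fixture convention, configurable
via `gq_model`), missingness at a configurable rate, and multi-SNP loci on
demand. The simulator records the true ancestral allele as REF; folding
downstream is what discards it. It does **not** emulate linkage within
loci, allele-dropout correlated with genotype, selection, reference bias,
or >2 demes -- so passing tests demonstrate correctness of the inference
machinery under the model's own assumptions, not robustness to those
real-data violations.

Generator defaults used by the acceptance script are the package's chosen
study conditions: founder_nomig with $s = 0.2$, $\nu_2 = 1$, $T = 0.3$,
20+20 haploid samples, 6000 variant sites, 10% missingness, coverage
$25 \pm 8$. Its desk-scale run settings are a folds (2,1) / reps (8,8)
schedule on grids (30,40,50) with the time box capped at $T \le 3$
(divergence older than a few $2N_{ref}$ generations is indistinguishable
from equilibrium isolation at these sample sizes), and a short
perturbed re-fit (folds 1, reps 3) from the fitted optimum per dataset
inside the 100-simulation bootstrap. Test problem sizes (oracle runs of $10^5$ genealogies at
$n = 8$; recovery and calibration fits at folded $(10,10)$ spectra of
~5000 segregating sites with reduced schedules -- folds (3,2,1), reps
(20,20,20) for recovery; folds (2,1), reps (8,8) for the 120-fit selection
calibration; fitting grids (30,40,50)) were chosen as the smallest designs
whose pass/fail criteria are statistically meaningful.

## Decisions on points the sources leave open

* **Polarisation**: nothing indicates an outgroup, so spectra default to
  folded; the simulator records ancestral states and the unfolded path is
  fully supported and tested.
* **Presence threshold semantics**: the `-R` fraction counts individuals
  across the whole matrix (the tool parenthetical's reading), not
  per-population; a per-population variant would be a small extension.
* **Filter order** is fixed genotype-level, then presence, then
  heterozygosity, then single-SNP, and the per-rule tally is returned, so
  the (order-dependent) attribution of dropped sites is explicit.
* **DP/GQ filters mask genotypes** rather than dropping sites, preserving
  partially genotyped sites for projection.
* **Folding convention** follows the standard tool: entries beyond the
  fold line are masked and entries on it are halved after reflection;
  unmasked mass is conserved, and folding commutes with projection.
* **Q-matrix filtering** applies to population-level rows (means of
  individual rows when individual matrices are supplied); both admixture
  thresholds are strict inequalities.
* **Geographic isolation** (criterion iii of the group rule) is a
  caller-supplied flag -- it encodes judgement; a nearest-neighbour
  distance helper exists but does not decide.
* **$\pi$ denominator**: nucleotide diversity is normalised by a
  caller-supplied surveyed-site count, since the invariant-site total is
  not recoverable from a SNP matrix.
* **Evanno $\Delta K$** uses the field's definition
  $|\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / sd(L(K))$.
* **Niche grids**: the occurrence and background densities may use
  separate bandwidths (normal-reference defaults); the background
  correction divides occurrence density by availability where positive and
  renormalises. The overlap values depend on these defaults, which is why
  they are logged in the returned object.

## Known limitations

Composite-likelihood AIC assumes unlinked sites; residual linkage inflates
confidence. The diffusion engine's accuracy contract is stated (and
tested) for $n \le 20$ samples and $|M| \le 20$; stronger migration or
much larger samples need larger grids. Absolute times inherit the full
uncertainty of $\mu$, $g$ and $L$, none of which the data constrain. The
bootstrap treats the fitted model as true; its CIs do not propagate model
uncertainty.
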