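---
title: "Models and methods in rdhscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rdhscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`rdhscape` analyses genome-wide RNA:DNA hybrid (RDH) accumulation in
bacteria and its mutagenic consequences. The inputs are (i) strand-specific
binned read counts from hybrid-binding-domain (HBD) pull-down libraries and
their matched inputs, per genotype and replicate, optionally with spike-in
reference counts; (ii) a genome annotation with a replication origin and
terminus; (iii) per-gene expression values; (iv) mutation-accumulation (MA)
line tables of point mutations, indels and structural variants with
generation counts; and (v) binned whole-genome coverage for replication
profiling. A synthetic-data generator produces all of these with planted
ground truth, so every stage of the pipeline is testable without external
data.

# The enrichment model

For one genotype, strand and genomic bin, let $y_\ell$ be the read count of
library $\ell$ with size factor $c_\ell$. The model is

$$y_\ell \sim \mathrm{NB}(\mu_\ell, \phi), \qquad
\log \mu_\ell = \log c_\ell + \alpha + (\ln 2)\,\beta\,x_\ell,$$

where $x_\ell = 1$ for pull-down ("extracted") libraries and 0 for inputs,
$\alpha$ is the log input abundance of the bin, $\beta$ is the log2
enrichment of the pull-down over the input — the quantity of interest — and
the negative-binomial size $\phi$ gives variance $\mu + \mu^2/\phi$.
Input libraries are unstranded and shared between the two strand models;
extracted libraries are strand-resolved, so each bin yields a plus- and a
minus-strand $\beta$. Dispersion is shared within a genotype rather than
estimated per bin: at a few libraries per bin a per-bin dispersion is not
identifiable, while library-level overdispersion is well estimated by
pooling.

Priors: $\alpha \sim N(\log \bar d, 3^2)$ with $\bar d$ the mean input
depth; $\beta \sim N(0, 2^2)$ on the log2 scale; the overdispersion
$1/\phi$ has a half-Normal$(0, 5^2)$ prior. We place the prior on $1/\phi$
rather than $\phi$ so that the near-Poisson regime ($\phi$ large) is not
excluded a priori; the parameterisation $\mathrm{var} = \mu + \mu^2/\phi$
makes $1/\phi$ the natural "excess noise" scale.

## Inference

Given $\phi$, bins decouple: the posterior of $(\alpha, \beta)$ per bin is
log-concave, and the default `"vi"` engine computes a Gaussian
approximation at the posterior mode. The mode is found by a damped Newton
iteration vectorised across all bins (the $2\times2$ systems are solved in
closed form), and the reported 500 posterior draws are sampled from the
Gaussian with the curvature-based covariance. $\phi$ is estimated by a
penalised profile likelihood, alternating with the Newton updates; three
rounds suffice in practice. The `"mcmc"` engine replaces the Gaussian
draws with a vectorised random-walk Metropolis sampler (500 warmup
iterations, thinned draws, proposal scales from the Gaussian
approximation) and is intended for small genomes, where it provides a
check on the Gaussian approximation. All draws are reproducible from the
mandatory seed.

Masked bins (e.g. collapsed multi-copy rRNA loci) are carried through as
flagged records with missing draws, never dropped, so downstream tracks
stay genome-length.

## Spike-in normalisation and contrasts

Pull-down sequencing yields only relative enrichment within a genotype.
When spike-in reference bins are flagged, size factors are each library's
spike total divided by the geometric mean of all libraries' spike totals;
with them, $\beta$ is referenced to the spike's constant enrichment level
and becomes comparable across genotypes. Cross-genotype contrasts subtract
posterior draws pairwise by draw index, yielding per-bin draws of
$\beta_A - \beta_B$ that retain each fit's posterior spread. The
qPCR-based $\Delta\Delta C_q$ quantity (pull-down minus input cycle
difference at a target locus, referenced to a spike locus) is computed from
replicate means with the replicate spread propagated to a standard error;
one cycle corresponds to one log2 unit, with the opposite sign.

# Track operations

* **Robust z**: $z = (x - \mathrm{median})/(1.4826\,\mathrm{MAD})$. A zero
  MAD (majority-constant track) is an error that advises the IQR-based
  scale (IQR/1.349); the replication-slope transform applies this fallback
  chain automatically with a floating-point tolerance, so an exactly
  linear coverage profile yields all-zero z rather than amplified noise.
* **Rolling median**: centered windows of $\lceil w/\text{bin}\rceil$ bins
  (forced odd), truncated at contig edges so output stays aligned with
  input; missing values are excluded per window. Defaults follow the two
  scales used in practice: 10-kb smoothing for genome overviews, 500-bp
  for locus views. Circular wrap-around is deliberately off: plots and
  downstream aggregation treat the chromosome linearly.
* **Coverage**: log2 CPM with a +0.5-read pseudocount recorded in the
  track metadata.
* **Replication slope z**: coverage is smoothed by rolling median, a
  least-squares slope is fitted in a centered 10-kb window per bin, the
  slope is signed along the direction of fork travel from the replichore
  map (so impeded replication is strongly negative on either replichore),
  and the slope track is converted to robust z. The slope window is a
  parameter; 10 kb on 1-kb bins matches the smoothing scale of
  terminus-region profiles.
* **Event density**: Gaussian KDE on a 512-point grid with bandwidth
  $\text{adjust} \times 0.9 \min(\mathrm{sd}, \mathrm{IQR}/1.34)
  n^{-1/5}$; `adjust = 0.2` is the default for locus-scale structure in
  mutation positions. The curve integrates to 1 within 1% on its grid.

# Feature-level statistics

A feature's RDH score is the median robust z over same-strand bins whose
midpoint falls inside the feature (midpoints are half-integers for
even-width bins; the test suite pins the exact rule). Masked bins are
excluded; a feature with no usable bin is reported missing. CDS starts are
additionally scored over their first 100 bp, strand-aware. Expression z is
the robust z of log2 expression, computed once and shared across
comparisons.

Group contrasts use the Wilcoxon rank-sum test (exact for group sizes up
to 25, normal approximation with continuity correction beyond), the
Hodges–Lehmann median difference, and a percentile bootstrap 95% CI with
$10^4$ resamples under a fixed seed; cross-genotype comparisons are paired
by feature (per-feature differences, signed-rank test). P-values across a
comparison battery are adjusted by Benjamini–Hochberg, with the standard
star map (one star for $0.01 \le \mathrm{FDR} < 0.05$, two for
$0.001 \le \mathrm{FDR} < 0.01$, three below). The "top 20% expressed"
filter thresholds expression z at its 80th percentile per genotype, keeping
ties above the threshold — the conservative reading when a single
genotype's expression is not singled out. The bootstrap CI is a design
choice: the rank-based alternative conditions on the test statistic, while
the bootstrap reflects the scale of the scores actually plotted.

The orientation analysis fits, per genotype,
$z_{\mathrm{RDH}} \sim 1 + \mathrm{headOn} + z_{\mathrm{expr}} +
\mathrm{headOn}{:}z_{\mathrm{expr}}$ with $N(0, 2^2)$ coefficient priors
and a half-Normal residual scale, using the same posterior sampler as the
mutation model (below).

# Orientation relative to replication

A replichore map (contig length, oriC, ter) defines fork direction: on the
arc from oriC to ter traversed with increasing coordinate, forks travel in
the + direction, so + strand genes are codirectional and − strand genes
head-on; the other arc reverses the rule. Genes whose interval strictly
contains oriC or ter are classified by the arc holding their midpoint and
flagged — the choice is exposed rather than silent because no convention
for terminus-spanning genes is established. The terminus position is a
required input, never inferred from coverage.

# The mutation-rate model

Per mutation class $m$ (transition, transversion, indel — insertions and
deletions pooled), the count of class-$m$ events in CDS $i$ under genotype
$g$ is modelled as

$$n_{igm} \sim \mathrm{Poisson}\!\big(L_i G_g\, e^{\eta_{igm}}\big), \quad
\eta = \beta_0 + \beta_{\mathrm{geno}(g)} + \beta_{\mathrm{RDH}}
z^{\mathrm{RDH}}_{ig} + \beta_{\mathrm{expr}} z^{\mathrm{expr}}_i +
\beta_{\mathrm{HO}} h_i + \text{interactions},$$

with exposure = CDS length $\times$ pooled generations, standardized
covariates, and $N(0, 2^2)$ priors. The term set is configurable — the
leave-one-covariate-out analyses simply refit with `"rdh"` or `"expr"`
removed. Poisson rather than negative binomial is the default because
per-CDS MA counts are small and the exposure-offset Poisson is the
standard MA-line model; an overdispersed variant can be emulated by
fitting classes separately and checking PSIS-LOO diagnostics. Exposure
uses full CDS length for every class; restricting to class-available
sites (e.g. transition-capable sites) is deliberately off by default.

## Posterior sampling

Both regressions use one sampler: the posterior mode and curvature are
found by BFGS, a multivariate-t (7 df) proposal is built from the inflated
Laplace covariance, and several independence Metropolis–Hastings chains
are run. For log-concave GLM posteriors this proposal yields high
acceptance and near-independent draws; the acceptance rate, split-$\hat R$
and an effective-sample-size estimate are reported, $\hat R > 1.05$ is an
error, and the proposal is automatically widened (up to 8-fold) before
giving up — skewed posteriors from very sparse counts need a fatter
envelope than the curvature suggests. Pointwise log-likelihoods are stored
on every fit for LOO.

## Bayes factors against a ROPE

Evidence for each coefficient is summarised by partitioning its axis with
a region of practical equivalence (ROPE) of half-width $\delta$ around
zero; $\delta$ defaults to 0.05 on the log-rate scale (roughly a 5% rate
change) and is echoed on every result because conclusions can be
$\delta$-sensitive. With $H_{\mathrm{eff}}$ the event
"$|\beta| > \delta$ with the dominant posterior sign" and $H_0$ the event
"$|\beta| \le \delta$":

$$K = \frac{P(H_{\mathrm{eff}}\mid \mathrm{data})/P(H_0 \mid
\mathrm{data})}{P(H_{\mathrm{eff}})/P(H_0)}, \qquad
K_0 = \frac{\mathrm{posterior~odds}(H_0)}{\mathrm{prior~odds}(H_0)}.$$

Posterior probabilities come from the draws, prior probabilities from
exact Normal tail areas. Cells with no draws are clamped to one draw's
mass ($1/S$) with a warning: finite draws cannot estimate unbounded Bayes
factors, so $K$ saturates at the draw count times the prior-odds
correction. Categories follow the conventional ladder — positive for
$K \in [3, 20)$, strong for $[20, 150)$, very strong for $\ge 150$ — and a
precisely estimated coefficient close to zero can legitimately score high
on both $K$ and $K_0$'s scales at once.

## PSIS-LOO

Model comparison uses Pareto-smoothed importance-sampling leave-one-out
cross-validation implemented in the package: per observation the
importance ratios $1/p(y_i\mid\theta_s)$ are tail-smoothed by fitting a
generalised Pareto distribution (Zhang–Stephens posterior-mean estimator)
to the largest $\min(0.2S, 3\sqrt S)$ weights, and the expected log
predictive density is the weighted log mean. Observations with tail shape
$k > 0.7$ are reported in a warning. Differences between models are
summarised with the standard error of the pointwise differences.

# MA-line curation

Structural variants are removed when they intersect the line's engineered
locus extended by 100 bp on both sides, endpoints inclusive (SV callers
flag the construction scar itself); removals are reported, not silently
dropped. Lines whose SVs overlap guarded repair genes (e.g. the mismatch
repair gene *mutS*) are flagged for exclusion, since their mutation
spectrum is no longer representative. Rates are reported with exact
(Garwood) Poisson intervals from gamma quantiles, and rate contrasts use
the exact conditional binomial test.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions under which the recovery properties are demonstrated:

* a 200-kb circular contig in 100-bp bins, oriC at coordinate 1 and ter at
  mid-chromosome — large enough for stable genome-wide summaries while a
  full three-genotype fit runs in seconds;
* gene-dense annotation (~85% feature territory, as in a bacterial
  chromosome): CDS cassettes with 5′- and 3′-UTRs plus ncRNA/rRNA/tRNA,
  placed without overlap, 25% head-on;
* planted log2 enrichment by feature class (strongest at rRNA and ncRNA,
  elevated 5′-UTRs), an expression slope per genotype (steeper in the
  RNase HIII deletion), a small positive head-on effect with a negative
  head-on-by-expression interaction, and a per-gene hybrid propensity
  deviation (sd 0.5) independent of expression — without it RDH and
  expression would be collinear; with it their correlation sits near 0.5,
  the regime the joint regression must disentangle;
* negative-binomial counts with mean depth 100 reads/bin and size
  $\phi = 1000$ (variance $\mu + \mu^2/1000$), i.e. counting noise with a
  small excess — appropriate for replicate libraries prepared from one
  culture and deeply sequenced DNA; a Poisson switch exposes the limiting
  case. Input means follow a log2-linear replication gradient from oriC
  to ter;
* a spike-in contig with constant true enrichment shared by all genotypes,
  playing the role of an unchanging cross-sample reference;
* 72 MA lines per genotype at 3688 generations each (~265,500 pooled),
  with per-CDS Poisson mutation counts driven by planted coefficients and
  realistic per-bp-per-generation intercepts, uniformly placed events with
  class-consistent alleles, structural variants at a configurable rate,
  and engineered-locus records per line;
* coverage profiles with a planted slow-replication interval upstream of
  the terminus, attributed to the stressed genotype, where the log2
  decline is locally several-fold steeper.

What the generator does **not** emulate: raw reads, fragmentation and
mappability bias, GC effects, operon structure, selection on MA lines, or
batch effects. Passing recovery tests therefore demonstrates correctness
of the inference given the stated measurement model, not robustness to
alignment artefacts in real libraries.

Problem sizes used by the test-suite recovery studies — a 200-kb genome
for enrichment, 1000 CDSs (~1.2 Mb) for the mutation regression, 4000
posterior draws, 20 replicates for calibration — were chosen as the
smallest sizes at which the planted effects are identifiable with the
precision the checks assert; the mutation-recovery scenario plants an
indel intercept of $5\times10^{-10}$ per bp-generation (upper range of
reported MA rates) so that roughly 400 indel events inform the
coefficient.

# Known limitations

* The Gaussian approximation is per-bin; it does not pool information
  across neighbouring bins, so single-bin estimates at low depth are
  noisy where a spatial model could smooth. The posterior intervals are
  slightly conservative relative to full MCMC at very low counts.
* Size factors are treated as fixed, not estimated jointly; spike-count
  noise propagates into a small common shift of $\beta$.
* The rate-ratio test conditions on totals and so discards marginal
  information; for large counts a likelihood-ratio test would be more
  powerful.
* Bayes factors saturate at the draw count; "very strong" at the clamp
  ceiling means "at least", not an estimate.
* The pipeline's comparison battery and mutation design matrix are
  configurable but validated only for the bundled configurations.
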