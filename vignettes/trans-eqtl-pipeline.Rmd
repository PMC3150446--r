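---
title: "Methods: cis/trans-eQTL discovery with permutation FDR and artifact falsification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis/trans-eQTL discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical model it
implements, the choices that were genuinely open, and what a passing test
suite does and does not establish.

## The discovery model

A cohort of unrelated individuals is measured on two array platforms (a
larger HT12-like set and a smaller H8v2-like set sharing a subset of
probes). For a SNP with genotype $g \in \{0,1,2\}$ (or imputed dosage in
$[0,2]$) and a probe with standardized expression $y$, association is the
Spearman rank correlation $\rho$ with two-sided p-value from the
$t$-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of
freedom, and $z$ the signed normal deviate matching that p. A pair present
on both platforms is combined by the weighted Z-method
$z_c = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}$, $w_i = \sqrt{n_i}$.

*Cis* pairs have SNP-to-transcript-midpoint distance $\le$ 250 kb on one
chromosome (boundary inclusive); *trans* pairs are $\ge$ 5 Mb apart or on
different chromosomes. Multiple testing is controlled by permuting sample
labels (expression relative to genotype) $B = 100$ times and estimating
$\mathrm{FDR}(t) = \frac{\frac1B\sum_b \#\{p^{(b)} \le t\}}{\#\{p \le t\}}$;
the significance threshold is the largest observed $p$ with
$\mathrm{FDR}(t) \le 0.05$. When the threshold falls inside a tie, all tied
tests are admitted (deterministic and conservative against exclusion).

Assumptions worth stating: samples are exchangeable under the null (no
relatedness or population stratification is modelled — they are out of
scope); the $t$-approximation for Spearman p-values is adequate at the
sample sizes involved (hundreds and above), and the global error control is
permutation-based anyway, so the approximation only affects ranking
resolution.

### Ties and the value of $\rho$

Tied observations receive average ranks. A consequence sometimes found
surprising: a perfectly monotone genotype–expression pair with tied
genotypes, e.g. $(0,0,1,1,2,2)$ against $(1,\dots,6)$, has $\rho = 0.956$,
not 1 — exactly what `stats::cor.test(method = "spearman")` reports. Exact
$\pm 1$ occurs only without ties. The package reports explained expression
variance as $100\rho^2$, i.e. on the rank scale.

## Confounder removal with genetic protection

Expression is dominated by batch and physiological structure. The pipeline
performs PCA on the sample $\times$ sample Pearson correlation matrix
(samples correlated over probes); scores are eigenvectors scaled by singular
values. The leading $k$ components are regressed out of every probe
($k = 50$ on the cis pathway, $k = 25$ on the trans pathway by default) and
residuals are re-standardized — cosmetic for rank-based association, but it
keeps matrices comparable across stages.

Because a strong trans-acting locus can itself generate a dominant
component, each leading component is screened against every SNP (Spearman,
permutation FDR 0.05): components with some SNP at squared correlation
$> 5\%$ (strict inequality) are flagged *genetically controlled* and are
skipped during removal. The default is to protect flagged components; this
is the conservative reading when the concern is false-negative trans
signals.

One numerical caveat, found while validating score recovery: when a single
batch component dominates *every* probe and the probes are standardized, the
sample correlation matrix saturates towards the batch *sign* pattern
($\mathrm{cor} \to \mathrm{sign}(u_j u_k)$), and PC1 tracks
$\mathrm{sign}(b)$ rather than $b$ (correlation $\approx 0.87$ for Gaussian
$b$). In the realistic regime — batch explaining a moderate share of each
probe's variance — PC1 recovers the planted batch vector with $|r| > 0.99$,
and that is the regime the tests exercise.

## Artifact falsification

Two failure modes of array probes masquerade as eQTLs:

- **Primer polymorphisms** (false cis): a known SNP inside the probe's 50-bp
  genomic target, in LD ($r^2 > 0.1$) with the cis SNP, changes
  hybridization efficiency by allele. Such SNP–probe combinations are
  removed.
- **Cross-hybridization** (false trans): the probe partially binds a locus
  near the SNP. Probes are re-mapped under a deliberately permissive local
  alignment (match 10, mismatch 0, gap open $-250$, gap extension $-100$,
  minimum 30% identity; the gap penalties effectively forbid gaps).
  A hit is *accepted* as plausible hybridization iff it has $\ge 15$
  aligned bases with 0 mismatches, or $\ge 20$ matches with $\le 1$
  mismatch, or $\ge 30$ matches with $\le 2$ mismatches, or covers the full
  50 bp with $\le 15$ mismatches. Any trans record whose probe has an
  accepted hit within 2 Mb of the SNP is discarded, and the FDR is then
  recomputed on the surviving observed tests (the permutation distributions
  are left untouched, matching the original procedure; this is slightly
  conservative).

The 15-base clause does not state a mismatch allowance; it is implemented as
0 mismatches, since the subsequent clauses grant explicit allowances at
larger overlaps. Genome-scale remapping itself is out of scope: the aligner
is provided for supplied target sequences, and externally produced hit
tables are ingested directly.

## Enrichment, convergence, and the GEV

Enrichment of a SNP category (e.g. trait-associated SNPs, or the MHC taken
as chromosome 6, 20–40 Mb inclusive) among eQTLs is assessed by re-running
the mapping on permuted data and counting category members among the
equally-sized top of each permuted ranking. The permutation null counts are
summarized by a maximum-likelihood generalized extreme value (GEV) fit, and
the enrichment p is the fitted upper-tail probability of the observed count,
floored at $10^{-16}$ (reported tail values below that are treated as a
display floor). The empirical permutation p, $(1 + \#\{null \ge obs\})/(1 +
B)$, is always reported alongside; with only 100 null points — and
especially with small discrete counts — the GEV fit can be fragile, and a
degenerate null falls back to the empirical p with a flag. No GEV package is
assumed: density, CDF, quantile and the Nelder–Mead MLE (Gumbel-moment
initialisation, shape unconstrained) are implemented here.

Convergence asks whether two *unlinked* SNPs (LD $r^2 < 0.001$) associated
with the same trait affect the same downstream gene. Its permutation null
keeps the real cis list fixed and replaces the trans set with the top
equally-many associations from each permuted trans ranking. Summary
quantities: fold $=$ observed / mean(null), rounded to the nearest integer
only for reporting, and the implied false-positive rate mean(null) /
observed — the definition consistent with both worked ratios (7 vs 0.15
$\to$ fold 47, rate 0.021; 18 vs 0.84 $\to$ fold 21, rate 0.047).

A finite-sample subtlety: for truly independent SNPs the *estimated* $r^2$
is approximately $\chi^2_1/n$, so at desk-scale $n$ a sizeable fraction of
genuinely unlinked pairs exceeds the 0.001 ceiling by sampling noise alone.
The synthetic generator therefore plants convergent pairs whose realised
$r^2$ in the emitted genotypes is below $5\times10^{-4}$, so planted truth
satisfies the rule the pipeline actually applies.

## Co-expression and phenotypic buffering

Co-expression uses Pearson correlation on the 25-PC-removed expression (the
same matrix the trans scan uses; configurable). The significance threshold
is Bonferroni-derived: with $n$ samples and $P$ probe pairs, the smallest
$r$ whose two-sided p is $\le \alpha/P$. The reported 2-decimal threshold is
the exact value rounded *up* (e.g. exact 0.1849 at $n = 1240$,
$P = 933{,}184{,}801$, $\alpha = 0.05$ reports as 0.19): the smallest
2-decimal coefficient that still guarantees family-wise significance. Set
shifts are tested with a one-sided (greater) Wilcoxon rank-sum against
background pairs — directional because the scientific claim is *stronger*
co-expression than expected; the background defaults to all probe pairs
excluding the tested set, which the source procedure leaves unspecified.
Regressing all significant eQTL genotypes out of the expression
(`regress_out_eqtls`) distinguishes genetically induced co-expression from
latent-factor co-regulation.

Phenotypic buffering joins each eQTL's explained expression variance
($100\rho^2$) with externally reported explained *trait* variance and
counts rows where the molecular effect exceeds the phenotypic one; the trait
variances are user-supplied inputs, not recomputed.

## The synthetic world

`sim_config()` defaults state the emulated design: 1,469 samples split
1,240 / 229 across two platforms (fraction 0.844). SNP and probe counts
default to desk scale (300 / 200) because genome-scale discovery counts are
explicitly not reproducible at desk scale; all tests and the acceptance
script set their own sizes.

- **Genotypes**: one MAF per LD block drawn from `maf_range` (0.05–0.5, the
  post-QC spectrum); the block founder site is two Bernoulli haplotypes and
  each subsequent site copies the previous site's haplotypes with per-site
  mutation probability `ld_decay` (0.1), redrawn at the block MAF. Drawing
  the MAF per block keeps every site marginally Hardy–Weinberg while
  adjacent-site haplotype correlation is $1 - \texttt{ld\_decay}$. Block
  size 1 gives independent SNPs. The genome model is 22 autosomes with
  configurable length, 1-based positions.
- **Expression**: probe = planted genotype effect + low-rank batch
  (per-sample components with probe-specific loadings, emulating dominant-PC
  structure) + Gaussian noise, exponentiated to raw intensities so the
  normalization path is exercised. The batch magnitudes are free parameters
  (the source states none): defaults `n_batch_components = 5`,
  `batch_sd = 2` against `noise_sd = 1` make the batch dominate total
  variance, as observed in real cohorts.
- **Planted effect sizes**: the non-genetic part is orthogonalised against
  the genotype and the effect is scaled so the realised explained variance
  equals `target_r2` — on the rank scale, i.e. the squared Spearman
  correlation the pipeline itself reports. Cis probes are placed within the
  cis window of their SNP (clear of other SNP positions so genuine records
  do not trip the primer filter); trans probes on another chromosome.
- **Artifacts**: cross-hybridizing probes receive extra signal from a decoy
  SNP on another chromosome and an accepted alignment hit 50 kb from it;
  primer-polymorphism probes sit directly on a SNP that also drives their
  spurious cis signal.
- **Missingness** defaults to 0 (post-QC arrays exceed 99% call rate);
  the association engine handles missing genotypes pairwise-complete when
  they are present, and QC tests exercise missingness explicitly.
- **Determinism**: every function derives all randomness from the config
  seed through a scoped RNG, so a fixed seed reproduces every emitted object
  bit for bit.

What the generator does *not* emulate — and hence what a green suite cannot
establish: realistic haplotype structure (no recombination maps or
coalescent genealogies), imputation uncertainty, sex chromosomes, RNA-seq
count noise, cell-type composition shifts, or population stratification.
Recovery rates measured here bound the pipeline's behaviour under its own
assumptions, not under cohort pathology.

## Numerical choices

- Exact HWE test: Levene's conditional distribution of the heterozygote
  count computed in log space; the two-sided p sums classes no more likely
  than observed, with a $1+10^{-10}$ relative guard against floating-point
  ties. Agreement with a binomial-coefficient enumeration oracle is $<
  10^{-12}$ for all totals $\le 200$.
- Quantile normalization targets the per-rank *median* across samples; tied
  values receive the mean of their tied ranks' targets; log2 follows
  normalization (stated order), then per-probe standardization with the
  $n-1$ denominator.
- Spearman p-values are computed in log space so $z$ stays finite at
  $|\rho| \to 1$; dosage genotypes rarely tie and use the same average-rank
  path.
- Cis effects are regressed out jointly per probe, ordered by significance,
  with QR handling of collinear genotype sets (the marginal alternative was
  considered; joint is the default because block-mates of a causal SNP are
  themselves significant and jointly spanning them is what makes the trans
  scan residual clean).
- Degenerate inputs: zero-variance probes are flagged and excluded from
  association; undefined LD returns 0 with a warning; degenerate GEV nulls
  fall back to empirical p.

## Known limitations

- The permutation FDR estimator is global per scan; probe-level or SNP-level
  summaries are derived counts, not separately controlled.
- The built-in aligner returns the best local hit per target sequence; true
  genome-scale remapping must be supplied as a hit table.
- With $\le 100$ permutation rounds the GEV tail extrapolation below the
  empirical resolution is a model-based statement, and for small discrete
  counts the fit is approximate; both p-values are always reported.
- Multi-tissue meta-analysis assumes identical sample sets across tissues
  (the synchronized-permutation design requires it) and errors otherwise.
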