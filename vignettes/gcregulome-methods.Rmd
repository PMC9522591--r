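---
title: "Models and methods in gcregulome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gcregulome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`gcregulome` is an integrative pipeline for dissecting how glucocorticoids
(GCs) rewire the gene-regulatory landscape of acute lymphoblastic leukemia
(ALL) cells, and how genetic and epigenetic disruption of those regulatory
elements relates to GC resistance. This vignette explains the statistical
models behind each stage, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices that were genuinely open.

## The biological setting

GC drugs act through the glucocorticoid receptor (GR, gene *NR3C1*), a
ligand-activated transcription factor that binds glucocorticoid response
elements (GREs) — palindromic nuclear-receptor motifs of two 6-bp
half-sites around a 3-bp spacer. GR binding remodels chromatin (ATAC-seq
accessibility, H3K27ac enhancer acetylation), assembles super-enhancers,
rewires enhancer–promoter loops, and drives the transcriptional program
that makes GCs effective chemotherapy in ALL. The pipeline integrates
these layers into *high-confidence GR regulatory sites* (HGRs: GR peaks
supported by both ATAC and H3K27ac at the same timepoint), validates
their activity with ATAC-STARR-seq and CRISPRi screening, and asks which
HGRs are disrupted — genetically (regulatory variants) or epigenetically
(accessibility/methylation shifts) — in GC-resistant patients.

## Differential counts

All count-based stages share one negative-binomial engine
(`size_factors()`, `estimate_dispersion()`, `nb_wald_test()`):

* **Normalization** is median-of-ratios: the size factor of sample $j$ is
  the median over features of $k_{ij}/\mathrm{geomean}_i$, restricted to
  features with no zero count. Factor *ratios* are equivariant to library
  scaling; the shared geometric-mean reference absorbs a $c^{1/n}$
  renormalization, exactly as in the standard implementation.
* **Dispersion** uses the parameterization
  $\mathrm{Var} = \mu + \alpha\mu^2$. Per-feature method-of-moments
  estimates are computed on normalized counts *within* replicate groups
  (so real treatment effects do not inflate $\alpha$), then shrunk 50/50
  toward a trend $\alpha(\mu) = a_0 + a_1/\mu$ fitted by least squares on
  the positive raw estimates. Features at or below Poisson variance sit at
  the floor of $10^{-8}$.
* **Testing** is a Wald test on normalized group means:
  $\log_2\mathrm{FC} = \log_2\frac{\bar\mu_t + 0.5}{\bar\mu_r + 0.5}$,
  with the delta-method variance
  $\mathrm{Var}(\log\hat\mu) = n^{-2}\sum_j (1/(s_j\hat\mu) + \alpha)$
  summed over the two groups. There is no design matrix, no fold-change
  shrinkage and no independent filtering: every contrast in this pipeline
  is two-group, and the transparent estimator is fully checkable against
  simulation. The +0.5 pseudocount bounds fold changes when a group is
  all-zero.

Under null simulations the test holds its nominal rates (type-I at
$p<0.01$ within [0.005, 0.02]; BH-FDR calls at $q<0.01$ well under 2%),
and planted 4-fold effects at 4 replicates and ~500 reads/feature are
recovered with sensitivity above 0.9.

Responsive chromatin uses per-timepoint contrasts against 0 h (FDR
< 0.01); differentially expressed genes (DEGs) are the union of the 6 h
and 24 h contrasts at FDR < 0.01 and fold change > 2. Per-timepoint
contrasts (rather than a time-course model) were chosen because every
downstream question is about *which* sites/genes respond, not the shape
of the response.

## Super-enhancers

H3K27ac peaks are stitched at a 12,500 bp gap (the rank-ordering
convention's default) and ranked by total normalized H3K27ac signal of
the stitched region. Rank and signal are min-max scaled to $[0,1]$ and
the cutoff falls at the first point where the discrete slope exceeds 1
(the tangent rule); regions above it are super-enhancers (SEs).
GC-responsive SEs must be reproducible — overlapping SE calls at two or
more treated timepoints — and are classed `de_novo` (no 0 h SE) or
`pre_established` (0 h SE with treated/0 h signal ratio ≥ 2; below that
the region is baseline and excluded). Two interpretation choices are
deliberate: the ≥ 2-fold criterion uses stitched-region *total* signal
(not constituent means), and TSS exclusion is off by default because
intragenic SEs are biologically real in this system.

## HGRs and GRE motifs

A GR peak becomes an HGR at a timepoint when it overlaps (≥ 1 bp) both an
ATAC peak and an H3K27ac peak at that timepoint; the final atlas is the
union over timepoints, merged when overlapping, always retaining the GR
footprint (never the ATAC/H3K27ac interval) — HGRs are sites of GR
occupancy. The GRE position-weight matrix shipped with the package
(`gre_pwm()`) is a fixed 15-column log-odds matrix built from the
canonical consensus structure (GGTACAnnnTGTTCT at 0.85/0.05 column
probabilities, uniform spacer): the motif is named but no matrix is
printed in the source literature, so a canonical construction is the
honest choice. A motif "hit" requires 80% of the maximal achievable
score (`motif_frac = 0.8`, exposed in the thresholds); `N` bases score as
the worst base of their column.

## Loops, STARR-seq, footprints, CRISPRi

**Loops** arrive as anchor pairs already filtered to q < 0.01. An anchor
is a promoter anchor when it overlaps a TSS ± 2 kb window
(`promoter_window`, a default chosen to cover typical promoter-proximal
accessibility); only unambiguous distal→promoter loops
enter the Fisher linkage counts, and each (loop, gene) pair counts once.

**STARR-seq** activity is called two ways. The binomial caller tests
each region's RNA output count against its DNA-input proportion
($P(X \ge x)$, $X\sim\mathrm{Bin}(n, p_0)$) at $p < 0.001$, after
seeded downsampling of RNA libraries to the minimum total (sequential
hypergeometric draws, preserving expected proportions), and requires
DNA coverage ≥ 10 because $p_0$ is unstable below that. The count-model
caller runs the NB engine on RNA replicates vs pooled input replicates
(FDR < 0.05, positive fold change). Merged replicate libraries feed the
binomial caller (per-replicate calling is available as an option);
GC-active sites are the union of 6 h and 24 h calls, and condition
specificity (`GC_specific` / `h0_specific` / `shared`) is assigned by
≥ 1 bp overlap between condition sets.

**Footprints** are scored per motif site as mean(flank) − mean(core) on
insertion profiles normalized to mean 1 over a ±100 bp window (core =
motif half-width, flank = 20 bp each side) — depth-invariant by
construction. Differential occupancy between conditions uses a site-level
label-swap permutation (≥ 100 permutations; add-one corrected p; BH
across TFs). No transposase sequence-bias correction is applied: the
synthetic profiles carry no sequence bias, and a correction hook is the
natural extension point for real data.

**CRISPRi screens** get per-sgRNA NB enrichment (post-selection vs
baseline) and element-level alpha-robust-rank aggregation: with a site's
sorted percentile ranks $r_{(1)} \le \dots \le r_{(k)}$,
$\rho = \min_{j \le j_{\max}} F_{\mathrm{Beta}(j,\,k-j+1)}(r_{(j)})$
where $j_{\max}$ counts sgRNAs passing $\alpha = 0.05$ ($\rho = 1$ if
none), calibrated by matched-size permutation draws from the pooled
ranks. Sites are *ranked* by mean log2 fold change, with $\rho$ and its
permutation p as companion evidence, and non-targeting controls can be
grouped into pseudo-elements to verify they sit mid-ranking.

## Cohort analyses and prioritization

Patients are stratified by the continuous resistance phenotype (median
split by default; threshold and provided-label rules available).
Resistance-associated accessibility runs the NB contrast resistant vs
sensitive on all samples and within each subtype with ≥ 4 samples,
keeping the union at FDR < 0.1 with arm provenance; direction
`occluded_in_resistant` is negative log2FC. Methylation concordance asks,
per CpG probe overlapping a resistance site, whether the beta difference
(resistant − sensitive) opposes the accessibility log2FC; probes with a
zero difference on either side are excluded from the denominator.
Fine-mapping expands lead variants (association q < 0.05) by LD proxies
at $r^2 > 0.8$ (squared Pearson correlation of dosages), keeps lead *or*
proxy variants inside HGRs, and scores each as best-PWM-score(alt) −
best-PWM-score(ref) over the HGR window, so a GRE-disrupting allele gets
a negative delta in bits. The prioritization funnel is: CRISPRi
candidates (mean log2FC > 0, HGR-overlapping) → genes by
regulatory-domain association (basal 5 kb/1 kb plus extension to 1 Mb,
the association tool's documented defaults) → GC-responsive DEGs →
genes on the supplied resistance list, with survivor counts at every
stage.

## The synthetic study

`simulate_study()` generates every input with planted truth on a toy
genome of three 10 Mb chromosomes with 200–1000 bp peaks in exclusive
6 kb slots (desk-scale, realistic geometry). Defaults are the study
conditions the recovery guarantees refer to: timepoints 0/2/6/12/24 h,
4 replicates, 1e6 mean reads (log-normal sd 0.2 so size factors are
non-trivial), NB dispersion 0.05 (typical bulk overdispersion), planted
|log2FC| = 2, STARR activity factor 4, ~6.5 sgRNAs per screened site
with 100 non-targeting controls and a 2× planted selection effect at 4
replicates per arm, 100 patients (the source cohorts' sizes per subtype
are not published, so cohort size is a parameter), 78% of planted
resistance sites occluded in resistant patients, and 85% planted
methylation concordance. Enhanced chromatin responses are planted
preferentially at GRE-bearing GR peaks and reduced responses at AP-1
sites; up/down DEGs are the nearest genes of enhanced/reduced peaks, and
planted loops wire those pairs, so every integrative statistic has a
known direction. One focal locus carries the full resistance story —
GRE-bearing HGR, enhanced response, upregulated nearest gene on the
resistance list, planted screen hit, occluded resistance site, and a
causal GRE-disrupting variant (plus two LD proxies) with additive
phenotype and expression effects — so the funnel has a known survivor.

What the generator does **not** emulate: raw reads, fragment-level
transposase sequence bias, chromatin contact matrices (loops are emitted
as lists), population structure in genotypes, and peak-calling noise
(peak presence is planted, not inferred). Passing tests therefore
demonstrate the pipeline's statistical behavior under its stated model,
not robustness to upstream artifacts of real data.

## Numerical choices and limitations

Determinism: every stage draws from a stage-salted seed, so a fixed
configuration reproduces byte-identical outputs (checked via file
checksums). Fisher's two-sided p uses the probability-mass rule with a
$1+10^{-7}$ relative tie guard; the K-S p is asymptotic only (samples in
use are hundreds); BH is the only multiplicity correction. Degenerate
inputs are defined, not fatal: all-equal SE signals yield zero SEs with
a warning, odds ratios with empty cells report `Inf`/`NA`, monomorphic
variants return `NA`, zero-DNA STARR regions are excluded from RNA.

Problem sizes in the test suite and acceptance script (1000–2000
regions, 250 genes, 100 patients, 10–20 seeded replicates) were chosen
as comfortable desk-scale settings at which every planted-recovery and
calibration property holds; all scale linearly if enlarged. Known
limitations: two-group contrasts only (no covariates or paired designs),
no per-sgRNA copy-number correction, the footprint significance scheme
is a permutation replacement rather than a replication of any external
tool's internal model, and the eQTL model is plain additive OLS — a
pipeline-stage linkage, not a method claim.
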