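---
title: "Methods: disease-activity transcriptomics of the rheumatoid synovium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-activity transcriptomics of the rheumatoid synovium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`synovact` implements an analysis chain for synovial-biopsy transcriptomics
in early rheumatoid arthritis (RA). The scientific question it serves is
whether synovial gene expression tracks composite clinical disease-activity
indices, which cytokine axes (IL6, TNF&alpha;) drive the activity-associated
transcripts, and whether baseline expression of TNF&alpha;-induced genes
predicts failure to respond to therapy. Five analytical stages implement
this chain, and a synthetic-data generator provides inputs with planted
ground truth so that every stage can be validated quantitatively.

The pipeline consumes **already-normalised log2 expression matrices**
(probes &times; samples). Array preprocessing (CEL files, RMA) is outside
its scope.

## Clinical disease-activity indices

Three composite indices are computed from five components — 28-joint tender
and swollen counts (TJC28, SJC28), C-reactive protein (CRP), and patient and
evaluator global assessments (PGA, EGA, 0–10 cm visual-analogue scales):

* **DAS28-CRP** $= 0.56\sqrt{TJC28} + 0.28\sqrt{SJC28} + 0.36\ln(CRP_{mg/L}+1) + 0.014\,GH_{mm} + 0.96$,
  with the patient global converted to millimetres internally;
* **SDAI** $= TJC28 + SJC28 + PGA_{cm} + EGA_{cm} + CRP_{mg/dL}$;
* **CDAI** = SDAI without the CRP term, so `sdai - cdai` equals CRP in
  mg/dL exactly — a convenient invariant, tested to machine precision.

CRP is stored once, in mg/L; all unit conversions are internal. This avoids
the classic silent double-conversion bug when mg/L and mg/dL conventions
meet.

**EULAR response** is classified from the DAS28 improvement
$\Delta = \text{baseline} - \text{follow-up}$ and the attained follow-up
score, per the published matrix: *good* requires $\Delta > 1.2$ **and**
attained $\le 3.2$ (inclusive); *none* when $\Delta \le 0.6$, or
$\Delta \le 1.2$ with attained $> 5.1$; *moderate* otherwise. Boundary
semantics matter here: an improvement of exactly 1.2 is not *good*, while
an attained score of exactly 3.2 is eligible. Because the thresholds carry
one decimal, improvements are rounded at $10^{-8}$ before comparison so
floating-point residue from score subtraction cannot flip a boundary cell.

## Correlation screen

For every probe the Pearson correlation $r$ with a per-sample clinical
covariate is computed. Probes with zero variance get an undefined (`NA`)
coefficient: undefined is not zero, and such probes are never selected.
Selection applies an inclusive threshold ($r \ge 0.5$ by default; strict
`>` behind a flag) either to $r$ ("positive" mode — the default reading,
since selected transcripts are interpreted as over-expressed with activity)
or to $|r|$. No multiple-testing correction is applied at this stage; the
screen is a threshold filter by design, and agreement between the three
indices' selections (Venn-region counts, Jaccard similarity) is the
robustness check.

## The eigenvalue gene-set statistic

For a gene set and a two-condition experiment, the set's submatrix (all
samples of both conditions pooled) is gene-centred and decomposed; the
statistic is the percentage of total variance carried by the first
principal component,
$100\,\lambda_1/\sum_k \lambda_k$. Genes are **not** unit-scaled: amplitude
structure is retained deliberately, and only the *share* of variance is
summarised. A coherent, perturbation-driven set approaches 100; an
incoherent set of the same size stays near the noise floor. Because PC1 of
a pooled matrix need not track the contrast, the absolute correlation
between PC1 sample scores and the 0/1 condition indicator is reported
alongside, so the user can see whether the dominant component is the
perturbation.

Numerical choices: the decomposition runs on the sample-by-sample
cross-product (samples are few, genes many); eigenvalues below a relative
floor of $10^{-12}$ are treated as exact zeros, so rank-1 inputs return
exactly 100; a zero-variance submatrix is an error (the statistic is
undefined, not zero). The eigendecomposition and singular-value routes
agree to $10^{-9}$ on random matrices, and this is tested.

Directional summaries use per-gene log2 fold changes: group-mean
differences, or means of within-pair differences when a pairing is given
(pairing affects fold changes only; the PCA always pools both conditions,
keeping one eigenvalue definition for paired and unpaired designs). For
receptor-blockade experiments (an anti-IL6R antibody suppressing
IL6-dependent transcripts) the `invert` flag flips interpreted fold-change
signs, so a drug-suppressed gene reads as cytokine-induced. The summary
reports the fractions of set genes beyond $\pm\log_2(1.5)$ and the mean
interpreted fold change; 1.5-fold is the package-wide default cutoff,
shared with the responder screen, and exposed everywhere as an argument.

**Permutation null.** The original analysis chain asserted enrichment
without a stated null; as an extension, a size-matched random-set null is
supplied: `n_perm` sets of equal size are drawn uniformly from the
experiment's probes and the statistic recomputed, giving the add-one
smoothed $p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)$. Null
draws tied with the observed value within $10^{-9}$ count as exceeding it,
so the degenerate whole-universe set gets $p = 1$ rather than an
order-dependent value.

## Responder differential-expression screen

Baseline expression is compared between poor and good responders with a
**pooled-variance Student t test** per probe (the named test; Welch is
available behind a flag), two-sided p from the t distribution with
$n_1+n_2-2$ df, and **no multiple-testing correction** — deliberately
mirroring a screen design in which an uncorrected p < 0.05 is combined
with a 1.5-fold over-expression gate ($\log_2\!fc \ge \log_2 1.5$, poor
minus good; strict `>` behind a flag). A Benjamini–Hochberg FDR column is
emitted for information but never gates the result. Probes with zero
pooled variance and zero mean difference get $p = 1$ by convention.

The pass-list is then tested for overrepresentation in a reference set
(typically the stimulation experiment's induced genes) with the upper
hypergeometric tail $P(X \ge k)$ over the universe of probes present in
both matrices — the universe choice guarantees the overlap is computable
for every member. The odds ratio uses a Haldane 0.5 correction when any
2&times;2 cell is zero.

## Immunostaining quantification

Each field image is segmented by fixed channel-difference scores: brown
immunostain pixels satisfy $R - B \ge 50$ with luminance $\le 200$ (the
luminance bound excludes the pale tissue background); blue hematoxylin
nuclei satisfy $B - R \ge 50$. The stain test is applied first, making the
masks disjoint by construction. Colour deconvolution was deliberately not
used: fixed thresholds are deterministic, bit-exactly testable against the
generator's palette, and exposed as arguments for real images. The
slide-level statistic is the mean stain/nuclei surface ratio (S/N) over
usable fields (a field is usable when its nuclei surface reaches
`min_nuclei_px`, default 50 px); slides with fewer than `min_fields`
(default 3 of 6) usable fields are *discarded* — a status, not an error,
since tissue-quality discards are part of the design.

Group comparisons use rank tests. `mann_whitney` counts
$U = \#\{x_i > y_j\} + \tfrac12\#\{x_i = y_j\}$ and, for pooled $n \le 12$,
computes the exact two-sided p by enumerating all group assignments of the
pooled values (deviations from the null mean $n_1 n_2/2$; identical
multisets therefore give $p = 1$). Enumeration is cheap below that size
($\binom{12}{6} = 924$ assignments) and the switch point is recorded in the
output. Larger samples use the tie-corrected normal approximation with
continuity correction. The exact route is hand-built because the standard
exact algorithm declines ties, while the tie convention above is part of
the operator's definition. `kruskal_wallis` delegates to the standard
tie-corrected H with a $\chi^2_{g-1}$ p-value, returning $p = 1$ when the
data are fully tied (the tie correction leaves H undefined there).

# The synthetic study generator

The generator emulates the *structure* of the study designs the pipeline
targets, with every effect planted and recorded as ground truth.

**Cohort.** Each of `n_patients` (default 60) carries a latent disease
activity $a_i \sim N(0,1)$. Probes are assigned in fixed blocks to a TNF
module (default 100), an IL6 module (100), a shared module (50) and
background (1750 of 2000). Activity-linked genes follow
$x_{ij} = \mu_j + \beta a_i + \varepsilon_{ij}$ with $\beta$ =
`activity_effect` (default 0.8 log2 units per SD) and
$\varepsilon \sim N(0, \sigma)$, `noise_sd` $\sigma = 1$; baselines
$\mu_j \sim U(4, 12)$ on the log2 scale. Clinical components are generated
*from the same latent* $a$ — the premise under test is precisely that
synovial transcripts track the composite indices — via monotone rounded
and clipped Gaussian transforms (counts bounded 0–28, globals 0–10 cm, CRP
log-normal). Tender/swollen counts use clipped Gaussians rather than
Poisson draws: the monotone link and hard bounds stay simple and testable.
At the defaults this yields baseline DAS28-CRP of roughly $5.0 \pm 1.3$
and a correlation of about 0.96 between DAS28-CRP and $a$.

**Responder labels.** A responder propensity
$t_i = 0.6\,a_i + 0.8\,e_i$, $e_i \sim N(0,1)$, marks the top 20% as poor
responders, who additionally receive `responder_shift` (default +1 log2)
on TNF-module genes at baseline. The correlation with $a$ encodes the
biological premise that a more TNF-driven, more active synovium predicts
non-response; it also means the poor group over-expresses all
activity-linked modules somewhat, with the TNF module elevated most.
Labels are assigned *before* 6-month data are generated, so the EULAR
classifier can be validated against them: 6-month components are generated
from a reduced activity $a_i - 1.9$ (good responders; expected DAS28
improvement well above 1.2) or $a_i - 0.25$ (poor; expected improvement
below 0.6).

**Perturbation experiments.** Both designs draw a per-gene baseline, a
per-pair per-gene random intercept (donor or patient effect), and residual
noise *before* adding the deterministic effect shift — so a fixed seed
yields common random numbers across effect sizes, and properties such as
"the module eigenvalue rises with stimulation strength" hold as
deterministic statements for a seeded fixture rather than on average. The
stimulation design (default 3 pairs, as in small culture experiments)
shifts TNF-module genes by `stimulation_effect`; the paired-treatment
design (default 12 pairs) shifts IL6 and shared module genes by
$-$`treatment_effect` and carries `invert = TRUE`. Residual SDs are
design-specific: 0.3 (donor effect 0.2) for cultures, which are far less
variable than human biopsies, versus the cohort's `noise_sd` (patient
effect 0.5) for the biopsy design. With biopsy-scale noise the 0.5-log2
stimulation step is swamped by sampling noise in a 6-sample experiment and
the eigenvalue trajectory is not reliably monotone; at culture-scale noise
it is (checked structurally across 200 seeds during design).

**Histology fields.** 512&times;512 RGB canvases on a pale background
(235, 230, 225) with brown stain (150, 90, 40) painted in the left half
and blue nuclei (60, 70, 150) in the right half, each as a contiguous
wrapped band at a seeded random offset — regions are disjoint and surface
totals exact by construction, so segmentation can be validated bit-exactly.
The fixed palette clears the channel-difference thresholds by 60 levels,
so the optional per-pixel jitter (fraction of 255, e.g. 5%) perturbs
appearance without crossing them. For group-comparison power studies,
`simulate_slide_ratios` draws slide-level S/N ratios log-normally
(geometric mean 2.0, log-SD 0.3) with a 1.5&times; stain shift in the poor
group — the magnitude of between-group immunostaining differences the
analysis is meant to resolve at $n = 12$ per group.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: probe-level microarray noise
(hybridisation, normalisation artefacts), batch effects, heavy-tailed or
correlated residuals within modules beyond the single latent, missing
clinical components, realistic histology texture (folds, debris,
out-of-focus fields), and the joint distribution of clinical components in
any real cohort. Tests on this generator validate the *operators*; they
do not validate biological conclusions.

# Problem sizes and reproducibility

The default test and acceptance runs use 2,000 probes &times; 60 patients
for cohorts, 6-sample culture experiments, 999 permutations for planted-set
tests and 199 for null-rate studies, 25 replicates for power estimates —
sizes chosen so the full validation runs in seconds while keeping binomial
3-SD tolerance bands tight enough to detect miscalibration. All randomness
descends from explicit integer seeds; workflow outputs include a run
manifest (package version, configuration, seed, MD5 checksum per file, no
timestamp), so a configuration reproduces byte-identically.

# Known limitations

* The correlation screen treats samples as exchangeable; repeated biopsies
  from one patient would need mixed models, which are out of scope.
* The eigenvalue statistic summarises coherence, not direction; a set
  uniformly *suppressed* by a perturbation scores as high as one induced.
  Direction lives in the fold-change profile, and the two must be read
  together.
* The exact Mann–Whitney enumeration is quadratic in the number of
  assignments and is therefore capped at pooled $n = 12$; beyond that the
  tie-corrected normal approximation is used even when an exact network
  algorithm could still be feasible.
* Segmentation thresholds are tuned to the generator's palette; real
  slides require threshold calibration (arguments are exposed) or a
  deconvolution-based operator outside this package's scope.
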