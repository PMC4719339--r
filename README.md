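# synovact

Analysis pipeline for synovial-biopsy transcriptomics in early rheumatoid
arthritis (RA). The package answers three linked questions the way a
synovial tissue study would: do synovial transcripts track composite
clinical disease-activity indices; which cytokine axes (IL6, TNFα) drive
the activity-associated transcripts; and does baseline over-expression of
TNFα-induced genes predict failure to respond to therapy — with a parallel
immunostaining arm quantifying TNFα-dependent protein markers on tissue
sections.

## What it computes

* **Clinical scores** — DAS28-CRP
  (`0.56·√TJC28 + 0.28·√SJC28 + 0.36·ln(CRP+1) + 0.014·GH + 0.96`),
  SDAI, CDAI, and EULAR good/moderate/none response from paired DAS28
  evaluations.
* **Correlation screen** — transcriptome-wide Pearson *r* between probe
  expression and a clinical covariate, threshold selection (default
  *r* ≥ 0.5), and Venn/Jaccard overlap between the selections of the three
  indices.
* **Eigenvalue gene-set statistic** — the percentage of a gene set's
  variance carried by its first principal component across a two-condition
  experiment, `100·λ₁/Σλ`, with directional log2 fold-change profiles
  (paired or unpaired, with a sign-inversion convention for
  receptor-blockade designs) and a size-matched random-set permutation
  null.
* **Responder screen** — pooled-variance Student t per probe on
  good-vs-poor responders (uncorrected p < 0.05 plus a ≥1.5-fold gate),
  then hypergeometric overrepresentation of the pass-list in a reference
  set of cytokine-induced genes.
* **Immunostaining quantification** — stain and nuclei surfaces per field
  from channel-difference segmentation, slide-level S/N ratios, and
  Mann-Whitney / Kruskal-Wallis group comparisons (exact by enumeration at
  small n).
* **Synthetic study generator** — cohorts with a latent activity variable
  driving both clinical components and planted expression modules, paired
  treatment and cytokine-stimulation experiments, responder labels tied to
  baseline TNF-module expression, and painted histology fields with exact
  ground-truth surfaces.

See `vignettes/synovact-methods.Rmd` for the model, parameter and design
details.

## Worked example

```r
library(synovact)

params <- simulation_params(seed = 42)       # default study conditions
bundle <- simulate_cohort(params)

panel <- score_panel(bundle$clinical_baseline)
head(panel[, c("patient_id", "tjc28", "sjc28", "crp_mg_l",
               "das28_crp", "sdai", "cdai")], 3)
#>   patient_id tjc28 sjc28  crp_mg_l das28_crp     sdai     cdai
#> 1       P001    19    14 33.520801  6.394949 47.18541 43.83333
#> 2       P002     9     9  8.615153  4.855931 28.07518 27.21366
#> 3       P003    11     9  9.603940  5.172860 28.80549 27.84509

# screen all probes against DAS28-CRP and select at r >= 0.5
y    <- setNames(panel$das28_crp, panel$patient_id)
cors <- correlate_probes(bundle$expression, y)
sel  <- select_probes(cors, threshold = 0.5)
length(sel)
#> [1] 249

# are the selected transcripts TNF-dependent? profile them in a
# stimulated-culture experiment and test against size-matched random sets
stim <- simulate_perturbation(params, "stimulation")
prof <- perturbation_profile(sel, stim)
prof$perm_p <- eigen_permutation_test(sel, stim, n_perm = 999,
                                      seed = 1)$perm_p
print(prof)
#> enrichment summary: eigenvalue 57.9% (PC1~condition |r| = 1.00)
#>   genes used 249 (absent 0); mean log2FC +0.394; up 40%, down 0%
#>   permutation p = 0.001

# responder arm: transcripts over-expressed in poor responders at baseline,
# and their overlap with stimulation-induced genes
de   <- de_screen(bundle$expression, bundle$truth$response)
pass <- de$probe_id[de$passes]
ot   <- overrepresentation_test(pass, induced_set(stim),
                                rownames(bundle$expression))
sprintf("overlap %d/%d probes, p_hyper = %.3g, OR = %.1f",
        ot$k, ot$n, ot$p_hyper, ot$odds_ratio)
#> [1] "overlap 99/198 probes, p_hyper = 5.93e-91, OR = 93.8"
```

Reading the output: 249 of 2,000 probes correlate with DAS28-CRP at
*r* ≥ 0.5; as a set, 57.9% of their variance in the stimulation experiment
sits on one principal component that tracks the stimulated/unstimulated
contrast almost perfectly, 40% of them rise by more than 1.5-fold under
TNFα, and no size-matched random set among 999 reaches that coherence
(p = 0.001). Half the transcripts over-expressed in poor responders at
baseline are themselves TNFα-induced — far beyond chance overlap
(p ≈ 10⁻⁹¹) — the transcript-level signature whose protein-level analogue
the immunostaining arm quantifies.

A command-line surface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("exec/synovact", package="synovact"))')
Rscript $CLI simulate --out study --seed 5
Rscript $CLI screen --expr study/cohort_expression.tsv \
    --clinical study/clinical.csv --covariate das28_crp \
    --threshold 0.5 --out screen.tsv
Rscript $CLI enrich --expr study/stimulation_expression.tsv \
    --design study/stimulation_design.csv \
    --sets study/planted_modules.gmt --nperm 199 --out enrich.json
```

Subcommands: `simulate`, `scores`, `screen`, `enrich`, `respond-de`,
`ihc`, `run-activity`, `run-responder`.

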