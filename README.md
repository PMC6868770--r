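# TICFnet

Integration of heterogeneous cancer cohorts along two axes — horizontal
(schema inference over clinical, expression and copy-number files from
different studies) and vertical (a two-layer patient–protein relation
network enriched from external protein-knowledge sources) — with a
composite clinical feature, per-patient cohort enrichment, and
cross-validated survival-time regression. The package is aimed at
computational biologists who need to join multi-study, multi-platform
cohort data and model patient survival on the integrated result, and it
ships a synthetic two-study generator with full ground truth so every
step is testable without restricted clinical data.

## The method in brief

**Horizontal integration.** Files with unknown delimiters and
study-specific field names are parsed into records; a *semi-structure*
(field name → occurrence count) is inferred record by record per data
type and acts as a data schema: validated documents keep the mandatory
`ID`/`Sample ID` plus known fields only, and land in a line-delimited
document store.

**Vertical integration.** Molecular profiles are turned into per-patient
aberrant-protein calls (expression: cohort z-score |z| ≥ 2; copy number:
log-ratio ≥ +0.5 or ≤ −0.5). Calls become patient→protein relations whose
*frequency* is the number of distinct carrier patients; relations with
frequency > 10 are *trusted*. Scores rank internal relations
(`1 + 0.05·(f−1)`) above externally linked ones (`0.5·s + 0.05·(f−1)`,
provider score s ∈ [0,1]), and untrusted linked relations are pruned.

**TICF.** The Tumor Integrated Clinical Feature concatenates tumor
stage, tumor size (mm) and age at diagnosis (years) as fixed-width
digits — `stage·10⁶ + size·10³ + age` — so numeric order equals the
lexicographic clinical-severity order. Composites are z-normalized and
patients stratified into 5 near-equal groups.

**Enrichment and prediction.** Around a studied patient, the cohort
grows from the TICF group (ring 0) through shared trusted proteins
(ring 1) and one hop of trusted linked relations (ring 2); features are
the normalized TICF plus per-protein carrier indicators, all
z-normalized. Survival months are modelled by SVR (RBF / linear /
polynomial) and decision-tree regression under seeded k-fold
cross-validation reporting R², explained variance and negative
mean/median absolute error, plus a ±TICF × ±network ablation grid.

## Worked example

```r
library(TICFnet)

dir <- file.path(tempdir(), "demo")
cfg <- syntheticConfig(seed = 7L)            # default two-study scenario
man <- generateCohort(cfg, dir)
generateEdksFixture(cfg, man, file.path(dir, "edks.tsv"))

docs <- list()
for (dt in c("clinical", "expression", "cnv")) {
  files <- vapply(names(man$files), function(st)
    file.path(dir, man$files[[st]][[dt]]), character(1))
  docs <- c(docs, ingestStudyFiles(files, dt, file.path(dir, "store"))$documents)
}

net <- buildInternalNetwork(docs)
net <- addLinkedRelations(net, edksFixtureProvider(file.path(dir, "edks.tsv")))
net <- pruneUntrusted(markTrusted(net))
net
#> IntegratedNetwork: 550 patients, 120 proteins, 4904 relations
#>   patient_patient_shared     3341  (0 trusted)
#>   patient_protein_cnv         495  (495 trusted)
#>   patient_protein_expr       1045  (532 trusted)
#>   protein_protein_linked       23  (23 trusted)
#>   trusted threshold: support > 10 distinct patients

buildTICF(2, 15, 47)   # stage 2, 15 mm, 47 years
#> [1] 2015047

ticf <- buildTICFTable(docs)
ticf
#> TICFTable: 379 patients with a defined TICF, 5 groups

cohort <- enrichCohort(defaultSeedPatient(ticf), net, ticf, docs)
cohort
#> EnrichedCohort for seed 'NB016': ring0 76, ring1 84, ring2 46 patients
#>   37 proteins used, 38 features, 188/206 patients with targets

y <- survivalTargets(cohort); obs <- !is.na(y)
crossValidate(featureMatrix(cohort)[obs, ], y[obs], k = 5, seed = 8)
#> CVReport: 5-fold cross-validation on 188 rows (seed 8)
#>   svr_rbf     r2 0.237±0.038  explained_variance 0.275±0.029  ...
#>   svr_linear  r2 0.695±0.077  explained_variance 0.703±0.071  ...
#>   svr_poly    r2 0.294±0.126  explained_variance 0.317±0.124  ...
#>   dtr         r2 0.593±0.059  explained_variance 0.600±0.057  ...
```

Reading the output: 550 simulated patients across two differently
formatted studies were integrated; 1,540 patient–protein relations were
called from the molecular layers, of which those carried by more than 10
distinct patients are trusted and drive enrichment. 379 patients have all
three TICF components. Around the representative patient `NB016`, the
enriched cohort grows from its 76-patient TICF group to 206 patients; on
the 188 with survival targets, the linear-kernel SVR explains ~70% of the
held-out variance of survival months and the decision tree ~59%, while
the RBF and polynomial kernels trail — the qualitative pattern the
framework is designed to surface. `runAblation()` repeats the
cross-validation with the composite replaced by separate clinical columns
and/or enrichment disabled; `runPipeline(NULL, outDir)` chains all stages
(simulate → ingest → network → link → ticf → enrich → predict → ablate)
with resumable artifacts, and `inst/scripts/ticfnet-pipeline.R` wraps it
for the shell.

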