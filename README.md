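# ddmrd — tumor-informed MRD detection by droplet digital PCR

`ddmrd` implements the computational workflow behind tumor-informed
measurable residual disease (MRD) monitoring of liquid biopsies — the
setting where patient-specific somatic variants found by tumor/normal
whole-genome sequencing are turned into droplet digital PCR (ddPCR)
assays and used to count circulating tumor DNA molecules in
cerebrospinal fluid or plasma. It is aimed at researchers building or
evaluating such pipelines who need every stage to be explicit,
reproducible and testable.

The package covers:

* **Target selection** — post-calling somatic filter chains
  (SNV/indel: `PASS ∧ alt ≥ 5 ∧ (MAX_AF ≤ 0.001 ∨ absent) ∧
  (CADD ≥ 20 ∨ absent) ∧ IMPACT ∈ {HIGH, MODERATE}`;
  SV: `PASS ∧ PR ≥ 5 ∧ SR ≥ 5 ∧ normal support ≤ 1 ∧
  SOMATICSCORE ≥ 50`), gene-list prioritization (recurrent-in-MB >
  cancer census > other, then read support), and timepoint
  intersection for relapsed cases. VCF parsing via `vcfR`.
* **Droplet classification** — rectangular amplitude gates derived from
  each plate's control wells; every droplet assigned to empty,
  reference-positive, a multiplexed target band, double-positive, or
  unassigned (rain), with counts conserved.
* **Quantification** — Poisson partition statistics
  `λ = −ln(1 − k/n)`, `c = λ/V_d` copies/µL with exact Clopper–Pearson
  95% intervals; triplicate merging with a total-error (wider-of)
  interval; conversion to copies/mL of biofluid (33/40 input-fraction
  correction), haploid genome equivalents (3.3 pg/hGE) and DNA mass.
* **MRD calling** — per-assay false-positive rates from 12-well
  negative-control cfDNA plates; the positive / trace-positive /
  negative decision cascade (≥ 3 FAM droplets; CI separation from NC;
  zero-FPR trace rule); sample-level status; limit-of-detection
  assessment on 10-ng dilution series.
* **Synthetic data** — a generator for droplet tables (Poisson
  partitioning, Gaussian amplitude clusters, rain, false positives,
  control layouts, dilution series) and annotated somatic VCF pairs
  with truth labels, so the whole pipeline runs and is tested without
  any external data.

## Worked example

Simulate a two-assay plate (an SNV assay and an SV breakpoint assay,
amplitude-multiplexed in FAM) with one ctDNA-positive CSF sample and one
negative follow-up, then run the full pipeline:

```r
library(ddmrd)

am <- amplitude_model(
  target_bands = data.frame(target_id = c("CSNK2B_c.T59C", "SV_dup1p21"),
                            mean_fam = c(4000, 6500), sd_fam = 150))
cfg <- run_config(panel = c("CSNK2B_c.T59C", "SV_dup1p21"), seed = 20,
                  simulation = list(
                    sample_concentrations = list(
                      csf_d0  = list(CSNK2B_c.T59C = 3, SV_dup1p21 = 1.2),
                      csf_d30 = list()),
                    biofluid_volume_ml = 2))
run <- run_pipeline(cfg, amplitude_model = am)
run
#> <mrd_run>
#>   27 wells classified, NTC clean
#>   csf_d0: positive
#>   csf_d30: negative
run$calls
#>   sample        target     call fam_droplets ci_nonoverlap fpr
#>   csf_d0 CSNK2B_c.T59C positive          116          TRUE   0
#>   csf_d0    SV_dup1p21 positive           49          TRUE   0
#>  csf_d30 CSNK2B_c.T59C negative            0         FALSE   0
#>  csf_d30    SV_dup1p21 negative            0         FALSE   0
```

The merged triplicates behind those calls (three 16,000-droplet wells per
sample, hence `n = 48000`):

```r
run$results[, c("sample", "target", "k", "n", "copies_per_ul",
                "copies_per_ml", "hge_per_ml")]
#>   sample        target   k     n copies_per_ul copies_per_ml hge_per_ml
#>   csf_d0 CSNK2B_c.T59C 116 48000         2.847        113.86       1953
#>   csf_d0    SV_dup1p21  49 48000         1.202         48.06       1953
#>  csf_d30 CSNK2B_c.T59C   0 48000         0.000          0.00       1955
#>  csf_d30    SV_dup1p21   0 48000         0.000          0.00       1955
```

Reading one row: 116 mutant droplets across the `csf_d0` triplicate give
2.85 copies/µL of reaction; over three 22-µL wells, corrected for the
33/40 input fraction and 2 mL of CSF, that is ~114 mutant copies per mL
of CSF against a total cfDNA background of ~1950 hGE/mL — a clearly
MRD-positive sample. The day-30 sample has zero mutant droplets on both
assays and is negative.

Unit conversions use one constant (3.3 pg per haploid genome
equivalent) with display rounding separated from arithmetic:

```r
display_hge(hge_mass_convert(100, "mass_pg_to_hge"))
#> 30
display_mass_pg(hge_mass_convert(8573, "hge_to_mass_pg"))
#> "28.3 ng"
```

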