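---
title: "Methods: tumor-informed MRD detection by droplet digital PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-informed MRD detection by droplet digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmrd)
```

## The problem

In pediatric brain tumors such as medulloblastoma, measurable residual
disease (MRD) after surgery is usually invisible to imaging and cytology.
A tumor-informed liquid-biopsy workflow makes it measurable: whole-genome
sequencing of the resected tumor and matched blood yields somatic variants
unique to that patient's tumor, a small panel (at least two aberrations per
patient, ideally one SNV and one structural variant) is turned into
patient-specific droplet digital PCR (ddPCR) assays, and those assays are
then run on cell-free DNA (cfDNA) from cerebrospinal fluid or plasma, where
a handful of mutant molecules among thousands of wild-type genomes must be
counted reliably. `ddmrd` implements the computational side of that
workflow end to end: variant filter chains and target prioritization,
droplet gating and classification, Poisson quantification with confidence
intervals, false-positive-rate estimation, and the MRD decision rules.

## Partition statistics

A ddPCR reaction distributes template molecules into roughly 16,000
droplets of volume $V_d$. Under random (Poisson) partitioning, a droplet is
template-free with probability $e^{-\lambda}$, where $\lambda$ is the mean
copies per droplet, so with $k$ positive droplets out of $n$,

$$\hat\lambda = -\ln(1 - k/n), \qquad
  \hat c = \hat\lambda / V_d \;\; \text{copies/µL}.$$

We take $V_d = 0.85$ nL, the nominal QX200 partition volume, as an
overridable constant; instruments do not report it per run, and the value
only rescales concentrations, never calls.

The 95% "Poisson" interval is the exact Clopper–Pearson binomial interval
on $p = k/n$ pushed through the monotone map $p \mapsto -\ln(1-p)/V_d$.
We chose the exact interval rather than a normal approximation because MRD
calls hinge on $k \in \{0,\dots,5\}$, exactly where Wald-type intervals
fail. A saturated well ($k = n$) is flagged and never silently estimated.

Replicate wells (triplicates in the standard layout) are merged by pooling
droplet counts. The reported *total error* interval for a merged estimate
is the wider of (a) the pooled Poisson interval and (b) a
$t$-interval, $\bar c \pm t_{0.975,\,m-1}\, s/\sqrt{m}$, over the $m$
per-well concentrations. The wider-of rule means inter-well variability
(pipetting, droplet-count differences) can only widen, never narrow, the
claimed uncertainty; with identical replicates the Poisson interval wins by
construction. In simulation (50 triplicates at 2 copies/µL) empirical
coverage of this interval is at or above the nominal 95%.

## From reaction to biofluid

Copies per mL of biofluid are computed as

$$\text{copies/mL} = \frac{\hat c \times V_\text{reaction} \times
  n_\text{wells}}{f_\text{input} \times V_\text{biofluid}},$$

with $V_\text{reaction} = 22$ µL per well and
$f_\text{input} = 33/40$: three 11-µL wells analyse 33 of the 40 µL of
extraction eluate, so detected copies are scaled by $40/33$ before
division by the biopsy volume. CI endpoints are transformed identically.
A sample without a recorded biofluid volume keeps its per-reaction
estimates but suppresses all per-mL outputs.

Total cfDNA is expressed in haploid genome equivalents (hGE): in
reference-gene mode the copies/mL of a copy-number-neutral reference locus
(one locus per haploid genome, *ABCC9* in the standard assay set) directly
equal hGE/mL; in SNV mode wild-type (HEX) and mutant (FAM) copies of the
SNV locus are summed. Mass conversions use a single constant,
**3.3 pg per hGE**. All arithmetic is at full precision; display rounding
(integer hGE; integer pg below 1000 pg, otherwise ng to one decimal) is
applied only by `display_hge()` / `display_mass_pg()`. One published
worked value (18 hGE/mL described as 50 pg/mL) is inconsistent with any
fixed pg-per-hGE constant near 3.3 (which gives 59.4 pg/mL); we flag it
here and do not reproduce it. Likewise, the conversion of per-well
false-positive rates to events per mL of plasma depends on extraction
volumes that are not fully determined, so `fpr_per_ml()` requires the
volume explicitly rather than hard-coding a factor.

## Gates and classification

Manual 2D threshold-setting on instrument software is replaced by
reproducible rectangular gates derived from the control wells on each
plate: negative-control (NC) gDNA wells define the FAM negative cluster,
positive-control (PC) gDNA wells define the target bands (found by
deterministic, quantile-seeded 1-D k-means), and the HEX reference band is
read from both. The FAM threshold is placed at
$\max(\mu_{NC} + 7\sigma_{NC},\ (\mu_{NC} + b_1)/2)$ where $b_1$ is the
lowest PC band median — the 7-SD floor keeps the threshold clear of the
negative cluster's tail, the midpoint keeps it sensible when the negative
cluster is extremely tight — and derivation fails loudly ("inseparable
assay") if the floor reaches the lowest band. Boundaries between bands
fall at band-median midpoints; amplitude multiplexing therefore requires
pairwise-resolvable bands, and PC wells showing fewer clusters than panel
targets are reported as an unresolvable multiplex rather than gated
arbitrarily (assays with overlapping FAM bands are discarded in practice,
and that is the behaviour the error encodes).

Gate intervals are half-open $[low, high)$ and an amplitude exactly at the
FAM threshold is negative — a fixed tie-break replacing manual review.
Droplets above threshold but inside no gate (rain, off-band events) are
counted as *unassigned*: excluded from positives but never dropped, so
class counts always sum to the droplet total. Classification is
deterministic and order-independent given (well, gates).

## Decision rules

Per-assay false-positive rates (FPR, events/well) are the total
target-band events across the 12 NC cfDNA wells run on every plate,
divided by 12; the exact rational is kept and displayed to two decimals.

A target call follows a fixed cascade on the merged sample estimate
versus the merged 12-well NC cfDNA estimate from the same plate:

1. fewer than 3 merged FAM droplets → **negative**;
2. sample CI lower bound strictly above the NC CI upper bound
   (non-overlapping error bars, on the copies/µL scale) → **positive**;
3. otherwise, assay FPR exactly zero → **trace positive**;
4. otherwise → **negative**.

Testing CI separation before the zero-FPR rule means unambiguous
positives are never downgraded to trace. Whether an overlapping-CI,
zero-FPR borderline arises at a given droplet count depends on the
accepted-droplet totals on both sides: with equal droplets per well, a
12-well clean NC bound is tight enough that a 4-droplet triplicate sample
separates, while lower NC droplet totals (or fewer NC wells) widen the NC
bound and produce the trace call — the regime the borderline rule exists
for. A sample is MRD positive if any target is positive, trace positive
if any is trace (and none positive), otherwise negative. Plate QC flags
any target-gate droplet in an NTC well.

The limit of detection of an assay is read from a ten-fold dilution
series of tumor gDNA in normal gDNA at constant 10 ng total input
($10^{-1}$–$10^{-4}$, i.e. 1000 → 1 pg tumor DNA, about 303 → 0.3 tumor
hGE): the LoD is the smallest mass whose call, and every larger mass's
call, is positive. One well per dilution step is the default (replicates
configurable); a non-monotone call pattern is flagged rather than
silently interpolated.

## Target selection

The somatic filter chains operate on flat variant-record tables parsed
from VCF (via `vcfR`). SNV/indels are retained iff
`PASS ∧ alt_count ≥ 5 ∧ (MAX_AF ≤ 0.001 ∨ absent) ∧ (CADD ≥ 20 ∨ absent)
∧ IMPACT ∈ {HIGH, MODERATE}`; SVs iff
`PASS ∧ PR ≥ 5 ∧ SR ≥ 5 ∧ normal support ≤ 1 ∧ SOMATICSCORE ≥ 50`.
Absence is tolerated exactly where the rules say so (population frequency
and CADD may be missing for novel variants); a record missing a required
annotation is rejected with reason `"unannotated"`, never crashed on.
All boundaries are inclusive per the "≥"/"≤" semantics above, and every
rejection carries a reason.

Prioritization ranks survivors by gene-list tier — recurrently-altered-
in-medulloblastoma genes first, then cancer-census genes, then the rest —
and within a tier by read support (alternate allele count for SNVs,
$\min(PR, SR)$ for SVs). Tier strictly dominates support: a recurrent
driver with modest support is a better assay target than a heavily
supported passenger, which is one consistent reading of a weighting the
source protocols leave open. Mixed panels are preferred: when both kinds
survive, the best SNV and the best SV are always selected. Panels smaller
than the two-target minimum are emitted with an explicit under-target
flag (single-target patients occur in practice). For relapsed cases,
targets must be present at both timepoints: SNVs match exactly on
(chrom, pos, ref, alt); SV breakpoints match within a ±10 bp window —
a parameter, since breakpoint reproducibility between caller runs is
assay- and pipeline-dependent. The bundled gene lists are small editable
plain-text examples; production use should substitute the full curated
sources (e.g. the licensed cancer gene census).

## The synthetic-data generator

Raw droplet and WGS data behind this kind of study are not public, so the
package ships a generator reproducing the statistical structure the
analysis assumes, making every stage testable without downloads:

* **Partitioning.** Each droplet is positive for each template
  independently with $p = 1 - e^{-cV_d}$ — the exact model the estimator
  inverts. Positive-count distributions are checked against the binomial
  law by goodness-of-fit in the test suite.
* **Amplitudes.** Gaussian clusters: a negative cluster per channel, one
  FAM band per target, one HEX reference band. Instruments report
  arbitrary units and no public amplitude scale exists, so the defaults
  (negative FAM 1000 ± 100, bands from 4000 upward, HEX reference
  4500 ± 150) are explicit synthetic conventions, constrained to ≥ 5 SD
  separation so rectangular gates resolve them.
* **Artifacts.** A `Poisson(fp_rate)` number of template-negative
  droplets per well is relabelled into a random target band (false
  positives); a configurable fraction of positive droplets gets a FAM
  amplitude uniform between the negative mean and its band mean (rain).
* **Controls and designs.** Triplicate wells, 12-well NC cfDNA plates,
  and 10-ng dilution series at $10^{-1}$–$10^{-4}$ tumor fraction with
  the reference assay seeing the full input mass.
* **Variant calls.** Annotated SNV and SV VCFs in the dialects the filter
  chains consume, with a truth table recording which records were built
  to pass — the oracle for the filter tests.

Defaults of 16,000 accepted droplets per well and 0.85 nL droplets are
instrument-typical; both are configurable. Randomness follows one
integer seed per plate with per-well streams derived deterministically,
so identical seeds reproduce byte-identical droplet tables and pipeline
outputs.

What the generator does **not** emulate: amplitude drift and cluster
skew, droplet-size variation, probe cross-talk, PCR inhibition,
fragmentation-dependent amplifiability of cfDNA, and sequence-context
error processes. Passing tests therefore demonstrate that the
*statistical machinery* is correct under the model's assumptions — not
that a wet-lab assay will achieve these error rates on real biofluid.

## Validation problem sizes

The packaged checks run the pipeline at sizes chosen to keep the full
suite fast while leaving sampling error far below the tested margins:
dilution-series detection rates use 200 seeded series (one 16,000-droplet
well per step plus a triplicate NC per seed); estimator bias uses 200
wells at each of $\lambda \in \{0.001, 0.01, 0.1, 1\}$; interval coverage
uses 50 triplicates; the filter oracle uses 500 SNV and 200 SV records at
30% truth prevalence. Under these conditions the 100 pg (≈30 hGE)
dilution step is called positive in ≈100% of series and the 10 pg
(≈3 hGE) step in only a few percent — reproducing the qualitative gap
between universal detection at 100 pg and occasional detection at 10 pg —
and the worst median relative bias of the concentration estimator stays
below 2%.

## Known limitations

* Gate derivation assumes well-separated Gaussian clusters; it refuses,
  rather than attempts, gating of overlapping multiplexes or real
  instrument exports with heavy rain.
* The trace-positive rule is sensitive to accepted-droplet totals through
  the CI-overlap test, as discussed above; reporting both CIs with every
  call makes that dependence auditable.
* Cohort-level detection rates reported for real patients depend on
  non-public clinical data and are deliberately out of scope; the package
  validates machinery, not clinical performance.
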