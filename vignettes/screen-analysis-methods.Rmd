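---
title: "Analyzing in vivo pooled CRISPR knockout screens for metastasis suppressors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing in vivo pooled CRISPR knockout screens for metastasis suppressors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprmet)
```

## The scientific problem

A pooled in vivo knockout screen for metastasis suppressors works by loss of
function: tumor cells are infected at low multiplicity with a genome-wide
sgRNA library (GeCKO-style, several guides per gene), selected, and implanted
orthotopically into mice. Cells whose knocked-out gene normally restrains
dissemination seed distant organs at elevated rates; sequencing the sgRNA
cassette from primary tumors, recurrent tumors, blood, and metastatic lesions
in each organ reads out which knockouts traveled. Because implantation and
organ seeding are severe population bottlenecks, the analysis is not a
differential-abundance problem but a *detection* problem: which guides are
present, where, and how ubiquitously.

`crisprmet` implements that analysis as composable stages:

1. **Quantification** (`quantify_fastq`): each read is assigned to at most
   one sgRNA by the spacer-length k-mer at a fixed offset — exact match
   first, then (optionally) a unique Hamming-distance-1 rescue. Ambiguous
   reads are counted as unassigned, never split, so assigned + unassigned
   equals the read count by construction.
2. **Enrichment filtering** (`call_presence`): a gene is *present* in a
   sample when at least `m` of its sgRNAs reach `tau` reads (defaults
   `tau = 10`, `m = 1`). This hard cut, with no depth normalization, is the
   screen's enrichment criterion; `m` is exposed for stringency studies.
3. **Set analysis** (`compartment_sets`, `organ_ubiquity`): compartment gene
   sets are unions over that compartment's samples; the shared set is the
   intersection across compartments (preimplant excluded by default, since
   it is the reference the post-implantation compartments are compared
   against); per-organ sets pool metastasis samples across mice, and a
   gene's ubiquity `k` counts the organs containing it, with `k` equal to
   the number of observed organs defining a pan-organ hit.
4. **Prioritization** (`rank_by_frequency`, `call_hits`): genes are ranked
   by the number of qualifying samples (recurrent, blood, metastasis) in
   which they are present, with ties broken by summed passing reads and then
   alphabetically so the order is a reproducible total order.
5. **Human catalog** (`candidate_catalog`): in an expression/survival
   cohort, a gene is a candidate suppressor when (i) its tumor mean is below
   its normal mean with a two-tailed t test `P < 0.05`, and (ii) splitting
   tumor subjects at the gene's median expression, the low arm shows a
   significant excess of observed deaths by the log-rank test. Candidates
   are exactly the intersection of the two gene sets.

## Design choices where the procedure was open

**Read structure.** Published screen workflows rarely pin down read
architecture; we use a fixed-offset k-mer extraction with a configurable
offset, which is deterministic and exactly matched by the simulator's read
synthesis. Vector trimming, UMIs, and quality filtering are out of scope.

**Gene presence unit.** The filter operates on sgRNA counts but results are
reported per gene; we call a gene present when at least `m = 1` of its
guides passes. Raising `m` is a stringency knob, and the monotonicity
property (raising `tau` or `m` never adds a call, never enlarges a derived
set) is enforced by tests.

**Union vs per-mouse concordance.** Organ sets pool metastasis samples
across mice. Requiring per-mouse concordance would confound mouse-to-mouse
bottleneck variance with biology; pooling matches the Venn-style set logic
the compartment analysis uses.

**Expression test.** The pooled-variance Student's t is the default for the
low-expression criterion, with Welch available by flag. No multiple-testing
correction is applied to the selection itself — the double raw-`P` filter is
the procedure being modeled — but Benjamini–Hochberg q-values are annotated
in the output table for reference.

**Survival cut.** "Relatively high expression" is read as a per-gene median
split, ties and the median going to the low arm (so the low arm is never the
smaller one). A significant log-rank result with the *high* arm worse is
excluded by the direction flag: the criterion is poor outcome when
expression is low.

**Homolog mapping.** The default mouse-to-human rule uppercases the symbol
(`Atp11b` → `ATP11B`); a user table overrides it, and unmapped symbols are
reported rather than dropped.

## The screen simulator

`simulate_screen()` generates the whole experiment with planted ground
truth, so recovery is measurable. Stages, each independently seeded from the
master seed:

1. Founder sgRNA abundances are log-normal (`sigma = 0.5`), with each guide
   independently lost with probability `dropout_frac = 0.05`, summarizing
   low-MOI infection (MOI 0.1) and 7-day selection losses.
2. Implantation is a multinomial bottleneck of `cells_implanted = 1e5` cells
   per mouse.
3. The primary tumor expands neutrally; the recurrent tumor is a second
   multinomial bottleneck of the primary.
4. Dissemination: for each mouse, organ, and guide, seeded clones are
   Poisson with mean (expanded clone size) × `p0` × `h(gene, organ)`, where
   `p0 = 1e-6` is the per-cell baseline seeding probability and `h = 100`
   for planted suppressors (all organs for pan-organ suppressors, one organ
   for organ-specific ones). Each seeded clone expands by an independent
   log-normal factor (`clone_sigma = 1`), making lesions oligoclonal.
5. Blood is a 90/10 mixture of primary tumor and pooled disseminating
   clones.
6. Sequencing is Dirichlet-multinomial at `reads_per_sample = 1e6` with
   concentration `alpha_od = 100` (moderate overdispersion). Every
   mouse×organ metastasis sample is emitted; organs that received no clone
   yield all-zero columns.

The neutral `expansion = 150` factor between implantation and dissemination
sets the scale of the Poisson seeding rates. It was chosen from a design
target, not fitted: with ~17 cells per guide after the bottleneck, it gives
a background per-gene colonization probability of roughly 1.5% per
mouse-organ — metastatic inefficiency, under which non-planted genes almost
never appear in all five organs across 8 mice — while `h = 100` suppressors
colonize each organ with near certainty. In vivo bottleneck sizes are
unknown; these defaults are plausibility choices, and all of them are config
fields.

What the simulator does *not* emulate: spatial tumor structure, immune
interactions, guide-efficiency heterogeneity, PCR jackpotting beyond the
Dirichlet-multinomial, or sequencing error in the spacer itself. Passing
recovery tests therefore show the *pipeline logic* is sound under a
plausible noise model, not that real screens of this design will achieve the
same operating characteristics.

## The cohort simulator

`simulate_cohort()` plants `n_planted = 50` of 500 genes in a cohort of 200
tumor and 100 normal subjects. Expression is standard normal per gene on the
log scale; planted genes are shifted down by `delta = 1.5` SD in tumors.
Survival times are exponential with hazard `lambda * hr^z` (`lambda = 0.1`,
`hr = 3`), where `z = 1` for tumor subjects in the low median-split arm of
the planted-gene mean expression; censoring thins 30% of subjects to a
uniform fraction of their event time.

One modeling point deserves emphasis. If the 50 planted genes were mutually
independent, any *single* gene's median split would agree with the
hazard-driving arm only at chance plus O(1/sqrt(50)), and per-gene log-rank
power would be near zero regardless of `hr` — a cohort in which every
suppressor is survival-relevant *jointly* but none is *marginally*
detectable. Real tumor suppressors in one program are co-regulated, so the
simulator gives planted genes a shared latent "aggressiveness" factor with
loading `rho = 0.8`: each planted gene then correlates ~0.8 with the
hazard-driving burden, its median split agrees with the true arm ~80% of the
time, and the marginal per-gene hazard ratio is about `hr^0.6 ≈ 1.9`, which
~140 observed events detect with power ≈ 0.95. `rho` is the knob that
interpolates between "undetectable by design" (`rho = 0`) and "every gene a
perfect proxy" (`rho = 1`).

## Numerical and degenerate-input conventions

- Ties: the median itself goes to the low arm; rank ties break by read sum
  then symbol; a read at Hamming distance 1 from two guides is unassigned.
- Zero variance in both groups with equal means gives `t = 0, p = 1`; with
  unequal means it is an error. Genes flat across the whole cohort are
  skipped and listed, not silently dropped.
- A cohort with no observed deaths is an error, as is a sheet with no
  metastasis samples when organ analysis is requested.
- All simulators are exactly reproducible from the master seed, and the
  pipeline manifest records parameter values plus MD5 checksums of every
  input and output, so identical config + seed implies identical checksums.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run the
simulators at the default desk scale (1000 genes × 6 guides, 8 mice,
1e6 reads/sample; 500-gene cohort), with 10–20 independent seeds for the
recovery tables. These sizes give stable recovery estimates (binomial SE on
a recall from 20 runs ≈ 0.05) while keeping any single script in the tens of
seconds on a laptop; all of them scale up by config alone.

## Known limitations

- The fixed-offset spacer extraction will undercount if real reads have
  variable-length vector sequence; use the offset that matches the library
  prep, or pre-trim.
- The hard read-count cut makes presence calls depth-sensitive; samples
  sequenced much deeper than others will call more genes. Depth
  normalization is deliberately out of scope because the filter being
  modeled is an absolute cut.
- The catalog applies no multiple-testing correction by design; its
  false-positive behavior is therefore governed by the double filter's joint
  null rate (~alpha^2/4 under independence), not by any FDR guarantee.
- The log-rank direction flag uses total observed-vs-expected events, which
  can mask crossing hazards; crossing-hazard survival patterns are outside
  the model.
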