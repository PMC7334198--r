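---
title: "Transcript expression-aware annotation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript expression-aware annotation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pextr)
library(data.table)
```

## The model

A gene's transcriptional output in a tissue is the sum of the expression
of its transcripts. A variant does not affect that output uniformly: its
consequence differs between transcripts (a stop codon in an exon skipped
by the dominant isoform is harmless to it), and transcripts differ in
abundance. The pext metric combines the two. Writing $m_{x,t}$ for the
median TPM of transcript $x$ in tissue $t$, and $A(v,a)$ for the set of
protein-coding transcripts on which variant $v$ has worst consequence
class $a$,

$$\mathrm{ext}(v,a,t) = \sum_{x \in A(v,a)} m_{x,t}, \qquad
  \mathrm{pext}(v,a,t) = \frac{\mathrm{ext}(v,a,t)}
  {\sum_{x \in \mathrm{gene}(v)} m_{x,t}}.$$

The denominator runs over **all** transcripts of the gene, coding and
non-coding: when a quantifier assigns most of a gene's expression to a
non-coding isoform, the coding share genuinely is small, and the
denominator must reflect it (this is also what makes the gene-level QC
filter below necessary). The numerator's class $a$ is the worst
consequence per transcript under the VEP severity ordering, combined with
the LOFTEE filter and flags when those annotations are present, so that
e.g. high- and low-confidence stop-gains on different transcripts form
separate classes.

Where the denominator is zero the value is undefined and reported NA —
unevaluable, not unexpressed. Cross-tissue summaries (the default is the
arithmetic mean, with maximum-across-tissues as an alternative for
any-tissue interpretation goals) drop NA tissues, and a record whose
summary is NA is never silently filtered: it is carried through with an
NA bin and a warning.

## Assumptions and inputs

The metric inherits the assumptions of isoform quantification: TPMs are
relative within a sample, short-read quantifiers resolve isoforms
imperfectly, and transcript models are taken at face value. Medians
across the samples of a tissue (midpoint convention for even counts)
damp per-sample noise; zero-TPM transcripts are kept so denominators and
NA semantics are exact; transcript version suffixes are stripped before
joining quantifications to gene models because releases disagree on
versions. Expression is never renormalized after tissue subsetting.

Tissue selection follows the convention for GTEx-style panels:
reproductive tissues and derived cell lines are excluded by name, and
tissues with fewer than 100 samples are dropped; on the 53 GTEx v7
labels this retains 38 tissues. Both the exclusion list and the minimum
are configuration (`run_config()`), as is the tissue subset used for the
cross-tissue mean — brain-only means are the natural choice for
neurodevelopmental analyses, and the subset is explicit configuration
precisely because "brain" can reasonably mean different tissue sets.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| bin boundaries | 0.1, 0.9 | mean pext < 0.1 is "low" (filtering candidate), > 0.9 "high" (near-constitutive); both boundaries belong to "medium" |
| gene QC threshold | 0.2 | a gene is excluded when its maximum attainable coding pext is *strictly below* 0.2; equality retains |
| minimum samples/tissue | 100 | tissues with fewer samples give unstable medians |
| severity order | packaged VEP table | editable two-column TSV (`term`, `rank`) |

The gene QC filter computes, per gene, the maximum over tissues and
coding-footprint bases of the coding-transcript base-level pext. This is
the upper envelope of any coding variant's summed class pext, so it
equals the maximum over all possible coding SNVs without enumerating
them. Genes with no protein-coding transcript are unevaluable and
excluded by construction, with a distinct reason code.

## Base-level tracks

For browser-style display the per-base value in a tissue is the summed
median TPM of the transcripts whose **exons** contain the base, over the
gene total. Exon (not CDS) membership is used because the track covers
transcribed sequence; the gene QC filter, by contrast, restricts both
transcripts and footprint to coding sequence, since it guards coding
variant interpretation. bedGraph export converts the 1-based closed
per-base records to 0-based half-open intervals with equal-value runs
merged.

## The built-in classifier

Real analyses consume VEP CSQ annotations; the built-in classifier
exists so fixtures are self-contained, and is deliberately minimal:
stop/missense/synonymous by codon translation, the canonical 2-bp
splice donor/acceptor windows, frameshift versus in-frame by indel
length, splice-region at 3 exonic / 3–8 intronic bases, intron, and a
non-coding exon fallback. No UTR terms, no stop/start-loss, no MNVs.
Where an exonic base is both coding and within the splice region, the
coding call wins (the classifier returns one term per transcript;
worst-consequence reduction across *multiple* terms only arises for CSQ
input, where VEP supplies the full term list). Tests verify the
classifier against a full-translation oracle on every possible SNV of a
fixture CDS and against reverse-complemented gene copies.

## Validation statistics

**Exact Poisson rate ratio.** For counts $x_1, x_2$ from cohorts of size
$n_1, n_2$, inference conditions on $x_1 + x_2$: under rate ratio $R$,
$x_1$ is binomial with success probability $n_1 R/(n_1 R + n_2)$. The
two-sided p doubles the smaller binomial tail (capped at 1) — a
reproducible convention chosen over the minimum-likelihood alternative —
and the 95% interval inverts the Clopper–Pearson interval of the
conditional proportion. Exact intervals are conservative: simulated
coverage of a true ratio sits at or a little above the nominal 95%.
When $x_2 = 0$ the estimate and the upper bound are reported as
infinite rather than truncated.

**MAPS.** The proportion of a class's variants seen exactly once
(singletons) reflects selection and mutation rate. A neutral
calibration class (synonymous by default) is aggregated per mutational
context, and proportion singleton is regressed on the context mutation
rate by weighted least squares (weights = site counts). The
weighted-residual identity makes the calibration class's MAPS exactly
zero, which the tests assert to 1e-12 — and is why predictions are not
clamped to [0, 1]. Each class's MAPS is observed minus predicted
proportion singleton; the interval uses the binomial standard error of
the observed proportion, which is accurate when the calibration class
dwarfs the test classes (as synonymous variants do in population data)
and understates uncertainty otherwise. A constant-mutability
calibration cannot support a slope and falls back to a constant
expectation with a warning. MAPS is relative: comparable within a
dataset, meaningless across datasets.

**Conservation versus expression.** Regions are classed highly conserved
(phyloCSF > 1000) or unconserved (< −100); expression bins are
cross-tabulated against status and a logistic regression of conservation
on mean pext adjusts for region length, which influences both phyloCSF
scores and quantification. Complete separation is detected both from the
glm warning and from degenerate fitted probabilities, and flagged rather
than silently reported.

**Fisher comparisons** of filtered proportions report the sample
(cross-product) odds ratio — matching how proportions are usually
quoted — alongside the exact two-sided p from `stats::fisher.test`;
zero margins yield an infinite or zero odds ratio with the p still
defined.

## What the synthetic data emulates — and what it does not

The generator builds genes with a shared first exon, one isoform-unique
middle exon per coding isoform and a shared terminal exon; every exon
length is a multiple of three so codon boundaries align with exon
boundaries in every isoform, making engineered stop-gains exact. Strands
alternate. Tissue-specific isoform usage is drawn from gamma weights;
designated QC-fail genes hand 85–95% of their output to a non-coding
isoform; one gene is unexpressed in one tissue to exercise NA semantics.
Per-sample TPMs multiply the noiseless profile by log-normal noise
(median 1, so sample medians converge on the profile — the reason this
noise model was chosen). Every engineered variant's affected-transcript
set is known **by construction**, so its expected pext is computed
analytically, independent of the classifier under test.

Passing tests on these fixtures show the arithmetic is right, not that
real data are this clean: real genes have overlapping paralogs,
quantifier-specific isoform assignment errors, 3′ bias residuals and
transcript-model errors, none of which are modelled. Fixture sizes used
by the tests and the acceptance script (3–10 genes, 4 tissues, 30
samples per tissue, noise σ = 0.2; 100 random single-gene fixtures for
the oracle comparison; 200–1000 replicates for the statistical
calibration checks) were chosen as the smallest scales at which the
checks are sharp.

## Numerical choices and degenerate inputs

Sums and divisions are double precision; test comparisons use 1e-9
absolute tolerance. Outputs are sorted by (chromosome, position, ref,
alt, class severity rank) so runs are byte-reproducible. Empty variant
sets produce empty outputs and success; unknown transcripts in strict
mode fail with the offending identifier, or are treated as unexpressed
with a warning when requested; a transcript quantified in only some
samples counts as zero TPM in the others, keeping medians over the full
tissue sample count.

## Known limitations

Per-tissue medians hide within-tissue (cell-type) heterogeneity; the
metric is only as good as the isoform quantification and transcript
models behind it; intermediate (medium-bin) values resist
interpretation; the CSQ parser handles the VEP-minimal allele
representation for simple indels but not complex rearrangements; and the
built-in classifier must not be used as a VEP substitute on real data.
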