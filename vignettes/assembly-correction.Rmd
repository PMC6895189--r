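---
title: "Pileup-driven assembly correction: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pileup-driven assembly correction: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqbug)
library(data.table)
```

## The problem and the model

Draft genome assemblies carry single-nucleotide errors introduced by read
error correction and by the assembler itself. When the reads that produced
the assembly are mapped back to it, a true assembly error shows up as a
position where almost all reads disagree with the assembled base. seqbug
formalises this as a per-position decision over quality-filtered allele
counts (mapping quality >= 25, base quality >= 25, applied upstream by the
readcount step):

* a position is **eligible** when its depth lies in `[min_cov, max_cov]`
  (default 10-200x) and at most `max_indel_fraction` (default 10%) of its
  reads support an insertion or deletion. The coverage floor removes sites
  where the majority base is poorly supported; the ceiling and the indel
  filter remove collapsed repeats and misalignment around indels, which
  produce spurious disagreement.
* among eligible positions, let `max_base` be the most frequent base over
  A/C/G/T and `ref_base` the assembled base. The assembled base is declared
  an error and replaced by `max_base` when
  `ref_count * ratio_denominator <= max_count` (default denominator 5 --
  the "one-fifth rule", inclusive at the boundary). The comparison is done
  by integer cross-multiplication, so there is no floating-point boundary
  artifact: counts {A:50, C(ref):10} correct, {A:50, C(ref):11} do not.

The rule is deliberately stringent: it corrects only where the replacement
allele outweighs the assembled base at least fivefold, trading sensitivity
for a very low false-correction rate. Heterozygous sites in the sequenced
individual sit near 50/50 and are far from firing the rule.

Corrections are then projected through CDS gene models (Ensembl-dialect
GTF) into codons, classified as synonymous / nonsynonymous / stop_gain /
stop_loss / start_loss under the standard nuclear genetic code, and can be
cross-validated against an independent individual's pileup: a corrected
site is *validated* when that individual's unique most-frequent base equals
the corrected base.

Finally, the error load itself has a dating consequence: with a clock rate
of $\mu$ substitutions/base/year, $E$ erroneous bases in a genome of $G$
bases shift an estimated divergence time by $(E/G)/\mu$ years. At the
felid-scale numbers (roughly $10^6$ errors in a 2.44 Gb genome at
$\mu = 1.1\times10^{-9}$) this is of order 0.4 Myr -- not negligible for
recent divergences.

## Tunable parameters

| parameter | default | unit | why this value |
|---|---|---|---|
| `min_cov` | 10 | reads | below this the "majority" is too noisy to trust |
| `max_cov` | 200 | reads | high-coverage sites are usually collapsed repeats |
| `max_indel_fraction` | 0.10 | fraction | indel-adjacent misalignment mimics substitutions |
| `ratio_denominator` | 5 | -- | replacement must be >= 5x better supported than the assembled base |
| `correct_N_reference` | FALSE | -- | replacing assembly N is gap filling, a different problem |
| validation `min_cov` | 10 | reads | reused from correction for symmetry; both the strict and inclusive rates are reported |
| `gap_flank` | 5 | alignment columns | alignment quality degrades near gaps; +-5 columns around any gap column are ignored |
| MSA `threshold` | 3 | signals | "multiple signs" = at least 3 of the 5 signals |

All thresholds are flags on the CLI (`seqbug correct --min-cov 10
--max-cov 200 --max-indel 0.10 --ratio 5 ...`) and every run serialises its
resolved parameters into a JSON manifest, so a published run can be
reproduced even though the thresholds are tunable.

## What the simulator emulates -- and what it does not

`simulate_truth()` / `simulate_pileup()` generate the full test world: a
random genome (default 100 kb over 2 scaffolds at 42% GC, a typical
mammalian value), non-overlapping multi-exon genes on both strands with
clean ORFs, 500 injected assembly errors (30% inside CDS), per-site depth
Poisson(60), 1% symmetric sequencing error, and an independent individual
carrying SNPs at 0.1% per base. These defaults are the stated test
conditions; they are not tuned per test.

The pileup is simulated **at the count level**: no reads, no mapper.
Per-site depth is Poisson; errors are multinomial over the three non-true
bases; designated indel sites (0.1% of positions) put ~25% of reads on an
indel allele so they trip the 10% filter the way real indel/repeat regions
would. This isolates the decision rule, which consumes counts -- but it
means mapping artifacts (mismapping, reference bias, soft-clip pileup,
non-uniform coverage along repeats) are *outside* what a green test
establishes. A green recovery test says: given counts distributed as
modelled, the rule recovers the injected errors. It does not certify
behaviour on real alignments, where the eligibility filters are doing the
heavy lifting against artifacts the simulator does not produce.

Two deliberate bookkeeping choices:

* error sites and inter-individual SNP sites are disjoint in the generated
  truth, so ground-truth effect classes stay unambiguous. Validation
  stress tests that need SNPs *at* corrected sites plant them explicitly
  via `simulate_pileup(..., planted_snp_sites = )`.
* injected errors avoid designated indel sites, so at default coverage
  (Poisson(60); P(depth < 10) is ~1e-15) every injected error is eligible,
  as the stated world requires. A low-coverage stress world can be built by
  lowering `coverage_mean`, which reproduces the qualitative concentration
  of corrections at low coverage.

## Numerical and policy choices

* **Tie-breaking (correction).** The rule text does not say what to do
  when two non-reference bases tie for most frequent. We refuse to correct
  (`ambiguous_tie`) rather than pick arbitrarily -- consistent with the
  stringency intent, and the case is vanishingly rare at real coverage.
  Ties that include the reference base cannot fire the rule and are `kept`.
* **Tie-breaking (validation).** A tied most-frequent base in the
  independent pileup cannot be "identical to" the corrected base under a
  strict reading, so ties count as `contradicted` by default;
  `tie_policy = "uninformative"` is available, and both denominators
  (excluding and including uninformative sites) are always reported, since
  published validation rates rarely state which one they use.
* **Sites absent from the pileup** are implicitly below the coverage floor
  (`ineligible_low_cov` for correction, `uninformative_low_cov` for
  validation).
* **Filter order** is fixed (low coverage, high coverage, indel, reference
  N) so each position carries exactly one status and reports are
  reproducible.
* **Partial CDS.** A non-zero first frame is honoured by trimming the
  leading bases before codon numbering; an internally inconsistent frame
  chain flags the transcript `partial`, excluded from codon calls, and any
  corrected site falling in it is reported `unprojectable` rather than
  silently dropped.
* **Stop/start changes** are their own effect classes; the per-gene
  "nonsynonymous" flag includes them, since a stop or start change is a
  protein-changing correction.
* **Root-to-tip "significantly higher".** No test is specified for the
  divergence ranking, so we expose raw distances plus a strict-maximum
  flag and leave formal testing to the caller. Trees whose root is a
  basal multifurcation are treated as unrooted (the `ape` convention) and
  rejected with instructions to root first.
* **Depth cap interaction.** Upstream readcount tools cap depth (commonly
  at 400); reported depth is passed through unmodified and the >200x
  filter acts on it as reported.
* **Corrected-fraction denominators.** Reports emit the corrected fraction
  against both the full genome length and the non-N length, since assembly
  N-run accounting is a perennial ambiguity in published percentages.

## A worked run

```{r pipeline}
sim <- simulate_truth(sim_config(seed = 11))
pileup <- simulate_pileup(sim, "same")
decisions <- classify_positions(pileup, correction_params())
table(decisions$status)

corrected <- correct_assembly(sim$corrupted_genome, decisions)
corrected$report$corrected
identical(corrected$sequences, sim$true_genome)

gtf <- tempfile(fileext = ".gtf"); writeLines(sim$gtf, gtf)
proj <- project_corrections(load_gtf(gtf), decisions, sim$corrupted_genome)
table(proj$codon_corrections$effect)

val <- validate_sites(decisions[status == "corrected"],
                      simulate_pileup(sim, "independent"))
val$summary$rate

round(divergence_time_bias(982606, 2.44e9, 1.1e-9) / 1e6, 2)
```

## Known limitations

* Substitution errors only: no indel correction, scaffolding or
  gap filling (`correct_N_reference` exists for experimentation but N
  replacement is off by default).
* The validation rate cannot distinguish an over-correction from a true
  inter-individual SNP at the corrected site; the contradicted fraction is
  therefore an *upper bound* on the over-correction (Type 1) rate.
* Effect classification assumes the standard nuclear genetic code and
  single-transcript-resolution GTF input; UTR/splice consequences and
  protein-impact prediction are out of scope.
* The five adaptation signals are consumed as precomputed booleans; this
  package aggregates them but does not compute dN/dS, branch-site tests or
  functional-impact predictions.
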