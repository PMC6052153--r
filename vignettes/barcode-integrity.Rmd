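---
title: "Auditing mitochondrial barcode datasets: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing mitochondrial barcode datasets: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtsweep)
```

## The problem

Mitochondrial cytochrome oxidase I (mtCOI) barcodes are routinely used to
assign specimens to putative species by comparing pairwise divergence with a
fixed threshold (3.5% here). Two well-known failure modes undermine this
practice:

1. **Corrupt sequences.** Nuclear copies of mitochondrial genes (NUMTs),
   polymerase and editing errors produce database records that are not the
   organism's mitochondrial haplotype. Because NUMTs evolve without
   protein-coding constraint, they accumulate frame-shifting INDELs, premature
   stop codons and amino-acid changes at otherwise invariant positions.
2. **Region dependence.** Divergence is not uniform along the gene. Two
   lineages can sit below the threshold in one barcode region and above it in
   another, so the species boundary inferred from a barcode depends on which
   fragment of the gene was amplified.

`numtsweep` implements a screening and analysis pipeline for both problems,
plus a codon-constrained synthetic-data generator that produces labelled
datasets for validating every stage without external downloads.

## The four-criterion pseudogene screen

Each partial haplotype is mapped semiglobally onto a conspecific full-length
reference gene (`map_partial_to_reference()`), projected into reference
coordinates, and then assessed by four criteria:

* **(i) Interior INDELs** (`screen_criterion_i()`): any insertion or deletion
  relative to the reference, excluding terminal amplicon overhangs. Events in
  homopolymer runs are left-normalised, since a single-base deletion within an
  `AA` run is only determined up to the run.
* **(ii) Premature stop codons** (`screen_criterion_ii()`): the covered
  complete codons are translated under the invertebrate mitochondrial code
  (NCBI table 5, where `TGA` encodes tryptophan); a stop anywhere before the
  reference's terminal codon is flagged.
* **(iii) Anomalous polymorphisms** (`screen_criterion_iii()`): three
  sub-tests, any of which flags the haplotype — a dense terminal cluster of
  non-synonymous substitutions, whole-sequence divergence from the group
  consensus at or above a cut-off, or higher identity to a supplied *decoy*
  sequence (another species, a chloroplast gene, ...) than to the group
  consensus. The decoy test is the offline counterpart of "my best database
  hit is not my study organism".
* **(iv) Substitutions at conserved amino-acid sites**
  (`screen_criterion_iv()`): the translation is compared column-wise with a
  panel of reference proteins (`build_reference_panel()`); any difference at a
  site conserved across the whole panel is flagged. Columns where the panel
  itself varies are ignored, and translations shorter than 30 residues are
  reported "too short to assess" rather than flagged.

The criteria are **gated** the way a human analyst would apply them: the
amino-acid level analyses (ii and iv) are only run on INDEL-free haplotypes
(an interior gap makes the downstream translation meaningless), and (iv)
additionally requires no premature stop. A haplotype hit by several criteria
contributes to every per-criterion count but only once to the union reported
as "potential NUMTs".

### Threshold choices

The numeric thresholds in `screen_config()` are deliberately exposed
configuration, bracketing lesion scales rather than deriving from first
principles:

* `cluster_min_len = 9`, `cluster_density = 0.1`: terminal non-synonymous
  stretches from 9 bp up at roughly one substitution per 10 bp.
* `cluster_min_count = 2`: a *single* terminal substitution is never a
  "cluster". Without this guard the density test degenerates for the shortest
  windows (1 substitution in 9 bp passes 0.1/bp), which would flag authentic
  haplotypes carrying one unlucky terminal replacement.
* `outlier_pct = 4.0`: whole-sequence divergence from the group consensus at
  or above 4% is anomalous against within-group spreads well below 1.5%.
* `min_identity = 0.6`: mappings below 60% identity are declared unalignable
  (wrong locus or orientation) and reported as such instead of screened.

## Divergence analysis

All distances are Jukes–Cantor corrected p-distances,
`d = -(3/4) log(1 - (4/3) p)`, computed over **all** compared sites (silent
and replacement alike). Compared sites are alignment columns where both
residues are unambiguous bases; gaps and IUPAC ambiguity codes are excluded
pairwise (`deletion = "pairwise"`, the default) or across all sequences at
once (`"complete"`).

* `group_divergence()` is the Dxy-style between-group mean over all
  inter-group pairs, with min/max extremes.
* `sliding_window()` moves a 657 bp window (the partial-barcode length) in
  5 bp steps; windows start at 1, 6, 11, ... and the last partial window is
  discarded, so a 1,542 bp gene yields 178 windows. `autoplot()` draws the
  profile against the threshold.
* `region_matrix()` builds a percent divergence matrix over a fixed region
  such as the 3' barcode, exportable as TSV (percent) or square PHYLIP
  (per-site).

The 3' barcode region defaults to positions **783–1439** of the COI gene
(1-based inclusive), i.e. the 657 bp window ending at position 1,439 —
matching the length of the common 3' amplicon. The 5' comparison region in
the examples is simply `c(1, 657)`; both are arguments, not constants.

## Delimitation and discordance

`single_linkage_delimit()` applies the threshold rule: pairs at or **at or
above** the threshold are split, and samples chain into one cluster when
connected by pairwise divergences strictly below it (single linkage; a
complete-linkage mode is included for sensitivity analysis, requiring *every*
within-cluster pair below threshold). `discordance_report()` delimits several
region matrices at the same threshold and lists each sample pair whose
co-cluster status flips between regions — the headline signature of
region-dependent barcode delimitation.

## The synthetic generator

`simulate_dataset()` produces a fully labelled study from a seed:

* a random full-length ORF (`simulate_reference_gene()`; ATG start, TAA stop,
  no internal stops, 514 codons = 1,542 bp by default) with a planted
  conserved-codon set (60% of codons);
* a protein panel whose recovered conservation mask equals the planted set
  exactly (every non-conserved codon receives an amino-acid change in exactly
  one panel member);
* authentic haplotype groups evolved on a star phylogeny: each group ancestor
  receives `round(d_anc * L)` substitutions from the root, each haplotype
  `round(d_within / 2 * L)` more, all respecting reading frame, the genetic
  code (never creating stops) and synonymous-only changes at conserved
  codons, so authentic sequences are clean by construction;
* optional per-group rate profiles concentrating substitutions along the gene
  (e.g. `c(3, 1)` makes the 5' half evolve three times faster);
* decoys (constrained genes at 10% divergence, standing in for other
  species) and five NUMT lesion classes applied to partial haplotypes:
  `indel`, `stop`, `terminal_cluster`, `global_divergent` and
  `decoy_chimera`.

The default configuration is a three-group design: two close groups
(`Q1`, `Q2`, within 0.4%, between ~0.8–1.5%) and a third group (`ASL`) at
~2.6% ancestor divergence with a 5'-weighted rate profile. These values were
chosen, before any tests were written against them, to land the realized
divergences inside empirically plausible ranges for closely related insect
lineages — around 2–2.5% at the 3' barcode and 4–5% at the 5' end — so the 3'
barcode sits below the 3.5% species threshold while the 5' region sits above
it, with a comfortable margin over the generator's binomial site-sampling
noise at both boundaries.

What the generator deliberately does **not** emulate: substitution-model
complexity beyond Jukes–Cantor (no transition/transversion bias, no
among-site rate Gamma), recombination, heteroplasmy, or sequencing-quality
artefacts. It is a validation harness for the screen and the divergence
machinery, not a population-genetics simulator.

## Numerical conventions

* Coordinates are 1-based inclusive throughout (GenBank convention); region
  `783–1439` has length `1439 - 783 + 1 = 657`.
* A gap of length L costs `gap_open + (L - 1) * gap_extend` (defaults
  −6/−1 with +2/−1 match/mismatch).
* INDELs are left-normalised within homopolymer runs; `ref_position` is the
  reference base immediately left of the event.
* Consensus ties are broken alphabetically (A < C < G < T).
* Flagged percentages are rounded half-up to one decimal
  (`screen_percent()`).
* `d >= threshold` splits; `d < threshold` may join.
* Exact-mode haplotype collapsing treats identical sequences of different
  lengths as distinct haplotypes (replicating common collapsing tools, whose
  haplotype counts inflate when read lengths vary); `length_aware` mode
  merges substrings and is the recommended setting for heterogeneous-length
  data.

## A worked example

```{r example, eval = FALSE}
library(numtsweep)

ds <- simulate_dataset(sim_config(seed = 1))
decoys <- extract_region(ds$decoys, 783, 1439, suffix_id = FALSE)

# four-criterion screen, per-group summary
report <- screen_dataset(ds$records, ds$references,
                         panel = ds$panel, decoys = decoys)
report$summary

# region-dependent delimitation
seqs <- ds$records_full
med <- group_ids(seqs, "Q1+Q2"); asl <- group_ids(seqs, "ASL")
group_divergence(seqs, med, asl, region = c(783, 1439)) # below 3.5%
group_divergence(seqs, med, asl, region = c(1, 657))    # above 3.5%

prof <- sliding_window(seqs, list("MED vs ASL" = list(a = med, b = asl)))
autoplot(prof, threshold = 3.5)
```

The same pipeline is scriptable through `cli_main()` /
`inst/cli/numtsweep`: `simulate`, `collapse`, `screen`, `scan`, `regiondiv`
and `delimit` subcommands write deterministic report files plus a
`run_log.json` with input digests.

## Limitations

* The screen needs a conspecific (or congeneric) full-length reference per
  group; without one, mapping coordinates and translations are undefined.
* Criterion (iii)'s decoy test is only as good as the decoy set supplied; an
  empty decoy set disables it (recorded in the evidence, not silently).
* The generator's guarantees (authentic sequences never flagged by i, ii or
  iv) hold for its own lesion-free outputs; real data contain sequencing
  error that this package reports but cannot distinguish from biology.
* GenBank parsing is a minimal flat-file reader for simple
  `start..end` / `complement(start..end)` features; spliced `join(...)`
  locations are rejected rather than misparsed.
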