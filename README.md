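# numtsweep

Pseudogene screening, divergence profiling and threshold species delimitation
for mitochondrial barcode data.

## Why

Mitochondrial cytochrome oxidase I (mtCOI) barcodes are widely used to assign
specimens to putative species by comparing pairwise divergence with a fixed
threshold (3.5% in the workflows this package targets). Two things quietly
break that practice:

* **Corrupt records.** Nuclear mitochondrial pseudogenes (NUMTs) and other
  artefacts sit in public databases alongside authentic haplotypes. Freed from
  protein-coding constraint, they accumulate interior INDELs, premature stop
  codons, and amino-acid changes at otherwise invariant sites — and they
  distort haplotype counts, divergence estimates and species delimitation if
  not removed.
* **Region dependence.** Divergence is uneven along the gene. Two lineages can
  fall below the threshold over one barcode region and above it over another,
  so the inferred species boundary depends on which fragment was amplified.

`numtsweep` provides:

1. a **four-criterion pseudogene screen** for partial mtCOI haplotypes —
   (i) interior INDELs, (ii) premature stops under the invertebrate
   mitochondrial code, (iii) anomalous polymorphisms (terminal non-synonymous
   clusters, consensus outliers, decoy-identity), (iv) substitutions at
   panel-conserved amino-acid sites — with the amino-acid criteria gated on
   INDEL-free (and stop-free) sequences and a per-group union summary;
2. **Jukes–Cantor divergence** analysis (`d = -(3/4) log(1 - (4/3) p)` over
   all compared sites, pairwise deletion of gaps/ambiguities): between-group
   means, 657 bp / 5 bp-step sliding-window profiles, fixed-region matrices;
3. **3.5%-threshold delimitation** (single linkage: `d >= threshold` splits,
   chains below it join) with a cross-region **discordance report**;
4. sequence utilities: FASTA and minimal GenBank flat-file ingest,
   strand-aware gene extraction, haplotype collapsing (exact and
   length-aware), multigene concatenation of annotated mitogenomes;
5. a **codon-constrained synthetic generator** producing labelled haplotype
   groups, rate heterogeneity along the gene, a conserved-site protein panel,
   decoys and five NUMT lesion classes — so the whole pipeline is testable
   offline;
6. a scriptable CLI (`inst/cli/numtsweep`, or `cli_main()` in-process) with
   `simulate`, `collapse`, `screen`, `scan`, `regiondiv` and `delimit`
   subcommands writing deterministic reports.

Everything is tidyverse-native: sequence sets are tibbles (`id`, `group`,
`seq`), results are tibbles or carry `tidy()`/`glance()` methods, and profiles
and matrices have `autoplot()` methods.

## Worked example

```r
library(numtsweep)

# a labelled synthetic study: 40 authentic haplotypes in 3 groups (Q1, Q2,
# ASL), 45 NUMT-like corruptions of Q1 partials, 2 decoy species
ds <- simulate_dataset(sim_config(seed = 1))
decoys <- extract_region(ds$decoys, 783, 1439, suffix_id = FALSE)

report <- screen_dataset(ds$records, ds$references,
                         panel = ds$panel, decoys = decoys)
report$summary
#> # A tibble: 3 × 8
#>   group total n_indel n_stop n_polymorphism n_aa_change n_flagged pct_flagged
#>   <chr> <int>   <int>  <int>          <int>       <int>     <int>       <dbl>
#> 1 ASL      10       0      0              0           0         0         0
#> 2 Q1       65      10     10             25          20        45        69.2
#> 3 Q2       10       0      0              0           0         0         0
```

All 45 planted NUMTs are flagged, no authentic haplotype is (the 65 Q1
records are 20 authentic + 45 NUMTs). The same dataset shows the
region-dependent delimitation signature:

```r
seqs <- ds$records_full
med <- group_ids(seqs, "Q1+Q2")
asl <- group_ids(seqs, "ASL")

group_divergence(seqs, med, asl, region = c(783, 1439))  # 3' barcode
#>        d  d_min  d_max p_mean n_pairs
#> 1 0.0232 0.0201 0.0295 0.0228     300
group_divergence(seqs, med, asl, region = c(1, 657))     # 5' barcode
#>        d  d_min  d_max p_mean n_pairs
#> 1 0.0471 0.0391 0.0536 0.0457     300
```

2.3% at the 3' barcode (joined at a 3.5% threshold) versus 4.7% at the 5'
end (split): a single species pair delimits differently depending on the
region sequenced. `sliding_window()` + `autoplot()` draw the full profile,
and `discordance_report()` lists the flipping pairs:

```r
prof <- sliding_window(seqs, list("MED vs ASL" = list(a = med, b = asl)))
autoplot(prof, threshold = 3.5)

m3 <- region_matrix(seqs[c(1, 31), ], region = c(783, 1439))
round(unclass(m3), 2)
#>         Q1_h01 ASL_h01
#> Q1_h01    0.00    2.16
#> ASL_h01   2.16    0.00
```

Small pieces work standalone:

```r
jc_distance("ACGTACGTAC", "ACGTACGTCC")
#>       p     d sites
#> 1   0.1 0.107    10
```

## Command line

```sh
numtsweep simulate  --seed 1 --out fixture/
numtsweep collapse  --fasta fixture/records.fasta --mode length_aware --out haps/
numtsweep screen    --fasta fixture/records.fasta --reference fixture/reference.fasta \
                    --panel fixture/panel.fasta --decoys fixture/decoys.fasta --out screen/
numtsweep scan      --fasta fixture/records_full.fasta --comparisons "Q1+Q2:ASL,Q1:Q2" --out scan/
numtsweep regiondiv --fasta fixture/records_full.fasta --region 783-1439 --out div3/
numtsweep delimit   --matrices "barcode3=div3/matrix.tsv,barcode5=div5/matrix.tsv" --out delim/
```

Exit codes: 0 success, 1 analysis error, 2 usage/configuration error. Report
files are deterministic; timestamps appear only in `run_log.json`.

## Documentation

See the vignette source `vignettes/barcode-integrity.Rmd` for the method
description, threshold rationale and numerical conventions.
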