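# Four-criterion pseudogene screen: reference panel, individual criteria,
# gating and per-group summaries.

# reusable reference + helpers -----------------------------------------------

screen_ref <- simulate_reference_gene(sim_config(seed = 9))
screen_barcode <- substr(screen_ref$seq, 783, 1439)
CODE5 <- Biostrings::getGeneticCode("5")

# local codon starts within the 3' barcode (frame offset 2 -> first full codon
# starts at local position 2)
barcode_codon_starts <- seq.int(2L, nchar(screen_barcode) - 2L, by = 3L)

# plant an amino-acid change in the codon at local start s: either replace the
# codon with a stop, or apply exactly one nucleotide substitution that changes
# the amino acid without creating a stop (deterministic first hit)
swap_codon_aa <- function(seq, s, to_stop = FALSE, stop_codon = "TAA") {
  old <- substr(seq, s, s + 2L)
  if (to_stop) {
    return(paste0(substr(seq, 1, s - 1L), stop_codon,
                  substr(seq, s + 3L, nchar(seq))))
  }
  codon <- strsplit(old, "", fixed = TRUE)[[1]]
  for (off in 0:2) {
    for (alt in setdiff(c("A", "C", "G", "T"), codon[off + 1L])) {
      cand <- codon
      cand[off + 1L] <- alt
      aa <- CODE5[[paste(cand, collapse = "")]]
      if (aa != "*" && aa != CODE5[[old]]) {
        return(paste0(substr(seq, 1, s + off - 1L), alt,
                      substr(seq, s + off + 1L, nchar(seq))))
      }
    }
  }
  stop("no single-base amino-acid change available for codon ", old)
}

test_that("reference panel conservation mask is exact", {
  pan <- build_reference_panel(c("MKLV", "MKLV", "MKLV"))
  expect_true(all(pan$conserved_mask))
  pan2 <- build_reference_panel(c("MKLV", "MRLV"))
  expect_equal(pan2$conserved_mask, c(TRUE, FALSE, TRUE, TRUE))
  # gaps, X and stops are never conserved
  pan3 <- build_reference_panel(c("M-XV*", "M-XV*"))
  expect_equal(pan3$conserved_mask, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_error(build_reference_panel("MKLV"), "at least 2")
  expect_error(build_reference_panel(c("MKLV", "MKL")), "equal length")
})

test_that("simulated panel recovers exactly the planted conserved set", {
  ds <- get_fixture()
  expect_equal(which(ds$panel$conserved_mask), ds$reference$conserved_codons)
  # the terminal stop column is never conserved
  expect_false(ds$panel$conserved_mask[ds$reference$gene_codons])
})

test_that("criterion i flags interior INDELs and nothing else", {
  clean <- screen_criterion_i(screen_barcode, screen_ref$seq)
  expect_false(clean$flag)
  expect_equal(nrow(clean$events), 0)
  lesioned <- paste0(substr(screen_barcode, 1, 300),
                     substr(screen_barcode, 302, 657))
  hit <- screen_criterion_i(lesioned, screen_ref$seq)
  expect_true(hit$flag)
  expect_equal(hit$events$kind, "deletion")
})

test_that("criterion ii flags TAA and TAG internal stops but not TGA (code 5)", {
  s <- barcode_codon_starts[101] # local 302, interior codon
  for (stop_codon in c("TAA", "TAG")) {
    mutant <- swap_codon_aa(screen_barcode, s, to_stop = TRUE,
                            stop_codon = stop_codon)
    proj <- screen_criterion_i(mutant, screen_ref$seq)$projection
    res <- screen_criterion_ii(proj, screen_ref$seq)
    expect_true(res$flag, info = stop_codon)
    # gene position of the planted stop: 783 + 302 - 1 = 1084 -> codon 362
    expect_true(362 %in% res$stops$codon)
    expect_true(1084 %in% res$stops$ref_position)
  }
  # TGA is tryptophan under the invertebrate mitochondrial code
  tga <- swap_codon_aa(screen_barcode, s, to_stop = TRUE, stop_codon = "TGA")
  proj <- screen_criterion_i(tga, screen_ref$seq)$projection
  expect_false(screen_criterion_ii(proj, screen_ref$seq)$flag)
})

test_that("the reference's own terminal stop codon is not 'premature'", {
  tail_partial <- substr(screen_ref$seq, 1300, 1542) # includes codon 514 (TAA)
  proj <- screen_criterion_i(tail_partial, screen_ref$seq)$projection
  expect_false(screen_criterion_ii(proj, screen_ref$seq)$flag)
})

test_that("criterion iii outlier test fires at >= 4% divergence from consensus", {
  proj_of <- function(s) screen_criterion_i(s, screen_ref$seq)$projection
  group <- replicate(5, proj_of(screen_barcode), simplify = FALSE)
  consensus <- numtsweep:::group_consensus(group, nchar(screen_ref$seq))

  # flip 31 evenly spaced sites: 31/657 = 4.7% divergence
  flip <- function(seq, positions) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    rot <- c(A = "C", C = "G", G = "T", T = "A")
    chars[positions] <- rot[chars[positions]]
    paste(chars, collapse = "")
  }
  outlier <- flip(screen_barcode, round(seq(10, 650, length.out = 31)))
  res <- screen_criterion_iii(proj_of(outlier), screen_ref$seq,
                              consensus = consensus, group_n = 6)
  expect_true(res$flag)
  ev <- res$evidence[res$evidence$test == "outlier", ]
  expect_equal(nrow(ev), 1)
  expect_match(ev$description, "4\\.7[0-9]% divergence")

  # an identical haplotype is not an outlier
  res0 <- screen_criterion_iii(proj_of(screen_barcode), screen_ref$seq,
                               consensus = consensus, group_n = 6)
  expect_false(res0$flag)

  # the outlier test is suppressed for groups of fewer than 3 haplotypes
  res2 <- screen_criterion_iii(proj_of(outlier), screen_ref$seq,
                               consensus = consensus, group_n = 2)
  expect_false(any(res2$evidence$test == "outlier"))
})

test_that("criterion iii cluster test needs a dense multi-substitution stretch", {
  # 10 amino-acid-changing substitutions in the last 87 bp
  mutant <- screen_barcode
  last29 <- utils::tail(barcode_codon_starts, 29)
  for (s in last29[1:10]) mutant <- swap_codon_aa(mutant, s)
  proj <- screen_criterion_i(mutant, screen_ref$seq)$projection
  res <- screen_criterion_iii(proj, screen_ref$seq)
  expect_true(res$flag)
  ev <- res$evidence[res$evidence$test == "cluster", ]
  expect_equal(nrow(ev), 1)
  expect_match(ev$description, "3' end")

  # a single terminal non-synonymous substitution is not a cluster
  single <- swap_codon_aa(screen_barcode, utils::tail(barcode_codon_starts, 1))
  proj1 <- screen_criterion_i(single, screen_ref$seq)$projection
  expect_false(screen_criterion_iii(proj1, screen_ref$seq)$flag)
})

test_that("criterion iii decoy test flags sequences closer to a decoy", {
  ds <- get_fixture()
  b3 <- ds$config$barcode3
  decoys_partial <- extract_region(ds$decoys, b3[1], b3[2], suffix_id = FALSE)
  proj_of <- function(s) screen_criterion_i(s, screen_ref$seq)$projection
  group <- replicate(3, proj_of(screen_barcode), simplify = FALSE)
  consensus <- numtsweep:::group_consensus(group, nchar(screen_ref$seq))

  # a decoy barcode masquerading as a haplotype: identity to itself beats the
  # ~90% identity to the group consensus
  impostor <- decoys_partial$seq[1]
  aln <- map_partial_to_reference(impostor, screen_ref$seq, min_identity = 0)
  proj <- list(aln = aln, ref_start = aln$ref_offset,
               ref_end = aln$ref_offset +
                 length(numtsweep:::project_onto_reference(aln)) - 1L,
               res = numtsweep:::project_onto_reference(aln),
               indels = call_indels(aln))
  res <- screen_criterion_iii(proj, screen_ref$seq, consensus = consensus,
                              group_n = 3, decoys = decoys_partial)
  expect_true(any(res$evidence$test == "decoy" &
                    grepl("exceeds", res$evidence$description)))
  expect_true(res$flag)

  # without decoys the test is recorded as disabled
  res0 <- screen_criterion_iii(proj_of(screen_barcode), screen_ref$seq,
                               consensus = consensus, group_n = 3)
  expect_true(any(res0$evidence$test == "decoy" &
                    grepl("disabled", res0$evidence$description)))
  expect_false(res0$flag)
})

test_that("criterion iv flags conserved-site substitutions only", {
  ds <- get_fixture()
  panel <- ds$panel
  ref <- ds$reference
  barcode <- substr(ref$seq, 783, 1439)
  # covered codons are 262..479
  conserved_in <- intersect(ref$conserved_codons, 263:478)
  variable_in <- setdiff(263:478, ref$conserved_codons)
  local_start <- function(codon) 3L * codon - 2L - 783L + 1L

  clean <- screen_criterion_i(barcode, ref$seq)$projection
  res0 <- screen_criterion_iv(clean, panel)
  expect_false(res0$flag)
  expect_equal(res0$status, "ok")

  bad <- swap_codon_aa(barcode, local_start(conserved_in[5]))
  proj <- screen_criterion_i(bad, ref$seq)$projection
  res1 <- screen_criterion_iv(proj, panel)
  expect_true(res1$flag)
  expect_equal(res1$violations$codon, conserved_in[5])

  ok <- swap_codon_aa(barcode, local_start(variable_in[5]))
  proj2 <- screen_criterion_i(ok, ref$seq)$projection
  expect_false(screen_criterion_iv(proj2, panel)$flag)
})

test_that("criterion iv reports short translations instead of flagging them", {
  ds <- get_fixture()
  stub <- substr(ds$reference$seq, 783, 842) # 60 bp -> < 30 assessable codons
  proj <- screen_criterion_i(stub, ds$reference$seq)$projection
  res <- screen_criterion_iv(proj, ds$panel)
  expect_false(res$flag)
  expect_equal(res$status, "too_short")
})

test_that("screening only the reference yields zero flags", {
  rep <- screen_dataset(seq_tbl("ref_bar", screen_barcode, group = "Q1"),
                        references = c(Q1 = screen_ref$seq))
  expect_equal(rep$summary$total, 1L)
  expect_equal(rep$summary$n_flagged, 0L)
  expect_equal(rep$summary$pct_flagged, 0)
})

test_that("gating: amino-acid criteria are withheld from INDEL carriers", {
  report <- get_fixture_screen()
  fl <- report$flags
  # flag_ii and flag_iv are NA wherever flag_i is TRUE
  carriers <- which(!is.na(fl$flag_i) & fl$flag_i)
  expect_gt(length(carriers), 0)
  expect_true(all(is.na(fl$flag_ii[carriers])))
  expect_true(all(is.na(fl$flag_iv[carriers])))
  expect_true(all(!fl$analysed_at_aa_level[carriers]))
  # flag_iv is NA wherever flag_ii is TRUE
  stoppers <- which(!is.na(fl$flag_ii) & fl$flag_ii)
  expect_true(all(is.na(fl$flag_iv[stoppers])))
})

test_that("union counts are bounded by per-criterion counts", {
  report <- get_fixture_screen()
  s <- report$summary
  per <- cbind(s$n_indel, s$n_stop, s$n_polymorphism, s$n_aa_change)
  expect_true(all(s$n_flagged <= rowSums(per)))
  expect_true(all(s$n_flagged >= apply(per, 1, max)))
  expect_true(all(s$n_flagged <= s$total))
  expect_equal(s$pct_flagged, screen_percent(s$n_flagged, s$total))
})

test_that("flagged percentages follow the published rounding convention", {
  expect_equal(screen_percent(116, 212), 54.7)
  expect_equal(screen_percent(17, 33), 51.5)
  expect_equal(screen_percent(20, 37), 54.1)
  expect_equal(screen_percent(0, 10), 0)
})

test_that("unalignable records are reported, not fatal", {
  set.seed(510)
  tb <- seq_tbl(c("good", "junk"),
                c(screen_barcode, random_dna(657)), group = "Q1")
  rep <- screen_dataset(tb, c(Q1 = screen_ref$seq))
  expect_equal(nrow(rep$flags), 2)
  junk <- rep$flags[rep$flags$id == "junk", ]
  expect_equal(junk$status, "unalignable")
  expect_true(is.na(junk$flag_i))
})

test_that("tidy and glance summarise a screen report", {
  report <- get_fixture_screen()
  expect_identical(tidy(report), report$flags)
  g <- glance(report)
  expect_equal(g$total, sum(report$summary$total))
  expect_equal(g$n_flagged, sum(report$summary$n_flagged))
})

test_that("screen reports round-trip to disk", {
  report <- get_fixture_screen()
  dir <- withr::local_tempdir()
  write_screen_report(report, dir)
  expect_true(file.exists(file.path(dir, "screen_summary.tsv")))
  expect_true(file.exists(file.path(dir, "screen_flags.tsv")))
  expect_true(file.exists(file.path(dir, "screen_evidence.tsv")))
  back <- utils::read.delim(file.path(dir, "screen_summary.tsv"))
  expect_equal(back$n_flagged, report$summary$n_flagged)
  js <- jsonlite::read_json(file.path(dir, "screen_summary.json"))
  expect_equal(js$config$outlier_pct, report$config$outlier_pct)
})
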