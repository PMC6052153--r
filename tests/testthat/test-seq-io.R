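# Sequence ingest, GenBank parsing, region/gene extraction, haplotype
# collapsing and multigene concatenation.

make_gb_record <- function(id, seq, features) {
  origin <- {
    starts <- seq.int(1L, nchar(seq), by = 60L)
    vapply(starts, function(s) {
      chunk <- substr(seq, s, min(s + 59L, nchar(seq)))
      grp <- gsub("(.{10})", "\\1 ", chunk)
      sprintf("%9d %s", s, tolower(trimws(grp)))
    }, character(1))
  }
  feat_lines <- unlist(lapply(seq_len(nrow(features)), function(k) {
    f <- features[k, ]
    loc <- if (f$strand == "-") {
      sprintf("complement(%d..%d)", f$start, f$end)
    } else sprintf("%d..%d", f$start, f$end)
    c(sprintf("     %-16s%s", f$type, loc),
      sprintf("                     /gene=\"%s\"", f$gene))
  }))
  c(sprintf("LOCUS       %s             %d bp    DNA     circular INV", id, nchar(seq)),
    sprintf("ACCESSION   %s", id),
    "FEATURES             Location/Qualifiers",
    "     source          1..450",
    feat_lines,
    "ORIGIN",
    origin,
    "//")
}

test_that("seq_tbl validates ids and residues", {
  tb <- seq_tbl(c("a", "b"), c("acgt", "NRY-"), group = c("g1", NA))
  expect_equal(tb$seq, c("ACGT", "NRY-"))
  expect_error(seq_tbl(c("a", "a"), c("ACGT", "ACGT")), "duplicate")
  expect_error(seq_tbl("a", "ACJT"),
               "record 'a': non-IUPAC character 'J' at sequence position 3")
  expect_error(seq_tbl("a", ""), "empty sequence")
  expect_error(seq_tbl(character(0), character(0)), "no sequences")
})

test_that("FASTA round-trips with ids and group labels", {
  tb <- seq_tbl(c("s1", "s2", "s3"), c("ACGTACGT", "ACGTTCGT", "TTTTCCCC"),
                group = c("Q1", "Q1", NA))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(tb, path)
  back <- read_fasta(path)
  expect_equal(back$id, tb$id)
  expect_equal(back$seq, tb$seq)
  expect_equal(back$group, tb$group)
})

test_that("read_fasta takes the first header token as id and errors usefully", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">rec1 some description group=ASL", "ACGTACGT",
               ">rec2 other", "AC", "GT"), path)
  tb <- read_fasta(path)
  expect_equal(tb$id, c("rec1", "rec2"))
  expect_equal(tb$group, c("ASL", NA))
  expect_equal(tb$seq[2], "ACGT")
  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")), "not found")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty FASTA")
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACJT"), bad)
  expect_error(read_fasta(bad), "non-IUPAC character 'J' at sequence position 3")
})

test_that("GenBank records parse with strand-aware gene extraction", {
  set.seed(401)
  seq <- random_dna(450)
  # 13 CDS + 2 rRNA of 30 bp each; genes 4 and 9 on the minus strand
  ft <- tibble::tibble(
    type = c(rep("CDS", 13), rep("rRNA", 2)),
    gene = sprintf("g%02d", 1:15),
    start = seq(1, by = 30, length.out = 15),
    end = seq(30, by = 30, length.out = 15),
    strand = ifelse(1:15 %in% c(4, 9), "-", "+"))
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(make_gb_record("TR000001", seq, ft), path)

  rec <- read_genbank_features(path)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$id, "TR000001")
  expect_equal(rec$seq, seq)
  parsed <- rec$features[[1]]
  expect_equal(nrow(parsed), 15)
  expect_equal(parsed$gene, ft$gene)
  expect_equal(parsed$strand, ft$strand)

  genes <- extract_genes(rec)
  expect_equal(nrow(genes), 15)
  expect_true(all(nchar(genes$seq) == 30))
  # plus strand: verbatim; minus strand: reverse complement
  expect_equal(genes$seq[1], substr(seq, 1, 30))
  expect_equal(genes$seq[4], revcomp(substr(seq, 91, 120)))
  one <- extract_genes(rec, gene = "g09")
  expect_equal(one$id, "TR000001|g09")
  expect_equal(one$seq, revcomp(substr(seq, 241, 270)))
  expect_error(extract_genes(rec, gene = "nadh99"), "no matching CDS/rRNA")
})

test_that("GenBank reader rejects spliced locations and missing ORIGIN", {
  set.seed(402)
  seq <- random_dna(120)
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       J1             120 bp DNA",
               "FEATURES             Location/Qualifiers",
               "     CDS             join(1..30,61..90)",
               "                     /gene=\"gx\"",
               "ORIGIN",
               sprintf("%9d %s", 1, tolower(seq)),
               "//"), path)
  expect_error(read_genbank_features(path), "join/order")

  writeLines(c("LOCUS       J2             120 bp DNA",
               "FEATURES             Location/Qualifiers",
               "     CDS             1..30",
               "//"), path)
  expect_error(read_genbank_features(path), "no ORIGIN")
})

test_that("extract_region obeys 1-based inclusive arithmetic", {
  set.seed(403)
  tb <- seq_tbl("full", random_dna(1542))
  got <- extract_region(tb, 783, 1439)
  expect_equal(nchar(got$seq), 1439 - 783 + 1)
  expect_equal(nchar(got$seq), 657)
  expect_equal(got$id, "full:783-1439")
  expect_equal(got$seq, substr(tb$seq, 783, 1439))
  same <- extract_region(tb, 1, 1542, suffix_id = FALSE)
  expect_equal(same$seq, tb$seq)
  expect_equal(same$id, "full")
  expect_error(extract_region(tb, 5, 4), "need 1 <= start <= end")
  expect_error(extract_region(tb, 0, 10), "need 1 <= start <= end")
  expect_error(extract_region(tb, 1, 2000), "out of range for record 'full' \\(length 1542\\)")
})

test_that("exact collapsing keeps length variants apart; length_aware merges substrings", {
  tb <- seq_tbl(c("r1", "r2", "r3", "r4"),
                c("ACGTACGTAA", "ACGTACGTAA", "ACGTACGT", "TTTTTTTT"))
  ex <- collapse_haplotypes(tb, mode = "exact")
  expect_equal(nrow(ex), 3)
  expect_equal(ex$n, c(2L, 1L, 1L))
  expect_equal(sort(ex$members[[1]]), c("r1", "r2"))
  expect_equal(attr(ex, "collapse_mode"), "exact")

  la <- collapse_haplotypes(tb, mode = "length_aware")
  expect_equal(nrow(la), 2)
  merged <- la[la$seq == "ACGTACGTAA", ]
  expect_equal(merged$n, 3L)
  expect_setequal(merged$members[[1]], c("r1", "r2", "r3"))
})

test_that("collapsing conserves total multiplicity (property)", {
  set.seed(404)
  for (rep in 1:10) {
    pool <- replicate(4, random_dna(sample(8:12, 1)))
    n <- sample(3:12, 1)
    tb <- seq_tbl(sprintf("r%02d", seq_len(n)),
                  sample(pool, n, replace = TRUE))
    for (mode in c("exact", "length_aware")) {
      haps <- collapse_haplotypes(tb, mode = mode)
      expect_equal(sum(haps$n), n)
      expect_setequal(unlist(haps$members), tb$id)
      expect_equal(haps$haplotype, sprintf("hap%03d", seq_len(nrow(haps))))
    }
  }
})

test_that("concatenation joins genes in order with correct boundaries", {
  set.seed(405)
  g1 <- random_dna(300); g2 <- random_dna(150)
  mk_sample <- function(id, s1, s2) {
    seq_tbl(id, paste0(s1, s2),
            features = list(tibble::tibble(
              type = "CDS", gene = c("cox1", "cox2"),
              start = c(1L, nchar(s1) + 1L),
              end = c(nchar(s1), nchar(s1) + nchar(s2)),
              strand = "+")))
  }
  mito <- dplyr::bind_rows(mk_sample("A", g1, g2), mk_sample("B", g1, g2))
  cc <- build_concatenation(mito, c("cox1", "cox2"))
  expect_s3_class(cc, "concatenation")
  expect_equal(cc$length, 450)
  expect_equal(cc$boundaries$start, c(0L, 300L))
  expect_equal(cc$boundaries$end, c(300L, 450L))
  expect_equal(cc$seqs$seq[1], paste0(g1, g2))
  expect_equal(cc$seqs$seq, rep(paste0(g1, g2), 2))
})

test_that("concatenation flush-trims a 3 bp length variant", {
  set.seed(406)
  g1 <- random_dna(300); g2 <- random_dna(150)
  # sample B carries a 3 bp insertion in cox1
  g1b <- paste0(substr(g1, 1, 150), "TAG", substr(g1, 151, 300))
  mito <- dplyr::bind_rows(
    seq_tbl("A", paste0(g1, g2),
            features = list(tibble::tibble(type = "CDS",
                                           gene = c("cox1", "cox2"),
                                           start = c(1L, 301L),
                                           end = c(300L, 450L), strand = "+"))),
    seq_tbl("B", paste0(g1b, g2),
            features = list(tibble::tibble(type = "CDS",
                                           gene = c("cox1", "cox2"),
                                           start = c(1L, 304L),
                                           end = c(303L, 453L), strand = "+"))))
  cc <- build_concatenation(mito, c("cox1", "cox2"))
  # insertion columns are dropped, so both samples share sample A's length
  expect_equal(unique(nchar(cc$seqs$seq)), 450L)
  expect_equal(cc$length, 450L)
  expect_equal(cc$seqs$seq[1], cc$seqs$seq[2])
  expect_equal(cc$seqs$seq[1], paste0(g1, g2))
})

test_that("concatenation reports a missing gene by sample", {
  set.seed(407)
  mito <- dplyr::bind_rows(
    seq_tbl("A", random_dna(100),
            features = list(tibble::tibble(type = "CDS", gene = "cox1",
                                           start = 1L, end = 100L, strand = "+"))),
    seq_tbl("B", random_dna(100),
            features = list(tibble::tibble(type = "CDS", gene = "nad1",
                                           start = 1L, end = 100L, strand = "+"))))
  expect_error(build_concatenation(mito, "cox1"), "sample 'B' is missing gene 'cox1'")
})

test_that("revcomp is an involution that complements bases", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAACCC"), "GGGTTT")
  set.seed(408)
  s <- random_dna(100)
  expect_equal(revcomp(revcomp(s)), s)
})
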