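# Codon-constrained synthetic data: a full-length protein-coding reference
# gene, groups of authentic haplotypes evolved under a Jukes-Cantor
# substitution process with purifying constraint (synonymous-only changes at
# conserved codons, no stops, no indels), optional 5'/3' rate heterogeneity,
# a conserved-site protein panel, decoy sequences, and NUMT-like corrupted
# copies in five lesion classes. Everything is reproducible from
# (config, seed).

#' Simulation configuration
#'
#' Defaults emulate a three-group study design: two closely related groups
#' ("Q1", "Q2") and a third ("ASL") whose divergence from them is
#' concentrated towards the 5' end of the gene, so that the 3' barcode sits
#' below a 3.5% species threshold while the 5' barcode sits above it.
#' Between-group divergence for groups i and j is approximately
#' `d_anc_i + d_anc_j (+ d_within)`, since group ancestors radiate
#' independently from the root reference (star phylogeny).
#'
#' @param seed integer seed; all generator stages derive their RNG state from
#'   it.
#' @param gene_codons gene length in codons (default 514, i.e. 1,542 bp
#'   including the terminal stop).
#' @param conserved_fraction fraction of codons whose amino acid is immutable
#'   in authentic sequences (default 0.6).
#' @param groups tibble with `name`, `n` (haplotypes), `d_within` (target
#'   within-group pairwise divergence) and `d_anc` (ancestor-to-root
#'   divergence).
#' @param profiles named list of per-group rate profiles; each profile is a
#'   numeric vector of region multipliers spread evenly along the gene
#'   (e.g. `c(2, 1)` doubles the substitution rate on the 5' half). Groups
#'   not named evolve uniformly.
#' @param barcode3 1-based inclusive coordinates of the 3' barcode region
#'   (default `c(783, 1439)`, the 657 bp window ending at gene position
#'   1,439).
#' @param numts tibble with `class` (one of `indel`, `stop`,
#'   `terminal_cluster`, `global_divergent`, `decoy_chimera`), `n` and
#'   `group` (parent group).
#' @param numt_divergence target divergence of `global_divergent` copies
#'   (default 0.05).
#' @param decoy_divergence divergence of decoy species from the reference
#'   (default 0.10).
#' @param panel_n number of reference panel proteins (default 12).
#' @param n_decoys number of decoy sequences.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, gene_codons = 514L, conserved_fraction = 0.6,
                       groups = NULL, profiles = list(ASL = c(3, 1)),
                       barcode3 = c(783L, 1439L), numts = NULL,
                       numt_divergence = 0.05, decoy_divergence = 0.10,
                       panel_n = 12L, n_decoys = 2L) {
  if (is.null(groups)) {
    groups <- tibble::tibble(name = c("Q1", "Q2", "ASL"), n = c(20L, 10L, 10L),
                             d_within = 0.004, d_anc = c(0.004, 0.004, 0.026))
  }
  if (is.null(numts)) {
    numts <- tibble::tibble(
      class = c("indel", "stop", "terminal_cluster", "global_divergent",
                "decoy_chimera"),
      n = c(10L, 10L, 10L, 10L, 5L), group = "Q1")
  }
  stopifnot(all(groups$d_within >= 0 & groups$d_within < 0.5),
            all(groups$d_anc >= 0 & groups$d_anc < 0.5),
            conserved_fraction >= 0, conserved_fraction <= 1,
            all(numts$n >= 0))
  structure(list(seed = as.integer(seed), gene_codons = as.integer(gene_codons),
                 conserved_fraction = conserved_fraction, groups = groups,
                 profiles = profiles, barcode3 = as.integer(barcode3),
                 numts = numts, numt_divergence = numt_divergence,
                 decoy_divergence = decoy_divergence,
                 panel_n = as.integer(panel_n), n_decoys = as.integer(n_decoys)),
            class = "sim_config")
}

expand_profile <- function(profile, len) {
  if (is.null(profile)) return(rep(1, len))
  k <- length(profile)
  rep(profile, times = diff(round(seq(0, len, length.out = k + 1))))
}

# Apply exactly n_sub substitutions at distinct sites, sampled with
# probability proportional to `weights`. Substitutions never create a stop
# codon; at conserved codons only synonymous changes are allowed unless
# `respect_conservation` is FALSE. `ref_offset` maps local position 1 to that
# gene coordinate so codon identity is computed in gene frame.
mutate_sequence <- function(seq, n_sub, weights = NULL,
                            conserved_codons = integer(), code_tbl,
                            ref_offset = 1L, respect_conservation = TRUE,
                            protect_codons = integer()) {
  chars <- seq_chars(seq)
  len <- length(chars)
  if (is.null(weights)) weights <- rep(1, len)
  stopifnot(length(weights) == len)
  if (n_sub == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  codon_idx <- (ref_offset + seq_len(len) - 2L) %/% 3L + 1L
  candidates <- which(weights > 0 & !codon_idx %in% protect_codons)
  done <- 0L
  tried <- logical(len)
  while (done < n_sub) {
    avail <- candidates[!tried[candidates]]
    if (length(avail) == 0) {
      stop("unattainable divergence target under codon constraints; lower the target",
           call. = FALSE)
    }
    pos <- if (length(avail) == 1) avail else
      sample(avail, 1, prob = weights[avail])
    tried[pos] <- TRUE
    ci <- codon_idx[pos]
    # local indices of this codon, if fully inside the sequence
    gene_pos <- ref_offset + pos - 1L
    cod_start_local <- pos - (gene_pos - 1L) %% 3L
    cod_local <- cod_start_local:(cod_start_local + 2L)
    full_codon <- all(cod_local >= 1 & cod_local <= len)
    old_aa <- if (full_codon) {
      translate_codons(paste(chars[cod_local], collapse = ""), code_tbl)
    } else NA_character_
    for (alt in sample(setdiff(bases, chars[pos]))) {
      if (full_codon) {
        new_chars <- chars[cod_local]
        new_chars[pos - cod_start_local + 1L] <- alt
        new_aa <- translate_codons(paste(new_chars, collapse = ""), code_tbl)
        if (new_aa == "*") next
        if (respect_conservation && ci %in% conserved_codons && new_aa != old_aa) next
      }
      chars[pos] <- alt
      done <- done + 1L
      break
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a full-length protein-coding reference gene
#'
#' Codons are drawn uniformly from the sense codons of the configured genetic
#' code; the gene starts with ATG and ends with a TAA stop, with no internal
#' stops by construction. A random set of `conserved_fraction` of the codons
#' (always including the start codon) is designated conserved.
#'
#' @param config a [sim_config()].
#' @return A list of class `"sim_reference"`: `seq`, `conserved_codons`
#'   (gene codon indices), `gene_codons`.
#' @export
simulate_reference_gene <- function(config = sim_config()) {
  set.seed(config$seed)
  code_tbl <- genetic_code_table("5")
  sense <- names(code_tbl)[code_tbl != "*"]
  n <- config$gene_codons
  codons <- c("ATG", sample(sense, n - 2L, replace = TRUE), "TAA")
  n_cons <- round(config$conserved_fraction * n)
  conserved <- sort(unique(c(1L, sample(2:(n - 1L), max(0L, n_cons - 1L)))))
  structure(list(seq = paste(codons, collapse = ""), conserved_codons = conserved,
                 gene_codons = n), class = "sim_reference")
}

#' Simulate the reference protein panel
#'
#' Panel proteins are derived from the reference: every non-conserved codon
#' (other than the terminal stop) receives an amino-acid-changing mutation in
#' exactly one randomly chosen panel member, so the conserved-site mask
#' recovered by [build_reference_panel()] equals the planted conserved set.
#'
#' @param reference a [simulate_reference_gene()] result.
#' @param config a [sim_config()].
#' @return A `reference_panel`.
#' @export
simulate_panel <- function(reference, config = sim_config()) {
  set.seed(config$seed + 4L)
  code_tbl <- genetic_code_table("5")
  n <- reference$gene_codons
  ref_codons <- substring(reference$seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  members <- replicate(config$panel_n, ref_codons, simplify = FALSE)
  variable <- setdiff(seq_len(n - 1L), reference$conserved_codons)
  sense <- names(code_tbl)[code_tbl != "*"]
  for (ci in variable) {
    m <- sample.int(config$panel_n, 1)
    old_aa <- code_tbl[[ref_codons[ci]]]
    alt <- sample(sense[code_tbl[sense] != old_aa], 1)
    members[[m]][ci] <- alt
  }
  proteins <- vapply(members, function(cod)
    paste(translate_codons(cod, code_tbl), collapse = ""), character(1))
  build_reference_panel(proteins)
}

#' Simulate authentic haplotype groups
#'
#' Each group's ancestor is evolved from the reference by exactly
#' `round(d_anc * L)` substitutions at distinct sites (sampled by the group's
#' rate profile); each haplotype then receives `round(d_within / 2 * L)`
#' further substitutions, so expected within-group pairwise divergence is
#' `d_within` and expected between-group divergence is the sum of the two
#' ancestor divergences plus the within-group contributions. All mutations
#' respect reading frame, the genetic code (no stops) and the conserved-codon
#' set (synonymous only), so authentic haplotypes are never flagged by the
#' INDEL, stop-codon or conserved-site criteria.
#'
#' @param reference a [simulate_reference_gene()] result.
#' @param config a [sim_config()].
#' @return A list: `records` (full-length sequence tibble with `group`),
#'   `ancestors` (named character vector of full-length group ancestor genes,
#'   the synthetic analogue of each group's own mitogenome-derived reference)
#'   and `truth` (tibble `id`, `group`, `class`, `lesion`).
#' @export
simulate_groups <- function(reference, config = sim_config()) {
  set.seed(config$seed + 1L)
  code_tbl <- genetic_code_table("5")
  L <- nchar(reference$seq)
  last_codon <- reference$gene_codons
  recs <- list(); truth <- list(); ancestors <- character(0)
  for (g in seq_len(nrow(config$groups))) {
    grp <- config$groups[g, ]
    weights <- expand_profile(config$profiles[[grp$name]], L)
    ancestor <- mutate_sequence(reference$seq, round(grp$d_anc * L), weights,
                                reference$conserved_codons, code_tbl,
                                protect_codons = c(1L, last_codon))
    ancestors[[grp$name]] <- ancestor
    for (h in seq_len(grp$n)) {
      hap <- mutate_sequence(ancestor, round(grp$d_within / 2 * L), NULL,
                             reference$conserved_codons, code_tbl,
                             protect_codons = c(1L, last_codon))
      id <- sprintf("%s_h%02d", grp$name, h)
      recs[[length(recs) + 1L]] <- tibble::tibble(id = id, group = grp$name,
                                                  seq = hap)
      truth[[length(truth) + 1L]] <- tibble::tibble(id = id, group = grp$name,
                                                    class = "authentic",
                                                    lesion = NA_character_)
    }
  }
  list(records = dplyr::bind_rows(recs), ancestors = ancestors,
       truth = dplyr::bind_rows(truth))
}

#' Simulate decoy sequences
#'
#' Decoys stand in for sequences from unrelated species: full-length genes at
#' `decoy_divergence` from the reference, still protein-constrained (they are
#' real genes, just from another lineage).
#'
#' @param reference a [simulate_reference_gene()] result.
#' @param config a [sim_config()].
#' @return A full-length sequence tibble.
#' @export
simulate_decoys <- function(reference, config = sim_config()) {
  set.seed(config$seed + 2L)
  code_tbl <- genetic_code_table("5")
  L <- nchar(reference$seq)
  seqs <- vapply(seq_len(config$n_decoys), function(k) {
    mutate_sequence(reference$seq, round(config$decoy_divergence * L), NULL,
                    reference$conserved_codons, code_tbl,
                    protect_codons = c(1L, reference$gene_codons))
  }, character(1))
  seq_tbl(id = sprintf("decoy%d", seq_len(config$n_decoys)), seq = seqs,
          group = "decoy")
}

#' Simulate NUMT-like corrupted copies of partial haplotypes
#'
#' Five lesion classes: `indel` (1-4 bp interior insertion/deletion with
#' homopolymer-biased placement), `stop` (an internal stop codon),
#' `terminal_cluster` (a 9-116 bp terminal stretch densely packed with
#' non-synonymous substitutions), `global_divergent` (uniform substitutions to
#' `numt_divergence`, ignoring codon constraint but avoiding stops so the
#' lesion classes stay separable), and `decoy_chimera` (a splice in which most
#' of the sequence comes from a decoy). Lesion details are recorded in the
#' truth table.
#'
#' @param parents a sequence tibble of partial authentic haplotypes (all the
#'   same region of the gene).
#' @param config a [sim_config()].
#' @param ref_offset gene coordinate of the partials' first base.
#' @param decoys_partial decoy sequences extracted over the same region
#'   (required for class `decoy_chimera`).
#' @return A list: `records` (partial sequence tibble) and `truth`.
#' @export
simulate_numts <- function(parents, config = sim_config(),
                           ref_offset = config$barcode3[1],
                           decoys_partial = NULL) {
  set.seed(config$seed + 3L)
  code_tbl <- genetic_code_table("5")
  if ("decoy_chimera" %in% config$numts$class[config$numts$n > 0] &&
      (is.null(decoys_partial) || nrow(decoys_partial) == 0)) {
    stop("decoy_chimera NUMTs requested but no decoys supplied", call. = FALSE)
  }
  recs <- list(); truth <- list()
  for (r in seq_len(nrow(config$numts))) {
    cls <- config$numts$class[r]
    src <- parents[parents$group == config$numts$group[r], ]
    if (nrow(src) == 0) stop("no parent haplotypes in group '",
                             config$numts$group[r], "'", call. = FALSE)
    for (k in seq_len(config$numts$n[r])) {
      parent <- src[sample.int(nrow(src), 1), ]
      lesioned <- switch(
        cls,
        indel = lesion_indel(parent$seq),
        stop = lesion_stop(parent$seq, ref_offset, code_tbl),
        terminal_cluster = lesion_cluster(parent$seq, ref_offset, code_tbl),
        global_divergent = lesion_divergent(parent$seq, config$numt_divergence,
                                            code_tbl, ref_offset),
        decoy_chimera = lesion_chimera(parent$seq, decoys_partial),
        stop("unknown NUMT class '", cls, "'", call. = FALSE))
      id <- sprintf("NUMT_%s_%02d", cls, k)
      recs[[length(recs) + 1L]] <- tibble::tibble(id = id, group = parent$group,
                                                  seq = lesioned$seq)
      truth[[length(truth) + 1L]] <- tibble::tibble(
        id = id, group = parent$group, class = paste0("numt:", cls),
        lesion = lesioned$lesion)
    }
  }
  list(records = dplyr::bind_rows(recs), truth = dplyr::bind_rows(truth))
}

lesion_indel <- function(seq) {
  chars <- seq_chars(seq)
  len <- length(chars)
  margin <- 25L
  runs <- rle(chars)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hp <- which(runs$lengths >= 2 & starts > margin & ends < len - margin)
  if (length(hp) > 0 && stats::runif(1) < 0.7) {
    # echo the common single-base deletion in a homopolymer run
    r <- if (length(hp) == 1) hp else sample(hp, 1)
    pos <- starts[r]
    new <- paste0(substr(seq, 1, pos - 1L), substr(seq, pos + 1L, len))
    lesion <- sprintf("deletion of 1 bp ('%s') at partial position %d (homopolymer run %d)",
                      chars[pos], pos, runs$lengths[r])
  } else {
    pos <- sample(seq.int(margin, len - margin), 1)
    ilen <- sample(1:4, 1)
    if (stats::runif(1) < 0.5 && pos + ilen <= len - margin) {
      new <- paste0(substr(seq, 1, pos - 1L), substr(seq, pos + ilen, len))
      lesion <- sprintf("deletion of %d bp at partial position %d", ilen, pos)
    } else {
      ins <- paste(sample(c("A", "C", "G", "T"), ilen, replace = TRUE),
                   collapse = "")
      new <- paste0(substr(seq, 1, pos), ins, substr(seq, pos + 1L, len))
      lesion <- sprintf("insertion of %d bp ('%s') after partial position %d",
                        ilen, ins, pos)
    }
  }
  list(seq = new, lesion = lesion)
}

# local positions of complete in-frame codon starts
codon_starts_local <- function(len, ref_offset) {
  fo <- (ref_offset - 1L) %% 3L
  s0 <- ((3L - fo) %% 3L) + 1L
  starts <- seq.int(s0, len - 2L, by = 3L)
  starts
}

lesion_stop <- function(seq, ref_offset, code_tbl) {
  len <- nchar(seq)
  starts <- codon_starts_local(len, ref_offset)
  mid <- starts[starts > len / 3 & starts < 2 * len / 3]
  pos <- if (length(mid) == 1) mid else sample(mid, 1)
  new <- paste0(substr(seq, 1, pos - 1L), "TAA", substr(seq, pos + 3L, len))
  list(seq = new,
       lesion = sprintf("premature stop codon TAA at partial position %d (ref %d)",
                        pos, ref_offset + pos - 1L))
}

lesion_cluster <- function(seq, ref_offset, code_tbl) {
  len <- nchar(seq)
  chars <- seq_chars(seq)
  side <- sample(c("5'", "3'"), 1)
  stretch_len <- sample(9:116, 1)
  span <- if (side == "5'") c(1L, stretch_len) else c(len - stretch_len + 1L, len)
  starts <- codon_starts_local(len, ref_offset)
  inside <- starts[starts >= span[1] & starts + 2L <= span[2]]
  n_mut <- max(2L, ceiling(stretch_len / 5))
  picked <- if (length(inside) <= n_mut) inside else sort(sample(inside, n_mut))
  bases <- c("A", "C", "G", "T")
  for (s in picked) {
    codon <- chars[s:(s + 2L)]
    old_aa <- translate_codons(paste(codon, collapse = ""), code_tbl)
    done <- FALSE
    for (off in sample(0:2)) {
      for (alt in sample(setdiff(bases, codon[off + 1L]))) {
        cand <- codon
        cand[off + 1L] <- alt
        aa <- translate_codons(paste(cand, collapse = ""), code_tbl)
        if (aa != "*" && aa != old_aa) {
          chars[s + off] <- alt
          done <- TRUE
          break
        }
      }
      if (done) break
    }
  }
  list(seq = paste(chars, collapse = ""),
       lesion = sprintf("%d non-synonymous substitutions in %d bp at %s end",
                        length(picked), stretch_len, side))
}

lesion_divergent <- function(seq, divergence, code_tbl, ref_offset) {
  n_sub <- round(divergence * nchar(seq))
  new <- mutate_sequence(seq, n_sub, NULL, integer(), code_tbl,
                         ref_offset = ref_offset, respect_conservation = FALSE)
  list(seq = new,
       lesion = sprintf("%d substitutions (~%.1f%% divergence), codon constraint ignored",
                        n_sub, 100 * divergence))
}

lesion_chimera <- function(seq, decoys_partial) {
  k <- sample.int(nrow(decoys_partial), 1)
  decoy <- decoys_partial$seq[k]
  stopifnot(nchar(decoy) == nchar(seq))
  b <- round(0.15 * nchar(seq))
  list(seq = paste0(substr(seq, 1, b), substr(decoy, b + 1L, nchar(seq))),
       lesion = sprintf("chimera: positions %d-%d replaced by decoy '%s'",
                        b + 1L, nchar(seq), decoys_partial$id[k]))
}

#' Simulate a complete labelled dataset
#'
#' Orchestrates the generator: reference gene, protein panel, authentic
#' full-length haplotype groups, their partial barcode extracts, decoys, and
#' NUMT-like copies of the partials, with a ground-truth table covering every
#' emitted sequence.
#'
#' @param config a [sim_config()].
#' @return A list of class `"sim_dataset"`: `config`, `reference`, `panel`,
#'   `references` (named vector of full-length group ancestor genes, for
#'   per-group screening), `records_full` (authentic full-length), `records`
#'   (partial barcode region: authentic + NUMTs), `decoys` (full-length),
#'   `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  reference <- simulate_reference_gene(config)
  panel <- simulate_panel(reference, config)
  auth <- simulate_groups(reference, config)
  decoys <- simulate_decoys(reference, config)
  b3 <- config$barcode3
  partials <- extract_region(auth$records, b3[1], b3[2], suffix_id = FALSE)
  decoys_partial <- extract_region(decoys, b3[1], b3[2], suffix_id = FALSE)
  numts <- simulate_numts(partials, config, ref_offset = b3[1],
                          decoys_partial = decoys_partial)
  structure(list(config = config, reference = reference, panel = panel,
                 references = auth$ancestors,
                 records_full = auth$records,
                 records = dplyr::bind_rows(partials, numts$records),
                 decoys = decoys,
                 truth = dplyr::bind_rows(auth$truth, numts$truth)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> seed %d: %d authentic haplotypes in %d groups, %d NUMTs, %d decoys\n",
              x$config$seed, nrow(x$records_full), nrow(x$config$groups),
              sum(grepl("^numt:", x$truth$class)), nrow(x$decoys)))
  invisible(x)
}

#' Write a simulated dataset as a reusable fixture
#'
#' Emits the partial records (group labels in FASTA descriptions), the
#' full-length records, the reference gene, panel proteins, decoys, the
#' ground-truth TSV and the generating configuration as YAML. Regenerating
#' from the echoed configuration reproduces the FASTA files byte-for-byte.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param outdir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
emit_fixture <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$records, file.path(outdir, "records.fasta"))
  write_fasta(dataset$records_full, file.path(outdir, "records_full.fasta"))
  write_fasta(seq_tbl("reference", dataset$reference$seq),
              file.path(outdir, "reference.fasta"))
  write_fasta(dataset$decoys, file.path(outdir, "decoys.fasta"))
  set <- Biostrings::AAStringSet(dataset$panel$proteins)
  names(set) <- sprintf("panel%02d", seq_along(dataset$panel$proteins))
  Biostrings::writeXStringSet(set, file.path(outdir, "panel.fasta"))
  utils::write.table(dataset$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_sim_config(dataset$config, file.path(outdir, "config.yml"))
  invisible(outdir)
}

#' Write a simulation configuration as YAML
#' @param config a [sim_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$groups <- purrr::transpose(as.list(config$groups))
  x$numts <- purrr::transpose(as.list(config$numts))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#' @param path a YAML file written by [write_sim_config()].
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim_config(seed = x$seed, gene_codons = x$gene_codons,
             conserved_fraction = x$conserved_fraction,
             groups = dplyr::bind_rows(purrr::map(x$groups, tibble::as_tibble)),
             profiles = purrr::map(x$profiles, unlist),
             barcode3 = unlist(x$barcode3),
             numts = dplyr::bind_rows(purrr::map(x$numts, tibble::as_tibble)),
             numt_divergence = x$numt_divergence,
             decoy_divergence = x$decoy_divergence, panel_n = x$panel_n,
             n_decoys = x$n_decoys)
}
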