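# Sequence ingest, region/gene extraction, haplotype collapsing and
# multigene concatenation. Coordinates are 1-based inclusive throughout
# (GenBank convention).

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")

#' Build a sequence table
#'
#' The package's working container for labelled nucleotide sequences is a
#' plain tibble with columns `id`, `group`, `seq` and (optionally) a
#' `features` list-column of per-record feature tables
#' (`gene`, `start`, `end`, `strand`). Residues are upper-cased on ingest and
#' must be IUPAC DNA codes or the gap symbol `-`.
#'
#' @param id character vector of unique record identifiers.
#' @param seq character vector of nucleotide sequences.
#' @param group optional character vector of group labels (e.g. "Q1", "ASL").
#' @param features optional list of feature tibbles, one per record, each with
#'   columns `gene`, `start`, `end`, `strand`.
#' @return A tibble with one row per sequence.
#' @export
seq_tbl <- function(id, seq, group = NA_character_, features = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  validate_residues(seq, id)
  out <- tibble::tibble(id = id, group = rep_len(as.character(group), length(id)),
                        seq = seq)
  if (!is.null(features)) out$features <- features
  out
}

validate_residues <- function(seq, id) {
  if (length(seq) == 0L) stop("no sequences supplied", call. = FALSE)
  if (any(!nzchar(seq))) {
    stop("empty sequence for record ", id[!nzchar(seq)][1], call. = FALSE)
  }
  ok <- paste0("^[", paste(IUPAC_DNA, collapse = ""), "]+$")
  bad <- !grepl(ok, seq)
  if (any(bad)) {
    i <- which(bad)[1]
    chars <- strsplit(seq[i], "", fixed = TRUE)[[1]]
    pos <- which(!chars %in% IUPAC_DNA)[1]
    stop(sprintf("record '%s': non-IUPAC character '%s' at sequence position %d",
                 id[i], chars[pos], pos), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read sequences from a FASTA file
#'
#' The token before the first whitespace in each header becomes the record
#' `id`; a `group=<label>` key anywhere in the remaining description is parsed
#' into the `group` column.
#'
#' @param path path to a FASTA file.
#' @return A sequence tibble (see [seq_tbl()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  grp <- ifelse(grepl("group=", headers),
                sub("^.*group=([^[:space:]]+).*$", "\\1", headers),
                NA_character_)
  seq_tbl(id = ids, seq = as.character(set), group = grp)
}

#' Write a sequence table to FASTA
#'
#' @param seqs a sequence tibble.
#' @param path output path.
#' @param width line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  hdr <- seqs$id
  if ("group" %in% names(seqs)) {
    hdr <- ifelse(is.na(seqs$group), hdr, paste0(hdr, " group=", seqs$group))
  }
  set <- Biostrings::BStringSet(seqs$seq)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read annotated records from a GenBank flat file
#'
#' A minimal reader for GenBank flat files carrying `gene`, `CDS`, `rRNA` or
#' `tRNA` features with simple `start..end` or `complement(start..end)`
#' locations and an `ORIGIN` sequence block. Spliced `join(...)` locations are
#' not supported.
#'
#' @param path path to a GenBank flat file (one or more records).
#' @return A sequence tibble with a `features` list-column; coordinates are
#'   1-based inclusive and strand is `"+"` or `"-"`.
#' @export
read_genbank_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec_end <- grep("^//", lines)
  if (length(rec_end) == 0L) rec_end <- length(lines)
  starts <- c(1L, utils::head(rec_end, -1L) + 1L)
  recs <- purrr::map2(starts, rec_end, function(s, e) {
    parse_genbank_record(lines[s:e])
  })
  recs <- purrr::compact(recs)
  if (length(recs) == 0L) stop("no GenBank records found in ", path, call. = FALSE)
  seq_tbl(id = purrr::map_chr(recs, "id"),
          seq = purrr::map_chr(recs, "seq"),
          features = purrr::map(recs, "features"))
}

parse_genbank_record <- function(lines) {
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) return(NULL)
  id <- strsplit(trimws(locus[1]), "\\s+")[[1]][2]
  acc <- grep("^VERSION|^ACCESSION", lines, value = TRUE)
  if (length(acc) > 0) {
    tok <- strsplit(trimws(acc[1]), "\\s+")[[1]]
    if (length(tok) >= 2) id <- tok[2]
  }
  origin <- grep("^ORIGIN", lines)
  if (length(origin) == 0L) {
    stop(sprintf("GenBank record '%s' has no ORIGIN sequence", id), call. = FALSE)
  }
  seq_lines <- lines[(origin[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z-]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(seq)) {
    stop(sprintf("GenBank record '%s' has an empty ORIGIN sequence", id), call. = FALSE)
  }
  feat_start <- grep("^FEATURES", lines)
  features <- empty_features()
  if (length(feat_start) > 0) {
    block <- lines[(feat_start[1] + 1L):(origin[1] - 1L)]
    features <- parse_genbank_features(block, id)
  }
  list(id = id, seq = seq, features = features)
}

empty_features <- function() {
  tibble::tibble(type = character(), gene = character(),
                 start = integer(), end = integer(), strand = character())
}

parse_genbank_features <- function(block, id) {
  # feature lines start at column 6; qualifiers are indented further
  is_key <- grepl("^\\s{1,10}\\S", block) & !grepl("^\\s*/", block)
  keep_types <- c("gene", "CDS", "rRNA", "tRNA")
  rows <- list()
  idx <- which(is_key)
  for (k in seq_along(idx)) {
    line <- block[idx[k]]
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    type <- tok[1]
    if (!type %in% keep_types) next
    loc <- paste(tok[-1], collapse = "")
    # location may continue on following non-key lines before qualifiers
    nxt <- idx[k] + 1L
    while (nxt <= length(block) && !is_key[nxt] && !grepl("^\\s*/", block[nxt])) {
      loc <- paste0(loc, trimws(block[nxt]))
      nxt <- nxt + 1L
    }
    if (grepl("join|order", loc)) {
      stop(sprintf("record '%s': spliced feature locations (join/order) are not supported", id),
           call. = FALSE)
    }
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
    if (length(nums) < 2) next
    span <- range(as.integer(nums))
    # gene name from qualifiers up to the next feature key
    stop_at <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
    quals <- block[seq.int(idx[k], stop_at)]
    gene <- NA_character_
    g <- grep("/gene=", quals, value = TRUE)
    if (length(g) == 0) g <- grep("/product=", quals, value = TRUE)
    if (length(g) > 0) gene <- gsub('^.*="?([^"]*)"?.*$', "\\1", g[1])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      type = type, gene = gene, start = span[1], end = span[2], strand = strand)
  }
  if (length(rows) == 0L) return(empty_features())
  dplyr::bind_rows(rows)
}

#' Extract a coordinate-defined region from each sequence
#'
#' @param seqs a sequence tibble.
#' @param start,end 1-based inclusive coordinates; the result has length
#'   `end - start + 1`.
#' @param suffix_id if `TRUE` (default), ids are suffixed with
#'   `":start-end"`.
#' @return A sequence tibble of the extracted regions.
#' @export
extract_region <- function(seqs, start, end, suffix_id = TRUE) {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == 1, length(end) == 1)
  if (start < 1 || start > end) {
    stop(sprintf("invalid region %d-%d: need 1 <= start <= end", start, end),
         call. = FALSE)
  }
  lens <- nchar(seqs$seq)
  if (any(end > lens)) {
    i <- which(end > lens)[1]
    stop(sprintf("region %d-%d out of range for record '%s' (length %d)",
                 start, end, seqs$id[i], lens[i]), call. = FALSE)
  }
  out <- seqs[intersect(c("id", "group", "seq"), names(seqs))]
  out$seq <- substr(seqs$seq, start, end)
  if (suffix_id) out$id <- paste0(seqs$id, ":", start, "-", end)
  out
}

#' Extract annotated genes from a record, honouring strand
#'
#' Minus-strand features are reverse-complemented so every extracted gene
#' reads 5' to 3'.
#'
#' @param record one row of a sequence tibble carrying a `features` table.
#' @param gene name of the gene to extract; if `NULL`, all `CDS` and `rRNA`
#'   features are extracted.
#' @return A sequence tibble, one row per extracted gene, ids
#'   `<record id>|<gene>`.
#' @export
extract_genes <- function(record, gene = NULL) {
  stopifnot(nrow(record) == 1, "features" %in% names(record))
  ft <- record$features[[1]]
  ft <- ft[ft$type %in% c("CDS", "rRNA"), , drop = FALSE]
  if (!is.null(gene)) ft <- ft[ft$gene %in% gene, , drop = FALSE]
  if (nrow(ft) == 0L) {
    stop(sprintf("record '%s': no matching CDS/rRNA feature%s", record$id,
                 if (is.null(gene)) "" else paste0(" for gene '", gene, "'")),
         call. = FALSE)
  }
  res <- purrr::pmap_chr(ft[c("start", "end", "strand")], function(start, end, strand) {
    s <- substr(record$seq, start, end)
    if (strand == "-") s <- revcomp(s)
    s
  })
  seq_tbl(id = paste0(record$id, "|", ft$gene), seq = res, group = record$group)
}

#' Reverse-complement a DNA string
#' @param x a character vector of DNA strings.
#' @return The reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Collapse sequences into unique haplotypes
#'
#' `mode = "exact"` merges records only when their full residue strings are
#' identical, so identical sequences of different lengths remain distinct
#' haplotypes (replicating the behaviour of common collapsing tools, which
#' inflates haplotype counts when read lengths vary). `mode = "length_aware"`
#' additionally merges any sequence that is an exact substring of a longer
#' haplotype into that longer haplotype.
#'
#' @param seqs a sequence tibble.
#' @param mode `"exact"` (default) or `"length_aware"`.
#' @return A tibble with columns `haplotype`, `seq`, `n` (multiplicity) and
#'   `members` (list of member ids); attribute `collapse_mode` records the
#'   mode. The sum of `n` always equals `nrow(seqs)`.
#' @export
collapse_haplotypes <- function(seqs, mode = c("exact", "length_aware")) {
  mode <- match.arg(mode)
  if (nrow(seqs) == 0L) stop("no sequences to collapse", call. = FALSE)
  grp <- split(seq_len(nrow(seqs)), factor(seqs$seq, levels = unique(seqs$seq)))
  reps <- names(grp)
  members <- purrr::map(grp, ~ seqs$id[.x])
  if (mode == "length_aware") {
    ord <- order(nchar(reps), decreasing = TRUE)
    reps <- reps[ord]; members <- members[ord]
    keep <- rep(TRUE, length(reps))
    for (i in seq_along(reps)) {
      if (!keep[i]) next
      for (j in seq_along(reps)) {
        if (i == j || !keep[j]) next
        if (nchar(reps[j]) < nchar(reps[i]) &&
            grepl(reps[j], reps[i], fixed = TRUE)) {
          members[[i]] <- c(members[[i]], members[[j]])
          keep[j] <- FALSE
        }
      }
    }
    reps <- reps[keep]; members <- members[keep]
    # restore input order of representatives
    ord2 <- order(match(reps, unique(seqs$seq)))
    reps <- reps[ord2]; members <- members[ord2]
  }
  out <- tibble::tibble(
    haplotype = sprintf("hap%03d", seq_along(reps)),
    seq = unname(reps),
    n = unname(lengths(members)),
    members = unname(members))
  attr(out, "collapse_mode") <- mode
  out
}

#' Write a haplotype table as TSV
#'
#' Columns: haplotype id, multiplicity, member ids (semicolon-separated).
#' @param haps a haplotype table from [collapse_haplotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(haps, path) {
  df <- data.frame(haplotype = haps$haplotype, n = haps$n,
                   members = purrr::map_chr(haps$members, paste, collapse = ";"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Concatenate shared genes across annotated mitogenomes
#'
#' Each gene in `gene_order` is extracted from every sample (minus-strand
#' genes reverse-complemented), aligned to a common per-gene coordinate frame
#' when raw lengths differ, trimmed to flush shared columns, and joined in
#' order. When lengths differ, the longest copy anchors the frame: every other
#' copy is aligned to it pairwise, insertions relative to the anchor are
#' dropped, and columns where any sample has a gap are removed, so all samples
#' end up the same length.
#'
#' @param mitogenomes a sequence tibble with `features` (one row per sample).
#' @param gene_order character vector of gene names in concatenation order.
#' @return A list of class `"concatenation"`: `seqs` (sequence tibble of the
#'   concatenated samples), `gene_order`, `boundaries` (tibble with gene,
#'   `start`/`end` half-open 0-based offsets), `length`.
#' @export
build_concatenation <- function(mitogenomes, gene_order) {
  stopifnot(nrow(mitogenomes) >= 1, length(gene_order) >= 1)
  per_gene <- purrr::map(gene_order, function(g) {
    copies <- purrr::map_chr(seq_len(nrow(mitogenomes)), function(i) {
      rec <- mitogenomes[i, ]
      got <- tryCatch(extract_genes(rec, gene = g),
                      error = function(e) NULL)
      if (is.null(got)) {
        stop(sprintf("sample '%s' is missing gene '%s'", rec$id, g), call. = FALSE)
      }
      got$seq[1]
    })
    flush_trim_gene(copies, g)
  })
  lens <- purrr::map_int(per_gene, ~ nchar(.x[1]))
  cat_seq <- purrr::reduce(per_gene, paste0)
  ends <- cumsum(lens)
  boundaries <- tibble::tibble(gene = gene_order,
                               start = c(0L, utils::head(ends, -1L)),
                               end = ends)
  out <- list(
    seqs = seq_tbl(id = mitogenomes$id, seq = cat_seq,
                   group = if ("group" %in% names(mitogenomes)) mitogenomes$group else NA),
    gene_order = gene_order,
    boundaries = boundaries,
    length = sum(lens))
  class(out) <- "concatenation"
  out
}

# Bring unequal-length gene copies to a common frame anchored on the longest
# copy, then drop any column where a sample has a gap.
flush_trim_gene <- function(copies, gene) {
  if (length(unique(nchar(copies))) == 1L) return(copies)
  anchor <- copies[which.max(nchar(copies))]
  proj <- purrr::map(copies, function(s) {
    if (identical(s, anchor)) {
      strsplit(anchor, "", fixed = TRUE)[[1]]
    } else {
      aln <- nw_align(s, anchor)
      project_onto_reference(aln)
    }
  })
  mat <- do.call(rbind, proj)
  keep <- colSums(mat == "-") == 0
  if (!any(keep)) {
    stop(sprintf("gene '%s': no shared flush columns after alignment", gene),
         call. = FALSE)
  }
  apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
}

# Per-reference-position residues of the aligned query (gap where deleted);
# query insertions relative to the reference are dropped.
project_onto_reference <- function(aln) {
  a <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  a[b != "-"]
}

#' @export
print.concatenation <- function(x, ...) {
  cat(sprintf("<concatenation> %d samples, %d genes, %d bp\n",
              nrow(x$seqs), length(x$gene_order), x$length))
  invisible(x)
}
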