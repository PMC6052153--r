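# Global and semiglobal pairwise alignment with affine gaps, plus
# reference-relative INDEL calling. The dynamic programming is delegated to
# Biostrings::pairwiseAlignment; this module fixes the scoring convention,
# coordinate bookkeeping and indel normalisation the screen relies on.

# Scoring convention: a gap of length L costs gap_open + (L - 1) * gap_extend
# (both negative). Biostrings charges gapOpening + L * gapExtension, so the
# parameters are translated below.
iupac_substitution_matrix <- function(match, mismatch) {
  letters <- setdiff(IUPAC_DNA, "-")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

new_pairwise_alignment <- function(aligned_a, aligned_b, score, ref_offset,
                                   frame_offset = NA_integer_, identity = NA_real_) {
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b, score = score,
                 ref_offset = as.integer(ref_offset),
                 frame_offset = frame_offset, identity = identity),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.1f, ref offset %d%s\n",
              x$score, x$ref_offset,
              if (!is.na(x$frame_offset)) sprintf(", frame %d", x$frame_offset) else ""))
  n <- nchar(x$aligned_a)
  w <- min(60L, n)
  cat(substr(x$aligned_a, 1, w), if (n > w) "...", "\n")
  cat(substr(x$aligned_b, 1, w), if (n > w) "...", "\n")
  invisible(x)
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch alignment in which a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. Defaults (+2/-1/-6/-1) discourage
#' spurious terminal micro-indels in high-identity mappings, where the INDEL
#' criterion of the pseudogene screen must reflect true length variants.
#' Traceback ties are broken deterministically so indel coordinates are
#' reproducible.
#'
#' @param a,b nucleotide strings (a is the query, b the reference).
#' @param match,mismatch,gap_open,gap_extend scoring parameters; gap penalties
#'   are negative.
#' @return A `pairwise_alignment`: equal-length gapped strings `aligned_a`,
#'   `aligned_b`, the `score`, and `ref_offset` (1-based position in `b` of
#'   the first aligned reference column; always 1 for global alignment).
#' @export
nw_align <- function(a, b, match = 2, mismatch = -1, gap_open = -6,
                     gap_extend = -1) {
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = iupac_substitution_matrix(match, mismatch),
    gapOpening = -(gap_open) + gap_extend, gapExtension = -gap_extend)
  new_pairwise_alignment(
    aligned_a = as.character(Biostrings::alignedPattern(aln)),
    aligned_b = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln), ref_offset = 1L)
}

#' Map a partial barcode haplotype onto a full-length reference gene
#'
#' Semiglobal alignment: the partial is aligned end-to-end while reference
#' overhangs are free, as expected for an amplicon fragment of a longer gene.
#' The reference must be a protein-coding gene starting at codon position 1;
#' the returned `frame_offset` in \{0, 1, 2\} is the codon phase of the
#' partial's first aligned base, `(ref_offset - 1) mod 3`.
#'
#' @param partial,reference nucleotide strings.
#' @param min_identity identity floor (proportion) below which the input is
#'   declared unalignable, signalling wrong-locus (or reverse-complemented)
#'   input; the mapper does not auto-orient.
#' @inheritParams nw_align
#' @return A `pairwise_alignment` with `ref_offset`, `frame_offset` and
#'   `identity` filled in.
#' @export
map_partial_to_reference <- function(partial, reference, min_identity = 0.6,
                                     match = 2, mismatch = -1, gap_open = -6,
                                     gap_extend = -1) {
  stopifnot(nzchar(partial), nzchar(reference))
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(partial),
    subject = Biostrings::DNAString(reference),
    type = "global-local",
    substitutionMatrix = iupac_substitution_matrix(match, mismatch),
    gapOpening = -(gap_open) + gap_extend, gapExtension = -gap_extend)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ident <- alignment_identity(pa, pb)
  if (is.na(ident) || ident < min_identity) {
    stop(sprintf(
      "unalignable: identity %.1f%% below floor %.1f%% (wrong locus or orientation?)",
      100 * ident, 100 * min_identity), call. = FALSE)
  }
  ref_offset <- Biostrings::start(Biostrings::subject(aln))
  new_pairwise_alignment(pa, pb, Biostrings::score(aln), ref_offset,
                         frame_offset = (ref_offset - 1L) %% 3L,
                         identity = ident)
}

alignment_identity <- function(aligned_a, aligned_b) {
  a <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  comp <- a != "-" & b != "-"
  if (!any(comp)) return(NA_real_)
  sum(a[comp] == b[comp]) / sum(comp)
}

#' Call INDEL events from a partial-to-reference alignment
#'
#' Maximal gap runs are reported as single events with reference-relative
#' coordinates: `ref_position` is the reference base immediately left of the
#' event. Gap runs abutting either terminus of the alignment are amplicon
#' overhangs, not INDELs, and are not reported. Events inside homopolymer
#' runs are left-normalised (the left-most equivalent placement is reported)
#' and the homopolymer run length is recorded, since a single-base deletion in
#' an `AA` run is only determined up to the run.
#'
#' @param alignment a `pairwise_alignment` from [map_partial_to_reference()]
#'   or [nw_align()].
#' @return A tibble with columns `kind` ("insertion"/"deletion", relative to
#'   the reference), `ref_position`, `length`, `residues`,
#'   `homopolymer_run`.
#' @export
call_indels <- function(alignment) {
  a <- strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]]
  n <- length(a)
  empty <- tibble::tibble(kind = character(), ref_position = integer(),
                          length = integer(), residues = character(),
                          homopolymer_run = integer())
  gap <- a == "-" | b == "-"
  if (!any(gap)) return(empty)
  # interior = columns strictly between the first and last non-gap-run columns
  first_solid <- match(FALSE, gap)
  last_solid <- n + 1L - match(FALSE, rev(gap))
  runs <- rle(gap)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ref_full <- gsub("-", "", alignment$aligned_b, fixed = TRUE)
  qry_full <- gsub("-", "", alignment$aligned_a, fixed = TRUE)
  refpos <- cumsum(b != "-") # 1-based within aligned reference segment
  qrypos <- cumsum(a != "-")
  out <- list()
  for (k in which(runs$values)) {
    i <- starts[k]; j <- ends[k]
    if (i <= first_solid || j >= last_solid) next # terminal overhang
    if (a[i] == "-") {
      # deletion: reference residues ref[r1..r2] absent from the partial
      r1 <- refpos[i]; r2 <- refpos[j]
      while (r1 > 1 &&
             substr(ref_full, r1 - 1L, r1 - 1L) == substr(ref_full, r2, r2)) {
        r1 <- r1 - 1L; r2 <- r2 - 1L
      }
      res <- substr(ref_full, r1, r2)
      hp <- homopolymer_len(ref_full, r1)
      out[[length(out) + 1L]] <- tibble::tibble(
        kind = "deletion",
        ref_position = alignment$ref_offset + r1 - 2L,
        length = r2 - r1 + 1L, residues = res, homopolymer_run = hp)
    } else {
      # insertion: partial residues qry[q1..q2] absent from the reference
      q1 <- qrypos[i]; q2 <- qrypos[j]
      r <- refpos[i] # reference base left of the insertion
      while (q1 > 1 && r > 1 &&
             substr(qry_full, q1 - 1L, q1 - 1L) == substr(qry_full, q2, q2)) {
        q1 <- q1 - 1L; q2 <- q2 - 1L; r <- r - 1L
      }
      res <- substr(qry_full, q1, q2)
      hp <- homopolymer_len(qry_full, q1)
      out[[length(out) + 1L]] <- tibble::tibble(
        kind = "insertion",
        ref_position = alignment$ref_offset + r - 1L,
        length = q2 - q1 + 1L, residues = res, homopolymer_run = hp)
    }
  }
  if (length(out) == 0L) return(empty)
  dplyr::bind_rows(out)
}

homopolymer_len <- function(s, pos) {
  base <- substr(s, pos, pos)
  run <- 1L
  i <- pos - 1L
  while (i >= 1 && substr(s, i, i) == base) { run <- run + 1L; i <- i - 1L }
  i <- pos + 1L
  while (i <= nchar(s) && substr(s, i, i) == base) { run <- run + 1L; i <- i + 1L }
  run
}

#' Tidy an alignment into its INDEL events
#' @param x a `pairwise_alignment`.
#' @param ... unused.
#' @return The [call_indels()] tibble.
#' @export
tidy.pairwise_alignment <- function(x, ...) call_indels(x)

#' Write a pairwise alignment as two-record FASTA for inspection
#' @param alignment a `pairwise_alignment`.
#' @param path output path.
#' @param names ids for the two rows.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path, names = c("query", "reference")) {
  set <- Biostrings::BStringSet(c(alignment$aligned_a, alignment$aligned_b))
  names(set) <- names
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
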