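# Four-criterion pseudogene screen for partial mtCOI haplotypes:
#   (i)   interior INDELs relative to a conspecific full-length gene,
#   (ii)  premature stop codons under the invertebrate mitochondrial code,
#   (iii) anomalous polymorphisms (terminal clusters of non-synonymous
#         substitutions, outlying divergence from the group consensus, or
#         higher identity to a decoy sequence than to the group),
#   (iv)  amino-acid substitutions at positions conserved across a reference
#         protein panel.
# Only sequences free of INDELs are analysed at the amino-acid level, and
# criterion (iv) is assessed only for sequences passing (i) and (ii).

#' Screen configuration
#'
#' Numeric thresholds for the anomalous-polymorphism tests are deliberately
#' configuration-exposed: they bracket observed pseudogene lesions (terminal
#' non-synonymous stretches from 9 bp up, roughly one substitution per 10 bp;
#' whole-sequence outliers near 5% against within-group spreads well below
#' 1.5%) rather than deriving from any first-principles rule.
#'
#' @param cluster_min_len minimum terminal window length (bp) for the
#'   non-synonymous cluster test.
#' @param cluster_density minimum non-synonymous substitution density
#'   (substitutions per bp) in a terminal window.
#' @param cluster_min_count minimum number of non-synonymous substitutions in
#'   the window: a single substitution is never a "cluster".
#' @param outlier_pct whole-sequence percent divergence from the group
#'   consensus at or above which a haplotype is an outlier.
#' @param min_identity identity floor for mapping (see
#'   [map_partial_to_reference()]).
#' @param genetic_code NCBI genetic code id; `"5"` is the invertebrate
#'   mitochondrial code (TGA = Trp, ATA = Met).
#' @param min_aa_length translations shorter than this many residues are
#'   reported "too short to assess" for criterion (iv) instead of flagged.
#' @return A list of class `"screen_config"`.
#' @export
screen_config <- function(cluster_min_len = 9L, cluster_density = 0.1,
                          cluster_min_count = 2L, outlier_pct = 4.0,
                          min_identity = 0.6, genetic_code = "5",
                          min_aa_length = 30L) {
  structure(list(cluster_min_len = as.integer(cluster_min_len),
                 cluster_density = cluster_density,
                 cluster_min_count = as.integer(cluster_min_count),
                 outlier_pct = outlier_pct, min_identity = min_identity,
                 genetic_code = as.character(genetic_code),
                 min_aa_length = as.integer(min_aa_length)),
            class = "screen_config")
}

genetic_code_table <- function(id) Biostrings::getGeneticCode(id)

translate_codons <- function(codons, code_tbl) {
  aa <- unname(code_tbl[codons])
  aa[is.na(aa)] <- "X" # codons containing gaps or ambiguity codes
  aa
}

#' Build a conserved-site reference panel from aligned proteins
#'
#' @param proteins character vector (or tibble with a `seq` column) of
#'   aligned amino-acid strings from at least two reference taxa; all rows
#'   must have equal length.
#' @return A list of class `"reference_panel"`: `proteins` and
#'   `conserved_mask`, a logical vector that is `TRUE` exactly at columns
#'   where all panel members share one residue and none has a gap or `X`.
#' @export
build_reference_panel <- function(proteins) {
  if (is.data.frame(proteins)) proteins <- proteins$seq
  proteins <- toupper(as.character(proteins))
  if (length(proteins) < 2) {
    stop("a reference panel needs at least 2 protein sequences", call. = FALSE)
  }
  if (length(unique(nchar(proteins))) != 1) {
    stop("panel proteins must be aligned to equal length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(proteins, "", fixed = TRUE))
  mask <- apply(mat, 2, function(col) {
    length(unique(col)) == 1 && !col[1] %in% c("-", "X", "*")
  })
  structure(list(proteins = proteins, conserved_mask = unname(mask)),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d proteins x %d columns, %d conserved\n",
              length(x$proteins), length(x$conserved_mask),
              sum(x$conserved_mask)))
  invisible(x)
}

# A mapped haplotype projected into reference coordinates: residues per
# reference position over the covered interval ('-' where the haplotype has a
# deletion; haplotype insertions are dropped but recorded as indel events).
project_partial <- function(partial, reference, config) {
  aln <- map_partial_to_reference(partial, reference,
                                  min_identity = config$min_identity)
  res <- project_onto_reference(aln)
  list(aln = aln, ref_start = aln$ref_offset,
       ref_end = aln$ref_offset + length(res) - 1L, res = res,
       indels = call_indels(aln))
}

# reference codon indices fully covered by a projection
covered_codons <- function(proj) {
  c_first <- ceiling((proj$ref_start + 2L) / 3L)
  c_last <- proj$ref_end %/% 3L
  if (c_last < c_first) integer(0) else seq.int(c_first, c_last)
}

codon_at <- function(chars, offset_start, ref_pos3) {
  paste(chars[(ref_pos3 - 2L):ref_pos3 - offset_start + 1L], collapse = "")
}

# amino acids of a projection at given reference codon indices
projection_aa <- function(proj, codons, code_tbl) {
  if (length(codons) == 0) return(character(0))
  cods <- vapply(codons, function(c) codon_at(proj$res, proj$ref_start, 3L * c),
                 character(1))
  translate_codons(cods, code_tbl)
}

reference_aa <- function(reference, codons, code_tbl) {
  if (length(codons) == 0) return(character(0))
  chars <- seq_chars(reference)
  cods <- vapply(codons, function(c) paste(chars[(3L * c - 2L):(3L * c)],
                                           collapse = ""), character(1))
  translate_codons(cods, code_tbl)
}

#' Criterion (i): interior INDELs
#'
#' @param partial a partial haplotype string.
#' @param reference the group's full-length gene.
#' @param config a [screen_config()].
#' @return A list: `flag`, `events` (the [call_indels()] tibble) and the
#'   underlying projection.
#' @export
screen_criterion_i <- function(partial, reference, config = screen_config()) {
  proj <- project_partial(partial, reference, config)
  list(flag = nrow(proj$indels) > 0, events = proj$indels, projection = proj)
}

#' Criterion (ii): premature stop codons
#'
#' The covered complete codons are translated with the configured genetic
#' code; any stop at a codon other than the reference's terminal codon flags
#' the haplotype. Only meaningful for INDEL-free haplotypes (an in-frame
#' translation requires no interior gaps), which callers must ensure.
#'
#' @param projection a projection from [screen_criterion_i()].
#' @param reference the full-length gene.
#' @param config a [screen_config()].
#' @return A list: `flag` and `stops`, a tibble of codon indices and 1-based
#'   reference coordinates of internal stops.
#' @export
screen_criterion_ii <- function(projection, reference, config = screen_config()) {
  code_tbl <- genetic_code_table(config$genetic_code)
  codons <- covered_codons(projection)
  aa <- projection_aa(projection, codons, code_tbl)
  n_ref_codons <- nchar(reference) %/% 3L
  internal <- aa == "*" & codons < n_ref_codons
  list(flag = any(internal),
       stops = tibble::tibble(codon = codons[internal],
                              ref_position = 3L * codons[internal] - 2L))
}

# Non-synonymous substitution positions (reference coordinates) of a
# projection, judged codon-wise against the reference's codon.
nonsyn_positions <- function(proj, reference, code_tbl) {
  codons <- covered_codons(proj)
  if (length(codons) == 0) return(integer(0))
  aa_h <- projection_aa(proj, codons, code_tbl)
  aa_r <- reference_aa(reference, codons, code_tbl)
  diff_codon <- codons[aa_h != aa_r & aa_h != "X" & aa_r != "X"]
  ref_chars <- seq_chars(reference)
  unlist(lapply(diff_codon, function(c) {
    pos <- (3L * c - 2L):(3L * c)
    pos[proj$res[pos - proj$ref_start + 1L] != ref_chars[pos] &
          proj$res[pos - proj$ref_start + 1L] %in% c("A", "C", "G", "T")]
  }), use.names = FALSE)
}

# divergence (proportion) of a projection from a consensus vector in
# reference coordinates; NA if no comparable sites
projection_p <- function(proj, consensus) {
  idx <- proj$ref_start:proj$ref_end
  h <- proj$res
  k <- consensus[idx]
  comp <- comparable_mask(h) & !is.na(k) & comparable_mask(k)
  if (!any(comp)) return(NA_real_)
  sum(h[comp] != k[comp]) / sum(comp)
}

# per-site majority consensus over a list of projections, in reference
# coordinates (ties broken A < C < G < T; NA where uncovered)
group_consensus <- function(projections, ref_len) {
  counts <- matrix(0L, 4, ref_len, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (proj in projections) {
    idx <- proj$ref_start:proj$ref_end
    ok <- comparable_mask(proj$res)
    if (any(ok)) {
      tab <- table(factor(proj$res[ok], levels = c("A", "C", "G", "T")),
                   idx[ok])
      counts[, as.integer(colnames(tab))] <-
        counts[, as.integer(colnames(tab))] + unclass(tab)
    }
  }
  covered <- colSums(counts) > 0
  cons <- rep(NA_character_, ref_len)
  cons[covered] <- rownames(counts)[apply(counts[, covered, drop = FALSE], 2,
                                          which.max)]
  cons
}

#' Criterion (iii): anomalous polymorphisms
#'
#' Flags a haplotype when any of three tests fires: (a) a terminal window of
#' at least `cluster_min_len` bp whose non-synonymous substitution density
#' reaches `cluster_density` with at least `cluster_min_count` substitutions;
#' (b) whole-sequence divergence from the group consensus at or above
#' `outlier_pct` percent (run only when the group has 3 or more haplotypes);
#' (c) higher identity to a supplied decoy sequence (another species,
#' chloroplast, ...) than to the group consensus. An empty decoy set disables
#' test (c), which is recorded in the evidence.
#'
#' @param projection a projection from [screen_criterion_i()].
#' @param reference the full-length gene.
#' @param consensus group consensus vector in reference coordinates (from the
#'   other group members), or `NULL` when unavailable.
#' @param group_n number of haplotypes in the group.
#' @param decoys optional sequence tibble of decoy sequences.
#' @param config a [screen_config()].
#' @return A list: `flag` and `evidence` (tibble of test, description,
#'   coordinates).
#' @export
screen_criterion_iii <- function(projection, reference, consensus = NULL,
                                 group_n = 1L, decoys = NULL,
                                 config = screen_config()) {
  code_tbl <- genetic_code_table(config$genetic_code)
  ev <- list()
  flag <- FALSE

  # (a) terminal non-synonymous clusters
  ns <- nonsyn_positions(projection, reference, code_tbl)
  cov_len <- projection$ref_end - projection$ref_start + 1L
  if (cov_len >= config$cluster_min_len && length(ns) >= config$cluster_min_count) {
    offsets5 <- ns - projection$ref_start + 1L # 1-based from 5' end
    offsets3 <- projection$ref_end - ns + 1L   # 1-based from 3' end
    for (side in c("5'", "3'")) {
      off <- if (side == "5'") offsets5 else offsets3
      Ls <- seq.int(config$cluster_min_len, cov_len)
      cnt <- vapply(Ls, function(L) sum(off <= L), integer(1))
      hit <- cnt >= config$cluster_min_count & cnt / Ls >= config$cluster_density
      if (any(hit)) {
        L <- Ls[which(hit)[1]]
        flag <- TRUE
        ev[[length(ev) + 1L]] <- tibble::tibble(
          test = "cluster",
          description = sprintf(
            "%d non-synonymous substitutions in %d bp at %s end", cnt[which(hit)[1]],
            L, side),
          coordinates = sprintf(
            "ref %d-%d",
            if (side == "5'") projection$ref_start else projection$ref_end - L + 1L,
            if (side == "5'") projection$ref_start + L - 1L else projection$ref_end))
        break
      }
    }
  }

  # (b) outlying divergence from the group consensus
  p_cons <- NA_real_
  if (!is.null(consensus)) {
    p_cons <- projection_p(projection, consensus)
    if (group_n >= 3 && !is.na(p_cons) && 100 * p_cons >= config$outlier_pct) {
      flag <- TRUE
      ev[[length(ev) + 1L]] <- tibble::tibble(
        test = "outlier",
        description = sprintf("%.2f%% divergence from group consensus (cut-off %.1f%%)",
                              100 * p_cons, config$outlier_pct),
        coordinates = sprintf("ref %d-%d", projection$ref_start, projection$ref_end))
    }
  }

  # (c) closer to a decoy than to the group
  if (is.null(decoys) || nrow(decoys) == 0) {
    ev[[length(ev) + 1L]] <- tibble::tibble(
      test = "decoy", description = "no decoy set supplied; test disabled",
      coordinates = NA_character_)
  } else if (!is.na(p_cons)) {
    partial <- paste(projection$res[projection$res != "-"], collapse = "")
    id_cons <- 1 - p_cons
    for (k in seq_len(nrow(decoys))) {
      id_dec <- tryCatch({
        aln <- map_partial_to_reference(partial, decoys$seq[k],
                                        min_identity = 0)
        aln$identity
      }, error = function(e) NA_real_)
      if (!is.na(id_dec) && id_dec > id_cons) {
        flag <- TRUE
        ev[[length(ev) + 1L]] <- tibble::tibble(
          test = "decoy",
          description = sprintf("identity %.2f%% to decoy '%s' exceeds %.2f%% to group consensus",
                                100 * id_dec, decoys$id[k], 100 * id_cons),
          coordinates = NA_character_)
        break
      }
    }
  }

  list(flag = flag,
       evidence = if (length(ev)) dplyr::bind_rows(ev) else
         tibble::tibble(test = character(), description = character(),
                        coordinates = character()))
}

#' Criterion (iv): substitutions at conserved amino-acid positions
#'
#' Assessed only for haplotypes passing criteria (i) and (ii), which callers
#' must ensure. The haplotype's translation is compared, column by column in
#' reference-codon coordinates, with a panel of reference proteins; a residue
#' differing from the panel at a column conserved across all panel members
#' flags the haplotype. Columns where the panel itself varies are ignored.
#'
#' @param projection a projection from [screen_criterion_i()].
#' @param panel a [build_reference_panel()] result whose columns correspond
#'   to reference codons.
#' @param config a [screen_config()].
#' @return A list: `flag`, `status` ("ok" or "too_short"), and `violations`,
#'   a tibble of codon index, panel residue and observed residue.
#' @export
screen_criterion_iv <- function(projection, panel, config = screen_config()) {
  code_tbl <- genetic_code_table(config$genetic_code)
  codons <- covered_codons(projection)
  aa <- projection_aa(projection, codons, code_tbl)
  keep <- codons <= length(panel$conserved_mask)
  codons <- codons[keep]; aa <- aa[keep]
  assessable <- aa != "X"
  if (sum(assessable) < config$min_aa_length) {
    return(list(flag = FALSE, status = "too_short",
                violations = tibble::tibble(codon = integer(),
                                            panel = character(),
                                            observed = character())))
  }
  panel_res <- seq_chars(panel$proteins[1])[codons]
  bad <- assessable & panel$conserved_mask[codons] & aa != panel_res
  list(flag = any(bad), status = "ok",
       violations = tibble::tibble(codon = codons[bad], panel = panel_res[bad],
                                   observed = aa[bad]))
}

#' Screen a haplotype dataset and summarise per group
#'
#' Runs criteria (i)-(iv) on every haplotype, gated as in the screening
#' protocol: the amino-acid level analyses ((ii) and (iv)) run only on
#' INDEL-free haplotypes, and (iv) additionally requires no premature stop.
#' A haplotype flagged by several criteria appears in every applicable
#' per-criterion count but only once in the union ("potential NUMTs total").
#'
#' @param haps a tibble with columns `id`, `group`, `seq` (typically the
#'   output of [collapse_haplotypes()] joined back to groups, or a raw
#'   sequence tibble).
#' @param references full-length reference gene per group: a named character
#'   vector (names = group labels), or a single string used for all groups.
#' @param panel optional [build_reference_panel()] result (criterion iv is
#'   skipped without it).
#' @param decoys optional sequence tibble of decoys for criterion (iii)(c).
#' @param config a [screen_config()].
#' @return A list of class `"screen_report"`: `flags` (per-haplotype tibble
#'   with flag columns, status and an `evidence` list-column) and `summary`
#'   (per-group counts: `total`, `n_indel`, `n_stop`, `n_polymorphism`,
#'   `n_aa_change`, `n_flagged`, `pct_flagged`).
#' @export
screen_dataset <- function(haps, references, panel = NULL, decoys = NULL,
                           config = screen_config()) {
  stopifnot(all(c("id", "seq") %in% names(haps)))
  if (!"group" %in% names(haps)) haps$group <- "all"
  haps$group[is.na(haps$group)] <- "ungrouped"
  groups <- unique(haps$group)
  if (length(references) == 1 && is.null(names(references))) {
    references <- stats::setNames(rep(references, length(groups)), groups)
  }
  missing_ref <- setdiff(groups, names(references))
  if (length(missing_ref) > 0) {
    stop("no reference gene for group(s): ", paste(missing_ref, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (g in groups) {
    sub <- haps[haps$group == g, ]
    if (nrow(sub) == 0) { warning("group '", g, "' has no haplotypes; omitted"); next }
    reference <- references[[g]]
    projections <- purrr::map(sub$seq, function(s) {
      tryCatch(project_partial(s, reference, config), error = function(e) e)
    })
    ok <- !purrr::map_lgl(projections, inherits, "error")
    consensus <- if (any(ok)) {
      group_consensus(projections[ok], nchar(reference))
    } else NULL
    for (k in seq_len(nrow(sub))) {
      if (!ok[k]) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = sub$id[k], group = g, flag_i = NA, flag_ii = NA, flag_iii = NA,
          flag_iv = NA, analysed_at_aa_level = FALSE, status = "unalignable",
          evidence = list(tibble::tibble(
            test = "mapping", description = conditionMessage(projections[[k]]),
            coordinates = NA_character_)))
        next
      }
      proj <- projections[[k]]
      flag_i <- nrow(proj$indels) > 0
      aa_level <- !flag_i
      flag_ii <- NA
      if (aa_level) {
        flag_ii <- screen_criterion_ii(proj, reference, config)$flag
      }
      res3 <- screen_criterion_iii(proj, reference, consensus,
                                   group_n = sum(ok), decoys = decoys,
                                   config = config)
      flag_iv <- NA
      status <- "ok"
      if (aa_level && !isTRUE(flag_ii) && !is.null(panel)) {
        res4 <- screen_criterion_iv(proj, panel, config)
        flag_iv <- res4$flag
        if (res4$status == "too_short") status <- "too_short_for_aa"
      }
      ev <- res3$evidence
      if (flag_i) {
        ev <- dplyr::bind_rows(tibble::tibble(
          test = "indel",
          description = sprintf("%s of %d bp ('%s')", proj$indels$kind,
                                proj$indels$length, proj$indels$residues),
          coordinates = sprintf("ref %d (homopolymer run %d)",
                                proj$indels$ref_position,
                                proj$indels$homopolymer_run)), ev)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sub$id[k], group = g, flag_i = flag_i, flag_ii = flag_ii,
        flag_iii = res3$flag, flag_iv = flag_iv,
        analysed_at_aa_level = aa_level, status = status, evidence = list(ev))
    }
  }
  flags <- dplyr::bind_rows(rows)
  summary <- flags |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      total = dplyr::n(),
      n_indel = sum(.data$flag_i, na.rm = TRUE),
      n_stop = sum(.data$flag_ii, na.rm = TRUE),
      n_polymorphism = sum(.data$flag_iii, na.rm = TRUE),
      n_aa_change = sum(.data$flag_iv, na.rm = TRUE),
      n_flagged = sum(.data$flag_i | isTRUE_v(.data$flag_ii) |
                        isTRUE_v(.data$flag_iii) | isTRUE_v(.data$flag_iv),
                      na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(pct_flagged = screen_percent(.data$n_flagged, .data$total))
  structure(list(flags = flags, summary = summary, config = config),
            class = "screen_report")
}

isTRUE_v <- function(x) !is.na(x) & x

#' Percent of haplotypes flagged, to one decimal
#' @param flagged,total counts.
#' @return `round(100 * flagged / total, 1)`.
#' @export
screen_percent <- function(flagged, total) round(100 * flagged / total, 1)

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  print(x$summary)
  invisible(x)
}

#' Tidy a screen report into per-haplotype flags
#' @param x a `screen_report`.
#' @param ... unused.
#' @return The per-haplotype flags tibble.
#' @export
tidy.screen_report <- function(x, ...) x$flags

#' One-row overview of a screen report
#' @param x a `screen_report`.
#' @param ... unused.
#' @return A one-row tibble: groups, haplotypes, flagged count and percent.
#' @export
glance.screen_report <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$summary),
                 total = sum(x$summary$total),
                 n_flagged = sum(x$summary$n_flagged),
                 pct_flagged = screen_percent(sum(x$summary$n_flagged),
                                              sum(x$summary$total)))
}

#' Write a screen report to disk
#'
#' Writes the per-group summary as TSV and JSON and the per-haplotype
#' evidence as TSV.
#'
#' @param report a `screen_report`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$summary, file.path(dir, "screen_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            config = unclass(report$config)),
                       file.path(dir, "screen_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ev <- report$flags |>
    dplyr::select("id", "group", "evidence") |>
    tidyr::unnest("evidence")
  flags_flat <- report$flags |> dplyr::select(-"evidence")
  utils::write.table(flags_flat, file.path(dir, "screen_flags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ev, file.path(dir, "screen_evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
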