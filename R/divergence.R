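# Jukes-Cantor nucleotide divergence: pairwise p-distances with pairwise (or
# complete) deletion of gaps and ambiguity codes, JC correction over all
# compared sites, between-group means, fixed-region matrices and
# sliding-window profiles.

# Columns where both residues are unambiguous bases; everything else (gaps,
# IUPAC ambiguity codes) is excluded from the comparison.
comparable_mask <- function(chars) chars %in% c("A", "C", "G", "T")

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# mismatches and compared sites for one pair of equal-length strings,
# optionally restricted to a site mask
p_count <- function(a, b, mask = NULL) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  if (length(ca) != length(cb)) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  comp <- comparable_mask(ca) & comparable_mask(cb)
  if (!is.null(mask)) comp <- comp & mask
  c(mismatch = sum(ca != cb & comp), sites = sum(comp))
}

#' Observed proportion of differing sites (p-distance)
#'
#' Compared sites are alignment columns where both residues are unambiguous
#' bases (A, C, G, T): gaps and IUPAC ambiguity codes are excluded pairwise.
#'
#' @param a,b equal-length aligned nucleotide strings.
#' @return A one-row tibble with `p` (mismatch proportion) and `sites`
#'   (number of compared positions).
#' @export
pairwise_p <- function(a, b) {
  n <- p_count(a, b)
  if (n[["sites"]] == 0L) stop("no comparable sites", call. = FALSE)
  tibble::tibble(p = n[["mismatch"]] / n[["sites"]], sites = n[["sites"]])
}

#' Jukes-Cantor correction
#'
#' Converts an observed mismatch proportion into estimated substitutions per
#' site under the Jukes-Cantor model, `d = -(3/4) log(1 - (4/3) p)`, applied
#' over all compared sites (silent and replacement alike).
#'
#' @param p numeric vector of mismatch proportions in `[0, 0.75)`.
#' @return Corrected divergence `d` (substitutions/site).
#' @export
jc_correct <- function(p) {
  if (any(p < 0 | p >= 0.75)) {
    stop("Jukes-Cantor correction undefined for p outside [0, 0.75)", call. = FALSE)
  }
  -0.75 * log(1 - (4 / 3) * p)
}

#' Jukes-Cantor distance between two aligned sequences
#' @inheritParams pairwise_p
#' @return A one-row tibble with `p`, `d` and `sites`.
#' @export
jc_distance <- function(a, b) {
  res <- pairwise_p(a, b)
  tibble::tibble(p = res$p, d = jc_correct(res$p), sites = res$sites)
}

slice_region <- function(seqs, region) {
  if (is.null(region)) return(seqs)
  stopifnot(length(region) == 2)
  extract_region(seqs, region[1], region[2], suffix_id = FALSE)
}

complete_mask <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs$seq, "", fixed = TRUE))
  apply(mat, 2, function(col) all(comparable_mask(col)))
}

#' Between-group average Jukes-Cantor divergence
#'
#' The Dxy-style statistic: the arithmetic mean of JC-corrected pairwise
#' distances over all inter-group sequence pairs, optionally restricted to a
#' region.
#'
#' @param seqs an aligned sequence tibble (equal lengths).
#' @param ids_a,ids_b disjoint, non-empty vectors of sequence ids.
#' @param region optional `c(start, end)` (1-based inclusive).
#' @param deletion `"pairwise"` (default) excludes gap/ambiguity columns per
#'   pair; `"complete"` excludes them once, across all sequences involved.
#' @return A one-row tibble: `d` (mean), `d_min`, `d_max` (extremes over
#'   pairs), `p_mean`, `n_pairs`.
#' @export
group_divergence <- function(seqs, ids_a, ids_b, region = NULL,
                             deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(length(ids_a) >= 1, length(ids_b) >= 1)
  if (length(intersect(ids_a, ids_b)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  sub <- slice_region(seqs[seqs$id %in% c(ids_a, ids_b), ], region)
  missing <- setdiff(c(ids_a, ids_b), sub$id)
  if (length(missing) > 0) {
    stop("unknown sequence ids: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  mask <- if (deletion == "complete") complete_mask(sub) else NULL
  lookup <- stats::setNames(sub$seq, sub$id)
  pairs <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE)
  ps <- purrr::map2_dbl(pairs$a, pairs$b, function(i, j) {
    n <- p_count(lookup[[i]], lookup[[j]], mask)
    if (n[["sites"]] == 0L) stop("no comparable sites", call. = FALSE)
    n[["mismatch"]] / n[["sites"]]
  })
  ds <- jc_correct(ps)
  tibble::tibble(d = mean(ds), d_min = min(ds), d_max = max(ds),
                 p_mean = mean(ps), n_pairs = length(ds))
}

#' Sliding-window divergence profile along an alignment
#'
#' Windows start at 1, 1 + step, ... for as long as the full window fits in
#' the alignment (the final partial window is discarded). Within each window
#' the between-group mean, minimum and maximum JC divergences are computed for
#' every comparison.
#'
#' @param seqs an aligned sequence tibble.
#' @param comparisons a named list; each element is `list(a = ids, b = ids)`
#'   naming the two groups to compare. See [group_pair()] for building these
#'   from the `group` column.
#' @param window window length in bp (default 657, the partial-barcode
#'   length).
#' @param step step in bp (default 5).
#' @inheritParams group_divergence
#' @return A tibble of class `"window_profile"` with columns `comparison`,
#'   `start`, `midpoint`, `d`, `d_min`, `d_max`; attributes `window` and
#'   `step`.
#' @export
sliding_window <- function(seqs, comparisons, window = 657L, step = 5L,
                           deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(is.list(comparisons), length(comparisons) >= 1)
  if (is.null(names(comparisons)) || any(!nzchar(names(comparisons)))) {
    stop("comparisons must be a named list", call. = FALSE)
  }
  len <- unique(nchar(seqs$seq))
  if (length(len) != 1) stop("sequences must be aligned to equal length", call. = FALSE)
  if (step < 1) stop("step must be >= 1", call. = FALSE)
  if (window > len) {
    stop(sprintf("window (%d) exceeds alignment length (%d)", window, len),
         call. = FALSE)
  }
  starts <- seq.int(1L, len - window + 1L, by = step)
  lookup <- stats::setNames(seqs$seq, seqs$id)
  mask <- if (deletion == "complete") complete_mask(seqs) else rep(TRUE, len)
  profiles <- purrr::imap(comparisons, function(cmp, name) {
    stopifnot(all(c("a", "b") %in% names(cmp)))
    pairs <- expand.grid(a = cmp$a, b = cmp$b, stringsAsFactors = FALSE)
    # per-pair cumulative mismatch / comparable-site counts
    per_pair <- purrr::map2(pairs$a, pairs$b, function(i, j) {
      ca <- seq_chars(lookup[[i]]); cb <- seq_chars(lookup[[j]])
      comp <- comparable_mask(ca) & comparable_mask(cb) & mask
      mism <- comp & ca != cb
      list(comp = c(0, cumsum(comp)), mism = c(0, cumsum(mism)))
    })
    d_pairs <- purrr::map(per_pair, function(pp) {
      sites <- pp$comp[starts + window] - pp$comp[starts]
      mism <- pp$mism[starts + window] - pp$mism[starts]
      if (any(sites == 0)) stop("no comparable sites in a window", call. = FALSE)
      jc_correct(mism / sites)
    })
    dmat <- do.call(cbind, d_pairs)
    tibble::tibble(comparison = name, start = starts,
                   midpoint = starts + (window - 1) / 2,
                   d = rowMeans(dmat),
                   d_min = apply(dmat, 1, min),
                   d_max = apply(dmat, 1, max))
  })
  out <- dplyr::bind_rows(profiles)
  attr(out, "window") <- as.integer(window)
  attr(out, "step") <- as.integer(step)
  class(out) <- c("window_profile", class(out))
  out
}

#' Ids of sequences belonging to a group expression
#'
#' Group expressions combine labels with `+`, e.g. `"Q1+Q2"`.
#' @param seqs a sequence tibble with a `group` column.
#' @param expr a group expression.
#' @return Character vector of ids.
#' @export
group_ids <- function(seqs, expr) {
  labs <- strsplit(expr, "+", fixed = TRUE)[[1]]
  ids <- seqs$id[seqs$group %in% labs]
  if (length(ids) == 0) stop("no sequences in group '", expr, "'", call. = FALSE)
  ids
}

#' Build a comparison between two group expressions
#' @inheritParams group_ids
#' @param a,b group expressions (see [group_ids()]).
#' @return A `list(a = ids, b = ids)` suitable for [sliding_window()].
#' @export
group_pair <- function(seqs, a, b) {
  list(a = group_ids(seqs, a), b = group_ids(seqs, b))
}

#' Pairwise divergence matrix over a region
#'
#' @param seqs an aligned sequence tibble (or the `seqs` element of a
#'   [build_concatenation()] result).
#' @param region optional `c(start, end)`; `NULL` uses the full alignment.
#' @param region_label descriptor stored with the matrix (defaults to the
#'   coordinates or "full").
#' @inheritParams group_divergence
#' @return A symmetric matrix of class `"divergence_matrix"` holding percent
#'   JC divergences (100 * d), zero diagonal; attributes `unit` ("percent")
#'   and `region`.
#' @export
region_matrix <- function(seqs, region = NULL, region_label = NULL,
                          deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (inherits(seqs, "concatenation")) seqs <- seqs$seqs
  sub <- slice_region(seqs, region)
  if (is.null(region_label)) {
    region_label <- if (is.null(region)) "full" else paste(region, collapse = "-")
  }
  n <- nrow(sub)
  mask <- if (deletion == "complete") complete_mask(sub) else NULL
  m <- matrix(0, n, n, dimnames = list(sub$id, sub$id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        cnt <- p_count(sub$seq[i], sub$seq[j], mask)
        if (cnt[["sites"]] == 0L) stop("no comparable sites", call. = FALSE)
        m[i, j] <- m[j, i] <- 100 * jc_correct(cnt[["mismatch"]] / cnt[["sites"]])
      }
    }
  }
  as_divergence_matrix(m, region = region_label)
}

#' Mark a matrix as a percent divergence matrix
#' @param m a symmetric numeric matrix with dimnames.
#' @param region region descriptor.
#' @param unit unit of the entries.
#' @return The matrix with class `"divergence_matrix"`.
#' @export
as_divergence_matrix <- function(m, region = "full", unit = "percent") {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  structure(m, class = c("divergence_matrix", "matrix"),
            unit = unit, region = region)
}

#' Tidy a divergence matrix into long form
#' @param x a `divergence_matrix`.
#' @param ... unused.
#' @return A tibble with `sample_a`, `sample_b`, `d` (one row per unordered
#'   pair).
#' @export
tidy.divergence_matrix <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(sample_a = labs[idx[, 1]], sample_b = labs[idx[, 2]],
                 d = x[idx])
}

#' Export a divergence matrix
#'
#' `"phylip"` writes a square PHYLIP distance matrix with per-site values;
#' `"tsv"` writes a labelled table in percent with the unit stated in a
#' header comment.
#'
#' @param m a `divergence_matrix` (percent).
#' @param path output path.
#' @param format `"phylip"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_matrix <- function(m, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  labs <- rownames(m)
  if (any(is.na(labs) | !nzchar(labs))) stop("matrix labels must be non-empty", call. = FALSE)
  if (format == "phylip") {
    lines <- c(sprintf("%5d", nrow(m)),
               vapply(seq_len(nrow(m)), function(i) {
                 paste(formatC(labs[i], width = -10),
                       paste(sprintf("%.6f", m[i, ] / 100), collapse = " "))
               }, character(1)))
    writeLines(lines, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# divergence matrix; unit: percent; region: %s",
                       attr(m, "region")), con)
    df <- data.frame(sample = labs, unclass(m)[, , drop = FALSE],
                     check.names = FALSE)
    utils::write.table(format(df, digits = NULL, nsmall = 6, trim = TRUE,
                              scientific = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a TSV divergence matrix written by [export_matrix()]
#' @param path path to the TSV file.
#' @return A `divergence_matrix` in percent.
#' @export
read_matrix_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  region <- sub("^.*region: ", "", hdr)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  as_divergence_matrix(m, region = region)
}
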