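# Threshold-based putative-species grouping and cross-region concordance.
# The 3.5% divergence boundary splits: pairs at or above the threshold belong
# to different clusters; samples are joined when connected by a chain of
# pairwise divergences strictly below it (single linkage).

#' Single-linkage species delimitation at a divergence threshold
#'
#' @param m a `divergence_matrix` in percent (see [region_matrix()]).
#' @param threshold percent divergence; pairs with `d < threshold` may be
#'   chained into one cluster, pairs at or above it are split.
#' @param linkage `"single"` (default; chains of below-threshold pairs join)
#'   or `"complete"` (every within-cluster pair must be below threshold), the
#'   latter for sensitivity analysis.
#' @return A tibble with columns `sample` and `cluster` (integer ids numbered
#'   by first appearance); attribute `threshold`.
#' @export
single_linkage_delimit <- function(m, threshold = 3.5,
                                   linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  labs <- rownames(m)
  n <- length(labs)
  if (linkage == "single") {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in seq.int(i + 1, n)) {
          if (m[i, j] < threshold) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
          }
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    cluster <- match(roots, unique(roots))
  } else {
    hc <- stats::hclust(stats::as.dist(m), method = "complete")
    eps <- sqrt(.Machine$double.eps)
    cl <- stats::cutree(hc, h = threshold * (1 - eps))
    cluster <- match(cl, unique(cl))
  }
  out <- tibble::tibble(sample = labs, cluster = as.integer(cluster))
  attr(out, "threshold") <- threshold
  out
}

co_clustered <- function(clusters) {
  cl <- stats::setNames(clusters$cluster, clusters$sample)
  function(a, b) cl[[a]] == cl[[b]]
}

#' Cross-region delimitation discordance report
#'
#' Delimits every region's matrix at the same threshold and lists each sample
#' pair whose co-cluster status flips between regions, together with the two
#' divergence values: the headline signature of region-dependent barcode
#' delimitation.
#'
#' @param matrices a named list of `divergence_matrix` objects over the same
#'   sample labels (names are region labels).
#' @param threshold percent divergence threshold.
#' @param linkage passed to [single_linkage_delimit()].
#' @return A list of class `"delimitation_result"`: `threshold`, `clusters`
#'   (named list of per-region cluster tibbles) and `discordant_pairs`
#'   (tibble: `sample_a`, `sample_b`, `region_joined`, `region_split`,
#'   `d_joined`, `d_split`).
#' @export
discordance_report <- function(matrices, threshold = 3.5,
                               linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(is.list(matrices), length(matrices) >= 1)
  if (is.null(names(matrices)) || any(!nzchar(names(matrices)))) {
    stop("matrices must be a named list (names = region labels)", call. = FALSE)
  }
  labs <- sort(rownames(matrices[[1]]))
  for (r in names(matrices)) {
    if (!identical(sort(rownames(matrices[[r]])), labs)) {
      stop("sample labels differ between region matrices ('", r, "')",
           call. = FALSE)
    }
  }
  clusters <- purrr::map(matrices, single_linkage_delimit,
                         threshold = threshold, linkage = linkage)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  regions <- names(matrices)
  rows <- list()
  for (pr in pairs) {
    joined <- purrr::map_lgl(clusters, ~ co_clustered(.x)(pr[1], pr[2]))
    if (length(unique(joined)) > 1) {
      for (rj in regions[joined]) for (rs in regions[!joined]) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_a = pr[1], sample_b = pr[2],
          region_joined = rj, region_split = rs,
          d_joined = matrices[[rj]][pr[1], pr[2]],
          d_split = matrices[[rs]][pr[1], pr[2]])
      }
    }
  }
  discordant <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(sample_a = character(), sample_b = character(),
                   region_joined = character(), region_split = character(),
                   d_joined = numeric(), d_split = numeric())
  structure(list(threshold = threshold, clusters = clusters,
                 discordant_pairs = discordant),
            class = "delimitation_result")
}

#' @export
print.delimitation_result <- function(x, ...) {
  cat(sprintf("<delimitation_result> threshold %.2f%%, %d region(s), %d discordant pair(s)\n",
              x$threshold, length(x$clusters), nrow(x$discordant_pairs)))
  for (r in names(x$clusters)) {
    k <- length(unique(x$clusters[[r]]$cluster))
    cat(sprintf("  %s: %d cluster(s)\n", r, k))
  }
  if (nrow(x$discordant_pairs) > 0) print(x$discordant_pairs)
  invisible(x)
}

#' Tidy a delimitation result into per-region cluster assignments
#' @param x a `delimitation_result`.
#' @param ... unused.
#' @return A tibble with `region`, `sample`, `cluster`.
#' @export
tidy.delimitation_result <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$clusters,
                               ~ dplyr::mutate(.x, region = .y, .before = 1)))
}

#' One-row overview of a delimitation result
#' @param x a `delimitation_result`.
#' @param ... unused.
#' @return A one-row tibble: threshold, number of regions, cluster counts and
#'   discordant-pair count.
#' @export
glance.delimitation_result <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, n_regions = length(x$clusters),
                 n_clusters_min = min(purrr::map_int(x$clusters, ~ max(.x$cluster))),
                 n_clusters_max = max(purrr::map_int(x$clusters, ~ max(.x$cluster))),
                 n_discordant = nrow(x$discordant_pairs))
}

#' Write a delimitation result as JSON and readable text
#' @param result a `delimitation_result`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_delimitation <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(threshold = result$threshold,
         clusters = purrr::map(result$clusters, ~ split(.x$sample, .x$cluster)),
         discordant_pairs = result$discordant_pairs),
    file.path(dir, "delimitation.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  txt <- c(sprintf("Species delimitation at %.2f%% divergence threshold",
                   result$threshold), "")
  for (r in names(result$clusters)) {
    cl <- result$clusters[[r]]
    txt <- c(txt, sprintf("Region %s:", r),
             vapply(split(cl$sample, cl$cluster), function(s)
               paste0("  cluster: ", paste(s, collapse = ", ")), character(1)),
             "")
  }
  if (nrow(result$discordant_pairs) > 0) {
    txt <- c(txt, "Discordant pairs:",
             sprintf("  %s / %s: joined in %s (%.2f%%), split in %s (%.2f%%)",
                     result$discordant_pairs$sample_a,
                     result$discordant_pairs$sample_b,
                     result$discordant_pairs$region_joined,
                     result$discordant_pairs$d_joined,
                     result$discordant_pairs$region_split,
                     result$discordant_pairs$d_split))
  } else {
    txt <- c(txt, "No discordant pairs.")
  }
  writeLines(txt, file.path(dir, "delimitation.txt"))
  invisible(dir)
}

#' Percent identity of partial haplotypes to a reference partial
#'
#' Each partial is aligned to the reference partial (semiglobal) and percent
#' identity over compared sites, `100 * (1 - p)`, is reported. Unalignable
#' records are listed with a status rather than failing the run.
#'
#' @param partials a sequence tibble.
#' @param reference_partial a nucleotide string.
#' @param min_identity floor below which a record is reported unalignable.
#' @return A tibble: `id`, `identity_pct`, `sites`, `status`.
#' @export
similarity_report <- function(partials, reference_partial, min_identity = 0.6) {
  rows <- purrr::map2(partials$id, partials$seq, function(id, s) {
    aln <- tryCatch(
      map_partial_to_reference(s, reference_partial, min_identity = min_identity),
      error = function(e) NULL)
    if (is.null(aln)) {
      return(tibble::tibble(id = id, identity_pct = NA_real_,
                            sites = NA_integer_, status = "unalignable"))
    }
    a <- seq_chars(aln$aligned_a); b <- seq_chars(aln$aligned_b)
    comp <- comparable_mask(a) & comparable_mask(b)
    tibble::tibble(id = id,
                   identity_pct = 100 * sum(a[comp] == b[comp]) / sum(comp),
                   sites = sum(comp), status = "ok")
  })
  dplyr::bind_rows(rows)
}
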