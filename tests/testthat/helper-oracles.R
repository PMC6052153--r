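# Independent oracles and shared fixtures for the test suite. The oracles are
# deliberately naive re-derivations, structured differently from the package
# implementations they check.

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Affine-gap global alignment score by memoised top-down recursion over
# (i, j, previous-move), enumerating column choices directly.
oracle_align_score <- function(a, b, match = 2, mismatch = -1,
                               gap_open = -6, gap_extend = -1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    if (i > n && j > m) return(0)
    key <- paste0(i, ",", j, ",", state)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (A[i] == B[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) { # consume A[i] against a gap in b
      pen <- if (state == "GB") gap_extend else gap_open
      best <- max(best, pen + rec(i + 1, j, "GB"))
    }
    if (j <= m) { # consume B[j] against a gap in a
      pen <- if (state == "GA") gap_extend else gap_open
      best <- max(best, pen + rec(i, j + 1, "GA"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "M")
}

# Naive per-column mismatch count over unambiguous bases.
oracle_p <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  sites <- 0L; mism <- 0L
  for (k in seq_along(A)) {
    if (A[k] %in% c("A", "C", "G", "T") && B[k] %in% c("A", "C", "G", "T")) {
      sites <- sites + 1L
      if (A[k] != B[k]) mism <- mism + 1L
    }
  }
  list(p = mism / sites, sites = sites)
}

# Connected components of the graph joining pairs with d < threshold,
# by breadth-first search.
oracle_components <- function(m, threshold) {
  n <- nrow(m)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- which(m[v, ] < threshold & is.na(comp))
      queue <- c(queue, setdiff(nb, v))
    }
  }
  comp
}

# Canonical form of a partition: sorted list of sorted member groups.
canonical_partition <- function(samples, clusters) {
  groups <- split(samples, clusters)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, character(1), collapse = ",")),
        collapse = "|")
}

random_distance_matrix <- function(n, max_d = 7) {
  m <- matrix(0, n, n)
  vals <- stats::runif(n * (n - 1) / 2, 0, max_d)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  numtsweep::as_divergence_matrix(m)
}

# Reapply called INDEL events to the reference segment covered by the
# alignment; for an indel-only derivative this reconstructs the partial.
apply_indel_events <- function(reference, ref_offset, ref_cov_len, events) {
  s <- substr(reference, ref_offset, ref_offset + ref_cov_len - 1)
  if (nrow(events) == 0) return(s)
  ev <- events[order(-events$ref_position), ]
  for (k in seq_len(nrow(ev))) {
    loc <- ev$ref_position[k] - ref_offset + 1L
    if (ev$kind[k] == "deletion") {
      s <- paste0(substr(s, 1, loc), substr(s, loc + 1L + ev$length[k], nchar(s)))
    } else {
      s <- paste0(substr(s, 1, loc), ev$residues[k], substr(s, loc + 1L, nchar(s)))
    }
  }
  s
}

# Shared default synthetic dataset and its screen report, computed once per
# session (the screen is the expensive step).
.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(seed = 1L) {
  key <- paste0("ds", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- numtsweep::simulate_dataset(numtsweep::sim_config(seed = seed))
  }
  .fixture_cache[[key]]
}

get_fixture_screen <- function(seed = 1L) {
  key <- paste0("screen", seed)
  if (is.null(.fixture_cache[[key]])) {
    ds <- get_fixture(seed)
    decoys_partial <- numtsweep::extract_region(ds$decoys, ds$config$barcode3[1],
                                                ds$config$barcode3[2],
                                                suffix_id = FALSE)
    .fixture_cache[[key]] <- numtsweep::screen_dataset(
      ds$records, ds$references, panel = ds$panel, decoys = decoys_partial)
  }
  .fixture_cache[[key]]
}
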