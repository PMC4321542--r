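## Shared synthetic fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

## desk-size three-library experiment used across test files
test_config <- function(seed = 42) {
  synthetic_config(
    seed = seed,
    library_sizes = c(control = 15000L, drought = 15000L, salt = 15000L),
    background_unique = 400L
  )
}

get_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_srna_experiment(test_config())
  }
  .fixture_env$sim
}

## cleaned/collapsed/annotated/matched table + discovered loci (cached: the
## discovery step folds a few hundred windows)
get_pipeline <- function() {
  if (is.null(.fixture_env$pipe)) {
    sim <- get_sim()
    cleaned <- lapply(sim$libraries, clean_reads, adapter = sim$config$adapter)
    collapsed <- collapse_reads(cleaned)
    ann <- annotate_category(collapsed, sim$contaminant_catalog,
                             sim$known_catalog)
    ann <- match_reference(ann, list(genome = sim$contigs))
    loci <- discover_mirnas(ann, sim$contigs, sim$known_catalog)
    .fixture_env$pipe <- list(cleaned = cleaned, collapsed = collapsed,
                              annotated = ann, loci = loci)
  }
  .fixture_env$pipe
}

## brute-force maximum base-pair count over all nested structures (min loop
## `min_loop`), by explicit recursion over "first position unpaired or paired
## with k" -- the independent oracle for fold_hairpin on short windows
brute_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(toupper(seq), "")[[1]]
  ok <- function(a, b) {
    paste0(ch[a], ch[b]) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  rec <- function(lo, hi) {
    if (hi <= lo) return(0L)
    best <- rec(lo + 1L, hi)
    k <- lo + min_loop + 1L
    while (k <= hi) {
      if (ok(lo, k)) {
        best <- max(best, 1L + rec(lo + 1L, k - 1L) + rec(k + 1L, hi))
      }
      k <- k + 1L
    }
    best
  }
  rec(1L, length(ch))
}

## brute-force read-vs-catalog distance: all offsets, read-side overhang
## counted as mismatches
brute_offset_distance <- function(read, entry) {
  r <- strsplit(read, "")[[1]]
  e <- strsplit(entry, "")[[1]]
  best <- length(r) + 1L
  for (o in seq(-(length(r) - 1L), length(e) - 1L)) {
    matches <- 0L
    for (p in seq_along(r)) {
      q <- p + o
      if (q >= 1 && q <= length(e) && r[p] == e[q]) matches <- matches + 1L
    }
    best <- min(best, length(r) - matches)
  }
  best
}

## dense independent power iteration for the CitationRank oracle
brute_rank <- function(M, damping = 0.85, iters = 5000) {
  n <- nrow(M)
  freq <- diag(M)
  r0 <- if (sum(freq) > 0) freq / sum(freq) else rep(1 / n, n)
  A <- M
  diag(A) <- 0
  Tm <- matrix(0, n, n)
  for (j in seq_len(n)) {
    s <- sum(A[, j])
    Tm[, j] <- if (s > 0) A[, j] / s else r0
  }
  r <- r0
  for (i in seq_len(iters)) r <- damping * Tm %*% r + (1 - damping) * r0
  setNames(as.vector(r), rownames(M))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
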