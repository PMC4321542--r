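## read_processing module: clean, collapse, categorize and summarize the
## small-RNA libraries; library similarity.

CATEGORY_LEVELS <- c("miRNA", "rRNA", "snRNA", "snoRNA", "tRNA", "repeat",
                     "unannotated")
## exclusion priority when a read matches several contaminant entries
CONTAMINANT_PRIORITY <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")

#' Clean a raw small-RNA library
#'
#' Removes the 3' adapter at its leftmost full occurrence (or a terminal
#' partial match of at least 6 nt), then drops reads that are too short, too
#' long (which catches untrimmed reads at machine read length), contain `N`,
#' or carry any base below the quality floor after trimming. The counts of
#' dropped reads by reason are attached as the `"drop_log"` attribute.
#'
#' @param reads Tibble with columns `id`, `sequence` and optionally
#'   `quality` (Phred+33).
#' @param adapter 3' adapter sequence (non-empty).
#' @param min_len,max_len Retained insert length window (nt).
#' @param quality_floor Minimum per-base Phred score; reads with any base
#'   below it are dropped (ignored when there is no `quality` column).
#' @return Tibble of cleaned reads (`id`, `sequence`, and `quality` if
#'   supplied), inserts only, with attribute `drop_log`.
#' @export
#' @examples
#' reads <- tibble::tibble(
#'   id = "r1", sequence = paste0("ACGTACGTACGTACGTACGTA", "TGGAATTCTCGGG"),
#'   quality = strrep("I", 34)
#' )
#' clean_reads(reads, adapter = "TGGAATTCTCGGGTGCCAAGG")
clean_reads <- function(reads, adapter, min_len = 18L, max_len = 30L,
                        quality_floor = 20L) {
  stopifnot(nchar(adapter) > 0, all(c("id", "sequence") %in% names(reads)))
  has_qual <- "quality" %in% names(reads)
  if (has_qual) {
    bad <- which(nchar(reads$quality) != nchar(reads$sequence))
    if (length(bad)) {
      stop(sprintf("malformed FASTQ record %d: sequence/quality length differ",
                   bad[1]), call. = FALSE)
    }
  }
  seqs <- toupper(reads$sequence)
  n <- length(seqs)
  ## leftmost full adapter occurrence
  cut <- regexpr(adapter, seqs, fixed = TRUE)
  cut <- ifelse(cut > 0, cut, NA_integer_)
  ## terminal partial match >= 6 nt for reads without a full occurrence
  miss <- which(is.na(cut))
  if (length(miss) && nchar(adapter) - 1L >= 6L) {
    for (k in seq(nchar(adapter) - 1L, 6L)) {
      if (!length(miss)) break
      pre <- substr(adapter, 1L, k)
      hit <- endsWith(seqs[miss], pre)
      cut[miss[hit]] <- nchar(seqs[miss[hit]]) - k + 1L
      miss <- miss[!hit]
    }
  }
  insert_len <- ifelse(is.na(cut), nchar(seqs), cut - 1L)
  out <- reads
  out$sequence <- substr(seqs, 1L, insert_len)
  if (has_qual) out$quality <- substr(reads$quality, 1L, insert_len)

  reason <- rep(NA_character_, n)
  reason[insert_len < min_len] <- "too_short"
  reason[is.na(reason) & insert_len > max_len] <- "too_long_or_untrimmed"
  reason[is.na(reason) & grepl("N", out$sequence, fixed = TRUE)] <- "contains_n"
  if (has_qual) {
    idx <- which(is.na(reason))
    if (length(idx)) {
      low <- min_quality(out$quality[idx]) < quality_floor
      reason[idx[low]] <- "low_quality"
    }
  }
  drop_log <- tibble::tibble(reason = names(table(reason)),
                             n = as.integer(table(reason)))
  kept <- out[is.na(reason), , drop = FALSE]
  attr(kept, "drop_log") <- drop_log
  kept
}

#' Collapse cleaned libraries into unique reads with per-library counts
#'
#' @param libraries Named list of cleaned read tibbles (see [clean_reads()]);
#'   the names become the count column suffixes.
#' @return Tibble with one row per distinct sequence: `sequence`, `length`,
#'   and one `count_<library>` column per input library.
#' @export
collapse_reads <- function(libraries) {
  stopifnot(length(libraries) >= 1, !is.null(names(libraries)))
  tabs <- purrr::imap(libraries, function(lib, nm) {
    if (nrow(lib) == 0) {
      return(tibble::tibble(sequence = character(0), !!paste0("count_", nm) := integer(0)))
    }
    dplyr::count(lib, .data$sequence, name = paste0("count_", nm))
  })
  out <- purrr::reduce(tabs, dplyr::full_join, by = "sequence")
  out <- dplyr::mutate(out, dplyr::across(dplyr::starts_with("count_"),
                                          ~ tidyr::replace_na(.x, 0L)))
  out <- dplyr::mutate(out, length = nchar(.data$sequence), .after = "sequence")
  dplyr::arrange(out, .data$sequence)
}

#' Per-library totals of a collapsed read set
#'
#' @param collapsed Result of [collapse_reads()].
#' @return Tibble with `library`, `total_unique`, `total_redundant`.
#' @export
library_stats <- function(collapsed) {
  cols <- grep("^count_", names(collapsed), value = TRUE)
  purrr::map_dfr(cols, function(cl) {
    tibble::tibble(
      library = sub("^count_", "", cl),
      total_unique = sum(collapsed[[cl]] > 0),
      total_redundant = sum(collapsed[[cl]])
    )
  })
}

## enumerate all substrings of catalog entries within the read-length window,
## keeping the highest-priority class per substring
substring_dictionary <- function(entries, classes, min_len = 18L,
                                 max_len = 30L) {
  pieces <- purrr::map2(entries, classes, function(e, cl) {
    el <- nchar(e)
    lens <- min_len:min(max_len, el)
    if (!length(lens) || el < min_len) return(NULL)
    subs <- unlist(lapply(lens, function(l) {
      substring(e, seq_len(el - l + 1L), seq_len(el - l + 1L) + l - 1L)
    }))
    tibble::tibble(sequence = subs, class = cl)
  })
  dict <- dplyr::bind_rows(pieces)
  if (nrow(dict) == 0) return(dict)
  dict$priority <- match(dict$class, CONTAMINANT_PRIORITY)
  dict <- dict[order(dict$priority), ]
  dict[!duplicated(dict$sequence), c("sequence", "class")]
}

#' Align reads against the known-miRNA catalog (ungapped, <= 3 mismatches)
#'
#' Distance is the Hamming distance at the best ungapped offset, with read
#' positions hanging off the catalog sequence counted as mismatches; a hit is
#' returned iff the distance is at most `max_mismatch`. Ties are broken by
#' lower distance, then lexicographic catalog id.
#'
#' @param reads Character vector of read sequences (18-30 nt), or a collapsed
#'   tibble with a `sequence` column.
#' @param known_catalog Tibble with `id`, `family`, `sequence`.
#' @param max_mismatch Maximum allowed distance (default 3, the conserved-read
#'   rule).
#' @return Tibble with `sequence`, `hit_id`, `family`, `distance` (`NA` for
#'   no hit).
#' @export
#' @examples
#' cat <- tibble::tibble(id = "a", family = "miR1",
#'                       sequence = "ACGTACGTACGTACGTACGTA")
#' assign_known("ACGTACGTACGTACGTACGTA", cat)$distance
assign_known <- function(reads, known_catalog, max_mismatch = 3L) {
  if (is.data.frame(reads)) reads <- reads$sequence
  cat <- dplyr::arrange(known_catalog, .data$id)
  if (length(reads) == 0) {
    return(tibble::tibble(sequence = character(0), hit_id = character(0),
                          family = character(0), distance = integer(0)))
  }
  best <- .offset_distance_best(reads, cat$sequence)
  hit <- best[, 2] <= max_mismatch
  tibble::tibble(
    sequence = reads,
    hit_id = ifelse(hit, cat$id[best[, 1]], NA_character_),
    family = ifelse(hit, cat$family[best[, 1]], NA_character_),
    distance = ifelse(hit, best[, 2], NA_integer_)
  )
}

#' Categorize collapsed reads
#'
#' Reads exactly substring-matching a contaminant catalog entry take that
#' entry's class (tie priority rRNA > tRNA > snRNA > snoRNA > repeat);
#' contaminant exclusion happens before miRNA assignment. Remaining reads
#' within `max_mismatch` of a known miRNA are `miRNA`; everything else is
#' `unannotated`.
#'
#' @param collapsed Collapsed read tibble (see [collapse_reads()]).
#' @param contaminant_catalog Tibble with `class` and `sequence`.
#' @param known_catalog Tibble with `id`, `family`, `sequence`.
#' @param max_mismatch Conserved-read mismatch allowance (default 3).
#' @return `collapsed` plus `category` (factor with the full category set)
#'   and, for miRNA reads, `mirna_family`.
#' @export
annotate_category <- function(collapsed, contaminant_catalog, known_catalog,
                              max_mismatch = 3L) {
  stopifnot(nrow(contaminant_catalog) > 0, nrow(known_catalog) > 0)
  lens <- range(collapsed$length, 18L, 30L)
  dict <- substring_dictionary(contaminant_catalog$sequence,
                               contaminant_catalog$class,
                               min_len = lens[1], max_len = lens[2])
  cls <- dict$class[match(collapsed$sequence, dict$sequence)]
  category <- cls
  family <- rep(NA_character_, nrow(collapsed))
  todo <- which(is.na(category))
  if (length(todo)) {
    hits <- assign_known(collapsed$sequence[todo], known_catalog, max_mismatch)
    is_mir <- !is.na(hits$distance)
    category[todo[is_mir]] <- "miRNA"
    family[todo[is_mir]] <- hits$family[is_mir]
    category[todo[!is_mir]] <- "unannotated"
  }
  collapsed$category <- factor(category, levels = CATEGORY_LEVELS)
  collapsed$mirna_family <- family
  collapsed
}

#' Match reads back to reference sequence sets
#'
#' A read matches a set iff it is an exact full-length substring of some
#' sequence in that set; genome-like sets are searched on both strands,
#' transcript sets sense-only. An `matched_any` column is the union over all
#' sets.
#'
#' @param collapsed Collapsed read tibble.
#' @param references Named list of reference tibbles (`id`, `sequence`).
#' @param both_strands Named logical (per reference set) or single logical;
#'   default `TRUE` (genomic convention).
#' @return `collapsed` plus one `matched_<set>` logical column per set and
#'   `matched_any`.
#' @export
match_reference <- function(collapsed, references, both_strands = TRUE) {
  stopifnot(length(references) >= 1, !is.null(names(references)))
  if (length(both_strands) == 1) {
    both_strands <- setNames(rep(both_strands, length(references)),
                             names(references))
  }
  seqs <- collapsed$sequence
  for (nm in names(references)) {
    subj <- Biostrings::DNAStringSet(references[[nm]]$sequence)
    if (isTRUE(both_strands[[nm]])) {
      subj <- c(subj, Biostrings::reverseComplement(subj))
    }
    matched <- rep(FALSE, length(seqs))
    for (w in unique(nchar(seqs))) {
      idx <- which(nchar(seqs) == w)
      pd <- Biostrings::PDict(seqs[idx])
      cnt <- Biostrings::vcountPDict(pd, subj)
      matched[idx] <- rowSums(cnt) > 0
    }
    collapsed[[paste0("matched_", nm)]] <- matched
  }
  mcols <- paste0("matched_", names(references))
  collapsed$matched_any <- Reduce(`|`, collapsed[mcols])
  collapsed
}

#' Library similarity over the most abundant reads (Jaccard index)
#'
#' Takes each library's `n_top` most abundant unique sequences (ties broken
#' lexicographically for determinism) and reports
#' `|A intersect B| / |A union B| * 100`.
#'
#' @param collapsed Collapsed read tibble.
#' @param lib_a,lib_b Library names (count column suffixes).
#' @param n_top Number of top sequences per library (default 5000).
#' @return Tibble with `library_a`, `library_b`, `n_top`, `jaccard_percent`.
#' @export
jaccard_top <- function(collapsed, lib_a, lib_b, n_top = 5000L) {
  top_of <- function(lib) {
    cl <- paste0("count_", lib)
    stopifnot(cl %in% names(collapsed))
    x <- collapsed[collapsed[[cl]] > 0, c("sequence", cl)]
    stopifnot(nrow(x) >= 1)
    x <- x[order(-x[[cl]], x$sequence), ]
    head(x$sequence, n_top)
  }
  a <- top_of(lib_a)
  b <- top_of(lib_b)
  tibble::tibble(
    library_a = lib_a, library_b = lib_b, n_top = n_top,
    jaccard_percent = 100 * length(intersect(a, b)) / length(union(a, b))
  )
}

#' All pairwise library similarities
#'
#' @inheritParams jaccard_top
#' @return Tibble of [jaccard_top()] rows for every unordered library pair.
#' @export
library_similarity <- function(collapsed, n_top = 5000L) {
  libs <- sub("^count_", "", grep("^count_", names(collapsed), value = TRUE))
  pairs <- utils::combn(libs, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    jaccard_top(collapsed, pairs[1, i], pairs[2, i], n_top)
  })
}

#' Read-length distribution per library
#'
#' @param collapsed Collapsed read tibble (optionally filtered, e.g. to
#'   reference-matched reads, before calling).
#' @return Long tibble: `length`, `library`, `unique_count`,
#'   `redundant_count`, with zero-filled bins over the observed length range.
#' @export
size_distribution <- function(collapsed) {
  cols <- grep("^count_", names(collapsed), value = TRUE)
  rng <- if (nrow(collapsed)) range(collapsed$length) else c(18L, 30L)
  grid <- tidyr::expand_grid(length = rng[1]:rng[2],
                             library = sub("^count_", "", cols))
  obs <- purrr::map_dfr(cols, function(cl) {
    x <- collapsed[collapsed[[cl]] > 0, ]
    dplyr::summarise(
      dplyr::group_by(x, .data$length),
      library = sub("^count_", "", cl),
      unique_count = dplyr::n(),
      redundant_count = sum(.data[[cl]]),
      .groups = "drop"
    )
  })
  out <- dplyr::left_join(grid, obs, by = c("length", "library"))
  dplyr::mutate(out,
                unique_count = tidyr::replace_na(.data$unique_count, 0L),
                redundant_count = tidyr::replace_na(as.numeric(.data$redundant_count), 0))
}

#' Per-category library table (unique/redundant counts and percentages)
#'
#' The category breakdown each library's reads fall into, mirroring the
#' standard small-RNA categorization table layout.
#'
#' @param annotated Collapsed tibble after [annotate_category()] (and
#'   optionally [match_reference()]).
#' @return Tibble: `library`, `category`, `unique`, `redundant`,
#'   `unique_pct`, `redundant_pct` (percentages of the library totals).
#' @export
category_table <- function(annotated) {
  stopifnot("category" %in% names(annotated))
  cols <- grep("^count_", names(annotated), value = TRUE)
  purrr::map_dfr(cols, function(cl) {
    x <- annotated[annotated[[cl]] > 0, ]
    tot_u <- nrow(x)
    tot_r <- sum(x[[cl]])
    out <- dplyr::summarise(
      dplyr::group_by(x, .data$category, .drop = FALSE),
      unique = dplyr::n(), redundant = sum(.data[[cl]]), .groups = "drop"
    )
    dplyr::mutate(out,
                  library = sub("^count_", "", cl), .before = 1,
                  unique_pct = 100 * .data$unique / tot_u,
                  redundant_pct = 100 * .data$redundant / tot_r)
  })
}
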