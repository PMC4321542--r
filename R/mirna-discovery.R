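## mirna_discovery module: hairpin folding, duplex geometry, novelty calls,
## redundancy removal, families and genomic clusters.

#' Candidate reads for precursor search
#'
#' Keeps collapsed reads with at least `min_reads` counts in at least one
#' library, an exact reference match, and no contaminant class (miRNA or
#' unannotated category only).
#'
#' @param annotated Collapsed tibble after [annotate_category()] and
#'   [match_reference()].
#' @param min_reads Per-library count threshold (default 3, the
#'   sequencing-error guard).
#' @return Filtered tibble.
#' @export
candidate_reads <- function(annotated, min_reads = 3L) {
  stopifnot(all(c("category", "matched_any") %in% names(annotated)))
  cols <- grep("^count_", names(annotated), value = TRUE)
  enough <- Reduce(`|`, lapply(cols, function(cl) annotated[[cl]] >= min_reads))
  keep <- enough & annotated$matched_any &
    annotated$category %in% c("miRNA", "unannotated")
  annotated[keep, , drop = FALSE]
}

#' Fold a precursor window by base-pair maximization
#'
#' Nested secondary structure maximizing Watson-Crick plus G:U pairs with a
#' minimum loop of `min_loop` unpaired bases, computed by dynamic
#' programming; among maximal structures the one pairing positions closest
#' to the window center is chosen, making the result deterministic.
#'
#' @param window DNA window sequence (<= 400 nt).
#' @param min_loop Minimum hairpin loop length (default 3).
#' @return A list of class `hairpin_candidate`: `sequence`, `pairing`
#'   (integer partner per position, 0 = unpaired), `max_pairs`; or `NULL`
#'   when the window is shorter than the smallest mature-plus-loop hairpin
#'   (39 nt).
#' @export
#' @examples
#' fold_hairpin("GGGAAACCC")$max_pairs
fold_hairpin <- function(window, min_loop = 3L) {
  n <- nchar(window)
  if (n > 400) stop("window longer than 400 nt", call. = FALSE)
  if (n < 39) return(NULL)
  res <- .nussinov_fold(toupper(window), min_loop)
  structure(list(sequence = toupper(window), pairing = res$pairing,
                 max_pairs = res$max_pairs),
            class = "hairpin_candidate")
}

## pairing partner at position t, trusting only the consistent stem positions
## in `stem`; elsewhere extrapolate from the nearest stem position (stems are
## locally antiparallel, so partner(t) ~ partner(q) + (q - t))
partner_at <- function(pairing, t, stem) {
  if (t %in% stem) return(pairing[t])
  if (!length(stem)) return(NA_integer_)
  q <- stem[which.min(abs(stem - t))]
  pairing[q] + (q - t)
}

#' Evaluate a mapped read as a miRNA locus within a folded window
#'
#' Acceptance requires (a) at least `min_paired_frac` of mature positions
#' paired onto the dominant arm, (b) the mature wholly on one arm (more
#' than 20% of positions pairing within the mature span marks a
#' loop-spanning read; stray pairings to the minority side count as
#' structural noise, not arm evidence), (c) a star computed from the
#' duplex geometry with 2-nt 3' overhangs on both duplex ends that does
#' not overlap the mature, and (d) at most `max_bulge` nt of asymmetric
#' bulge within the largest consistent stem segment. Star support is
#' counted from collapsed reads falling inside the star region extended by
#' `star_slop` nt on each side (length within 4 nt of the mature).
#'
#' @param mature Mature (read) sequence; must occur in the window.
#' @param candidate A [fold_hairpin()] result for the window.
#' @param collapsed Optional collapsed read tibble for star-count lookup.
#' @param min_paired_frac Minimum fraction of paired mature positions.
#' @param max_bulge Maximum summed duplex asymmetry (nt).
#' @param star_slop Star-region extension for support counting (nt).
#' @return A list with mature/star window coordinates (1-based inclusive),
#'   sequences, `arm`, `paired_frac`, `bulge`, the trimmed `precursor` and
#'   its window offset, and `star_counts` (named per library, zeros when
#'   `collapsed` is `NULL`); or `NULL` when rejected.
#' @export
evaluate_locus <- function(mature, candidate, collapsed = NULL,
                           min_paired_frac = 0.6, max_bulge = 4L,
                           star_slop = 3L) {
  if (is.null(candidate)) return(NULL)
  win <- candidate$sequence
  L <- nchar(mature)
  mlo <- as.integer(regexpr(mature, win, fixed = TRUE))
  if (mlo < 1) return(NULL)
  mhi <- mlo + L - 1L
  span <- mlo:mhi
  pairing <- candidate$pairing
  partners <- pairing[span]
  paired <- partners > 0
  ## (b) one arm: mature must not fold onto itself (spanning the loop);
  ## occasional stray pairings to the minority side are treated as unpaired
  ## noise of the maximum-pairing structure, not as arm evidence
  inside <- paired & partners >= mlo & partners <= mhi
  if (sum(inside) > 0.2 * L) return(NULL)
  n5 <- sum(paired & partners < mlo)
  n3 <- sum(paired & partners > mhi)
  if (n3 >= n5) {
    arm <- "5p"
    good <- paired & partners > mhi
  } else {
    arm <- "3p"
    good <- paired & partners < mlo
  }
  ## keep the largest consistent stem segment: stray pairings that would
  ## imply an asymmetry jump beyond max_bulge are noise, not duplex
  pidx <- span[good]
  bulge <- 0L
  if (length(pidx) >= 2) {
    jump <- abs(diff(pidx) - abs(diff(pairing[pidx])))
    seg <- cumsum(c(1L, jump > max_bulge))
    pidx <- pidx[seg == which.max(tabulate(seg))]
    if (length(pidx) >= 2) {
      bulge <- sum(abs(diff(pidx) - abs(diff(pairing[pidx]))))
    }
  }
  ## (a) pairing fraction on the duplex arm, (d) duplex asymmetry
  if (length(pidx) < min_paired_frac * L) return(NULL)
  if (bulge > max_bulge) return(NULL)
  ## (c) star from 2-nt 3' overhang geometry
  p_hi <- partner_at(pairing, mhi - 2L, pidx)
  p_lo <- partner_at(pairing, mlo, pidx)
  if (is.na(p_hi) || is.na(p_lo)) return(NULL)
  star_lo <- min(p_hi, p_lo + 2L)
  star_hi <- max(p_hi, p_lo + 2L)
  star_lo <- max(1L, star_lo)
  star_hi <- min(nchar(win), star_hi)
  if (star_hi - star_lo + 1L < L - 4L) return(NULL)
  ## mature and star must be non-overlapping subsequences on opposite arms
  if (star_lo <= mhi && star_hi >= mlo) return(NULL)
  star <- substr(win, star_lo, star_hi)
  prec_lo <- max(1L, min(mlo, star_lo) - 7L)
  prec_hi <- min(nchar(win), max(mhi, star_hi) + 7L)

  star_counts <- NULL
  if (!is.null(collapsed)) {
    cols <- grep("^count_", names(collapsed), value = TRUE)
    ext_lo <- max(1L, star_lo - star_slop)
    ext_hi <- min(nchar(win), star_hi + star_slop)
    ext <- substr(win, ext_lo, ext_hi)
    lens <- max(18L, L - 4L):min(30L, L + 4L, nchar(ext))
    subs <- unlist(lapply(lens, function(l) {
      if (nchar(ext) < l) return(character(0))
      substring(ext, seq_len(nchar(ext) - l + 1L),
                seq_len(nchar(ext) - l + 1L) + l - 1L)
    }))
    hit <- collapsed[collapsed$sequence %in% subs, cols, drop = FALSE]
    star_counts <- vapply(hit, sum, numeric(1))
  }
  list(
    mature = mature, mature_lo = mlo, mature_hi = mhi,
    star = star, star_lo = star_lo, star_hi = star_hi,
    arm = arm, paired_frac = length(pidx) / L, bulge = bulge,
    max_pairs = candidate$max_pairs,
    precursor = substr(win, prec_lo, prec_hi),
    precursor_lo = prec_lo, precursor_hi = prec_hi,
    star_counts = star_counts
  )
}

#' Conserved/novel labels for evaluated loci
#'
#' A locus is conserved when its mature is within `max_mismatch` of a known
#' miRNA (no star requirement: well-known miRNAs often lack a sequenced
#' star); otherwise it is novel iff its star has at least one read, by
#' default in the same library as the mature (set `same_library = FALSE` for
#' the looser any-library reading). Loci that are neither are dropped.
#'
#' @param loci Locus tibble from [discover_mirnas()] internals: needs
#'   `mature`, per-library `count_*` and `star_count_*` columns.
#' @param known_catalog Known-miRNA catalog (`id`, `family`, `sequence`).
#' @param max_mismatch Conserved-read mismatch allowance.
#' @param same_library Require mature and star to co-exist in one library.
#' @return `loci` filtered, with `novel` (logical), `catalog_id` and
#'   `catalog_family` columns.
#' @export
call_novel <- function(loci, known_catalog, max_mismatch = 3L,
                       same_library = TRUE) {
  if (nrow(loci) == 0) {
    return(dplyr::mutate(loci, novel = logical(0),
                         catalog_id = character(0),
                         catalog_family = character(0)))
  }
  hits <- assign_known(loci$mature, known_catalog, max_mismatch)
  conserved <- !is.na(hits$distance)
  ccols <- grep("^count_", names(loci), value = TRUE)
  scols <- paste0("star_", ccols)
  stopifnot(all(scols %in% names(loci)))
  if (same_library) {
    star_ok <- Reduce(`|`, lapply(seq_along(ccols), function(i) {
      loci[[ccols[i]]] >= 1 & loci[[scols[i]]] >= 1
    }))
  } else {
    star_ok <- Reduce(`|`, lapply(scols, function(cl) loci[[cl]] >= 1))
  }
  loci$novel <- !conserved
  loci$catalog_id <- hits$hit_id
  loci$catalog_family <- hits$family
  loci[conserved | (loci$novel & star_ok), , drop = FALSE]
}

## percent identity of the shorter sequence against the longer at the best
## ungapped offset
pair_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  d <- .offset_distance_best(a, b)[1, 2]
  100 * (nchar(a) - d) / nchar(a)
}

#' Remove redundant precursors
#'
#' Precursors at least `min_identity` percent identical over the shorter
#' length (best ungapped offset) are merged by single linkage; each merged
#' group keeps the locus with the highest summed mature count (ties: contig,
#' then start). Idempotent.
#'
#' @param loci Locus tibble with `precursor`, `contig`, `precursor_start`
#'   and per-library `count_*` columns.
#' @param min_identity Percent identity threshold (default 95, inclusive).
#' @return Deduplicated locus tibble.
#' @export
dedupe_precursors <- function(loci, min_identity = 95) {
  n <- nrow(loci)
  if (n <= 1) return(loci)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i] <<- comp[comp[i]]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (pair_identity(loci$precursor[i], loci$precursor[j]) >= min_identity) {
        comp[find(j)] <- find(i)
      }
    }
  }
  groups <- vapply(seq_len(n), find, 1L)
  ccols <- grep("^count_", names(loci), value = TRUE)
  ccols <- ccols[!startsWith(ccols, "star_")]
  total <- Reduce(`+`, loci[ccols])
  ord <- order(groups, -total, loci$contig, loci$precursor_start)
  keep <- ord[!duplicated(groups[ord])]
  loci[sort(keep), , drop = FALSE]
}

#' Cross-reference precursor homology
#'
#' A precursor is homologous to a reference set iff an ungapped sliding
#' alignment against some reference sequence reaches at least `min_identity`
#' percent identity over the full precursor length (inclusive threshold).
#'
#' @param precursors Character vector of precursor sequences (or locus
#'   tibble with a `precursor` column).
#' @param reference Reference tibble (`id`, `sequence`).
#' @param min_identity Percent identity threshold (default 95).
#' @return Logical vector.
#' @export
cross_genome_homology <- function(precursors, reference, min_identity = 95) {
  if (is.data.frame(precursors)) precursors <- precursors$precursor
  stopifnot(nrow(reference) > 0)
  if (!length(precursors)) return(logical(0))
  best <- .offset_distance_best(precursors, reference$sequence)
  ident <- 100 * (nchar(precursors) - best[, 2]) / nchar(precursors)
  ident >= min_identity
}

#' Group loci into miRNA families
#'
#' Conserved loci inherit the catalog family of their best hit; novel loci
#' are single-linkage clustered at `max_mismatch` mismatches between matures
#' (same ungapped offset distance as [assign_known()]) and named
#' `ghr-n1`, `ghr-n2`, ... in discovery order.
#'
#' @param loci Deduplicated locus tibble with `mature`, `novel`,
#'   `catalog_family` columns.
#' @param max_mismatch Linkage threshold between novel matures.
#' @return `loci` with a `family` column.
#' @export
assign_family <- function(loci, max_mismatch = 3L) {
  loci$family <- loci$catalog_family
  nov <- which(loci$novel)
  if (length(nov)) {
    mats <- loci$mature[nov]
    n <- length(mats)
    comp <- seq_len(n)
    find <- function(i) { while (comp[i] != i) i <- comp[i] <<- comp[comp[i]]; i }
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (.offset_distance_best(mats[i], mats[j])[1, 2] <= max_mismatch) {
            comp[find(j)] <- find(i)
          }
        }
      }
    }
    roots <- vapply(seq_len(n), find, 1L)
    fam_id <- match(roots, unique(roots))  # discovery order
    loci$family[nov] <- sprintf("ghr-n%d", fam_id)
  }
  loci
}

#' Genomic miRNA clusters
#'
#' Maximal runs of two or more loci on one contig whose consecutive start
#' gaps are at most `cluster_distance`.
#'
#' @param loci Locus tibble with `contig` and `precursor_start`.
#' @param cluster_distance Maximum gap between consecutive starts (nt,
#'   default 10 kb).
#' @return Tibble: `cluster_id`, `contig`, `n_loci`, `span`, `members`
#'   (list-column of row indices into `loci` ordered by start).
#' @export
find_clusters <- function(loci, cluster_distance = 10000L) {
  if (nrow(loci) == 0) {
    return(tibble::tibble(cluster_id = character(0), contig = character(0),
                          n_loci = integer(0), span = integer(0),
                          members = list()))
  }
  ord <- order(loci$contig, loci$precursor_start)
  contig <- loci$contig[ord]
  start <- loci$precursor_start[ord]
  newrun <- c(TRUE, contig[-1] != contig[-length(contig)] |
                diff(start) > cluster_distance)
  run <- cumsum(newrun)
  out <- purrr::map_dfr(split(seq_along(run), run), function(idx) {
    if (length(idx) < 2) return(NULL)
    tibble::tibble(contig = contig[idx[1]],
                   n_loci = length(idx),
                   span = max(start[idx]) - min(start[idx]),
                   members = list(ord[idx]))
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(cluster_id = character(0), contig = character(0),
                          n_loci = integer(0), span = integer(0),
                          members = list()))
  }
  dplyr::mutate(out, cluster_id = sprintf("cluster-%d", dplyr::row_number()),
                .before = 1)
}

#' Discover miRNA loci from collapsed, annotated, reference-matched reads
#'
#' The full discovery driver: selects candidate reads, locates each exactly
#' in the contigs, folds a `window_size`-nt window placed with `flank` nt on
#' the read's 5' side (plus the mirrored window; the better-evaluating one
#' is kept), applies the duplex geometry rules of [evaluate_locus()], labels
#' conserved/novel loci ([call_novel()]), removes redundant precursors
#' ([dedupe_precursors()]) and assigns families ([assign_family()]).
#'
#' @param annotated Collapsed tibble after [annotate_category()] and
#'   [match_reference()].
#' @param contigs Reference contig tibble (`id`, `sequence`).
#' @param known_catalog Known-miRNA catalog (`id`, `family`, `sequence`).
#' @param min_reads Candidate-read count threshold (default 3).
#' @param window_size,flank Folding window geometry (nt).
#' @param max_matches Positions examined per read (default 4).
#' @inheritParams evaluate_locus
#' @inheritParams call_novel
#' @param min_identity Dedupe identity threshold (percent).
#' @return Locus tibble: coordinates (1-based inclusive contig coordinates),
#'   mature/star/precursor sequences, arm, pairing diagnostics, per-library
#'   mature `count_*` and `star_count_*` columns, `novel`, `family`.
#' @export
discover_mirnas <- function(annotated, contigs, known_catalog,
                            min_reads = 3L, window_size = 200L, flank = 20L,
                            min_paired_frac = 0.6, max_bulge = 4L,
                            max_mismatch = 3L, same_library = TRUE,
                            min_identity = 95, max_matches = 4L) {
  cand <- candidate_reads(annotated, min_reads)
  if (nrow(cand) == 0) {
    return(empty_loci(grep("^count_", names(annotated), value = TRUE)))
  }
  hits <- locate_reads(cand$sequence, contigs, max_matches)
  ccols <- grep("^count_", names(cand), value = TRUE)
  rows <- vector("list", nrow(hits))
  for (h in seq_len(nrow(hits))) {
    seq_h <- hits$sequence[h]
    contig_seq <- contigs$sequence[contigs$id == hits$contig[h]]
    best <- NULL
    for (side in c("five", "three")) {
      if (side == "five") {
        wlo <- hits$start[h] - flank
      } else {
        wlo <- hits$end[h] + flank - window_size + 1L
      }
      wlo <- max(1L, min(wlo, nchar(contig_seq) - window_size + 1L))
      whi <- min(nchar(contig_seq), wlo + window_size - 1L)
      cand_fold <- fold_hairpin(substr(contig_seq, wlo, whi))
      ev <- evaluate_locus(seq_h, cand_fold, collapsed = annotated,
                          min_paired_frac = min_paired_frac,
                          max_bulge = max_bulge)
      if (!is.null(ev)) {
        ev$window_lo <- wlo
        if (is.null(best) ||
            ev$paired_frac > best$paired_frac ||
            (ev$paired_frac == best$paired_frac && ev$max_pairs > best$max_pairs)) {
          best <- ev
        }
      }
    }
    if (is.null(best)) next
    counts <- cand[cand$sequence == seq_h, ccols][1, ]
    off <- best$window_lo - 1L
    row <- tibble::tibble(
      contig = hits$contig[h],
      precursor_start = best$precursor_lo + off,
      precursor_end = best$precursor_hi + off,
      precursor = best$precursor,
      mature = best$mature,
      mature_start = best$mature_lo + off,
      mature_end = best$mature_hi + off,
      star = best$star,
      star_start = best$star_lo + off,
      star_end = best$star_hi + off,
      arm = best$arm,
      paired_frac = best$paired_frac,
      bulge = best$bulge
    )
    row[ccols] <- counts
    row[paste0("star_", ccols)] <- as.list(best$star_counts)
    rows[[h]] <- row
  }
  loci <- dplyr::bind_rows(rows)
  if (nrow(loci) == 0) return(empty_loci(ccols))
  ## one locus per distinct mature: keep the best-pairing placement
  loci <- dplyr::arrange(loci, dplyr::desc(.data$paired_frac),
                         .data$contig, .data$mature_start)
  loci <- loci[!duplicated(loci$mature), , drop = FALSE]
  loci <- call_novel(loci, known_catalog, max_mismatch, same_library)
  loci <- dedupe_precursors(loci, min_identity)
  loci <- assign_family(loci, max_mismatch)
  loci <- dplyr::arrange(loci, .data$contig, .data$precursor_start)
  dplyr::mutate(loci, locus_id = sprintf("locus-%03d", dplyr::row_number()),
                .before = 1)
}

empty_loci <- function(ccols) {
  out <- tibble::tibble(
    locus_id = character(0), contig = character(0),
    precursor_start = integer(0), precursor_end = integer(0),
    precursor = character(0), mature = character(0),
    mature_start = integer(0), mature_end = integer(0),
    star = character(0), star_start = integer(0), star_end = integer(0),
    arm = character(0), paired_frac = numeric(0), bulge = integer(0),
    novel = logical(0), catalog_id = character(0),
    catalog_family = character(0), family = character(0)
  )
  for (cl in ccols) out[[cl]] <- integer(0)
  for (cl in ccols) out[[paste0("star_", cl)]] <- numeric(0)
  out
}

## exact sense-strand positions of reads in contigs (up to max_matches each)
locate_reads <- function(seqs, contigs, max_matches = 4L) {
  out <- list()
  for (w in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == w)
    pd <- Biostrings::PDict(seqs[idx])
    for (ci in seq_len(nrow(contigs))) {
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(contigs$sequence[ci]))
      starts <- Biostrings::startIndex(m)
      for (k in seq_along(idx)) {
        st <- starts[[k]]
        if (is.null(st) || !length(st)) next
        st <- head(st, max_matches)
        out[[length(out) + 1L]] <- tibble::tibble(
          sequence = seqs[idx[k]], contig = contigs$id[ci],
          start = st, end = st + w - 1L
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(sequence = character(0), contig = character(0),
                          start = integer(0), end = integer(0)))
  }
  ## cap total positions per read
  res <- dplyr::arrange(res, .data$sequence, .data$contig, .data$start)
  res <- dplyr::group_by(res, .data$sequence)
  res <- dplyr::slice_head(res, n = max_matches)
  dplyr::ungroup(res)
}

#' Export discovered loci as GFF3
#'
#' Writes `miRNA_primary_transcript` and `miRNA` features (1-based inclusive,
#' sense strand) for a locus table.
#'
#' @param loci Result of [discover_mirnas()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_loci_gff3 <- function(loci, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(loci))) {
    id <- loci$locus_id[i]
    lines <- c(lines,
      paste(loci$contig[i], "stressmir", "miRNA_primary_transcript",
            loci$precursor_start[i], loci$precursor_end[i], ".", "+", ".",
            sprintf("ID=%s;family=%s;novel=%s", id, loci$family[i],
                    tolower(loci$novel[i])), sep = "\t"),
      paste(loci$contig[i], "stressmir", "miRNA",
            loci$mature_start[i], loci$mature_end[i], ".", "+", ".",
            sprintf("ID=%s.mature;Parent=%s", id, id), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
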