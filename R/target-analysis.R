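## target_analysis module: plant-style complementarity scoring, target-site
## scanning, and degradome (PARE) cleavage-site validation.

## seed-proximal region where penalties are doubled (miRNA positions, 5'->3')
SEED_REGION <- 2:13

#' Score a miRNA/target-window duplex
#'
#' Plant complementarity scoring of an ungapped antiparallel duplex between
#' a miRNA and a same-length target window: per miRNA position (1..L from
#' the 5' end) a Watson-Crick pair costs 0, a G:U wobble 0.5 and a mismatch
#' 1, with penalties doubled at positions 2-13. The window is the target
#' site read 5'->3', so miRNA position k faces window position L+1-k.
#'
#' @param mirna miRNA sequence (DNA alphabet).
#' @param window Target window sequence, same length.
#' @return List with `score`, `codes` (per miRNA position: `"|"` match,
#'   `"o"` G:U, `"x"` mismatch) and `alignment` (the codes as one string).
#' @export
#' @examples
#' score_duplex("ACGTACGTACGTACGTACGTA", revcomp("ACGTACGTACGTACGTACGTA"))$score
score_duplex <- function(mirna, window) {
  L <- nchar(mirna)
  stopifnot(nchar(window) == L)
  mi <- strsplit(toupper(mirna), "")[[1]]
  tg <- strsplit(toupper(window), "")[[1]][L:1]  # antiparallel partner per k
  wc <- chartr("ACGT", "TGCA", mi) == tg
  gu <- (mi == "G" & tg == "T") | (mi == "T" & tg == "G")
  codes <- ifelse(wc, "|", ifelse(gu, "o", "x"))
  pen <- ifelse(wc, 0, ifelse(gu, 0.5, 1))
  pen[SEED_REGION[SEED_REGION <= L]] <- 2 * pen[SEED_REGION[SEED_REGION <= L]]
  list(score = sum(pen), codes = codes,
       alignment = paste(codes, collapse = ""))
}

#' Scan a transcriptome for miRNA target sites
#'
#' Evaluates every window of each transcript with [score_duplex()] rules
#' (vectorized) and keeps sites with score at most `max_score`, no more than
#' `max_run` consecutive mismatches, and at most `max_seed_mismatch`
#' mismatches within miRNA positions 2-13. Output is ordered by miRNA id,
#' transcript id, then position.
#'
#' @param mirnas Tibble with `mirna_id` and `mature` (or `id`/`sequence`)
#'   columns, or a named character vector.
#' @param transcripts Tibble with `id`, `sequence`.
#' @param max_score Maximum penalty score (default 4.0).
#' @param max_run Maximum allowed run of consecutive mismatches (default 2).
#' @param max_seed_mismatch Maximum mismatches in positions 2-13 (default 1).
#' @return Tibble of target sites: `mirna_id`, `transcript_id`,
#'   `site_start`, `site_end` (1-based inclusive), `score`, `alignment`.
#' @export
scan_targets <- function(mirnas, transcripts, max_score = 4.0,
                         max_run = 2L, max_seed_mismatch = 1L) {
  stopifnot(nrow(transcripts) > 0)
  if (is.character(mirnas)) {
    mirnas <- tibble::tibble(mirna_id = names(mirnas), mature = unname(mirnas))
  }
  if (!"mirna_id" %in% names(mirnas)) {
    mirnas <- dplyr::rename(mirnas, mirna_id = "id", mature = "sequence")
  }
  out <- list()
  for (i in seq_len(nrow(mirnas))) {
    mi <- strsplit(toupper(mirnas$mature[i]), "")[[1]]
    L <- length(mi)
    comp_mi <- chartr("ACGT", "TGCA", mi)
    seed <- SEED_REGION[SEED_REGION <= L]
    for (t in seq_len(nrow(transcripts))) {
      tx <- strsplit(toupper(transcripts$sequence[t]), "")[[1]]
      n <- length(tx)
      if (n < L) next
      n_win <- n - L + 1L
      ## target base facing miRNA position k in the window starting at s is
      ## tx[s + L - k]; build an L x n_win character matrix
      idx <- outer(L:1, 0:(n_win - 1L), `+`)  # row k: s + L - k
      tg <- matrix(tx[idx], nrow = L)
      wc <- tg == comp_mi
      gu <- (mi == "G" & tg == "T") | (mi == "T" & tg == "G")
      pen <- ifelse(wc, 0, ifelse(gu, 0.5, 1))
      pen[seed, ] <- 2 * pen[seed, ]
      score <- colSums(pen)
      mm <- !(wc | gu)
      seed_mm <- colSums(mm[seed, , drop = FALSE])
      runs <- apply(mm, 2, function(v) {
        r <- rle(v); max(c(0L, r$lengths[r$values]))
      })
      keep <- which(score <= max_score & runs <= max_run &
                      seed_mm <= max_seed_mismatch)
      if (!length(keep)) next
      codes <- ifelse(wc, "|", ifelse(gu, "o", "x"))
      out[[length(out) + 1L]] <- tibble::tibble(
        mirna_id = mirnas$mirna_id[i],
        transcript_id = transcripts$id[t],
        site_start = keep,
        site_end = keep + L - 1L,
        score = score[keep],
        alignment = apply(codes[, keep, drop = FALSE], 2, paste,
                          collapse = "")
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(mirna_id = character(0), transcript_id = character(0),
                          site_start = integer(0), site_end = integer(0),
                          score = numeric(0), alignment = character(0)))
  }
  dplyr::arrange(res, .data$mirna_id, .data$transcript_id, .data$site_start)
}

#' Validate predicted target sites against degradome tags
#'
#' The expected cleavage position of a site is the transcript nucleotide
#' paired to miRNA position 10 (the first nucleotide of the 3' cleavage
#' fragment, i.e. `site_end - 9`). Significance of the tag pileup there is
#' the upper-tail binomial probability of observing at least that many of
#' the transcript's tags at one position under a uniform per-position null
#' (probability 1/transcript length). A site is validated iff p <= 0.05 and
#' the alignment shows strict Watson-Crick matches at miRNA positions 10
#' and 11 (wobbles do not qualify).
#'
#' @param sites Target-site tibble from [scan_targets()].
#' @param degradome Tag tibble: `transcript_id`, `position` (1-based 5'
#'   end), `count`.
#' @param transcripts Transcript tibble (`id`, `sequence`) supplying
#'   lengths.
#' @param alpha Validation threshold on the binomial p-value.
#' @return `sites` plus `cleavage_pos`, `tags_at_site`, `total_tags`,
#'   `p_value`, `validated`.
#' @export
validate_targets <- function(sites, degradome, transcripts, alpha = 0.05) {
  lens <- setNames(nchar(transcripts$sequence), transcripts$id)
  totals <- dplyr::summarise(dplyr::group_by(degradome, .data$transcript_id),
                             total = sum(.data$count), .groups = "drop")
  tot <- setNames(totals$total, totals$transcript_id)
  out <- sites
  out$cleavage_pos <- sites$site_end - 9L
  key <- paste(degradome$transcript_id, degradome$position)
  hit <- match(paste(sites$transcript_id, out$cleavage_pos), key)
  out$tags_at_site <- ifelse(is.na(hit), 0L, degradome$count[hit])
  out$total_tags <- unname(tot[sites$transcript_id])
  out$total_tags[is.na(out$total_tags)] <- 0L
  tx_len <- unname(lens[sites$transcript_id])
  out$p_value <- ifelse(
    out$total_tags == 0, 1,
    pbinom(out$tags_at_site - 1L, out$total_tags, 1 / tx_len,
           lower.tail = FALSE)
  )
  pos_ok <- substr(sites$alignment, 10L, 10L) == "|" &
    substr(sites$alignment, 11L, 11L) == "|"
  out$validated <- out$p_value <= alpha & pos_ok
  out
}

#' Per-position degradome table for a T-plot
#'
#' @param degradome Tag tibble (`transcript_id`, `position`, `count`).
#' @param validation One row of [validate_targets()] output (or anything
#'   with `transcript_id` and `cleavage_pos`).
#' @return Tibble `position`, `count`, `at_cleavage` for the site's
#'   transcript.
#' @export
tplot_data <- function(degradome, validation) {
  x <- degradome[degradome$transcript_id == validation$transcript_id[1], ]
  tibble::tibble(
    position = x$position,
    count = x$count,
    at_cleavage = x$position == validation$cleavage_pos[1]
  )
}

#' T-plot of degradome tags with the predicted cleavage site marked
#'
#' @inheritParams tplot_data
#' @return A ggplot object.
#' @export
plot_tplot <- function(degradome, validation) {
  dat <- tplot_data(degradome, validation)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$count)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0),
                          colour = "grey40") +
    ggplot2::geom_point(data = dat[dat$at_cleavage, ], colour = "red",
                        size = 2) +
    ggplot2::labs(
      title = sprintf("%s on %s", validation$mirna_id[1],
                      validation$transcript_id[1]),
      x = "transcript position (5' tag end)", y = "tag count"
    ) +
    ggplot2::theme_minimal()
}
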