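## synthetic_data module: every input the pipeline consumes, with planted
## ground truth, generated deterministically from a single config.

#' Generate reference contigs, catalogs, transcripts and planted truth
#'
#' Builds the synthetic reference world for one experiment: random contigs
#' with planted miRNA hairpin precursors (two arms reverse-complementary over
#' the mature span, separated by a terminal loop), a known-miRNA catalog
#' containing the matures of the "conserved" loci plus decoys, a contaminant
#' catalog (rRNA/tRNA/snRNA/snoRNA), synthetic mRNAs hosting planted target
#' sites, and the expected per-condition read counts for every source
#' sequence. All coordinates are 1-based inclusive.
#'
#' The first three planted loci are placed on the same contig so that a
#' genomic miRNA cluster exists by construction.
#'
#' @param config A [synthetic_config()] object.
#' @return A list with tibbles `contigs`, `known_catalog`,
#'   `contaminant_catalog`, `transcripts`, and a `truth` list carrying
#'   `mirna_loci`, `sources` (expected per-condition counts summing exactly to
#'   each library size), `cleavage_sites`, and `cluster_contig`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "stressmir_config"))
  with_seed(config$seed, generate_reference_impl(config))
}

generate_reference_impl <- function(config) {
  L <- config$mature_length
  f <- config$flank_length
  loop <- config$loop_length
  prec_len <- 2L * f + 2L * L + loop
  ids <- mirna_ids(config$n_known_mirnas, config$n_novel_mirnas)
  n_mir <- nrow(ids)

  ## ---- planted hairpins ----
  matures <- random_dna(rep(L, n_mir))
  ## guard against accidental duplicate matures
  while (anyDuplicated(matures)) {
    dup <- duplicated(matures)
    matures[dup] <- random_dna(rep(L, sum(dup)))
  }
  loops <- random_dna(rep(loop, n_mir))
  flank5 <- random_dna(rep(f, n_mir))
  flank3 <- random_dna(rep(f, n_mir))
  arm2 <- revcomp(matures)
  if (config$stem_mismatches > 0) {
    for (i in seq_len(n_mir)) {
      pos <- sample(3:(L - 3), config$stem_mismatches)
      tmp <- arm2[i]
      for (p in pos) {
        old <- substring(tmp, p, p)
        substring(tmp, p, p) <- sample(setdiff(DNA_BASES, old), 1)
      }
      arm2[i] <- tmp
    }
  }
  precursors <- paste0(flank5, matures, loops, arm2, flank3)
  ## star by duplex geometry (2-nt 3' overhangs): precursor positions
  ## [f+L+loop+3, f+2L+loop+2]
  star_lo_rel <- f + L + loop + 3L
  star_hi_rel <- f + 2L * L + loop + 2L
  stars <- substring(precursors, star_lo_rel, star_hi_rel)

  ## ---- contig placement ----
  slot <- prec_len + 120L
  contig_ids <- sprintf("contig%02d", seq_len(config$n_contigs))
  contigs <- random_dna(rep(config$contig_length, config$n_contigs))
  ## first three loci share contig 1 (a planted genomic cluster); the rest
  ## round-robin over the remaining contigs
  n_cluster <- min(3L, n_mir)
  contig_of <- integer(n_mir)
  slot_of <- integer(n_mir)
  contig_of[seq_len(n_cluster)] <- 1L
  slot_of[seq_len(n_cluster)] <- seq_len(n_cluster)
  rest <- setdiff(seq_len(n_mir), seq_len(n_cluster))
  pool <- if (config$n_contigs > 1) 2:config$n_contigs else 1L
  contig_of[rest] <- pool[(seq_along(rest) - 1L) %% length(pool) + 1L]
  slot_of[rest] <- (seq_along(rest) - 1L) %/% length(pool) + 1L
  if (n_cluster == 3L && config$n_contigs > 1) {
    slot_of[rest] <- slot_of[rest] + ifelse(contig_of[rest] == 1L, n_cluster, 0L)
  }
  prec_start <- 60L + (slot_of - 1L) * slot
  prec_end <- prec_start + prec_len - 1L
  bad <- which(prec_end > config$contig_length - 30L)
  if (length(bad)) {
    stop(sprintf(
      "contig_length %d too small to host locus %s (needs %d nt)",
      config$contig_length, ids$mirna_id[bad[1]], prec_end[bad[1]] + 30L
    ), call. = FALSE)
  }
  for (i in seq_len(n_mir)) {
    substring(contigs[contig_of[i]], prec_start[i], prec_end[i]) <- precursors[i]
  }

  mirna_loci <- tibble::tibble(
    mirna_id = ids$mirna_id,
    known = ids$known,
    family = as.character(ifelse(ids$known,
                                 sub("mir-0*", "miR", ids$mirna_id),
                                 ids$mirna_id)),
    contig = contig_ids[contig_of],
    precursor_start = prec_start,
    precursor_end = prec_end,
    precursor = precursors,
    mature = matures,
    star = stars,
    arm = "5p",
    mature_start = prec_start + f,
    mature_end = prec_start + f + L - 1L,
    star_start = prec_start + star_lo_rel - 1L,
    star_end = prec_start + star_hi_rel - 1L
  )

  ## ---- catalogs ----
  known_catalog <- tibble::tibble(
    id = sprintf("cat-%s", ids$mirna_id[ids$known]),
    family = mirna_loci$family[ids$known],
    sequence = matures[ids$known]
  )
  decoys <- random_dna(rep(L, 5))
  known_catalog <- dplyr::bind_rows(known_catalog, tibble::tibble(
    id = sprintf("cat-decoy-%d", seq_along(decoys)),
    family = sprintf("miRdecoy%d", seq_along(decoys)),
    sequence = decoys
  ))

  cls_len <- c(rRNA = 120L, tRNA = 76L, snRNA = 100L, snoRNA = 90L)
  contaminant_catalog <- purrr::map_dfr(names(config$n_contaminants), function(cl) {
    n <- config$n_contaminants[[cl]]
    tibble::tibble(
      id = sprintf("%s-%02d", cl, seq_len(n)),
      class = cl,
      sequence = random_dna(rep(cls_len[[cl]], n))
    )
  })

  ## ---- transcripts with planted cleavage sites ----
  tx_ids <- sprintf("tx-%03d", seq_len(config$n_transcripts))
  tx_seq <- random_dna(rep(config$transcript_length, config$n_transcripts))
  tx_of <- (seq_len(n_mir) - 1L) %% config$n_transcripts + 1L
  within <- stats::ave(seq_len(n_mir), tx_of, FUN = seq_along)
  site_start <- 80L + (within - 1L) * (L + 40L)
  site_end <- site_start + L - 1L
  ok <- site_end <= config$transcript_length - 20L
  site_seq <- revcomp(matures)
  for (i in which(ok)) {
    substring(tx_seq[tx_of[i]], site_start[i], site_end[i]) <- site_seq[i]
  }
  cleavage_sites <- tibble::tibble(
    mirna_id = ids$mirna_id[ok],
    transcript_id = tx_ids[tx_of[ok]],
    site_start = site_start[ok],
    site_end = site_end[ok],
    ## transcript base paired to miRNA position 10 = first nt of 3' fragment
    cleavage_pos = site_end[ok] - 9L
  )
  transcripts <- tibble::tibble(id = tx_ids, sequence = tx_seq)

  ## ---- expected per-condition counts for every source sequence ----
  sources <- build_sources(config, ids, matures, stars, contaminant_catalog,
                           contigs, mirna_loci)

  list(
    contigs = tibble::tibble(id = contig_ids, sequence = contigs),
    known_catalog = known_catalog,
    contaminant_catalog = contaminant_catalog,
    transcripts = transcripts,
    truth = list(
      mirna_loci = mirna_loci,
      sources = sources,
      cleavage_sites = cleavage_sites,
      cluster_contig = contig_ids[1]
    )
  )
}

## expected read counts per source and condition; columns e_control/e_drought/
## e_salt sum exactly to the configured library sizes (background absorbs the
## remainder so planted miRNA expectations keep exact 2^fc ratios)
build_sources <- function(config, ids, matures, stars, contaminant_catalog,
                          contigs, mirna_loci) {
  n_mir <- nrow(ids)
  N <- config$library_sizes
  fc <- config$planted_log2_fc[ids$mirna_id, , drop = FALSE]

  base <- round(rlnorm(n_mir, log(300), 0.7)) + 30
  base[!ids$known] <- pmax(base[!ids$known], 40)
  ## a couple of deliberately low-abundance loci to exercise the >= 3 read rule
  if (config$n_known_mirnas >= 6) base[config$n_known_mirnas] <- 4
  if (config$n_novel_mirnas >= 3) base[n_mir] <- 2
  star_flag <- seq_len(n_mir) <= round(config$star_fraction * n_mir)
  ## scale the well-expressed loci so miRNA mass ~ mirna_fraction of control
  big <- base > 10
  target <- config$mirna_fraction * N[["control"]]
  mass <- sum(base[big] * (1 + star_flag[big] * config$star_to_mature_ratio))
  if (target > 0 && mass > 0) base[big] <- base[big] * target / mass

  e_mat <- cbind(control = base,
                 drought = base * 2^fc[, "drought"],
                 salt = base * 2^fc[, "salt"])
  e_star <- e_mat * config$star_to_mature_ratio * star_flag

  src_mat <- tibble::tibble(
    sequence = matures, class = "mirna_mature", source_id = ids$mirna_id,
    mappable = TRUE,
    e_control = e_mat[, "control"], e_drought = e_mat[, "drought"],
    e_salt = e_mat[, "salt"]
  )
  src_star <- tibble::tibble(
    sequence = stars, class = "mirna_star", source_id = ids$mirna_id,
    mappable = TRUE,
    e_control = e_star[, "control"], e_drought = e_star[, "drought"],
    e_salt = e_star[, "salt"]
  )[star_flag, ]

  ## contaminant fragments: exact substrings of catalog entries
  frag <- purrr::map_dfr(seq_len(nrow(contaminant_catalog)), function(i) {
    entry <- contaminant_catalog$sequence[i]
    len <- sample_read_lengths(config, 3L)
    len <- pmin(len, nchar(entry))
    start <- vapply(len, function(l) sample.int(nchar(entry) - l + 1L, 1L), 1L)
    tibble::tibble(
      sequence = substring(entry, start, start + len - 1L),
      class = contaminant_catalog$class[i],
      source_id = contaminant_catalog$id[i],
      mappable = FALSE
    )
  })
  frag <- dplyr::distinct(frag, .data$sequence, .keep_all = TRUE)
  cls_n <- table(frag$class)
  cls_frac <- config$contaminant_fractions[frag$class]
  for (cond in c("control", "drought", "salt")) {
    frag[[paste0("e_", cond)]] <-
      unname(cls_frac * N[[cond]] / as.numeric(cls_n[frag$class]))
  }

  ## background: half mappable (contig substrings outside precursors), half
  ## random; Zipf-like abundance
  nb <- config$background_unique
  n_map <- nb %/% 2L
  bg_len <- sample_read_lengths(config, nb)
  bg_seq <- character(nb)
  if (n_map > 0) {
    bg_seq[seq_len(n_map)] <- sample_contig_substrings(
      contigs, bg_len[seq_len(n_map)], mirna_loci
    )
  }
  if (nb > n_map) bg_seq[(n_map + 1L):nb] <- random_dna(bg_len[(n_map + 1L):nb])
  keep <- !duplicated(bg_seq) &
    !bg_seq %in% c(src_mat$sequence, src_star$sequence, frag$sequence)
  bg <- tibble::tibble(
    sequence = bg_seq[keep],
    class = "background",
    source_id = sprintf("bg-%05d", which(keep)),
    mappable = seq_len(nb)[keep] <= n_map
  )
  ## shifted-Zipf abundance: a long low-count tail (so most background
  ## uniques stay below the candidate-read threshold, as in real libraries)
  ## without letting a single sequence dominate the library
  w <- 1 / (seq_len(nrow(bg)) + 20)^1.5
  w <- w / sum(w)
  planted <- dplyr::bind_rows(src_mat, src_star, frag)
  for (cond in c("control", "drought", "salt")) {
    ecol <- paste0("e_", cond)
    if (N[[cond]] == 0) {
      planted[[ecol]] <- 0
      bg[[ecol]] <- 0
      next
    }
    rem <- N[[cond]] - sum(planted[[ecol]])
    if (rem <= 0) {
      stop("library size too small for the planted miRNA/contaminant mass",
           call. = FALSE)
    }
    bg[[ecol]] <- w * rem
  }
  dplyr::bind_rows(planted, bg)
}

sample_read_lengths <- function(config, n) {
  d <- config$read_length_distribution
  lens <- as.integer(names(d))
  sample(lens, n, replace = TRUE, prob = d / sum(d))
}

## contig substrings avoiding planted precursor spans
sample_contig_substrings <- function(contigs, lens, mirna_loci) {
  out <- character(length(lens))
  for (i in seq_along(lens)) {
    repeat {
      ci <- sample.int(length(contigs), 1L)
      start <- sample.int(nchar(contigs[ci]) - lens[i] + 1L, 1L)
      end <- start + lens[i] - 1L
      hit <- mirna_loci$contig == sprintf("contig%02d", ci) &
        mirna_loci$precursor_start <= end & mirna_loci$precursor_end >= start
      if (!any(hit)) break
    }
    out[i] <- substring(contigs[ci], start, end)
  }
  out
}

#' Simulate the three small-RNA sequencing libraries
#'
#' Draws per-source read counts multinomially around the planted expected
#' counts, appends the 3' adapter, truncates every read to the machine read
#' length, applies per-base substitution errors (written at Phred 10 against
#' a Phred 40 baseline), and returns FASTQ-ready tibbles. Per-library seeds
#' are `config$seed + 0/1/2` so the libraries are independent but jointly
#' reproducible.
#'
#' @param config A [synthetic_config()].
#' @param ref The result of [generate_reference()] (or its `truth` element).
#' @return A list with `libraries` (named list of tibbles with `id`,
#'   `sequence`, `quality`) and `ledger` (the source table with sampled
#'   `count_control`/`count_drought`/`count_salt`).
#' @export
simulate_libraries <- function(config, ref) {
  truth <- if (!is.null(ref$truth)) ref$truth else ref
  sources <- truth$sources
  conds <- c("control", "drought", "salt")
  ledger <- sources
  libraries <- list()
  for (k in seq_along(conds)) {
    cond <- conds[k]
    N <- config$library_sizes[[cond]]
    counts <- with_seed(config$seed + k - 1L, {
      if (N == 0) rep(0L, nrow(sources))
      else as.integer(rmultinom(1, N, sources[[paste0("e_", cond)]]))
    })
    ledger[[paste0("count_", cond)]] <- counts
    if (N == 0) {
      warning(sprintf("library size 0 for %s: empty library", cond),
              call. = FALSE)
      libraries[[cond]] <- tibble::tibble(
        id = character(0), sequence = character(0), quality = character(0)
      )
      next
    }
    libraries[[cond]] <- with_seed(config$seed + 100L + k, {
      make_reads(sources$sequence, counts, config, cond)
    })
  }
  list(libraries = libraries, ledger = ledger)
}

#' Draw per-source library counts without materialising reads
#'
#' Fast path used for count-level calibration experiments: the same
#' multinomial draw as [simulate_libraries()] but skipping read/quality
#' string construction.
#'
#' @inheritParams simulate_libraries
#' @return The `ledger` tibble of [simulate_libraries()].
#' @export
simulate_library_counts <- function(config, ref) {
  truth <- if (!is.null(ref$truth)) ref$truth else ref
  sources <- truth$sources
  ledger <- sources
  conds <- c("control", "drought", "salt")
  for (k in seq_along(conds)) {
    cond <- conds[k]
    N <- config$library_sizes[[cond]]
    ledger[[paste0("count_", cond)]] <- with_seed(config$seed + k - 1L, {
      if (N == 0) rep(0L, nrow(sources))
      else as.integer(rmultinom(1, N, sources[[paste0("e_", cond)]]))
    })
  }
  ledger
}

## expand counts into adapter-ligated, truncated, error-bearing reads
make_reads <- function(insert, counts, config, cond) {
  ml <- config$machine_read_length
  seqs <- substr(paste0(rep.int(insert, counts), config$adapter), 1L, ml)
  n <- length(seqs)
  qual <- rep.int(strrep("I", ml), n)
  rate <- config$sequencing_error_rate
  if (rate > 0 && n > 0) {
    n_err <- rbinom(1, n * ml, rate)
    if (n_err > 0) {
      idx <- sample.int(n, n_err, replace = TRUE)
      pos <- sample.int(ml, n_err, replace = TRUE)
      old <- substring(seqs[idx], pos, pos)
      new <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1L), "",
                    USE.NAMES = FALSE)
      while (length(idx)) {
        take <- !duplicated(idx)
        s <- seqs[idx[take]]; q <- qual[idx[take]]
        substring(s, pos[take], pos[take]) <- new[take]
        substring(q, pos[take], pos[take]) <- "+"  # Phred 10
        seqs[idx[take]] <- s
        qual[idx[take]] <- q
        idx <- idx[!take]; pos <- pos[!take]; new <- new[!take]
      }
    }
  }
  tibble::tibble(
    id = sprintf("%s_%07d", cond, seq_len(n)),
    sequence = seqs,
    quality = qual
  )
}

#' Simulate degradome (PARE) tag counts
#'
#' Places `degradome_signal_fraction` of each transcript's tags exactly at its
#' planted cleavage positions and spreads the remainder uniformly over the
#' transcript, emulating 5'-end tag pileups at miRNA-guided cleavage sites.
#'
#' @inheritParams simulate_libraries
#' @return Tibble with `transcript_id`, `position` (1-based 5' end) and
#'   `count`.
#' @export
simulate_degradome <- function(config, ref) {
  truth <- if (!is.null(ref$truth)) ref$truth else ref
  tx <- if (!is.null(ref$transcripts)) ref$transcripts else NULL
  stopifnot(!is.null(tx))
  sites <- truth$cleavage_sites
  with_seed(config$seed + 10L, {
    purrr::map_dfr(seq_len(nrow(tx)), function(i) {
      id <- tx$id[i]
      len <- nchar(tx$sequence[i])
      total <- config$degradome_tags_per_transcript
      my_sites <- sites$cleavage_pos[sites$transcript_id == id]
      n_sig <- if (length(my_sites)) round(config$degradome_signal_fraction * total) else 0L
      n_noise <- total - n_sig
      counts <- integer(len)
      if (n_sig > 0) {
        per <- as.integer(rmultinom(1, n_sig, rep(1, length(my_sites))))
        counts[my_sites] <- counts[my_sites] + per
      }
      if (n_noise > 0) {
        noise_pos <- sample.int(len, n_noise, replace = TRUE)
        tab <- tabulate(noise_pos, nbins = len)
        counts <- counts + tab
      }
      keep <- which(counts > 0)
      tibble::tibble(transcript_id = id, position = keep, count = counts[keep])
    })
  })
}

#' Simulate a gene-document literature corpus
#'
#' Generates homologous gene families (the truth partition), a pairwise gene
#' similarity table separating within-family from between-family pairs, and a
#' document set in which one designated hub family co-occurs with every other
#' family and per-family citation frequency decays with family index. A
#' configurable fraction of documents carries a non-plant species label (to
#' be removed by [filter_species()]); a few extra genes appear only in those
#' documents.
#'
#' @inheritParams simulate_libraries
#' @return A list with `documents` (tibble: `doc_id`, `species`, `genes` as a
#'   comma-separated string), `similarity` (tibble: `gene_a`, `gene_b`,
#'   `similarity`), `clusters` (truth partition tibble: `gene_id`,
#'   `cluster_id`) and `expected_top` (the hub cluster id).
#' @export
simulate_corpus <- function(config, ref = NULL) {
  with_seed(config$seed + 20L, simulate_corpus_impl(config, ref))
}

simulate_corpus_impl <- function(config, ref = NULL) {
  K <- config$corpus_n_gene_families
  nd <- config$corpus_n_documents
  if (nd == 0L || K == 0L) {
    return(list(
      documents = tibble::tibble(doc_id = character(0), species = character(0),
                                 genes = character(0)),
      similarity = tibble::tibble(gene_a = character(0), gene_b = character(0),
                                  similarity = numeric(0)),
      clusters = tibble::tibble(gene_id = character(0), cluster_id = character(0)),
      gene_sequences = tibble::tibble(gene_id = character(0),
                                      sequence = character(0)),
      linked_truth = tibble::tibble(gene_id = character(0),
                                    transcript_id = character(0)),
      expected_top = NA_character_
    ))
  }
  sizes <- rep_len(c(3L, 2L, 2L), K)
  cluster_id <- sprintf("fam-%02d", seq_len(K))
  genes <- purrr::map2(cluster_id, sizes, function(cid, s) {
    sprintf("%s-g%d", sub("fam-", "gene", cid), seq_len(s))
  })
  clusters <- tibble::tibble(
    gene_id = unlist(genes),
    cluster_id = rep(cluster_id, sizes)
  )
  ## similarity: within-family pairs high, a sprinkle of low cross pairs
  within <- purrr::map_dfr(genes, function(g) {
    if (length(g) < 2) return(NULL)
    cmb <- utils::combn(g, 2)
    tibble::tibble(gene_a = cmb[1, ], gene_b = cmb[2, ],
                   similarity = runif(ncol(cmb), 0.75, 0.95))
  })
  cross_n <- 2L * K
  ca <- sample(clusters$gene_id, cross_n, replace = TRUE)
  cb <- sample(clusters$gene_id, cross_n, replace = TRUE)
  cross_ok <- clusters$cluster_id[match(ca, clusters$gene_id)] !=
    clusters$cluster_id[match(cb, clusters$gene_id)]
  cross <- tibble::tibble(gene_a = ca[cross_ok], gene_b = cb[cross_ok],
                          similarity = runif(sum(cross_ok), 0.05, 0.30))
  similarity <- dplyr::bind_rows(within, cross)

  ## documents: hub family (fam-01) co-occurs with every other family;
  ## remaining plant documents cite families with frequency ~ 1/index
  plant_species <- c("cotton", "arabidopsis", "rice", "maize")
  off_species <- c("human", "mouse")
  n_off <- round(config$corpus_offtarget_species_fraction * nd)
  n_plant <- nd - n_off
  pick_gene <- function(ci) sample(genes[[ci]], 1L)
  docs <- vector("list", nd)
  hub_pairs <- if (K > 1) 2:K else integer(0)
  for (d in seq_len(nd)) {
    if (d <= n_plant) {
      if (d <= length(hub_pairs)) {
        cl <- c(1L, hub_pairs[d])
      } else {
        k <- sample(1:2, 1L)
        cl <- unique(sample.int(K, k, prob = 1 / seq_len(K), replace = FALSE))
      }
      docs[[d]] <- list(
        species = sample(plant_species, 1L),
        genes = vapply(cl, pick_gene, "")
      )
    } else {
      ## non-plant documents mention decoy genes plus the odd real one
      g <- c(sprintf("offgene%d", sample.int(5L, 1L)),
             if (runif(1) < 0.5) pick_gene(sample.int(K, 1L)))
      docs[[d]] <- list(species = sample(off_species, 1L), genes = g)
    }
  }
  documents <- tibble::tibble(
    doc_id = sprintf("doc-%04d", seq_len(nd)),
    species = vapply(docs, `[[`, "", "species"),
    genes = vapply(docs, function(d) paste(d$genes, collapse = ","), "")
  )
  if (n_plant < length(hub_pairs)) {
    warning("corpus too small for the hub family to reach every other family",
            call. = FALSE)
  }
  ## gene sequences: random 300-mers; the first gene of each of the first
  ## three families shares a planted 250-nt stretch with a transcript so that
  ## target linkage has ground truth
  all_genes <- clusters$gene_id
  gene_seq <- random_dna(rep(300L, length(all_genes)))
  linked <- tibble::tibble(gene_id = character(0), transcript_id = character(0))
  if (!is.null(ref) && !is.null(ref$transcripts) && nrow(ref$transcripts)) {
    n_link <- min(3L, K, nrow(ref$transcripts))
    for (j in seq_len(n_link)) {
      g <- genes[[j]][1]
      txs <- ref$transcripts$sequence[j]
      ins <- substr(txs, 101L, 350L)
      gi <- match(g, all_genes)
      gene_seq[gi] <- paste0(substr(gene_seq[gi], 1L, 25L), ins,
                             substr(gene_seq[gi], 276L, 300L))
      linked <- dplyr::bind_rows(linked, tibble::tibble(
        gene_id = g, transcript_id = ref$transcripts$id[j]
      ))
    }
  }
  list(documents = documents, similarity = similarity, clusters = clusters,
       gene_sequences = tibble::tibble(gene_id = all_genes,
                                       sequence = gene_seq),
       linked_truth = linked,
       expected_top = cluster_id[1])
}

#' Run the whole synthetic generator
#'
#' One call producing every input of the pipeline: reference + truth,
#' libraries, degradome tags and literature corpus.
#'
#' @param config A [synthetic_config()].
#' @return A list: `config`, everything from [generate_reference()], plus
#'   `libraries`, `ledger`, `degradome`, `corpus`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 7, library_sizes = c(
#'   control = 5000, drought = 5000, salt = 5000
#' ), background_unique = 300)
#' sim <- simulate_srna_experiment(cfg)
#' names(sim)
simulate_srna_experiment <- function(config) {
  ref <- generate_reference(config)
  libs <- simulate_libraries(config, ref)
  degradome <- simulate_degradome(config, ref)
  corpus <- simulate_corpus(config, ref)
  c(list(config = config), ref,
    list(libraries = libs$libraries, ledger = libs$ledger,
         degradome = degradome, corpus = corpus))
}

#' Write a simulated dataset to disk
#'
#' Materialises the synthetic experiment in the pipeline's on-disk formats:
#' FASTA (contigs, catalogs, transcripts), FASTQ (libraries), TSV (degradome
#' tags, corpus documents and gene similarity) and JSON (planted truth).
#'
#' @param sim Result of [simulate_srna_experiment()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$contigs, file.path(dir, "contigs.fa"))
  write_fasta(dplyr::transmute(sim$known_catalog, id = .data$id,
                               sequence = .data$sequence),
              file.path(dir, "known_mirnas.fa"))
  write_fasta(dplyr::transmute(sim$contaminant_catalog,
                               id = paste(.data$class, .data$id, sep = "|"),
                               sequence = .data$sequence),
              file.path(dir, "contaminants.fa"))
  write_fasta(sim$transcripts, file.path(dir, "transcripts.fa"))
  for (cond in names(sim$libraries)) {
    write_fastq(sim$libraries[[cond]], file.path(dir, paste0(cond, ".fq")))
  }
  write_tsv_plain(sim$degradome, file.path(dir, "degradome.tsv"))
  write_tsv_plain(sim$corpus$documents, file.path(dir, "corpus_documents.tsv"))
  write_tsv_plain(sim$corpus$similarity, file.path(dir, "gene_similarity.tsv"))
  truth <- sim$truth
  truth$sources <- NULL  # bulky; the ledger TSV carries the counts
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  write_tsv_plain(sim$ledger, file.path(dir, "source_ledger.tsv"))
  invisible(dir)
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
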