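test_that("candidate selection enforces the 3-read, matched, clean rules", {
  tbl <- tibble::tibble(
    sequence = c("A", "B", "C", "D", "E"),
    length = 21L,
    count_control = c(2L, 0L, 3L, 5L, 4L),
    count_drought = c(2L, 0L, 0L, 1L, 0L),
    count_salt = c(2L, 3L, 0L, 2L, 9L),
    category = factor(c("unannotated", "miRNA", "unannotated", "rRNA",
                        "unannotated"),
                      levels = c("miRNA", "rRNA", "snRNA", "snoRNA", "tRNA",
                                 "repeat", "unannotated")),
    matched_any = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  out <- candidate_reads(tbl)
  ## (2,2,2) excluded; (0,0,3) included; contaminant and unmatched excluded
  expect_setequal(out$sequence, c("B", "C"))
})

test_that("hairpin folding matches brute-force enumeration on short windows", {
  expect_equal(stressmir:::.nussinov_fold("GGGAAACCC")$max_pairs, 3L)
  expect_equal(stressmir:::.nussinov_fold("AAAAAAAAA")$max_pairs, 0L)
  withr::with_seed(7, {
    for (n in c(8, 10, 12)) {
      for (rep in 1:8) {
        s <- random_seq(n)
        expect_equal(stressmir:::.nussinov_fold(s)$max_pairs,
                     brute_max_pairs(s), label = s)
      }
    }
  })
})

test_that("folded pairings are nested with the minimum loop respected", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      s <- random_seq(60)
      p <- stressmir:::.nussinov_fold(s)$pairing
      idx <- which(p > 0 & p > seq_along(p))
      expect_true(all(p[idx] - idx - 1 >= 3))       # min loop
      for (i in idx) {
        for (j in idx) {                            # no pseudoknots
          if (i < j) expect_false(i < j & j < p[i] & p[i] < p[j])
        }
      }
      expect_equal(p[p[idx]], idx)                  # involution
    }
  })
})

test_that("a planted perfect duplex yields the 2-nt overhang star", {
  sim <- get_sim()
  loci <- sim$truth$mirna_loci
  for (i in c(1, 5, nrow(loci))) {
    fh <- fold_hairpin(loci$precursor[i])
    ev <- evaluate_locus(loci$mature[i], fh)
    expect_false(is.null(ev))
    expect_equal(ev$star, loci$star[i])
    expect_equal(ev$arm, "5p")
    ## star is the shifted reverse complement of the mature over the stem
    L <- nchar(loci$mature[i])
    expect_equal(substr(ev$star, 1, L - 2),
                 substr(revcomp(loci$mature[i]), 3, L))
  }
})

test_that("a mature spanning the loop is rejected", {
  sim <- get_sim()
  prec <- sim$truth$mirna_loci$precursor[1]
  fh <- fold_hairpin(prec)
  f <- sim$config$flank_length
  L <- sim$config$mature_length
  ## center the candidate on the terminal loop
  loop_mid <- f + L + sim$config$loop_length %/% 2
  spanning <- substr(prec, loop_mid - 10, loop_mid + 10)
  expect_null(evaluate_locus(spanning, fh))
})

test_that("insufficient mature pairing is rejected at the 60% boundary", {
  ## A/T-only stem of 10 bp; the C-block can pair nothing (no G anywhere),
  ## so at most 10 of 21 mature positions can be paired (~48% < 60%)
  prec <- paste0(strrep("A", 10), strrep("C", 14), strrep("A", 5),
                 strrep("T", 10))
  fh <- fold_hairpin(prec)
  mature <- substr(prec, 1, 21)
  expect_null(evaluate_locus(mature, fh, min_paired_frac = 0.6))
})

test_that("novelty calls require a star read in the same library", {
  cat <- tibble::tibble(id = "k", family = "miRk",
                        sequence = "ACGTACGTACGTACGTACGTA")
  base <- tibble::tibble(
    mature = c("ACGTACGTACGTACGTACGTA",  # conserved, no star anywhere
               "TTGGCCAATTGGCCAATTGGA",  # unmatched, star in salt only
               "GGGGCCCCAAAATTTTGGGGC"), # unmatched, no star
    count_control = c(10L, 0L, 8L),
    count_drought = c(5L, 0L, 8L),
    count_salt = c(2L, 4L, 8L),
    star_count_control = c(0, 0, 0),
    star_count_drought = c(0, 0, 0),
    star_count_salt = c(0, 1, 0)
  )
  out <- call_novel(base, cat)
  expect_setequal(out$mature, base$mature[1:2])
  expect_equal(out$novel[out$mature == base$mature[1]], FALSE)
  expect_equal(out$novel[out$mature == base$mature[2]], TRUE)
  ## stricter same-library reading: star in salt but mature absent there
  strict <- base
  strict$count_salt[2] <- 0L
  out2 <- call_novel(strict, cat, same_library = TRUE)
  expect_false(base$mature[2] %in% out2$mature)
  out3 <- call_novel(strict, cat, same_library = FALSE)
  expect_true(base$mature[2] %in% out3$mature)
})

test_that("precursor dedupe merges >=95% identity and is idempotent", {
  withr::with_seed(5, {
    p1 <- random_seq(80)
    p2 <- p1
    for (pos in sample(80, 2)) {  # 97.5% identity
      substr(p2, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(p2, pos, pos)), 1)
    }
    p3 <- random_seq(80)          # unrelated
    loci <- tibble::tibble(
      precursor = c(p1, p2, p3),
      contig = "c1", precursor_start = c(1L, 200L, 400L),
      count_control = c(10L, 3L, 5L),
      count_drought = 0L, count_salt = 0L
    )
    out <- dedupe_precursors(loci)
    expect_equal(nrow(out), 2)
    expect_true(p1 %in% out$precursor)   # higher summed count survives
    expect_identical(dedupe_precursors(out), out)
    ## 80%-identical precursors stay separate
    p4 <- p1
    for (pos in sample(80, 16)) {
      substr(p4, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(p4, pos, pos)), 1)
    }
    both <- tibble::tibble(precursor = c(p1, p4), contig = "c1",
                           precursor_start = c(1L, 100L),
                           count_control = c(1L, 1L),
                           count_drought = 0L, count_salt = 0L)
    expect_equal(nrow(dedupe_precursors(both)), 2)
  })
})

test_that("cross-set homology uses an inclusive 95% identity boundary", {
  withr::with_seed(9, {
    prec <- random_seq(100)
    ref <- tibble::tibble(id = "r1",
                          sequence = paste0(random_seq(50), prec,
                                            random_seq(50)))
    expect_true(cross_genome_homology(prec, ref))
    ## exactly 95.0%: 5 mismatches in 100 nt
    p5 <- prec
    for (pos in seq(5, 85, by = 20)) {
      substr(p5, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(p5, pos, pos)), 1)
    }
    expect_true(cross_genome_homology(p5, ref))
    ## 10% mutated: below threshold
    p10 <- prec
    for (pos in seq(3, 93, by = 9)) {
      substr(p10, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substr(p10, pos, pos)), 1)
    }
    expect_false(cross_genome_homology(p10, ref, min_identity = 95))
  })
})

test_that("family assignment links novel matures at <=3 mismatches", {
  m1 <- "ACGTACGTACGTACGTACGTA"
  m2 <- m1; substr(m2, 2, 3) <- "TT"    # 2 mismatches from m1
  m3 <- "GGGGCCCCAAAATTTTGGGGC"         # unrelated singleton
  loci <- tibble::tibble(
    mature = c(m1, m2, m3),
    novel = TRUE,
    catalog_family = NA_character_
  )
  fam <- assign_family(loci)
  expect_equal(fam$family[1], fam$family[2])
  expect_false(fam$family[3] == fam$family[1])
  expect_match(fam$family, "^ghr-n")
  ## permutation invariance up to naming
  fam_rev <- assign_family(loci[3:1, ])
  expect_equal(fam_rev$family[3] == fam_rev$family[2], TRUE)
})

test_that("a planted family of five matures forms one novel family", {
  withr::with_seed(13, {
    base <- random_seq(21)
    variants <- vapply(1:5, function(i) {
      s <- base
      if (i > 1) {
        pos <- sample(21, 1)
        substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substr(s, pos, pos)), 1)
      }
      s
    }, "")
    loci <- tibble::tibble(mature = variants, novel = TRUE,
                           catalog_family = NA_character_)
    fam <- assign_family(loci)
    expect_equal(length(unique(fam$family)), 1)
  })
})

test_that("genomic clustering respects contig and distance rules", {
  loci <- tibble::tibble(
    contig = c("c1", "c1", "c2"),
    precursor_start = c(1000L, 2000L, 1000L)
  )
  cl <- find_clusters(loci, cluster_distance = 10000)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_loci, 2L)
  ## loci on different contigs never cluster
  far <- tibble::tibble(contig = c("c1", "c2"),
                        precursor_start = c(1L, 2L))
  expect_equal(nrow(find_clusters(far)), 0)
})

test_that("the planted 3-locus cluster is recovered exactly", {
  sim <- get_sim()
  pipe <- get_pipeline()
  cl <- find_clusters(pipe$loci)
  hub <- cl[cl$contig == sim$truth$cluster_contig, ]
  expect_gte(nrow(hub), 1)
  expect_gte(max(hub$n_loci), 3L)
})

test_that("end-to-end discovery recovers every recoverable planted locus", {
  sim <- get_sim()
  pipe <- get_pipeline()
  loci <- pipe$loci
  led <- sim$ledger[sim$ledger$class == "mirna_mature", ]
  star_ids <- sim$ledger$source_id[sim$ledger$class == "mirna_star"]
  truth <- sim$truth$mirna_loci
  expressed <- led$source_id[led$e_control >= 3]
  known_t <- truth[truth$known & truth$mirna_id %in% expressed, ]
  novel_t <- truth[!truth$known & truth$mirna_id %in% expressed &
                     truth$mirna_id %in% star_ids, ]
  expect_true(all(known_t$mature %in% loci$mature))
  expect_true(all(novel_t$mature %in% loci$mature[loci$novel]))
  ## known loci inherit catalog families
  idx <- match(known_t$mature, loci$mature)
  expect_equal(loci$family[idx], known_t$family)
  ## no contaminant sequence ever yields a locus
  contam <- sim$ledger$sequence[sim$ledger$class %in%
                                  c("rRNA", "tRNA", "snRNA", "snoRNA")]
  expect_false(any(loci$mature %in% contam))
})
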