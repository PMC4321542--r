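ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter removal trims full and terminal-partial occurrences", {
  insert <- "ACGTACGTACGTACGTACGTA"
  reads <- tibble::tibble(
    id = c("full", "partial", "none"),
    sequence = c(
      substr(paste0(insert, ADAPTER), 1, 36),           # full occurrence
      paste0(insert, substr(ADAPTER, 1, 8)),            # terminal 8-nt match
      paste0(insert, "ACGTACGTACGTACG")                 # 36 nt, no adapter
    ),
    quality = strrep("I", c(36, 29, 36))
  )
  out <- clean_reads(reads, ADAPTER)
  expect_equal(out$sequence[out$id == "full"], insert)
  expect_equal(out$sequence[out$id == "partial"], insert)
  expect_false("none" %in% out$id)  # untrimmed 36-mer exceeds max_len
  log <- attr(out, "drop_log")
  expect_equal(log$n[log$reason == "too_long_or_untrimmed"], 1L)
})

test_that("cleaning drops short, low-quality and N-containing reads", {
  insert <- "ACGTACGTACGTACGTACGTA"
  lowq <- strrep("I", 21); substr(lowq, 5, 5) <- "+"    # Phred 10 base
  reads <- tibble::tibble(
    id = c("short", "lowq", "withN", "good"),
    sequence = c(paste0("ACGTACGTACGT", ADAPTER),       # 12-nt insert
                 paste0(insert, ADAPTER),
                 paste0(sub("^A", "N", insert), ADAPTER),
                 paste0(insert, ADAPTER)),
    quality = c(strrep("I", 33), paste0(lowq, strrep("I", 21)),
                strrep("I", 42), strrep("I", 42))
  )
  out <- clean_reads(reads, ADAPTER)
  expect_equal(out$id, "good")
  log <- attr(out, "drop_log")
  expect_setequal(log$reason, c("too_short", "low_quality", "contains_n"))
})

test_that("malformed records are reported with their index", {
  reads <- tibble::tibble(id = c("a", "b"),
                          sequence = c("ACGT", "ACGT"),
                          quality = c("IIII", "III"))
  expect_error(clean_reads(reads, ADAPTER), "record 2")
})

test_that("collapsing counts distinct sequences per library", {
  libs <- list(
    a = tibble::tibble(id = as.character(1:4),
                       sequence = c("AAAC", "AAAC", "AAAC", "CCCG")),
    b = tibble::tibble(id = "1", sequence = "CCCG")
  )
  col <- collapse_reads(libs)
  expect_equal(nrow(col), 2)
  expect_equal(col$count_a[col$sequence == "AAAC"], 3L)
  expect_equal(col$count_b[col$sequence == "AAAC"], 0L)
  stats <- library_stats(col)
  expect_equal(stats$total_redundant[stats$library == "a"], 4L)
  expect_equal(stats$total_unique[stats$library == "a"], 2L)
  empty <- collapse_reads(list(
    a = tibble::tibble(id = character(0), sequence = character(0))
  ))
  expect_equal(nrow(empty), 0)
})

test_that("collapsed totals match the generator ledger", {
  sim <- get_sim()
  pipe <- get_pipeline()
  stats <- library_stats(pipe$collapsed)
  ## error-bearing reads are dropped by the quality filter, so cleaned totals
  ## equal the ledger counts minus errored reads; with the planted error rate
  ## the deficit stays below ~5%
  for (lib in c("control", "drought", "salt")) {
    led_total <- sum(sim$ledger[[paste0("count_", lib)]])
    got <- stats$total_redundant[stats$library == lib]
    expect_lte(got, led_total)
    expect_gt(got, 0.9 * led_total)
  }
})

test_that("known-miRNA assignment follows the 3-mismatch offset rule", {
  cat <- tibble::tibble(
    id = c("cat-a", "cat-b"),
    family = c("miRa", "miRb"),
    sequence = c("ACGTACGTACGTACGTACGTA", "TTTTCCCCGGGGAAAATTTTC")
  )
  expect_equal(assign_known("ACGTACGTACGTACGTACGTA", cat)$distance, 0L)
  m3 <- "ACGTACGTACGTACGTACCCC"  # 3 substitutions at the tail
  expect_equal(assign_known(m3, cat)$distance, 3L)
  m4 <- "ACGTACGTACGTACGTCCCCC"  # 4 substitutions
  expect_true(is.na(assign_known(m4, cat)$distance))
  ## a read contained in a catalog entry matches at distance 0
  expect_equal(assign_known(substr(cat$sequence[2], 2, 20), cat)$distance, 0L)
})

test_that("assign_known equals the brute-force all-offset oracle", {
  withr::with_seed(99, {
    cat <- tibble::tibble(id = sprintf("c%02d", 1:6),
                          family = sprintf("f%02d", 1:6),
                          sequence = vapply(rep(21, 6), random_seq, ""))
    reads <- c(
      vapply(sample(18:30, 12, replace = TRUE), random_seq, ""),
      ## near-misses built from catalog entries
      vapply(1:6, function(i) {
        s <- cat$sequence[i]
        for (p in sample(21, sample(0:4, 1))) {
          substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(s, p, p)), 1)
        }
        s
      }, "")
    )
    got <- assign_known(reads, cat, max_mismatch = 3)
    oracle <- vapply(reads, function(r) {
      min(vapply(cat$sequence, function(e) brute_offset_distance(r, e), 1L))
    }, 1L)
    expect_equal(ifelse(is.na(got$distance), NA_integer_, got$distance),
                 ifelse(oracle <= 3, oracle, NA_integer_),
                 ignore_attr = TRUE)
  })
})

test_that("contaminant exclusion precedes miRNA assignment", {
  trna <- "GGGCCCAAATTTGGGCCCAAATTTGGGCCCAAATTTGGGCCCAAATTTGGGCCCAAATTTGGGCCCAAATTTGGGC"
  read <- substr(trna, 1, 21)
  contam <- tibble::tibble(class = "tRNA", sequence = trna)
  ## catalog entry within 3 mismatches of the same read
  near <- read; substr(near, 3, 3) <- "T"
  cat <- tibble::tibble(id = "k1", family = "miRx", sequence = near)
  col <- tibble::tibble(sequence = c(read, "ACGTACGTACGTACGTACGTA"),
                        length = 21L, count_a = c(5L, 2L))
  ann <- annotate_category(col, contam, cat)
  expect_equal(as.character(ann$category[1]), "tRNA")
  expect_equal(as.character(ann$category[2]), "unannotated")
  ## partition: no read is both contaminant- and miRNA-classed
  expect_true(all(table(ann$sequence) == 1))
})

test_that("category percentages track the planted contaminant fractions", {
  sim <- get_sim()
  pipe <- get_pipeline()
  ct <- category_table(pipe$annotated)
  rr <- ct[ct$category == "rRNA", ]
  planted <- sim$config$contaminant_fractions[["rRNA"]] * 100
  expect_true(all(abs(rr$redundant_pct - planted) < 1.5))
})

test_that("reference matching is exact, full length, and strand-aware", {
  contig <- paste0(strrep("A", 30), "CCGGTTAACCGGTTAACCGGTCA", strrep("G", 30))
  refs <- list(genome = tibble::tibble(id = "c1", sequence = contig))
  reads <- tibble::tibble(
    sequence = c(substr(contig, 31, 53),          # sense substring
                 revcomp(substr(contig, 31, 53)), # antisense substring
                 random_seq(23)),
    length = 23L, count_a = 1L
  )
  out <- match_reference(reads, refs)
  expect_equal(out$matched_genome, c(TRUE, TRUE, FALSE))
  sense_only <- match_reference(reads, refs, both_strands = FALSE)
  expect_equal(sense_only$matched_genome, c(TRUE, FALSE, FALSE))
})

test_that("mean matched fraction reflects the planted mappable fraction", {
  sim <- get_sim()
  pipe <- get_pipeline()
  mt <- matched_table(pipe$annotated)
  led <- sim$ledger
  for (lib in c("control", "drought", "salt")) {
    cl <- paste0("count_", lib)
    planted <- sum(led[[cl]][led$mappable]) / sum(led[[cl]]) * 100
    got <- mt$redundant_pct[mt$library == lib & mt$set == "genome"]
    expect_lt(abs(got - planted), 2.5)
  }
})

test_that("top-N Jaccard similarity behaves as set arithmetic", {
  col <- tibble::tibble(
    sequence = c("AAAA", "CCCC", "GGGG", "TTTT"),
    length = 4L,
    count_a = c(10L, 5L, 0L, 0L),
    count_b = c(0L, 7L, 3L, 0L)
  )
  ## A_top = {AAAA, CCCC}, B_top = {CCCC, GGGG}: J = 1/3
  expect_equal(jaccard_top(col, "a", "b", n_top = 2)$jaccard_percent,
               100 / 3)
  expect_equal(jaccard_top(col, "a", "a", n_top = 2)$jaccard_percent, 100)
  expect_equal(jaccard_top(col, "a", "b", n_top = 2)$jaccard_percent,
               jaccard_top(col, "b", "a", n_top = 2)$jaccard_percent)
  disj <- tibble::tibble(sequence = c("AAAA", "CCCC"), length = 4L,
                         count_a = c(1L, 0L), count_b = c(0L, 1L))
  expect_equal(jaccard_top(disj, "a", "b")$jaccard_percent, 0)
})

test_that("size distribution is zero-filled and finds the planted mode", {
  one <- tibble::tibble(sequence = c("AAAAAAAAAAAAAAAAAAAAA"),
                        length = 21L, count_a = 5L)
  sd1 <- size_distribution(one)
  expect_equal(sd1$redundant_count[sd1$length == 21], 5)
  sim <- get_sim()
  pipe <- get_pipeline()
  bg <- pipe$annotated[pipe$annotated$category != "miRNA", ]
  sdist <- size_distribution(bg)
  ctrl <- sdist[sdist$library == "control", ]
  ## generator weights favor 21 then 24 nt for background/contaminant reads
  expect_true(ctrl$length[which.max(ctrl$redundant_count)] %in% c(21L, 24L))
})
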