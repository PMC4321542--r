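plant_species <- c("cotton", "arabidopsis", "rice", "maize")

test_that("species filtering keeps allowed labels only", {
  docs <- tibble::tibble(
    doc_id = c("d1", "d2", "d3"),
    species = c("rice", "human", "cotton"),
    genes = c("g1,g2", "g3", "g1")
  )
  expect_equal(nrow(filter_species(docs, plant_species)), 2)
  expect_identical(filter_species(docs, c("rice", "human", "cotton")), docs)
  expect_equal(nrow(filter_species(docs, character(0))), 0)
  ## genes only present in removed documents vanish from the corpus
  kept <- filter_species(docs, plant_species)
  expect_false("g3" %in% unlist(strsplit(kept$genes, ",")))
})

test_that("single-linkage clustering takes the transitive closure", {
  sim <- tibble::tibble(
    gene_a = c("a", "b", "a"),
    gene_b = c("b", "c", "c"),
    similarity = c(0.9, 0.8, 0.1)
  )
  cl <- cluster_homologs(c("a", "b", "c", "d"), sim, threshold = 0.5)
  expect_equal(unique(cl$cluster_id[cl$gene_id %in% c("a", "b", "c")]), "a")
  expect_equal(cl$cluster_id[cl$gene_id == "d"], "d")
  ## nothing above threshold: all singletons
  low <- cluster_homologs(c("a", "b"), sim, threshold = 0.95)
  expect_equal(low$cluster_id, c("a", "b"))
})

test_that("synthetic corpus clustering recovers the planted families", {
  sim <- get_sim()
  corp <- sim$corpus
  docs <- filter_species(corp$documents, plant_species)
  genes <- intersect(unique(unlist(strsplit(docs$genes, ","))),
                     corp$clusters$gene_id)
  cl <- cluster_homologs(genes, corp$similarity, threshold = 0.5)
  truth_of <- corp$clusters$cluster_id[match(cl$gene_id,
                                             corp$clusters$gene_id)]
  ## the recovered partition refines to exactly the planted partition
  expect_equal(length(unique(cl$cluster_id)), length(unique(truth_of)))
  tab <- table(cl$cluster_id, truth_of)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("co-existence matrix counts documents on and off the diagonal", {
  clusters <- tibble::tibble(gene_id = c("a1", "a2", "b1", "c1"),
                             cluster_id = c("A", "A", "B", "C"))
  docs <- tibble::tibble(
    doc_id = c("d1", "d2", "d3"),
    genes = c("a1,b1", "a2", "a1,a2")
  )
  M <- build_coexistence(docs, clusters)
  expect_equal(M["A", "B"], 1)
  expect_equal(M["B", "A"], 1)
  expect_equal(M["A", "A"], 3)  # document frequency
  expect_equal(M["B", "B"], 1)
  expect_equal(M["C", "C"], 0)
  expect_true(isSymmetric(M))
  ## disjoint documents produce a diagonal matrix
  dd <- tibble::tibble(doc_id = c("d1", "d2"), genes = c("a1", "b1"))
  expect_true(all(build_coexistence(dd, clusters)[upper.tri(M)] == 0))
})

test_that("citation rank handles the degenerate and symmetric cases", {
  single <- matrix(5, 1, 1, dimnames = list("A", "A"))
  r1 <- citation_rank(single)
  expect_equal(unname(r1$scores), 1)
  ## symmetric complete graph with equal counts: uniform scores
  M <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(M) <- 3
  ru <- citation_rank(M)
  expect_equal(unname(ru$scores), rep(0.25, 4), tolerance = 1e-9)
  expect_equal(sum(ru$scores), 1, tolerance = 1e-9)
  ## empty matrix: empty result
  expect_length(citation_rank(matrix(numeric(0), 0, 0))$scores, 0)
})

test_that("the middle of a 3-node path ranks first (oracle-checked)", {
  M <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  M["A", "B"] <- M["B", "A"] <- 1
  M["B", "C"] <- M["C", "B"] <- 1
  diag(M) <- 2
  r <- citation_rank(M)
  expect_equal(tidy(r)$cluster_id[1], "B")
  oracle <- brute_rank(M)
  expect_equal(r$scores, oracle, tolerance = 1e-9)
})

test_that("citation rank equals dense power iteration on random matrices", {
  withr::with_seed(31, {
    for (rep in 1:6) {
      n <- sample(3:10, 1)
      M <- matrix(rpois(n * n, 1.2), n, n)
      M <- M + t(M)
      diag(M) <- rpois(n, 4) + 1
      dimnames(M) <- list(sprintf("c%02d", 1:n), sprintf("c%02d", 1:n))
      r <- citation_rank(M)
      expect_equal(r$scores, brute_rank(M), tolerance = 1e-8)
      expect_equal(sum(r$scores), 1, tolerance = 1e-9)
      expect_lt(r$final_delta, 1e-9)
      expect_lt(r$iterations_run, 1000)
    }
  })
})

test_that("scores are conserved and permutation-equivariant", {
  withr::with_seed(5, {
    n <- 6
    M <- matrix(rpois(n * n, 1), n, n)
    M <- M + t(M)
    diag(M) <- rpois(n, 3) + 1
    dimnames(M) <- list(letters[1:n], letters[1:n])
    r <- citation_rank(M)
    perm <- sample(n)
    Mp <- M[perm, perm]
    rp <- citation_rank(Mp)
    expect_equal(rp$scores[letters[1:n]], r$scores[letters[1:n]],
                 tolerance = 1e-10)
  })
})

test_that("adding a co-mention edge never lowers the touched cluster's score", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      n <- 5
      M <- matrix(rpois(n * n, 1), n, n)
      M <- M + t(M)
      diag(M) <- rpois(n, 3) + 2
      dimnames(M) <- list(letters[1:n], letters[1:n])
      before <- citation_rank(M)$scores["a"]
      j <- sample(2:n, 1)
      M2 <- M
      M2["a", j] <- M2["a", j] + 2
      M2[j, "a"] <- M2[j, "a"] + 2
      after <- citation_rank(M2)$scores["a"]
      expect_gte(after, before - 1e-12)
    }
  })
})

test_that("the planted hub family is ranked first", {
  sim <- get_sim()
  corp <- sim$corpus
  docs <- filter_species(corp$documents, plant_species)
  genes <- intersect(unique(unlist(strsplit(docs$genes, ","))),
                     corp$clusters$gene_id)
  cl <- cluster_homologs(genes, corp$similarity, threshold = 0.5)
  r <- citation_rank(build_coexistence(docs, cl))
  hub_genes <- corp$clusters$gene_id[corp$clusters$cluster_id ==
                                       corp$expected_top]
  hub_cluster <- unique(cl$cluster_id[cl$gene_id %in% hub_genes])
  expect_equal(tidy(r)$cluster_id[1], hub_cluster)
})

test_that("target linkage recovers the planted gene-transcript overlaps", {
  sim <- get_sim()
  corp <- sim$corpus
  truth <- sim$truth
  mirnas <- truth$mirna_loci[, c("mirna_id", "mature")]
  sites <- scan_targets(mirnas, sim$transcripts)
  cl <- corp$clusters  # truth partition doubles as the cluster table
  edges <- link_targets(sites, sim$transcripts, corp$gene_sequences, cl)
  got <- unique(edges[, c("gene_id", "transcript_id")])
  expect_setequal(paste(got$gene_id, got$transcript_id),
                  paste(corp$linked_truth$gene_id,
                        corp$linked_truth$transcript_id))
  ## a gene with no sequence overlap yields no edge
  noisy <- tibble::tibble(gene_id = "lonely", sequence = random_seq(300))
  e0 <- link_targets(sites[1, ], sim$transcripts, noisy,
                     tibble::tibble(gene_id = "lonely",
                                    cluster_id = "lonely"))
  expect_equal(nrow(e0), 0)
})
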