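## citation_rank module: species filtering, homolog clustering, co-existence
## matrix and the PageRank-style CitationRank over gene clusters.

split_genes <- function(genes) {
  strsplit(genes, ",", fixed = TRUE)
}

#' Filter a document corpus by species
#'
#' Removes documents whose species label is not in `allowed`; genes that
#' appeared only in removed documents disappear with them.
#'
#' @param documents Tibble: `doc_id`, `species`, `genes` (comma-separated
#'   gene ids).
#' @param allowed Character vector of allowed species labels.
#' @return Filtered tibble.
#' @export
filter_species <- function(documents, allowed) {
  documents[documents$species %in% allowed, , drop = FALSE]
}

#' Single-linkage homolog clustering
#'
#' Connected components of the similarity graph restricted to `genes`, with
#' edges where similarity >= `threshold` (the orthology cut-off expressed as
#' a similarity); genes with no qualifying edge become singletons. Cluster
#' ids are deterministic: each component is named after its smallest member
#' gene id.
#'
#' @param genes Character vector of gene ids (the filtered gene universe).
#' @param similarity Tibble: `gene_a`, `gene_b`, `similarity` (symmetric).
#' @param threshold Edge threshold (inclusive).
#' @return Tibble: `gene_id`, `cluster_id`.
#' @export
cluster_homologs <- function(genes, similarity, threshold) {
  genes <- sort(unique(genes))
  n <- length(genes)
  if (n == 0) {
    return(tibble::tibble(gene_id = character(0), cluster_id = character(0)))
  }
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i] <<- comp[comp[i]]; i }
  edges <- similarity[similarity$similarity >= threshold, , drop = FALSE]
  ia <- match(edges$gene_a, genes)
  ib <- match(edges$gene_b, genes)
  ok <- which(!is.na(ia) & !is.na(ib))
  for (e in ok) comp[find(ib[e])] <- find(ia[e])
  roots <- vapply(seq_len(n), find, 1L)
  cluster_of <- vapply(split(genes, roots), min, "")
  tibble::tibble(gene_id = genes,
                 cluster_id = unname(cluster_of[as.character(roots)]))
}

#' Cluster co-existence matrix from a document corpus
#'
#' Square symmetric matrix over clusters: off-diagonal entry (i, j) counts
#' documents mentioning members of both clusters; the diagonal is each
#' cluster's document frequency (documents mentioning at least one member).
#'
#' @param documents Filtered document tibble (`doc_id`, `genes`).
#' @param clusters Gene-to-cluster tibble from [cluster_homologs()].
#' @return Named square matrix.
#' @export
build_coexistence <- function(documents, clusters) {
  ids <- sort(unique(clusters$cluster_id))
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(documents) == 0 || length(ids) == 0) return(M)
  lookup <- setNames(clusters$cluster_id, clusters$gene_id)
  for (gl in split_genes(documents$genes)) {
    cl <- unique(stats::na.omit(unname(lookup[gl])))
    if (!length(cl)) next
    M[cbind(cl, cl)] <- M[cbind(cl, cl)] + 1  # document frequency
    if (length(cl) > 1) {
      prs <- utils::combn(cl, 2)
      for (k in seq_len(ncol(prs))) {
        M[prs[1, k], prs[2, k]] <- M[prs[1, k], prs[2, k]] + 1
        M[prs[2, k], prs[1, k]] <- M[prs[2, k], prs[1, k]] + 1
      }
    }
  }
  M
}

#' CitationRank over a cluster co-existence matrix
#'
#' Damped power iteration in which literature importance flows along
#' co-mention edges and teleports back to the document-frequency prior:
#' starting from the frequency vector normalized to sum 1, each step applies
#' `damping * T %*% r + (1 - damping) * r0`, where `T` column-normalizes
#' the off-diagonal co-existence counts (columns with zero sum are replaced
#' by the prior). Exactly `iterations` steps are run unless the L1 change
#' drops below `tol` first (recorded in the result).
#'
#' @param M Co-existence matrix from [build_coexistence()].
#' @param iterations Maximum iterations (default 1000).
#' @param damping Damping factor (default 0.85).
#' @param tol Early-stop L1 tolerance (default 1e-12).
#' @return Object of class `citation_rank`: `scores` (named, sums to 1),
#'   `iterations_run`, `final_delta`, `prior`.
#' @export
citation_rank <- function(M, iterations = 1000L, damping = 0.85,
                          tol = 1e-12) {
  n <- nrow(M)
  if (is.null(n) || n == 0) {
    return(structure(list(scores = numeric(0), iterations_run = 0L,
                          final_delta = NA_real_, prior = numeric(0)),
                     class = "citation_rank"))
  }
  freq <- diag(M)
  r0 <- if (sum(freq) > 0) freq / sum(freq) else rep(1 / n, n)
  Toff <- M
  diag(Toff) <- 0
  cs <- colSums(Toff)
  Tm <- matrix(0, n, n, dimnames = dimnames(M))
  pos <- cs > 0
  if (any(pos)) Tm[, pos] <- sweep(Toff[, pos, drop = FALSE], 2, cs[pos], "/")
  if (any(!pos)) Tm[, !pos] <- r0
  r <- r0
  delta <- NA_real_
  it <- 0L
  while (it < iterations) {
    rn <- damping * as.vector(Tm %*% r) + (1 - damping) * r0
    delta <- sum(abs(rn - r))
    r <- rn
    it <- it + 1L
    if (delta < tol) break
  }
  structure(list(scores = setNames(r, rownames(M)), iterations_run = it,
                 final_delta = delta, prior = setNames(r0, rownames(M))),
            class = "citation_rank")
}

#' @export
print.citation_rank <- function(x, ...) {
  cat("<citation_rank> ", length(x$scores), " clusters, ",
      x$iterations_run, " iterations (final L1 delta ",
      format(x$final_delta, digits = 3), ")\n", sep = "")
  print(utils::head(sort(x$scores, decreasing = TRUE), 5))
  invisible(x)
}

#' @rdname citation_rank
#' @param x,object A `citation_rank` object.
#' @param ... Unused.
#' @method tidy citation_rank
#' @export
tidy.citation_rank <- function(x, ...) {
  ord <- order(-x$scores, names(x$scores))
  tibble::tibble(
    cluster_id = names(x$scores)[ord],
    score = unname(x$scores[ord]),
    rank = seq_along(ord)
  )
}

#' @rdname citation_rank
#' @method glance citation_rank
#' @export
glance.citation_rank <- function(x, ...) {
  tibble::tibble(
    n_clusters = length(x$scores),
    iterations_run = x$iterations_run,
    final_delta = x$final_delta,
    score_sum = sum(x$scores)
  )
}

#' @rdname citation_rank
#' @method autoplot citation_rank
#' @export
autoplot.citation_rank <- function(object, ...) {
  dat <- utils::head(tidy(object), 20)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$cluster_id, .data$score), y = .data$score
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "CitationRank score") +
    ggplot2::theme_minimal()
}

#' Shared k-mer identity between two sequences
#'
#' Fraction of the first sequence's k-mers that occur anywhere in the
#' second; the default sequence-similarity plug-in for [link_targets()].
#'
#' @param a,b DNA sequences.
#' @param k K-mer size (default 8).
#' @return Numeric in [0, 1].
#' @export
kmer_identity <- function(a, b, k = 8L) {
  na <- nchar(a)
  if (na < k || nchar(b) < k) return(0)
  ka <- substring(a, seq_len(na - k + 1L), seq_len(na - k + 1L) + k - 1L)
  kb <- substring(b, seq_len(nchar(b) - k + 1L),
                  seq_len(nchar(b) - k + 1L) + k - 1L)
  mean(ka %in% kb)
}

#' Link ranked gene clusters to predicted miRNA targets
#'
#' Emits an edge (miRNA, cluster) whenever the transcript of one of the
#' miRNA's predicted target sites exceeds the similarity threshold against
#' some member gene's sequence; edges carry the cluster's CitationRank.
#'
#' @param sites Target-site tibble ([scan_targets()] or
#'   [validate_targets()] output).
#' @param transcripts Transcript tibble (`id`, `sequence`).
#' @param gene_sequences Tibble: `gene_id`, `sequence`.
#' @param clusters Gene-to-cluster tibble.
#' @param rank Optional `citation_rank` result for rank annotation.
#' @param sim_fun Similarity function `(a, b) -> [0, 1]` (default
#'   [kmer_identity()]).
#' @param threshold Similarity threshold (strict, default 0.1).
#' @return Edge tibble: `mirna_id`, `cluster_id`, `transcript_id`,
#'   `gene_id`, `similarity`, `cluster_rank`.
#' @export
link_targets <- function(sites, transcripts, gene_sequences, clusters,
                         rank = NULL, sim_fun = kmer_identity,
                         threshold = 0.1) {
  if (nrow(sites) == 0 || nrow(gene_sequences) == 0) {
    return(tibble::tibble(mirna_id = character(0), cluster_id = character(0),
                          transcript_id = character(0), gene_id = character(0),
                          similarity = numeric(0), cluster_rank = integer(0)))
  }
  tx_seq <- setNames(transcripts$sequence, transcripts$id)
  pairs <- dplyr::distinct(sites, .data$mirna_id, .data$transcript_id)
  edges <- list()
  for (i in seq_len(nrow(pairs))) {
    tseq <- tx_seq[[pairs$transcript_id[i]]]
    sims <- vapply(gene_sequences$sequence, function(g) sim_fun(tseq, g),
                   numeric(1), USE.NAMES = FALSE)
    hit <- which(sims > threshold)
    if (!length(hit)) next
    edges[[length(edges) + 1L]] <- tibble::tibble(
      mirna_id = pairs$mirna_id[i],
      transcript_id = pairs$transcript_id[i],
      gene_id = gene_sequences$gene_id[hit],
      similarity = sims[hit]
    )
  }
  out <- dplyr::bind_rows(edges)
  if (nrow(out) == 0) {
    return(tibble::tibble(mirna_id = character(0), cluster_id = character(0),
                          transcript_id = character(0), gene_id = character(0),
                          similarity = numeric(0), cluster_rank = integer(0)))
  }
  out$cluster_id <- clusters$cluster_id[match(out$gene_id, clusters$gene_id)]
  ## one edge per miRNA-cluster pair, keeping the strongest support
  out <- dplyr::arrange(out, dplyr::desc(.data$similarity))
  out <- dplyr::distinct(out, .data$mirna_id, .data$cluster_id,
                         .keep_all = TRUE)
  if (!is.null(rank)) {
    rk <- tidy(rank)
    out$cluster_rank <- rk$rank[match(out$cluster_id, rk$cluster_id)]
  } else {
    out$cluster_rank <- NA_integer_
  }
  dplyr::arrange(out, .data$mirna_id, .data$cluster_id)[
    , c("mirna_id", "cluster_id", "transcript_id", "gene_id",
        "similarity", "cluster_rank")
  ]
}
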