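## Internal sequence and I/O helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAT"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## uniform random DNA strings of the given lengths
random_dna <- function(lengths) {
  if (length(lengths) == 0) return(character(0))
  total <- sum(lengths)
  bases <- sample(DNA_BASES, total, replace = TRUE)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1
  big <- paste(bases, collapse = "")
  substring(big, starts, ends)
}

## Watson-Crick complement lookup without reversing
complement_chr <- function(x) chartr("ACGT", "TGCA", x)

## split a character vector of equal treatment into a per-string integer matrix
## of byte codes; used by the duplex scorer.
seq_to_int <- function(x) {
  lapply(x, function(s) utf8ToInt(s))
}

## minimum Phred score per read, fully vectorised: one pass over the
## concatenated quality strings (offset 33).
min_quality <- function(qual) {
  n <- length(qual)
  if (n == 0) return(integer(0))
  widths <- nchar(qual)
  codes <- utf8ToInt(paste(qual, collapse = ""))
  grp <- rep.int(seq_len(n), widths)
  out <- rep.int(NA_integer_, n)
  mins <- vapply(split(codes, grp), min, integer(1))
  out[as.integer(names(mins))] <- mins
  out - 33L
}

## ---- FASTA / FASTQ as tibbles -------------------------------------------

#' Read and write FASTA/FASTQ as tibbles
#'
#' All pipeline functions exchange sequences as tibbles; these helpers move
#' between that representation and on-disk FASTA/FASTQ via Biostrings.
#'
#' @param path File path.
#' @param x For writers, a tibble with columns `id`, `sequence` (and `quality`
#'   for FASTQ).
#' @return Readers return a tibble with columns `id`, `sequence` (FASTQ adds
#'   `quality`); writers return `path` invisibly.
#' @name sequence_io
NULL

#' @rdname sequence_io
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble::tibble(id = names(ss), sequence = as.character(ss))
}

#' @rdname sequence_io
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname sequence_io
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readQualityScaledDNAStringSet(path)
  tibble::tibble(
    id = names(ss),
    sequence = as.character(ss),
    quality = as.character(Biostrings::quality(ss))
  )
}

#' @rdname sequence_io
#' @export
write_fastq <- function(x, path) {
  qual <- Biostrings::PhredQuality(x$quality)
  ss <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(x$sequence, x$id)), qual
  )
  Biostrings::writeQualityScaledXStringSet(ss, path)
  invisible(path)
}

## deterministic seed scoping: run `expr` under `seed` and restore RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
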