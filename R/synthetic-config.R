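#' Configuration for the synthetic three-library small-RNA experiment
#'
#' Builds the single configuration object consumed by [generate_reference()],
#' [simulate_libraries()], [simulate_degradome()] and [simulate_corpus()].
#' Defaults emulate the study design the package is built around: three
#' small-RNA libraries (control, drought, salt) dominated by 21/24-nt reads,
#' a contaminant background of rRNA/tRNA/snRNA/snoRNA fragments, planted
#' conserved and novel miRNA hairpins with miRNA* partners, planted
#' per-condition log2 fold changes, degradome tags peaked at cleavage sites,
#' and a gene-document corpus with homologous gene families of varying
#' citation frequency.
#'
#' @param seed Integer seed; the same config (including seed) yields
#'   byte-identical outputs.
#' @param n_contigs,contig_length Reference contigs standing in for the
#'   EST/GSS/genome assemblies (counts, nt).
#' @param n_known_mirnas,n_novel_mirnas Numbers of planted miRNA loci whose
#'   matures are/are not present in the known-miRNA catalog.
#' @param n_contaminants Named counts of catalog entries per contaminant class
#'   (`rRNA`, `tRNA`, `snRNA`, `snoRNA`).
#' @param library_sizes Named integer vector of reads per condition
#'   (`control`, `drought`, `salt`).
#' @param planted_log2_fc Matrix (rows = miRNA ids, columns `drought`, `salt`)
#'   of planted log2 fold changes versus control, or `NULL` for the default
#'   plan (a handful of +/-2 effects on well-expressed miRNAs, 0 elsewhere).
#' @param star_fraction Fraction of planted miRNAs whose star strand is
#'   sequenced at all.
#' @param read_length_distribution Weights over read lengths 18-30 nt for
#'   contaminant/background inserts (21 and 24 nt dominate by default).
#' @param adapter 3' adapter sequence appended to every insert before the
#'   machine truncates reads to `machine_read_length`.
#' @param sequencing_error_rate Per-base substitution probability; errored
#'   bases are written at Phred 10 so the quality filter can see them.
#' @param degradome_signal_fraction Fraction of degradome tags placed exactly
#'   at planted cleavage positions (the rest are uniform noise).
#' @param corpus_n_documents,corpus_n_gene_families Size of the synthetic
#'   literature corpus.
#' @param corpus_offtarget_species_fraction Fraction of documents labeled with
#'   a non-plant species (removed by [filter_species()]).
#' @param mirna_fraction Expected fraction of each library drawn from planted
#'   mature miRNAs (the paper-scale libraries run ~20-26% miRNA reads).
#' @param contaminant_fractions Expected library mass per contaminant class.
#' @param star_to_mature_ratio Expected star:mature count ratio for miRNAs
#'   with a sequenced star.
#' @param background_unique Number of distinct background (unannotated) read
#'   sequences; half are sampled from the contigs so they map, half are random.
#' @param mature_length,loop_length,flank_length Planted precursor geometry
#'   (nt): mature arm length, terminal loop, flank on each side of the stem.
#' @param stem_mismatches Planted mismatches in each precursor stem (0-2).
#' @param n_transcripts,transcript_length Synthetic mRNA set hosting planted
#'   target sites.
#' @param degradome_tags_per_transcript Total degradome tags per transcript.
#' @param machine_read_length Fixed sequencer read length (nt).
#'
#' @return A list of class `stressmir_config` with validated fields.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1, library_sizes = c(
#'   control = 20000, drought = 20000, salt = 20000
#' ))
#' cfg$n_novel_mirnas
synthetic_config <- function(seed = 1L,
                             n_contigs = 12L,
                             contig_length = 50000L,
                             n_known_mirnas = 12L,
                             n_novel_mirnas = 8L,
                             n_contaminants = c(rRNA = 8L, tRNA = 8L,
                                                snRNA = 4L, snoRNA = 4L),
                             library_sizes = c(control = 100000L,
                                               drought = 100000L,
                                               salt = 100000L),
                             planted_log2_fc = NULL,
                             star_fraction = 0.8,
                             read_length_distribution = NULL,
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             sequencing_error_rate = 0.001,
                             degradome_signal_fraction = 0.8,
                             corpus_n_documents = 120L,
                             corpus_n_gene_families = 10L,
                             corpus_offtarget_species_fraction = 0.15,
                             mirna_fraction = 0.22,
                             contaminant_fractions = c(rRNA = 0.065,
                                                       tRNA = 0.010,
                                                       snRNA = 1e-4,
                                                       snoRNA = 5e-5),
                             star_to_mature_ratio = 0.25,
                             background_unique = 800L,
                             mature_length = 21L,
                             loop_length = 12L,
                             flank_length = 6L,
                             stem_mismatches = 0L,
                             n_transcripts = 15L,
                             transcript_length = 800L,
                             degradome_tags_per_transcript = 200L,
                             machine_read_length = 36L) {
  if (is.null(read_length_distribution)) {
    read_length_distribution <- setNames(
      c(1, 1, 2, 10, 3, 2, 8, 1, 1, 1, 1, 1, 1), as.character(18:30)
    )
    ## 21 and 24 nt dominate, as in plant small-RNA libraries
  }
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n_contigs > 0, contig_length > 0,
    n_known_mirnas >= 0, n_novel_mirnas >= 0,
    all(n_contaminants > 0),
    all(library_sizes >= 0), length(library_sizes) == 3,
    star_fraction >= 0, star_fraction <= 1,
    sequencing_error_rate >= 0, sequencing_error_rate <= 1,
    degradome_signal_fraction >= 0, degradome_signal_fraction <= 1,
    corpus_offtarget_species_fraction >= 0,
    corpus_offtarget_species_fraction <= 1,
    nchar(adapter) >= 6,
    mirna_fraction > 0, mirna_fraction < 1,
    stem_mismatches >= 0, stem_mismatches <= 2,
    loop_length >= 8,
    mature_length >= 18, mature_length <= 30
  )
  if (!all(c("control", "drought", "salt") %in% names(library_sizes))) {
    stop("`library_sizes` must be named control/drought/salt", call. = FALSE)
  }
  ids <- mirna_ids(n_known_mirnas, n_novel_mirnas)
  if (is.null(planted_log2_fc)) {
    planted_log2_fc <- default_fc_plan(ids)
  } else {
    planted_log2_fc <- as.matrix(planted_log2_fc)
    stopifnot(
      all(rownames(planted_log2_fc) %in% ids$mirna_id),
      all(c("drought", "salt") %in% colnames(planted_log2_fc)),
      all(is.finite(planted_log2_fc))
    )
    full <- default_fc_plan(ids) * 0
    full[rownames(planted_log2_fc), colnames(planted_log2_fc)] <-
      planted_log2_fc
    planted_log2_fc <- full
  }
  structure(list(
    seed = as.integer(seed),
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    n_known_mirnas = as.integer(n_known_mirnas),
    n_novel_mirnas = as.integer(n_novel_mirnas),
    n_contaminants = n_contaminants,
    library_sizes = library_sizes[c("control", "drought", "salt")],
    planted_log2_fc = planted_log2_fc,
    star_fraction = star_fraction,
    read_length_distribution = read_length_distribution,
    adapter = adapter,
    sequencing_error_rate = sequencing_error_rate,
    degradome_signal_fraction = degradome_signal_fraction,
    corpus_n_documents = as.integer(corpus_n_documents),
    corpus_n_gene_families = as.integer(corpus_n_gene_families),
    corpus_offtarget_species_fraction = corpus_offtarget_species_fraction,
    mirna_fraction = mirna_fraction,
    contaminant_fractions = contaminant_fractions,
    star_to_mature_ratio = star_to_mature_ratio,
    background_unique = as.integer(background_unique),
    mature_length = as.integer(mature_length),
    loop_length = as.integer(loop_length),
    flank_length = as.integer(flank_length),
    stem_mismatches = as.integer(stem_mismatches),
    n_transcripts = as.integer(n_transcripts),
    transcript_length = as.integer(transcript_length),
    degradome_tags_per_transcript = as.integer(degradome_tags_per_transcript),
    machine_read_length = as.integer(machine_read_length)
  ), class = "stressmir_config")
}

## miRNA id table: known ("mir-###") then novel ("nov-###")
mirna_ids <- function(n_known, n_novel) {
  tibble::tibble(
    mirna_id = c(sprintf("mir-%03d", seq_len(n_known)),
                 sprintf("nov-%03d", seq_len(n_novel))),
    known = rep(c(TRUE, FALSE), c(n_known, n_novel))
  )
}

## default planted-effect plan: strong (|log2 FC| = 2) effects on a few
## well-expressed miRNAs, null elsewhere
default_fc_plan <- function(ids) {
  fc <- matrix(0, nrow = nrow(ids), ncol = 2,
               dimnames = list(ids$mirna_id, c("drought", "salt")))
  known <- ids$mirna_id[ids$known]
  novel <- ids$mirna_id[!ids$known]
  if (length(known) >= 1) fc[known[1], ] <- c(2, 0)
  if (length(known) >= 2) fc[known[2], ] <- c(-2, 0)
  if (length(known) >= 3) fc[known[3], ] <- c(0, 2)
  if (length(known) >= 4) fc[known[4], ] <- c(0, -2)
  if (length(novel) >= 1) fc[novel[1], ] <- c(2, 2)
  fc
}
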