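#' Pipeline configuration
#'
#' Collects every numeric threshold used by the identification and
#' conservation stages in one place, so that command-line flags, config
#' files and function arguments all draw on a single source of defaults.
#'
#' @param min_transcript_len Minimum spliced transcript length in nt.
#'   Transcripts must be strictly longer than this to be retained (default
#'   200, the conventional lncRNA length floor).
#' @param max_noncoding_orf_aa Longest open reading frame, in amino acids,
#'   compatible with a non-coding call. An ORF strictly longer than this
#'   marks the transcript as protein-coding (default 100).
#' @param protein_evalue E-value at or below which a protein-database hit
#'   marks a transcript as coding (default 1e-5).
#' @param te_bitscore,te_evalue Bit-score floor and E-value ceiling that
#'   together classify a transcript as transposable-element derived
#'   (defaults 200 and 1e-20; both conditions must hold).
#' @param tss_window Maximum distance in bp between a lincRNA 5' end and a
#'   transcription start site for the CAGE_PLUS flag (default 100,
#'   inclusive).
#' @param flank_extension Flank in bp added to both ends of annotated gene
#'   spans before overlap classification (default 500).
#' @param search_evalue E-value cutoff for the homology search (default
#'   1e-20).
#' @param segment_len Segment length in nt for the segmented fallback
#'   search (default 200).
#' @param min_segment_len Shortest trailing remainder segment kept
#'   (default 100); shorter remainders are discarded because their
#'   E-values are unstable at genome scale.
#' @param merge_gap Maximum gap in bp between hits on the same subject
#'   sequence and strand for them to be merged into one locus (default
#'   10000, wide enough to span typical introns without bridging
#'   neighbouring genes).
#' @param bootstrap_threshold Bootstrap support below which gene-tree
#'   edges are collapsed before reconciliation (default 70).
#' @param match,mismatch Nucleotide match reward and mismatch penalty for
#'   the built-in aligner (defaults +2/-3, the classic nucleotide-search
#'   scheme).
#' @param gap_open,gap_extend Gap opening and extension penalties, given
#'   as positive costs (defaults 5 and 2).
#' @param word_size Seed k-mer length for the built-in aligner (default
#'   11).
#' @param band_extra Extra window, in nt, added around a seed cluster
#'   when extracting the subject region for gapped extension (default
#'   50).
#' @param reciprocal_min_overlap Minimum overlap, in bp, between the
#'   reciprocal top hit and the original query locus for the reciprocity
#'   test to pass (default 1).
#' @param bootstrap_n Number of bootstrap replicates for internal
#'   gene-tree inference (default 100).
#' @param seed Integer seed for any stochastic step (bootstrap
#'   resampling); NULL leaves the RNG state alone.
#'
#' @return An object of class `linckit_config`, a named list.
#' @export
#' @examples
#' cfg <- linckit_config()
#' cfg$min_transcript_len
linckit_config <- function(min_transcript_len = 200,
                           max_noncoding_orf_aa = 100,
                           protein_evalue = 1e-5,
                           te_bitscore = 200,
                           te_evalue = 1e-20,
                           tss_window = 100,
                           flank_extension = 500,
                           search_evalue = 1e-20,
                           segment_len = 200,
                           min_segment_len = 100,
                           merge_gap = 10000,
                           bootstrap_threshold = 70,
                           match = 2,
                           mismatch = -3,
                           gap_open = 5,
                           gap_extend = 2,
                           word_size = 11,
                           band_extra = 50,
                           reciprocal_min_overlap = 1,
                           bootstrap_n = 100,
                           seed = NULL) {
  cfg <- list(min_transcript_len = min_transcript_len,
              max_noncoding_orf_aa = max_noncoding_orf_aa,
              protein_evalue = protein_evalue,
              te_bitscore = te_bitscore,
              te_evalue = te_evalue,
              tss_window = tss_window,
              flank_extension = flank_extension,
              search_evalue = search_evalue,
              segment_len = segment_len,
              min_segment_len = min_segment_len,
              merge_gap = merge_gap,
              bootstrap_threshold = bootstrap_threshold,
              match = match,
              mismatch = mismatch,
              gap_open = gap_open,
              gap_extend = gap_extend,
              word_size = word_size,
              band_extra = band_extra,
              reciprocal_min_overlap = reciprocal_min_overlap,
              bootstrap_n = bootstrap_n,
              seed = seed)
  pos <- c("min_transcript_len", "max_noncoding_orf_aa", "protein_evalue",
           "te_bitscore", "te_evalue", "tss_window", "search_evalue",
           "segment_len", "min_segment_len", "merge_gap",
           "bootstrap_threshold", "match", "gap_open", "gap_extend",
           "word_size", "bootstrap_n")
  for (nm in pos) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("config field '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  if (cfg$mismatch >= 0)
    stop("config field 'mismatch' must be negative", call. = FALSE)
  if (cfg$flank_extension < 0)
    stop("config field 'flank_extension' must be >= 0", call. = FALSE)
  structure(cfg, class = "linckit_config")
}

#' @export
print.linckit_config <- function(x, ...) {
  cat("linckit configuration\n")
  flds <- setdiff(names(x), "seed")
  for (nm in flds) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  if (!is.null(x$seed)) cat(sprintf("  %-24s %s\n", "seed", x$seed))
  invisible(x)
}

as_config <- function(cfg) {
  if (is.null(cfg)) return(linckit_config())
  if (inherits(cfg, "linckit_config")) return(cfg)
  if (is.list(cfg)) return(do.call(linckit_config, cfg))
  stop("'cfg' must be a linckit_config or a named list", call. = FALSE)
}
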