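#' Spliced transcript sequences
#'
#' Extracts and concatenates the exon sequences of each transcript from
#' the genome, reverse-complementing minus-strand transcripts. Unknown
#' strand is treated as plus (the caller decides what unknown strand
#' means for classification).
#'
#' @param genome A named `DNAStringSet` of chromosome sequences.
#' @param annot An [annotation_set].
#' @param ids Transcript ids to extract (default: all).
#' @return A `DNAStringSet` named by transcript id.
#' @export
spliced_transcript_seqs <- function(genome, annot, ids = NULL) {
  tx <- annot$transcripts
  if (is.null(ids)) ids <- names(tx)
  missing_chr <- setdiff(
    unique(as.character(GenomicRanges::seqnames(tx[ids]))), names(genome))
  if (length(missing_chr) > 0L) {
    bad <- ids[as.character(GenomicRanges::seqnames(tx[ids])) %in% missing_chr]
    stop("transcript(s) reference sequences absent from the genome: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- lapply(ids, function(id) {
    ex <- transcript_exons(annot, id)
    chr <- as.character(GenomicRanges::seqnames(ex))[1]
    parts <- Biostrings::extractAt(
      genome[[chr]],
      IRanges::IRanges(BiocGenerics::start(ex), BiocGenerics::end(ex)))
    s <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
    if (as.character(BiocGenerics::strand(ex))[1] == "-")
      s <- Biostrings::reverseComplement(s)
    s
  })
  res <- Biostrings::DNAStringSet(out)
  names(res) <- ids
  res
}

#' Infer strand of unstranded multi-exon transcripts from splice sites
#'
#' Multi-exon transcripts assembled without strand information still carry
#' orientation in their introns: canonical splice junctions read GT..AG on
#' the transcribed strand. Each intron votes; a majority on one strand
#' assigns it, otherwise the strand stays unknown. Single-exon transcripts
#' are never changed.
#'
#' @param genome Named `DNAStringSet`.
#' @param annot An [annotation_set].
#' @return The `annotation_set` with inferred strands applied to both
#'   exons and spans.
#' @export
infer_strand_from_splice_sites <- function(genome, annot) {
  tx <- annot$transcripts
  unknown <- names(tx)[as.character(BiocGenerics::strand(tx)) == "*" &
                         S4Vectors::mcols(tx)$exon_count > 1L]
  if (length(unknown) == 0L) return(annot)
  newstrand <- vapply(unknown, function(id) {
    ex <- transcript_exons(annot, id)
    chr <- as.character(GenomicRanges::seqnames(ex))[1]
    if (!chr %in% names(genome)) return("*")
    g <- genome[[chr]]
    n <- length(ex)
    votes <- c(`+` = 0L, `-` = 0L)
    for (i in seq_len(n - 1L)) {
      a <- BiocGenerics::end(ex)[i] + 1L        # intron start
      b <- BiocGenerics::start(ex)[i + 1L] - 1L # intron end
      if (b - a + 1L < 4L || a < 1L || b > length(g)) next
      donor <- as.character(Biostrings::subseq(g, a, a + 1L))
      accept <- as.character(Biostrings::subseq(g, b - 1L, b))
      if (donor == "GT" && accept == "AG") votes["+"] <- votes["+"] + 1L
      if (donor == "CT" && accept == "AC") votes["-"] <- votes["-"] + 1L
    }
    if (votes["+"] > votes["-"]) "+"
    else if (votes["-"] > votes["+"]) "-"
    else "*"
  }, character(1))
  fix <- unknown[newstrand != "*"]
  if (length(fix) > 0L) {
    idx <- match(fix, names(annot$transcripts))
    BiocGenerics::strand(annot$transcripts)[idx] <- newstrand[newstrand != "*"]
    exid <- S4Vectors::mcols(annot$exons)$transcript_id
    m <- match(exid, fix)
    hit <- !is.na(m)
    BiocGenerics::strand(annot$exons)[hit] <- newstrand[newstrand != "*"][m[hit]]
  }
  annot
}

#' Longest complete open reading frame, in amino acids
#'
#' Scans all six reading frames (three per strand) for ATG-initiated,
#' stop-terminated ORFs and returns the longest, counting codons from the
#' initiator ATG (inclusive) to the stop (exclusive). Incomplete ORFs (no
#' in-frame stop) do not count; 0 is returned when no complete ORF exists.
#'
#' @param seq A `DNAString`, `DNAStringSet` element, or character string.
#' @return Integer amino-acid length of the longest complete ORF.
#' @export
find_longest_orf <- function(seq) {
  if (!is.character(seq)) seq <- as.character(seq)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 6L) return(0L)
  x <- unname(BASE_CODE[chars])          # NA for ambiguity codes
  best <- 0L
  ATG <- 14L                              # 16*A + 4*T + G
  STOPS <- c(48L, 50L, 56L)               # TAA, TAG, TGA
  scan_strand <- function(x) {
    for (frame in 0:2) {
      n_cod <- (n - frame) %/% 3L
      if (n_cod < 2L) next
      i <- frame + 3L * (seq_len(n_cod) - 1L) + 1L
      code <- 16L * x[i] + 4L * x[i + 1L] + x[i + 2L]
      code[is.na(code)] <- -1L            # fuzzy codon: neither ATG nor stop
      atg <- which(code == ATG)
      stp <- which(code %in% STOPS)
      if (length(atg) == 0L || length(stp) == 0L) next
      nxt <- stp[findInterval(atg, stp) + 1L]   # first stop after each ATG
      lens <- nxt - atg
      lens <- lens[!is.na(lens)]
      if (length(lens) > 0L) best <<- max(best, lens)
    }
  }
  scan_strand(x)
  scan_strand(rev(3L - x))               # reverse complement
  as.integer(best)
}
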