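#' Transcript annotation container
#'
#' Groups exon intervals into transcript models and keeps an overlap index
#' over their genomic spans. Internally all coordinates follow the
#' Bioconductor convention (1-based, closed intervals, `GRanges`); BED
#' output converts at the boundary. Strand `"*"` means unknown.
#'
#' @param exons A [GenomicRanges::GRanges] of exon intervals with
#'   `transcript_id` and `gene_id` metadata columns.
#' @return An object of class `annotation_set` with elements:
#'   \describe{
#'     \item{exons}{the exon `GRanges`, sorted within each transcript}
#'     \item{transcripts}{a `GRanges` of transcript spans, named by
#'       transcript id, with `gene_id` and `exon_count` columns}
#'   }
#' @export
annotation_set <- function(exons) {
  stopifnot(methods::is(exons, "GRanges"))
  if (length(exons) == 0L) {
    tx <- GenomicRanges::GRanges()
    S4Vectors::mcols(tx)$gene_id <- character(0)
    S4Vectors::mcols(tx)$exon_count <- integer(0)
    return(structure(list(exons = exons, transcripts = tx),
                     class = "annotation_set"))
  }
  mc <- S4Vectors::mcols(exons)
  if (is.null(mc$transcript_id))
    stop("exon GRanges must carry a 'transcript_id' column", call. = FALSE)
  if (is.null(mc$gene_id)) mc$gene_id <- mc$transcript_id
  S4Vectors::mcols(exons) <- mc[, c("transcript_id", "gene_id")]

  txid <- mc$transcript_id
  # one seqname and one strand per transcript
  chk <- tapply(seq_along(exons), txid, function(i) {
    length(unique(as.character(GenomicRanges::seqnames(exons)[i]))) > 1L ||
      length(unique(as.character(BiocGenerics::strand(exons)[i]))) > 1L
  })
  if (any(chk))
    stop("transcript(s) with conflicting seqnames or strand across exons: ",
         paste(names(chk)[chk], collapse = ", "), call. = FALSE)

  o <- order(txid, BiocGenerics::start(exons))
  exons <- exons[o]
  txid <- S4Vectors::mcols(exons)$transcript_id

  ov <- tapply(seq_along(exons), txid, function(i) {
    s <- BiocGenerics::start(exons)[i]; e <- BiocGenerics::end(exons)[i]
    length(i) > 1L && any(s[-1L] <= e[-length(i)])
  })
  if (any(ov))
    stop("transcript(s) with overlapping exons: ",
         paste(names(ov)[ov], collapse = ", "), call. = FALSE)

  first <- !duplicated(txid)
  ids <- txid[first]
  st <- tapply(BiocGenerics::start(exons), txid, min)[ids]
  en <- tapply(BiocGenerics::end(exons), txid, max)[ids]
  tx <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(exons)[first],
    ranges = IRanges::IRanges(as.integer(st), as.integer(en)),
    strand = BiocGenerics::strand(exons)[first])
  names(tx) <- ids
  S4Vectors::mcols(tx)$gene_id <- S4Vectors::mcols(exons)$gene_id[first]
  S4Vectors::mcols(tx)$exon_count <-
    as.integer(table(txid)[ids])
  structure(list(exons = exons, transcripts = tx), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$transcripts), "transcripts,",
      length(x$exons), "exons on",
      length(unique(as.character(GenomicRanges::seqnames(x$transcripts)))),
      "sequence(s)\n")
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$transcripts)

#' Exons of one transcript
#' @param annot An `annotation_set`.
#' @param transcript_id Transcript id.
#' @return `GRanges` of that transcript's exons, 5'-agnostic (left to
#'   right on the genome).
#' @export
transcript_exons <- function(annot, transcript_id) {
  i <- S4Vectors::mcols(annot$exons)$transcript_id == transcript_id
  if (!any(i)) stop("unknown transcript: ", transcript_id, call. = FALSE)
  annot$exons[i]
}

#' Transcripts overlapping a probe interval
#'
#' The overlap index every classification step relies on: returns the ids
#' of transcripts whose genomic span overlaps the probe by at least 1 bp.
#'
#' @param annot An `annotation_set`.
#' @param probe A `GRanges` of probe intervals.
#' @param ignore_strand Ignore strand when testing overlap (default TRUE;
#'   strand comparison is done by the callers that need it).
#' @return A list, one element per probe, of overlapping transcript ids.
#' @export
overlapping_transcripts <- function(annot, probe, ignore_strand = TRUE) {
  hits <- GenomicRanges::findOverlaps(probe, annot$transcripts,
                                      ignore.strand = ignore_strand)
  ids <- names(annot$transcripts)[S4Vectors::subjectHits(hits)]
  out <- split(ids, factor(S4Vectors::queryHits(hits),
                           levels = seq_along(probe)))
  names(out) <- NULL
  out
}

#' Read assembled transcripts from GTF
#'
#' Parses exon features into an [annotation_set]. Any GTF dialect that
#' provides a `transcript_id` attribute on its exon lines is accepted;
#' strand `"."` is kept as unknown (`"*"`).
#'
#' @param path Path to a GTF file (1-based inclusive coordinates).
#' @return An `annotation_set`.
#' @export
read_transcript_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)) & !startsWith(lines, "#")))
    return(annotation_set(GenomicRanges::GRanges()))
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) return(annotation_set(GenomicRanges::GRanges()))
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$type)) gr <- gr[tolower(as.character(mc$type)) == "exon"]
  mc <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) return(annotation_set(GenomicRanges::GRanges()))
  if (is.null(mc$transcript_id) || anyNA(mc$transcript_id))
    stop("GTF exon lines in '", path, "' lack a transcript_id attribute",
         call. = FALSE)
  annotation_set(gr)
}

#' Read a reference annotation from GFF/GTF
#'
#' Returns gene-level loci for overlap classification. When the file
#' distinguishes `gene` features those are used; otherwise features are
#' collapsed per `ID`/`gene_id`/`transcript_id` attribute (whichever is
#' present), so plain exon-only files also work.
#'
#' @param path Path to a GFF3/GTF file.
#' @return A `GRanges` of gene loci, named by feature id.
#' @export
read_annotation_gff <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  fmt <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  if (length(gr) == 0L) {
    out <- GenomicRanges::GRanges()
    return(out)
  }
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$type) && any(tolower(as.character(mc$type)) == "gene")) {
    gr <- gr[tolower(as.character(mc$type)) == "gene"]
    mc <- S4Vectors::mcols(gr)
  }
  id <- NULL
  for (cand in c("ID", "gene_id", "transcript_id", "Name"))
    if (is.null(id) && !is.null(mc[[cand]])) id <- as.character(mc[[cand]])
  if (is.null(id)) id <- paste0("feature_", seq_along(gr))
  id[is.na(id)] <- paste0("feature_", which(is.na(id)))
  # collapse multi-line features (e.g. exon rows of one gene) to spans
  key <- paste(id, as.character(GenomicRanges::seqnames(gr)),
               as.character(BiocGenerics::strand(gr)))
  first <- !duplicated(key)
  st <- tapply(BiocGenerics::start(gr), key, min)
  en <- tapply(BiocGenerics::end(gr), key, max)
  k <- key[first]
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr)[first],
    ranges = IRanges::IRanges(as.integer(st[k]), as.integer(en[k])),
    strand = BiocGenerics::strand(gr)[first])
  names(out) <- id[first]
  out
}

#' Extend gene spans by a fixed flank
#'
#' Widens every locus by `flank` bp on both sides, clamped to the
#' chromosome, so that overlap classification treats a margin around each
#' gene (UTRs, promoters) as genic. Exon structure is untouched.
#'
#' @param annot A `GRanges` of gene loci or an [annotation_set] (whose
#'   transcript spans are extended).
#' @param flank Non-negative flank in bp.
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   clamp the right end.
#' @return Object of the same type with extended spans.
#' @export
extend_gene_coordinates <- function(annot, flank, chrom_sizes = NULL) {
  if (flank < 0) stop("flank must be >= 0", call. = FALSE)
  ext <- function(gr) {
    if (length(gr) == 0L) return(gr)
    st <- pmax(1L, BiocGenerics::start(gr) - as.integer(flank))
    en <- BiocGenerics::end(gr) + as.integer(flank)
    if (!is.null(chrom_sizes)) {
      len <- chrom_sizes[as.character(GenomicRanges::seqnames(gr))]
      en <- ifelse(is.na(len), en, pmin(en, as.integer(len)))
    }
    GenomicRanges::ranges(gr) <- IRanges::IRanges(st, as.integer(en))
    gr
  }
  if (inherits(annot, "annotation_set")) {
    annot$transcripts <- ext(annot$transcripts)
    return(annot)
  }
  ext(annot)
}
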