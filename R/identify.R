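#' @title Transcript classification engine
#' @description Internal helpers and exported steps that partition an
#'   assembled transcriptome into lincRNA and related classes. Classes:
#'   \describe{
#'     \item{LINCRNA}{long intergenic non-coding RNA: > 200 nt spliced
#'       length, no long ORF, no protein similarity, no overlap with an
#'       annotated gene}
#'     \item{SOT / AOT}{sense- / antisense-overlapping transcript}
#'     \item{TE_DERIVED}{high similarity to a transposable-element
#'       database}
#'     \item{AMBIGUOUS_OVERLAP}{overlaps a gene but strand cannot be
#'       resolved (single-exon, unstranded assembly)}
#'     \item{REJECTED_SHORT / REJECTED_CODING}{failed the length or
#'       coding-potential filters}
#'   }
#' @name identify
NULL

LNC_CLASSES <- c("LINCRNA", "SOT", "AOT", "TE_DERIVED", "AMBIGUOUS_OVERLAP",
                 "REJECTED_SHORT", "REJECTED_CODING")

#' Length filter
#'
#' Keeps transcripts whose spliced length is strictly greater than
#' `min_len`; a transcript of exactly `min_len` nt is rejected.
#'
#' @param lengths Named integer vector of spliced lengths.
#' @param min_len Length floor in nt (default 200).
#' @return List with `kept` and `rejected` character vectors of ids.
#' @export
filter_by_length <- function(lengths, min_len = 200) {
  keep <- lengths > min_len
  list(kept = names(lengths)[keep], rejected = names(lengths)[!keep])
}

#' Coding-potential assessment
#'
#' A transcript is called coding when its longest complete ORF exceeds
#' `max_noncoding_orf_aa` amino acids, or when any supplied
#' protein-database hit has E-value at or below `protein_evalue`. Both
#' boundaries follow the usual convention: an ORF of exactly 100 aa and a
#' hit at exactly the E-value cutoff count as coding evidence only for the
#' E-value (the ORF rule is strict, the E-value rule inclusive).
#'
#' @param orf_aa Longest-ORF length in amino acids.
#' @param hit_evalues Numeric vector of protein-hit E-values (possibly
#'   empty). The search itself is pluggable: supply a table from an
#'   external BLASTp run or from the fixture generator.
#' @param cfg A [linckit_config].
#' @return List with `verdict` ("coding"/"noncoding"), `orf_aa`,
#'   `best_evalue` (NA when no hits).
#' @export
assess_coding <- function(orf_aa, hit_evalues = numeric(0), cfg = NULL) {
  cfg <- as_config(cfg)
  best <- if (length(hit_evalues)) min(hit_evalues) else NA_real_
  coding <- orf_aa > cfg$max_noncoding_orf_aa ||
    (!is.na(best) && best <= cfg$protein_evalue)
  list(verdict = if (coding) "coding" else "noncoding",
       orf_aa = orf_aa, best_evalue = best)
}

#' Transposable-element filter
#'
#' A transcript is TE-derived when its best hit against the TE database
#' reaches bit score >= `te_bitscore` AND E-value <= `te_evalue`; both
#' conditions are required, so weak similarity to an old TE insertion
#' does not remove a transcript.
#'
#' @param te_hits data.frame with columns `transcript_id`, `bitscore`,
#'   `evalue` (best hit per transcript; transcripts without a hit may be
#'   absent).
#' @param ids Character vector of transcript ids being filtered.
#' @param cfg A [linckit_config].
#' @return List with `te_derived` and `retained` id vectors.
#' @export
filter_te <- function(te_hits, ids, cfg = NULL) {
  cfg <- as_config(cfg)
  if (is.null(te_hits) || nrow(te_hits) == 0L)
    return(list(te_derived = character(0), retained = ids))
  m <- match(ids, te_hits$transcript_id)
  is_te <- !is.na(m) &
    te_hits$bitscore[m] >= cfg$te_bitscore &
    te_hits$evalue[m] <= cfg$te_evalue
  list(te_derived = ids[is_te], retained = ids[!is_te])
}

#' Classify a transcript's overlap with annotated genes
#'
#' Span overlap (>= 1 bp, strand-blind) with any annotated locus removes a
#' transcript from the intergenic class. Overlapping transcripts are
#' sense (SOT) or antisense (AOT) according to strand; when the
#' transcript strand is unknown (single-exon, unstranded library, or
#' splice-site inference failed) the direction cannot be resolved and the
#' transcript is AMBIGUOUS_OVERLAP.
#'
#' @param span `GRanges` of length 1: the transcript's genomic span,
#'   strand already inferred where possible.
#' @param genes `GRanges` of annotated gene loci (possibly flank-extended
#'   via [extend_gene_coordinates()]).
#' @return One of "LINCRNA", "SOT", "AOT", "AMBIGUOUS_OVERLAP".
#' @export
classify_overlap <- function(span, genes) {
  hits <- GenomicRanges::findOverlaps(span, genes, ignore.strand = TRUE)
  if (length(hits) == 0L) return("LINCRNA")
  txs <- as.character(BiocGenerics::strand(span))
  if (txs == "*") return("AMBIGUOUS_OVERLAP")
  gs <- as.character(BiocGenerics::strand(genes))[S4Vectors::subjectHits(hits)]
  gs <- gs[gs != "*"]
  if (length(gs) == 0L) return("AMBIGUOUS_OVERLAP")
  if (any(gs == txs)) "SOT" else "AOT"
}

#' Flag lincRNAs near transcription start sites
#'
#' A lincRNA whose 5' end lies within `tss_window` bp (inclusive) of any
#' TSS is flagged CAGE_PLUS, i.e. supported by independent evidence of
#' transcription initiation. The 5' end is the span start on the plus
#' strand and the span end on the minus strand; for unknown strand the
#' span start is used and a warning recorded.
#'
#' @param spans `GRanges` of lincRNA spans (named by id).
#' @param tss `GRanges` of TSS positions (e.g. from a CAGE BED file).
#' @param cfg A [linckit_config].
#' @return Named logical vector `cage_plus`.
#' @export
annotate_tss <- function(spans, tss, cfg = NULL) {
  cfg <- as_config(cfg)
  if (length(spans) == 0L)
    return(stats::setNames(logical(0), character(0)))
  st <- as.character(BiocGenerics::strand(spans))
  if (any(st == "*"))
    warning("lincRNA(s) with unknown strand: using span start as 5' end: ",
            paste(names(spans)[st == "*"], collapse = ", "), call. = FALSE)
  p5 <- ifelse(st == "-", BiocGenerics::end(spans),
               BiocGenerics::start(spans))
  if (length(tss) == 0L)
    return(stats::setNames(rep(FALSE, length(spans)), names(spans)))
  # distance in bp between the 5' point and the TSS interval (0 inside);
  # computed directly so "within 100 bp" is an inclusive base-pair count
  tss_chr <- as.character(GenomicRanges::seqnames(tss))
  res <- vapply(seq_along(spans), function(i) {
    same <- tss_chr == as.character(GenomicRanges::seqnames(spans)[i])
    if (!any(same)) return(FALSE)
    d <- pmax(0L, BiocGenerics::start(tss)[same] - p5[i],
              p5[i] - BiocGenerics::end(tss)[same])
    min(d) <= cfg$tss_window
  }, logical(1))
  stats::setNames(res, names(spans))
}

#' Mark lincRNAs overlapping a user-supplied set of known lincRNAs
#'
#' Any genomic-span overlap with a known lincRNA locus appends
#' `_overlapping_known_lncRNA` to the record id; the overlapping locus id
#' is recorded (nearest by midpoint when several overlap; all overlap ids
#' are kept for the summary table).
#'
#' @param spans `GRanges` of lincRNA spans, named by id.
#' @param known `GRanges` of known lincRNA loci, named by id.
#' @return data.frame with `transcript_id`, `known_lincrna_id` (NA when
#'   none), `known_all` (comma-separated, "" when none), `final_id`.
#' @export
reconcile_known_lincRNAs <- function(spans, known) {
  ids <- if (is.null(names(spans))) character(0) else names(spans)
  out <- data.frame(transcript_id = ids,
                    known_lincrna_id = rep(NA_character_, length(ids)),
                    known_all = rep("", length(ids)),
                    final_id = ids,
                    stringsAsFactors = FALSE)
  if (length(spans) == 0L || is.null(known) || length(known) == 0L)
    return(out)
  hits <- GenomicRanges::findOverlaps(spans, known, ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  mid_q <- (BiocGenerics::start(spans) + BiocGenerics::end(spans)) / 2
  mid_k <- (BiocGenerics::start(known) + BiocGenerics::end(known)) / 2
  for (i in unique(qh)) {
    ks <- sh[qh == i]
    nearest <- ks[which.min(abs(mid_k[ks] - mid_q[i]))]
    out$known_lincrna_id[i] <- names(known)[nearest]
    out$known_all[i] <- paste(names(known)[ks], collapse = ",")
    out$final_id[i] <- paste0(ids[i], "_overlapping_known_lncRNA")
  }
  out
}

#' Cluster isoforms into unique loci
#'
#' Transcripts on the same sequence whose exons overlap, with compatible
#' strands (equal, or either unknown), belong to one locus; the relation
#' is closed transitively so chains of partially overlapping isoforms form
#' a single locus.
#'
#' @param annot An [annotation_set] restricted to the transcripts of
#'   interest.
#' @return List with `locus` (named integer vector: locus index per
#'   transcript) and `n_loci`.
#' @export
group_into_loci <- function(annot) {
  tx <- annot$transcripts
  n <- length(tx)
  if (n == 0L) return(list(locus = stats::setNames(integer(0), character(0)),
                           n_loci = 0L))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  ex <- annot$exons
  exid <- match(S4Vectors::mcols(ex)$transcript_id, names(tx))
  hits <- GenomicRanges::findOverlaps(ex, ex, ignore.strand = TRUE)
  qh <- exid[S4Vectors::queryHits(hits)]; sh <- exid[S4Vectors::subjectHits(hits)]
  keep <- qh < sh
  qh <- qh[keep]; sh <- sh[keep]
  st <- as.character(BiocGenerics::strand(tx))
  compat <- st[qh] == st[sh] | st[qh] == "*" | st[sh] == "*"
  for (k in which(compat)) union2(qh[k], sh[k])
  roots <- vapply(seq_len(n), find, integer(1))
  locus <- as.integer(factor(roots, levels = unique(roots)))
  list(locus = stats::setNames(locus, names(tx)), n_loci = length(unique(locus)))
}

#' Per-class demographics report
#'
#' For each transcript class reports isoform and unique-locus counts, GC
#' content over the concatenated sequence, and minimum / maximum / mean
#' spliced length. Empty classes yield a zero row.
#'
#' @param records data.frame with at least `transcript_id` and `class`.
#' @param seqs `DNAStringSet` of spliced sequences named by transcript id.
#' @param annot [annotation_set] covering the records (for locus
#'   grouping).
#' @param classes Classes to report (default SOT, AOT, LINCRNA,
#'   TE_DERIVED).
#' @return data.frame, one row per class.
#' @export
demographics <- function(records, seqs, annot,
                         classes = c("LINCRNA", "SOT", "AOT", "TE_DERIVED")) {
  rows <- lapply(classes, function(cl) {
    ids <- records$transcript_id[records$class == cl]
    if (length(ids) == 0L)
      return(data.frame(class = cl, n_transcripts = 0L, n_loci = 0L,
                        gc_percent = 0, min_len = 0L, max_len = 0L,
                        mean_len = 0, stringsAsFactors = FALSE))
    sub <- subset_annotation(annot, ids)
    loci <- group_into_loci(sub)
    ss <- seqs[ids]
    lens <- Biostrings::width(ss)
    gc <- sum(Biostrings::letterFrequency(ss, "GC")) / sum(lens) * 100
    data.frame(class = cl, n_transcripts = length(ids),
               n_loci = loci$n_loci, gc_percent = gc,
               min_len = min(lens), max_len = max(lens),
               mean_len = mean(lens), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# restrict an annotation_set to a subset of transcript ids
subset_annotation <- function(annot, ids) {
  keep <- S4Vectors::mcols(annot$exons)$transcript_id %in% ids
  annotation_set(annot$exons[keep])
}

#' Run the full lincRNA identification pipeline
#'
#' Filters assembled transcripts in the canonical order: spliced length,
#' coding potential (ORF + protein similarity), transposable-element
#' similarity, overlap with annotated genes, then annotates surviving
#' lincRNAs with TSS support and overlap with user-curated known
#' lincRNAs. Each transcript receives exactly one class.
#'
#' @param transcripts An [annotation_set] (from [read_transcript_gtf()])
#'   or a path to a GTF file.
#' @param genome Named `DNAStringSet` or path to a genome FASTA.
#' @param annotation `GRanges` of gene loci, an `annotation_set`, or a
#'   path to a GFF/GTF file.
#' @param te_db Optional TE database: `DNAStringSet` or FASTA path. When
#'   supplied (and `te_hits` is not), transcripts are searched against it
#'   with the built-in aligner.
#' @param tss Optional TSS set: `GRanges` or BED path.
#' @param known_lincrna Optional known-lincRNA loci: `GRanges` or GFF
#'   path.
#' @param protein_hits Optional data.frame `transcript_id`, `evalue` of
#'   protein-database hits (external BLASTp results); transcripts absent
#'   from the table have no hit.
#' @param te_hits Optional precomputed TE hit table (`transcript_id`,
#'   `bitscore`, `evalue`); overrides the built-in search.
#' @param cfg A [linckit_config].
#' @param flank Flank added to annotated gene spans before overlap
#'   classification; default taken from `cfg$flank_extension`. Use 0 for
#'   annotations that already include UTRs.
#' @return An object of class `linckit_identify` with elements `records`
#'   (per-transcript table), `seqs`, `lincRNA_ids`, `summary_table`,
#'   `demographics`, `annotation_updated` (reference genes plus lincRNA
#'   loci) and `config`.
#' @seealso [write_identify_outputs()] to materialise the output bundle.
#' @export
run_identify <- function(transcripts, genome, annotation,
                         te_db = NULL, tss = NULL, known_lincrna = NULL,
                         protein_hits = NULL, te_hits = NULL,
                         cfg = NULL, flank = NULL) {
  cfg <- as_config(cfg)
  if (is.null(flank)) flank <- cfg$flank_extension
  if (is.character(transcripts)) transcripts <- read_transcript_gtf(transcripts)
  if (is.character(genome)) genome <- read_fasta(genome)
  if (is.character(annotation)) annotation <- read_annotation_gff(annotation)
  if (inherits(annotation, "annotation_set"))
    annotation <- annotation$transcripts
  if (is.character(te_db)) te_db <- read_fasta(te_db)
  if (is.character(tss)) tss <- read_bed(tss)
  if (is.character(known_lincrna)) known_lincrna <- read_annotation_gff(known_lincrna)

  annot <- infer_strand_from_splice_sites(genome, transcripts)
  tx <- annot$transcripts
  ids <- names(tx)
  if (length(ids) == 0L) return(empty_identify_result(cfg))

  seqs <- spliced_transcript_seqs(genome, annot)
  lens <- stats::setNames(Biostrings::width(seqs), ids)

  cls <- stats::setNames(rep(NA_character_, length(ids)), ids)
  lf <- filter_by_length(lens, cfg$min_transcript_len)
  cls[lf$rejected] <- "REJECTED_SHORT"
  alive <- lf$kept

  orf_aa <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  orf_aa[alive] <- vapply(alive, function(id) find_longest_orf(seqs[[id]]),
                          integer(1))
  pe <- function(id) {
    if (is.null(protein_hits)) return(numeric(0))
    protein_hits$evalue[protein_hits$transcript_id == id]
  }
  coding <- vapply(alive, function(id)
    assess_coding(orf_aa[[id]], pe(id), cfg)$verdict == "coding", logical(1))
  cls[alive[coding]] <- "REJECTED_CODING"
  alive <- alive[!coding]

  if (is.null(te_hits) && !is.null(te_db) && length(alive) > 0L)
    te_hits <- te_hit_table(seqs[alive], te_db, cfg)
  tef <- filter_te(te_hits, alive, cfg)
  cls[tef$te_derived] <- "TE_DERIVED"
  alive <- tef$retained

  genes_ext <- extend_gene_coordinates(annotation, flank)
  for (id in alive)
    cls[id] <- classify_overlap(tx[id], genes_ext)

  linc_ids <- ids[!is.na(cls) & cls == "LINCRNA"]
  cage <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (!is.null(tss) && length(linc_ids) > 0L)
    cage[linc_ids] <- annotate_tss(tx[linc_ids], tss, cfg)

  known_tab <- reconcile_known_lincRNAs(tx[linc_ids],
                                        if (is.null(known_lincrna))
                                          GenomicRanges::GRanges()
                                        else known_lincrna)

  records <- data.frame(
    transcript_id = ids,
    seq_id = as.character(GenomicRanges::seqnames(tx)),
    start = BiocGenerics::start(tx),
    end = BiocGenerics::end(tx),
    strand = as.character(BiocGenerics::strand(tx)),
    exon_count = S4Vectors::mcols(tx)$exon_count,
    length = as.integer(lens),
    orf_aa = orf_aa,
    class = cls,
    cage_plus = cage,
    known_lincrna_id = NA_character_,
    final_id = ids,
    stringsAsFactors = FALSE)
  m <- match(known_tab$transcript_id, records$transcript_id)
  records$known_lincrna_id[m] <- known_tab$known_lincrna_id
  records$final_id[m] <- known_tab$final_id

  li <- records[records$class == "LINCRNA", , drop = FALSE]
  summary_table <- data.frame(
    lincRNA_id = li$final_id,
    length = li$length,
    exon_count = li$exon_count,
    TSS_support = ifelse(li$cage_plus, "CAGE_PLUS", "."),
    overlapping_known_lincRNA = ifelse(is.na(li$known_lincrna_id), ".",
                                       li$known_lincrna_id),
    stringsAsFactors = FALSE)
  summary_table <- summary_table[order(summary_table$lincRNA_id), ,
                                 drop = FALSE]
  rownames(summary_table) <- NULL

  demo <- demographics(records, seqs, annot)

  upd <- annotation
  if (length(linc_ids) > 0L) {
    linc_gr <- tx[linc_ids]
    S4Vectors::mcols(linc_gr) <- NULL
    names(linc_gr) <- records$final_id[match(linc_ids, records$transcript_id)]
    S4Vectors::mcols(linc_gr)$type <- "lincRNA"
    base <- annotation
    S4Vectors::mcols(base) <- NULL
    S4Vectors::mcols(base)$type <- rep("gene", length(base))
    upd <- c(base, linc_gr)
  }

  structure(list(records = records, seqs = seqs, annot = annot,
                 lincRNA_ids = linc_ids, summary_table = summary_table,
                 demographics = demo, annotation_updated = upd,
                 config = cfg),
            class = "linckit_identify")
}

empty_identify_result <- function(cfg) {
  structure(list(
    records = data.frame(transcript_id = character(0), seq_id = character(0),
                         start = integer(0), end = integer(0),
                         strand = character(0), exon_count = integer(0),
                         length = integer(0), orf_aa = integer(0),
                         class = character(0), cage_plus = logical(0),
                         known_lincrna_id = character(0),
                         final_id = character(0), stringsAsFactors = FALSE),
    seqs = Biostrings::DNAStringSet(),
    annot = annotation_set(GenomicRanges::GRanges()),
    lincRNA_ids = character(0),
    summary_table = data.frame(lincRNA_id = character(0), length = integer(0),
                               exon_count = integer(0),
                               TSS_support = character(0),
                               overlapping_known_lincRNA = character(0),
                               stringsAsFactors = FALSE),
    demographics = NULL, annotation_updated = GenomicRanges::GRanges(),
    config = cfg), class = "linckit_identify")
}

#' @export
print.linckit_identify <- function(x, ...) {
  cat("lincRNA identification result\n")
  cat("  transcripts:", nrow(x$records), "\n")
  if (nrow(x$records) > 0L) {
    tab <- table(factor(x$records$class, levels = LNC_CLASSES))
    for (cl in names(tab)) if (tab[[cl]] > 0L)
      cat(sprintf("    %-18s %d\n", cl, tab[[cl]]))
  }
  invisible(x)
}

#' @export
summary.linckit_identify <- function(object, ...) {
  object$demographics
}

# best TE hit per transcript using the built-in aligner
te_hit_table <- function(seqs, te_db, cfg) {
  idx <- build_search_index(te_db, cfg)
  rows <- lapply(names(seqs), function(id) {
    hits <- seeded_local_search(seqs[id], te_db, cfg, index = idx,
                                evalue_cutoff = Inf)
    if (nrow(hits) == 0L) return(NULL)
    best <- hits[which.max(hits$bitscore), , drop = FALSE]
    data.frame(transcript_id = id, bitscore = best$bitscore,
               evalue = best$evalue, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(transcript_id = character(0), bitscore = numeric(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write the identification output bundle
#'
#' Materialises the standard per-class files: `lincRNAs.FASTA` and
#' `lincRNAs.bed`, per-class FASTA/BED for SOT, AOT and TE-derived
#' transcripts, `Final_summary_table.tsv`, a demographics report, and an
#' updated annotation GFF with the lincRNA loci appended to the reference
#' genes. CAGE-supported lincRNAs carry `CAGE_PLUS` in their FASTA
#' description.
#'
#' @param result A `linckit_identify` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_identify_outputs <- function(result, dir) {
  stopifnot(inherits(result, "linckit_identify"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- result$records
  tx <- result$annot$transcripts

  emit <- function(cls, stem) {
    ids <- rec$transcript_id[rec$class == cls]
    ss <- result$seqs[ids]
    fid <- rec$final_id[match(ids, rec$transcript_id)]
    names(ss) <- fid
    desc <- ifelse(rec$cage_plus[match(ids, rec$transcript_id)],
                   "CAGE_PLUS", "")
    S4Vectors::mcols(ss)$description <- desc
    write_fasta(ss, file.path(dir, paste0(stem, ".FASTA")))
    gr <- tx[ids]
    S4Vectors::mcols(gr) <- NULL
    if (length(gr)) names(gr) <- fid
    write_bed(gr, file.path(dir, paste0(stem, ".bed")))
  }
  emit("LINCRNA", "lincRNAs")
  emit("SOT", "SOT")
  emit("AOT", "AOT")
  emit("TE_DERIVED", "TE_lncRNAs")

  utils::write.table(result$summary_table,
                     file.path(dir, "Final_summary_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$demographics))
    utils::write.table(result$demographics,
                       file.path(dir, "demographics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_gff(result$annotation_updated,
            file.path(dir, "annotation_updated.gff"))
  invisible(dir)
}
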