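#' @title Built-in homology search
#' @description A k-mer seeded local aligner with Karlin-Altschul
#'   significance, standing behind the same contract as an external
#'   `blastn` adapter: exact word seeds on both strands, seed clustering
#'   by diagonal, optimal local extension within the clustered window,
#'   and E-values from the ungapped scoring statistics.
#' @name search
NULL

BASE_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L)

# numeric k-mer codes for a character sequence; NA where the window
# contains a non-ACGT character
kmer_codes <- function(chars, k) {
  x <- BASE_CODE[chars]
  n <- length(x)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  code <- numeric(m)
  ok <- rep(TRUE, m)
  for (j in 0:(k - 1L)) {
    xj <- x[(1L + j):(m + j)]
    bad <- is.na(xj)
    ok <- ok & !bad
    xj[bad] <- 0L
    code <- code + xj * 4^j
  }
  code[!ok] <- NA_real_
  code
}

#' Build a reusable k-mer index over a subject sequence set
#'
#' Indexing a genome once and reusing it across queries dominates the
#' cost of a panel search; every search function accepts a prebuilt
#' index.
#'
#' @param subject Named `DNAStringSet`.
#' @param cfg A [linckit_config] (uses `word_size`).
#' @return An opaque index object for [seeded_local_search()].
#' @export
build_search_index <- function(subject, cfg = NULL) {
  cfg <- as_config(cfg)
  k <- cfg$word_size
  per_seq <- lapply(seq_along(subject), function(i) {
    chars <- strsplit(as.character(subject[[i]]), "", fixed = TRUE)[[1L]]
    codes <- kmer_codes(chars, k)
    keep <- !is.na(codes)
    split(which(keep), codes[keep])
  })
  names(per_seq) <- names(subject)
  structure(list(k = k, index = per_seq,
                 widths = stats::setNames(Biostrings::width(subject),
                                          names(subject)),
                 total_len = sum(Biostrings::width(subject))),
            class = "linckit_search_index")
}

empty_hits <- function() {
  data.frame(query_id = character(0), q_start = integer(0),
             q_end = integer(0), subject_id = character(0),
             s_start = integer(0), s_end = integer(0),
             strand = character(0), score = numeric(0),
             bitscore = numeric(0), evalue = numeric(0),
             pident = numeric(0), stringsAsFactors = FALSE)
}

#' Seeded local similarity search
#'
#' Finds local alignments of one query against a set of subject
#' sequences. Exact `word_size`-mers seed candidate regions on both
#' strands; seeds falling on nearby diagonals are clustered, the clustered
#' subject window is extracted, and an optimal local alignment
#' (match/mismatch scores with affine gaps from `cfg`) is computed inside
#' it. Raw scores are converted with the ungapped Karlin-Altschul
#' parameters of the match/mismatch scheme: bit score
#' \eqn{S' = (\lambda S - \ln K)/\ln 2}, expect value
#' \eqn{E = K m n e^{-\lambda S}} with m the query length and n the total
#' subject length. Hits with E-value above the cutoff are dropped; the
#' rest are returned sorted by bit score, descending.
#'
#' @param query `DNAStringSet` of length 1 (or `DNAString`), named.
#' @param subject Named `DNAStringSet` of subject sequences (e.g. the
#'   chromosomes of one genome).
#' @param cfg A [linckit_config].
#' @param index Optional prebuilt [build_search_index()] for `subject`.
#' @param evalue_cutoff E-value ceiling (default `cfg$search_evalue`).
#' @return data.frame of hits with query/subject intervals (1-based
#'   closed; query interval always on the query's own coordinates),
#'   strand of the subject relative to the query, raw score, bit score,
#'   E-value and percent identity.
#' @export
seeded_local_search <- function(query, subject, cfg = NULL, index = NULL,
                                evalue_cutoff = NULL) {
  cfg <- as_config(cfg)
  if (is.null(evalue_cutoff)) evalue_cutoff <- cfg$search_evalue
  if (methods::is(query, "DNAString"))
    query <- Biostrings::DNAStringSet(list(query = query))
  qid <- if (!is.null(names(query))) names(query)[1L] else "query"
  qseq <- query[[1L]]
  qlen <- length(qseq)
  k <- cfg$word_size
  if (qlen < k) {
    warning("query '", qid, "' shorter than word size ", k,
            "; no search performed", call. = FALSE)
    return(empty_hits())
  }
  if (is.null(index)) index <- build_search_index(subject, cfg)
  stopifnot(index$k == k)
  ka <- karlin_altschul_params(cfg$match, cfg$mismatch)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = cfg$match, mismatch = cfg$mismatch, baseOnly = FALSE)
  n_total <- index$total_len

  out <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") qseq else Biostrings::reverseComplement(qseq)
    qchars <- strsplit(as.character(qs), "", fixed = TRUE)[[1L]]
    qcodes <- kmer_codes(qchars, k)
    valid <- which(!is.na(qcodes))
    if (length(valid) == 0L) next
    keys <- as.character(qcodes[valid])
    for (si in seq_along(index$index)) {
      idx <- index$index[[si]]
      pos_list <- idx[keys]
      nhit <- lengths(pos_list)
      if (sum(nhit, na.rm = TRUE) == 0L) next
      has <- which(!vapply(pos_list, is.null, logical(1)))
      qpos <- rep(valid[has], nhit[has])
      spos <- unlist(pos_list[has], use.names = FALSE)
      hits_i <- extend_seed_clusters(qs, subject[[si]], qpos, spos, cfg,
                                     submat)
      if (is.null(hits_i) || nrow(hits_i) == 0L) next
      hits_i$subject_id <- names(subject)[si]
      hits_i$strand <- strand
      if (strand == "-") {
        qstart <- qlen - hits_i$q_end + 1L
        qend <- qlen - hits_i$q_start + 1L
        hits_i$q_start <- qstart
        hits_i$q_end <- qend
      }
      out[[length(out) + 1L]] <- hits_i
    }
  }
  if (length(out) == 0L) return(empty_hits())
  hits <- do.call(rbind, out)
  hits$query_id <- qid
  hits$bitscore <- (ka$lambda * hits$score - log(ka$K)) / log(2)
  hits$evalue <- ka$K * qlen * n_total * exp(-ka$lambda * hits$score)
  hits <- hits[hits$evalue <= evalue_cutoff & hits$score > 0, , drop = FALSE]
  # drop duplicate alignments found from different seed clusters
  key <- paste(hits$subject_id, hits$strand, hits$s_start, hits$s_end)
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits <- hits[order(-hits$bitscore, hits$evalue, hits$subject_id,
                     hits$s_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("query_id", "q_start", "q_end", "subject_id", "s_start",
           "s_end", "strand", "score", "bitscore", "evalue", "pident")]
}

# cluster seeds by subject position/diagonal and run one optimal local
# alignment per clustered window
extend_seed_clusters <- function(qs, sseq, qpos, spos, cfg, submat) {
  qlen <- length(qs)
  slen <- length(sseq)
  o <- order(spos, qpos)
  qpos <- qpos[o]; spos <- spos[o]
  gap_lim <- max(200L, qlen)
  brk <- c(0L, which(diff(spos) > gap_lim), length(spos))
  rows <- list()
  seen <- character(0)
  for (ci in seq_len(length(brk) - 1L)) {
    sel <- (brk[ci] + 1L):brk[ci + 1L]
    diag <- spos[sel] - qpos[sel]
    w_start <- max(1L, min(diag) + 1L - cfg$band_extra)
    w_end <- min(slen, max(diag) + qlen + cfg$band_extra)
    wkey <- paste(w_start, w_end)
    if (wkey %in% seen) next
    seen <- c(seen, wkey)
    win <- Biostrings::subseq(sseq, w_start, w_end)
    aln <- Biostrings::pairwiseAlignment(
      qs, win, type = "local", substitutionMatrix = submat,
      gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend)
    sc <- Biostrings::score(aln)
    if (sc <= 0) next
    pat <- Biostrings::pattern(aln)
    sub <- Biostrings::subject(aln)
    rows[[length(rows) + 1L]] <- data.frame(
      q_start = BiocGenerics::start(pat), q_end = BiocGenerics::end(pat),
      s_start = w_start + BiocGenerics::start(sub) - 1L,
      s_end = w_start + BiocGenerics::end(sub) - 1L,
      score = sc, pident = Biostrings::pid(aln),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Merge nearby hits into candidate loci
#'
#' Hits of one query against one genome that fall on the same subject
#' sequence and strand, within `merge_gap` bp of each other, are chained
#' by single linkage into one locus — the typical signature of a
#' multi-exon query hitting its homolog's exons. The locus score is the
#' sum of member bit scores; its E-value is the minimum over members.
#' Output is independent of input row order.
#'
#' @param hits Hit data.frame from [seeded_local_search()] (one query).
#' @param cfg A [linckit_config].
#' @return data.frame of merged loci sorted by total bit score
#'   descending, with a `members` list column of member-hit rows.
#' @export
merge_hits <- function(hits, cfg = NULL) {
  cfg <- as_config(cfg)
  if (nrow(hits) == 0L)
    return(data.frame(subject_id = character(0), strand = character(0),
                      s_start = integer(0), s_end = integer(0),
                      total_bitscore = numeric(0), min_evalue = numeric(0),
                      n_members = integer(0), stringsAsFactors = FALSE))
  hits <- hits[order(hits$subject_id, hits$strand, hits$s_start,
                     hits$s_end), , drop = FALSE]
  grp_key <- paste(hits$subject_id, hits$strand)
  loci <- list()
  for (g in unique(grp_key)) {
    h <- hits[grp_key == g, , drop = FALSE]
    cluster <- cumsum(c(1L, as.integer(
      h$s_start[-1L] - cummax_end(h$s_end)[-nrow(h)] - 1L > cfg$merge_gap)))
    for (cl in unique(cluster)) {
      m <- h[cluster == cl, , drop = FALSE]
      loci[[length(loci) + 1L]] <- data.frame(
        subject_id = m$subject_id[1L], strand = m$strand[1L],
        s_start = min(m$s_start), s_end = max(m$s_end),
        total_bitscore = sum(m$bitscore), min_evalue = min(m$evalue),
        n_members = nrow(m), stringsAsFactors = FALSE)
      loci[[length(loci)]]$members <- I(list(m))
    }
  }
  res <- do.call(rbind, loci)
  res <- res[order(-res$total_bitscore, res$min_evalue, res$subject_id,
                   res$s_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

cummax_end <- function(e) cummax(e)

#' Select the top hit locus
#'
#' Highest total bit score wins; ties break by lower minimum E-value,
#' then lexicographically by (subject sequence, start), so selection is
#' deterministic across runs.
#'
#' @param loci Merged loci from [merge_hits()].
#' @return A one-row data.frame, or `NULL` when `loci` is empty.
#' @export
select_tbh <- function(loci) {
  if (is.null(loci) || nrow(loci) == 0L) return(NULL)
  loci[1L, , drop = FALSE]  # merge_hits already sorts by the tie-break order
}

#' Split a query into non-overlapping segments
#'
#' Fallback for queries without a full-length top hit: the query is cut
#' into `segment_len`-nt pieces; a trailing remainder shorter than
#' `min_segment_len` is discarded. Segment names encode the parent id and
#' the 1-based offset so hits can be mapped back to parent coordinates.
#'
#' @param seq Named `DNAStringSet` of length 1 (or `DNAString`).
#' @param cfg A [linckit_config].
#' @return `DNAStringSet` of segments with an `offset` metadata column
#'   (1-based start of each segment on the parent).
#' @export
segment_query <- function(seq, cfg = NULL) {
  cfg <- as_config(cfg)
  if (methods::is(seq, "DNAString"))
    seq <- Biostrings::DNAStringSet(list(query = seq))
  parent <- if (!is.null(names(seq))) names(seq)[1L] else "query"
  s <- seq[[1L]]
  L <- length(s)
  starts <- seq(1L, L, by = cfg$segment_len)
  ends <- pmin(starts + cfg$segment_len - 1L, L)
  keep <- (ends - starts + 1L) >= pmin(cfg$segment_len, cfg$min_segment_len)
  keep[ends - starts + 1L == cfg$segment_len] <- TRUE
  starts <- starts[keep]; ends <- ends[keep]
  segs <- Biostrings::DNAStringSet(lapply(seq_along(starts), function(i)
    Biostrings::subseq(s, starts[i], ends[i])))
  names(segs) <- if (length(starts)) paste0(parent, ".seg", starts)
                 else character(0)
  S4Vectors::mcols(segs)$offset <- starts
  segs
}

#' Search one query against one genome, with segmented fallback
#'
#' Runs the full-length search, merges hits into loci and selects the top
#' hit. When no locus passes the E-value cutoff the query is segmented
#' ([segment_query()]), every segment searched, hits mapped back to
#' parent-query coordinates, and merging/selection repeated — useful for
#' long queries with short conserved cores.
#'
#' @param query Named `DNAStringSet` of length 1.
#' @param subject Named `DNAStringSet` (one genome).
#' @param cfg A [linckit_config].
#' @param index Optional prebuilt index for `subject`.
#' @param evalue_cutoff E-value ceiling (default `cfg$search_evalue`).
#' @return List with `tbh` (one-row data.frame or NULL), `loci` (all
#'   merged loci), `hits` (all passing hits), `segmented` (logical).
#' @export
search_query_genome <- function(query, subject, cfg = NULL, index = NULL,
                                evalue_cutoff = NULL) {
  cfg <- as_config(cfg)
  if (is.null(evalue_cutoff)) evalue_cutoff <- cfg$search_evalue
  if (is.null(index)) index <- build_search_index(subject, cfg)
  hits <- seeded_local_search(query, subject, cfg, index, evalue_cutoff)
  segmented <- FALSE
  if (nrow(hits) == 0L) {
    segmented <- TRUE
    segs <- segment_query(query, cfg)
    offs <- S4Vectors::mcols(segs)$offset
    parts <- lapply(seq_along(segs), function(i) {
      h <- suppressWarnings(
        seeded_local_search(segs[i], subject, cfg, index, evalue_cutoff))
      if (nrow(h) > 0L) {
        h$q_start <- h$q_start + offs[i] - 1L
        h$q_end <- h$q_end + offs[i] - 1L
        h$query_id <- names(query)[1L]
      }
      h
    })
    hits <- if (length(parts)) do.call(rbind, parts) else empty_hits()
  }
  loci <- merge_hits(hits, cfg)
  list(tbh = select_tbh(loci), loci = loci, hits = hits,
       segmented = segmented)
}

#' Extract the sequence of a merged locus from its genome
#'
#' @param locus One-row merged-locus data.frame.
#' @param genome Named `DNAStringSet` the locus lives on.
#' @return A `DNAString`; minus-strand loci are reverse-complemented so
#'   the result reads in the query's orientation.
#' @export
locus_sequence <- function(locus, genome) {
  s <- Biostrings::subseq(genome[[locus$subject_id]], locus$s_start,
                          locus$s_end)
  if (locus$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

#' Reciprocity test for a candidate homolog locus
#'
#' Extracts the top-hit locus from the subject genome, searches it back
#' against the query genome, and accepts the candidate only when the
#' reciprocal top hit overlaps the original query locus (by at least
#' `cfg$reciprocal_min_overlap` bp) — the mutual-top-hit criterion that
#' guards against paralogs and repetitive sequence.
#'
#' @param tbh One-row merged locus (the candidate homolog) in a subject
#'   genome.
#' @param subject_genome Named `DNAStringSet` containing the candidate.
#' @param query_genome Named `DNAStringSet` of the query species.
#' @param query_locus `GRanges` of length 1: the query lincRNA's genomic
#'   span in `query_genome`. `NULL` skips the test with a warning.
#' @param cfg A [linckit_config].
#' @param query_index Optional prebuilt index for `query_genome`.
#' @return Logical: TRUE when the reciprocal top hit returns to the query
#'   locus. `NA` when the test was skipped.
#' @export
reciprocity_test <- function(tbh, subject_genome, query_genome, query_locus,
                             cfg = NULL, query_index = NULL) {
  cfg <- as_config(cfg)
  if (is.null(query_locus) || length(query_locus) == 0L) {
    warning("query locus unknown in the query genome; reciprocity skipped",
            call. = FALSE)
    return(NA)
  }
  s <- locus_sequence(tbh, subject_genome)
  q <- Biostrings::DNAStringSet(list(reciprocal = s))
  res <- search_query_genome(q, query_genome, cfg, index = query_index)
  if (is.null(res$tbh)) return(FALSE)
  r <- res$tbh
  if (r$subject_id != as.character(GenomicRanges::seqnames(query_locus)))
    return(FALSE)
  ov <- min(r$s_end, BiocGenerics::end(query_locus)) -
    max(r$s_start, BiocGenerics::start(query_locus)) + 1L
  ov >= cfg$reciprocal_min_overlap
}
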