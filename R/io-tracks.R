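#' Write intervals to BED6
#'
#' Converts from the internal 1-based closed convention to BED's 0-based
#' half-open. Names come from `names(gr)` (or a `name` metadata column);
#' missing scores are written as `"."`.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  nm <- names(gr)
  if (is.null(nm)) nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- rep(".", length(gr))
  sc <- S4Vectors::mcols(gr)$score
  sc <- if (is.null(sc)) rep(".", length(gr)) else {
    s <- as.character(sc); s[is.na(s)] <- "."; s
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  lines <- paste(as.character(GenomicRanges::seqnames(gr)),
                 BiocGenerics::start(gr) - 1L,
                 BiocGenerics::end(gr),
                 nm, sc, strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file
#'
#' @param path Path to a BED file (3-6 columns).
#' @return A `GRanges` in the internal 1-based closed convention, named by
#'   the BED name column when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L)
    return(GenomicRanges::GRanges())
  gr <- rtracklayer::import(path, format = "bed")
  gr
}

#' Write intervals to GFF3
#'
#' @param gr A `GRanges`; names become the `ID` attribute. Optional
#'   metadata columns `type` and `source` override the defaults
#'   (`"gene"`, `"linckit"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(gr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(gr) == 0L) return(invisible(path))
  nm <- names(gr)
  if (is.null(nm)) nm <- paste0("feature_", seq_along(gr))
  type <- S4Vectors::mcols(gr)$type
  if (is.null(type)) type <- rep("gene", length(gr))
  src <- S4Vectors::mcols(gr)$source
  if (is.null(src)) src <- rep("linckit", length(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  lines <- paste(as.character(GenomicRanges::seqnames(gr)), src,
                 as.character(type),
                 BiocGenerics::start(gr), BiocGenerics::end(gr),
                 ".", strand, ".", paste0("ID=", nm), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write transcript models to GTF
#'
#' Emits one `exon` line per exon with `gene_id` and `transcript_id`
#' attributes, 1-based inclusive. `read_transcript_gtf(write_transcript_gtf(x))`
#' reproduces the models.
#'
#' @param annot An [annotation_set].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_transcript_gtf <- function(annot, path, source = "linckit") {
  ex <- annot$exons
  if (length(ex) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  strand <- as.character(BiocGenerics::strand(ex))
  strand[strand == "*"] <- "."
  mc <- S4Vectors::mcols(ex)
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   mc$gene_id, mc$transcript_id)
  lines <- paste(as.character(GenomicRanges::seqnames(ex)), source, "exon",
                 BiocGenerics::start(ex), BiocGenerics::end(ex),
                 ".", strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a Newick tree
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] so tree I/O
#' goes through one place.
#'
#' @param path File path.
#' @return `read_newick` returns an [ape::phylo]; `write_newick` returns
#'   `path` invisibly.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path, call. = FALSE)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick in '", path, "'",
                        call. = FALSE)
  tr
}

#' @rdname read_newick
#' @param tree An `ape::phylo` tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
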