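#' Read a DNA FASTA file
#'
#' Reads sequences into a [Biostrings::DNAStringSet]. The record id is the
#' header token before the first whitespace; the remainder of the header is
#' kept as a per-record `description` metadata column. Sequences are stored
#' uppercase. Pipe (`|`) characters, which break several downstream genome
#' tools, are stripped from ids with a warning rather than causing a
#' failure.
#'
#' @param path Path to a FASTA file. CRLF line endings and trailing blank
#'   lines are tolerated; an empty file yields an empty set.
#' @return A `DNAStringSet` named by record id, with a `description`
#'   metadata column.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out)$description <- character(0)
    return(out)
  }
  is_hdr <- startsWith(lines, ">")
  bad <- nonblank[!is_hdr[nonblank] & nonblank < min(which(is_hdr))]
  if (!any(is_hdr) || length(bad) > 0L) {
    at <- if (length(bad)) bad[1L] else nonblank[1L]
    stop("malformed FASTA: line ", at, " of '", path,
         "' is not preceded by a '>' header", call. = FALSE)
  }
  hdr_idx <- which(is_hdr)
  headers <- sub("^>", "", lines[hdr_idx])
  grp <- cumsum(is_hdr)
  seq_lines <- lines[!is_hdr & nzchar(lines)]
  seq_grp <- grp[!is_hdr & nzchar(lines)]
  seqs <- vapply(seq_along(hdr_idx), function(i)
    paste(seq_lines[seq_grp == i], collapse = ""), character(1))
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (any(grepl("|", ids, fixed = TRUE))) {
    warning("pipe characters stripped from FASTA ids in '", path, "'",
            call. = FALSE)
    ids <- gsub("|", "", ids, fixed = TRUE)
  }
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(seqs)))
    stop("empty sequence for FASTA record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  out <- Biostrings::DNAStringSet(toupper(seqs))
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write sequences to FASTA
#'
#' @param records A `DNAStringSet` (or named character vector of DNA
#'   strings). A `description` metadata column, when present, is appended
#'   to the header after the id.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) records <- Biostrings::DNAStringSet(records)
  x <- records
  desc <- S4Vectors::mcols(x)$description
  if (!is.null(desc)) {
    keep <- !is.na(desc) & nzchar(desc)
    nm <- names(x)
    nm[keep] <- paste(nm[keep], desc[keep])
    y <- x
    names(y) <- nm
    x <- y
  }
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}
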