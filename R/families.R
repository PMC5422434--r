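#' @title Homolog families across a ranked species panel
#' @name families
#' @description Builds, for every query lincRNA, the set of reciprocal
#'   top-hit homolog loci across a panel of genomes ordered by
#'   phylogenetic distance from the query species, labels them against
#'   optional per-species annotations, and summarises conservation depth.
NULL

#' Construct a species panel
#'
#' @param species Character vector of species names, ordered by
#'   increasing phylogenetic distance from the query species; the first
#'   entry is the query species itself. Names must be unique.
#' @param genomes Named list (by species) of genome `DNAStringSet`s or
#'   FASTA paths.
#' @param annotations Optional named list of gene-locus `GRanges` or GFF
#'   paths per species.
#' @param known_lincrnas Optional named list of known-lincRNA `GRanges`
#'   or GFF paths per species.
#' @param species_tree Optional `ape::phylo` species tree or Newick path.
#' @return A `species_panel` object.
#' @export
species_panel <- function(species, genomes, annotations = NULL,
                          known_lincrnas = NULL, species_tree = NULL) {
  if (anyDuplicated(species))
    stop("species names must be unique", call. = FALSE)
  if (length(species) == 0L) stop("empty species panel", call. = FALSE)
  missing <- setdiff(species, names(genomes))
  if (length(missing) > 0L)
    stop("no genome supplied for species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.character(species_tree)) species_tree <- read_newick(species_tree)
  structure(list(species = species, genomes = genomes[species],
                 annotations = annotations, known_lincrnas = known_lincrnas,
                 species_tree = species_tree),
            class = "species_panel")
}

#' Read a species panel from a one-column species list
#'
#' The list file contains one species name per line, ordered by
#' phylogenetic relatedness to the query species (first line). Genome
#' FASTA files are looked up as `<dir>/<species>.fa[sta]`; optional
#' annotation and known-lincRNA files as `<dir>/<species>.gff` and
#' `<dir>/<species>.known.gff`.
#'
#' @param list_path Path to the species list.
#' @param dir Directory holding the per-species files.
#' @param species_tree Optional Newick path.
#' @return A [species_panel].
#' @export
read_species_panel <- function(list_path, dir, species_tree = NULL) {
  sp <- trimws(readLines(list_path, warn = FALSE))
  sp <- sp[nzchar(sp)]
  if (length(sp) == 0L)
    stop("species list '", list_path, "' is empty", call. = FALSE)
  genomes <- lapply(sp, function(s) {
    for (ext in c(".fa", ".fasta")) {
      p <- file.path(dir, paste0(s, ext))
      if (file.exists(p)) return(p)
    }
    stop("genome FASTA for species '", s, "' not found under ", dir,
         call. = FALSE)
  })
  names(genomes) <- sp
  opt <- function(suffix) {
    out <- list()
    for (s in sp) {
      p <- file.path(dir, paste0(s, suffix))
      if (file.exists(p)) out[[s]] <- p
    }
    if (length(out)) out else NULL
  }
  species_panel(sp, genomes, annotations = opt(".gff"),
                known_lincrnas = opt(".known.gff"),
                species_tree = species_tree)
}

#' @export
print.species_panel <- function(x, ...) {
  cat("species_panel:", length(x$species), "species (query species:",
      x$species[1L], ")\n")
  invisible(x)
}

panel_genome <- function(panel, sp) {
  g <- panel$genomes[[sp]]
  if (is.character(g)) g <- read_fasta(g)
  g
}

panel_resource <- function(res_list, sp) {
  if (is.null(res_list) || is.null(res_list[[sp]])) return(NULL)
  r <- res_list[[sp]]
  if (is.character(r)) r <- read_annotation_gff(r)
  r
}

#' Label a homolog call against per-species annotations
#'
#' Overlap of the homolog locus with an annotated gene adds the label
#' `Known_gene`; overlap with a known lincRNA adds `Known_lincRNA`. The
#' ids of overlapping features are recorded (all of them, first by
#' coordinate) so the summary table can report transcriptional evidence
#' in the target species.
#'
#' @param call A homolog-call list (fields `subject_id`, `s_start`,
#'   `s_end`, `labels`, `feature_ids`).
#' @param annotation `GRanges` of gene loci for the species (or NULL).
#' @param known `GRanges` of known lincRNA loci (or NULL).
#' @return The call with `labels` and `feature_ids` updated.
#' @export
label_homolog <- function(call, annotation = NULL, known = NULL) {
  span <- GenomicRanges::GRanges(call$subject_id,
                                 IRanges::IRanges(call$s_start, call$s_end))
  scan <- function(gr) {
    if (is.null(gr) || length(gr) == 0L) return(character(0))
    h <- GenomicRanges::findOverlaps(span, gr, ignore.strand = TRUE)
    ids <- names(gr)[S4Vectors::subjectHits(h)]
    ids[order(BiocGenerics::start(gr)[S4Vectors::subjectHits(h)])]
  }
  g <- scan(annotation)
  l <- scan(known)
  if (length(g) > 0L) call$labels <- union(call$labels, "Known_gene")
  if (length(l) > 0L) call$labels <- union(call$labels, "Known_lincRNA")
  call$feature_ids <- c(g, l)
  call
}

#' Build homolog families across the panel
#'
#' For each query and each panel species: search the genome
#' ([search_query_genome()], with segmented fallback), take the top hit
#' locus, and keep it only if it passes the reciprocity test against the
#' query genome. Reciprocal top hits become homolog calls labelled
#' `Homolog` (plus `Known_gene`/`Known_lincRNA` from optional
#' annotations); species without a passing, reciprocal top hit are absent
#' from the family.
#'
#' @param queries Named `DNAStringSet` of query lincRNAs.
#' @param panel A [species_panel]. The first species is the query
#'   species; its genome anchors the reciprocity test.
#' @param query_loci Optional `GRanges` named by query id giving each
#'   query's genomic span in the query-species genome. When NULL, loci
#'   are located by searching each query against the query genome.
#' @param cfg A [linckit_config].
#' @param evalue_cutoff E-value ceiling (default `cfg$search_evalue`).
#' @return A `linckit_families` object: list of families (each with
#'   `query_id`, `query_seq`, `calls` in panel order), plus `all_loci`
#'   (per-species merged-locus tables for the retained-hits GFF) and the
#'   panel.
#' @export
build_families <- function(queries, panel, query_loci = NULL, cfg = NULL,
                           evalue_cutoff = NULL) {
  cfg <- as_config(cfg)
  if (is.null(evalue_cutoff)) evalue_cutoff <- cfg$search_evalue
  stopifnot(inherits(panel, "species_panel"))
  qsp <- panel$species[1L]
  qgenome <- panel_genome(panel, qsp)
  qindex <- build_search_index(qgenome, cfg)

  if (is.null(query_loci)) {
    locs <- lapply(names(queries), function(qid) {
      res <- search_query_genome(queries[qid], qgenome, cfg, index = qindex,
                                 evalue_cutoff = evalue_cutoff)
      if (is.null(res$tbh)) return(NULL)
      GenomicRanges::GRanges(res$tbh$subject_id,
                             IRanges::IRanges(res$tbh$s_start,
                                              res$tbh$s_end),
                             strand = res$tbh$strand)
    })
    names(locs) <- names(queries)
    keep <- !vapply(locs, is.null, logical(1))
    query_loci <- if (any(keep)) {
      g <- do.call(c, unname(locs[keep])); names(g) <- names(queries)[keep]; g
    } else GenomicRanges::GRanges()
  }

  families <- lapply(names(queries), function(qid)
    list(query_id = qid, query_seq = queries[[qid]], calls = list()))
  names(families) <- names(queries)
  all_loci <- list()

  for (rank in seq_along(panel$species)) {
    sp <- panel$species[rank]
    genome <- tryCatch(panel_genome(panel, sp), error = function(e) e)
    if (inherits(genome, "error")) {
      warning("genome for species '", sp, "' unreadable; species skipped (",
              conditionMessage(genome), ")", call. = FALSE)
      next
    }
    index <- build_search_index(genome, cfg)
    annot <- panel_resource(panel$annotations, sp)
    known <- panel_resource(panel$known_lincrnas, sp)
    sp_loci <- list()
    for (qid in names(queries)) {
      res <- search_query_genome(queries[qid], genome, cfg, index = index,
                                 evalue_cutoff = evalue_cutoff)
      if (nrow(res$loci) > 0L) {
        tab <- res$loci[, setdiff(names(res$loci), "members"), drop = FALSE]
        tab$query_id <- qid
        sp_loci[[qid]] <- tab
      }
      if (is.null(res$tbh)) next
      qloc <- if (qid %in% names(query_loci)) query_loci[qid] else NULL
      recip <- reciprocity_test(res$tbh, genome, qgenome, qloc, cfg,
                                query_index = qindex)
      if (!isTRUE(recip)) next
      call <- list(species = sp, rank = rank,
                   subject_id = res$tbh$subject_id,
                   s_start = res$tbh$s_start, s_end = res$tbh$s_end,
                   strand = res$tbh$strand,
                   total_bitscore = res$tbh$total_bitscore,
                   min_evalue = res$tbh$min_evalue,
                   sequence = as.character(locus_sequence(res$tbh, genome)),
                   reciprocal = TRUE, labels = "Homolog",
                   feature_ids = character(0),
                   members = res$tbh$members[[1L]],
                   segmented = res$segmented)
      call <- label_homolog(call, annot, known)
      families[[qid]]$calls[[sp]] <- call
    }
    if (length(sp_loci) > 0L) all_loci[[sp]] <- do.call(rbind, sp_loci)
  }
  structure(list(families = families, all_loci = all_loci, panel = panel,
                 query_loci = query_loci, config = cfg,
                 evalue_cutoff = evalue_cutoff),
            class = "linckit_families")
}

#' @export
print.linckit_families <- function(x, ...) {
  n <- length(x$families)
  sizes <- vapply(x$families, function(f) length(f$calls), integer(1))
  cat("linckit_families:", n, "queries across", length(x$panel$species),
      "species; homolog calls per query:",
      if (n) paste(range(sizes), collapse = "-") else "none", "\n")
  invisible(x)
}

#' Conservation-depth summary
#'
#' Per query: presence/absence in each panel species and the deepest
#' conserved species (the farthest panel rank with a reciprocal homolog).
#' Per species: homolog count and percent of queries recovered — the
#' table behind the conservation bar chart.
#'
#' @param fams A `linckit_families` object.
#' @return List with `per_query` and `per_species` data.frames.
#' @export
conservation_summary <- function(fams) {
  panel <- fams$panel
  sp <- panel$species
  qids <- names(fams$families)
  pres <- matrix(FALSE, nrow = length(qids), ncol = length(sp),
                 dimnames = list(qids, sp))
  feats <- matrix("", nrow = length(qids), ncol = length(sp),
                  dimnames = list(qids, sp))
  for (qid in qids) {
    for (call in fams$families[[qid]]$calls) {
      pres[qid, call$species] <- TRUE
      if (length(call$feature_ids) > 0L)
        feats[qid, call$species] <- paste(call$feature_ids, collapse = ",")
    }
  }
  deepest <- apply(pres, 1L, function(r) {
    w <- which(r)
    if (length(w) == 0L) NA_character_ else sp[max(w)]
  })
  per_query <- data.frame(query_id = qids,
                          n_species = rowSums(pres),
                          deepest_species = as.character(deepest),
                          stringsAsFactors = FALSE)
  for (s in sp) per_query[[paste0("in_", s)]] <- pres[, s]
  for (s in sp) per_query[[paste0("features_", s)]] <- feats[, s]
  nq <- length(qids)
  per_species <- data.frame(species = sp, rank = seq_along(sp),
                            n_homologs = colSums(pres),
                            percent = if (nq > 0) colSums(pres) / nq * 100
                                      else rep(0, length(sp)),
                            stringsAsFactors = FALSE)
  rownames(per_query) <- rownames(per_species) <- NULL
  list(per_query = per_query, per_species = per_species)
}

#' Project conserved regions onto query-genome coordinates
#'
#' Each homolog call retains the query-transcript intervals of its member
#' hits. Those intervals are projected through the query's exon map onto
#' genomic coordinates, producing one BED record per species and
#' contiguous block — ready for genome-browser display of which parts of
#' the query lincRNA are conserved where.
#'
#' @param family One family element of a `linckit_families` object.
#' @param query_exons `GRanges` of the query's exons in the query genome
#'   (in transcription order on the genome), or NULL when the query has
#'   no genomic model — then BED records are emitted in transcript
#'   coordinates with a warning.
#' @return `GRanges` named by species, ready for [write_bed()].
#' @export
query_centric_bed <- function(family, query_exons = NULL) {
  calls <- family$calls
  if (length(calls) == 0L) return(GenomicRanges::GRanges())
  out <- list()
  for (call in calls) {
    m <- call$members
    for (i in seq_len(nrow(m))) {
      blocks <- project_to_genome(m$q_start[i], m$q_end[i], query_exons,
                                  family$query_id)
      if (length(blocks) > 0L) {
        names(blocks) <- rep(call$species, length(blocks))
        out[[length(out) + 1L]] <- blocks
      }
    }
  }
  if (length(out) == 0L) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, unname(out)))  # seqlevels may differ
}

# map a transcript-coordinate interval through the exon chain
project_to_genome <- function(t_start, t_end, exons, qid) {
  if (is.null(exons) || length(exons) == 0L) {
    warning("query '", qid, "' has no genomic exon map; ",
            "emitting transcript coordinates", call. = FALSE)
    return(GenomicRanges::GRanges(qid, IRanges::IRanges(t_start, t_end)))
  }
  strand <- as.character(BiocGenerics::strand(exons))[1L]
  widths <- BiocGenerics::width(exons)
  # transcript coordinates run 5'->3': reverse exon order on minus strand
  ord <- if (strand == "-") rev(seq_along(exons)) else seq_along(exons)
  offs <- cumsum(c(0L, widths[ord][-length(ord)]))
  blocks <- list()
  for (j in seq_along(ord)) {
    ex <- exons[ord[j]]
    lo <- offs[j] + 1L
    hi <- offs[j] + widths[ord[j]]
    a <- max(t_start, lo); b <- min(t_end, hi)
    if (a > b) next
    if (strand == "-") {
      g_end <- BiocGenerics::end(ex) - (a - lo)
      g_start <- BiocGenerics::end(ex) - (b - lo)
    } else {
      g_start <- BiocGenerics::start(ex) + (a - lo)
      g_end <- BiocGenerics::start(ex) + (b - lo)
    }
    blocks[[length(blocks) + 1L]] <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(ex), IRanges::IRanges(g_start, g_end),
      strand = strand)
  }
  if (length(blocks) == 0L) return(GenomicRanges::GRanges())
  do.call(c, unname(blocks))
}

#' Write the conservation-stage output bundle
#'
#' Emits `final_summary_table.tsv` (per-query conservation depth and
#' overlapping features), `conservation_by_species.tsv` (bar-chart
#' table), per-family alignment FASTA (`<query>_alignment.FASTA`, homolog
#' ids carrying their labels), the query-centric BED, and per-species
#' `Homology_search/<species>.out.merged.gff` files with all merged loci
#' that passed the cutoff.
#'
#' @param fams A `linckit_families` object.
#' @param dir Output directory.
#' @param query_exon_maps Optional named list (by query id) of exon
#'   `GRanges` for the query-centric BED projection.
#' @return `dir`, invisibly.
#' @export
write_family_outputs <- function(fams, dir, query_exon_maps = NULL) {
  dir.create(file.path(dir, "Homology_search"), recursive = TRUE,
             showWarnings = FALSE)
  cs <- conservation_summary(fams)
  utils::write.table(cs$per_query, file.path(dir, "final_summary_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cs$per_species,
                     file.path(dir, "conservation_by_species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bed_all <- list()
  for (qid in names(fams$families)) {
    fam <- fams$families[[qid]]
    seqs <- family_sequences(fam)
    if (length(seqs) >= 2L) seqs <- align_family(seqs, cfg = fams$config)
    write_fasta(seqs, file.path(dir, paste0(qid, "_alignment.FASTA")))
    exmap <- if (!is.null(query_exon_maps)) query_exon_maps[[qid]] else NULL
    bed <- suppressWarnings(query_centric_bed(fam, exmap))
    if (length(bed) > 0L) bed_all[[qid]] <- bed
  }
  if (length(bed_all) > 0L) {
    write_bed(suppressWarnings(do.call(c, unname(bed_all))),
              file.path(dir, "query_centric.bed"))
  } else {
    writeLines(character(0), file.path(dir, "query_centric.bed"))
  }
  for (sp in names(fams$all_loci)) {
    tab <- fams$all_loci[[sp]]
    gr <- GenomicRanges::GRanges(tab$subject_id,
                                 IRanges::IRanges(tab$s_start, tab$s_end),
                                 strand = tab$strand)
    names(gr) <- paste0(tab$query_id, ".locus", seq_len(nrow(tab)))
    S4Vectors::mcols(gr)$type <- "match"
    write_gff(gr, file.path(dir, "Homology_search",
                            paste0(sp, ".out.merged.gff")))
  }
  invisible(dir)
}

#' Alignment, gene tree and reconciliation for one family
#'
#' Collects the family's homolog sequences (one leaf per reciprocal
#' top-hit call; additional same-query loci that passed the cutoff are
#' included as paralog copies when `include_paralogs` is TRUE), aligns
#' them, infers a bootstrap-supported gene tree and reconciles it with
#' the panel's species tree to call duplication and loss events on the
#' lincRNA locus.
#'
#' @param fams A `linckit_families` object built from a panel that
#'   carries a species tree.
#' @param qid Query id.
#' @param include_paralogs Include non-top-hit loci of this query as
#'   extra gene copies (default TRUE).
#' @param bootstrap Bootstrap replicates (default `cfg$bootstrap_n`).
#' @param cfg A [linckit_config] (default: the one the families were
#'   built with).
#' @return List with `sequences`, `alignment`, `gene_tree`,
#'   `reconciliation` (NULL when fewer than 3 leaves).
#' @export
family_phylogeny <- function(fams, qid, include_paralogs = TRUE,
                             bootstrap = NULL, cfg = NULL) {
  if (is.null(cfg)) cfg <- fams$config
  cfg <- as_config(cfg)
  panel <- fams$panel
  if (is.null(panel$species_tree))
    stop("the species panel carries no species tree", call. = FALSE)
  fam <- fams$families[[qid]]
  if (is.null(fam)) stop("unknown query: ", qid, call. = FALSE)
  seqs <- list(); ids <- character(0)
  for (call in fam$calls) {
    seqs[[length(seqs) + 1L]] <- call$sequence
    ids <- c(ids, paste(qid, call$species, "Homolog", sep = "_"))
  }
  if (!panel$species[1L] %in% names(fam$calls)) {
    seqs[[length(seqs) + 1L]] <- as.character(fam$query_seq)
    ids <- c(ids, paste(qid, panel$species[1L], "query", sep = "_"))
  }
  if (include_paralogs) {
    for (sp in names(fams$all_loci)) {
      tab <- fams$all_loci[[sp]]
      tab <- tab[tab$query_id == qid, , drop = FALSE]
      if (nrow(tab) < 2L) next
      call <- fam$calls[[sp]]
      genome <- panel_genome(panel, sp)
      copy_n <- 1L
      for (r in seq_len(nrow(tab))) {
        if (!is.null(call) && tab$s_start[r] == call$s_start &&
            tab$s_end[r] == call$s_end &&
            tab$subject_id[r] == call$subject_id) next
        copy_n <- copy_n + 1L
        seqs[[length(seqs) + 1L]] <-
          as.character(locus_sequence(tab[r, ], genome))
        ids <- c(ids, paste(qid, sp, paste0("copy", copy_n), sep = "_"))
      }
    }
  }
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- ids
  res <- list(sequences = out, alignment = NULL, gene_tree = NULL,
              reconciliation = NULL)
  if (length(out) < 3L) return(res)
  res$alignment <- align_family(out, cfg = cfg)
  res$gene_tree <- infer_gene_tree(res$alignment, bootstrap, cfg)
  res$reconciliation <- reconcile(res$gene_tree, panel$species_tree,
                                  cfg = cfg)
  res
}

#' Sequences of one family, labelled for alignment output
#'
#' @param family One family element; the query comes first, homolog ids
#'   are `<query>_<species>_<labels>` joined with underscores.
#' @return Named `DNAStringSet`.
#' @export
family_sequences <- function(family) {
  seqs <- c(list(as.character(family$query_seq)),
            lapply(family$calls, function(cl) cl$sequence))
  ids <- c(family$query_id,
           vapply(family$calls, function(cl)
             paste(c(family$query_id, cl$species, cl$labels),
                   collapse = "_"), character(1)))
  out <- Biostrings::DNAStringSet(unlist(seqs, use.names = FALSE))
  names(out) <- ids
  out
}
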