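#' @title Synthetic data with planted ground truth
#' @name fixtures
#' @description Seeded generators for genomes, annotations, transcript
#'   assemblies, TE databases, TSS sets and multi-species panels in which
#'   the true class of every transcript and the true location of every
#'   homolog is known, so each pipeline stage can be validated without
#'   external databases. Sequences are uniform random DNA; evolution is a
#'   Jukes-Cantor-like per-site substitution process with single indel
#'   events of geometric length, applied intergenically so planted locus
#'   coordinates stay exact.
NULL

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) sample(DNA_BASES, n, replace = TRUE)

# random DNA of length n whose longest complete ORF stays noncoding
random_noncoding <- function(n, max_orf_aa = 100) {
  repeat {
    s <- random_dna(n)
    if (find_longest_orf(paste(s, collapse = "")) <= max_orf_aa) return(s)
  }
}

# an ORF-bearing coding sequence: ATG + n_codons non-stop codons + stop
coding_sequence <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  i <- 1L
  while (i <= n_codons) {
    cd <- paste(sample(DNA_BASES, 3, replace = TRUE), collapse = "")
    if (!cd %in% stops) { codons[i] <- cd; i <- i + 1L }
  }
  strsplit(paste0("ATG", paste(codons, collapse = ""),
                  sample(stops, 1)), "")[[1L]]
}

mutate_seq <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) == 0L) return(chars)
  code <- match(chars[hit], DNA_BASES) - 1L
  off <- sample.int(3L, length(hit), replace = TRUE)
  chars[hit] <- DNA_BASES[((code + off) %% 4L) + 1L]
  chars
}

#' Specification for the identification fixture
#'
#' @param seed Integer RNG seed; the same spec reproduces byte-identical
#'   files.
#' @param n_coding Planted protein-coding transcripts (ORFs of 120-300
#'   codons, so well over the 100-aa limit).
#' @param n_linc Planted lincRNAs (1-3 exons, 300-800 nt, no long ORF,
#'   far from any annotated gene).
#' @param n_te Planted TE-derived transcripts (copies of the TE database
#'   with at most `te_divergence` substitution).
#' @param n_sot,n_aot Planted sense-/antisense-overlapping transcripts.
#' @param n_ambiguous Planted single-exon unstranded transcripts
#'   overlapping a gene (strand unresolvable).
#' @param n_short Planted transcripts at or below the 200-nt floor.
#' @param n_te_db Sequences in the TE database.
#' @param te_divergence Per-site substitution applied to TE copies
#'   (default 0.03).
#' @param tss_fraction Fraction of lincRNAs given a TSS at their 5' end.
#' @param flank Intergenic margin kept between lincRNAs and annotated
#'   genes, in bp; must be at least the flank extension used when running
#'   the classifier (default 500).
#' @return A `fixture_spec` list.
#' @export
identify_fixture_spec <- function(seed = 1, n_coding = 20, n_linc = 10,
                                  n_te = 5, n_sot = 5, n_aot = 5,
                                  n_ambiguous = 3, n_short = 3,
                                  n_te_db = 3, te_divergence = 0.03,
                                  tss_fraction = 0.5, flank = 500) {
  stopifnot(seed == as.integer(seed),
            te_divergence >= 0, te_divergence < 0.75)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate the identification fixture
#'
#' Builds a genome, a reference annotation, a transcript assembly GTF, a
#' TE database, a TSS BED and a truth table in which every transcript's
#' intended class is recorded. Planted classes satisfy the classifier's
#' definitions by construction: coding transcripts carry complete ORFs
#' > 100 aa; lincRNAs are > 200 nt with no long ORF and are separated
#' from annotated genes by more than the flank margin; TE transcripts are
#' near-identical TE copies; SOT/AOT transcripts overlap annotated genes
#' on the stated strand.
#'
#' @param spec An [identify_fixture_spec()].
#' @param dir Optional directory: when given, files `genome.fa`,
#'   `annotation.gff`, `transcripts.gtf`, `te_db.fa`, `tss.bed`,
#'   `known_lincrna.gff` and `truth.tsv` are written there.
#' @return List with in-memory objects: `genome` (`DNAStringSet`),
#'   `transcripts` ([annotation_set]), `annotation` (`GRanges`), `te_db`,
#'   `tss` (`GRanges`), `known_lincrna` (`GRanges`), `truth`
#'   (data.frame: transcript_id, class, cage_plus, known_overlap).
#' @export
make_identify_fixture <- function(spec = identify_fixture_spec(),
                                  dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  gap <- function() sample(spec$flank + 200:800, 1) + spec$flank

  te_db <- Biostrings::DNAStringSet(vapply(seq_len(spec$n_te_db), function(i)
    paste(random_noncoding(sample(450:700, 1)), collapse = ""), character(1)))
  names(te_db) <- paste0("TE", seq_len(spec$n_te_db))

  feats <- list()   # each: list(kind, seq chars, strand, exon break plan)
  add <- function(kind, chars, strand, n_exons = 1L, in_gene = FALSE) {
    feats[[length(feats) + 1L]] <<- list(kind = kind, chars = chars,
                                         strand = strand, n_exons = n_exons,
                                         in_gene = in_gene)
  }
  for (i in seq_len(spec$n_coding))
    add("coding", coding_sequence(sample(120:300, 1)), "+",
        n_exons = sample(1:2, 1))
  for (i in seq_len(spec$n_linc))
    add("linc", random_noncoding(sample(300:800, 1)),
        sample(c("+", "-"), 1), n_exons = sample(1:3, 1))
  for (i in seq_len(spec$n_te)) {
    src <- strsplit(as.character(te_db[[sample(spec$n_te_db, 1)]]),
                    "")[[1L]]
    repeat {  # mutation must not create a long ORF by chance
      copy <- mutate_seq(src, spec$te_divergence)
      if (find_longest_orf(paste(copy, collapse = "")) <= 100L) break
    }
    add("te", copy, "+")
  }
  for (i in seq_len(spec$n_sot))
    add("sot", random_noncoding(sample(300:600, 1)), NA, n_exons = 2L,
        in_gene = TRUE)
  for (i in seq_len(spec$n_aot))
    add("aot", random_noncoding(sample(300:600, 1)), NA, n_exons = 2L,
        in_gene = TRUE)
  for (i in seq_len(spec$n_ambiguous))
    add("ambiguous", random_noncoding(sample(300:600, 1)), "*",
        in_gene = TRUE)
  for (i in seq_len(spec$n_short))
    add("short", random_noncoding(sample(100:200, 1)),
        sample(c("+", "-"), 1))

  # lay features left to right; transcripts marked in_gene get an
  # annotated gene planted around them
  chrom <- list()   # pieces; pasted once at the end
  pos <- 1L
  tx_rows <- list()      # exon GRanges rows
  gene_rows <- list()
  truth <- list()
  counter <- c(coding = 0L, linc = 0L, te = 0L, sot = 0L, aot = 0L,
               ambiguous = 0L, short = 0L)
  class_of <- c(coding = "REJECTED_CODING", linc = "LINCRNA",
                te = "TE_DERIVED", sot = "SOT", aot = "AOT",
                ambiguous = "AMBIGUOUS_OVERLAP", short = "REJECTED_SHORT")
  linc_spans <- list()
  for (f in feats) {
    counter[f$kind] <- counter[f$kind] + 1L
    id <- paste0(f$kind, counter[f$kind])
    g <- gap()
    chrom[[length(chrom) + 1L]] <- random_dna(g)
    pos <- pos + g
    tx_strand <- f$strand
    gene_strand <- NULL
    if (f$kind == "sot") { tx_strand <- sample(c("+", "-"), 1); gene_strand <- tx_strand }
    if (f$kind == "aot") { tx_strand <- sample(c("+", "-"), 1)
      gene_strand <- if (tx_strand == "+") "-" else "+" }
    if (f$kind == "ambiguous") { tx_strand <- "*"; gene_strand <- sample(c("+", "-"), 1) }

    n_ex <- f$n_exons
    len <- length(f$chars)
    # split the spliced sequence into n_ex exons with random introns
    cuts <- if (n_ex > 1L)
      sort(sample(seq(50L, len - 50L), n_ex - 1L)) else integer(0)
    ex_bounds <- cbind(c(1L, cuts + 1L), c(cuts, len))
    write_chars <- if (!is.na(tx_strand) && tx_strand == "-")
      as_rc_chars(f$chars) else f$chars
    ex_starts <- integer(n_ex); ex_ends <- integer(n_ex)
    # on minus strand genome order of exons is reversed relative to
    # transcript order; keep genome layout left-to-right
    tx_order <- if (!is.na(tx_strand) && tx_strand == "-")
      rev(seq_len(n_ex)) else seq_len(n_ex)
    wpos <- 1L
    for (j in seq_len(n_ex)) {
      e <- tx_order[j]
      wlen <- ex_bounds[e, 2L] - ex_bounds[e, 1L] + 1L
      if (!is.na(tx_strand) && tx_strand == "-") {
        piece_start <- len - ex_bounds[e, 2L] + 1L
      } else piece_start <- ex_bounds[e, 1L]
      piece <- write_chars[piece_start:(piece_start + wlen - 1L)]
      chrom[[length(chrom) + 1L]] <- piece
      ex_starts[j] <- pos
      ex_ends[j] <- pos + wlen - 1L
      pos <- pos + wlen
      if (j < n_ex) {
        intr <- sample(80:200, 1)
        chrom[[length(chrom) + 1L]] <- random_dna(intr)
        pos <- pos + intr
      }
    }
    span <- c(min(ex_starts), max(ex_ends))
    if (f$in_gene) {
      gid <- paste0("gene", length(gene_rows) + 1L)
      gene_rows[[gid]] <- data.frame(
        start = max(1L, span[1L] - sample(20:80, 1)),
        end = span[2L] + sample(20:80, 1),
        strand = gene_strand, id = gid, stringsAsFactors = FALSE)
    }
    for (j in seq_len(n_ex))
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        start = ex_starts[j], end = ex_ends[j],
        strand = if (is.na(tx_strand)) "*" else tx_strand,
        transcript_id = id, stringsAsFactors = FALSE)
    if (f$kind == "linc")
      linc_spans[[id]] <- span
    truth[[id]] <- data.frame(transcript_id = id,
                              class = unname(class_of[f$kind]),
                              cage_plus = FALSE, known_overlap = NA_character_,
                              stringsAsFactors = FALSE)
  }
  chrom[[length(chrom) + 1L]] <- random_dna(gap())
  genome <- Biostrings::DNAStringSet(
    paste(unlist(chrom), collapse = ""))
  names(genome) <- "chr1"

  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(transcript_id = character(0), class = character(0),
               cage_plus = logical(0), known_overlap = character(0),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  transcripts <- if (length(tx_rows) > 0L) {
    ex <- do.call(rbind, tx_rows)
    exons <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(ex$start, ex$end),
                                    strand = ex$strand)
    S4Vectors::mcols(exons)$transcript_id <- ex$transcript_id
    S4Vectors::mcols(exons)$gene_id <- paste0("XLOC.", ex$transcript_id)
    annotation_set(exons)
  } else annotation_set(GenomicRanges::GRanges())

  annotation <- if (length(gene_rows) > 0L) {
    gtab <- do.call(rbind, gene_rows)
    g <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(gtab$start, gtab$end),
                                strand = gtab$strand)
    names(g) <- gtab$id
    g
  } else GenomicRanges::GRanges()

  # TSS at the 5' end of a subset of lincRNAs (distance 0)
  linc_ids <- names(linc_spans)
  n_tss <- round(length(linc_ids) * spec$tss_fraction)
  tss_ids <- if (n_tss > 0) sample(linc_ids, n_tss) else character(0)
  tss_pos <- vapply(tss_ids, function(id) {
    sp <- linc_spans[[id]]
    strand <- as.character(BiocGenerics::strand(
      transcripts$transcripts[id]))
    as.integer(if (strand == "-") sp[2L] else sp[1L])
  }, integer(1))
  tss <- if (length(tss_pos) > 0L)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(tss_pos, tss_pos))
  else GenomicRanges::GRanges()
  truth$cage_plus[match(tss_ids, truth$transcript_id)] <- TRUE

  # known lincRNA loci overlapping a subset of the planted lincRNAs
  n_known <- min(2L, length(linc_ids))
  known_ids <- if (n_known > 0L) sample(linc_ids, n_known) else character(0)
  known <- if (length(known_ids) > 0L) {
    spans <- do.call(rbind, linc_spans[known_ids])
    g <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(spans[, 1L] + 10L,
                                                 spans[, 2L] - 10L))
    names(g) <- paste0("KnownLinc", seq_along(known_ids))
    g
  } else GenomicRanges::GRanges()
  truth$known_overlap[match(known_ids, truth$transcript_id)] <-
    names(known)

  out <- list(genome = genome, transcripts = transcripts,
              annotation = annotation, te_db = te_db, tss = tss,
              known_lincrna = known, truth = truth, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome, file.path(dir, "genome.fa"))
    write_gff(annotation, file.path(dir, "annotation.gff"))
    write_transcript_gtf(transcripts, file.path(dir, "transcripts.gtf"))
    write_fasta(te_db, file.path(dir, "te_db.fa"))
    write_bed(tss, file.path(dir, "tss.bed"))
    write_gff(known, file.path(dir, "known_lincrna.gff"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

as_rc_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

#' Specification for the species-panel fixture
#'
#' @param seed Integer RNG seed.
#' @param n_species Number of panel species (ladder topology; the first
#'   species is the query species).
#' @param genome_len Ancestral genome length in nt (planted loci and
#'   their spacing are carved out of it).
#' @param n_queries Planted lincRNA loci (each 300-600 nt).
#' @param sub_rate Expected substitutions per site per branch (in
#'   `[0, 0.75)`).
#' @param indel_rate Expected indel events per site per branch; indels
#'   are single events of geometric length (mean ~3 nt) placed between
#'   planted loci so truth coordinates stay exact.
#' @param losses List of planted losses: each element
#'   `list(query = <index>, clade = <species names>)` deletes the locus
#'   on the branch leading to the smallest clade containing exactly those
#'   species.
#' @param duplications List of planted duplications: each element
#'   `list(query = <index>, clade = <species names>)` inserts a second
#'   copy on that branch.
#' @return A `panel_spec` list.
#' @export
panel_fixture_spec <- function(seed = 1, n_species = 5, genome_len = 50000,
                               n_queries = 20, sub_rate = 0.03,
                               indel_rate = 0.001,
                               losses = list(), duplications = list()) {
  stopifnot(seed == as.integer(seed), n_species >= 2,
            sub_rate >= 0, sub_rate < 0.75, indel_rate >= 0)
  structure(as.list(environment()), class = "panel_spec")
}

panel_species_names <- function(n)
  paste0("sp", LETTERS[seq_len(n)])

ladder_tree <- function(species) {
  nwk <- paste0("(", species[1L], ":1,", species[2L], ":1)")
  for (i in seq_along(species)[-(1:2)])
    nwk <- paste0("(", nwk, ":1,", species[i], ":1)")
  ape::read.tree(text = paste0(nwk, ";"))
}

#' Generate the species-panel fixture
#'
#' Plants lincRNA loci in an ancestral genome and evolves it along a
#' ladder species tree with per-branch substitutions and intergenic
#' indels; optional loss and duplication events are applied on the stated
#' branches. The truth table records, for every query and species,
#' whether a homolog is present and where each copy lies.
#'
#' @param spec A [panel_fixture_spec()].
#' @param dir Optional directory: writes `<species>.fa` genomes,
#'   `species.txt`, `species_tree.nwk`, `queries.fa` and `truth.tsv`.
#' @return List with `genomes` (named list of `DNAStringSet`), `species`,
#'   `tree` (`ape::phylo`), `queries` (`DNAStringSet`, taken from the
#'   query-species genome), `query_loci` (`GRanges` in the query genome),
#'   `panel` (a ready [species_panel]), `truth` (data.frame: query_id,
#'   species, present, n_copies, coords).
#' @export
make_panel_fixture <- function(spec = panel_fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  species <- panel_species_names(spec$n_species)
  tree <- ladder_tree(species)

  qlen <- sample(300:600, spec$n_queries, replace = TRUE)
  spacing <- floor(spec$genome_len / (spec$n_queries + 1L))
  if (spacing < max(qlen) + 200L)
    stop("genome_len too small for ", spec$n_queries, " planted loci",
         call. = FALSE)
  anc <- random_dna(spec$genome_len)
  qstart <- integer(spec$n_queries)
  for (i in seq_len(spec$n_queries)) {
    qstart[i] <- (i - 1L) * spacing + sample(50:150, 1)
    anc[qstart[i]:(qstart[i] + qlen[i] - 1L)] <-
      random_noncoding(qlen[i])
  }
  qids <- paste0("q", seq_len(spec$n_queries))
  loci0 <- data.frame(query = rep(qids, 1L),
                      start = qstart, end = qstart + qlen - 1L,
                      copy = 1L, stringsAsFactors = FALSE)

  # recursive evolution along the ladder; each state = genome chars +
  # locus table
  results <- list()
  clade_of <- function(node_species) paste(sort(node_species), collapse = "+")
  branch_events <- function(kind) {
    evs <- spec[[kind]]
    function(node_species) {
      keep <- vapply(evs, function(e)
        clade_of(e$clade) == clade_of(node_species), logical(1))
      evs[keep]
    }
  }
  losses_at <- branch_events("losses")
  dups_at <- branch_events("duplications")

  evolve_branch <- function(chars, loci, node_species) {
    # planted events first (they act on the ancestral state of the branch)
    for (e in losses_at(node_species)) {
      qid <- qids[e$query]
      rows <- which(loci$query == qid)
      for (r in rev(rows)) {
        span <- loci$start[r]:loci$end[r]
        chars[span] <- random_dna(length(span))
      }
      loci <- loci[loci$query != qid, , drop = FALSE]
    }
    for (e in dups_at(node_species)) {
      qid <- qids[e$query]
      rows <- which(loci$query == qid)
      if (length(rows) > 0L) {
        r <- rows[1L]
        copy <- chars[loci$start[r]:loci$end[r]]
        # the new copy must lie beyond the hit-merging gap from every
        # existing copy of this query, so it registers as a distinct locus
        ins_at <- NA_integer_
        for (try in 1:100) {
          cand <- pick_intergenic(loci, length(chars))
          if (is.na(cand)) next
          d <- pmin(abs(cand - loci$start[rows]), abs(cand - loci$end[rows]))
          if (all(d > 12000L)) { ins_at <- cand; break }
        }
        if (is.na(ins_at))
          stop("could not place a duplicate copy away from existing loci; ",
               "increase genome_len", call. = FALSE)
        chars <- append(chars, copy, after = ins_at)
        shift <- length(copy)
        later <- loci$start > ins_at
        loci$start[later] <- loci$start[later] + shift
        loci$end[later] <- loci$end[later] + shift
        loci <- rbind(loci, data.frame(query = qid, start = ins_at + 1L,
                                       end = ins_at + shift,
                                       copy = max(loci$copy[rows]) + 1L,
                                       stringsAsFactors = FALSE))
      }
    }
    chars <- mutate_seq(chars, spec$sub_rate)
    n_indel <- stats::rpois(1, spec$indel_rate * length(chars))
    for (i in seq_len(n_indel)) {
      len <- 1L + stats::rgeom(1, 0.3)
      at <- pick_intergenic(loci, length(chars), len + 1L)
      if (is.na(at)) next
      if (stats::runif(1) < 0.5) {  # insertion after `at`
        chars <- append(chars, random_dna(len), after = at)
        later <- loci$start > at
        loci$start[later] <- loci$start[later] + len
        loci$end[later] <- loci$end[later] + len
      } else {                      # deletion of [at+1, at+len]
        if (at + len > length(chars)) next
        if (any(loci$start <= at + len & loci$end >= at + 1L)) next
        chars <- chars[-((at + 1L):(at + len))]
        later <- loci$start > at
        loci$start[later] <- loci$start[later] - len
        loci$end[later] <- loci$end[later] - len
      }
    }
    list(chars = chars, loci = loci)
  }

  walk <- function(chars, loci, node_species) {
    if (length(node_species) == 1L) {
      st <- evolve_branch(chars, loci, node_species)
      results[[node_species]] <<- st
      return(invisible(NULL))
    }
    # ladder topology: last species splits off
    st <- if (length(node_species) == spec$n_species) {
      list(chars = chars, loci = loci)  # root: no branch above
    } else evolve_branch(chars, loci, node_species)
    k <- length(node_species)
    walk(st$chars, st$loci, node_species[seq_len(k - 1L)])
    walk(st$chars, st$loci, node_species[k])
  }
  walk(anc, loci0, species)

  genomes <- lapply(results, function(st) {
    g <- Biostrings::DNAStringSet(paste(st$chars, collapse = ""))
    names(g) <- "chr1"
    g
  })
  genomes <- genomes[species]

  truth <- do.call(rbind, lapply(species, function(sp) {
    lt <- results[[sp]]$loci
    do.call(rbind, lapply(qids, function(q) {
      rows <- lt[lt$query == q, , drop = FALSE]
      data.frame(query_id = q, species = sp,
                 present = nrow(rows) > 0L, n_copies = nrow(rows),
                 coords = paste(sprintf("%d-%d", rows$start, rows$end),
                                collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(truth) <- NULL

  qloci_tab <- results[[species[1L]]]$loci
  qloci_tab <- qloci_tab[qloci_tab$copy == 1L, , drop = FALSE]
  queries <- Biostrings::DNAStringSet(vapply(qids, function(q) {
    r <- qloci_tab[qloci_tab$query == q, , drop = FALSE]
    if (nrow(r) == 0L) return(NA_character_)
    paste(results[[species[1L]]]$chars[r$start[1L]:r$end[1L]],
          collapse = "")
  }, character(1))[qids %in% qloci_tab$query])
  present_q <- qids[qids %in% qloci_tab$query]
  names(queries) <- present_q
  query_loci <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(
      qloci_tab$start[match(present_q, qloci_tab$query)],
      qloci_tab$end[match(present_q, qloci_tab$query)]))
  names(query_loci) <- present_q

  panel <- species_panel(species, genomes, species_tree = tree)
  out <- list(genomes = genomes, species = species, tree = tree,
              queries = queries, query_loci = query_loci, panel = panel,
              truth = truth, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (sp in species)
      write_fasta(genomes[[sp]], file.path(dir, paste0(sp, ".fa")))
    writeLines(species, file.path(dir, "species.txt"))
    write_newick(tree, file.path(dir, "species_tree.nwk"))
    write_fasta(queries, file.path(dir, "queries.fa"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

# a position not inside (or adjacent to) any tracked locus
pick_intergenic <- function(loci, glen, need = 1L) {
  for (try in 1:50) {
    at <- sample.int(glen - need, 1)
    margin <- 25L
    if (!any(loci$start - margin <= at + need &
             loci$end + margin >= at)) return(at)
  }
  NA_integer_
}

#' Random decoy queries absent from every genome
#'
#' @param n Number of decoys.
#' @param len_range Length range.
#' @param seed RNG seed.
#' @return Named `DNAStringSet` (`decoy1`...).
#' @export
make_decoy_queries <- function(n = 20, len_range = c(250, 400), seed = 1) {
  set.seed(seed)
  lens <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
  out <- Biostrings::DNAStringSet(vapply(lens, function(L)
    paste(random_dna(L), collapse = ""), character(1)))
  names(out) <- paste0("decoy", seq_len(n))
  out
}
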