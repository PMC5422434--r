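test_that("length filter is strictly greater-than", {
  lens <- c(a = 200L, b = 201L, c = 5000L)
  r <- filter_by_length(lens, 200)
  expect_equal(r$kept, c("b", "c"))
  expect_equal(r$rejected, "a")
  r0 <- filter_by_length(stats::setNames(integer(0), character(0)), 200)
  expect_length(r0$kept, 0L)
  expect_length(r0$rejected, 0L)
})

test_that("longest ORF matches a translation-based oracle", {
  # constructed boundary cases
  s100 <- paste0("ATG", paste(rep("GCA", 99), collapse = ""), "TAA")
  expect_equal(find_longest_orf(s100), 100L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s100)))
  expect_equal(find_longest_orf(rc), 100L)
  expect_equal(find_longest_orf("CCCCCCCCCCCC"), 0L)
  expect_equal(find_longest_orf("ATGAAAAAA"), 0L)  # no stop: incomplete

  # independent oracle: six-frame translation via Biostrings::translate,
  # longest M..* run
  oracle <- function(seq) {
    s <- Biostrings::DNAString(seq)
    best <- 0L
    for (str in list(s, Biostrings::reverseComplement(s))) {
      for (f in 0:2) {
        len <- (length(str) - f) %/% 3 * 3
        if (len < 6) next
        aa <- as.character(suppressWarnings(Biostrings::translate(
          Biostrings::subseq(str, f + 1, f + len),
          if.fuzzy.codon = "X", no.init.codon = TRUE)))
        stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
        if (stops[1] == -1) next
        prev <- 0L
        for (st in stops) {
          seg <- substr(aa, prev + 1, st - 1)
          m <- regexpr("M", seg, fixed = TRUE)
          if (m > 0) best <- max(best, nchar(seg) - m + 1L)
          prev <- st
        }
      }
    }
    as.integer(best)
  }
  set.seed(33)
  for (i in 1:25) {
    seq <- random_seq(sample(60:400, 1))
    expect_equal(find_longest_orf(seq), oracle(seq), info = seq)
  }
})

test_that("coding verdict combines the ORF and protein-hit rules", {
  cfg <- linckit_config()
  expect_equal(assess_coding(101, numeric(0), cfg)$verdict, "coding")
  expect_equal(assess_coding(100, numeric(0), cfg)$verdict, "noncoding")
  expect_equal(assess_coding(50, 1e-6, cfg)$verdict, "coding")
  expect_equal(assess_coding(50, 1e-5, cfg)$verdict, "coding")   # inclusive
  expect_equal(assess_coding(50, 2e-5, cfg)$verdict, "noncoding")
})

test_that("TE filter requires both bit-score and E-value thresholds", {
  cfg <- linckit_config()
  hits <- data.frame(transcript_id = c("a", "b", "c", "d"),
                     bitscore = c(250, 150, 250, 200),
                     evalue = c(1e-30, 1e-30, 1e-10, 1e-20))
  r <- filter_te(hits, c("a", "b", "c", "d", "e"), cfg)
  expect_setequal(r$te_derived, c("a", "d"))  # d: exact boundary passes
  expect_setequal(r$retained, c("b", "c", "e"))
  r2 <- filter_te(NULL, c("a", "b"), cfg)
  expect_length(r2$te_derived, 0L)
})

test_that("overlap classification follows the strand rule table", {
  gene_p <- GenomicRanges::GRanges("c", IRanges::IRanges(100, 500),
                                   strand = "+")
  gene_m <- GenomicRanges::GRanges("c", IRanges::IRanges(100, 500),
                                   strand = "-")
  tx <- function(strand) GenomicRanges::GRanges(
    "c", IRanges::IRanges(300, 700), strand = strand)
  expect_equal(classify_overlap(tx("+"), gene_p), "SOT")
  expect_equal(classify_overlap(tx("+"), gene_m), "AOT")
  expect_equal(classify_overlap(tx("-"), gene_p), "AOT")
  expect_equal(classify_overlap(tx("*"), gene_p), "AMBIGUOUS_OVERLAP")
  far <- GenomicRanges::GRanges("c", IRanges::IRanges(5000, 5400),
                                strand = "+")
  expect_equal(classify_overlap(far, gene_p), "LINCRNA")
  gene_u <- GenomicRanges::GRanges("c", IRanges::IRanges(100, 500))
  expect_equal(classify_overlap(tx("+"), gene_u), "AMBIGUOUS_OVERLAP")
})

test_that("TSS support is inclusive at the window boundary", {
  cfg <- linckit_config()
  tss <- GenomicRanges::GRanges("c", IRanges::IRanges(1000, 1000))
  span_at <- function(d) {
    g <- GenomicRanges::GRanges("c", IRanges::IRanges(1000 + d, 1600 + d),
                                strand = "+")
    names(g) <- "L"
    g
  }
  expect_true(annotate_tss(span_at(0), tss, cfg)[["L"]])
  expect_true(annotate_tss(span_at(100), tss, cfg)[["L"]])
  expect_false(annotate_tss(span_at(101), tss, cfg)[["L"]])
  # minus strand: 5' end is the span end
  g <- GenomicRanges::GRanges("c", IRanges::IRanges(400, 1000),
                              strand = "-")
  names(g) <- "M"
  expect_true(annotate_tss(g, tss, cfg)[["M"]])
  expect_warning(annotate_tss({
    u <- GenomicRanges::GRanges("c", IRanges::IRanges(1000, 1500))
    names(u) <- "U"; u
  }, tss, cfg), "unknown strand")
})

test_that("known-lincRNA overlap appends the suffix and records ids", {
  spans <- GenomicRanges::GRanges("c", IRanges::IRanges(c(100, 2000),
                                                        c(400, 2400)))
  names(spans) <- c("L1", "L2")
  known <- GenomicRanges::GRanges("c", IRanges::IRanges(c(300, 320),
                                                        c(600, 380)))
  names(known) <- c("K1", "K2")
  r <- reconcile_known_lincRNAs(spans, known)
  expect_equal(r$final_id[1], "L1_overlapping_known_lncRNA")
  expect_equal(r$final_id[2], "L2")
  # nearest by midpoint among the two overlapping loci
  expect_equal(r$known_lincrna_id[1], "K2")   # midpoint 350 vs 450; span mid 250
  expect_setequal(strsplit(r$known_all[1], ",")[[1]], c("K1", "K2"))
  expect_true(is.na(r$known_lincrna_id[2]))
})

test_that("locus grouping clusters exon-overlapping same-strand isoforms", {
  mk <- function(id, start, end, strand) {
    g <- GenomicRanges::GRanges("c", IRanges::IRanges(start, end),
                                strand = strand)
    S4Vectors::mcols(g)$transcript_id <- id
    S4Vectors::mcols(g)$gene_id <- id
    g
  }
  # shared exon interval -> one locus
  a <- annotation_set(c(mk("t1", 100, 400, "+"), mk("t2", 300, 600, "+")))
  expect_equal(group_into_loci(a)$n_loci, 1L)
  # opposite strands -> two loci
  b <- annotation_set(c(mk("t1", 100, 400, "+"), mk("t2", 300, 600, "-")))
  expect_equal(group_into_loci(b)$n_loci, 2L)
  # disjoint -> two loci
  d <- annotation_set(c(mk("t1", 100, 400, "+"), mk("t2", 5000, 5600, "+")))
  expect_equal(group_into_loci(d)$n_loci, 2L)
  # transitive chain t1~t2~t3 -> one locus even if t1,t3 disjoint
  e <- annotation_set(c(mk("t1", 100, 400, "+"), mk("t2", 350, 900, "+"),
                        mk("t3", 850, 1200, "+")))
  expect_equal(group_into_loci(e)$n_loci, 1L)
  # unknown strand joins either strand
  f <- annotation_set(c(mk("t1", 100, 400, "+"), mk("t2", 300, 600, "*")))
  expect_equal(group_into_loci(f)$n_loci, 1L)
})

test_that("demographics report min/max/mean lengths and GC content", {
  seqs <- dna_set(a = "ATGC", b = "GGCC")
  mk <- function(id, start, end) {
    g <- GenomicRanges::GRanges("c", IRanges::IRanges(start, end),
                                strand = "+")
    S4Vectors::mcols(g)$transcript_id <- id
    S4Vectors::mcols(g)$gene_id <- id
    g
  }
  annot <- annotation_set(c(mk("a", 1, 4), mk("b", 100, 103)))
  rec <- data.frame(transcript_id = c("a", "b"),
                    class = c("LINCRNA", "LINCRNA"))
  d <- demographics(rec, seqs, annot, classes = "LINCRNA")
  expect_equal(d$gc_percent, 75)            # (2+4)/8 by direct count
  expect_equal(d$n_transcripts, 2L)
  expect_equal(d$n_loci, 2L)

  lens <- dna_set(a = random_seq(300), b = random_seq(500))
  annot2 <- annotation_set(c(mk("a", 1, 300), mk("b", 1000, 1499)))
  d2 <- demographics(rec, lens, annot2, classes = "LINCRNA")
  expect_equal(c(d2$min_len, d2$max_len, d2$mean_len), c(300, 500, 400))

  single <- demographics(rec[1, , drop = FALSE], lens, annot2,
                         classes = c("LINCRNA", "SOT"))
  expect_equal(single$min_len[1], single$max_len[1])
  expect_equal(single$n_transcripts[2], 0L)  # empty class row of zeros
})

test_that("splice-site orientation assigns strand to unstranded multi-exon
          transcripts", {
  left <- random_seq(100)
  exon1 <- random_seq(80); exon2 <- random_seq(90)
  intron <- paste0("GT", random_seq(60), "AG")
  genome <- dna_set(chr1 = paste0(left, exon1, intron, exon2,
                                  random_seq(50)))
  ex <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(101, 245), c(180, 334)),
                               strand = "*")
  S4Vectors::mcols(ex)$transcript_id <- "t1"
  S4Vectors::mcols(ex)$gene_id <- "t1"
  a <- infer_strand_from_splice_sites(genome, annotation_set(ex))
  expect_equal(as.character(BiocGenerics::strand(a$transcripts["t1"])), "+")

  intron_m <- paste0("CT", random_seq(60), "AC")  # reverse-strand junction
  genome2 <- dna_set(chr1 = paste0(left, exon1, intron_m, exon2,
                                   random_seq(50)))
  a2 <- infer_strand_from_splice_sites(genome2, annotation_set(ex))
  expect_equal(as.character(BiocGenerics::strand(a2$transcripts["t1"])), "-")
})

test_that("the pipeline reproduces the planted classes exactly", {
  fx <- small_identify_fixture()
  res <- small_identify_result()
  m <- merge(res$records[, c("transcript_id", "class", "cage_plus")],
             fx$truth, by = "transcript_id")
  expect_equal(nrow(m), nrow(fx$truth))
  expect_equal(m$class.x, m$class.y)
  expect_equal(m$cage_plus.x, m$cage_plus.y)
  known_called <- !is.na(m$known_overlap)
  expect_equal(grepl("_overlapping_known_lncRNA",
                     res$records$final_id[match(m$transcript_id,
                                                res$records$transcript_id)]),
               known_called)
})

test_that("each transcript lands in exactly one class and lincRNA output
          respects the filters", {
  fx <- small_identify_fixture()
  res <- small_identify_result()
  expect_false(anyNA(res$records$class))
  expect_equal(sum(table(res$records$class)), nrow(fx$truth))
  li <- res$records[res$records$class == "LINCRNA", ]
  expect_true(all(li$length > 200))
  expect_true(all(li$orf_aa <= 100))
})

test_that("removing the annotation reclassifies former SOT/AOT as
          intergenic", {
  fx <- small_identify_fixture()
  res0 <- small_identify_result()
  res2 <- run_identify(fx$transcripts, fx$genome,
                       GenomicRanges::GRanges(), te_db = fx$te_db)
  was_overlap <- res0$records$transcript_id[
    res0$records$class %in% c("SOT", "AOT", "AMBIGUOUS_OVERLAP")]
  now <- res2$records$class[match(was_overlap,
                                  res2$records$transcript_id)]
  expect_true(all(now == "LINCRNA"))
})

test_that("growing the annotation or the flank never grows the lincRNA
          set", {
  fx <- small_identify_fixture()
  res0 <- small_identify_result()
  # add a gene on top of one planted lincRNA
  li1 <- res0$records[res0$records$class == "LINCRNA", ][1, ]
  extra <- GenomicRanges::GRanges(li1$seq_id,
                                  IRanges::IRanges(li1$start, li1$end),
                                  strand = "+")
  names(extra) <- "extra_gene"
  res_grown <- run_identify(fx$transcripts, fx$genome,
                            c(fx$annotation, extra), te_db = fx$te_db)
  expect_true(all(res_grown$lincRNA_ids %in% res0$lincRNA_ids))
  expect_false(li1$transcript_id %in% res_grown$lincRNA_ids)

  res_flank0 <- run_identify(fx$transcripts, fx$genome, fx$annotation,
                             te_db = fx$te_db, flank = 0)
  res_flank2k <- run_identify(fx$transcripts, fx$genome, fx$annotation,
                              te_db = fx$te_db, flank = 2000)
  expect_true(all(res_flank2k$lincRNA_ids %in% res_flank0$lincRNA_ids))
})

test_that("identical inputs produce byte-identical summary tables", {
  fx <- small_identify_fixture()
  run <- function() run_identify(fx$transcripts, fx$genome, fx$annotation,
                                 te_db = fx$te_db, tss = fx$tss)
  f1 <- tempfile(); f2 <- tempfile()
  utils::write.table(run()$summary_table, f1, sep = "\t", row.names = FALSE)
  utils::write.table(run()$summary_table, f2, sep = "\t", row.names = FALSE)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("an empty assembly yields empty outputs", {
  gtf <- write_lines_tmp(character(0), ".gtf")
  res <- run_identify(read_transcript_gtf(gtf),
                      dna_set(chr1 = random_seq(1000)),
                      GenomicRanges::GRanges())
  expect_equal(nrow(res$records), 0L)
  expect_equal(nrow(res$summary_table), 0L)
})

test_that("transcripts on absent chromosomes are reported by id", {
  ex <- GenomicRanges::GRanges("chrMissing", IRanges::IRanges(300, 800),
                               strand = "+")
  S4Vectors::mcols(ex)$transcript_id <- "tbad"
  S4Vectors::mcols(ex)$gene_id <- "g"
  expect_error(
    run_identify(annotation_set(ex), dna_set(chr1 = random_seq(1000)),
                 GenomicRanges::GRanges()),
    "tbad")
})

test_that("the output bundle contains the per-class files", {
  res <- small_identify_result()
  dir <- tempfile()
  write_identify_outputs(res, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "lincRNAs.FASTA", "lincRNAs.bed", "SOT.FASTA", "AOT.FASTA",
    "TE_lncRNAs.FASTA", "Final_summary_table.tsv", "demographics.tsv",
    "annotation_updated.gff")))))
  li <- read_fasta(file.path(dir, "lincRNAs.FASTA"))
  expect_equal(sort(names(li)), sort(res$summary_table$lincRNA_id))
  cage <- S4Vectors::mcols(li)$description == "CAGE_PLUS"
  expect_equal(sum(cage),
               sum(res$summary_table$TSS_support == "CAGE_PLUS"))
  upd <- read_annotation_gff(file.path(dir, "annotation_updated.gff"))
  expect_true(length(upd) >= length(res$lincRNA_ids))
})
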