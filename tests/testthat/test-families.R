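test_that("species panels validate their inputs", {
  g <- list(a = dna_set(chr1 = random_seq(500)))
  expect_error(species_panel(c("a", "a"), g), "unique")
  expect_error(species_panel(character(0), g), "empty")
  expect_error(species_panel(c("a", "b"), g), "b")
  p <- species_panel("a", g)
  expect_s3_class(p, "species_panel")
})

test_that("families contain exactly the species with planted homologs", {
  fx <- small_panel_fixture()
  fams <- small_panel_families()
  tr <- fx$truth
  for (i in seq_len(nrow(tr))) {
    called <- tr$species[i] %in% names(fams$families[[tr$query_id[i]]]$calls)
    expect_equal(called, tr$present[i],
                 info = paste(tr$query_id[i], tr$species[i]))
  }
  # q1 was deleted on the spC and spD branches
  expect_setequal(names(fams$families[["q1"]]$calls), c("spA", "spB"))
})

test_that("decoy queries yield query-only families", {
  fx <- small_panel_fixture()
  decoys <- make_decoy_queries(3, seed = 5)
  fams <- suppressWarnings(build_families(decoys, fx$panel))
  for (f in fams$families) expect_length(f$calls, 0L)
  expect_equal(length(family_sequences(fams$families[[1]])), 1L)
})

test_that("homolog call sequences equal the strand-adjusted genome
          substring", {
  fx <- small_panel_fixture()
  fams <- small_panel_families()
  for (fam in fams$families) {
    for (call in fam$calls) {
      g <- fx$genomes[[call$species]][[call$subject_id]]
      s <- Biostrings::subseq(g, call$s_start, call$s_end)
      if (call$strand == "-") s <- Biostrings::reverseComplement(s)
      expect_equal(call$sequence, as.character(s))
    }
  }
})

test_that("binning the query set does not change the result", {
  fx <- small_panel_fixture()
  full <- small_panel_families()
  bins <- split(names(fx$queries),
                rep(1:2, length.out = length(fx$queries)))
  merged <- list()
  for (b in bins) {
    part <- build_families(fx$queries[b], fx$panel,
                           query_loci = fx$query_loci[b])
    merged <- c(merged, part$families)
  }
  merged <- merged[names(fx$queries)]
  for (qid in names(fx$queries)) {
    expect_equal(names(merged[[qid]]$calls),
                 names(full$families[[qid]]$calls))
    for (sp in names(merged[[qid]]$calls))
      expect_equal(merged[[qid]]$calls[[sp]][c("s_start", "s_end", "strand")],
                   full$families[[qid]]$calls[[sp]][c("s_start", "s_end",
                                                      "strand")])
  }
  # bytewise identity of the summary tables
  d1 <- tempfile(); d2 <- tempfile()
  write_family_outputs(full, d1)
  stitched <- full
  stitched$families <- merged
  write_family_outputs(stitched, d2)
  expect_equal(unname(tools::md5sum(file.path(d1, "final_summary_table.tsv"))),
               unname(tools::md5sum(file.path(d2, "final_summary_table.tsv"))))
})

test_that("shuffling the deeper panel entries changes order, not content", {
  fx <- small_panel_fixture()
  full <- small_panel_families()
  sp <- fx$species
  shuffled <- c(sp[1], rev(sp[-1]))
  panel2 <- species_panel(shuffled, fx$genomes, species_tree = fx$tree)
  fams2 <- build_families(fx$queries, panel2, query_loci = fx$query_loci)
  for (qid in names(fx$queries))
    expect_setequal(names(fams2$families[[qid]]$calls),
                    names(full$families[[qid]]$calls))
})

test_that("homolog labels record overlapping annotation features", {
  call <- list(subject_id = "chr1", s_start = 1000, s_end = 1400,
               labels = "Homolog", feature_ids = character(0))
  gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1200, 2000))
  names(gene) <- "G7"
  linc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 1100))
  names(linc) <- "KL1"
  r1 <- label_homolog(call, gene, NULL)
  expect_setequal(r1$labels, c("Homolog", "Known_gene"))
  expect_equal(r1$feature_ids, "G7")
  r2 <- label_homolog(call, NULL, NULL)
  expect_equal(r2$labels, "Homolog")
  r3 <- label_homolog(call, gene, linc)
  expect_setequal(r3$labels, c("Homolog", "Known_gene", "Known_lincRNA"))
  expect_setequal(r3$feature_ids, c("G7", "KL1"))
})

test_that("per-species annotations flow into the summary table", {
  fx <- small_panel_fixture()
  fams <- small_panel_families()
  # plant an annotation over q2's homolog locus in spB
  call <- fams$families[["q2"]]$calls[["spB"]]
  gene <- GenomicRanges::GRanges(call$subject_id,
                                 IRanges::IRanges(call$s_start,
                                                  call$s_end))
  names(gene) <- "GENE9"
  panel2 <- species_panel(fx$species, fx$genomes,
                          annotations = list(spB = gene),
                          species_tree = fx$tree)
  fams2 <- build_families(fx$queries["q2"], panel2,
                          query_loci = fx$query_loci["q2"])
  cl <- fams2$families[["q2"]]$calls[["spB"]]
  expect_true("Known_gene" %in% cl$labels)
  cs <- conservation_summary(fams2)
  expect_equal(cs$per_query$features_spB, "GENE9")
})

test_that("conservation summary reports counts, percentages and depth", {
  fams <- small_panel_families()
  cs <- conservation_summary(fams)
  nq <- length(fams$families)
  for (i in seq_len(nrow(cs$per_species))) {
    sp <- cs$per_species$species[i]
    n <- sum(vapply(fams$families, function(f) sp %in% names(f$calls),
                    logical(1)))
    expect_equal(cs$per_species$n_homologs[i], n)
    expect_equal(cs$per_species$percent[i], n / nq * 100)
  }
  # deepest conserved species = farthest panel rank with a call
  for (i in seq_len(nrow(cs$per_query))) {
    qid <- cs$per_query$query_id[i]
    ranks <- vapply(fams$families[[qid]]$calls, function(cl) cl$rank,
                    integer(1))
    expect_equal(cs$per_query$deepest_species[i],
                 fams$panel$species[max(ranks)])
  }
  expect_equal(cs$per_query$deepest_species[cs$per_query$query_id == "q1"],
               "spB")
})

test_that("an empty query set gives empty, finite summaries", {
  fx <- small_panel_fixture()
  fams <- build_families(Biostrings::DNAStringSet(), fx$panel)
  cs <- conservation_summary(fams)
  expect_equal(nrow(cs$per_query), 0L)
  expect_true(all(cs$per_species$percent == 0))
})

test_that("query-centric BED projects hits through the exon map", {
  # single-exon query at genome 1001..1332: transcript 101..250 ->
  # genome 1101..1250
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1332),
                                  strand = "+")
  fam <- list(query_id = "q", query_seq = Biostrings::DNAString("A"),
              calls = list(spB = list(
                species = "spB",
                members = data.frame(q_start = 101L, q_end = 250L))))
  bed <- query_centric_bed(fam, exons)
  expect_equal(names(bed), "spB")
  expect_equal(BiocGenerics::start(bed), 1101L)
  expect_equal(BiocGenerics::end(bed), 1250L)

  # a hit spanning an exon junction splits into two genomic blocks
  exons2 <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(c(1001, 2001),
                                                    c(1100, 2100)),
                                   strand = "+")
  fam2 <- fam
  fam2$calls$spB$members <- data.frame(q_start = 51L, q_end = 150L)
  bed2 <- query_centric_bed(fam2, exons2)
  expect_equal(length(bed2), 2L)
  expect_equal(BiocGenerics::start(bed2), c(1051L, 2001L))
  expect_equal(BiocGenerics::end(bed2), c(1100L, 2050L))

  # minus-strand query: transcript coordinates run from the right
  exons3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1200),
                                   strand = "-")
  fam3 <- fam
  fam3$calls$spB$members <- data.frame(q_start = 1L, q_end = 50L)
  bed3 <- query_centric_bed(fam3, exons3)
  expect_equal(BiocGenerics::start(bed3), 1151L)
  expect_equal(BiocGenerics::end(bed3), 1200L)

  # query-only family -> empty BED; no exon map -> transcript coords
  expect_length(query_centric_bed(list(query_id = "q", calls = list())),
                0L)
  expect_warning(bed4 <- query_centric_bed(fam, NULL), "exon map")
  expect_equal(BiocGenerics::start(bed4), 101L)
})

test_that("the conservation output bundle is complete", {
  fams <- small_panel_families()
  dir <- tempfile()
  write_family_outputs(fams, dir)
  expect_true(file.exists(file.path(dir, "final_summary_table.tsv")))
  expect_true(file.exists(file.path(dir, "conservation_by_species.tsv")))
  expect_true(file.exists(file.path(dir, "q1_alignment.FASTA")))
  hs <- list.files(file.path(dir, "Homology_search"), full.names = TRUE)
  expect_gt(length(hs), 0L)
  gff <- read_annotation_gff(hs[1])
  expect_gt(length(gff), 0L)
  aln <- read_fasta(file.path(dir, "q2_alignment.FASTA"))
  expect_gte(length(aln), 2L)
  expect_true(any(grepl("Homolog", names(aln))))
})
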