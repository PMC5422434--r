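test_that("Karlin-Altschul lambda agrees with an independent root-finder", {
  for (sc in list(c(1, -2), c(2, -3))) {
    got <- karlin_altschul_params(sc[1], sc[2])
    # independent oracle: uniroot on the moment condition
    f <- function(l) 0.25 * exp(l * sc[1]) + 0.75 * exp(l * sc[2]) - 1
    oracle <- stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
    expect_lt(abs(got$lambda - oracle), 1e-6)
    expect_gt(got$K, 0)
    expect_gt(got$H, 0)
  }
  expect_error(karlin_altschul_params(1, 1), "negative")
  expect_error(karlin_altschul_params(1, -0.2), "negative")  # E[score] >= 0
})

test_that("expect values decrease strictly as the raw score grows", {
  ka <- karlin_altschul_params(2, -3)
  S <- seq(20, 200, by = 5)
  E <- ka$K * 500 * 1e5 * exp(-ka$lambda * S)
  expect_true(all(diff(E) < 0))
  bits <- (ka$lambda * S - log(ka$K)) / log(2)
  expect_true(all(diff(bits) > 0))
})

test_that("a planted query is recovered at its exact coordinates", {
  set.seed(71)
  subj_chars <- sample(c("A", "C", "G", "T"), 50000, replace = TRUE)
  q <- paste(subj_chars[20001:20500], collapse = "")
  subj <- dna_set(chrX = paste(subj_chars, collapse = ""))
  idx <- build_search_index(subj)
  h <- seeded_local_search(dna_set(q1 = q), subj, index = idx)
  expect_gte(nrow(h), 1L)
  expect_equal(h$s_start[1], 20001L)
  expect_equal(h$s_end[1], 20500L)
  expect_equal(h$strand[1], "+")
  expect_equal(h$pident[1], 100)
  expect_lt(h$evalue[1], 1e-20)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  h2 <- seeded_local_search(dna_set(q1 = rc), subj, index = idx)
  expect_equal(h2$s_start[1], 20001L)
  expect_equal(h2$s_end[1], 20500L)
  expect_equal(h2$strand[1], "-")
})

test_that("random queries return nothing at stringent cutoffs", {
  set.seed(72)
  subj <- dna_set(chrX = random_seq(30000))
  idx <- build_search_index(subj)
  hits_per_trial <- vapply(1:50, function(i) {
    nrow(seeded_local_search(dna_set(d = random_seq(200)), subj,
                             index = idx))
  }, integer(1))
  expect_true(all(hits_per_trial == 0L))
})

test_that("queries shorter than the word size warn and return nothing", {
  subj <- dna_set(chrX = random_seq(1000))
  expect_warning(h <- seeded_local_search(dna_set(tiny = "ACGTAC"), subj),
                 "word size")
  expect_equal(nrow(h), 0L)
})

mk_hits <- function(s_start, s_end, strand = "+", subject_id = "c1",
                    bitscore = 100, evalue = 1e-30) {
  n <- length(s_start)
  data.frame(query_id = "q", q_start = rep(1L, n), q_end = rep(100L, n),
             subject_id = rep(subject_id, length.out = n),
             s_start = s_start, s_end = s_end,
             strand = rep(strand, length.out = n),
             score = rep(50, n),
             bitscore = rep(bitscore, length.out = n),
             evalue = rep(evalue, length.out = n),
             pident = rep(95, n), stringsAsFactors = FALSE)
}

test_that("hit merging chains nearby same-strand hits", {
  cfg <- linckit_config()
  h <- mk_hits(c(1000, 1500), c(1200, 1700), bitscore = c(80, 120))
  m <- merge_hits(h, cfg)   # gap 300 within merge_gap
  expect_equal(nrow(m), 1L)
  expect_equal(m$total_bitscore, 200)
  expect_equal(c(m$s_start, m$s_end), c(1000L, 1700L))
  expect_equal(m$n_members, 2L)

  h2 <- mk_hits(c(1000, 1500), c(1200, 1700), strand = c("+", "-"))
  expect_equal(nrow(merge_hits(h2, cfg)), 2L)

  h3 <- mk_hits(c(1000, 60000), c(1200, 60200))
  expect_equal(nrow(merge_hits(h3, cfg)), 2L)
})

test_that("hit merging is independent of input order", {
  cfg <- linckit_config()
  set.seed(9)
  h <- mk_hits(s_start = sample(seq(1000, 900000, by = 7000), 30),
               s_end = sample(seq(1000, 900000, by = 7000), 30) + 500,
               bitscore = runif(30, 50, 200))
  h$s_end <- h$s_start + 400L
  m1 <- merge_hits(h, cfg)
  m2 <- merge_hits(h[sample(nrow(h)), ], cfg)
  expect_equal(m1[, setdiff(names(m1), "members")],
               m2[, setdiff(names(m2), "members")])
})

test_that("top-hit selection is deterministic with documented tie-breaks", {
  cfg <- linckit_config()
  loci <- merge_hits(mk_hits(c(1000, 60000), c(1400, 60400),
                             bitscore = c(400, 300)), cfg)
  expect_equal(select_tbh(loci)$s_start, 1000L)
  # exact tie on score and E: leftmost coordinate wins
  tie <- merge_hits(mk_hits(c(70000, 2000), c(70400, 2400),
                            bitscore = c(250, 250)), cfg)
  expect_equal(select_tbh(tie)$s_start, 2000L)
  expect_null(select_tbh(merge_hits(mk_hits(1000, 1200)[0, ], cfg)))
})

test_that("query segmentation drops sub-minimum remainders", {
  cfg <- linckit_config()
  s650 <- segment_query(dna_set(p = random_seq(650)), cfg)
  expect_equal(length(s650), 3L)             # 50-nt remainder dropped
  expect_equal(S4Vectors::mcols(s650)$offset, c(1L, 201L, 401L))
  expect_true(all(grepl("^p\\.seg", names(s650))))

  s400 <- segment_query(dna_set(p = random_seq(400)), cfg)
  expect_equal(length(s400), 2L)

  # 250-nt query: the 50-nt remainder is below min_segment_len
  s250 <- segment_query(dna_set(p = random_seq(250)), cfg)
  expect_equal(length(s250), 1L)

  # remainder at the minimum is kept
  s300 <- segment_query(dna_set(p = random_seq(300)), cfg)
  expect_equal(length(s300), 2L)
  expect_equal(Biostrings::width(s300), c(200L, 100L))
})

test_that("genome search finds partial-coverage homologs with correct
          query coordinates", {
  set.seed(77)
  q <- random_seq(650)
  core <- substr(q, 301, 500)
  subj <- dna_set(chr1 = paste0(random_seq(5000), core, random_seq(5000)))
  res <- search_query_genome(dna_set(p = q), subj)
  expect_false(is.null(res$tbh))
  m <- res$tbh$members[[1]]
  expect_equal(min(m$q_start), 301L)
  expect_equal(max(m$q_end), 500L)
  # a hopeless query goes through the segmented fallback and still
  # returns nothing
  res2 <- search_query_genome(dna_set(p = random_seq(650)), subj)
  expect_true(res2$segmented)
  expect_null(res2$tbh)
})

test_that("reciprocity accepts orthologs and rejects paralogs", {
  set.seed(78)
  base <- random_seq(500)
  qA <- base
  qB <- paste(mutate_chars(base, 0.08), collapse = "")
  qgenome <- dna_set(chr1 = paste0(random_seq(3000), qA, random_seq(15000),
                                   qB, random_seq(3000)))
  qA_locus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3001, 3500))
  names(qA_locus) <- "qA"
  # subject carries a near-exact copy of qA: reciprocal
  subjA <- dna_set(chr1 = paste0(random_seq(4000),
                                 paste(mutate_chars(base, 0.02),
                                       collapse = ""),
                                 random_seq(4000)))
  resA <- search_query_genome(dna_set(qA = qA), subjA)
  expect_true(reciprocity_test(resA$tbh, subjA, qgenome, qA_locus))
  # subject carries a copy derived from the paralog qB: its reciprocal
  # top hit is qB's locus, not qA's
  subjB <- dna_set(chr1 = paste0(random_seq(4000),
                                 paste(mutate_chars(strsplit(qB, "")[[1]],
                                                    0.02), collapse = ""),
                                 random_seq(4000)))
  resB <- search_query_genome(dna_set(qA = qA), subjB)
  expect_false(is.null(resB$tbh))
  expect_false(reciprocity_test(resB$tbh, subjB, qgenome, qA_locus))
  # a hit with no reciprocal match above the cutoff fails
  fake <- resA$tbh
  fake$s_start <- 1L; fake$s_end <- 400L   # random region of subjA
  expect_false(reciprocity_test(fake, subjA, qgenome, qA_locus))
  # unknown query locus: skipped with a warning
  expect_warning(r <- reciprocity_test(resA$tbh, subjA, qgenome, NULL),
                 "skipped")
  expect_true(is.na(r))
})
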