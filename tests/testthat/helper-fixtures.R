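# shared fixtures, built once per test run
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) assign(key, force(expr), envir = .cache)
  .cache[[key]]
}

# a small identification fixture exercising every class
small_identify_fixture <- function() {
  cached("identify_fx", make_identify_fixture(identify_fixture_spec(seed = 101)))
}

small_identify_result <- function() {
  cached("identify_res", {
    fx <- small_identify_fixture()
    run_identify(fx$transcripts, fx$genome, fx$annotation,
                 te_db = fx$te_db, tss = fx$tss,
                 known_lincrna = fx$known_lincrna)
  })
}

# a small panel (4 species, 6 queries, one query restricted to the two
# shallowest species via planted losses)
small_panel_fixture <- function() {
  cached("panel_fx", make_panel_fixture(panel_fixture_spec(
    seed = 202, n_species = 4, genome_len = 30000, n_queries = 6,
    sub_rate = 0.03,
    losses = list(list(query = 1, clade = "spC"),
                  list(query = 1, clade = "spD")))))
}

small_panel_families <- function() {
  cached("panel_fams", {
    fx <- small_panel_fixture()
    build_families(fx$queries, fx$panel, query_loci = fx$query_loci)
  })
}

dna_set <- function(...) {
  x <- c(...)
  out <- Biostrings::DNAStringSet(unname(x))
  names(out) <- names(x)
  out
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# per-site substitutions on a DNA string or character vector
mutate_chars <- function(x, rate) {
  if (is.character(x) && length(x) == 1L) x <- strsplit(x, "")[[1L]]
  hit <- which(stats::runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  x
}
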