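#' Align a homolog family
#'
#' Multiple alignment of a family's sequences. By default an internal
#' star-alignment is used: every sequence is globally aligned to the
#' longest member and gaps are propagated into a common profile, so all
#' input residues appear, in order, in the output rows. When a `mafft`
#' executable is available it can be used instead (run with
#' `--maxiterate 1000`).
#'
#' @param seqs Named `DNAStringSet` with >= 2 sequences (e.g. from
#'   [family_sequences()]).
#' @param method "internal" (default) or "mafft".
#' @param cfg A [linckit_config] (scoring for the internal aligner).
#' @return A gapped `DNAStringSet` (all rows equal width), of class also
#'   usable with `Biostrings::DNAMultipleAlignment`.
#' @export
align_family <- function(seqs, method = c("internal", "mafft"), cfg = NULL) {
  method <- match.arg(method)
  cfg <- as_config(cfg)
  if (length(seqs) < 2L)
    stop("alignment needs at least 2 sequences", call. = FALSE)
  if (method == "mafft") return(align_family_mafft(seqs))

  center_i <- which.max(Biostrings::width(seqs))
  center <- seqs[[center_i]]
  L <- length(center)
  others <- setdiff(seq_along(seqs), center_i)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = cfg$match, mismatch = cfg$mismatch, baseOnly = FALSE)

  # per-pair: characters of the other sequence at each center junction
  # (junction i = between center residues i and i+1; 0 = before start)
  pair_data <- lapply(others, function(i) {
    aln <- Biostrings::pairwiseAlignment(
      seqs[[i]], center, type = "global", substitutionMatrix = submat,
      gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    ins <- vector("list", L + 1L)   # insertions after junction 0..L
    aligned <- character(L)          # residue aligned to center pos
    cpos <- 0L
    buf <- character(0)
    for (j in seq_along(sa)) {
      if (sa[j] == "-") {
        buf <- c(buf, pa[j])
      } else {
        ins[[cpos + 1L]] <- buf
        buf <- character(0)
        cpos <- cpos + 1L
        aligned[cpos] <- pa[j]
      }
    }
    ins[[cpos + 1L]] <- buf
    list(ins = ins, aligned = aligned)
  })
  ins_len <- integer(L + 1L)
  for (pd in pair_data)
    ins_len <- pmax(ins_len, vapply(pd$ins, length, integer(1)))

  build_row <- function(aligned, ins) {
    parts <- character(0)
    for (i in 0:L) {
      g <- ins[[i + 1L]]
      if (is.null(g)) g <- character(0)
      parts <- c(parts, g, rep("-", ins_len[i + 1L] - length(g)))
      if (i < L) parts <- c(parts, aligned[i + 1L])
    }
    paste(parts, collapse = "")
  }
  rows <- character(length(seqs))
  center_chars <- strsplit(as.character(center), "")[[1L]]
  rows[center_i] <- build_row(center_chars,
                              rep(list(character(0)), L + 1L))
  for (j in seq_along(others))
    rows[others[j]] <- build_row(pair_data[[j]]$aligned,
                                 pair_data[[j]]$ins)
  out <- Biostrings::DNAStringSet(rows)
  names(out) <- names(seqs)
  out
}

align_family_mafft <- function(seqs) {
  mafft <- Sys.which("mafft")
  if (!nzchar(mafft))
    stop("mafft executable not found on PATH", call. = FALSE)
  tf <- tempfile(fileext = ".fa"); of <- tempfile(fileext = ".fa")
  on.exit(unlink(c(tf, of)))
  write_fasta(seqs, tf)
  status <- system2(mafft, c("--maxiterate", "1000", "--quiet", tf),
                    stdout = of)
  if (status != 0L) stop("mafft failed with status ", status, call. = FALSE)
  aln <- Biostrings::readDNAStringSet(of)
  names(aln) <- sub("\\s.*$", "", names(aln))
  Biostrings::DNAStringSet(toupper(as.character(aln)))
}

#' Infer a gene tree with bootstrap support
#'
#' Neighbour joining on p-distances (gaps treated as missing data,
#' pairwise deletion) with nonparametric bootstrap over alignment
#' columns. Supports, in percent, are attached as node labels of the
#' internal edges.
#'
#' @param alignment Gapped `DNAStringSet` (>= 3 rows) from
#'   [align_family()].
#' @param bootstrap Number of bootstrap replicates (default
#'   `cfg$bootstrap_n`).
#' @param cfg A [linckit_config]; `cfg$seed` fixes the resampling.
#' @return An `ape::phylo` (unrooted), `node.label` carrying bootstrap
#'   percentages.
#' @export
infer_gene_tree <- function(alignment, bootstrap = NULL, cfg = NULL) {
  cfg <- as_config(cfg)
  if (is.null(bootstrap)) bootstrap <- cfg$bootstrap_n
  n <- length(alignment)
  if (n < 3L) stop("gene-tree inference needs >= 3 sequences",
                   call. = FALSE)
  mat <- do.call(rbind, strsplit(tolower(as.character(alignment)), ""))
  rownames(mat) <- names(alignment)
  bin <- ape::as.DNAbin(mat)
  dfun <- function(x) {
    d <- ape::dist.dna(x, model = "raw", pairwise.deletion = TRUE)
    d[is.na(d) | is.nan(d)] <- 1
    ape::nj(d)
  }
  tree <- dfun(bin)
  if (bootstrap > 0L) {
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    bp <- ape::boot.phylo(tree, bin, dfun, B = bootstrap, quiet = TRUE)
    tree$node.label <- round(bp / bootstrap * 100)
    tree$node.label[1L] <- NA  # root of the unrooted representation
  }
  tree
}

# ---- reconciliation ------------------------------------------------------

# internal recursive tree node representation
phylo_to_node <- function(tree) {
  nt <- ape::Ntip(tree)
  labs <- tree$node.label
  build <- function(i) {
    if (i <= nt) return(list(leaf = TRUE, label = tree$tip.label[i]))
    kids <- tree$edge[tree$edge[, 1L] == i, 2L]
    sup <- if (!is.null(labs)) suppressWarnings(
      as.numeric(labs[i - nt])) else NA_real_
    list(leaf = FALSE, support = sup, children = lapply(kids, build))
  }
  build(nt + 1L)
}

node_to_newick <- function(node) {
  rec <- function(n) {
    if (isTRUE(n$leaf)) return(n$label)
    lab <- if (!is.null(n$event) && n$event == "D") "D" else ""
    paste0("(", paste(vapply(n$children, rec, character(1)),
                      collapse = ","), ")", lab)
  }
  paste0(rec(node), ";")
}

# species-tree bookkeeping: parent pointers, depths, tip mapping
species_index <- function(stree) {
  stopifnot(ape::is.rooted(stree))
  nt <- ape::Ntip(stree)
  nn <- nt + stree$Nnode
  parent <- integer(nn)
  parent[stree$edge[, 2L]] <- stree$edge[, 1L]
  root <- nt + 1L
  parent[root] <- 0L
  # compute depths by sweeping edges until all settle (edge order in a
  # phylo object is not guaranteed top-down)
  depth <- integer(nn)
  depth[root] <- 0L
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(stree$edge))) {
      p <- stree$edge[e, 1L]; c <- stree$edge[e, 2L]
      if (depth[c] == 0L && c != root) {
        if (p == root || depth[p] > 0L) depth[c] <- depth[p] + 1L
        else done <- FALSE
      }
    }
    if (done) break
  }
  list(parent = parent, depth = depth, root = root, ntip = nt,
       tips = stats::setNames(seq_len(nt), stree$tip.label))
}

species_lca <- function(si, a, b) {
  while (a != b) {
    if (si$depth[a] > si$depth[b]) a <- si$parent[a]
    else if (si$depth[b] > si$depth[a]) b <- si$parent[b]
    else { a <- si$parent[a]; b <- si$parent[b] }
  }
  a
}

#' Map gene-tree leaf labels to species
#'
#' Leaves named exactly after a species map directly; otherwise the
#' species name is looked for as a delimited token or substring of the
#' leaf label (homolog ids are of the form
#' `<query>_<species>_<labels>`).
#'
#' @param leaves Character vector of gene-tree tip labels.
#' @param species Character vector of species-tree tip labels.
#' @return Named character vector: species per leaf.
#' @export
map_leaves_to_species <- function(leaves, species) {
  out <- vapply(leaves, function(lf) {
    if (lf %in% species) return(lf)
    hit <- species[vapply(species, function(s)
      grepl(s, lf, fixed = TRUE), logical(1))]
    if (length(hit) == 0L) return(NA_character_)
    hit[which.max(nchar(hit))]
  }, character(1))
  if (anyNA(out))
    stop("gene-tree leaf/leaves map to no species-tree tip: ",
         paste(leaves[is.na(out)], collapse = ", "), call. = FALSE)
  out
}

collapse_weak_edges <- function(node, threshold) {
  if (isTRUE(node$leaf)) return(node)
  node$children <- lapply(node$children, collapse_weak_edges, threshold)
  kids <- list()
  for (ch in node$children) {
    weak <- !isTRUE(ch$leaf) && !is.null(ch$support) &&
      !is.na(ch$support) && ch$support < threshold
    if (weak) kids <- c(kids, ch$children) else kids <- c(kids, list(ch))
  }
  node$children <- kids
  node
}

# resolve multifurcations guided by the species tree: repeatedly join the
# pair of children whose species mapping has the deepest LCA
resolve_polytomies <- function(node, si, leafmap) {
  if (isTRUE(node$leaf)) return(node)
  node$children <- lapply(node$children, resolve_polytomies, si, leafmap)
  while (length(node$children) > 2L) {
    maps <- vapply(node$children, function(ch)
      node_species_map(ch, si, leafmap), integer(1))
    best <- c(1L, 2L); bestd <- -1L
    nch <- length(node$children)
    for (i in seq_len(nch - 1L)) for (j in (i + 1L):nch) {
      d <- si$depth[species_lca(si, maps[i], maps[j])]
      if (d > bestd) { bestd <- d; best <- c(i, j) }
    }
    newn <- list(leaf = FALSE, support = NA_real_,
                 children = node$children[best])
    node$children <- c(node$children[-best], list(newn))
  }
  node
}

node_species_map <- function(node, si, leafmap) {
  if (isTRUE(node$leaf)) return(si$tips[[leafmap[[node$label]]]])
  maps <- vapply(node$children, node_species_map, integer(1), si, leafmap)
  m <- maps[1L]
  for (k in maps[-1L]) m <- species_lca(si, m, k)
  m
}

#' Reconcile a gene tree with a species tree
#'
#' Standard last-common-ancestor (LCA) mapping: each gene-tree node maps
#' to the LCA of its leaves' species; a node is a duplication when it
#' maps to the same species-tree node as one of its children; losses are
#' counted from the depth gaps along each child edge (a speciation child
#' edge spanning k species-tree edges implies k-1 losses, a duplication
#' child edge k losses). Before mapping, internal gene-tree edges with
#' bootstrap support below `threshold` are collapsed and the resulting
#' polytomies re-resolved guided by the species tree, so weakly supported
#' conflict does not inflate the event count.
#'
#' @param gene_tree `ape::phylo`, node labels carrying bootstrap support
#'   (may be unrooted: every rooting is then tried and the minimum-event
#'   one kept).
#' @param species_tree Rooted `ape::phylo`.
#' @param threshold Bootstrap threshold for collapsing (default
#'   `cfg$bootstrap_threshold`, 70).
#' @param cfg A [linckit_config].
#' @return An object of class `linckit_reconciliation`: list with
#'   `duplications`, `losses`, `events` (data.frame of D events and
#'   per-edge loss counts), `annotated_newick` (gene tree with `D` marks
#'   on duplication nodes), `gene_tree`, `species_tree`.
#' @export
reconcile <- function(gene_tree, species_tree, threshold = NULL,
                      cfg = NULL) {
  cfg <- as_config(cfg)
  if (is.null(threshold)) threshold <- cfg$bootstrap_threshold
  if (!ape::is.rooted(species_tree))
    stop("species tree must be rooted", call. = FALSE)
  si <- species_index(species_tree)
  leafmap <- map_leaves_to_species(gene_tree$tip.label,
                                   species_tree$tip.label)

  run_one <- function(gt) {
    node <- phylo_to_node(gt)
    node <- collapse_weak_edges(node, threshold)
    node <- resolve_polytomies(node, si, leafmap)
    score_node(node, si, leafmap)
  }

  if (ape::is.rooted(gene_tree)) {
    best <- run_one(gene_tree)
  } else {
    # try all rootings, keep the minimum-event one
    roots <- all_rootings(gene_tree)
    best <- NULL
    for (gt in roots) {
      r <- run_one(gt)
      if (is.null(best) ||
          (r$duplications + r$losses) < (best$duplications + best$losses))
        best <- r
    }
  }
  structure(c(best, list(gene_tree = gene_tree,
                         species_tree = species_tree,
                         threshold = threshold)),
            class = "linckit_reconciliation")
}

all_rootings <- function(tree) {
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    gt <- tryCatch(
      ape::root(tree, node = tree$edge[e, 2L], resolve.root = TRUE,
                edgelabel = TRUE),
      error = function(err) NULL)
    if (is.null(gt))
      gt <- tryCatch(
        if (tree$edge[e, 2L] <= ape::Ntip(tree))
          ape::root(tree, outgroup = tree$tip.label[tree$edge[e, 2L]],
                    resolve.root = TRUE, edgelabel = TRUE) else NULL,
        error = function(err) NULL)
    if (!is.null(gt) && ape::is.rooted(gt)) out[[length(out) + 1L]] <- gt
  }
  if (length(out) == 0L) out <- list(phangorn::midpoint(tree))
  out
}

# LCA mapping + event counting on the internal node representation
score_node <- function(node, si, leafmap) {
  dups <- 0L
  losses <- 0L
  events <- list()
  annotate <- function(n) {
    if (isTRUE(n$leaf)) {
      n$map <- si$tips[[leafmap[[n$label]]]]
      return(n)
    }
    n$children <- lapply(n$children, annotate)
    maps <- vapply(n$children, function(ch) ch$map, integer(1))
    m <- maps[1L]
    for (k in maps[-1L]) m <- species_lca(si, m, k)
    n$map <- m
    is_dup <- any(maps == m)
    n$event <- if (is_dup) "D" else "S"
    if (is_dup) {
      dups <<- dups + 1L
      events[[length(events) + 1L]] <<- data.frame(
        event = "D", species_node = species_node_label(si, m),
        stringsAsFactors = FALSE)
    }
    for (ch in n$children) {
      k <- si$depth[ch$map] - si$depth[m]
      nl <- if (is_dup) k else k - 1L
      if (nl > 0L) {
        losses <<- losses + nl
        events[[length(events) + 1L]] <<- data.frame(
          event = "L", species_node = species_node_label(si, ch$map),
          stringsAsFactors = FALSE)
      }
    }
    n
  }
  node <- annotate(node)
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(event = character(0), species_node = character(0),
               stringsAsFactors = FALSE)
  list(duplications = dups, losses = losses, events = ev,
       annotated_newick = node_to_newick(node))
}

species_node_label <- function(si, m) {
  if (m <= si$ntip) names(si$tips)[m] else paste0("ancestor", m)
}

#' @export
print.linckit_reconciliation <- function(x, ...) {
  cat("gene/species tree reconciliation\n")
  cat("  duplications:", x$duplications, "  losses:", x$losses, "\n")
  cat("  annotated tree:", x$annotated_newick, "\n")
  invisible(x)
}
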