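# Independent brute-force duplication-loss reconciliation oracle over the
# fixed species tree ((A,B),C), plus an exhaustive enumerator of distinct
# gene trees with species-labelled leaves. Used by the phylogenetics and
# acceptance tests.

# species tree ((A,B),C) encoded by parent pointers; nodes:
# 1=A 2=B 3=C 4=AB 5=ABC
sp_parent <- c(4L, 4L, 5L, 5L, 0L)
sp_depth <- c(2L, 2L, 1L, 1L, 0L)
sp_anc <- function(x) { out <- x; while (sp_parent[x] != 0L) { x <- sp_parent[x]; out <- c(out, x) }; out }
sp_lca <- function(a, b) {
  aa <- sp_anc(a)
  for (x in sp_anc(b)) if (x %in% aa) return(x)
}
sp_child_of <- function(anc, x) {  # which child subtree of anc holds x
  while (sp_parent[x] != 0L && sp_parent[x] != anc) x <- sp_parent[x]
  x
}

# gene trees as nested lists: leaf = species id 1..3
enum_trees <- function(n) {
  if (n == 1L) return(as.list(1:3))
  out <- list()
  seen <- character(0)
  canon <- function(t) if (is.list(t))
    paste0("(", paste(sort(vapply(t, canon, character(1))),
                      collapse = ","), ")") else as.character(t)
  for (k in 1:(n - 1L)) {
    for (l in enum_trees(k)) for (r in enum_trees(n - k)) {
      t <- list(l, r)
      key <- canon(t)
      if (!key %in% seen) { seen <- c(seen, key); out[[length(out) + 1L]] <- t }
    }
  }
  out
}

# minimum duplication+loss cost by exhaustive enumeration of valid
# mappings (speciation iff the children map into distinct child subtrees)
brute_min_cost <- function(t) {
  nodes <- list(); idx <- 0L
  flatten <- function(t) {
    if (!is.list(t)) {
      idx <<- idx + 1L
      nodes[[idx]] <<- list(leaf = TRUE, sp = t)
      return(idx)
    }
    kl <- flatten(t[[1]]); kr <- flatten(t[[2]])
    idx <<- idx + 1L
    nodes[[idx]] <<- list(leaf = FALSE, kids = c(kl, kr))
    idx
  }
  flatten(t)
  internal <- which(!vapply(nodes, `[[`, logical(1), "leaf"))
  leafmap <- integer(length(nodes))
  for (i in seq_along(nodes)) if (nodes[[i]]$leaf) leafmap[i] <- nodes[[i]]$sp
  lca_of <- function(i) {
    if (nodes[[i]]$leaf) return(leafmap[i])
    k <- nodes[[i]]$kids
    sp_lca(lca_of(k[1]), lca_of(k[2]))
  }
  cands <- lapply(seq_along(nodes), function(i)
    if (nodes[[i]]$leaf) leafmap[i] else sp_anc(lca_of(i)))
  best <- Inf
  assign_next <- function(pos, M) {
    if (pos > length(internal)) {
      cost <- 0L
      for (v in internal) {
        k <- nodes[[v]]$kids
        # validity: M[v] must be ancestor-or-equal of each child's map
        for (c in k) if (!(M[v] %in% sp_anc(M[c]))) return(invisible(NULL))
        dup <- M[v] == M[k[1]] || M[v] == M[k[2]] ||
          sp_child_of(M[v], M[k[1]]) == sp_child_of(M[v], M[k[2]])
        if (dup) cost <- cost + 1L
        for (c in k) {
          d <- sp_depth[M[c]] - sp_depth[M[v]]
          cost <- cost + if (dup) d else d - 1L
        }
        if (cost >= best) return(invisible(NULL))
      }
      best <<- min(best, cost)
      return(invisible(NULL))
    }
    v <- internal[pos]
    for (m in cands[[v]]) { M[v] <- m; assign_next(pos + 1L, M) }
  }
  M0 <- integer(length(nodes))
  for (i in seq_along(nodes)) if (nodes[[i]]$leaf) M0[i] <- leafmap[i]
  assign_next(1L, M0)
  best
}

tree_to_newick <- function(t, counter = new.env()) {
  lab <- function(t) {
    if (!is.list(t)) {
      sp <- c("A", "B", "C")[t]
      n <- get0(sp, envir = counter, inherits = FALSE,
                ifnotfound = 0L) + 1L
      assign(sp, n, envir = counter)
      paste0(sp, "cp", n)
    } else paste0("(", lab(t[[1]]), ",", lab(t[[2]]), ")")
  }
  paste0(lab(t), ";")
}

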