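# Independent brute-force oracles. Each re-derives the quantity under test
# from first principles (enumeration or the direct formula), sharing no code
# with the implementation it checks.

# --- tree bookkeeping (re-derived, independent of the package internals) ---

tree_parents <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  p <- integer(n)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

tree_ancestors_self <- function(v, parents) {
  out <- v
  while (parents[v] != 0) {
    v <- parents[v]
    out <- c(out, v)
  }
  out
}

tree_lca <- function(nodes, parents) {
  paths <- lapply(nodes, tree_ancestors_self, parents = parents)
  common <- Reduce(intersect, paths)
  common[1]  # first common ancestor along the upward path = deepest
}

tree_children <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

tips_under <- function(v, ch) {
  if (is.null(ch[[v]])) return(v)
  unlist(lapply(ch[[v]], tips_under, ch = ch))
}

# --- reconciliation oracle: minimum duplications + losses over every valid
# map of gene-tree internal nodes to species-tree nodes -------------------

oracle_min_reconciliation_cost <- function(gtree, stree, gene_species) {
  sp_par <- tree_parents(stree)
  sp_ch <- tree_children(stree)
  g_ch <- tree_children(gtree)
  g_par <- tree_parents(gtree)
  g_ntip <- length(gtree$tip.label)
  internal <- which(vapply(g_ch, length, 1L) > 0)
  # postorder: children before parents
  ord <- internal[order(-vapply(internal, function(v)
    length(tree_ancestors_self(v, g_par)), 1L))]
  leaf_map <- match(gene_species[gtree$tip.label], stree$tip.label)

  path_len <- function(anc, des) {
    d <- 0
    while (des != anc) {
      des <- sp_par[des]
      d <- d + 1
    }
    d
  }
  under <- function(x, anc) anc %in% tree_ancestors_self(x, sp_par)

  cost_of <- function(map) {
    M <- function(v) if (v <= g_ntip) leaf_map[v] else map[[as.character(v)]]
    dup <- 0; loss <- 0
    for (v in ord) {
      kids <- g_ch[[v]]
      mv <- M(v)
      mk <- vapply(kids, M, 1L)
      is_spec <- FALSE
      if (all(mk != mv)) {
        # speciation iff children map under two distinct children of mv
        holders <- vapply(mk, function(m) {
          for (c_ in sp_ch[[mv]]) if (under(m, c_)) return(c_)
          NA_integer_
        }, 1L)
        is_spec <- !anyNA(holders) && holders[1] != holders[2]
      }
      if (!is_spec) dup <- dup + 1
      for (kk in seq_along(kids)) {
        d <- path_len(mv, mk[kk])
        loss <- loss + if (is_spec) max(0, d - 1) else d
      }
    }
    dup + loss
  }

  best <- Inf
  assign_next <- function(i, map) {
    if (i > length(ord)) {
      best <<- min(best, cost_of(map))
      return(invisible())
    }
    v <- ord[i]
    kids_imgs <- vapply(g_ch[[v]], function(k)
      if (k <= g_ntip) leaf_map[k] else map[[as.character(k)]], 1L)
    lo <- tree_lca(as.list(kids_imgs), sp_par)
    for (cand in tree_ancestors_self(lo, sp_par)) {
      map[[as.character(v)]] <- cand
      assign_next(i + 1, map)
    }
  }
  assign_next(1, list())
  best
}

# --- Dollo oracle: min losses over all gain placements and loss sets -----

oracle_min_dollo_losses <- function(tree, present_species) {
  parents <- tree_parents(tree)
  ch <- tree_children(tree)
  present_tips <- match(present_species, tree$tip.label)
  gains <- tree_ancestors_self(tree_lca(as.list(present_tips), parents),
                               parents)
  best <- Inf
  for (g in gains) {
    below <- setdiff(unlist(lapply(ch[[g]], function(c_)
      c(c_, setdiff(tree_ancestors_self_all(c_, ch), c_)))), integer(0))
    below <- unique(below)
    nb <- length(below)
    for (mask in 0:(2^nb - 1)) {
      S <- below[bitwAnd(mask, 2^(seq_len(nb) - 1)) > 0]
      if (length(S) >= best) next
      ok <- TRUE
      for (tip in seq_along(tree$tip.label)) {
        path <- tree_ancestors_self(tip, parents)
        reachable <- g %in% path && !any(S %in% setdiff(path,
          tree_ancestors_self(g, parents)))
        if (reachable != (tip %in% present_tips)) { ok <- FALSE; break }
      }
      if (ok) best <- min(best, length(S))
    }
  }
  best
}

tree_ancestors_self_all <- function(v, ch) {
  # all nodes in the subtree rooted at v (descendants incl. v)
  if (is.null(ch[[v]])) return(v)
  c(v, unlist(lapply(ch[[v]], tree_ancestors_self_all, ch = ch)))
}

# --- collinear chaining oracle: best monotone chain by subset search ------

oracle_best_chain_genes <- function(pairs, pos, max_rank_gap) {
  ra <- pos$rank[match(pairs$gene_a, pos$gene_id)]
  rb <- pos$rank[match(pairs$gene_b, pos$gene_id)]
  n <- nrow(pairs)
  valid <- function(idx, orient) {
    o <- idx[order(ra[idx])]
    da <- diff(ra[o])
    db <- diff(rb[o]) * if (orient == "same") 1 else -1
    all(da >= 1 & da <= max_rank_gap & db >= 1 & db <= max_rank_gap)
  }
  best <- integer(0)
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= length(best)) next
    if (valid(idx, "same") || valid(idx, "inverted")) best <- idx
  }
  sort(unique(c(pairs$gene_a[best], pairs$gene_b[best])))
}

# --- hypergeometric enrichment oracle: full enumeration of draws ----------

oracle_hypergeom_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  special <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% special) >= k))
}

# --- PCC direct-formula oracle -------------------------------------------

oracle_pcc <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# --- HSE sliding-window oracle -------------------------------------------

oracle_hse_hits <- function(seq, both_strands = TRUE) {
  comp <- function(s) chartr("ACGT", "TGCA", s)
  is_hse <- function(w) {
    ch <- strsplit(w, "")[[1]]
    all(ch %in% c("A", "C", "G", "T")) &&
      all(ch[c(1, 2, 3, 11, 12, 13)] == c("G", "A", "A", "G", "A", "A")) &&
      all(ch[6:7] == c("T", "T"))
  }
  out <- list()
  L <- nchar(seq)
  for (i in seq_len(max(0, L - 12))) {
    w <- substr(seq, i, i + 12)
    if (is_hse(w))
      out[[length(out) + 1]] <- data.frame(offset = i - 1, strand = "+")
    if (both_strands) {
      rc <- paste(rev(strsplit(comp(w), "")[[1]]), collapse = "")
      if (is_hse(rc))
        out[[length(out) + 1]] <- data.frame(offset = i - 1, strand = "-")
    }
  }
  if (!length(out)) return(data.frame(offset = integer(),
                                      strand = character()))
  do.call(rbind, out)
}

# random uniform DNA of given length
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
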