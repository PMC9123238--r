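# Internal helpers over ape "phylo" trees. Branches are identified throughout
# by the label of the node below them (leaf label, or node label; unlabeled
# internal nodes get deterministic "N<k>" labels in ape node order).

ensure_node_labels <- function(tree) {
  nint <- tree$Nnode
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)) ||
      anyNA(tree$node.label)) {
    lab <- if (is.null(tree$node.label)) rep("", nint) else tree$node.label
    lab[is.na(lab)] <- ""
    fill <- paste0("N", seq_len(nint))
    lab[!nzchar(lab)] <- fill[!nzchar(lab)]
    tree$node.label <- lab
  }
  if (anyDuplicated(c(tree$tip.label, tree$node.label)))
    stop("tree labels are not unique")
  tree
}

node_labels <- function(tree) c(tree$tip.label, tree$node.label)

parent_vec <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  p <- integer(n)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p  # 0 for the root
}

children_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1L]]] <- c(ch[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  ch
}

node_depths <- function(tree) {
  # edges from the root, root = 0
  n <- length(tree$tip.label) + tree$Nnode
  p <- parent_vec(tree)
  d <- rep(NA_integer_, n)
  root <- which(p == 0L)
  d[root] <- 0L
  # ape edge matrices are not guaranteed preorder; iterate to convergence
  repeat {
    todo <- which(is.na(d))
    if (!length(todo)) break
    d[todo] <- d[p[todo]] + 1L
  }
  d
}

ancestors_or_self <- function(node, parent) {
  out <- node
  while (parent[node] != 0L) {
    node <- parent[node]
    out <- c(out, node)
  }
  out
}

lca2 <- function(a, b, parent, depth) {
  while (a != b) {
    if (depth[a] >= depth[b]) a <- parent[a] else b <- parent[b]
  }
  a
}

lca_set <- function(nodes, parent, depth) Reduce(
  function(a, b) lca2(a, b, parent, depth), nodes)

is_binary_rooted <- function(tree) {
  ch <- children_list(tree)
  internal <- which(vapply(ch, length, 1L) > 0L)
  all(vapply(ch[internal], length, 1L) == 2L)
}

# deterministic structural fingerprint used to verify two phylo objects
# describe the same species tree
tree_fingerprint <- function(tree) {
  tree <- ensure_node_labels(tree)
  ch <- children_list(tree)
  lab <- node_labels(tree)
  rec <- function(v) {
    if (is.null(ch[[v]])) return(lab[v])
    paste0("(", paste(sort(vapply(ch[[v]], rec, "")), collapse = ","),
           ")", lab[v])
  }
  p <- parent_vec(tree)
  rec(which(p == 0L))
}
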