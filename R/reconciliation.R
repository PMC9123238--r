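#' LCA-mapping reconciliation of a gene tree against a species tree
#'
#' Maps every gene-tree node `v` to the lowest common ancestor (in the
#' species tree) of the species below `v`. An internal node is a duplication
#' when it maps to the same species node as one of its children, otherwise a
#' speciation. For a gene-tree edge `u -> v` whose mappings are `d` species
#' branches apart, the implied number of losses is `d - 1` when `u` is a
#' speciation and `d` when `u` is a duplication; each loss is attributed to
#' the off-path child branch at the species node where the gene lineage
#' failed to survive. Duplications are attributed to the branch above the
#' species node a duplication node maps to. This is the most-parsimonious
#' (minimum duplication + loss) reconciliation.
#'
#' The species tree may contain polytomies; at a multifurcating species node
#' every off-path child counts one loss. Gene trees must be rooted and
#' strictly binary.
#'
#' @param gtree rooted binary gene tree (`phylo`), tips labeled by gene id.
#' @param stree rooted species tree (`phylo`), tips labeled by species id.
#' @param gene_species named character vector gene id -> species id, or a
#'   function applied to tip labels (e.g. a prefix extractor).
#' @return object of class `reconciliation`: list with `branches` (data.frame
#'   `branch`, `duplications`, `losses`, `annotation`, one row per species
#'   branch, identified by the label of the node below it; the root label row
#'   is the stem branch), `events` (one row per internal gene-tree node:
#'   `node`, `event`, `maps_to`), and totals `n_duplications`, `n_losses`.
#' @export
lca_reconcile <- function(gtree, stree, gene_species) {
  if (!ape::is.rooted(gtree)) stop("gene tree must be rooted")
  if (!ape::is.rooted(stree)) stop("species tree must be rooted")
  if (!is_binary_rooted(gtree))
    stop("gene tree must be strictly binary")
  stree <- ensure_node_labels(stree)

  if (is.function(gene_species)) {
    gene_species <- stats::setNames(
      vapply(gtree$tip.label, gene_species, ""), gtree$tip.label)
  }
  tip_sp <- gene_species[gtree$tip.label]
  if (anyNA(tip_sp) || any(!tip_sp %in% stree$tip.label)) {
    bad <- gtree$tip.label[is.na(tip_sp) | !tip_sp %in% stree$tip.label][1L]
    stop("gene-tree leaf cannot be mapped to a species-tree tip: ", bad)
  }

  sp_par <- parent_vec(stree)
  sp_dep <- node_depths(stree)
  sp_ch <- children_list(stree)
  sp_lab <- node_labels(stree)

  g_ntip <- length(gtree$tip.label)
  g_n <- g_ntip + gtree$Nnode
  g_ch <- children_list(gtree)
  # postorder: sort nodes by decreasing depth
  g_dep <- node_depths(gtree)
  post <- order(g_dep, decreasing = TRUE)

  M <- integer(g_n)
  M[seq_len(g_ntip)] <- match(tip_sp, stree$tip.label)
  event <- rep(NA_character_, g_n)
  for (v in post) {
    if (is.null(g_ch[[v]])) next
    kids <- g_ch[[v]]
    M[v] <- lca_set(M[kids], sp_par, sp_dep)
    event[v] <- if (any(M[kids] == M[v])) "duplication" else "speciation"
  }

  dup <- integer(length(sp_lab))
  loss <- integer(length(sp_lab))
  internal <- which(!is.na(event))
  for (v in internal) if (event[v] == "duplication") {
    dup[M[v]] <- dup[M[v]] + 1L
  }
  for (u in internal) {
    for (v in g_ch[[u]]) {
      if (M[v] == M[u]) next
      # species-tree path M(u)=s0 > s1 > ... > sd=M(v)
      path <- integer(0)
      s <- M[v]
      while (s != M[u]) {
        path <- c(s, path)
        s <- sp_par[s]
      }
      path <- c(M[u], path)
      d <- length(path) - 1L
      first <- if (event[u] == "duplication") 1L else 2L
      if (first > d) next
      for (i in seq(first, d)) {
        at <- path[i]        # node where the lineage passes through
        nxt <- path[i + 1L]  # on-path child
        for (c_ in sp_ch[[at]]) if (c_ != nxt) loss[c_] <- loss[c_] + 1L
      }
    }
  }

  branches <- data.frame(branch = sp_lab, duplications = dup, losses = loss,
                         annotation = paste0("+", dup, "/-", loss))
  gl <- c(gtree$tip.label,
          paste0("g", g_ntip + seq_len(gtree$Nnode)))
  events <- data.frame(node = gl[internal],
                       event = event[internal],
                       maps_to = sp_lab[M[internal]])
  structure(list(branches = branches, events = events,
                 n_duplications = sum(dup), n_losses = sum(loss),
                 stree_fingerprint = tree_fingerprint(stree)),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("reconciliation:", x$n_duplications, "duplications,",
      x$n_losses, "losses\n")
  invisible(x)
}

#' Sum per-branch duplication/loss counts over several reconciliations
#'
#' All summaries must refer to the same species tree (checked by a structural
#' fingerprint); counts are added branch-wise, as when many gene-family trees
#' are reconciled against one species phylogeny.
#'
#' @param summaries list of `reconciliation` objects.
#' @param stree the shared rooted species tree.
#' @return a `reconciliation` object with summed branch counts (the per-node
#'   event table is dropped).
#' @export
aggregate_reconciliations <- function(summaries, stree) {
  stopifnot(length(summaries) >= 1L,
            all(vapply(summaries, inherits, TRUE, "reconciliation")))
  stree <- ensure_node_labels(stree)
  fp <- tree_fingerprint(stree)
  for (s in summaries)
    if (!identical(s$stree_fingerprint, fp))
      stop("summaries refer to different species trees")
  br <- summaries[[1L]]$branches[, "branch", drop = FALSE]
  dup <- Reduce(`+`, lapply(summaries, function(s) s$branches$duplications))
  loss <- Reduce(`+`, lapply(summaries, function(s) s$branches$losses))
  branches <- data.frame(branch = br$branch, duplications = dup,
                         losses = loss,
                         annotation = paste0("+", dup, "/-", loss))
  structure(list(branches = branches, events = NULL,
                 n_duplications = sum(dup), n_losses = sum(loss),
                 stree_fingerprint = fp),
            class = "reconciliation")
}

#' Write a per-branch duplication/loss table as TSV
#'
#' @param x a `reconciliation` object.
#' @param path output file.
#' @export
write_reconciliation_tsv <- function(x, path) {
  stopifnot(inherits(x, "reconciliation"))
  utils::write.table(x$branches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
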