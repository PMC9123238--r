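#' Per-species motif states from a gene x motif presence/absence matrix
#'
#' For each (species, motif) pair the state is `"complete"` when every family
#' gene of the species carries the motif, `"absent"` when none does, and
#' `"partial"` otherwise. Partial loss (some genes lost the motif) is thereby
#' kept distinct from complete loss, mirroring how conserved-motif figures
#' annotate the two cases.
#'
#' @param matrix binary matrix or data.frame, rows = genes (rownames = gene
#'   ids), columns = motifs (e.g. `M1..M10`); entries 0/1.
#' @param gene_species named character vector mapping gene id to species id.
#' @return data.frame with columns `species_id`, `motif_id`, `state`,
#'   `n_genes`, `n_present`, ordered by species then motif.
#' @export
species_motif_state <- function(matrix, gene_species) {
  m <- as.matrix(matrix)
  if (is.null(rownames(m))) stop("motif matrix needs gene ids as rownames")
  if (!all(m %in% c(0, 1))) stop("motif matrix entries must be 0/1")
  miss <- setdiff(rownames(m), names(gene_species))
  if (length(miss)) stop("gene without species mapping: ", miss[1L])
  sp <- gene_species[rownames(m)]
  species <- sort(unique(sp))
  motifs <- colnames(m)
  if (is.null(motifs)) motifs <- paste0("M", seq_len(ncol(m)))
  out <- do.call(rbind, lapply(species, function(s) {
    sub <- m[sp == s, , drop = FALSE]
    if (nrow(sub) == 0L) stop("species with zero genes: ", s)
    pres <- colSums(sub)
    data.frame(
      species_id = s, motif_id = motifs,
      state = ifelse(pres == nrow(sub), "complete",
                     ifelse(pres == 0, "absent", "partial")),
      n_genes = nrow(sub), n_present = as.integer(pres)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Dollo gain/loss trajectory of motifs on a species tree
#'
#' Under Dollo parsimony a motif is gained exactly once — on the branch above
#' the most recent common ancestor of all species carrying it — and
#' subsequently lost any number of times. The loss set is the minimal set of
#' branches whose removal explains every absent descendant of the gain node:
#' one loss on the root branch of each maximal motif-free clade below the
#' gain. Species in state `"partial"` count as carrying the motif (partial
#' loss is reported separately by [species_motif_state()]).
#'
#' @param states data.frame from [species_motif_state()] (columns
#'   `species_id`, `motif_id`, `state`).
#' @param tree rooted species tree (`phylo`); polytomies allowed. Every
#'   species in `states` must be a tip.
#' @return data.frame with one row per motif: `motif_id`, `gain_branch`
#'   (label of the node below the gain branch, `NA` if the motif is present
#'   nowhere), `n_losses`, `loss_branches` (comma-separated labels).
#' @export
dollo_trajectory <- function(states, tree) {
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  tree <- ensure_node_labels(tree)
  miss <- setdiff(unique(states$species_id), tree$tip.label)
  if (length(miss)) stop("species not in tree: ", miss[1L])
  parent <- parent_vec(tree)
  depth <- node_depths(tree)
  ch <- children_list(tree)
  labs <- node_labels(tree)
  ntip <- length(tree$tip.label)

  one_motif <- function(df) {
    present_sp <- df$species_id[df$state %in% c("complete", "partial")]
    if (!length(present_sp))
      return(data.frame(motif_id = df$motif_id[1L], gain_branch = NA_character_,
                        n_losses = 0L, loss_branches = ""))
    tips <- match(present_sp, tree$tip.label)
    gain <- lca_set(tips, parent, depth)
    # postorder presence flag under the gain node; losses at the roots of
    # maximal all-absent clades
    has_present <- logical(ntip + tree$Nnode)
    has_present[tips] <- TRUE
    mark <- function(v) {
      if (!is.null(ch[[v]])) {
        for (c_ in ch[[v]]) {
          mark(c_)
          if (has_present[c_]) has_present[v] <<- TRUE
        }
      }
    }
    mark(gain)
    losses <- character()
    collect <- function(v) {
      for (c_ in ch[[v]]) {
        if (!has_present[c_]) losses <<- c(losses, labs[c_])
        else if (!is.null(ch[[c_]])) collect(c_)
      }
    }
    if (!is.null(ch[[gain]])) collect(gain)
    data.frame(motif_id = df$motif_id[1L], gain_branch = labs[gain],
               n_losses = length(losses),
               loss_branches = paste(sort(losses), collapse = ","))
  }
  out <- do.call(rbind, lapply(split(states, states$motif_id), one_motif))
  out <- out[order(out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene x motif 0/1 matrix from TSV
#'
#' First column must be the gene id; remaining columns one per motif.
#'
#' @param path file path.
#' @return binary matrix with gene-id rownames.
#' @export
read_motif_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}
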