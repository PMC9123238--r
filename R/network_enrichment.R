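#' Assemble the regulatory target network around a gene family
#'
#' Keeps directed regulator -> target edges with `score >= score_min`,
#' then splits the neighbourhood of the family: downstream genes are targets
#' of family regulators, upstream genes are regulators of family targets, and
#' the feedback set is the intersection of the two (genes both regulated by
#' and regulating the family).
#'
#' @param edges data.frame `regulator`, `target`, `score` (score in `[0,1]`).
#' @param family_ids character vector of family gene ids.
#' @param score_min minimum score kept (inclusive).
#' @return list with `per_gene` (per family gene: `gene_id`,
#'   `downstream_count`, `upstream_count`), `downstream_genes`,
#'   `upstream_genes`, `feedback_genes` (sorted character vectors), and
#'   `n_edges_kept`.
#' @export
build_target_network <- function(edges, family_ids, score_min = 0.60) {
  stopifnot(all(c("regulator", "target", "score") %in% names(edges)))
  keep <- edges[edges$score >= score_min, , drop = FALSE]
  down_e <- keep[keep$regulator %in% family_ids, , drop = FALSE]
  up_e <- keep[keep$target %in% family_ids, , drop = FALSE]
  downstream <- sort(unique(down_e$target))
  upstream <- sort(unique(up_e$regulator))
  fam <- sort(unique(family_ids))
  per_gene <- data.frame(
    gene_id = fam,
    downstream_count = vapply(fam, function(g)
      length(unique(down_e$target[down_e$regulator == g])), 1L),
    upstream_count = vapply(fam, function(g)
      length(unique(up_e$regulator[up_e$target == g])), 1L)
  )
  rownames(per_gene) <- NULL
  list(per_gene = per_gene,
       downstream_genes = downstream,
       upstream_genes = upstream,
       feedback_genes = intersect(downstream, upstream),
       n_edges_kept = nrow(keep))
}

#' Pearson-correlation co-expression network
#'
#' Computes the Pearson correlation coefficient (PCC, sample `n - 1`
#' normalization) between every unordered pair of genes across the sample
#' columns and keeps pairs with `pcc > pos_thr` (positive regulatory edge) or
#' `pcc < neg_thr` (negative edge); inequalities are strict. Genes with zero
#' sample variance are excluded with a warning.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns; at least 3 samples required.
#' @param families named character vector gene id -> family label (e.g.
#'   `"Hsf"`, `"Hsp20"`, ..., `"Hsp100"`); genes absent from the map get
#'   `NA` family labels.
#' @param pos_thr,neg_thr PCC thresholds for positive/negative edges.
#' @param cross_family_only if `TRUE`, only pairs of genes from different
#'   families are reported.
#' @return data.frame `gene_a`, `gene_b` (canonical order), `pcc`, `sign`,
#'   `family_a`, `family_b`.
#' @export
pcc_network <- function(expr, families = NULL, pos_thr = 0.95,
                        neg_thr = -0.95, cross_family_only = FALSE) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("at least 3 samples are required")
  if (is.null(rownames(expr))) stop("expr needs gene ids as rownames")
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " zero-variance gene(s)")
    expr <- expr[v > 0, , drop = FALSE]
  }
  n <- nrow(expr)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      pcc = numeric(), sign = character(),
                      family_a = character(), family_b = character())
  if (n < 2L) return(empty)
  cc <- stats::cor(t(expr))
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  pcc <- cc[ut]
  pass <- pcc > pos_thr | pcc < neg_thr
  if (!any(pass)) return(empty)
  ga <- rownames(expr)[ut[pass, 1L]]
  gb <- rownames(expr)[ut[pass, 2L]]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  fam <- function(g) if (is.null(families)) rep(NA_character_, length(g))
                     else unname(families[g])
  out <- data.frame(gene_a = ga, gene_b = gb, pcc = pcc[pass],
                    sign = ifelse(pcc[pass] > pos_thr, "positive",
                                  "negative"),
                    family_a = fam(ga), family_b = fam(gb))
  if (cross_family_only)
    out <- out[is.na(out$family_a) | is.na(out$family_b) |
                 out$family_a != out$family_b, , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree table and top-k family composition of a co-expression network
#'
#' Counts, per node, total degree and negative-edge degree; ranks nodes by
#' degree (ties broken by gene id) and summarizes which family labels make up
#' the top `k`.
#'
#' @param edges edge table as returned by [pcc_network()] (columns `gene_a`,
#'   `gene_b`, `sign`, and `family_a`/`family_b` if family composition is
#'   wanted).
#' @param k size of the top table.
#' @param families_in optional character vector: restrict the ranking to
#'   nodes whose family label is in this set (e.g. the Hsp families only).
#' @return list with `degrees` (per node: `gene_id`, `family`, `degree`,
#'   `negative_degree`, sorted by decreasing degree then gene id), `top`
#'   (head `k` rows), and `composition` (family label counts within the top).
#' @export
hub_ranking <- function(edges, k = 20L, families_in = NULL) {
  if (nrow(edges) == 0L)
    return(list(degrees = data.frame(gene_id = character(),
                                     family = character(), degree = integer(),
                                     negative_degree = integer()),
                top = NULL, composition = integer()))
  nodes <- c(edges$gene_a, edges$gene_b)
  fams <- if (all(c("family_a", "family_b") %in% names(edges)))
    c(edges$family_a, edges$family_b) else rep(NA_character_, length(nodes))
  neg <- rep(edges$sign == "negative", 2L)
  ids <- sort(unique(nodes))
  deg <- as.integer(table(factor(nodes, levels = ids)))
  ndeg <- as.integer(tapply(neg, factor(nodes, levels = ids), sum))
  fam <- fams[match(ids, nodes)]
  degrees <- data.frame(gene_id = ids, family = fam, degree = deg,
                        negative_degree = ndeg)
  if (!is.null(families_in))
    degrees <- degrees[!is.na(degrees$family) &
                         degrees$family %in% families_in, , drop = FALSE]
  degrees <- degrees[order(-degrees$degree, degrees$gene_id), , drop = FALSE]
  rownames(degrees) <- NULL
  top <- utils::head(degrees, k)
  comp <- table(top$family, useNA = "no")
  list(degrees = degrees, top = top,
       composition = stats::setNames(as.integer(comp), names(comp)))
}

#' Edge counts, negative share and per-family node coverage of a network
#'
#' @param edges edge table as returned by [pcc_network()].
#' @param family_totals optional named vector of total family sizes, used to
#'   compute the fraction of each family's genes present in the network.
#' @return list with `n_edges`, `n_negative`, `n_positive`,
#'   `negative_share`, and `family_coverage` (data.frame `family`,
#'   `nodes_in_network`, `family_total`, `coverage`).
#' @export
summarize_coexpression <- function(edges, family_totals = NULL) {
  n_neg <- sum(edges$sign == "negative")
  nodes <- data.frame(gene_id = c(edges$gene_a, edges$gene_b),
                      family = c(edges$family_a, edges$family_b))
  nodes <- unique(nodes)
  cov <- NULL
  if (!is.null(family_totals)) {
    fams <- names(family_totals)
    in_net <- vapply(fams, function(f)
      length(unique(nodes$gene_id[!is.na(nodes$family) &
                                    nodes$family == f])), 1L)
    cov <- data.frame(family = fams, nodes_in_network = in_net,
                      family_total = unname(family_totals),
                      coverage = in_net / unname(family_totals))
    rownames(cov) <- NULL
  }
  list(n_edges = nrow(edges), n_negative = n_neg,
       n_positive = nrow(edges) - n_neg,
       negative_share = if (nrow(edges)) n_neg / nrow(edges) else NA_real_,
       family_coverage = cov)
}

#' Hypergeometric term enrichment with Bonferroni correction
#'
#' For each functional term, tests whether annotated target genes carry the
#' term more often than the annotated background: upper-tail hypergeometric
#' `P(X >= k)` with `N` annotated background genes, `K` of them carrying the
#' term, and `n` annotated targets of which `k` carry it (equivalent to a
#' one-sided Fisher test). Bonferroni q = `min(1, m p)` with `m` the number
#' of terms tested (terms with `k >= 1`). Fold change is
#' `(k/n) / (K/N)`; a term is significant when `q < .05` and fold `> 2`.
#'
#' @param target_genes character vector of target gene ids (must be a subset
#'   of `background`).
#' @param annotations data.frame `gene_id`, `term` (one row per assignment).
#' @param background character vector of background gene ids.
#' @return data.frame `term`, `k`, `n`, `K`, `N`, `p`, `q`, `fold`,
#'   `significant`, sorted by `q` then `term`.
#' @export
term_enrichment <- function(target_genes, annotations, background) {
  stopifnot(all(c("gene_id", "term") %in% names(annotations)))
  if (!all(target_genes %in% background))
    stop("target_genes must be a subset of background")
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  annotated_bg <- unique(ann$gene_id)
  annotated_tg <- intersect(target_genes, annotated_bg)
  N <- length(annotated_bg)
  n <- length(annotated_tg)
  if (N == 0L || n == 0L)
    stop("no annotated background/target genes")
  terms <- sort(unique(ann$term))
  K <- vapply(terms, function(t)
    length(unique(ann$gene_id[ann$term == t])), 1L)
  k <- vapply(terms, function(t)
    length(intersect(annotated_tg, ann$gene_id[ann$term == t])), 1L)
  tested <- k >= 1L
  m <- sum(tested)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  q <- pmin(1, m * p)
  fold <- (k / n) / (K / N)
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N,
                    p = p, q = q, fold = fold,
                    significant = q < 0.05 & fold > 2)
  out <- out[tested, , drop = FALSE]
  out <- out[order(out$q, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region counts of a Venn partition
#'
#' Counts the elements falling in every region of the Venn partition of two
#' or more named sets (all `2^m - 1` membership patterns are reported, zero
#' counts included).
#'
#' @param sets named list of at least two character vectors.
#' @return data.frame `region` (set names joined by `&`), `count`.
#' @export
venn_partition <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  elements <- unique(unlist(sets))
  m <- length(sets)
  member <- vapply(sets, function(s) elements %in% s,
                   logical(length(elements)))
  if (length(elements) == 1L) member <- matrix(member, nrow = 1L)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), m))[-1L, , drop = FALSE]
  names(patterns) <- names(sets)
  counts <- apply(patterns, 1L, function(pat) {
    if (length(elements) == 0L) return(0L)
    sum(apply(member, 1L, function(row) all(row == pat)))
  })
  data.frame(
    region = apply(patterns, 1L, function(pat)
      paste(names(sets)[as.logical(pat)], collapse = "&")),
    count = as.integer(counts)
  )
}

#' Write a co-expression edge list as TSV
#'
#' Columns `source`, `target`, `weight` (PCC) and `sign`, loadable by
#' standard graph tools.
#'
#' @param edges edge table from [pcc_network()].
#' @param path output file.
#' @export
write_edge_list <- function(edges, path) {
  out <- data.frame(source = edges$gene_a, target = edges$gene_b,
                    weight = edges$pcc, sign = edges$sign)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
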