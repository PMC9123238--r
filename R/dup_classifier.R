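#' Chain homolog pairs into collinear (syntenic) blocks
#'
#' Anchors (homologous gene pairs with gene-order ranks on their respective
#' chromosomes) are chained by dynamic programming within each chromosome
#' pair: consecutive anchors must advance by at least 1 and at most
#' `max_rank_gap` ranks on both chromosomes, monotonically increasing on the
#' first chromosome and either increasing (`same` orientation) or decreasing
#' (`inverted`) on the second. Chains are extracted best-first (most anchors;
#' ties broken by the smallest starting ranks), each anchor belongs to at
#' most one reported block, and chains shorter than `min_pairs` are
#' discarded. Rank (gene-order) coordinates, not bp, drive all gap tests.
#'
#' @param pairs data.frame of homolog pairs (`gene_a`, `gene_b`, optionally
#'   `e_value`); unordered, self-pairs forbidden.
#' @param pos gene position table: data.frame `gene_id`, `chrom`, `rank`
#'   (1-based order index along the chromosome; unique per chromosome).
#' @param min_pairs minimum number of anchors per reported block.
#' @param max_rank_gap maximum rank gap between consecutive anchors on either
#'   chromosome.
#' @return data.frame of block anchors: `block_id`, `orientation`, `chrom_a`,
#'   `chrom_b`, `gene_a`, `gene_b`, `rank_a`, `rank_b`; zero rows when no
#'   block passes `min_pairs`. Invariant under permutation of `pairs`.
#' @export
chain_collinear_blocks <- function(pairs, pos, min_pairs = 5L,
                                   max_rank_gap = 25L) {
  anchors <- anchor_table(pairs, pos)
  empty <- data.frame(block_id = integer(), orientation = character(),
                      chrom_a = character(), chrom_b = character(),
                      gene_a = character(), gene_b = character(),
                      rank_a = integer(), rank_b = integer())
  if (nrow(anchors) == 0L) return(empty)
  out <- list()
  bid <- 0L
  groups <- split(anchors, paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))
  for (g in groups[order(names(groups))]) {
    g <- g[order(g$rank_a, g$rank_b, g$gene_a, g$gene_b), , drop = FALSE]
    avail <- rep(TRUE, nrow(g))
    repeat {
      best <- NULL
      for (orient in c("same", "inverted")) {
        ch <- best_chain(g[avail, , drop = FALSE], orient, max_rank_gap)
        if (is.null(ch)) next
        if (is.null(best) ||
            length(ch$idx) > length(best$idx) ||
            (length(ch$idx) == length(best$idx) &&
             chain_key(g[avail, , drop = FALSE], ch) <
             chain_key(g[avail, , drop = FALSE], best)))
          best <- c(ch, list(orient = orient))
      }
      if (is.null(best) || length(best$idx) < min_pairs) break
      sub <- g[avail, , drop = FALSE][best$idx, , drop = FALSE]
      bid <- bid + 1L
      sub$block_id <- bid
      sub$orientation <- best$orient
      out[[bid]] <- sub
      take <- which(avail)[best$idx]
      avail[take] <- FALSE
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("block_id", "orientation", "chrom_a", "chrom_b",
          "gene_a", "gene_b", "rank_a", "rank_b")]
}

# canonicalized anchor table: endpoint order fixed by (chrom, rank) so the
# result does not depend on how pairs were written
anchor_table <- function(pairs, pos) {
  stopifnot(is.data.frame(pairs), is.data.frame(pos))
  if (!all(c("gene_a", "gene_b") %in% names(pairs)))
    stop("pairs needs columns gene_a, gene_b")
  if (!all(c("gene_id", "chrom", "rank") %in% names(pos)))
    stop("pos needs columns gene_id, chrom, rank")
  if (nrow(pairs) && any(pairs$gene_a == pairs$gene_b))
    stop("self-pairs are not allowed")
  for (cc in split(pos$rank, pos$chrom))
    if (anyDuplicated(cc)) stop("ranks must be unique within a chromosome")
  ix_a <- match(pairs$gene_a, pos$gene_id)
  ix_b <- match(pairs$gene_b, pos$gene_id)
  if (anyNA(ix_a) || anyNA(ix_b)) {
    bad <- c(pairs$gene_a[is.na(ix_a)], pairs$gene_b[is.na(ix_b)])[1L]
    stop("pair member without position: ", bad)
  }
  if (nrow(pairs) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      chrom_a = character(), chrom_b = character(),
                      rank_a = integer(), rank_b = integer()))
  a_first <- pos$chrom[ix_a] < pos$chrom[ix_b] |
    (pos$chrom[ix_a] == pos$chrom[ix_b] & pos$rank[ix_a] <= pos$rank[ix_b])
  an <- data.frame(
    gene_a = ifelse(a_first, pairs$gene_a, pairs$gene_b),
    gene_b = ifelse(a_first, pairs$gene_b, pairs$gene_a),
    chrom_a = ifelse(a_first, pos$chrom[ix_a], pos$chrom[ix_b]),
    chrom_b = ifelse(a_first, pos$chrom[ix_b], pos$chrom[ix_a]),
    rank_a = ifelse(a_first, pos$rank[ix_a], pos$rank[ix_b]),
    rank_b = ifelse(a_first, pos$rank[ix_b], pos$rank[ix_a])
  )
  unique(an)
}

# longest admissible chain by O(n^2) DP; returns indices into g (row order)
best_chain <- function(g, orientation, max_rank_gap) {
  n <- nrow(g)
  if (n == 0L) return(NULL)
  len <- rep(1L, n)
  pred <- rep(0L, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      da <- g$rank_a[j] - g$rank_a[i]
      db <- if (orientation == "same") g$rank_b[j] - g$rank_b[i]
            else g$rank_b[i] - g$rank_b[j]
      ok <- da >= 1L && da <= max_rank_gap && db >= 1L && db <= max_rank_gap
      if (ok && len[i] + 1L > len[j]) {
        len[j] <- len[i] + 1L
        pred[j] <- i
      } else if (ok && len[i] + 1L == len[j] && pred[j] > 0L) {
        # prefer the predecessor chain with the smaller starting anchor
        if (chain_start(pred, i) < chain_start(pred, pred[j])) pred[j] <- i
      }
    }
  }
  best_len <- max(len)
  cand <- which(len == best_len)
  idxs <- lapply(cand, function(j) {
    path <- j
    while (pred[path[1L]] > 0L) path <- c(pred[path[1L]], path)
    path
  })
  starts <- vapply(idxs, `[`, 1L, 1L)
  pick <- which.min(starts * n + cand)  # earliest start, then earliest end
  list(idx = idxs[[pick]], length = best_len)
}

chain_start <- function(pred, j) {
  while (pred[j] > 0L) j <- pred[j]
  j
}

chain_key <- function(g, ch) {
  i <- ch$idx[1L]
  g$rank_a[i] * 1e6 + g$rank_b[i]
}

#' Classify family genes by duplication type
#'
#' Applies the standard precedence used by gene-order duplicate classifiers:
#' a gene anchoring any collinear block is `wgd_segmental`; otherwise a gene
#' with a homolog at rank distance 1 on the same chromosome is `tandem`;
#' otherwise within `proximal_max_gap` ranks, `proximal`; otherwise any
#' homolog at all makes it `dispersed`; genes with no homolog are
#' `singleton`. Every gene in `members` receives exactly one class.
#'
#' @param members character vector of gene ids to classify.
#' @param pairs homolog pair table (`gene_a`, `gene_b`).
#' @param pos gene position table (`gene_id`, `chrom`, `rank`).
#' @param blocks block anchor table from [chain_collinear_blocks()] built
#'   from the same `pairs`/`pos`.
#' @param proximal_max_gap maximum rank distance for the proximal class.
#' @return data.frame `gene_id`, `class`.
#' @export
classify_duplicates <- function(members, pairs, pos, blocks,
                                proximal_max_gap = 10L) {
  anchors <- unique(c(blocks$gene_a, blocks$gene_b))
  an <- anchor_table(pairs, pos)
  partner <- rbind(
    data.frame(gene = an$gene_a, other_chrom = an$chrom_b,
               chrom = an$chrom_a, gap = abs(an$rank_b - an$rank_a),
               same = an$chrom_a == an$chrom_b),
    data.frame(gene = an$gene_b, other_chrom = an$chrom_a,
               chrom = an$chrom_b, gap = abs(an$rank_b - an$rank_a),
               same = an$chrom_a == an$chrom_b)
  )
  cls <- vapply(members, function(g) {
    if (g %in% anchors) return("wgd_segmental")
    p <- partner[partner$gene == g, , drop = FALSE]
    if (nrow(p) == 0L) return("singleton")
    if (any(p$same & p$gap == 1L)) return("tandem")
    if (any(p$same & p$gap <= proximal_max_gap)) return("proximal")
    "dispersed"
  }, "")
  data.frame(gene_id = members, class = unname(cls))
}

#' Chi-square enrichment of duplication types in a family vs the genome
#'
#' For each duplication type, builds the 2x2 table (focal type vs all other
#' types) x (family vs whole genome) and applies Pearson's chi-square test
#' without continuity correction (1 df, upper tail). A type is flagged
#' significant at `p < .01`; Bonferroni-adjusted p-values over the tested
#' types are reported alongside.
#'
#' @param family_counts named numeric vector of per-type counts in the family
#'   (names = types).
#' @param genome_counts per-type counts for the whole genome, or per-type
#'   proportions (sums to 1) together with `genome_total`.
#' @param genome_total total genome gene count; required when
#'   `genome_counts` are proportions.
#' @return data.frame `type`, `family_count`, `family_share`, `genome_share`,
#'   `chi2`, `p`, `p_bonferroni`, `significant`.
#' @export
type_enrichment_chi2 <- function(family_counts, genome_counts,
                                 genome_total = NULL) {
  stopifnot(length(family_counts) == length(genome_counts))
  types <- names(family_counts)
  if (is.null(types)) types <- names(genome_counts)
  if (is.null(types)) types <- paste0("type", seq_along(family_counts))
  if (abs(sum(genome_counts) - 1) < 1e-8) {
    if (is.null(genome_total))
      stop("genome_counts look like proportions; supply genome_total")
    genome_counts <- genome_counts * genome_total
  }
  if (any(genome_counts <= 0))
    stop("genome counts must be > 0 for compared categories")
  nf <- sum(family_counts)
  ng <- sum(genome_counts)
  rows <- lapply(seq_along(types), function(i) {
    tab <- matrix(c(family_counts[i], nf - family_counts[i],
                    genome_counts[i], ng - genome_counts[i]), nrow = 2L)
    if (any(chisq_expected(tab) == 0))
      stop("zero expected cell for type '", types[i],
           "'; use an exact test")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(type = types[i],
               family_count = unname(family_counts[i]),
               family_share = unname(family_counts[i]) / nf,
               genome_share = unname(genome_counts[i]) / ng,
               chi2 = unname(ct$statistic), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$significant <- out$p < 0.01
  rownames(out) <- NULL
  out
}

chisq_expected <- function(tab) outer(rowSums(tab), colSums(tab)) / sum(tab)

#' Read homolog pairs from 12-column BLAST tabular output
#'
#' Uses columns 1 (query), 2 (subject) and 11 (e-value); self-hits are
#' dropped, pairs are canonically sorted and deduplicated keeping the
#' smallest e-value, and filtered at `e_max`.
#'
#' @param path file path.
#' @param e_max keep pairs with e-value `<= e_max`.
#' @param top_per_query keep at most this many subjects per query (by
#'   e-value, before symmetrization); `Inf` keeps all.
#' @return data.frame `gene_a`, `gene_b`, `e_value`.
#' @export
read_blast_pairs <- function(path, e_max = 1e-5, top_per_query = 5) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 11L) stop("expected 12-column BLAST tabular input")
  df <- data.frame(q = df[[1L]], s = df[[2L]], e = as.numeric(df[[11L]]))
  df <- df[df$q != df$s & df$e <= e_max, , drop = FALSE]
  if (is.finite(top_per_query) && nrow(df)) {
    df <- df[order(df$q, df$e, df$s), , drop = FALSE]
    df <- do.call(rbind, lapply(split(df, df$q), function(x)
      utils::head(x, top_per_query)))
  }
  a <- pmin(df$q, df$s)
  b <- pmax(df$q, df$s)
  out <- data.frame(gene_a = a, gene_b = b, e_value = df$e)
  out <- out[order(out$gene_a, out$gene_b, out$e_value), , drop = FALSE]
  out <- out[!duplicated(paste(out$gene_a, out$gene_b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
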