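# Seeded generators producing inputs with known ground truth for every
# pipeline stage. These are pure test instruments: they emulate the
# statistical structure each analysis assumes (not real sequence evolution),
# and every generator returns its truth tables alongside the data. With
# `out_dir` set, data and truth are also written as TSV/FASTA.

#' Simulate gene-family evolution along a species tree (birth-death)
#'
#' Gene lineages evolve along a clock-scaled species tree under a linear
#' birth-death process: duplications (births) at rate `lambda` and losses
#' (deaths) at rate `mu` per unit branch length, with exponential waiting
#' times. Surviving lineages yield rooted binary gene trees whose tips are
#' labeled `<species>|f<family>|g<k>`; the event log records the species-tree
#' branch (labeled by the node below it) of every duplication and loss,
#' whether or not descendants survive.
#'
#' @param stree rooted species tree (`phylo`) with edge lengths (a tree
#'   without them gets unit branch lengths); depths are rescaled so the
#'   maximum root-to-tip distance is 1, making rates interpretable per unit
#'   tree depth.
#' @param lambda,mu duplication and loss rates (>= 0).
#' @param n_families number of independent root genes (one gene tree each).
#' @param seed integer RNG seed.
#' @param out_dir optional directory; writes `gene_trees.nwk`,
#'   `gene_species.tsv` and `events.tsv`.
#' @return list with `gene_trees` (list of `phylo`, `NULL` where the family
#'   went extinct), `gene_species` (named vector tip -> species),
#'   `event_counts` (data.frame `branch`, `duplications`, `losses`), and
#'   totals `n_duplications`, `n_losses`.
#' @export
simulate_family_evolution <- function(stree, lambda = 0.5, mu = 0,
                                      n_families = 1L, seed = 1L,
                                      out_dir = NULL) {
  stopifnot(lambda >= 0, mu >= 0)
  if (!ape::is.rooted(stree)) stop("species tree must be rooted")
  stree <- ensure_node_labels(stree)
  if (is.null(stree$edge.length))
    stree$edge.length <- rep(1, nrow(stree$edge))
  depth_bl <- ape::node.depth.edgelength(stree)
  stree$edge.length <- stree$edge.length / max(depth_bl)
  set.seed(seed)

  ch <- children_list(stree)
  labs <- node_labels(stree)
  brlen <- numeric(length(labs))
  brlen[stree$edge[, 2L]] <- stree$edge.length
  ntip <- length(stree$tip.label)
  root <- which(parent_vec(stree) == 0L)

  env <- new.env()
  run_family <- function(fam) {
    env$counter <- 0L
    env$dup <- integer(length(labs))
    env$loss <- integer(length(labs))
    # lineage travelling down the branch above node v with time t left;
    # returns a newick fragment or NA if nothing survives
    on_branch <- function(v, t) {
      rate <- lambda + mu
      repeat {
        if (rate == 0) break
        x <- stats::rexp(1L, rate)
        if (x >= t) break
        t <- t - x
        if (stats::runif(1L) < lambda / rate) {
          env$dup[v] <- env$dup[v] + 1L
          left <- on_branch(v, t)
          right <- on_branch(v, t)
          if (is.na(left) && is.na(right)) return(NA_character_)
          if (is.na(left)) return(right)
          if (is.na(right)) return(left)
          return(paste0("(", left, ",", right, ")"))
        }
        env$loss[v] <- env$loss[v] + 1L
        return(NA_character_)
      }
      at_node(v)
    }
    at_node <- function(v) {
      if (v <= ntip) {
        env$counter <- env$counter + 1L
        return(paste0(labs[v], "|f", fam, "|g", env$counter))
      }
      parts <- vapply(ch[[v]], function(c_) on_branch(c_, brlen[c_]), "")
      parts <- parts[!is.na(parts)]
      if (length(parts) == 0L) return(NA_character_)
      if (length(parts) == 1L) return(parts)
      Reduce(function(a, b) paste0("(", a, ",", b, ")"), parts)
    }
    nwk <- at_node(root)
    tree <- NULL
    if (!is.na(nwk) && grepl(",", nwk, fixed = TRUE))
      tree <- ape::read.tree(text = paste0(nwk, ";"))
    list(tree = tree, dup = env$dup, loss = env$loss)
  }

  res <- lapply(seq_len(n_families), run_family)
  dup <- Reduce(`+`, lapply(res, `[[`, "dup"))
  loss <- Reduce(`+`, lapply(res, `[[`, "loss"))
  trees <- lapply(res, `[[`, "tree")
  tips <- unlist(lapply(trees, function(t) if (is.null(t)) character(0)
                        else t$tip.label))
  gene_species <- stats::setNames(sub("\\|.*$", "", tips), tips)
  event_counts <- data.frame(branch = labs, duplications = dup,
                             losses = loss)
  out <- list(gene_trees = trees, gene_species = gene_species,
              event_counts = event_counts,
              n_duplications = sum(dup), n_losses = sum(loss))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ok <- !vapply(trees, is.null, TRUE)
    if (any(ok))
      ape::write.tree(do.call(c, trees[ok]),
                      file.path(out_dir, "gene_trees.nwk"))
    utils::write.table(
      data.frame(gene_id = names(gene_species),
                 species_id = unname(gene_species)),
      file.path(out_dir, "gene_species.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(event_counts, file.path(out_dir, "events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Simulate a gene-order genome with planted duplicate classes
#'
#' Builds a multi-chromosome gene-order genome and plants, in disjoint,
#' widely separated rank windows: adjacent duplicate pairs (tandem truth),
#' near duplicates at rank gap 2-10 (proximal truth), copied segments of
#' `segment_length >= 5` genes on another chromosome (WGD/segmental truth),
#' and isolated cross-chromosome homolog pairs (dispersed truth). All other
#' genes are singleton truth. The separation (>= 30 ranks between planted
#' features) guarantees that no unintended collinear chain or proximity
#' relationship arises, so classification truth is exact.
#'
#' @param genes_per_chrom genes per chromosome.
#' @param n_chroms number of chromosomes (>= 5).
#' @param n_tandem,n_proximal,n_dispersed numbers of planted pairs.
#' @param n_segmental_blocks,segment_length planted collinear blocks and
#'   their length in genes.
#' @param seed integer RNG seed (draws the proximal gaps).
#' @param out_dir optional directory; writes `positions.tsv`, `pairs.tsv`,
#'   `truth.tsv`.
#' @return list with `pos` (`gene_id`, `chrom`, `rank`), `pairs` (`gene_a`,
#'   `gene_b`, `e_value`), `truth` (`gene_id`, `class` for every gene).
#' @export
simulate_genome_with_duplicates <- function(genes_per_chrom = 200L,
                                            n_chroms = 5L,
                                            n_tandem = 5L,
                                            n_proximal = 5L,
                                            n_segmental_blocks = 2L,
                                            segment_length = 6L,
                                            n_dispersed = 5L,
                                            seed = 1L, out_dir = NULL) {
  stopifnot(n_chroms >= 5L, segment_length >= 5L)
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chroms))
  pos <- do.call(rbind, lapply(chroms, function(cc)
    data.frame(gene_id = sprintf("%s_g%03d", cc, seq_len(genes_per_chrom)),
               chrom = cc, rank = seq_len(genes_per_chrom))))
  gid <- function(cc, r) sprintf("%s_g%03d", cc, r)
  spacing <- 30L
  capacity <- function(n_feat, span)
    if (n_feat > 0 && (n_feat - 1L) * spacing + span > genes_per_chrom)
      stop("planted events exceed genome capacity")

  pairs <- list()
  truth <- stats::setNames(rep("singleton", nrow(pos)), pos$gene_id)
  add_pair <- function(a, b) pairs[[length(pairs) + 1L]] <<-
    data.frame(gene_a = min(a, b), gene_b = max(a, b), e_value = 1e-50)

  # tandem: chr1, pairs (r, r+1)
  capacity(n_tandem, 2L)
  for (i in seq_len(n_tandem)) {
    r <- 1L + (i - 1L) * spacing
    a <- gid("chr1", r); b <- gid("chr1", r + 1L)
    add_pair(a, b); truth[c(a, b)] <- "tandem"
  }
  # proximal: chr2, pairs (r, r+gap), gap in 2..10
  capacity(n_proximal, 11L)
  for (i in seq_len(n_proximal)) {
    r <- 1L + (i - 1L) * spacing
    gap <- sample(2:10, 1L)
    a <- gid("chr2", r); b <- gid("chr2", r + gap)
    add_pair(a, b); truth[c(a, b)] <- "proximal"
  }
  # segmental: chr3 segment copied to chr4 at the same span
  capacity(n_segmental_blocks, segment_length)
  for (i in seq_len(n_segmental_blocks)) {
    r <- 1L + (i - 1L) * spacing
    for (j in seq_len(segment_length) - 1L) {
      a <- gid("chr3", r + j); b <- gid("chr4", r + j)
      add_pair(a, b); truth[c(a, b)] <- "wgd_segmental"
    }
  }
  # dispersed: isolated chr5 x chr4 pairs, clear of the segmental windows
  base4 <- (max(n_segmental_blocks - 1L, 0L)) * spacing + segment_length +
    spacing
  if (n_dispersed > 0 &&
      (base4 + (n_dispersed - 1L) * spacing > genes_per_chrom ||
       (n_dispersed - 1L) * spacing + 1L > genes_per_chrom))
    stop("planted events exceed genome capacity")
  for (i in seq_len(n_dispersed)) {
    a <- gid("chr5", 1L + (i - 1L) * spacing)
    b <- gid("chr4", base4 + (i - 1L) * spacing)
    add_pair(a, b); truth[c(a, b)] <- "dispersed"
  }

  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(), gene_b = character(),
               e_value = numeric())
  truth_df <- data.frame(gene_id = names(truth), class = unname(truth))
  out <- list(pos = pos, pairs = pairs, truth = truth_df)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(pos, file.path(out_dir, "positions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pairs, file.path(out_dir, "pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth_df, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Condition labels for the emulated expression designs
#'
#' The heat series mirrors a 38 degC time course (control and 1, 4, 8, 12 h);
#' the tissue panel a six-tissue survey.
#'
#' @param design `"heat"`, `"tissue"` or `"both"`.
#' @return character vector of sample labels.
#' @export
expression_conditions <- function(design = c("heat", "tissue", "both")) {
  design <- match.arg(design)
  heat <- c("control", "T1", "T4", "T8", "T12")
  tissue <- c("root", "stem", "leaf", "flower", "silique", "callus")
  switch(design, heat = heat, tissue = tissue, both = c(heat, tissue))
}

#' Simulate block-correlated FPKM-like expression
#'
#' Genes within a block share one latent condition-response profile on the
#' log2 scale plus a gene-specific baseline and independent Gaussian noise of
#' standard deviation `sigma`; profiles of different blocks are independent.
#' Values are exponentiated (base 2) so they are non-negative and
#' right-skewed like FPKM. At `sigma = 0`, genes of a block are exact
#' positive scalings of each other, so within-block PCC is exactly 1.
#'
#' @param n_blocks,block_size block design.
#' @param sigma noise standard deviation (log2 scale).
#' @param design `"heat"`, `"tissue"` or `"both"` (see
#'   [expression_conditions()]), or a character vector of custom condition
#'   labels; at least 3 conditions required.
#' @param families optional vector of family labels recycled over blocks
#'   (every gene of a block gets its block's label).
#' @param seed integer RNG seed.
#' @param out_dir optional directory; writes `expression.tsv` and
#'   `true_pairs.tsv`.
#' @return list with `expr` (matrix genes x samples, FPKM-like),
#'   `true_pairs` (data.frame `gene_a`, `gene_b`: all within-block pairs,
#'   canonical order), `families` (named vector gene -> family label, or
#'   `NULL`).
#' @export
simulate_expression <- function(n_blocks = 6L, block_size = 8L, sigma = 1,
                                design = "heat", families = NULL,
                                seed = 1L, out_dir = NULL) {
  cond <- if (length(design) == 1L &&
              design %in% c("heat", "tissue", "both"))
    expression_conditions(design) else design
  if (length(cond) < 3L) stop("fewer than 3 conditions")
  set.seed(seed)
  genes <- as.vector(vapply(seq_len(n_blocks), function(b)
    sprintf("B%02d_g%02d", b, seq_len(block_size)),
    character(block_size)))
  profiles <- matrix(stats::rnorm(n_blocks * length(cond), mean = 4, sd = 2),
                     n_blocks, length(cond))
  baseline <- stats::rnorm(length(genes), 0, 1)
  block_of <- rep(seq_len(n_blocks), each = block_size)
  logx <- profiles[block_of, , drop = FALSE] + baseline +
    matrix(stats::rnorm(length(genes) * length(cond), 0, sigma),
           length(genes), length(cond))
  expr <- 2^logx
  dimnames(expr) <- list(genes, cond)
  tp <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    g <- genes[block_of == b]
    if (length(g) < 2L) return(NULL)
    cmb <- utils::combn(sort(g), 2L)
    data.frame(gene_a = cmb[1L, ], gene_b = cmb[2L, ])
  }))
  fam <- NULL
  if (!is.null(families)) {
    fam <- stats::setNames(rep(families, length.out = n_blocks)[block_of],
                           genes)
  }
  out <- list(expr = expr, true_pairs = tp, families = fam)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(data.frame(gene_id = genes, expr,
                                  check.names = FALSE),
                       file.path(out_dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tp, file.path(out_dir, "true_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Simulate promoters with planted heat shock elements
#'
#' Promoters are i.i.d. uniform A/C/G/T; each receives `n_planted`
#' non-overlapping HSE instances (consensus `GAAnnTTnnnGAA` with the `n`
#' positions drawn uniformly) at recorded offsets and strands. With
#' `disrupt = TRUE` every instance carries a disrupting substitution (the
#' pattern's first G becomes C) so it can no longer match at the planted
#' offset.
#'
#' @param n number of promoters.
#' @param length promoter length (nt).
#' @param n_planted HSE instances per promoter.
#' @param both_strands plant on randomly chosen strands; otherwise `+` only.
#' @param disrupt apply the disrupting point substitution to every instance.
#' @param seed integer RNG seed.
#' @param out_dir optional directory; writes `promoters.fasta` and
#'   `true_hse.tsv`.
#' @return list with `promoters` (data.frame `gene_id`, `sequence`) and
#'   `truth` (data.frame `gene_id`, `offset` (0-based), `strand`).
#' @export
simulate_promoters <- function(n = 100L, length = 2000L, n_planted = 1L,
                               both_strands = TRUE, disrupt = FALSE,
                               seed = 1L, out_dir = NULL) {
  if (n_planted > 0 && length < 13L * n_planted * 2L)
    stop("planting beyond sequence bounds")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ids <- sprintf("prom%04d", seq_len(n))
  seqs <- character(n)
  truth <- list()
  for (i in seq_len(n)) {
    s <- sample(bases, length, replace = TRUE)
    if (n_planted > 0) {
      # non-overlapping offsets: one per stratum of width >= 13
      strata <- as.integer(length %/% n_planted)
      off <- vapply(seq_len(n_planted), function(j)
        (j - 1L) * strata + sample(strata - 12L, 1L), 1L)
      strands <- if (both_strands) sample(c("+", "-"), n_planted,
                                          replace = TRUE)
                 else rep("+", n_planted)
      for (j in seq_len(n_planted)) {
        el <- c("G", "A", "A", sample(bases, 2L, TRUE), "T", "T",
                sample(bases, 3L, TRUE), "G", "A", "A")
        if (disrupt) el[1L] <- "C"
        ins <- if (strands[j] == "+") el else
          rev(chartr("ACGT", "TGCA", el))
        s[off[j]:(off[j] + 12L)] <- ins
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = ids[i], offset = off[j] - 1L, strand = strands[j])
      }
    }
    seqs[i] <- paste(s, collapse = "")
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), offset = integer(),
               strand = character())
  out <- list(promoters = data.frame(gene_id = ids, sequence = seqs),
              truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(paste0(">", ids, "\n", seqs),
               file.path(out_dir, "promoters.fasta"))
    utils::write.table(truth, file.path(out_dir, "true_hse.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Simulate a scored regulatory edge table around a gene family
#'
#' Directed regulator -> target edges with scores in `[0, 1]`: true edges
#' score in `[0.60, 1]`, decoy edges (a configurable fraction) score below
#' 0.60 and must be filtered out by the network builder. Designated feedback
#' genes appear both as targets and as regulators of family genes.
#'
#' @param n_family family genes (`fam01`, ...).
#' @param n_downstream,n_upstream true downstream/upstream genes.
#' @param n_feedback genes planted on both sides.
#' @param n_decoy below-threshold edges.
#' @param seed integer RNG seed.
#' @param out_dir optional directory; writes `edges.tsv` and `truth.tsv`.
#' @return list with `edges` (`regulator`, `target`, `score`) and `truth`
#'   (list `downstream`, `upstream`, `feedback`).
#' @export
simulate_regulatory_edges <- function(n_family = 5L, n_downstream = 40L,
                                      n_upstream = 10L, n_feedback = 3L,
                                      n_decoy = 20L, seed = 1L,
                                      out_dir = NULL) {
  stopifnot(n_feedback <= n_downstream, n_feedback <= n_upstream)
  set.seed(seed)
  fam <- sprintf("fam%02d", seq_len(n_family))
  down <- sprintf("down%03d", seq_len(n_downstream))
  up <- sprintf("up%03d", seq_len(n_upstream))
  # feedback genes are both downstream and upstream: reuse the first
  # n_feedback downstream genes as regulators of the family too
  feedback <- down[seq_len(n_feedback)]
  upstream_all <- c(up, feedback)
  e1 <- data.frame(regulator = sample(fam, n_downstream, replace = TRUE),
                   target = down)
  e2 <- data.frame(regulator = upstream_all,
                   target = sample(fam, length(upstream_all),
                                   replace = TRUE))
  edges <- rbind(e1, e2)
  edges$score <- stats::runif(nrow(edges), 0.60, 1)
  if (n_decoy > 0) {
    decoy <- data.frame(
      regulator = sample(fam, n_decoy, replace = TRUE),
      target = sprintf("decoy%03d", seq_len(n_decoy)),
      score = stats::runif(n_decoy, 0, 0.599))
    edges <- rbind(edges, decoy)
  }
  rownames(edges) <- NULL
  out <- list(edges = edges,
              truth = list(downstream = sort(down),
                           upstream = sort(upstream_all),
                           feedback = sort(feedback)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(edges, file.path(out_dir, "edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = out$truth$downstream, role = "downstream"),
      file.path(out_dir, "truth.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
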