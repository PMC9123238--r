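sp4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("identical seed and config give byte-identical outputs", {
  s1 <- simulate_family_evolution(sp4(), 1, 0.2, n_families = 5, seed = 9)
  s2 <- simulate_family_evolution(sp4(), 1, 0.2, n_families = 5, seed = 9)
  expect_identical(lapply(s1$gene_trees, function(t)
    if (is.null(t)) NULL else ape::write.tree(t)),
    lapply(s2$gene_trees, function(t)
      if (is.null(t)) NULL else ape::write.tree(t)))
  expect_identical(s1$event_counts, s2$event_counts)

  e1 <- simulate_expression(seed = 9)
  e2 <- simulate_expression(seed = 9)
  expect_identical(e1$expr, e2$expr)

  p1 <- simulate_promoters(n = 5, length = 200, seed = 9)
  p2 <- simulate_promoters(n = 5, length = 200, seed = 9)
  expect_identical(p1, p2)

  g1 <- simulate_genome_with_duplicates(seed = 9)
  g2 <- simulate_genome_with_duplicates(seed = 9)
  expect_identical(g1, g2)
})

test_that("without events the gene tree is congruent with the species tree", {
  sim <- simulate_family_evolution(sp4(), 0, 0, seed = 10)
  gt <- sim$gene_trees[[1]]
  gt$tip.label <- sub("\\|.*$", "", gt$tip.label)
  expect_equal(sort(gt$tip.label), c("A", "B", "C", "D"))
  expect_equal(sim$n_duplications, 0L)
  expect_equal(sim$n_losses, 0L)
  expect_equal(unname(ape::dist.topo(ape::unroot(gt),
                                     ape::unroot(sp4()))[1]), 0)
})

test_that("with no losses, leaves per species equal 1 + ancestral dups", {
  st <- hsfkit:::ensure_node_labels(sp4())
  labs <- c(st$tip.label, st$node.label)
  parents <- tree_parents(st)
  sim <- simulate_family_evolution(st, lambda = 1.2, mu = 0,
                                   n_families = 1, seed = 11)
  gt <- sim$gene_trees[[1]]
  dup <- stats::setNames(sim$event_counts$duplications,
                         sim$event_counts$branch)
  for (s in st$tip.label) {
    anc <- labs[tree_ancestors_self(match(s, labs), parents)]
    expected <- 1L + sum(dup[anc])
    expect_equal(sum(sub("\\|.*$", "", gt$tip.label) == s), expected)
  }
})

test_that("pure-loss simulations match the closed-form loss probability", {
  mu <- 0.8
  n <- 10000L
  st <- ape::read.tree(text = "(A:1,B:1);")
  sim <- simulate_family_evolution(st, lambda = 0, mu = mu,
                                   n_families = n, seed = 12)
  # each branch has (scaled) length 1; a lineage dies with prob 1 - e^-mu
  p_hat <- sim$event_counts$losses[
    sim$event_counts$branch %in% c("A", "B")] / n
  p_true <- 1 - exp(-mu)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_true(all(abs(p_hat - p_true) <= 3 * se))
  expect_equal(sim$n_duplications, 0L)
})

test_that("planted duplicate classes are emitted with exact truth labels", {
  g <- simulate_genome_with_duplicates(seed = 13)
  expect_equal(sum(g$truth$class == "tandem"), 2L * 5L)
  expect_equal(sum(g$truth$class == "wgd_segmental"), 2L * 2L * 6L)
  # planted tandem pair is classified tandem
  bl <- chain_collinear_blocks(g$pairs, g$pos)
  cls <- classify_duplicates(g$truth$gene_id, g$pairs, g$pos, bl)
  t_genes <- g$truth$gene_id[g$truth$class == "tandem"]
  expect_true(all(cls$class[cls$gene_id %in% t_genes] == "tandem"))
  # all genes of a copied segment are wgd_segmental
  s_genes <- g$truth$gene_id[g$truth$class == "wgd_segmental"]
  expect_true(all(cls$class[cls$gene_id %in% s_genes] == "wgd_segmental"))

  # empty plant spec: all singletons
  g0 <- simulate_genome_with_duplicates(n_tandem = 0, n_proximal = 0,
                                        n_segmental_blocks = 0,
                                        n_dispersed = 0, seed = 13)
  expect_true(all(g0$truth$class == "singleton"))
  expect_equal(nrow(g0$pairs), 0L)

  expect_error(simulate_genome_with_duplicates(genes_per_chrom = 20,
                                               n_tandem = 10, seed = 1),
               "capacity")
})

test_that("noise-free expression blocks have PCC exactly 1 within blocks", {
  e <- simulate_expression(n_blocks = 3, block_size = 4, sigma = 0,
                           seed = 14)
  cc <- stats::cor(t(e$expr))
  for (i in seq_len(nrow(e$true_pairs)))
    expect_equal(cc[e$true_pairs$gene_a[i], e$true_pairs$gene_b[i]], 1)
  # single block: every pair is a true pair
  e1 <- simulate_expression(n_blocks = 1, block_size = 5, seed = 14)
  expect_equal(nrow(e1$true_pairs), choose(5, 2))

  expect_error(simulate_expression(design = c("c1", "c2"), seed = 1),
               "3 conditions")
})

test_that("at high noise, cross-block pairs rarely exceed the threshold", {
  e <- simulate_expression(n_blocks = 8, block_size = 5, sigma = 2,
                           design = "both", seed = 15)
  cc <- stats::cor(t(log2(e$expr)))  # PCC on the log2 expression scale
  tp <- paste(e$true_pairs$gene_a, e$true_pairs$gene_b)
  ids <- rownames(e$expr)
  cross <- 0L; exceed <- 0L
  for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
    if (paste(ids[i], ids[j]) %in% tp) next
    cross <- cross + 1L
    if (abs(cc[i, j]) > 0.95) exceed <- exceed + 1L
  }
  expect_lt(exceed / cross, 0.01)
})

test_that("planted regulatory structure is recovered after filtering", {
  sim <- simulate_regulatory_edges(n_family = 5, n_feedback = 3, seed = 16)
  fam <- sprintf("fam%02d", 1:5)
  nw <- build_target_network(sim$edges, fam)
  expect_equal(nw$downstream_genes, sim$truth$downstream)
  expect_equal(nw$upstream_genes, sim$truth$upstream)
  expect_equal(nw$feedback_genes, sim$truth$feedback)

  # sub-threshold scores are filtered to an empty network
  low <- data.frame(regulator = fam, target = paste0("t", 1:5), score = 0.5)
  nw0 <- build_target_network(low, fam)
  expect_equal(length(nw0$downstream_genes), 0L)

  # a table without family genes yields an empty summary
  other <- data.frame(regulator = "x", target = "y", score = 0.9)
  nw1 <- build_target_network(other, fam)
  expect_equal(length(nw1$downstream_genes), 0L)
  expect_equal(length(nw1$upstream_genes), 0L)
})

test_that("generators write machine-readable truth tables", {
  d <- tempfile()
  sim <- simulate_family_evolution(sp4(), 1, 0, n_families = 3, seed = 17,
                                   out_dir = d)
  ev <- utils::read.delim(file.path(d, "events.tsv"))
  expect_equal(ev$duplications, sim$event_counts$duplications)
  gs <- utils::read.delim(file.path(d, "gene_species.tsv"))
  expect_equal(nrow(gs), length(sim$gene_species))

  d2 <- tempfile()
  g <- simulate_genome_with_duplicates(seed = 17, out_dir = d2)
  tr <- utils::read.delim(file.path(d2, "truth.tsv"))
  expect_equal(tr$class, g$truth$class)

  d3 <- tempfile()
  p <- simulate_promoters(n = 4, length = 120, seed = 17, out_dir = d3)
  ft <- utils::read.delim(file.path(d3, "true_hse.tsv"))
  expect_equal(ft$offset, p$truth$offset)
})
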