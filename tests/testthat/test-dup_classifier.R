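diag_pos <- function(n_per_chrom = 30L) {
  data.frame(gene_id = c(paste0("a", 1:n_per_chrom),
                         paste0("b", 1:n_per_chrom)),
             chrom = rep(c("c1", "c2"), each = n_per_chrom),
             rank = rep(1:n_per_chrom, 2))
}

test_that("a perfect diagonal of five pairs forms one block", {
  pos <- diag_pos()
  pairs <- data.frame(gene_a = paste0("a", 1:5), gene_b = paste0("b", 11:15))
  bl <- chain_collinear_blocks(pairs, pos)
  expect_equal(nrow(bl), 5L)
  expect_equal(unique(bl$block_id), 1L)
  expect_equal(bl$orientation, rep("same", 5))

  # below min_pairs: nothing reported
  expect_equal(nrow(chain_collinear_blocks(pairs[1:4, ], pos)), 0L)
})

test_that("chaining excludes off-diagonal outliers like brute force", {
  pos <- diag_pos()
  pairs <- data.frame(
    gene_a = paste0("a", c(1, 2, 3, 4, 5, 6, 10)),
    gene_b = paste0("b", c(11, 12, 13, 14, 15, 16, 2)))
  bl <- chain_collinear_blocks(pairs, pos)
  expect_equal(nrow(bl), 6L)
  got <- sort(unique(c(bl$gene_a, bl$gene_b)))
  expect_equal(got, oracle_best_chain_genes(pairs, pos, 25L))
})

test_that("inverted blocks are chained on the antidiagonal", {
  pos <- diag_pos()
  pairs <- data.frame(gene_a = paste0("a", 1:5), gene_b = paste0("b", 15:11))
  bl <- chain_collinear_blocks(pairs, pos)
  expect_equal(nrow(bl), 5L)
  expect_equal(unique(bl$orientation), "inverted")
})

test_that("block chaining is invariant to pair order and respects gaps", {
  set.seed(41)
  pos <- diag_pos()
  pairs <- data.frame(gene_a = paste0("a", c(1:6, 20)),
                      gene_b = paste0("b", c(11:16, 30)))
  bl1 <- chain_collinear_blocks(pairs, pos)
  for (i in 1:5) {
    perm <- pairs[sample(nrow(pairs)), ]
    # also randomly swap endpoint order
    sw <- sample(c(TRUE, FALSE), nrow(perm), replace = TRUE)
    tmp <- perm$gene_a[sw]; perm$gene_a[sw] <- perm$gene_b[sw]
    perm$gene_b[sw] <- tmp
    expect_equal(chain_collinear_blocks(perm, pos), bl1)
  }
  # a gap larger than max_rank_gap breaks the chain
  far <- data.frame(gene_a = paste0("a", c(1:5, 31 - 1)),
                    gene_b = paste0("b", c(11:15, 30)))
  bl2 <- chain_collinear_blocks(far, pos, max_rank_gap = 10L)
  expect_equal(nrow(bl2), 5L)

  expect_error(chain_collinear_blocks(
    data.frame(gene_a = "a1", gene_b = "zz"), pos), "position")
})

test_that("duplicate classes follow the documented precedence", {
  pos <- data.frame(gene_id = paste0("g", 1:30), chrom = "c1", rank = 1:30)
  pairs <- data.frame(gene_a = c("g7", "g20"), gene_b = c("g8", "g28"))
  cls <- classify_duplicates(paste0("g", c(1, 7, 8, 20, 28)), pairs, pos,
                             blocks = data.frame(gene_a = character(),
                                                 gene_b = character()))
  got <- stats::setNames(cls$class, cls$gene_id)
  expect_equal(unname(got["g1"]), "singleton")
  expect_equal(unname(got[c("g7", "g8")]), rep("tandem", 2))   # rank gap 1
  expect_equal(unname(got[c("g20", "g28")]), rep("proximal", 2))  # gap 8

  # rank gap beyond proximal_max_gap on the same chromosome: dispersed
  pairs2 <- data.frame(gene_a = "g1", gene_b = "g29")
  cls2 <- classify_duplicates(c("g1", "g29"), pairs2, pos,
                              blocks = data.frame(gene_a = character(),
                                                  gene_b = character()))
  expect_equal(cls2$class, rep("dispersed", 2))
})

test_that("block anchors outrank tandem in the precedence", {
  # g1..g5 on c1 anchor a block with c2 and g1 is also tandem-adjacent to g2
  pos <- diag_pos()
  pairs <- data.frame(gene_a = paste0("a", 1:5), gene_b = paste0("b", 1:5))
  pairs <- rbind(pairs, data.frame(gene_a = "a1", gene_b = "a2"))
  bl <- chain_collinear_blocks(pairs, pos)
  cls <- classify_duplicates(c("a1", "a2"), pairs, pos, bl)
  # by hand: a1 anchors a block (wgd wins) and is tandem-adjacent; the
  # precedence list puts wgd_segmental first
  expect_equal(cls$class, rep("wgd_segmental", 2))
})

test_that("classes partition the member set", {
  g <- simulate_genome_with_duplicates(seed = 42)
  bl <- chain_collinear_blocks(g$pairs, g$pos)
  cls <- classify_duplicates(g$pos$gene_id, g$pairs, g$pos, bl)
  expect_equal(nrow(cls), nrow(g$pos))
  expect_equal(sum(table(cls$class)), nrow(g$pos))
  expect_true(all(cls$class %in% c("singleton", "dispersed", "proximal",
                                   "tandem", "wgd_segmental")))
})

test_that("chi-square enrichment matches hand arithmetic", {
  # identical shares: statistic 0, p 1
  same <- type_enrichment_chi2(c(wgd = 10, other = 90),
                               c(wgd = 100, other = 900))
  expect_equal(same$chi2[1], 0)
  expect_equal(same$p[1], 1)

  # direct textbook formula on the 2x2 table (8,2 / 100,900)
  res <- type_enrichment_chi2(c(focal = 8, rest = 2),
                              c(focal = 100, rest = 900))
  tab <- matrix(c(8, 2, 100, 900), 2)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2_hand <- sum((tab - exp_tab)^2 / exp_tab)
  expect_equal(res$chi2[1], chi2_hand)
  expect_equal(res$p[1], stats::pchisq(chi2_hand, 1, lower.tail = FALSE))

  # WGD share 56% among 25 family genes vs 10.27% genome-wide: significant
  wgd <- type_enrichment_chi2(
    c(wgd = 14, other = 11),
    c(wgd = 0.1027, other = 0.8973), genome_total = 28000)
  expect_true(wgd$significant[1])
  expect_lt(wgd$p[1], 0.01)

  expect_error(type_enrichment_chi2(c(a = 0, b = 5), c(a = 2, b = 0)),
               "> 0")
  expect_error(type_enrichment_chi2(c(a = 0, b = 0), c(a = 10, b = 90)),
               "zero expected")
})

test_that("BLAST tabular reader canonicalizes and filters pairs", {
  tf <- tempfile(fileext = ".blast")
  rows <- c(
    "g2\tg1\t98.1\t100\t1\t0\t1\t100\t1\t100\t1e-50\t200",
    "g1\tg2\t98.1\t100\t1\t0\t1\t100\t1\t100\t1e-48\t198",
    "g1\tg1\t100\t100\t0\t0\t1\t100\t1\t100\t0\t300",
    "g3\tg4\t90\t80\t5\t0\t1\t80\t1\t80\t2e-3\t90")
  writeLines(rows, tf)
  p <- read_blast_pairs(tf, e_max = 1e-5)
  expect_equal(nrow(p), 1L)  # self-hit and weak hit dropped, pair deduped
  expect_equal(p$gene_a, "g1")
  expect_equal(p$gene_b, "g2")
})
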