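test_that("target networks split downstream/upstream and filter scores", {
  edges <- data.frame(
    regulator = c("G", "G", "G", "u", "G"),
    target = c("x", "y", "z", "G", "w"),
    score = c(0.9, 0.8, 0.61, 0.7, 0.59))
  nw <- build_target_network(edges, "G")
  expect_equal(nw$per_gene$downstream_count, 3L)  # w dropped at 0.59
  expect_equal(nw$per_gene$upstream_count, 1L)
  expect_equal(nw$downstream_genes, c("x", "y", "z"))
  expect_equal(nw$upstream_genes, "u")

  # boundary: exactly 0.60 is kept
  nw2 <- build_target_network(
    data.frame(regulator = "G", target = "t", score = 0.60), "G")
  expect_equal(nw2$downstream_genes, "t")
})

test_that("feedback genes equal the set-algebra intersection", {
  set.seed(51)
  fam <- c("F1", "F2")
  others <- paste0("n", 1:6)
  edges <- data.frame(
    regulator = c(rep(fam, 3), others[1:4], "n1", "n2"),
    target = c(others[1:6], rep(fam, 2), "F1", "F2"),
    score = stats::runif(12, 0.6, 1))
  nw <- build_target_network(edges, fam)
  down <- unique(edges$target[edges$regulator %in% fam])
  up <- unique(edges$regulator[edges$target %in% fam])
  expect_equal(nw$feedback_genes, sort(intersect(down, up)))
})

test_that("PCC edges obey the strict thresholds", {
  x <- c(1, 2, 3, 4, 5)
  expr <- rbind(g1 = x, g2 = 2 * x + 1, g3 = -x + 10, g4 = c(5, 1, 4, 2, 3))
  net <- pcc_network(expr)
  edge <- function(a, b) net[net$gene_a == a & net$gene_b == b, ]
  expect_equal(edge("g1", "g2")$sign, "positive")   # identical profile
  expect_equal(edge("g1", "g2")$pcc, 1)
  expect_equal(edge("g1", "g3")$sign, "negative")   # exact negation
  expect_equal(edge("g1", "g3")$pcc, -1)
  expect_equal(nrow(edge("g1", "g4")), 0L)

  expect_error(pcc_network(expr[, 1:2]), "3 samples")
  expect_warning(pcc_network(rbind(expr, g5 = rep(1, 5))), "zero-variance")
})

test_that("the edge set matches the direct-formula PCC on random data", {
  set.seed(52)
  expr <- matrix(stats::rnorm(30), 6, 5,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
  net <- pcc_network(expr, pos_thr = 0.3, neg_thr = -0.3)
  ids <- rownames(expr)
  manual <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    r <- oracle_pcc(expr[i, ], expr[j, ])
    if (r > 0.3 || r < -0.3)
      manual[[length(manual) + 1]] <- data.frame(
        gene_a = ids[i], gene_b = ids[j], pcc = r,
        sign = if (r > 0.3) "positive" else "negative")
  }
  manual <- do.call(rbind, manual)
  manual <- manual[order(manual$gene_a, manual$gene_b), ]
  expect_equal(net$gene_a, manual$gene_a)
  expect_equal(net$pcc, manual$pcc, tolerance = 1e-12)
  expect_equal(net$sign, manual$sign)
  expect_true(all(abs(net$pcc) <= 1))
  expect_equal(sum(net$sign == "positive") + sum(net$sign == "negative"),
               nrow(net))
})

test_that("the edge set is invariant under gene relabeling", {
  set.seed(53)
  expr <- matrix(stats::rnorm(25), 5, 5,
                 dimnames = list(paste0("g", 1:5), NULL))
  net <- pcc_network(expr, pos_thr = 0.2, neg_thr = -0.2)
  relab <- c(g1 = "z9", g2 = "a1", g3 = "m5", g4 = "b2", g5 = "q7")
  expr2 <- expr
  rownames(expr2) <- relab[rownames(expr)]
  net2 <- pcc_network(expr2, pos_thr = 0.2, neg_thr = -0.2)
  key1 <- sort(unname(apply(cbind(relab[net$gene_a], relab[net$gene_b]), 1,
                            function(r) paste(sort(r), collapse = "~"))))
  key2 <- sort(paste(net2$gene_a, net2$gene_b, sep = "~"))
  expect_equal(key1, key2)
})

test_that("hub ranking counts degrees and top-k composition", {
  edges <- data.frame(
    gene_a = rep("c", 4), gene_b = paste0("l", 1:4),
    sign = c("positive", "positive", "negative", "positive"),
    family_a = "Hsf", family_b = rep("Hsp40", 4))
  hr <- hub_ranking(edges, k = 3)
  expect_equal(hr$degrees$degree[hr$degrees$gene_id == "c"], 4L)
  expect_equal(hr$degrees$negative_degree[hr$degrees$gene_id == "c"], 1L)
  expect_equal(hr$top$gene_id[1], "c")

  hsp_only <- hub_ranking(edges, k = 3, families_in = "Hsp40")
  expect_false("c" %in% hsp_only$degrees$gene_id)

  empty <- hub_ranking(edges[0, ])
  expect_equal(nrow(empty$degrees), 0L)
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  # N=20 background genes, K=5 carry the term, n=4 targets, k=3
  bg <- sprintf("b%02d", 1:20)
  term_genes <- bg[1:5]
  targets <- c(bg[1:3], bg[10])
  ann <- rbind(data.frame(gene_id = term_genes, term = "T1"),
               data.frame(gene_id = bg, term = "ALL"))
  res <- term_enrichment(targets, ann, bg)
  row <- res[res$term == "T1", ]
  expect_equal(row$k, 3L)
  expect_equal(row$p, oracle_hypergeom_upper(20, 5, 4, 3),
               tolerance = 1e-12)
  expect_true(all(res$q >= res$p))
  expect_equal(row$fold, (3 / 4) / (5 / 20))

  # k/n equal to K/N: fold 1, never significant
  ann2 <- rbind(data.frame(gene_id = bg[1:10], term = "T2"),
                data.frame(gene_id = bg, term = "ALL"))
  res2 <- term_enrichment(bg[c(1, 2, 11, 12)], ann2, bg)
  r2 <- res2[res2$term == "T2", ]
  expect_equal(r2$fold, 1)
  expect_false(r2$significant)

  expect_error(term_enrichment("zz", ann, bg), "subset")
})

test_that("enrichment p decreases as k grows with n, K, N fixed", {
  p_at <- function(k)
    term_enrichment(c(sprintf("b%02d", seq_len(k)),
                      sprintf("c%02d", seq_len(6 - k))),
                    rbind(data.frame(gene_id = sprintf("b%02d", 1:8),
                                     term = "T"),
                          data.frame(gene_id = c(sprintf("b%02d", 1:8),
                                                 sprintf("c%02d", 1:12)),
                                     term = "ALL")),
                    c(sprintf("b%02d", 1:8), sprintf("c%02d", 1:12)))
  ps <- vapply(1:6, function(k) {
    res <- p_at(k)
    res$p[res$term == "T"]
  }, 1)
  expect_true(all(diff(ps) < 0))
})

test_that("significance needs both q < .05 and fold > 2", {
  # a strongly enriched term passes both rules
  bg <- sprintf("b%03d", 1:500)
  ann <- rbind(data.frame(gene_id = bg[1:10], term = "AP2"),
               data.frame(gene_id = bg, term = "ALL"))
  res <- term_enrichment(bg[1:10], ann, bg)
  row <- res[res$term == "AP2", ]
  expect_true(row$significant)
  expect_gt(row$fold, 2)
  expect_lt(row$q, 0.05)
})

test_that("Venn regions follow inclusion-exclusion", {
  # disjoint two sets
  v <- venn_partition(list(A = "a", B = "b"))
  expect_equal(v$count[v$region == "A"], 1L)
  expect_equal(v$count[v$region == "B"], 1L)
  expect_equal(v$count[v$region == "A&B"], 0L)

  # identical sets: all mass in the intersection
  v2 <- venn_partition(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(v2$count[v2$region == "A&B"], 2L)
  expect_equal(sum(v2$count), 2L)

  # three random sets vs inclusion-exclusion
  set.seed(54)
  u <- letters
  S <- list(A = sample(u, 10), B = sample(u, 12), C = sample(u, 8))
  v3 <- venn_partition(S)
  cnt <- function(r) v3$count[v3$region == r]
  expect_equal(cnt("A") + cnt("A&B") + cnt("A&C") + cnt("A&B&C"),
               length(S$A))
  expect_equal(cnt("A&B") + cnt("A&B&C"), length(intersect(S$A, S$B)))
  expect_equal(sum(v3$count), length(unique(unlist(S))))
})

test_that("coexpression summaries report negative share and coverage", {
  edges <- data.frame(
    gene_a = c("f1", "f1", "h1"), gene_b = c("h1", "h2", "h3"),
    pcc = c(0.96, -0.97, 0.99),
    sign = c("positive", "negative", "positive"),
    family_a = c("Hsf", "Hsf", "Hsp20"),
    family_b = c("Hsp20", "Hsp20", "Hsp40"))
  s <- summarize_coexpression(edges, c(Hsf = 4L, Hsp20 = 3L, Hsp40 = 2L))
  expect_equal(s$n_edges, 3L)
  expect_equal(s$negative_share, 1 / 3)
  cov <- stats::setNames(s$family_coverage$coverage,
                         s$family_coverage$family)
  expect_equal(unname(cov["Hsf"]), 1 / 4)     # f1 of 4 Hsf genes
  expect_equal(unname(cov["Hsp20"]), 2 / 3)   # h1, h2 of 3 Hsp20 genes
  expect_equal(unname(cov["Hsp40"]), 1 / 2)   # h3 of 2 Hsp40 genes
})
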