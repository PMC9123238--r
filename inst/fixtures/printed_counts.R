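# Deterministic fixtures assembled from published summary counts. These
# builders construct concrete data objects (a family catalog, a
# co-expression edge table) whose marginal counts equal the published ones;
# all derived ratios and shares are then computed by hsfkit functions, never
# hard-coded.

# A 111-species Hsf catalog with 2950 members in total, 97 species holding
# more than 10 genes, and one alga-like species with a single member among
# 15285 genome genes.
make_catalog_from_printed_counts <- function() {
  n_species <- 111L
  counts <- integer(n_species)
  counts[1L] <- 1L                                   # V. carteri-like
  counts[2:14] <- c(4L, 6L, 8L, 10L, 3L, 5L, 7L, 9L, 2L, 4L, 6L, 8L, 10L)
  rest <- 2950L - sum(counts)                        # spread over 97 species
  base <- rest %/% 97L
  extra <- rest %% 97L
  counts[15:111] <- base + c(rep(1L, extra), rep(0L, 97L - extra))
  stopifnot(sum(counts) == 2950L, sum(counts > 10L) == 97L)
  sp <- sprintf("sp%03d", seq_len(n_species))
  members <- data.frame(
    species_id = rep(sp, counts),
    gene_id = unlist(lapply(seq_len(n_species), function(i)
      sprintf("%s_hsf%02d", sp[i], seq_len(counts[i])))),
    protein_length = 420L
  )
  genome_stats <- data.frame(
    species_id = sp,
    genome_gene_count = c(15285L, rep(30000L, n_species - 1L)),
    mean_protein_length = 380
  )
  hsfkit::family_catalog(members, genome_stats)
}

# Published Hsp subfamily sizes in B. rapa.
hsp_family_totals <- function() {
  c(Hsp20 = 38L, Hsp40 = 155L, Hsp60 = 53L, Hsp70 = 34L,
    Hsp90 = 16L, Hsp100 = 97L)
}

# A co-expression edge table matching the published B. rapa network
# marginals: 1275 edges of which 65 are negative; 22 Hsf and 216 Hsp genes
# in the network; 20 Hsp hub genes with degrees 49..30, 19 of them from
# Hsp40/Hsp60/Hsp100; one Hsf gene carrying 22 negative edges (the maximum).
make_coexpression_from_printed_counts <- function() {
  hsf <- sprintf("Hsf%02d", 1:22)
  in_net <- c(Hsp20 = 20L, Hsp40 = 90L, Hsp60 = 30L, Hsp70 = 18L,
              Hsp90 = 10L, Hsp100 = 48L)          # sums to 216
  stopifnot(sum(in_net) == 216L, all(in_net <= hsp_family_totals()))
  hsp <- unlist(lapply(names(in_net), function(f)
    sprintf("%s_%03d", f, seq_len(in_net[[f]]))))
  fam <- c(stats::setNames(rep("Hsf", 22L), hsf),
           stats::setNames(rep(names(in_net), in_net), NULL))
  names(fam) <- c(hsf, hsp)
  fam[hsp] <- sub("_.*$", "", hsp)

  # hub genes: degrees 49..30; ranks 1-3 Hsp60, Hsp100, Hsp90, then 17 more
  # from Hsp40/Hsp60/Hsp100
  hubs <- c("Hsp60_001", "Hsp100_001", "Hsp90_001",
            sprintf("Hsp40_%03d", 1:6), sprintf("Hsp60_%03d", 2:7),
            sprintf("Hsp100_%03d", 2:6))
  stopifnot(length(hubs) == 20L)
  hub_deg <- 49:30
  non_hub <- setdiff(hsp, hubs)
  partners <- c(hsf, non_hub)                      # 238 - 20 = 218 nodes

  ea <- character(0); eb <- character(0); sg <- character(0)
  at <- 0L
  for (i in seq_along(hubs)) {
    take <- (at + seq_len(hub_deg[i]) - 1L) %% length(partners) + 1L
    ea <- c(ea, rep(hubs[i], hub_deg[i]))
    eb <- c(eb, partners[take])
    sg <- c(sg, rep("positive", hub_deg[i]))
    at <- at + hub_deg[i]
  }
  # negative edges: Hsf02 carries 22 (the maximum); 43 spread over the rest
  neg_partner <- non_hub
  ea <- c(ea, rep("Hsf02", 22L)); eb <- c(eb, neg_partner[1:22])
  sg <- c(sg, rep("negative", 22L))
  others <- rep(sprintf("Hsf%02d", 3:22), length.out = 43L)
  ea <- c(ea, others); eb <- c(eb, neg_partner[23:65])
  sg <- c(sg, rep("negative", 43L))
  # positive filler among non-hub Hsp genes up to 1275 edges
  need <- 1275L - length(ea)
  n0 <- length(non_hub)
  fill_a <- character(0); fill_b <- character(0)
  k <- 1L
  while (length(fill_a) < need) {
    m <- min(n0, need - length(fill_a))
    i <- seq_len(m)
    fill_a <- c(fill_a, non_hub[i])
    fill_b <- c(fill_b, non_hub[(i + k - 1L) %% n0 + 1L])
    k <- k + 1L
  }
  ea <- c(ea, fill_a); eb <- c(eb, fill_b)
  sg <- c(sg, rep("positive", need))

  swap <- ea > eb
  tmp <- ea[swap]; ea[swap] <- eb[swap]; eb[swap] <- tmp
  edges <- data.frame(gene_a = ea, gene_b = eb,
                      pcc = ifelse(sg == "positive", 0.97, -0.97),
                      sign = sg,
                      family_a = unname(fam[ea]), family_b = unname(fam[eb]))
  stopifnot(nrow(edges) == 1275L,
            !anyDuplicated(paste(edges$gene_a, edges$gene_b)))
  edges
}
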