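#' Collapse alternative isoforms to one representative per locus
#'
#' Gene models downloaded from genome databases usually carry several
#' alternative splice forms per locus. Family statistics must count loci, not
#' transcripts, so each locus is reduced to its longest protein; length ties
#' are broken by the lexicographically smallest `gene_id` so the result is
#' reproducible.
#'
#' @param records data.frame of gene records with columns `gene_id`,
#'   `species_id`, `locus_id`, `protein_length`, and optionally `chrom`,
#'   `start`, `end`, `strand`.
#' @return data.frame with exactly one row per (`species_id`, `locus_id`),
#'   sorted by `species_id` then `locus_id`.
#' @export
dedupe_isoforms <- function(records) {
  records <- validate_gene_records(records)
  if (nrow(records) == 0L) return(records)
  key <- paste(records$species_id, records$locus_id, sep = "\r")
  # max length, then smallest gene_id: order so the winner is first in group
  o <- order(key, -records$protein_length, records$gene_id)
  records <- records[o, , drop = FALSE]
  keep <- !duplicated(key[o])
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$species_id, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_gene_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("gene_id", "species_id", "locus_id", "protein_length")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("gene records missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(records)) {
    if (any(records$protein_length < 1))
      stop("protein_length must be >= 1")
    key <- paste(records$species_id, records$gene_id)
    if (anyDuplicated(key))
      stop("duplicated (species_id, gene_id): ",
           key[duplicated(key)][1L])
    if (all(c("start", "end") %in% names(records))) {
      both <- !is.na(records$start) & !is.na(records$end)
      if (any(records$start[both] > records$end[both]))
        stop("start > end for some gene records")
    }
  }
  records
}

#' Build a gene-family catalog from profile-domain hits
#'
#' A gene belongs to the family iff it has at least one hit to the family's
#' profile domain (for plant Hsfs, Pfam PF00447) with e-value strictly below
#' `e_max`. Records must already be isoform-deduplicated (one row per locus);
#' genome-wide gene counts and mean protein lengths are taken from `records`
#' unless `genome_stats` overrides them.
#'
#' @param hits data.frame of domain hits with columns `gene_id`,
#'   `domain_accession`, `e_value` (and optionally `ali_from`, `ali_to`).
#' @param records deduplicated gene records (see [dedupe_isoforms()]); every
#'   hit `gene_id` must be present here.
#' @param accession profile accession defining the family, e.g. `"PF00447"`.
#' @param e_max e-value threshold; membership requires `e_value < e_max`
#'   (strict).
#' @param hits2 optional second hit table (e.g. SMART/CDD validation);
#'   membership is the intersection of the two qualifying sets.
#' @param genome_stats optional data.frame (`species_id`, `genome_gene_count`,
#'   `mean_protein_length`) replacing per-species genome statistics derived
#'   from `records` — useful when `records` holds family candidates only.
#' @return a `family_catalog` object; see [family_catalog()].
#' @export
select_family_members <- function(hits, records, accession, e_max = 1e-4,
                                  hits2 = NULL, genome_stats = NULL) {
  records <- validate_gene_records(records)
  qualify <- function(h) {
    stopifnot(is.data.frame(h))
    need <- c("gene_id", "domain_accession", "e_value")
    miss <- setdiff(need, names(h))
    if (length(miss))
      stop("hit table missing column(s): ", paste(miss, collapse = ", "))
    if (nrow(h) && any(h$e_value < 0)) stop("e_value must be >= 0")
    unknown <- setdiff(unique(h$gene_id), records$gene_id)
    if (length(unknown))
      stop("hit for gene absent from gene records: ", unknown[1L])
    unique(h$gene_id[h$domain_accession == accession & h$e_value < e_max])
  }
  members <- qualify(hits)
  if (!is.null(hits2)) members <- intersect(members, qualify(hits2))

  if (is.null(genome_stats)) {
    sp <- sort(unique(records$species_id))
    genome_stats <- data.frame(
      species_id = sp,
      genome_gene_count = as.integer(
        table(factor(records$species_id, levels = sp))),
      mean_protein_length = as.numeric(tapply(
        records$protein_length,
        factor(records$species_id, levels = sp), mean))
    )
  }
  m <- records[records$gene_id %in% members,
               c("species_id", "gene_id", "protein_length")]
  m <- m[order(m$species_id, m$gene_id), , drop = FALSE]
  rownames(m) <- NULL
  family_catalog(m, genome_stats)
}

#' Construct a family catalog object
#'
#' Container pairing per-species family membership (with protein lengths)
#' with genome-wide gene counts and mean protein lengths. Normally produced
#' by [select_family_members()]; the constructor is exported so catalogs can
#' also be assembled from published per-species counts.
#'
#' @param members data.frame with columns `species_id`, `gene_id`,
#'   `protein_length`.
#' @param genome_stats data.frame with columns `species_id`,
#'   `genome_gene_count`, `mean_protein_length`. Every member species must
#'   appear; species without members may be listed (they count as zero-member
#'   species in summaries).
#' @return object of class `family_catalog`.
#' @export
family_catalog <- function(members, genome_stats) {
  stopifnot(is.data.frame(members), is.data.frame(genome_stats))
  need_m <- c("species_id", "gene_id", "protein_length")
  need_g <- c("species_id", "genome_gene_count", "mean_protein_length")
  if (!all(need_m %in% names(members)))
    stop("members needs columns: ", paste(need_m, collapse = ", "))
  if (!all(need_g %in% names(genome_stats)))
    stop("genome_stats needs columns: ", paste(need_g, collapse = ", "))
  if (anyDuplicated(genome_stats$species_id))
    stop("duplicated species in genome_stats")
  extra <- setdiff(unique(members$species_id), genome_stats$species_id)
  if (length(extra))
    stop("member species missing from genome_stats: ", extra[1L])
  cnt <- table(factor(members$species_id, levels = genome_stats$species_id))
  if (any(as.integer(cnt) > genome_stats$genome_gene_count))
    stop("member count exceeds genome_gene_count for some species")
  members <- members[order(members$species_id, members$gene_id), ,
                     drop = FALSE]
  rownames(members) <- NULL
  structure(list(members = members, genome_stats = genome_stats),
            class = "family_catalog")
}

#' @export
print.family_catalog <- function(x, ...) {
  cat("family_catalog:", nrow(x$members), "members across",
      nrow(x$genome_stats), "species\n")
  invisible(x)
}

#' Per-species and global summary statistics of a family catalog
#'
#' Computes, per species: member count, count ratio (members / genome genes),
#' log2 member count and log10 genome gene count (counts of zero are reported
#' as `NA`, not `-Inf`), and the length ratio (mean family protein length /
#' mean genome protein length). Global rows give the mean member count over
#' species, the fraction of species with more than 10 members, and the
#' fraction of species whose length ratio exceeds 1.2. Ratios are on a 0-1
#' scale; format as percentages at the reporting layer.
#'
#' @param catalog a [family_catalog()] object.
#' @return list with elements `species` (one row per species) and `global`
#'   (one-row data.frame).
#' @export
summarize_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "family_catalog"))
  gs <- catalog$genome_stats
  if (any(gs$genome_gene_count <= 0))
    stop("genome_gene_count must be > 0 for every species")
  sp <- gs$species_id
  fct <- factor(catalog$members$species_id, levels = sp)
  n <- as.integer(table(fct))
  fam_len <- as.numeric(tapply(catalog$members$protein_length, fct, mean))
  species <- data.frame(
    species_id = sp,
    member_count = n,
    genome_gene_count = gs$genome_gene_count,
    count_ratio = n / gs$genome_gene_count,
    log2_member_count = ifelse(n > 0, log2(n), NA_real_),
    log10_genome_count = ifelse(gs$genome_gene_count > 0,
                                log10(gs$genome_gene_count), NA_real_),
    length_ratio = fam_len / gs$mean_protein_length
  )
  global <- data.frame(
    n_species = length(sp),
    total_members = sum(n),
    mean_member_count = mean(n),
    frac_gt10 = mean(n > 10),
    frac_length_ratio_gt1.2 = mean(!is.na(species$length_ratio) &
                                     species$length_ratio > 1.2)
  )
  list(species = species, global = global)
}

#' Read HMMER3 per-domain tabular output
#'
#' Parses the fixed-column `--domtblout` layout (whitespace-delimited, `#`
#' comment lines). Only the columns needed for family cataloguing are kept:
#' target (gene) id, query accession, independent per-domain e-value, and the
#' alignment span on the target.
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `domain_accession`, `e_value`,
#'   `ali_from`, `ali_to`.
#' @export
read_domtbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(gene_id = character(), domain_accession = character(),
                      e_value = numeric(), ali_from = integer(),
                      ali_to = integer()))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- vapply(fields, length, 1L) < 23L
  if (any(bad)) stop("malformed domtblout line: ", which(bad)[1L])
  # domtblout columns: 1 target, 5 query accession, 13 i-Evalue, 18-19 ali span
  data.frame(
    gene_id = vapply(fields, `[[`, "", 1L),
    domain_accession = sub("\\.\\d+$", "",
                           vapply(fields, `[[`, "", 5L)),
    e_value = as.numeric(vapply(fields, `[[`, "", 13L)),
    ali_from = as.integer(vapply(fields, `[[`, "", 18L)),
    ali_to = as.integer(vapply(fields, `[[`, "", 19L))
  )
}

#' Read a gene table (TSV)
#'
#' Expected columns: `gene_id`, `species_id`, `locus_id`, `protein_length`
#' and optionally `chrom`, `start`, `end`, `strand`.
#'
#' @param path file path.
#' @return validated data.frame of gene records.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_gene_records(df)
}

#' Protein lengths from a FASTA file
#'
#' @param path FASTA file of protein sequences.
#' @return named integer vector of sequence lengths (aa).
#' @export
fasta_protein_lengths <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(Biostrings::width(aa), sub("\\s.*$", "", names(aa)))
}
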