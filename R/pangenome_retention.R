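#' Build a retention matrix from syntenic subgenome assignments
#'
#' A triplicated genome (e.g. *Brassica rapa* after its whole-genome
#' triplication) carries up to one syntenic copy of each reference gene in
#' each of its three subgenomes: the least fractionated (LF) and the two more
#' fractionated ones (MF1, MF2). The matrix entry for (reference gene,
#' accession) is therefore the number of distinct subgenomes with a copy
#' (0-3); per-subgenome counts are kept alongside. Two assignments of
#' different copy genes to the same (reference, accession, subgenome) slot
#' violate this structure and raise an error.
#'
#' @param assignments data.frame `ref_gene`, `accession`, `subgenome`
#'   (`LF`/`MF1`/`MF2`), `copy_gene`.
#' @param ref_genes,accessions optional vectors fixing row/column order (and
#'   including rows/columns with no assignment); defaults to the sorted
#'   values present.
#' @return object of class `retention_matrix`: list with `matrix` (ref genes
#'   x accessions, integer 0-3), `by_subgenome` (data.frame `ref_gene`,
#'   `accession`, `subgenome`, `copy_gene`), `subgenome_totals` (accession x
#'   subgenome counts).
#' @export
count_retention <- function(assignments, ref_genes = NULL,
                            accessions = NULL) {
  need <- c("ref_gene", "accession", "subgenome", "copy_gene")
  if (!all(need %in% names(assignments)))
    stop("assignments needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(assignments$subgenome), c("LF", "MF1", "MF2"))
  if (length(bad)) stop("invalid subgenome label: ", bad[1L])
  key <- paste(assignments$ref_gene, assignments$accession,
               assignments$subgenome, sep = "\r")
  if (anyDuplicated(key)) {
    d <- assignments[key %in% key[duplicated(key)], , drop = FALSE]
    stop("multiple copies in one subgenome slot: ",
         d$ref_gene[1L], " / ", d$accession[1L], " / ", d$subgenome[1L])
  }
  if (is.null(ref_genes)) ref_genes <- sort(unique(assignments$ref_gene))
  if (is.null(accessions)) accessions <- sort(unique(assignments$accession))
  m <- matrix(0L, length(ref_genes), length(accessions),
              dimnames = list(ref_genes, accessions))
  tab <- table(factor(assignments$ref_gene, levels = ref_genes),
               factor(assignments$accession, levels = accessions))
  m[] <- as.integer(tab)
  sub_tot <- table(factor(assignments$accession, levels = accessions),
                   factor(assignments$subgenome,
                          levels = c("LF", "MF1", "MF2")))
  asg <- assignments[order(assignments$ref_gene, assignments$accession,
                           assignments$subgenome), , drop = FALSE]
  rownames(asg) <- NULL
  structure(list(matrix = m, by_subgenome = asg,
                 subgenome_totals = unclass(sub_tot)),
            class = "retention_matrix")
}

#' @export
print.retention_matrix <- function(x, ...) {
  cat("retention_matrix:", nrow(x$matrix), "reference genes x",
      ncol(x$matrix), "accessions\n")
  invisible(x)
}

#' Syntenic retention summary per accession
#'
#' @param x a `retention_matrix`.
#' @param family_totals named vector: total family size per accession
#'   (denominator of the syntenic ratio).
#' @return list with `per_accession` (data.frame `accession`,
#'   `syntenic_genes` (distinct copy genes), `family_total`,
#'   `syntenic_ratio`) and `family_size_range` (min/max of the per-accession
#'   family sizes).
#' @export
retention_summary <- function(x, family_totals) {
  stopifnot(inherits(x, "retention_matrix"))
  acc <- colnames(x$matrix)
  miss <- setdiff(acc, names(family_totals))
  if (length(miss)) stop("family_totals missing accession: ", miss[1L])
  if (any(family_totals <= 0)) stop("family_totals must be > 0")
  syn <- vapply(acc, function(a)
    length(unique(x$by_subgenome$copy_gene[x$by_subgenome$accession == a])),
    1L)
  per <- data.frame(accession = acc, syntenic_genes = syn,
                    family_total = unname(family_totals[acc]),
                    syntenic_ratio = syn / unname(family_totals[acc]))
  rownames(per) <- NULL
  list(per_accession = per,
       family_size_range = range(family_totals[acc]))
}

#' Detect syntenic losses in a retention matrix
#'
#' @param x a `retention_matrix`.
#' @return list with `pairs` (data.frame `ref_gene`, `accession` for every
#'   zero entry) and `lost_in_all` (reference genes with all-zero rows).
#' @export
detect_losses <- function(x) {
  stopifnot(inherits(x, "retention_matrix"))
  zero <- which(x$matrix == 0L, arr.ind = TRUE)
  pairs <- data.frame(ref_gene = rownames(x$matrix)[zero[, 1L]],
                      accession = colnames(x$matrix)[zero[, 2L]])
  pairs <- pairs[order(pairs$ref_gene, pairs$accession), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       lost_in_all = rownames(x$matrix)[rowSums(x$matrix) == 0L])
}

#' Write / read a retention matrix as TSV
#'
#' The TSV holds the ref gene x accession copy-count matrix; reading it back
#' reproduces the matrix exactly (subgenome detail is not round-tripped).
#'
#' @param x a `retention_matrix`.
#' @param path file path.
#' @param accession_order optional column order.
#' @return `write_retention_tsv` returns `path` invisibly;
#'   `read_retention_tsv` returns the integer matrix.
#' @export
write_retention_tsv <- function(x, path, accession_order = NULL) {
  m <- x$matrix
  if (!is.null(accession_order)) m <- m[, accession_order, drop = FALSE]
  df <- data.frame(ref_gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_retention_tsv
#' @export
read_retention_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}
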