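#' Extract promoter sequences upstream of the translation initiation site
#'
#' For a plus-strand gene the promoter is the `length` bases ending
#' immediately before the CDS start; for a minus-strand gene, the `length`
#' bases after the CDS end, reverse-complemented. Promoters are reported
#' 5' -> 3' relative to the gene and are truncated at chromosome edges.
#' "Translation initiation site" is the CDS start, not the transcript start.
#'
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences, uppercase `A/C/G/T/N`.
#' @param genes data.frame `gene_id`, `chrom`, `cds_start`, `cds_end`,
#'   `strand` (`+`/`-`); coordinates 1-based inclusive and within chromosome
#'   bounds.
#' @param length promoter length in nt (default 2000, i.e. 2 kb upstream).
#' @return data.frame `gene_id`, `sequence`, `length`; zero-length promoters
#'   (CDS at the chromosome edge) are reported with empty sequences.
#' @export
extract_promoters <- function(genome, genes, length = 2000L) {
  if (inherits(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  stopifnot(is.character(genome), !is.null(names(genome)))
  need <- c("gene_id", "chrom", "cds_start", "cds_end", "strand")
  if (!all(need %in% names(genes)))
    stop("genes needs columns: ", paste(need, collapse = ", "))
  seqs <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    chr <- genes$chrom[i]
    if (!chr %in% names(genome)) stop("unknown chromosome: ", chr)
    L <- nchar(genome[[chr]])
    s <- genes$cds_start[i]; e <- genes$cds_end[i]
    if (s < 1L || e > L || s > e)
      stop("gene beyond chromosome bounds: ", genes$gene_id[i])
    if (genes$strand[i] == "+") {
      from <- max(1L, s - length)
      seqs[i] <- if (s == 1L) "" else substr(genome[[chr]], from, s - 1L)
    } else {
      to <- min(L, e + length)
      seqs[i] <- if (e == L) "" else revcomp(substr(genome[[chr]], e + 1L, to))
    }
  }
  data.frame(gene_id = genes$gene_id, sequence = seqs,
             length = nchar(seqs))
}

revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nchar(s)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "", USE.NAMES = FALSE)
}

# pattern constants for the heat shock element consensus GAAnnTTnnnGAA;
# lookahead regexes report all overlapping windows, and windows containing N
# never match
HSE_FWD <- "(?=(GAA[ACGT]{2}TT[ACGT]{3}GAA))"
HSE_REV <- "(?=(TTC[ACGT]{3}AA[ACGT]{2}TTC))"

#' Scan promoters for the heat shock element consensus
#'
#' Finds every (possibly overlapping) 13-nt window matching the HSE consensus
#' `GAAnnTTnnnGAA` (`n` = any of A/C/G/T). When `both_strands = TRUE` the
#' reverse strand is scanned by matching the reverse-complement pattern
#' `TTCnnnAAnnTTC` on the forward sequence; those hits are reported with
#' strand `-` and forward-coordinate offsets. Offsets are 0-based.
#'
#' @param promoters data.frame from [extract_promoters()] (columns `gene_id`,
#'   `sequence`) or a named character vector of sequences.
#' @param both_strands scan both strands (default) or the forward strand
#'   only.
#' @return data.frame `gene_id`, `offset` (0-based match start on the forward
#'   coordinate system), `strand`, `matched` (the 13-nt element as read on
#'   the reported strand), sorted by gene, offset, strand.
#' @export
scan_hse <- function(promoters, both_strands = TRUE) {
  if (is.data.frame(promoters)) {
    ids <- promoters$gene_id
    seqs <- promoters$sequence
  } else {
    ids <- names(promoters)
    seqs <- unname(promoters)
  }
  hits <- list()
  scan1 <- function(pattern) {
    m <- gregexpr(pattern, seqs, perl = TRUE)
    lapply(m, function(x) if (x[1L] == -1L) integer(0) else as.integer(x))
  }
  fwd <- scan1(HSE_FWD)
  rev_ <- if (both_strands) scan1(HSE_REV) else vector("list", length(seqs))
  out <- list()
  for (i in seq_along(seqs)) {
    f <- fwd[[i]]
    r <- rev_[[i]]
    if (length(f))
      out[[length(out) + 1L]] <- data.frame(
        gene_id = ids[i], offset = f - 1L, strand = "+",
        matched = substring(seqs[i], f, f + 12L))
    if (!is.null(r) && length(r))
      out[[length(out) + 1L]] <- data.frame(
        gene_id = ids[i], offset = r - 1L, strand = "-",
        matched = revcomp(substring(seqs[i], r, r + 12L)))
  }
  if (!length(out))
    return(data.frame(gene_id = character(), offset = integer(),
                      strand = character(), matched = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Restrict a co-expression network to HSE-positive Hsp genes
#'
#' Keeps edges whose Hsp-family endpoints all carry at least one promoter HSE
#' (Hsf endpoints are always kept), reconstructing the heat-response
#' subnetwork from promoter evidence.
#'
#' @param edges edge table from [pcc_network()] with `family_a`/`family_b`
#'   labels.
#' @param hse_positive character vector of genes with at least one HSE hit.
#' @param hsf_family family label treated as Hsf (never filtered); every
#'   other labeled endpoint is treated as an Hsp gene and must be
#'   HSE-positive.
#' @return filtered edge table, same columns as `edges`.
#' @export
hse_subnetwork <- function(edges, hse_positive, hsf_family = "Hsf") {
  ok_end <- function(gene, fam)
    is.na(fam) | fam == hsf_family | gene %in% hse_positive
  keep <- ok_end(edges$gene_a, edges$family_a) &
    ok_end(edges$gene_b, edges$family_b)
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read chromosome sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named uppercase character vector of sequences.
#' @export
read_fasta_chroms <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(dna)), sub("\\s.*$", "", names(dna)))
}

#' Write HSE hits as TSV (1-based inclusive coordinates)
#'
#' @param hits hit table from [scan_hse()].
#' @param path output file.
#' @export
write_hse_tsv <- function(hits, path) {
  out <- data.frame(gene_id = hits$gene_id, offset_1based = hits$offset + 1L,
                    strand = hits$strand, sequence = hits$matched)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
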