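# Published SNP catalog for the three drought candidate genes and the
# fixture alignments built from it.

.CATALOG <- local({
  row <- function(gene, pos, maj, pmaj, mnr, pmin, coding)
    data.frame(gene = gene, position = pos, major_allele = maj,
               major_freq = pmaj, minor_allele = mnr, minor_freq = pmin,
               coding = coding, stringsAsFactors = FALSE)
  rbind(
    row("Asr2",   1,   "C", 0.50, "T", 0.50, FALSE),
    row("Asr2",   101, "A", 0.67, "G", 0.33, TRUE),
    row("Asr2",   185, "T", 0.73, "A", 0.27, FALSE),
    row("Asr2",   188, "T", 0.55, "A", 0.45, FALSE),
    row("Asr2",   189, "A", 0.67, "T", 0.33, FALSE),
    row("Asr2",   190, "A", 0.74, "T", 0.26, FALSE),
    row("Asr2",   191, "T", 0.69, "A", 0.31, FALSE),
    row("Asr2",   192, "T", 0.69, "A", 0.31, FALSE),
    row("Asr2",   200, "A", 0.88, "T", 0.12, FALSE),
    row("Asr2",   246, "T", 0.88, "A", 0.12, FALSE),
    row("Asr2",   407, "G", 0.67, "A", 0.33, TRUE),
    row("Asr2",   455, "C", 0.74, "A", 0.26, TRUE),
    row("Asr2",   486, "C", 0.90, "T", 0.10, TRUE),
    row("Dreb2B", 24,  "C", 0.89, "G", 0.11, TRUE),
    row("Dreb2B", 33,  "C", 0.64, "G", 0.36, TRUE),
    row("Dreb2B", 81,  "A", 0.93, "T", 0.07, TRUE),
    row("Dreb2B", 134, "A", 0.68, "G", 0.32, TRUE),
    row("Dreb2B", 135, "C", 0.68, "T", 0.32, TRUE),
    row("Dreb2B", 136, "A", 0.68, "G", 0.32, TRUE),
    row("Dreb2B", 342, "C", 0.80, "T", 0.20, TRUE),
    row("Dreb2B", 357, "G", 0.82, "C", 0.18, TRUE),
    row("ERECTA", 32,  "C", 0.85, "T", 0.15, FALSE),
    row("ERECTA", 33,  "T", 0.53, "A", 0.48, FALSE),
    row("ERECTA", 46,  "C", 0.80, "T", 0.20, FALSE),
    row("ERECTA", 47,  "A", 0.80, "G", 0.20, FALSE),
    row("ERECTA", 55,  "T", 0.93, "A", 0.08, FALSE),
    row("ERECTA", 137, "G", 0.93, "A", 0.08, TRUE),
    row("ERECTA", 172, "G", 0.93, "A", 0.08, FALSE),
    row("ERECTA", 187, "G", 0.95, "A", 0.05, FALSE),
    row("ERECTA", 189, "C", 0.93, "T", 0.08, FALSE),
    row("ERECTA", 223, "T", 0.95, "C", 0.05, FALSE),
    row("ERECTA", 228, "C", 0.93, "T", 0.08, FALSE),
    row("ERECTA", 285, "T", 0.93, "C", 0.08, FALSE),
    row("ERECTA", 286, "G", 0.93, "A", 0.08, FALSE),
    row("ERECTA", 311, "C", 0.63, "A", 0.38, FALSE),
    row("ERECTA", 449, "C", 0.93, "G", 0.08, FALSE),
    row("ERECTA", 476, "T", 0.65, "A", 0.35, FALSE),
    row("ERECTA", 480, "A", 0.93, "G", 0.08, FALSE),
    row("ERECTA", 615, "T", 0.93, "C", 0.08, TRUE),
    row("ERECTA", 637, "G", 0.90, "A", 0.10, TRUE),
    row("ERECTA", 683, "T", 0.93, "A", 0.08, TRUE),
    row("ERECTA", 725, "C", 0.63, "A", 0.38, TRUE),
    row("ERECTA", 734, "T", 0.95, "G", 0.05, TRUE))
})

.GENE_LENGTHS <- c(Asr2 = 547L, Dreb2B = 373L, ERECTA = 750L)

#' Published SNP catalog for the candidate genes
#'
#' The reported biallelic SNP positions, major/minor alleles and allele
#' frequencies for the Asr2, Dreb2B and ERECTA-encoding amplicons in the
#' tepary bean panel (13, 8 and 22 sites respectively), with a coding-region
#' flag. Positions are 1-based amplicon coordinates.
#'
#' @param gene Optional gene name to subset (\code{"Asr2"}, \code{"Dreb2B"},
#'   \code{"ERECTA"}).
#' @return Data frame \code{gene, position, major_allele, major_freq,
#'   minor_allele, minor_freq, coding}.
#' @export
candidate_snp_catalog <- function(gene = NULL) {
  out <- .CATALOG
  if (!is.null(gene)) {
    if (!gene %in% names(.GENE_LENGTHS)) stop("unknown gene: ", gene)
    out <- out[out$gene == gene, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Amplicon lengths of the candidate genes
#' @return Named integer vector (bp).
#' @export
candidate_gene_lengths <- function() .GENE_LENGTHS

#' Fixture alignment encoding the published SNP catalog
#'
#' Builds a deterministic n-sequence alignment of the gene's reported
#' amplicon length, monomorphic ('A') except at catalog positions, where the
#' minor allele is assigned to the first \code{ceiling(minor_freq * n)}
#' sequences and the major allele to the rest (per-site independent
#' assignment; haplotype phase in the published table is unknowable, so
#' haplotype-level analyses should use \code{\link{simulate_alignment}}
#' instead). With the default n = 100 the recomputed frequencies reproduce
#' the printed 2-decimal values exactly.
#'
#' @param gene One of \code{"Asr2"}, \code{"Dreb2B"}, \code{"ERECTA"}.
#' @param n Number of sequences (default 100).
#' @return A \code{\link{gene_alignment}} with taxa set to
#'   \code{"acutifolius_wild"}.
#' @export
catalog_fixture <- function(gene, n = 100L) {
  if (!gene %in% names(.GENE_LENGTHS)) stop("unknown gene: ", gene)
  cat_g <- candidate_snp_catalog(gene)
  L <- .GENE_LENGTHS[[gene]]
  m <- matrix("A", nrow = n, ncol = L)
  for (r in seq_len(nrow(cat_g))) {
    n_min <- as.integer(ceiling(cat_g$minor_freq[r] * n - 1e-9))
    col <- rep(cat_g$major_allele[r], n)
    if (n_min > 0L) col[seq_len(n_min)] <- cat_g$minor_allele[r]
    m[, cat_g$position[r]] <- col
  }
  gene_alignment(m, ids = sprintf("%s_%03d", gene, seq_len(n)),
                 taxa = rep("acutifolius_wild", n), gene = gene)
}
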