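# SNP calling from amplicon alignments, allele frequencies, He, maf filter.

.BASES <- c("A", "C", "G", "T")

#' Call biallelic SNPs from an alignment
#'
#' Scans every alignment column; a column is emitted when exactly two of
#' {A,C,G,T} are observed among non-missing calls. Gaps, N and ambiguity
#' codes are treated as missing. Columns with more than two allele states, or
#' with a missing fraction above \code{max_missing}, are excluded (and
#' recorded in the \code{excluded} attribute). Sequences whose taxon label is
#' in \code{exclude_taxa} (sequencing controls by default) are ignored.
#'
#' @param aln A \code{\link{gene_alignment}}.
#' @param max_missing Maximum tolerated fraction of missing calls per column.
#' @param exclude_taxa Taxon labels excluded from frequency computations.
#' @return A \code{variant_table}: data frame with columns \code{position}
#'   (1-based alignment column), \code{major_allele}, \code{major_freq},
#'   \code{minor_allele}, \code{minor_freq}, \code{n_called}, \code{he},
#'   \code{coding}, \code{nonsyn}; attributes \code{gene}, \code{excluded}.
#' @export
call_variants <- function(aln, max_missing = 0.5, exclude_taxa = "control") {
  stopifnot(inherits(aln, "gene_alignment"))
  keep <- !(aln$taxa %in% exclude_taxa)
  m <- aln$seq[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("no sequences left after excluding taxa")
  rows <- list()
  excluded <- list()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    called <- col[col %in% .BASES]
    miss_frac <- 1 - length(called) / length(col)
    tab <- sort(table(factor(called, levels = .BASES)), decreasing = TRUE)
    tab <- tab[tab > 0]
    if (length(tab) < 2L) next # monomorphic or all-missing
    if (length(tab) > 2L) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(position = j, reason = "multiallelic")
      next
    }
    if (miss_frac > max_missing) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(position = j, reason = "missing_fraction")
      next
    }
    n <- length(called)
    p <- as.numeric(tab[1]) / n
    q <- as.numeric(tab[2]) / n
    rows[[length(rows) + 1L]] <- data.frame(
      position = j,
      major_allele = names(tab)[1], major_freq = p,
      minor_allele = names(tab)[2], minor_freq = q,
      n_called = n,
      he = expected_heterozygosity(c(p, q)),
      coding = NA, nonsyn = NA,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), major_allele = character(),
               major_freq = numeric(), minor_allele = character(),
               minor_freq = numeric(), n_called = integer(), he = numeric(),
               coding = logical(), nonsyn = logical(),
               stringsAsFactors = FALSE)
  attr(out, "gene") <- aln$gene
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else NULL
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Expected heterozygosity
#'
#' \eqn{H_e = 1 - \sum_i p_i^2}; for a biallelic site this is 2pq, bounded by
#' 0.5. Used as a polymorphism-information-content proxy.
#'
#' @param freqs Allele frequencies summing to 1.
#' @return H_e at full precision.
#' @export
expected_heterozygosity <- function(freqs) {
  if (abs(sum(freqs) - 1) > 1e-8) stop("allele frequencies must sum to 1")
  1 - sum(freqs^2)
}

#' Minor-allele-frequency filter
#'
#' Retains rows whose minor-allele frequency is at least \code{threshold}
#' (inclusive, so sites printed at exactly the threshold survive); row order
#' is preserved and the operation is idempotent.
#'
#' @param table A \code{variant_table}.
#' @param threshold Minimum minor-allele frequency (default 0.05).
#' @return The filtered \code{variant_table}.
#' @export
maf_filter <- function(table, threshold = 0.05) {
  keep <- table$minor_freq >= threshold
  out <- table[keep, , drop = FALSE]
  attr(out, "gene") <- attr(table, "gene")
  attr(out, "excluded") <- attr(table, "excluded")
  class(out) <- class(table)
  rownames(out) <- NULL
  out
}

#' Haploid genotype matrix
#'
#' Codes each retained SNP per individual as 0 (major allele), 1 (minor
#' allele) or NA (missing/other), individuals in alignment order (excluding
#' \code{exclude_taxa}). Column allele frequencies reproduce the variant
#' table's.
#'
#' @param aln The \code{gene_alignment} the table was called from.
#' @param table A \code{variant_table}.
#' @param exclude_taxa Taxon labels to drop (must match the call used for
#'   \code{table}).
#' @return Integer matrix individuals x SNPs with dimnames (accession IDs,
#'   \code{pos<position>}); attribute \code{taxa} carries the labels.
#' @export
genotype_matrix <- function(aln, table, exclude_taxa = "control") {
  stopifnot(inherits(aln, "gene_alignment"))
  keep <- !(aln$taxa %in% exclude_taxa)
  m <- aln$seq[keep, , drop = FALSE]
  if (any(table$position < 1L | table$position > ncol(m)))
    stop("variant position out of alignment range")
  gm <- matrix(NA_integer_, nrow = nrow(m), ncol = nrow(table),
               dimnames = list(rownames(m), paste0("pos", table$position)))
  for (k in seq_len(nrow(table))) {
    col <- m[, table$position[k]]
    gm[col == table$major_allele[k], k] <- 0L
    gm[col == table$minor_allele[k], k] <- 1L
  }
  attr(gm, "taxa") <- aln$taxa[keep]
  attr(gm, "gene") <- aln$gene
  gm
}

#' Per-gene variant summary
#'
#' @param table A \code{variant_table} for one gene.
#' @return List with \code{S} (segregating-site count), \code{mean_maf} and
#'   \code{mean_he} (arithmetic means across rows; NA when S = 0).
#' @export
gene_summary <- function(table) {
  S <- nrow(table)
  list(S = S,
       mean_maf = if (S) mean(table$minor_freq) else NA_real_,
       mean_he = if (S) mean(table$he) else NA_real_)
}

#' Write a variant table to CSV
#' @param table A \code{variant_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_variant_csv <- function(table, path) {
  df <- as.data.frame(table)
  df$gene <- attr(table, "gene")
  utils::write.csv(df[, c("gene", setdiff(names(df), "gene"))], path,
                   row.names = FALSE)
  invisible(path)
}
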