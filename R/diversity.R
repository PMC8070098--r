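# Site-frequency-spectrum summary statistics: pi, Watterson's theta, Tajima's D.

# Missing = anything outside A/C/G/T (gaps, N, ambiguity codes).
.is_called <- function(m) m == "A" | m == "C" | m == "G" | m == "T"

#' Nucleotide diversity (pi)
#'
#' Average proportion of differing sites over all C(n,2) sequence pairs.
#' Under \code{deletion = "pairwise"} (default, DnaSP-like) each pair is
#' compared over the sites called in both sequences, with that pair's own
#' effective length; \code{deletion = "complete"} first drops every column
#' with any missing call.
#'
#' @param aln A \code{gene_alignment} (or subset).
#' @param deletion Missing-data rule, \code{"pairwise"} or \code{"complete"}.
#' @return Per-site nucleotide diversity.
#' @export
nucleotide_diversity <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- aln$seq
  n <- nrow(m)
  if (n < 2L) stop("nucleotide diversity needs at least 2 sequences")
  ok <- .is_called(m)
  if (deletion == "complete") {
    keep <- colSums(ok) == n
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
    if (ncol(m) == 0L) stop("no columns left after complete deletion")
  }
  tot <- 0
  np <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- ok[i, ] & ok[j, ]
      L <- sum(both)
      if (L == 0L) next
      tot <- tot + sum(m[i, both] != m[j, both]) / L
      np <- np + 1L
    }
  }
  if (np == 0L) stop("no comparable sequence pairs")
  tot / np
}

#' Watterson's theta per site
#'
#' \eqn{\theta_W = S / (a_1 L)} with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param S Number of segregating sites.
#' @param n Number of sequences.
#' @param L Sequence length (bp).
#' @return Per-site Watterson estimate.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2L) stop("Watterson's theta needs at least 2 sequences")
  if (L <= 0) stop("L must be positive")
  S / (sum(1 / seq_len(n - 1L)) * L)
}

#' Count segregating sites
#'
#' Columns with two or more called allele states among A/C/G/T.
#'
#' @param aln A \code{gene_alignment}.
#' @return Integer count.
#' @export
segregating_sites <- function(aln) {
  m <- aln$seq
  sum(apply(m, 2, function(col) {
    length(unique(col[col %in% .BASES])) >= 2L
  }))
}

# Tajima (1989) normalising constants for sample size n.
.tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' \eqn{D = (\hat\pi - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}} where
#' \eqn{\hat\pi} is the unnormalised mean pairwise difference count and the
#' constants follow Tajima's original derivation. Undefined (NA) for S = 0 or
#' n < 4. Negative D reflects an excess of rare variants
#' (purifying/directional selection or expansion), positive D an excess of
#' intermediate-frequency variants (balancing selection or structure).
#'
#' @param aln A \code{gene_alignment} (or subset).
#' @return Tajima's D, or NA when undefined.
#' @export
tajimas_d <- function(aln) {
  m <- aln$seq
  n <- nrow(m)
  if (n < 4L) return(NA_real_)
  S <- segregating_sites(aln)
  if (S == 0L) return(NA_real_)
  # mean pairwise difference count (not per site)
  ok <- .is_called(m)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- ok[i, ] & ok[j, ]
      tot <- tot + sum(m[i, both] != m[j, both])
    }
  }
  pi_total <- tot / choose(n, 2)
  k <- .tajima_constants(n)
  (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Site-frequency-spectrum summary per taxon
#'
#' One summary row per taxon with at least \code{min_n} sequences, plus an
#' "All" row over every non-excluded sequence. Per-taxon rows use the sites
#' segregating within that taxon, unfiltered; the "All" row applies the
#' minor-allele-frequency filter (\code{maf}) before counting S and averaging
#' maf/He, and computes pi, theta_W and Tajima's D on the same filtered
#' columns, mirroring how whole-panel tables are conventionally reported.
#'
#' @param aln A \code{gene_alignment}.
#' @param min_n Minimum sequences for a per-taxon row (default 4).
#' @param maf Minor-allele-frequency threshold applied to the "All" row.
#' @param exclude_taxa Taxon labels excluded throughout (controls).
#' @param deletion Missing-data rule for pi (see
#'   \code{\link{nucleotide_diversity}}).
#' @return Data frame with columns \code{gene, taxon, n, length_bp, S,
#'   mean_maf, mean_he, pi, theta_w, tajima_d}.
#' @export
summarize_by_taxon <- function(aln, min_n = 4L, maf = 0.05,
                               exclude_taxa = "control",
                               deletion = "pairwise") {
  stopifnot(inherits(aln, "gene_alignment"))
  keep <- !(aln$taxa %in% exclude_taxa)
  aln <- subset_alignment(aln, keep)

  one_row <- function(sub, label, maf_threshold = 0) {
    vt <- call_variants(sub, exclude_taxa = character())
    if (maf_threshold > 0) vt <- maf_filter(vt, maf_threshold)
    gs <- gene_summary(vt)
    n <- n_sequences(sub)
    L <- alignment_length(sub)
    if (maf_threshold > 0 && gs$S > 0) {
      # restrict the SFS statistics to the filtered columns
      cols <- vt$position
      sub_stats <- gene_alignment(sub$seq[, cols, drop = FALSE],
                                  ids = sub$ids, taxa = sub$taxa,
                                  gene = sub$gene)
      pi <- nucleotide_diversity(sub_stats, deletion) * ncol(sub_stats$seq) / L
      td <- tajimas_d(sub_stats)
    } else {
      pi <- if (n >= 2L) nucleotide_diversity(sub, deletion) else NA_real_
      td <- tajimas_d(sub)
    }
    data.frame(gene = aln$gene, taxon = label, n = n, length_bp = L,
               S = gs$S, mean_maf = gs$mean_maf, mean_he = gs$mean_he,
               pi = pi,
               theta_w = if (n >= 2L) watterson_theta(gs$S, n, L) else NA_real_,
               tajima_d = td, stringsAsFactors = FALSE)
  }

  rows <- list(one_row(aln, "All", maf_threshold = maf))
  for (tx in sort(unique(aln$taxa))) {
    idx <- aln$taxa == tx
    if (sum(idx) < min_n) {
      message("skipping taxon '", tx, "' (n = ", sum(idx), " < ", min_n, ")")
      next
    }
    rows[[length(rows) + 1L]] <- one_row(subset_alignment(aln, idx), tx)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
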