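# Population differentiation and structure: Hudson Fst, PCA, IBS kinship,
# neighbor-joining dendrograms with bootstrap.

.taxa_of <- function(gm, grouping = NULL) {
  if (is.null(grouping)) grouping <- attr(gm, "taxa")
  if (is.null(grouping)) stop("no taxon grouping available")
  if (length(grouping) != nrow(gm)) stop("grouping length must match individuals")
  as.character(grouping)
}

#' Per-SNP Hudson Fst between two taxa
#'
#' Hudson's estimator in its heterozygosity form: Fst = 1 - Hw/Hb, where Hw
#' averages the two unbiased within-taxon heterozygosities
#' \eqn{2 p_i (1-p_i) n_i/(n_i-1)} and \eqn{H_b = p_1(1-p_2) + p_2(1-p_1)}.
#' A SNP is scored only when both taxa have at least 2 non-missing haplotypes
#' there; SNPs with Hb = 0 (both populations fixed for the same allele) are
#' skipped. Sampling correction makes near-equal frequencies dip slightly
#' below 0; raw values are kept and \code{pmax(0, fst)} is left to reporting.
#'
#' @param gm A haploid \code{\link{genotype_matrix}} (0/1/NA).
#' @param pair Character vector of two taxon labels.
#' @param grouping Optional taxon label per individual; defaults to the
#'   matrix's \code{taxa} attribute.
#' @return Data frame \code{snp, n1, n2, p1, p2, fst} (one row per scored
#'   SNP).
#' @export
pairwise_fst <- function(gm, pair, grouping = NULL) {
  grouping <- .taxa_of(gm, grouping)
  if (length(pair) != 2L) stop("pair must name exactly two taxa")
  i1 <- grouping == pair[1]
  i2 <- grouping == pair[2]
  if (!any(i1) || !any(i2)) stop("empty taxon in pair")
  rows <- list()
  for (k in seq_len(ncol(gm))) {
    g1 <- gm[i1, k]; g1 <- g1[!is.na(g1)]
    g2 <- gm[i2, k]; g2 <- g2[!is.na(g2)]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 2L || n2 < 2L) next
    p1 <- mean(g1); p2 <- mean(g2)
    hb <- p1 * (1 - p2) + p2 * (1 - p1)
    if (hb == 0) next
    hw <- mean(c(2 * p1 * (1 - p1) * n1 / (n1 - 1),
                 2 * p2 * (1 - p2) * n2 / (n2 - 1)))
    rows[[length(rows) + 1L]] <- data.frame(
      snp = colnames(gm)[k], n1 = n1, n2 = n2, p1 = p1, p2 = p2,
      fst = 1 - hw / hb, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp = character(), n1 = integer(), n2 = integer(),
               p1 = numeric(), p2 = numeric(), fst = numeric())
  rownames(out) <- NULL
  out
}

#' Per-SNP Fst for every taxon pair
#'
#' @param gm A haploid genotype matrix.
#' @param grouping Optional taxon labels (defaults to matrix attribute).
#' @return Named list of \code{\link{pairwise_fst}} data frames, one per
#'   unordered taxon pair, plus a \code{quartiles} summary data frame
#'   (min/Q1/median/Q3/max of the raw per-SNP values per pair).
#' @export
fst_report <- function(gm, grouping = NULL) {
  grouping <- .taxa_of(gm, grouping)
  taxa <- sort(unique(grouping))
  if (length(taxa) < 2L) stop("need at least two taxa")
  pairs <- utils::combn(taxa, 2, simplify = FALSE)
  per_pair <- lapply(pairs, function(p) pairwise_fst(gm, p, grouping))
  names(per_pair) <- vapply(pairs, paste, character(1), collapse = " vs ")
  qs <- do.call(rbind, lapply(names(per_pair), function(nm) {
    v <- per_pair[[nm]]$fst
    if (!length(v)) return(NULL)
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(pair = nm, min = q[1], q1 = q[2], median = q[3], q3 = q[4],
               max = q[5], n_snps = length(v), stringsAsFactors = FALSE)
  }))
  list(per_pair = per_pair, quartiles = qs)
}

#' PCA of a genotype matrix
#'
#' Missing genotypes are imputed to the column mean, columns mean-centred,
#' and scores taken from the singular value decomposition. Variance fractions
#' are non-increasing and sum to at most 1.
#'
#' @param gm A haploid genotype matrix.
#' @param k Number of components to return (capped at the matrix rank).
#' @return List with \code{scores} (individuals x k), \code{explained}
#'   (variance fractions) and \code{k}.
#' @export
pca_genotypes <- function(gm, k = 2L) {
  if (nrow(gm) < 2L || ncol(gm) < 1L) stop("need >= 2 individuals and >= 1 SNP")
  X <- apply(gm, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    if (is.nan(mu)) stop("column with all genotypes missing")
    col[is.na(col)] <- mu
    col - mu
  })
  X <- matrix(X, nrow = nrow(gm), dimnames = dimnames(gm))
  sv <- svd(X)
  ev <- sv$d^2
  total <- sum(ev)
  k <- min(k, sum(sv$d > 1e-12))
  k <- max(k, 0L)
  scores <- if (k > 0) sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k) else matrix(0, nrow(gm), 0)
  rownames(scores) <- rownames(gm)
  if (k > 0) colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       explained = if (total > 0) ev[seq_len(k)] / total else rep(0, k),
       k = k)
}

#' Identity-by-state kinship matrix
#'
#' \eqn{K_{ij}} is the fraction of SNPs, non-missing in both individuals, at
#' which i and j carry the same allele. Symmetric with unit diagonal; a pair
#' with zero co-observed SNPs yields NA (callers must error on downstream
#' use).
#'
#' @param gm A haploid genotype matrix (0/1/NA).
#' @return Individuals x individuals similarity matrix.
#' @export
ibs_kinship <- function(gm) {
  if (ncol(gm) < 1L) stop("need at least 1 SNP")
  n <- nrow(gm)
  K <- matrix(NA_real_, n, n, dimnames = list(rownames(gm), rownames(gm)))
  obs <- !is.na(gm)
  for (i in seq_len(n)) {
    K[i, i] <- 1
    if (i == n) break
    for (j in (i + 1L):n) {
      both <- obs[i, ] & obs[j, ]
      m <- sum(both)
      if (m == 0L) next
      K[i, j] <- K[j, i] <- sum(gm[i, both] == gm[j, both]) / m
    }
  }
  K
}

#' Pairwise p-distances between aligned sequences
#'
#' Proportion of differing sites per pair, pairwise deletion of missing
#' calls; optionally Jukes-Cantor corrected.
#'
#' @param aln A \code{gene_alignment}.
#' @param model \code{"p"} (default) or \code{"JC69"}.
#' @return A \code{dist}-convertible symmetric matrix.
#' @export
p_distance <- function(aln, model = c("p", "JC69")) {
  model <- match.arg(model)
  m <- aln$seq
  n <- nrow(m)
  ok <- .is_called(m)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- ok[i, ] & ok[j, ]
      L <- sum(both)
      d <- if (L == 0L) NA_real_ else sum(m[i, both] != m[j, both]) / L
      if (model == "JC69" && !is.na(d))
        d <- if (d >= 0.75) Inf else -0.75 * log(1 - 4 * d / 3)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining dendrogram with bootstrap support
#'
#' Saitou-Nei agglomeration (via \code{ape::nj}) on p-distances, negative
#' branch lengths floored at 0. Bootstrap resamples alignment columns with
#' replacement; support is the percentage of replicates containing each
#' internal bipartition, attached as internal node labels.
#'
#' @param aln A \code{gene_alignment} with at least 3 sequences, or a
#'   pre-computed distance matrix / \code{dist} (bootstrap then unavailable).
#' @param bootstrap Number of bootstrap replicates (0 skips support).
#' @param model Distance model, see \code{\link{p_distance}}.
#' @param seed Optional RNG seed for the bootstrap.
#' @return An \code{ape::phylo} tree (node labels carry support when
#'   bootstrapped).
#' @export
nj_tree <- function(aln, bootstrap = 0L, model = "p", seed = NULL) {
  if (!inherits(aln, "gene_alignment")) {
    D <- stats::as.dist(aln)
    if (attr(D, "Size") < 3L) stop("neighbor joining needs at least 3 sequences")
    if (bootstrap > 0L) stop("bootstrap requires an alignment, not distances")
    tr <- ape::nj(D)
    tr$edge.length[tr$edge.length < 0] <- 0
    return(tr)
  }
  if (n_sequences(aln) < 3L) stop("neighbor joining needs at least 3 sequences")
  build <- function(m) {
    a <- gene_alignment(m, ids = rownames(m), gene = aln$gene)
    tr <- ape::nj(stats::as.dist(p_distance(a, model)))
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
  }
  tree <- build(aln$seq)
  if (bootstrap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    bp <- ape::boot.phylo(tree, aln$seq, build, B = bootstrap,
                          quiet = TRUE, trees = FALSE, rooted = FALSE)
    tree$node.label <- round(100 * bp / bootstrap)
  }
  tree
}
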