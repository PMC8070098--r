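# Haplotype collapsing and median-joining networks (Bandelt-style).

#' Collapse an alignment into distinct haplotypes
#'
#' Drops individuals carrying any missing call over the analysed columns
#' (complete deletion), then tallies distinct sequence strings, their
#' frequencies and taxon composition, plus all pairwise Hamming distances.
#'
#' @param aln A \code{gene_alignment}.
#' @param columns Optional alignment columns to analyse (default: all).
#' @return An object of class \code{haplotype_set}: \code{haplotypes}
#'   (character vector), \code{freq}, \code{composition} (taxon x haplotype
#'   count matrix), \code{diffs} (symmetric Hamming matrix), \code{members}
#'   (list of accession IDs per haplotype).
#' @export
collapse_haplotypes <- function(aln, columns = NULL) {
  stopifnot(inherits(aln, "gene_alignment"))
  m <- aln$seq
  if (!is.null(columns)) m <- m[, columns, drop = FALSE]
  called <- .is_called(m)
  keep <- rowSums(!called) == 0L
  if (!any(keep)) stop("no individual is fully called over the analysed columns")
  m <- m[keep, , drop = FALSE]
  taxa <- aln$taxa[keep]
  ids <- aln$ids[keep]
  strs <- apply(m, 1, paste, collapse = "")
  uh <- unique(strs)
  hid <- match(strs, uh)
  freq <- tabulate(hid, nbins = length(uh))
  comp <- table(factor(taxa), factor(hid, levels = seq_along(uh)))
  comp <- matrix(comp, nrow = nrow(comp),
                 dimnames = list(rownames(comp), paste0("H", seq_along(uh))))
  members <- split(ids, hid)
  names(members) <- paste0("H", seq_along(uh))
  diffs <- .hamming_matrix(uh)
  dimnames(diffs) <- list(paste0("H", seq_along(uh)), paste0("H", seq_along(uh)))
  structure(list(haplotypes = uh, freq = freq, composition = comp,
                 diffs = diffs, members = members, gene = aln$gene),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set> ", x$gene, ": ", length(x$haplotypes),
      " haplotypes over ", sum(x$freq), " individuals\n", sep = "")
  df <- data.frame(haplotype = paste0("H", seq_along(x$freq)), freq = x$freq)
  print(df, row.names = FALSE)
  invisible(x)
}

.hamming_matrix <- function(strs) {
  k <- length(strs)
  M <- matrix(0L, k, k)
  if (k < 2L) return(M)
  sp <- strsplit(strs, "")
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k)
      M[i, j] <- M[j, i] <- sum(sp[[i]] != sp[[j]])
  M
}

# Union-find helpers for the minimum spanning network.
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Minimum spanning network over a distance matrix: process distinct edge
# weights in increasing order; all edges of weight w (+/- epsilon) joining
# components that were distinct before this weight level are kept.
.msn_edges <- function(D, epsilon = 0L) {
  k <- nrow(D)
  if (k < 2L) return(data.frame(from = integer(), to = integer(), weight = numeric()))
  ed <- which(upper.tri(D), arr.ind = TRUE)
  ew <- D[upper.tri(D)]
  ord <- order(ew)
  ed <- ed[ord, , drop = FALSE]; ew <- ew[ord]
  parent <- seq_len(k)
  out <- list()
  i <- 1L
  while (i <= length(ew)) {
    w <- ew[i]
    batch <- which(ew >= w & ew <= w + epsilon)
    batch <- batch[batch >= i]
    # component structure frozen at this weight level
    comp <- vapply(seq_len(k), function(v) .uf_find(parent, v), integer(1))
    joins <- list()
    for (b in batch) {
      a <- comp[ed[b, 1]]; z <- comp[ed[b, 2]]
      if (a != z) {
        out[[length(out) + 1L]] <- data.frame(from = ed[b, 1], to = ed[b, 2],
                                              weight = ew[b])
        joins[[length(joins) + 1L]] <- c(a, z)
      }
    }
    for (jn in joins) {
      ra <- .uf_find(parent, jn[1]); rz <- .uf_find(parent, jn[2])
      if (ra != rz) parent[rz] <- ra
    }
    i <- max(batch) + 1L
  }
  if (!length(out)) return(data.frame(from = integer(), to = integer(), weight = numeric()))
  do.call(rbind, out)
}

# Total length of a minimum spanning tree over D (Prim).
.mst_length <- function(D) {
  k <- nrow(D)
  if (k < 2L) return(0)
  in_tree <- c(TRUE, rep(FALSE, k - 1L))
  best <- D[1, ]
  tot <- 0
  for (step in seq_len(k - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    tot <- tot + best[v]
    in_tree[v] <- TRUE
    best <- pmin(best, D[v, ])
  }
  tot
}

# Majority-rule median of three equal-length strings, per position; when all
# three states differ the first sequence's state is kept (quasi-median
# restricted to observed states; for biallelic data the branch never fires).
.median_seq <- function(s1, s2, s3) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]; c3 <- strsplit(s3, "")[[1]]
  out <- a
  agree_bc <- b == c3
  out[agree_bc] <- b[agree_bc]
  paste(out, collapse = "")
}

#' Median-joining haplotype network
#'
#' Bandelt-style median joining: iteratively build the minimum spanning
#' network (tolerance \code{epsilon}) over observed haplotypes plus inferred
#' median vectors, propose the majority-consensus median of every connected
#' triplet, and keep medians that shorten the total (spanning-tree) length.
#' Terminates when no candidate median helps; median vectors that end up
#' with fewer than 3 network neighbours are pruned. With \code{epsilon = 0}
#' the result contains a minimum spanning network of the observed haplotypes
#' as a subgraph.
#'
#' @param hs A \code{\link{haplotype_set}}.
#' @param epsilon Weight tolerance of the spanning-network construction.
#' @param max_iter Safety cap on median-addition sweeps.
#' @return An object of class \code{haplo_network}: \code{nodes} (data frame
#'   \code{node, type, freq}), \code{edges} (data frame
#'   \code{node1, node2, weight}), \code{sequences} (node sequences).
#' @export
mj_network <- function(hs, epsilon = 0L, max_iter = 20L) {
  stopifnot(inherits(hs, "haplotype_set"))
  seqs <- hs$haplotypes
  n_obs <- length(seqs)
  types <- rep("observed", n_obs)
  it <- 0L
  repeat {
    it <- it + 1L
    D <- .hamming_matrix(seqs)
    ed <- .msn_edges(D, epsilon)
    base_len <- .mst_length(D)
    # connected triplets in the current spanning network
    adj <- vector("list", length(seqs))
    for (r in seq_len(nrow(ed))) {
      adj[[ed$from[r]]] <- c(adj[[ed$from[r]]], ed$to[r])
      adj[[ed$to[r]]] <- c(adj[[ed$to[r]]], ed$from[r])
    }
    cands <- character()
    for (u in seq_along(seqs)) {
      nb <- adj[[u]]
      if (length(nb) < 2L) next
      prs <- utils::combn(nb, 2, simplify = FALSE)
      for (p in prs) {
        med <- .median_seq(seqs[u], seqs[p[1]], seqs[p[2]])
        if (!(med %in% seqs) && !(med %in% cands)) cands <- c(cands, med)
      }
    }
    if (!length(cands) || it > max_iter) break
    # greedily add the single best median this sweep
    gains <- vapply(cands, function(md) {
      base_len - .mst_length(.hamming_matrix(c(seqs, md)))
    }, numeric(1))
    if (max(gains) <= 0) break
    best <- cands[which.max(gains)]
    seqs <- c(seqs, best)
    types <- c(types, "median")
  }
  # prune obsolete median vectors (degree < 3), innermost first
  repeat {
    D <- .hamming_matrix(seqs)
    ed <- .msn_edges(D, epsilon)
    deg <- tabulate(c(ed$from, ed$to), nbins = length(seqs))
    drop <- which(types == "median" & deg < 3L)
    if (!length(drop)) break
    keep <- setdiff(seq_along(seqs), drop[1])
    seqs <- seqs[keep]; types <- types[keep]
  }
  D <- .hamming_matrix(seqs)
  ed <- .msn_edges(D, epsilon)
  labels <- character(length(seqs))
  labels[types == "observed"] <- paste0("H", seq_len(sum(types == "observed")))
  if (any(types == "median"))
    labels[types == "median"] <- paste0("MV", seq_len(sum(types == "median")))
  freq <- integer(length(seqs))
  freq[types == "observed"] <- hs$freq[match(seqs[types == "observed"], hs$haplotypes)]
  nodes <- data.frame(node = labels, type = types, freq = freq,
                      stringsAsFactors = FALSE)
  edges <- data.frame(node1 = labels[ed$from], node2 = labels[ed$to],
                      weight = ed$weight, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 sequences = stats::setNames(seqs, labels), gene = hs$gene),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("<haplo_network> ", x$gene, ": ", nrow(x$nodes), " nodes (",
      sum(x$nodes$type == "median"), " median vectors), ",
      nrow(x$edges), " edges\n", sep = "")
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Export a haplotype network as CSV files
#'
#' Writes an edge list (\code{node1,node2,weight}) and a node attribute table
#' (haplotype label, type, frequency, per-taxon counts).
#'
#' @param net A \code{haplo_network}.
#' @param hs The \code{haplotype_set} it was built from (for composition).
#' @param prefix Output path prefix; files \code{<prefix>_edges.csv} and
#'   \code{<prefix>_nodes.csv} are written.
#' @return The two paths, invisibly.
#' @export
write_network_csv <- function(net, hs, prefix) {
  ep <- paste0(prefix, "_edges.csv")
  np <- paste0(prefix, "_nodes.csv")
  utils::write.csv(net$edges, ep, row.names = FALSE)
  nodes <- net$nodes
  comp <- t(hs$composition)
  obs <- nodes$type == "observed"
  for (tx in rownames(hs$composition)) {
    nodes[[paste0("n_", tx)]] <- 0L
    nodes[[paste0("n_", tx)]][obs] <- comp[nodes$node[obs], tx]
  }
  utils::write.csv(nodes, np, row.names = FALSE)
  invisible(c(ep, np))
}
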