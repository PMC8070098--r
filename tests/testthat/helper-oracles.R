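# Independent oracles and small fixture builders shared across tests.

# Build an alignment from a character vector of strings.
aln_from_strings <- function(strs, taxa = NULL, gene = "toy") {
  gene_alignment(strs, ids = paste0("s", seq_along(strs)), taxa = taxa,
                 gene = gene)
}

# Brute-force nucleotide diversity: explicit loop over all pairs, per-pair
# effective length, written independently of the package internals.
oracle_pi <- function(strs) {
  n <- length(strs)
  sp <- strsplit(strs, "")
  vals <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- sp[[i]]; b <- sp[[j]]
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      vals <- c(vals, sum(a[ok] != b[ok]) / sum(ok))
    }
  }
  mean(vals)
}

# Tajima's D from first principles with the published constants, written out
# term by term.
oracle_tajima_d <- function(strs) {
  n <- length(strs)
  sp <- do.call(rbind, strsplit(strs, ""))
  seg <- apply(sp, 2, function(col) length(unique(col)) > 1)
  S <- sum(seg)
  diffs <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    diffs <- c(diffs, sum(sp[i, ] != sp[j, ]))
  k_hat <- mean(diffs)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Exhaustive-permutation two-sided rank-sum p-value for two samples with no
# ties: distribution of the group-1 rank sum over all assignments.
oracle_ranksum_p <- function(x1, x2) {
  n1 <- length(x1); n <- n1 + length(x2)
  r <- rank(c(x1, x2))
  obs <- sum(r[1:n1])
  combos <- utils::combn(n, n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  mu <- n1 * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu))
}

# Minimal Steiner-tree total length for a haplotype set over <= 4 sites:
# enumerate every subset of candidate interior sequences and take the
# shortest spanning tree over observed + chosen interior nodes.
oracle_steiner_length <- function(strs) {
  k <- nchar(strs[1])
  states <- lapply(seq_len(k), function(i)
    unique(substring(strs, i, i)))
  cand <- do.call(expand.grid, c(states, stringsAsFactors = FALSE))
  cand <- apply(cand, 1, paste, collapse = "")
  cand <- setdiff(cand, strs)
  best <- Inf
  hamm <- function(v) {
    m <- length(v)
    D <- matrix(0, m, m)
    sp <- strsplit(v, "")
    for (i in 1:(m - 1)) for (j in (i + 1):m)
      D[i, j] <- D[j, i] <- sum(sp[[i]] != sp[[j]])
    D
  }
  mst_len <- function(D) {
    m <- nrow(D)
    if (m < 2) return(0)
    intree <- c(TRUE, rep(FALSE, m - 1))
    bestd <- D[1, ]
    tot <- 0
    for (s in 1:(m - 1)) {
      v <- which(!intree)[which.min(bestd[!intree])]
      tot <- tot + bestd[v]
      intree[v] <- TRUE
      bestd <- pmin(bestd, D[v, ])
    }
    tot
  }
  subsets <- list(integer(0))
  if (length(cand)) {
    for (sz in 1:min(length(cand), 3)) {
      subsets <- c(subsets, utils::combn(length(cand), sz, simplify = FALSE))
    }
  }
  for (sub in subsets) {
    v <- c(strs, cand[sub])
    best <- min(best, mst_len(hamm(v)))
  }
  best
}

# Total spanning-tree length of a haplo_network's node set.
network_mst_length <- function(net) {
  v <- unname(net$sequences)
  m <- length(v)
  if (m < 2) return(0)
  sp <- strsplit(v, "")
  D <- matrix(0, m, m)
  for (i in 1:(m - 1)) for (j in (i + 1):m)
    D[i, j] <- D[j, i] <- sum(sp[[i]] != sp[[j]])
  intree <- c(TRUE, rep(FALSE, m - 1))
  bestd <- D[1, ]
  tot <- 0
  for (s in 1:(m - 1)) {
    v2 <- which(!intree)[which.min(bestd[!intree])]
    tot <- tot + bestd[v2]
    intree[v2] <- TRUE
    bestd <- pmin(bestd, D[v2, ])
  }
  tot
}

# Random structured genotype/kinship instance for association tests.
make_structured_instance <- function(n = 50, n_snps = 40, seed = 1) {
  set.seed(seed)
  pop <- rep(1:2, length.out = n)
  p1 <- runif(n_snps, 0.1, 0.9)
  p2 <- pmin(0.95, pmax(0.05, p1 + runif(n_snps, -0.4, 0.4)))
  gm <- sapply(seq_len(n_snps), function(k)
    rbinom(n, 1, ifelse(pop == 1, p1[k], p2[k])))
  rownames(gm) <- paste0("i", 1:n)
  colnames(gm) <- paste0("snp", 1:n_snps)
  K <- ibs_kinship(gm)
  list(gm = gm, K = K, pop = pop)
}

# Draw a phenotype with polygenic background u ~ N(0, h2 * K) and residual
# variance 1 - h2 (uses the kinship's own eigen-structure, independent of the
# package's REML machinery).
draw_polygenic <- function(K, h2) {
  eig <- eigen(K, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  u <- eig$vectors %*% (sqrt(lam) * rnorm(nrow(K)))
  sqrt(h2) * as.vector(u) + rnorm(nrow(K), 0, sqrt(1 - h2))
}
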