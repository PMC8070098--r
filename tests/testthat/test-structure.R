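# Fst, PCA, kinship, neighbor joining.

test_that("Hudson Fst matches direct arithmetic and its boundary cases", {
  # fixed difference -> Fst = 1
  gm <- rbind(matrix(0L, 5, 3), matrix(1L, 5, 3))
  rownames(gm) <- paste0("i", 1:10)
  colnames(gm) <- paste0("s", 1:3)
  attr(gm, "taxa") <- rep(c("a", "b"), each = 5)
  fst <- pairwise_fst(gm, c("a", "b"))
  expect_equal(fst$fst, rep(1, 3))
  # equal frequencies, equal n: the unbiased estimator dips slightly below 0
  gm2 <- rbind(c(0L, 1L), c(1L, 0L), c(0L, 1L), c(1L, 0L))
  rownames(gm2) <- paste0("i", 1:4)
  colnames(gm2) <- c("s1", "s2")
  attr(gm2, "taxa") <- c("a", "a", "b", "b")
  fst2 <- pairwise_fst(gm2, c("a", "b"))
  p <- 0.5; n <- 2
  hw <- 2 * p * (1 - p) * n / (n - 1)
  hb <- 2 * p * (1 - p)
  expect_equal(fst2$fst, rep(1 - hw / hb, 2))
  expect_true(all(fst2$fst <= 0))
  expect_true(all(pmax(0, fst2$fst) == 0)) # floored value for reporting
  # p1 = 0.2, p2 = 0.8, n = 10 each: direct formula evaluation
  g1 <- c(rep(1L, 2), rep(0L, 8)); g2 <- c(rep(1L, 8), rep(0L, 2))
  gm3 <- matrix(c(g1, g2), ncol = 1)
  rownames(gm3) <- paste0("i", 1:20); colnames(gm3) <- "s1"
  attr(gm3, "taxa") <- rep(c("a", "b"), each = 10)
  hw3 <- mean(c(2 * 0.2 * 0.8 * 10 / 9, 2 * 0.8 * 0.2 * 10 / 9))
  hb3 <- 0.2 * (1 - 0.8) + 0.8 * (1 - 0.2)
  expect_equal(pairwise_fst(gm3, c("a", "b"))$fst, 1 - hw3 / hb3)
  # symmetry in taxon order
  expect_equal(pairwise_fst(gm3, c("b", "a"))$fst,
               pairwise_fst(gm3, c("a", "b"))$fst)
  # both populations fixed for the same allele -> SNP skipped
  gm4 <- matrix(0L, 6, 1, dimnames = list(paste0("i", 1:6), "s1"))
  attr(gm4, "taxa") <- rep(c("a", "b"), each = 3)
  expect_equal(nrow(pairwise_fst(gm4, c("a", "b"))), 0)
  # values never exceed 1
  rep <- fst_report(gm)
  expect_true(all(rep$quartiles$max <= 1))
})

test_that("genotype PCA separates clusters and behaves on duplicates", {
  gm <- rbind(matrix(0L, 4, 6), matrix(1L, 4, 6))
  rownames(gm) <- paste0("i", 1:8)
  pc <- pca_genotypes(gm, k = 3)
  # one diagnostic axis: PC1 explains everything and splits the clusters
  expect_equal(pc$explained[1], 1)
  expect_true(all(pc$scores[1:4, 1] * pc$scores[5:8, 1] < 0) ||
                all(diff(sign(pc$scores[, 1])[c(1, 5)]) != 0))
  expect_equal(unname(pc$scores[1, 1]), unname(pc$scores[2, 1]))
  # variance fractions sorted, sum <= 1
  set.seed(3)
  gm2 <- matrix(rbinom(100, 1, 0.4), 10, 10,
                dimnames = list(paste0("i", 1:10), NULL))
  pc2 <- pca_genotypes(gm2, k = 5)
  expect_true(all(diff(pc2$explained) <= 1e-12))
  expect_lte(sum(pc2$explained), 1 + 1e-12)
  # duplicate individuals get identical scores
  gm3 <- rbind(gm2, dup = gm2[1, ])
  rownames(gm3) <- c(rownames(gm2), "dup")
  pc3 <- pca_genotypes(gm3, k = 2)
  expect_equal(unname(pc3$scores["dup", ]), unname(pc3$scores["i1", ]))
  # scores invariant (up to sign) to individual order
  perm <- sample(10)
  pc4 <- pca_genotypes(gm2[perm, ], k = 2)
  for (k in 1:2)
    expect_equal(abs(pc4$scores[rownames(gm2), k]), abs(pc2$scores[, k]),
                 tolerance = 1e-8)
})

test_that("IBS kinship counts shared alleles over co-observed SNPs", {
  gm <- rbind(a = c(0L, 1L, 0L, 1L),
              b = c(0L, 1L, 0L, 1L),
              c = c(1L, 0L, 1L, 0L),
              d = c(0L, 1L, 1L, 0L))
  K <- ibs_kinship(gm)
  expect_equal(unname(diag(K)), rep(1, 4))
  expect_equal(K["a", "b"], 1)   # identical
  expect_equal(K["a", "c"], 0)   # complementary
  expect_equal(K["a", "d"], 0.5) # half-matching
  expect_equal(K, t(K))
  # invariant to SNP order
  expect_equal(ibs_kinship(gm[, c(3, 1, 4, 2)]), K)
  # missing data: fraction over co-observed SNPs only
  gm2 <- rbind(a = c(0L, NA, 1L), b = c(0L, 1L, 0L))
  expect_equal(ibs_kinship(gm2)["a", "b"], 0.5)
  # a pair with no co-observed SNPs is NA
  gm3 <- rbind(a = c(0L, NA), b = c(NA, 1L))
  expect_true(is.na(ibs_kinship(gm3)["a", "b"]))
})

test_that("neighbor joining recovers additive trees and three-point lengths", {
  # 3 leaves: unique topology, branch lengths solve the three-point equations
  D <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(D)
  pl <- ape::cophenetic.phylo(tr)
  expect_equal(pl[letters[1:3], letters[1:3]], D, tolerance = 1e-9)
  # additive 4-leaf matrix from a known tree: NJ reproduces its path lengths
  # tree: ((a:1, b:2):1.5, (c:0.5, d:3))
  D4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D4["a", "b"] <- D4["b", "a"] <- 3
  D4["a", "c"] <- D4["c", "a"] <- 1 + 1.5 + 0.5
  D4["a", "d"] <- D4["d", "a"] <- 1 + 1.5 + 3
  D4["b", "c"] <- D4["c", "b"] <- 2 + 1.5 + 0.5
  D4["b", "d"] <- D4["d", "b"] <- 2 + 1.5 + 3
  D4["c", "d"] <- D4["d", "c"] <- 3.5
  tr4 <- nj_tree(D4)
  expect_equal(ape::cophenetic.phylo(tr4)[letters[1:4], letters[1:4]], D4,
               tolerance = 1e-9)
  # the generating topology is recovered: a,b vs c,d bipartition present
  split_ab <- ape::prop.part(tr4)
  expect_true(any(vapply(split_ab, function(p)
    setequal(tr4$tip.label[p], c("a", "b")) ||
      setequal(tr4$tip.label[p], c("c", "d")), logical(1))))
})

test_that("bootstrap support is 100% for a clean two-clade split", {
  L <- 60
  clade1 <- paste(rep("A", L), collapse = "")
  clade2 <- paste(rep(c("A", "T"), c(L / 2, L / 2)), collapse = "")
  jitter1 <- sub("^A", "C", clade1) # one private mutation per clade
  jitter2 <- sub("^A", "G", clade2)
  aln <- aln_from_strings(c(clade1, clade1, jitter1, clade2, clade2, jitter2))
  tr <- nj_tree(aln, bootstrap = 100, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_true(all(tr$edge.length >= 0))
  expect_true(max(tr$node.label, na.rm = TRUE) == 100)
  expect_error(nj_tree(aln_from_strings(c("A", "T"))), "at least 3")
})
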