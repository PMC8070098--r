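# Association scans: GLM, MLM, CMLM, haplotype models.

test_that("GLM recovers a perfect linear signal and reduces to the t-test", {
  set.seed(21)
  n <- 20
  gm <- matrix(rbinom(n * 4, 1, 0.5), n, 4,
               dimnames = list(paste0("i", 1:n), paste0("s", 1:4)))
  env <- 3 * gm[, 1] + 2 # exact linear function of the marker
  res <- glm_scan(gm, env, n_pc = 0)
  r1 <- res[res$marker == "s1", ]
  expect_lt(r1$p, 1e-10)
  expect_equal(r1$effect, 3, tolerance = 1e-8)
  # with no covariates the marker F test is the squared two-group t test
  env2 <- gm[, 2] + rnorm(n)
  res2 <- glm_scan(gm, env2, n_pc = 0)
  tt <- t.test(env2[gm[, 3] == 1], env2[gm[, 3] == 0], var.equal = TRUE)
  expect_equal(res2$p[res2$marker == "s3"], tt$p.value, tolerance = 1e-10)
  # constant SNPs are skipped
  gm_const <- cbind(gm, s5 = 1L)
  expect_false("s5" %in% glm_scan(gm_const, env2, n_pc = 0)$marker)
})

test_that("MLM equals GLM when kinship is the identity", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 25
    gm <- matrix(rbinom(n * 8, 1, runif(1, 0.2, 0.8)), n, 8,
                 dimnames = list(paste0("i", 1:n), paste0("s", 1:8)))
    keep <- apply(gm, 2, var) > 0
    gm <- gm[, keep, drop = FALSE]
    env <- rnorm(n) + gm[, 1]
    KI <- diag(n)
    dimnames(KI) <- list(rownames(gm), rownames(gm))
    g <- glm_scan(gm, env, n_pc = 2)
    m <- mlm_scan(gm, env, KI, n_pc = 2)
    shared <- intersect(g$marker, m$marker)
    expect_gt(length(shared), 0)
    expect_lt(max(abs(g$p[match(shared, g$marker)] -
                        m$p[match(shared, m$marker)])), 1e-6)
  }
})

test_that("MLM REML machinery is exact on a known GLS problem", {
  # with delta fixed by construction, the marker test must match a direct
  # generalized-least-squares computation
  inst <- make_structured_instance(n = 30, n_snps = 10, seed = 3)
  set.seed(33)
  env <- draw_polygenic(inst$K, h2 = 0.5) + 0.8 * inst$gm[, 1]
  m <- mlm_scan(inst$gm, env, inst$K, n_pc = 0)
  delta <- attr(m, "delta")
  eigv <- eigen(inst$K, symmetric = TRUE)
  Kb <- eigv$vectors %*% (pmax(eigv$values, 1e-6) * t(eigv$vectors))
  V <- Kb + delta * diag(30)
  Vi <- solve(V)
  X <- cbind(1, g = inst$gm[, 1])
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% env)
  r <- env - X %*% beta
  s2 <- as.numeric(t(r) %*% Vi %*% r) / (30 - 2)
  se <- sqrt(s2 * solve(t(X) %*% Vi %*% X)[2, 2])
  p_direct <- pf((beta[2] / se)^2, 1, 28, lower.tail = FALSE)
  row <- m[m$marker == "snp1", ]
  expect_equal(row$effect, as.numeric(beta[2]), tolerance = 1e-8)
  expect_equal(row$p, p_direct, tolerance = 1e-8)
})

test_that("CMLM interpolates between MLM and the group-degenerate model", {
  inst <- make_structured_instance(n = 24, n_snps = 12, seed = 8)
  set.seed(88)
  env <- draw_polygenic(inst$K, h2 = 0.4)
  m <- mlm_scan(inst$gm, env, inst$K, n_pc = 0)
  # n groups: identical to MLM
  cn <- suppressWarnings(cmlm_scan(inst$gm, env, inst$K, n_pc = 0, groups = 24))
  expect_equal(attr(cn, "n_groups"), 24)
  expect_equal(cn$p, m$p[match(cn$marker, m$marker)], tolerance = 1e-8)
  # 1 group: an exchangeable random part; marker p equals the plain GLM p
  # (GLS with equicorrelation and an intercept is OLS)
  c1 <- suppressWarnings(cmlm_scan(inst$gm, env, inst$K, n_pc = 0, groups = 1))
  g <- glm_scan(inst$gm, env, n_pc = 0)
  expect_equal(c1$p, g$p[match(c1$marker, g$marker)], tolerance = 1e-6)
  # default grid picks the group count by null REML likelihood
  cd <- suppressWarnings(cmlm_scan(inst$gm, env, inst$K, n_pc = 0))
  expect_true(attr(cd, "n_groups") %in% c(1, 3, 6, 12, 24))
})

test_that("haplotype factor model reduces to the marker model for two classes", {
  inst <- make_structured_instance(n = 30, n_snps = 10, seed = 5)
  set.seed(55)
  env <- draw_polygenic(inst$K, h2 = 0.3) + inst$gm[, 2]
  hap <- ifelse(inst$gm[, 2] == 1, "hapA", "hapB")
  hm <- haplotype_mlm(hap, env, inst$K)
  mm <- mlm_scan(inst$gm[, 2, drop = FALSE], env, inst$K, n_pc = 0)
  expect_equal(hm$p, mm$p, tolerance = 1e-6)
  # rare haplotypes are pooled; a single class yields a missing result
  hap_one <- rep("h1", 30)
  expect_true(is.na(haplotype_mlm(hap_one, env, inst$K)$p))
  hap_rare <- c("solo", rep("h1", 29)) # pooled into 'other' -> two classes
  expect_false(is.na(haplotype_mlm(hap_rare, env, inst$K)$p))
  # constant environment -> missing result
  expect_true(is.na(haplotype_mlm(hap, rep(1, 30), inst$K)$p))
})

test_that("association results are invariant to individual ordering", {
  inst <- make_structured_instance(n = 20, n_snps = 8, seed = 13)
  set.seed(14)
  env <- draw_polygenic(inst$K, h2 = 0.5)
  perm <- sample(20)
  m1 <- mlm_scan(inst$gm, env, inst$K, n_pc = 0)
  m2 <- mlm_scan(inst$gm[perm, ], env[perm], inst$K[perm, perm], n_pc = 0)
  expect_equal(m2$p, m1$p[match(m2$marker, m1$marker)], tolerance = 1e-8)
})

test_that("significance flags use the dual threshold convention", {
  res <- data.frame(gene = "g", marker = c("a", "b", "c", "d"),
                    index = "m3", model = "GLM",
                    effect = 1, se = 1, p = c(0.010, 0.05, 0.049, 0.2),
                    sig05 = NA, sig01 = NA)
  class(res) <- c("gea_scan", "data.frame")
  rep <- significance_report(res)
  expect_equal(rep$results$sig01, c(TRUE, FALSE, FALSE, FALSE)) # p <= 0.01
  expect_equal(rep$results$sig05, c(TRUE, FALSE, TRUE, FALSE))  # strict <
  expect_equal(rep$summary$n_sig05, 2)
  expect_equal(rep$summary$frac_sig01, 0.25)
  # sig01 implies sig05
  expect_true(all(!rep$results$sig01 | rep$results$sig05))
})
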