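# Genotype x environment association scans: fixed-effect (GLM), kinship mixed
# model (EMMA-style REML), compressed mixed model, and haplotype-factor mixed
# models, with the dual significance convention (p < 0.05, p <= 0.01).
#
# Model: env = marker*beta + PCs*gamma + u + e, u ~ N(0, sg2 * K). The
# variance ratio delta = se2/sg2 is estimated once per scan by REML under the
# null (no-marker) model through a single spectral decomposition of K
# (P3D-style), then every marker is tested by GLS with delta held fixed.

# Bend a kinship matrix to positive semi-definiteness by flooring eigenvalues.
.bend_kinship <- function(K, floor_ev = 1e-6) {
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < floor_ev) {
    warning("kinship matrix is not positive definite; eigenvalues floored at ",
            floor_ev)
    eig$values <- pmax(eig$values, floor_ev)
  }
  eig
}

# Profile REML log-likelihood of delta for y = X b + u + e with cov
# sg2*(K + delta I), given the eigen-rotated data (yt = U'y, Xt = U'X).
.reml_loglik <- function(logdelta, yt, Xt, lam) {
  d <- exp(logdelta)
  w <- lam + d
  XtWX <- crossprod(Xt, Xt / w)
  beta <- solve(XtWX, crossprod(Xt, yt / w))
  r <- yt - Xt %*% beta
  rss <- sum(r^2 / w)
  n <- length(yt); p <- ncol(Xt)
  -0.5 * ((n - p) * log(rss) + sum(log(w)) +
            as.numeric(determinant(XtWX, logarithm = TRUE)$modulus))
}

# Estimate delta by REML on the null model (intercept + covariates).
.estimate_delta <- function(y, X, eig, interval = c(-12, 12)) {
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  opt <- stats::optimize(.reml_loglik, interval, yt = yt, Xt = Xt,
                         lam = eig$values, maximum = TRUE)
  list(delta = exp(opt$maximum), loglik = opt$objective)
}

# GLS fit of y on X under covariance proportional to K + delta I (given via
# cholesky of the subsetted V). Returns coefficients, their covariance scale,
# RSS and residual df.
.gls_fit <- function(y, X, V) {
  R <- chol(V)
  yw <- backsolve(R, y, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  p <- fit$rank
  rss <- sum(fit$residuals^2)
  XtX_inv <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  # map original column -> row/col of the (pivoted) unscaled covariance
  pos <- match(seq_len(ncol(X)), fit$qr$pivot)
  list(coef = fit$coefficients, rss = rss, df = length(y) - p,
       cov_unscaled = XtX_inv, cov_pos = pos, rank = p)
}

.pc_covariates <- function(gm, n_pc) {
  if (n_pc <= 0L) return(NULL)
  pcs <- pca_genotypes(gm, k = n_pc)$scores
  if (ncol(pcs) == 0L) NULL else pcs
}

.new_gea_scan <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("gea_scan", "data.frame")
  df
}

#' Fixed-effect (GLM) association scan
#'
#' Per SNP, ordinary least squares of the environmental index on the haploid
#' genotype plus the first \code{n_pc} principal-component covariates;
#' individuals missing that SNP are dropped for that SNP; the marker is
#' tested by its partial F (equivalently squared t) statistic. Constant SNPs
#' after missing-data removal are skipped.
#'
#' @param gm Haploid genotype matrix (0/1/NA), individuals x SNPs.
#' @param env Environmental index values aligned to the rows of \code{gm}.
#' @param n_pc Number of principal-component covariates (default 2).
#' @param gene Gene label for the result (defaults to the matrix attribute).
#' @param index Index label for the result.
#' @return A \code{gea_scan} data frame: \code{gene, marker, index, model,
#'   effect, se, p, sig05, sig01}.
#' @export
glm_scan <- function(gm, env, n_pc = 2L, gene = NULL, index = "env") {
  if (length(env) != nrow(gm)) stop("env must align with genotype rows")
  if (is.null(gene)) gene <- attr(gm, "gene") %||% "gene"
  pcs <- .pc_covariates(gm, n_pc)
  rows <- lapply(seq_len(ncol(gm)), function(k) {
    g <- gm[, k]
    use <- !is.na(g) & !is.na(env)
    if (sum(use) < 3L || stats::var(g[use]) == 0) return(NULL)
    X <- cbind(1, if (!is.null(pcs)) pcs[use, , drop = FALSE], g = g[use])
    fit <- stats::lm.fit(X, env[use])
    if (fit$rank < ncol(X)) return(NULL) # marker confounded with covariates
    rss <- sum(fit$residuals^2)
    df <- sum(use) - fit$rank
    if (df < 1L || rss <= 0) return(NULL)
    XtX_inv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank)])
    pos <- match(ncol(X), fit$qr$pivot)
    beta <- fit$coefficients[ncol(X)]
    se <- sqrt(rss / df * XtX_inv[pos, pos])
    Fstat <- (beta / se)^2
    p <- stats::pf(Fstat, 1, df, lower.tail = FALSE)
    data.frame(gene = gene, marker = colnames(gm)[k], index = index,
               model = "GLM", effect = unname(beta), se = se, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), marker = character(),
                      index = character(), model = character(),
                      effect = numeric(), se = numeric(), p = numeric())
  out$sig05 <- out$p < 0.05
  out$sig01 <- out$p <= 0.01
  .new_gea_scan(out)
}

#' Kinship mixed-model (MLM) association scan
#'
#' EMMA-style single-random-effect mixed model with the IBS kinship as the
#' random-effect covariance. The variance ratio is REML-estimated once under
#' the null through one spectral decomposition of K and reused across SNPs;
#' each marker is then tested by GLS Wald F. A non-positive-definite kinship
#' is bent by flooring its eigenvalues at 1e-6 (with a warning). With K = I
#' the scan collapses to \code{\link{glm_scan}}.
#'
#' @inheritParams glm_scan
#' @param K Kinship matrix over the same individuals.
#' @return A \code{gea_scan} data frame (model \code{"MLM"}).
#' @export
mlm_scan <- function(gm, env, K, n_pc = 2L, gene = NULL, index = "env") {
  if (length(env) != nrow(gm)) stop("env must align with genotype rows")
  if (!isTRUE(all.equal(dim(K), rep(nrow(gm), 2)))) stop("kinship dimension mismatch")
  if (anyNA(K)) stop("kinship matrix contains missing entries")
  if (is.null(gene)) gene <- attr(gm, "gene") %||% "gene"
  .mixed_scan(gm, env, K, n_pc, gene, index, model_label = "MLM")
}

.mixed_scan <- function(gm, env, K, n_pc, gene, index, model_label) {
  pcs <- .pc_covariates(gm, n_pc)
  X0 <- cbind(`(Intercept)` = rep(1, nrow(gm)),
              if (!is.null(pcs)) pcs)
  use0 <- !is.na(env)
  eig <- .bend_kinship(K[use0, use0, drop = FALSE])
  est <- .estimate_delta(env[use0], X0[use0, , drop = FALSE], eig)
  delta <- est$delta
  Kb <- eig$vectors %*% (eig$values * t(eig$vectors)) # bent kinship
  V0 <- Kb + delta * diag(nrow(Kb))
  idx0 <- which(use0)
  rows <- lapply(seq_len(ncol(gm)), function(k) {
    g <- gm[, k]
    use <- use0 & !is.na(g)
    if (sum(use) < 3L || stats::var(g[use]) == 0) return(NULL)
    sel <- match(which(use), idx0)
    X <- cbind(X0[use, , drop = FALSE], g = g[use])
    fit <- .gls_fit(env[use], X, V0[sel, sel, drop = FALSE])
    if (fit$rank < ncol(X) || fit$df < 1L || fit$rss <= 0) return(NULL)
    pos <- fit$cov_pos[ncol(X)]
    beta <- fit$coef[ncol(X)]
    se <- sqrt(fit$rss / fit$df * fit$cov_unscaled[pos, pos])
    Fstat <- (beta / se)^2
    p <- stats::pf(Fstat, 1, fit$df, lower.tail = FALSE)
    data.frame(gene = gene, marker = colnames(gm)[k], index = index,
               model = model_label, effect = unname(beta), se = se, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), marker = character(),
                      index = character(), model = character(),
                      effect = numeric(), se = numeric(), p = numeric())
  out$sig05 <- out$p < 0.05
  out$sig01 <- out$p <= 0.01
  attr(out, "delta") <- delta
  attr(out, "null_loglik") <- est$loglik
  .new_gea_scan(out)
}

#' Compressed mixed-model (CMLM) association scan
#'
#' Individuals are clustered on kinship distance (average linkage, 1 - K) and
#' the random effect is carried by group membership: the group kinship is the
#' mean pairwise K between (and within) groups, expanded back to individuals.
#' The group count is chosen from a grid (default
#' \code{{1, ceil(n/8), ceil(n/4), ceil(n/2), n}}) by the maximum null-model
#' REML log-likelihood; markers are then tested exactly as in
#' \code{\link{mlm_scan}} on the compressed covariance. With n groups the
#' scan is identical to MLM.
#'
#' @inheritParams mlm_scan
#' @param groups Optional integer vector of candidate group counts.
#' @return A \code{gea_scan} data frame (model \code{"CMLM"}) with attributes
#'   \code{n_groups} (chosen count) and \code{group_loglik}.
#' @export
cmlm_scan <- function(gm, env, K, n_pc = 2L, groups = NULL, gene = NULL,
                      index = "env") {
  n <- nrow(gm)
  if (is.null(groups)) groups <- unique(pmax(1L, pmin(n, c(1L, ceiling(n / 8),
                                                           ceiling(n / 4),
                                                           ceiling(n / 2), n))))
  if (is.null(gene)) gene <- attr(gm, "gene") %||% "gene"
  hc <- stats::hclust(stats::as.dist(1 - K), method = "average")
  pcs <- .pc_covariates(gm, n_pc)
  X0 <- cbind(`(Intercept)` = rep(1, n), if (!is.null(pcs)) pcs)
  use0 <- !is.na(env)
  best <- NULL
  for (gcount in sort(unique(as.integer(groups)))) {
    Kc <- .compress_kinship(K, stats::cutree(hc, k = gcount))
    eig <- suppressWarnings(.bend_kinship(Kc[use0, use0, drop = FALSE]))
    est <- .estimate_delta(env[use0], X0[use0, , drop = FALSE], eig)
    if (is.null(best) || est$loglik > best$loglik)
      best <- list(gcount = gcount, Kc = Kc, loglik = est$loglik)
  }
  out <- suppressWarnings(
    .mixed_scan(gm, env, best$Kc, n_pc, gene, index, model_label = "CMLM"))
  attr(out, "n_groups") <- best$gcount
  attr(out, "group_loglik") <- best$loglik
  out
}

# Replace K by the between/within group means implied by a grouping.
.compress_kinship <- function(K, grp) {
  g <- as.integer(factor(grp))
  k <- max(g)
  Kg <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in a:k) {
      Kg[a, b] <- Kg[b, a] <- mean(K[g == a, g == b])
    }
  }
  Kc <- Kg[g, g]
  dimnames(Kc) <- dimnames(K)
  Kc
}

#' Haplotype-factor mixed-model association
#'
#' Tests the haplotype class of each individual as a multi-level fixed factor
#' in the kinship mixed model, with an omnibus F test for the factor.
#' Haplotypes with fewer than \code{min_carriers} carriers are pooled into
#' "other"; a single class after pooling yields a missing result.
#'
#' @param hap Character (or factor) haplotype label per individual.
#' @param env Environmental index values.
#' @param K Kinship matrix over the same individuals.
#' @param covariates Optional numeric covariate matrix (e.g. PC scores).
#' @param min_carriers Minimum carriers for an unpooled haplotype class.
#' @param gene,index Labels for the result row.
#' @return A one-row \code{gea_scan} data frame (model \code{"HAP-MLM"};
#'   \code{effect} is NA, the omnibus p is reported), or a row with NA p when
#'   undefined.
#' @export
haplotype_mlm <- function(hap, env, K, covariates = NULL, min_carriers = 2L,
                          gene = "gene", index = "env") {
  hap <- as.character(hap)
  n <- length(hap)
  if (length(env) != n || nrow(K) != n) stop("hap, env and K must align")
  counts <- table(hap)
  rare <- names(counts)[counts < min_carriers]
  hap[hap %in% rare] <- "other"
  hf <- factor(hap)
  na_row <- .new_gea_scan(data.frame(
    gene = gene, marker = "haplotype", index = index, model = "HAP-MLM",
    effect = NA_real_, se = NA_real_, p = NA_real_, sig05 = NA, sig01 = NA,
    stringsAsFactors = FALSE))
  if (nlevels(hf) < 2L) return(na_row)
  use <- !is.na(env)
  if (stats::var(env[use]) == 0) return(na_row)
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)[use, , drop = FALSE]
  Xh <- stats::model.matrix(~hf)[use, -1, drop = FALSE]
  eig <- .bend_kinship(K[use, use, drop = FALSE])
  est <- .estimate_delta(env[use], X0, eig)
  Kb <- eig$vectors %*% (eig$values * t(eig$vectors))
  V <- Kb + est$delta * diag(nrow(Kb))
  fit0 <- .gls_fit(env[use], X0, V)
  fit1 <- .gls_fit(env[use], cbind(X0, Xh), V)
  q <- fit1$rank - fit0$rank
  if (q < 1L || fit1$df < 1L || fit1$rss <= 0) return(na_row)
  Fstat <- ((fit0$rss - fit1$rss) / q) / (fit1$rss / fit1$df)
  p <- stats::pf(Fstat, q, fit1$df, lower.tail = FALSE)
  .new_gea_scan(data.frame(
    gene = gene, marker = "haplotype", index = index, model = "HAP-MLM",
    effect = NA_real_, se = NA_real_, p = p, sig05 = p < 0.05, sig01 = p <= 0.01,
    stringsAsFactors = FALSE))
}

#' Significance report over association results
#'
#' Applies the dual convention used for candidate-gene scans: \code{sig05}
#' for p < 0.05 (strict) and \code{sig01} for p <= 0.01, the latter the fixed
#' FDR-equivalent cutoff for an a-priori candidate-gene design. Summarises,
#' per gene and model, the count and fraction of markers significant at each
#' level.
#'
#' @param results A \code{gea_scan} (rows may mix genes, indices, models).
#' @return List with \code{results} (flags refreshed) and \code{summary}
#'   (per gene x model x index counts and fractions).
#' @export
significance_report <- function(results) {
  if (!nrow(results)) stop("no association results to summarise")
  results$sig05 <- results$p < 0.05
  results$sig01 <- results$p <= 0.01
  key <- interaction(results$gene, results$model, results$index, drop = TRUE)
  summ <- do.call(rbind, lapply(split(results, key), function(d) {
    ok <- !is.na(d$p)
    data.frame(gene = d$gene[1], model = d$model[1], index = d$index[1],
               n_markers = sum(ok),
               n_sig05 = sum(d$sig05[ok]), n_sig01 = sum(d$sig01[ok]),
               frac_sig05 = if (any(ok)) sum(d$sig05[ok]) / sum(ok) else 0,
               frac_sig01 = if (any(ok)) sum(d$sig01[ok]) / sum(ok) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(results = results, summary = summ)
}

#' @export
print.gea_scan <- function(x, ...) {
  cat("<gea_scan> ", nrow(x), " marker tests",
      if (!is.null(attr(x, "delta")))
        paste0(" (REML variance ratio delta = ",
               format(attr(x, "delta"), digits = 4), ")"),
      "\n", sep = "")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
summary.gea_scan <- function(object, ...) {
  rep <- significance_report(object)
  cat("Association scan: ", nrow(object), " tests, ",
      sum(rep$results$sig05, na.rm = TRUE), " at p < 0.05, ",
      sum(rep$results$sig01, na.rm = TRUE), " at p <= 0.01\n", sep = "")
  print(rep$summary, digits = 3)
  invisible(rep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
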