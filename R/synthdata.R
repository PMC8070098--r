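# Synthetic alignments, climate series and coupled genotype-environment
# datasets with known truth. The neutral generator is a standard n-coalescent
# with infinite-sites mutation; it exists to test the statistics (the study
# panel: 23 wild + 6 cultivated P. acutifolius, 4 var. tenuifolius,
# 19 P. parvifolius, is the default taxon structure).

#' Simulation configuration
#'
#' @param seed RNG seed; every generator draws all randomness from it.
#' @param taxa Named integer vector: sequences per taxon. Defaults to the
#'   study panel structure (23 wild / 6 cultivated P. acutifolius, 4 var.
#'   tenuifolius, 19 P. parvifolius).
#' @param L Alignment length (bp).
#' @param theta Per-locus scaled mutation rate (expected heterozygosity
#'   parameter of the coalescent; E[S] = theta * sum 1/i).
#' @param divergence Fraction of variant sites carrying a per-taxon
#'   allele-frequency shift (0 = panmictic neutral).
#' @param causal Optional list \code{list(position=..., beta=..., noise_sd=...)}
#'   describing an environmentally associated SNP for
#'   \code{\link{simulate_coupled}}. \code{position} indexes the variant
#'   sites (1 = first segregating site), not alignment columns.
#' @param climate List of climate-generator settings: \code{mean_t} (degrees
#'   C), \code{amplitude} (seasonal temperature swing, degrees C),
#'   \code{peak_month}, \code{t_noise_sd}, \code{precip_scale} (mm, mean
#'   monthly total at the seasonal peak), \code{lat_range}.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       taxa = c(acutifolius_wild = 23L, acutifolius_cult = 6L,
                                tenuifolius = 4L, parvifolius = 19L),
                       L = 600L, theta = 5, divergence = 0,
                       causal = NULL,
                       climate = list(mean_t = 24, amplitude = 6,
                                      peak_month = 6L, t_noise_sd = 0.5,
                                      precip_scale = 40, lat_range = c(15, 32))) {
  if (any(taxa < 1L)) stop("each taxon needs at least one sequence")
  if (L <= 0L) stop("L must be positive")
  if (theta <= 0) stop("theta must be positive")
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  structure(list(seed = as.integer(seed), taxa = taxa, L = as.integer(L),
                 theta = theta, divergence = divergence, causal = causal,
                 climate = climate),
            class = "sim_config")
}

# Simulate the standard n-coalescent: returns per-sequence mutation sets.
# Mutations are placed on branches (Poisson theta/2 per unit time) and
# assigned to all descendant tips; each mutation is a distinct site.
.coalescent_mutations <- function(n, theta) {
  # active lineages, each a set of tip indices; branch birth times
  lineages <- as.list(seq_len(n))
  tbirth <- rep(0, n)
  t_now <- 0
  muts <- vector("list", n) # per-tip mutation id sets
  for (i in seq_len(n)) muts[[i]] <- integer()
  next_mut <- 1L
  while (length(lineages) > 1L) {
    k <- length(lineages)
    t_now <- t_now + stats::rexp(1, rate = k * (k - 1) / 2)
    pick <- sample.int(k, 2L)
    for (b in pick) {
      # mutations on this branch (length t_now - birth)
      nm <- stats::rpois(1, theta / 2 * (t_now - tbirth[b]))
      if (nm > 0L) {
        ids <- next_mut:(next_mut + nm - 1L)
        next_mut <- next_mut + nm
        for (tip in lineages[[b]]) muts[[tip]] <- c(muts[[tip]], ids)
      }
    }
    merged <- c(lineages[[pick[1]]], lineages[[pick[2]]])
    lineages <- c(lineages[-pick], list(merged))
    tbirth <- c(tbirth[-pick], t_now)
  }
  # root branch carries no observable polymorphism
  list(muts = muts, n_sites = next_mut - 1L)
}

#' Simulate a neutral or structured alignment
#'
#' Neutral mode (\code{divergence = 0}): an ancestral sequence with
#' infinite-sites mutations dropped on a standard n-coalescent genealogy, so
#' E[segregating sites] = theta * sum_{i<n} 1/i. Structured mode
#' (\code{divergence > 0}): after the neutral draw, a \code{divergence}
#' fraction of variant sites is overwritten with a fixed between-taxon
#' difference (one taxon carries the derived allele, all others the
#' ancestral), emulating taxon-differentiated allele frequencies; with
#' \code{divergence = 1} and two taxa every variant site is a fixed
#' difference (per-SNP Hudson Fst = 1).
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A \code{\link{gene_alignment}} with taxa from \code{cfg$taxa}.
#' @export
simulate_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  .simulate_alignment_impl(cfg)
}

.simulate_alignment_impl <- function(cfg) {
  n <- sum(cfg$taxa)
  taxa <- rep(names(cfg$taxa), cfg$taxa)
  co <- .coalescent_mutations(n, cfg$theta)
  S <- co$n_sites
  if (S > cfg$L)
    stop("theta too large: ", S, " mutations exceed alignment length ", cfg$L)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, cfg$L, replace = TRUE)
  m <- matrix(rep(anc, each = n), nrow = n)
  if (S > 0L) {
    cols <- sample.int(cfg$L, S) # infinite sites: distinct columns
    derived <- vapply(cols, function(j) sample(setdiff(bases, anc[j]), 1L),
                      character(1))
    for (mut in seq_len(S)) {
      carriers <- which(vapply(co$muts, function(x) mut %in% x, logical(1)))
      if (length(carriers) == 0L || length(carriers) == n) next
      m[carriers, cols[mut]] <- derived[mut]
    }
    if (cfg$divergence > 0 && length(names(cfg$taxa)) >= 2L) {
      n_shift <- round(cfg$divergence * S)
      shift_sites <- cols[seq_len(n_shift)]
      for (j in shift_sites) {
        tx <- sample(names(cfg$taxa), 1L)
        d <- sample(setdiff(bases, anc[j]), 1L)
        m[, j] <- anc[j]
        m[taxa == tx, j] <- d
      }
    }
  }
  gene_alignment(m, ids = sprintf("sim_%03d", seq_len(n)), taxa = taxa,
                 gene = "sim")
}

#' Simulate monthly climate normals
#'
#' Temperatures follow a seasonal cosine with peak at \code{peak_month} plus
#' Gaussian noise; precipitation is drawn from a gamma distribution whose
#' mean follows the same seasonal cycle (wet season at the temperature
#' peak); latitudes are uniform over \code{lat_range}.
#'
#' @param cfg A \code{\link{sim_config}} (its \code{climate} entry is used).
#' @param accessions Character vector of accession IDs.
#' @return List of \code{\link{monthly_climate}} objects.
#' @export
simulate_climate <- function(cfg, accessions) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  .simulate_climate_impl(cfg, accessions)
}

.simulate_climate_impl <- function(cfg, accessions) {
  cc <- cfg$climate
  lapply(accessions, function(acc) {
    lat <- stats::runif(1, cc$lat_range[1], cc$lat_range[2])
    season <- cos(2 * pi * ((1:12) - cc$peak_month) / 12)
    Tm <- cc$mean_t + cc$amplitude * season +
      stats::rnorm(12, 0, cc$t_noise_sd)
    pmean <- pmax(1e-8, cc$precip_scale * (0.5 + 0.5 * season))
    P <- if (cc$precip_scale <= 0) rep(0, 12) else
      stats::rgamma(12, shape = 2, scale = pmean / 2)
    monthly_climate(acc, lat, Tm, P)
  })
}

#' Simulate a coupled genotype-environment dataset
#'
#' Draws a structured alignment, picks the causal variant site configured in
#' \code{cfg$causal}, and builds an environmental index per accession as
#' \code{beta * genotype + taxon effect + N(0, noise_sd)}; taxon effects are
#' equally spaced on \code{[-1, 1] * structure_sd}. If the configured causal
#' position is not polymorphic the alignment is resampled (the retry count
#' is recorded). A truth record carries everything needed for recovery
#' tests.
#'
#' @param cfg A \code{\link{sim_config}} with \code{causal} set.
#' @param structure_sd Scale of the between-taxon environmental effect.
#' @param max_retries Resampling cap for unlucky causal positions.
#' @return List with \code{alignment}, \code{climate} (simulated monthly
#'   records), \code{env} (index vector), and \code{truth} (list: beta,
#'   causal column, genotype vector, taxon effects, noise_sd, retries).
#' @export
simulate_coupled <- function(cfg, structure_sd = 0, max_retries = 20L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$causal)) stop("cfg$causal must be configured")
  set.seed(cfg$seed)
  retries <- 0L
  repeat {
    aln <- .simulate_alignment_impl(cfg)
    vt <- call_variants(aln, exclude_taxa = character())
    if (nrow(vt) >= cfg$causal$position) break
    retries <- retries + 1L
    if (retries > max_retries)
      stop("causal position not polymorphic after ", max_retries, " retries")
  }
  g <- genotype_matrix(aln, vt, exclude_taxa = character())
  causal_col <- cfg$causal$position
  geno <- g[, causal_col]
  geno_filled <- ifelse(is.na(geno), 0L, geno)
  taxa <- attr(g, "taxa")
  lev <- unique(taxa)
  tx_eff <- if (length(lev) > 1L)
    stats::setNames(structure_sd * seq(-1, 1, length.out = length(lev)), lev)
  else stats::setNames(0, lev)
  env <- cfg$causal$beta * geno_filled + tx_eff[taxa] +
    stats::rnorm(nrow(g), 0, cfg$causal$noise_sd)
  climate <- .simulate_climate_impl(cfg, aln$ids)
  list(alignment = aln, climate = climate, env = unname(env),
       truth = list(beta = cfg$causal$beta,
                    causal_variant = causal_col,
                    causal_column = vt$position[causal_col],
                    genotype = unname(geno),
                    taxon_effects = tx_eff,
                    noise_sd = cfg$causal$noise_sd,
                    retries = retries))
}
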