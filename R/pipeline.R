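# End-to-end pipeline driver: climate -> variants -> diversity -> structure
# -> GEA, with a reproducibility manifest.

#' Run the full candidate-gene pipeline
#'
#' Chains every stage for one or more genes: drought indices from the climate
#' table; SNP calling, maf filtering and genotype matrices per gene; SFS
#' summaries; kinship, PCA, per-SNP Fst, NJ tree and haplotype network; and
#' GLM/MLM/CMLM association scans of every timeframe index. All outputs are
#' plain-text CSV/Newick files plus a JSON manifest recording the seed and
#' parameters.
#'
#' @param config Either a list or a path to a YAML file with entries:
#'   \code{fasta} (named list/map gene -> FASTA path), \code{samples}
#'   (sample sheet CSV), \code{climate} (climate CSV), \code{out_dir},
#'   and optional \code{maf} (default 0.05), \code{anchor_month} (1),
#'   \code{n_pc} (2), \code{models} (glm, mlm, cmlm), \code{bootstrap} (0),
#'   \code{seed} (1), \code{scale_indices} (FALSE; raw indices are the
#'   association response by default).
#' @return Invisibly, a list with the in-memory results per stage and the
#'   manifest path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  need <- c("fasta", "samples", "climate", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing entries: ", paste(miss, collapse = ", "))
  maf <- config$maf %||% 0.05
  anchor <- config$anchor_month %||% 1L
  n_pc <- config$n_pc %||% 2L
  models <- tolower(config$models %||% c("glm", "mlm", "cmlm"))
  bootstrap <- config$bootstrap %||% 0L
  seed <- config$seed %||% 1L
  use_scaled <- isTRUE(config$scale_indices)

  if (!file.exists(config$climate))
    stop("climate stage: missing climate table ", config$climate)
  if (!file.exists(config$samples))
    stop("missing sample sheet ", config$samples)
  for (f in unlist(config$fasta))
    if (!file.exists(f)) stop("missing FASTA ", f)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, paste0(...))

  samples <- read_sample_sheet(config$samples)
  climate <- read_climate_csv(config$climate)
  indices <- drought_index_table(climate, anchor_month = anchor, scale = TRUE)
  utils::write.csv(indices, out("indices.csv"), row.names = FALSE)

  idx_cols <- .TIMEFRAMES
  if (use_scaled) idx_cols <- paste0(idx_cols, "_z")

  genes <- list()
  assoc <- list()
  for (gene in names(config$fasta)) {
    aln <- read_fasta(config$fasta[[gene]], samples = samples, gene = gene)
    vt <- maf_filter(call_variants(aln), maf)
    write_variant_csv(vt, out(gene, "_snps.csv"))
    gm <- genotype_matrix(aln, vt)
    utils::write.csv(data.frame(accession = rownames(gm), gm,
                                check.names = FALSE),
                     out(gene, "_genotypes.csv"), row.names = FALSE)
    div <- summarize_by_taxon(aln, maf = maf)
    utils::write.csv(div, out(gene, "_diversity.csv"), row.names = FALSE)
    K <- ibs_kinship(gm)
    if (anyNA(K)) stop("kinship for ", gene, " has pairs with no co-observed SNPs")
    utils::write.csv(K, out(gene, "_kinship.csv"), row.names = TRUE)
    fst <- fst_report(gm)
    if (!is.null(fst$quartiles))
      utils::write.csv(fst$quartiles, out(gene, "_fst.csv"), row.names = FALSE)
    if (n_sequences(aln) >= 3L) {
      tree <- nj_tree(subset_alignment(aln, !(aln$taxa %in% "control")),
                      bootstrap = bootstrap, seed = seed)
      ape::write.tree(tree, out(gene, "_nj.nwk"))
    }
    hs <- collapse_haplotypes(aln, columns = vt$position)
    net <- mj_network(hs)
    write_network_csv(net, hs, out(gene, "_network"))

    acc <- rownames(gm)
    env_tab <- indices[match(acc, indices$accession), , drop = FALSE]
    scans <- list()
    for (ic in idx_cols) {
      env <- env_tab[[ic]]
      if (all(is.na(env))) next
      if ("glm" %in% models)
        scans[[length(scans) + 1L]] <- glm_scan(gm, env, n_pc, gene, ic)
      if ("mlm" %in% models)
        scans[[length(scans) + 1L]] <- mlm_scan(gm, env, K, n_pc, gene, ic)
      if ("cmlm" %in% models)
        scans[[length(scans) + 1L]] <- cmlm_scan(gm, env, K, n_pc,
                                                 gene = gene, index = ic)
    }
    genes[[gene]] <- list(alignment = aln, variants = vt, genotypes = gm,
                          diversity = div, kinship = K, fst = fst,
                          haplotypes = hs, network = net)
    if (length(scans)) assoc[[gene]] <- .new_gea_scan(do.call(rbind, scans))
  }
  assoc_all <- if (length(assoc)) .new_gea_scan(do.call(rbind, assoc)) else NULL
  if (!is.null(assoc_all)) {
    rep <- significance_report(assoc_all)
    utils::write.csv(rep$results, out("assoc.csv"), row.names = FALSE)
    utils::write.csv(rep$summary, out("assoc_summary.csv"), row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("drygene")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = list(maf = maf, anchor_month = anchor, n_pc = n_pc,
                      models = models, bootstrap = bootstrap,
                      scale_indices = use_scaled),
    inputs = list(fasta = config$fasta, samples = config$samples,
                  climate = config$climate))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(indices = indices, genes = genes, assoc = assoc_all,
                 manifest = out("manifest.json")))
}

#' Write a simulated dataset bundle to disk
#'
#' Convenience for testing the pipeline end to end: writes FASTA, sample
#' sheet, climate CSV and a truth JSON from \code{\link{simulate_coupled}}
#' output.
#'
#' @param sim Output of \code{\link{simulate_coupled}}.
#' @param prefix Path prefix for the four files.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_sim_bundle <- function(sim, prefix) {
  fa <- paste0(prefix, ".fa")
  ss <- paste0(prefix, "_samples.csv")
  cl <- paste0(prefix, "_climate.csv")
  tr <- paste0(prefix, "_truth.json")
  write_fasta(sim$alignment, fa)
  aln <- sim$alignment
  lats <- vapply(sim$climate, function(x) x$latitude, numeric(1))
  utils::write.csv(data.frame(accession = aln$ids, taxon = aln$taxa,
                              latitude = lats, longitude = -110),
                   ss, row.names = FALSE)
  tm <- do.call(rbind, lapply(sim$climate, function(x)
    c(x$temperature, x$precipitation)))
  colnames(tm) <- c(sprintf("t%02d", 1:12), sprintf("p%02d", 1:12))
  utils::write.csv(data.frame(accession = aln$ids, taxon = aln$taxa,
                              latitude = lats, longitude = -110, tm),
                   cl, row.names = FALSE)
  jsonlite::write_json(sim$truth, tr, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(fasta = fa, samples = ss, climate = cl, truth = tr))
}
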