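#' Configuration for an MSA comparison run
#'
#' Every stochastic stage draws its seed from the global `seed` via
#' [derive_seed()] with a fixed stage tag, so identical configurations and
#' inputs yield identical reports while stages stay independent.
#'
#' @param seed Global integer seed.
#' @param delta Neighborhood radius for weights / neighbor counts.
#' @param r20_orders,r20_sets,top_k r20 curve parameters.
#' @param pca_k Number of principal components.
#' @param n_stat_pairs,n_stat_triplets How many random site pairs / triplets
#'   enter the correlation scatters.
#' @param n_trees,subsample MGL bootstrap parameters (skipped if
#'   `n_trees = 0`).
#' @return A list of class `"compare_config"`.
#' @export
compare_config <- function(seed = 1L, delta = 0.2, r20_orders = 2:10,
                           r20_sets = 200L, top_k = 20L, pca_k = 2L,
                           n_stat_pairs = 50L, n_stat_triplets = 20L,
                           n_trees = 20L, subsample = 100L) {
  structure(list(seed = as.integer(seed), delta = delta,
                 r20_orders = r20_orders, r20_sets = as.integer(r20_sets),
                 top_k = as.integer(top_k), pca_k = as.integer(pca_k),
                 n_stat_pairs = as.integer(n_stat_pairs),
                 n_stat_triplets = as.integer(n_stat_triplets),
                 n_trees = as.integer(n_trees),
                 subsample = as.integer(subsample)),
            class = "compare_config")
}

#' Compare a synthetic MSA against its natural counterpart
#'
#' Runs the package's full battery on a pair of equal-length alignments:
#' statistical-energy score distributions (when a Potts model is supplied;
#' the section is marked skipped otherwise), the r20 curve, one/two/three-
#' body statistic scatters over random site sets, closest-natural distance
#' distributions, effective depths, neighbor counts, PCA coordinates in the
#' natural basis, and MGL spectral summaries.
#'
#' @param natural,synthetic [new_msa()] objects of equal length (paths to
#'   FASTA files are also accepted).
#' @param potts Optional [potts_model()] (or path to its JSON file) for
#'   energy scoring.
#' @param config A [compare_config()].
#' @return A list of class `"compare_report"` with one element per section.
#' @export
run_compare <- function(natural, synthetic, potts = NULL,
                        config = compare_config()) {
  if (is.character(natural)) natural <- read_fasta_msa(natural)
  if (is.character(synthetic)) synthetic <- read_fasta_msa(synthetic)
  if (is.character(potts)) potts <- read_potts(potts)
  L <- msa_length(natural)
  if (msa_length(synthetic) != L) stop("MSAs must have the same length")

  report <- list(dims = list(L = L, M_natural = msa_depth(natural),
                             M_synthetic = msa_depth(synthetic)))

  report$energy <- if (is.null(potts)) {
    list(skipped = TRUE)
  } else {
    sn <- statistical_energy_score(potts, natural)
    ss <- statistical_energy_score(potts, synthetic)
    list(skipped = FALSE,
         natural = list(mean = mean(sn), sd = stats::sd(sn), scores = sn),
         synthetic = list(mean = mean(ss), sd = stats::sd(ss), scores = ss))
  }

  r20 <- r20_curve(synthetic, natural, orders = config$r20_orders,
                   n_sets = config$r20_sets, top_k = config$top_k,
                   seed = derive_seed(config$seed, "r20"))
  report$r20 <- r20$curve

  pairs_triplets <- with_seed(derive_seed(config$seed, "stats"), {
    pr <- if (L >= 2) replicate(config$n_stat_pairs, sort(sample.int(L, 2)),
                                simplify = FALSE) else list()
    tr <- if (L >= 3) replicate(config$n_stat_triplets,
                                sort(sample.int(L, 3)), simplify = FALSE)
          else list()
    list(pairs = unique(pr), triplets = unique(tr))
  })
  fn <- frequencies(natural, pairs = pairs_triplets$pairs,
                    triplets = pairs_triplets$triplets)
  fs <- frequencies(synthetic, pairs = pairs_triplets$pairs,
                    triplets = pairs_triplets$triplets)
  report$statistics <- list(
    f1 = data.frame(natural = as.vector(fn$f1),
                    synthetic = as.vector(fs$f1)),
    c2 = data.frame(
      natural = unlist(lapply(pairs_triplets$pairs, function(p)
        as.vector(connected_corr2(fn, p[1], p[2])))),
      synthetic = unlist(lapply(pairs_triplets$pairs, function(p)
        as.vector(connected_corr2(fs, p[1], p[2]))))),
    c3 = data.frame(
      natural = unlist(lapply(pairs_triplets$triplets, function(p)
        as.vector(connected_corr3(fn, p[1], p[2], p[3])))),
      synthetic = unlist(lapply(pairs_triplets$triplets, function(p)
        as.vector(connected_corr3(fs, p[1], p[2], p[3]))))))

  report$closest <- list(
    synthetic_to_natural = closest_natural(synthetic, natural)$distance,
    natural_to_natural = if (msa_depth(natural) > 1)
      closest_natural(natural, natural, exclude_self = TRUE)$distance
    else numeric(0))

  report$depth <- list(
    m_eff_natural = sequence_weights(natural, config$delta)$m_eff,
    m_eff_synthetic = sequence_weights(synthetic, config$delta)$m_eff,
    neighbor_counts_natural = neighbor_counts(natural, config$delta),
    neighbor_counts_synthetic = neighbor_counts(synthetic, config$delta))

  basis <- pca_fit(natural, k = config$pca_k)
  report$pca <- list(var_explained = basis$var_explained,
                     natural = pca_project(natural, basis),
                     synthetic = pca_project(synthetic, basis))

  report$mgl <- if (config$n_trees < 1L) {
    list(skipped = TRUE)
  } else {
    sdn <- suppressWarnings(bootstrap_spectral_density(
      natural, n_trees = config$n_trees, subsample = config$subsample,
      seed = derive_seed(config$seed, "mgl-nat")))
    sds <- suppressWarnings(bootstrap_spectral_density(
      synthetic, n_trees = config$n_trees, subsample = config$subsample,
      seed = derive_seed(config$seed, "mgl-syn")))
    list(skipped = FALSE,
         natural = list(skewness = sdn$skewness,
                        mean = mean(sdn$eigenvalues)),
         synthetic = list(skewness = sds$skewness,
                          mean = mean(sds$eigenvalues)))
  }
  structure(report, class = "compare_report")
}

#' @export
print.compare_report <- function(x, ...) {
  cat("MSA comparison report\n")
  cat("  L =", x$dims$L, "; M natural =", x$dims$M_natural,
      "; M synthetic =", x$dims$M_synthetic, "\n")
  if (!isTRUE(x$energy$skipped))
    cat("  mean energy score: natural", signif(x$energy$natural$mean, 5),
        "synthetic", signif(x$energy$synthetic$mean, 5), "\n")
  cat("  r20:", paste(sprintf("%d:%.3f", x$r20$order, x$r20$score),
                      collapse = " "), "\n")
  cat("  M_eff: natural", signif(x$depth$m_eff_natural, 5),
      "synthetic", signif(x$depth$m_eff_synthetic, 5), "\n")
  if (!isTRUE(x$mgl$skipped))
    cat("  MGL skewness: natural", signif(x$mgl$natural$skewness, 4),
        "synthetic", signif(x$mgl$synthetic$skewness, 4), "\n")
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits `report.json` (the full report) plus TSV files for the tabular
#' sections (r20 curve, statistic scatters, PCA coordinates).
#'
#' @param report A [run_compare()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_compare_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), paths[1], auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  paths <- c(paths, tsv(report$r20, "r20.tsv"),
             tsv(report$statistics$f1, "stats_f1.tsv"),
             tsv(report$statistics$c2, "stats_c2.tsv"),
             tsv(as.data.frame(report$pca$natural), "pca_natural.tsv"),
             tsv(as.data.frame(report$pca$synthetic), "pca_synthetic.tsv"))
  invisible(paths)
}
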