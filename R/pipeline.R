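#' Configuration for a full pipeline run
#'
#' Bundles every stage parameter of the synth -> flux -> community ->
#' network -> linkage chain. A single global seed fans out to per-stage
#' seeds via [stage_seed()], so each stochastic stage is independently
#' reproducible.
#'
#' @param synth A [synth_config()] describing the dataset to generate, or
#'   `NULL` when `input_dir` is given.
#' @param input_dir Directory holding `counts.tsv`, `samples.csv` and
#'   `incubation.csv` (the [write_dataset()] layout) to analyse instead of
#'   generating data.
#' @param min_reads Rare-ASV filter threshold (dataset-wide total reads).
#' @param rarefy_depth Rarefaction depth.
#' @param min_occurrence Occurrence filter before correlation.
#' @param r_threshold,p_threshold Network edge thresholds.
#' @param n_perm Permutations for PERMANOVA.
#' @param n_boot Bootstrap resamples for the PLS path model (0 skips).
#' @param network_scope `"pooled"` builds one network from all samples;
#'   `"per_site"` builds one per site and extracts each sample's subnetwork
#'   from its own site network.
#' @param units Mixing-ratio dialect of the incubation records.
#' @param seed Global seed.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synth = synth_config(), input_dir = NULL,
                            min_reads = 10, rarefy_depth = 1016,
                            min_occurrence = 0.2, r_threshold = 0.6,
                            p_threshold = 0.01, n_perm = 999, n_boot = 200,
                            network_scope = c("pooled", "per_site"),
                            units = "mmol_per_mol", seed = 1) {
  network_scope <- match.arg(network_scope)
  if (is.null(synth) && is.null(input_dir)) {
    stop("pipeline_config: need either a synth config or an input_dir")
  }
  structure(list(synth = synth, input_dir = input_dir, min_reads = min_reads,
                 rarefy_depth = rarefy_depth, min_occurrence = min_occurrence,
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 n_perm = n_perm, n_boot = n_boot,
                 network_scope = network_scope, units = units,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Derive a per-stage seed from the global pipeline seed
#'
#' `(seed * 1009 + sum of the stage name's character codes) mod (2^31 - 1)`;
#' stated so any stage can be re-run in isolation with the same stream.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + sum(utf8ToInt(stage))) %% (2^31 - 1))
}

#' Default PLS path model for the PMPR pipeline
#'
#' Seven latent blocks: Nutrition (TOC, TN), NonNutrition (pH, EC),
#' Abundance (log10 mcrA), Diversity (richness, Shannon), Community (PC1,
#' PC2), Complexity (network complexity index) and CH4 (PMPR). Soil blocks
#' predict the biotic blocks; the CH4 block is predicted by all six.
#'
#' @param community_pc `"pc1_pc2"` (default) measures the Community block by
#'   both principal components, `"pc1"` by PC1 only.
#' @return A [plspm_spec()].
#' @export
default_plspm_spec <- function(community_pc = c("pc1_pc2", "pc1")) {
  community_pc <- match.arg(community_pc)
  blocks <- list(
    Nutrition = c("TOC", "TN"),
    NonNutrition = c("pH", "EC"),
    Abundance = "mcrA_log10",
    Diversity = c("richness", "shannon"),
    Community = if (community_pc == "pc1_pc2") c("PC1", "PC2") else "PC1",
    Complexity = "complexity",
    CH4 = "pmpr"
  )
  bn <- names(blocks)
  paths <- matrix(0, 7, 7, dimnames = list(bn, bn))
  paths["Abundance", c("Nutrition", "NonNutrition")] <- 1
  paths["Diversity", c("Nutrition", "NonNutrition")] <- 1
  paths["Community", c("Nutrition", "NonNutrition")] <- 1
  paths["Complexity", c("Nutrition", "NonNutrition", "Diversity", "Community")] <- 1
  paths["CH4", bn[1:6]] <- 1
  plspm_spec(blocks, paths)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: data (synthetic generation or
#' file input), flux (per-sample PMPR from incubation records), community
#' hygiene (rare-ASV filter, rarefaction, diversity, PCA), network
#' (Spearman co-occurrence network, topology, Zi-Pi keystones, per-sample
#' subnetwork complexity), and linkage (PMPR regressions, PERMANOVA on
#' Bray-Curtis, variation partitioning, PLS path model). Every table is
#' written to `outdir` and listed in the returned manifest with MD5
#' checksums; an empty network downgrades the complexity and path-model
#' stages to a structured warning instead of an error.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory; write-once per run (must not already
#'   contain a manifest).
#' @return List with `results` (all stage outputs) and `manifest` (data
#'   frame `file`, `md5`, `bytes`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.exists(file.path(outdir, "manifest.csv"))) {
    stop("run_pipeline: '", outdir, "' already holds a run (outputs are write-once)")
  }
  res <- list()

  # --- stage: data ---------------------------------------------------------
  if (!is.null(config$input_dir)) {
    counts <- read_count_table(file.path(config$input_dir, "counts.tsv"))
    samples <- utils::read.csv(file.path(config$input_dir, "samples.csv"),
                               stringsAsFactors = FALSE)
    incubation <- utils::read.csv(file.path(config$input_dir, "incubation.csv"),
                                  stringsAsFactors = FALSE)
    truth <- NULL
  } else {
    ds <- generate_dataset(config$synth)
    counts <- ds$counts; samples <- ds$samples; incubation <- ds$incubation
    truth <- ds$truth
  }
  needed <- c("sample_id", "site", "pH", "EC", "TOC", "TN", "mcrA_log10")
  miss <- setdiff(needed, names(samples))
  if (length(miss) > 0L) stop("run_pipeline: sample frame missing column(s): ",
                              paste(miss, collapse = ", "))
  sym_diff <- c(setdiff(rownames(counts), samples$sample_id),
                setdiff(samples$sample_id, rownames(counts)))
  if (length(sym_diff) > 0L) {
    stop("run_pipeline: count table and sample frame disagree on samples: ",
         paste(sym_diff, collapse = ", "))
  }
  samples <- samples[match(rownames(counts), samples$sample_id), ]

  # --- stage: flux ---------------------------------------------------------
  flux <- batch_pmpr(incubation, units = config$units)
  samples$pmpr <- flux$pmpr[match(samples$sample_id, flux$sample_id)]
  res$flux <- flux

  # --- stage: community ----------------------------------------------------
  filtered <- filter_rare_asvs(counts, config$min_reads)
  rare <- rarefy(filtered, config$rarefy_depth,
                 seed = stage_seed(config$seed, "rarefy"))
  samples <- samples[match(rownames(rare), samples$sample_id), ]
  div <- alpha_diversity(rare)
  pca <- community_pca(rare)
  res$diversity <- div
  res$pca <- pca

  bc <- bray_curtis(rare)
  res$permanova_site <- permanova(bc, samples$site, n_perm = config$n_perm,
                                  seed = stage_seed(config$seed, "permanova"))

  # --- stage: network ------------------------------------------------------
  make_net <- function(tab) {
    sp <- spearman_matrix(tab, min_occurrence = config$min_occurrence)
    net <- build_network(sp$rho, sp$p, r_threshold = config$r_threshold,
                         p_threshold = config$p_threshold)
    net$params$n_samples <- sp$n
    net
  }
  nets <- if (config$network_scope == "pooled") {
    list(pooled = suppressWarnings(make_net(filtered)))
  } else {
    sites <- unique(samples$site)
    stats::setNames(lapply(sites, function(s) {
      suppressWarnings(make_net(filtered[samples$site == s, , drop = FALSE]))
    }), sites)
  }
  res$networks <- nets
  res$topology <- do.call(rbind, lapply(nets, topology))

  has_edges <- any(vapply(nets, function(nt) nrow(nt$edges) > 0, logical(1)))
  if (has_edges) {
    res$zipi <- do.call(rbind, lapply(names(nets), function(nm) {
      nt <- nets[[nm]]
      if (nrow(nt$edges) == 0L) return(NULL)
      cbind(network = nm, zi_pi(nt))
    }))
    net_for_sample <- function(i) {
      if (config$network_scope == "pooled") nets$pooled else nets[[samples$site[i]]]
    }
    profiles <- do.call(rbind, lapply(seq_len(nrow(rare)), function(i) {
      sub <- suppressWarnings(sample_subnetwork(net_for_sample(i), rare[i, ]))
      topology(sub)
    }))
    profiles <- cbind(sample_id = rownames(rare), profiles)
    res$complexity <- complexity_index(profiles)
  } else {
    warning("run_pipeline: empty co-occurrence network; ",
            "complexity and path-model stages skipped")
    res$zipi <- NULL
    res$complexity <- NULL
  }

  # --- stage: linkage ------------------------------------------------------
  res$regression_mcra <- fit_regression(10^samples$mcrA_log10, samples$pmpr,
                                        x_transform = "log10")
  frame <- data.frame(samples,
                      richness = div$richness[match(samples$sample_id, div$sample_id)],
                      shannon = div$shannon[match(samples$sample_id, div$sample_id)],
                      PC1 = pca$scores$PC1[match(samples$sample_id, pca$scores$sample_id)],
                      PC2 = pca$scores$PC2[match(samples$sample_id, pca$scores$sample_id)])
  if (!is.null(res$complexity)) {
    frame$complexity <- res$complexity$complexity[
      match(frame$sample_id, res$complexity$sample_id)]
    res$regression_complexity <- fit_regression(frame$complexity, frame$pmpr)
    biotic <- frame[, c("mcrA_log10", "richness", "shannon", "PC1", "complexity")]
    abiotic <- frame[, intersect(soil_properties, names(frame))]
    res$vpa <- variation_partition(frame$pmpr, biotic, abiotic)
    res$plspm <- fit_plspm(frame, default_plspm_spec(), n_boot = config$n_boot,
                           seed = stage_seed(config$seed, "plspm"))
  }
  res$frame <- frame

  # --- write artifacts -----------------------------------------------------
  p <- function(f) file.path(outdir, f)
  write_count_table(filtered, p("counts_filtered.tsv"))
  write_count_table(rare, p("counts_rarefied.tsv"))
  utils::write.csv(frame, p("sample_frame.csv"), row.names = FALSE)
  utils::write.csv(flux, p("flux.csv"), row.names = FALSE)
  utils::write.csv(res$topology, p("network_topology.csv"), row.names = TRUE)
  for (nm in names(nets)) {
    utils::write.table(nets[[nm]]$edges, p(paste0("edges_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$zipi)) utils::write.csv(res$zipi, p("zipi.csv"), row.names = FALSE)
  if (!is.null(res$complexity)) {
    utils::write.csv(res$complexity, p("complexity.csv"), row.names = FALSE)
  }
  if (!is.null(res$plspm)) {
    utils::write.csv(res$plspm$paths, p("plspm_paths.csv"), row.names = FALSE)
    jsonlite::write_json(list(gof = res$plspm$gof, r2 = as.list(res$plspm$r2)),
                         p("plspm_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  summary_json <- list(
    seed = config$seed,
    n_samples = nrow(rare),
    n_asvs_filtered = ncol(filtered),
    permanova_site = list(f = res$permanova_site$f,
                          p = res$permanova_site$p_value),
    network_scope = config$network_scope,
    params = config[c("min_reads", "rarefy_depth", "min_occurrence",
                      "r_threshold", "p_threshold", "n_perm", "n_boot")]
  )
  jsonlite::write_json(summary_json, p("run_summary.json"), auto_unbox = TRUE,
                       digits = NA)
  # the manifest lists every artifact of the run (itself excluded)
  files <- list.files(outdir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         bytes = unname(file.size(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, p("manifest.csv"), row.names = FALSE)
  if (!is.null(truth)) res$truth <- truth
  list(results = res, manifest = manifest)
}
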