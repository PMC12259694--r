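#' Configuration for the synthetic wetland methanogen dataset
#'
#' Describes a nested field design (sites x plots x depth layers), a
#' methanogen community with planted correlated ASV blocks, per-site soil
#' chemistry, mcrA abundances, and a potential methane production rate (PMPR)
#' generated as a known linear combination of three standardized drivers:
#' log10 mcrA abundance, soil nutrition (TOC/TN) and a per-sample network
#' complexity driver. Identical config + seed gives bit-identical output.
#'
#' Community model: each sample draws one latent Gaussian factor per module;
#' an ASV in module k has latent value
#' `sqrt(rho) * m_k + sqrt(1 - rho) * noise` (exchangeable within-module
#' correlation `rho`), background ASVs are independent noise. Latents map
#' rank-preservingly through log-normal quantiles to expected relative
#' abundances (a Gaussian copula), and counts are multinomial at a jittered
#' sequencing depth. Each module contains abundant "core" members (which
#' carry the recoverable correlation signal) and rarer "satellite" members
#' whose presence/absence varies between samples; the mean of the module
#' factors is the planted complexity driver, so samples with high factors
#' carry more satellite ASVs and hence denser per-sample subnetworks.
#'
#' With `module_structure = "hub"` each module instead gets a hub-and-spoke
#' correlation pattern (first member loads 0.975 on the module factor,
#' remaining members 0.80), planting module hubs as recoverable keystones.
#'
#' @param n_sites,plots_per_site,depths Field design; the default is 4 sites
#'   x 8 plots x 4 depth layers = 128 samples.
#' @param n_asvs Number of ASVs in the community table.
#' @param n_modules,module_size Number and size of planted correlated blocks.
#' @param n_satellites Presence-variable (rare) members per module; must be
#'   smaller than `module_size`.
#' @param within_module_rho Latent correlation inside a module, in (0, 1).
#' @param module_structure `"exchangeable"` (default) or `"hub"`.
#' @param site_effects Numeric matrix `n_sites` x 8 of per-site means for
#'   pH, EC (mS/cm), SWC (%), TOC (g/kg), TN (g/kg), TP (g/kg),
#'   NO3 (mg/kg), NH4 (mg/kg). Default contrasts two mineral (higher pH/EC,
#'   low carbon) and two peatland (carbon-rich) wetlands.
#' @param beta_abund,beta_nutrition,beta_complexity Standardized linear
#'   effects of the three drivers on the PMPR score, in the order
#'   abundance > nutrition > complexity.
#' @param noise_sd Residual standard deviation of the PMPR score.
#' @param depth_mean,depth_sd,min_depth Sequencing depth model: normal jitter
#'   around `depth_mean`, truncated below at `min_depth`.
#' @param n_dropped Number of randomly dropped samples (mimicking failed
#'   libraries); default 0 keeps the full design.
#' @param seed Integer random seed.
#' @return Validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_sites = 4, plots_per_site = 8,
                         depths = c("0_5cm", "5_10cm", "10_20cm", "20_40cm"),
                         n_asvs = 300, n_modules = 4, module_size = 10,
                         n_satellites = 8, within_module_rho = 0.75,
                         module_structure = c("exchangeable", "hub"),
                         site_effects = NULL,
                         beta_abund = 0.8, beta_nutrition = 0.6,
                         beta_complexity = 0.58, noise_sd = 0.25,
                         depth_mean = 2000, depth_sd = 150, min_depth = 1016,
                         n_dropped = 0, seed = 1) {
  module_structure <- match.arg(module_structure)
  counts <- c(n_sites = n_sites, plots_per_site = plots_per_site,
              n_asvs = n_asvs, n_modules = n_modules, module_size = module_size)
  if (any(counts < 1)) stop("all design counts must be >= 1")
  if (length(depths) < 1) stop("need at least one depth layer")
  if (!(within_module_rho > 0 && within_module_rho < 1)) {
    stop("within_module_rho must be strictly in (0, 1)")
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (module_size * n_modules > n_asvs) {
    stop("module_size * n_modules exceeds n_asvs")
  }
  if (n_satellites >= module_size) stop("n_satellites must be < module_size")
  if (is.null(site_effects)) site_effects <- default_site_effects(n_sites)
  site_effects <- as.matrix(site_effects)
  if (nrow(site_effects) != n_sites || ncol(site_effects) != 8) {
    stop("site_effects must be an n_sites x 8 matrix")
  }
  colnames(site_effects) <- soil_properties
  n_samples <- n_sites * plots_per_site * length(depths)
  if (n_dropped < 0 || n_dropped >= n_samples) stop("invalid n_dropped")
  structure(list(n_sites = n_sites, plots_per_site = plots_per_site,
                 depths = depths, n_asvs = n_asvs, n_modules = n_modules,
                 module_size = module_size, n_satellites = n_satellites,
                 within_module_rho = within_module_rho,
                 module_structure = module_structure,
                 site_effects = site_effects,
                 beta_abund = beta_abund, beta_nutrition = beta_nutrition,
                 beta_complexity = beta_complexity, noise_sd = noise_sd,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 min_depth = min_depth, n_dropped = n_dropped,
                 seed = as.integer(seed)),
            class = "synth_config")
}

soil_properties <- c("pH", "EC", "SWC", "TOC", "TN", "TP", "NO3", "NH4")

# Two mineral wetlands (higher pH and salinity, carbon-poor) and two
# peatlands (carbon- and nitrogen-rich); recycled if n_sites != 4.
default_site_effects <- function(n_sites) {
  base <- rbind(
    c(8.2, 1.5, 35, 30, 2.5, 0.7, 8, 12),
    c(7.9, 1.1, 40, 45, 3.2, 0.8, 10, 15),
    c(6.8, 0.4, 65, 180, 9.0, 1.2, 15, 30),
    c(7.1, 0.5, 60, 150, 7.5, 1.1, 12, 25)
  )
  m <- base[rep_len(seq_len(4), n_sites), , drop = FALSE]
  colnames(m) <- soil_properties
  m
}

# Abundance tiers of the log-normal copula map (relative-abundance scale).
# Satellite members are conditionally rare: they sit near the detection limit
# with a steep copula (large sdlog) and load more strongly on their module
# factor than the exchangeable core (sat_loading vs sqrt(within_module_rho)),
# so their presence/absence tracks the module's activity and the per-sample
# subnetwork complexity becomes a recoverable readout of the planted driver.
synth_tiers <- function() {
  list(core = list(meanlog = log(0.018), sdlog = 1.0),
       satellite = list(meanlog = log(0.0018), sdlog = 1.5),
       background = list(meanlog = log(5e-4), sdlog = 1.5),
       sat_loading = 0.95,
       site_boost = 1.5)  # added to meanlog of a site's dominant ASVs
}

#' Generate a complete synthetic dataset with known ground truth
#'
#' Produces a count table, a per-sample metadata frame, replicated incubation
#' records back-computed so that [batch_pmpr()] recovers each sample's PMPR
#' exactly, and the planted ground truth (true edges, module assignment,
#' keystones, true path coefficients and the per-sample driver scores).
#'
#' @param config A [synth_config()].
#' @return List of class `"methanonet_dataset"` with elements `counts`
#'   (samples x ASVs integer matrix), `samples` (data frame: design factors,
#'   soil properties, `mcrA_log10`, `pmpr`), `incubation` (data frame of vial
#'   records: three identical replicates plus an N2 blank per sample),
#'   `truth` (list: `true_edges`, `module_assignment`, `planted_keystones`,
#'   `true_path_coefficients`, `drivers`) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cf <- config
  n_depths <- length(cf$depths)
  n <- cf$n_sites * cf$plots_per_site * n_depths

  meta <- expand.grid(depth = cf$depths,
                      plot = paste0("P", seq_len(cf$plots_per_site)),
                      site = paste0("S", seq_len(cf$n_sites)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("site", "plot", "depth")]
  meta$sample_id <- paste(meta$site, meta$plot, gsub("cm$", "", meta$depth),
                          sep = "_")

  # --- ASV roles -----------------------------------------------------------
  n_mod_asvs <- cf$n_modules * cf$module_size
  asv_ids <- sprintf("ASV%04d", seq_len(cf$n_asvs))
  module_of <- rep(NA_integer_, cf$n_asvs)
  module_of[seq_len(n_mod_asvs)] <- rep(seq_len(cf$n_modules), each = cf$module_size)
  rank_in_module <- integer(cf$n_asvs)
  rank_in_module[seq_len(n_mod_asvs)] <- rep(seq_len(cf$module_size), cf$n_modules)
  is_satellite <- !is.na(module_of) &
    rank_in_module > (cf$module_size - cf$n_satellites)
  is_hub <- cf$module_structure == "hub" & !is.na(module_of) & rank_in_module == 1L

  tiers <- synth_tiers()
  meanlog <- rep(tiers$background$meanlog, cf$n_asvs)
  sdlog <- rep(tiers$background$sdlog, cf$n_asvs)
  meanlog[!is.na(module_of)] <- tiers$core$meanlog
  sdlog[!is.na(module_of)] <- tiers$core$sdlog
  meanlog[is_satellite] <- tiers$satellite$meanlog
  sdlog[is_satellite] <- tiers$satellite$sdlog

  # site-specific dominant background ASVs (15 per site, disjoint blocks)
  bg <- which(is.na(module_of))
  n_dom <- min(15L, floor(length(bg) / cf$n_sites))
  dom_sets <- lapply(seq_len(cf$n_sites), function(s) {
    bg[seq((s - 1) * n_dom + 1, s * n_dom)]
  })

  # --- latent field and counts --------------------------------------------
  m_fac <- matrix(stats::rnorm(n * cf$n_modules), n, cf$n_modules)
  complexity_driver <- rowSums(m_fac) / sqrt(cf$n_modules)

  z <- matrix(stats::rnorm(n * cf$n_asvs), n, cf$n_asvs)
  rho <- cf$within_module_rho
  for (j in seq_len(cf$n_asvs)) {
    k <- module_of[j]
    if (is.na(k)) next
    loading <- if (cf$module_structure == "hub") {
      if (is_hub[j]) 0.975 else 0.80
    } else if (is_satellite[j]) tiers$sat_loading else sqrt(rho)
    z[, j] <- loading * m_fac[, k] + sqrt(1 - loading^2) * z[, j]
  }

  site_idx <- match(meta$site, paste0("S", seq_len(cf$n_sites)))
  boost <- matrix(0, n, cf$n_asvs)
  for (s in seq_len(cf$n_sites)) {
    boost[site_idx == s, dom_sets[[s]]] <- tiers$site_boost
  }
  lambda <- stats::qlnorm(stats::pnorm(z),
                          meanlog = rep(meanlog, each = n) + boost,
                          sdlog = rep(sdlog, each = n))
  pmat <- lambda / rowSums(lambda)
  depth_reads <- pmax(cf$min_depth,
                      round(stats::rnorm(n, cf$depth_mean, cf$depth_sd)))
  counts <- t(vapply(seq_len(n), function(i) {
    as.integer(stats::rmultinom(1, depth_reads[i], pmat[i, ]))
  }, integer(cf$n_asvs)))
  dimnames(counts) <- list(meta$sample_id, asv_ids)

  # --- soil properties -----------------------------------------------------
  prop_sd <- 0.08 * colMeans(cf$site_effects)
  corr <- diag(8)
  dimnames(corr) <- list(soil_properties, soil_properties)
  corr["TOC", "TN"] <- corr["TN", "TOC"] <- 0.6
  corr["pH", "EC"] <- corr["EC", "pH"] <- 0.4
  corr["TOC", "SWC"] <- corr["SWC", "TOC"] <- 0.4
  sigma <- diag(prop_sd) %*% corr %*% diag(prop_sd)
  soil <- cf$site_effects[site_idx, , drop = FALSE] +
    MASS::mvrnorm(n, mu = rep(0, 8), Sigma = sigma)
  colnames(soil) <- soil_properties

  # --- drivers and PMPR ----------------------------------------------------
  z_abund <- stats::rnorm(n)
  mcrA_log10 <- 1.8 + 0.2 * z_abund
  z_nutr <- as.numeric(scale((scale(soil[, "TOC"]) + scale(soil[, "TN"])) / 2))
  z_cplx <- as.numeric(scale(complexity_driver))
  pmpr_z <- cf$beta_abund * z_abund + cf$beta_nutrition * z_nutr +
    cf$beta_complexity * z_cplx + stats::rnorm(n, 0, cf$noise_sd)
  pmpr <- 200 + 80 * pmpr_z  # ng CH4 g^-1 dry soil day^-1

  samples <- data.frame(meta[, c("sample_id", "site", "plot", "depth")],
                        soil, mcrA_log10 = mcrA_log10, pmpr = pmpr,
                        stringsAsFactors = FALSE)

  # --- incubation records back-computed from the PMPRs ---------------------
  incubation <- make_incubation(samples$sample_id, pmpr)

  # --- optional dropped samples -------------------------------------------
  if (cf$n_dropped > 0) {
    drop <- sample(n, cf$n_dropped)
    kept_ids <- samples$sample_id[-drop]
    counts <- counts[kept_ids, , drop = FALSE]
    samples <- samples[samples$sample_id %in% kept_ids, , drop = FALSE]
    incubation <- incubation[incubation$sample_id %in% kept_ids, , drop = FALSE]
  }

  mod_named <- stats::setNames(module_of, asv_ids)
  pairs <- do.call(rbind, lapply(seq_len(cf$n_modules), function(k) {
    ids <- asv_ids[which(module_of == k)]
    t(utils::combn(ids, 2))
  }))
  truth <- list(
    true_edges = data.frame(from = pairs[, 1], to = pairs[, 2],
                            stringsAsFactors = FALSE),
    module_assignment = mod_named[!is.na(mod_named)],
    planted_keystones = asv_ids[is_hub],
    true_path_coefficients = c(abundance = cf$beta_abund,
                               nutrition = cf$beta_nutrition,
                               complexity = cf$beta_complexity),
    drivers = data.frame(sample_id = samples$sample_id,
                         abundance_z = z_abund[match(samples$sample_id, meta$sample_id)],
                         nutrition_z = z_nutr[match(samples$sample_id, meta$sample_id)],
                         complexity_z = z_cplx[match(samples$sample_id, meta$sample_id)],
                         stringsAsFactors = FALSE)
  )
  structure(list(counts = counts, samples = samples, incubation = incubation,
                 truth = truth, config = cf),
            class = "methanonet_dataset")
}

# Three identical replicate vials plus one N2 blank per sample, with the
# mixing-ratio change solved from the target PMPR so the flux equation
# round-trips exactly. Vial constants: 120 mL serum vial with 5 g soil and
# 1:1 water (headspace 0.115 L), plateau atmospheric pressure 67 kPa,
# incubation at 25 C, measurements on day 1 and day 15.
make_incubation <- function(sample_ids, pmpr,
                            VH = 0.115, PA = 67, Ws = 5, Tinc = 25,
                            t0 = 1, t1 = 15, c_base = 0.5) {
  MM <- 16.04; T_ST <- 273.15; Rgas <- 8.314
  dc_dt <- pmpr * Ws * Rgas * (T_ST + Tinc) / (1e-3 * MM * 1e9 * PA * VH)
  one <- function(id, dd, role, rep_no) {
    data.frame(sample_id = id, role = role, replicate = rep_no,
               c_t0 = c_base, c_t1 = c_base + dd * (t1 - t0),
               t0 = t0, t1 = t1, VH = VH, PA = PA, Ws = Ws, T = Tinc,
               stringsAsFactors = FALSE)
  }
  recs <- lapply(seq_along(sample_ids), function(i) {
    rbind(one(sample_ids[i], dc_dt[i], "sample", 1L),
          one(sample_ids[i], dc_dt[i], "sample", 2L),
          one(sample_ids[i], dc_dt[i], "sample", 3L),
          one(sample_ids[i], 0, "blank", 1L))
  })
  do.call(rbind, recs)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the count table as TSV (samples as rows, header of ASV ids, first
#' column `sample_id`), the sample frame and incubation records as CSV, and
#' the ground truth as JSON; all four round-trip losslessly through
#' [read_count_table()] / [utils::read.csv()].
#'
#' @param dataset A `methanonet_dataset`.
#' @param dir Output directory (created if needed).
#' @return Manifest data frame: `file`, `md5`, `bytes`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "methanonet_dataset"))
  if (nrow(dataset$counts) == 0L) stop("write_dataset: empty sample set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.csv"),
             incubation = file.path(dir, "incubation.csv"),
             truth = file.path(dir, "ground_truth.json"))
  ok <- tryCatch({
    write_count_table(dataset$counts, paths["counts"])
    utils::write.csv(dataset$samples, paths["samples"], row.names = FALSE)
    utils::write.csv(dataset$incubation, paths["incubation"], row.names = FALSE)
    truth <- dataset$truth
    truth$module_assignment <- as.list(truth$module_assignment)
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) {
    stop("write_dataset: I/O failure under '", dir, "': ", conditionMessage(e))
  })
  data.frame(file = unname(paths),
             md5 = unname(tools::md5sum(paths)),
             bytes = unname(file.size(paths)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a sample-by-ASV count table from TSV
#'
#' @param path TSV file with a header row of ASV ids and sample ids in the
#'   first column.
#' @return Integer count matrix (samples x ASVs).
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  validate_count_table(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count table as TSV
#'
#' @param x Count table (samples x ASVs).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
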