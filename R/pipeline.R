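#' Run configuration for the end-to-end analysis
#'
#' Either simulation mode (a [sim_config()] describes the cohort) or VCF
#' mode (`vcf` + `manifest_file` point at phased input). Every analysis
#' parameter — MAF threshold, window sizes and steps, ancestry model
#' parameters, migration sign convention and z threshold, selection-scan
#' thresholds — is surfaced here.
#'
#' @param mode `"simulate"` or `"vcf"`.
#' @param sim a [sim_config()] (simulation mode).
#' @param vcf,manifest_file input paths (VCF mode).
#' @param external_ancestry optional path to a precomputed ancestry TSV
#'   (see [read_external_ancestry()]); skips internal inference.
#' @param use_truth_ancestry in simulation mode, use the simulated tracts
#'   as a one-hot oracle ancestry instead of running the HMM.
#' @param maf MAF filter threshold (default 0.01).
#' @param window_size,scan_step window size and migration-scan step in SNPs
#'   (defaults 30 and 15; training windows are non-overlapping).
#' @param eps,rho,tau ancestry-model copying error, switch probability and
#'   exclusivity threshold.
#' @param prior ancestry prior (default uniform).
#' @param z_threshold migration outlier threshold on |z| (default 3).
#' @param convention migration sign convention.
#' @param ihs_threshold,region_min_hits,region_span candidate-region rule:
#'   |iHS| threshold, minimum run and bp span (defaults 3, 3, 1 Mb).
#' @param fst_pairs list of 2-vectors of population labels to contrast.
#' @param rsb_pair 2-vector of population labels for Rsb (optional).
#' @param seed integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "vcf"), sim = sim_config(),
                       vcf = NULL, manifest_file = NULL,
                       external_ancestry = NULL,
                       use_truth_ancestry = FALSE,
                       maf = 0.01, window_size = 30L, scan_step = 15L,
                       eps = 0.01, rho = 0.05, tau = 0.95, prior = NULL,
                       z_threshold = 3, convention = "observed-minus-expected",
                       ihs_threshold = 3, region_min_hits = 3L,
                       region_span = 1e6, fst_pairs = NULL, rsb_pair = NULL,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "vcf") {
    for (p in c(vcf, manifest_file, external_ancestry))
      if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
    if (is.null(vcf) || is.null(manifest_file))
      stop("vcf mode needs both vcf and manifest_file")
  }
  cfg <- list(mode = mode, sim = sim, vcf = vcf,
              manifest_file = manifest_file,
              external_ancestry = external_ancestry,
              use_truth_ancestry = use_truth_ancestry,
              maf = maf, window_size = as.integer(window_size),
              scan_step = as.integer(scan_step), eps = eps, rho = rho,
              tau = tau, prior = prior, z_threshold = z_threshold,
              convention = convention, ihs_threshold = ihs_threshold,
              region_min_hits = as.integer(region_min_hits),
              region_span = region_span, fst_pairs = fst_pairs,
              rsb_pair = rsb_pair, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file; keys as in [run_config()] (a `sim:` block is
#'   passed to [sim_config()]).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(run_config, y)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: load or simulate genotypes; MAF filter;
#' window grids (non-overlapping training grid, stepped scan grid); local
#' ancestry (internal HMM, external TSV, or simulation-truth oracle);
#' haplotype-migration scan and outlier regions; iHS on the admixed cohort
#' with candidate-region calling; optional Rsb and F_ST contrasts. Outputs
#' (migration.tsv, ihs.tsv, rsb.tsv, fst.tsv, regions.bed, regions.tsv,
#' ancestry.tsv, report.md, provenance.json) are written under `out_dir`;
#' every run is deterministic given (config, seed).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return A list of in-memory artifacts (panels, grids, ancestry field,
#'   migration records, scans, regions, file paths), invisibly usable by
#'   [make_report()].
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  truth <- NULL
  if (config$mode == "simulate") {
    sim <- stage("simulate", {
      par <- simulate_parental_panels(config$sim)
      adm <- simulate_admixed(par$panel, config$sim)
      list(par = par, adm = adm)
    })
    parental <- sim$par$panel
    admixed <- sim$adm$panel
    truth <- sim$adm$truth
    merged <- genotype_panel(
      rbind(parental$hap, admixed$hap), parental$map,
      {
        m <- rbind(parental$manifest, admixed$manifest)
        class(m) <- c("sample_manifest", "data.frame")
        m
      })
  } else {
    merged <- stage("load", {
      manifest <- read_manifest(config$manifest_file)
      read_phased_vcf(config$vcf, manifest)
    })
  }
  merged <- stage("filter", filter_maf(merged, config$maf))
  n_dropped <- length(attr(merged, "dropped"))
  parental_pops <- unique(
    merged$manifest$population[merged$manifest$role == "parental_panel"])
  admixed_rows <- merged$manifest$role == "admixed"
  parental <- genotype_panel(
    merged$hap[rep(!admixed_rows, each = 2L), , drop = FALSE], merged$map,
    { m <- merged$manifest[!admixed_rows, ]; rownames(m) <- NULL
      class(m) <- c("sample_manifest", "data.frame"); m })
  admixed <- genotype_panel(
    merged$hap[rep(admixed_rows, each = 2L), , drop = FALSE], merged$map,
    { m <- merged$manifest[admixed_rows, ]; rownames(m) <- NULL
      class(m) <- c("sample_manifest", "data.frame"); m })
  train_grid <- stage("windows",
                      build_windows(merged$map, config$window_size))
  scan_grid <- build_windows(merged$map, config$window_size,
                             config$scan_step)
  field <- stage("ancestry", {
    if (!is.null(config$external_ancestry)) {
      read_external_ancestry(config$external_ancestry, train_grid)
    } else if (config$mode == "simulate" && config$use_truth_ancestry) {
      ancestry_from_truth(truth, train_grid)
    } else {
      model <- train_ancestry_model(parental, train_grid, eps = config$eps,
                                    rho = config$rho, prior = config$prior)
      infer_local_ancestry(admixed, model)
    }
  })
  migration <- stage("migration",
                     migration_scan(parental, admixed, field, scan_grid,
                                    convention = config$convention))
  outliers <- call_migration_outliers(migration, config$z_threshold)
  mig_regions <- merge_outlier_regions(outliers)
  ihs_scan <- stage("ihs", ihs(admixed))
  regions <- candidate_regions(ihs_scan, "ihs", config$ihs_threshold,
                               config$region_min_hits, config$region_span)
  rsb_scan <- NULL
  if (!is.null(config$rsb_pair)) {
    rsb_scan <- stage("rsb", rsb(subset_population(merged, config$rsb_pair[1]),
                                 subset_population(merged, config$rsb_pair[2])))
  }
  fst_tabs <- list()
  fst_pairs <- config$fst_pairs
  if (is.null(fst_pairs) && length(parental_pops) && any(admixed_rows)) {
    adm_pop <- unique(merged$manifest$population[admixed_rows])[1]
    fst_pairs <- lapply(parental_pops, function(p) c(adm_pop, p))
  }
  for (pair in fst_pairs) {
    fst_tabs[[paste(pair, collapse = "_vs_")]] <-
      stage("fst", fst(merged, pair[1], pair[2]))
  }
  # ---- outputs ----
  seed_header <- function(path, lines) {
    writeLines(c(sprintf("# hapflow seed=%d config=%s", config$seed,
                         config_hash(config)), lines), path)
  }
  fwrite_seeded <- function(d, path) {
    tmp <- tempfile(); data.table::fwrite(d, tmp, sep = "\t")
    seed_header(path, readLines(tmp)); unlink(tmp)
  }
  fwrite_seeded(migration, file.path(out_dir, "migration.tsv"))
  fwrite_seeded(ihs_scan, file.path(out_dir, "ihs.tsv"))
  if (!is.null(rsb_scan))
    fwrite_seeded(rsb_scan, file.path(out_dir, "rsb.tsv"))
  if (length(fst_tabs)) {
    fst_summary <- data.table::rbindlist(lapply(names(fst_tabs), function(n)
      data.table::data.table(pair = n,
                             mean_raw = fst_tabs[[n]]$mean_raw,
                             mean_truncated = fst_tabs[[n]]$mean_truncated,
                             overall = fst_tabs[[n]]$overall)))
    fwrite_seeded(fst_summary, file.path(out_dir, "fst.tsv"))
  }
  mean_sum <- ancestry_summaries(field, "mean")
  min_sum <- ancestry_summaries(field, "minimum", tau = config$tau)
  anc_out <- cbind(field$grid[, c("chrom", "start_bp", "end_bp")],
                   mean_sum[, -1, drop = FALSE])
  names(anc_out)[-(1:3)] <- paste0("mean_", field$breeds)
  for (b in field$breeds) anc_out[[paste0("min_", b)]] <- min_sum[[b]]
  fwrite_seeded(anc_out, file.path(out_dir, "ancestry.tsv"))
  # candidate regions as BED (0-based half-open) + TSV
  if (nrow(regions)) {
    bed <- data.table::data.table(chrom = regions$chrom,
                                  start = regions$start_bp - 1L,
                                  end = regions$end_bp,
                                  name = sprintf("iHS_region_%d",
                                                 seq_len(nrow(regions))),
                                  score = round(regions$max_score, 3))
    data.table::fwrite(bed, file.path(out_dir, "regions.bed"), sep = "\t",
                       col.names = FALSE)
  } else {
    file.create(file.path(out_dir, "regions.bed"))
  }
  fwrite_seeded(regions, file.path(out_dir, "regions.tsv"))
  provenance <- list(config = unclass(config), seed = config$seed,
                     config_hash = config_hash(config),
                     n_sites_dropped_maf = n_dropped,
                     n_sites = n_sites(merged),
                     n_samples = nrow(merged$manifest),
                     package_version = as.character(
                       utils::packageVersion("hapflow")))
  provenance$config$sim <- if (config$mode == "simulate")
    unclass(config$sim) else NULL
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  artifacts <- list(parental = parental, admixed = admixed, truth = truth,
                    train_grid = train_grid, scan_grid = scan_grid,
                    ancestry = field, migration = migration,
                    migration_outliers = outliers,
                    migration_regions = mig_regions,
                    ihs = ihs_scan, ihs_regions = regions, rsb = rsb_scan,
                    fst = fst_tabs, out_dir = out_dir, config = config)
  report <- make_report(artifacts)
  writeLines(report, file.path(out_dir, "report.md"))
  invisible(artifacts)
}

#' Summary report tables
#'
#' Builds a migration summary (only rows where the parental or admixed
#' frequency exceeds 0.3 are displayed, mirroring the field's reporting
#' convention) and a candidate-region summary, as a markdown report.
#'
#' @param artifacts result of [run_pipeline()], or a list with elements
#'   `migration_regions` and `ihs_regions` (each possibly empty).
#' @return Character vector of markdown lines.
#' @export
make_report <- function(artifacts) {
  fmt_table <- function(d, digits = 3) {
    if (!nrow(d)) return(c(paste(names(d), collapse = " | "), "(no rows)"))
    num <- vapply(d, is.numeric, logical(1))
    for (j in which(num)) d[[j]] <- round(d[[j]], digits)
    c(paste(names(d), collapse = " | "),
      paste(rep("---", ncol(d)), collapse = " | "),
      apply(d, 1L, paste, collapse = " | "))
  }
  mig <- artifacts$migration_regions
  if (!is.null(mig) && nrow(mig)) {
    mig <- mig[mig$freq_parental > 0.3 | mig$observed > 0.3, ]
    mig <- mig[order(mig$chrom, mig$start_bp), ]
  }
  ihs_r <- artifacts$ihs_regions
  if (!is.null(ihs_r) && nrow(ihs_r))
    ihs_r <- ihs_r[order(ihs_r$chrom, ihs_r$start_bp), ]
  c("# hapflow run report", "",
    "## Haplotype-migration outlier regions (display: frequency > 0.3)", "",
    fmt_table(if (is.null(mig)) data.table::data.table() else mig), "",
    "## iHS candidate regions", "",
    fmt_table(if (is.null(ihs_r)) data.table::data.table() else ihs_r))
}
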