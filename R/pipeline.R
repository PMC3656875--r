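default_run_config <- function() {
  list(
    seed = 1L,
    enzyme = "PstI",
    tag_length = 64L,
    key = NA_character_,              # path; NA = packaged cattle key
    out = NA_character_,              # output directory; NA = no files
    simulate = list(
      n_sites = 400L, n_paralog = 25L, mean_locus_depth = 10,
      error_rate = 0.002, cv_reads = 0.39, overdispersion = 10,
      size_window = c(100, 900), genome_chroms = 5L,
      genome_chrom_bp = 2e6, cnv = "default", maf_range = c(0.1, 0.5)),
    filters = list(
      mnMAF = 0.05, mnF = 0.05, min_minor_individuals = 3L,
      min_site_call_rate = 0.70, high_confidence_call_rate = 0.90,
      min_individual_call_rate = 0.50),
    cnv_scan = list(window_bp = 50000L, fold_threshold = 1.75,
                    min_tags = 3L))
}

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected; values round-trip losslessly through JSON.
#'
#' @param config named list of overrides, or a path to a JSON config file.
#' @param ... additional top-level overrides.
#' @return validated config list of class `RunConfig`.
#' @export
run_config <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- utils::modifyList(config, list(...))
  def <- default_run_config()
  check_keys <- function(given, ref, path = "") {
    unknown <- setdiff(names(given), names(ref))
    if (length(unknown) > 0)
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "))
    for (k in names(given))
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]])))
        check_keys(as.list(given[[k]]), ref[[k]], paste0(k, "."))
  }
  check_keys(config, def)
  cfg <- utils::modifyList(def, config)
  # modifyList drops NULL-valued entries; restore them as their defaults
  # so the canonical shape (and hash) does not depend on how an unset
  # field was spelled
  for (k in setdiff(names(def), names(cfg))) cfg[k] <- def[k]
  cfg <- cfg[names(def)]
  if (cfg$filters$mnMAF > 0.5)
    stop("mnMAF > 0.5 is not a valid minor-allele-frequency floor")
  fr <- unlist(cfg$filters[c("min_site_call_rate",
                             "high_confidence_call_rate",
                             "min_individual_call_rate")])
  if (any(fr < 0 | fr > 1)) stop("call-rate thresholds must be in [0,1]")
  if (cfg$simulate$error_rate >= 0.1) stop("error_rate must be < 0.1")
  cfg$version <- as.character(utils::packageVersion("gbskit"))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Fingerprint a configuration
#'
#' The output path is not part of the analytic configuration and is
#' excluded, so runs writing to different directories still produce
#' byte-identical artifacts.
#'
#' @param cfg a `RunConfig`.
#' @return md5 hash of the canonical JSON serialization.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  x <- unclass(cfg)
  x <- x[setdiff(names(x), c("out", "version"))]
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full GBS pipeline on a simulated experiment
#'
#' Executes simulate -> demultiplex -> tag counting -> anchoring ->
#' SNP discovery/genotyping -> sample exclusion -> filter cascade ->
#' population statistics -> NJ tree -> CNV scan, logging row counts per
#' stage. With `cfg$out` set, writes the VCF, Newick tree and TSV reports
#' (all byte-deterministic for a fixed config).
#'
#' @param cfg a `RunConfig`.
#' @return list of class `GBSRun` with the intermediate objects, the
#'   per-sample read/call-rate table, and a `stages` log.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "RunConfig"))
  stages <- list()
  log_stage <- function(name, ...) {
    stages[[name]] <<- list(...)
  }
  key <- if (is.null(cfg$key) || is.na(cfg$key))
    read_key(system.file("extdata", "cattle_key.tsv", package = "gbskit"))
  else read_key(cfg$key)

  sc <- cfg$simulate
  pop <- population_spec(n_sites = sc$n_sites,
                         maf_range = sc$maf_range, seed = cfg$seed)
  rsc <- read_sim_config(mean_locus_depth = sc$mean_locus_depth,
                         cv_reads = sc$cv_reads,
                         error_rate = sc$error_rate,
                         overdispersion = sc$overdispersion,
                         tag_length = cfg$tag_length,
                         size_window = sc$size_window)
  genome <- simulate_genome(
    stats::setNames(rep(sc$genome_chrom_bp, sc$genome_chroms),
                    paste0("chr", seq_len(sc$genome_chroms))),
    seed = cfg$seed + 1L)
  sim <- simulate_gbs(key = key, enzyme = cfg$enzyme, pop = pop, cfg = rsc,
                      genome = genome, cnv = sc$cnv,
                      n_paralog = sc$n_paralog, seed = cfg$seed)
  log_stage("simulate", n_reads = length(sim$reads),
            n_sites = nrow(sim$truth$sites),
            n_fragments = nrow(sim$fragments))

  dx <- demultiplex(sim$reads, key, sim$enzyme)
  log_stage("demultiplex", n_assigned = sum(!is.na(dx$assign)),
            n_no_barcode = dx$n_unassigned_no_barcode,
            n_no_remnant = dx$n_unassigned_no_remnant)
  tag_df <- extract_tags(sim$reads, dx, sim$enzyme, cfg$tag_length)
  tcm <- count_tags(tag_df, samples = key$sample[!key$blank])
  log_stage("count_tags", n_tags = length(tcm$tags),
            n_reads = sum(tcm$counts))

  aligned <- anchor_tags(tcm, reference = sim$genome, enzyme = sim$enzyme)
  log_stage("anchor", n_anchored = nrow(aligned),
            n_unique = sum(aligned$unique))

  fc <- filter_config(mnMAF = cfg$filters$mnMAF, mnF = cfg$filters$mnF,
                      min_minor_individuals =
                        cfg$filters$min_minor_individuals,
                      min_site_call_rate = cfg$filters$min_site_call_rate,
                      high_confidence_call_rate =
                        cfg$filters$high_confidence_call_rate,
                      min_individual_call_rate =
                        cfg$filters$min_individual_call_rate)
  snp <- discover_and_genotype(aligned, tcm,
                               min_minor_individuals =
                                 fc$min_minor_individuals)
  snp <- site_statistics(snp)
  log_stage("discover", n_sites = nrow(snp$sites))

  ex <- exclude_samples(snp, fc$min_individual_call_rate)
  snp2 <- ex$snp
  log_stage("exclude_samples", n_excluded = length(ex$excluded))

  fl <- filter_sites(snp2, fc)
  kept <- fl$snp
  log_stage("filter", n_kept = nrow(kept$sites),
            ledger = fl$ledger)

  breeds <- stats::setNames(key$breed, key$sample)
  spect <- maf_spectrum(kept, groups = breeds)
  het <- heterozygosity(kept, groups = breeds)
  hc <- subset_snp(kept, kept$sites$call_rate >=
                     fc$high_confidence_call_rate)
  nj <- NULL; dist <- NULL
  if (nrow(hc$sites) >= 50 && length(hc$samples) >= 3) {
    dist <- pairwise_distances(hc, groups = breeds,
                               min_overlap = min(100L, nrow(hc$sites)))
    if (!anyNA(dist$d)) nj <- neighbor_joining(dist)
  }
  prof <- depth_profile(tcm, aligned,
                        window_bp = cfg$cnv_scan$window_bp)
  cnv <- call_gains(prof, fold_threshold = cfg$cnv_scan$fold_threshold,
                    min_tags = cfg$cnv_scan$min_tags)
  log_stage("cnv", n_calls = nrow(cnv))

  # Per-sample read numbers and call rates (the run's sample QC table)
  reads_per_sample <- dx$summary
  cr <- colMeans(!is.na(snp$geno))
  reads_per_sample$call_rate <-
    as.numeric(cr[reads_per_sample$sample])

  hash <- config_hash(cfg)
  if (!is.null(cfg$out) && !is.na(cfg$out)) {
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    contigs <- vapply(sim$genome, nchar, integer(1))
    if (nrow(kept$sites) > 0)
      write_vcf(kept, file.path(cfg$out, "snps.vcf"), contigs = contigs,
                config_hash = hash)
    if (!is.null(nj))
      write_newick(nj$newick, file.path(cfg$out, "tree.nwk"))
    utils::write.table(reads_per_sample,
                       file.path(cfg$out, "samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fl$ledger, file.path(cfg$out, "filter_ledger.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(cnv) > 0)
      write_bed(data.frame(chrom = cnv$chrom, start = cnv$start,
                           end = cnv$end, name = cnv$carrier),
                file.path(cfg$out, "cnv_calls.bed"))
  }
  structure(list(config = cfg, config_hash = hash, sim = sim, demux = dx,
                 tcm = tcm, aligned = aligned, snp_all = snp,
                 sample_exclusion = ex, snp = kept,
                 filter_ledger = fl$ledger, maf = spect, het = het,
                 dist = dist, nj = nj, depth = prof, cnv = cnv,
                 samples_table = reads_per_sample, stages = stages),
            class = "GBSRun")
}

#' @export
print.GBSRun <- function(x, ...) {
  cat(sprintf(
    "<GBSRun: %d reads -> %d tags -> %d SNPs (%d after filters)>\n",
    length(x$sim$reads), length(x$tcm$tags), nrow(x$snp_all$sites),
    nrow(x$snp$sites)))
  invisible(x)
}
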