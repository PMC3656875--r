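# Shared simulated worlds, built once per test session and cached.
.worlds <- new.env(parent = emptyenv())

cattle_key <- function() {
  read_key(system.file("extdata", "cattle_key.tsv", package = "gbskit"))
}

# full-scale discovery world: 10-Mb genome, 48-plex, depth 10, error 0.002,
# 400 planted SNPs, 25 collapsed-paralog loci, one copy-gain-2 CNV region
world_main <- function() {
  if (is.null(.worlds$main))
    .worlds$main <- run_pipeline(run_config(list(seed = 1)))
  .worlds$main
}

# deep, clean world for depth-sensitive checks (het concordance, CNV):
# depth 30, near-Poisson depth noise, no paralogs
world_deep <- function() {
  if (is.null(.worlds$deep))
    .worlds$deep <- run_pipeline(run_config(list(
      seed = 2,
      simulate = list(mean_locus_depth = 30, overdispersion = 200,
                      n_paralog = 0L))))
  .worlds$deep
}

# small error-free world for exact bookkeeping checks
world_clean_small <- function() {
  if (is.null(.worlds$small)) {
    key <- cattle_key()
    genome <- simulate_genome(stats::setNames(rep(6e5L, 2),
                                              c("chr1", "chr2")), seed = 5)
    sim <- simulate_gbs(key, "PstI",
                        pop = population_spec(n_sites = 40L, seed = 5),
                        cfg = read_sim_config(error_rate = 0),
                        genome = genome, cnv = NULL, seed = 5)
    .worlds$small <- sim
  }
  .worlds$small
}

# recall/concordance/MAF-correlation of a pipeline run against its truth
recovery_metrics <- function(run) {
  tr <- run$sim$truth$sites
  truth_key <- paste(tr$chrom, tr$pos)
  all_key <- paste(run$snp_all$sites$chrom, run$snp_all$sites$pos)
  kept_key <- paste(run$snp$sites$chrom, run$snp$sites$pos)
  rec <- truth_key[tr$polymorphic_in_sample]
  idx <- match(truth_key, all_key)
  ok <- !is.na(idx)
  g_est <- run$snp_all$geno[idx[ok], , drop = FALSE]
  g_tru <- run$sim$truth$geno[ok, colnames(g_est), drop = FALSE]
  nc <- rowSums(!is.na(g_est))
  pa <- rowSums(g_est, na.rm = TRUE) / (2 * nc)
  maf_est <- pmin(pa, 1 - pa)
  pt <- rowSums(g_tru) / (2 * ncol(g_tru))
  maf_tru <- pmin(pt, 1 - pt)
  het <- g_tru == 1
  list(discovery = mean(rec %in% all_key),
       recall = mean(rec %in% kept_key),
       concordance = mean(g_est == g_tru, na.rm = TRUE),
       het_concordance = mean(g_est[het] == 1, na.rm = TRUE),
       maf_r = stats::cor(maf_est, maf_tru, use = "complete.obs"))
}
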