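test_that("maf_spectrum bins and mean MAF behave as defined", {
  # 6 individuals, every site engineered to MAF 0.25
  g <- matrix(c(2L, 1L, 0L, 0L, 0L, 0L), nrow = 4, ncol = 6, byrow = TRUE)
  colnames(g) <- paste0("s", 1:6)
  sp <- maf_spectrum(g)
  expect_equal(sp$overall$fraction[sp$overall$bin == "[0.2,0.3)"], 1)
  expect_equal(sum(sp$overall$fraction), 1)
  expect_equal(sp$mean_maf, 0.25)
  # mean MAF equals the arithmetic mean of per-site MAFs (oracle: direct)
  set.seed(61)
  g2 <- matrix(rbinom(200 * 20, 2, 0.3), 200, 20)
  colnames(g2) <- paste0("s", 1:20)
  nc <- rowSums(!is.na(g2))
  p <- rowSums(g2) / (2 * nc)
  expect_equal(maf_spectrum(g2)$mean_maf, mean(pmin(p, 1 - p)))
  # per-group spectra use group-restricted frequencies
  groups <- stats::setNames(rep(c("u", "v"), each = 10), colnames(g2))
  sp2 <- maf_spectrum(g2, groups)
  pu <- rowSums(g2[, 1:10]) / 20
  expect_equal(sp2$group_mean_maf[["u"]], mean(pmin(pu, 1 - pu)))
})

test_that("heterozygosity per individual and group", {
  g <- rbind(c(1L, 0L, NA), c(1L, 2L, NA), c(1L, 1L, 1L), c(1L, 0L, 0L))
  colnames(g) <- c("a", "b", "c")
  h <- heterozygosity(g, groups = c(a = "g1", b = "g1", c = "g2"))
  expect_equal(h$individual$ho, c(1, 0.25, 0.5))
  expect_equal(h$individual$n_called, c(4L, 4L, 2L))
  expect_equal(h$group$ho[h$group$group == "g1"], mean(c(1, 0.25)))
})

test_that("allele-sharing distances: identity, opposition, completeness", {
  n <- 120
  gi <- matrix(rep(c(0L, 1L, 2L), each = n / 3), n, 4)
  colnames(gi) <- paste0("s", 1:4)
  gi[, 2] <- gi[, 1]                       # identical pair
  gi[, 3] <- 2L - gi[, 1]                  # opposite where homozygous
  d <- pairwise_distances(gi, min_overlap = 10)
  expect_equal(unname(d$d["s1", "s2"]), 0)
  # opposite homozygotes at 2/3 of sites, het identical at 1/3
  expect_equal(unname(d$d["s1", "s3"]), 2 / 3)
  expect_true(isSymmetric(d$d))
  expect_true(all(diag(d$d) == 0))
  # insufficient overlap is flagged missing
  gmiss <- gi
  gmiss[1:(n - 5), 4] <- NA
  dm <- pairwise_distances(gmiss, min_overlap = 100)
  expect_true(is.na(dm$d["s1", "s4"]))
  # fully opposite homozygotes: distance 1
  gop <- cbind(a = rep(0L, 50), b = rep(2L, 50))
  expect_equal(unname(pairwise_distances(gop, min_overlap = 10)$d["a", "b"]),
               1)
})

test_that("between-breed distance grows with divergence", {
  make_between <- function(fst) {
    b <- data.frame(name = c("x", "y"), n = c(12L, 12L), fst = c(fst, fst))
    p <- simulate_population(population_spec(b, n_sites = 2000L,
                                             seed = 63))
    d <- pairwise_distances(p$geno, groups = stats::setNames(
      p$individuals$breed, p$individuals$sample), min_overlap = 10)
    gm <- d$group_means
    gm$mean_distance[!gm$within]
  }
  expect_gt(make_between(0.3), make_between(0.05))
})

test_that("NJ: 3-taxon closed form and additive 4-taxon exactness", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nj3 <- neighbor_joining(d3)
  co <- ape::cophenetic.phylo(nj3$tree)
  expect_equal(co[rownames(d3), colnames(d3)], d3)
  expect_equal(sum(nj3$tree$edge.length), (0 + 2 + 4))
  # additive 4-taxon metric from tree ((A:1,B:2):1,(C:3,D:4))
  labs <- c("A", "B", "C", "D")
  d4 <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d4["A", "B"] <- d4["B", "A"] <- 3
  d4["A", "C"] <- d4["C", "A"] <- 5
  d4["A", "D"] <- d4["D", "A"] <- 6
  d4["B", "C"] <- d4["C", "B"] <- 6
  d4["B", "D"] <- d4["D", "B"] <- 7
  d4["C", "D"] <- d4["D", "C"] <- 7
  nj4 <- neighbor_joining(d4)
  co4 <- ape::cophenetic.phylo(nj4$tree)
  expect_equal(co4[labs, labs], d4)
  expect_true(has_split(nj4$tree, c("A", "B")))
  expect_equal(nj4$negative_branch_deficit, 0)
})

test_that("NJ matches the ape oracle on random distance matrices", {
  set.seed(64)
  for (i in 1:5) {
    n <- sample(5:9, 1)
    x <- matrix(runif(n * 12), n)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- neighbor_joining(d)$tree
    ref <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ output is deterministic and byte-stable", {
  set.seed(65)
  x <- matrix(runif(6 * 5), 6)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("t", 1:6), paste0("t", 1:6))
  expect_identical(neighbor_joining(d)$newick, neighbor_joining(d)$newick)
  # labels are sanitized for Newick
  dimnames(d) <- list(paste0("t ", 1:6), paste0("t ", 1:6))
  expect_false(grepl(" ", neighbor_joining(d)$newick))
})

test_that("simulated breeds cluster monophyletically at F_ST 0.25", {
  b <- data.frame(name = c("x", "y", "z"), n = c(8L, 8L, 8L),
                  fst = c(0.25, 0.25, 0.25))
  p <- simulate_population(population_spec(b, n_sites = 3000L, seed = 66))
  d <- pairwise_distances(p$geno, min_overlap = 10)
  tree <- neighbor_joining(d)$tree
  for (br in b$name) {
    tips <- p$individuals$sample[p$individuals$breed == br]
    expect_true(has_split(tree, tips), info = br)
  }
})

test_that("chromosome_density reproduces the published cattle table", {
  dt <- chromosome_density("gbs_snps", unmapped = 191L)
  tab <- dt$table
  expect_equal(round(tab$snp_density[tab$chrom == "1"], 2), 14.66)
  expect_equal(round(tab$snp_density[tab$chrom == "X"], 2), 7.68)
  tot <- tab[tab$chrom == "Total", ]
  expect_equal(tot$snps, 52748L)
  expect_equal(round(tot$snp_density, 2), 19.77)    # mapped density
  expect_equal(tot$size_mbp, 2658.9)
  # totals are column sums
  expect_equal(tot$genes, sum(tab$genes[tab$chrom != "Total"]))
  # densities recompute from the printed columns at 2 decimals everywhere
  body <- tab[tab$chrom != "Total", ]
  expect_equal(round(body$snp_density, 2),
               round(body$snps / body$size_mbp, 2))
  # frozen correlations (verified by direct recomputation from Table 1)
  expect_equal(round(dt$correlations$r_genedensity_density, 3), 0.568)
  expect_equal(round(dt$correlations$r_size_density, 4), -0.7427)
  expect_equal(round(dt$correlations$r_size_spacing, 4), 0.7964)
  expect_equal(round(dt$correlations$r2_size_spacing, 3), 0.634)
})

test_that("degenerate density tables warn and return NA correlations", {
  ann <- data.frame(chrom = c("1", "2", "3"), size_mbp = c(10, 10, 10),
                    genes = c(5L, 5L, 5L))
  cnt <- stats::setNames(c(100L, 100L, 100L), ann$chrom)
  expect_warning(dt <- chromosome_density(cnt, ann), "degenerate")
  expect_true(is.na(dt$correlations$r_size_density))
})

test_that("gap_statistics bins within chromosomes and splits thirds", {
  snp <- data.frame(chrom = rep("1", 11), pos = seq(0L, 100000L, 10000L))
  gs <- gap_statistics(snp, chrom_sizes = c("1" = 100001))
  expect_equal(unname(gs$bins["<50kb"]), 1)
  expect_equal(sum(gs$bins), 1)
  # two SNPs on different chromosomes: no gaps
  snp2 <- data.frame(chrom = c("1", "2"), pos = c(100L, 200L))
  expect_equal(nrow(gap_statistics(snp2)$gaps), 0L)
  # order invariance
  sh <- snp[sample(nrow(snp)), ]
  expect_equal(gap_statistics(sh, chrom_sizes = c("1" = 100001))$bins,
               gs$bins)
  # uniform random SNPs: regional means statistically equal across thirds
  set.seed(67)
  u <- data.frame(chrom = "1", pos = sort(sample.int(1e7, 3000)))
  gu <- gap_statistics(u, chrom_sizes = c("1" = 1e7))
  m <- gu$regional$mean_gap
  expect_lt(max(m) / min(m), 1.25)
})

test_that("density extrapolation reproduces published arithmetic", {
  # 63,697 SNPs over 22.1 Mb of tag sequence -> 2.88/kb, > 8.6e6 genome-wide
  e1 <- density_extrapolation(63697, 22.1e6, 3000e6)
  expect_equal(round(e1$snps_per_kb, 2), 2.88)
  expect_gt(e1$genome_total, 8.6e6)
  # reduced-representation comparison: 62,042 over 49,492,755 bp -> 1.25/kb
  e2 <- density_extrapolation(62042, 49492755, 3000e6)
  expect_equal(round(e2$snps_per_kb, 2), 1.25)
  expect_equal(density_extrapolation(0, 1000, 1e6)$snps_per_kb, 0)
  expect_error(density_extrapolation(10, 0, 1e6))
})

test_that("admixed (hybrid) groups show elevated heterozygosity", {
  # an admixed breed drawn from two diverged parents has excess hets
  b <- data.frame(name = c("p1", "p2"), n = c(10L, 10L), fst = c(.3, .3))
  p <- simulate_population(population_spec(b, n_sites = 4000L, seed = 68))
  f1 <- (p$breed_freq[, 1] + p$breed_freq[, 2]) / 2
  set.seed(68)
  gh <- sapply(1:10, function(i)
    rbinom(nrow(p$geno), 1, p$breed_freq[, 1]) +
      rbinom(nrow(p$geno), 1, p$breed_freq[, 2]))
  colnames(gh) <- paste0("h", 1:10)
  g <- cbind(p$geno, gh)
  groups <- stats::setNames(c(p$individuals$breed, rep("hyb", 10)),
                            colnames(g))
  h <- heterozygosity(g, groups)
  ho <- stats::setNames(h$group$ho, h$group$group)
  expect_gt(ho[["hyb"]], ho[["p1"]])
  expect_gt(ho[["hyb"]], ho[["p2"]])
})
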