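pad64 <- function(x) paste0(x, strrep(".", 64 - nchar(x)))

# hand-built locus: one reference tag plus allele variants, full control
# over per-sample counts
toy_world <- function(tags, counts, samples, chrom = "chr1", pos0 = 1000L,
                      strand = "+", ref_tag = tags[1]) {
  tcm <- structure(list(tags = tags,
                        effective_length = rep(64L, length(tags)),
                        counts = counts, samples = samples),
                   class = "TagCountMatrix")
  al <- data.frame(tag_idx = seq_along(tags), tag = tags, chrom = chrom,
                   pos0 = pos0, strand = strand,
                   anchor = if (strand == "+") pos0 else pos0 - 59L,
                   unique = TRUE,
                   mismatches = as.integer(tags != ref_tag),
                   ref_tagseq = ref_tag, stringsAsFactors = FALSE)
  list(tcm = tcm, al = al)
}

test_that("discover_and_genotype: presence-based calls on a toy locus", {
  samples <- paste0("s", 1:10)
  base <- paste0("TGCAG", strrep("A", 59))
  alt <- base
  substr(alt, 7, 7) <- "G"                       # SNP at tag offset 6
  counts <- rbind(rep(2L, 10),                   # ref tag in everyone
                  c(rep(2L, 4), rep(0L, 6)))     # alt tag in s1..s4
  w <- toy_world(c(base, alt), counts, samples)
  snp <- site_statistics(discover_and_genotype(w$al, w$tcm))
  expect_equal(nrow(snp$sites), 1L)
  expect_equal(snp$sites$pos, 1006L)
  expect_equal(snp$sites$ref, "A")
  expect_equal(snp$sites$alt, "G")
  expect_false(snp$sites$tightly_linked)
  expect_equal(unname(snp$geno[1, ]), c(rep(1L, 4), rep(0L, 6)))
  expect_equal(snp$sites$maf, 0.2)
  expect_equal(snp$sites$ho, 0.4)
  expect_equal(snp$sites$he, 0.32)
  expect_equal(snp$sites$f, 1 - 0.4 / 0.32)
  expect_equal(snp$sites$n_minor_ind, 4L)
  expect_equal(snp$sites$call_rate, 1)
  # allele depths follow the member-tag counts
  expect_equal(unname(snp$alt_depth[1, 1:4]), rep(2L, 4))
  expect_equal(unname(snp$ref_depth[1, ]), rep(2L, 10))
})

test_that("reverse-strand loci report reference-oriented alleles", {
  samples <- paste0("s", 1:6)
  base <- paste0("TGCAG", strrep("A", 59))
  alt <- base
  substr(alt, 11, 11) <- "G"                     # tag offset 10
  counts <- rbind(rep(3L, 6), c(3L, 3L, 3L, 0L, 0L, 0L))
  w <- toy_world(c(base, alt), counts, samples, pos0 = 2000L,
                 strand = "-")
  snp <- site_statistics(discover_and_genotype(w$al, w$tcm))
  expect_equal(snp$sites$pos, 2000L - 10L)
  # tag alleles A->G read on the minus strand are T->C on the reference
  expect_equal(snp$sites$ref, "T")
  expect_equal(snp$sites$alt, "C")
})

test_that("monomorphic and tri-allelic positions yield no SNP", {
  samples <- paste0("s", 1:6)
  base <- paste0("TGCAG", strrep("C", 59))
  w1 <- toy_world(base, matrix(5L, 1, 6), samples)
  expect_equal(nrow(discover_and_genotype(w1$al, w1$tcm)$sites), 0L)
  v2 <- v3 <- base
  substr(v2, 9, 9) <- "A"; substr(v3, 9, 9) <- "G"
  counts <- rbind(rep(3L, 6), rep(3L, 6), rep(3L, 6))
  w2 <- toy_world(c(base, v2, v3), counts, samples)
  expect_equal(nrow(discover_and_genotype(w2$al, w2$tcm)$sites), 0L)
})

test_that("min_minor_individuals and the tag-count floor gate candidates", {
  samples <- paste0("s", 1:10)
  base <- paste0("TGCAG", strrep("T", 59))
  alt <- base; substr(alt, 20, 20) <- "A"
  counts <- rbind(rep(2L, 10), c(3L, 3L, rep(0L, 8)))
  w <- toy_world(c(base, alt), counts, samples)
  # minor allele in only 2 individuals: rejected at the default 3
  expect_equal(nrow(discover_and_genotype(w$al, w$tcm)$sites), 0L)
  expect_equal(nrow(discover_and_genotype(w$al, w$tcm,
                                          min_minor_individuals = 2L)$sites),
               1L)
  # a sub-floor variant cannot nominate an allele
  counts2 <- rbind(rep(2L, 10), c(4L, rep(0L, 9)))
  w2 <- toy_world(c(base, alt), counts2, samples)
  expect_equal(nrow(discover_and_genotype(w2$al, w2$tcm,
                                          min_minor_individuals = 1L)$sites),
               0L)
})

test_that("two SNPs in one tag span are flagged tightly linked", {
  samples <- paste0("s", 1:8)
  base <- paste0("TGCAG", strrep("G", 59))
  v1 <- base; substr(v1, 10, 10) <- "A"
  v2 <- base; substr(v2, 30, 30) <- "T"
  counts <- rbind(rep(2L, 8), c(rep(2L, 4), rep(0L, 4)),
                  c(rep(0L, 4), rep(2L, 4)))
  w <- toy_world(c(base, v1, v2), counts, samples)
  snp <- site_statistics(discover_and_genotype(w$al, w$tcm))
  expect_equal(nrow(snp$sites), 2L)
  expect_true(all(snp$sites$tightly_linked))
  un <- select_unlinked(snp)
  expect_equal(nrow(un$sites), 1L)
  # equal call rates: tie broken by lower coordinate
  expect_equal(un$sites$pos, min(snp$sites$pos))
})

test_that("genotype calls are invariant to doubling all counts", {
  sim <- world_clean_small()
  dx <- demultiplex(sim$reads, sim$key, "PstI")
  td <- extract_tags(sim$reads, dx, "PstI")
  tcm <- count_tags(td, sim$key$sample[!sim$key$blank])
  al <- anchor_tags(tcm, reference = sim$genome, enzyme = "PstI")
  tcm2 <- tcm
  tcm2$counts <- tcm$counts * 2L
  s1 <- discover_and_genotype(al, tcm)
  s2 <- discover_and_genotype(al, tcm2)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$geno, s2$geno)
})

test_that("anchor_tags places tags and excludes duplicated locations", {
  # genome with one PstI site: unique forward/reverse tags
  set.seed(41)
  mid <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  g <- c(chr1 = paste0(strrep("A", 150), "CTGCAG", mid, "CTGCAG",
                       strrep("T", 150)))
  fr <- digest_genome(g, "PstI")
  expect_equal(nrow(fr), 3L)
  fwd_tag <- substr(g, 152, 152 + 63)         # canonical cut at 151 0-based
  tcm <- structure(list(tags = fwd_tag, effective_length = 64L,
                        counts = matrix(10L, 1, 2,
                                        dimnames = list(NULL, c("a", "b"))),
                        samples = c("a", "b")), class = "TagCountMatrix")
  al <- anchor_tags(tcm, reference = g, enzyme = "PstI")
  expect_equal(nrow(al), 1L)
  expect_equal(al$chrom, "chr1")
  expect_equal(al$anchor, 151L)
  expect_equal(al$strand, "+")
  expect_true(al$unique)
  expect_equal(al$mismatches, 0L)

  # the same 64-nt span after two different interior cut sites: ambiguous
  dupseq <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  g2 <- c(chr1 = paste0(strrep("A", 60), "CTGCAG", dupseq,
                        strrep("C", 40), "CTGCAG", dupseq,
                        strrep("G", 40), "CTGCAG", strrep("T", 60)))
  tcm2 <- structure(list(tags = paste0("TGCAG", substr(dupseq, 1, 59)),
                         effective_length = 64L,
                         counts = matrix(10L, 1, 1,
                                         dimnames = list(NULL, "a")),
                         samples = "a"), class = "TagCountMatrix")
  al2 <- anchor_tags(tcm2, reference = g2, enzyme = "PstI")
  expect_equal(nrow(al2), 1L)
  expect_false(al2$unique)
})

test_that("simulated tag ends anchor back to their fragment ends", {
  sim <- world_clean_small()
  dx <- demultiplex(sim$reads, sim$key, "PstI")
  td <- extract_tags(sim$reads, dx, "PstI")
  tcm <- count_tags(td, sim$key$sample[!sim$key$blank])
  al <- anchor_tags(tcm, reference = sim$genome, enzyme = "PstI")
  ends <- sim$ends
  emitted <- ends$tagseq %in% tcm$tags
  key_e <- paste(ends$chrom, ends$anchor, ends$strand)
  key_a <- paste(al$chrom, al$anchor, al$strand)
  hit <- match(ends$tagseq[emitted], al$tag)
  expect_gt(mean(!is.na(hit)), 0.99)
  expect_true(all(key_a[hit[!is.na(hit)]] ==
                    key_e[emitted][!is.na(hit)]))
})

test_that("SAM-based anchoring handles strand, duplicates, unknown names", {
  tags <- c(pad64(paste0("TGCAG", strrep("A", 40))),
            pad64(paste0("TGCAG", strrep("C", 40))),
            pad64(paste0("TGCAG", strrep("G", 40))))
  tcm <- structure(list(tags = tags, effective_length = rep(45L, 3),
                        counts = matrix(5L, 3, 1,
                                        dimnames = list(NULL, "a")),
                        samples = "a"), class = "TagCountMatrix")
  sam <- c("@HD\tVN:1.6",
           "@SQ\tSN:chr1\tLN:10000",
           paste("tag000001", 0, "chr1", 101, 60, "45M", "*", 0, 0,
                 substr(tags[1], 1, 45), "*", sep = "\t"),
           paste("tag000002", 16, "chr1", 501, 60, "45M", "*", 0, 0,
                 substr(tags[2], 1, 45), "*", sep = "\t"),
           paste("tag000002", 256, "chr2", 901, 0, "45M", "*", 0, 0,
                 substr(tags[2], 1, 45), "*", sep = "\t"),
           paste("nosuchtag", 0, "chr1", 201, 60, "45M", "*", 0, 0,
                 substr(tags[3], 1, 45), "*", sep = "\t"))
  tmp <- tempfile(fileext = ".sam")
  writeLines(sam, tmp)
  expect_warning(al <- anchor_tags(tcm, sam = tmp), "no tag")
  expect_equal(nrow(al), 2L)
  expect_equal(al$pos0[al$tag_idx == 1], 100L)
  expect_equal(al$strand[al$tag_idx == 1], "+")
  expect_true(!al$unique[al$tag_idx == 2])       # multi-mapped
  expect_equal(al$strand[al$tag_idx == 2], "-")
  unlink(tmp)
  # malformed SAM: missing mandatory fields
  tmp2 <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "brokenline\t0\tchr1"), tmp2)
  expect_error(read_sam(tmp2), "malformed")
  unlink(tmp2)
})

test_that("site_statistics boundary cases", {
  samples <- paste0("s", 1:10)
  base <- paste0("TGCAG", strrep("A", 59))
  alt <- base; substr(alt, 15, 15) <- "C"
  # everyone carries both alleles: all-het paralog signature, F = -1
  counts <- rbind(rep(3L, 10), rep(3L, 10))
  w <- toy_world(c(base, alt), counts, samples)
  snp <- site_statistics(discover_and_genotype(w$al, w$tcm))
  expect_equal(snp$sites$ho, 1)
  expect_equal(snp$sites$he, 0.5)
  expect_equal(snp$sites$f, -1)
  # 2 het / 8 hom-major with one uncovered sample
  counts2 <- rbind(c(0L, rep(2L, 9)), c(0L, 3L, 3L, rep(0L, 7)))
  w2 <- toy_world(c(base, alt), counts2, samples)
  snp2 <- site_statistics(discover_and_genotype(w2$al, w2$tcm,
                                                min_minor_individuals = 1L))
  expect_true(is.na(snp2$geno[1, 1]))
  expect_equal(snp2$sites$call_rate, 0.9)
  expect_equal(snp2$sites$maf, 2 / 18)
})

test_that("filter cascade applies all rules and keeps an honest ledger", {
  run <- world_main()
  snp <- run$snp_all
  res <- filter_sites(snp, filter_config())
  s <- snp$sites
  manual_keep <- s$maf >= 0.05 & !is.na(s$maf) &
    (is.na(s$f) | s$f >= 0.05) &
    s$n_minor_ind >= 3 & s$call_rate >= 0.70
  expect_equal(nrow(res$snp$sites), sum(manual_keep))
  expect_equal(sum(res$fails[, "call_rate"]), sum(s$call_rate < 0.70))
  expect_equal(res$ledger$n_failing,
               unname(colSums(res$fails)))
  # neutral thresholds are the identity
  all_cfg <- filter_config(mnMAF = 0, mnF = -10,
                           min_minor_individuals = 0L,
                           min_site_call_rate = 0)
  expect_equal(nrow(filter_sites(snp, all_cfg)$snp$sites), nrow(s))
  # F = -1 paralog signature is removed by mnF
  expect_false(any(res$snp$sites$f < 0.05, na.rm = TRUE))
})

test_that("filter cascade is monotone in every threshold", {
  run <- world_main()
  snp <- run$snp_all
  kept_n <- function(...) nrow(filter_sites(snp, filter_config(...))$snp$sites)
  base <- kept_n()
  for (v in list(list(mnMAF = 0.1), list(mnF = 0.2),
                 list(min_minor_individuals = 5L),
                 list(min_site_call_rate = 0.9))) {
    expect_lte(do.call(kept_n, v), base)
  }
  # and lowering never removes
  expect_gte(kept_n(mnMAF = 0.01), base)
})

test_that("exclude_samples drops low-call-rate samples and recomputes", {
  key <- cattle_key()
  g <- simulate_genome(c(c1 = 8e5L), seed = 51)
  sim <- simulate_gbs(key, "PstI",
                      pop = population_spec(n_sites = 60L, seed = 51),
                      cfg = read_sim_config(
                        error_rate = 0,
                        depth_override = c(HOL01 = 0.04)),
                      genome = g, cnv = NULL, seed = 51)
  dx <- demultiplex(sim$reads, key, "PstI")
  td <- extract_tags(sim$reads, dx, "PstI")
  tcm <- count_tags(td, key$sample[!key$blank])
  al <- anchor_tags(tcm, reference = sim$genome, enzyme = "PstI")
  snp <- site_statistics(discover_and_genotype(al, tcm))
  ex <- exclude_samples(snp, 0.5)
  expect_true("HOL01" %in% ex$excluded)
  expect_false("HOL01" %in% ex$snp$samples)
  expect_equal(ex$report$call_rate[ex$report$sample == "HOL01"],
               mean(!is.na(snp$geno[, "HOL01"])))
  # threshold 0 excludes nobody
  expect_equal(length(exclude_samples(snp, 0)$excluded), 0L)
  # statistics were recomputed on the retained panel
  expect_equal(ex$snp$sites$call_rate,
               rowMeans(!is.na(ex$snp$geno)))
})
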