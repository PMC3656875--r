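new_snp_table <- function(sites, geno, ref_depth, alt_depth, samples) {
  stopifnot(nrow(sites) == nrow(geno), ncol(geno) == length(samples))
  structure(list(sites = sites, geno = geno, ref_depth = ref_depth,
                 alt_depth = alt_depth, samples = samples),
            class = "SNPTable")
}

#' @export
print.SNPTable <- function(x, ...) {
  cat(sprintf("<SNPTable: %d sites x %d samples>\n", nrow(x$sites),
              length(x$samples)))
  invisible(x)
}

#' Write the tag universe as FASTA (for an external aligner)
#' @param tcm a `TagCountMatrix`.
#' @param path output path.
#' @export
write_tag_fasta <- function(tcm, path) {
  seqs <- substr(tcm$tags, 1, tcm$effective_length)
  names(seqs) <- sprintf("tag%06d", seq_along(seqs))
  write_fasta(seqs, path)
}

hamming_pairs <- function(a, b) {
  # number of differing characters between equal-length string pairs
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

#' Anchor tags to reference coordinates
#'
#' Either aligns tags with the built-in cut-site-anchored matcher (exact or
#' few-mismatch lookup against the expected tag at every restriction
#' fragment end -- sufficient for synthetic genomes, since GBS tags start
#' at cut sites by construction) or imports alignments from a plain SAM
#' file produced by an external aligner such as BWA.
#'
#' Tags matching more than one reference location are flagged non-unique:
#' they are excluded from SNP calling but retained for read-depth CNV
#' profiling.
#'
#' @param tcm a `TagCountMatrix`.
#' @param reference named character vector (genome) for the built-in
#'   matcher.
#' @param sam path to a SAM file of tag alignments (tag names as written
#'   by [write_tag_fasta()]).
#' @param enzyme `RestrictionEnzyme` or name (built-in route).
#' @param max_mismatch maximum Hamming distance for a built-in match
#'   (default 5: several linked SNP alleles on one haplotype plus a
#'   sequencing error).
#' @return data.frame of class `AlignedTags`: `tag_idx`, `tag`, `chrom`,
#'   `pos0` (reference position of tag offset 0), `strand`, `anchor` (cut
#'   position), `unique`, `mismatches`, `ref_tagseq`.
#' @export
anchor_tags <- function(tcm, reference = NULL, sam = NULL, enzyme = "PstI",
                        max_mismatch = 5L) {
  if (is.null(reference) && is.null(sam))
    stop("provide either a reference genome or a SAM file")
  if (!is.null(sam)) return(anchor_from_sam(tcm, sam))
  enzyme <- get_enzyme(enzyme)
  tag_length <- nchar(tcm$tags[1])
  frags <- digest_genome(reference, enzyme, with_sequence = FALSE)
  world <- build_tag_ends(reference, frags, enzyme, tag_length)
  ends <- world$ends
  refseq <- ends$tagseq
  # reference locations sharing an identical expected tag are ambiguous
  dup_seq <- refseq %in% refseq[duplicated(refseq)]

  obs <- tcm$tags
  hit <- match(obs, refseq)
  mm <- ifelse(is.na(hit), NA_integer_, 0L)
  multi <- rep(FALSE, length(obs))
  miss <- which(is.na(hit))
  if (length(miss) > 0) {
    # pigeonhole seeding: with k seed blocks an exact block match is
    # guaranteed up to k-1 mismatches (8 blocks of 8 nt for 64-nt tags)
    qb <- unique(c(round(seq(0L, tag_length, length.out = 9L))))
    nq <- length(qb) - 1L
    envs <- vector("list", nq)
    okey <- vector("list", nq)
    for (q in seq_len(nq)) {
      kq <- substr(refseq, qb[q] + 1L, qb[q + 1L])
      envs[[q]] <- list2env(split(seq_along(refseq), kq))
      okey[[q]] <- substr(obs[miss], qb[q] + 1L, qb[q + 1L])
    }
    for (ii in seq_along(miss)) {
      i <- miss[ii]
      cand <- unique(unlist(lapply(seq_len(nq), function(q)
        get0(okey[[q]][ii], envir = envs[[q]], ifnotfound = NULL))))
      if (length(cand) == 0) next
      dd <- hamming_pairs(rep(obs[i], length(cand)), refseq[cand])
      ok <- cand[dd <= max_mismatch]
      if (length(ok) == 0) next
      best_d <- min(dd[dd <= max_mismatch])
      at_best <- cand[dd == best_d]
      hit[i] <- at_best[1]
      multi[i] <- length(at_best) > 1    # tied best locations: ambiguous
      mm[i] <- best_d
    }
  }
  found <- which(!is.na(hit))
  out <- data.frame(
    tag_idx = found, tag = obs[found], chrom = ends$chrom[hit[found]],
    pos0 = ends$pos0[hit[found]], strand = ends$strand[hit[found]],
    anchor = ends$anchor[hit[found]],
    unique = !(multi[found] | dup_seq[hit[found]]),
    mismatches = mm[found], ref_tagseq = refseq[hit[found]],
    stringsAsFactors = FALSE)
  class(out) <- c("AlignedTags", "data.frame")
  out
}

anchor_from_sam <- function(tcm, sam) {
  aln <- read_sam(sam)
  aln <- aln[bitwAnd(aln$flag, 4L) == 0L, , drop = FALSE]
  idx <- match(aln$qname, sprintf("tag%06d", seq_along(tcm$tags)))
  if (anyNA(idx))
    warning(sum(is.na(idx)), " SAM record(s) match no tag; ignored")
  aln <- aln[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  rev <- bitwAnd(aln$flag, 16L) != 0L
  alen <- nchar(aln$seq)
  non_unique <- idx %in% idx[duplicated(idx)] | aln$mapq == 0L
  out <- data.frame(
    tag_idx = idx, tag = tcm$tags[idx], chrom = aln$rname,
    pos0 = ifelse(rev, aln$pos - 1L + alen - 1L, aln$pos - 1L),
    strand = ifelse(rev, "-", "+"),
    anchor = ifelse(rev, aln$pos - 1L + alen, aln$pos - 1L),
    unique = !non_unique, mismatches = NA_integer_,
    ref_tagseq = NA_character_, stringsAsFactors = FALSE)
  # deduplicate multi-mapped tags to one row (their best/first location)
  out <- out[!duplicated(out$tag_idx), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("AlignedTags", "data.frame")
  out
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Discover SNPs and genotype samples from co-located tags
#'
#' Unique anchored tags sharing a (chrom, cut position, strand) locus are
#' compared position-wise over their common effective length. Positions
#' with exactly two observed alleles become candidate SNPs; positions with
#' more are discarded. A sample's genotype is determined by allele
#' presence: homozygous if only one allele's tags are observed,
#' heterozygous if both, missing if no covering read -- the behaviour a
#' low-depth GBS pipeline exhibits. A candidate is kept only if the minor
#' allele occurs in at least `min_minor_individuals` samples. SNPs sharing
#' one tag span are flagged tightly linked.
#'
#' A tag-count floor (`min_tag_count`, default 5 summed over samples)
#' suppresses singleton sequencing-error tags, which would otherwise
#' create spurious third alleles at true sites.
#'
#' @param aligned `AlignedTags` from [anchor_tags()].
#' @param tcm the `TagCountMatrix` the tags came from (columns restricted
#'   to the samples to genotype, i.e. excluding the blank).
#' @param min_minor_individuals minimum samples carrying the minor allele.
#' @param min_tag_count minimum total read count for a tag to enter
#'   comparison.
#' @return a `SNPTable` (statistics not yet filled; see
#'   [site_statistics()]).
#' @export
discover_and_genotype <- function(aligned, tcm, min_minor_individuals = 3L,
                                  min_tag_count = 5L) {
  samples <- tcm$samples
  ns <- length(samples)
  tag_length <- if (length(tcm$tags)) nchar(tcm$tags[1]) else 64L
  al <- aligned[aligned$unique, , drop = FALSE]
  tot <- rowSums(tcm$counts)
  al$floor_pass <- tot[al$tag_idx] >= min_tag_count
  if (nrow(al) == 0 || sum(al$floor_pass) == 0)
    return(new_snp_table(empty_sites(), matrix(NA_integer_, 0, ns,
             dimnames = list(NULL, samples)),
             matrix(0L, 0, ns), matrix(0L, 0, ns), samples))
  locus_id <- paste0(al$chrom, ":", al$anchor, ":", al$strand)
  groups <- split(seq_len(nrow(al)), locus_id)

  res_sites <- list(); res_geno <- list(); res_rd <- list()
  res_ad <- list(); li <- 0L
  for (gname in names(groups)) {
    rows <- groups[[gname]]
    g_al <- al[rows, , drop = FALSE]
    fl <- g_al$floor_pass
    if (!any(fl)) next
    # allele discovery and the comparable span use floor-passing tags
    # only; all anchored member tags then contribute allele evidence
    eff <- tcm$effective_length[g_al$tag_idx]
    common <- min(eff[fl])
    if (common < 1) next
    chm <- do.call(rbind, strsplit(substr(g_al$tag, 1, common), "",
                                   fixed = TRUE))
    cnts <- tcm$counts[g_al$tag_idx, , drop = FALSE]
    ref_seq <- g_al$ref_tagseq[1]
    if (is.na(ref_seq)) {
      # no reference sequence (external SAM): majority-count tag stands in
      ref_seq <- g_al$tag[fl][which.max(rowSums(cnts[fl, , drop = FALSE]))]
    }
    refch <- strsplit(substr(ref_seq, 1, common), "", fixed = TRUE)[[1]]
    chf <- chm[fl, , drop = FALSE]
    var_off <- which(vapply(seq_len(common), function(o) {
      a <- unique(chf[, o]); a <- a[!a %in% c(PAD_CHAR, "N")]
      length(a) == 2
    }, logical(1)))
    loc_sites <- list()
    for (o in var_off) {
      alleles <- unique(chf[, o]); alleles <- alleles[!alleles %in%
                                                       c(PAD_CHAR, "N")]
      ref_a <- refch[o]
      if (!ref_a %in% alleles) next   # neither allele matches reference
      alt_a <- setdiff(alleles, ref_a)
      rd <- colSums(cnts[chm[, o] == ref_a, , drop = FALSE])
      ad <- colSums(cnts[chm[, o] == alt_a, , drop = FALSE])
      geno <- ifelse(rd > 0 & ad > 0, 1L,
              ifelse(rd > 0, 0L, ifelse(ad > 0, 2L, NA_integer_)))
      called <- !is.na(geno)
      if (!any(called)) next
      altc <- sum(geno[called])
      minor_is_alt <- altc <= 2 * sum(called) - altc
      n_minor <- if (minor_is_alt) sum(geno[called] > 0) else
        sum(geno[called] < 2)
      if (n_minor < min_minor_individuals) next
      strand <- g_al$strand[1]
      pos <- if (strand == "+") g_al$pos0[1] + (o - 1L) else
        g_al$pos0[1] - (o - 1L)
      ref_out <- if (strand == "+") ref_a else COMPLEMENT[[ref_a]]
      alt_out <- if (strand == "+") alt_a else COMPLEMENT[[alt_a]]
      loc_sites[[length(loc_sites) + 1L]] <- list(
        site = data.frame(chrom = g_al$chrom[1], pos = pos, ref = ref_out,
                          alt = alt_out, locus = gname, offset = o - 1L,
                          tightly_linked = FALSE, stringsAsFactors = FALSE),
        geno = geno, rd = rd, ad = ad)
    }
    if (length(loc_sites) == 0) next
    tl <- length(loc_sites) > 1
    for (x in loc_sites) {
      li <- li + 1L
      x$site$tightly_linked <- tl
      res_sites[[li]] <- x$site
      res_geno[[li]] <- x$geno
      res_rd[[li]] <- x$rd
      res_ad[[li]] <- x$ad
    }
  }
  if (li == 0L)
    return(new_snp_table(empty_sites(), matrix(NA_integer_, 0, ns,
             dimnames = list(NULL, samples)),
             matrix(0L, 0, ns), matrix(0L, 0, ns), samples))
  sites <- do.call(rbind, res_sites)
  geno <- do.call(rbind, res_geno)
  rd <- do.call(rbind, res_rd)
  ad <- do.call(rbind, res_ad)
  storage.mode(rd) <- "integer"
  storage.mode(ad) <- "integer"
  colnames(geno) <- colnames(rd) <- colnames(ad) <- samples
  # the same physical position can be seen from both ends of a short
  # fragment: keep the better-covered copy
  o <- order(sites$chrom, sites$pos, -rowSums(!is.na(geno)),
             method = "radix")
  sites <- sites[o, , drop = FALSE]
  geno <- geno[o, , drop = FALSE]
  rd <- rd[o, , drop = FALSE]; ad <- ad[o, , drop = FALSE]
  dup <- duplicated(paste(sites$chrom, sites$pos))
  sites <- sites[!dup, , drop = FALSE]
  geno <- geno[!dup, , drop = FALSE]
  rd <- rd[!dup, , drop = FALSE]; ad <- ad[!dup, , drop = FALSE]
  rownames(sites) <- NULL
  new_snp_table(sites, geno, rd, ad, samples)
}

empty_sites <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), locus = character(0), offset = integer(0),
             tightly_linked = logical(0), stringsAsFactors = FALSE)
}

#' Per-site statistics
#'
#' Fills, per site over non-missing calls: call rate, minor allele
#' frequency (MAF), observed heterozygosity Ho, expected heterozygosity
#' He = 2p(1-p), and the inbreeding coefficient F = 1 - Ho/He (NA when
#' He = 0). Strongly negative F flags collapsed paralogs.
#'
#' @param snp a `SNPTable`.
#' @return the `SNPTable` with statistics columns filled.
#' @export
site_statistics <- function(snp) {
  g <- snp$geno
  ns <- length(snp$samples)
  called <- !is.na(g)
  n_called <- rowSums(called)
  altc <- rowSums(g, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, altc / (2 * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  ho <- ifelse(n_called > 0,
               rowSums(g == 1L, na.rm = TRUE) / n_called, NA_real_)
  he <- 2 * p_alt * (1 - p_alt)
  f <- ifelse(!is.na(he) & he > 0, 1 - ho / he, NA_real_)
  minor_is_alt <- !is.na(p_alt) & p_alt <= 0.5
  n_minor <- ifelse(minor_is_alt, rowSums(g > 0L, na.rm = TRUE),
                    rowSums(g < 2L, na.rm = TRUE))
  s <- snp$sites
  s$call_rate <- n_called / ns
  s$maf <- maf
  s$ho <- ho
  s$he <- he
  s$f <- f
  s$n_minor_ind <- as.integer(n_minor)
  snp$sites <- s
  snp
}

#' Filter configuration (the mnMAF / mnF / call-rate cascade)
#'
#' @param mnMAF minimum minor allele frequency (default 0.05).
#' @param mnF minimum inbreeding coefficient F (default 0.05; removes
#'   collapsed paralogs, which show strongly negative F).
#' @param min_minor_individuals minimum samples carrying the minor allele
#'   (default 3).
#' @param min_site_call_rate minimum fraction of samples called at a site
#'   (default 0.70).
#' @param high_confidence_call_rate call-rate cut for the high-confidence
#'   subset used for distances (default 0.90).
#' @param min_individual_call_rate per-sample call-rate floor below which
#'   a sample is excluded (default 0.50).
#' @export
filter_config <- function(mnMAF = 0.05, mnF = 0.05,
                          min_minor_individuals = 3L,
                          min_site_call_rate = 0.70,
                          high_confidence_call_rate = 0.90,
                          min_individual_call_rate = 0.50) {
  vals <- c(mnMAF, min_site_call_rate, high_confidence_call_rate,
            min_individual_call_rate)
  stopifnot(all(vals >= 0), all(vals <= 1))
  structure(list(mnMAF = mnMAF, mnF = mnF,
                 min_minor_individuals = as.integer(min_minor_individuals),
                 min_site_call_rate = min_site_call_rate,
                 high_confidence_call_rate = high_confidence_call_rate,
                 min_individual_call_rate = min_individual_call_rate),
            class = "FilterConfig")
}

#' Apply the site filter cascade
#'
#' Keeps a site iff MAF >= mnMAF, F >= mnF (sites with undefined F fail
#' the MAF floor anyway), the minor allele occurs in at least
#' `min_minor_individuals` samples, and the call rate is at least
#' `min_site_call_rate`. The ledger labels each removed site with every
#' filter it fails, so the per-filter counts are order-independent.
#'
#' @param snp a `SNPTable` with statistics filled.
#' @param config a `FilterConfig`.
#' @return list: `snp` (kept sites), `ledger` (data.frame filter /
#'   n_failing), `fails` (logical matrix sites x filters).
#' @export
filter_sites <- function(snp, config = filter_config()) {
  s <- snp$sites
  if (is.null(s$maf)) stop("run site_statistics() first")
  fails <- cbind(
    maf = !(s$maf >= config$mnMAF) | is.na(s$maf),
    f = !is.na(s$f) & s$f < config$mnF,
    minor_individuals = s$n_minor_ind < config$min_minor_individuals,
    call_rate = s$call_rate < config$min_site_call_rate)
  keep <- rowSums(fails) == 0
  ledger <- data.frame(filter = colnames(fails),
                       n_failing = colSums(fails),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(snp = subset_snp(snp, keep), ledger = ledger, fails = fails)
}

#' Subset a SNPTable by sites and/or samples
#' @param snp a `SNPTable`.
#' @param keep logical or integer site selector.
#' @param samples optional character vector of samples to retain.
#' @export
subset_snp <- function(snp, keep, samples = NULL) {
  sel <- if (is.null(samples)) rep(TRUE, length(snp$samples)) else
    snp$samples %in% samples
  out <- new_snp_table(snp$sites[keep, , drop = FALSE],
                       snp$geno[keep, sel, drop = FALSE],
                       snp$ref_depth[keep, sel, drop = FALSE],
                       snp$alt_depth[keep, sel, drop = FALSE],
                       snp$samples[sel])
  rownames(out$sites) <- NULL
  out
}

#' Exclude low-call-rate samples and recompute statistics
#'
#' @param snp a `SNPTable`.
#' @param min_individual_call_rate threshold; samples with a lower
#'   fraction of called sites are removed.
#' @return list: `snp` (retained panel, statistics recomputed), `report`
#'   (per-sample call rates and exclusion flags), `excluded`.
#' @export
exclude_samples <- function(snp, min_individual_call_rate = 0.5) {
  cr <- colMeans(!is.na(snp$geno))
  excl <- names(cr)[cr < min_individual_call_rate]
  report <- data.frame(sample = snp$samples, call_rate = as.numeric(cr),
                       excluded = snp$samples %in% excl,
                       stringsAsFactors = FALSE)
  out <- subset_snp(snp, rep(TRUE, nrow(snp$sites)),
                    samples = setdiff(snp$samples, excl))
  out <- site_statistics(out)
  list(snp = out, report = report, excluded = excl)
}

#' One SNP per tag span
#'
#' Among tightly linked SNPs (same 64-nt tag span) keeps the site with the
#' highest call rate, ties broken by lower coordinate.
#'
#' @param snp a `SNPTable` with statistics.
#' @export
select_unlinked <- function(snp) {
  s <- snp$sites
  o <- order(s$locus, -s$call_rate, s$pos, method = "radix")
  first <- !duplicated(s$locus[o])
  keep <- logical(nrow(s))
  keep[o[first]] <- TRUE
  subset_snp(snp, keep)
}
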