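#' Extract a genotype dosage matrix from a SNPTable
#'
#' @param snp a `SNPTable`.
#' @param coding "alt" (ALT-allele dosage) or "minor" (minor-allele
#'   dosage).
#' @return integer matrix sites x samples with values 0/1/2/NA.
#' @export
as_genotype_matrix <- function(snp, coding = c("alt", "minor")) {
  coding <- match.arg(coding)
  g <- snp$geno
  if (coding == "minor") {
    p_alt <- rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
    flip <- !is.na(p_alt) & p_alt > 0.5
    g[flip, ] <- 2L - g[flip, ]
  }
  g
}

MAF_BINS <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)

#' Minor-allele-frequency spectrum
#'
#' Bins per-site MAFs into the classes [0.05,0.1), [0.1,0.2), [0.2,0.3),
#' [0.3,0.4), [0.4,0.5]; per-group spectra use group-restricted allele
#' frequencies (only that group's called genotypes).
#'
#' @param geno genotype matrix (sites x samples, 0/1/2/NA ALT dosage) or a
#'   `SNPTable`.
#' @param groups optional named character vector mapping sample -> group
#'   (e.g. breed); per-group spectra are added.
#' @return list: `overall` (data.frame bin / fraction), `mean_maf`,
#'   `by_group` (list of data.frames), `group_mean_maf`.
#' @export
maf_spectrum <- function(geno, groups = NULL) {
  if (inherits(geno, "SNPTable")) geno <- geno$geno
  spec_of <- function(g) {
    nc <- rowSums(!is.na(g))
    p <- rowSums(g, na.rm = TRUE) / (2 * nc)
    maf <- pmin(p, 1 - p)
    maf <- maf[nc > 0 & !is.na(maf)]
    bin <- cut(maf, MAF_BINS, right = FALSE, include.lowest = TRUE,
               labels = c("[0.05,0.1)", "[0.1,0.2)", "[0.2,0.3)",
                          "[0.3,0.4)", "[0.4,0.5]"))
    frac <- as.numeric(table(bin)) / max(1, sum(!is.na(bin)))
    list(df = data.frame(bin = levels(bin), fraction = frac,
                         stringsAsFactors = FALSE),
         mean_maf = mean(maf))
  }
  ov <- spec_of(geno)
  out <- list(overall = ov$df, mean_maf = ov$mean_maf,
              by_group = NULL, group_mean_maf = NULL)
  if (!is.null(groups)) {
    gs <- unique(groups[colnames(geno)])
    by <- lapply(gs, function(gr)
      spec_of(geno[, names(groups)[groups == gr &
                     names(groups) %in% colnames(geno)], drop = FALSE]))
    names(by) <- gs
    out$by_group <- lapply(by, `[[`, "df")
    out$group_mean_maf <- vapply(by, `[[`, numeric(1), "mean_maf")
  }
  out
}

#' Observed heterozygosity per individual and group
#'
#' Per individual: fraction of heterozygous calls among called sites.
#' Group Ho: mean over members.
#'
#' @param geno genotype matrix or `SNPTable`.
#' @param groups optional named character vector sample -> group.
#' @return list: `individual` (data.frame sample / ho / n_called),
#'   `group` (data.frame group / ho).
#' @export
heterozygosity <- function(geno, groups = NULL) {
  if (inherits(geno, "SNPTable")) geno <- geno$geno
  nc <- colSums(!is.na(geno))
  ho <- colSums(geno == 1L, na.rm = TRUE) / pmax(1L, nc)
  ho[nc == 0] <- NA_real_
  ind <- data.frame(sample = colnames(geno), ho = as.numeric(ho),
                    n_called = as.integer(nc), stringsAsFactors = FALSE)
  grp <- NULL
  if (!is.null(groups)) {
    ind$group <- groups[ind$sample]
    agg <- tapply(ind$ho, ind$group, mean, na.rm = TRUE)
    grp <- data.frame(group = names(agg), ho = as.numeric(agg),
                      stringsAsFactors = FALSE)
  }
  list(individual = ind, group = grp)
}

#' Allele-sharing pairwise distances
#'
#' Distance between two individuals is 1 - (shared alleles)/2 averaged
#' over co-called sites (identity-by-state distance): identical genotypes
#' contribute 0, het vs hom 0.5, opposite homozygotes 1. Pairs with fewer
#' than `min_overlap` co-called sites get a missing distance.
#'
#' @param geno genotype matrix (sites x samples) or `SNPTable` (its
#'   genotypes; the caller is responsible for pre-filtering to the
#'   high-confidence call-rate set).
#' @param groups optional named character vector sample -> group for
#'   within/between-group averages.
#' @param min_overlap minimum co-called sites (default 100).
#' @return list of class `DistanceMatrix`: `d` (symmetric matrix),
#'   `n_overlap`, `group_means` (data.frame), `groups`.
#' @export
pairwise_distances <- function(geno, groups = NULL, min_overlap = 100L) {
  if (inherits(geno, "SNPTable")) geno <- geno$geno
  ns <- ncol(geno)
  d <- matrix(0, ns, ns, dimnames = list(colnames(geno), colnames(geno)))
  nov <- matrix(0L, ns, ns, dimnames = dimnames(d))
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (j <= i) next
    gi <- geno[, i]; gj <- geno[, j]
    ok <- !is.na(gi) & !is.na(gj)
    n <- sum(ok)
    nov[i, j] <- nov[j, i] <- n
    if (n < min_overlap) {
      d[i, j] <- d[j, i] <- NA_real_
    } else {
      d[i, j] <- d[j, i] <- mean(abs(gi[ok] - gj[ok])) / 2
    }
  }
  gm <- NULL
  if (!is.null(groups)) {
    gl <- groups[colnames(geno)]
    gs <- unique(gl)
    rows <- list()
    for (a in seq_along(gs)) for (b in seq_len(a)) {
      ia <- which(gl == gs[a]); ib <- which(gl == gs[b])
      if (a == b) {
        if (length(ia) < 2) next
        vals <- d[ia, ia][upper.tri(d[ia, ia])]
      } else vals <- as.vector(d[ia, ib, drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = gs[a], group2 = gs[b], mean_distance = mean(vals,
                                                            na.rm = TRUE),
        within = a == b, stringsAsFactors = FALSE)
    }
    gm <- do.call(rbind, rows)
  }
  structure(list(d = d, n_overlap = nov, group_means = gm,
                 groups = groups), class = "DistanceMatrix")
}

#' Neighbor-joining tree
#'
#' Classic agglomerative NJ with the Q-criterion and standard
#' branch-length formulas. Ties in Q are broken deterministically by the
#' lexicographically smallest joined label pair; negative branch lengths
#' are clamped to zero and the clamped total reported.
#'
#' @param d a `DistanceMatrix` or symmetric numeric matrix with labels.
#' @return list of class `NJTree`: `newick` (string, branch lengths at 6
#'   significant digits), `tree` (an `ape::phylo`),
#'   `negative_branch_deficit`.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "DistanceMatrix")) d <- d$d
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 3,
            !anyNA(d))
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  fmt <- function(x) formatC(x, format = "g", digits = 6)
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit - x; 0 } else x
  }
  node_str <- sanitize_newick(labels)
  active <- seq_len(nrow(d))
  D <- d
  while (length(active) > 3) {
    n <- length(active)
    Da <- D[active, active, drop = FALSE]
    R <- rowSums(Da)
    Q <- (n - 2) * Da - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_lab <- apply(cand, 1, function(ij) {
      ls <- sort(c(node_str[active[ij[1]]], node_str[active[ij[2]]]))
      paste(ls, collapse = "\r")
    })
    pick <- cand[order(pair_lab)[1], ]
    i <- pick[1]; j <- pick[2]
    ai <- active[i]; aj <- active[j]
    dij <- Da[i, j]
    li <- clamp(dij / 2 + (R[i] - R[j]) / (2 * (n - 2)))
    lj <- clamp(dij - (dij / 2 + (R[i] - R[j]) / (2 * (n - 2))))
    new_d <- (Da[i, ] + Da[j, ] - dij) / 2
    # grow matrix with the new internal node
    D <- rbind(cbind(D, 0), 0)
    nn <- nrow(D)
    D[nn, active] <- new_d; D[active, nn] <- new_d
    D[nn, nn] <- 0
    node_str <- c(node_str, sprintf("(%s:%s,%s:%s)", node_str[ai],
                                    fmt(li), node_str[aj], fmt(lj)))
    active <- c(setdiff(active, c(ai, aj)), nn)
  }
  # final three nodes: closed-form star branch lengths
  a <- active[order(node_str[active])]
  dxy <- D[a[1], a[2]]; dxz <- D[a[1], a[3]]; dyz <- D[a[2], a[3]]
  lx <- clamp((dxy + dxz - dyz) / 2)
  ly <- clamp((dxy + dyz - dxz) / 2)
  lz <- clamp((dxz + dyz - dxy) / 2)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", node_str[a[1]], fmt(lx),
                    node_str[a[2]], fmt(ly), node_str[a[3]], fmt(lz))
  tree <- ape::read.tree(text = newick)
  structure(list(newick = newick, tree = tree,
                 negative_branch_deficit = deficit), class = "NJTree")
}

sanitize_newick <- function(x) {
  gsub("[][(),:;'\" \t]", "_", x)
}

#' @export
print.NJTree <- function(x, ...) {
  cat(sprintf("<NJTree: %d tips%s>\n", length(x$tree$tip.label),
              if (x$negative_branch_deficit > 0)
                sprintf(", clamped %.4g of negative branch length",
                        x$negative_branch_deficit) else ""))
  invisible(x)
}

#' Per-chromosome marker density table and correlations
#'
#' Computes gene and SNP densities (N/Mbp) per chromosome, a totals row,
#' and Pearson correlations over the autosomes between (i) chromosome size
#' and SNP density, (ii) gene density and SNP density, and (iii)
#' chromosome size and mean inter-SNP spacing (size/count). The X
#' chromosome is excluded from correlations and reported separately.
#'
#' @param snp_counts named integer vector of SNP counts per chromosome, or
#'   the name of a count column present in `annotation`.
#' @param annotation data.frame from [read_annotation()] (`chrom`,
#'   `size_mbp`, `genes`).
#' @param unmapped number of SNPs not placed on any chromosome (added to
#'   the totals row count).
#' @param autosomes chromosome names treated as autosomes (default: all
#'   except "X", "Y", "MT").
#' @return list of class `DensityTable`: `table` (per-chromosome densities
#'   plus totals row), `correlations` (r_size_density, r2_size_density,
#'   r_genedensity_density, r_size_spacing, r2_size_spacing), `unmapped`.
#' @export
chromosome_density <- function(snp_counts, annotation = read_annotation(),
                               unmapped = 0L, autosomes = NULL) {
  ann <- annotation
  if (is.character(snp_counts) && length(snp_counts) == 1) {
    cnt <- stats::setNames(ann[[snp_counts]], ann$chrom)
  } else cnt <- snp_counts
  cnt <- cnt[match(ann$chrom, names(cnt))]
  cnt[is.na(cnt)] <- 0L
  tab <- data.frame(
    chrom = ann$chrom, size_mbp = ann$size_mbp, genes = ann$genes,
    snps = as.integer(cnt),
    gene_density = ann$genes / ann$size_mbp,
    snp_density = as.numeric(cnt) / ann$size_mbp,
    stringsAsFactors = FALSE)
  totals <- data.frame(
    chrom = "Total", size_mbp = sum(tab$size_mbp), genes = sum(tab$genes),
    snps = sum(tab$snps) + as.integer(unmapped),
    gene_density = sum(tab$genes) / sum(tab$size_mbp),
    # mapped density: unmapped SNPs have no genomic extent
    snp_density = sum(tab$snps) / sum(tab$size_mbp),
    stringsAsFactors = FALSE)
  if (is.null(autosomes))
    autosomes <- setdiff(ann$chrom, c("X", "Y", "MT", "chrX", "chrY"))
  au <- tab[tab$chrom %in% autosomes, , drop = FALSE]
  corr <- list(r_size_density = NA_real_, r2_size_density = NA_real_,
               r_genedensity_density = NA_real_,
               r_size_spacing = NA_real_, r2_size_spacing = NA_real_)
  if (nrow(au) >= 3) {
    if (stats::sd(au$snp_density) == 0 || stats::sd(au$size_mbp) == 0) {
      warning("degenerate density table: correlation undefined")
    } else {
      corr$r_size_density <- stats::cor(au$size_mbp, au$snp_density)
      corr$r2_size_density <- corr$r_size_density^2
      corr$r_genedensity_density <- stats::cor(au$gene_density,
                                               au$snp_density)
      spacing <- au$size_mbp * 1000 / pmax(1L, au$snps)   # kb between SNPs
      corr$r_size_spacing <- stats::cor(au$size_mbp, spacing)
      corr$r2_size_spacing <- corr$r_size_spacing^2
    }
  }
  structure(list(table = rbind(tab, totals), correlations = corr,
                 unmapped = as.integer(unmapped)), class = "DensityTable")
}

#' Adjacent-SNP gap statistics
#'
#' Gaps are computed between adjacent SNPs within a chromosome only,
#' binned into <50, 50-100, 100-150 and >150 kb classes, and assigned to
#' chromosome thirds (first/middle/last, by gap midpoint) for regional
#' mean gaps.
#'
#' @param snp a `SNPTable` or data.frame with `chrom` and `pos`.
#' @param chrom_sizes named vector of chromosome lengths in bp (for the
#'   thirds); defaults to the max SNP position per chromosome.
#' @return list of class `GapDistribution`: `gaps` (data.frame), `bins`
#'   (fractions), `regional` (mean gap per chromosome third).
#' @export
gap_statistics <- function(snp, chrom_sizes = NULL) {
  df <- if (inherits(snp, "SNPTable")) snp$sites else snp
  df <- df[order(df$chrom, df$pos, method = "radix"), , drop = FALSE]
  out <- list()
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (length(p) < 2) next
    gap <- diff(p)
    mid <- (p[-length(p)] + p[-1]) / 2
    out[[ch]] <- data.frame(chrom = ch, gap = gap, midpoint = mid,
                            stringsAsFactors = FALSE)
  }
  gaps <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), gap = numeric(0),
               midpoint = numeric(0))
  rownames(gaps) <- NULL
  brk <- c(-Inf, 50e3, 100e3, 150e3, Inf)
  lab <- c("<50kb", "50-100kb", "100-150kb", ">150kb")
  bins <- if (nrow(gaps) > 0) {
    as.numeric(table(cut(gaps$gap, brk, labels = lab))) / nrow(gaps)
  } else rep(NA_real_, 4)
  names(bins) <- lab
  regional <- NULL
  if (nrow(gaps) > 0) {
    if (is.null(chrom_sizes)) {
      chrom_sizes <- tapply(df$pos, df$chrom, max) + 1
    }
    L <- chrom_sizes[gaps$chrom]
    third <- pmin(3L, floor(gaps$midpoint / (L / 3)) + 1L)
    agg <- stats::aggregate(gaps$gap,
                            by = list(chrom = gaps$chrom, third = third),
                            FUN = mean)
    names(agg)[3] <- "mean_gap"
    regional <- agg
  }
  structure(list(gaps = gaps, bins = bins, regional = regional),
            class = "GapDistribution")
}

#' Genome-wide SNP density extrapolation
#'
#' SNPs per kilobase of sequenced tag space, extrapolated to a full genome
#' size.
#'
#' @param total_snps number of SNPs discovered.
#' @param total_tag_bp total tag sequence surveyed, in bp.
#' @param genome_bp genome size in bp.
#' @return list: `snps_per_kb`, `genome_total`.
#' @export
density_extrapolation <- function(total_snps, total_tag_bp, genome_bp) {
  stopifnot(total_tag_bp > 0, genome_bp > 0, total_snps >= 0)
  snps_per_kb <- total_snps / (total_tag_bp / 1000)
  list(snps_per_kb = snps_per_kb,
       genome_total = snps_per_kb * genome_bp / 1000)
}
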