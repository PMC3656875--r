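#' Simulate a random genome
#'
#' I.i.d. bases at a given GC content, as a stand-in reference for
#' end-to-end pipeline validation. Not a model of real genome composition
#' (no repeats, no isochores) beyond optional planted duplications.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param gc GC fraction (default 0.42, cattle-like).
#' @param seed integer seed.
#' @return named character vector of sequences.
#' @export
simulate_genome <- function(chrom_lengths, gc = 0.42, seed = 1) {
  set.seed(seed)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(chrom_lengths, function(L)
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
    character(1))
}

#' Default multi-breed panel
#'
#' Emulates the 47-animal, 7-group cattle panel: 6 Holstein, 6 Angus,
#' 3 Hereford, 27 Brangus, 2 White Fulani and 3 Muturu. Divergence
#' (Balding-Nichols F_ST) defaults: 0.10 for the US taurine/composite
#' breeds, 0.20 for the African breeds.
#' @export
default_breed_panel <- function() {
  data.frame(
    name = c("Holstein", "Angus", "Hereford", "Brangus", "WhiteFulani",
             "Muturu"),
    n = c(6L, 6L, 3L, 27L, 2L, 3L),
    fst = c(0.10, 0.10, 0.10, 0.10, 0.20, 0.20),
    stringsAsFactors = FALSE)
}

#' Population specification
#'
#' @param breeds data.frame with `name`, `n`, `fst` (0 <= fst < 1).
#' @param maf_range range of the ancestral minor-allele frequency law
#'   (uniform); default c(0.1, 0.5), emulating the common-variant spectrum
#'   a GBS discovery panel ascertains.
#' @param n_sites number of segregating sites to plant.
#' @param seed integer seed.
#' @export
population_spec <- function(breeds = default_breed_panel(),
                            maf_range = c(0.1, 0.5), n_sites = 600L,
                            seed = 1L) {
  stopifnot(all(breeds$fst >= 0), all(breeds$fst < 1), all(breeds$n >= 1),
            maf_range[1] >= 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  structure(list(breeds = breeds, maf_range = maf_range,
                 n_sites = as.integer(n_sites), seed = as.integer(seed)),
            class = "PopulationSpec")
}

#' Simulate breed-structured genotypes (Balding-Nichols model)
#'
#' Ancestral frequencies p are drawn uniformly from `maf_range`; each
#' breed's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) (equal to p when
#' F = 0); individual diploid genotypes are binomial draws from the breed
#' frequency.
#'
#' @param spec a `PopulationSpec`.
#' @return list: `ancestral_p` (length n_sites), `breed_freq`
#'   (n_sites x breeds), `geno` (n_sites x individuals, ALT dosage 0/1/2),
#'   `individuals` (data.frame sample/breed).
#' @export
simulate_population <- function(spec) {
  set.seed(spec$seed)
  ns <- spec$n_sites
  p <- stats::runif(ns, spec$maf_range[1], spec$maf_range[2])
  nb <- nrow(spec$breeds)
  bf <- matrix(0, ns, nb, dimnames = list(NULL, spec$breeds$name))
  for (b in seq_len(nb)) {
    f <- spec$breeds$fst[b]
    bf[, b] <- if (f == 0) p else
      stats::rbeta(ns, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  breed_of <- rep(spec$breeds$name, spec$breeds$n)
  ind <- data.frame(
    sample = paste0(rep(spec$breeds$name, spec$breeds$n), "_",
                    unlist(lapply(spec$breeds$n, seq_len))),
    breed = breed_of, stringsAsFactors = FALSE)
  geno <- matrix(0L, ns, nrow(ind), dimnames = list(NULL, ind$sample))
  for (j in seq_len(nrow(ind))) {
    f <- bf[, match(ind$breed[j], spec$breeds$name)]
    geno[, j] <- stats::rbinom(ns, 2L, f)
  }
  list(ancestral_p = p, breed_freq = bf, geno = geno, individuals = ind)
}

#' Read simulation configuration
#'
#' @param read_length read length in nt (default 100, single-end).
#' @param mean_locus_depth mean reads per tag locus per sample (default 10;
#'   a realistic single-run GBS depth for presence/absence genotyping).
#' @param cv_reads coefficient of variation of per-sample library size
#'   (default 0.39), applied as a lognormal per-sample depth multiplier.
#' @param error_rate per-base substitution probability (default 0.002).
#' @param overdispersion negative-binomial size for per-locus depth
#'   (default 10; smaller = noisier).
#' @param tag_length canonical tag span (default 64).
#' @param size_window fragment size-selection window in bp (default
#'   c(100, 900), an amplifiable/sequencable window).
#' @param contamination expected fraction of a normal library leaking into
#'   the blank lane (default 0: the blank emits no reads).
#' @param depth_override optional named vector of per-sample depth
#'   multipliers (e.g. a failing DNA sample at 0.1).
#' @export
read_sim_config <- function(read_length = 100L, mean_locus_depth = 10,
                            cv_reads = 0.39, error_rate = 0.002,
                            overdispersion = 10, tag_length = 64L,
                            size_window = c(100, 900), contamination = 0,
                            depth_override = NULL) {
  stopifnot(error_rate >= 0, error_rate < 0.1, cv_reads >= 0)
  structure(list(read_length = as.integer(read_length),
                 mean_locus_depth = mean_locus_depth, cv_reads = cv_reads,
                 error_rate = error_rate, overdispersion = overdispersion,
                 tag_length = as.integer(tag_length),
                 size_window = size_window, contamination = contamination,
                 depth_override = depth_override),
            class = "ReadSimConfig")
}

# reference tag ends for retained fragments: one forward tag at the left
# cut and one reverse tag at the right cut (both flanks must be cut sites;
# a fragment without two cut ends cannot carry both adapters).
# Returns per-end bookkeeping plus the molecule body strings from which
# both reads and reference tags derive.
build_tag_ends <- function(genome, fragments, enzyme, tag_length = 64L) {
  enzyme <- get_enzyme(enzyme)
  ext <- enzyme$overhang_ext
  ok <- fragments$left_enzyme != "END" & fragments$right_enzyme != "END"
  fr <- fragments[ok, , drop = FALSE]
  if (nrow(fr) == 0) stop("no fragments with two cut ends")
  mol <- substr(genome[fr$chrom], fr$start + 1L, fr$end + ext)
  body_len <- 96L + tag_length          # ample for any barcode length
  fill <- strrep(COMMON_ADAPTER, ceiling(body_len / nchar(COMMON_ADAPTER)))
  pad_to <- function(x) {
    need <- pmax(0L, body_len - nchar(x))
    paste0(x, substr(fill, 1L, need))
  }
  fwd_body <- pad_to(mol)
  rev_body <- pad_to(revcomp(mol))
  ends <- data.frame(
    frag = rep(seq_len(nrow(fr)), 2L),
    chrom = rep(fr$chrom, 2L),
    endtype = rep(c("fwd", "rev"), each = nrow(fr)),
    strand = rep(c("+", "-"), each = nrow(fr)),
    anchor = c(fr$start, fr$end),
    pos0 = c(fr$start, fr$end + ext - 1L),
    mol_len = rep(nchar(mol), 2L),
    stringsAsFactors = FALSE)
  ends$body <- c(fwd_body, rev_body)
  raw <- substr(ends$body, 1L, tag_length)
  ends$eff <- tag_effective_length(raw, enzyme, tag_length)
  tag <- substr(raw, 1L, ends$eff)
  short <- ends$eff < tag_length
  tag[short] <- paste0(tag[short], strrep(PAD_CHAR, tag_length -
                                            ends$eff[short]))
  ends$tagseq <- tag
  list(fragments = fr, ends = ends, mol = mol, ext = ext,
       tag_length = tag_length)
}

#' Simulate a complete GBS experiment with ground truth
#'
#' Generates (or accepts) a reference genome, digests and size-selects it,
#' plants biallelic SNPs with breed-structured frequencies on the retained
#' tag spans, optionally plants a polymorphic copy-number gain and
#' collapsed-paralog loci, and emits barcoded single-end reads with
#' sequencing error. Ground truth (site positions, alleles, genotypes,
#' carriers) is returned for validation.
#'
#' All randomness flows from `seed` via fixed per-stage offsets
#' (genome +1, population +2, site placement +3, depths +4, errors +5).
#'
#' @param key `BarcodeKey`; non-blank rows are matched to panel
#'   individuals in order.
#' @param enzyme `RestrictionEnzyme` or name (default PstI).
#' @param pop `PopulationSpec`.
#' @param cfg `ReadSimConfig`.
#' @param genome optional named character vector; default a simulated
#'   10-Mb genome over 5 chromosomes.
#' @param cnv list(chrom, start, end, copy_gain, n_carriers) or NULL;
#'   default plants a 0.4-Mb copy_gain-2 region on the last chromosome
#'   carried by a subset of the US-breed samples.
#' @param n_paralog number of collapsed-paralog (ghost duplicate) loci.
#' @param seed master seed.
#' @return list of class `GBSSimulation`: `reads`, `read_origin`, `truth`,
#'   `key`, `genome`, `fragments`, `ends`, `enzyme`, `cfg`.
#' @export
simulate_gbs <- function(key, enzyme = "PstI", pop = population_spec(),
                         cfg = read_sim_config(), genome = NULL,
                         cnv = "default", n_paralog = 0L, seed = 1L) {
  enzyme <- get_enzyme(enzyme)
  if (is.null(genome))
    genome <- simulate_genome(stats::setNames(rep(2e6L, 5),
                                              paste0("chr", 1:5)),
                              seed = seed + 1L)
  frags <- digest_genome(genome, enzyme, with_sequence = FALSE)
  kept <- size_select(frags, cfg$size_window[1], cfg$size_window[2])
  world <- build_tag_ends(genome, kept, enzyme, cfg$tag_length)
  ends <- world$ends
  fr <- world$fragments
  nfrag <- nrow(fr)

  samples <- key$sample[!key$blank]
  if (sum(pop$breeds$n) != length(samples))
    stop("panel size (", sum(pop$breeds$n), ") != non-blank key rows (",
         length(samples), ")")

  # ---- population genotypes -------------------------------------------
  popr <- simulate_population(
    population_spec(pop$breeds, pop$maf_range, pop$n_sites, seed + 2L))
  breed_of <- stats::setNames(popr$individuals$breed, samples)
  colnames(popr$geno) <- samples

  # ---- site placement on molecule coordinates -------------------------
  set.seed(seed + 3L)
  rl <- nchar(enzyme$remnant)
  elig <- vector("list", nfrag)
  for (f in seq_len(nfrag)) {
    mlen <- nchar(world$mol[f])
    flen <- fr$end[f] - fr$start[f]
    fe <- ends[ends$frag == f & ends$endtype == "fwd", ]
    re <- ends[ends$frag == f & ends$endtype == "rev", ]
    m <- seq_len(mlen) - 1L
    vis_f <- m < fe$eff
    vis_r <- (mlen - 1L - m) < re$eff
    okm <- (m >= rl) & (m <= flen - 2L) & (vis_f | vis_r)
    if (any(okm))
      elig[[f]] <- data.frame(frag = f, m = m[okm],
                              pos = fr$start[f] + m[okm],
                              chrom = fr$chrom[f])
  }
  elig <- do.call(rbind, elig)
  elig <- elig[!duplicated(paste(elig$chrom, elig$pos)), , drop = FALSE]
  if (is.null(elig))
    stop("requested ", pop$n_sites + n_paralog, " sites but only 0 ",
         "eligible tag-span positions are available")
  # collapsed-paralog (ghost duplicate) loci occupy whole fragments of
  # their own: their reads carry reference bases at every other position
  # and would contaminate co-located true SNPs
  par_rows <- NULL
  if (n_paralog > 0) {
    pfrags <- sample(unique(elig$frag), min(n_paralog,
                                            length(unique(elig$frag))))
    if (length(pfrags) < n_paralog)
      stop("requested ", n_paralog, " paralog loci but only ",
           length(pfrags), " fragments are available")
    pe <- elig[elig$frag %in% pfrags, , drop = FALSE]
    pe <- pe[!duplicated(pe$frag), , drop = FALSE]   # one ghost per frag
    par_rows <- pe
    elig <- elig[!elig$frag %in% pfrags, , drop = FALSE]
  }
  if (nrow(elig) < pop$n_sites)
    stop("requested ", pop$n_sites, " sites but only ", nrow(elig),
         " eligible tag-span positions are available")
  site_rows <- elig[sample.int(nrow(elig), pop$n_sites), , drop = FALSE]

  base_at <- function(chrom, pos)
    substr(genome[chrom], pos + 1L, pos + 1L)
  other_base <- function(ref) {
    alt <- c("A", "C", "G", "T")
    vapply(ref, function(r) sample(setdiff(alt, r), 1L), character(1))
  }
  sites <- data.frame(
    chrom = site_rows$chrom, pos = site_rows$pos, frag = site_rows$frag,
    m = site_rows$m, stringsAsFactors = FALSE)
  sites$ref <- base_at(sites$chrom, sites$pos)
  sites$alt <- other_base(sites$ref)
  sites$ancestral_p <- popr$ancestral_p
  ord <- order(sites$chrom, sites$pos, method = "radix")
  sites <- sites[ord, , drop = FALSE]
  geno <- popr$geno[ord, , drop = FALSE]
  bf <- popr$breed_freq[ord, , drop = FALSE]
  rownames(sites) <- NULL
  sites$polymorphic_in_sample <- apply(geno, 1, function(g)
    any(g > 0) && any(g < 2))
  # recoverable by construction (planted on retained tag spans)
  sites$recoverable <- TRUE

  # ---- CNV region ------------------------------------------------------
  cnv_truth <- NULL
  if (identical(cnv, "default")) {
    # anchor the 0.4-Mb region where the library actually has loci: the
    # retained-fragment window with the most fragments on the last chrom
    ch <- names(genome)[length(genome)]
    fch <- fr$start[fr$chrom == ch]
    if (length(fch) == 0) {
      cnv <- NULL
    } else {
      span <- 400000L
      n_in <- vapply(fch, function(s) sum(fch >= s & fch < s + span),
                     integer(1))
      start <- fch[which.max(n_in)]
      cnv <- list(chrom = ch, start = start, end = start + span,
                  copy_gain = 2L, n_carriers = 12L)
    }
  }
  if (!is.null(cnv)) {
    us <- samples[breed_of[samples] %in%
                    c("Holstein", "Angus", "Hereford", "Brangus")]
    if (length(us) == 0) us <- samples
    carriers <- us[seq_len(min(cnv$n_carriers, length(us)))]
    cnv_truth <- list(chrom = cnv$chrom, start = cnv$start, end = cnv$end,
                      copy_gain = cnv$copy_gain, carriers = carriers)
  }

  # ---- paralog (collapsed duplicate) loci ------------------------------
  paralog_truth <- NULL
  if (!is.null(par_rows) && nrow(par_rows) > 0) {
    par_rows$ref <- base_at(par_rows$chrom, par_rows$pos)
    par_rows$ghost <- other_base(par_rows$ref)
    paralog_truth <- par_rows
  }

  # ---- per-sample depth multipliers -----------------------------------
  set.seed(seed + 4L)
  ns <- length(samples)
  if (cfg$cv_reads > 0) {
    s2 <- log(1 + cfg$cv_reads^2)
    mult <- stats::rlnorm(ns, meanlog = -s2 / 2, sdlog = sqrt(s2))
  } else mult <- rep(1, ns)
  names(mult) <- samples
  if (!is.null(cfg$depth_override))
    mult[names(cfg$depth_override)] <- cfg$depth_override

  truth <- list(sites = sites, geno = geno, breed_freq = bf,
                sample_info = data.frame(sample = samples,
                                         breed = breed_of[samples],
                                         depth_multiplier = mult[samples],
                                         stringsAsFactors = FALSE),
                cnv = cnv_truth, paralogs = paralog_truth)
  sim <- structure(list(reads = NULL, read_origin = NULL, truth = truth,
                        key = key, genome = genome, fragments = fr,
                        ends = ends, mol = world$mol, enzyme = enzyme,
                        cfg = cfg, seed = seed),
                   class = "GBSSimulation")
  em <- emit_gbs_reads(sim, cfg$mean_locus_depth, seed + 4000L)
  sim$reads <- em$reads
  sim$read_origin <- em$origin
  sim
}

# Emit barcoded reads from a planted library world. Re-callable with a new
# seed/depth to model re-sequencing the same library (accrual experiments).
emit_gbs_reads <- function(sim, mean_locus_depth, seed) {
  set.seed(seed)
  cfg <- sim$cfg
  key <- sim$key
  fr <- sim$fragments
  sites <- sim$truth$sites
  geno <- sim$truth$geno
  paralog <- sim$truth$paralogs
  cnv <- sim$truth$cnv
  samples <- sim$truth$sample_info$sample
  mult <- stats::setNames(sim$truth$sample_info$depth_multiplier, samples)
  nfrag <- nrow(fr)
  sites_by_frag <- split(seq_len(nrow(sites)), sites$frag)
  par_by_frag <- if (!is.null(paralog))
    split(seq_len(nrow(paralog)), paralog$frag) else list()
  bclen <- stats::setNames(nchar(key$barcode), key$sample)
  barcode <- stats::setNames(key$barcode, key$sample)
  subst <- function(str, at, base) {          # at: 0-based molecule offset
    substr(str, at + 1L, at + 1L) <- base
    str
  }
  acc_seq <- vector("list", nfrag)
  acc_cnt <- vector("list", nfrag)
  acc_org <- vector("list", nfrag)
  for (f in seq_len(nfrag)) {
    sidx <- sites_by_frag[[as.character(f)]]
    pidx <- par_by_frag[[as.character(f)]]
    mol0 <- sim$mol[f]
    nsit <- length(sidx)
    mol_ghost <- if (length(pidx) > 0) {
      mg <- mol0
      for (k in pidx) mg <- subst(mg, paralog$m[k], paralog$ghost[k])
      mg
    } else NULL
    cnv_here <- !is.null(cnv) && fr$chrom[f] == cnv$chrom &&
      fr$start[f] < cnv$end && fr$end[f] > cnv$start
    # two phased haplotypes per individual; only the haplotypes actually
    # present in the panel are materialized as molecule variants
    ns_samp <- length(samples)
    hapm1 <- matrix(0L, nsit, ns_samp)
    hapm2 <- matrix(0L, nsit, ns_samp)
    if (nsit > 0) {
      for (k in seq_len(nsit)) {
        g <- geno[sidx[k], samples]
        a1 <- ifelse(g == 2L, 1L, ifelse(g == 0L, 0L,
                     stats::rbinom(length(g), 1L, 0.5)))
        hapm1[k, ] <- a1
        hapm2[k, ] <- ifelse(g == 1L, 1L - a1, a1)
      }
    }
    if (nsit > 0) {
      hkey1 <- apply(hapm1, 2, paste, collapse = "")
      hkey2 <- apply(hapm2, 2, paste, collapse = "")
    } else {
      hkey1 <- hkey2 <- rep("", ns_samp)
    }
    ukeys <- sort(unique(c(hkey1, hkey2)))
    mol_var <- vapply(ukeys, function(kk) {
      mv <- mol0
      if (nsit > 0) {
        bits <- as.integer(strsplit(kk, "", fixed = TRUE)[[1]])
        for (k in which(bits == 1L))
          mv <- subst(mv, sites$m[sidx[k]], sites$alt[sidx[k]])
      }
      mv
    }, character(1), USE.NAMES = FALSE)
    hap1 <- match(hkey1, ukeys)
    hap2 <- match(hkey2, ukeys)
    mu_base <- mean_locus_depth * mult[samples]
    if (cnv_here)
      mu_base[samples %in% cnv$carriers] <-
        mu_base[samples %in% cnv$carriers] * cnv$copy_gain
    fs <- list(); fc <- list(); fo <- list(); li <- 0L
    for (ei in c("fwd", "rev")) {
      bodies <- if (ei == "fwd") mol_var else revcomp(mol_var)
      gbody <- if (!is.null(mol_ghost)) {
        if (ei == "fwd") mol_ghost else revcomp(mol_ghost)
      } else NULL
      tots <- stats::rnbinom(length(samples), mu = mu_base,
                             size = cfg$overdispersion)
      n1 <- stats::rbinom(length(samples), tots, 0.5)
      for (j in which(tots > 0)) {
        s <- samples[j]
        cnts <- integer(length(mol_var))
        cnts[hap1[j]] <- cnts[hap1[j]] + n1[j]
        cnts[hap2[j]] <- cnts[hap2[j]] + tots[j] - n1[j]
        use <- which(cnts > 0)
        li <- li + 1L
        fs[[li]] <- paste0(barcode[[s]],
                           substr(bodies[use], 1L,
                                  cfg$read_length - bclen[[s]]))
        fc[[li]] <- cnts[use]
        fo[[li]] <- rep(s, length(use))
      }
      if (!is.null(gbody)) {
        gtots <- stats::rnbinom(length(samples),
                                mu = mean_locus_depth * mult[samples],
                                size = cfg$overdispersion)
        for (j in which(gtots > 0)) {
          s <- samples[j]
          li <- li + 1L
          fs[[li]] <- paste0(barcode[[s]],
                             substr(gbody, 1L,
                                    cfg$read_length - bclen[[s]]))
          fc[[li]] <- gtots[j]
          fo[[li]] <- s
        }
      }
    }
    acc_seq[[f]] <- unlist(fs); acc_cnt[[f]] <- unlist(fc)
    acc_org[[f]] <- unlist(fo)
  }
  tmpl_seq <- unlist(acc_seq); tmpl_cnt <- unlist(acc_cnt)
  tmpl_org <- unlist(acc_org)
  reads <- rep(tmpl_seq, tmpl_cnt)
  origin <- rep(tmpl_org, tmpl_cnt)

  # blank-lane contamination (default none)
  if (cfg$contamination > 0 && any(key$blank) && length(reads) > 0) {
    bs <- key$sample[key$blank][1]
    nc <- stats::rpois(1L, cfg$contamination * length(reads) /
                         max(1L, length(samples)))
    if (nc > 0) {
      src <- sample.int(length(reads), nc, replace = TRUE)
      body <- substr(reads[src], nchar(barcode[origin[src]]) + 1L,
                     nchar(reads[src]))
      reads <- c(reads, paste0(barcode[[bs]],
                               substr(body, 1L,
                                      cfg$read_length - bclen[[bs]])))
      origin <- c(origin, rep(bs, nc))
    }
  }

  # sequencing errors: per-read Binomial(n, error_rate) substitutions
  if (cfg$error_rate > 0 && length(reads) > 0) {
    nerr <- stats::rbinom(length(reads), nchar(reads), cfg$error_rate)
    mx <- max(nerr)
    bases <- c("A", "C", "G", "T")
    k <- 1L
    while (k <= mx) {
      idx <- which(nerr >= k)
      pos <- floor(stats::runif(length(idx)) * nchar(reads[idx])) + 1L
      old <- substr(reads[idx], pos, pos)
      shift <- sample.int(3L, length(idx), replace = TRUE)
      new <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
      substr(reads[idx], pos, pos) <- new
      k <- k + 1L
    }
  }
  if (length(reads) > 0) {
    ord2 <- sample.int(length(reads))
    reads <- reads[ord2]; origin <- origin[ord2]
  }
  list(reads = reads, origin = origin)
}

#' @export
print.GBSSimulation <- function(x, ...) {
  cat(sprintf(
    "<GBSSimulation: %d reads, %d fragments, %d planted SNPs, %d samples>\n",
    length(x$reads), nrow(x$fragments), nrow(x$truth$sites),
    nrow(x$truth$sample_info)))
  invisible(x)
}

#' Write simulation outputs to disk
#'
#' FASTQ reads plus plain-text truth files (sites TSV, genotype matrix TSV,
#' CNV carriers TSV).
#'
#' @param sim a `GBSSimulation`.
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(sim$reads, file.path(dir, "reads.fastq"),
              names = sprintf("read%07d origin=%s", seq_along(sim$reads),
                              sim$read_origin))
  utils::write.table(sim$truth$sites, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- cbind(sim$truth$sites[, c("chrom", "pos")], sim$truth$geno)
  utils::write.table(gt, file.path(dir, "truth_genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth$cnv))
    utils::write.table(
      data.frame(chrom = sim$truth$cnv$chrom, start = sim$truth$cnv$start,
                 end = sim$truth$cnv$end,
                 copy_gain = sim$truth$cnv$copy_gain,
                 carrier = sim$truth$cnv$carriers),
      file.path(dir, "truth_cnv.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  invisible(dir)
}

#' SNP accrual over repeated sequencing runs
#'
#' Re-sequences the same simulated library `n_runs` times at a given
#' per-run depth, accumulates tag counts, and reports the cumulative number
#' of filter-passing SNPs after each run. Discovery saturates: counts are
#' non-decreasing and marginal gains shrink in expectation.
#'
#' @param sim a `GBSSimulation` (its genome/truth are reused; reads are
#'   re-drawn per run).
#' @param n_runs number of sequencing runs.
#' @param depth_per_run mean per-locus per-sample depth of each run.
#' @param filter a `FilterConfig` (see [filter_config()]).
#' @param seed seed for the re-sequencing draws.
#' @return data.frame with `run` and `cumulative_snps`.
#' @export
accrual_experiment <- function(sim, n_runs, depth_per_run = 1,
                               filter = filter_config(), seed = 99L) {
  stopifnot(n_runs >= 1)
  tcms <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    em <- emit_gbs_reads(sim, depth_per_run, seed + 17L * r)
    dx <- demultiplex(em$reads, sim$key, sim$enzyme)
    td <- extract_tags(em$reads, dx, sim$enzyme, sim$cfg$tag_length)
    tcms[[r]] <- count_tags(td, samples = sim$key$sample[!sim$key$blank])
  }
  out <- data.frame(run = seq_len(n_runs), cumulative_snps = NA_integer_)
  seen <- character(0)     # a SNP once identified stays identified
  for (r in seq_len(n_runs)) {
    tcm <- merge_tag_counts(tcms[seq_len(r)])
    al <- anchor_tags(tcm, reference = sim$genome, enzyme = sim$enzyme)
    snp <- discover_and_genotype(al, tcm,
                                 min_minor_individuals =
                                   filter$min_minor_individuals)
    if (nrow(snp$sites) > 0) {
      snp <- site_statistics(snp)
      kept <- filter_sites(snp, filter)$snp
      seen <- union(seen, paste(kept$sites$chrom, kept$sites$pos))
    }
    out$cumulative_snps[r] <- length(seen)
  }
  out
}
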