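# IUPAC nucleotide code expansion. N in a *subject* sequence never matches
# any pattern code (conservative handling of assembly gaps).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_iupac <- function(x) {
  all(strsplit(x, "", fixed = TRUE)[[1]] %in% names(IUPAC_SETS))
}

iupac_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

#' Construct a restriction enzyme
#'
#' Models a type II restriction enzyme by its IUPAC recognition sequence and
#' the position of the 5'-most cut across the two strands. With that
#' convention the cut-site remnant -- the sequence every read starts with
#' after the barcode -- is simply the recognition-site suffix from
#' `cut_offset`, and in-silico fragments tile the chromosome exactly.
#'
#' Only palindromic recognition sites are supported (sufficient for the GBS
#' enzymes PstI, EcoT22I and ApeKI); non-palindromic enzymes are rejected.
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition sequence (palindromic).
#' @param cut_offset 0-based position of the 5'-most top/bottom strand cut
#'   within the recognition site.
#' @param remnant expected read prefix after the barcode; must equal the
#'   recognition suffix from `cut_offset`.
#' @param methylation_sensitive metadata flag; no masking is applied by
#'   default (no methylation map is consumed).
#' @return an object of class `RestrictionEnzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset, remnant,
                               methylation_sensitive = FALSE) {
  recognition <- toupper(recognition)
  remnant <- toupper(remnant)
  if (!nzchar(recognition) || !is_iupac(recognition))
    stop("invalid IUPAC code in recognition sequence for ", name)
  L <- nchar(recognition)
  if (cut_offset < 0 || cut_offset > L)
    stop("cut_offset out of range for ", name)
  if (iupac_revcomp(recognition) != recognition)
    stop("non-palindromic recognition site for ", name,
         "; only palindromic enzymes are supported")
  expected_remnant <- substr(recognition, cut_offset + 1, L)
  if (remnant != expected_remnant)
    stop("remnant for ", name, " must equal the recognition suffix after ",
         "the cut (expected ", expected_remnant, ")")
  structure(list(
    name = name, recognition = recognition, cut_offset = as.integer(cut_offset),
    remnant = remnant,
    # extra reference bases beyond the canonical cut that the sequenced
    # molecule retains at its far end (filled-in overhang)
    overhang_ext = as.integer(L - 2L * cut_offset),
    methylation_sensitive = isTRUE(methylation_sensitive)
  ), class = "RestrictionEnzyme")
}

#' @export
print.RestrictionEnzyme <- function(x, ...) {
  cat(sprintf("<RestrictionEnzyme %s: %s, cut at +%d, remnant %s%s>\n",
              x$name, x$recognition, x$cut_offset, x$remnant,
              if (x$methylation_sensitive) ", methylation-sensitive" else ""))
  invisible(x)
}

#' Load the packaged enzyme registry
#'
#' @return named list of `RestrictionEnzyme` objects (PstI, EcoT22I, ApeKI).
#' @export
gbs_enzymes <- function() {
  path <- system.file("extdata", "enzymes.tsv", package = "gbskit")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    restriction_enzyme(tab$name[i], tab$recognition[i], tab$cut_offset[i],
                       tab$remnant[i], tab$methylation_sensitive[i] == "yes"))
  names(out) <- tab$name
  out
}

#' Fetch one enzyme by name
#' @param name enzyme name, e.g. "PstI".
#' @export
get_enzyme <- function(name) {
  if (inherits(name, "RestrictionEnzyme")) return(name)
  reg <- gbs_enzymes()
  if (!name %in% names(reg))
    stop("unknown enzyme '", name, "'; registry has: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' Find restriction sites in a sequence
#'
#' Scans the top strand for IUPAC matches of the enzyme recognition
#' sequence. All overlapping matches are reported. Subject `N` bases never
#' match.
#'
#' @param sequence a character string or `Biostrings::DNAString`.
#' @param enzyme a `RestrictionEnzyme` or enzyme name.
#' @return integer vector of 0-based site start positions, strictly
#'   increasing.
#' @export
find_sites <- function(sequence, enzyme) {
  enzyme <- get_enzyme(enzyme)
  if (is.character(sequence)) {
    if (!nzchar(sequence)) stop("empty sequence")
    sequence <- Biostrings::DNAString(sequence)
  }
  m <- Biostrings::matchPattern(enzyme$recognition, sequence,
                                fixed = "subject")
  as.integer(Biostrings::start(m)) - 1L
}

#' In-silico digestion of a genome
#'
#' Cuts every sequence at `site + cut_offset` for each enzyme (union of cut
#' positions for a double digest). Fragments tile each sequence exactly:
#' 0-based half-open intervals whose concatenation is `[0, len)`.
#'
#' @param genome named character vector or `DNAStringSet` (uppercase
#'   A/C/G/T/N).
#' @param enzyme first (or only) enzyme.
#' @param enzyme2 optional second enzyme for a double digest.
#' @param with_sequence attach fragment sequences (needed for
#'   [fragment_profile()] repeat detection).
#' @return data.frame of class `gbs_fragments` with columns `chrom`,
#'   `start`, `end`, `left_enzyme`, `right_enzyme` and optionally
#'   `sequence`. Chromosome ends carry the sentinel label `"END"`.
#' @export
digest_genome <- function(genome, enzyme, enzyme2 = NULL,
                          with_sequence = TRUE) {
  if (length(genome) == 0) stop("empty genome")
  if (inherits(genome, "DNAStringSet"))
    genome <- as.character(genome)
  if (is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  enz <- list(get_enzyme(enzyme))
  if (!is.null(enzyme2)) enz <- c(enz, list(get_enzyme(enzyme2)))
  res <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    s <- genome[[ci]]
    len <- nchar(s)
    cuts <- integer(0); labs <- character(0)
    for (e in enz) {
      sites <- find_sites(s, e)
      cc <- sites + e$cut_offset
      cc <- cc[cc > 0L & cc < len]
      cuts <- c(cuts, cc); labs <- c(labs, rep(e$name, length(cc)))
    }
    if (anyDuplicated(cuts)) {       # coincident cuts in a double digest
      keep <- !duplicated(cuts)
      labs <- labs[keep]; cuts <- cuts[keep]
    }
    o <- order(cuts); cuts <- cuts[o]; labs <- labs[o]
    starts <- c(0L, cuts); ends <- c(cuts, len)
    res[[ci]] <- data.frame(
      chrom = names(genome)[ci], start = starts, end = ends,
      left_enzyme = c("END", labs), right_enzyme = c(labs, "END"),
      stringsAsFactors = FALSE)
  }
  frags <- do.call(rbind, res)
  if (with_sequence)
    frags$sequence <- substring(genome[frags$chrom], frags$start + 1L,
                                frags$end)
  rownames(frags) <- NULL
  class(frags) <- c("gbs_fragments", "data.frame")
  frags
}

#' Size-select fragments
#'
#' Retains fragments whose length lies in `[min_bp, max_bp]`. The number of
#' rejected fragments is attached as attribute `rejected` so that
#' kept + rejected equals the input count.
#'
#' @param fragments a `gbs_fragments` data.frame.
#' @param min_bp,max_bp inclusive length window.
#' @export
size_select <- function(fragments, min_bp, max_bp) {
  stopifnot(min_bp >= 0, min_bp <= max_bp)
  len <- fragments$end - fragments$start
  keep <- len >= min_bp & len <= max_bp
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- sum(!keep)
  class(out) <- c("gbs_fragments", "data.frame")
  out
}

#' Fragment-size profile and repeat diagnostics
#'
#' Histograms fragment sizes, flags over-represented identical sequences
#' ("repeat peaks", the discrete spikes a BioAnalyzer trace of a repetitive
#' library shows) and size bins whose count exceeds `bin_factor` times the
#' median bin count, and reports the fraction of fragments inside a
#' size-selection window.
#'
#' @param fragments `gbs_fragments` (with a `sequence` column for sequence
#'   repeat detection).
#' @param bin_bp histogram bin width in bp.
#' @param repeat_threshold minimum identical-sequence multiplicity flagged.
#' @param bin_factor bins with count >= `bin_factor` x median bin count are
#'   flagged.
#' @param window optional `c(min, max)` size window for the yield fraction.
#' @return list of class `FragmentSizeProfile`: `histogram` (data.frame
#'   `size`, `count`), `repeat_peaks` (data.frame `size`, `count`,
#'   `sequence`), `peak_bins`, `window_yield`, `n_fragments`.
#' @export
fragment_profile <- function(fragments, bin_bp = 10, repeat_threshold = 10,
                             bin_factor = 5, window = NULL) {
  stopifnot(bin_bp >= 1)
  len <- fragments$end - fragments$start
  bin <- (len %/% bin_bp) * bin_bp
  hist_tab <- as.data.frame(table(bin), stringsAsFactors = FALSE)
  names(hist_tab) <- c("size", "count")
  hist_tab$size <- as.integer(hist_tab$size)
  hist_tab$count <- as.integer(hist_tab$count)

  peaks <- data.frame(size = integer(0), count = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  if (!is.null(fragments$sequence) && nrow(fragments) > 0) {
    tab <- table(fragments$sequence)
    hot <- tab[tab >= repeat_threshold]
    if (length(hot) > 0) {
      peaks <- data.frame(size = nchar(names(hot)),
                          count = as.integer(hot),
                          sequence = names(hot), stringsAsFactors = FALSE)
      peaks <- peaks[order(-peaks$count, peaks$size), , drop = FALSE]
      rownames(peaks) <- NULL
    }
  }
  med <- stats::median(hist_tab$count)
  peak_bins <- hist_tab[hist_tab$count >= bin_factor * med & med > 0, ,
                        drop = FALSE]
  yield <- NA_real_
  if (!is.null(window))
    yield <- mean(len >= window[1] & len <= window[2])
  structure(list(histogram = hist_tab, repeat_peaks = peaks,
                 peak_bins = peak_bins, window_yield = yield,
                 n_fragments = nrow(fragments)),
            class = "FragmentSizeProfile")
}

#' @export
print.FragmentSizeProfile <- function(x, ...) {
  cat(sprintf("<FragmentSizeProfile: %d fragments, %d repeat peak(s)%s>\n",
              x$n_fragments, nrow(x$repeat_peaks),
              if (!is.na(x$window_yield))
                sprintf(", window yield %.3f", x$window_yield) else ""))
  invisible(x)
}
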