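# Reserved pad symbol for tags shorter than the fixed tag length; never a
# valid base, and excluded from SNP comparison via effective_length.
PAD_CHAR <- "."

# Illumina common adapter: a read that runs off a short insert continues
# into this sequence. The first 10 nt are used for read-through detection.
COMMON_ADAPTER <- "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAG"

iupac_to_regex <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# vectorized IUPAC comparison of fixed strings against a degenerate pattern
iupac_equal <- function(strings, pattern) {
  ok <- nchar(strings) == nchar(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  for (j in seq_along(chars)) {
    set <- IUPAC_SETS[[chars[j]]]
    ok <- ok & substr(strings, j, j) %in% set
  }
  ok
}

#' Validate a barcode key against an enzyme
#'
#' Checks for duplicate barcodes, prefix ambiguity (one entry's
#' barcode + remnant being a prefix of another's, so that a read could be
#' parsed both ways), and barcodes that recreate the enzyme recognition
#' site at the barcode/remnant junction.
#'
#' @param key a `BarcodeKey` data.frame (see [read_key()]).
#' @param enzyme `RestrictionEnzyme` or name.
#' @param strict stop on duplicates or ambiguities (default); otherwise
#'   report only.
#' @return list with `ok`, `duplicates`, `ambiguous_pairs`,
#'   `site_in_barcode`.
#' @export
validate_key <- function(key, enzyme, strict = TRUE) {
  enzyme <- get_enzyme(enzyme)
  if (nrow(key) == 0) stop("empty barcode key")
  if (any(!grepl("^[ACGT]+$", key$barcode)))
    stop("barcodes must be plain A/C/G/T strings")
  dup <- key$barcode[duplicated(key$barcode)]
  full <- paste0(key$barcode, enzyme$remnant)
  bc <- key$barcode
  amb <- list()
  # a shorter barcode B1 collides with a longer B2 when B1 + remnant
  # begins like B2: a read from B1's sample is then parseable as B2's
  for (i in seq_along(bc)) for (j in seq_along(bc)) {
    if (i == j || nchar(bc[i]) >= nchar(bc[j])) next
    span <- min(nchar(bc[j]), nchar(full[i]))
    if (iupac_pref_of(substr(bc[j], 1, span), substr(full[i], 1, span)))
      amb[[length(amb) + 1L]] <- c(bc[i], bc[j])
  }
  site_hit <- vapply(full, function(s)
    regexpr(iupac_to_regex(enzyme$recognition), s, perl = TRUE) > 0,
    logical(1))
  rep_ <- list(ok = length(dup) == 0 && length(amb) == 0,
               duplicates = dup,
               ambiguous_pairs = amb,
               site_in_barcode = key$barcode[site_hit])
  if (strict && !rep_$ok)
    stop("barcode key validation failed: ",
         if (length(dup)) paste("duplicates:", paste(dup, collapse = ",")),
         if (length(amb)) paste(" ambiguous pairs:",
           paste(vapply(amb, paste, character(1), collapse = "~"),
                 collapse = ",")))
  rep_
}

# is a (possibly IUPAC-degenerate via remnant) string a prefix of b, with
# degenerate positions treated as overlapping-compatible sets
iupac_pref_of <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(substr(b, 1, nchar(a)), "", fixed = TRUE)[[1]]
  all(vapply(seq_along(ca), function(j)
    length(intersect(IUPAC_SETS[[ca[j]]], IUPAC_SETS[[cb[j]]])) > 0,
    logical(1)))
}

#' Demultiplex reads by barcode + cut-site remnant
#'
#' A read is assigned to a sample iff it begins exactly with that sample's
#' barcode immediately followed by the enzyme cut-site remnant; the longest
#' matching barcode wins. No mismatch rescue is applied.
#'
#' @param reads character vector of read sequences, or a FASTQ path.
#' @param key validated `BarcodeKey`.
#' @param enzyme `RestrictionEnzyme` or name.
#' @return list of class `DemuxResult`: `assign` (integer key-row index per
#'   read, NA when unassigned), `class` (factor: assigned / no_barcode /
#'   no_remnant), `summary` (per-sample read counts, blank reported
#'   separately), `key`.
#' @export
demultiplex <- function(reads, key, enzyme) {
  enzyme <- get_enzyme(enzyme)
  if (length(reads) == 1 && file.exists(reads[1]))
    reads <- read_fastq(reads)$seqs
  validate_key(key, enzyme)
  n <- length(reads)
  assign <- rep(NA_integer_, n)
  bc_seen <- rep(FALSE, n)
  rl <- nchar(enzyme$remnant)
  for (i in order(-nchar(key$barcode))) {
    bc <- key$barcode[i]
    b <- nchar(bc)
    open <- which(is.na(assign))
    if (length(open) == 0) break
    cand <- open[substr(reads[open], 1, b) == bc]
    if (length(cand) == 0) next
    bc_seen[cand] <- TRUE
    rem_ok <- iupac_equal(substr(reads[cand], b + 1L, b + rl),
                          enzyme$remnant)
    assign[cand[rem_ok]] <- i
  }
  cls <- factor(ifelse(!is.na(assign), "assigned",
                ifelse(bc_seen, "no_remnant", "no_barcode")),
                levels = c("assigned", "no_barcode", "no_remnant"))
  counts <- tabulate(assign, nbins = nrow(key))
  summary <- data.frame(sample = key$sample, blank = key$blank,
                        n_reads = counts, stringsAsFactors = FALSE)
  structure(list(assign = assign, class = cls, summary = summary, key = key,
                 n_unassigned_no_barcode = sum(cls == "no_barcode"),
                 n_unassigned_no_remnant = sum(cls == "no_remnant")),
            class = "DemuxResult")
}

#' @export
print.DemuxResult <- function(x, ...) {
  cat(sprintf(
    "<DemuxResult: %d reads, %d assigned, %d no-barcode, %d no-remnant>\n",
    length(x$assign), sum(!is.na(x$assign)),
    x$n_unassigned_no_barcode, x$n_unassigned_no_remnant))
  invisible(x)
}

# effective length of raw tag spans: truncate at the first internal full
# recognition-site occurrence (5' portion kept; the 3' side belongs to the
# next fragment) or at the common-adapter start, whichever comes first.
tag_effective_length <- function(raw, enzyme, tag_length = 64L) {
  eff <- pmin(nchar(raw), tag_length)
  site <- regexpr(iupac_to_regex(enzyme$recognition), raw, perl = TRUE)
  hit <- site > 0
  eff[hit] <- pmin(eff[hit], site[hit] - 1L)
  adap <- regexpr(substr(COMMON_ADAPTER, 1, 10), raw, fixed = TRUE)
  hit <- adap > 0
  eff[hit] <- pmin(eff[hit], adap[hit] - 1L)
  as.integer(eff)
}

#' Extract fixed-length tags from assigned reads
#'
#' Removes the barcode; the tag begins at the cut-site remnant and is
#' truncated at `tag_length`, at an internal recognition-site occurrence,
#' or at the common-adapter start. Short tags are padded with the reserved
#' pad character and their pre-padding length recorded.
#'
#' @param reads read sequences.
#' @param demux a `DemuxResult` from [demultiplex()].
#' @param enzyme `RestrictionEnzyme` or name.
#' @param tag_length canonical tag span (default 64 nt).
#' @return data.frame with `sample`, `tag` (padded canonical sequence) and
#'   `effective_length`.
#' @export
extract_tags <- function(reads, demux, enzyme, tag_length = 64L) {
  enzyme <- get_enzyme(enzyme)
  if (length(reads) == 1 && file.exists(reads[1]))
    reads <- read_fastq(reads)$seqs
  keep <- which(!is.na(demux$assign))
  idx <- demux$assign[keep]
  bclen <- nchar(demux$key$barcode)[idx]
  raw <- substr(reads[keep], bclen + 1L, bclen + tag_length)
  eff <- tag_effective_length(raw, enzyme, tag_length)
  tag <- substr(raw, 1L, eff)
  short <- eff < tag_length
  tag[short] <- paste0(tag[short],
                       strrep(PAD_CHAR, tag_length - eff[short]))
  data.frame(sample = demux$key$sample[idx], tag = tag,
             effective_length = eff, stringsAsFactors = FALSE)
}

#' Build the tag x sample count matrix
#'
#' Collapses identical canonical tag sequences, dropping tags with an
#' unresolved N inside the effective span. Tag rows are ordered
#' lexicographically (byte order) for determinism.
#'
#' @param tag_df output of [extract_tags()] (columns `sample`, `tag`,
#'   `effective_length`).
#' @param samples column order; defaults to the samples present.
#' @return object of class `TagCountMatrix`: `tags`, `effective_length`,
#'   `counts` (integer matrix tags x samples), `samples`.
#' @export
count_tags <- function(tag_df, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(tag_df$sample))
  keep <- !grepl("N", tag_df$tag, fixed = TRUE)
  tag_df <- tag_df[keep, , drop = FALSE]
  if (nrow(tag_df) == 0) {
    counts <- matrix(0L, 0, length(samples),
                     dimnames = list(NULL, samples))
    return(structure(list(tags = character(0),
                          effective_length = integer(0),
                          counts = counts, samples = samples),
                     class = "TagCountMatrix"))
  }
  dt <- data.table::data.table(tag = tag_df$tag, sample = tag_df$sample)
  agg <- dt[, .N, by = c("tag", "sample")]
  tags <- sort(unique(agg$tag), method = "radix")
  counts <- matrix(0L, length(tags), length(samples),
                   dimnames = list(NULL, samples))
  ri <- match(agg$tag, tags)
  ci <- match(agg$sample, samples)
  ok <- !is.na(ci)
  counts[cbind(ri[ok], ci[ok])] <- agg$N[ok]
  eff <- tag_df$effective_length[match(tags, tag_df$tag)]
  structure(list(tags = tags, effective_length = as.integer(eff),
                 counts = counts, samples = samples),
            class = "TagCountMatrix")
}

#' @export
print.TagCountMatrix <- function(x, ...) {
  cat(sprintf("<TagCountMatrix: %d tags x %d samples, %d reads>\n",
              length(x$tags), length(x$samples), sum(x$counts)))
  invisible(x)
}

#' Tag depth summary
#'
#' Fraction of tags whose maximum per-sample count exceeds a threshold
#' (the "counts > 10 in at least 1 individual" style summary), plus the
#' mean reads per tag per covered sample.
#'
#' @param tcm a `TagCountMatrix`.
#' @param threshold count threshold (default 10).
#' @export
tag_depth_summary <- function(tcm, threshold = 10) {
  if (length(tcm$tags) == 0)
    return(list(frac_above = NA_real_, mean_depth = NA_real_))
  mx <- apply(tcm$counts, 1, max)
  covered <- tcm$counts > 0
  list(frac_above = mean(mx > threshold),
       mean_depth = sum(tcm$counts) / max(1, sum(covered)))
}

#' Merge tag count matrices (e.g. multiple sequencing runs)
#' @param ... `TagCountMatrix` objects over the same sample set.
#' @export
merge_tag_counts <- function(...) {
  ms <- list(...)
  if (length(ms) == 1 && is.list(ms[[1]]) &&
      !inherits(ms[[1]], "TagCountMatrix")) ms <- ms[[1]]
  samples <- ms[[1]]$samples
  for (m in ms) stopifnot(identical(m$samples, samples))
  tags <- sort(unique(unlist(lapply(ms, `[[`, "tags"))), method = "radix")
  counts <- matrix(0L, length(tags), length(samples),
                   dimnames = list(NULL, samples))
  eff <- integer(length(tags))
  for (m in ms) {
    ri <- match(m$tags, tags)
    counts[ri, ] <- counts[ri, ] + m$counts
    eff[ri] <- m$effective_length
  }
  structure(list(tags = tags, effective_length = eff, counts = counts,
                 samples = samples), class = "TagCountMatrix")
}
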