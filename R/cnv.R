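#' Library-size-normalized windowed depth profile
#'
#' Normalizes each sample's tag read counts by
#' `panel median library size / sample library size` (rank-preserving
#' within a sample) and aggregates them over fixed-width genomic windows.
#' Non-unique tags contribute at their recorded (best) location -- a
#' duplicated segment makes its tags multi-map, so excluding them would
#' blind the scan to exactly the signal sought.
#'
#' @param tcm a `TagCountMatrix`.
#' @param aligned `AlignedTags` (including non-unique tags).
#' @param window_bp window width (default 50000).
#' @return list of class `DepthProfile`: `window` (data.frame chrom /
#'   start / end / n_tags), `depth` (matrix windows x samples, normalized
#'   aggregate), `lib_size`, `norm_factor`.
#' @export
depth_profile <- function(tcm, aligned, window_bp = 50000L) {
  stopifnot(window_bp >= 1)
  lib <- colSums(tcm$counts)
  med <- stats::median(lib[lib > 0])
  nf <- ifelse(lib > 0, med / lib, 0)
  counts <- sweep(tcm$counts[aligned$tag_idx, , drop = FALSE], 2, nf, `*`)
  win_id <- paste0(aligned$chrom, ":",
                   (aligned$anchor %/% window_bp) * window_bp)
  uw <- sort(unique(win_id), method = "radix")
  fw <- factor(win_id, levels = uw)
  depth <- rowsum(counts, group = fw, reorder = FALSE)
  depth <- depth[match(uw, rownames(depth)), , drop = FALSE]
  n_tags <- as.integer(table(fw))
  parts <- strsplit(uw, ":", fixed = TRUE)
  win <- data.frame(
    chrom = vapply(parts, `[[`, character(1), 1),
    start = as.integer(vapply(parts, `[[`, character(1), 2)),
    stringsAsFactors = FALSE)
  win$end <- win$start + as.integer(window_bp)
  win$n_tags <- n_tags
  structure(list(window = win, depth = depth, lib_size = lib,
                 norm_factor = nf, window_bp = as.integer(window_bp)),
            class = "DepthProfile")
}

#' Call polymorphic copy-number gains
#'
#' A sample is a carrier in a window when its normalized aggregate depth
#' is at least `fold_threshold` times the cross-sample median and the
#' window holds at least `min_tags` anchored tags. Windows with at least
#' one carrier and at least one baseline sample are polymorphic CNV calls.
#' Losses are not called: a zero-depth window looks like missing coverage
#' at this scale.
#'
#' @param profile a `DepthProfile`.
#' @param fold_threshold carrier fold over the median (default 1.75,
#'   between the 1- and 2-copy expectations).
#' @param min_tags minimum anchored tags per window (default 3).
#' @return data.frame of class `CNVCalls`: one row per (window, carrier)
#'   with `chrom`, `start`, `end`, `carrier`, `fold`, `n_tags`,
#'   `polymorphic`.
#' @export
call_gains <- function(profile, fold_threshold = 1.75, min_tags = 3L) {
  if (fold_threshold <= 1) {
    warning("fold_threshold <= 1 calls every sample a carrier; ",
            "no calls made")
    return(empty_cnv_calls())
  }
  dp <- profile$depth
  win <- profile$window
  rows <- list()
  for (w in seq_len(nrow(win))) {
    if (win$n_tags[w] < min_tags) next
    x <- dp[w, ]
    med <- stats::median(x)
    if (med <= 0) next
    fold <- x / med
    carriers <- names(x)[fold >= fold_threshold]
    if (length(carriers) == 0 || length(carriers) == length(x)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = win$chrom[w], start = win$start[w], end = win$end[w],
      carrier = carriers, fold = as.numeric(fold[carriers]),
      n_tags = win$n_tags[w], polymorphic = TRUE,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_cnv_calls()
  rownames(out) <- NULL
  class(out) <- c("CNVCalls", "data.frame")
  out
}

empty_cnv_calls <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             carrier = character(0), fold = numeric(0), n_tags = integer(0),
             polymorphic = logical(0), stringsAsFactors = FALSE)
}
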