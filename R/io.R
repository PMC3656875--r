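#' Reverse complement of character sequences
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a (multi-record, wrapped) FASTA file
#' @param path file path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a 4-line FASTQ file
#' @param path file path (plain or gzipped).
#' @return list with `names` and `seqs` character vectors.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("truncated FASTQ record in ", path, ": ", n,
         " lines is not a multiple of 4 (record ", n %/% 4L + 1L, ")")
  hd <- lines[seq(1L, n, by = 4L)]
  if (any(substr(hd, 1, 1) != "@"))
    stop("malformed FASTQ header in ", path, " at record ",
         which(substr(hd, 1, 1) != "@")[1])
  list(names = sub("^@", "", hd), seqs = toupper(lines[seq(2L, n, by = 4L)]))
}

#' Write reads to FASTQ with a constant quality
#' @param seqs read sequences.
#' @param path output path.
#' @param names read names (default read000001, ...).
#' @param qual_char constant per-base quality character.
#' @export
write_fastq <- function(seqs, path, names = NULL, qual_char = "I") {
  if (is.null(names))
    names <- sprintf("read%07d", seq_along(seqs))
  quals <- vapply(nchar(seqs), function(n)
    strrep(qual_char, n), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  invisible(path)
}

#' Read a barcode key file
#'
#' TSV with mandatory header columns `sample`, `barcode`, `breed`, `blank`
#' (blank = 1 marks the no-DNA negative control lane entry).
#'
#' @param path file path.
#' @return data.frame of class `BarcodeKey`.
#' @export
read_key <- function(path) {
  key <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sample", "barcode", "breed", "blank")
  miss <- setdiff(need, names(key))
  if (length(miss) > 0)
    stop("key file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  key$blank <- as.integer(key$blank) == 1L
  key$barcode <- toupper(key$barcode)
  class(key) <- c("BarcodeKey", "data.frame")
  key
}

#' Read the per-chromosome annotation table
#'
#' Columns: `chrom`, `size_mbp`, `genes` and optionally marker counts. The
#' packaged fixture `bos_umd31_chromosomes.tsv` carries the UMD 3.1 cattle
#' assembly sizes, gene counts and published GBS / BeadChip SNP counts.
#'
#' @param path file path; default loads the packaged cattle table.
#' @export
read_annotation <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "bos_umd31_chromosomes.tsv",
                        package = "gbskit")
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  need <- c("chrom", "size_mbp", "genes")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0)
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  ann
}

#' Minimal SAM alignment reader
#'
#' Parses the mandatory fields of a plain-text SAM file. Used to accept tag
#' alignments from an external aligner.
#'
#' @param path file path.
#' @return data.frame with qname, flag, rname, pos (1-based), mapq, cigar,
#'   seq.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("malformed SAM record at line ", which(nf < 11)[1] ,
         ": fewer than 11 fields")
  g <- function(i) vapply(fields, `[[`, character(1), i)
  data.frame(qname = g(1), flag = as.integer(g(2)), rname = g(3),
             pos = as.integer(g(4)), mapq = as.integer(g(5)), cigar = g(6),
             seq = g(10), stringsAsFactors = FALSE)
}

#' Write intervals to BED
#'
#' BED is 0-based half-open, matching the internal fragment convention, so
#' coordinates pass through unchanged.
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally `name`
#'   (or `left_enzyme`/`right_enzyme` for fragments).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  name <- if (!is.null(df$name)) df$name
  else if (!is.null(df$left_enzyme))
    paste0(df$left_enzyme, "/", df$right_enzyme)
  else rep(".", nrow(df))
  out <- data.frame(df$chrom, df$start, df$end, name)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 0-based half-open intervals
#' @param path file path.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}

geno_to_gt <- c("0/0", "0/1", "1/1")

#' Write a SNPTable to VCF 4.2
#'
#' Emits GT and AD fields. Output is deterministic (byte-identical for
#' identical inputs): the header carries the package version and an
#' optional configuration hash, never a timestamp.
#'
#' @param snp a `SNPTable`.
#' @param path output path.
#' @param contigs optional named integer vector of contig lengths.
#' @param config_hash optional config fingerprint recorded in the header.
#' @export
write_vcf <- function(snp, path, contigs = NULL, config_hash = NULL) {
  stopifnot(inherits(snp, "SNPTable"))
  ver <- as.character(utils::packageVersion("gbskit"))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=gbskit-", ver))
  if (!is.null(config_hash))
    hdr <- c(hdr, paste0("##gbskit_config_hash=", config_hash))
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr,
    '##INFO=<ID=TL,Number=0,Type=Flag,Description="Tightly linked: shares a 64-nt tag span with another SNP">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", snp$samples), collapse = "\t"))
  s <- snp$sites
  n <- nrow(s)
  body <- character(n)
  for (i in seq_len(n)) {
    g <- snp$geno[i, ]
    gt <- ifelse(is.na(g), "./.", geno_to_gt[g + 1L])
    ad <- paste0(snp$ref_depth[i, ], ",", snp$alt_depth[i, ])
    body[i] <- paste(c(s$chrom[i], s$pos[i] + 1L, ".", s$ref[i], s$alt[i],
                       ".", "PASS",
                       if (isTRUE(s$tightly_linked[i])) "TL" else ".",
                       "GT:AD", paste0(gt, ":", ad)), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a gbskit VCF back into a SNPTable
#'
#' Inverse of [write_vcf()]; per-site statistics are recomputed so that a
#' write/read round trip reproduces the table exactly.
#'
#' @param path VCF path.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hi <- which(startsWith(lines, "#CHROM"))
  if (length(hi) != 1) stop("malformed VCF ", path, ": no #CHROM header")
  header <- strsplit(lines[hi], "\t", fixed = TRUE)[[1]]
  samples <- header[-(1:9)]
  body <- lines[-seq_len(hi)]
  if (length(body) == 0) stop("VCF ", path, " has no records")
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header)))
    stop("malformed VCF record at data line ", which(nf != length(header))[1])
  g <- function(i) vapply(fields, `[[`, character(1), i)
  sites <- data.frame(chrom = g(1), pos = as.integer(g(2)) - 1L,
                      ref = g(4), alt = g(5),
                      tightly_linked = grepl("\\bTL\\b", g(8)),
                      stringsAsFactors = FALSE)
  n <- length(body); ns <- length(samples)
  geno <- matrix(NA_integer_, n, ns, dimnames = list(NULL, samples))
  rd <- matrix(0L, n, ns, dimnames = list(NULL, samples))
  ad <- matrix(0L, n, ns, dimnames = list(NULL, samples))
  gt_code <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)
  for (i in seq_len(n)) {
    cells <- fields[[i]][-(1:9)]
    parts <- strsplit(cells, ":", fixed = TRUE)
    gt <- vapply(parts, `[[`, character(1), 1)
    advals <- strsplit(vapply(parts, `[[`, character(1), 2), ",", fixed = TRUE)
    geno[i, ] <- gt_code[gt]
    rd[i, ] <- as.integer(vapply(advals, `[[`, character(1), 1))
    ad[i, ] <- as.integer(vapply(advals, `[[`, character(1), 2))
  }
  snp <- new_snp_table(sites, geno, rd, ad, samples)
  site_statistics(snp)
}

#' Write a Newick string to file
#' @param newick Newick string (with trailing semicolon).
#' @param path output path.
#' @export
write_newick <- function(newick, path) {
  writeLines(newick, path)
  invisible(path)
}

#' Write a TagCountMatrix as TSV (tags x samples)
#' @param tcm a `TagCountMatrix`.
#' @param path output path.
#' @export
write_tag_counts <- function(tcm, path) {
  df <- data.frame(tag = tcm$tags,
                   effective_length = tcm$effective_length,
                   tcm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TagCountMatrix written by [write_tag_counts()]
#' @param path file path.
#' @export
read_tag_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(tag = "character"))
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- NULL
  structure(list(tags = df$tag,
                 effective_length = as.integer(df$effective_length),
                 counts = counts, samples = colnames(counts)),
            class = "TagCountMatrix")
}

#' Write tag anchors as a BED-like table
#'
#' Columns: chrom, start (anchor), end, name (tag index), strand, unique
#' flag, mismatches.
#'
#' @param aligned `AlignedTags`.
#' @param path output path.
#' @export
write_anchors <- function(aligned, path) {
  df <- data.frame(chrom = aligned$chrom, start = aligned$anchor,
                   end = aligned$anchor + 1L,
                   name = sprintf("tag%06d", aligned$tag_idx),
                   strand = aligned$strand,
                   unique = as.integer(aligned$unique),
                   mismatches = aligned$mismatches,
                   pos0 = aligned$pos0)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read anchors written by [write_anchors()] back into AlignedTags
#' @param tcm the matching `TagCountMatrix`.
#' @param path file path.
#' @export
read_anchors <- function(tcm, path) {
  df <- utils::read.delim(path, colClasses = c(name = "character"))
  idx <- as.integer(sub("^tag", "", df$name))
  out <- data.frame(tag_idx = idx, tag = tcm$tags[idx], chrom = df$chrom,
                    pos0 = df$pos0, strand = df$strand, anchor = df$start,
                    unique = df$unique == 1L,
                    mismatches = df$mismatches,
                    ref_tagseq = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("AlignedTags", "data.frame")
  out
}
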