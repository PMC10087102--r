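## Plain-text interchange: GTF (1-based closed on disk), BED (0-based
## half-open), FASTA, one-id-per-line gene lists, TSV site tables.

.gtf_feature_out <- c(gene = "gene", transcript = "transcript", exon = "exon",
                      UTR5 = "five_prime_UTR", UTR3 = "three_prime_UTR")
.gtf_feature_in <- stats::setNames(names(.gtf_feature_out), .gtf_feature_out)

#' Write an annotation data.frame as GTF
#'
#' Converts the internal 0-based half-open intervals to the 1-based closed
#' GTF convention. Transcript confidence tags are written as a single
#' `tag "a,b"` attribute.
#'
#' @param annotation internal annotation data.frame.
#' @param path output path.
#' @export
write_gtf <- function(annotation, path) {
  .check_annotation(annotation)
  attrs <- paste0('gene_id "', annotation$gene_id, '"; transcript_id "',
                  annotation$transcript_id, '";')
  if ("tags" %in% names(annotation)) {
    has <- !is.na(annotation$tags) & nzchar(annotation$tags)
    attrs[has] <- paste0(attrs[has], ' tag "', annotation$tags[has], '";')
  }
  lines <- paste(annotation$seqid, "svtarget",
                 .gtf_feature_out[annotation$feature],
                 annotation$start + 1L, annotation$end, ".",
                 annotation$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF file into the internal annotation data.frame
#'
#' Uses rtracklayer for parsing and converts 1-based closed coordinates to
#' the internal 0-based half-open convention (the two converters are
#' mutually inverse).
#'
#' @param path GTF file.
#' @return annotation data.frame (gene_id, transcript_id, feature, seqid,
#'   start, end, strand, tags).
#' @export
read_gtf <- function(path) {
  svt_assert(requireNamespace("rtracklayer", quietly = TRUE), "io_error",
             "read_gtf requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  feat <- as.character(md$type)
  feat <- ifelse(feat %in% names(.gtf_feature_in), .gtf_feature_in[feat], feat)
  tags <- if ("tag" %in% names(md)) as.character(md$tag) else NA_character_
  data.frame(
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    feature = feat,
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    tags = tags,
    stringsAsFactors = FALSE
  )
}

#' Write sequences as FASTA (DNA letters by default)
#'
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}

#' Read/write 6-column BED read intervals
#'
#' Columns: chrom, start, end, name, score (read length), strand. 0-based
#' half-open, tab separated.
#'
#' @param reads data.frame with `start`, `end` and optionally `name`,
#'   `strand`.
#' @param path file path.
#' @param chrom reference name (recycled).
#' @export
write_bed_reads <- function(reads, path, chrom = "ref") {
  reads <- as.data.frame(reads)
  n <- nrow(reads)
  bed <- data.frame(
    chrom = if ("chrom" %in% names(reads)) reads$chrom else rep(chrom, n),
    start = reads$start, end = reads$end,
    name = if ("name" %in% names(reads)) reads$name else
      sprintf("read%06d", seq_len(max(n, 0L))),
    score = reads$end - reads$start,
    strand = if ("strand" %in% names(reads)) reads$strand else rep("+", n))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed_reads
#' @export
read_bed_reads <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  svt_assert(ncol(bed) >= 3L, "parse_error", "BED needs >= 3 columns")
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (ncol(bed) >= 6L) names(bed)[4:6] <- c("name", "score", "strand")
  bed
}

#' Read/write one-gene-id-per-line text lists
#' @param ids character vector of gene ids.
#' @param path file path.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}

#' Write a data.frame as TSV with header
#' @param df data.frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
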