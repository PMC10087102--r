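#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

## Internal annotation convention: a data.frame with one row per record,
## columns gene_id, transcript_id, feature (gene | transcript | exon |
## UTR5 | UTR3), seqid, start, end (0-based half-open), strand, tags
## (comma-separated GTF tag values, transcript rows only). On-disk GTF is
## 1-based closed; the converters in io.R are bijective.

.check_annotation <- function(annotation) {
  need <- c("gene_id", "transcript_id", "feature", "seqid", "start", "end",
            "strand")
  svt_assert(is.data.frame(annotation) && all(need %in% names(annotation)),
             "annotation_error", "annotation must have columns ",
             paste(need, collapse = ", "))
  invisible(annotation)
}

#' Default transcript-confidence tag allowlist
#'
#' The GTF tags counted when ranking transcripts by annotation confidence.
#' The exact set used by annotation pipelines varies; this list covers the
#' common GENCODE confidence tags and is fully configurable.
#' @return character vector of tag names.
#' @export
default_tag_allowlist <- function() {
  c("basic", "CCDS", "appris_principal", "MANE_Select", "exp_conf",
    "verified")
}

#' Select one canonical transcript per gene
#'
#' Ranks each gene's transcripts by the number of confidence tags they carry
#' (restricted to `allowlist`) and keeps the best one; ties break to the
#' lexicographically smaller transcript id so the choice is deterministic.
#'
#' @param annotation internal annotation data.frame (see [read_gtf()]).
#' @param allowlist tags that count towards confidence.
#' @return named character vector mapping gene_id to transcript_id.
#' @export
select_canonical <- function(annotation, allowlist = default_tag_allowlist()) {
  .check_annotation(annotation)
  tx <- annotation[annotation$feature == "transcript", , drop = FALSE]
  svt_assert(nrow(tx) > 0, "annotation_error", "annotation has no transcripts")
  genes <- unique(annotation$gene_id[annotation$feature == "gene"])
  if (length(genes) == 0L) genes <- unique(tx$gene_id)
  missing <- setdiff(genes, tx$gene_id)
  svt_assert(length(missing) == 0L, "annotation_error",
             "gene without transcript: ", paste(missing, collapse = ", "))
  tags <- if ("tags" %in% names(tx)) tx$tags else rep("", nrow(tx))
  tag_count <- vapply(strsplit(ifelse(is.na(tags), "", tags), ","),
                      function(t) sum(trimws(t) %in% allowlist), numeric(1L))
  out <- character(0)
  for (g in sort(unique(tx$gene_id))) {
    idx <- which(tx$gene_id == g)
    best <- idx[tag_count[idx] == max(tag_count[idx])]
    out[g] <- sort(tx$transcript_id[best])[1L]
  }
  out
}

#' Build the intron/exon/UTR/junction feature table
#'
#' For every gene's canonical transcript, derives intron records from the
#' gaps between consecutive exons, classifies exonic sequence into `UTR5`,
#' `UTR3` and (non-UTR) `exon`, and emits fixed-width junction features
#' (`UTR5/exon`, `UTR3/exon`, default +/- 10 nt) around each UTR-CDS
#' boundary. Intervals are 0-based half-open (BED convention); per-class
#' total lengths are accumulated for length normalisation.
#'
#' @param annotation internal annotation data.frame.
#' @param canonical_map output of [select_canonical()]; computed when `NULL`.
#' @param junction_width half-width of junction windows in nt (default 10).
#' @return object of class `feature_table`: list with `records` (data.frame
#'   gene_id, feature, start, end) and `total_length` (named vector).
#' @export
build_feature_table <- function(annotation, canonical_map = NULL,
                                junction_width = 10L) {
  .check_annotation(annotation)
  if (is.null(canonical_map)) canonical_map <- select_canonical(annotation)
  recs <- list()
  add <- function(gene, feat, start, end) {
    if (length(start) > 0L && any(end > start)) {
      keep <- end > start
      recs[[length(recs) + 1L]] <<- data.frame(
        gene_id = gene, feature = feat, start = start[keep], end = end[keep],
        stringsAsFactors = FALSE)
    }
  }
  for (g in names(canonical_map)) {
    txid <- canonical_map[[g]]
    rows <- annotation[annotation$transcript_id %in% txid &
                         annotation$gene_id == g, , drop = FALSE]
    ex <- rows[rows$feature == "exon", , drop = FALSE]
    svt_assert(nrow(ex) > 0, "annotation_error",
               "transcript ", txid, " has no exons")
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L) {
      svt_assert(all(ex$start[-1L] >= ex$end[-nrow(ex)]), "annotation_error",
                 "overlapping exons in transcript ", txid)
      add(g, "intron", ex$end[-nrow(ex)], ex$start[-1L])
    }
    exon_ir <- IRanges::IRanges(ex$start + 1L, ex$end)
    utr_ir <- IRanges::IRanges()
    for (u in c("UTR5", "UTR3")) {
      ur <- rows[rows$feature == u, , drop = FALSE]
      if (nrow(ur) > 0L) {
        add(g, u, ur$start, ur$end)
        utr_ir <- c(utr_ir, IRanges::IRanges(ur$start + 1L, ur$end))
        ## junction window around the CDS-facing boundary of each UTR
        b <- if (u == "UTR5") max(ur$end) else min(ur$start)
        tx_span <- c(min(ex$start), max(ex$end))
        js <- max(tx_span[1L], b - junction_width)
        je <- min(tx_span[2L], b + junction_width)
        add(g, paste0(u, "/exon"), js, je)
      }
    }
    cds_ex <- IRanges::setdiff(exon_ir, utr_ir)
    add(g, "exon", IRanges::start(cds_ex) - 1L, IRanges::end(cds_ex))
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene_id = character(0), feature = character(0),
               start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  lens <- tapply(records$end - records$start, records$feature, sum)
  structure(list(records = records,
                 total_length = stats::setNames(as.numeric(lens), names(lens)),
                 junction_width = as.integer(junction_width)),
            class = "feature_table")
}

.sites_frame <- function(sites) {
  if (is.data.frame(sites)) sites else sites_to_frame(sites)
}

#' Assign sites to gene features (left-outer-join semantics)
#'
#' Intersects predicted binding sites with the feature table the way
#' `bedtools intersect -wa -wb -loj` does: every site appears in the
#' output; a site overlapping no feature carries an `NA` feature; a site
#' overlapping several features yields one row per overlap. Sites and
#' features must share the per-gene coordinate system.
#'
#' @param sites data.frame with `gene_id`, `start`, `end` (0-based
#'   half-open), or a list of `target_site`s.
#' @param feature_table a [build_feature_table()] result.
#' @return data.frame: site columns plus `feature`, `feature_start`,
#'   `feature_end`.
#' @export
annotate_sites <- function(sites, feature_table) {
  sites <- .sites_frame(sites)
  ft <- feature_table$records
  if (nrow(sites) == 0L) {
    return(cbind(sites, feature = character(0), feature_start = integer(0),
                 feature_end = integer(0)))
  }
  sg <- GenomicRanges::GRanges(sites$gene_id,
                               IRanges::IRanges(sites$start + 1L, sites$end))
  fg <- GenomicRanges::GRanges(ft$gene_id,
                               IRanges::IRanges(ft$start + 1L, ft$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(sg, fg))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  orphan <- setdiff(seq_len(nrow(sites)), unique(qh))
  out <- rbind(
    if (length(qh)) cbind(sites[qh, , drop = FALSE],
                          feature = ft$feature[sh],
                          feature_start = ft$start[sh],
                          feature_end = ft$end[sh]),
    if (length(orphan)) cbind(sites[orphan, , drop = FALSE],
                              feature = NA_character_,
                              feature_start = NA_integer_,
                              feature_end = NA_integer_)
  )
  rownames(out) <- NULL
  out[order(match(out$gene_id, sites$gene_id), out$start), , drop = FALSE]
}

#' Length-normalised feature percentages
#'
#' The share of binding sites per feature class after normalising counts to
#' the class's total length: `density_f = count_f / length_f`,
#' `percentage_f = 100 * density_f / sum(densities)`. This is the
#' normalisation under which intronic targeting dominates even though
#' introns are long.
#'
#' @param annotated_sites output of [annotate_sites()].
#' @param feature_table the matching [build_feature_table()] result.
#' @param classes feature classes to report (default: all classes present
#'   in the table).
#' @return named numeric vector of percentages summing to 100.
#' @export
feature_percentages <- function(annotated_sites, feature_table,
                                classes = NULL) {
  lens <- feature_table$total_length
  if (is.null(classes)) classes <- names(lens)
  counts <- vapply(classes, function(cl)
    sum(annotated_sites$feature == cl, na.rm = TRUE), numeric(1L))
  lens <- lens[classes]
  lens[is.na(lens)] <- 0
  bad <- lens == 0 & counts > 0
  svt_assert(!any(bad), "consistency_error",
             "zero-length feature class with sites: ",
             paste(classes[bad], collapse = ", "))
  dens <- ifelse(lens > 0, counts / lens, 0)
  svt_assert(sum(dens) > 0, "empty_input", "no sites in any reported class")
  100 * dens / sum(dens)
}

#' Metagene profile of binding-site positions
#'
#' Maps each site's midpoint to a relative position in [0, 1) along its
#' canonical transcript (strand-aware: minus-strand transcripts are
#' flipped so bin 1 is always the 5' end), bins the positions, and
#' normalises to a density summing to 1.
#'
#' @param sites data.frame with `gene_id`, `start`, `end`, or a list of
#'   `target_site`s.
#' @param transcripts data.frame with `gene_id`, `start`, `end`, `strand`
#'   giving each canonical transcript's span on the site coordinate system.
#' @param n_bins number of bins (default 100).
#' @return object of class `metagene_profile`: list with `n_bins`,
#'   `density` (sums to 1), `counts`.
#' @export
metagene_profile <- function(sites, transcripts, n_bins = 100L) {
  sites <- .sites_frame(sites)
  svt_assert(is_count(n_bins, 1L), "config_error", "n_bins must be >= 1")
  counts <- integer(n_bins)
  if (nrow(sites) > 0L) {
    idx <- match(sites$gene_id, transcripts$gene_id)
    svt_assert(!anyNA(idx), "coordinate_error",
               "site gene_id not present in transcripts")
    ts <- transcripts$start[idx]; te <- transcripts$end[idx]
    mid <- (sites$start + sites$end) / 2
    svt_assert(all(mid >= ts & mid <= te), "coordinate_error",
               "site outside its transcript span")
    rel <- (mid - ts) / (te - ts)
    minus <- transcripts$strand[idx] == "-"
    rel[minus] <- 1 - rel[minus]
    bin <- pmin(n_bins, floor(rel * n_bins) + 1L)
    tab <- tabulate(bin, nbins = n_bins)
    counts <- tab
  }
  dens <- if (sum(counts) > 0) counts / sum(counts) else rep(0, n_bins)
  structure(list(n_bins = as.integer(n_bins), density = dens,
                 counts = counts),
            class = "metagene_profile")
}
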