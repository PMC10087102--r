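#' @useDynLib svtarget, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.core_params <- function(params) {
  params[c("match_score", "wobble_score", "mismatch_penalty", "gap_open",
           "gap_extend", "seed_scale", "seed_range", "max_target_loop",
           "max_guide_bulge")]
}

.pair_type_labels <- c("mismatch", "WC", "wobble")

## Assemble a duplex_alignment from the C++ core output. `offset` shifts
## target positions (0-based) when the scanned window is a transcript slice.
.build_alignment <- function(raw, guide, target_rna, params, offset = 0L,
                             guide_id = NULL) {
  cols <- data.frame(
    guide_pos = raw$guide_pos,
    target_pos = raw$target_pos + offset,
    pair_type = .pair_type_labels[raw$pair_type + 1L],
    stringsAsFactors = FALSE
  )
  span <- c(min(cols$target_pos) - 1L, max(cols$target_pos))  # 0-based half-open
  aln <- structure(list(
    columns = cols,
    score = raw$score,
    guide_id = guide_id,
    guide_seq = guide,
    target_span = as.integer(span),
    guide_span = c(min(cols$guide_pos), max(cols$guide_pos)),
    target_seq = substr(target_rna, span[1L] + 1L - offset, span[2L] - offset),
    energy = NA_real_
  ), class = "duplex_alignment")
  ## target_seq is stored in absolute span coordinates; fix offset bookkeeping
  aln$target_seq <- substr(target_rna, span[1L] - offset + 1L, span[2L] - offset)
  aln$energy <- duplex_energy(aln)
  aln
}

#' Align a guide against a single target window
#'
#' Finds the highest-scoring local duplex alignment of an RNA guide against
#' a target window, pairing the strands antiparallel: Watson-Crick pairs
#' (A:U, G:C) score `match_score`, G:U wobbles score `wobble_score`,
#' mismatches and bounded single-strand gaps are penalised, and all column
#' scores within the seed (guide positions 2-8 by default) are scaled by
#' `seed_scale`. Guide position 1 is never required (or allowed) to pair,
#' matching the convention that the 5' nucleotide sits in the Argonaute
#' pocket.
#'
#' @param guide a [guide_rna] or RNA string (5'->3').
#' @param target_window target sequence (DNA or RNA, 5'->3').
#' @param params an [align_params] object.
#' @return a `duplex_alignment` (fields `columns`, `score`, `energy`,
#'   `target_span` 0-based half-open, `guide_span` 1-based closed) or
#'   `NULL` when no positive-scoring duplex exists.
#' @examples
#' g <- guide_rna("g", "GGACUACGUACGUACGUACGUACG")
#' w <- rna_revcomp(substr(g$sequence, 2, 24))
#' align_window(g, w)
#' @export
align_window <- function(guide, target_window, params = align_params()) {
  params <- as_align_params(params)
  gid <- NULL
  if (inherits(guide, "guide_rna")) { gid <- guide$id; guide <- guide$sequence }
  guide <- dna_to_rna(guide)
  target_rna <- dna_to_rna(target_window)
  raw <- .align_core(guide, target_rna, .core_params(params))
  if (is.null(raw)) return(NULL)
  .build_alignment(raw, guide, target_rna, params, guide_id = gid)
}

## Independent re-scoring of an alignment's columns under `params`
## (used by tests to validate the C++ core; intentionally plain R).
.score_columns <- function(cols, params) {
  base <- c(WC = params$match_score, wobble = params$wobble_score,
            mismatch = params$mismatch_penalty)
  sc <- unname(base[cols$pair_type])
  in_seed <- cols$guide_pos >= params$seed_range[1L] &
    cols$guide_pos <= params$seed_range[2L]
  sc[in_seed] <- sc[in_seed] * params$seed_scale
  total <- sum(sc)
  if (nrow(cols) > 1L) {
    dg <- diff(cols$guide_pos) - 1L
    dt <- -diff(cols$target_pos) - 1L
    for (k in seq_along(dg)) {
      run <- dg[k] + dt[k]
      if (run > 0L) total <- total + params$gap_open + params$gap_extend * (run - 1L)
    }
  }
  total
}

.seed_ok <- function(aln, params) {
  sr <- params$seed_range
  seed_cols <- aln$columns[aln$columns$guide_pos >= sr[1L] &
                             aln$columns$guide_pos <= sr[2L], , drop = FALSE]
  n_seed <- sr[2L] - sr[1L] + 1L
  if (nrow(seed_cols) != n_seed) return(FALSE)
  if (!setequal(seed_cols$guide_pos, sr[1L]:sr[2L])) return(FALSE)
  if (any(seed_cols$pair_type == "mismatch")) return(FALSE)
  if (sum(seed_cols$pair_type == "wobble") > params$max_seed_wobble) return(FALSE)
  ## contiguity: target positions step by exactly -1 across the seed
  ord <- order(seed_cols$guide_pos)
  all(diff(seed_cols$target_pos[ord]) == -1L)
}

.new_target_site <- function(alignment, params, gene_id = NA_character_,
                             transcript_id = NA_character_, guide_id = NULL) {
  passes <- alignment$score >= params$score_threshold &&
    alignment$energy <= params$energy_threshold &&
    (!params$strict_seed || .seed_ok(alignment, params))
  structure(list(
    gene_id = gene_id, transcript_id = transcript_id,
    guide_id = if (is.null(guide_id)) alignment$guide_id else guide_id,
    alignment = alignment, passes_thresholds = passes
  ), class = "target_site")
}

#' Scan a transcript for guide target sites
#'
#' Scans the sense strand of a (pre-m)RNA sequence for duplexes with the
#' guide that clear the score threshold, the free-energy ceiling, and (when
#' `strict_seed`) perfect seed pairing. Overlapping hits are resolved by
#' greedy selection of non-overlapping local score maxima: the best
#' alignment is taken, its target span masked, and the scan repeated until
#' no alignment reaches `score_threshold`. Returned sites all have
#' `passes_thresholds = TRUE` and are sorted by target start; scanning
#' unspliced pre-mRNA is the intended default since the guide acts on
#' nascent, largely intronic transcripts.
#'
#' @param guide a [guide_rna] or RNA string.
#' @param transcript_sequence DNA or RNA sequence, 5'->3'.
#' @param params an [align_params].
#' @param gene_id,transcript_id identifiers carried onto the sites.
#' @param max_sites safety cap on hits per transcript (default 100).
#' @return list of `target_site` objects (possibly empty).
#' @export
scan_transcript <- function(guide, transcript_sequence,
                            params = align_params(),
                            gene_id = NA_character_,
                            transcript_id = NA_character_,
                            max_sites = 100L) {
  params <- as_align_params(params)
  gid <- NULL
  if (inherits(guide, "guide_rna")) { gid <- guide$id; guide <- guide$sequence }
  guide <- dna_to_rna(guide)
  tx <- dna_to_rna(transcript_sequence)
  svt_assert(nchar(tx) >= nchar(guide), "config_error",
             "transcript shorter than guide")
  cpar <- .core_params(params)
  masked <- tx
  hits <- list()
  repeat {
    raw <- .align_core(guide, masked, cpar)
    if (is.null(raw) || raw$score < params$score_threshold) break
    aln <- .build_alignment(raw, guide, tx, params, guide_id = gid)
    hits[[length(hits) + 1L]] <- aln
    span <- aln$target_span
    substr(masked, span[1L] + 1L, span[2L]) <-
      strrep("N", span[2L] - span[1L])
    if (length(hits) >= max_sites) break
  }
  sites <- lapply(hits, .new_target_site, params = params, gene_id = gene_id,
                  transcript_id = transcript_id, guide_id = gid)
  sites <- Filter(function(s) s$passes_thresholds, sites)
  starts <- vapply(sites, function(s) s$alignment$target_span[1L], numeric(1L))
  sites[order(starts)]
}

#' Classify the pairing architecture of a target site
#'
#' Reports the duplex features used to characterise guide-target
#' hybridisation: whether the seed (positions 2-8) is fully paired, wobble
#' positions, the furthest guide position contiguously paired from the seed
#' onward, the target-side loop (total unpaired target nucleotides between
#' paired flanks, with the longest run's guide anchors and 5'->3' target
#' sequence), the central pairing scheme at guide positions 10-11-12, and
#' the target-side alignment length. A 24-nt guide fully paired over
#' positions 2-24 gives a target alignment length of 23 with no loop; one
#' 5-nt target-side insertion gives 28 with a 5-nt loop.
#'
#' @param site a `target_site` or `duplex_alignment`.
#' @param params an [align_params] (for seed range and central positions).
#' @return object of class `architecture_report`.
#' @export
classify_architecture <- function(site, params = align_params()) {
  params <- as_align_params(params)
  aln <- if (inherits(site, "target_site")) site$alignment else site
  svt_assert(inherits(aln, "duplex_alignment"), "config_error",
             "site must be a target_site or duplex_alignment")
  cols <- aln$columns
  paired <- cols[cols$pair_type != "mismatch", , drop = FALSE]
  paired <- paired[order(paired$guide_pos), , drop = FALSE]
  sr <- params$seed_range
  span_len <- aln$target_span[2L] - aln$target_span[1L]
  loop_total <- span_len - nrow(paired)

  ## largest unpaired-target run between consecutive paired columns
  loop_len <- 0L; loop_anchor <- c(NA_integer_, NA_integer_); loop_seq <- ""
  if (nrow(paired) > 1L) {
    ut <- paired$target_pos[-nrow(paired)] - paired$target_pos[-1L] - 1L
    k <- which.max(ut)
    if (ut[k] > 0L) {
      loop_len <- ut[k]
      loop_anchor <- c(paired$guide_pos[k], paired$guide_pos[k + 1L])
      from <- paired$target_pos[k + 1L] + 1L
      to <- paired$target_pos[k] - 1L
      off <- aln$target_span[1L]
      loop_seq <- substr(aln$target_seq, from - off, to - off)
    }
  }

  pos_type <- function(p) {
    t <- cols$pair_type[cols$guide_pos == p]
    if (length(t) == 0L || t[1L] == "mismatch") "unpaired" else t[1L]
  }
  seed_paired <- all(vapply(sr[1L]:sr[2L], function(p)
    pos_type(p) != "unpaired", logical(1L)))
  extent <- 1L
  p <- 2L
  while (p <= nchar(aln$guide_seq) && pos_type(p) != "unpaired") {
    extent <- p; p <- p + 1L
  }

  structure(list(
    seed_paired = seed_paired,
    wobble_positions = sort(cols$guide_pos[cols$pair_type == "wobble"]),
    pairing_extent = extent,
    loop_length = as.integer(loop_total),
    longest_loop = as.integer(loop_len),
    loop_guide_anchor = loop_anchor,
    loop_sequence = loop_seq,
    central_scheme = vapply(params$central_positions, pos_type, character(1L)),
    alignment_length_target = as.integer(span_len)
  ), class = "architecture_report")
}

#' Tally 5-nt target-loop sequences across sites
#'
#' Counts the target-strand 5'->3' loop sequences over sites whose total
#' target-side loop is exactly 5 nt (the conserved loop class). Sites with
#' no loop or other loop sizes are ignored.
#'
#' @param sites list of `target_site` objects.
#' @param params an [align_params].
#' @return named integer vector mapping loop 5-mers to counts (empty when
#'   no 5-nt loops exist).
#' @export
loop_consensus <- function(sites, params = align_params()) {
  seqs <- character(0)
  for (s in sites) {
    rep <- classify_architecture(s, params)
    if (rep$loop_length == 5L && rep$longest_loop == 5L)
      seqs <- c(seqs, rep$loop_sequence)
  }
  if (length(seqs) == 0L) return(integer(0))
  tab <- table(seqs)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cols <- x$columns
  gchar <- strsplit(x$guide_seq, "", fixed = TRUE)[[1L]]
  tchar <- strsplit(x$target_seq, "", fixed = TRUE)[[1L]]
  off <- x$target_span[1L]
  gl <- ml <- tl <- character(0)
  tp_prev <- x$target_span[2L] + 1L
  for (k in seq_len(nrow(cols))) {
    gp <- cols$guide_pos[k]; tp <- cols$target_pos[k]
    if (k > 1L) {
      gp_prev <- cols$guide_pos[k - 1L]
      for (p in seq_len(max(0L, gp - gp_prev - 1L))) {  # guide bulge
        gl <- c(gl, gchar[gp_prev + p]); ml <- c(ml, " "); tl <- c(tl, "-")
      }
      for (q in seq_len(max(0L, tp_prev - tp - 1L))) {  # target loop
        gl <- c(gl, "-"); ml <- c(ml, " ")
        tl <- c(tl, tchar[tp_prev - q - off])
      }
    }
    gl <- c(gl, gchar[gp])
    ml <- c(ml, switch(cols$pair_type[k], WC = "|", wobble = ":", " "))
    tl <- c(tl, tchar[tp - off])
    tp_prev <- tp
  }
  cat("<duplex_alignment> score ", format(x$score), ", energy ",
      format(round(x$energy, 2)), " kcal/mol\n", sep = "")
  cat("  guide  5'-", paste(gl, collapse = ""), "-3' [",
      x$guide_span[1L], "-", x$guide_span[2L], "]\n", sep = "")
  cat("            ", paste(ml, collapse = ""), "\n", sep = "")
  cat("  target 3'-", paste(tl, collapse = ""), "-5' [",
      x$target_span[1L], ", ", x$target_span[2L], ")\n", sep = "")
  invisible(x)
}

#' @export
print.target_site <- function(x, ...) {
  cat("<target_site> guide ", x$guide_id %||% "?", " on ",
      x$gene_id, " (passes: ", x$passes_thresholds, ")\n", sep = "")
  print(x$alignment)
  invisible(x)
}

#' @export
print.architecture_report <- function(x, ...) {
  cat("<architecture_report>\n")
  cat("  seed_paired:", x$seed_paired,
      " pairing_extent:", x$pairing_extent, "\n")
  cat("  loop_length:", x$loop_length,
      if (x$loop_length > 0)
        paste0(" (", x$loop_sequence, ", anchors ",
               paste(x$loop_guide_anchor, collapse = "-"), ")"), "\n")
  cat("  central 10-11-12:", paste(x$central_scheme, collapse = "-"), "\n")
  cat("  target alignment length:", x$alignment_length_target, "nt\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert target sites to a data frame
#'
#' @param sites list of `target_site` objects.
#' @return data.frame with one row per site (gene, transcript, guide,
#'   0-based half-open target span, score, energy).
#' @export
sites_to_frame <- function(sites) {
  if (length(sites) == 0L) {
    return(data.frame(gene_id = character(0), transcript_id = character(0),
                      guide_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      energy = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(sites, function(s) {
    data.frame(gene_id = s$gene_id, transcript_id = s$transcript_id,
               guide_id = s$guide_id %||% NA_character_,
               start = s$alignment$target_span[1L],
               end = s$alignment$target_span[2L],
               score = s$alignment$score, energy = s$alignment$energy,
               stringsAsFactors = FALSE)
  }))
}
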