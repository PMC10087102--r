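#' Guide RNA objects
#'
#' A `guide_rna` is a short 5'->3' RNA sequence with 1-based position
#' semantics: position 1 is the 5' nucleotide, the seed region spans
#' positions 2-8. Guides may record their origin (parent sequence id and the
#' 0-based half-open interval on the parent they were excised from), as is
#' the case for small vault RNA fragments cut out of a full-length vault RNA.
#'
#' @param id single identifier.
#' @param sequence RNA string over `A`, `C`, `G`, `U` (`T` is transliterated),
#'   length >= 15 (the small-RNA read-length filter floor).
#' @param origin optional list with elements `parent_id` and `interval`
#'   (0-based half-open on the parent).
#' @return An object of class `guide_rna` with fields `id`, `sequence`,
#'   `origin`.
#' @examples
#' g <- guide_rna("svt", "GGACUACGUACGUACGUACGUACG")
#' nchar(g$sequence)
#' @export
guide_rna <- function(id, sequence, origin = NULL) {
  svt_assert(is.character(id) && length(id) == 1L && nzchar(id),
             "config_error", "guide id must be a non-empty string")
  sequence <- dna_to_rna(sequence)
  check_rna(sequence, paste0("guide '", id, "'"))
  svt_assert(nchar(sequence) >= 15L, "config_error",
             "guide '", id, "' is shorter than 15 nt")
  structure(list(id = id, sequence = sequence, origin = origin),
            class = "guide_rna")
}

#' @export
print.guide_rna <- function(x, ...) {
  cat("<guide_rna> ", x$id, " (", nchar(x$sequence), " nt)\n", sep = "")
  cat("  5'-", x$sequence, "-3'\n", sep = "")
  if (!is.null(x$origin)) {
    cat("  origin: ", x$origin$parent_id, " [",
        x$origin$interval[1L], ", ", x$origin$interval[2L], ")\n", sep = "")
  }
  invisible(x)
}

#' Load guide RNAs from a FASTA file
#'
#' Reads one `guide_rna` per FASTA record. `T` is transliterated to `U` and
#' lower case is normalised; any other non-`ACGU` character is a parse error
#' naming the offending record.
#'
#' @param fasta_path path to a readable FASTA file.
#' @param min_length minimum accepted guide length (default 15 nt).
#' @return list of [guide_rna] objects, named by record id.
#' @export
load_guides <- function(fasta_path, min_length = 15L) {
  svt_assert(file.exists(fasta_path), "io_error",
             "FASTA file not found: ", fasta_path)
  set <- Biostrings::readBStringSet(fasta_path)
  if (length(set) == 0L) svt_stop("empty_input", "no records in ", fasta_path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    seq <- dna_to_rna(as.character(set[[i]]))
    if (grepl("[^ACGU]", seq)) {
      svt_stop("parse_error", "non-nucleotide characters in record '",
               ids[i], "'")
    }
    svt_assert(nchar(seq) >= min_length, "parse_error",
               "record '", ids[i], "' shorter than ", min_length, " nt")
    out[[i]] <- guide_rna(ids[i], seq)
  }
  names(out) <- ids
  out
}

#' Write guides to FASTA
#'
#' @param guides list of [guide_rna].
#' @param path output file.
#' @param as_dna write `T` instead of `U` (genome FASTA convention).
#' @return `path`, invisibly.
#' @export
write_guides <- function(guides, path, as_dna = FALSE) {
  if (inherits(guides, "guide_rna")) guides <- list(guides)
  seqs <- vapply(guides, function(g) g$sequence, character(1L))
  if (as_dna) seqs <- rna_to_dna(seqs)
  set <- Biostrings::BStringSet(seqs)
  names(set) <- vapply(guides, function(g) g$id, character(1L))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Excise a processed fragment from a parent RNA
#'
#' Given a parent RNA (e.g., full-length vtRNA1-2) and a Dicer-dependent
#' fragment call, returns the fragment subsequence as a new guide whose
#' origin records the parent id and interval. This is how the ~22-24-nt
#' small vault RNA guide is derived from the 3' end of its parent.
#'
#' @param parent a [guide_rna] (or any list with `id` and `sequence`).
#' @param call a [fragment_call] or a 0-based half-open integer interval
#'   `c(start, end)` on the parent.
#' @param id id for the fragment (default `<parent>_frag`).
#' @return a [guide_rna] with `origin` set.
#' @export
extract_fragment_guide <- function(parent, call, id = NULL) {
  iv <- if (inherits(call, "fragment_call")) call$interval else as.numeric(call)
  svt_assert(length(iv) == 2L && iv[1L] < iv[2L], "coordinate_error",
             "fragment interval must be a non-empty [start, end)")
  L <- nchar(parent$sequence)
  svt_assert(iv[1L] >= 0 && iv[2L] <= L, "coordinate_error",
             "fragment interval [", iv[1L], ", ", iv[2L],
             ") outside parent of length ", L)
  if (is.null(id)) id <- paste0(parent$id, "_frag")
  guide_rna(id, substr(parent$sequence, iv[1L] + 1L, iv[2L]),
            origin = list(parent_id = parent$id, interval = as.integer(iv)))
}

#' Shuffle a region of a guide (scrambled-control construction)
#'
#' Permutes the bases inside a 1-based closed region with a seeded PRNG,
#' leaving everything outside untouched. The whole-guide base-composition
#' multiset is unchanged, which is the property that makes shuffled guides
#' valid null controls for target prediction.
#'
#' @param guide a [guide_rna].
#' @param region 1-based closed interval `c(from, to)` on the guide,
#'   length >= 2.
#' @param seed integer seed for the permutation.
#' @param id id for the control (default `<id>_shuf<from>_<to>`).
#' @return a [guide_rna] with the region permuted.
#' @export
shuffle_region <- function(guide, region, seed, id = NULL) {
  region <- as.integer(region)
  L <- nchar(guide$sequence)
  svt_assert(length(region) == 2L && region[1L] >= 1L && region[2L] <= L,
             "config_error",
             "shuffle region must be a 1-based closed interval within the guide")
  svt_assert(region[1L] <= region[2L], "config_error",
             "shuffle region has length 0")
  chars <- strsplit(guide$sequence, "", fixed = TRUE)[[1L]]
  idx <- region[1L]:region[2L]
  chars[idx] <- with_seed(seed, sample(chars[idx]))
  if (is.null(id)) id <- paste0(guide$id, "_shuf", region[1L], "_", region[2L])
  guide_rna(id, paste(chars, collapse = ""), origin = guide$origin)
}

#' Swap two equal-length blocks of a guide (swapped-seed control)
#'
#' Exchanges the 5' and 3' blocks (1-based closed intervals) of a guide,
#' e.g., to build a control whose seed and 3'-supplementary sequences trade
#' places. Blocks must be equal length, non-overlapping and in 5'->3' order;
#' composition and length are preserved and the operation is an involution.
#'
#' @param guide a [guide_rna].
#' @param block5,block3 1-based closed intervals `c(from, to)`.
#' @param id id for the control (default `<id>_swap`).
#' @return a [guide_rna].
#' @export
swap_ends <- function(guide, block5, block3, id = NULL) {
  block5 <- as.integer(block5); block3 <- as.integer(block3)
  L <- nchar(guide$sequence)
  ok_iv <- function(b) length(b) == 2L && b[1L] >= 1L && b[2L] <= L && b[1L] <= b[2L]
  svt_assert(ok_iv(block5) && ok_iv(block3), "config_error",
             "blocks must be 1-based closed intervals within the guide")
  svt_assert(diff(block5) == diff(block3), "config_error",
             "blocks must have equal length")
  svt_assert(block5[2L] < block3[1L], "config_error",
             "blocks must be non-overlapping and in 5'->3' order")
  chars <- strsplit(guide$sequence, "", fixed = TRUE)[[1L]]
  i5 <- block5[1L]:block5[2L]; i3 <- block3[1L]:block3[2L]
  tmp <- chars[i5]; chars[i5] <- chars[i3]; chars[i3] <- tmp
  if (is.null(id)) id <- paste0(guide$id, "_swap")
  guide_rna(id, paste(chars, collapse = ""), origin = guide$origin)
}

#' Base composition of a guide
#'
#' @param guide a [guide_rna] or RNA string.
#' @return named numeric vector of fractions over `A`, `C`, `G`, `U`,
#'   summing to 1.
#' @export
base_composition <- function(guide) {
  seq <- if (inherits(guide, "guide_rna")) guide$sequence else dna_to_rna(guide)
  svt_assert(nchar(seq) > 0L, "empty_input", "empty guide")
  check_rna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  counts <- vapply(RNA_BASES, function(b) sum(chars == b), numeric(1L))
  counts / length(chars)
}

#' Build the standard set of control guides
#'
#' Convenience wrapper producing the scrambled-5', scrambled-3' and swapped
#' controls used to probe seed and 3'-supplementary pairing requirements.
#' Defaults mirror the transfected constructs: 5' scramble over positions
#' 2-8 (the seed), 3' scramble over positions 12-18, and a swap of those two
#' blocks.
#'
#' @param guide a [guide_rna].
#' @param region5,region3 1-based closed intervals.
#' @param seed integer seed for the shuffles.
#' @return named list with elements `shuffle5`, `shuffle3`, `swap`.
#' @export
make_control_guides <- function(guide, region5 = c(2L, 8L),
                                region3 = c(12L, 18L), seed = 1L) {
  list(
    shuffle5 = shuffle_region(guide, region5, seed = child_seed(seed, 1L),
                              id = paste0(guide$id, "_shuffled5")),
    shuffle3 = shuffle_region(guide, region3, seed = child_seed(seed, 2L),
                              id = paste0(guide$id, "_shuffled3")),
    swap = swap_ends(guide, region5, region3)
  )
}

#' The printed vault RNA sequences bundled with the package
#'
#' Returns the three human vault RNA paralogues whose sequences ship with
#' the package (vtRNA1-1, vtRNA1-2, vtRNA1-3) as guides. vtRNA1-2 (89 nt)
#' is the parent of the Dicer-dependent 3'-end fragment studied by the
#' pipeline.
#'
#' @return named list of [guide_rna].
#' @export
vault_rnas <- function() {
  load_guides(system.file("extdata", "vtRNA.fa", package = "svtarget"))
}

#' Default small vault RNA guide (3'-terminal fragment of vtRNA1-2)
#'
#' The endogenous fragment is 22-24 nt long with unreported exact endpoints;
#' the package default is the 3'-terminal 24-mer of vtRNA1-2, configurable
#' via `length`.
#'
#' @param length fragment length in nt (default 24).
#' @return a [guide_rna] with origin on vtRNA1-2.
#' @export
svtRNA1_2 <- function(length = 24L) {
  parent <- vault_rnas()[["vtRNA1-2"]]
  L <- nchar(parent$sequence)
  svt_assert(is_count(length, 15L) && length <= L, "config_error",
             "fragment length must be in [15, ", L, "]")
  extract_fragment_guide(parent, c(L - length, L), id = "svtRNA1-2")
}
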