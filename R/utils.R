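## Internal helpers: classed errors, alphabet handling, seeded RNG scoping.

svt_stop <- function(class, ..., call. = FALSE) {
  msg <- paste0(...)
  cnd <- structure(
    class = c(paste0("svtarget_", class), "svtarget_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cnd)
}

svt_assert <- function(ok, class, ...) {
  if (!isTRUE(ok)) svt_stop(class, ...)
  invisible(TRUE)
}

RNA_BASES <- c("A", "C", "G", "U")

#' Sequence alphabet utilities
#'
#' The package stores genomic/annotation sequence as DNA text (`ACGT`) and
#' guide/duplex sequence as RNA text (`ACGU`); conversion at module
#' boundaries is explicit via these helpers. `rna_revcomp` returns the
#' reverse complement of an RNA string (vectorised).
#'
#' @param x character vector of sequences.
#' @return character vector of converted sequences.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

check_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    svt_stop("parse_error", "non-nucleotide characters in ", what,
             if (length(x) > 1L) paste0(" (record ", which(bad)[1L], ")") else "")
  }
  invisible(x)
}

#' @rdname dna_to_rna
#' @export
rna_revcomp <- function(x) {
  chartr("ACGU", "UGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE))
}

## Run `expr` under a fixed seed without disturbing the caller's RNG state.
## Mersenne-Twister + Rejection sampling is the package's single named PRNG.
with_seed <- function(seed, expr) {
  svt_assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
             "config_error", "rng seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", sample.kind = "Rejection")
  force(expr)
}

## Derive a stream-specific child seed below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 9973) %% 2147483629
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}
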