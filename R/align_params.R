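#' Duplex alignment parameters
#'
#' Scoring and threshold parameters for the guide-target duplex aligner.
#' Defaults mirror the miRanda-style settings `-sc 150 -en -30 -strict`:
#' a dimensionless score threshold of 150, a duplex free-energy ceiling of
#' -30 kcal/mol, and a strict seed requirement (guide positions 2-8
#' contiguously paired with no gaps, at most `max_seed_wobble` G:U wobbles
#' and no mismatches). Scoring constants follow the reference
#' implementation's published defaults: Watson-Crick match +5, G:U wobble
#' +1, mismatch -3, gap open -9, gap extend -4, with scores inside the seed
#' scaled by 4. All constants are configurable.
#'
#' @param score_threshold minimum alignment score (default 150, > 0).
#' @param energy_threshold maximum duplex free energy in kcal/mol
#'   (default -30, < 0).
#' @param strict_seed require perfect seed pairing (default `TRUE`).
#' @param seed_range 1-based closed guide-position interval of the seed
#'   (default `c(2, 8)`).
#' @param extension_boundary guide position up to which near-perfect pairing
#'   typically extends (default 18; informational, used in reports).
#' @param central_positions guide positions reported as the central pairing
#'   scheme (default `10:12`).
#' @param match_score,wobble_score,mismatch_penalty per-column scores.
#' @param gap_open,gap_extend affine gap costs; a run of k unpaired
#'   nucleotides costs `gap_open + gap_extend * (k - 1)`.
#' @param seed_scale multiplier applied to column scores within
#'   `seed_range` (>= 1).
#' @param max_target_loop maximum unpaired target-side run (nt, default 6).
#' @param max_guide_bulge maximum unpaired guide-side run (nt, default 3).
#' @param max_seed_wobble wobbles tolerated inside a strict seed (default 1).
#' @return object of class `align_params`.
#' @export
align_params <- function(score_threshold = 150, energy_threshold = -30,
                         strict_seed = TRUE, seed_range = c(2L, 8L),
                         extension_boundary = 18L, central_positions = 10:12,
                         match_score = 5, wobble_score = 1,
                         mismatch_penalty = -3, gap_open = -9, gap_extend = -4,
                         seed_scale = 4, max_target_loop = 6L,
                         max_guide_bulge = 3L, max_seed_wobble = 1L) {
  svt_assert(score_threshold > 0, "config_error", "score_threshold must be > 0")
  svt_assert(energy_threshold < 0, "config_error", "energy_threshold must be < 0")
  svt_assert(seed_scale >= 1, "config_error", "seed_scale must be >= 1")
  svt_assert(length(seed_range) == 2L && seed_range[1L] >= 2L &&
               seed_range[1L] <= seed_range[2L], "config_error",
             "seed_range must be a closed interval starting at position >= 2")
  svt_assert(mismatch_penalty <= 0 && gap_open <= 0 && gap_extend <= 0,
             "config_error", "penalties must be <= 0")
  svt_assert(is_count(max_target_loop, 1L) && is_count(max_guide_bulge, 0L),
             "config_error", "loop/bulge caps must be counts")
  structure(list(
    score_threshold = score_threshold, energy_threshold = energy_threshold,
    strict_seed = isTRUE(strict_seed), seed_range = as.integer(seed_range),
    extension_boundary = as.integer(extension_boundary),
    central_positions = as.integer(central_positions),
    match_score = match_score, wobble_score = wobble_score,
    mismatch_penalty = mismatch_penalty, gap_open = gap_open,
    gap_extend = gap_extend, seed_scale = seed_scale,
    max_target_loop = as.integer(max_target_loop),
    max_guide_bulge = as.integer(max_guide_bulge),
    max_seed_wobble = as.integer(max_seed_wobble)
  ), class = "align_params")
}

as_align_params <- function(params) {
  if (is.null(params)) return(align_params())
  svt_assert(inherits(params, "align_params"), "config_error",
             "params must be created by align_params()")
  params
}
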