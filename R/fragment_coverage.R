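#' Per-base read coverage over a reference
#'
#' Computes, for every position of a reference, the number of reads covering
#' it (the `genomecov -dz` convention), optionally scaled to reads per
#' million (RPM) by `1e6 / rpm_total`. Raw depths conserve mass: the sum of
#' depths equals the summed lengths of the overlapping reads.
#'
#' @param reads data.frame with 0-based half-open columns `start`, `end`
#'   (extra columns ignored), or a 2-column matrix.
#' @param reference_length reference length in nt.
#' @param rpm_total optional total mapped-read count used for RPM scaling.
#' @return object of class `coverage_profile`: list with `reference_id`,
#'   `values` (length `reference_length`), `scale` (1 when unscaled),
#'   `length`.
#' @export
per_base_coverage <- function(reads, reference_length, rpm_total = NULL,
                              reference_id = "ref") {
  reads <- as.data.frame(reads)
  if (nrow(reads) > 0L) {
    svt_assert(all(reads$start >= 0) && all(reads$end <= reference_length) &&
                 all(reads$end > reads$start), "coordinate_error",
               "reads must lie within [0, ", reference_length,
               ") with end > start")
  }
  cov <- if (nrow(reads) == 0L) {
    integer(reference_length)
  } else {
    ir <- IRanges::IRanges(start = reads$start + 1L, end = reads$end)
    as.integer(IRanges::coverage(ir, width = reference_length))
  }
  scale <- 1
  values <- as.numeric(cov)
  if (!is.null(rpm_total)) {
    svt_assert(is_count(rpm_total, 1L), "config_error",
               "rpm_total must be a positive count")
    scale <- 1e6 / rpm_total
    values <- values * scale
  }
  structure(list(reference_id = reference_id, values = values,
                 scale = scale, length = as.integer(reference_length)),
            class = "coverage_profile")
}

#' Read-length histogram with the small-RNA size filter
#'
#' Tabulates read lengths after discarding reads outside the
#' `[min_len, max_len]` window (default 15-30 nt, the standard small-RNA
#' library filter).
#'
#' @param reads data.frame with `start`, `end` (0-based half-open).
#' @param min_len,max_len inclusive length bounds.
#' @return named integer vector mapping retained lengths to counts.
#' @export
size_distribution <- function(reads, min_len = 15L, max_len = 30L) {
  svt_assert(min_len <= max_len, "config_error",
             "min_len must not exceed max_len")
  reads <- as.data.frame(reads)
  len <- reads$end - reads$start
  len <- len[len >= min_len & len <= max_len]
  if (length(len) == 0L) return(integer(0))
  tab <- table(len)
  stats::setNames(as.integer(tab), names(tab))
}

#' Call Dicer-dependent fragments from paired coverage profiles
#'
#' Identifies maximal runs of positions whose wild-type depth is at least
#' `rel_threshold` times the wild-type maximum (the dominant coverage
#' block), then annotates each run with the WT/KD mean-depth ratio. The KD
#' mean is floored at one raw read-equivalent (times the profile scale)
#' before division, a standard pseudocount that avoids division by zero. A
#' run is flagged `dicer_dependent` when the ratio reaches
#' `ratio_threshold`.
#'
#' @param profile_wt,profile_kd `coverage_profile`s over the same reference.
#' @param rel_threshold fraction of the WT maximum defining a block
#'   (default 0.5).
#' @param ratio_threshold WT/KD fold-change calling Dicer dependence
#'   (default 2).
#' @return list of `fragment_call` objects, disjoint and sorted; empty when
#'   the WT profile is all zero.
#' @export
call_fragment <- function(profile_wt, profile_kd, rel_threshold = 0.5,
                          ratio_threshold = 2) {
  svt_assert(inherits(profile_wt, "coverage_profile") &&
               inherits(profile_kd, "coverage_profile"),
             "config_error", "profiles must come from per_base_coverage()")
  svt_assert(profile_wt$length == profile_kd$length, "config_error",
             "profiles must cover the same reference length")
  svt_assert(rel_threshold > 0 && rel_threshold <= 1, "config_error",
             "rel_threshold must be in (0, 1]")
  wt <- profile_wt$values
  mx <- max(wt)
  if (mx <= 0) return(list())
  keep <- wt >= rel_threshold * mx
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  calls <- list()
  for (k in which(r$values)) {
    iv <- c(starts[k] - 1L, ends[k])  # 0-based half-open
    idx <- starts[k]:ends[k]
    mean_wt <- mean(wt[idx])
    mean_kd <- mean(profile_kd$values[idx])
    floor_kd <- max(mean_kd, 1 * profile_kd$scale)
    ratio <- mean_wt / floor_kd
    calls[[length(calls) + 1L]] <- structure(list(
      interval = as.integer(iv), mean_wt_rpm = mean_wt, mean_kd_rpm = mean_kd,
      depletion_ratio = ratio,
      dicer_dependent = ratio >= ratio_threshold
    ), class = "fragment_call")
  }
  calls
}

#' @export
print.fragment_call <- function(x, ...) {
  cat("<fragment_call> [", x$interval[1L], ", ", x$interval[2L],
      ")  WT/KD ratio ", format(round(x$depletion_ratio, 2)),
      if (x$dicer_dependent) "  (Dicer-dependent)", "\n", sep = "")
  invisible(x)
}

#' Write a coverage profile as 2-column TSV (position, depth)
#'
#' Mirrors `bedtools genomecov -dz` output: 0-based positions, one row per
#' position with non-zero depth.
#'
#' @param profile a `coverage_profile`.
#' @param path output path.
#' @export
write_coverage <- function(profile, path) {
  nz <- which(profile$values != 0)
  utils::write.table(
    data.frame(pos = nz - 1L, depth = profile$values[nz]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
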