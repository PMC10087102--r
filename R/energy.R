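## Nearest-neighbour duplex free-energy model (Turner-style, 37 C).
##
## The contract of this model is threshold behaviour and monotonicity
## (appending Watson-Crick pairs never raises the energy), not bit parity
## with any folding package. Stacking terms for Watson-Crick and G:U steps
## follow the widely tabulated nearest-neighbour values; loop terms use
## small-loop tables with logarithmic extrapolation.

## Rows: 5' pair of the step, columns: 3' pair; pair labelled by
## top-strand base (target, 5'->3') followed by bottom-strand base (guide).
.pair_levels <- c("AU", "CG", "GC", "UA", "GU", "UG")

.stack_table <- matrix(c(
  # AU     CG     GC     UA     GU     UG
  -0.93, -2.24, -2.08, -1.10, -0.55, -1.36,  # AU
  -2.11, -3.26, -2.36, -2.08, -1.41, -2.11,  # CG
  -2.35, -3.42, -3.26, -2.24, -1.53, -2.51,  # GC
  -1.33, -2.35, -2.11, -0.93, -1.00, -1.27,  # UA
  -1.27, -2.51, -2.11, -1.36, -0.50,  1.29,  # GU
  -1.00, -1.53, -1.41, -0.55,  0.30, -0.50   # UG
), nrow = 6L, byrow = TRUE, dimnames = list(.pair_levels, .pair_levels))

.duplex_init <- 4.09

## Bulge loops (one strand only) and internal loops (both strands), kcal/mol,
## indexed by total unpaired length; extrapolated as dG(n) = dG(6) +
## 1.08 * log(n/6) beyond the table.
.bulge_dg <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)
.internal_dg <- c(NA, 1.5, 1.6, 1.7, 1.8, 2.0)

.loop_dg <- function(table, n) {
  if (n <= length(table)) table[n] else table[length(table)] + 1.08 * log(n / 6)
}

#' Duplex free energy of a guide-target alignment
#'
#' Sums nearest-neighbour stacking terms over consecutive base-pair steps
#' and adds duplex initiation (+4.09 kcal/mol) plus bulge/internal-loop
#' penalties for unpaired runs between paired flanks (a mismatch column is a
#' 1x1 internal loop). An alignment with zero pairs has energy 0 by
#' definition (no duplex forms).
#'
#' @param alignment a [duplex_alignment].
#' @param guide,target_window optional sequences; defaults to those stored
#'   on the alignment.
#' @return free energy in kcal/mol (more negative = more stable).
#' @export
duplex_energy <- function(alignment, guide = NULL, target_window = NULL) {
  cols <- alignment$columns
  paired <- cols[cols$pair_type != "mismatch", , drop = FALSE]
  if (nrow(paired) == 0L) return(0)
  gseq <- if (is.null(guide)) alignment$guide_seq else
    if (inherits(guide, "guide_rna")) guide$sequence else dna_to_rna(guide)
  tchar <- strsplit(if (is.null(target_window)) alignment$target_seq else
    dna_to_rna(target_window), "", fixed = TRUE)[[1L]]
  gchar <- strsplit(gseq, "", fixed = TRUE)[[1L]]
  t0 <- alignment$target_span[1L]  # 0-based offset of target_seq

  ## order pairs along the target strand 5'->3' (guide positions descend)
  ord <- order(paired$target_pos)
  tp <- paired$target_pos[ord]
  gp <- paired$guide_pos[ord]
  svt_assert(all(diff(gp) < 0), "internal_error",
             "pairs are not chainable (guide/target order mismatch)")
  lab <- paste0(tchar[tp - t0], gchar[gp])
  svt_assert(all(lab %in% .pair_levels), "internal_error",
             "non-canonical pair in alignment")

  dg <- .duplex_init
  if (length(tp) > 1L) {
    for (k in seq_len(length(tp) - 1L)) {
      ut <- tp[k + 1L] - tp[k] - 1L   # unpaired target nts in between
      ug <- gp[k] - gp[k + 1L] - 1L   # unpaired guide nts in between
      if (ut == 0L && ug == 0L) {
        dg <- dg + .stack_table[lab[k], lab[k + 1L]]
      } else if (ut == 0L || ug == 0L) {
        dg <- dg + .loop_dg(.bulge_dg, ut + ug)
      } else {
        dg <- dg + .loop_dg(.internal_dg, ut + ug) +
          min(3, 0.5 * abs(ut - ug))
      }
    }
  }
  unname(dg)
}
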