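test_that("perfect complement of positions 2..L pairs fully (no loop)", {
  g <- svtRNA1_2()
  w <- rna_revcomp(substr(g$sequence, 2, 24))
  a <- align_window(g, w)
  expect_s3_class(a, "duplex_alignment")
  expect_equal(nrow(a$columns), 23L)
  expect_true(all(a$columns$pair_type == "WC"))
  expect_equal(a$target_span, c(0L, 23L))
  expect_equal(a$guide_span, c(2L, 24L))
  ## guide position 1 never appears; antiparallel orientation
  expect_false(1L %in% a$columns$guide_pos)
  expect_true(all(diff(a$columns$guide_pos) > 0))
  expect_true(all(diff(a$columns$target_pos) < 0))
  ## score arithmetic: 7 seed pairs x5x4 + 16 pairs x5
  expect_equal(a$score, 7 * 5 * 4 + 16 * 5)
})

test_that("a guide does not align against its own (non-complementary) sequence", {
  g <- svtRNA1_2()
  a <- align_window(g, g$sequence)
  if (!is.null(a)) expect_lt(a$score, 150)
})

test_that("alignment score matches the brute-force enumeration oracle", {
  params <- align_params()
  cpar <- svtarget:::.core_params(params)
  n_eq <- 0L
  svtarget:::with_seed(7, {
    for (trial in 1:500) {
      m <- sample(6:10, 1); n <- sample(8:14, 1)
      guide <- paste(sample(c("A","C","G","U"), m, TRUE), collapse = "")
      win <- paste(sample(c("A","C","G","U"), n, TRUE), collapse = "")
      brute <- svtarget:::.align_brute_score(guide, win, cpar, 2L)
      a <- align_window(guide, win, params)
      if (is.null(a)) {
        expect_lte(brute, 0)
        next
      }
      ## the DP alignment must re-score to its reported score (plain-R check)
      expect_equal(svtarget:::.score_columns(a$columns, params), a$score)
      expect_gte(a$score, brute - 1e-9)
      jumps <- sum(diff(a$columns$guide_pos) - 1L > 0 |
                     -diff(a$columns$target_pos) - 1L > 0)
      if (jumps <= 2L) {
        expect_equal(a$score, brute)
        n_eq <- n_eq + 1L
      }
    }
  })
  expect_gt(n_eq, 400L)  # the <=2-gap regime dominates at these sizes
})

test_that("orientation symmetry: reversing guide and window mirrors the score", {
  params <- align_params(seed_scale = 1)  # position weights break symmetry
  svtarget:::with_seed(13, {
    for (trial in 1:50) {
      guide <- paste(sample(c("A","C","G","U"), 12, TRUE), collapse = "")
      win <- paste(sample(c("A","C","G","U"), 20, TRUE), collapse = "")
      a <- align_window(guide, win, params)
      rev_s <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
      b <- align_window(rev_s(guide), rev_s(win), params)
      ## guide position 1 never pairs, so compare on interior-only windows
      if (!is.null(a) && !is.null(b) &&
          !(1 %in% (13 - a$columns$guide_pos)) &&
          !(1 %in% (13 - b$columns$guide_pos))) {
        expect_equal(a$score, b$score)
      }
    }
  })
})

test_that("threshold monotonicity: stricter thresholds never add sites", {
  fx <- fix_txome()
  seqs <- fx$planted$sequences[1:10]
  loose <- align_params(score_threshold = 120, energy_threshold = -20)
  strict <- align_params(score_threshold = 170, energy_threshold = -35)
  for (gene in names(seqs)) {
    s_loose <- sites_to_frame(scan_transcript(svtRNA1_2(), seqs[[gene]],
                                              loose, gene_id = gene))
    s_strict <- sites_to_frame(scan_transcript(svtRNA1_2(), seqs[[gene]],
                                               strict, gene_id = gene))
    expect_lte(nrow(s_strict), nrow(s_loose))
    if (nrow(s_strict) > 0)
      expect_true(all(paste(s_strict$start, s_strict$end) %in%
                        paste(s_loose$start, s_loose$end)))
  }
})

test_that("architecture classification reads loops, seed and central scheme", {
  g <- svtRNA1_2()
  w <- rna_revcomp(substr(g$sequence, 2, 24))

  rep0 <- classify_architecture(align_window(g, w))
  expect_true(rep0$seed_paired)
  expect_equal(rep0$loop_length, 0L)
  expect_equal(rep0$loop_sequence, "")
  expect_equal(rep0$alignment_length_target, 23L)
  expect_equal(rep0$pairing_extent, 24L)
  expect_equal(unname(rep0$central_scheme), c("WC", "WC", "WC"))

  ## canonical 5-nt target loop between the bases pairing positions 12 and 11
  for (loop in c("CAUCA", "CAUUA")) {
    wl <- paste0(substr(w, 1, 13), loop, substr(w, 14, 23))
    repl <- classify_architecture(align_window(g, wl))
    expect_equal(repl$loop_length, 5L)
    expect_equal(repl$alignment_length_target, 28L)
    expect_equal(repl$loop_sequence, loop)
    expect_equal(repl$loop_guide_anchor, c(11L, 12L))
  }

  ## hand-built 2-nt target bulge between positions pairing 14 and 13
  wb <- paste0(substr(w, 1, 11), "GG", substr(w, 12, 23))
  repb <- classify_architecture(align_window(g, wb))
  expect_equal(repb$loop_length, 2L)
  expect_equal(repb$loop_guide_anchor, c(13L, 14L))
})

test_that("scan_transcript returns planted sites and only passing sites", {
  cfg <- synthetic_config(rng_seed = 5L, n_genes = 3L,
                          site_architecture_mix = c(canonical_loop = 1,
                                                    no_loop = 0, seed_only = 0))
  g <- svtRNA1_2()
  tx <- generate_transcriptome(cfg)
  planted <- plant_sites(tx, g, cfg)
  for (i in seq_len(nrow(planted$sites))) {
    truth <- planted$sites[i, ]
    sites <- scan_transcript(g, planted$sequences[[truth$gene_id]],
                             gene_id = truth$gene_id)
    expect_equal(length(sites), 1L)
    expect_true(sites[[1]]$passes_thresholds)
    expect_equal(sites[[1]]$alignment$target_span,
                 c(truth$start, truth$end))
  }
})

test_that("seed-only complementarity scores below the 150 threshold", {
  cfg <- synthetic_config(rng_seed = 6L, n_genes = 5L,
                          site_architecture_mix = c(canonical_loop = 0,
                                                    no_loop = 0, seed_only = 1))
  g <- svtRNA1_2()
  planted <- plant_sites(generate_transcriptome(cfg), g, cfg)
  for (gene in names(planted$sequences)) {
    sites <- scan_transcript(g, planted$sequences[[gene]], gene_id = gene)
    truth <- planted$sites[planted$sites$gene_id == gene, ]
    found <- sites_to_frame(sites)
    expect_false(any(found$start == truth$start & found$end == truth$end))
  }
})

test_that("loop_consensus counts only 5-nt loops, keyed 5'->3'", {
  g <- svtRNA1_2()
  w <- rna_revcomp(substr(g$sequence, 2, 24))
  wl <- paste0(substr(w, 1, 13), "CAUCA", substr(w, 14, 23))
  site <- scan_transcript(g, paste0(random_rna(50, 1), rna_to_dna(wl),
                                    random_rna(50, 2)))[[1]]
  expect_equal(loop_consensus(list(site)), c(CAUCA = 1L))
  no_loop_site <- scan_transcript(g, paste0(random_rna(50, 3), rna_to_dna(w),
                                            random_rna(50, 4)))[[1]]
  expect_equal(loop_consensus(list(no_loop_site)), integer(0))
  expect_equal(loop_consensus(list()), integer(0))
})

test_that("align_params validates its invariants", {
  expect_error(align_params(score_threshold = 0), class = "svtarget_config_error")
  expect_error(align_params(energy_threshold = 5), class = "svtarget_config_error")
  expect_error(align_params(seed_scale = 0.5), class = "svtarget_config_error")
  expect_error(align_params(seed_range = c(1, 8)), class = "svtarget_config_error")
})
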