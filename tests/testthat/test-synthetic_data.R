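test_that("synthetic_config validates fields, naming the offender", {
  expect_error(synthetic_config(intron_fraction = 0.99), "intron_fraction",
               class = "svtarget_config_error")
  expect_error(synthetic_config(site_architecture_mix =
                                  c(canonical_loop = 0.5, no_loop = 0.5,
                                    seed_only = 0.1)),
               "site_architecture_mix", class = "svtarget_config_error")
  expect_error(synthetic_config(fragment_length_range = c(10, 24)),
               "fragment_length_range", class = "svtarget_config_error")
  expect_error(synthetic_config(fragment_length_range = c(22, 31)),
               "fragment_length_range", class = "svtarget_config_error")
  expect_error(synthetic_config(dicer_depletion_factor = 0.9),
               "dicer_depletion_factor", class = "svtarget_config_error")
  expect_error(synthetic_config(forced_overlap = 300),
               "forced_overlap", class = "svtarget_config_error")
  expect_error(synthetic_config(set_sizes = c(20000, 10)),
               "set_sizes", class = "svtarget_config_error")
})

test_that("degenerate structure: no introns means single-exon transcripts", {
  cfg <- synthetic_config(rng_seed = 2L, n_genes = 3L, intron_fraction = 0)
  tx <- generate_transcriptome(cfg)
  ann <- tx$annotation
  expect_equal(sum(ann$feature == "intron"), 0)
  for (g in unique(ann$gene_id))
    expect_equal(sum(ann$feature == "exon" & ann$gene_id == g), 1)
})

test_that("intron fraction of the emitted annotation matches the config", {
  fx <- fix_txome()  # 50 genes, intron_fraction 0.8
  ann <- fx$transcriptome$annotation
  ft <- build_feature_table(ann)
  gene_len <- sum(ann$end[ann$feature == "gene"] -
                    ann$start[ann$feature == "gene"])
  expect_equal(ft$total_length[["intron"]] / gene_len, 0.8, tolerance = 0.0625)
  ## sequences match annotated gene lengths
  expect_equal(unname(nchar(fx$transcriptome$sequences)),
               ann$end[ann$feature == "gene"])
})

test_that("generation is byte-identical for a fixed seed", {
  cfg <- synthetic_config(rng_seed = 9L, n_genes = 4L, n_reads = 200L,
                          universe_size = 100L, set_sizes = c(10L, 20L),
                          forced_overlap = 3L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  ## and a different seed changes the sequences
  d3 <- withr::local_tempdir()
  simulate_dataset(synthetic_config(rng_seed = 10L, n_genes = 4L,
                                    n_reads = 200L, universe_size = 100L,
                                    set_sizes = c(10L, 20L),
                                    forced_overlap = 3L), d3)
  expect_false(identical(readLines(file.path(d1, "transcriptome.fa")),
                         readLines(file.path(d3, "transcriptome.fa"))))
})

test_that("planted windows have the architecture-determined lengths", {
  fx <- fix_txome()
  sites <- fx$planted$sites
  w <- sites$end - sites$start
  expect_true(all(w[sites$architecture == "no_loop"] == 23))
  expect_true(all(w[sites$architecture == "canonical_loop"] == 28))
  expect_true(all(w[sites$architecture == "seed_only"] == 7))
  ## canonical loops carry one of the configured 5-mers
  expect_true(all(sites$loop_seq[sites$architecture == "canonical_loop"]
                  %in% c("CAUCA", "CAUUA")))
  ## every site lies inside its recorded feature class
  ft <- build_feature_table(fx$transcriptome$annotation)
  for (i in seq_len(nrow(sites))) {
    recs <- ft$records
    within <- recs$gene_id == sites$gene_id[i] &
      recs$feature == sites$feature[i] &
      recs$start <= sites$start[i] & recs$end >= sites$end[i]
    expect_true(any(within), label = paste("site", i, "inside its feature"))
  }
})

test_that("planted loop sequence appears verbatim on the target strand", {
  fx <- fix_txome()
  sites <- fx$planted$sites
  canon <- sites[sites$architecture == "canonical_loop", ][1, ]
  gseq <- fx$planted$sequences[[canon$gene_id]]
  L <- nchar(svtRNA1_2()$sequence)
  cut <- canon$start + (L - 11)
  expect_equal(dna_to_rna(substr(gseq, cut + 1, cut + 5)), canon$loop_seq)
})

test_that("architecture mix matches the configured fractions", {
  cfg <- synthetic_config(rng_seed = 303L, n_genes = 150L,
                          planted_sites_per_gene = 2L)
  planted <- plant_sites(generate_transcriptome(cfg), svtRNA1_2(), cfg)
  n <- nrow(planted$sites)
  emp <- table(planted$sites$architecture) / n
  for (arch in names(cfg$site_architecture_mix)) {
    expect_equal(unname(emp[[arch]]),
                 unname(cfg$site_architecture_mix[[arch]]),
                 tolerance = 3 / sqrt(n) /
                   max(cfg$site_architecture_mix[[arch]], 0.01))
  }
})

test_that("plant_sites rejects short guides", {
  cfg <- synthetic_config(rng_seed = 1L, n_genes = 1L)
  tx <- generate_transcriptome(cfg)
  expect_error(plant_sites(tx, guide_rna("short", "ACGUACGUACGUACGUAC"), cfg),
               class = "svtarget_config_error")  # 18 nt < 19
})
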