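## Shared fixtures, built in code and memoised for the test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

random_rna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else svtarget:::with_seed(seed, draw())
}

toy_guide <- function() guide_rna("toy", "GGACUACGUACGUACGUACGUACG")  # 24 nt

## A 50-gene transcriptome with one planted site per gene (default config).
fix_txome <- function() memo("txome", {
  cfg <- synthetic_config(rng_seed = 101L, n_genes = 50L)
  tx <- generate_transcriptome(cfg)
  planted <- plant_sites(tx, svtRNA1_2(), cfg)
  list(config = cfg, transcriptome = tx, planted = planted)
})

## The large recovery fixture: 200 genes x 2 sites, canonical/no-loop only,
## scanned with the wild-type guide and its shuffled controls. This is the
## expensive shared computation behind the acceptance properties.
fix_recovery <- function() memo("recovery", {
  cfg <- synthetic_config(
    rng_seed = 202L, n_genes = 200L, planted_sites_per_gene = 2L,
    site_architecture_mix = c(canonical_loop = 0.5, no_loop = 0.5,
                              seed_only = 0))
  guide <- svtRNA1_2()
  tx <- generate_transcriptome(cfg)
  planted <- plant_sites(tx, guide, cfg)
  controls <- make_control_guides(guide, seed = 11L)
  scan_all <- function(g) {
    out <- list()
    for (gene in names(planted$sequences))
      out <- c(out, scan_transcript(g, planted$sequences[[gene]],
                                    gene_id = gene))
    out
  }
  list(config = cfg, guide = guide, transcriptome = tx, planted = planted,
       controls = controls,
       sites_wt = scan_all(guide),
       sites_s5 = scan_all(controls$shuffle5),
       sites_s3 = scan_all(controls$shuffle3))
})

## How many of the planted loop-capable sites are recovered at their exact
## coordinates by a scan result.
recovered_count <- function(sites, truth) {
  found <- sites_to_frame(sites)
  hits <- 0L
  for (i in seq_len(nrow(truth))) {
    hits <- hits + any(found$gene_id == truth$gene_id[i] &
                         found$start == truth$start[i] &
                         found$end == truth$end[i])
  }
  hits
}
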