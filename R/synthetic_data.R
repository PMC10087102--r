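#' Configuration for the synthetic-data generator
#'
#' Describes the statistical world the generator emulates: a transcriptome
#' of intron-rich genes, guide-binding sites planted with the canonical
#' duplex architectures, a vault-gene small-RNA pileup with a
#' Dicer-dependent 3'-end fragment, and overlapping gene sets of
#' configurable sizes. Defaults encode the conditions the pipeline's
#' analyses assume: ~80% intronic gene bodies, 22-24-nt fragments (within
#' the 15-30-nt read-length filter window), a canonical-loop-dominated
#' architecture mix with loop sequences drawn from {CAUCA, CAUUA} at
#' 0.6/0.4, intron-biased site placement, and gene-set sizes 227/584 with a
#' forced overlap of 29 in a universe of 14,759.
#'
#' @param rng_seed integer master seed; all outputs are deterministic in it.
#' @param n_genes number of genes.
#' @param intron_fraction fraction of gene length that is intronic, in
#'   [0, 0.95] (default 0.8).
#' @param site_architecture_mix named fractions over `canonical_loop`,
#'   `no_loop`, `seed_only`; must sum to 1 within 1e-9.
#' @param planted_sites_per_gene sites planted per gene (default 1).
#' @param fragment_length_range `c(min, max)` fragment lengths in nt,
#'   within [15, 30] (default `c(22, 24)`).
#' @param dicer_depletion_factor WT/KD fragment-rate ratio, >= 1 (default 4).
#' @param universe_size,set_sizes,forced_overlap gene-set dimensions:
#'   `|setA| = set_sizes[1]`, `|setB| = set_sizes[2]`,
#'   `|setA intersect setB| = forced_overlap` exactly.
#' @param site_feature_mix named fractions over `intron`, `exon`, `UTR5`,
#'   `UTR3` giving where sites are planted (intron-biased by default).
#' @param loop_sequence_mix named fractions over the planted 5-nt loop
#'   sequences (RNA alphabet).
#' @param exonic_length_mean mean exonic (mature) length per gene in nt.
#' @param n_reads small-RNA reads per condition.
#' @param fragment_read_fraction fraction of WT reads that are 3'-end
#'   fragments (the rest are background reads elsewhere on the gene).
#' @param gc_content optional GC fraction for background sequence; `NULL`
#'   means i.i.d. uniform over the four bases.
#' @return validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(rng_seed = 1L,
                             n_genes = 50L,
                             intron_fraction = 0.8,
                             site_architecture_mix = c(canonical_loop = 0.7,
                                                       no_loop = 0.2,
                                                       seed_only = 0.1),
                             planted_sites_per_gene = 1L,
                             fragment_length_range = c(22L, 24L),
                             dicer_depletion_factor = 4,
                             universe_size = 14759L,
                             set_sizes = c(227L, 584L),
                             forced_overlap = 29L,
                             site_feature_mix = c(intron = 0.90, exon = 0.04,
                                                  UTR5 = 0.03, UTR3 = 0.03),
                             loop_sequence_mix = c(CAUCA = 0.6, CAUUA = 0.4),
                             exonic_length_mean = 1200L,
                             n_reads = 10000L,
                             fragment_read_fraction = 0.9,
                             gc_content = NULL) {
  svt_assert(is_count(rng_seed), "config_error", "invalid field: rng_seed")
  svt_assert(is_count(n_genes, 1L), "config_error", "invalid field: n_genes")
  svt_assert(is.numeric(intron_fraction) && intron_fraction >= 0 &&
               intron_fraction <= 0.95, "config_error",
             "invalid field: intron_fraction (must be in [0, 0.95])")
  for (mix in list(site_architecture_mix = site_architecture_mix,
                   site_feature_mix = site_feature_mix,
                   loop_sequence_mix = loop_sequence_mix)) TRUE
  svt_assert(setequal(names(site_architecture_mix),
                      c("canonical_loop", "no_loop", "seed_only")) &&
               abs(sum(site_architecture_mix) - 1) <= 1e-9 &&
               all(site_architecture_mix >= 0), "config_error",
             "invalid field: site_architecture_mix (fractions must sum to 1)")
  svt_assert(abs(sum(site_feature_mix) - 1) <= 1e-9 &&
               all(site_feature_mix >= 0) &&
               all(names(site_feature_mix) %in%
                     c("intron", "exon", "UTR5", "UTR3")), "config_error",
             "invalid field: site_feature_mix")
  svt_assert(abs(sum(loop_sequence_mix) - 1) <= 1e-9 &&
               all(nchar(names(loop_sequence_mix)) == 5L), "config_error",
             "invalid field: loop_sequence_mix (5-nt RNA keys summing to 1)")
  svt_assert(is_count(planted_sites_per_gene), "config_error",
             "invalid field: planted_sites_per_gene")
  flr <- as.integer(fragment_length_range)
  svt_assert(length(flr) == 2L && flr[1L] <= flr[2L] && flr[1L] >= 15L &&
               flr[2L] <= 30L, "config_error",
             "invalid field: fragment_length_range (must lie within [15, 30])")
  svt_assert(is.numeric(dicer_depletion_factor) &&
               dicer_depletion_factor >= 1, "config_error",
             "invalid field: dicer_depletion_factor (must be >= 1)")
  svt_assert(is_count(universe_size, 1L), "config_error",
             "invalid field: universe_size")
  ss <- as.integer(set_sizes)
  svt_assert(length(ss) == 2L && all(ss >= 0) &&
               all(ss <= universe_size), "config_error",
             "invalid field: set_sizes (n1, n2 must be <= universe_size)")
  svt_assert(is_count(forced_overlap) && forced_overlap <= min(ss) &&
               universe_size >= sum(ss) - forced_overlap, "config_error",
             "invalid field: forced_overlap (infeasible for the set sizes)")
  svt_assert(is.numeric(fragment_read_fraction) &&
               fragment_read_fraction > 0 && fragment_read_fraction <= 1,
             "config_error", "invalid field: fragment_read_fraction")
  svt_assert(is.null(gc_content) ||
               (gc_content > 0 && gc_content < 1), "config_error",
             "invalid field: gc_content")
  structure(list(
    rng_seed = as.integer(rng_seed), n_genes = as.integer(n_genes),
    intron_fraction = intron_fraction,
    site_architecture_mix = site_architecture_mix,
    planted_sites_per_gene = as.integer(planted_sites_per_gene),
    fragment_length_range = flr,
    dicer_depletion_factor = dicer_depletion_factor,
    universe_size = as.integer(universe_size), set_sizes = ss,
    forced_overlap = as.integer(forced_overlap),
    site_feature_mix = site_feature_mix,
    loop_sequence_mix = loop_sequence_mix,
    exonic_length_mean = as.integer(exonic_length_mean),
    n_reads = as.integer(n_reads),
    fragment_read_fraction = fragment_read_fraction,
    gc_content = gc_content
  ), class = "synthetic_config")
}

.base_probs <- function(config) {
  if (is.null(config$gc_content)) rep(0.25, 4) else
    c((1 - config$gc_content) / 2, config$gc_content / 2,
      config$gc_content / 2, (1 - config$gc_content) / 2)
}

.random_dna <- function(n, config) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = .base_probs(config)), collapse = "")
}

#' Generate a synthetic transcriptome
#'
#' Emits `n_genes` single-transcript genes in gene-local coordinates (each
#' gene is its own contig starting at 0, plus strand). Every gene has a
#' 100-nt 5' UTR, a 200-nt 3' UTR, and an exon/intron alternation whose
#' total intronic share matches `intron_fraction`; sequences are i.i.d.
#' random DNA. Deterministic for a fixed `rng_seed`.
#'
#' @param config a [synthetic_config].
#' @return list with `annotation` (internal data.frame, see [read_gtf()]),
#'   `sequences` (named DNA strings, pre-mRNA), and `transcripts` (spans
#'   for metagene profiles).
#' @export
generate_transcriptome <- function(config) {
  svt_assert(inherits(config, "synthetic_config"), "config_error",
             "config must come from synthetic_config()")
  u5 <- 100L; u3 <- 200L
  with_seed(child_seed(config$rng_seed, 10L), {
    rows <- list(); seqs <- character(0)
    for (i in seq_len(config$n_genes)) {
      g <- sprintf("g%04d", i)
      E <- max(600L, as.integer(round(stats::rnorm(1, config$exonic_length_mean,
                                                   config$exonic_length_mean / 6))))
      f <- config$intron_fraction
      I <- if (f > 0) as.integer(round(E * f / (1 - f))) else 0L
      if (I > 0L) {
        n_intron <- sample(2:4, 1L)
        grid <- seq(u5 + 50L, E - u3 - 50L, by = 50L)
        cuts <- sort(sample(grid, n_intron))
        extra <- I - 100L * n_intron
        w <- stats::runif(n_intron)
        ilen <- 100L + floor(extra * w / sum(w))
        ilen[n_intron] <- I - sum(ilen[-n_intron])
      } else {
        n_intron <- 0L; cuts <- integer(0); ilen <- integer(0)
      }
      ex_start_ex <- c(0L, cuts)              # exonic coordinates
      ex_end_ex <- c(cuts, E)
      shift <- cumsum(c(0L, ilen))            # genomic shift per exon
      ex_start <- ex_start_ex + shift
      ex_end <- ex_end_ex + shift
      L <- E + I
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, transcript_id = paste0(g, ".t1"),
        feature = c("gene", "transcript", rep("exon", n_intron + 1L),
                    "UTR5", "UTR3"),
        seqid = g,
        start = c(0L, 0L, ex_start, 0L, L - u3),
        end = c(L, L, ex_end, u5, L),
        strand = "+",
        tags = c(NA, "basic,CCDS", rep(NA, n_intron + 1L), NA, NA),
        stringsAsFactors = FALSE)
      seqs[g] <- .random_dna(L, config)
    }
    annotation <- do.call(rbind, rows)
    gene_rows <- annotation[annotation$feature == "gene", , drop = FALSE]
    list(annotation = annotation, sequences = seqs,
         transcripts = data.frame(gene_id = gene_rows$gene_id,
                                  start = gene_rows$start,
                                  end = gene_rows$end, strand = "+",
                                  stringsAsFactors = FALSE))
  })
}

## Target window (DNA) for one architecture of `guide` (RNA).
.planted_window <- function(guide_seq, architecture, loop_seq = NULL) {
  L <- nchar(guide_seq)
  full <- rna_to_dna(rna_revcomp(substr(guide_seq, 2L, L)))
  switch(architecture,
    no_loop = full,
    canonical_loop = {
      cut <- L - 11L  # after the base pairing guide position 12
      paste0(substr(full, 1L, cut), rna_to_dna(loop_seq),
             substr(full, cut + 1L, L - 1L))
    },
    seed_only = rna_to_dna(rna_revcomp(substr(guide_seq, 2L, 8L))),
    svt_stop("config_error", "unknown architecture: ", architecture))
}

#' Plant guide-binding sites into a synthetic transcriptome
#'
#' Overwrites transcript sequence with target windows complementary to the
#' guide: `no_loop` windows are the reverse complement of guide positions
#' 2..L (length L-1); `canonical_loop` windows additionally carry one
#' unpaired 5-nt insertion on the target strand between the bases pairing
#' guide positions 12 and 11 (length L+4), with the insertion drawn from
#' `loop_sequence_mix`; `seed_only` windows are complementary to the seed
#' (positions 2-8) alone. Placement follows `site_feature_mix` across
#' intron/exon/UTR intervals and records exact coordinates as ground truth.
#'
#' @param transcriptome output of [generate_transcriptome()].
#' @param guide a [guide_rna], length >= 19.
#' @param config a [synthetic_config].
#' @return list with `sequences` (modified) and `sites` (data.frame:
#'   gene_id, start, end 0-based half-open, feature, architecture,
#'   loop_seq, guide_id).
#' @export
plant_sites <- function(transcriptome, guide, config) {
  svt_assert(inherits(guide, "guide_rna"), "config_error",
             "guide must be a guide_rna")
  L <- nchar(guide$sequence)
  svt_assert(L >= 19L, "config_error",
             "guide must be >= 19 nt so that positions 2-18 exist")
  ann <- transcriptome$annotation
  seqs <- transcriptome$sequences
  arch_names <- names(config$site_architecture_mix)
  feat_names <- names(config$site_feature_mix)
  loop_names <- names(config$loop_sequence_mix)
  margin <- 5L

  ## per-gene candidate intervals per feature class
  feature_intervals <- function(g) {
    rows <- ann[ann$gene_id == g, , drop = FALSE]
    ex <- rows[rows$feature == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    out <- list()
    if (nrow(ex) > 1L)
      out$intron <- cbind(ex$end[-nrow(ex)], ex$start[-1L])
    utr_ir <- IRanges::IRanges()
    for (u in c("UTR5", "UTR3")) {
      ur <- rows[rows$feature == u, , drop = FALSE]
      if (nrow(ur) > 0L) {
        out[[u]] <- cbind(ur$start, ur$end)
        utr_ir <- c(utr_ir, IRanges::IRanges(ur$start + 1L, ur$end))
      }
    }
    cds <- IRanges::setdiff(IRanges::IRanges(ex$start + 1L, ex$end), utr_ir)
    if (length(cds) > 0L)
      out$exon <- cbind(IRanges::start(cds) - 1L, IRanges::end(cds))
    out
  }

  with_seed(child_seed(config$rng_seed, 20L), {
    sites <- list()
    for (g in names(seqs)) {
      ivs <- feature_intervals(g)
      used <- IRanges::IRanges()
      for (s in seq_len(config$planted_sites_per_gene)) {
        arch <- sample(arch_names, 1L, prob = config$site_architecture_mix)
        loop_seq <- if (arch == "canonical_loop")
          sample(loop_names, 1L, prob = config$loop_sequence_mix) else
            NA_character_
        window <- .planted_window(guide$sequence, arch, loop_seq)
        wlen <- nchar(window)
        placed <- FALSE
        for (try in seq_len(60L)) {
          feat <- sample(feat_names, 1L, prob = config$site_feature_mix)
          cand <- ivs[[feat]]
          if (is.null(cand)) next
          ok <- cand[, 2L] - cand[, 1L] >= wlen + 2L * margin
          if (!any(ok)) next
          row <- cand[sample(which(ok), 1L), ]
          start <- row[1L] + margin +
            sample.int(row[2L] - row[1L] - wlen - 2L * margin + 1L, 1L) - 1L
          iv <- IRanges::IRanges(start + 1L, start + wlen)
          if (length(IRanges::findOverlaps(
            iv, used, maxgap = 30L, type = "any")) > 0L) next
          used <- c(used, iv)
          substr(seqs[g], start + 1L, start + wlen) <- window
          sites[[length(sites) + 1L]] <- data.frame(
            gene_id = g, start = start, end = start + wlen, feature = feat,
            architecture = arch, loop_seq = loop_seq, guide_id = guide$id,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed)
          svt_stop("placement_error", "could not place a ", arch,
                   " site in gene ", g)
      }
    }
    list(sequences = seqs,
         sites = do.call(rbind, sites))
  })
}

#' Simulate small-RNA reads over a vault gene
#'
#' Produces BED-like read intervals on the vault gene's local coordinates
#' for two conditions. Fragment reads end at the gene's 3' terminus with
#' lengths from `fragment_length_range`; in WT a fraction
#' `fragment_read_fraction` of reads are fragments, and in the Dicer
#' knockdown that rate is divided by `dicer_depletion_factor`. Background
#' reads (lengths 15-30 nt) fall upstream, clear of the 3' window, so the
#' WT/KD coverage ratio over the 3' window estimates the depletion factor.
#'
#' @param vault_sequence the vault gene sequence (any alphabet; only its
#'   length is used), length >= max fragment length + 45.
#' @param config a [synthetic_config].
#' @return data.frame with `start`, `end` (0-based half-open), `length`,
#'   `condition` (`WT` or `DicerKD`).
#' @export
generate_reads <- function(vault_sequence, config) {
  svt_assert(config$dicer_depletion_factor >= 1, "config_error",
             "dicer_depletion_factor must be >= 1")
  L <- nchar(vault_sequence)
  rng <- config$fragment_length_range
  svt_assert(L >= rng[2L] + 45L, "config_error",
             "vault sequence too short for fragment + background layout")
  with_seed(child_seed(config$rng_seed, 30L), {
    one_condition <- function(cond, frag_rate) {
      n <- config$n_reads
      is_frag <- stats::runif(n) < frag_rate
      len <- integer(n); start <- integer(n)
      nf <- sum(is_frag)
      len[is_frag] <- sample(rng[1L]:rng[2L], nf, replace = TRUE)
      start[is_frag] <- L - len[is_frag]
      nb <- n - nf
      len[!is_frag] <- sample(15:30, nb, replace = TRUE)
      ## background stays >= 30 nt clear of the 3' end
      start[!is_frag] <- vapply(len[!is_frag], function(l)
        sample.int(L - 30L - l + 1L, 1L) - 1L, integer(1L))
      data.frame(start = start, end = start + len, length = len,
                 condition = cond, stringsAsFactors = FALSE)
    }
    rbind(one_condition("WT", config$fragment_read_fraction),
          one_condition("DicerKD",
                        config$fragment_read_fraction /
                          config$dicer_depletion_factor))
  })
}

#' The 3'-terminal window where fragments are planted
#'
#' @param vault_sequence vault gene sequence.
#' @param config a [synthetic_config].
#' @return 0-based half-open interval covered by every fragment read.
#' @export
fragment_truth_window <- function(vault_sequence, config) {
  L <- nchar(vault_sequence)
  c(L - config$fragment_length_range[1L], L)
}

#' Generate a gene universe and two overlapping gene sets
#'
#' Draws `setA` (size `set_sizes[1]`) and `setB` (size `set_sizes[2]`) from
#' a universe of `universe_size` ids such that their intersection has
#' exactly `forced_overlap` elements; membership is otherwise uniform at
#' random given the seed.
#'
#' @param config a [synthetic_config].
#' @return list with `universe`, `setA`, `setB` (character vectors).
#' @export
generate_gene_sets <- function(config) {
  N <- config$universe_size
  n1 <- config$set_sizes[1L]; n2 <- config$set_sizes[2L]
  k <- config$forced_overlap
  universe <- sprintf("gene%05d", seq_len(N))
  with_seed(child_seed(config$rng_seed, 40L), {
    perm <- sample(universe)
    shared <- perm[seq_len(k)]
    a_only <- perm[k + seq_len(n1 - k)]
    b_only <- perm[n1 + seq_len(n2 - k)]
    list(universe = universe,
         setA = sample(c(shared, a_only)),
         setB = sample(c(shared, b_only)))
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Generates the transcriptome, plants sites for `guide`, simulates vault
#' reads and gene sets, and writes: `annotation.gtf`, `transcriptome.fa`,
#' `reads_wt.bed` / `reads_kd.bed`, `universe.txt` / `setA.txt` /
#' `setB.txt`, and the planted-site truth table `planted_sites.tsv`.
#' Deterministic for a fixed config.
#'
#' @param config a [synthetic_config].
#' @param outdir output directory (created if needed).
#' @param guide guide to plant (default [svtRNA1_2()]).
#' @param vault_sequence sequence used for read simulation (default the
#'   bundled vtRNA1-2).
#' @return invisibly, a list of all generated objects.
#' @export
simulate_dataset <- function(config, outdir, guide = svtRNA1_2(),
                             vault_sequence = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(vault_sequence))
    vault_sequence <- vault_rnas()[["vtRNA1-2"]]$sequence
  txome <- generate_transcriptome(config)
  planted <- plant_sites(txome, guide, config)
  reads <- generate_reads(vault_sequence, config)
  sets <- generate_gene_sets(config)
  write_gtf(txome$annotation, file.path(outdir, "annotation.gtf"))
  write_fasta(planted$sequences, file.path(outdir, "transcriptome.fa"))
  write_bed_reads(reads[reads$condition == "WT", ],
                  file.path(outdir, "reads_wt.bed"), chrom = "vault")
  write_bed_reads(reads[reads$condition == "DicerKD", ],
                  file.path(outdir, "reads_kd.bed"), chrom = "vault")
  write_gene_list(sets$universe, file.path(outdir, "universe.txt"))
  write_gene_list(sets$setA, file.path(outdir, "setA.txt"))
  write_gene_list(sets$setB, file.path(outdir, "setB.txt"))
  write_tsv(planted$sites, file.path(outdir, "planted_sites.tsv"))
  invisible(list(transcriptome = txome, planted = planted, reads = reads,
                 gene_sets = sets))
}
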