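## small hand-built annotation: 2 genes on their own contigs
hand_annotation <- function() {
  rbind(
    data.frame(gene_id = "gA", transcript_id = c("gA.t1", "gA.t1", "gA.t1",
                                                 "gA.t1", "gA.t1", "gA.t1"),
               feature = c("gene", "transcript", "exon", "exon", "UTR5", "UTR3"),
               seqid = "gA", start = c(0, 0, 0, 200, 0, 280),
               end = c(300, 300, 100, 300, 40, 300), strand = "+",
               tags = c(NA, "basic", NA, NA, NA, NA),
               stringsAsFactors = FALSE),
    data.frame(gene_id = "gB", transcript_id = "gB.t1",
               feature = c("gene", "transcript", "exon"),
               seqid = "gB", start = c(0, 0, 0), end = c(150, 150, 150),
               strand = "+", tags = c(NA, "basic,CCDS", NA),
               stringsAsFactors = FALSE))
}

test_that("select_canonical picks max tags with lexicographic tie-break", {
  ann <- rbind(
    data.frame(gene_id = "g1", transcript_id = c("g1.tA", "g1.tB"),
               feature = "transcript", seqid = "g1", start = 0, end = 100,
               strand = "+", tags = c("basic,CCDS,appris_principal", "basic"),
               stringsAsFactors = FALSE),
    data.frame(gene_id = "g2", transcript_id = c("g2.tZ", "g2.tA"),
               feature = "transcript", seqid = "g2", start = 0, end = 100,
               strand = "+", tags = c("basic,CCDS", "basic,CCDS"),
               stringsAsFactors = FALSE))
  cm <- select_canonical(ann)
  expect_equal(cm[["g1"]], "g1.tA")
  expect_equal(cm[["g2"]], "g2.tA")  # tie -> lexicographically smaller

  ## chosen transcript always carries the max tag count (random annotations)
  svtarget:::with_seed(41, {
    for (i in 1:20) {
      n <- sample(2:5, 1)
      tags <- vapply(seq_len(n), function(j)
        paste(sample(default_tag_allowlist(), sample(0:4, 1)), collapse = ","),
        character(1))
      a <- data.frame(gene_id = "g", transcript_id = sprintf("t%02d", 1:n),
                      feature = "transcript", seqid = "g", start = 0, end = 10,
                      strand = "+", tags = tags, stringsAsFactors = FALSE)
      counts <- lengths(regmatches(tags, gregexpr("[^,]+", tags)))
      pick <- select_canonical(a)[["g"]]
      expect_equal(counts[a$transcript_id == pick], max(counts),
                   ignore_attr = TRUE)
    }
  })
})

test_that("build_feature_table derives introns, UTRs and junctions", {
  ft <- build_feature_table(hand_annotation())
  recs <- ft$records
  introns <- recs[recs$feature == "intron", ]
  expect_equal(nrow(introns), 1)
  expect_equal(c(introns$start, introns$end), c(100, 200))
  ## single-exon gene contributes no intron
  expect_false("gB" %in% introns$gene_id)
  ## exon class excludes UTR sequence
  exA <- recs[recs$feature == "exon" & recs$gene_id == "gA", ]
  expect_equal(sum(exA$end - exA$start), 200 - 40 - 20)
  ## junction windows clipped to the transcript
  j5 <- recs[recs$feature == "UTR5/exon" & recs$gene_id == "gA", ]
  expect_equal(c(j5$start, j5$end), c(30, 50))
  expect_error(build_feature_table(
    data.frame(gene_id = "g", transcript_id = "t",
               feature = c("transcript", "exon", "exon"), seqid = "g",
               start = c(0, 0, 40), end = c(100, 50, 100), strand = "+",
               tags = NA, stringsAsFactors = FALSE)),
    class = "svtarget_annotation_error")
})

test_that("feature lengths tile the gene span (generator oracle)", {
  fx <- fix_txome()
  ann <- fx$transcriptome$annotation
  ft <- build_feature_table(ann)
  recs <- ft$records[!ft$records$feature %in% c("UTR5/exon", "UTR3/exon"), ]
  for (g in unique(ann$gene_id)[1:10]) {
    span <- ann[ann$gene_id == g & ann$feature == "gene", ]
    expect_equal(sum(recs$end[recs$gene_id == g] -
                       recs$start[recs$gene_id == g]),
                 span$end - span$start)
  }
})

test_that("annotate_sites implements left-outer-join semantics", {
  ft <- build_feature_table(hand_annotation())
  sites <- data.frame(gene_id = c("gA", "gA", "gZ"),
                      start = c(120, 95, 10), end = c(140, 110, 30),
                      stringsAsFactors = FALSE)
  out <- annotate_sites(sites, ft)
  in_intron <- out[out$start == 120, ]
  expect_equal(in_intron$feature, "intron")
  spanning <- out[out$start == 95, ]
  expect_setequal(spanning$feature, c("exon", "intron"))  # one row per overlap
  orphan <- out[out$gene_id == "gZ", ]
  expect_equal(nrow(orphan), 1)
  expect_true(is.na(orphan$feature))

  ## join conservation: overlap pairs + orphans == rows
  expect_equal(nrow(out), 3 + 1)
})

test_that("feature_percentages normalises by feature length", {
  ft <- structure(list(records = NULL,
                       total_length = c(intron = 900, exon = 100)),
                  class = "feature_table")
  hits <- data.frame(feature = c(rep("intron", 9), rep("exon", 2)))
  pct <- feature_percentages(hits, ft)
  expect_equal(sum(pct), 100, tolerance = 1e-6)
  expect_equal(unname(pct["intron"]), 100 / 3, tolerance = 1e-9)
  expect_equal(unname(pct["exon"]), 200 / 3, tolerance = 1e-9)

  only <- feature_percentages(data.frame(feature = rep("exon", 5)), ft)
  expect_equal(unname(only["exon"]), 100)

  bad <- structure(list(records = NULL,
                        total_length = c(intron = 0, exon = 100)),
                   class = "feature_table")
  expect_error(feature_percentages(hits, bad),
               class = "svtarget_consistency_error")
})

test_that("uniform placements yield near-equal densities (oracle)", {
  ## one gene, features of very different lengths, uniform random sites
  ann <- hand_annotation()
  ft <- build_feature_table(ann[ann$gene_id == "gA", ])
  svtarget:::with_seed(55, {
    start <- sample(0:298, 3000, TRUE)
    sites <- data.frame(gene_id = "gA", start = start, end = start + 1)
  })
  hits <- annotate_sites(sites, ft)
  pct <- feature_percentages(hits, ft,
                             classes = c("intron", "exon", "UTR5", "UTR3"))
  ## uniform density: every class's share ~ 25% regardless of length
  expect_true(all(abs(pct - 25) < 5))
})

test_that("metagene_profile bins midpoints strand-aware", {
  tx <- data.frame(gene_id = c("plus", "minus"), start = 0, end = 1000,
                   strand = c("+", "-"), stringsAsFactors = FALSE)
  at_start <- data.frame(gene_id = "plus", start = 0, end = 10)
  mp <- metagene_profile(at_start, tx, n_bins = 100)
  expect_equal(mp$density[1], 1)
  expect_equal(sum(mp$density), 1)

  ## minus-strand site at the genomic end maps to bin 1
  at_end <- data.frame(gene_id = "minus", start = 990, end = 1000)
  expect_equal(metagene_profile(at_end, tx, 100)$density[1], 1)

  ## uniform sites flatten out
  svtarget:::with_seed(66, {
    s <- sample(0:990, 5000, TRUE)
    u <- data.frame(gene_id = "plus", start = s, end = s + 10)
  })
  mu <- metagene_profile(u, tx, n_bins = 20)
  expect_lt(max(abs(mu$density - 1 / 20)), 3 / sqrt(5000))

  expect_error(metagene_profile(data.frame(gene_id = "plus", start = 1500,
                                           end = 1510), tx),
               class = "svtarget_coordinate_error")
  expect_error(metagene_profile(data.frame(gene_id = "nope", start = 1,
                                           end = 2), tx),
               class = "svtarget_coordinate_error")
})

test_that("intron-biased planting yields intron-dominant percentages", {
  fx <- fix_txome()
  ft <- build_feature_table(fx$transcriptome$annotation)
  hits <- annotate_sites(fx$planted$sites[, c("gene_id", "start", "end")], ft)
  pct <- feature_percentages(hits, ft,
                             classes = c("intron", "exon", "UTR5", "UTR3"))
  expect_equal(sum(pct), 100, tolerance = 1e-6)
  expect_gt(pct[["intron"]], pct[["exon"]])
})
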