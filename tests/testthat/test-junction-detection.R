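# junction_detection: evidence extraction, clustering, context annotation.

test_that("junction pairs appear for an insertion and not for a control", {
  w <- make_small_world(seed = 14, depth = 60)
  idx <- build_index(w$ref$seqs, k = 15, extra = c(vector = w$vec$seq))
  aln <- map_reads(idx, w$reads)
  ev <- extract_junction_pairs(aln, "vector")
  expect_gt(nrow(ev), 10)
  expect_true(all(ev$chrom == "chr1"))
  expect_true(all(ev$side %in% c("left", "right")))
  # untransformed library: no junction pairs at all
  nt <- simulate_paired_reads(w$ref$seqs, read_sim_config(depth = 60, error_rate = 0,
                                                          seed = 99))
  aln0 <- map_reads(idx, nt)
  expect_equal(nrow(extract_junction_pairs(aln0, "vector")), 0)
})

test_that("pairs with the vector mate inside a masked interval are excluded", {
  targets <- c(chr1 = 10000L, vector = 6000L)
  a <- fake_alignments(
    list(qname = "p1", target = "chr1", pos = 500L, strand = "+", mate_of = 2L),
    list(qname = "p1", target = "vector", pos = 4300L, strand = "-", mate_of = 1L),
    targets = targets)
  mask <- data.frame(start = 4200L, end = 4800L)
  expect_equal(nrow(extract_junction_pairs(a, "vector", mask)), 0)
  expect_equal(nrow(extract_junction_pairs(a, "vector", NULL)), 1)
})

test_that("split reads give base-exact junction coordinates", {
  rv <- make_small_refvec(15)
  idx <- build_index(rv$ref$seqs, k = 15, extra = c(vector = rv$vec$seq))
  # junction chr1:p | vector:0 at a position with no coincidental
  # continuation (microhomology 0), read split 60 genome / 41 vector
  chr1 <- rv$ref$seqs[["chr1"]]
  p <- 6000
  while (substr(chr1, p + 1, p + 1) == substr(rv$vec$seq, 1, 1) ||
         substr(chr1, p, p) == substr(rv$vec$seq, 41, 41)) p <- p + 1
  jread <- paste0(substr(chr1, p - 59, p), substr(rv$vec$seq, 1, 41))
  aln <- map_reads(idx, jread)
  ev <- extract_split_reads(aln, idx, "vector", min_clip = 15)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$gpos, p)
  expect_equal(ev$side, "left")
  expect_equal(ev$vpos, 0)
  expect_equal(ev$precision, "exact")
  # clip below min_clip yields nothing
  short <- paste0(substr(chr1, 5908, 6000),
                  substr(rv$vec$seq, 1, 8))
  expect_equal(nrow(extract_split_reads(map_reads(idx, short), idx, "vector",
                                        min_clip = 15)), 0)
  # clip falling in the host-shared segment remaps ambiguously: no evidence
  hs <- rv$vec$host_segments
  amb <- paste0(substr(rv$ref$seqs[["chr1"]], 5940, 6000),
                substr(rv$vec$seq, hs$v_start + 101, hs$v_start + 140))
  eva <- extract_split_reads(map_reads(idx, amb), idx, "vector", min_clip = 15)
  expect_equal(nrow(eva), 0)
  expect_gte(attr(eva, "ambiguous_clips"), 1L)
  expect_error(extract_split_reads(aln, idx, "vector", min_clip = 5), "min_clip")
})

test_that("clustering separates loci, enforces support, and assigns status", {
  mk <- function(chrom, pos, side, n, exact = TRUE) {
    data.frame(kind = if (exact) "split_read" else "discordant_pair", chrom = chrom,
               cluster_pos = rep(pos, n), gpos = if (exact) rep(pos, n) else NA,
               side = side, vpos = NA_integer_,
               precision = if (exact) "exact" else "interval", qname = "q")
  }
  ev <- rbind(mk("chr1", 5000, "left", 6), mk("chr1", 5005, "right", 6),
              mk("chr1", 55000, "left", 4), mk("chr1", 55400, "right", 4),
              mk("chr2", 800, "left", 2))   # below min_support
  calls <- cluster_evidence(ev, window = 530, min_support = 3)
  expect_length(calls, 2)
  expect_equal(calls[[1]]$status, "both_ends")
  expect_equal(calls[[1]]$left_bp, 5000)
  expect_equal(calls[[1]]$right_bp, 5005)
  expect_equal(attr(calls, "dropped"), 1L)
  # one-sided evidence -> left_only
  calls2 <- cluster_evidence(mk("chr1", 9000, "left", 5))
  expect_equal(calls2[[1]]$status, "left_only")
  expect_true(is.na(calls2[[1]]$right_bp))
})

test_that("pair-only clusters fall back to interval-precision midpoints", {
  ev <- data.frame(kind = "discordant_pair", chrom = "chr1",
                   cluster_pos = c(4000, 4010, 3990), gpos = NA_integer_,
                   side = "left", vpos = NA_integer_, precision = "interval",
                   qname = "q")
  call <- cluster_evidence(ev, insert_mean = 265)[[1]]
  expect_equal(call$left_precision, "interval")
  expect_equal(call$left_bp, 4000 + round(265 / 2), tolerance = 10)
})

test_that("breakpoints stay within 2 bp under 1% substitution error", {
  errs <- integer(0)
  for (s in 1:20) {
    w <- make_small_world(seed = 100 + s, depth = 60, error_rate = 0.01)
    idx <- build_index(w$ref$seqs, k = 15, extra = c(vector = w$vec$seq))
    aln <- map_reads(idx, w$reads)
    ev <- rbind(extract_junction_pairs(aln, "vector"),
                extract_split_reads(aln, idx, "vector"))
    calls <- cluster_evidence(ev, vector_length = 6000)
    expect_length(calls, 1)
    errs <- c(errs, abs(calls[[1]]$left_bp - w$truth$left_bp),
              abs(calls[[1]]$right_bp - w$truth$right_bp))
  }
  # junction microhomology bounds attainable precision: the blunt chr1:6000
  # junction in this world has a fixed homology run, identical across
  # replicates, so the modal coordinate is within that run
  expect_true(mean(errs <= 2) >= 0.9)
  expect_true(all(errs <= 5))
})

test_that("annotate_context classifies exon, intron, and intergenic sites", {
  gff <- data.frame(seqid = "chr1", type = c("gene", "mRNA", "exon", "exon", "gene"),
                    start = c(1000L, 1000L, 1000L, 2500L, 6000L),
                    end = c(3000L, 3000L, 1500L, 3000L, 7000L),
                    strand = "+",
                    id = c("g1", "m1", "e1", "e2", "g2"),
                    name = c("MetAP2", NA, NA, NA, "PKS"),
                    parent = c(NA, "g1", "m1", "m1", NA))
  exon <- annotate_context(fake_locus_call(left = 1200, right = 1200), gff)
  expect_equal(exon$context$class, "exon")
  expect_equal(exon$context$gene, "MetAP2")
  intron <- annotate_context(fake_locus_call(left = 2000, right = 2000), gff)
  expect_equal(intron$context$class, "intron")
  inter <- annotate_context(fake_locus_call(left = 4000, right = 4000), gff)
  expect_equal(inter$context$class, "intergenic")
  expect_setequal(inter$context$neighbors$gene, c("MetAP2", "PKS"))
  off <- annotate_context(fake_locus_call(chrom = "chrZ", left = 10, right = 10), gff)
  expect_equal(off$context$class, "unannotated")
})

test_that("support multiplicity tracks tandem copy count", {
  # constructed: vector at 400x over a 100x genome -> multiplicity ~4
  vp <- fake_profile("vector", rep(400L, 6000))
  call <- fake_locus_call(left = 100, right = 100)
  expect_equal(support_multiplicity(call, vp, 100), 4, tolerance = 0.01)
  nocall <- fake_locus_call(left = 100, right = 100,
                            support = c(left_pairs = 0L, left_splits = 0L,
                                        right_pairs = 0L, right_splits = 0L))
  expect_true(is.na(support_multiplicity(nocall, vp, 100)))
})
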