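# coverage_stats: depth profiles, feature coverage and the copy-number
# estimator, replicon ratios, masking, integrity.

test_that("depth_profile counts only aligned bases", {
  targets <- c(chrA = 1000L)
  a <- fake_alignments(list(target = "chrA", pos = 100L), targets = targets)
  p <- depth_profile(a, "chrA")
  expect_equal(sum(p$depth), 101)
  expect_equal(sum(p$depth == 1), 101)
  # 40-bp soft clip: only 61 aligned positions contribute
  a2 <- fake_alignments(list(target = "chrA", pos = 100L, clip_left = 40L, alen = 61L),
                        targets = targets)
  expect_equal(sum(depth_profile(a2, "chrA")$depth), 61)
  # ambiguous records are excluded
  a3 <- fake_alignments(list(target = "chrA", pos = 0L, status = "ambiguous"),
                        targets = targets)
  expect_equal(sum(depth_profile(a3, "chrA")$depth), 0)
  expect_error(depth_profile(a, "nope"), "unknown target")
})

test_that("median depth of a simulated 100x library sits in the Poisson band", {
  g <- generate_reference(1, 20000, seed = 41)
  rd <- simulate_paired_reads(g, read_sim_config(depth = 100, error_rate = 0, seed = 3))
  idx <- build_index(g, k = 15)
  aln <- map_reads(idx, rd)
  attr(aln, "targets") <- c(chr1 = 20000L)
  p <- depth_profile(aln, "chr1")
  expect_gte(median(p$depth), 90)
  expect_lte(median(p$depth), 110)
})

test_that("feature coverage and copy number reproduce printed arithmetic", {
  # marker 809 bp / housekeeping 3527 bp rows
  m <- feature_coverage(mapped_length_bp = 680437, feature_length_bp = 809,
                        label = "G418")
  h <- feature_coverage(mapped_length_bp = 2944554, feature_length_bp = 3527,
                        label = "polB")
  expect_equal(round(m$C), 841)
  expect_equal(round(h$C), 835)
  cn <- estimate_copy_number(
    feature_coverage(mapped_length_bp = 1833049, feature_length_bp = 809),
    feature_coverage(mapped_length_bp = 1707102, feature_length_bp = 3527))
  expect_equal(cn$reported, 4.68, tolerance = 0.011)
  expect_equal(cn$copy_call, 5L)   # 4.68 rounds to 5; flagged uncertain
  expect_true(cn$uncertain)
  same <- feature_coverage(mapped_length_bp = 1000, feature_length_bp = 100)
  expect_equal(estimate_copy_number(same, same)$reported, 1.00)
  zero <- feature_coverage(mapped_length_bp = 0, feature_length_bp = 100)
  expect_equal(zero$C, 0)
  expect_error(estimate_copy_number(same, zero), "housekeeping")
  expect_error(feature_coverage(fake_profile("v", rep(1, 10)), 5, 5), "empty feature")
})

test_that("a simulated 2-copy tandem recovers copy number ~2", {
  ev <- insertion_event("chr1", 6000, copies = 2,
                        orientations = c("forward", "forward"))
  w <- make_small_world(seed = 10, event = ev, depth = 100)
  rep <- characterize_world(w)
  expect_gte(rep$copy_number$ratio, 1.8)
  expect_lte(rep$copy_number$ratio, 2.2)
  expect_equal(rep$copy_number$copy_call, 2L)
})

test_that("replicon copy ratio recovers organelle multiplicity", {
  # constructed profiles: nuclear at ~100x, organelle at ~400x
  p <- list(chr1 = fake_profile("chr1", rep(100L, 5000)),
            chr2 = fake_profile("chr2", rep(98L, 5000)),
            mito = fake_profile("mito", rep(400L, 2000)),
            empty = fake_profile("empty", rep(0L, 1000)))
  rr <- replicon_copy_ratio(p, nuclear = c("chr1", "chr2"))
  expect_equal(rr$ratio[rr$target == "mito"], 400 / 99, tolerance = 0.01)
  expect_equal(rr$ratio[rr$target == "empty"], 0)
  expect_equal(rr$ratio[rr$target == "chr1"], 100 / 99, tolerance = 0.01)
  expect_error(replicon_copy_ratio(p, nuclear = "nope"), "nuclear")

  # simulated: genome carries four copies of the organelle sequence
  ref <- generate_reference(2, c(8000, 3000), seed = 17)
  names(ref$seqs)[2] <- "mito"
  sim_genome <- c(ref$seqs["chr1"],
                  setNames(rep(ref$seqs["mito"], 4), paste0("m", 1:4)))
  rd <- simulate_paired_reads(sim_genome, read_sim_config(depth = 80, error_rate = 0,
                                                          seed = 4))
  idx <- build_index(setNames(ref$seqs, c("chr1", "mito")), k = 15)
  aln <- map_reads(idx, rd)
  attr(aln, "targets") <- c(chr1 = 8000L, mito = 3000L)
  prof <- list(chr1 = depth_profile(aln, "chr1"), mito = depth_profile(aln, "mito"))
  r <- replicon_copy_ratio(prof, nuclear = "chr1")
  expect_gte(r$ratio[r$target == "mito"], 3.6)
  expect_lte(r$ratio[r$target == "mito"], 4.4)
})

test_that("mask_shared_segments recovers declared host segments", {
  rv <- make_small_refvec(12)
  mask <- mask_shared_segments(rv$vec, rv$ref)
  hs <- rv$vec$host_segments
  expect_equal(nrow(mask), 1)
  expect_lte(abs(mask$start - hs$v_start), 5)
  expect_lte(abs(mask$end - hs$v_end), 5)
  novec <- build_vector(rv$ref, 4000)
  expect_equal(nrow(mask_shared_segments(novec, rv$ref)), 0)
})

test_that("integrity_report grades coverage and features", {
  rv <- make_small_refvec(13)
  mask <- mask_shared_segments(rv$vec, rv$ref)
  feats <- rv$vec$features
  # fully covered vector
  full <- fake_profile("vector", rep(50L, 6000))
  ir <- integrity_report(full, mask, feats)
  expect_gte(ir$covered_fraction, 0.99)
  expect_true(all(ir$feature_verdicts$verdict[feats$label %in% c("Ap", "marker")]
                  %in% "intact"))
  expect_true(ir$vector_present)
  # 5' interior loss (part of the ampicillin-resistance region absent),
  # marker untouched
  d <- rep(50L, 6000); d[301:800] <- 0L
  ir2 <- integrity_report(fake_profile("vector", d), mask, feats)
  expect_true(any(ir2$uncovered_segments$start >= 290 &
                    ir2$uncovered_segments$end <= 810))
  fv <- ir2$feature_verdicts
  expect_equal(fv$verdict[fv$label == "marker"], "intact")
  expect_equal(fv$verdict[fv$label == "Ap"], "partially deleted")
  # untransformed: coverage only inside the mask
  d3 <- rep(0L, 6000)
  hs <- rv$vec$host_segments
  d3[(hs$v_start + 1):hs$v_end] <- 60L
  ir3 <- integrity_report(fake_profile("vector", d3), mask, feats)
  expect_lte(ir3$covered_fraction, 0.02)
  expect_false(ir3$vector_present)
})
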