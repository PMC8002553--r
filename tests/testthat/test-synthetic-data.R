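# synthetic_data: reference/vector generation, insertion grammar, read
# simulation, contig emission.

test_that("generate_reference is deterministic, respects lengths and GC", {
  r1 <- generate_reference(2, c(20000, 15000), gc = 0.58, seed = 1)
  r2 <- generate_reference(2, c(20000, 15000), gc = 0.58, seed = 1)
  expect_identical(r1$seqs, r2$seqs)
  expect_identical(unname(nchar(r1$seqs)), c(20000L, 15000L))
  r3 <- generate_reference(2, c(20000, 15000), gc = 0.58, seed = 2)
  expect_false(identical(r1$seqs, r3$seqs))
  # empirical GC close to requested at 50 kb (frozen derived bound)
  g <- generate_reference(1, 50000, gc = 0.30, seed = 3)
  gcf <- mean(strsplit(g$seqs[[1]], "")[[1]] %in% c("G", "C"))
  expect_gte(gcf, 0.28); expect_lte(gcf, 0.32)
  expect_error(generate_reference(1, -5, seed = 1), "length")
  expect_error(generate_reference(1, 10000, gc = 1.2), "gc")
})

test_that("build_vector embeds host segments verbatim and validates features", {
  rv <- make_small_refvec(4)
  hs <- rv$vec$host_segments
  expect_equal(nrow(hs), 1)
  v_seg <- substr(rv$vec$seq, hs$v_start + 1, hs$v_end)
  g_seg <- substr(rv$ref$seqs[[hs$chrom]], hs$g_start + 1, hs$g_end)
  expect_identical(v_seg, g_seg)   # 100% identity self-check
  v0 <- build_vector(rv$ref, 3000)
  expect_equal(nrow(v0$host_segments), 0)
  expect_error(build_vector(rv$ref, 6000,
                            data.frame(label = c("a", "b"), start = c(0, 50),
                                       end = c(100, 150), strand = "+")),
               "overlapping")
  expect_error(build_vector(rv$ref, 6000,
                            host_segments = list(list(chrom = "chrX", start = 0,
                                                      end = 100, at = 0))),
               "not in reference")
})

test_that("make_filler shares no 20-mer with reference or vector", {
  rv <- make_small_refvec(5)
  f <- make_filler(55, rv$ref, rv$vec, seed = 9)
  expect_equal(nchar(f), 55)
  kmers <- substring(f, 1:36, 20:55)
  hay <- c(unname(rv$ref$seqs), rv$vec$seq)
  hay <- c(hay, revcomp(hay))
  hits <- vapply(kmers, function(k) any(grepl(k, hay, fixed = TRUE)), logical(1))
  expect_false(any(hits))
})

test_that("insertion_event enforces its invariants", {
  expect_error(insertion_event("chr1", 100, tsd_bp = 10, target_deletion_bp = 5),
               "cannot both")
  expect_error(insertion_event("chr1", 100, copies = 0), "copies")
  expect_error(insertion_event("chr1", 100, copies = 2, orientations = "forward"),
               "orientation")
})

test_that("apply_insertion does exact length bookkeeping and replays", {
  rv <- make_small_refvec(1)
  # clean blunt single copy: mutated length = original + vector length
  ins <- apply_insertion(rv$ref, rv$vec, insertion_event("chr1", 6000))
  expect_equal(nchar(ins$genome[["chr1"]]), 12000 + 6000)
  expect_true(replay_truth(ins$truth, rv$ref, rv$vec))
  expect_equal(ins$truth$left_bp, 6000)
  expect_equal(ins$truth$right_bp, 6000)

  # TSD: duplicated host block flanks the insert on both sides, direct
  tsd <- apply_insertion(rv$ref, rv$vec, insertion_event("chr1", 6000, tsd_bp = 518))
  m <- tsd$genome[["chr1"]]
  block <- substr(rv$ref$seqs[["chr1"]], 6001, 6518)
  expect_identical(substr(m, 6001, 6518), block)
  ie <- tsd$truth$insert_end
  expect_identical(substr(m, ie + 1, ie + 518), block)
  expect_equal(nchar(m), 12000 + 6000 + 518)
  expect_true(replay_truth(tsd$truth, rv$ref, rv$vec))

  # tandem with one reverse copy
  td <- apply_insertion(rv$ref, rv$vec,
                        insertion_event("chr1", 6000, copies = 2,
                                        orientations = c("forward", "reverse")))
  ev <- td$truth$events
  expect_true(any(ev$type == "tandem_multicopy" & ev$length == 2 &
                    ev$orientation == "+-"))
  expect_true(replay_truth(td$truth, rv$ref, rv$vec))

  # deletions and truncations change length accordingly
  del <- apply_insertion(rv$ref, rv$vec,
                         insertion_event("chr1", 6000, target_deletion_bp = 206,
                                         right_truncation_bp = 300))
  expect_equal(nchar(del$genome[["chr1"]]), 12000 - 206 + 6000 - 300)
  expect_true(replay_truth(del$truth, rv$ref, rv$vec))

  expect_error(apply_insertion(rv$ref, rv$vec,
                               insertion_event("chr1", 11999, tsd_bp = 100)),
               "bounds")
})

test_that("every preset truth replays byte-for-byte", {
  for (p in c("T3", "T6", "T12", "T14", "T16")) {
    w <- simulate_preset(p, seed = 3, depth = 1)  # depth irrelevant here
    expect_true(replay_truth(w$truth, w$reference, w$vector), label = p)
  }
})

test_that("simulate_paired_reads matches the expected pair count and insert law", {
  g <- generate_reference(1, 20000, seed = 11)
  cfg <- read_sim_config(depth = 100, error_rate = 0, seed = 5)
  rd <- simulate_paired_reads(g, cfg)
  expect_equal(length(rd$qname), round(20000 * 100 / 202))  # ~9901
  # error-free reads are exact (reverse-complemented) substrings
  for (i in c(1, 500, 2000)) {
    fr <- substr(g$seqs[[1]], rd$truth$f_start[i] + 1,
                 rd$truth$f_start[i] + rd$truth$f_len[i])
    expect_identical(rd$r1[i], substr(fr, 1, 101))
    expect_identical(rd$r2[i], revcomp(substr(fr, nchar(fr) - 100, nchar(fr))))
  }
  # truncated-normal insert: sample mean near 265 at n ~ 10k
  expect_gt(mean(rd$truth$f_len), 262)
  expect_lt(mean(rd$truth$f_len), 268)
  # determinism
  rd2 <- simulate_paired_reads(g, cfg)
  expect_identical(rd$r1, rd2$r1)
  expect_identical(rd$r2, rd2$r2)
})

test_that("degenerate depth warns and returns an empty library", {
  g <- generate_reference(1, 1000, seed = 1)
  expect_warning(rd <- simulate_paired_reads(g, read_sim_config(depth = 0.01, seed = 1)),
                 "0 fragments")
  expect_length(rd$qname, 0)
})

test_that("coverage of a 50-kb genome at 100x is within 5%", {
  g <- generate_reference(1, 50000, seed = 13)
  rd <- simulate_paired_reads(g, read_sim_config(depth = 100, error_rate = 0, seed = 2))
  ir <- IRanges::IRanges(start = c(rd$truth$f_start + 1L,
                                   rd$truth$f_start + rd$truth$f_len - 100L),
                         width = 101L)
  depth <- as.integer(IRanges::coverage(ir, width = 50000L))
  expect_gt(mean(depth), 95); expect_lt(mean(depth), 105)
  expect_gte(median(depth), 90); expect_lte(median(depth), 110)
})

test_that("emit_locus_contig arithmetic and chromosome-end clipping", {
  rv <- make_small_refvec(2)
  clean <- apply_insertion(rv$ref, rv$vec, insertion_event("chr1", 6000))
  expect_equal(unname(nchar(emit_locus_contig(clean$truth, 2000))), 6000 + 4000)
  tsd <- apply_insertion(rv$ref, rv$vec, insertion_event("chr1", 6000, tsd_bp = 100))
  expect_equal(unname(nchar(emit_locus_contig(tsd$truth, 0))), 6000 + 200)
  # adjacent deletion reaching the chromosome end: contig stops at the end
  t14 <- apply_insertion(rv$ref, rv$vec,
                         insertion_event("chr1", 2000, adjacent_deletion_bp = 10000))
  ctg <- emit_locus_contig(t14$truth, 2000)
  expect_identical(unname(ctg),
                   substr(t14$genome[["chr1"]], 1, nchar(t14$genome[["chr1"]])))
  expect_equal(t14$truth$status, "left_only")
})
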