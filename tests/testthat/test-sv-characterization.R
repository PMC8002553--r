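# sv_characterization: breakpoint reconciliation, filler classification,
# anchors, chaining, chain classification, adjacent-deletion scan.

test_that("reconcile_breakpoints follows the sign convention", {
  del <- reconcile_breakpoints(fake_locus_call(left = 1000, right = 1206))
  expect_equal(del$type, "target_deletion")
  expect_equal(del$length, 206)
  tsd <- reconcile_breakpoints(fake_locus_call(left = 5518, right = 5000))
  expect_equal(tsd$type, "target_site_duplication")
  expect_equal(tsd$length, 518)
  blunt <- reconcile_breakpoints(fake_locus_call(left = 700, right = 700))
  expect_equal(blunt$type, "blunt_junction")
  expect_equal(blunt$length, 0)
  unres <- reconcile_breakpoints(fake_locus_call(left = 100, right = 400,
                                                 lprec = "interval"))
  expect_equal(unres$type, "unresolved")
  expect_error(reconcile_breakpoints(fake_locus_call(left = 100)), "both")
})

test_that("TSD reconciliation is self-inverse over event sizes", {
  rv <- make_small_refvec(16)
  set.seed(7)
  for (x in c(6L, 10L, sample(11:600, 10), 518L, 600L)) {
    ins <- apply_insertion(rv$ref, rv$vec, insertion_event("chr1", 6000, tsd_bp = x))
    ev <- ins$truth$events
    expect_equal(ev$length[ev$type == "target_site_duplication"], x)
    rec <- reconcile_breakpoints(fake_locus_call(left = ins$truth$left_bp,
                                                 right = ins$truth$right_bp))
    expect_equal(rec$type, "target_site_duplication", label = paste("x =", x))
    expect_equal(rec$length, x)   # always x, never -x
  }
  # below the microhomology tolerance the junction is reported blunt, but
  # the simulator's own truth still carries the exact TSD
  for (x in c(1L, 4L)) {
    ins <- apply_insertion(rv$ref, rv$vec, insertion_event("chr1", 6000, tsd_bp = x))
    expect_equal(ins$truth$events$length[ins$truth$events$type == "target_site_duplication"], x)
  }
})

test_that("classify_filler assigns vector, genome, and unknown origins", {
  rv <- make_small_refvec(17)
  vdup <- substr(rv$vec$seq, 1482, 1543)   # 62-bp vector interval [1481,1543)
  fv <- classify_filler(vdup, rv$vec, rv$ref)
  expect_equal(fv$verdict, "vector_duplicate")
  expect_lte(abs(fv$source$start - 1481), 2)
  expect_lte(abs(fv$source$end - 1543), 2)
  gd <- classify_filler(substr(rv$ref$seqs[["chr1"]], 501, 580), rv$vec, rv$ref)
  expect_equal(gd$verdict, "genome_derived")
  expect_equal(gd$source$target, "chr1")
  unk <- classify_filler(make_filler(83, rv$ref, rv$vec, seed = 3), rv$vec, rv$ref)
  expect_equal(unk$verdict, "unknown_origin")
  micro <- classify_filler("ACGTAC", rv$vec, rv$ref)
  expect_equal(micro$verdict, "micro-insertion")
})

test_that("find_anchors handles identity, reverse complement, and inversions", {
  rv <- make_small_refvec(18)
  tgt <- c(vector = rv$vec$seq)
  id <- find_anchors(rv$vec$seq, tgt)
  expect_equal(nrow(id), 1)
  expect_equal(id$len, 6000)
  expect_equal(id$strand, "+")
  rc <- find_anchors(revcomp(rv$vec$seq), tgt)
  expect_equal(nrow(rc), 1)
  expect_equal(rc$strand, "-")
  # 171-bp inverted block: anchors break, inner anchor on minus strand
  v <- rv$vec$seq
  inv <- paste0(substr(v, 1, 1000), revcomp(substr(v, 1001, 1171)),
                substr(v, 1172, 6000))
  ai <- find_anchors(inv, tgt)
  minus <- ai[ai$strand == "-", ]
  expect_equal(nrow(minus), 1)
  expect_gte(minus$len, 171 - 2)
  expect_lte(abs(minus$tstart - 1000), 2)
})

test_that("chain DP matches exhaustive enumeration on small contigs", {
  # oracle: brute-force over anchor subsets under the same objective
  chain_oracle <- function(a, lambda = 0.01, max_overlap = 20L) {
    a <- a[order(a$cstart, a$cend), ]
    n <- nrow(a)
    best <- 0
    for (m in seq_len(2^n) - 1L) {
      sel <- which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0)
      if (!length(sel)) next
      ok <- TRUE; wt <- 0; last_end <- NULL; last_start <- -1
      for (i in sel) {
        if (!is.null(last_end)) {
          gap <- a$cstart[i] - last_end
          if (gap < -max_overlap || a$cstart[i] <= last_start) { ok <- FALSE; break }
          wt <- wt - (if (gap >= 0) lambda * gap else -gap)
        }
        wt <- wt + a$len[i]
        last_end <- a$cend[i]; last_start <- a$cstart[i]
      }
      if (ok) best <- max(best, wt)
    }
    best
  }
  rv <- make_small_refvec(19)
  # contig: genome flank + vector piece + genome flank (~4.5 kb, <= 5 kb)
  contig <- paste0(substr(rv$ref$seqs[["chr1"]], 2001, 3500),
                   substr(rv$vec$seq, 1, 1500),
                   substr(rv$ref$seqs[["chr1"]], 3501, 5000))
  targets <- c(rv$ref$seqs, vector = rv$vec$seq)
  anchors <- find_anchors(contig, targets)
  expect_lte(nrow(anchors), 12)
  ch <- chain_anchors(anchors)
  expect_equal(ch$weight, chain_oracle(anchors), tolerance = 1e-9)
  # single anchor: identity chain
  one <- find_anchors(rv$vec$seq, c(vector = rv$vec$seq))
  expect_equal(nrow(chain_anchors(one)$blocks), 1)
  # no anchors: unalignable
  expect_true(chain_anchors(find_anchors(strrep("ACGT", 100),
                                         c(vector = rv$vec$seq)))$unalignable)
})

test_that("classify_chain reads the preset architectures from contigs", {
  # identity contig: no calls
  rv <- make_small_refvec(20)
  targets <- c(rv$ref$seqs, vector = rv$vec$seq)
  idchain <- chain_anchors(find_anchors(substr(rv$ref$seqs[["chr1"]], 1, 5000), targets))
  expect_equal(nrow(classify_chain(idchain, substr(rv$ref$seqs[["chr1"]], 1, 5000),
                                   rv$vec, rv$ref$seqs)), 0)

  # tandem four copies, one inverted
  w12 <- simulate_preset("T12", seed = 4, depth = 1)
  t12 <- c(w12$reference$seqs, vector = w12$vector$seq)
  ch12 <- chain_anchors(find_anchors(w12$contig[[1]], t12))
  cs12 <- classify_chain(ch12, w12$contig[[1]], w12$vector, w12$reference$seqs)
  td <- cs12[cs12$type == "tandem_multicopy", ]
  expect_equal(nrow(td), 1)
  expect_equal(td$length, 4)
  expect_equal(td$orientation, "+-++")

  # inverted duplication at the vector 3' end, vector at the contig end
  w14 <- simulate_preset("T14", seed = 4, depth = 1)
  t14 <- c(w14$reference$seqs, vector = w14$vector$seq)
  ch14 <- chain_anchors(find_anchors(w14$contig[[1]], t14))
  cs14 <- classify_chain(ch14, w14$contig[[1]], w14$vector, w14$reference$seqs)
  invdup <- cs14[cs14$type == "inverted_duplication", ]
  expect_equal(nrow(invdup), 1)
  expect_lte(abs(invdup$length - 90), 5)
  expect_true("vector_at_contig_end" %in% attr(cs14, "annotations"))

  # T3: TSD + two fillers with origins
  w3 <- simulate_preset("T3", seed = 4, depth = 1)
  t3 <- c(w3$reference$seqs, vector = w3$vector$seq)
  ch3 <- chain_anchors(find_anchors(w3$contig[[1]], t3))
  cs3 <- classify_chain(ch3, w3$contig[[1]], w3$vector, w3$reference$seqs)
  expect_true(any(cs3$type == "target_site_duplication" &
                    abs(cs3$length - 518) <= 5))
  fil <- cs3[cs3$type == "filler_insertion", ]
  expect_true(any(abs(fil$length - 83) <= 5 & fil$detail == "unknown_origin"))
  expect_true(any(abs(fil$length - 62) <= 5 & grepl("vector_duplicate", fil$detail)))
})

test_that("truncated vectors are reported as truncations", {
  rv <- make_small_refvec(21)
  ins <- apply_insertion(rv$ref, rv$vec,
                         insertion_event("chr1", 6000, right_truncation_bp = 800))
  ctg <- emit_locus_contig(ins$truth, 1500)
  targets <- c(rv$ref$seqs, vector = rv$vec$seq)
  cs <- classify_chain(chain_anchors(find_anchors(ctg[[1]], targets)), ctg[[1]],
                       rv$vec, rv$ref$seqs)
  tr <- cs[cs$type == "vector_truncation", ]
  expect_equal(nrow(tr), 1)
  expect_lte(abs(tr$length - 800), 5)
  expect_equal(tr$detail, "3p")
})

test_that("scan_adjacent_deletion is median-relative and window-accurate", {
  d <- rep(100L, 60000); d[20001:40000] <- 0L
  profiles <- list(chr1 = fake_profile("chr1", d),
                   chr2 = fake_profile("chr2", rep(100L, 20000)))
  locus <- fake_locus_call(left = 20000, right = 20000)
  sv <- scan_adjacent_deletion(profiles, locus)
  expect_equal(sv$type, "adjacent_large_deletion")
  expect_lte(abs(sv$start - 20000), 1000)
  expect_lte(abs(sv$end - 40000), 1000)
  # clean locus: nothing adjacent
  clean <- list(chr1 = fake_profile("chr1", rep(100L, 60000)))
  expect_null(scan_adjacent_deletion(clean, locus))
  # uniform half-coverage chromosome: median-relative rule stays silent
  half <- list(chr1 = fake_profile("chr1", rep(50L, 60000)))
  expect_null(scan_adjacent_deletion(half, locus))
})
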