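# Shared fixtures, built in code at test time. The "small world" is a
# 22-kb two-chromosome genome with a 6-kb vector carrying one host-derived
# segment; cheap enough for per-test simulation.

small_world_plan <- function() {
  list(features = data.frame(label = c("Ap", "marker", "Luc"),
                             start = c(100L, 2000L, 3000L),
                             end = c(1000L, 2809L, 3900L),
                             strand = "+", stringsAsFactors = FALSE),
       host_segments = list(list(chrom = "chr2", start = 8000L, end = 8600L, at = 4200L)),
       marker = list(label = "marker", start = 2000L, end = 2809L),
       housekeeping = list(label = "hk", chrom = "chr2", start = 1000L, end = 4527L))
}

make_small_refvec <- function(seed = 1) {
  plan <- small_world_plan()
  ref <- generate_reference(2L, c(12000L, 10000L), gc = 0.55, seed = seed)
  vec <- build_vector(ref, 6000L, plan$features, plan$host_segments)
  list(ref = ref, vec = vec, plan = plan)
}

make_small_world <- function(seed = 1, event = NULL, depth = 80, error_rate = 0) {
  rv <- make_small_refvec(seed)
  if (is.null(event)) event <- insertion_event("chr1", 6000L)
  ins <- apply_insertion(rv$ref, rv$vec, event, seed = seed)
  cfg <- read_sim_config(depth = depth, error_rate = error_rate,
                         seed = derive_seed_t(seed))
  reads <- simulate_paired_reads(ins$genome, cfg)
  c(rv, list(event = event, genome = ins$genome, truth = ins$truth, reads = reads))
}

derive_seed_t <- function(seed) (seed * 131 + 7) %% 2147483647

# a minimal hand-built vt_alignments row set for coverage/evidence tests
fake_alignments <- function(..., targets) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    base <- list(qname = "r", target = NA_character_, pos = NA_integer_,
                 strand = "+", clip_left = 0L, clip_right = 0L, alen = 101L,
                 read_len = 101L, seq = strrep("A", 101L),
                 mate_target = NA_character_, mate_pos = NA_integer_,
                 proper = FALSE, status = "unique", mate_of = NA_integer_)
    as.data.frame(modifyList(base, r), stringsAsFactors = FALSE)
  }))
  class(df) <- c("vt_alignments", class(df))
  attr(df, "targets") <- targets
  df
}

fake_profile <- function(target, depth) {
  structure(list(target = target, depth = as.integer(depth),
                 windows = local({
                   ws <- seq(0L, length(depth) - 1L, by = 500L)
                   we <- pmin(ws + 500L, length(depth))
                   data.frame(start = ws, end = we,
                              mean_depth = vapply(seq_along(ws), function(i)
                                mean(depth[(ws[i] + 1L):we[i]]), numeric(1)))
                 })),
            class = "coverage_profile")
}

fake_locus_call <- function(chrom = "chr1", left = NA, right = NA,
                            lprec = "exact", rprec = "exact",
                            support = c(left_pairs = 5L, left_splits = 5L,
                                        right_pairs = 5L, right_splits = 5L)) {
  status <- if (!is.na(left) && !is.na(right)) "both_ends"
    else if (!is.na(left)) "left_only" else "right_only"
  structure(list(chrom = chrom, left_bp = left, right_bp = right,
                 left_precision = lprec, right_precision = rprec,
                 support = support, vector_end = c(left = NA, right = NA),
                 status = status, n_evidence = sum(support)),
            class = "locus_call")
}

characterize_world <- function(w, preset = NULL, ...) {
  contig <- if (!is.null(w$truth)) emit_locus_contig(w$truth, 2000L) else NULL
  characterize(w$reference %||% w$ref, w$vector %||% w$vec, reads = w$reads,
               contigs = contig,
               marker = w$marker %||% w$plan$marker,
               housekeeping = w$housekeeping %||% w$plan$housekeeping, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
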