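# Preset transformant worlds. Each preset realizes one observed insertion
# architecture, borrowing the published event sizes (518-bp target-site
# duplication; 206-bp target deletion with a 171-bp vector inversion and a
# 64-bp filler; a four-copy tandem with one inverse-orientation copy; a
# 90-bp inverted duplication next to a ~98-kb adjacent deletion at a
# chromosome end; a 10-bp target deletion with a 55-bp filler of external
# origin). Insertion coordinates are arbitrary (the source data carry them
# only graphically); event sizes are the point.

#' Names of the available simulation presets
#' @export
preset_names <- function() c("T3", "T6", "T12", "T14", "T16", "NT")

preset_chrom_lengths <- function(preset) {
  switch(preset,
         T14 = c(150000L, 20000L),
         T12 = c(30000L, 20000L),
         c(25000L, 20000L))
}

preset_vector_plan <- function() {
  list(
    length = 6000L,
    features = data.frame(
      label = c("Ap", "ubiP", "KanR", "Luc", "tubPT"),
      start = c(40L, 1150L, 2000L, 2900L, 4660L),
      end = c(1040L, 1950L, 2809L, 4600L, 5560L),
      strand = c("+", "+", "+", "+", "+"),
      stringsAsFactors = FALSE),
    # promoter/terminator segments copied verbatim from the host genome;
    # these recruit genomic reads in every line and drive the masking logic
    host_segments = list(
      list(chrom = "chr2", start = 10000L, end = 10800L, at = 1150L),
      list(chrom = "chr2", start = 12000L, end = 12900L, at = 4660L)),
    marker = list(label = "KanR", start = 2000L, end = 2809L),          # 809 bp
    housekeeping = list(label = "polB", chrom = "chr2",
                        start = 5000L, end = 8527L))                    # 3527 bp
}

preset_event <- function(preset) {
  switch(preset,
    T3 = insertion_event("chr1", 12000L, tsd_bp = 518L,
                         fillers = list(
                           list(side = "left", seq = NULL, len = 83L, origin = "unknown"),
                           list(side = "right", seq = NULL, origin = "vector-duplicate:1481-1543"))),
    T6 = insertion_event("chr1", 10000L, target_deletion_bp = 206L,
                         fillers = list(
                           list(side = "right", seq = NULL, len = 64L, origin = "unknown")),
                         internal_events = list(
                           list(type = "inversion", interval = c(40L, 211L)))),
    T12 = insertion_event("chr1", 15000L, copies = 4L,
                          orientations = c("forward", "reverse", "forward", "forward")),
    T14 = insertion_event("chr1", 52000L, adjacent_deletion_bp = 98000L,
                          internal_events = list(
                            list(type = "inverted_duplication", interval = c(5828L, 5918L)))),
    T16 = insertion_event("chr1", 8000L, target_deletion_bp = 10L,
                          fillers = list(
                            list(side = "left", seq = NULL, len = 55L, origin = "external"))),
    NT = NULL,
    stop("unknown preset: ", preset))
}

#' Build a complete preset transformant world
#'
#' Generates the reference genome, the vector template, the insertion event
#' (none for the untransformed "NT" control), the mutated genome with its
#' truth record, a simulated paired-end library, and a locus contig.
#'
#' @param preset one of [preset_names()].
#' @param seed integer master seed; all randomness derives from it.
#' @param depth simulated depth (x).
#' @param error_rate per-base substitution error rate.
#' @param flank_bp contig flank length.
#' @return a `vt_world`: list with `preset`, `reference`, `vector`, `event`,
#'   `genome`, `truth` (NULL for NT), `reads`, `contig`, and the
#'   marker/housekeeping definitions.
#' @export
simulate_preset <- function(preset = "T3", seed = 1L, depth = 100,
                            error_rate = 0.001, flank_bp = 2000L) {
  preset <- match.arg(preset, preset_names())
  plan <- preset_vector_plan()
  ref <- generate_reference(2L, preset_chrom_lengths(preset), gc = 0.58, seed = seed)
  vec <- build_vector(ref, plan$length, plan$features, plan$host_segments)
  event <- preset_event(preset)
  if (is.null(event)) {
    genome <- ref$seqs
    truth <- NULL
    contig <- NULL
  } else {
    ins <- apply_insertion(ref, vec, event, seed = derive_seed(seed, 3L))
    genome <- ins$genome
    truth <- ins$truth
    contig <- emit_locus_contig(truth, flank_bp)
  }
  cfg <- read_sim_config(depth = depth, error_rate = error_rate,
                         seed = derive_seed(seed, 7L))
  reads <- simulate_paired_reads(genome, cfg)
  structure(list(preset = preset, seed = as.integer(seed), reference = ref,
                 vector = vec, event = event, genome = genome, truth = truth,
                 reads = reads, contig = contig,
                 marker = plan$marker, housekeeping = plan$housekeeping),
            class = "vt_world")
}

#' @export
print.vt_world <- function(x, ...) {
  cat(sprintf("<vt_world> preset %s (seed %d): %d chromosome(s), %d read pairs%s\n",
              x$preset, x$seed, length(x$reference$seqs), length(x$reads$qname),
              if (is.null(x$truth)) ", untransformed" else
                sprintf(", insertion at %s:%s", x$truth$chrom,
                        format(x$truth$left_bp + 1, big.mark = ","))))
  invisible(x)
}

#' Expected structural-variant set of a preset
#'
#' The (type, length) pairs a successful characterization must recover,
#' read from the truth record. Used by [verify_against_truth()] and the
#' acceptance tests.
#'
#' @param truth a `vt_truth`.
#' @return data.frame with `type` and `length`.
#' @export
expected_sv_set <- function(truth) {
  ev <- truth$events
  keep <- !(ev$type %in% c("vector_truncation"))
  data.frame(type = ev$type[keep], length = ev$length[keep])
}
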