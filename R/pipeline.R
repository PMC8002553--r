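# Orchestration: simulate -> map -> profile -> detect -> characterize, as a
# configured, logged run producing a consolidated per-line report, plus
# truth verification for simulated fixtures.

default_params <- function() {
  list(k = 15L,              # seed length (toy fixtures; real-scale would use 20)
       seed_step = 5L, min_score = 20L,
       min_clip = 15L,       # smallest informative soft clip
       window = 530L,        # junction cluster gap: 2 x insert mean
       min_support = 3L,     # evidence items per reported locus
       min_depth = 5L,       # depth for a vector position to count covered
       del_frac = 0.1, min_del_len = 10000L, scan_window = 1000L,
       insert_mean = 265, min_anchor_len = 50L,
       vector_name = "vector")
}

#' Characterize one transformant line
#'
#' Runs the full analysis against in-memory objects: joint mapping of the
#' library to genome + vector, mapping statistics, depth profiles, homology
#' masking and vector integrity, marker/housekeeping copy number, junction
#' evidence extraction and locus calling, junction-variant reconciliation,
#' contig-level anchor-chain classification, and the adjacent large
#' deletion scan.
#'
#' @param reference a `vt_reference` (or named character vector).
#' @param vector a `vt_vector`.
#' @param reads a `vt_reads` library (ignored when `alignments` given).
#' @param alignments optional precomputed `vt_alignments`.
#' @param contigs optional named character vector of locus contigs.
#' @param gff optional annotation (path or [read_gff()] data.frame).
#' @param marker list(label, start, end): selectable-marker interval on the
#'   vector.
#' @param housekeeping list(label, chrom, start, end): single-copy
#'   housekeeping gene on the genome.
#' @param params parameter overrides over `default_params()`.
#' @param line_name label for the report.
#' @return a `line_report`.
#' @export
characterize <- function(reference, vector, reads = NULL, alignments = NULL,
                         contigs = NULL, gff = NULL,
                         marker = list(label = "marker", start = 2000L, end = 2809L),
                         housekeeping = list(label = "housekeeping", chrom = "chr2",
                                             start = 5000L, end = 8527L),
                         params = list(), line_name = "line") {
  p <- modifyList(default_params(), params)
  refseqs <- if (inherits(reference, "vt_reference")) reference$seqs else reference
  vname <- p$vector_name
  targets <- c(refseqs, setNames(vector$seq, vname))
  idx <- build_index(targets, k = p$k)
  if (is.null(alignments)) {
    stopifnot_msg(!is.null(reads), "either reads or alignments must be provided")
    if (!is.null(reads$config$insert_mean)) p$insert_mean <- reads$config$insert_mean
    aln <- map_reads(idx, reads, seed_step = p$seed_step, min_score = p$min_score)
  } else aln <- alignments
  attr(aln, "targets") <- setNames(str_len(targets), names(targets))
  n_pairs <- sum(!is.na(aln$mate_of) & aln$mate_of > seq_len(nrow(aln)))
  if (n_pairs == 0) n_pairs <- nrow(aln)

  stats <- compute_mapping_stats(aln, reference_length_bp = sum(str_len(refseqs)),
                                 total_raw_reads = n_pairs)

  profiles <- lapply(names(targets), function(t) depth_profile(aln, t))
  names(profiles) <- names(targets)
  nuclear <- setdiff(names(targets), vname)

  mask <- mask_shared_segments(vector, refseqs)
  integrity <- integrity_report(profiles[[vname]], mask, vector$features,
                                min_depth = p$min_depth)
  marker_stat <- feature_coverage(profiles[[vname]], marker$start, marker$end,
                                  label = marker$label)
  hk_stat <- feature_coverage(profiles[[housekeeping$chrom]], housekeeping$start,
                              housekeeping$end, label = housekeeping$label)
  copy_number <- if (hk_stat$C > 0) estimate_copy_number(marker_stat, hk_stat) else NULL

  # robust genome baseline: median of nonzero window means
  wm <- unlist(lapply(profiles[nuclear], function(pr) pr$windows$mean_depth))
  genome_baseline <- median(wm[wm > 0])

  ev_pairs <- extract_junction_pairs(aln, vname, mask)
  ev_splits <- extract_split_reads(aln, idx, vname, mask, min_clip = p$min_clip)
  evidence <- rbind(ev_pairs, ev_splits)
  calls <- cluster_evidence(evidence, window = p$window, min_support = p$min_support,
                            insert_mean = p$insert_mean,
                            vector_length = str_len(vector$seq))
  if (!is.null(gff)) calls[] <- lapply(calls, annotate_context, annotation = gff)

  sv <- empty_sv()
  for (call in calls) {
    if (call$status == "both_ends") sv <- rbind(sv, reconcile_breakpoints(call))
    adj <- scan_adjacent_deletion(profiles[nuclear], call, window = p$scan_window,
                                  del_frac = p$del_frac, min_del_len = p$min_del_len)
    if (!is.null(adj)) sv <- rbind(sv, adj)
  }
  multiplicities <- vapply(calls, support_multiplicity, numeric(1),
                           vector_profile = profiles[[vname]],
                           genome_mean_depth = genome_baseline, mask = mask)

  contig_sv <- list()
  chains <- list()
  if (!is.null(contigs)) {
    for (cn in names(contigs)) {
      anchors <- find_anchors(contigs[[cn]], targets, min_len = p$min_anchor_len)
      chain <- chain_anchors(anchors)
      chains[[cn]] <- chain
      cs <- classify_chain(chain, contigs[[cn]], vector, refseqs, vector_name = vname)
      if (nrow(cs)) contig_sv[[cn]] <- cs
    }
  }
  sv_contig <- if (length(contig_sv)) do.call(rbind, contig_sv) else empty_sv()

  structure(list(line = line_name,
                 mapping_stats = stats,
                 copy_number = copy_number,
                 integrity = integrity,
                 mask = mask,
                 locus_calls = calls,
                 locus_multiplicity = multiplicities,
                 sv_junction = sv,
                 sv_contig = sv_contig,
                 chains = chains,
                 genome_baseline = genome_baseline,
                 params = p,
                 config_hash = config_hash(p),
                 n_pairs = n_pairs),
            class = "line_report")
}

#' @export
print.line_report <- function(x, ...) {
  cat(sprintf("== line report: %s (config %s) ==\n", x$line, x$config_hash))
  print(x$mapping_stats)
  if (!is.null(x$copy_number)) print(x$copy_number)
  print(x$integrity)
  print(x$locus_calls)
  svs <- rbind(x$sv_junction, x$sv_contig)
  if (nrow(svs)) {
    cat(sprintf("structural variants (%d):\n", nrow(svs)))
    for (i in seq_len(nrow(svs)))
      cat(sprintf("  %-24s %-6s %9s  %6d bp  [%s]\n", svs$type[i], svs$target[i],
                  format(svs$start[i] + 1, big.mark = ","), svs$length[i],
                  svs$provenance[i]))
  } else cat("structural variants: none\n")
  invisible(x)
}

#' All structural variant calls of a report, junction and contig provenance
#' @param report a `line_report`.
#' @export
report_sv_calls <- function(report) rbind(report$sv_junction, report$sv_contig)

report_to_list <- function(report) {
  calls <- lapply(report$locus_calls, function(c) {
    list(chrom = c$chrom, left_bp = c$left_bp, right_bp = c$right_bp,
         left_precision = c$left_precision, right_precision = c$right_precision,
         support = as.list(c$support), status = c$status,
         vector_end = as.list(c$vector_end),
         context = if (!is.null(c$context)) c$context[c("class", "gene")] else NULL)
  })
  list(line = report$line, config_hash = report$config_hash,
       mapping_stats = unclass(report$mapping_stats),
       copy_number = if (!is.null(report$copy_number))
         report$copy_number[c("ratio", "reported", "copy_call", "uncertain")] else NULL,
       integrity = list(covered_fraction = report$integrity$covered_fraction,
                        vector_present = report$integrity$vector_present,
                        feature_verdicts = report$integrity$feature_verdicts,
                        masked_intervals = report$integrity$masked_intervals,
                        uncovered_segments = report$integrity$uncovered_segments),
       locus_calls = calls,
       locus_multiplicity = report$locus_multiplicity,
       sv_calls = report_sv_calls(report),
       params = report$params)
}

#' Serialize a line report to JSON
#' @param report a `line_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Simulate a preset fixture to disk
#'
#' Writes reference and mutated genome FASTA, paired FASTQ, the locus
#' contig, true breakpoints as BED, the truth as JSON, and a ready-made
#' characterize config pointing at the files.
#'
#' @param preset preset name (see [preset_names()]).
#' @param out_dir output directory.
#' @param seed master seed.
#' @param depth,error_rate library parameters.
#' @param force overwrite an existing non-empty directory.
#' @return the world object, invisibly.
#' @export
run_simulate <- function(preset = "T3", out_dir, seed = 1L, depth = 100,
                         error_rate = 0.001, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory exists and is non-empty (use force = TRUE)", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- simulate_preset(preset, seed = seed, depth = depth, error_rate = error_rate)
  fp <- function(x) file.path(out_dir, x)
  write_fasta(w$reference$seqs, fp("reference.fasta"))
  write_fasta(setNames(w$vector$seq, "vector"), fp("vector.fasta"))
  write.table(w$vector$features, fp("vector_features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(w$genome, fp("genome.fasta"))
  write_fastq(w$reads, fp("reads_1.fastq"), fp("reads_2.fastq"))
  truth_json <- fp("truth.json")
  if (!is.null(w$truth)) {
    write_fasta(w$contig, fp("contig.fasta"))
    t <- w$truth
    jsonlite::write_json(list(preset = preset, seed = seed, chrom = t$chrom,
                              left_bp = t$left_bp, right_bp = t$right_bp,
                              status = t$status, copies = t$copies,
                              orientations = t$orientations, events = t$events),
                         truth_json, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    bed <- data.frame(chrom = t$chrom,
                      start = c(t$left_bp, if (!is.na(t$right_bp)) t$right_bp),
                      name = c("left_breakpoint", if (!is.na(t$right_bp)) "right_breakpoint"))
    write.table(data.frame(bed$chrom, bed$start, bed$start + 1L, bed$name),
                fp("breakpoints.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    jsonlite::write_json(list(preset = preset, seed = seed, events = list()),
                         truth_json, auto_unbox = TRUE, null = "null", pretty = TRUE)
  }
  cfg <- list(paths = list(reference = "reference.fasta", vector = "vector.fasta",
                           vector_features = "vector_features.tsv",
                           reads1 = "reads_1.fastq", reads2 = "reads_2.fastq",
                           contigs = if (!is.null(w$truth)) "contig.fasta" else NULL,
                           truth = "truth.json"),
              marker = w$marker, housekeeping = w$housekeeping,
              params = list(insert_mean = w$reads$config$insert_mean),
              line_name = preset, seed = seed)
  jsonlite::write_json(cfg, fp("characterize_config.json"), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(w)
}

#' Run characterization from a config file
#'
#' The config is a single JSON file with module-namespaced parameters (see
#' the file written by [run_simulate()]); relative paths resolve against
#' the config's directory. Host-segment annotations for the vector are
#' rediscovered by homology masking, so only sequences are needed.
#'
#' @param config_path path to a characterize config JSON.
#' @param out_dir optional directory for report artifacts (JSON report,
#'   mask BED, coverage TSV, SV TSV).
#' @return a `line_report`.
#' @export
run_characterize <- function(config_path, out_dir = NULL) {
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  base <- dirname(normalizePath(config_path))
  rp <- function(x) if (is.null(x)) NULL else
    if (file.exists(x)) x else file.path(base, x)
  refseqs <- read_fasta(rp(cfg$paths$reference))
  for (nm in names(refseqs))
    stopifnot_msg(grepl("^[ACGTNacgtn]+$", refseqs[[nm]]),
                  sprintf("reference %s: invalid alphabet", nm))
  vseq <- read_fasta(rp(cfg$paths$vector))[[1]]
  feats <- if (!is.null(cfg$paths$vector_features))
    read.table(rp(cfg$paths$vector_features), header = TRUE, sep = "\t",
               stringsAsFactors = FALSE) else NULL
  vec <- structure(list(seq = vseq, length = str_len(vseq), features = feats,
                        host_segments = NULL), class = "vt_vector")
  aln <- NULL; reads <- NULL
  if (!is.null(cfg$paths$sam)) {
    aln <- read_sam(rp(cfg$paths$sam))
  } else {
    r1 <- read_fastq(rp(cfg$paths$reads1))
    r2 <- read_fastq(rp(cfg$paths$reads2))
    stopifnot_msg(length(r1) == length(r2), "mate files differ in read count")
    vt_log("read QC: %d pairs, lengths %d-%d", length(r1),
           min(str_len(c(r1, r2))), max(str_len(c(r1, r2))))
    reads <- structure(list(qname = names(r1), r1 = unname(r1), r2 = unname(r2),
                            config = list(insert_mean = cfg$params$insert_mean %||% 265)),
                       class = "vt_reads")
  }
  contigs <- if (!is.null(cfg$paths$contigs)) read_fasta(rp(cfg$paths$contigs)) else NULL
  gff <- if (!is.null(cfg$paths$gff)) rp(cfg$paths$gff) else NULL
  params <- as.list(cfg$params %||% list())
  rep <- characterize(refseqs, vec, reads = reads, alignments = aln,
                      contigs = contigs, gff = gff,
                      marker = as.list(cfg$marker), housekeeping = as.list(cfg$housekeeping),
                      params = params, line_name = cfg$line_name %||% "line")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(rep, file.path(out_dir, "report.json"))
    if (nrow(rep$mask))
      write.table(data.frame("vector", rep$mask$start, rep$mask$end),
                  file.path(out_dir, "mask.bed"), sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    write_sv_tsv(report_sv_calls(rep), file.path(out_dir, "sv_calls.tsv"))
  }
  rep
}

#' Verify a report against a simulation truth record
#'
#' Scorecard: locus count and position error, copy-number error, and a
#' per-type structural-variant confusion table (expected vs found by type
#' and length).
#'
#' @param report a `line_report`.
#' @param truth a `vt_truth` (or NULL for an untransformed line).
#' @param bp_tol breakpoint tolerance in bp.
#' @param len_tol SV length tolerance in bp: lengths derive from two
#'   breakpoints, each exact up to junction microhomology (large deletions get
#'   `del_len_tol`).
#' @param del_len_tol tolerance for adjacent large deletion lengths (the
#'   scan resolves to within about a window).
#' @return a `vt_scorecard` list with a logical `pass`.
#' @export
verify_against_truth <- function(report, truth, bp_tol = 5L, len_tol = 5L,
                                 del_len_tol = 2500L) {
  calls <- report$locus_calls
  if (is.null(truth)) {
    pass <- length(calls) == 0
    return(structure(list(pass = pass, n_loci = length(calls),
                          expected_loci = 0L, notes = if (pass) "clean control"
                          else "false locus call(s) on untransformed line"),
                     class = "vt_scorecard"))
  }
  n_ok <- length(calls) == 1
  left_err <- right_err <- NA_integer_
  status_ok <- copy_ok <- FALSE
  copy_call <- NA_integer_
  if (n_ok) {
    call <- calls[[1]]
    left_err <- abs(call$left_bp - truth$left_bp)
    right_err <- if (is.na(truth$right_bp) || is.na(call$right_bp)) NA_integer_
      else abs(call$right_bp - truth$right_bp)
    status_ok <- call$status == truth$status
  }
  if (!is.null(report$copy_number)) {
    copy_call <- report$copy_number$copy_call
    copy_ok <- copy_call == truth$copies
  }
  exp <- expected_sv_set(truth)
  found <- report_sv_calls(report)
  confusion <- do.call(rbind, lapply(seq_len(nrow(exp)), function(i) {
    tol <- if (exp$type[i] == "adjacent_large_deletion") del_len_tol else len_tol
    hit <- sum(found$type == exp$type[i] &
                 abs(found$length - exp$length[i]) <= tol)
    data.frame(type = exp$type[i], length = exp$length[i], expected = 1L,
               found = hit)
  }))
  sv_ok <- all(confusion$found >= 1L)
  bp_ok <- n_ok && !is.na(left_err) && left_err <= bp_tol &&
    (is.na(truth$right_bp) || (!is.na(right_err) && right_err <= bp_tol))
  pass <- n_ok && bp_ok && status_ok && copy_ok && sv_ok
  structure(list(pass = pass, n_loci = length(calls), expected_loci = 1L,
                 left_bp_error = left_err, right_bp_error = right_err,
                 status_ok = status_ok, copy_call = copy_call,
                 copy_expected = truth$copies, copy_ok = copy_ok,
                 sv_confusion = confusion, sv_ok = sv_ok),
            class = "vt_scorecard")
}

#' @export
print.vt_scorecard <- function(x, ...) {
  cat(sprintf("<vt_scorecard> %s\n", if (x$pass) "PASS" else "FAIL"))
  if (!is.null(x$sv_confusion)) {
    cat(sprintf("  loci %d/%d, bp error L=%s R=%s, status %s, copies %s/%s\n",
                x$n_loci, x$expected_loci, x$left_bp_error, x$right_bp_error,
                x$status_ok, x$copy_call, x$copy_expected))
    print(x$sv_confusion, row.names = FALSE)
  } else if (!is.null(x$notes)) cat("  ", x$notes, "\n")
  invisible(x)
}
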