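# Reconciliation of junction breakpoints into the junction-variant
# taxonomy, filler-origin classification, contig-level rearrangement
# classification by maximal-exact-match anchor chaining (the machine-readable
# dot plot), and the locus-adjacent large-deletion scan.

#' Reconcile a locus call's breakpoints into a junction variant
#'
#' With both breakpoints exact, let d = right - left on the reference:
#' d > 0 is a target deletion of length d (reference sequence lost at the
#' junction), d < 0 a target-site duplication of length -d (the same
#' reference block appears on both sides of the insert), d = 0 a blunt
#' junction.
#'
#' @param call a `locus_call` with status `both_ends`.
#' @param blunt_tol junctions whose breakpoints coincide within this many bp
#'   are blunt: read alignments over-run a junction by the length of any
#'   coincidental sequence match (microhomology), so |d| carries a few bp
#'   of systematic uncertainty.
#' @return one-row StructuralVariantCall data.frame, or a row with type
#'   "unresolved" when breakpoints are interval-precision.
#' @export
reconcile_breakpoints <- function(call, blunt_tol = 5L) {
  stopifnot_msg(call$status == "both_ends", "reconciliation requires both breakpoints")
  if (!identical(call$left_precision, "exact") || !identical(call$right_precision, "exact"))
    return(sv_call("unresolved", call$chrom, NA_integer_, NA_integer_, NA_integer_,
                   provenance = "junction_reads"))
  d <- call$right_bp - call$left_bp
  if (abs(d) <= blunt_tol)
    sv_call("blunt_junction", call$chrom, min(call$left_bp, call$right_bp),
            min(call$left_bp, call$right_bp), 0L, provenance = "junction_reads")
  else if (d > 0) sv_call("target_deletion", call$chrom, call$left_bp, call$right_bp, d,
                     provenance = "junction_reads")
  else if (d < 0) sv_call("target_site_duplication", call$chrom, call$right_bp,
                          call$left_bp, -d, orientation = "+",
                          provenance = "junction_reads")
  else sv_call("blunt_junction", call$chrom, call$left_bp, call$left_bp, 0L,
               provenance = "junction_reads")
}

sv_call <- function(type, target, start, end, length, orientation = NA_character_,
                    detail = "", provenance = "contig") {
  data.frame(type = type, target = target, start = start, end = end,
             length = length, orientation = orientation, detail = detail,
             provenance = provenance, stringsAsFactors = FALSE)
}

empty_sv <- function() {
  data.frame(type = character(0), target = character(0), start = integer(0),
             end = integer(0), length = integer(0), orientation = character(0),
             detail = character(0), provenance = character(0),
             stringsAsFactors = FALSE)
}

local_align_stats <- function(filler, subject) {
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(filler),
                                      Biostrings::DNAString(subject),
                                      type = "local",
                                      substitutionMatrix =
                                        Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1),
                                      gapOpening = 2, gapExtension = 2)
  pat <- Biostrings::pattern(al)
  aln_len <- Biostrings::nchar(al)
  nmatch <- Biostrings::nmatch(al)
  list(identity = if (aln_len > 0) nmatch / aln_len else 0,
       qcov = (Biostrings::end(pat) - Biostrings::start(pat) + 1) / nchar(filler),
       s_start = Biostrings::start(Biostrings::subject(al)) - 1L,
       s_end = Biostrings::end(Biostrings::subject(al)))
}

#' Classify the origin of a junction filler sequence
#'
#' Aligns the filler locally against the vector, then the reference (both
#' strands). A hit with >= `min_identity` identity over >= `min_coverage`
#' of the filler length assigns the origin (vector first, with the matched
#' vector interval; then genome with the source locus); otherwise the
#' verdict is `unknown_origin` -- the in-silico analogue of "no database
#' similarity". Fillers under 10 bp are reported as micro-insertions with
#' no origin assigned.
#'
#' @param filler filler nucleotide string.
#' @param vector a `vt_vector` or sequence string.
#' @param reference a `vt_reference` or named character vector.
#' @param min_identity,min_coverage acceptance thresholds.
#' @return a `filler_classification` list: `verdict`, `source`, `identity`.
#' @export
classify_filler <- function(filler, vector, reference, min_identity = 0.8,
                            min_coverage = 0.9) {
  if (nchar(filler) < 10)
    return(structure(list(verdict = "micro-insertion", source = NULL,
                          identity = NA_real_, length = nchar(filler)),
                     class = "filler_classification"))
  vseq <- if (inherits(vector, "vt_vector")) vector$seq else vector
  refs <- if (inherits(reference, "vt_reference")) reference$seqs else reference
  best <- function(name, subject) {
    hits <- lapply(c("+", "-"), function(st) {
      s <- if (st == "+") filler else cpp_revcomp(filler)
      a <- local_align_stats(s, subject)
      a$strand <- st; a$name <- name
      a
    })
    hits[[which.max(vapply(hits, function(h) h$identity * h$qcov, numeric(1)))]]
  }
  ok <- function(h) h$identity >= min_identity && h$qcov >= min_coverage
  hv <- best("vector", vseq)
  if (ok(hv))
    return(structure(list(verdict = "vector_duplicate",
                          source = list(target = "vector", start = hv$s_start,
                                        end = hv$s_end, strand = hv$strand),
                          identity = hv$identity, length = nchar(filler)),
                     class = "filler_classification"))
  for (chrom in names(refs)) {
    hg <- best(chrom, refs[[chrom]])
    if (ok(hg))
      return(structure(list(verdict = "genome_derived",
                            source = list(target = chrom, start = hg$s_start,
                                          end = hg$s_end, strand = hg$strand),
                            identity = hg$identity, length = nchar(filler)),
                       class = "filler_classification"))
  }
  structure(list(verdict = "unknown_origin", source = NULL,
                 identity = max(hv$identity, 0), length = nchar(filler)),
            class = "filler_classification")
}

#' @export
print.filler_classification <- function(x, ...) {
  cat(sprintf("<filler_classification> %d bp -> %s", x$length, x$verdict))
  if (!is.null(x$source))
    cat(sprintf(" (%s:%d-%d %s, identity %.2f)", x$source$target,
                x$source$start + 1, x$source$end, x$source$strand, x$identity))
  cat("\n")
  invisible(x)
}

#' Find maximal exact match anchors between a contig and targets
#'
#' All maximal exact matches >= `min_len` bp between the contig and each
#' target, both strands, with orientation. The anchor set is the
#' machine-readable form of a dot plot.
#'
#' @param contig contig sequence (string).
#' @param targets named character vector of target sequences (genome
#'   chromosomes plus vector).
#' @param min_len minimum anchor length (default 50: below this, repeat
#'   noise dominates in toy genomes).
#' @return data.frame with `target`, `cstart`, `cend`, `tstart`, `tend`,
#'   `len`, `strand` (0-based half-open).
#' @export
find_anchors <- function(contig, targets, min_len = 50L) {
  out <- lapply(names(targets), function(nm) {
    m <- cpp_find_mems(contig, targets[[nm]], as.integer(min_len))
    if (nrow(m)) cbind(data.frame(target = nm, stringsAsFactors = FALSE), m)
    else NULL
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(target = character(0), cstart = integer(0), cend = integer(0),
                      tstart = integer(0), tend = integer(0), len = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  out[order(out$cstart, -out$len), , drop = FALSE]
}

#' Maximum-weight colinear anchor chain
#'
#' Dynamic program over anchors sorted by contig start: a chain is a set of
#' anchors with non-overlapping, increasing contig intervals (orientation
#' and target switches allowed at block boundaries); its weight is the
#' anchored base total minus `lambda` times the contig gaps between
#' consecutive blocks. O(n^2) in the anchor count, which the fixture scale
#' keeps tiny.
#'
#' @param anchors data.frame from [find_anchors()].
#' @param lambda contig-gap penalty per bp.
#' @param max_overlap largest tolerated contig overlap between consecutive
#'   blocks (maximal exact matches over-extend by a few coincidental bases
#'   at junction boundaries); overlapping bases are charged against the
#'   chain weight.
#' @return an `anchor_chain`: list with `blocks` (the chained anchors in
#'   contig order) and `weight`.
#' @export
chain_anchors <- function(anchors, lambda = 0.01, max_overlap = 20L) {
  if (is.null(anchors) || nrow(anchors) == 0)
    return(structure(list(blocks = anchors, weight = 0, unalignable = TRUE),
                     class = "anchor_chain"))
  a <- anchors[order(anchors$cstart, anchors$cend), , drop = FALSE]
  n <- nrow(a)
  score <- as.numeric(a$len)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      gap <- a$cstart[i] - a$cend[j]
      if (gap >= -max_overlap && a$cstart[j] < a$cstart[i] && a$cend[j] < a$cend[i]) {
        s <- score[j] + a$len[i] - (if (gap >= 0) lambda * gap else -gap)
        if (s > score[i]) { score[i] <- s; prev[i] <- j }
      }
    }
  }
  best <- which.max(score)
  path <- integer(0); i <- best
  while (i > 0) { path <- c(i, path); i <- prev[i] }
  structure(list(blocks = a[path, , drop = FALSE], weight = score[best],
                 unalignable = FALSE),
            class = "anchor_chain")
}

#' @export
print.anchor_chain <- function(x, ...) {
  if (isTRUE(x$unalignable)) { cat("<anchor_chain> unalignable contig\n"); return(invisible(x)) }
  cat(sprintf("<anchor_chain> %d block(s), weight %.1f\n", nrow(x$blocks), x$weight))
  b <- x$blocks
  for (i in seq_len(nrow(b)))
    cat(sprintf("  contig %6d-%6d -> %s:%d-%d (%s)\n", b$cstart[i] + 1, b$cend[i],
                b$target[i], b$tstart[i] + 1, b$tend[i], b$strand[i]))
  invisible(x)
}

#' Classify an anchor chain into structural variant calls
#'
#' Truth-free reading of the chain: a contig gap at a junction is filler
#' DNA (classified by origin when sequences are supplied); a target gap
#' across the insert is a target deletion, a target overlap a target-site
#' duplication; an opposite-orientation block is an internal inversion, or
#' an inverted duplication when its target interval is covered elsewhere in
#' the chain; adjacent near-full-length vector blocks are a tandem
#' multi-copy insert; a vector block starting or ending well inside the
#' vector ends is a truncation. Two post-processing rules keep the calls
#' faithful at fixture scale: a short same-orientation duplicate block
#' contained in a neighbour's interval is folded into its junction gap and
#' classified as filler (vector-duplicate), and a junction gap whose
#' sequence contiguously extends a neighbouring vector block (vector
#' sequence too short to anchor) is merged rather than called.
#'
#' @param chain an `anchor_chain`.
#' @param contig the contig sequence (needed to classify junction gaps).
#' @param vector a `vt_vector` or vector sequence, or NULL.
#' @param reference a `vt_reference` or named character vector, or NULL.
#' @param vector_name the vector's target name in the anchor set.
#' @param min_gap smallest contig gap considered an insertion.
#' @param end_margin bp tolerance at vector extremities for truncation calls.
#' @param tandem_frac minimum per-copy fraction of the vector for a tandem call.
#' @param max_fold_dup largest contained duplicate folded into a filler call.
#' @return StructuralVariantCall data.frame (possibly 0 rows), provenance
#'   "contig"; attribute `annotations` carries non-call notes (e.g. vector
#'   block abutting a contig end).
#' @export
classify_chain <- function(chain, contig, vector = NULL, reference = NULL,
                           vector_name = "vector", min_gap = 10L,
                           end_margin = 20L, tandem_frac = 0.8,
                           max_fold_dup = 100L) {
  calls <- empty_sv()
  notes <- character(0)
  if (isTRUE(chain$unalignable) || nrow(chain$blocks) == 0) {
    attr(calls, "annotations") <- "unalignable"
    return(calls)
  }
  b <- chain$blocks
  b <- b[order(b$cstart), , drop = FALSE]
  vseq <- if (inherits(vector, "vt_vector")) vector$seq else vector
  vlen <- if (!is.null(vseq)) nchar(vseq) else NA_integer_

  is_vec <- b$target == vector_name
  covered_elsewhere <- function(i) {
    any(b$target == b$target[i] & seq_len(nrow(b)) != i &
          b$tstart <= b$tstart[i] & b$tend >= b$tend[i])
  }

  # 1. contained inverted duplicates get their own call; any other short
  #    block sandwiched between two larger blocks is folded into the
  #    junction gap, whose sequence is then classified by origin (a
  #    duplicate of vector or genome sequence at a junction is filler DNA,
  #    whichever target its anchor happened to pick)
  fold <- logical(nrow(b))
  fold_called <- logical(nrow(b))
  dominant_strand <- if (any(is_vec)) {
    names(sort(tapply(b$len[is_vec], b$strand[is_vec], sum), decreasing = TRUE))[1]
  } else "+"
  for (i in seq_len(nrow(b))) {
    # near-full-length vector copies belong to the tandem rule, not here
    if (!is.na(vlen) && b$target[i] == vector_name && b$len[i] >= tandem_frac * vlen) next
    if (covered_elsewhere(i) && b$strand[i] != dominant_strand &&
        b$target[i] == vector_name) {
      calls <- rbind(calls, sv_call("inverted_duplication", b$target[i],
                                    b$tstart[i], b$tend[i], b$len[i],
                                    orientation = "-"))
      fold[i] <- TRUE; fold_called[i] <- TRUE
    } else if (b$len[i] <= max_fold_dup && i > 1 && i < nrow(b) &&
               b$len[i - 1L] > max_fold_dup && b$len[i + 1L] > max_fold_dup) {
      fold[i] <- TRUE
    }
  }
  k <- b[!fold, , drop = FALSE]
  kv <- k$target == vector_name

  # 2. inversions: opposite-orientation blocks not covered elsewhere
  if (nrow(k) > 1) {
    for (i in seq_len(nrow(k))) {
      same_t <- which(k$target == k$target[i])
      if (length(same_t) > 1 && k$strand[i] != dominant_strand && kv[i] &&
          !any(k$tstart[same_t] <= k$tstart[i] & k$tend[same_t] >= k$tend[i] & same_t != i)) {
        # tandem copies legitimately carry whole reversed copies; only
        # sub-vector-length reversed blocks are internal inversions
        if (k$len[i] < tandem_frac * vlen || is.na(vlen))
          calls <- rbind(calls, sv_call("internal_inversion", k$target[i],
                                        k$tstart[i], k$tend[i], k$len[i],
                                        orientation = "-"))
      }
    }
  }

  # 3. junction gaps and same-target gaps between consecutive blocks
  vec_cov_lo <- if (any(kv)) min(k$tstart[kv]) else NA_integer_
  vec_cov_hi <- if (any(kv)) max(k$tend[kv]) else NA_integer_
  if (nrow(k) > 1) {
    for (i in seq_len(nrow(k) - 1L)) {
      gap <- k$cstart[i + 1L] - k$cend[i]
      same_target <- k$target[i] == k$target[i + 1L]
      if (same_target && k$strand[i] == k$strand[i + 1L] && gap < min_gap) {
        tgap <- if (k$strand[i] == "+") k$tstart[i + 1L] - k$tend[i]
                else k$tstart[i] - k$tend[i + 1L]
        if (tgap >= min_gap)
          calls <- rbind(calls, sv_call("target_deletion", k$target[i],
                                        min(k$tend[i], k$tend[i + 1L]),
                                        min(k$tend[i], k$tend[i + 1L]) + tgap, tgap))
        else if (-tgap >= min_gap)
          calls <- rbind(calls, sv_call("duplication", k$target[i],
                                        k$tstart[i + 1L], k$tend[i], -tgap,
                                        orientation = "+"))
      }
      if (gap >= min_gap) {
        # skip gaps already explained by a called fold (inverted duplicate)
        folded_cov <- if (any(fold_called))
          sum(pmax(0L, pmin(b$cend[fold_called], k$cstart[i + 1L]) -
                     pmax(b$cstart[fold_called], k$cend[i]))) else 0L
        if (gap - folded_cov < min_gap) next
        gap_seq <- substr(contig, k$cend[i] + 1L, k$cstart[i + 1L])
        fc <- if (!is.null(vseq) && !is.null(reference))
          classify_filler(gap_seq, vseq, reference) else NULL
        merged <- FALSE
        if (!is.null(fc) && fc$verdict == "vector_duplicate") {
          # vector sequence too short to anchor: matched interval abuts a
          # neighbouring vector block's interval
          for (nb in c(i, i + 1L)) {
            if (k$target[nb] != vector_name) next
            if (abs(fc$source$start - k$tend[nb]) <= 5 ||
                abs(k$tstart[nb] - fc$source$end) <= 5) {
              vec_cov_lo <- min(vec_cov_lo, fc$source$start)
              vec_cov_hi <- max(vec_cov_hi, fc$source$end)
              merged <- TRUE
              break
            }
          }
        }
        if (!merged) {
          detail <- if (is.null(fc)) "unclassified" else
            if (fc$verdict == "vector_duplicate")
              sprintf("vector_duplicate:%d-%d", fc$source$start, fc$source$end)
            else if (fc$verdict == "genome_derived")
              sprintf("genome_derived:%s:%d-%d", fc$source$target,
                      fc$source$start, fc$source$end)
            else fc$verdict
          calls <- rbind(calls, sv_call("filler_insertion",
                                        k$target[i + 1L], k$cend[i], k$cstart[i + 1L],
                                        gap, detail = detail))
        }
      }
    }
  }

  # 4. genome junction across the insert: first/last genome blocks
  gb <- which(!kv)
  vb <- which(kv)
  if (length(vb) && length(gb) >= 2) {
    leftg <- max(gb[gb < min(vb)], -Inf)
    rightg <- min(gb[gb > max(vb)], Inf)
    if (is.finite(leftg) && is.finite(rightg) &&
        k$target[leftg] == k$target[rightg] &&
        k$strand[leftg] == "+" && k$strand[rightg] == "+") {
      d <- k$tstart[rightg] - k$tend[leftg]
      if (d >= min_gap)
        calls <- rbind(calls, sv_call("target_deletion", k$target[leftg],
                                      k$tend[leftg], k$tstart[rightg], d))
      else if (-d >= min_gap)
        calls <- rbind(calls, sv_call("target_site_duplication", k$target[leftg],
                                      k$tstart[rightg], k$tend[leftg], -d,
                                      orientation = "+"))
    }
  }

  # 5. tandem multi-copy: >= 2 near-full-length vector blocks adjacent on contig
  if (!is.na(vlen)) {
    full <- vb[k$len[vb] >= tandem_frac * vlen]
    if (length(full) >= 2 && all(diff(full) == 1)) {
      ori <- paste(ifelse(k$strand[full] == "+", "+", "-"), collapse = "")
      calls <- rbind(calls, sv_call("tandem_multicopy", vector_name,
                                    min(k$tstart[full]), max(k$tend[full]),
                                    length(full), orientation = ori,
                                    detail = sprintf("copies=%d", length(full))))
    }
    # 6. truncation of the vector extremities
    if (!is.na(vec_cov_lo) && vec_cov_lo > end_margin)
      calls <- rbind(calls, sv_call("vector_truncation", vector_name, 0L,
                                    vec_cov_lo, vec_cov_lo, detail = "5p"))
    if (!is.na(vec_cov_hi) && vec_cov_hi < vlen - end_margin)
      calls <- rbind(calls, sv_call("vector_truncation", vector_name, vec_cov_hi,
                                    vlen, vlen - vec_cov_hi, detail = "3p"))
  }
  # annotation: vector-derived block abutting a contig end (chromosome-end
  # events); folded blocks (e.g. an inverted duplicate at the junction)
  # still count as vector material here
  if (any(is_vec)) {
    if (min(b$cstart[is_vec]) <= end_margin) notes <- c(notes, "vector_at_contig_start")
    if (max(b$cend[is_vec]) >= nchar(contig) - end_margin) notes <- c(notes, "vector_at_contig_end")
  }
  attr(calls, "annotations") <- notes
  calls
}

#' Scan for a large deletion adjacent to an insertion locus
#'
#' Windows adjacent to the locus with mean depth below `del_frac` times the
#' robust nuclear baseline are merged while contiguous and reported as an
#' adjacent large deletion when the merged run reaches `min_del_len`. The
#' baseline is the median of per-window mean depths over nuclear windows
#' with nonzero depth (a plain per-base median degenerates when the
#' deletion spans most of a chromosome).
#'
#' @param profiles named list of `coverage_profile` objects (nuclear).
#' @param locus a `locus_call`.
#' @param window scan window in bp.
#' @param del_frac depth fraction under which a window counts as deleted.
#' @param min_del_len minimum reported deletion length (10 kb floors out
#'   windowing noise).
#' @return one-row StructuralVariantCall data.frame, or NULL.
#' @export
scan_adjacent_deletion <- function(profiles, locus, window = 1000L,
                                   del_frac = 0.1, min_del_len = 10000L) {
  stopifnot_msg(locus$chrom %in% names(profiles), "locus chromosome is not profiled")
  wmeans <- unlist(lapply(profiles, function(p) {
    d <- p$depth
    ws <- seq(0L, length(d) - 1L, by = window)
    vapply(seq_along(ws), function(i) mean(d[(ws[i] + 1L):min(ws[i] + window, length(d))]),
           numeric(1))
  }))
  baseline <- median(wmeans[wmeans > 0])
  if (!is.finite(baseline) || baseline <= 0) return(NULL)
  thr <- del_frac * baseline
  depth <- profiles[[locus$chrom]]$depth
  L <- length(depth)
  scan_dir <- function(from, dir) {
    # dir +1: rightward from `from`; dir -1: leftward
    lo <- from; hi <- from
    repeat {
      ws <- if (dir > 0) hi else lo - window
      we <- ws + window
      if (ws < 0 || we > L) break
      if (mean(depth[(ws + 1L):we]) >= thr) break
      if (dir > 0) hi <- we else lo <- ws
    }
    c(lo, hi)
  }
  best <- NULL
  starts <- c(right = locus$right_bp, left = locus$left_bp)
  if (!is.na(starts["right"]) || !is.na(starts["left"])) {
    from_r <- if (!is.na(starts["right"])) starts["right"] else starts["left"]
    r <- scan_dir(from_r, +1L)
    if (r[2] - r[1] >= min_del_len) best <- r
    if (is.null(best) && !is.na(starts["left"])) {
      l <- scan_dir(starts["left"], -1L)
      if (l[2] - l[1] >= min_del_len) best <- l
    }
  }
  if (is.null(best)) return(NULL)
  sv_call("adjacent_large_deletion", locus$chrom, as.integer(best[1]),
          as.integer(best[2]), as.integer(best[2] - best[1]),
          provenance = "junction_reads")
}

#' Write structural variant calls as a VCF-like TSV
#'
#' Columns CHROM, POS (1-based), END, SVTYPE, SVLEN and an INFO field
#' carrying orientation, provenance and detail.
#'
#' @param calls StructuralVariantCall data.frame.
#' @param path output TSV.
#' @export
write_sv_tsv <- function(calls, path) {
  df <- data.frame(CHROM = calls$target, POS = calls$start + 1L, END = calls$end,
                   SVTYPE = calls$type, SVLEN = calls$length,
                   INFO = sprintf("ORIENT=%s;PROV=%s;DETAIL=%s",
                                  ifelse(is.na(calls$orientation), ".", calls$orientation),
                                  calls$provenance, ifelse(calls$detail == "", ".", calls$detail)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dump an anchor chain as a PAF-like TSV
#'
#' For external dot-plot rendering: contig name/length/interval, strand,
#' target name/interval, per-block anchored length.
#'
#' @param chain an `anchor_chain`.
#' @param contig_name,contig_len contig identity.
#' @param path output TSV.
#' @export
write_chain_paf <- function(chain, contig_name, contig_len, path) {
  b <- chain$blocks
  df <- data.frame(qname = contig_name, qlen = contig_len, qstart = b$cstart,
                   qend = b$cend, strand = b$strand, tname = b$target,
                   tstart = b$tstart, tend = b$tend, nmatch = b$len,
                   alnlen = b$len)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
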