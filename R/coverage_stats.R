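# Per-base depth profiles, feature-level coverage, the coverage-ratio copy
# number estimator, replicon copy ratios, and vector integrity profiling
# with masking of genome-shared vector segments.

#' Per-base depth profile of one target
#'
#' Only aligned (M) bases of uniquely mapped records contribute; soft
#' clipped bases do not. Ambiguous reads are excluded (conservative
#' multi-mapping policy).
#'
#' @param alignments a `vt_alignments`.
#' @param target target name.
#' @param target_len target length in bp (taken from the `targets` attribute
#'   if present).
#' @param window window size for the windowed summary.
#' @return a `coverage_profile`: list with `target`, `depth` (integer
#'   vector), and `windows` (data.frame start/end/mean_depth).
#' @export
depth_profile <- function(alignments, target, target_len = NULL, window = 500L) {
  if (is.null(target_len)) {
    tl <- attr(alignments, "targets")
    stopifnot_msg(!is.null(tl) && target %in% names(tl),
                  sprintf("unknown target '%s' (no length available)", target))
    target_len <- tl[[target]]
  }
  a <- alignments[!is.na(alignments$target) & alignments$target == target &
                    alignments$status == "unique", , drop = FALSE]
  if (nrow(a)) {
    ir <- IRanges::IRanges(start = a$pos + 1L, width = a$alen)
    cov <- IRanges::coverage(ir, width = target_len)
    depth <- as.integer(cov)
  } else depth <- integer(target_len)
  ws <- seq(0L, target_len - 1L, by = window)
  we <- pmin(ws + window, target_len)
  wmean <- vapply(seq_along(ws), function(i) mean(depth[(ws[i] + 1L):we[i]]), numeric(1))
  structure(list(target = target, depth = depth,
                 windows = data.frame(start = ws, end = we, mean_depth = wmean)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: %s bp, mean depth %.1fx\n", x$target,
              format(length(x$depth), big.mark = ","), mean(x$depth)))
  invisible(x)
}

#' Feature-level coverage statistic
#'
#' Average coverage C = L / G where L is the total mapped length attributed
#' to the feature (sum of per-base depth over the interval) and G the
#' feature length.
#'
#' @param profile a `coverage_profile` (or NULL if `mapped_length_bp` given).
#' @param start,end 0-based half-open feature interval.
#' @param label feature label.
#' @param mapped_length_bp override L directly (printed-table arithmetic).
#' @param feature_length_bp override G directly.
#' @return a `coverage_stat` with fields `label`, `G`, `L`, `C`.
#' @export
feature_coverage <- function(profile = NULL, start = NULL, end = NULL,
                             label = "feature", mapped_length_bp = NULL,
                             feature_length_bp = NULL) {
  if (is.null(mapped_length_bp)) {
    stopifnot_msg(end > start, "empty feature is rejected")
    mapped_length_bp <- sum(as.numeric(profile$depth[(start + 1L):end]))
    feature_length_bp <- end - start
  }
  stopifnot_msg(feature_length_bp > 0, "feature length must be > 0")
  structure(list(label = label, G = feature_length_bp, L = mapped_length_bp,
                 C = mapped_length_bp / feature_length_bp),
            class = "coverage_stat")
}

#' @export
print.coverage_stat <- function(x, ...) {
  cat(sprintf("<coverage_stat> %s: L=%s bp over G=%s bp -> C=%dx\n", x$label,
              format(x$L, big.mark = ","), format(x$G, big.mark = ","), round(x$C)))
  invisible(x)
}

#' Coverage-ratio transgene copy number
#'
#' Ratio of the average coverage of the vector's selectable marker to that
#' of a single-copy housekeeping gene. The ratio is computed on unrounded
#' coverages; the reported value is rounded to 2 decimals only at print
#' time. The integerized call is round(N), flagged when |N - round(N)| >
#' 0.25 (an uncertain call).
#'
#' @param marker,housekeeping `coverage_stat` objects.
#' @return a `copy_number_estimate`.
#' @export
estimate_copy_number <- function(marker, housekeeping) {
  stopifnot_msg(housekeeping$C > 0,
                "zero housekeeping coverage is rejected (bad reference choice)")
  n <- marker$C / housekeeping$C
  structure(list(marker = marker, housekeeping = housekeeping,
                 ratio = n, reported = round(n, 2),
                 copy_call = as.integer(round(n)),
                 uncertain = abs(n - round(n)) > 0.25),
            class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("<copy_number_estimate> %.2f (%dx / %dx) -> %d cop%s%s\n",
              x$reported, round(x$marker$C), round(x$housekeeping$C),
              x$copy_call, if (x$copy_call == 1) "y" else "ies",
              if (x$uncertain) " [uncertain]" else ""))
  invisible(x)
}

#' Per-replicon copy ratio versus the nuclear genome
#'
#' Organellar genomes are present in several copies per cell; their read
#' depth scales accordingly. Ratio = target mean depth / median of the
#' nuclear per-target mean depths.
#'
#' @param profiles named list of `coverage_profile` objects.
#' @param nuclear character vector naming the nuclear targets.
#' @return data.frame with `target`, `mean_depth`, `ratio`.
#' @export
replicon_copy_ratio <- function(profiles, nuclear) {
  stopifnot_msg(length(nuclear) >= 1 && all(nuclear %in% names(profiles)),
                "at least one nuclear target must be designated and profiled")
  md <- vapply(profiles, function(p) mean(p$depth), numeric(1))
  base <- median(md[nuclear])
  stopifnot_msg(base > 0, "nuclear baseline depth is zero")
  data.frame(target = names(profiles), mean_depth = unname(md),
             ratio = unname(md / base))
}

#' Mask vector intervals shared with the host genome
#'
#' Every maximal vector interval of at least `min_len` bp sharing at least
#' `min_identity` with some reference locus is masked. Identity is computed
#' over same-diagonal chains of exact 31-mer anchors (banded,
#' substitution-only), mirroring a BLAST >= 95% identity acceptance rule.
#'
#' @param vector a `vt_vector` (or plain sequence string).
#' @param reference a `vt_reference` (or named character vector).
#' @param min_len minimum masked interval length.
#' @param min_identity minimum identity of a masked interval.
#' @param max_gap maximum same-diagonal gap bridged between exact anchors.
#' @return data.frame of disjoint sorted 0-based half-open `start`/`end`
#'   intervals on the vector.
#' @export
mask_shared_segments <- function(vector, reference, min_len = 100L,
                                 min_identity = 0.95, max_gap = 50L) {
  vseq <- if (inherits(vector, "vt_vector")) vector$seq else vector
  refs <- if (inherits(reference, "vt_reference")) reference$seqs else reference
  iv <- data.frame(start = integer(0), end = integer(0))
  for (chrom in names(refs)) {
    mem <- cpp_find_mems(vseq, refs[[chrom]], 31L)
    if (!nrow(mem)) next
    for (st in c("+", "-")) {
      m <- mem[mem$strand == st, , drop = FALSE]
      if (!nrow(m)) next
      key <- if (st == "+") m$tstart - m$cstart else m$tstart + m$cend
      for (d in unique(key)) {
        g <- m[key == d, , drop = FALSE]
        g <- g[order(g$cstart), , drop = FALSE]
        runs <- split(seq_len(nrow(g)),
                      cumsum(c(0, diff(g$cstart) > (g$cend[-nrow(g)] - g$cstart[-nrow(g)]) + max_gap)))
        for (r in runs) {
          cs <- min(g$cstart[r]); ce <- max(g$cend[r])
          if (ce - cs < min_len) next
          span_v <- subseq0(vseq, cs, ce)
          if (st == "+") {
            ts <- d + cs
            span_t <- subseq0(refs[[chrom]], ts, ts + (ce - cs))
          } else {
            te <- d - cs
            span_t <- cpp_revcomp(subseq0(refs[[chrom]], te - (ce - cs), te))
          }
          ident <- mean(strsplit(span_v, "")[[1]] == strsplit(span_t, "")[[1]])
          if (ident >= min_identity) iv <- rbind(iv, data.frame(start = cs, end = ce))
        }
      }
    }
  }
  merge_intervals(iv)
}

#' Vector integrity report
#'
#' Positions with depth >= `min_depth` count as covered; the covered
#' fraction is computed over the unmasked vector length. A feature is
#' "intact" iff >= 99% of its unmasked length is covered, "deleted" iff <=
#' 1%, else "partially deleted". `vector_present` is FALSE when the
#' unmasked covered fraction stays at background (<= 0.05).
#'
#' @param profile a `coverage_profile` of the vector.
#' @param mask data.frame of masked vector intervals (from
#'   [mask_shared_segments()]).
#' @param features data.frame with `label`, `start`, `end` (0-based
#'   half-open), e.g. the vector template's `features`.
#' @param min_depth minimum depth for a position to count as covered.
#' @return an `integrity_report`.
#' @export
integrity_report <- function(profile, mask = NULL, features = NULL, min_depth = 5L) {
  depth <- profile$depth
  L <- length(depth)
  if (is.null(mask)) mask <- data.frame(start = integer(0), end = integer(0))
  masked <- logical(L)
  if (nrow(mask)) for (i in seq_len(nrow(mask))) masked[(mask$start[i] + 1L):mask$end[i]] <- TRUE
  covered <- depth >= min_depth
  unmasked_n <- sum(!masked)
  covered_fraction <- if (unmasked_n > 0) sum(covered & !masked) / unmasked_n else NA_real_
  # uncovered segments over the unmasked vector
  unc <- !covered & !masked
  r <- rle(unc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  verdicts <- NULL
  if (!is.null(features) && nrow(features)) {
    verdicts <- data.frame(label = features$label, verdict = NA_character_,
                           covered_fraction = NA_real_)
    for (i in seq_len(nrow(features))) {
      idx <- (features$start[i] + 1L):features$end[i]
      idx <- idx[!masked[idx]]
      cf <- if (length(idx)) mean(covered[idx]) else NA_real_
      verdicts$covered_fraction[i] <- cf
      verdicts$verdict[i] <- if (is.na(cf)) "masked"
        else if (cf >= 0.99) "intact"
        else if (cf <= 0.01) "deleted"
        else "partially deleted"
    }
  }
  structure(list(masked_intervals = mask, covered_fraction = covered_fraction,
                 uncovered_segments = seg, feature_verdicts = verdicts,
                 vector_present = !is.na(covered_fraction) && covered_fraction > 0.05,
                 min_depth = min_depth),
            class = "integrity_report")
}

#' @export
print.integrity_report <- function(x, ...) {
  cat(sprintf("<integrity_report> %s: %.1f%% of unmasked vector covered (depth >= %d), %d uncovered segment(s)\n",
              if (x$vector_present) "vector present" else "no vector present",
              100 * x$covered_fraction, x$min_depth, nrow(x$uncovered_segments)))
  if (!is.null(x$feature_verdicts)) {
    for (i in seq_len(nrow(x$feature_verdicts)))
      cat(sprintf("  %-12s %s\n", x$feature_verdicts$label[i], x$feature_verdicts$verdict[i]))
  }
  invisible(x)
}

#' Write a per-window coverage TSV
#'
#' The textual twin of a coverage heatmap: target, window start/end (1-based
#' inclusive in the report), mean depth.
#'
#' @param profiles named list of `coverage_profile` objects.
#' @param path output TSV.
#' @export
write_coverage_tsv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(target = p$target, start = p$windows$start + 1L,
               end = p$windows$end, mean_depth = round(p$windows$mean_depth, 2))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
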