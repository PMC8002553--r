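# Alignment infrastructure: a joint k-mer seed index over genome + vector,
# a fixture-scale seed-and-extend read mapper (ungapped, substitution-only,
# soft-clips at junctions), Table-1-style mapping statistics, and a minimal
# SAM 1.x subset reader/writer.

#' Build a joint k-mer seed index over all targets
#'
#' The genome and the vector are indexed together so a read is placed
#' against both at once; reads from host-derived vector segments then see
#' two equally good locations and come out ambiguous, which is what forces
#' homology masking downstream.
#'
#' @param targets named character vector of sequences (chromosomes plus the
#'   vector), or a `vt_reference` (vector added via `extra`).
#' @param k seed length, in `[11, 31]`. Default 20 mirrors the typical
#'   short-read aligner seed for this task; toy fixtures may use 15.
#' @param extra optional additional named sequences (e.g. the vector).
#' @return a `vt_index`.
#' @export
build_index <- function(targets, k = 20L, extra = NULL) {
  if (inherits(targets, "vt_reference")) targets <- targets$seqs
  if (!is.null(extra)) targets <- c(targets, extra)
  stopifnot_msg(length(targets) > 0, "empty sequence set is rejected")
  stopifnot_msg(!is.null(names(targets)) && all(nzchar(names(targets))),
                "targets must be named")
  if (anyDuplicated(names(targets)))
    stop("duplicate target names are rejected", call. = FALSE)
  stopifnot_msg(k >= 11 && k <= 31, "k must be in [11, 31]")
  ptr <- cpp_build_index(names(targets), unname(targets), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), names = names(targets),
                 lengths = setNames(cpp_index_lengths(ptr), names(targets)),
                 seqs = targets),
            class = "vt_index")
}

#' @export
print.vt_index <- function(x, ...) {
  cat(sprintf("<vt_index> k=%d over %d target(s), %s bp\n", x$k,
              length(x$names), format(sum(x$lengths), big.mark = ",")))
  invisible(x)
}

#' Occurrence list of one k-mer in the index
#' @param index a `vt_index`.
#' @param kmer a string of length `k`.
#' @return data.frame with `target` (name) and `pos` (0-based).
#' @export
query_index <- function(index, kmer) {
  d <- cpp_index_query(index$ptr, kmer)
  data.frame(target = index$names[d$target], pos = d$pos - 1L)
}

empty_alignments <- function() {
  data.frame(qname = character(0), target = character(0), pos = integer(0),
              strand = character(0), clip_left = integer(0), clip_right = integer(0),
              alen = integer(0), read_len = integer(0), seq = character(0),
              mate_target = character(0), mate_pos = integer(0),
              proper = logical(0), status = character(0), mate_of = integer(0),
              stringsAsFactors = FALSE)
}

#' Map reads against an index
#'
#' Seed-vote then ungapped extension: the candidate diagonal with the
#' best-scoring extension wins; an unextendable prefix/suffix is reported as
#' a soft clip; reads whose best and second-best placements score equally
#' are `ambiguous`; reads with no usable seed are `unmapped`.
#'
#' @param index a `vt_index`.
#' @param reads character vector of read sequences, or a `vt_reads` object
#'   (both mates are mapped and paired).
#' @param qnames read names (defaults to `read_<i>`).
#' @param seed_step distance between successive seeds along the read.
#' @param min_score minimum extension score (match +1 / mismatch -3).
#' @param proper_max_insert maximum outer distance for a proper pair.
#' @return a `vt_alignments` data.frame; one row per read, with SAM-style
#'   reference-forward `seq`, 0-based `pos`, soft-clip lengths, mate fields
#'   and `status` in unique/ambiguous/unmapped.
#' @export
map_reads <- function(index, reads, qnames = NULL, seed_step = 5L, min_score = 20L,
                      proper_max_insert = 1000L) {
  paired <- inherits(reads, "vt_reads")
  if (paired) {
    qn <- reads$qname
    seqs <- c(reads$r1, reads$r2)
    qnames <- c(qn, qn)
    mate_of <- c(seq_along(qn) + length(qn), seq_along(qn))
  } else {
    seqs <- as.character(reads)
    if (is.null(qnames)) qnames <- sprintf("read_%06d", seq_along(seqs))
    mate_of <- rep(NA_integer_, length(seqs))
  }
  m <- cpp_map_reads(index$ptr, seqs, as.integer(seed_step), as.integer(min_score))
  status <- c("unique", "ambiguous", "unmapped")[m$status + 1L]
  oriented <- ifelse(!is.na(m$strand) & m$strand == "-",
                     vapply(seqs, cpp_revcomp, character(1), USE.NAMES = FALSE), seqs)
  aln <- data.frame(qname = qnames, target = ifelse(is.na(m$tid), NA_character_,
                                                    index$names[m$tid]),
                    pos = m$pos, strand = m$strand,
                    clip_left = m$qstart,
                    clip_right = str_len(seqs) - m$qend,
                    alen = m$qend - m$qstart,
                    read_len = str_len(seqs), seq = oriented,
                    mate_target = NA_character_, mate_pos = NA_integer_,
                    proper = FALSE, status = status, mate_of = mate_of,
                    stringsAsFactors = FALSE)
  if (paired) {
    ok <- aln$status == "unique"
    mt <- aln$target[aln$mate_of]; mp <- aln$pos[aln$mate_of]
    mok <- ok[aln$mate_of]
    aln$mate_target <- ifelse(mok, mt, NA_character_)
    aln$mate_pos <- ifelse(mok, mp, NA_integer_)
    # proper: both unique, same target, opposite strands, inward, sane span
    ms <- aln$strand[aln$mate_of]
    mend <- aln$pos[aln$mate_of] + aln$alen[aln$mate_of]
    myend <- aln$pos + aln$alen
    outer_lo <- pmin(aln$pos, aln$pos[aln$mate_of], na.rm = FALSE)
    outer_hi <- pmax(myend, mend)
    inward <- ifelse(aln$strand == "+", aln$pos <= aln$pos[aln$mate_of],
                     aln$pos[aln$mate_of] <= aln$pos)
    aln$proper <- ok & mok & !is.na(mt) & aln$target == mt &
      !is.na(ms) & aln$strand != ms & inward &
      (outer_hi - outer_lo) <= proper_max_insert
    aln$proper[is.na(aln$proper)] <- FALSE
  }
  class(aln) <- c("vt_alignments", class(aln))
  aln
}

#' Outer insert sizes of proper pairs
#' @param aln a `vt_alignments` with mate links.
#' @return numeric vector, one entry per proper pair.
#' @export
insert_sizes <- function(aln) {
  i <- which(aln$proper & !is.na(aln$mate_of) & aln$mate_of > seq_len(nrow(aln)))
  if (!length(i)) return(numeric(0))
  j <- aln$mate_of[i]
  pmax(aln$pos[i] + aln$alen[i], aln$pos[j] + aln$alen[j]) - pmin(aln$pos[i], aln$pos[j])
}

#' Table-1-style mapping statistics
#'
#' Pure arithmetic on the declared definitions: average coverage = total
#' mapped read length / reference length; mapped percent = 100 x read pairs
#' mapped / total raw reads (the published table counts raw totals in pairs,
#' and its footnote arithmetic is reproduced exactly). Values are kept at
#' full precision; `print` rounds coverage to an integer and percent to one
#' decimal, matching report precision.
#'
#' @param alignments a `vt_alignments`, or NULL if totals are given directly.
#' @param reference_length_bp total reference length.
#' @param total_raw_reads total raw read pairs (mapped + unmapped).
#' @param total_mapped_length_bp override: sum of mapped read lengths.
#' @param read_pairs_mapped,proper_pairs_mapped,average_insert_size overrides.
#' @return a `mapping_stats` list.
#' @export
compute_mapping_stats <- function(alignments = NULL, reference_length_bp,
                                  total_raw_reads,
                                  total_mapped_length_bp = NULL,
                                  read_pairs_mapped = NULL,
                                  proper_pairs_mapped = NULL,
                                  average_insert_size = NULL) {
  stopifnot_msg(reference_length_bp > 0, "reference_length_bp must be > 0")
  stopifnot_msg(total_raw_reads > 0, "zero raw reads is rejected")
  if (!is.null(alignments)) {
    uniq <- alignments$status == "unique"
    if (is.null(total_mapped_length_bp))
      total_mapped_length_bp <- sum(as.numeric(alignments$read_len[uniq]))
    if (is.null(read_pairs_mapped)) {
      first <- !is.na(alignments$mate_of) & alignments$mate_of > seq_len(nrow(alignments))
      read_pairs_mapped <- sum(first & uniq & uniq[alignments$mate_of])
    }
    if (is.null(proper_pairs_mapped)) {
      first <- !is.na(alignments$mate_of) & alignments$mate_of > seq_len(nrow(alignments))
      proper_pairs_mapped <- sum(first & alignments$proper)
    }
    if (is.null(average_insert_size)) {
      is <- insert_sizes(alignments)
      average_insert_size <- if (length(is)) mean(is) else NA_real_
    }
  }
  out <- list(total_raw_reads = total_raw_reads,
              total_mapped_length_bp = total_mapped_length_bp,
              reference_length_bp = reference_length_bp,
              average_coverage = total_mapped_length_bp / reference_length_bp,
              read_pairs_mapped = read_pairs_mapped,
              proper_pairs_mapped = proper_pairs_mapped,
              mapped_percent = 100 * read_pairs_mapped / total_raw_reads,
              average_insert_size = average_insert_size)
  structure(out, class = "mapping_stats")
}

#' @export
print.mapping_stats <- function(x, ...) {
  cat(sprintf("<mapping_stats> coverage %dx, mapped %.1f%% (%s pairs of %s raw), insert %.1f\n",
              round(x$average_coverage), round(x$mapped_percent, 1),
              format(x$read_pairs_mapped, big.mark = ","),
              format(x$total_raw_reads, big.mark = ","),
              if (is.null(x$average_insert_size) || is.na(x$average_insert_size)) NA
              else x$average_insert_size))
  invisible(x)
}

# ---- SAM 1.x subset ---------------------------------------------------------

cigar_from_row <- function(clip_left, clip_right, alen) {
  paste0(if (clip_left > 0) paste0(clip_left, "S") else "",
         alen, "M",
         if (clip_right > 0) paste0(clip_right, "S") else "")
}

parse_cigar <- function(cig) {
  if (cig == "*") return(data.frame(len = integer(0), op = character(0)))
  lens <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
  ops <- regmatches(cig, gregexpr("[MIDSH=X]", cig))[[1]]
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

cigar_query_len <- function(cig) {
  d <- parse_cigar(cig)
  sum(d$len[d$op %in% c("M", "I", "S", "=", "X")])
}

cigar_ref_len <- function(cig) {
  d <- parse_cigar(cig)
  sum(d$len[d$op %in% c("M", "D", "=", "X")])
}

#' Write alignments to a SAM file
#'
#' Emits the SAM 1.x subset the pipeline consumes: `@SQ` header lines and
#' FLAG/RNAME/POS/MAPQ/CIGAR/RNEXT/PNEXT/TLEN/SEQ columns. MAPQ encodes the
#' mapping status (60 unique, 0 ambiguous).
#'
#' @param alignments a `vt_alignments`.
#' @param targets named integer vector of target lengths.
#' @param path output file.
#' @export
write_sam <- function(alignments, targets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(targets), as.integer(targets)), con)
  a <- alignments
  n <- nrow(a)
  paired <- !is.na(a$mate_of)
  first <- paired & a$mate_of > seq_len(n)
  mapped <- a$status != "unmapped"
  mate_mapped <- rep(TRUE, n)
  mate_rev <- rep(FALSE, n)
  if (any(paired)) {
    mate_mapped[paired] <- mapped[a$mate_of[paired]]
    ms <- a$strand[a$mate_of[paired]]
    mate_rev[paired] <- !is.na(ms) & ms == "-"
  }
  flag <- ifelse(paired, 1L, 0L) +
    ifelse(a$proper, 2L, 0L) +
    ifelse(!mapped, 4L, 0L) +
    ifelse(paired & !mate_mapped, 8L, 0L) +
    ifelse(mapped & !is.na(a$strand) & a$strand == "-", 16L, 0L) +
    ifelse(paired & mate_rev, 32L, 0L) +
    ifelse(first, 64L, 0L) + ifelse(paired & !first, 128L, 0L)
  rname <- ifelse(mapped, a$target, "*")
  pos1 <- ifelse(mapped, a$pos + 1L, 0L)
  mapq <- ifelse(!mapped, 0L, ifelse(a$status == "unique", 60L, 0L))
  cig <- ifelse(mapped, mapply(cigar_from_row, a$clip_left, a$clip_right, a$alen), "*")
  rnext <- ifelse(paired & !is.na(a$mate_target),
                  ifelse(a$mate_target == rname & rname != "*", "=", a$mate_target), "*")
  pnext <- ifelse(paired & !is.na(a$mate_pos), a$mate_pos + 1L, 0L)
  tlen <- rep(0L, n)
  same <- paired & !is.na(a$mate_target) & !is.na(a$target) & a$mate_target == a$target
  if (any(same)) {
    i <- which(same)
    j <- a$mate_of[i]
    span <- pmax(a$pos[i] + a$alen[i], a$pos[j] + a$alen[j]) - pmin(a$pos[i], a$pos[j])
    tlen[i] <- ifelse(a$pos[i] <= a$pos[j], span, -span)
  }
  qual <- strrep("I", a$read_len)
  writeLines(paste(a$qname, flag, rname, pos1, mapq, cig, rnext, pnext, tlen,
                   a$seq, qual, sep = "\t"), con)
  invisible(path)
}

#' Read a SAM file into a `vt_alignments`
#'
#' Accepts external aligner output as long as mate fields and CIGAR are
#' populated. Records whose CIGAR query length disagrees with the sequence
#' length are skipped with a warning and counted in the `skipped` attribute.
#'
#' @param path SAM file with an `@SQ` header.
#' @return a `vt_alignments`; attributes `targets` (named lengths) and
#'   `skipped` (malformed record count).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hd <- grepl("^@", lines)
  sq <- lines[grepl("^@SQ\t", lines)]
  if (length(sq) == 0) stop("SAM header with @SQ target lengths is required", call. = FALSE)
  tnames <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  tlens <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  body <- lines[!hd & nzchar(lines)]
  skipped <- 0L
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    seq <- f[10]
    cig <- f[6]
    mapped <- !bitwAnd(flag, 4L)
    if (mapped && cig != "*" && seq != "*" && cigar_query_len(cig) != str_len(seq)) {
      skipped <- skipped + 1L
      next
    }
    d <- if (mapped) parse_cigar(cig) else data.frame(len = integer(0), op = character(0))
    clip_l <- if (nrow(d) && d$op[1] == "S") d$len[1] else 0L
    clip_r <- if (nrow(d) && d$op[nrow(d)] == "S") d$len[nrow(d)] else 0L
    rows[[i]] <- data.frame(
      qname = f[1],
      target = if (mapped) f[3] else NA_character_,
      pos = if (mapped) as.integer(f[4]) - 1L else NA_integer_,
      strand = if (!mapped) NA_character_ else if (bitwAnd(flag, 16L)) "-" else "+",
      clip_left = clip_l, clip_right = clip_r,
      alen = if (mapped) cigar_ref_len(cig) else 0L,
      read_len = if (seq != "*") str_len(seq) else NA_integer_,
      seq = seq,
      mate_target = if (f[7] == "*") NA_character_ else if (f[7] == "=") f[3] else f[7],
      mate_pos = if (f[8] == "0") NA_integer_ else as.integer(f[8]) - 1L,
      proper = bitwAnd(flag, 2L) > 0,
      status = if (!mapped) "unmapped" else if (as.integer(f[5]) == 0L) "ambiguous" else "unique",
      flag_first = bitwAnd(flag, 64L) > 0,
      flag_paired = bitwAnd(flag, 1L) > 0,
      stringsAsFactors = FALSE)
  }
  aln <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(aln)) aln <- cbind(empty_alignments(), flag_first = logical(0),
                                 flag_paired = logical(0))
  # rebuild mate links for paired records by qname
  aln$mate_of <- NA_integer_
  if (nrow(aln)) {
    pr <- which(aln$flag_paired)
    if (length(pr)) {
      sp <- split(pr, aln$qname[pr])
      for (idx in sp) if (length(idx) == 2) {
        aln$mate_of[idx[1]] <- idx[2]
        aln$mate_of[idx[2]] <- idx[1]
      }
    }
  }
  aln$flag_first <- NULL
  aln$flag_paired <- NULL
  class(aln) <- c("vt_alignments", class(aln))
  attr(aln, "targets") <- setNames(tlens, tnames)
  attr(aln, "skipped") <- skipped
  if (skipped > 0) warning(sprintf("%d record(s) with CIGAR/sequence length mismatch skipped", skipped))
  aln
}
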