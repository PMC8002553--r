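# Ground-truthed synthetic transformant generator. A stated world: a small
# multi-chromosome haploid genome, a ~6 kb linearized vector carrying
# host-derived promoter/terminator segments, and insertion events drawn from
# the observed repertoire of PEG-transformant lines (target-site
# duplications, target deletions, fillers, inversions, inverted
# duplications, tandem multi-copy inserts, adjacent large deletions).

#' Generate a simulated multi-chromosome haploid reference genome
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param lengths integer vector of chromosome lengths in bp (>= 1000 each).
#' @param gc target GC fraction in (0, 1).
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @return a `vt_reference`: list with `seqs` (named character vector),
#'   `lengths`, `gc`, `seed`.
#' @export
generate_reference <- function(n_chrom, lengths, gc = 0.58, seed = 1) {
  stopifnot_msg(n_chrom >= 1, "n_chrom must be >= 1")
  stopifnot_msg(length(lengths) == n_chrom, "lengths must have n_chrom entries")
  stopifnot_msg(all(lengths >= 1000), "chromosome lengths must be >= 1000 bp (non-positive or tiny lengths rejected)")
  stopifnot_msg(gc > 0 && gc < 1, "gc must be in (0, 1)")
  seqs <- vapply(seq_len(n_chrom), function(i) {
    cpp_random_seq(lengths[i], gc, derive_seed(seed, i))
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  structure(list(seqs = seqs, lengths = setNames(as.integer(lengths), names(seqs)),
                 gc = gc, seed = as.integer(seed)),
            class = "vt_reference")
}

#' @export
print.vt_reference <- function(x, ...) {
  cat(sprintf("<vt_reference> %d sequence(s), %s bp total, GC target %.2f, seed %d\n",
              length(x$seqs), format(sum(x$lengths), big.mark = ","), x$gc, x$seed))
  invisible(x)
}

#' Build a linearized vector template carrying host-derived segments
#'
#' Models the post-linearization transforming molecule: a linear sequence
#' with annotated features (selectable marker, reporter, promoters,
#' terminator) in which declared intervals are verbatim copies of reference
#' loci. Those shared segments recruit genomic reads in any line and must be
#' masked downstream.
#'
#' @param reference a `vt_reference`.
#' @param length vector length in bp.
#' @param feature_plan data.frame with columns `label`, `start`, `end`,
#'   `strand` (0-based half-open, non-overlapping).
#' @param host_segments list of lists with fields `chrom`, `start`, `end`
#'   (source interval on the reference) and `at` (vector start position).
#' @param seed seed for the vector-specific (non host-derived) sequence.
#' @return a `vt_vector`: list with `seq`, `features`, `host_segments`.
#' @export
build_vector <- function(reference, length = 6000L, feature_plan = NULL,
                         host_segments = list(), seed = reference$seed + 101L) {
  stopifnot_msg(inherits(reference, "vt_reference"), "reference must be a vt_reference")
  if (is.null(feature_plan)) {
    feature_plan <- data.frame(label = character(0), start = integer(0),
                               end = integer(0), strand = character(0))
  }
  if (nrow(feature_plan)) {
    stopifnot_msg(all(feature_plan$start >= 0 & feature_plan$end <= length &
                        feature_plan$start < feature_plan$end),
                  "feature intervals must lie within the vector")
    fp <- feature_plan[order(feature_plan$start), ]
    if (nrow(fp) > 1 && any(fp$start[-1] < fp$end[-nrow(fp)]))
      stop("overlapping feature plan entries are rejected", call. = FALSE)
  }
  seq <- cpp_random_seq(length, reference$gc, derive_seed(seed, 0))
  hs <- data.frame(v_start = integer(0), v_end = integer(0), chrom = character(0),
                   g_start = integer(0), g_end = integer(0))
  for (h in host_segments) {
    stopifnot_msg(h$chrom %in% names(reference$seqs),
                  sprintf("host segment source '%s' not in reference", h$chrom))
    L <- reference$lengths[[h$chrom]]
    stopifnot_msg(h$start >= 0 && h$end <= L && h$start < h$end,
                  "host segment interval outside its source chromosome")
    seg <- subseq0(reference$seqs[[h$chrom]], h$start, h$end)
    w <- h$end - h$start
    stopifnot_msg(h$at >= 0 && h$at + w <= length, "host segment does not fit in the vector")
    substr(seq, h$at + 1L, h$at + w) <- seg
    hs <- rbind(hs, data.frame(v_start = h$at, v_end = h$at + w, chrom = h$chrom,
                               g_start = h$start, g_end = h$end))
  }
  structure(list(seq = seq, length = as.integer(length),
                 features = feature_plan, host_segments = hs),
            class = "vt_vector")
}

#' @export
print.vt_vector <- function(x, ...) {
  cat(sprintf("<vt_vector> %d bp, %d feature(s), %d host-derived segment(s)\n",
              x$length, nrow(x$features), nrow(x$host_segments)))
  invisible(x)
}

#' Generate a filler sequence of unknown origin
#'
#' Random sequence at the reference GC, rejection-sampled so that no 20-mer
#' is shared with the reference or the vector. This makes "no database hit"
#' classifiable without any database.
#'
#' @param len filler length in bp.
#' @param reference a `vt_reference`.
#' @param vector a `vt_vector` (optional).
#' @param seed integer seed.
#' @export
make_filler <- function(len, reference, vector = NULL, seed = 1) {
  hay <- c(unname(reference$seqs), if (!is.null(vector)) vector$seq)
  hay <- c(hay, revcomp(hay))
  for (try in 1:200) {
    cand <- cpp_random_seq(len, reference$gc, derive_seed(seed, try))
    if (len < 20) return(cand)
    kmers <- substring(cand, 1:(len - 19), 20:len)
    hit <- FALSE
    for (h in hay) {
      if (any(vapply(kmers, function(k) grepl(k, h, fixed = TRUE), logical(1)))) { hit <- TRUE; break }
    }
    if (!hit) return(cand)
  }
  stop("could not generate a shared-20-mer-free filler", call. = FALSE)
}

#' Describe one vector insertion event
#'
#' The event grammar is the union of the observed junction repertoire:
#' multi-copy cassettes with per-copy orientation, end truncations,
#' target-site duplication (TSD) or target deletion (mutually exclusive),
#' junction fillers, internal vector inversions / inverted duplications, and
#' an adjacent large deletion of chromosome sequence on the right side.
#'
#' @param chrom target chromosome name.
#' @param position 0-based insertion position on the reference.
#' @param copies number of vector copies (>= 1).
#' @param orientations per-copy orientation, "forward" or "reverse".
#' @param left_truncation_bp,right_truncation_bp bp trimmed from the
#'   cassette's outer 5'/3' ends.
#' @param tsd_bp target-site duplication length (duplicates the reference
#'   bases immediately right of `position`).
#' @param target_deletion_bp deleted reference bp at the insertion point.
#' @param fillers list of lists with `side` ("left"/"right"), `seq` (or NULL
#'   to generate), `origin` ("unknown", "external", or
#'   "vector-duplicate:<start>-<end>" 0-based half-open).
#' @param internal_events list of lists with `type` ("inversion" or
#'   "inverted_duplication") and `interval` (0-based half-open on the
#'   vector). Inversions apply inside the first copy; inverted duplications
#'   append a reverse-complement copy of the interval at the cassette 3' end.
#' @param adjacent_deletion_bp deleted reference bp immediately right of the
#'   insertion (after any target deletion); may extend to the chromosome end.
#' @return an `insertion_event`.
#' @export
insertion_event <- function(chrom, position, copies = 1L,
                            orientations = rep("forward", copies),
                            left_truncation_bp = 0L, right_truncation_bp = 0L,
                            tsd_bp = 0L, target_deletion_bp = 0L,
                            fillers = list(), internal_events = list(),
                            adjacent_deletion_bp = 0L) {
  stopifnot_msg(copies >= 1, "copies must be >= 1")
  stopifnot_msg(length(orientations) == copies, "one orientation per copy")
  stopifnot_msg(all(orientations %in% c("forward", "reverse")), "bad orientation")
  stopifnot_msg(!(tsd_bp > 0 && target_deletion_bp > 0),
                "tsd_bp and target_deletion_bp cannot both be > 0")
  stopifnot_msg(left_truncation_bp >= 0 && right_truncation_bp >= 0, "negative truncation")
  stopifnot_msg(adjacent_deletion_bp >= 0, "negative adjacent deletion")
  structure(list(chrom = chrom, position = as.integer(position),
                 copies = as.integer(copies), orientations = orientations,
                 left_truncation_bp = as.integer(left_truncation_bp),
                 right_truncation_bp = as.integer(right_truncation_bp),
                 tsd_bp = as.integer(tsd_bp),
                 target_deletion_bp = as.integer(target_deletion_bp),
                 fillers = fillers, internal_events = internal_events,
                 adjacent_deletion_bp = as.integer(adjacent_deletion_bp)),
            class = "insertion_event")
}

# realize filler sequences (generate any NULL ones) and give them ids
realize_fillers <- function(event, reference, vector, seed) {
  fl <- event$fillers
  if (length(fl) == 0) return(fl)
  for (i in seq_along(fl)) {
    f <- fl[[i]]
    stopifnot_msg(f$side %in% c("left", "right"), "filler side must be 'left' or 'right'")
    if (is.null(f$origin)) f$origin <- "unknown"
    if (is.null(f$seq)) {
      if (grepl("^vector-duplicate:", f$origin)) {
        iv <- as.integer(strsplit(sub("^vector-duplicate:", "", f$origin), "-")[[1]])
        f$seq <- subseq0(vector$seq, iv[1], iv[2])
      } else {
        f$seq <- make_filler(f$len, reference, vector, derive_seed(seed, 500 + i))
      }
    }
    f$len <- str_len(f$seq)
    f$id <- paste0("filler", i)
    fl[[i]] <- f
  }
  fl
}

#' Apply an insertion event to a reference genome
#'
#' Returns the mutated genome together with a truth record whose attribution
#' map assigns every base of the mutated chromosome to reference, vector, or
#' a declared filler; replaying the attribution reproduces the mutated
#' genome byte-for-byte (see [replay_truth()]).
#'
#' @param reference a `vt_reference`.
#' @param vector a `vt_vector`.
#' @param event an [insertion_event()].
#' @param seed seed used only to generate fillers declared without sequence.
#' @return list with `genome` (named character vector of mutated sequences)
#'   and `truth` (a `vt_truth`).
#' @export
apply_insertion <- function(reference, vector, event, seed = 1) {
  stopifnot_msg(inherits(event, "insertion_event"), "event must be an insertion_event")
  stopifnot_msg(event$chrom %in% names(reference$seqs), "event chromosome not in reference")
  L <- reference$lengths[[event$chrom]]
  p <- event$position
  vlen <- vector$length
  stopifnot_msg(event$left_truncation_bp < vlen && event$right_truncation_bp < vlen,
                "truncations must be smaller than the vector")
  stopifnot_msg(p >= 0 && p + event$tsd_bp <= L, "event exceeds chromosome bounds")
  stopifnot_msg(p + event$target_deletion_bp + event$adjacent_deletion_bp <= L,
                "event exceeds chromosome bounds")
  fillers <- realize_fillers(event, reference, vector, seed)

  # attribution blocks: (source, s_start, s_end, strand, seq)
  blocks <- list()
  add <- function(source, s_start, s_end, strand, seq) {
    blocks[[length(blocks) + 1]] <<- list(source = source, s_start = s_start,
                                          s_end = s_end, strand = strand, seq = seq)
  }
  events <- list()
  add_ev <- function(type, target, start, end, length, orientation = NA_character_, detail = "") {
    events[[length(events) + 1]] <<- data.frame(type = type, target = target,
                                                start = start, end = end, length = length,
                                                orientation = orientation, detail = detail)
  }

  vseq <- vector$seq
  # per-copy sequences; internal inversion applies inside the first copy
  copy_seqs <- character(event$copies)
  inv_done <- FALSE
  for (ci in seq_len(event$copies)) {
    s <- vseq
    if (ci == 1) {
      for (ie in event$internal_events) {
        if (ie$type == "inversion") {
          iv <- ie$interval
          s <- paste0(subseq0(s, 0, iv[1]), revcomp(subseq0(s, iv[1], iv[2])),
                      subseq0(s, iv[2], str_len(s)))
          add_ev("internal_inversion", "vector", iv[1], iv[2], iv[2] - iv[1], "-")
          inv_done <- TRUE
        }
      }
    }
    if (event$orientations[ci] == "reverse") s <- cpp_revcomp(s)
    copy_seqs[ci] <- s
  }
  # end truncations trim the cassette's outer extremities
  if (event$left_truncation_bp > 0) {
    copy_seqs[1] <- subseq0(copy_seqs[1], event$left_truncation_bp, str_len(copy_seqs[1]))
    add_ev("vector_truncation", "vector", 0, event$left_truncation_bp,
           event$left_truncation_bp, detail = "5p")
  }
  if (event$right_truncation_bp > 0) {
    nlast <- str_len(copy_seqs[event$copies])
    copy_seqs[event$copies] <- subseq0(copy_seqs[event$copies], 0, nlast - event$right_truncation_bp)
    add_ev("vector_truncation", "vector", vlen - event$right_truncation_bp, vlen,
           event$right_truncation_bp, detail = "3p")
  }
  invdup_seq <- ""
  for (ie in event$internal_events) {
    if (ie$type == "inverted_duplication") {
      iv <- ie$interval
      invdup_seq <- paste0(invdup_seq, cpp_revcomp(subseq0(vseq, iv[1], iv[2])))
      add_ev("inverted_duplication", "vector", iv[1], iv[2], iv[2] - iv[1], "-")
    }
  }

  tsd <- event$tsd_bp
  tdel <- event$target_deletion_bp
  refseq <- reference$seqs[[event$chrom]]

  # left genome flank (ends with TSD copy 1 when tsd > 0)
  add(paste0("reference:", event$chrom), 0L, p + tsd, "+", subseq0(refseq, 0, p + tsd))
  insert_start <- p + tsd
  for (f in fillers) if (f$side == "left") {
    add(paste0("filler:", f$id), 0L, f$len, "+", f$seq)
    add_ev("filler_insertion", event$chrom, p, p, f$len,
           detail = paste0("left;", f$origin))
  }
  for (ci in seq_len(event$copies)) {
    # record in vector coordinates of the untruncated copy
    cs <- if (ci == 1) event$left_truncation_bp else 0L
    ce <- if (ci == event$copies) vlen - event$right_truncation_bp else vlen
    add("vector", cs, ce, if (event$orientations[ci] == "forward") "+" else "-",
        copy_seqs[ci])
  }
  if (nzchar(invdup_seq)) add("vector:invdup", 0L, str_len(invdup_seq), "-", invdup_seq)
  for (f in fillers) if (f$side == "right") {
    add(paste0("filler:", f$id), 0L, f$len, "+", f$seq)
    add_ev("filler_insertion", event$chrom, p + tdel, p + tdel, f$len,
           detail = paste0("right;", f$origin))
  }
  cassette_len <- sum(vapply(blocks, function(b) str_len(b$seq), numeric(1))) - (p + tsd)
  insert_end <- insert_start + cassette_len

  # right genome flank (starts with TSD copy 2 when tsd > 0)
  right_from <- p + tdel + event$adjacent_deletion_bp
  right_absent <- right_from >= L
  if (tsd > 0) {
    # resume at p: the duplicated block reappears in direct orientation
    add(paste0("reference:", event$chrom), p, L, "+", subseq0(refseq, p, L))
  } else if (!right_absent) {
    add(paste0("reference:", event$chrom), right_from, L, "+", subseq0(refseq, right_from, L))
  }

  if (tsd > 0) add_ev("target_site_duplication", event$chrom, p, p + tsd, tsd, "+")
  if (tdel > 0) add_ev("target_deletion", event$chrom, p, p + tdel, tdel)
  if (tsd == 0 && tdel == 0 && length(fillers) == 0 && !right_absent)
    add_ev("blunt_junction", event$chrom, p, p, 0L)
  if (event$copies >= 2)
    add_ev("tandem_multicopy", event$chrom, p, p, event$copies,
           orientation = paste(ifelse(event$orientations == "forward", "+", "-"),
                               collapse = ""),
           detail = sprintf("copies=%d", event$copies))
  if (event$adjacent_deletion_bp > 0)
    add_ev("adjacent_large_deletion", event$chrom, p + tdel, right_from,
           event$adjacent_deletion_bp)

  mutated <- paste(vapply(blocks, function(b) b$seq, character(1)), collapse = "")
  genome <- reference$seqs
  genome[[event$chrom]] <- mutated

  ev_df <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(0), target = character(0), start = integer(0),
               end = integer(0), length = integer(0), orientation = character(0),
               detail = character(0))

  truth <- structure(list(
    genome = genome, chrom = event$chrom,
    left_bp = p + tsd,
    right_bp = if (right_absent) NA_integer_ else p + tdel,
    status = if (right_absent) "left_only" else "both_ends",
    copies = event$copies, orientations = event$orientations,
    insert_start = insert_start, insert_end = insert_end,
    contig_core = c(p, insert_end + tsd),
    events = ev_df,
    attribution = lapply(blocks, function(b) b[c("source", "s_start", "s_end", "strand")]),
    event = event, fillers = fillers,
    original_length = L, mutated_length = str_len(mutated)
  ), class = "vt_truth")
  list(genome = genome, truth = truth)
}

#' Replay a truth record's attribution map
#'
#' Reconstructs the mutated chromosome from the attribution blocks and
#' checks byte-identity with the recorded genome.
#'
#' @param truth a `vt_truth`.
#' @param reference,vector the objects the truth was generated from.
#' @return TRUE invisibly; errors on mismatch.
#' @export
replay_truth <- function(truth, reference, vector) {
  parts <- vapply(truth$attribution, function(b) {
    src <- b$source
    if (startsWith(src, "reference:")) {
      s <- subseq0(reference$seqs[[sub("^reference:", "", src)]], b$s_start, b$s_end)
    } else if (src == "vector") {
      s <- subseq0(vector$seq, b$s_start, b$s_end)
      # an internal inversion modifies the copy; reapply it
      for (ie in truth$event$internal_events) {
        if (ie$type == "inversion") {
          iv <- ie$interval - b$s_start
          s <- paste0(subseq0(s, 0, iv[1]), cpp_revcomp(subseq0(s, iv[1], iv[2])),
                      subseq0(s, iv[2], str_len(s)))
        }
      }
      if (b$strand == "-") s <- cpp_revcomp(s)
    } else if (src == "vector:invdup") {
      s <- ""
      for (ie in truth$event$internal_events) {
        if (ie$type == "inverted_duplication")
          s <- paste0(s, cpp_revcomp(subseq0(vector$seq, ie$interval[1], ie$interval[2])))
      }
    } else if (startsWith(src, "filler:")) {
      id <- sub("^filler:", "", src)
      f <- Filter(function(x) x$id == id, truth$fillers)[[1]]
      s <- f$seq
    } else stop("unknown attribution source: ", src)
    s
  }, character(1))
  rebuilt <- paste(parts, collapse = "")
  stopifnot_msg(identical(rebuilt, truth$genome[[truth$chrom]]),
                "attribution replay does not reproduce the mutated chromosome")
  invisible(TRUE)
}

#' Read-simulation configuration
#'
#' Defaults emulate the study's libraries: 2 x 101 bp short-insert
#' paired-end reads with mean insert ~265 bp (the sequenced lines ranged
#' 249.7-277.6 bp).
#'
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd fragment-length distribution (truncated
#'   normal, minimum = read length).
#' @param depth mean sequencing depth (x).
#' @param error_rate independent per-base substitution probability.
#' @param seed integer seed.
#' @export
read_sim_config <- function(read_len = 101L, insert_mean = 265, insert_sd = 30,
                            depth = 100, error_rate = 0.001, seed = 1L) {
  stopifnot_msg(depth > 0, "depth must be > 0")
  if (insert_mean < 2 * read_len)
    warning("insert_mean < 2 x read_len: mates will overlap")
  structure(list(read_len = as.integer(read_len), insert_mean = insert_mean,
                 insert_sd = insert_sd, depth = depth, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate an inward-oriented paired-end library
#'
#' Fragment starts are uniform over the genome; fragment lengths follow a
#' truncated normal (minimum = read length); mate 2 is the reverse
#' complement of the fragment 3' end; substitution errors are independent
#' per base. Deterministic for a fixed seed.
#'
#' @param genome named character vector of sequences (or a `vt_reference`).
#' @param config a [read_sim_config()].
#' @return a `vt_reads`: list with `qname`, `r1`, `r2`, and a `truth` data
#'   frame of fragment placements.
#' @export
simulate_paired_reads <- function(genome, config = read_sim_config()) {
  if (inherits(genome, "vt_reference")) genome <- genome$seqs
  stopifnot_msg(length(genome) > 0 && all(str_len(genome) > 0), "genome is empty")
  total <- sum(str_len(genome))
  n_pairs <- round(config$depth * total / (2 * config$read_len))
  if (n_pairs < 1) {
    warning("requested depth yields 0 fragments; returning empty library")
    return(structure(list(qname = character(0), r1 = character(0), r2 = character(0),
                          truth = data.frame(), config = config), class = "vt_reads"))
  }
  sim <- cpp_simulate_reads(unname(genome), config$read_len, config$insert_mean,
                            config$insert_sd, n_pairs, config$error_rate,
                            config$seed)
  qname <- sprintf("sim_%07d", seq_len(n_pairs))
  structure(list(qname = qname, r1 = sim$r1, r2 = sim$r2,
                 truth = data.frame(qname = qname,
                                    target = names(genome)[sim$t_id],
                                    f_start = sim$f_start, f_len = sim$f_len),
                 config = config),
            class = "vt_reads")
}

#' @export
print.vt_reads <- function(x, ...) {
  cat(sprintf("<vt_reads> %d pairs of %d bp (insert %.0f +- %.0f, error %.4f)\n",
              length(x$qname), x$config$read_len, x$config$insert_mean,
              x$config$insert_sd, x$config$error_rate))
  invisible(x)
}

#' Emit a locus contig from a truth record
#'
#' Stand-in for a hybrid-assembly contig spanning the integration locus: the
#' mutated sequence from (left breakpoint - flank) to (right breakpoint +
#' flank), clipped at chromosome ends. With `flank_bp = 0` the contig is
#' exactly the inserted material plus both TSD copies.
#'
#' @param truth a `vt_truth`.
#' @param flank_bp flank length on each side.
#' @return single-element named character vector (the contig).
#' @export
emit_locus_contig <- function(truth, flank_bp = 2000L) {
  stopifnot_msg(flank_bp >= 0, "flank_bp must be >= 0")
  s <- truth$genome[[truth$chrom]]
  a <- max(0L, truth$contig_core[1] - flank_bp)
  b <- min(str_len(s), truth$contig_core[2] + flank_bp)
  setNames(subseq0(s, a, b), sprintf("%s_locus_contig", truth$chrom))
}
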