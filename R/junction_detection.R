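# Junction evidence extraction and insertion-locus calling: discordant
# genome/vector read pairs localize an integration boundary to within an
# insert size; soft-clipped reads whose clip remaps to the other target (or
# whose mate confirms vector linkage when filler DNA makes the clip
# unmappable) give base-exact breakpoints; single-linkage clustering turns
# evidence into per-line locus calls.

is_vector_target <- function(target, vector_name) !is.na(target) & target == vector_name

in_mask <- function(pos, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(rep(FALSE, length(pos)))
  point_in_intervals(pos, mask)
}

vend_class <- function(vpos, vlen, margin = 150L) {
  ifelse(is.na(vpos), NA_character_,
         ifelse(vpos <= margin, "5p", ifelse(vpos >= vlen - margin, "3p", "internal")))
}

empty_evidence <- function() {
  data.frame(kind = character(0), chrom = character(0), cluster_pos = numeric(0),
             gpos = integer(0), side = character(0), vpos = integer(0),
             precision = character(0), qname = character(0),
             stringsAsFactors = FALSE)
}

#' Extract junction read pairs
#'
#' A pair qualifies iff exactly one mate maps uniquely to a chromosome and
#' the other uniquely to the vector, and the vector-side alignment does not
#' fall within a masked (host-shared) vector interval. The genome mate's
#' reference orientation fixes the side: a forward mate points rightward
#' into the insert ("left" side of the insertion), a reverse mate leftward
#' ("right" side).
#'
#' @param alignments a `vt_alignments` with mate links.
#' @param vector_name the vector's target name.
#' @param mask masked vector intervals (data.frame start/end) or NULL.
#' @return junction-evidence data.frame sorted by chromosome and position;
#'   `precision` is "interval" (one insert size).
#' @export
extract_junction_pairs <- function(alignments, vector_name, mask = NULL) {
  a <- alignments
  n <- nrow(a)
  first <- !is.na(a$mate_of) & a$mate_of > seq_len(n)
  i <- which(first)
  if (!length(i)) return(empty_evidence())
  j <- a$mate_of[i]
  uniq <- a$status == "unique"
  iv <- is_vector_target(a$target, vector_name)
  qual <- uniq[i] & uniq[j] & (iv[i] != iv[j])
  i <- i[qual]; j <- j[qual]
  if (!length(i)) return(empty_evidence())
  g <- ifelse(iv[i], j, i)   # genome-side row
  v <- ifelse(iv[i], i, j)   # vector-side row
  vmid <- a$pos[v] + a$alen[v] %/% 2L
  keep <- !in_mask(vmid, mask)
  g <- g[keep]; v <- v[keep]
  if (!length(g)) return(empty_evidence())
  side <- ifelse(a$strand[g] == "+", "left", "right")
  cluster_pos <- ifelse(side == "left", a$pos[g] + a$alen[g], a$pos[g])
  ev <- data.frame(kind = "discordant_pair", chrom = a$target[g],
                   cluster_pos = as.numeric(cluster_pos), gpos = NA_integer_,
                   side = side, vpos = as.integer(vmid), precision = "interval",
                   qname = a$qname[g], stringsAsFactors = FALSE)
  ev[order(ev$chrom, ev$cluster_pos), , drop = FALSE]
}

#' Extract split (clipped) junction reads
#'
#' Soft-clipped tails of uniquely mapped reads are remapped against the
#' joint index. A clip mapping uniquely to the other target yields
#' base-exact evidence at the clip boundary. A clip that fails to remap
#' (filler DNA at the junction) still yields exact genome-side evidence
#' when the read's mate maps uniquely to the vector. Clips remapping
#' ambiguously (host-shared segments) are dropped and counted.
#'
#' @param alignments a `vt_alignments` (with `seq` retained).
#' @param index the `vt_index` used for mapping.
#' @param vector_name the vector's target name.
#' @param mask masked vector intervals or NULL.
#' @param min_clip minimum soft-clip length considered (>= 10).
#' @return junction-evidence data.frame; attribute `ambiguous_clips` counts
#'   the dropped ambiguous remaps.
#' @export
extract_split_reads <- function(alignments, index, vector_name, mask = NULL,
                                min_clip = 15L) {
  stopifnot_msg(min_clip >= 10, "min_clip must be >= 10")
  a <- alignments
  uniq <- which(a$status == "unique" &
                  (a$clip_left >= min_clip | a$clip_right >= min_clip))
  if (!length(uniq)) {
    ev <- empty_evidence(); attr(ev, "ambiguous_clips") <- 0L; return(ev)
  }
  # one entry per clipped end
  rows <- integer(0); sides_clip <- character(0)
  for (r in uniq) {
    if (a$clip_left[r] >= min_clip) { rows <- c(rows, r); sides_clip <- c(sides_clip, "L") }
    if (a$clip_right[r] >= min_clip) { rows <- c(rows, r); sides_clip <- c(sides_clip, "R") }
  }
  clip_seq <- vapply(seq_along(rows), function(t) {
    r <- rows[t]
    if (sides_clip[t] == "L") substr(a$seq[r], 1L, a$clip_left[r])
    else substr(a$seq[r], a$clip_left[r] + a$alen[r] + 1L, a$read_len[r])
  }, character(1))
  cm <- cpp_map_reads(index$ptr, clip_seq, 3L, max(12L, index$k))
  cm_status <- c("unique", "ambiguous", "unmapped")[cm$status + 1L]
  cm_target <- ifelse(is.na(cm$tid), NA_character_, index$names[cm$tid])
  vlen <- index$lengths[[vector_name]]
  n_ambig <- 0L
  out <- list()
  for (t in seq_along(rows)) {
    r <- rows[t]
    prim_vec <- is_vector_target(a$target[r], vector_name)
    clipL <- sides_clip[t] == "L"
    if (!prim_vec) {
      # primary on a chromosome
      side <- if (clipL) "right" else "left"
      gpos <- if (clipL) a$pos[r] else a$pos[r] + a$alen[r]
      if (cm_status[t] == "unique" && is_vector_target(cm_target[t], vector_name)) {
        vs <- cm$pos[t]; ve <- cm$pos[t] + (cm$qend[t] - cm$qstart[t])
        if (in_mask(vs + (ve - vs) %/% 2L, mask)) next
        interior_left <- !clipL  # right-clip: junction abuts the clip's left end
        vpos <- if (cm$strand[t] == "+") { if (interior_left) vs else ve }
                else { if (interior_left) ve else vs }
        out[[length(out) + 1]] <- data.frame(kind = "split_read", chrom = a$target[r],
                                             cluster_pos = as.numeric(gpos), gpos = gpos,
                                             side = side, vpos = as.integer(vpos),
                                             precision = "exact", qname = a$qname[r],
                                             stringsAsFactors = FALSE)
      } else {
        if (cm_status[t] == "ambiguous") n_ambig <- n_ambig + 1L
        # unmapped, ambiguous (e.g. a vector-duplicate filler shared with
        # the host) or mapping back to a chromosome: require the mate to
        # confirm vector linkage (filler DNA at the junction)
        mo <- a$mate_of[r]
        if (!is.na(mo) && a$status[mo] == "unique" &&
            is_vector_target(a$target[mo], vector_name) &&
            !in_mask(a$pos[mo] + a$alen[mo] %/% 2L, mask)) {
          out[[length(out) + 1]] <- data.frame(kind = "split_read", chrom = a$target[r],
                                               cluster_pos = as.numeric(gpos), gpos = gpos,
                                               side = side, vpos = NA_integer_,
                                               precision = "exact", qname = a$qname[r],
                                               stringsAsFactors = FALSE)
        }
      }
    } else {
      # primary on the vector; a clip remapping uniquely to a chromosome
      # gives the genome-side coordinate
      if (in_mask(a$pos[r] + a$alen[r] %/% 2L, mask)) next
      if (cm_status[t] == "ambiguous") { n_ambig <- n_ambig + 1L; next }
      if (cm_status[t] != "unique" || is.na(cm_target[t]) ||
          is_vector_target(cm_target[t], vector_name)) next
      gs <- cm$pos[t]; ge <- cm$pos[t] + (cm$qend[t] - cm$qstart[t])
      interior_right <- clipL  # left-clip: junction abuts the clip's right end
      at_ref_right <- (cm$strand[t] == "+") == interior_right
      gpos <- if (at_ref_right) ge else gs
      side <- if (at_ref_right) "left" else "right"
      vpos <- if (clipL) a$pos[r] else a$pos[r] + a$alen[r]
      out[[length(out) + 1]] <- data.frame(kind = "split_read", chrom = cm_target[t],
                                           cluster_pos = as.numeric(gpos), gpos = gpos,
                                           side = side, vpos = as.integer(vpos),
                                           precision = "exact", qname = a$qname[r],
                                           stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else empty_evidence()
  ev <- ev[order(ev$chrom, ev$cluster_pos), , drop = FALSE]
  attr(ev, "ambiguous_clips") <- n_ambig
  ev
}

modal_value <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

#' Cluster junction evidence into insertion locus calls
#'
#' Single-linkage clustering on the genome coordinate with gap <= `window`;
#' within a cluster, evidence splits into left/right side groups by strand
#' geometry; the breakpoint is the modal split-read coordinate if any split
#' evidence exists, else the discordant-pair interval midpoint. Clusters
#' with total support below `min_support` are dropped.
#'
#' @param evidence row-bound evidence from [extract_junction_pairs()] and
#'   [extract_split_reads()].
#' @param window maximum within-cluster gap (default 2 x insert mean).
#' @param min_support minimum total evidence per reported locus.
#' @param insert_mean mean insert size, used for pair-interval midpoints.
#' @param vector_length used to classify which vector end is engaged.
#' @return a list of `locus_call` objects (class `vt_locus_calls`).
#' @export
cluster_evidence <- function(evidence, window = 530L, min_support = 3L,
                             insert_mean = 265, vector_length = NA_integer_) {
  calls <- list()
  if (is.null(evidence) || nrow(evidence) == 0)
    return(structure(calls, class = "vt_locus_calls", dropped = 0L))
  dropped <- 0L
  for (chrom in unique(evidence$chrom)) {
    e <- evidence[evidence$chrom == chrom, , drop = FALSE]
    e <- e[order(e$cluster_pos), , drop = FALSE]
    grp <- cumsum(c(0, diff(e$cluster_pos) > window))
    for (g in unique(grp)) {
      ec <- e[grp == g, , drop = FALSE]
      if (nrow(ec) < min_support) { dropped <- dropped + 1L; next }
      side_bp <- function(side) {
        s <- ec[ec$side == side, , drop = FALSE]
        if (!nrow(s)) return(list(bp = NA_integer_, precision = NA_character_,
                                  pairs = 0L, splits = 0L, vend = NA_character_))
        splits <- s[s$precision == "exact", , drop = FALSE]
        if (nrow(splits)) {
          bp <- modal_value(splits$gpos); prec <- "exact"
        } else {
          mid <- median(s$cluster_pos) + (if (side == "left") 1 else -1) * insert_mean / 2
          bp <- as.integer(round(mid)); prec <- "interval"
        }
        vend <- NA_character_
        vp <- s$vpos[!is.na(s$vpos)]
        if (length(vp) && !is.na(vector_length)) {
          vc <- vend_class(vp, vector_length)
          tb <- table(vc)
          vend <- names(tb)[which.max(tb)]
        }
        list(bp = bp, precision = prec, pairs = sum(s$precision == "interval"),
             splits = nrow(splits), vend = vend)
      }
      L <- side_bp("left"); R <- side_bp("right")
      status <- if (!is.na(L$bp) && !is.na(R$bp)) "both_ends"
        else if (!is.na(L$bp)) "left_only" else "right_only"
      calls[[length(calls) + 1]] <- structure(list(
        chrom = chrom, left_bp = L$bp, right_bp = R$bp,
        left_precision = L$precision, right_precision = R$precision,
        support = c(left_pairs = L$pairs, left_splits = L$splits,
                    right_pairs = R$pairs, right_splits = R$splits),
        vector_end = c(left = L$vend, right = R$vend),
        status = status, n_evidence = nrow(ec)), class = "locus_call")
    }
  }
  structure(calls, class = "vt_locus_calls", dropped = dropped)
}

#' @export
print.locus_call <- function(x, ...) {
  fmt_bp <- function(bp, prec) if (is.na(bp)) "-" else
    sprintf("%s (%s)", format(bp + 1, big.mark = ","), prec)  # 1-based in reports
  cat(sprintf("<locus_call> %s: left %s | right %s  [%s, support %d]\n", x$chrom,
              fmt_bp(x$left_bp, x$left_precision), fmt_bp(x$right_bp, x$right_precision),
              x$status, x$n_evidence))
  invisible(x)
}

#' @export
print.vt_locus_calls <- function(x, ...) {
  cat(sprintf("<vt_locus_calls> %d call(s), %d cluster(s) dropped below support\n",
              length(x), attr(x, "dropped") %||% 0L))
  for (c in x) print(c)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Junction-proximal copy multiplicity
#'
#' Ratio of the mean unmasked vector depth to the genome average coverage:
#' a locus carrying n tandem copies recruits approximately n times the
#' average depth of vector-mapped reads. Reported alongside the
#' marker/housekeeping estimator as corroboration.
#'
#' @param call a `locus_call` (absent/zero-support loci return NA).
#' @param vector_profile `coverage_profile` of the vector.
#' @param genome_mean_depth average nuclear genome depth.
#' @param mask masked vector intervals or NULL.
#' @return numeric multiplicity, or NA when undefined.
#' @export
support_multiplicity <- function(call, vector_profile, genome_mean_depth, mask = NULL) {
  if (is.null(call) || sum(call$support) == 0) return(NA_real_)
  stopifnot_msg(genome_mean_depth > 0, "average genome coverage must be known and > 0")
  depth <- vector_profile$depth
  keep <- rep(TRUE, length(depth))
  if (!is.null(mask) && nrow(mask))
    for (i in seq_len(nrow(mask))) keep[(mask$start[i] + 1L):mask$end[i]] <- FALSE
  vd <- depth[keep]
  covered <- vd[vd > 0]
  if (!length(covered)) return(NA_real_)
  mean(covered) / genome_mean_depth
}

#' Read a GFF3 annotation into a data.frame
#'
#' Minimal 9-column reader sufficient for context annotation: seqid, type,
#' start, end, strand and the ID/Name/Parent attributes.
#'
#' @param path GFF3 file.
#' @export
read_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(seqid = character(0), type = character(0), start = integer(0),
                      end = integer(0), strand = character(0), id = character(0),
                      name = character(0), parent = character(0)))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, character(1))
  }
  data.frame(seqid = f[, 1], type = f[, 3],
             start = as.integer(f[, 4]) - 1L, end = as.integer(f[, 5]),  # to 0-based half-open
             strand = f[, 7],
             id = attr_get(f[, 9], "ID"), name = attr_get(f[, 9], "Name"),
             parent = attr_get(f[, 9], "Parent"), stringsAsFactors = FALSE)
}

#' Annotate the genomic context of a locus call
#'
#' Reports the overlapping gene and sub-feature class (exon / intron / UTR /
#' intergenic) at the breakpoint, and the two nearest flanking genes with
#' distances.
#'
#' @param call a `locus_call`.
#' @param annotation a GFF3 path or a data.frame from [read_gff()].
#' @return the call with a `context` element added.
#' @export
annotate_context <- function(call, annotation) {
  gff <- if (is.character(annotation)) read_gff(annotation) else annotation
  bp <- if (!is.na(call$left_bp)) call$left_bp else call$right_bp
  g <- gff[gff$seqid == call$chrom, , drop = FALSE]
  if (!nrow(g)) {
    call$context <- list(class = "unannotated", gene = NA_character_,
                         neighbors = NULL)
    return(call)
  }
  genes <- g[g$type == "gene", , drop = FALSE]
  lbl <- function(rows) ifelse(is.na(rows$name), rows$id, rows$name)
  hit <- genes[bp >= genes$start & bp < genes$end, , drop = FALSE]
  if (nrow(hit)) {
    gid <- hit$id[1]
    sub <- g[!is.na(g$parent) & (g$parent == gid |
                                   g$parent %in% g$id[!is.na(g$parent) & g$parent == gid]), , drop = FALSE]
    cls <- if (any(sub$type == "exon" & bp >= sub$start & bp < sub$end)) "exon"
      else if (any(grepl("UTR", sub$type) & bp >= sub$start & bp < sub$end)) "UTR"
      else "intron"
    call$context <- list(class = cls, gene = lbl(hit)[1], neighbors = NULL)
  } else {
    up <- genes[genes$end <= bp, , drop = FALSE]
    dn <- genes[genes$start > bp, , drop = FALSE]
    nb <- rbind(
      if (nrow(up)) { u <- up[which.max(up$end), ]; data.frame(gene = lbl(u), side = "upstream", distance = bp - u$end) },
      if (nrow(dn)) { d <- dn[which.min(dn$start), ]; data.frame(gene = lbl(d), side = "downstream", distance = d$start - bp) })
    call$context <- list(class = "intergenic", gene = NA_character_, neighbors = nb)
  }
  call
}
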