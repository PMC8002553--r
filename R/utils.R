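# Small shared helpers: sequence utilities, interval arithmetic on plain
# data frames, FASTA/FASTQ text writers, and a config hash.

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) vapply(as.character(x), cpp_revcomp, character(1), USE.NAMES = FALSE)

str_len <- function(x) nchar(x, type = "bytes")

#' @noRd
subseq0 <- function(s, start, end) {
  # 0-based half-open substring
  substr(s, start + 1L, end)
}

gc_fraction <- function(s) {
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  sum(b %in% c("G", "C", "g", "c")) / length(b)
}

stopifnot_msg <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# merge sorted 0-based half-open intervals given as a 2-col matrix/data.frame
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(data.frame(start = integer(0), end = integer(0)))
  iv <- iv[order(iv[[1]], iv[[2]]), , drop = FALSE]
  out_s <- iv[[1]][1]; out_e <- iv[[2]][1]
  ss <- integer(0); ee <- integer(0)
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv[[1]][i] <= out_e) out_e <- max(out_e, iv[[2]][i])
      else { ss <- c(ss, out_s); ee <- c(ee, out_e); out_s <- iv[[1]][i]; out_e <- iv[[2]][i] }
    }
  }
  data.frame(start = c(ss, out_s), end = c(ee, out_e))
}

# total length of 0-based half-open intervals overlapping [start, end)
interval_overlap_bp <- function(iv, start, end) {
  if (nrow(iv) == 0) return(0L)
  lo <- pmax(iv$start, start); hi <- pmin(iv$end, end)
  sum(pmax(hi - lo, 0L))
}

point_in_intervals <- function(p, iv) {
  if (nrow(iv) == 0) return(rep(FALSE, length(p)))
  vapply(p, function(x) any(x >= iv$start & x < iv$end), logical(1))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, str_len(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, str_len(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write paired reads as FASTQ (Phred+33, fixed quality "I")
#'
#' @param reads a `vt_reads` object from [simulate_paired_reads()].
#' @param path1,path2 output FASTQ files for mate 1 and mate 2.
#' @export
write_fastq <- function(reads, path1, path2) {
  wr <- function(nms, seqs, path) {
    if (length(seqs) == 0) { file.create(path); return(invisible(path)) }
    qual <- strrep("I", str_len(seqs))
    writeLines(as.vector(rbind(paste0("@", nms), seqs, "+", qual)), path)
  }
  wr(reads$qname, reads$r1, path1)
  wr(reads$qname, reads$r2, path2)
  invisible(c(path1, path2))
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

# FNV-1a over the deparsed object; stable config fingerprint without
# external digest dependencies
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  b <- utf8ToInt(s)
  h <- 17
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

# derive a bounded child seed (< 2^31) from a base seed and a stream label
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647 + 1
}

vt_log <- function(..., verbose = getOption("vectrace.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}
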