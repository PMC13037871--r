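# I/O for aligned fragments, alignments and trees.

#' Write aligned fragments in the tab-separated pileup-ready format
#'
#' Columns: `read_id`, `start` (1-based), `strand`, `seq`, `qual`
#' (Phred+33).
#'
#' @param fragments an `aligned_fragments` data frame.
#' @param path output file.
#' @export
write_fragments <- function(fragments, path) {
  cols <- c("read_id", "start", "strand", "seq", "qual")
  utils::write.table(fragments[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read aligned fragments from the tab-separated format
#' @param path file written by [write_fragments()].
#' @param genome_length reference length (defaults to the rCRS length).
#' @return `aligned_fragments` data frame.
#' @export
read_fragments <- function(path, genome_length = RCRS_LENGTH) {
  fr <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character",
                                         "character", "character"))
  class(fr) <- c("aligned_fragments", "data.frame")
  attr(fr, "genome_length") <- genome_length
  fr
}

#' Read mapped single-end fragments from a SAM file
#'
#' A thin reader for pre-aligned reads: keeps mapped records, and skips
#' reads whose CIGAR contains anything other than matches (`M`, `=`,
#' `X`) or soft/hard clips at the ends — indels are outside the aligned
#' fragment contract. Soft-clipped bases are removed.
#'
#' @param path SAM file (text).
#' @param genome_length reference length for circular coordinates.
#' @return `aligned_fragments` data frame.
#' @export
read_fragments_sam <- function(path, genome_length = RCRS_LENGTH) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next            # unmapped
    cigar <- f[6]
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    lens <- as.integer(sub("[A-Z=]", "", ops))
    typ <- sub("\\d+", "", ops)
    if (any(!typ %in% c("M", "=", "X", "S", "H"))) next
    core <- typ %in% c("M", "=", "X")
    if (sum(core) == 0 || any(diff(which(core)) != 1L)) next
    seq <- f[10]; qual <- f[11]
    # strip soft clips
    pre <- if (typ[1] == "S") lens[1] else 0L
    post <- if (typ[length(typ)] == "S") lens[length(typ)] else 0L
    keep <- (pre + 1L):(nchar(seq) - post)
    out[[length(out) + 1L]] <- data.frame(
      read_id = f[1], start = as.integer(f[4]),
      strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
      seq = substr(seq, keep[1], keep[length(keep)]),
      qual = substr(qual, keep[1], keep[length(keep)]),
      stringsAsFactors = FALSE)
  }
  fr <- do.call(rbind, out)
  class(fr) <- c("aligned_fragments", "data.frame")
  attr(fr, "genome_length") <- genome_length
  fr
}

#' Write sequences to FASTA
#'
#' @param seqs character matrix (rows = sequences) or named list/vector
#'   of sequence strings or character vectors.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.matrix(seqs)) {
    ids <- rownames(seqs)
    strings <- apply(seqs, 1, chars_to_seq)
  } else {
    ids <- names(seqs)
    strings <- vapply(seqs, function(s)
      if (length(s) > 1L) chars_to_seq(s) else s, character(1))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(strings))
    writeLines(c(paste0(">", ids[i]), strings[i]), con)
  invisible(path)
}

#' Read a FASTA alignment as a character matrix
#'
#' @param path FASTA file; sequences must share one length to form an
#'   alignment matrix.
#' @return Uppercase character matrix, rows named by FASTA headers.
#' @export
read_fasta_matrix <- function(path) {
  dna <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(dna)))
  m[!(m %in% DNA_BASES)] <- "N"
  m
}
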