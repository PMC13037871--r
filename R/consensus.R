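#' Consensus-calling policy
#'
#' Thresholds for damage-aware consensus reconstruction. Defaults follow
#' the standard ancient-mtDNA rule set: a base is called when covered by
#' at least three independent (deduplicated) fragments and at least 65%
#' of them agree; deaminated positions are quality-masked; up to three
#' terminal positions with base quality below 20 are trimmed from each
#' read end; C->T (or G->A) mismatches within the first/last three read
#' positions mark a fragment as deaminated.
#'
#' @param min_depth minimum independent fragments per called position.
#' @param min_agreement minimum modal-base fraction (inclusive).
#' @param damage_window terminal positions inspected for deamination.
#' @param trim_quality quality threshold for terminal trimming.
#' @param trim_max maximum positions trimmed per read end.
#' @return An object of class `consensus_policy`.
#' @export
consensus_policy <- function(min_depth = 3L, min_agreement = 0.65,
                             damage_window = 3L, trim_quality = 20L,
                             trim_max = 3L) {
  if (min_depth < 1) stop_invalid("'min_depth' must be >= 1")
  if (min_agreement <= 0 || min_agreement > 1)
    stop_invalid("'min_agreement' must be in (0, 1]")
  structure(list(min_depth = as.integer(min_depth),
                 min_agreement = min_agreement,
                 damage_window = as.integer(damage_window),
                 trim_quality = as.integer(trim_quality),
                 trim_max = as.integer(trim_max)),
            class = "consensus_policy")
}

# Reference bases under a fragment, honouring circular coordinates.
fragment_ref_chars <- function(start, len, reference) {
  reference[wrap_pos(start + 0:(len - 1L), length(reference))]
}

#' Classify fragments as deaminated
#'
#' A fragment is deaminated if a C->T mismatch against the reference (or
#' the strand-equivalent G->A) occurs within `window` positions of either
#' fragment end.
#'
#' @param fragments `aligned_fragments` data frame.
#' @param reference reference genome as a character vector (circular).
#' @param window terminal positions inspected (default 3).
#' @return Logical vector, one element per fragment.
#' @export
classify_deaminated <- function(fragments, reference, window = 3L) {
  if (window < 1) stop_invalid("'window' must be >= 1")
  vapply(seq_len(nrow(fragments)), function(i) {
    bases <- seq_to_chars(fragments$seq[i])
    L <- length(bases)
    ref <- fragment_ref_chars(fragments$start[i], L, reference)
    ends <- unique(c(seq_len(min(window, L)),
                     seq.int(max(1L, L - window + 1L), L)))
    any((ref[ends] == "C" & bases[ends] == "T") |
        (ref[ends] == "G" & bases[ends] == "A"))
  }, logical(1))
}

#' Mask deaminated positions and trim low-quality read ends
#'
#' Sets the base quality of every damage-susceptible mismatch (reference
#' C read T, or reference G read A, anywhere in the read) to 0, which
#' excludes those bases from consensus evidence, then removes up to
#' `policy$trim_max` consecutive terminal positions with quality below
#' `policy$trim_quality` from each end. Interior bases are never removed.
#'
#' @param fragments `aligned_fragments` data frame.
#' @param reference reference genome character vector.
#' @param policy a [consensus_policy()].
#' @return The fragments with updated `start`, `seq` and `qual`.
#' @export
mask_and_trim <- function(fragments, reference, policy = consensus_policy()) {
  G <- length(reference)
  for (i in seq_len(nrow(fragments))) {
    bases <- seq_to_chars(fragments$seq[i])
    quals <- chr_to_qual(fragments$qual[i])
    L <- length(bases)
    ref <- fragment_ref_chars(fragments$start[i], L, reference)
    dmg <- (ref == "C" & bases == "T") | (ref == "G" & bases == "A")
    quals[dmg] <- 0L
    # trim up to trim_max consecutive low-quality bases from each end
    left <- 0L
    while (left < policy$trim_max && left < L &&
           quals[left + 1L] < policy$trim_quality) left <- left + 1L
    right <- 0L
    while (right < policy$trim_max && left + right < L &&
           quals[L - right] < policy$trim_quality) right <- right + 1L
    keep <- if (left + right >= L) integer(0) else (left + 1L):(L - right)
    fragments$start[i] <- wrap_pos(fragments$start[i] + left, G)
    fragments$seq[i] <- chars_to_seq(bases[keep])
    fragments$qual[i] <- qual_to_chr(quals[keep])
  }
  fragments[nchar(fragments$seq) > 0L, , drop = FALSE]
}

#' Contamination estimate
#'
#' Point estimate and interval for the present-day contamination fraction
#' of a library, as produced by an external likelihood-based estimator;
#' consumed by [contamination_gate()].
#'
#' @param point point estimate in `[0, 1]`.
#' @param lower,upper interval bounds.
#' @return Object of class `contamination_estimate`.
#' @export
contamination_estimate <- function(point, lower = point, upper = point) {
  if (any(c(point, lower, upper) < 0) || any(c(point, lower, upper) > 1))
    stop_invalid("contamination values must be in [0, 1]")
  if (lower > point || point > upper)
    stop_invalid("'lower' <= 'point' <= 'upper' required")
  structure(list(point = point, lower = lower, upper = upper),
            class = "contamination_estimate")
}

#' Gate a library on its contamination estimate
#'
#' Libraries whose contamination point estimate exceeds `threshold`
#' (strictly above; default 10%) are restricted to fragments showing the
#' diagnostic ancient-DNA damage signal ([classify_deaminated()]); at or
#' below the threshold all fragments pass.
#'
#' @param fragments `aligned_fragments` data frame.
#' @param estimate a [contamination_estimate()] or a single number.
#' @param reference reference genome character vector.
#' @param threshold gate threshold (default 0.10).
#' @param window deamination window passed to [classify_deaminated()].
#' @return List with `decision` (`"all_reads"` or `"deaminated_only"`)
#'   and `fragments` (the retained set).
#' @export
contamination_gate <- function(fragments, estimate, reference,
                               threshold = 0.10, window = 3L) {
  if (threshold <= 0 || threshold >= 1) stop_invalid("'threshold' must be in (0, 1)")
  point <- if (inherits(estimate, "contamination_estimate")) estimate$point
           else as.numeric(estimate)
  if (point <= threshold)
    return(list(decision = "all_reads", fragments = fragments))
  keep <- classify_deaminated(fragments, reference, window)
  if (!any(keep))
    stop_invalid("no deaminated fragments remain after contamination gating; ",
                 "sample is unprocessable")
  list(decision = "deaminated_only",
       fragments = fragments[keep, , drop = FALSE])
}

# Remove duplicate fragments: identical start, end and strand.
dedup_fragments <- function(fragments, genome_length) {
  ends <- wrap_pos(fragments$start + nchar(fragments$seq) - 1L, genome_length)
  key <- paste(fragments$start, ends, fragments$strand)
  fragments[!duplicated(key), , drop = FALSE]
}

#' Call a consensus sequence from aligned fragments
#'
#' Per reference position, tallies the bases of deduplicated fragments
#' (bases with quality 0 are excluded as evidence) and emits the modal
#' base when at least `policy$min_depth` fragments cover the position and
#' the modal base reaches `policy$min_agreement` of them; otherwise `N`.
#' Modal-base ties emit `N`.
#'
#' @param fragments `aligned_fragments` data frame (typically after
#'   [contamination_gate()] and [mask_and_trim()]).
#' @param policy a [consensus_policy()].
#' @param genome_length reference length (defaults to the fragments'
#'   `genome_length` attribute, then to the rCRS length).
#' @param dedup remove duplicate fragments (identical start, end,
#'   strand) before tallying; on by default so "independent fragments"
#'   means post-deduplication molecules.
#' @return Object of class `consensus_sequence`: list with `calls`
#'   (character vector over the reference), `depth` (per-position counted
#'   evidence), `n_count` and `completeness`.
#' @examples
#' ref <- c("A","C","G","T")
#' fr <- data.frame(read_id = paste0("r", 1:3), start = 1L, strand = "+",
#'                  seq = "ACGT", qual = "IIII")
#' call_consensus(fr, genome_length = 4L)$calls
#' @export
call_consensus <- function(fragments, policy = consensus_policy(),
                           genome_length = NULL, dedup = TRUE) {
  G <- genome_length %||% attr(fragments, "genome_length") %||% RCRS_LENGTH
  counts <- matrix(0L, G, 4L, dimnames = list(NULL, DNA_BASES))
  if (nrow(fragments) > 0) {
    if (dedup) fragments <- dedup_fragments(fragments, G)
    lens <- nchar(fragments$seq)
    pos <- wrap_pos(rep(fragments$start, lens) +
                      sequence(lens, from = 0L, by = 1L), G)
    bases <- unlist(strsplit(fragments$seq, "", fixed = TRUE), use.names = FALSE)
    quals <- unlist(lapply(fragments$qual, chr_to_qual), use.names = FALSE)
    use <- quals > 0L & bases %in% DNA_BASES
    b <- match(bases[use], DNA_BASES)
    counts <- matrix(tabulate(pos[use] + (b - 1L) * G, nbins = 4L * G),
                     G, 4L, dimnames = list(NULL, DNA_BASES))
  }
  depth <- rowSums(counts)
  top <- max.col(counts, ties.method = "first")
  top_count <- counts[cbind(seq_len(G), top)]
  tied <- rowSums(counts == top_count & counts > 0L) > 1L
  frac <- ifelse(depth > 0, top_count / depth, 0)
  called <- depth >= policy$min_depth &
    frac >= policy$min_agreement - 1e-12 & !tied
  calls <- ifelse(called, DNA_BASES[top], "N")
  n_count <- sum(calls == "N")
  structure(list(calls = calls, depth = as.integer(depth),
                 n_count = n_count, completeness = 1 - n_count / G),
            class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat(sprintf("Consensus over %d positions: %d called (%.1f%% complete), %d N\n",
              length(x$calls), length(x$calls) - x$n_count,
              100 * x$completeness, x$n_count))
  invisible(x)
}
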