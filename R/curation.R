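# Dataset-construction rules: completeness filtering, within-site
# duplicate pruning, control-region trimming, alignment site deletion.

#' Default D-loop (control region) bounds on the rCRS coordinate system
#' @export
DLOOP_BOUNDS <- list(c(16024L, 16569L), c(1L, 576L))

as_seq_matrix <- function(sequences) {
  if (is.matrix(sequences)) return(sequences)
  if (inherits(sequences, "consensus_sequence"))
    return(matrix(sequences$calls, 1L))
  if (is.list(sequences)) {
    rows <- lapply(sequences, function(s)
      if (inherits(s, "consensus_sequence")) s$calls
      else if (length(s) == 1L) seq_to_chars(s) else s)
    return(do.call(rbind, rows))
  }
  stop_invalid("cannot interpret 'sequences' as an alignment matrix")
}

#' Filter sequences on completeness
#'
#' Excludes mitogenomes with more than `max_n` unresolved positions
#' (default 2,600 on the 16,569-bp reference, i.e. below 85% complete);
#' a sequence with exactly `max_n` Ns is retained. High missingness
#' destabilises parsimony topologies, which is why heavily incomplete
#' genomes are excluded from tree building.
#'
#' @param sequences character matrix (rows = individuals, values
#'   A/C/G/T/N) or list of sequences/[call_consensus()] results.
#' @param max_n maximum unresolved positions (strictly more excludes).
#' @return List with `retained` (matrix subset) and `log` (data frame
#'   `id`, `n_count`, `retained`, `reason`).
#' @export
completeness_filter <- function(sequences, max_n = 2600L) {
  m <- as_seq_matrix(sequences)
  n_count <- rowSums(matrix(!(m %in% DNA_BASES), nrow(m)))
  keep <- n_count <= max_n
  log <- data.frame(id = rownames(m) %||% as.character(seq_len(nrow(m))),
                    n_count = as.integer(n_count), retained = keep,
                    reason = ifelse(keep, "",
                                    sprintf("more than %d unresolved positions", max_n)),
                    stringsAsFactors = FALSE)
  list(retained = m[keep, , drop = FALSE], log = log)
}

# TRUE iff the two rows agree at every position resolved in both.
pairwise_resolved_equal <- function(a, b) {
  both <- a %in% DNA_BASES & b %in% DNA_BASES
  all(a[both] == b[both])
}

#' Prune duplicate individuals within an archaeological site
#'
#' Two sequences from the same site are duplicates when they show no
#' variable sites across their mitochondrial genomes, i.e. they agree at
#' every position resolved in both. Duplicate classes are the transitive
#' closure of this relation; each class is represented by the sequence
#' with the fewest unresolved positions (ties broken by lexicographic
#' id).
#'
#' @param sequences character matrix with rownames (individual ids).
#' @param sites named character vector mapping individual id to site id;
#'   individuals from different sites are never merged.
#' @return List with `retained` (matrix of representatives), `classes`
#'   (list of id vectors) and `log` (data frame `id`, `site`, `class`,
#'   `representative`).
#' @export
prune_duplicates <- function(sequences, sites) {
  m <- as_seq_matrix(sequences)
  ids <- rownames(m)
  if (is.null(ids)) stop_invalid("'sequences' must have rownames (ids)")
  sites <- sites[ids]
  n <- nrow(m)
  # union-find over within-site duplicate pairs
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || sites[i] != sites[j]) next
    if (pairwise_resolved_equal(m[i, ], m[j, ])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  n_unres <- rowSums(matrix(!(m %in% DNA_BASES), n))
  classes <- split(seq_len(n), comp)
  rep_idx <- vapply(classes, function(members) {
    o <- order(n_unres[members], ids[members])
    members[o[1]]
  }, integer(1))
  class_id <- match(comp, names(classes))
  log <- data.frame(id = ids, site = unname(sites), class = class_id,
                    representative = ids[rep_idx[class_id]],
                    stringsAsFactors = FALSE)
  keep <- sort(unname(rep_idx))
  list(retained = m[keep, , drop = FALSE],
       classes = lapply(classes, function(k) ids[k]),
       log = log)
}

#' Extract the whole or coding region of an alignment
#'
#' `coding` removes the D-loop (control region) columns; the default
#' bounds are the rCRS control region, 16024-16569 and 1-576. Column
#' order is preserved.
#'
#' @param alignment character matrix in reference coordinates.
#' @param region `"whole"` or `"coding"`.
#' @param dloop_bounds list of `c(start, end)` reference intervals.
#' @return Sub-alignment matrix; attribute `columns` holds the retained
#'   reference coordinates.
#' @export
extract_region <- function(alignment, region = c("whole", "coding"),
                           dloop_bounds = DLOOP_BOUNDS) {
  region <- match.arg(region)
  if (region == "whole") {
    attr(alignment, "columns") <- seq_len(ncol(alignment))
    return(alignment)
  }
  drop <- unique(unlist(lapply(dloop_bounds, function(b) seq.int(b[1], b[2]))))
  keep <- setdiff(seq_len(ncol(alignment)), drop)
  out <- alignment[, keep, drop = FALSE]
  attr(out, "columns") <- keep
  out
}

#' Filter alignment columns by missing-data mode
#'
#' `complete` deletion keeps only columns with no unresolved base in any
#' row; `partial` deletion keeps columns where the fraction of resolved
#' rows is at least `p` (default 0.90, inclusive threshold).
#'
#' @param alignment rectangular character matrix.
#' @param mode `"complete"` or `"partial"`.
#' @param p per-column resolved fraction for partial deletion, in (0, 1].
#' @return Filtered alignment; attribute `columns` gives the kept column
#'   indices of the input.
#' @export
site_deletion <- function(alignment, mode = c("complete", "partial"), p = 0.90) {
  mode <- match.arg(mode)
  resolved <- matrix(alignment %in% DNA_BASES, nrow(alignment))
  frac <- colMeans(resolved)
  if (mode == "complete") {
    keep <- which(frac == 1)
  } else {
    if (p <= 0 || p > 1) stop_invalid("'p' must be in (0, 1]")
    keep <- which(frac >= p - 1e-12)
  }
  out <- alignment[, keep, drop = FALSE]
  attr(out, "columns") <- keep
  out
}
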