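#' Evolve sequences along a time tree under a strict clock
#'
#' Simulates nucleotide sequences on a rooted time tree (branch lengths in
#' years) under the substitution model in `clock`. A fixed proportion of
#' sites (`clock$invariant_fraction`) is drawn once per simulation and
#' never substitutes; the remaining sites evolve at `clock$rate`
#' substitutions/bp/year. Transition probabilities per branch come from
#' the matrix exponential of the scaled TN93 (or JC69) generator.
#'
#' @param tree rooted [ape::phylo] with branch lengths in years.
#' @param clock a [clock_model()].
#' @param length alignment length in bp.
#' @param root_seq optional root sequence (character vector of A/C/G/T of
#'   length `length`); drawn from the stationary frequencies if omitted.
#' @param return_internal if `TRUE`, attach internal-node sequences as
#'   attribute `internal` (rows named by node number) for truth
#'   bookkeeping in simulations.
#' @param seed optional RNG seed.
#' @return Character matrix (tips x sites, values A/C/G/T) with rownames
#'   `tree$tip.label`; attributes `invariant` (logical mask) and
#'   optionally `internal`.
#' @examples
#' tr <- simulate_tree(5, c(0, 50000), seed = 1)
#' aln <- evolve_sequences(tr, clock_model(rate = 1e-7), length = 500, seed = 2)
#' dim(aln)
#' @export
evolve_sequences <- function(tree, clock, length, root_seq = NULL,
                             return_internal = FALSE, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(clock, "clock_model"))
  if (length < 1) stop_invalid("'length' must be >= 1")
  if (!ape::is.rooted(tree)) stop_invalid("'tree' must be rooted")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  Q <- clock_rate_matrix(clock)
  with_seed(seed, {
    invariant <- stats::runif(length) < clock$invariant_fraction
    if (is.null(root_seq)) {
      root_int <- sample.int(4L, length, replace = TRUE, prob = clock$base_freqs)
    } else {
      root_int <- match(toupper(root_seq), DNA_BASES)
      if (anyNA(root_int)) stop_invalid("'root_seq' must contain only A/C/G/T")
    }
    seqs <- matrix(NA_integer_, n_node, length)
    root <- n_tip + 1L
    seqs[root, ] <- root_int
    tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    var_idx <- which(!invariant)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      d <- clock$rate * tree$edge.length[e]
      child_seq <- seqs[parent, ]
      if (d > 0 && length(var_idx)) {
        P <- clock_pmatrix(Q, d)
        pv <- child_seq[var_idx]
        for (s in 1:4) {
          at <- which(pv == s)
          if (length(at))
            child_seq[var_idx[at]] <-
              sample.int(4L, length(at), replace = TRUE, prob = P[s, ])
        }
      }
      seqs[child, ] <- child_seq
    }
    tips <- matrix(DNA_BASES[seqs[seq_len(n_tip), , drop = FALSE]],
                   n_tip, length, dimnames = list(tree$tip.label, NULL))
    attr(tips, "invariant") <- invariant
    if (return_internal) {
      internal <- matrix(DNA_BASES[seqs[(n_tip + 1L):n_node, , drop = FALSE]],
                         tree$Nnode, length,
                         dimnames = list(as.character((n_tip + 1L):n_node), NULL))
      attr(tips, "internal") <- internal
    }
    tips
  })
}
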