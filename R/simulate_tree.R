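#' Simulate a serially sampled coalescent tree
#'
#' Generates a rooted binary time tree under a constant-population-size
#' coalescent with heterochronous (serially sampled) tips, the standard
#' model for ancient-DNA phylogenies where specimens span tens of
#' millennia. Branch lengths are in years; tip ages (years before present)
#' are drawn uniformly from `tip_age_range` and attached to the result.
#'
#' @param n_tips number of tips (>= 2).
#' @param tip_age_range length-2 numeric, range of tip sampling ages in
#'   years before present.
#' @param pop_size coalescent population-size parameter in years: two
#'   active lineages coalesce at rate `1/pop_size` per year. Controls tree
#'   depth relative to the sampling window.
#' @param tip_ages optional explicit tip ages (overrides `tip_age_range`).
#' @param seed optional RNG seed for reproducibility.
#' @return An [ape::phylo] object with branch lengths in years and an
#'   attribute `tip_ages` (named numeric vector, years BP).
#' @examples
#' tr <- simulate_tree(10, tip_age_range = c(40000, 120000), seed = 1)
#' attr(tr, "tip_ages")
#' @export
simulate_tree <- function(n_tips, tip_age_range = c(0, 40000),
                          pop_size = 50000, tip_ages = NULL, seed = NULL) {
  if (n_tips < 2) stop_invalid("'n_tips' must be at least 2")
  if (pop_size <= 0) stop_invalid("'pop_size' must be positive")
  with_seed(seed, {
    if (is.null(tip_ages)) {
      tip_ages <- stats::runif(n_tips, tip_age_range[1], tip_age_range[2])
    } else if (length(tip_ages) != n_tips) {
      stop_invalid("'tip_ages' must have length 'n_tips'")
    }
    names(tip_ages) <- sprintf("t%02d", seq_len(n_tips))
    simulate_serial_coalescent(tip_ages, pop_size)
  })
}

# Event-driven heterochronous coalescent. Time runs backwards (age
# increasing). Lineages enter at their tip age; while k >= 2 lineages are
# active, the next coalescence is exponential with rate k(k-1)/2 / pop_size.
simulate_serial_coalescent <- function(tip_ages, pop_size) {
  n <- length(tip_ages)
  ord <- order(tip_ages)
  pending <- ord                    # tip indices not yet active, by age
  heights <- c(tip_ages, rep(NA_real_, n - 1L))
  active <- integer(0)
  t_now <- tip_ages[pending[1]]
  events <- matrix(0L, n - 1L, 2L)  # children of each internal node
  ev <- 0L
  while (ev < n - 1L) {
    # absorb all pending tips at or before current time
    while (length(pending) && tip_ages[pending[1]] <= t_now) {
      active <- c(active, pending[1]); pending <- pending[-1]
    }
    k <- length(active)
    next_tip <- if (length(pending)) tip_ages[pending[1]] else Inf
    if (k < 2) { t_now <- next_tip; next }
    wait <- stats::rexp(1, rate = k * (k - 1) / 2 / pop_size)
    if (t_now + wait > next_tip) { t_now <- next_tip; next }
    t_now <- t_now + wait
    pair <- sample(k, 2L)
    ev <- ev + 1L
    events[ev, ] <- active[pair]
    node_idx <- n + ev              # creation-order index
    heights[node_idx] <- t_now
    active <- c(active[-pair], node_idx)
  }
  # ape numbering: tips 1..n, root n+1. Internal creation order i maps to
  # ape node number 2n - i (root, created last, becomes n+1).
  ape_num <- function(idx) ifelse(idx <= n, idx, 2L * n - (idx - n))
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  for (i in seq_len(n - 1L)) {
    parent <- n + i
    for (j in 1:2) {
      child <- events[i, j]
      r <- 2L * (i - 1L) + j
      edge[r, ] <- c(ape_num(parent), ape_num(child))
      elen[r] <- heights[parent] - heights[child]
    }
  }
  tree <- structure(
    list(edge = edge, edge.length = elen, Nnode = n - 1L,
         tip.label = names(tip_ages)),
    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "tip_ages") <- tip_ages
  tree
}
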