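# Pairwise nucleotide distances with pairwise deletion, and the
# within-site versus branch-wide diversity comparison.

#' Pairwise nucleotide distance with pairwise deletion
#'
#' Counts differing positions among positions resolved (A/C/G/T) in both
#' sequences; positions where either sequence is N are excluded.
#'
#' @param a,b character vectors of equal length.
#' @return List with `d` (mismatch count) and `n_compared`.
#' @examples
#' pairwise_distance(c("A","C","G","T"), c("A","C","N","T"))
#' @export
pairwise_distance <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("sequences must have equal length")
  both <- a %in% DNA_BASES & b %in% DNA_BASES
  list(d = sum(a[both] != b[both]), n_compared = sum(both))
}

#' All pairwise distances within and between sequences
#'
#' @param sequences character matrix (rows = sequences).
#' @return List of symmetric matrices `d` and `n_compared`.
#' @export
distance_matrix <- function(sequences) {
  m <- as_seq_matrix(sequences)
  n <- nrow(m)
  ids <- rownames(m) %||% as.character(seq_len(n))
  d <- matrix(0L, n, n, dimnames = list(ids, ids))
  nc <- matrix(ncol(m), n, n, dimnames = list(ids, ids))
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pd <- pairwise_distance(m[i, ], m[j, ])
    d[i, j] <- d[j, i] <- pd$d
    nc[i, j] <- nc[j, i] <- pd$n_compared
  }
  list(d = d, n_compared = nc)
}

# Vector of distances over all unordered pairs in a group.
group_distance_vector <- function(sequences) {
  d <- distance_matrix(sequences)$d
  d[upper.tri(d)]
}

#' Wilcoxon rank-sum comparison of two distance vectors
#'
#' Two-sided test. For small tie-free samples (n + m <= 25) the exact
#' distribution is used; small tied samples (n + m <= 12) get an exact
#' permutation p-value by complete enumeration of group assignments
#' (the permutation distribution of the rank-sum is symmetric, so the
#' two-sided p is the probability of a statistic at least as far from
#' its mean as observed); larger samples use the normal approximation
#' with continuity correction.
#'
#' @param x,y numeric vectors.
#' @return List with `W` (Mann-Whitney statistic for `x`), `p` and
#'   `method`.
#' @export
rank_sum_test <- function(x, y) {
  n <- length(x); m <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (!ties && n + m <= 25) {
    wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = TRUE)
    return(list(W = unname(wt$statistic), p = wt$p.value, method = "exact"))
  }
  if (ties && n + m <= 12) {
    idx <- utils::combn(n + m, n)
    ws <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    mu <- n * m / 2
    p <- mean(abs(ws - mu) >= abs(W - mu) - 1e-9)
    return(list(W = W, p = p, method = "exact-permutation"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                       correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value, method = "normal")
}

#' Compare within-site diversity to branch-wide diversity
#'
#' Computes pairwise nucleotide distances within each archaeological
#' site's sequences and within the branch-wide reference group, then
#' compares each site's distance vector to the branch-wide vector with a
#' two-sided Wilcoxon rank-sum test; p-values are adjusted across sites
#' (Benjamini-Hochberg by default).
#'
#' @param site_groups named list of character matrices (one per site).
#' @param branch_group character matrix of branch-wide sequences.
#' @param adjust multiple-testing method for [stats::p.adjust()].
#' @return `data.frame` with one row per comparable site: `site`,
#'   `n_seqs`, `n_pairs`, `W`, `p_raw`, `p_adjusted`, `method`. Sites
#'   with fewer than two sequences are skipped with a warning. The
#'   branch-wide distance vector is attached as attribute
#'   `branch_distances`, per-site vectors as `site_distances`.
#' @export
compare_site_diversity <- function(site_groups, branch_group, adjust = "BH") {
  branch_d <- group_distance_vector(branch_group)
  usable <- vapply(site_groups, function(g) nrow(as_seq_matrix(g)) >= 2, logical(1))
  if (any(!usable))
    warning("skipping sites with fewer than 2 sequences: ",
            paste(names(site_groups)[!usable], collapse = ", "))
  site_groups <- site_groups[usable]
  rows <- lapply(names(site_groups), function(site) {
    g <- as_seq_matrix(site_groups[[site]])
    dv <- group_distance_vector(g)
    ts <- rank_sum_test(dv, branch_d)
    data.frame(site = site, n_seqs = nrow(g), n_pairs = length(dv),
               W = ts$W, p_raw = ts$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(site = character(0), n_seqs = integer(0),
                      n_pairs = integer(0), W = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0),
                      method = character(0)))
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = adjust)
  out$method <- adjust
  attr(out, "branch_distances") <- branch_d
  attr(out, "site_distances") <-
    lapply(site_groups, function(g) group_distance_vector(as_seq_matrix(g)))
  out
}
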