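# Shared fixtures built in code.

random_genome <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

# Build an aligned_fragments data frame directly from character data.
make_fragments <- function(starts, seqs, quals = NULL, strands = NULL,
                           genome_length = NULL) {
  n <- length(seqs)
  if (is.null(quals)) quals <- vapply(nchar(seqs), function(L)
    strrep("I", L), character(1))  # "I" = Q40
  if (is.null(strands)) strands <- rep("+", n)
  fr <- data.frame(read_id = sprintf("r%03d", seq_len(n)),
                   start = as.integer(starts), strand = strands,
                   seq = seqs, qual = quals, stringsAsFactors = FALSE)
  class(fr) <- c("aligned_fragments", "data.frame")
  if (!is.null(genome_length)) attr(fr, "genome_length") <- genome_length
  fr
}

qualstr <- function(q) intToUtf8(q + 33L, multiple = FALSE)

# Independent brute-force consensus oracle: per-position tally applying
# the depth >= min_depth and modal fraction >= min_agreement rule, after
# removing duplicate (start, end, strand) fragments and quality-0 bases.
brute_force_consensus <- function(fragments, G, min_depth = 3,
                                  min_agreement = 0.65) {
  ends <- ((fragments$start + nchar(fragments$seq) - 2L) %% G) + 1L
  dup <- duplicated(paste(fragments$start, ends, fragments$strand))
  fragments <- fragments[!dup, , drop = FALSE]
  calls <- character(G)
  for (pos in seq_len(G)) {
    votes <- character(0)
    for (i in seq_len(nrow(fragments))) {
      L <- nchar(fragments$seq[i])
      offs <- pos - fragments$start[i]
      offs <- ((offs %% G) + G) %% G        # offset on the circle
      if (offs < L) {
        b <- substr(fragments$seq[i], offs + 1, offs + 1)
        q <- utf8ToInt(substr(fragments$qual[i], offs + 1, offs + 1)) - 33L
        if (q > 0 && b %in% c("A", "C", "G", "T")) votes <- c(votes, b)
      }
    }
    if (length(votes) < min_depth) { calls[pos] <- "N"; next }
    tab <- sort(table(votes), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) { calls[pos] <- "N"; next }
    calls[pos] <- if (tab[1] / length(votes) >= min_agreement - 1e-12)
      names(tab)[1] else "N"
  }
  calls
}

# Exhaustive two-sided rank-sum oracle: enumerate every assignment of
# the pooled values to the two groups; statistic is the Mann-Whitney U
# of the first group; p is the probability of a U at least as far from
# n*m/2 as observed.
enumerate_rank_sum <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(n + m, n)
  ws <- apply(idx, 2, function(k) sum(r[k]) - n * (n + 1) / 2)
  mu <- n * m / 2
  list(W = W_obs, p = mean(abs(ws - mu) >= abs(W_obs - mu) - 1e-9))
}

# All ancestors (node numbers) of a node on the root path, including it.
root_path_nodes <- function(tree, node) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path <- node
  while (parent[node] != 0L) { node <- parent[node]; path <- c(path, node) }
  path
}

# Labels matching the package's node-labelling scheme ("n<number>" for
# unlabelled internal nodes).
node_label_set <- function(tree, nodes) {
  n_tip <- length(tree$tip.label)
  vapply(nodes, function(k)
    if (k <= n_tip) tree$tip.label[k] else paste0("n", k), character(1))
}
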