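# Diagnostic-SNP extraction on a fixed rooted tree, and placement of
# incomplete query sequences by walking the tree over node-defining
# substitutions.

# Stable labels for every node: tips keep their names; internal nodes use
# tree$node.label when present, otherwise "n<number>".
node_labels <- function(tree) {
  n_tip <- length(tree$tip.label)
  lab <- character(n_tip + tree$Nnode)
  lab[seq_len(n_tip)] <- tree$tip.label
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  if (!is.null(tree$node.label) && all(nzchar(tree$node.label))) {
    lab[internal] <- tree$node.label
  } else {
    lab[internal] <- paste0("n", internal)
  }
  lab
}

BASE_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L)
bit_to_base <- function(bit) DNA_BASES[match(bit, c(1L, 2L, 4L, 8L))]
first_bit <- function(set) {
  for (b in c(1L, 2L, 4L, 8L)) if (bitwAnd(set, b) > 0L) return(b)
  0L
}

# Fitch small parsimony for one column. Returns minimum change count and
# one most-parsimonious ancestral reconstruction (root state preferring
# the outgroup's observed base), plus the edges on which changes fall.
fitch_column <- function(tip_bits, tree, postorder_edges, outgroup_idx) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sets <- integer(n_node)
  sets[seq_len(n_tip)] <- tip_bits
  score <- 0L
  # up-pass: combine children pairwise in postorder
  seen <- logical(n_node)
  for (e in seq_len(nrow(postorder_edges))) {
    p <- postorder_edges[e, 1L]; ch <- postorder_edges[e, 2L]
    if (!seen[p]) { sets[p] <- sets[ch]; seen[p] <- TRUE; next }
    inter <- bitwAnd(sets[p], sets[ch])
    if (inter > 0L) sets[p] <- inter
    else { sets[p] <- bitwOr(sets[p], sets[ch]); score <- score + 1L }
  }
  root <- n_tip + 1L
  final <- integer(n_node)
  og <- tip_bits[outgroup_idx]
  final[root] <- if (og %in% c(1L, 2L, 4L, 8L) && bitwAnd(sets[root], og) > 0L)
    og else first_bit(sets[root])
  # down-pass in cladewise (parents first) order
  clade_edges <- tree$edge
  changes <- integer(0)
  for (e in seq_len(nrow(clade_edges))) {
    p <- clade_edges[e, 1L]; ch <- clade_edges[e, 2L]
    final[ch] <- if (bitwAnd(sets[ch], final[p]) > 0L) final[p]
                 else first_bit(sets[ch])
    if (final[ch] != final[p]) changes <- c(changes, e)
  }
  list(score = score, final = final, change_edges = changes)
}

#' Extract node-defining diagnostic SNPs from an alignment and tree
#'
#' For every variable alignment column, Fitch parsimony on the fixed
#' rooted topology locates the branch(es) on which the substitution
#' arose, with ancestral states polarised by a designated outgroup tip.
#' Columns with a single inferred origin yield one diagnostic SNP
#' attached to that branch's child node; columns requiring multiple
#' changes are flagged `homoplasic`. Substitutions between C/T or G/A
#' are flagged `damage_susceptible`, since post-mortem deamination can
#' mimic them in either strand orientation.
#'
#' @param alignment character matrix (rows = tree tips plus possibly the
#'   outgroup, values A/C/G/T/N) in reference coordinates.
#' @param tree rooted [ape::phylo]; all tips must be alignment rows.
#' @param outgroup tip name used to polarise ancestral states.
#' @return `data.frame` of class `diagnostic_snp_table`: `position`,
#'   `ancestral`, `derived`, `node_id`, `node_num`, `damage_susceptible`,
#'   `homoplasic`. Attribute `labels` carries the node-label vector used.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' aln <- rbind(A = c("T","A"), B = c("T","A"), C = c("C","A"), D = c("C","A"))
#' node_defining_snps(aln, tr, outgroup = "C")
#' @export
node_defining_snps <- function(alignment, tree, outgroup) {
  if (!ape::is.rooted(tree)) stop_invalid("'tree' must be rooted")
  if (!all(tree$tip.label %in% rownames(alignment)))
    stop_invalid("all tree tips must be rows of 'alignment'")
  if (!outgroup %in% tree$tip.label)
    stop_invalid("'outgroup' must be a tip of the tree")
  tree <- ape::reorder.phylo(tree, "cladewise")
  postorder_edges <- ape::reorder.phylo(tree, "postorder")$edge
  labels <- node_labels(tree)
  n_tip <- length(tree$tip.label)
  m <- alignment[tree$tip.label, , drop = FALSE]
  bits_m <- matrix(BASE_BIT[m], n_tip, ncol(m))
  bits_m[is.na(bits_m)] <- 15L
  outgroup_idx <- match(outgroup, tree$tip.label)
  rows <- vector("list", ncol(m))
  for (col in seq_len(ncol(m))) {
    tb <- bits_m[, col]
    res <- tb[tb != 15L]
    if (length(res) == 0L || all(res == res[1L])) next  # invariant/uninformative
    ft <- fitch_column(tb, tree, postorder_edges, outgroup_idx)
    if (ft$score == 0L || length(ft$change_edges) == 0L) next
    hom <- ft$score > 1L
    rows[[col]] <- do.call(rbind, lapply(ft$change_edges, function(e) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      anc <- bit_to_base(ft$final[p]); der <- bit_to_base(ft$final[ch])
      data.frame(position = col, ancestral = anc, derived = der,
                 node_id = labels[ch], node_num = ch,
                 damage_susceptible = paste0(sort(c(anc, der)), collapse = "") %in%
                   c("CT", "AG"),
                 homoplasic = hom, stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(position = integer(0), ancestral = character(0),
                      derived = character(0), node_id = character(0),
                      node_num = integer(0), damage_susceptible = logical(0),
                      homoplasic = logical(0))
  rownames(out) <- NULL
  class(out) <- c("diagnostic_snp_table", "data.frame")
  attr(out, "labels") <- labels
  out
}

#' Place an incomplete query sequence on the reference tree
#'
#' Walks from the root toward the tips. At each step the query's state is
#' tallied over each candidate child's diagnostic SNPs (homoplasic sites
#' are excluded; damage-susceptible sites are excluded when
#' `omit_damage = TRUE`, so that deamination miscodings cannot masquerade
#' as derived alleles). The walk descends into the child with the
#' strongest excess of derived over conflicting matches, requires
#' `derived > conflicting` with at least one informative site, and stops
#' on ties or when no child qualifies. The assignment is the deepest
#' accepted node; a query with no informative site at the first step is
#' `"unresolved"`.
#'
#' @param query character vector in reference coordinates (A/C/G/T/N), or
#'   a [call_consensus()] result.
#' @param table a [node_defining_snps()] table.
#' @param tree the rooted reference tree used to build `table`.
#' @param omit_damage exclude damage-susceptible diagnostic sites.
#' @param include_homoplasic also use homoplasic sites (off by default).
#' @return Object of class `placement_result`: `assigned_node`,
#'   `path_support` (per accepted node: derived, ancestral, missing,
#'   conflicting counts), `sites_omitted_damage`, `confidence_note`
#'   (`"full"` when every accepted step is conflict-free and carries no
#'   ancestral matches, else `"tentative"`).
#' @export
place_sequence <- function(query, table, tree, omit_damage = TRUE,
                           include_homoplasic = FALSE) {
  if (inherits(query, "consensus_sequence")) query <- query$calls
  tree <- ape::reorder.phylo(tree, "cladewise")
  labels <- node_labels(tree)
  tab <- table
  if (!include_homoplasic) tab <- tab[!tab$homoplasic, , drop = FALSE]
  n_damage_omitted <- 0L
  if (omit_damage) {
    n_damage_omitted <- sum(tab$damage_susceptible)
    tab <- tab[!tab$damage_susceptible, , drop = FALSE]
  }
  if (max(tab$position, 0L) > length(query))
    stop_invalid("query length does not cover the diagnostic positions")
  n_tip <- length(tree$tip.label)
  children_of <- split(tree$edge[, 2L], tree$edge[, 1L])
  tally <- function(node) {
    sn <- tab[tab$node_num == node, , drop = FALSE]
    if (nrow(sn) == 0L)
      return(c(derived = 0L, ancestral = 0L, missing = 0L, conflicting = 0L))
    q <- query[sn$position]
    informative <- q %in% DNA_BASES
    c(derived = sum(informative & q == sn$derived),
      ancestral = sum(informative & q == sn$ancestral),
      missing = sum(!informative),
      conflicting = sum(informative & q != sn$derived & q != sn$ancestral))
  }
  cur <- n_tip + 1L
  path <- list()
  first_step <- TRUE
  any_informative_first <- FALSE
  repeat {
    kids <- children_of[[as.character(cur)]]
    if (is.null(kids)) break
    stats <- lapply(kids, tally)
    names(stats) <- kids
    if (first_step) {
      any_informative_first <- any(vapply(stats, function(s)
        sum(s[c("derived", "ancestral", "conflicting")]) > 0L, logical(1)))
      first_step <- FALSE
    }
    ok <- vapply(stats, function(s) s["derived"] > s["conflicting"], logical(1))
    if (!any(ok)) break
    margin <- vapply(stats, function(s)
      as.integer(s["derived"]) - as.integer(s["conflicting"]), integer(1))
    margin[!ok] <- -Inf
    best <- which(margin == max(margin))
    if (length(best) > 1L) break          # ambiguous between siblings
    cur <- kids[best]
    path[[length(path) + 1L]] <-
      data.frame(node = labels[cur], t(stats[[best]]))
  }
  path_support <- if (length(path)) do.call(rbind, path) else
    data.frame(node = character(0), derived = integer(0),
               ancestral = integer(0), missing = integer(0),
               conflicting = integer(0))
  assigned <- if (!any_informative_first && length(path) == 0L) "unresolved"
              else labels[cur]
  confidence <- if (length(path) &&
                    all(path_support$conflicting == 0L) &&
                    all(path_support$ancestral == 0L)) "full" else "tentative"
  structure(list(assigned_node = assigned, path_support = path_support,
                 sites_omitted_damage = n_damage_omitted,
                 confidence_note = confidence),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("Placement: %s (%s); %d damage-susceptible sites omitted\n",
              x$assigned_node, x$confidence_note, x$sites_omitted_damage))
  if (nrow(x$path_support)) print(x$path_support)
  invisible(x)
}

#' Write a Newick tree with the placement marked
#'
#' Appends `_PLACED` to the assigned node's label so the placement can be
#' inspected in standard tree viewers.
#'
#' @param tree reference tree.
#' @param result a [place_sequence()] result.
#' @param path output Newick file.
#' @export
write_placement_tree <- function(tree, result, path) {
  labels <- node_labels(tree)
  n_tip <- length(tree$tip.label)
  tree$node.label <- labels[(n_tip + 1L):(n_tip + tree$Nnode)]
  hit <- which(labels == result$assigned_node)
  if (length(hit) == 1L) {
    if (hit <= n_tip) tree$tip.label[hit] <- paste0(labels[hit], "_PLACED")
    else tree$node.label[hit - n_tip] <- paste0(labels[hit], "_PLACED")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
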