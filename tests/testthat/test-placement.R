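quartet <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("a single-origin clade marker yields one diagnostic SNP", {
  aln <- rbind(A = c("T", "A"), B = c("T", "A"),
               C = c("C", "A"), D = c("C", "A"))
  tab <- node_defining_snps(aln, quartet, outgroup = "C")
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$position, 1L)
  expect_identical(tab$ancestral, "C")
  expect_identical(tab$derived, "T")
  # the SNP marks the ancestor of {A, B} (node 6 in ape numbering)
  expect_identical(tab$node_num, 6L)
  expect_true(tab$damage_susceptible)    # C<->T change
  expect_false(tab$homoplasic)
  # invariant second column contributed nothing
})

test_that("multi-origin columns are flagged homoplasic with the parsimony score", {
  # T in A and C only: needs 2 changes on ((A,B),(C,D))
  aln <- rbind(A = "T", B = "G", C = "T", D = "G")
  tab <- node_defining_snps(aln, quartet, outgroup = "B")
  expect_true(all(tab$homoplasic))
  expect_identical(nrow(tab), 2L)        # one row per origin branch
  expect_false(any(tab$damage_susceptible))  # G<->T is a transversion
})

test_that("parsimony change counts agree with phangorn on random columns", {
  skip_if_not_installed("phangorn")
  set.seed(11)
  tr <- simulate_tree(8, c(0, 50000), seed = 11)
  aln <- matrix(sample(c("A", "C", "G", "T"), 8 * 40, replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)), 8, 40,
                dimnames = list(tr$tip.label, NULL))
  tab <- node_defining_snps(aln, tr, outgroup = tr$tip.label[1])
  pd <- phangorn::phyDat(aln, type = "DNA")
  scores <- phangorn::fitch(tr, pd, site = "site")
  # per column: number of origin branches in our table equals the Fitch score
  for (j in seq_len(40))
    expect_identical(sum(tab$position == j), as.integer(scores[j]))
})

test_that("perfect and empty queries place as expected", {
  aln <- rbind(A = c("T", "G", "A"), B = c("T", "C", "A"),
               C = c("C", "C", "A"), D = c("C", "C", "G"))
  tab <- node_defining_snps(aln, quartet, outgroup = "C")
  # query carrying all derived alleles on the path to A
  res <- place_sequence(aln["A", ], tab, quartet, omit_damage = FALSE)
  expect_identical(res$assigned_node, "A")
  expect_true(all(res$path_support$conflicting == 0))
  expect_identical(res$confidence_note, "full")
  # all-N query is unresolved
  res_n <- place_sequence(rep("N", 3), tab, quartet, omit_damage = FALSE)
  expect_identical(res_n$assigned_node, "unresolved")
})

test_that("placement is deterministic and support counts cover the path SNPs", {
  set.seed(21)
  tr <- simulate_tree(12, c(0, 80000), pop_size = 60000, seed = 21)
  clock <- clock_model(rate = 3e-7, model = "TN93", kappa1 = 4, kappa2 = 4)
  aln <- evolve_sequences(tr, clock, 2500, seed = 22)
  og <- names(which.max(attr(tr, "tip_ages")))
  tab <- node_defining_snps(aln, tr, outgroup = og)
  q <- aln[3, ]
  r1 <- place_sequence(q, tab, tr)
  r2 <- place_sequence(q, tab, tr)
  expect_identical(r1, r2)
  informative <- r1$path_support$derived + r1$path_support$ancestral +
    r1$path_support$missing + r1$path_support$conflicting
  usable <- tab[!tab$homoplasic & !tab$damage_susceptible, ]
  per_node <- table(usable$node_id)
  for (k in seq_len(nrow(r1$path_support)))
    expect_identical(informative[k],
                     as.integer(per_node[r1$path_support$node[k]]))
})

test_that("error-free tip sequences place on the tip or its ancestral path", {
  tr <- simulate_tree(15, c(0, 90000), pop_size = 70000, seed = 31)
  clock <- clock_model(rate = 3e-7, model = "TN93", kappa1 = 4, kappa2 = 4)
  aln <- evolve_sequences(tr, clock, 3000, seed = 32)
  og <- names(which.max(attr(tr, "tip_ages")))
  tab <- node_defining_snps(aln, tr, outgroup = og)
  for (tip in setdiff(tr$tip.label, og)) {
    res <- place_sequence(aln[tip, ], tab, tr, omit_damage = FALSE)
    tip_num <- match(tip, tr$tip.label)
    ok_nodes <- node_label_set(tr, root_path_nodes(tr, tip_num))
    expect_true(res$assigned_node %in% ok_nodes)
  }
})

test_that("omitting damage-susceptible sites never adds conflicts for damaged queries", {
  set.seed(41)
  tr <- simulate_tree(10, c(0, 70000), pop_size = 50000, seed = 41)
  clock <- clock_model(rate = 3e-7, model = "TN93", kappa1 = 4, kappa2 = 4)
  aln <- evolve_sequences(tr, clock, 2500, seed = 42)
  og <- names(which.max(attr(tr, "tip_ages")))
  tab <- node_defining_snps(aln, tr, outgroup = og)
  for (r in 1:10) {
    tip <- sample(setdiff(tr$tip.label, og), 1)
    q <- aln[tip, ]
    dmg <- (q == "C" & runif(length(q)) < 0.1)
    q[dmg] <- "T"
    dmg2 <- (q == "G" & runif(length(q)) < 0.1)
    q[dmg2] <- "A"
    with_omit <- place_sequence(q, tab, tr, omit_damage = TRUE)
    without <- place_sequence(q, tab, tr, omit_damage = FALSE)
    expect_lte(sum(with_omit$path_support$conflicting),
               sum(without$path_support$conflicting) + 0)
  }
})

test_that("input validation: unrooted trees and missing tips are rejected", {
  aln <- rbind(A = "A", B = "C", C = "G", D = "T")
  unrooted <- ape::unroot(quartet)
  expect_error(node_defining_snps(aln, unrooted, "A"), "rooted")
  expect_error(node_defining_snps(aln[1:3, , drop = FALSE], quartet, "A"),
               "tips")
  expect_error(node_defining_snps(aln, quartet, "Z"), "outgroup")
})
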