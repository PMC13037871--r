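# reference for the hand-built examples: positions 1..10
REF10 <- c("A", "C", "G", "T", "A", "C", "G", "T", "A", "C")

test_that("deamination classification inspects both read ends", {
  # C->T at read position 1
  fr <- make_fragments(2, "TGTAC")                 # ref C G T A C
  expect_true(classify_deaminated(fr, REF10, window = 3))
  # identical to reference
  fr <- make_fragments(2, "CGTAC")
  expect_false(classify_deaminated(fr, REF10, window = 3))
  # G->A at the last position
  fr <- make_fragments(4, "TACA")                  # ref T A C G
  expect_true(classify_deaminated(fr, REF10, window = 3))
  # only C->T mismatch sits 5 positions from both ends: outside window 3
  ref <- c("A", "A", "A", "A", "C", "A", "A", "A", "A")
  fr <- make_fragments(1, "AAAATAAAA")
  expect_false(classify_deaminated(fr, ref, window = 3))
  expect_true(classify_deaminated(fr, ref, window = 5))
})

test_that("masking zeroes damage-susceptible mismatches and trimming caps at trim_max", {
  pol <- consensus_policy()
  # no position below Q20: unchanged length
  fr <- make_fragments(1, "ACGTA")
  out <- mask_and_trim(fr, REF10, pol)
  expect_identical(nchar(out$seq), 5L)
  # C->T mismatch mid-read gets quality 0 (masked)
  fr <- make_fragments(1, "ATGTA")                 # pos 2: ref C read T
  out <- mask_and_trim(fr, REF10, pol)
  expect_identical(utf8ToInt(out$qual) - 33L, c(40L, 0L, 40L, 40L, 40L))
  # qualities 5,5,5,40...: exactly 3 trimmed, start shifts
  fr <- make_fragments(1, "ACGTAC", quals = qualstr(c(5, 5, 5, 40, 40, 40)))
  out <- mask_and_trim(fr, REF10, pol)
  expect_identical(out$start, 4L)
  expect_identical(out$seq, "TAC")
  # qualities 5,5,5,5,40...: cap at three; 4th low-quality base retained
  fr <- make_fragments(1, "ACGTAC", quals = qualstr(c(5, 5, 5, 5, 40, 40)))
  out <- mask_and_trim(fr, REF10, pol)
  expect_identical(out$seq, "TAC")
  expect_identical(utf8ToInt(out$qual)[1] - 33L, 5L)
})

test_that("contamination gate is strict at the 10% threshold", {
  g <- random_genome(2000, seed = 71)
  fr <- fragment_and_damage(g, damage_profile(p_ct_5p = 0.4, coverage = 8),
                            seed = 72)
  low <- contamination_gate(fr, contamination_estimate(0.02), g)
  expect_identical(low$decision, "all_reads")
  expect_identical(nrow(low$fragments), nrow(fr))
  # exactly 10% passes all reads ("above 10%" is strict)
  at <- contamination_gate(fr, 0.10, g)
  expect_identical(at$decision, "all_reads")
  hi <- contamination_gate(fr, contamination_estimate(0.25, 0.2, 0.3), g)
  expect_identical(hi$decision, "deaminated_only")
  expect_identical(nrow(hi$fragments),
                   sum(classify_deaminated(fr, g, 3)))
  # unprocessable when nothing is deaminated
  clean <- fragment_and_damage(g, damage_profile(p_ct_5p = 0, coverage = 5),
                               seed = 73)
  expect_error(contamination_gate(clean, 0.5, g), "unprocessable")
})

test_that("consensus applies the depth-3 / 65% agreement rule", {
  pol <- consensus_policy()
  G <- 4L
  ref4 <- c("A", "A", "A", "A")
  # three fragments all A at position 1 -> A; two fragments -> N
  fr3 <- make_fragments(c(1, 1, 1), c("A", "AA", "AAA"))
  expect_identical(call_consensus(fr3, pol, genome_length = G)$calls[1], "A")
  fr2 <- make_fragments(c(1, 1), c("A", "AA"))
  expect_identical(call_consensus(fr2, pol, genome_length = G)$calls[1], "N")
  # 6 A / 4 G -> N (0.60 < 0.65); 7 A / 3 G -> A
  # (lengths and strands vary so deduplication keeps every fragment)
  fr <- make_fragments(rep(1L, 10), c(paste0("A", strrep("C", 0:5)),
                                      paste0("G", strrep("C", 0:3))),
                       strands = rep(c("+", "-"), c(6, 4)))
  expect_identical(call_consensus(fr, pol, genome_length = 8L)$calls[1], "N")
  fr <- make_fragments(rep(1L, 10), c(paste0("A", strrep("C", 0:6)),
                                      paste0("G", strrep("C", 0:2))),
                       strands = rep(c("+", "-"), c(7, 3)))
  expect_identical(call_consensus(fr, pol, genome_length = 8L)$calls[1], "A")
  # empty input: all-N sequence of reference length
  empty <- make_fragments(integer(0), character(0))
  cs <- call_consensus(empty, pol, genome_length = 5L)
  expect_identical(cs$calls, rep("N", 5))
  expect_identical(cs$completeness, 0)
})

test_that("duplicate fragments (same start, end, strand) count once", {
  pol <- consensus_policy()
  fr <- make_fragments(c(1, 1, 1, 1), rep("AAAA", 4),
                       strands = c("+", "+", "+", "-"))
  cs <- call_consensus(fr, pol, genome_length = 6L)
  expect_identical(max(cs$depth), 2L)              # one per strand
  expect_identical(cs$calls[1], "N")
})

test_that("zero-quality bases contribute neither depth nor agreement", {
  pol <- consensus_policy()
  fr <- make_fragments(rep(1L, 4), c("A", "AA", "AAA", "AAAA"),
                       quals = c(qualstr(0), "II", "III", "IIII"))
  cs <- call_consensus(fr, pol, genome_length = 5L)
  expect_identical(cs$depth[1], 3L)
  expect_identical(cs$calls[1], "A")
})

test_that("supporting the modal base never un-calls a position", {
  pol <- consensus_policy()
  set.seed(91)
  G <- 40L
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    fr <- make_fragments(sample(G, n, replace = TRUE),
                         vapply(seq_len(n), function(i)
                           paste0(sample(c("A", "C", "G", "T"),
                                         sample(3:8, 1), replace = TRUE),
                                  collapse = ""), character(1)))
    base <- call_consensus(fr, pol, genome_length = G, dedup = FALSE)
    called <- which(base$calls != "N")
    if (!length(called)) next
    pos <- sample(called, 1)
    extra <- make_fragments(pos, base$calls[pos])
    fr2 <- rbind(fr, extra)
    class(fr2) <- class(fr)
    again <- call_consensus(fr2, pol, genome_length = G, dedup = FALSE)
    expect_identical(again$calls[pos], base$calls[pos])
  }
})

test_that("consensus recovers a known genome end-to-end with damage masking", {
  g <- random_genome(3000, seed = 101)
  fr <- fragment_and_damage(g, damage_profile(p_ct_5p = 0.3, coverage = 25),
                            seed = 102)
  pol <- consensus_policy()
  masked <- mask_and_trim(fr, g, pol)
  cs <- call_consensus(masked, pol, genome_length = 3000L)
  called <- cs$calls != "N"
  expect_gt(mean(cs$calls[called] == g[called]), 0.999)
})
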