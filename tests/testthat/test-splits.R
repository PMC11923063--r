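test_that("pairwise identity handles identity, disjoint and gapped cases", {
  expect_equal(pairwiseIdentity("ACDEFGH", "ACDEFGH"), 1.0)
  expect_equal(pairwiseIdentity("AAAA", "CCCC"), 0.0)
  expect_equal(pairwiseIdentity("ACDEF", "ACDGF"), 0.8)
  expect_error(pairwiseIdentity("", "ACD"), "non-empty")
})

test_that("pairwise identity is symmetric and matches an alignment oracle", {
  seqs <- randomProteins(8, 40, seed = 101)
  for (i in 1:4) {
    a <- seqs[2 * i - 1]; b <- seqs[2 * i]
    expect_equal(pairwiseIdentity(a, b), pairwiseIdentity(b, a))
    expect_equal(pairwiseIdentity(a, b), oracleIdentity(a, b),
                 tolerance = 1e-12)
  }
  # unequal lengths exercise the gap penalty and min-length denominator
  a <- substr(seqs[1], 1, 25)
  expect_equal(pairwiseIdentity(a, seqs[1]), oracleIdentity(a, seqs[1]))
})

test_that("greedy clustering groups identical and separates dissimilar sequences", {
  same <- setNames(rep("MKTAYIAKQRQISFVKSHFSRQLEERLGLIE", 3),
                   c("a", "b", "c"))
  cs <- greedyCluster(same, 0.4)
  expect_length(clusters(cs), 1)
  expect_setequal(clusters(cs)[[1]], c("a", "b", "c"))

  far <- randomProteins(3, 60, seed = 5)
  im <- outer(far, far, Vectorize(pairwiseIdentity))
  stopifnot(max(im[upper.tri(im)]) < 0.4)   # fixture sanity
  cs2 <- greedyCluster(setNames(far, c("x", "y", "z")), 0.4)
  expect_length(clusters(cs2), 3)
})

test_that("mutant families cluster together, independent sequences apart", {
  set.seed(202)
  anc <- strsplit(randomProteins(1, 120, seed = 33), "")[[1]]
  mutants <- vapply(1:5, function(i) {
    v <- anc
    hit <- sample(120, 6)   # 5% substitutions
    v[hit] <- vapply(v[hit], function(a)
      sample(setdiff(AA_STANDARD_20, a), 1), character(1))
    paste(v, collapse = "")
  }, character(1))
  others <- randomProteins(5, 120, seed = 44)
  seqs <- setNames(c(mutants, others), paste0("s", 1:10))
  # brute-force identity matrix certifies the expected grouping
  im <- outer(seqs, seqs, Vectorize(oracleIdentity))
  expect_true(min(im[1:5, 1:5]) >= 0.4)
  expect_true(max(im[1:5, 6:10]) < 0.4)
  cs <- greedyCluster(seqs, 0.4)
  member_of <- rep(names(clusters(cs)), lengths(clusters(cs)))
  names(member_of) <- unlist(clusters(cs))
  expect_length(unique(member_of[paste0("s", 1:5)]), 1)
  expect_length(unique(member_of[paste0("s", 6:10)]), 5)
})

test_that("every cluster member matches its representative at or above threshold", {
  seqs <- setNames(randomProteins(12, 50, seed = 9), paste0("q", 1:12))
  cs <- greedyCluster(seqs, 0.3)
  for (rep_id in names(clusters(cs))) {
    for (m in clusters(cs)[[rep_id]]) {
      expect_gte(pairwiseIdentity(seqs[[m]], seqs[[rep_id]]), 0.3)
    }
  }
  # deterministic given the input
  cs2 <- greedyCluster(seqs[sample(12)], 0.3)
  expect_identical(clusters(cs), clusters(cs2))
})

test_that("clustered partitioning follows the greedy largest-into-smallest rule", {
  # ten singleton clusters into ten folds: exactly one per fold
  seqs <- setNames(randomProteins(10, 60, seed = 77), paste0("c", 1:10))
  cs <- greedyCluster(seqs, 0.4)
  stopifnot(length(clusters(cs)) == 10)
  recs <- data.frame(sequence = unname(seqs), smiles = "CCO",
                     stringsAsFactors = FALSE)
  fa <- partitionFolds(cs, recs, k = 10, seed = 1)
  expect_equal(sort(unname(foldOf(fa))), 0:9)

  # record counts [5,4,3,2,1] into k=2 -> fold sizes (8,7)
  seqs5 <- setNames(randomProteins(5, 60, seed = 78), paste0("g", 1:5))
  cs5 <- greedyCluster(seqs5, 0.4)
  stopifnot(length(clusters(cs5)) == 5)
  counts <- c(5, 4, 3, 2, 1)
  recs5 <- do.call(rbind, lapply(1:5, function(i)
    data.frame(sequence = unname(seqs5[i]),
               smiles = paste0("C", strrep("C", seq_len(counts[i]))),
               stringsAsFactors = FALSE)))
  fa5 <- partitionFolds(cs5, recs5, k = 2, seed = 3)
  expect_setequal(unname(table(foldOf(fa5))), c(8, 7))

  expect_error(partitionFolds(cs5, recs5, k = 6, seed = 1), "exceeds")
})

test_that("a giant cluster occupies a fold alone; spread is bounded by the largest cluster", {
  fam <- setNames(rep("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", 30),
                  paste0("m", 1:30))
  singles <- setNames(randomProteins(9, 40, seed = 55), paste0("s", 1:9))
  seqs <- c(fam, singles)
  cs <- greedyCluster(seqs, 0.4)
  stopifnot(length(clusters(cs)) == 10)   # fixture sanity
  recs <- data.frame(sequence = unname(seqs),
                     smiles = paste0("C", strrep("C", seq_along(seqs))),
                     stringsAsFactors = FALSE)
  fa <- partitionFolds(cs, recs, k = 10, seed = 0)
  sizes <- table(foldOf(fa))
  expect_equal(sort(as.integer(sizes), decreasing = TRUE),
               c(30L, rep(1L, 9)))
  largest <- max(lengths(clusters(cs)))
  expect_lte(diff(range(sizes)), largest)
})

test_that("random partitioning deals records evenly and reproducibly", {
  recs <- data.frame(sequence = randomProteins(20, 30, seed = 8),
                     smiles = "CCO", stringsAsFactors = FALSE)
  fa <- randomPartition(recs, k = 10, seed = 4)
  expect_true(all(table(foldOf(fa)) == 2))
  fa2 <- randomPartition(recs, k = 10, seed = 4)
  expect_identical(foldOf(fa), foldOf(fa2))

  # ten copies of one sequence over ten folds must straddle folds
  dup <- data.frame(sequence = rep("MKTAYIAKQR", 10),
                    smiles = paste0(strrep("C", 1:10), "O"),
                    stringsAsFactors = FALSE)
  fad <- randomPartition(dup, k = 10, seed = 0)
  expect_gte(length(unique(foldOf(fad))), 2)
})

test_that("leakage audit reports exact cross-fold identity extremes", {
  # two singleton folds with disjoint sequences
  recs <- data.frame(sequence = c("AAAAAAAAAA", "CCCCCCCCCC"),
                     smiles = "CCO", stringsAsFactors = FALSE)
  fa <- randomPartition(recs, k = 2, seed = 0)
  seq_of <- setNames(recs$sequence, names(foldOf(fa)))
  expect_equal(auditLeakage(fa, seq_of)$max_identity, 0)

  # duplicated sequences under a random split leak with identity 1
  dup <- data.frame(sequence = rep("MKTAYIAKQRQISFVKSH", 10),
                    smiles = paste0(strrep("C", 1:10), "O"),
                    stringsAsFactors = FALSE)
  fad <- randomPartition(dup, k = 5, seed = 1)
  seq_of_d <- setNames(dup$sequence, names(foldOf(fad)))
  expect_equal(auditLeakage(fad, seq_of_d)$max_identity, 1)

  # clustered split stays below the threshold
  fams <- simulateFamilies(6, 4, seq_len = 60, within_rate = 0.05, seed = 3)
  sim <- simulateKinetics(fams, substratePool(4), seed = 3)
  cs <- greedyCluster(fams$sequences, 0.4)
  fac <- partitionFolds(cs, sim$records, k = 4, seed = 3)
  seq_of_c <- setNames(sim$records$sequence, names(foldOf(fac)))
  expect_lt(auditLeakage(fac, seq_of_c)$max_identity, 0.4)
})
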