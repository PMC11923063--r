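test_that("PSSM parsing handles toy, permuted and malformed files", {
  sc <- uniformPssmScores(3)
  sc[2, "W"] <- 11L
  path <- writePssmFile(sc, query = c("M", "K", "T"))
  p <- readPssm(path)
  expect_equal(dim(pssmScores(p)), c(3L, 20L))
  expect_equal(unname(pssmScores(p)[2, "W"]), 11L)

  # permuted header columns stay keyed by residue letter
  perm <- writePssmFile(sc, query = c("M", "K", "T"),
                        col_order = rev(AA_STANDARD_20))
  expect_equal(pssmScores(readPssm(perm)), pssmScores(p))

  trunc <- tempfile()
  writeLines(readLines(path)[1:3], trunc)   # header only, no rows
  expect_error(readPssm(trunc), "no score rows")
  bad <- tempfile()
  lines <- readLines(path)
  lines[4] <- substr(lines[4], 1, 30)       # fewer than 20 scores
  writeLines(lines, bad)
  expect_error(readPssm(bad), "malformed PSSM row")
})

test_that("delta-PSSM is the exact antisymmetric score difference", {
  sc <- uniformPssmScores(6)
  sc[5, "M"] <- 5L
  sc[5, "T"] <- -2L
  p <- new("Pssm", scores = sc, query = rep("T", 6))
  expect_equal(deltaPssm(p, 5, "T", "M"), 7)
  expect_equal(deltaPssm(p, 5, "M", "M"), 0)
  expect_equal(deltaPssm(p, 5, "M", "T"), -deltaPssm(p, 5, "T", "M"))
  expect_error(deltaPssm(p, 7, "T", "M"), "outside")
  expect_error(deltaPssm(p, 5, "B", "M"), "standard")
  set.seed(71)
  scr <- matrix(sample(-5:10, 20 * 4, TRUE), 4, 20,
                dimnames = list(NULL, AA_STANDARD_20))
  pr <- new("Pssm", scores = scr, query = rep("A", 4))
  for (i in 1:10) {
    s <- sample(4, 1); aa <- sample(AA_STANDARD_20, 2)
    expect_equal(deltaPssm(pr, s, aa[1], aa[2]),
                 -deltaPssm(pr, s, aa[2], aa[1]))
  }
})

test_that("saturation mutagenesis enumerates 19 mutants per site", {
  wt <- randomProteins(1, 200, seed = 81)
  m91 <- enumerateMutants(wt, 1:91)
  expect_equal(nrow(m91), 1729)          # 19 x 91
  m22 <- enumerateMutants(wt, 5:26)
  expect_equal(nrow(m22), 418)           # 19 x 22
  m1 <- enumerateMutants(wt, 42)
  expect_equal(nrow(m1), 19)
  expect_false(wt %in% m1$sequence)
  expect_false(anyDuplicated(m91$sequence) > 0)
  # every derived sequence differs from the wild-type at exactly one position
  wtv <- strsplit(wt, "")[[1]]
  for (i in sample(nrow(m91), 20)) {
    mv <- strsplit(m91$sequence[i], "")[[1]]
    expect_equal(sum(mv != wtv), 1)
  }
  expect_error(enumerateMutants(wt, c(3, 3)), "duplicate")
})

test_that("pocket sites obey the distance rule, exclusions and radius monotonicity", {
  coords <- rbind(c(5, 0, 0),     # residue 1: 5 A from ligand at origin
                  c(12.5, 0, 0),  # residue 2: beyond 12 A
                  c(0, 11.9, 0),  # residue 3: just inside
                  c(40, 40, 40))  # residue 4: far away
  pdb <- writeToyPdb(coords)
  sites <- pocketSites(pdb, "LIG", radius = 12)
  expect_equal(sites, c(1L, 3L))
  expect_equal(pocketSites(pdb, "LIG", radius = 12, excluded_sites = 3), 1L)
  r_small <- pocketSites(pdb, "LIG", radius = 6)
  r_large <- pocketSites(pdb, "LIG", radius = 15)
  expect_true(all(r_small %in% sites))
  expect_true(all(sites %in% r_large))
})

test_that("homolog mining applies the strict length filter and efficiency ranking", {
  ref <- randomProteins(1, 100, seed = 91)
  cands <- setNames(c(
    randomProteins(1, 125, seed = 92),   # +25: removed
    randomProteins(1, 120, seed = 93),   # +20: retained (strict rule)
    randomProteins(1, 100, seed = 94),
    randomProteins(1, 85, seed = 95)),   # -15: retained
    c("plus25", "plus20", "same", "minus15"))
  pp <- syntheticProvider(16, 1)
  mp <- syntheticProvider(8, 2)
  set.seed(96)
  X <- matrix(rnorm(30 * (16 + 8 + 167)), 30)
  kc <- trainRegressor(X, rnorm(30), regressorConfig(epochs = 10, hidden_dim = 8, seed = 1))
  km <- trainRegressor(X, rnorm(30), regressorConfig(epochs = 10, hidden_dim = 8, seed = 2))
  res <- mineHomologs(ref, cands, "CCO", kc, km, pp, mp)
  expect_setequal(res$id, c("plus20", "same", "minus15"))
  expect_equal(res$score, sort(res$score, decreasing = TRUE))
  expect_equal(res$score, res$kcat_pred - res$km_pred)
  expect_warning(
    empty <- mineHomologs(ref, cands["plus25"], "CCO", kc, km, pp, mp),
    "length filter")
  expect_equal(nrow(empty), 0)
})

test_that("mutant screening keeps the top half then applies the strict PSSM cutoff", {
  wt <- paste(rep("T", 10), collapse = "")
  muts <- enumerateMutants(wt, c(2, 5))   # 38 mutants
  # deterministic synthetic scores: distinct, known order
  muts$model_score <- seq(1, 0.05, length.out = nrow(muts))
  sc <- uniformPssmScores(10)
  sc[, "T"] <- 0L
  # give every mutation at site 2 delta 8 (kept), site 5 delta 7 (dropped)
  sc[2, setdiff(AA_STANDARD_20, "T")] <- 8L
  sc[5, setdiff(AA_STANDARD_20, "T")] <- 7L
  p <- new("Pssm", scores = sc, query = strsplit(wt, "")[[1]])
  res <- screenMutants(muts, p, top_fraction = 0.5, delta_min = 7)

  n_keep <- ceiling(0.5 * nrow(muts))
  top_half <- muts$mutation[order(-muts$model_score)][seq_len(n_keep)]
  # delta = 7 is dropped even in the top half ("greater than" is strict)
  expect_true(all(res$proposals$site == 2))
  expect_setequal(res$proposals$mutation,
                  intersect(top_half, muts$mutation[muts$site == 2]))
  # bottom-half mutants are dropped regardless of delta-PSSM
  bottom <- setdiff(muts$mutation, top_half)
  expect_true(all(res$table$dropped_reason[res$table$mutation %in% bottom]
                  == "model_score_bottom_half"))
  # proposals are a subset of the enumeration, sorted by model score
  expect_true(all(res$proposals$sequence %in% muts$sequence))
  expect_equal(res$proposals$model_score,
               sort(res$proposals$model_score, decreasing = TRUE))
  # result set is order-independent
  res2 <- screenMutants(muts[sample(nrow(muts)), ], p,
                        top_fraction = 0.5, delta_min = 7)
  expect_setequal(res2$proposals$mutation, res$proposals$mutation)
  # delta exactly above the cutoff is kept
  expect_true(all(res$proposals$delta_pssm == 8))
})

test_that("screening validates PSSM coverage of the sequence", {
  wt <- paste(rep("A", 8), collapse = "")
  muts <- enumerateMutants(wt, 3)
  muts$model_score <- rnorm(nrow(muts))
  short <- new("Pssm", scores = uniformPssmScores(5), query = rep("A", 5))
  expect_error(screenMutants(muts, short), "does not match")
})
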