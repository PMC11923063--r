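# Shared fixtures and independent oracles, all built in code at test time.

# Independent Needleman-Wunsch oracle: match +1, mismatch 0, linear gap -1,
# identity = identical aligned columns / min length. Plain dynamic
# programming with traceback, written without the package's alignment path.
oracleIdentity <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n)
  S[1, ] <- -(0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + (A[i] == B[j]),
                           S[i, j + 1] - 1,
                           S[i + 1, j] - 1)
  }
  # traceback counting identical columns
  i <- n; j <- m; ident <- 0
  while (i > 0 && j > 0) {
    if (S[i + 1, j + 1] == S[i, j] + (A[i] == B[j])) {
      ident <- ident + (A[i] == B[j])
      i <- i - 1; j <- j - 1
    } else if (S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  ident / min(n, m)
}

randomProteins <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(AA_STANDARD_20, len, replace = TRUE), collapse = ""),
    character(1))
}

# Minimal kinetic CSV on disk; returns the path.
writeKineticCsv <- function(rows, path = tempfile(fileext = ".csv")) {
  write.csv(rows, path, row.names = FALSE, quote = TRUE)
  path
}

kineticRow <- function(enzyme_id = "P00001", sequence = "MKTAYIAKQR",
                       smiles = "CCO", param = "kcat", value = 10,
                       unit = "s^(-1)", enzyme_type = "wild_type") {
  data.frame(enzyme_id = enzyme_id, sequence = sequence, smiles = smiles,
             param = param, value = value, unit = unit,
             enzyme_type = enzyme_type, stringsAsFactors = FALSE)
}

# Toy PSI-BLAST style ASCII PSSM with controllable per-site scores.
# scores: L x 20 integer matrix with columns named by residue letters.
writePssmFile <- function(scores, query, path = tempfile(fileext = ".pssm"),
                          col_order = colnames(scores)) {
  lines <- c("", "Last position-specific scoring matrix computed",
             paste0("            ", paste(sprintf("%3s", col_order),
                                          collapse = " ")))
  for (i in seq_len(nrow(scores))) {
    lines <- c(lines, paste0(sprintf("%5d %s ", i, query[i]),
                             paste(sprintf("%3d", scores[i, col_order]),
                                   collapse = " "),
                             "  ", paste(rep("0", 20), collapse = " "),
                             "  0.00 0.00"))
  }
  writeLines(c(lines, ""), path)
  path
}

uniformPssmScores <- function(L, fill = 0) {
  m <- matrix(as.integer(fill), L, 20,
              dimnames = list(NULL, AA_STANDARD_20))
  m
}

# Tiny PDB text fixture: a handful of CA-only residues at given coordinates
# plus one single-atom ligand (HETATM, resname LIG) at the origin.
writeToyPdb <- function(res_coords, path = tempfile(fileext = ".pdb")) {
  fmt <- "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C"
  lines <- vapply(seq_len(nrow(res_coords)), function(i)
    sprintf(fmt, i, i, res_coords[i, 1], res_coords[i, 2], res_coords[i, 3]),
    character(1))
  lig <- sprintf(
    "HETATM%5d  C1  LIG A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    nrow(res_coords) + 1, 900, 0, 0, 0)
  writeLines(c(lines, lig, "END"), path)
  path
}

# Panel constructed directly from label vectors.
makePanel <- function(experimental, predicted,
                      enzyme_id = "P1", smiles = "CCO") {
  n <- length(experimental)
  new("MutantPanel", enzyme_id = enzyme_id, smiles = smiles,
      variants = data.frame(
        sequence = paste0("SEQ", seq_len(n)),
        experimental = experimental,
        predicted = predicted,
        is_wild_type = c(TRUE, rep(FALSE, n - 1)),
        stringsAsFactors = FALSE))
}

# Brute-force pairwise ordering accuracy (independent double loop).
oraclePairwiseAccuracy <- function(experimental, predicted) {
  n <- length(experimental)
  good <- 0; total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    de <- experimental[i] - experimental[j]
    if (de == 0) next
    total <- total + 1
    dp <- predicted[i] - predicted[j]
    if (sign(dp) == sign(de)) good <- good + 1
  }
  if (total == 0) return(NA_real_)
  good / total
}
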