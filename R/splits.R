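# Homology-aware data splitting.
#
# Random cross-validation folds leak information whenever homologous enzymes
# end up on both sides of a split; a model can then score well by memorizing
# families rather than learning catalysis. The remedy used here: greedy
# identity-threshold clustering (CD-HIT style, threshold 0.4) followed by
# cluster-respecting fold assignment, plus an audit that certifies the
# maximum cross-fold identity.

# Substitution matrix for identity scoring: +1 match, 0 mismatch, over the
# full Biostrings AA alphabet so nonstandard letters never error out.
identitySubstMatrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      letters <- Biostrings::AA_ALPHABET
      m <- matrix(0L, length(letters), length(letters),
                  dimnames = list(letters, letters))
      diag(m) <- 1L
      cache <<- m
    }
    cache
  }
})

#' Pairwise sequence identity
#'
#' Global (Needleman-Wunsch) alignment with match +1, mismatch 0 and a
#' linear gap penalty of -1; identity is the number of identical aligned
#' positions divided by the length of the shorter sequence (the CD-HIT
#' convention). Symmetric in its arguments.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @return identity fraction in [0, 1].
#' @export
pairwiseIdentity <- function(seq_a, seq_b) {
  stopIfNotScalarString(seq_a, "seq_a")
  stopIfNotScalarString(seq_b, "seq_b")
  identityToMany(seq_a, seq_b)[[1]]
}

# Identity of one sequence against many (vectorized over `others`).
identityToMany <- function(seq, others) {
  if (!length(others)) return(numeric(0))
  if (any(!nzchar(others)) || !nzchar(seq)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(others),
    subject = Biostrings::AAString(seq),
    substitutionMatrix = identitySubstMatrix(),
    gapOpening = 0, gapExtension = 1, type = "global", scoreOnly = FALSE)
  Biostrings::nmatch(aln) / pmin(nchar(others), nchar(seq))
}

# Full identity matrix over a character vector of sequences.
identityMatrix <- function(seqs) {
  n <- length(seqs)
  m <- diag(1, n)
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    ids <- identityToMany(seqs[i], seqs[(i + 1):n])
    m[i, (i + 1):n] <- ids
    m[(i + 1):n, i] <- ids
  }
  m
}

#' Greedy identity-threshold clustering
#'
#' CD-HIT style greedy incremental clustering: sequences are processed
#' longest-first (ties by id, lexicographically); each joins the first
#' existing cluster whose representative it matches at or above the
#' threshold, otherwise it founds a new cluster. Deterministic for a given
#' input.
#'
#' @param sequences named character vector (id -> amino-acid string).
#' @param threshold identity fraction in (0, 1]; default 0.4.
#' @return a \code{\linkS4class{ClusterSet}}.
#' @export
greedyCluster <- function(sequences, threshold = 0.4) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (!length(sequences))
    return(new("ClusterSet", threshold = threshold, clusters = list(),
               sequences = character(0)))
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by id")
  ord <- order(-nchar(sequences), names(sequences), method = "radix")
  ids <- names(sequences)[ord]
  seqs <- unname(sequences[ord])
  reps_id <- character(0)
  reps_seq <- character(0)
  members <- list()
  for (i in seq_along(ids)) {
    joined <- FALSE
    if (length(reps_seq)) {
      ident <- identityToMany(seqs[i], reps_seq)
      hit <- which(ident >= threshold)
      if (length(hit)) {
        j <- hit[1]  # founding order
        members[[j]] <- c(members[[j]], ids[i])
        joined <- TRUE
      }
    }
    if (!joined) {
      reps_id <- c(reps_id, ids[i])
      reps_seq <- c(reps_seq, seqs[i])
      members[[length(members) + 1]] <- ids[i]
    }
  }
  names(members) <- reps_id
  new("ClusterSet", threshold = threshold, clusters = members,
      sequences = sequences)
}

# Map each record's sequence string to its cluster index. All identical
# sequence strings land in the same cluster by construction of the greedy
# pass (equal strings always match the same first representative).
clusterIndexOfSequence <- function(cluster_set, sequences) {
  id_to_cluster <- rep(seq_along(cluster_set@clusters),
                       lengths(cluster_set@clusters))
  names(id_to_cluster) <- unlist(cluster_set@clusters, use.names = FALSE)
  seq_of_id <- cluster_set@sequences
  seq_to_cluster <- id_to_cluster[names(seq_of_id)]
  names(seq_to_cluster) <- unname(seq_of_id)
  idx <- seq_to_cluster[sequences]
  if (anyNA(idx))
    stop("some record sequences are absent from the cluster set")
  unname(idx)
}

# Records argument normalization: a KineticDataset or a data.frame with
# sequence/smiles columns.
recordFrame <- function(records) {
  if (is(records, "KineticDataset")) records <- entries(records)
  if (!is.data.frame(records) ||
      !all(c("sequence", "smiles") %in% names(records)))
    stop("records must be a KineticDataset or a data.frame with ",
         "'sequence' and 'smiles' columns")
  records
}

#' Cluster-respecting k-fold partition
#'
#' Assigns whole identity clusters to folds so that no two folds share
#' sequences above the clustering threshold. Balancing is greedy by record
#' count: clusters sorted largest-first are placed into the currently
#' smallest fold; equal-sized clusters are ordered by a seeded shuffle, and
#' fold ties break toward the lowest index.
#'
#' @param cluster_set a \code{\linkS4class{ClusterSet}} covering every
#'   record's sequence.
#' @param records a \code{KineticDataset} or data.frame with
#'   \code{sequence}/\code{smiles} columns.
#' @param k number of folds (default 10).
#' @param seed integer seed for the tie-break shuffle.
#' @return a \code{\linkS4class{FoldAssignment}} keyed by
#'   (sequence, SMILES) pair.
#' @export
partitionFolds <- function(cluster_set, records, k = 10, seed = 0) {
  stopifnot(is(cluster_set, "ClusterSet"))
  records <- recordFrame(records)
  k <- as.integer(k)
  n_clusters <- length(cluster_set@clusters)
  if (k > n_clusters)
    stop("k (", k, ") exceeds the number of clusters (", n_clusters, ")")
  cluster_idx <- clusterIndexOfSequence(cluster_set, records$sequence)
  counts <- tabulate(cluster_idx, nbins = n_clusters)
  ord <- withSeed(childSeed(seed, "partition"), {
    shuffle <- sample.int(n_clusters)   # seeded tie-break among equal sizes
    order(-counts, shuffle)
  })
  fold_size <- integer(k)
  fold_of_cluster <- integer(n_clusters)
  for (cl in ord) {
    f <- which.min(fold_size)  # lowest index on ties
    fold_of_cluster[cl] <- f
    fold_size[f] <- fold_size[f] + counts[cl]
  }
  fold_of <- as.integer(fold_of_cluster[cluster_idx] - 1L)
  names(fold_of) <- pairKey(records$sequence, records$smiles)
  new("FoldAssignment", k = k, fold_of = fold_of, mode = "clustered",
      seed = as.integer(seed))
}

#' Random k-fold partition (leakage-prone baseline)
#'
#' Seeded uniform shuffle followed by round-robin dealing, so fold sizes
#' differ by at most one. Homologous or identical sequences will generally
#' straddle folds -- this is the biased baseline the clustered split is
#' compared against.
#'
#' @inheritParams partitionFolds
#' @export
randomPartition <- function(records, k = 10, seed = 0) {
  records <- recordFrame(records)
  k <- as.integer(k)
  n <- nrow(records)
  if (k > n) stop("k exceeds the number of records")
  perm <- withSeed(childSeed(seed, "random-partition"), sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- (seq_len(n) - 1L) %% k
  names(fold_of) <- pairKey(records$sequence, records$smiles)
  new("FoldAssignment", k = k, fold_of = fold_of, mode = "random",
      seed = as.integer(seed))
}

#' Audit a fold assignment for homology leakage
#'
#' Computes the exact maximum pairwise identity between sequences placed in
#' different folds, and the per-fold-pair maxima. A clustered split at
#' threshold t must report a maximum strictly below t.
#'
#' @param assignment a \code{\linkS4class{FoldAssignment}}.
#' @param sequences named character vector mapping record key (as in
#'   \code{foldOf(assignment)}) to the amino-acid sequence.
#' @return list with \code{max_identity} and \code{pair_max} (k x k matrix,
#'   NA on and below the diagonal).
#' @export
auditLeakage <- function(assignment, sequences) {
  stopifnot(is(assignment, "FoldAssignment"))
  fold_of <- foldOf(assignment)
  if (assignment@k < 2) stop("audit requires at least 2 folds")
  if (!all(names(fold_of) %in% names(sequences)))
    stop("sequences must cover every record key in the assignment")
  seq_of <- sequences[names(fold_of)]
  # distinct sequence strings and the set of folds each occurs in
  useq <- unique(unname(seq_of))
  fold_sets <- lapply(useq, function(s)
    sort(unique(fold_of[seq_of == s])))
  k <- assignment@k
  pair_max <- matrix(NA_real_, k, k,
                     dimnames = list(paste0("fold", 0:(k - 1)),
                                     paste0("fold", 0:(k - 1))))
  im <- identityMatrix(useq)
  for (a in 1:(k - 1)) for (b in (a + 1):k) {
    ia <- which(vapply(fold_sets, function(f) (a - 1L) %in% f, logical(1)))
    ib <- which(vapply(fold_sets, function(f) (b - 1L) %in% f, logical(1)))
    if (!length(ia) || !length(ib)) next
    best <- 0
    shared <- intersect(ia, ib)
    if (length(shared)) best <- 1  # same sequence string in both folds
    sub <- im[ia, ib, drop = FALSE]
    # exclude the self-diagonal only when it is the same unique-sequence index
    for (ii in seq_along(ia)) for (jj in seq_along(ib))
      if (ia[ii] != ib[jj]) best <- max(best, sub[ii, jj])
    pair_max[a, b] <- best
  }
  list(max_identity = max(pair_max, na.rm = TRUE), pair_max = pair_max)
}
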