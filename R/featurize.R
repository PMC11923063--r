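# Featurization: (sequence, SMILES) -> fixed-length numeric vectors.
#
# Protein and molecule embeddings come from pluggable providers (language
# models, precomputed matrices, or the synthetic stand-ins below); the
# substrate additionally contributes the 167-key MACCS structural
# fingerprint. The default full-width layout is 1024 (protein) + 768
# (molecule) + 167 (MACCS) = 1959 features, concatenated in that order.

#' Feature bundle for one enzyme-substrate pair
#'
#' @slot protein numeric protein embedding.
#' @slot molecule numeric molecule embedding.
#' @slot maccs integer MACCS key vector (length 167, entries 0/1).
#' @slot concat the concatenation (protein, molecule, maccs).
#' @export
setClass("FeatureBundle",
  representation(protein = "numeric", molecule = "numeric",
                 maccs = "integer", concat = "numeric"),
  validity = function(object) {
    if (length(object@maccs) != 167L) return("maccs must have length 167")
    if (!all(object@maccs %in% c(0L, 1L))) return("maccs entries must be 0/1")
    if (length(object@concat) !=
        length(object@protein) + length(object@molecule) + 167L)
      return("concat length must equal protein + molecule + 167")
    TRUE
  }
)

setMethod("show", "FeatureBundle", function(object) {
  cat("FeatureBundle: ", length(object@protein), " (protein) + ",
      length(object@molecule), " (molecule) + 167 (MACCS) = ",
      length(object@concat), " features\n", sep = "")
})

# ---- MACCS keys -----------------------------------------------------------

.maccs_cache <- new.env(parent = emptyenv())

# OpenBabel fingerprint bits for one parsed molecule; errors if the SMILES
# does not parse to any atoms.
obMaccsBits <- function(smiles) {
  res <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(mol)
      ChemmineOB::fingerprint_OB(list(mol), "MACCS")),
    error = function(e) NULL)
  if (is.null(res) || !length(res)) stop("unparsable SMILES: ", smiles)
  fp <- as.integer(res[[1]])
  if (length(fp) < 166L) stop("unparsable SMILES: ", smiles)
  fp
}

# Number of aromatic rings (all perceived rings flagged aromatic), used for
# MACCS key 125 ("more than one aromatic ring").
countAromaticRings <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  r <- ChemmineR::rings(sdf[[1]], type = "all", arom = TRUE)
  sum(unlist(r$AROMATIC))
}

# Syntax-level SMILES validation. The OpenBabel reader is lenient (it will
# parse "C(" as methane), so unbalanced branches/brackets and dangling ring
# closures are rejected here before the chemistry backend sees the string.
checkSmilesSyntax <- function(smiles) {
  bad <- function() stop("unparsable SMILES: ", smiles, call. = FALSE)
  if (!nzchar(smiles)) bad()
  chars <- strsplit(smiles, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")")) bad()
  if (sum(chars == "[") != sum(chars == "]")) bad()
  depth <- 0
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1
    if (ch == ")") { depth <- depth - 1; if (depth < 0) bad() }
  }
  # ring-closure labels must come in pairs
  stripped <- gsub("\\[[^]]*\\]", "", smiles)   # bracket atoms may hold digits
  ring <- c(regmatches(stripped, gregexpr("%[0-9]{2}", stripped))[[1]],
            strsplit(gsub("%[0-9]{2}", "", stripped), "")[[1]])
  ring <- ring[grepl("^(%[0-9]{2}|[0-9])$", ring)]
  if (length(ring) && any(table(ring) %% 2 != 0)) bad()
  invisible(TRUE)
}

# Parse check through OpenBabel: the SMILES must yield a molecule.
obParseable <- function(smiles) {
  res <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(mol)
      ChemmineOB::prop_OB(mol)),
    error = function(e) NULL)
  !is.null(res) && length(res) >= 1
}

#' MACCS keys fingerprint of a molecule
#'
#' Standard 167-position MACCS structural-key bit vector of a SMILES string
#' (position i corresponds to MACCS key i-1; key 0 is unused and always 0).
#' Substructure keys are evaluated by OpenBabel; the two count-based keys
#' (125: more than one aromatic ring; 166: more than one fragment) are
#' computed from ring perception and SMILES components. The resulting bits
#' match the de-facto RDKit 167-key convention.
#'
#' @param smiles a single SMILES string.
#' @return integer vector of length 167 with entries in \{0, 1\}.
#' @export
maccsKeys <- function(smiles) {
  stopIfNotScalarString(smiles, "smiles")
  hit <- .maccs_cache[[smiles]]
  if (!is.null(hit)) return(hit)
  checkSmilesSyntax(smiles)
  if (!obParseable(smiles)) stop("unparsable SMILES: ", smiles)
  fp <- obMaccsBits(smiles)
  v <- c(0L, fp[1:166])
  # key 166: more than one fragment ('.' is the SMILES disconnection operator)
  if (length(strsplit(smiles, ".", fixed = TRUE)[[1]]) > 1L) v[167] <- 1L
  # key 125: more than one aromatic ring (rings require ring-closure digits,
  # so skip the ring-perception pass for acyclic strings)
  if (v[126] == 0L && grepl("[0-9]", smiles) &&
      countAromaticRings(smiles) > 1L)
    v[126] <- 1L
  .maccs_cache[[smiles]] <- v
  v
}

# ---- embedding providers --------------------------------------------------

# 32-bit polynomial rolling hash of a string under a stream seed.
stringHash <- function(s, seed) {
  bytes <- utf8ToInt(s)
  h <- (as.double(seed) %% 2147483647) + 1
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Construct an embedding provider
#'
#' @param name provider label.
#' @param dim output dimension.
#' @param embed function mapping one input string to a numeric vector of
#'   length \code{dim}.
#' @return an \code{\linkS4class{EmbeddingProvider}}.
#' @export
embeddingProvider <- function(name, dim, embed) {
  new("EmbeddingProvider", name = name, dim = as.integer(dim), embed = embed)
}

#' Synthetic embedding providers
#'
#' Deterministic desk-scale stand-ins for language-model embeddings.
#' \describe{
#'   \item{\code{iid_hash}}{each distinct input string gets its own
#'     pseudo-random unit-scale vector (seeded by a string hash); distinct
#'     inputs are nearly orthogonal at moderate dimension.}
#'   \item{\code{kmer_composition}}{each k-mer gets a fixed seeded random
#'     vector; the embedding of a string is the mean over its k-mers, so
#'     similar sequences map to similar embeddings and embedding distance
#'     grows with substitution count.}
#' }
#'
#' @param dim output dimension (>= 1).
#' @param seed integer seed; the provider is a pure function of
#'   (dim, seed, mode, k).
#' @param mode \code{"iid_hash"} or \code{"kmer_composition"}.
#' @param k k-mer length for \code{kmer_composition}.
#' @return an \code{\linkS4class{EmbeddingProvider}}.
#' @export
syntheticProvider <- function(dim, seed = 0, mode = c("iid_hash",
                              "kmer_composition"), k = 3) {
  mode <- match.arg(mode)
  dim <- as.integer(dim)
  if (dim < 1L) stop("dim must be >= 1")
  cache <- new.env(parent = emptyenv())
  if (mode == "iid_hash") {
    embed <- function(x) {
      hit <- cache[[x]]
      if (!is.null(hit)) return(hit)
      v <- withSeed(stringHash(x, seed), rnorm(dim)) / sqrt(dim)
      cache[[x]] <- v
      v
    }
  } else {
    kmerVec <- function(km) {
      hit <- cache[[km]]
      if (!is.null(hit)) return(hit)
      v <- withSeed(stringHash(km, seed), rnorm(dim))
      cache[[km]] <- v
      v
    }
    embed <- function(x) {
      n <- nchar(x)
      if (k > n) stop("k (", k, ") exceeds input length (", n, ")")
      kms <- substring(x, 1:(n - k + 1), k:n)
      acc <- numeric(dim)
      for (km in kms) acc <- acc + kmerVec(km)
      acc / length(kms)
    }
  }
  embeddingProvider(paste0("synthetic_", mode, "_d", dim, "_s", seed),
                    dim, embed)
}

#' Matrix-backed embedding provider for precomputed embeddings
#'
#' Wraps a dense matrix of precomputed embeddings (e.g. exported from a
#' protein or molecule language model) whose row names are the input keys.
#'
#' @param mat numeric matrix with row names.
#' @param name provider label.
#' @return an \code{\linkS4class{EmbeddingProvider}}.
#' @export
matrixProvider <- function(mat, name = "precomputed") {
  if (is.null(rownames(mat))) stop("matrix must have row names as keys")
  embeddingProvider(name, ncol(mat), function(x) {
    if (!x %in% rownames(mat)) stop("no precomputed embedding for: ", x)
    as.numeric(mat[x, ])
  })
}

embedWith <- function(provider, x) {
  stopifnot(is(provider, "EmbeddingProvider"))
  v <- provider@embed(x)
  if (length(v) != provider@dim)
    stop("provider '", provider@name, "' returned length ", length(v),
         ", declared dim ", provider@dim)
  as.numeric(v)
}

#' Featurize one enzyme-substrate pair
#'
#' Concatenates the protein embedding, the molecule embedding and the MACCS
#' keys, in that fixed order. With the default 1024-d protein and 768-d
#' molecule providers the result has 1959 features.
#'
#' @param sequence amino-acid string.
#' @param smiles substrate SMILES.
#' @param protein_provider,molecule_provider
#'   \code{\linkS4class{EmbeddingProvider}}s.
#' @return a \code{\linkS4class{FeatureBundle}}.
#' @export
featurize <- function(sequence, smiles, protein_provider, molecule_provider) {
  p <- embedWith(protein_provider, sequence)
  m <- embedWith(molecule_provider, smiles)
  keys <- maccsKeys(smiles)
  new("FeatureBundle", protein = p, molecule = m, maccs = keys,
      concat = c(p, m, as.numeric(keys)))
}

#' Average substrate features over a multi-substrate reaction
#'
#' Elementwise arithmetic mean of the per-substrate feature vectors
#' (molecule embedding and MACCS parts averaged alike), used to represent
#' reactions with several substrates by a single feature vector.
#'
#' @param smiles_list nonempty character vector of SMILES.
#' @param molecule_provider molecule \code{EmbeddingProvider}.
#' @return numeric vector of length \code{dim(provider) + 167}.
#' @export
averageMoleculeFeatures <- function(smiles_list, molecule_provider) {
  if (!length(smiles_list)) stop("smiles_list must be nonempty")
  feats <- vapply(smiles_list, function(s)
    c(embedWith(molecule_provider, s), as.numeric(maccsKeys(s))),
    numeric(molecule_provider@dim + 167L))
  rowMeans(feats)
}

#' Feature matrix for a curated dataset
#'
#' Featurizes every entry of a dataset, caching per distinct sequence and
#' SMILES, and returns the design matrix with rows in entry order.
#'
#' @param dataset a \code{KineticDataset} (or entries data.frame).
#' @inheritParams featurize
#' @return numeric matrix, one row per entry, rownames = pair key.
#' @export
featurizeDataset <- function(dataset, protein_provider, molecule_provider) {
  ent <- recordFrame(dataset)
  useq <- unique(ent$sequence)
  usmi <- unique(ent$smiles)
  pm <- vapply(useq, function(s) embedWith(protein_provider, s),
               numeric(protein_provider@dim))
  mm <- vapply(usmi, function(s)
    c(embedWith(molecule_provider, s), as.numeric(maccsKeys(s))),
    numeric(molecule_provider@dim + 167L))
  X <- t(rbind(pm[, match(ent$sequence, useq), drop = FALSE],
               mm[, match(ent$smiles, usmi), drop = FALSE]))
  rownames(X) <- pairKey(ent$sequence, ent$smiles)
  X
}
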