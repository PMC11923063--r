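#' @import methods
#' @importFrom stats predict rnorm runif sd cor setNames
#' @importFrom utils head read.csv read.delim write.table
NULL

#' Curated kinetic dataset
#'
#' Container for a curated set of enzyme--substrate kinetic measurements of a
#' single parameter class. Entries are keyed by the exact
#' (sequence, SMILES) pair; labels live on the log10 scale (kcat in s^-1,
#' Km in mM, kcat/Km as the log-difference). Entries that collapsed several
#' raw measurements carry the standard deviation of the original log10 labels
#' as a per-entry noise annotation.
#'
#' @slot param one of \code{"kcat"}, \code{"km"}, \code{"ratio"}.
#' @slot entries \code{data.frame} with at least columns \code{enzyme_id},
#'   \code{sequence}, \code{smiles}, \code{label}; optionally
#'   \code{noise_std} (NA where only a single raw label existed),
#'   \code{enzyme_type}, and for ratio datasets the parent labels
#'   \code{kcat_label}, \code{km_label}.
#'
#' @export
setClass("KineticDataset",
  representation(param = "character", entries = "data.frame"),
  validity = function(object) {
    if (!object@param %in% c("kcat", "km", "ratio"))
      return("param must be one of 'kcat', 'km', 'ratio'")
    need <- c("enzyme_id", "sequence", "smiles", "label")
    miss <- setdiff(need, names(object@entries))
    if (length(miss))
      return(paste0("entries is missing column(s): ", paste(miss, collapse = ", ")))
    if (nrow(object@entries)) {
      key <- paste(object@entries$sequence, object@entries$smiles, sep = "\r")
      if (anyDuplicated(key))
        return("duplicate (sequence, smiles) keys in entries")
      if (!all(is.finite(object@entries$label)))
        return("all labels must be finite")
    }
    TRUE
  }
)

#' Identity-threshold cluster set
#'
#' Result of greedy incremental clustering of protein sequences at a pairwise
#' identity threshold. Every sequence belongs to exactly one cluster and has
#' identity at or above the threshold to its cluster representative.
#'
#' @slot threshold identity fraction in (0, 1].
#' @slot clusters named list; names are representative sequence ids, each
#'   element a character vector of member ids (representative included).
#' @slot sequences named character vector of the clustered sequences.
#'
#' @export
setClass("ClusterSet",
  representation(threshold = "numeric", clusters = "list",
                 sequences = "character"),
  validity = function(object) {
    if (length(object@threshold) != 1 || object@threshold <= 0 ||
        object@threshold > 1)
      return("threshold must be a single value in (0, 1]")
    members <- unlist(object@clusters, use.names = FALSE)
    if (anyDuplicated(members))
      return("a sequence id appears in more than one cluster")
    if (!setequal(members, names(object@sequences)))
      return("cluster members and sequence ids disagree")
    TRUE
  }
)

#' Cross-validation fold assignment
#'
#' Maps record keys to fold indices in \code{0:(k-1)}. In clustered mode all
#' records whose sequences share an identity cluster share a fold, which is
#' what makes the resulting cross-validation leakage-free at the clustering
#' threshold.
#'
#' @slot k number of folds.
#' @slot fold_of named integer vector, values in \code{0:(k-1)}.
#' @slot mode \code{"clustered"} or \code{"random"}.
#' @slot seed integer seed the assignment was generated with.
#'
#' @export
setClass("FoldAssignment",
  representation(k = "integer", fold_of = "integer", mode = "character",
                 seed = "integer"),
  validity = function(object) {
    if (object@k < 2L) return("k must be >= 2")
    if (!object@mode %in% c("clustered", "random"))
      return("mode must be 'clustered' or 'random'")
    if (length(object@fold_of) &&
        (min(object@fold_of) < 0L || max(object@fold_of) >= object@k))
      return("fold indices out of range")
    if (is.null(names(object@fold_of)))
      return("fold_of must be named by record key")
    TRUE
  }
)

#' Embedding provider
#'
#' A deterministic map from an input string (amino-acid sequence or SMILES)
#' to a fixed-length numeric vector. Real protein/molecule language models
#' plug in through this contract; the package ships synthetic providers for
#' desk-scale work and a matrix-backed provider for precomputed embeddings.
#'
#' @slot name provider label.
#' @slot dim output vector length.
#' @slot embed function(character(1)) -> numeric(dim).
#'
#' @export
setClass("EmbeddingProvider",
  representation(name = "character", dim = "integer", embed = "function"),
  validity = function(object) {
    if (object@dim < 1L) return("dim must be >= 1")
    TRUE
  }
)

#' Shallow neural kinetic regressor
#'
#' A one-hidden-layer network (dense -> ReLU -> linear output) trained with
#' an RMSE loss by Adam. \code{params} holds the weight matrices; training is
#' fully seeded so identical configurations reproduce identical parameters.
#'
#' @slot params list with elements \code{W1}, \code{b1}, \code{W2}, \code{b2}.
#' @slot config the \code{\link{regressorConfig}} list used for training.
#' @slot loss_history numeric vector of per-epoch training RMSE.
#'
#' @export
setClass("KineticRegressor",
  representation(params = "list", config = "list", loss_history = "numeric"))

#' Extra-trees style kinetic regressor
#'
#' Randomized tree-ensemble backend satisfying the same predict contract as
#' \code{\linkS4class{KineticRegressor}}.
#'
#' @slot fit fitted \code{ranger} object (extratrees splitrule).
#' @slot config training configuration list.
#'
#' @export
setClass("TreeRegressor",
  representation(fit = "ANY", config = "list"))

#' Two-stage kcat/Km model
#'
#' Combines frozen kcat and Km submodels with an attention-gated correction
#' network: prediction = a * (kcat_pred - km_pred) + b * correction, with the
#' log-ratio identity log10(kcat/Km) = log10 kcat - log10 Km.
#'
#' @slot kcat_model frozen \code{KineticRegressor} for log10 kcat.
#' @slot km_model frozen \code{KineticRegressor} for log10 Km.
#' @slot correction list of correction-network parameters
#'   (\code{Wd}, \code{bd}, \code{Wa}, \code{wo}, \code{bo}).
#' @slot blend numeric(2), the learnable weights (a, b).
#' @slot config correction-training configuration.
#'
#' @export
setClass("TwoStageRatioModel",
  representation(kcat_model = "KineticRegressor", km_model = "KineticRegressor",
                 correction = "list", blend = "numeric", config = "list"),
  validity = function(object) {
    if (length(object@blend) != 2) return("blend must be length 2 (a, b)")
    TRUE
  }
)

#' Mutant panel
#'
#' The wild-type and variants measured against one reaction (one
#' UniProtID--SMILES pair), with experimental and predicted log10 labels.
#' Panels are the unit of the mutant-ranking benchmarks: per-reaction
#' Spearman correlation and pairwise ordering accuracy over the
#' N(N-1)/2 variant pairs.
#'
#' @slot enzyme_id UniProt accession shared by all variants.
#' @slot smiles substrate SMILES shared by all variants.
#' @slot variants \code{data.frame} with columns \code{sequence},
#'   \code{experimental}, \code{predicted}, \code{is_wild_type}.
#'
#' @export
setClass("MutantPanel",
  representation(enzyme_id = "character", smiles = "character",
                 variants = "data.frame"),
  validity = function(object) {
    need <- c("sequence", "experimental", "predicted", "is_wild_type")
    miss <- setdiff(need, names(object@variants))
    if (length(miss))
      return(paste0("variants missing column(s): ", paste(miss, collapse = ", ")))
    if (anyDuplicated(object@variants$sequence))
      return("duplicate variant sequences in panel")
    TRUE
  }
)

#' Position-specific scoring matrix
#'
#' Integer log-odds scores for the 20 standard residues at each position of a
#' query sequence, as produced by PSI-BLAST style profile tools.
#'
#' @slot scores integer matrix, L rows (positions) by 20 columns named with
#'   the one-letter residue codes.
#' @slot query character vector of length L, the query residue per position.
#'
#' @export
setClass("Pssm",
  representation(scores = "matrix", query = "character"),
  validity = function(object) {
    if (ncol(object@scores) != 20L)
      return("scores must have exactly 20 residue columns")
    if (nrow(object@scores) != length(object@query))
      return("query length must match number of positions")
    if (!all(AA_STANDARD_20 %in% colnames(object@scores)))
      return("score columns must cover the 20 standard residues")
    TRUE
  }
)

# ---- accessors ------------------------------------------------------------

#' @describeIn KineticDataset-class entries data.frame
#' @param x,object a \code{KineticDataset}
#' @export
entries <- function(x) {
  stopifnot(is(x, "KineticDataset"))
  x@entries
}

#' @describeIn KineticDataset-class parameter class of the dataset
#' @export
kineticParam <- function(x) {
  stopifnot(is(x, "KineticDataset"))
  x@param
}

#' @describeIn ClusterSet-class list of clusters (representative -> members)
#' @export
clusters <- function(x) {
  stopifnot(is(x, "ClusterSet"))
  x@clusters
}

#' @describeIn FoldAssignment-class named integer vector of fold indices
#' @export
foldOf <- function(x) {
  stopifnot(is(x, "FoldAssignment"))
  x@fold_of
}

#' @describeIn MutantPanel-class variant table of a panel
#' @export
variants <- function(x) {
  stopifnot(is(x, "MutantPanel"))
  x@variants
}

#' @describeIn Pssm-class score matrix (L x 20)
#' @export
pssmScores <- function(x) {
  stopifnot(is(x, "Pssm"))
  x@scores
}

#' @describeIn TwoStageRatioModel-class blend weights (a, b)
#' @export
blendWeights <- function(x) {
  stopifnot(is(x, "TwoStageRatioModel"))
  x@blend
}

# ---- show methods ---------------------------------------------------------

setMethod("show", "KineticDataset", function(object) {
  cat("KineticDataset [", object@param, "] with ", nrow(object@entries),
      " entries\n", sep = "")
  if (nrow(object@entries)) {
    cat("  label range: [",
        format(min(object@entries$label), digits = 4), ", ",
        format(max(object@entries$label), digits = 4), "] (log10)\n", sep = "")
    if ("noise_std" %in% names(object@entries))
      cat("  entries with label-noise annotation: ",
          sum(!is.na(object@entries$noise_std)), "\n", sep = "")
  }
})

setMethod("show", "ClusterSet", function(object) {
  sizes <- lengths(object@clusters)
  cat("ClusterSet: ", length(object@clusters), " clusters over ",
      length(object@sequences), " sequences (identity threshold ",
      object@threshold, ")\n", sep = "")
  if (length(sizes))
    cat("  cluster sizes: min ", min(sizes), ", median ",
        stats::median(sizes), ", max ", max(sizes), "\n", sep = "")
})

setMethod("show", "FoldAssignment", function(object) {
  cat("FoldAssignment: ", length(object@fold_of), " records in ",
      object@k, " folds (", object@mode, " mode, seed ", object@seed,
      ")\n", sep = "")
  print(table(fold = object@fold_of))
})

setMethod("show", "EmbeddingProvider", function(object) {
  cat("EmbeddingProvider '", object@name, "' (dim ", object@dim, ")\n",
      sep = "")
})

setMethod("show", "KineticRegressor", function(object) {
  cat("KineticRegressor: ", nrow(object@params$W1), " -> ",
      ncol(object@params$W1), " -> 1 (ReLU hidden layer)\n", sep = "")
  if (length(object@loss_history))
    cat("  final training RMSE: ",
        format(tail2(object@loss_history), digits = 4), " over ",
        length(object@loss_history), " epochs\n", sep = "")
})

setMethod("show", "TreeRegressor", function(object) {
  cat("TreeRegressor (extratrees splitrule), ",
      object@config$num_trees, " trees\n", sep = "")
})

setMethod("show", "TwoStageRatioModel", function(object) {
  cat("TwoStageRatioModel: frozen kcat/Km submodels + attention correction\n")
  cat("  blend weights (a, b): ", paste(format(object@blend, digits = 4),
      collapse = ", "), "\n", sep = "")
})

setMethod("show", "MutantPanel", function(object) {
  cat("MutantPanel for ", object@enzyme_id, " / ", object@smiles, ": ",
      nrow(object@variants), " variants (",
      sum(object@variants$is_wild_type), " wild-type)\n", sep = "")
})

setMethod("show", "Pssm", function(object) {
  cat("Pssm: ", nrow(object@scores), " positions x 20 residues\n", sep = "")
})

tail2 <- function(x) x[length(x)]
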