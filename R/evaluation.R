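# Evaluation: regression metrics on log10 values and mutant-ranking
# benchmarks. Predictions X and experiments Y are compared by the Pearson
# correlation, the Spearman rank correlation and the root-mean-square error;
# enzyme-engineering ability is measured per reaction (one UniProtID-SMILES
# pair) by the within-panel Spearman correlation, the pairwise ordering
# accuracy M_true / M_total over the N(N-1)/2 variant pairs, and pooled
# correlations of panel-mean-centered mutation effects.

#' Pearson correlation coefficient
#'
#' PCC = sum((X-mean(X))(Y-mean(Y))) / sqrt(sum((X-mean(X))^2) *
#' sum((Y-mean(Y))^2)), computed directly.
#'
#' @param X,Y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1].
#' @export
pcc <- function(X, Y) {
  if (length(X) != length(Y)) stop("length mismatch")
  if (length(X) < 2) stop("need at least 2 points")
  dx <- X - mean(X)
  dy <- Y - mean(Y)
  den <- sqrt(sum(dx^2)) * sqrt(sum(dy^2))
  if (den == 0) stop("undefined: zero variance in X or Y")
  sum(dx * dy) / den
}

#' Spearman rank correlation coefficient
#'
#' Without ties: SCC = 1 - 6 * sum(d_i^2) / (n (n^2 - 1)) with d_i the rank
#' differences. With ties: Pearson correlation of average ranks (the
#' standard generalization, to which the explicit formula reduces when all
#' values are distinct).
#'
#' @param X,Y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1].
#' @export
scc <- function(X, Y) {
  if (length(X) != length(Y)) stop("length mismatch")
  n <- length(X)
  if (n < 2) stop("need at least 2 points")
  if (length(unique(X)) == 1 || length(unique(Y)) == 1)
    stop("undefined: constant vector")
  rx <- rank(X, ties.method = "average")
  ry <- rank(Y, ties.method = "average")
  if (!anyDuplicated(rx) && !anyDuplicated(ry)) {
    d <- rx - ry
    1 - 6 * sum(d^2) / (n * (n^2 - 1))
  } else {
    pcc(rx, ry)
  }
}

#' Root-mean-square error
#'
#' RMSE = sqrt(mean((Y - X)^2)).
#'
#' @param X predicted values; \code{Y} experimental values.
#' @param Y numeric vector the same length as \code{X}.
#' @return nonnegative real.
#' @export
rmse <- function(X, Y) {
  if (length(X) != length(Y)) stop("length mismatch")
  sqrt(mean((Y - X)^2))
}

#' Build mutant panels from a dataset and its predictions
#'
#' Groups entries by reaction (identical UniProt id and SMILES) and keeps
#' reactions whose number of distinct variant sequences -- wild-type
#' included -- is at least \code{min_variants}.
#'
#' @param dataset a \code{KineticDataset} (entries must carry
#'   \code{enzyme_id}; \code{enzyme_type} marks the wild-type).
#' @param predictions named numeric vector keyed by the pair key
#'   (as produced by \code{\link{crossValidate}}), or a numeric vector in
#'   entry order.
#' @param min_variants minimum panel size N (kept when variants >= N).
#' @return list of \code{\linkS4class{MutantPanel}}s.
#' @export
buildMutantPanels <- function(dataset, predictions, min_variants = 20) {
  ent <- recordFrame(dataset)
  key <- pairKey(ent$sequence, ent$smiles)
  pred <- if (!is.null(names(predictions))) unname(predictions[key])
          else as.numeric(predictions)
  if (length(pred) != nrow(ent))
    stop("predictions do not cover the dataset")
  rkey <- paste(ent$enzyme_id, ent$smiles, sep = "\r")
  panels <- list()
  for (rk in unique(rkey)) {
    idx <- which(rkey == rk)
    if (length(idx) < min_variants) next
    wt <- if ("enzyme_type" %in% names(ent))
      ent$enzyme_type[idx] == "wild_type" else rep(FALSE, length(idx))
    panels[[length(panels) + 1L]] <- new("MutantPanel",
      enzyme_id = ent$enzyme_id[idx[1]],
      smiles = ent$smiles[idx[1]],
      variants = data.frame(sequence = ent$sequence[idx],
                            experimental = ent$label[idx],
                            predicted = pred[idx],
                            is_wild_type = wt,
                            stringsAsFactors = FALSE))
  }
  panels
}

#' Per-panel Spearman correlation and its mean
#'
#' The within-panel SCC between predicted and experimental labels measures
#' how well a model ranks the variants of one reaction; the unweighted mean
#' over panels summarizes ranking ability across reactions.
#'
#' @param panels list of \code{MutantPanel}s.
#' @return list with \code{per_panel} (named numeric; NA where SCC is
#'   undefined), \code{mean} (over defined panels) and
#'   \code{n_undefined}.
#' @export
panelScc <- function(panels) {
  vals <- vapply(panels, function(p) {
    v <- variants(p)
    tryCatch(scc(v$predicted, v$experimental), error = function(e) NA_real_)
  }, numeric(1))
  names(vals) <- vapply(panels, function(p)
    paste(p@enzyme_id, p@smiles, sep = "|"), character(1))
  list(per_panel = vals, mean = mean(vals, na.rm = TRUE),
       n_undefined = sum(is.na(vals)))
}

#' Pairwise ordering accuracy of a mutant panel
#'
#' Over all unordered variant pairs with distinct experimental values, the
#' fraction whose predicted ordering matches the experimental ordering
#' (accuracy = M_true / M_total). Pairs tied experimentally are excluded
#' from M_total; pairs tied in prediction count as incorrect.
#'
#' @param panel a \code{MutantPanel} with at least 2 variants.
#' @return fraction in [0, 1].
#' @export
pairwiseAccuracy <- function(panel) {
  v <- variants(panel)
  n <- nrow(v)
  if (n < 2) stop("panel needs at least 2 variants")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  de <- v$experimental[idx[, 1]] - v$experimental[idx[, 2]]
  dp <- v$predicted[idx[, 1]] - v$predicted[idx[, 2]]
  informative <- de != 0
  if (!any(informative))
    stop("undefined: all variant pairs are experimentally tied")
  mean(sign(dp[informative]) == sign(de[informative]))
}

#' Panel-centered mutation effects
#'
#' Subtracts the panel mean from the experimental and predicted labels so
#' each variant is expressed as its effect relative to the reaction average;
#' each centered vector sums to zero.
#'
#' @param panel a \code{MutantPanel}.
#' @return list with \code{experimental} and \code{predicted} centered
#'   vectors.
#' @export
mutationEffects <- function(panel) {
  v <- variants(panel)
  list(experimental = v$experimental - mean(v$experimental),
       predicted = v$predicted - mean(v$predicted))
}

#' Pooled mutation-effect correlation across reactions
#'
#' Concatenates the centered mutation effects of all panels and computes the
#' pooled Pearson and Spearman correlations between predicted and
#' experimental effects.
#'
#' @param panels list of \code{MutantPanel}s.
#' @return list with \code{experimental}, \code{predicted} (pooled centered
#'   vectors), \code{pcc} and \code{scc}.
#' @export
concatenateEffects <- function(panels) {
  if (!length(panels)) stop("no panels")
  eff <- lapply(panels, mutationEffects)
  ex <- unlist(lapply(eff, `[[`, "experimental"), use.names = FALSE)
  pr <- unlist(lapply(eff, `[[`, "predicted"), use.names = FALSE)
  list(experimental = ex, predicted = pr,
       pcc = pcc(pr, ex), scc = scc(pr, ex))
}
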