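# Enzyme mining and in-silico directed evolution.
#
# Workflow: candidate homologs are length-filtered against the reference and
# ranked by predicted catalytic efficiency (log10 kcat - log10 Km); pocket
# residues near the docked substrate define the mutation sites; every site
# is mutated to the 19 alternative standard residues; and the mutant pool is
# screened first by predicted kcat/Km (top half) and then by evolutionary
# plausibility (Delta-PSSM strictly greater than a cutoff, default 7).

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the standard ASCII PSSM layout (header line of residue letters,
#' then one row per query position: position, query residue, 20 integer
#' log-odds scores, optionally followed by weighted-percentage and
#' information columns, which are ignored). Score columns are keyed by the
#' residue letters of the header, so permuted column orders parse
#' correctly.
#'
#' @param path file path.
#' @return a \code{\linkS4class{Pssm}}.
#' @export
readPssm <- function(path) {
  if (!file.exists(path)) stop("cannot read PSSM file: ", path)
  lines <- readLines(path)
  header_i <- NA_integer_
  res_cols <- NULL
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) >= 20 && all(toks[1:20] %in% AA_STANDARD_20) &&
        !anyDuplicated(toks[1:20])) {
      header_i <- i
      res_cols <- toks[1:20]
      break
    }
  }
  if (is.na(header_i)) stop("no residue header line found in PSSM file")
  scores <- list()
  query <- character(0)
  positions <- integer(0)
  for (i in (header_i + 1):length(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    toks <- strsplit(line, "\\s+")[[1]]
    if (is.na(suppressWarnings(as.integer(toks[1])))) break  # footer
    if (length(toks) < 22)
      stop("malformed PSSM row (fewer than 20 scores) at line ", i)
    sc <- suppressWarnings(as.integer(toks[3:22]))
    if (anyNA(sc))
      stop("malformed PSSM row (non-integer score) at line ", i)
    positions <- c(positions, as.integer(toks[1]))
    query <- c(query, toks[2])
    scores[[length(scores) + 1L]] <- sc
  }
  if (!length(scores)) stop("PSSM file contains no score rows")
  if (!identical(positions, seq_along(positions)))
    stop("PSSM positions are not consecutive from 1")
  m <- do.call(rbind, scores)
  colnames(m) <- res_cols
  m <- m[, AA_STANDARD_20, drop = FALSE]
  rownames(m) <- NULL
  new("Pssm", scores = m, query = query)
}

#' Score change of a point mutation under a PSSM
#'
#' Delta-PSSM of mutating residue \code{from_aa} to \code{to_aa} at
#' 1-based \code{site}: the target-residue score minus the wild-type-residue
#' score at that position. Antisymmetric in its residue arguments.
#'
#' @param pssm a \code{\linkS4class{Pssm}}.
#' @param site 1-based position.
#' @param from_aa,to_aa one-letter codes of standard residues.
#' @return integer score difference.
#' @export
deltaPssm <- function(pssm, site, from_aa, to_aa) {
  stopifnot(is(pssm, "Pssm"))
  L <- nrow(pssm@scores)
  if (site < 1 || site > L) stop("site ", site, " outside [1, ", L, "]")
  if (!from_aa %in% AA_STANDARD_20 || !to_aa %in% AA_STANDARD_20)
    stop("residues must be standard one-letter codes")
  unname(pssm@scores[site, to_aa] - pssm@scores[site, from_aa])
}

#' Enumerate single-point mutants at selected sites
#'
#' Each site is mutated to the 19 standard residues other than its
#' wild-type residue, giving exactly 19 x number-of-sites mutants, each
#' differing from the wild-type at exactly one position.
#'
#' @param sequence wild-type amino-acid string.
#' @param sites distinct 1-based positions within the sequence.
#' @return data.frame with columns \code{site}, \code{wt_aa}, \code{mut_aa},
#'   \code{mutation} (e.g. "T216M"), \code{sequence} (the derived mutant),
#'   and placeholder columns \code{model_score}, \code{delta_pssm} (NA).
#' @export
enumerateMutants <- function(sequence, sites) {
  stopIfNotScalarString(sequence, "sequence")
  sites <- as.integer(sites)
  if (anyDuplicated(sites)) stop("duplicate mutation sites")
  L <- nchar(sequence)
  if (any(sites < 1 | sites > L)) stop("site outside sequence range")
  chars <- strsplit(sequence, "")[[1]]
  rows <- lapply(sort(sites), function(s) {
    wt <- chars[s]
    if (!wt %in% AA_STANDARD_20)
      stop("nonstandard wild-type residue '", wt, "' at site ", s)
    muts <- setdiff(AA_STANDARD_20, wt)
    seqs <- vapply(muts, function(m) {
      v <- chars
      v[s] <- m
      paste(v, collapse = "")
    }, character(1))
    data.frame(site = s, wt_aa = wt, mut_aa = muts,
               mutation = paste0(wt, s, muts), sequence = seqs,
               model_score = NA_real_, delta_pssm = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pocket mutation sites from an enzyme-ligand complex structure
#'
#' Selects protein residues whose minimum heavy-atom distance to any ligand
#' heavy atom is at or below the radius (default 12 Angstrom), minus an
#' explicit exclusion list (e.g. catalytic histidines coordinating a metal).
#' Hydrogens are ignored on both sides.
#'
#' @param pdb a \code{bio3d} pdb object or a path to a PDB file.
#' @param ligand_resid residue name(s) of the ligand (HETATM records).
#' @param radius cutoff distance in Angstrom.
#' @param excluded_sites residue numbers excluded even when within radius.
#' @return sorted integer vector of residue numbers.
#' @export
pocketSites <- function(pdb, ligand_resid, radius = 12,
                        excluded_sites = integer(0)) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  atoms <- pdb$atom
  heavy <- is.na(atoms$elesy) | toupper(atoms$elesy) != "H"
  lig <- atoms$resid %in% ligand_resid & heavy
  if (!any(lig)) stop("no heavy ligand atoms with resid ",
                      paste(ligand_resid, collapse = "/"))
  prot <- atoms$type == "ATOM" & !atoms$resid %in% ligand_resid & heavy
  if (!any(prot)) stop("no protein heavy atoms in structure")
  lxyz <- as.matrix(atoms[lig, c("x", "y", "z")])
  pxyz <- as.matrix(atoms[prot, c("x", "y", "z")])
  # min distance from each protein atom to any ligand atom
  d2 <- outer(rowSums(pxyz^2), rowSums(lxyz^2), "+") -
    2 * pxyz %*% t(lxyz)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  resno <- atoms$resno[prot]
  per_res <- tapply(mind, resno, min)
  sites <- as.integer(names(per_res)[per_res <= radius])
  sort(setdiff(sites, as.integer(excluded_sites)))
}

#' Mine homologous enzyme candidates by predicted kinetics
#'
#' Removes candidates whose length differs from the reference by strictly
#' more than \code{max_len_diff} residues, scores the survivors with the
#' kcat and Km models against the target substrate, ranks them by predicted
#' catalytic efficiency (log10 kcat - log10 Km, descending) and keeps the
#' top \code{top_k}.
#'
#' @param reference_seq reference enzyme sequence.
#' @param candidates named character vector of candidate sequences.
#' @param smiles target substrate SMILES.
#' @param kcat_model,km_model trained regressors.
#' @param protein_provider,molecule_provider embedding providers matching
#'   the models' input layout.
#' @param max_len_diff length-difference cutoff (strict; equal-to kept).
#' @param top_k maximum number of ranked candidates returned.
#' @return data.frame: \code{id}, \code{length}, \code{len_diff},
#'   \code{kcat_pred}, \code{km_pred}, \code{score}, ordered by descending
#'   score.
#' @export
mineHomologs <- function(reference_seq, candidates, smiles,
                         kcat_model, km_model,
                         protein_provider, molecule_provider,
                         max_len_diff = 20, top_k = 150) {
  stopIfNotScalarString(reference_seq, "reference_seq")
  if (is.null(names(candidates))) stop("candidates must be named")
  len_diff <- nchar(candidates) - nchar(reference_seq)
  keep <- abs(len_diff) <= max_len_diff
  if (!any(keep)) {
    warning("no candidates within the length filter")
    return(data.frame(id = character(), length = integer(),
                      len_diff = integer(), kcat_pred = numeric(),
                      km_pred = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  cand <- candidates[keep]
  X <- t(vapply(cand, function(s)
    featurize(s, smiles, protein_provider, molecule_provider)@concat,
    numeric(protein_provider@dim + molecule_provider@dim + 167L)))
  kcat_pred <- predict(kcat_model, X)
  km_pred <- predict(km_model, X)
  out <- data.frame(id = names(cand), length = nchar(cand),
                    len_diff = len_diff[keep],
                    kcat_pred = kcat_pred, km_pred = km_pred,
                    score = kcat_pred - km_pred,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_k)
}

#' Screen enumerated mutants by model score and Delta-PSSM
#'
#' Two filters in fixed order: (1) keep the top \code{ceiling(top_fraction *
#' M)} mutants by predicted log10(kcat/Km); (2) among those, keep mutants
#' with Delta-PSSM strictly greater than \code{delta_min}. Mutants dropped
#' by filter 1 are dropped regardless of their Delta-PSSM.
#'
#' @param mutants data.frame from \code{\link{enumerateMutants}}; if
#'   \code{model_score} is all-NA a model and providers must be supplied.
#' @param pssm a \code{\linkS4class{Pssm}} covering the wild-type sequence.
#' @param ratio_model optional \code{TwoStageRatioModel} (or any predict
#'   contract model) used to score mutants.
#' @param smiles substrate SMILES (needed when scoring).
#' @param protein_provider,molecule_provider providers (needed when
#'   scoring).
#' @param top_fraction fraction of mutants retained by model score.
#' @param delta_min Delta-PSSM cutoff (strict inequality).
#' @return list with \code{proposals} (kept mutants sorted by descending
#'   model score, both scores filled) and \code{table} (all mutants with a
#'   \code{kept}/\code{dropped_reason} annotation).
#' @export
screenMutants <- function(mutants, pssm, ratio_model = NULL, smiles = NULL,
                          protein_provider = NULL, molecule_provider = NULL,
                          top_fraction = 0.5, delta_min = 7) {
  stopifnot(is(pssm, "Pssm"))
  M <- nrow(mutants)
  if (!M) stop("empty mutant table")
  L <- nrow(pssm@scores)
  if (any(nchar(mutants$sequence) != L))
    stop("PSSM length (", L, ") does not match mutant sequence length")
  if (all(is.na(mutants$model_score))) {
    if (is.null(ratio_model))
      stop("mutants are unscored and no ratio_model was supplied")
    X <- t(vapply(mutants$sequence, function(s)
      featurize(s, smiles, protein_provider, molecule_provider)@concat,
      numeric(protein_provider@dim + molecule_provider@dim + 167L)))
    mutants$model_score <- if (is(ratio_model, "TwoStageRatioModel"))
      ratioPredict(ratio_model, X) else predict(ratio_model, X)
  }
  mutants$delta_pssm <- mapply(function(s, f, t) deltaPssm(pssm, s, f, t),
                               mutants$site, mutants$wt_aa, mutants$mut_aa)
  n_keep <- ceiling(top_fraction * M)
  ord <- order(-mutants$model_score)
  top_half <- rep(FALSE, M)
  top_half[ord[seq_len(n_keep)]] <- TRUE
  conserved <- mutants$delta_pssm > delta_min
  mutants$kept <- top_half & conserved
  mutants$dropped_reason <- ifelse(mutants$kept, "",
    ifelse(!top_half, "model_score_bottom_half", "delta_pssm_too_low"))
  proposals <- mutants[mutants$kept, , drop = FALSE]
  proposals <- proposals[order(-proposals$model_score), , drop = FALSE]
  rownames(proposals) <- NULL
  list(proposals = proposals, table = mutants)
}
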