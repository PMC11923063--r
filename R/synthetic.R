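# Synthetic benchmark generator.
#
# Emulates the statistical structure that makes random cross-validation
# splits leak: homologous enzyme families (a random ancestor per family,
# members derived by iid substitutions), a fixed pool of small-molecule
# substrates, and log10-scale labels decomposed as
#   label = mu + family_effect + substrate_effect + variant_effect + noise.
# Variant effects are deliberately not encoded in the synthetic embeddings:
# they are irreducible noise to the model, so any performance difference
# between random and clustered splits is attributable to family
# memorization.

#' Fixed substrate SMILES pool
#'
#' Small organic molecules with valid SMILES, so fingerprinting never fails.
#'
#' @param n number of substrates (up to 16).
#' @return character vector of SMILES.
#' @export
substratePool <- function(n = 8) {
  pool <- c(
    "CCO",                         # ethanol
    "Oc1ccccc1",                   # phenol
    "CC(O)=O",                     # acetic acid
    "OCC1OC(O)C(O)C(O)C1O",        # hexose
    "COc1cc(C=C)ccc1O",            # 4-vinylguaiacol
    "COc1cc(C=O)ccc1O",            # vanillin
    "CC(=O)C(O)=O",                # pyruvic acid
    "OCC(O)CO",                    # glycerol
    "O=Cc1ccccc1",                 # benzaldehyde
    "C[C@H](N)C(O)=O",             # L-alanine
    "OC(=O)CCC(O)=O",              # succinic acid
    "NC(N)=O",                     # urea
    "c1ccc2[nH]ccc2c1",            # indole
    "CC(C)CC(N)C(O)=O",            # leucine
    "OC(=O)c1ccccc1O",             # salicylic acid
    "CN1C=NC2=C1C(=O)N(C)C(=O)N2C" # caffeine
  )
  if (n > length(pool)) stop("at most ", length(pool), " substrates available")
  pool[seq_len(n)]
}

#' Simulate homologous enzyme families
#'
#' Each family grows from a random ancestor of the 20 standard residues;
#' every member substitutes each position independently with probability
#' \code{within_rate} (uniformly to one of the 19 alternatives, no indels,
#' so alignment identity stays analytic).
#'
#' @param n_families number of families.
#' @param members_per_family members per family.
#' @param seq_len sequence length (>= 30).
#' @param within_rate per-position substitution probability in [0, 1).
#' @param seed integer seed.
#' @return list with \code{sequences} (named character vector,
#'   ids "f<i>m<j>"), \code{family} (named integer vector of family
#'   indices) and \code{ancestors} (one founding sequence per family).
#' @export
simulateFamilies <- function(n_families, members_per_family, seq_len = 120,
                             within_rate = 0.05, seed = 0) {
  if (within_rate < 0 || within_rate >= 1)
    stop("within_rate must be in [0, 1)")
  if (seq_len < 30) stop("seq_len must be >= 30")
  withSeed(childSeed(seed, "families"), {
    seqs <- character(0)
    fam <- integer(0)
    ancestors <- character(0)
    for (i in seq_len(n_families)) {
      anc <- sample(AA_STANDARD_20, seq_len, replace = TRUE)
      ancestors[paste0("f", i)] <- paste(anc, collapse = "")
      for (j in seq_len(members_per_family)) {
        member <- anc
        hit <- runif(seq_len) < within_rate
        if (any(hit))
          member[hit] <- vapply(member[hit], function(a)
            sample(setdiff(AA_STANDARD_20, a), 1), character(1))
        id <- paste0("f", i, "m", j)
        seqs[id] <- paste(member, collapse = "")
        fam[id] <- i
      }
    }
    list(sequences = seqs, family = fam, ancestors = ancestors)
  })
}

#' Simulate kinetic labels with variance components
#'
#' Each enzyme is paired with \code{substrates_per_enzyme} substrates drawn
#' from the pool; the log10 label of a record decomposes as mu +
#' family_effect + substrate_effect + variant_effect + measurement noise,
#' with each effect drawn once per family/substrate/enzyme from a normal
#' with the corresponding sigma. For \code{param = "both"}, independent
#' effect sets generate kcat and Km labels and the ratio label is their
#' difference.
#'
#' @param families output of \code{\link{simulateFamilies}}.
#' @param substrates character vector of SMILES.
#' @param sigma_fam,sigma_sub,sigma_var,sigma_eps nonnegative standard
#'   deviations of the variance components.
#' @param mu grand mean of the log10 labels.
#' @param substrates_per_enzyme substrates sampled per enzyme.
#' @param param \code{"kcat"}, \code{"km"} or \code{"both"}.
#' @param seed integer seed.
#' @return list with \code{records} (data.frame: enzyme_id, sequence,
#'   smiles, label [, kcat_label, km_label], enzyme_type) and
#'   \code{effects} (true per-family/substrate/enzyme effects, for recovery
#'   tests).
#' @export
simulateKinetics <- function(families, substrates, sigma_fam = 1.0,
                             sigma_sub = 0.5, sigma_var = 0.2,
                             sigma_eps = 0.2, mu = 1.0,
                             substrates_per_enzyme = 2,
                             param = c("kcat", "km", "both"), seed = 0) {
  param <- match.arg(param)
  if (any(c(sigma_fam, sigma_sub, sigma_var, sigma_eps) < 0))
    stop("sigmas must be nonnegative")
  if (!length(substrates)) stop("empty substrate pool")
  seqs <- families$sequences
  fam <- families$family
  n_fam <- max(fam)
  withSeed(childSeed(seed, "kinetics"), {
    drawSet <- function() list(
      family = rnorm(n_fam, 0, sigma_fam),
      substrate = setNames(rnorm(length(substrates), 0, sigma_sub),
                           substrates),
      variant = setNames(rnorm(length(seqs), 0, sigma_var), names(seqs)))
    sets <- if (param == "both") list(kcat = drawSet(), km = drawSet())
            else setNames(list(drawSet()), param)
    nsub <- min(substrates_per_enzyme, length(substrates))
    rows <- lapply(names(seqs), function(id) {
      subs <- sample(substrates, nsub)
      data.frame(enzyme_id = id, sequence = unname(seqs[id]), smiles = subs,
                 stringsAsFactors = FALSE)
    })
    rec <- do.call(rbind, rows)
    # two family members may coincide (e.g. both escaped substitution);
    # keep one record per (sequence, smiles) key, as in curated datasets
    rec <- rec[!duplicated(pairKey(rec$sequence, rec$smiles)), , drop = FALSE]
    labelOf <- function(set) {
      mu + set$family[fam[rec$enzyme_id]] + set$substrate[rec$smiles] +
        set$variant[rec$enzyme_id] +
        rnorm(nrow(rec), 0, sigma_eps)
    }
    if (param == "both") {
      rec$kcat_label <- labelOf(sets$kcat)
      rec$km_label <- labelOf(sets$km)
      rec$label <- rec$kcat_label - rec$km_label
    } else {
      rec$label <- labelOf(sets[[param]])
    }
    rec$enzyme_type <- "wild_type"
    rownames(rec) <- NULL
    list(records = rec, effects = sets)
  })
}

#' Simulate a mutant panel with known true ordering
#'
#' Single-point mutants of a wild-type sequence with experimental labels =
#' true effect + measurement noise (wild-type true effect 0). The true
#' effects are returned so ranking metrics can be checked against the known
#' ordering.
#'
#' @param wt_seq wild-type sequence.
#' @param n_mutants number of variants besides the wild-type (>= 1; at most
#'   19 x sequence length).
#' @param effect_sd standard deviation of true mutation effects.
#' @param noise_sd measurement noise standard deviation.
#' @param seed integer seed.
#' @param enzyme_id,smiles reaction key of the panel.
#' @return a \code{\linkS4class{MutantPanel}} whose variants carry an extra
#'   \code{true_effect} column (\code{predicted} is NA, to be filled by a
#'   model under evaluation).
#' @export
simulateMutantPanel <- function(wt_seq, n_mutants, effect_sd = 1,
                                noise_sd = 0.1, seed = 0,
                                enzyme_id = "WT0001", smiles = "CCO") {
  stopIfNotScalarString(wt_seq, "wt_seq")
  L <- nchar(wt_seq)
  if (n_mutants < 1) stop("n_mutants must be >= 1")
  if (n_mutants > 19 * L)
    stop("n_mutants exceeds the number of single-point mutants (19 x ", L, ")")
  withSeed(childSeed(seed, "panel"), {
    all_mut <- enumerateMutants(wt_seq, seq_len(L))
    pick <- sample.int(nrow(all_mut), n_mutants)
    true_eff <- c(0, rnorm(n_mutants, 0, effect_sd))
    labels <- true_eff + rnorm(n_mutants + 1, 0, noise_sd)
    v <- data.frame(
      sequence = c(wt_seq, all_mut$sequence[pick]),
      experimental = labels,
      predicted = NA_real_,
      is_wild_type = c(TRUE, rep(FALSE, n_mutants)),
      true_effect = true_eff,
      stringsAsFactors = FALSE)
    new("MutantPanel", enzyme_id = enzyme_id, smiles = smiles, variants = v)
  })
}

#' Default parameters of the leakage benchmark
#'
#' The study conditions of the random-versus-clustered split comparison:
#' 40 families of 10 members, 120-residue sequences at 5 percent
#' within-family substitution rate, 8 substrates (2 per enzyme), variance
#' components (1.0, 0.5, 0.2, 0.2), k-mer-composition embedding providers
#' and the default regressor configuration.
#'
#' @return named list of parameters accepted by
#'   \code{\link{leakageExperiment}}.
#' @export
leakageDefaults <- function() {
  list(n_families = 40, members_per_family = 10, seq_len = 120,
       within_rate = 0.05, n_substrates = 8, substrates_per_enzyme = 2,
       sigma_fam = 1.0, sigma_sub = 0.5, sigma_var = 0.2, sigma_eps = 0.2,
       mu = 1.0, protein_dim = 128, molecule_dim = 64, k = 10,
       threshold = 0.4, config = regressorConfig())
}

#' Random-versus-clustered split leakage experiment
#'
#' Generates a synthetic family benchmark, trains the shallow regressor
#' under ten-fold cross-validation with (a) a random partition and (b) a
#' cluster-respecting partition at the identity threshold, on identical
#' records and features, and reports the out-of-fold Pearson correlations
#' and their gap. Family-dominant labels are learnable only when homologs
#' straddle folds, so a positive gap quantifies how much a random split
#' overstates performance.
#'
#' @param params parameter list as from \code{\link{leakageDefaults}};
#'   supplied entries override the defaults.
#' @param seed integer seed for the whole experiment.
#' @return list with \code{pcc_random}, \code{pcc_clustered}, \code{gap},
#'   \code{n_records}, \code{audit_max_identity} (of the clustered split)
#'   and the two \code{crossValidate} results.
#' @export
leakageExperiment <- function(params = list(), seed = 0) {
  p <- leakageDefaults()
  p[names(params)] <- params
  fams <- simulateFamilies(p$n_families, p$members_per_family, p$seq_len,
                           p$within_rate, seed = childSeed(seed, "fam"))
  sim <- simulateKinetics(fams, substratePool(p$n_substrates),
                          sigma_fam = p$sigma_fam, sigma_sub = p$sigma_sub,
                          sigma_var = p$sigma_var, sigma_eps = p$sigma_eps,
                          mu = p$mu,
                          substrates_per_enzyme = p$substrates_per_enzyme,
                          param = "kcat", seed = childSeed(seed, "kin"))
  rec <- sim$records
  prot_prov <- syntheticProvider(p$protein_dim, seed = childSeed(seed, "pp"),
                                 mode = "kmer_composition", k = 3)
  mol_prov <- syntheticProvider(p$molecule_dim, seed = childSeed(seed, "mp"),
                                mode = "kmer_composition", k = 2)
  X <- featurizeDataset(rec, prot_prov, mol_prov)
  y <- setNames(rec$label, rownames(X))
  cl <- greedyCluster(fams$sequences, threshold = p$threshold)
  folds_cl <- partitionFolds(cl, rec, k = p$k, seed = childSeed(seed, "pf"))
  folds_rn <- randomPartition(rec, k = p$k, seed = childSeed(seed, "rp"))
  cfg <- p$config
  cfg$seed <- childSeed(seed, "train")
  cv_cl <- crossValidate(X, y, folds_cl, cfg)
  cv_rn <- crossValidate(X, y, folds_rn, cfg)
  seq_of <- setNames(rec$sequence, rownames(X))
  audit <- auditLeakage(folds_cl, seq_of)
  pcc_rn <- pcc(cv_rn$oof, y)
  pcc_cl <- pcc(cv_cl$oof, y)
  list(pcc_random = pcc_rn, pcc_clustered = pcc_cl, gap = pcc_rn - pcc_cl,
       n_records = nrow(rec), audit_max_identity = audit$max_identity,
       cv_random = cv_rn, cv_clustered = cv_cl)
}
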