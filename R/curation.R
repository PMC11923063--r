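# Curation of raw kinetic measurement tables into modelling-ready datasets.
#
# The cleaning rules: rows with multiple UniProt accessions are dropped, rows
# without SMILES or sequence are dropped, entries with units outside an
# explicit allow-list are removed (values converted to canonical units:
# kcat in s^-1, Km in mM), and duplicate (sequence, SMILES) measurements are
# collapsed by keeping the maximum kcat / minimum Km. The spread of the
# original log10 labels of collapsed duplicates is kept as a per-entry
# label-noise annotation.

#' Read a raw kinetic measurement table
#'
#' Parses a CSV/TSV table of kinetic measurements into a record data.frame
#' and a skip report. Required columns: \code{enzyme_id}, \code{param},
#' \code{value}, \code{unit}; optional: \code{sequence}, \code{smiles},
#' \code{substrate_name}, \code{organism}, \code{ec_number},
#' \code{enzyme_type}. Sequences may instead be supplied through a FASTA
#' file keyed by \code{enzyme_id}.
#'
#' Rows are skipped (and counted in the report) when the enzyme id contains
#' several accessions (separated by \code{;}, \code{,} or whitespace), when
#' no SMILES is available, or when no sequence is available.
#'
#' @param table_path path to a CSV or TSV file (extension decides the
#'   delimiter; \code{.tsv}/\code{.txt} are tab-separated).
#' @param fasta_path optional FASTA file supplying sequences by enzyme id;
#'   table sequences win where both are present.
#' @return list with \code{records} (data.frame of retained rows) and
#'   \code{skip_report} (named integer vector: \code{multiple_uniprot},
#'   \code{missing_smiles}, \code{missing_sequence}).
#' @export
readKineticTable <- function(table_path, fasta_path = NULL) {
  stopIfNotScalarString(table_path, "table_path")
  if (!file.exists(table_path)) stop("cannot read table: ", table_path)
  tab <- if (grepl("\\.(tsv|txt)$", table_path, ignore.case = TRUE))
    read.delim(table_path, stringsAsFactors = FALSE, check.names = FALSE)
  else
    read.csv(table_path, stringsAsFactors = FALSE, check.names = FALSE)

  required <- c("enzyme_id", "param", "value", "unit")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("kinetic table is missing required column(s): ",
         paste(miss, collapse = ", "))
  optional <- c("sequence", "smiles", "substrate_name", "organism",
                "ec_number", "enzyme_type")
  for (col in optional) if (!col %in% names(tab)) tab[[col]] <- NA_character_

  unknown <- setdiff(names(tab), c(required, optional))
  if (length(unknown))
    stop("unknown column(s) in kinetic table: ", paste(unknown, collapse = ", "))

  if (!is.null(fasta_path)) {
    fa <- Biostrings::readAAStringSet(fasta_path)
    ids <- sub("\\s.*$", "", names(fa))
    lookup <- setNames(as.character(fa), ids)
    missing_seq <- is.na(tab$sequence) | !nzchar(trimws(tab$sequence))
    tab$sequence[missing_seq] <- lookup[tab$enzyme_id[missing_seq]]
  }

  tab$param <- tolower(trimws(tab$param))
  bad_param <- !tab$param %in% c("kcat", "km")
  if (any(bad_param))
    stop("param column must be 'kcat' or 'km'; offending value(s): ",
         paste(unique(tab$param[bad_param]), collapse = ", "))

  multi_id <- grepl("[;,[:space:]]", trimws(tab$enzyme_id))
  no_smiles <- is.na(tab$smiles) | !nzchar(trimws(tab$smiles))
  no_seq <- is.na(tab$sequence) | !nzchar(trimws(tab$sequence))

  skip <- c(multiple_uniprot = sum(multi_id),
            missing_smiles = sum(!multi_id & no_smiles),
            missing_sequence = sum(!multi_id & !no_smiles & no_seq))
  keep <- !(multi_id | no_smiles | no_seq)

  rec <- tab[keep, , drop = FALSE]
  rec$enzyme_id <- trimws(rec$enzyme_id)
  rec$sequence <- toupper(trimws(rec$sequence))
  rec$smiles <- trimws(rec$smiles)
  rec$enzyme_type[is.na(rec$enzyme_type)] <- "wild_type"
  rownames(rec) <- NULL
  list(records = rec, skip_report = skip)
}

#' Default unit allow-list and conversion factors
#'
#' Multiplicative factors to the canonical units (kcat: s^-1; Km: mM).
#' Units outside this list are treated as ambiguous and their records
#' removed by \code{\link{filterUnits}}.
#'
#' @return named list with one named numeric vector per parameter.
#' @export
defaultUnitTable <- function() {
  list(
    kcat = c("s^(-1)" = 1, "1/s" = 1, "s-1" = 1, "/s" = 1,
             "min^(-1)" = 1 / 60, "1/min" = 1 / 60, "min-1" = 1 / 60,
             "h^(-1)" = 1 / 3600, "1/h" = 1 / 3600),
    km = c("mM" = 1, "M" = 1000, "uM" = 1e-3, "µM" = 1e-3, "nM" = 1e-6)
  )
}

#' Remove records with ambiguous units and convert values to canonical units
#'
#' @param records record data.frame (as from \code{\link{readKineticTable}}).
#' @param unit_table named list of allowed units and factors per parameter;
#'   defaults to \code{\link{defaultUnitTable}()}.
#' @return the filtered records with \code{value} in canonical units
#'   (kcat s^-1, Km mM) and \code{unit} rewritten accordingly.
#' @export
filterUnits <- function(records, unit_table = defaultUnitTable()) {
  if (!nrow(records)) return(records)
  keep <- logical(nrow(records))
  value <- records$value
  for (i in seq_len(nrow(records))) {
    allowed <- unit_table[[records$param[i]]]
    u <- records$unit[i]
    if (!is.null(allowed) && !is.na(u) && u %in% names(allowed)) {
      keep[i] <- TRUE
      value[i] <- records$value[i] * allowed[[u]]
    }
  }
  out <- records[keep, , drop = FALSE]
  out$value <- value[keep]
  out$unit <- ifelse(out$param == "kcat", "s^(-1)", "mM")
  rownames(out) <- NULL
  out
}

#' Collapse duplicate measurements into one entry per enzyme-substrate pair
#'
#' For each exact (sequence, SMILES) pair, retains the maximum kcat or the
#' minimum Km among its measurements and attaches the log10 label. Nonpositive
#' values are rejected (counted in the report) before collapsing. The
#' operation is idempotent and order-independent.
#'
#' @param records record data.frame, all of one parameter, values in
#'   canonical units.
#' @param param \code{"kcat"} or \code{"km"}.
#' @param noise optional named numeric vector from \code{\link{labelNoise}}
#'   to attach as \code{noise_std}.
#' @return a \code{\linkS4class{KineticDataset}}.
#' @export
deduplicateRecords <- function(records, param, noise = NULL) {
  param <- match.arg(param, c("kcat", "km"))
  if (nrow(records) && !all(records$param == param))
    stop("records contain parameters other than '", param, "'")
  bad <- !is.finite(records$value) | records$value <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with nonpositive value rejected")
    records <- records[!bad, , drop = FALSE]
  }
  if (!nrow(records)) {
    ent <- data.frame(enzyme_id = character(), sequence = character(),
                      smiles = character(), label = numeric(),
                      noise_std = numeric(), enzyme_type = character(),
                      stringsAsFactors = FALSE)
    return(new("KineticDataset", param = param, entries = ent))
  }
  key <- pairKey(records$sequence, records$smiles)
  pick <- tapply(seq_len(nrow(records)), key, function(idx) {
    v <- records$value[idx]
    idx[if (param == "kcat") which.max(v) else which.min(v)]
  })
  ent <- records[as.integer(pick), , drop = FALSE]
  ent$label <- log10(ent$value)
  kk <- pairKey(ent$sequence, ent$smiles)
  ent$noise_std <- if (is.null(noise)) NA_real_ else unname(noise[kk])
  ent <- ent[order(kk), c("enzyme_id", "sequence", "smiles", "label",
                          "noise_std", "enzyme_type")]
  rownames(ent) <- NULL
  new("KineticDataset", param = param, entries = ent)
}

#' Per-pair label noise from replicate measurements
#'
#' For every (sequence, SMILES) pair with more than one raw measurement,
#' computes the population standard deviation of the log10 values, a direct
#' measure of label noise. Single-measurement pairs are absent from the
#' result.
#'
#' @param records record data.frame of one parameter, canonical units,
#'   positive values.
#' @return named numeric vector keyed by the internal pair key.
#' @export
labelNoise <- function(records) {
  records <- records[is.finite(records$value) & records$value > 0, ,
                     drop = FALSE]
  if (!nrow(records)) return(setNames(numeric(0), character(0)))
  key <- pairKey(records$sequence, records$smiles)
  out <- tapply(log10(records$value), key, function(v) {
    if (length(v) < 2) return(NA_real_)
    sqrt(mean((v - mean(v))^2))  # population convention
  })
  res <- setNames(as.numeric(out), names(out))
  res[!is.na(res)]
}

#' Intersect kcat and Km datasets into a catalytic-efficiency dataset
#'
#' Entries are the (sequence, SMILES) pairs present in both datasets; the
#' label is log10(kcat/Km) = log10 kcat - log10 Km. Parent labels are kept
#' so the two-stage model can pre-train its submodels on them.
#'
#' @param kcat_ds,km_ds deduplicated \code{KineticDataset}s.
#' @return a ratio \code{\linkS4class{KineticDataset}} whose entries carry
#'   \code{kcat_label} and \code{km_label} columns.
#' @export
intersectRatio <- function(kcat_ds, km_ds) {
  stopifnot(is(kcat_ds, "KineticDataset"), is(km_ds, "KineticDataset"))
  if (kineticParam(kcat_ds) != "kcat" || kineticParam(km_ds) != "km")
    stop("arguments must be the kcat and km datasets, in that order")
  a <- entries(kcat_ds)
  b <- entries(km_ds)
  ka <- pairKey(a$sequence, a$smiles)
  kb <- pairKey(b$sequence, b$smiles)
  common <- intersect(ka, kb)
  ia <- match(common, ka)
  ib <- match(common, kb)
  ent <- data.frame(
    enzyme_id = a$enzyme_id[ia],
    sequence = a$sequence[ia],
    smiles = a$smiles[ia],
    label = a$label[ia] - b$label[ib],
    kcat_label = a$label[ia],
    km_label = b$label[ib],
    enzyme_type = a$enzyme_type[ia],
    stringsAsFactors = FALSE
  )
  rownames(ent) <- NULL
  new("KineticDataset", param = "ratio", entries = ent)
}

#' Write a curated dataset to TSV
#'
#' @param dataset a \code{KineticDataset}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCuratedDataset <- function(dataset, path) {
  stopifnot(is(dataset, "KineticDataset"))
  write.table(entries(dataset), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
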