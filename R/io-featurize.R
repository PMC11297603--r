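# Chemical table import, structure filtering, endpoint binarization and
# fingerprint computation. Structure handling (SMILES parsing, canonical
# forms, ECFP/MACCS bits) is delegated to Open Babel via ChemmineOB.

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to Open Babel's canonical form. Unparseable strings
#' yield \code{NA}, never an error, so callers can report rejects.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, \code{NA} where parsing
#'   failed.
#' @export
#' @examples
#' \donttest{canonicalSmiles(c("OCC", "CCO"))  # both "CCO"}
canonicalSmiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- suppressWarnings(tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = s),
      error = function(e) ""))
    out <- trimws(strsplit(out, "[ \t\n]")[[1]][1])
    if (is.na(out) || !nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Read a delimited chemical table
#'
#' Reads a CSV/TSV file (delimiter chosen by extension: \code{.tsv}/\code{.txt}
#' are tab-separated, everything else comma-separated) with one chemical per
#' row, or a plain SMILES file (one structure per line, optional
#' whitespace-separated identifier). Rows whose structure column is empty or
#' fails to parse are returned separately with a reason rather than dropped
#' silently.
#'
#' @param path file to read.
#' @param smilesColumn name of the structure column (ignored for plain
#'   SMILES files, selected by \code{format = "smi"} or extension
#'   \code{.smi}).
#' @param idColumn name of the identifier column, or \code{NULL} to number
#'   rows \code{chem1, chem2, ...}.
#' @param format \code{"auto"}, \code{"csv"}, \code{"tsv"} or \code{"smi"}.
#' @return list with \code{records} (data.frame: \code{chem_id},
#'   \code{smiles}, plus any endpoint columns) and \code{rejects}
#'   (data.frame: \code{row}, \code{chem_id}, \code{reason}).
#' @export
readChemicalTable <- function(path, smilesColumn = "smiles",
                              idColumn = NULL, format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (format == "auto")
    format <- switch(ext, smi = "smi", tsv = "tsv", txt = "tsv", "csv")
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    tab <- data.frame(
      smiles = vapply(parts, `[`, character(1), 1L),
      id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                  character(1)),
      stringsAsFactors = FALSE)
    smilesColumn <- "smiles"
    idColumn <- "id"
    if (all(is.na(tab$id))) idColumn <- NULL
  } else {
    sep <- if (format == "tsv") "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             quote = "\"", comment.char = "")
  }
  if (!smilesColumn %in% names(tab))
    stop("structure column '", smilesColumn, "' not found in ", path)
  if (!is.null(idColumn) && !idColumn %in% names(tab))
    stop("id column '", idColumn, "' not found in ", path)

  n <- nrow(tab)
  ids <- if (is.null(idColumn)) paste0("chem", seq_len(n)) else
    as.character(tab[[idColumn]])
  smi <- as.character(tab[[smilesColumn]])
  emptyRejects <- data.frame(row = integer(0), chem_id = character(0),
                             reason = character(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    rec <- data.frame(chem_id = character(0), smiles = character(0),
                      stringsAsFactors = FALSE)
    return(list(records = rec, rejects = emptyRejects))
  }
  noStructure <- is.na(smi) | !nzchar(trimws(smi))
  endpointCols <- setdiff(names(tab), c(smilesColumn, idColumn))
  rec <- data.frame(chem_id = ids, smiles = smi, stringsAsFactors = FALSE)
  for (ec in endpointCols) rec[[ec]] <- tab[[ec]]
  rejects <- emptyRejects
  if (any(noStructure)) {
    rejects <- data.frame(row = which(noStructure),
                          chem_id = ids[noStructure],
                          reason = "no structure", stringsAsFactors = FALSE)
    rec <- rec[!noStructure, , drop = FALSE]
    rownames(rec) <- NULL
  }
  list(records = rec, rejects = rejects)
}

#' Filter mixtures and collapse duplicate structures
#'
#' Rejects multi-fragment structures (mixtures, detected as a \code{.}
#' separator in the canonical SMILES), rejects unparseable structures, and
#' collapses chemicals with identical canonical structures to the first
#' occurrence; later occurrences are rejected as duplicates. No desalting is
#' attempted: a salt form is treated as a mixture and rejected, which is
#' conservative but reported.
#'
#' @param records data.frame with \code{chem_id} and \code{smiles} columns
#'   (as returned by \code{\link{readChemicalTable}}).
#' @return list with \code{kept} (records plus a \code{canonical_smiles}
#'   column, first-occurrence order) and \code{rejects} (\code{row},
#'   \code{chem_id}, \code{reason}).
#' @export
#' @examples
#' \donttest{
#' recs <- data.frame(chem_id = c("a", "b", "c"),
#'                    smiles = c("CCO", "OCC", "[Na+].[Cl-]"))
#' filterAndDeduplicate(recs)  # keeps only "a"
#' }
filterAndDeduplicate <- function(records) {
  n <- nrow(records)
  rejects <- data.frame(row = integer(0), chem_id = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    records$canonical_smiles <- character(0)
    return(list(kept = records, rejects = rejects))
  }
  canon <- canonicalSmiles(records$smiles)
  reason <- rep(NA_character_, n)
  reason[is.na(canon)] <- "unparseable structure"
  isMix <- !is.na(canon) & grepl(".", canon, fixed = TRUE)
  reason[isMix] <- "mixture"
  ok <- is.na(reason)
  dup <- ok & duplicated(ifelse(ok, canon, NA_character_), incomparables = NA)
  reason[dup] <- "duplicate"
  keep <- is.na(reason)
  kept <- records[keep, , drop = FALSE]
  kept$canonical_smiles <- canon[keep]
  rownames(kept) <- NULL
  if (any(!keep))
    rejects <- data.frame(row = which(!keep),
                          chem_id = records$chem_id[!keep],
                          reason = reason[!keep], stringsAsFactors = FALSE)
  list(kept = kept, rejects = rejects)
}

#' Write a rejected-record report
#'
#' @param rejects reject data.frame (\code{row}, \code{chem_id},
#'   \code{reason}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeRejectReport <- function(rejects, path) {
  utils::write.csv(rejects, path, row.names = FALSE)
  invisible(path)
}

#' Define an endpoint binarization rule
#'
#' A rule mapping a raw endpoint value to a binary toxicity label: direction
#' \code{"le"} labels values at or below the threshold toxic (e.g. a
#' benchmark dose BMD10 of at most 1 mM, or a lowest effect level LEL of at
#' most 64 uM), \code{"ge"} at or above, and \code{"gt"} strictly above
#' (e.g. a developmental toxicity score above 2.24). Comparison strictness
#' follows the printed operator exactly.
#'
#' @param endpointName endpoint the rule applies to.
#' @param threshold numeric cut-off.
#' @param direction one of \code{"le"}, \code{"ge"}, \code{"gt"}.
#' @param units free-text units annotation (e.g. \code{"mM"}).
#' @return an \code{endpointRule} list.
#' @export
#' @examples
#' endpointRule("BMD10", 1, "le", "mM")
endpointRule <- function(endpointName, threshold, direction = c("le", "ge", "gt"),
                         units = "") {
  direction <- match.arg(direction)
  structure(list(endpointName = endpointName,
                 threshold = as.numeric(threshold),
                 direction = direction, units = units),
            class = "endpointRule")
}

#' Binarize endpoint values against a threshold rule
#'
#' @param values numeric vector of raw endpoint values; \code{NA} propagates
#'   to an \code{NA} label (the chemical is excluded from that task only).
#' @param rule an \code{\link{endpointRule}}.
#' @return integer vector of labels in \{0, 1, \code{NA}\}.
#' @export
#' @examples
#' binarizeEndpoint(c(0.5, 2, NA), endpointRule("BMD10", 1, "le", "mM"))
binarizeEndpoint <- function(values, rule) {
  if (!inherits(rule, "endpointRule")) stop("rule must be an endpointRule")
  if (!is.numeric(values)) {
    bad <- which(is.na(suppressWarnings(as.numeric(values))) & !is.na(values))
    if (length(bad))
      stop("non-numeric endpoint value at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    values <- as.numeric(values)
  }
  out <- switch(rule$direction,
                le = as.integer(values <= rule$threshold),
                ge = as.integer(values >= rule$threshold),
                gt = as.integer(values > rule$threshold))
  out
}

# Fold a long hashed fingerprint down to nBits by OR-ing equal slices.
foldBits <- function(bits, nBits) {
  if (length(bits) == nBits) return(as.integer(bits))
  if (length(bits) %% nBits != 0L)
    stop("cannot fold ", length(bits), " bits to ", nBits)
  m <- matrix(as.integer(bits), nrow = nBits)
  as.integer(rowSums(m) > 0L)
}

#' Compute binary molecular fingerprints
#'
#' Computes extended-connectivity fingerprints of diameter 6 (ECFP6, i.e.
#' circular radius 3 — toolkits parameterize by radius, so diameter 6 means
#' radius 3) hashed and folded to \code{nBits} (default 1024), or 167-bit
#' MACCS structural keys. Fingerprints are deterministic: the same canonical
#' structure always yields identical bits, and two SMILES writings of one
#' molecule agree.
#'
#' @param smiles character vector of SMILES.
#' @param scheme \code{"ECFP6"} or \code{"MACCS"}.
#' @param nBits fingerprint length for ECFP6 (must divide 4096); ignored for
#'   MACCS (fixed 167 keys).
#' @return integer 0/1 matrix, one row per molecule, with \code{smiles} as
#'   rownames when unique.
#' @export
#' @examples
#' \donttest{featurize("CCO")[, 1:8]}
featurize <- function(smiles, scheme = c("ECFP6", "MACCS"), nBits = 1024L) {
  scheme <- match.arg(scheme)
  smiles <- as.character(smiles)
  width <- if (scheme == "MACCS") 167L else as.integer(nBits)
  out <- matrix(0L, nrow = length(smiles), ncol = width,
                dimnames = list(NULL, paste0("F", seq_len(width))))
  for (i in seq_along(smiles)) {
    s <- smiles[i]
    if (is.na(s) || !nzchar(trimws(s)))
      stop("invalid structure: '", s, "'")
    bits <- suppressWarnings(tryCatch({
      mol <- ChemmineOB::forEachMol("SMILES", s, identity)
      ChemmineOB::fingerprint_OB(mol, scheme)
    }, error = function(e) NULL))
    if (is.null(bits) || sum(bits) == 0L)
      stop("featurization failed for structure: '", s, "'")
    out[i, ] <- if (scheme == "MACCS") as.integer(bits[seq_len(167L)]) else
      foldBits(bits, width)
  }
  if (!anyDuplicated(smiles)) rownames(out) <- smiles
  out
}
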