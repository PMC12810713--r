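## Low-level OpenBabel access. Two routes are used deliberately:
##  * the `obabel` executable for batch canonicalization (it skips unparseable
##    records and keeps going, so one bad SMILES never aborts a batch);
##  * in-process ChemmineOB calls for molecules already known to parse
##    (properties, SMARTS counts, molblocks).

ob_noopt <- function() {
  data.frame(names = character(), args = character(), stringsAsFactors = FALSE)
}

#' @keywords internal
ob_find_obabel <- function() {
  path <- Sys.which("obabel")
  if (!nzchar(path)) {
    stop("The 'obabel' executable was not found on PATH; it is required ",
         "for SMILES parsing.", call. = FALSE)
  }
  path
}

## Canonicalize a character vector of SMILES. Returns a character vector of
## the same length with NA_character_ where parsing failed. Record order is
## restored through per-record titles, so dropped (unparseable) records are
## identified robustly.
ob_canonical <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  ok_input <- !is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles)
  idx <- which(ok_input)
  if (length(idx) == 0L) return(out)

  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles[idx], paste0("t", idx)), infile)
  res <- suppressWarnings(system2(
    ob_find_obabel(),
    c("-ismi", shQuote(infile), "-ocan", "-e"),
    stdout = TRUE, stderr = FALSE
  ))
  if (length(res) == 0L) return(out)
  parts <- strsplit(res, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) < 2L) next
    tag <- trimws(p[[2L]])
    i <- suppressWarnings(as.integer(sub("^t", "", tag)))
    if (!is.na(i)) out[i] <- trimws(p[[1L]])
  }
  out[!nzchar(out) | is.na(out)] <- NA_character_
  out
}

## OBMol references for SMILES that are known to parse. Errors loudly on
## unparseable input (callers must canonicalize first).
ob_mols <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
}

## Physico-chemical properties (logP, TPSA, HBD, HBA, MR, MW, ...) for
## parseable SMILES; one row per molecule.
ob_props <- function(smiles) {
  ChemmineOB::prop_OB(ob_mols(smiles))
}

## Count of unique SMARTS matches per molecule.
ob_smarts_count <- function(mols, pattern) {
  as.numeric(ChemmineOB::smartsSearch_OB(mols, pattern, uniqueMatches = TRUE))
}

## V2000 molblocks (no coordinate generation -- we only need the graph).
## Input must be pre-validated SMILES; output is a character vector of
## molblock texts, one per input.
ob_molblocks <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  sdf <- ChemmineOB::convertFormat(
    "SMILES", "SDF", paste(smiles, collapse = "\n"), options = ob_noopt()
  )
  blocks <- strsplit(sdf, "\\${4}\n?")[[1]]
  blocks <- blocks[trimws(blocks) != ""]
  if (length(blocks) != length(smiles)) {
    stop("Molblock conversion lost records; inputs must be valid SMILES.",
         call. = FALSE)
  }
  blocks
}
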