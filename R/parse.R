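#' Element whitelist for ion curation
#'
#' The default set of elements considered "common" when curating ion
#' datasets: H, B, C, N, O, F, P, Cl, Br, I, Li, Na, Al, Si, K and Fe.
#' Sulfur is not part of the default list even though several well-known IL
#' families (sulfonium cations, sulfonate and sulfonylimide anions) contain
#' it; set `include_sulfur = TRUE` to admit those families.
#'
#' @param include_sulfur Add `"S"` to the whitelist.
#' @return Character vector of element symbols.
#' @export
il_elements <- function(include_sulfur = FALSE) {
  base <- c("H", "B", "C", "N", "O", "F", "P", "Cl", "Br", "I",
            "Li", "Na", "Al", "Si", "K", "Fe")
  if (include_sulfur) base <- c(base, "S")
  base
}

#' Parse and canonicalize SMILES
#'
#' Canonicalizes a vector of SMILES strings. Parse failures never abort the
#' batch: they are returned as rows with `ok = FALSE` and a missing canonical
#' form. Canonicalization is idempotent, and different spellings of the same
#' molecule map to the same canonical string.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A tibble with columns `smiles` (input), `canonical` (canonical
#'   SMILES, `NA` on failure) and `ok` (logical).
#' @examples
#' parse_smiles(c("OCC", "CCO", "not_a_smiles"))
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  can <- ob_canonical(smiles)
  tibble::tibble(smiles = smiles, canonical = can, ok = !is.na(can))
}

#' Canonical SMILES
#'
#' Shorthand for [parse_smiles()] returning just the canonical strings
#' (`NA` where parsing fails).
#'
#' @inheritParams parse_smiles
#' @return Character vector, same length as the input.
#' @export
canonical_smiles <- function(smiles) {
  ob_canonical(smiles)
}

#' Net formal charge
#'
#' Sum of atomic formal charges of each molecule. Charges are taken from the
#' parsed structure; no protonation-state enumeration is attempted.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Integer vector of net charges (elementary charge units).
#' @examples
#' net_formal_charge(c("[NH4+]", "[O-]S(=O)(=O)[O-]", "CCO"))
#' @export
net_formal_charge <- function(smiles) {
  can <- ob_canonical(smiles)
  if (anyNA(can)) {
    stop("Unparseable SMILES: ",
         paste(utils::head(smiles[is.na(can)], 3L), collapse = ", "),
         call. = FALSE)
  }
  vapply(mol_graphs(can), function(g) sum(g$charge), integer(1))
}

#' Element whitelist check
#'
#' `TRUE` for molecules whose atoms (implicit hydrogens included) all belong
#' to the whitelist.
#'
#' @param smiles Character vector of valid SMILES.
#' @param elements Character vector of allowed element symbols; defaults to
#'   [il_elements()].
#' @return Logical vector.
#' @export
contains_only_elements <- function(smiles, elements = il_elements()) {
  can <- ob_canonical(smiles)
  if (anyNA(can)) {
    stop("Unparseable SMILES: ",
         paste(utils::head(smiles[is.na(can)], 3L), collapse = ", "),
         call. = FALSE)
  }
  vapply(mol_graphs(can), function(g) {
    all(g$elem %in% elements) && ("H" %in% elements || all(g$h_implicit == 0L))
  }, logical(1))
}

## Internal: TRUE where any atom carries unpaired electrons / an unfilled
## standard valence (radicals, carbenes).
has_unpaired_electrons <- function(graphs) {
  vapply(graphs, function(g) any(g$open_valence), logical(1))
}
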