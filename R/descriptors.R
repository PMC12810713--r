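## The frozen 1D/2D descriptor set. The set (names and definitions) is
## versioned and recorded in every fitted model artifact so that scoring and
## melting-point prediction stay reproducible: a descriptor-set id names a
## fixed list, never "whatever the toolkit currently returns".

DESCRIPTOR_SET_VERSION <- "ilgen-1"

## SMARTS-defined functional-group and substructure counts.
.fg_patterns <- c(
  carboxylate        = "[CX3](=O)[OX1-]",
  carboxylic_acid    = "[CX3](=O)[OX2H]",
  ester              = "[CX3](=O)[OX2][#6]",
  amide              = "[CX3](=O)[NX3]",
  aldehyde           = "[CX3H1]=O",
  ketone             = "[#6][CX3](=O)[#6]",
  hydroxyl           = "[OX2H]",
  ether              = "[OX2]([#6])[#6]",
  alkoxide           = "[OX1-][CX4]",
  oxo_anion          = "[OX1-]",
  amine_primary      = "[NX3H2][CX4]",
  amine_secondary    = "[NX3H1]([CX4])[CX4]",
  amine_tertiary     = "[NX3]([CX4])([CX4])[CX4]",
  ammonium_quat      = "[NX4+]",
  aromatic_n_pos     = "[n+]",
  aromatic_n         = "[nX2]",
  anionic_n          = "[NX2-]",
  nitrile            = "[NX1]#[CX2]",
  nitro              = "[NX3+](=O)[OX1-]",
  sulfonyl           = "[SX4](=O)(=O)",
  sulfonate          = "[SX4](=O)(=O)[OX1-]",
  thioether          = "[SX2]([#6])[#6]",
  thiol              = "[SX2H]",
  phosphonium        = "[PX4+]",
  phosphoryl         = "[PX4](=O)",
  fluorophosphate    = "[PX6-]",
  borate             = "[BX4-]",
  trifluoromethyl    = "[CX4](F)(F)F",
  c_fluorine         = "[#6]F",
  c_chlorine         = "[#6]Cl",
  c_bromine          = "[#6]Br",
  c_iodine           = "[#6]I",
  halide_ion         = "[F-,Cl-,Br-,I-]",
  carbanion          = "[#6-]",
  alkene             = "[CX3]=[CX3]",
  alkyne             = "[CX2]#[CX2]"
)

.ring_size_patterns <- c(
  ring3_atoms = "[r3]", ring4_atoms = "[r4]", ring5_atoms = "[r5]",
  ring6_atoms = "[r6]", ring7_atoms = "[r7]", ring8_atoms = "[r8]",
  macrocycle_atoms = "[r9,r10,r11,r12]",
  aromatic_atoms = "[a]",
  ring_junction_atoms = "[x3,x4]"
)

.rotatable_smarts <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

.graph_descriptor_names <- c(
  "n_heavy", "n_bonds", "n_rings", "n_components", "n_ring_atoms",
  "n_terminal_atoms", "n_branch_atoms", "mean_degree", "zagreb_index",
  "graph_diameter", "wiener_log", "longest_alkyl_chain", "n_implicit_h",
  "net_charge", "n_pos_atoms", "n_neg_atoms", "abs_charge_sum",
  "frac_carbon", "frac_hetero",
  "n_C", "n_N", "n_O", "n_P", "n_S", "n_B", "n_halogen", "n_metal"
)

.prop_descriptor_names <- c("mw", "logp", "mr", "tpsa", "hbd", "hba",
                            "n_fluorine")

#' The frozen descriptor set
#'
#' Names of the 1D/2D descriptors computed by [compute_descriptors()]:
#' physico-chemical estimates (molecular weight, Crippen-type log P, molar
#' refractivity, TPSA, hydrogen-bond donor/acceptor counts), whole-graph
#' topology (ring, branching, Wiener and Zagreb statistics, charge counts,
#' element counts) and SMARTS-defined functional-group counts. The list is
#' frozen under the id `"ilgen-1"`; fitted models store this id.
#'
#' @return Character vector of descriptor names with attribute `"version"`.
#' @export
il_descriptor_set <- function() {
  out <- c(.prop_descriptor_names, "n_rotatable", .graph_descriptor_names,
           names(.ring_size_patterns), names(.fg_patterns))
  attr(out, "version") <- DESCRIPTOR_SET_VERSION
  out
}

.graph_descriptors_one <- function(g) {
  n <- length(g$elem)
  deg <- g$degree
  halogen <- c("F", "Cl", "Br", "I")
  wiener <- 0
  diam <- 0
  if (n > 1L && !is.null(g$igraph)) {
    d <- igraph::distances(g$igraph)
    d[!is.finite(d)] <- 0
    wiener <- sum(d) / 2
    diam <- max(d)
  }
  hetero <- sum(!(g$elem %in% c("C", "H")))
  c(
    n_heavy = n, n_bonds = nrow(g$bonds), n_rings = g$n_rings,
    n_components = g$n_components, n_ring_atoms = sum(g$ring_atom),
    n_terminal_atoms = sum(deg == 1L), n_branch_atoms = sum(deg >= 3L),
    mean_degree = if (n) mean(deg) else 0, zagreb_index = sum(deg^2),
    graph_diameter = diam, wiener_log = log1p(wiener),
    longest_alkyl_chain = longest_alkyl_chain(g),
    n_implicit_h = sum(g$h_implicit),
    net_charge = sum(g$charge), n_pos_atoms = sum(g$charge > 0L),
    n_neg_atoms = sum(g$charge < 0L), abs_charge_sum = sum(abs(g$charge)),
    frac_carbon = if (n) sum(g$elem == "C") / n else 0,
    frac_hetero = if (n) hetero / n else 0,
    n_C = sum(g$elem == "C"), n_N = sum(g$elem == "N"),
    n_O = sum(g$elem == "O"), n_P = sum(g$elem == "P"),
    n_S = sum(g$elem == "S"), n_B = sum(g$elem == "B"),
    n_halogen = sum(g$elem %in% halogen),
    n_metal = sum(g$elem %in% .metal_elements)
  )
}

#' Compute molecular descriptors
#'
#' Computes the frozen [il_descriptor_set()] for each molecule. Values are
#' deterministic, identical for any SMILES spelling of the same molecule,
#' and finite; a molecule for which any descriptor fails to evaluate is
#' reported in the `"descriptor_failures"` attribute (its offending values
#' are `NA`), never silently dropped.
#'
#' @param smiles Character vector of valid SMILES.
#' @param descriptors Descriptor names to keep (default: the full frozen set).
#' @return A tibble with a `smiles` column followed by one numeric column per
#'   descriptor.
#' @export
compute_descriptors <- function(smiles, descriptors = il_descriptor_set()) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  unknown <- setdiff(descriptors, il_descriptor_set())
  if (length(unknown)) {
    stop("Unknown descriptors: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  can <- ob_canonical(smiles)
  if (anyNA(can)) {
    stop("Unparseable SMILES passed to compute_descriptors(): ",
         paste(utils::head(smiles[is.na(can)], 3L), collapse = ", "),
         call. = FALSE)
  }
  mols <- ob_mols(can)
  props <- ChemmineOB::prop_OB(mols)
  base <- data.frame(
    mw = props$MW, logp = props$logP, mr = props$MR, tpsa = props$TPSA,
    hbd = props$HBD, hba = props$HBA1, n_fluorine = props$nF
  )
  base$n_rotatable <- ob_smarts_count(mols, .rotatable_smarts)

  graphs <- mol_graphs(can)
  gmat <- t(vapply(graphs, .graph_descriptors_one,
                   numeric(length(.graph_descriptor_names))))
  for (nm in names(.ring_size_patterns)) {
    base[[nm]] <- ob_smarts_count(mols, .ring_size_patterns[[nm]])
  }
  for (nm in names(.fg_patterns)) {
    base[[nm]] <- ob_smarts_count(mols, .fg_patterns[[nm]])
  }
  out <- dplyr::bind_cols(
    tibble::tibble(smiles = smiles),
    tibble::as_tibble(base),
    tibble::as_tibble(gmat)
  )
  out <- out[, c("smiles", descriptors)]

  vals <- as.matrix(out[, descriptors])
  bad <- !is.finite(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    failures <- tibble::tibble(
      smiles = out$smiles[idx[, 1L]],
      descriptor = descriptors[idx[, 2L]]
    )
    vals[bad] <- NA_real_
    out[, descriptors] <- tibble::as_tibble(vals)
    attr(out, "descriptor_failures") <- failures
    warning(nrow(failures), " descriptor value(s) failed to evaluate; see ",
            "attr(, 'descriptor_failures').", call. = FALSE)
  }
  attr(out, "descriptor_set_version") <- DESCRIPTOR_SET_VERSION
  out
}
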