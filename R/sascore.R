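## Synthetic-accessibility scoring (1 = easy ... 10 = hard), following the
## classic fragment-contribution-plus-complexity recipe: a molecule scores
## well when it is built from frequently occurring circular fragments and
## poorly when it is large, polycyclic, macrocyclic or made of fragments the
## reference chemistry has never seen. The fragment frequency table is
## computed once per session from a fixed, code-defined reference corpus of
## common organic molecules and ions, so scores are deterministic across runs
## and machines (no external table is consulted). Fragment scores are
## absolute log10 frequencies clipped to [-4, 2.5]; fragments the corpus has
## never produced contribute the floor value -4.

.ilgen_env <- new.env(parent = emptyenv())

.sa_common_molecules <- function() {
  c(
    "C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CCCCCCCC", "CCCCCCCCCC",
    "CO", "CCO", "CCCO", "CCCCO", "CC(C)O", "CC(C)CO", "OCCO", "OCCCO",
    "CN", "CCN", "CCCN", "CCN(CC)CC", "CNC", "CN(C)C", "NCCN", "NCCO",
    "C=C", "CC=C", "CC=CC", "C#C", "CC#C", "C#N", "CC#N", "CCC#N",
    "CCl", "CCCl", "CBr", "CCBr", "CI", "CF", "FCF", "FC(F)F", "CC(F)(F)F",
    "C=O", "CC=O", "CCC=O", "CC(C)=O", "CCC(C)=O",
    "OC=O", "CC(=O)O", "CCC(=O)O", "CCCC(=O)O", "CC(C)C(=O)O",
    "COC", "CCOC", "CCOCC", "C1CCOC1", "C1CCOCC1",
    "COC=O", "CC(=O)OC", "CC(=O)OCC", "CCOC(C)=O",
    "NC=O", "CC(N)=O", "CC(=O)NC", "CNC(C)=O", "CC(=O)N(C)C",
    "CS", "CCS", "CSC", "CCSC", "CS(C)=O", "CS(C)(=O)=O",
    "OS(O)(=O)=O", "CS(O)(=O)=O", "COS(C)(=O)=O",
    "OP(O)(O)=O", "COP(=O)(OC)OC", "OB(O)O",
    "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Cc1ccccc1C", "Cc1ccc(C)cc1",
    "Oc1ccccc1", "COc1ccccc1", "Nc1ccccc1", "CNc1ccccc1",
    "Clc1ccccc1", "Fc1ccccc1", "Brc1ccccc1", "OCc1ccccc1", "NCc1ccccc1",
    "CC(=O)c1ccccc1", "OC(=O)c1ccccc1", "N#Cc1ccccc1", "Cc1ccccn1",
    "c1ccncc1", "c1ccoc1", "c1ccsc1", "c1cc[nH]c1", "c1cnc[nH]1",
    "c1ccc2ccccc2c1", "c1ccc2[nH]ccc2c1",
    "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "CC1CCCCC1", "C1CCNC1",
    "C1CCNCC1", "C1CCOC1", "C1CNCCN1", "C1COCCN1", "C1CCCCCC1",
    "OC1CCCCC1", "NC1CCCCC1", "O=C1CCCCC1", "CC(C)(C)C", "CC(C)CC(C)(C)C",
    "CC(N)C(=O)O", "NC(CO)C(=O)O", "NC(CC(=O)O)C(=O)O", "NCC(=O)O",
    "OCC(O)CO", "OCC(O)C(O)C(O)CO", "OC(=O)CC(O)(CC(=O)O)C(=O)O",
    "CC(O)C(=O)O", "OC(=O)C(=O)O", "OC(=O)CCC(=O)O", "CC(=O)CC(C)=O",
    "CCOC(=O)CC(=O)OCC", "CC(C)(C)OC(=O)N", "CCOCCO", "COCCOC",
    "CN1CCCC1", "CN1CCCCC1", "CN1CCOCC1", "O=C1CCCN1", "O=C1CCCCN1"
  )
}

## Ion templates keep charged environments (quaternary N, carboxylate,
## sulfonate, halide, borate...) in the reference distribution.
.sa_ion_molecules <- function() {
  alk <- vapply(1:8, function(k) strrep("C", k), character(1))
  c(
    paste0(alk, "[n+]1ccn(C)c1"),
    paste0(alk, "[n+]1ccccc1"),
    paste0("C[N+](C)(C)", alk),
    paste0("CC[N+](CC)(CC)", alk),
    paste0("CCC[N+](C)(C)", alk),
    paste0("CC[N+](C)(C)", alk),
    paste0(alk, "[N+]1(C)CCCC1"),
    paste0(alk, "[N+]1(CC)CCCC1"),
    paste0("CCCC[P+](CCCC)(CCCC)", alk),
    paste0("C[P+](C)(C)", alk),
    paste0(alk, "C(=O)[O-]"),
    paste0(alk, "S(=O)(=O)[O-]"),
    paste0(alk, "OS(=O)(=O)[O-]"),
    "[O-]S(=O)(=O)C(F)(F)F",
    "[N-](S(=O)(=O)C(F)(F)F)S(=O)(=O)C(F)(F)F",
    "[B-](F)(F)(F)F", "F[P-](F)(F)(F)(F)F",
    "[Cl-]", "[Br-]", "[I-]", "[F-]", "[N-](C#N)C#N",
    "[O-]C(=O)C(F)(F)F", "CC(=O)[O-]", "[NH4+]", "C[NH3+]", "CC[NH3+]",
    "O=C([O-])[O-]", "[O-][N+](=O)[O-]", "OS(=O)(=O)[O-]", "COS(=O)(=O)[O-]",
    ## reactive but structurally simple species: cheap to make even though
    ## chemically fragile. Accessibility and stability are separate axes --
    ## the unstable-substructure filter, not the SA score, rejects these.
    "C[O-]", "CC[O-]", "CCC[O-]", "CC(C)[O-]",
    "CC(=O)[N+](C)(C)C", "CC(=O)[n+]1ccn(C)c1",
    "[CH2-]C", "[CH2-]CC", "[CH2-]c1ccccc1"
  )
}

## Fragment log-frequency score table, frozen by construction. Scores are
## log10 counts centred on the corpus's 75th percentile and clipped to
## [-4, 2.5]; fragments absent from the table score -4.
sa_fragment_table <- function() {
  if (!is.null(.ilgen_env$sa_table)) return(.ilgen_env$sa_table)
  ## stock ionic species get extra weight: they are ubiquitous reagents even
  ## though each contributes only one structure to the corpus
  ## elementary stock chemicals (and ions, below) get extra weight: one
  ## corpus entry each, but ubiquitous in practice
  stock <- c("C", "CC", "CCC", "CCCC", "CO", "CCO", "CN", "CCN", "C=O",
             "CC=O", "CC(C)C", "C1CCCCC1", "c1ccccc1")
  parts <- list(
    list(smiles = .sa_common_molecules(), w = 2),
    list(smiles = stock, w = 5),
    list(smiles = .sa_ion_molecules(), w = 5)
  )
  counts <- new.env(parent = emptyenv())
  for (p in parts) {
    corpus <- unique(ob_canonical(p$smiles))
    corpus <- corpus[!is.na(corpus)]
    for (g in mol_graphs(corpus)) {
      tab <- morgan_fragment_counts(g, radius = 2L)
      for (id in names(tab)) {
        counts[[id]] <- (counts[[id]] %||% 0) + p$w * as.numeric(tab[[id]])
      }
    }
  }
  ids <- ls(counts)
  n <- vapply(ids, function(i) counts[[i]], numeric(1))
  ## 0.5 offset for "known" fragments plus a 1.3 gain compensate for the
  ## compact corpus (absolute counts are small); unseen fragments get -4.
  score <- pmin(pmax(0.5 + 1.3 * log10(n), -4), 2.5)
  names(score) <- ids
  .ilgen_env$sa_table <- score
  score
}

#' Synthetic-accessibility score
#'
#' Fragment-contribution synthetic-accessibility score on the conventional
#' 1 (easy) to 10 (hard) scale. The score combines the mean log-frequency of
#' the molecule's circular fragments in a fixed reference corpus with
#' complexity penalties for size, ring-junction (spiro/fused) atoms and
#' macrocycles, plus a symmetry bonus for repetitive structures. Stereo
#' centres are not penalised (stereochemistry is outside this package's
#' scope). Deterministic: identical molecules always receive identical
#' scores.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Numeric vector of scores in `[1, 10]`.
#' @examples
#' sa_score("CCO")              # simple molecule, low score
#' @export
sa_score <- function(smiles) {
  can <- ob_canonical(smiles)
  if (anyNA(can)) {
    stop("Unparseable SMILES passed to sa_score(): ",
         paste(utils::head(smiles[is.na(can)], 3L), collapse = ", "),
         call. = FALSE)
  }
  table <- sa_fragment_table()
  graphs <- mol_graphs(can)
  mols <- ob_mols(can)
  n_junction <- ob_smarts_count(mols, "[x3,x4]")
  n_macro <- ob_smarts_count(mols, "[r9,r10,r11,r12]")
  out <- numeric(length(graphs))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    frag <- morgan_fragment_counts(g, radius = 2L)
    ids <- names(frag)
    cnt <- as.numeric(frag)
    sc <- table[ids]
    sc[is.na(sc)] <- -4
    score1 <- sum(sc * cnt) / sum(cnt)

    n_atoms <- length(g$elem)
    size_penalty <- n_atoms^1.005 - n_atoms
    junction_penalty <- log10(n_junction[i] + 1)
    macro_penalty <- if (n_macro[i] > 0) log10(2) else 0
    score2 <- -(size_penalty + junction_penalty + macro_penalty)

    n_unique_frag <- length(ids)
    score3 <- 0
    if (n_atoms > n_unique_frag) {
      score3 <- 0.5 * log(n_atoms / n_unique_frag)
    }

    raw <- score1 + score2 + score3
    smin <- -4; smax <- 2.5
    sa <- 11 - (raw - smin) / (smax - smin) * 9
    if (sa > 8) sa <- 8 + log(sa - 7)
    out[i] <- min(max(sa, 1), 10)
  }
  out
}
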