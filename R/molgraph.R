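## Internal molecular-graph representation, built from OpenBabel V2000
## molblocks. ChemmineR's SDF reader discards the formal-charge and explicit-
## valence fields that the charge/radical checks need, so the few fixed-width
## fields of the molblock are read here directly.

.default_valence <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L, Si = 4L, Se = c(2L, 4L, 6L),
  As = c(3L, 5L)
)
## Metals are treated as ionic centres: no implicit hydrogens, never radicals.
.metal_elements <- c("Li", "Na", "K", "Rb", "Cs", "Mg", "Ca", "Al", "Fe",
                     "Zn", "Cu", "Ni", "Mn", "Co", "Ag", "Sn", "Pb")

## Allowed valences for an element at a given formal charge. For the common
## organic elements a positive charge raises the N/O/P/S valence by one and a
## negative charge lowers it; carbon loses one either way (carbanion 3,
## carbocation 3); boron gains with negative charge (borate 4).
.allowed_valence <- function(elem, charge) {
  base <- .default_valence[[elem]]
  if (is.null(base)) return(NULL)
  if (charge == 0L) return(base)
  shift <- switch(elem,
    C = -abs(charge),
    B = -charge,          # B(-1) -> 4 (tetrafluoroborate)
    N = , P = , O = , S = , Se = , As = charge,
    F = , Cl = , Br = , I = -abs(charge),
    H = -abs(charge),
    -abs(charge)
  )
  pmax(base + shift, 0L)
}

## Parse one V2000 molblock into atoms/bonds. Charges come from `M  CHG`
## lines when present (they override the legacy charge column).
parse_molblock <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  ## anchor on the counts line itself; header length varies with empty titles
  counts_at <- grep("V2000", lines, fixed = TRUE)[1L]
  if (is.na(counts_at)) stop("Not a V2000 molblock.", call. = FALSE)
  lines <- lines[counts_at:length(lines)]
  counts <- lines[1L]
  n_atoms <- as.integer(substr(counts, 1L, 3L))
  n_bonds <- as.integer(substr(counts, 4L, 6L))
  atom_lines <- lines[seq_len(n_atoms) + 1L]
  elem <- trimws(substr(atom_lines, 32L, 34L))
  legacy_chg <- as.integer(substr(atom_lines, 37L, 39L))
  valence_col <- as.integer(substr(atom_lines, 49L, 51L))
  charge <- integer(n_atoms)
  ## legacy codes: 1..3 => +3..+1, 4 => radical doublet, 5..7 => -1..-3
  pos <- legacy_chg %in% 1:3
  neg <- legacy_chg %in% 5:7
  charge[pos] <- 4L - legacy_chg[pos]
  charge[neg] <- 4L - legacy_chg[neg]
  radical_flag <- legacy_chg == 4L

  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge <- integer(n_atoms)  # spec: M CHG supersedes the atom column
    for (ln in chg_lines) {
      vals <- as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))),
                                  "[[:space:]]+")[[1]])
      k <- vals[1L]
      for (j in seq_len(k)) {
        charge[vals[2L * j]] <- vals[2L * j + 1L]
      }
    }
  }
  rad_lines <- grep("^M  RAD", lines, value = TRUE)
  for (ln in rad_lines) {
    vals <- as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))),
                                "[[:space:]]+")[[1]])
    for (j in seq_len(vals[1L])) {
      if (vals[2L * j + 1L] >= 2L) radical_flag[vals[2L * j]] <- TRUE
    }
  }

  if (n_bonds > 0L) {
    bond_lines <- lines[seq_len(n_bonds) + 1L + n_atoms]
    bonds <- data.frame(
      a1 = as.integer(substr(bond_lines, 1L, 3L)),
      a2 = as.integer(substr(bond_lines, 4L, 6L)),
      order = as.integer(substr(bond_lines, 7L, 9L))
    )
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  list(elem = elem, charge = charge, valence_col = valence_col,
       radical_flag = radical_flag, bonds = bonds)
}

## Full graph with derived per-atom quantities: bond-order sums, implicit
## hydrogens, ring membership (edges not on any cycle are bridges), and an
## open-valence flag for radical/under-valent atoms.
mol_graph <- function(block) {
  g <- parse_molblock(block)
  n <- length(g$elem)
  bsum <- numeric(n)
  deg <- integer(n)
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds$a1[i]; a2 <- g$bonds$a2[i]; o <- g$bonds$order[i]
      ## molfile order 4 = aromatic; count as 1.5
      ov <- if (o == 4L) 1.5 else as.numeric(o)
      bsum[a1] <- bsum[a1] + ov; bsum[a2] <- bsum[a2] + ov
      deg[a1] <- deg[a1] + 1L; deg[a2] <- deg[a2] + 1L
    }
  }
  h_imp <- integer(n)
  open_valence <- logical(n)
  for (i in seq_len(n)) {
    el <- g$elem[i]
    if (el %in% .metal_elements) next
    allowed <- .allowed_valence(el, g$charge[i])
    if (is.null(allowed)) next
    b <- ceiling(bsum[i])
    if (g$valence_col[i] > 0L) {
      ## explicit valence written by the toolkit (e.g. [CH3]): implicit H is
      ## fixed, and an unfilled standard valence means unpaired electrons.
      v <- if (g$valence_col[i] == 15L) 0L else g$valence_col[i]
      h_imp[i] <- max(0L, v - b)
      open_valence[i] <- !any(allowed >= v) || all(allowed != v)
    } else {
      fit <- allowed[allowed >= b]
      if (length(fit)) {
        h_imp[i] <- as.integer(min(fit) - b)
      } else {
        h_imp[i] <- 0L
      }
    }
  }
  open_valence <- open_valence | g$radical_flag

  ring_atom <- logical(n)
  ring_edge <- logical(nrow(g$bonds))
  n_comp <- if (n > 0L) 1L else 0L
  if (nrow(g$bonds) && n > 1L) {
    ig <- igraph::graph_from_edgelist(
      cbind(g$bonds$a1, g$bonds$a2), directed = FALSE)
    if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    br <- igraph::bridges(ig)
    ring_edge <- !(seq_len(nrow(g$bonds)) %in% as.integer(br))
    ring_atom[unique(c(g$bonds$a1[ring_edge], g$bonds$a2[ring_edge]))] <- TRUE
    n_comp <- as.integer(igraph::components(ig)$no)
    g$igraph <- ig
  } else if (n > 0L) {
    n_comp <- n
    g$igraph <- igraph::make_empty_graph(n, directed = FALSE)
  }
  g$bond_order_sum <- bsum
  g$degree <- deg
  g$h_implicit <- h_imp
  g$open_valence <- open_valence
  g$ring_atom <- ring_atom
  g$ring_edge <- ring_edge
  g$n_components <- as.integer(n_comp)
  g$n_rings <- as.integer(nrow(g$bonds) - n + n_comp)  # circuit rank (SSSR size)
  g
}

mol_graphs <- function(smiles) {
  lapply(ob_molblocks(smiles), mol_graph)
}

## Longest path (in atoms) through acyclic sp3 carbons: the "alkyl chain
## length" used by the fixture melting-point model and as a descriptor.
longest_alkyl_chain <- function(graph) {
  keep <- which(graph$elem == "C" & !graph$ring_atom & graph$charge == 0L &
                  graph$bond_order_sum == graph$degree)
  if (length(keep) == 0L) return(0L)
  if (length(keep) == 1L) return(1L)
  sub <- igraph::induced_subgraph(graph$igraph, keep)
  d <- igraph::distances(sub)
  d[!is.finite(d)] <- -1
  as.integer(max(d) + 1L)
}
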