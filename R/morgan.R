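## Extended-connectivity (Morgan) fragment identifiers. Each heavy atom is
## assigned an initial invariant (element, charge, degree, implicit H, ring
## membership); identifiers are then iteratively rehashed over sorted
## neighbour (bond order, identifier) pairs. The same identifiers feed both
## the folded ECFP bit vectors and the synthetic-accessibility fragment model,
## so the two are consistent by construction.

.elem_index <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Al = 13,
  Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26, Cu = 29,
  Zn = 30, As = 33, Se = 34, Br = 35, I = 53, Li = 3
)

## Deterministic integer-vector hash on [0, 2^31 - 2]; exact in doubles.
.hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 1000003 + (x %% 2147483647)) %% 2147483647
  h
}

## Per-atom fragment identifiers for radii 0..radius.
## Returns an integer matrix [n_atoms x (radius + 1)].
morgan_identifiers <- function(graph, radius = 2L) {
  n <- length(graph$elem)
  ids <- matrix(0, nrow = n, ncol = radius + 1L)
  elem_no <- .elem_index[graph$elem]
  elem_no[is.na(elem_no)] <- 90 + nchar(graph$elem[is.na(elem_no)])
  ## invariant: element, charge, heavy degree, ring membership. Hydrogen
  ## count is deliberately excluded so open-valence species (radicals,
  ## carbenes) share their parent atom's environments -- their rejection is
  ## the valence check's job, not the fragment model's.
  for (i in seq_len(n)) {
    ids[i, 1L] <- .hash_ints(c(
      elem_no[i], graph$charge[i] + 10, graph$degree[i],
      as.integer(graph$ring_atom[i])
    ))
  }
  if (radius == 0L || n == 0L) return(ids)
  nb <- vector("list", n)
  if (nrow(graph$bonds)) {
    for (k in seq_len(nrow(graph$bonds))) {
      a1 <- graph$bonds$a1[k]; a2 <- graph$bonds$a2[k]
      o <- graph$bonds$order[k]
      nb[[a1]] <- rbind(nb[[a1]], c(a2, o))
      nb[[a2]] <- rbind(nb[[a2]], c(a1, o))
    }
  }
  for (r in seq_len(radius)) {
    for (i in seq_len(n)) {
      if (is.null(nb[[i]])) {
        ids[i, r + 1L] <- .hash_ints(c(r, ids[i, r]))
        next
      }
      pairs <- cbind(nb[[i]][, 2L], ids[nb[[i]][, 1L], r])
      ord <- order(pairs[, 1L], pairs[, 2L])
      ids[i, r + 1L] <- .hash_ints(c(r, ids[i, r], t(pairs[ord, , drop = FALSE])))
    }
  }
  ids
}

## Fragment identifier counts (radii 0..radius) for one graph, used by the
## synthetic-accessibility fragment model.
morgan_fragment_counts <- function(graph, radius = 2L) {
  ids <- as.vector(morgan_identifiers(graph, radius))
  table(ids)
}

#' Extended-connectivity fingerprints
#'
#' Computes folded binary extended-connectivity (Morgan-style) fingerprints
#' for a vector of SMILES. Identical structures, whatever their SMILES
#' spelling, yield identical fingerprints because hashing runs on the
#' canonical molecular graph.
#'
#' @param smiles Character vector of valid SMILES strings.
#' @param radius Neighbourhood radius in bonds (default 2, the ECFP4
#'   convention of naming by diameter).
#' @param nbits Fingerprint length; a power of two (default 2048).
#' @return A binary integer matrix with one row per molecule and `nbits`
#'   columns; row names are the input SMILES.
#' @examples
#' fp <- compute_ecfp(c("CCO", "OCC", "c1ccccc1"))
#' tanimoto(fp[1, ], fp[2, ])  # 1: same molecule
#' @export
compute_ecfp <- function(smiles, radius = 2L, nbits = 2048L) {
  stopifnot(radius >= 1L, nbits >= 2L, bitwAnd(nbits, nbits - 1L) == 0L)
  can <- ob_canonical(smiles)
  if (anyNA(can)) {
    stop("Unparseable SMILES passed to compute_ecfp(): ",
         paste(utils::head(smiles[is.na(can)], 3L), collapse = ", "),
         call. = FALSE)
  }
  graphs <- mol_graphs(can)
  out <- matrix(0L, nrow = length(smiles), ncol = nbits,
                dimnames = list(smiles, NULL))
  for (i in seq_along(graphs)) {
    if (length(graphs[[i]]$elem) == 0L) {
      stop("Empty molecule at position ", i, call. = FALSE)
    }
    ids <- unique(as.vector(morgan_identifiers(graphs[[i]], radius)))
    out[i, (ids %% nbits) + 1L] <- 1L
  }
  out
}

#' Tanimoto similarity between two binary fingerprints
#'
#' @param a,b Binary vectors of equal length (rows of [compute_ecfp()]).
#' @return Jaccard/Tanimoto similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  num <- sum(a & b)
  den <- sum(a | b)
  if (den == 0) return(0)
  num / den
}
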