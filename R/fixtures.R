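## Synthetic corpora. Two populations are emulated:
##  * "IL-like" ions -- the classic ionic-liquid families (imidazolium,
##    pyridinium, pyrrolidinium, tetraalkylammonium/-phosphonium cations;
##    carboxylate, sulfonate, sulfate-ester, sulfonylimide, halide,
##    fluoroborate/-phosphate anions) decorated with C1-C8 alkyl and short
##    functional substituents;
##  * "decoy" ions -- charged but structurally un-IL-like species: polyol and
##    amino-acid ammoniums, protonated fused heteroaromatics, caged amines,
##    polyhydroxy/peptide-like carboxylates and phenolates, with many
##    hydrogen-bond donors.
## Enumeration is exhaustive and sorted, so a given seed always selects the
## same corpus.

## Evaluate expr under a local RNG seed without disturbing the caller's
## random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

## Substituents in two attachment spellings: `pre` attaches through its last
## atom (use before a core), `suf` through its first (use inside parens).
.il_substituents <- function() {
  linear <- vapply(1:8, function(k) strrep("C", k), character(1))
  tibble::tibble(
    pre = c(linear, "CC(C)", "CC(C)C", "OCC", "OCCC", "COCC", "FC(F)(F)C",
            "c1ccccc1C"),
    suf = c(linear, "C(C)C", "CC(C)C", "CCO", "CCCO", "CCOC", "CC(F)(F)F",
            "Cc1ccccc1")
  )
}

.il_cation_pool <- function() {
  s <- .il_substituents()
  lin <- s$suf[1:8]   # linear alkyls for the second slot
  out <- c(
    as.vector(outer(s$pre, lin,
                    function(a, b) paste0(a, "[n+]1ccn(", b, ")c1"))),
    paste0(s$pre, "[n+]1ccccc1"),
    paste0(s$pre, "[n+]1ccc(C)cc1"),
    as.vector(outer(s$pre, lin,
                    function(a, b) paste0(a, "[N+]1(", b, ")CCCC1"))),
    as.vector(outer(s$pre, lin,
                    function(a, b) paste0(a, "[N+](C)(C)", b))),
    as.vector(outer(s$pre, lin,
                    function(a, b) paste0(a, "[N+](CC)(CC)", b))),
    paste0(s$pre, "[P+](CCCC)(CCCC)CCCC"),
    paste0(s$pre, "[P+](C)(C)C")
  )
  k <- nrow(s) * 8L
  tibble::tibble(
    smiles = out,
    family = rep(c("imidazolium", "pyridinium", "picolinium", "pyrrolidinium",
                   "ammonium", "ammonium", "phosphonium", "phosphonium"),
                 c(k, nrow(s), nrow(s), k, k, k, nrow(s), nrow(s)))
  )
}

.il_anion_pool <- function() {
  s <- .il_substituents()
  im <- s$suf[c(1:8, 14)]   # linear alkyls plus trifluoromethyl
  imide_grid <- expand.grid(a = im, b = im, stringsAsFactors = FALSE)
  phos_grid <- expand.grid(a = s$pre[1:8], b = s$suf[1:8],
                           stringsAsFactors = FALSE)
  dialkylphosphate <- expand.grid(a = s$suf[1:6], b = s$suf[1:6],
                                  stringsAsFactors = FALSE)
  alpha_grid <- expand.grid(a = s$pre, b = s$suf[1:8],
                            stringsAsFactors = FALSE)
  ester_grid <- expand.grid(k = 1:6, r = s$suf[1:6],
                            stringsAsFactors = FALSE)
  out <- c(
    paste0(s$pre, "C(=O)[O-]"),
    paste0(alpha_grid$a, "C(", alpha_grid$b, ")C(=O)[O-]"),
    paste0(s$pre, "C(O)C(=O)[O-]"),
    paste0(s$pre, "C(F)(F)C(=O)[O-]"),
    paste0("[O-]C(=O)c1ccc(", s$suf, ")cc1"),
    paste0(s$pre, "S(=O)(=O)[O-]"),
    paste0(s$pre, "C(C)S(=O)(=O)[O-]"),
    paste0("[O-]S(=O)(=O)c1ccc(", s$suf, ")cc1"),
    paste0(s$pre, "OS(=O)(=O)[O-]"),
    paste0("[N-](S(=O)(=O)", imide_grid$a, ")S(=O)(=O)", imide_grid$b),
    paste0(phos_grid$a, "P(=O)([O-])O", phos_grid$b),
    paste0(phos_grid$a, "P(C)(=O)[O-]"),
    paste0("O=P([O-])(O", dialkylphosphate$a, ")O", dialkylphosphate$b),
    paste0(ester_grid$r, "OC(=O)", strrep("C", ester_grid$k), "C(=O)[O-]"),
    paste0("[O-]S(=O)(=O)C(F)(F)", s$suf[1:8]),
    "[O-]S(=O)(=O)C(F)(F)F", "[O-]C(=O)C(F)(F)F",
    "[B-](F)(F)(F)F", "F[P-](F)(F)(F)(F)F", "[B-](C#N)(C#N)(C#N)C#N",
    "[Cl-]", "[Br-]", "[I-]", "[N-](C#N)C#N", "[O-][N+](=O)[O-]"
  )
  ns <- nrow(s)
  fam <- rep(c("carboxylate", "carboxylate", "carboxylate", "carboxylate",
               "carboxylate",
               "sulfonate", "sulfonate", "sulfonate", "sulfate",
               "sulfonylimide", "phosphonate", "phosphonate", "phosphate",
               "carboxylate", "sulfonate",
               "triflate", "tfa", "bf4", "pf6", "bf4",
               "halide", "halide", "halide", "dicyanamide", "nitrate"),
             c(ns, nrow(alpha_grid), ns, ns, ns, ns, ns, ns, ns,
               nrow(imide_grid), nrow(phos_grid), nrow(phos_grid),
               nrow(dialkylphosphate),
               nrow(ester_grid), 8L,
               1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  tibble::tibble(smiles = out, family = fam)
}

.delocalized_families <- c("sulfonate", "sulfate", "sulfonylimide",
                           "triflate", "bf4", "pf6", "dicyanamide")

.decoy_cation_pool <- function() {
  r <- c("C", "CC", "CCC", "CCO", "CC(C)C", "CC(O)C", "CCCO")
  triples <- expand.grid(a = r, b = r, c = r, stringsAsFactors = FALSE)
  sides <- c("CC(C)C", "CO", "CCO", "Cc1ccccc1", "CCC(N)=O", "CCC(O)=O",
             "CC(O)C", "Cc1cc(O)ccc1O", "CCCNC(N)=[NH2+]", "CCCC[NH3+]",
             "Cc1c[nH]cn1", "CCOC")
  polyol <- function(k, tail) paste0("OC", strrep("C(O)", k), tail)
  out <- c(
    ## polyol quaternary/protonated ammoniums
    as.vector(outer(0:5, seq_len(nrow(triples)), function(k, i) {
      paste0("OC", strrep("C(O)", k), "C[N+](", triples$a[i], ")(",
             triples$b[i], ")", triples$c[i])
    })),
    vapply(0:5, function(k) polyol(k, "C[NH3+]"), character(1)),
    vapply(0:5, function(k) polyol(k, "C[NH2+]C"), character(1)),
    vapply(0:5, function(k) polyol(k, "C[NH+](C)C"), character(1)),
    ## amino-acid-like, with N-methylation states
    paste0("[NH3+]C(", sides, ")C(=O)O"),
    paste0("C[NH2+]C(", sides, ")C(=O)O"),
    paste0("C[N+](C)(C)C(", sides, ")C(=O)O"),
    paste0("[NH3+]C(", sides, ")C(=O)NC"),
    ## protonated fused heteroaromatics
    "[nH+]1ccc2ccccc2c1", "c1ccc2c(c1)cc[nH+]c2C",
    "Oc1ccc2cc[nH+]cc2c1",
    "[NH3+]c1ccc2ccccc2c1", "[NH3+]c1cccc2ccccc12",
    "C[n+]1ccc2ccccc2c1", "CC[n+]1ccc2ccccc2c1",
    "[NH3+]Cc1ccc2ccccc2c1", "Oc1ccc(C[NH3+])c2ccccc12",
    ## caged / bicyclic amines
    "[NH3+]C1CC2CCC1CC2", "C[NH2+]C1CC2CCC1CC2", "[NH3+]C1CC2CC1CC2",
    "C[N+]1(C)C2CCC1CC2", "[NH3+]C12CC3CC(CC(C3)C1)C2",
    "C[NH2+]C12CC3CC(CC(C3)C1)C2",
    ## bis-ammonium chains with hydroxyls
    vapply(2:8, function(k) {
      paste0("C[N+](C)(C)", strrep("C", k), "[N+](C)(C)C")
    }, character(1)),
    vapply(1:6, function(k) {
      paste0("[NH3+]C", strrep("C(O)", k), "C[NH3+]")
    }, character(1))
  )
  tibble::tibble(smiles = out, family = "decoy")
}

.decoy_anion_pool <- function() {
  units <- c("C", "C(O)", "C(C)(O)")
  seqs <- unlist(lapply(2:5, function(len) {
    grid <- do.call(expand.grid, c(rep(list(units), len),
                                   stringsAsFactors = FALSE))
    apply(grid, 1L, paste0, collapse = "")
  }))
  sides <- c("CC(C)C", "CO", "CCO", "Cc1ccccc1", "CCC(N)=O", "CCC(O)=O",
             "CC(O)C", "Cc1cc(O)ccc1O", "CCOC", "C(O)CO")
  out <- c(
    paste0("OC", seqs, "C(=O)[O-]"),
    vapply(1:8, function(k) {
      paste0("OC(=O)", strrep("C", k), "C(=O)[O-]")
    }, character(1)),
    vapply(1:5, function(k) {
      paste0("OC(=O)", strrep("C(O)", k), "C(=O)[O-]")
    }, character(1)),
    paste0("NC(", sides, ")C(=O)[O-]"),
    paste0("CC(=O)NC(", sides, ")C(=O)[O-]"),
    paste0("NC(", sides, ")C(=O)NCC(=O)[O-]"),
    "[O-]c1ccccc1O", "[O-]c1ccc(O)cc1", "[O-]c1cc(O)cc(O)c1",
    "[O-]c1ccc(CO)cc1", "[O-]c1ccc(C=O)cc1", "[O-]c1ccc2ccccc2c1",
    "OC(=O)c1ccccc1C(=O)[O-]", "Oc1ccccc1C(=O)[O-]",
    "OC(=O)CC(O)(CC(=O)O)C(=O)[O-]", "OCC(O)C(O)C(O)C(O)C(=O)[O-]"
  )
  tibble::tibble(smiles = out, family = "decoy")
}

.finish_pool <- function(pool, kind, source) {
  can <- ob_canonical(pool$smiles)
  pool$smiles <- can
  pool <- pool[!is.na(can), , drop = FALSE]
  pool <- pool[!duplicated(pool$smiles), , drop = FALSE]
  q <- net_formal_charge(pool$smiles)
  want <- if (kind == "cation") q > 0L else q < 0L
  pool <- pool[want, , drop = FALSE]
  pool$net_charge <- q[want]
  pool$kind <- kind
  pool$source <- source
  pool <- pool[order(pool$smiles), , drop = FALSE]
  tibble::as_tibble(pool[, c("smiles", "kind", "net_charge", "family",
                             "source")])
}

.il_pool <- function(kind) {
  key <- paste0("il_pool_", kind)
  if (is.null(.ilgen_env[[key]])) {
    raw <- if (kind == "cation") .il_cation_pool() else .il_anion_pool()
    .ilgen_env[[key]] <- .finish_pool(raw, kind, "il")
  }
  .ilgen_env[[key]]
}

.decoy_pool <- function(kind) {
  key <- paste0("decoy_pool_", kind)
  if (is.null(.ilgen_env[[key]])) {
    raw <- if (kind == "cation") .decoy_cation_pool() else .decoy_anion_pool()
    pool <- .finish_pool(raw, kind, "general")
    ## guaranteed disjoint from the IL-like pool
    pool <- pool[!pool$smiles %in% .il_pool(kind)$smiles, , drop = FALSE]
    .ilgen_env[[key]] <- pool
  }
  .ilgen_env[[key]]
}

.sample_pool <- function(pool, n, seed, label) {
  if (n > nrow(pool)) {
    stop("Requested ", n, " ", label, " but only ", nrow(pool),
         " unique structures are enumerable.", call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(nrow(pool), n))
  pool[idx, , drop = FALSE]
}

#' Synthetic IL-like ion corpus
#'
#' Deterministically enumerates classic ionic-liquid ion families and draws
#' a seeded sample of `n` unique, valid, correctly charged ions. Cations:
#' imidazolium, pyridinium, pyrrolidinium, tetraalkylammonium and
#' tetraalkylphosphonium cores with C1-C8 alkyl and short functional
#' substituents. Anions: carboxylates, sulfonates, sulfate esters,
#' sulfonylimides, phosphonates, halides, tetrafluoroborate-like and other
#' stock anions.
#'
#' @param n Number of ions to draw (at least 1).
#' @param seed Integer seed; the same seed always yields the same corpus.
#' @param kind `"cation"` or `"anion"`.
#' @return Tibble with columns `smiles` (canonical), `kind`, `net_charge`,
#'   `family`, `source = "il"`.
#' @export
make_il_like_corpus <- function(n, seed, kind = c("cation", "anion")) {
  kind <- match.arg(kind)
  stopifnot(n >= 1L)
  .sample_pool(.il_pool(kind), n, seed, paste0("IL-like ", kind, "s"))
}

#' Synthetic decoy ion corpus
#'
#' Seeded sample of charged species structurally unlike the ionic-liquid
#' families: polyol and amino-acid ammoniums, protonated fused aromatics,
#' caged amines, multi-charged chains (cations); polyhydroxy, dicarboxylate,
#' peptide-like carboxylates and phenolates (anions). Decoys carry many more
#' hydrogen-bond donors than the IL-like corpus and are disjoint from it by
#' canonical SMILES.
#'
#' @inheritParams make_il_like_corpus
#' @return Tibble with the same columns as [make_il_like_corpus()], with
#'   `source = "general"`.
#' @export
make_decoy_corpus <- function(n, seed, kind = c("cation", "anion")) {
  kind <- match.arg(kind)
  stopifnot(n >= 1L)
  .sample_pool(.decoy_pool(kind), n, seed, paste0("decoy ", kind, "s"))
}

#' Synthetic melting-point dataset
#'
#' Draws cation-anion pairs from the IL-like and decoy corpora and assigns
#' melting points from a fully disclosed generative model:
#' `mpt = 450 - 12 * min(longest alkyl chain of cation, 8)
#'        - 20 * [anion charge-delocalized] + 15 * HBD(pair) + e`,
#' `e ~ Normal(0, noise_sigma)`, clipped to `[150, 600]` K. Long cation
#' chains and charge-delocalized anions (sulfonate, sulfonylimide,
#' fluoroborate/-phosphate families) depress the melting point;
#' hydrogen-bond donors raise it — so IL-like pairs concentrate at low
#' melting points, as in experimental melting-point compilations.
#'
#' @param n Number of pair records (at least 50).
#' @param seed Integer seed.
#' @param noise_sigma Gaussian noise standard deviation in kelvin
#'   (default 10).
#' @return Tibble with `cation_smiles`, `anion_smiles`, `mpt_K`, `source`,
#'   plus the ground-truth covariates `chain_len`, `deloc`, `hbd_pair` and
#'   the noiseless `mpt_true`. The generative coefficients are attached as
#'   `attr(, "params")` for recovery tests.
#' @export
make_synthetic_mpt_dataset <- function(n, seed, noise_sigma = 10) {
  stopifnot(n >= 50L, noise_sigma >= 0)
  params <- list(intercept = 450, chain_coef = -12, chain_cap = 8,
                 deloc_coef = -20, hbd_coef = 15,
                 clip = c(150, 600), noise_sigma = noise_sigma, seed = seed)
  cat_pool <- dplyr::bind_rows(.il_pool("cation"), .decoy_pool("cation"))
  an_pool <- dplyr::bind_rows(.il_pool("anion"), .decoy_pool("anion"))
  draw <- with_seed(seed, {
    list(ci = sample.int(nrow(cat_pool), n, replace = TRUE),
         ai = sample.int(nrow(an_pool), n, replace = TRUE),
         eps = stats::rnorm(n, 0, noise_sigma))
  })
  cations <- cat_pool[draw$ci, , drop = FALSE]
  anions <- an_pool[draw$ai, , drop = FALSE]

  uc <- unique(cations$smiles)
  chain_u <- vapply(mol_graphs(uc), longest_alkyl_chain, integer(1))
  hbd_uc <- ob_props(uc)$HBD
  ua <- unique(anions$smiles)
  hbd_ua <- ob_props(ua)$HBD

  chain <- chain_u[match(cations$smiles, uc)]
  hbd_pair <- hbd_uc[match(cations$smiles, uc)] +
    hbd_ua[match(anions$smiles, ua)]
  deloc <- anions$family %in% .delocalized_families

  mpt_true <- params$intercept +
    params$chain_coef * pmin(chain, params$chain_cap) +
    params$deloc_coef * as.numeric(deloc) +
    params$hbd_coef * hbd_pair
  mpt <- pmin(pmax(mpt_true + draw$eps, params$clip[1]), params$clip[2])

  out <- tibble::tibble(
    cation_smiles = cations$smiles,
    anion_smiles = anions$smiles,
    mpt_K = mpt,
    source = "synthetic",
    chain_len = chain,
    deloc = deloc,
    hbd_pair = hbd_pair,
    mpt_true = pmin(pmax(mpt_true, params$clip[1]), params$clip[2])
  )
  attr(out, "params") <- params
  out
}
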