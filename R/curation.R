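#' Curation configuration
#'
#' Thresholds for ion-dataset curation. Defaults implement the standard
#' drug-like/ZINC-style protocol used to assemble large ion corpora:
#' molecular weight below 500 Da, calculated log P within `[-4, 6]`, at most
#' 6 hydrogen-bond donors, 11 acceptors and 15 rotatable bonds, anion formal
#' charge greater than -7 and cation formal charge less than +7 (both bounds
#' exclusive), a configurable element whitelist, single-component structures
#' only, and no unpaired electrons.
#'
#' @param element_whitelist Allowed elements; defaults to [il_elements()].
#' @param max_mw Maximum molecular weight in Da (exclusive).
#' @param anion_min_charge,cation_max_charge Exclusive net-charge bounds.
#' @param logp_min,logp_max Calculated log P window (inclusive). The
#'   estimator is the toolkit's Crippen-type atom-contribution log P; its
#'   name is recorded in every rejection report header.
#' @param max_hbd,max_hba,max_rot Maximum hydrogen-bond donor, acceptor and
#'   rotatable-bond counts (inclusive).
#' @return A list of class `"curation_config"`.
#' @export
curation_config <- function(element_whitelist = il_elements(),
                            max_mw = 500,
                            anion_min_charge = -7L,
                            cation_max_charge = 7L,
                            logp_min = -4,
                            logp_max = 6,
                            max_hbd = 6L,
                            max_hba = 11L,
                            max_rot = 15L) {
  stopifnot(logp_min < logp_max, max_hbd >= 0L, max_hba >= 0L, max_rot >= 0L,
            max_mw > 0, anion_min_charge < 0L, cation_max_charge > 0L,
            length(element_whitelist) >= 1L)
  structure(
    list(element_whitelist = element_whitelist, max_mw = max_mw,
         anion_min_charge = anion_min_charge,
         cation_max_charge = cation_max_charge,
         logp_min = logp_min, logp_max = logp_max,
         max_hbd = max_hbd, max_hba = max_hba, max_rot = max_rot),
    class = "curation_config"
  )
}

.new_report <- function(rules, counts, examples, n_input, n_kept) {
  structure(
    list(
      header = list(logp_estimator = "OpenBabel Crippen-type logP",
                    descriptor_set = DESCRIPTOR_SET_VERSION),
      counts = counts[rules],
      examples = examples,
      n_input = n_input,
      n_kept = n_kept
    ),
    class = "rejection_report"
  )
}

#' @export
print.rejection_report <- function(x, ...) {
  cat("Rejection report:", x$n_input, "input,", x$n_kept, "kept\n")
  nz <- x$counts[x$counts > 0]
  if (length(nz)) {
    for (nm in names(nz)) cat("  ", nm, ": ", nz[[nm]], "\n", sep = "")
  } else {
    cat("  (no rejections)\n")
  }
  invisible(x)
}

#' Filter a general-ion corpus
#'
#' Applies the ion curation rules in a fixed order — parseability, net
#' charge (bounds and sign consistent with the declared kind), molecular
#' weight, log P, hydrogen-bond donors, acceptors, rotatable bonds, element
#' whitelist, single-component, unpaired electrons — and attributes every
#' rejection to the first failing rule. Deterministic given input order, and
#' idempotent: filtering the kept set again removes nothing.
#'
#' @param ions A data frame with columns `smiles` and `kind`
#'   (`"cation"`/`"anion"`); extra columns are carried through.
#' @param config A [curation_config()].
#' @return A list with `kept` (tibble of curated ions with canonical
#'   `smiles`, `net_charge` and `mw` columns) and `report` (a
#'   `rejection_report` with per-rule counts and rejected examples).
#' @export
filter_general_ions <- function(ions, config = curation_config()) {
  stopifnot(is.data.frame(ions), all(c("smiles", "kind") %in% names(ions)))
  stopifnot(all(ions$kind %in% c("cation", "anion")))
  ions <- tibble::as_tibble(ions)
  n <- nrow(ions)
  rules <- c("parse", "charge", "mw", "logp", "hbd", "hba",
             "rotatable_bonds", "elements", "components",
             "unpaired_electrons")
  rule_of <- rep(NA_character_, n)

  can <- ob_canonical(ions$smiles)
  rule_of[is.na(can)] <- "parse"
  ok <- which(is.na(rule_of))

  if (length(ok)) {
    graphs <- mol_graphs(can[ok])
    mols <- ob_mols(can[ok])
    props <- ChemmineOB::prop_OB(mols)
    rot <- ob_smarts_count(mols, .rotatable_smarts)
    q <- vapply(graphs, function(g) sum(g$charge), integer(1))
    ncomp <- vapply(graphs, function(g) g$n_components, integer(1))
    unpaired <- has_unpaired_electrons(graphs)
    elem_ok <- vapply(graphs, function(g) {
      all(g$elem %in% config$element_whitelist) &&
        ("H" %in% config$element_whitelist || all(g$h_implicit == 0L))
    }, logical(1))
    kind <- ions$kind[ok]

    charge_bad <- (kind == "cation" &
                     (q <= 0L | q >= config$cation_max_charge)) |
                  (kind == "anion" &
                     (q >= 0L | q <= config$anion_min_charge))
    checks <- list(
      charge = charge_bad,
      mw = props$MW >= config$max_mw,
      logp = props$logP < config$logp_min | props$logP > config$logp_max,
      hbd = props$HBD > config$max_hbd,
      hba = props$HBA1 > config$max_hba,
      rotatable_bonds = rot > config$max_rot,
      elements = !elem_ok,
      components = ncomp != 1L,
      unpaired_electrons = unpaired
    )
    for (rule in names(checks)) {
      hit <- ok[checks[[rule]] & is.na(rule_of[ok])]
      rule_of[hit] <- rule
    }
    keep_idx <- ok[is.na(rule_of[ok])]
    kept <- ions[keep_idx, , drop = FALSE]
    kept$smiles <- can[keep_idx]
    kept$net_charge <- q[match(keep_idx, ok)]
    kept$mw <- props$MW[match(keep_idx, ok)]
  } else {
    kept <- ions[0, , drop = FALSE]
    kept$net_charge <- integer(0)
    kept$mw <- numeric(0)
  }

  rejected <- !is.na(rule_of)
  counts <- vapply(rules, function(r) sum(rule_of == r, na.rm = TRUE),
                   integer(1))
  examples <- tibble::tibble(smiles = ions$smiles[rejected],
                             rule = rule_of[rejected])
  list(kept = tibble::as_tibble(kept),
       report = .new_report(rules, counts, examples, n, nrow(kept)))
}

#' Filter raw ionic-liquid records
#'
#' Curates raw IL entries given as dot-separated multi-component SMILES.
#' Kept entries parse, consist of exactly two components — one cation and
#' one anion (a neutral co-component, e.g. a hydrate, also rejects the
#' entry) — and contain only whitelisted elements. Duplicate pairs
#' (by canonical cation/anion) are collapsed to one record.
#'
#' @param smiles Character vector of multi-component SMILES (`"cation.anion"`
#'   in either order).
#' @param config A [curation_config()]; only the element whitelist is used.
#' @return A list with `kept` (tibble `cation_smiles`, `anion_smiles`,
#'   unique pairs) and `report`.
#' @export
filter_il_records <- function(smiles, config = curation_config()) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  rules <- c("parse", "component_count", "charge_composition", "elements")
  rule_of <- rep(NA_character_, n)
  cat_s <- rep(NA_character_, n)
  an_s <- rep(NA_character_, n)

  can <- ob_canonical(smiles)
  rule_of[is.na(can)] <- "parse"

  for (i in which(is.na(rule_of))) {
    parts <- strsplit(can[i], ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      rule_of[i] <- "component_count"
      next
    }
    pcan <- ob_canonical(parts)
    if (anyNA(pcan)) {
      rule_of[i] <- "parse"
      next
    }
    graphs <- mol_graphs(pcan)
    q <- vapply(graphs, function(g) sum(g$charge), integer(1))
    if (!(any(q > 0L) && any(q < 0L))) {
      rule_of[i] <- "charge_composition"
      next
    }
    elem_ok <- vapply(graphs, function(g) {
      all(g$elem %in% config$element_whitelist) &&
        ("H" %in% config$element_whitelist || all(g$h_implicit == 0L))
    }, logical(1))
    if (!all(elem_ok)) {
      rule_of[i] <- "elements"
      next
    }
    cat_s[i] <- pcan[q > 0L]
    an_s[i] <- pcan[q < 0L]
  }

  keep <- is.na(rule_of)
  kept <- tibble::tibble(cation_smiles = cat_s[keep], anion_smiles = an_s[keep])
  kept <- dplyr::distinct(kept)
  counts <- vapply(rules, function(r) sum(rule_of == r, na.rm = TRUE),
                   integer(1))
  examples <- tibble::tibble(smiles = smiles[!keep], rule = rule_of[!keep])
  list(kept = kept, report = .new_report(rules, counts, examples, n, nrow(kept)))
}

#' Resolve duplicate melting-point records
#'
#' Collapses melting-point records sharing the same canonical cation/anion
#' pair: if the values within a duplicate group spread by more than
#' `tolerance` the whole group is discarded as irreconcilable; otherwise the
#' group is replaced by a single record carrying the arithmetic mean.
#' Singleton records pass through unchanged. The group spread is
#' `max - min`, the strictest reading that coincides with the pairwise rule
#' for two-record groups.
#'
#' @param records Data frame with columns `cation_smiles`, `anion_smiles`,
#'   `mpt_K` and optionally `source`.
#' @param tolerance Maximum in-group spread in kelvin (default 10).
#' @return Tibble with unique `(cation_smiles, anion_smiles)` keys; merged
#'   records get `source = "merged"`.
#' @export
deduplicate_mpt <- function(records, tolerance = 10) {
  stopifnot(is.data.frame(records),
            all(c("cation_smiles", "anion_smiles", "mpt_K") %in% names(records)),
            tolerance >= 0, all(records$mpt_K > 0))
  records <- tibble::as_tibble(records)
  if (!"source" %in% names(records)) records$source <- "unknown"
  records$cation_smiles <- ob_canonical(records$cation_smiles)
  records$anion_smiles <- ob_canonical(records$anion_smiles)
  if (anyNA(records$cation_smiles) || anyNA(records$anion_smiles)) {
    stop("Unparseable ion SMILES in melting-point records.", call. = FALSE)
  }
  records |>
    dplyr::group_by(.data$cation_smiles, .data$anion_smiles) |>
    dplyr::filter(dplyr::n() == 1L ||
                    (max(.data$mpt_K) - min(.data$mpt_K)) <= tolerance) |>
    dplyr::summarise(
      mpt_K = mean(.data$mpt_K),
      source = if (dplyr::n() == 1L) .data$source[1L] else "merged",
      .groups = "drop"
    )
}
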