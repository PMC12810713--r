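#' Default unstable-substructure pattern library
#'
#' Named SMARTS patterns for chemically implausible or unstable ion motifs:
#' bare carbanions without an adjacent stabilizing group, alkoxides on
#' sp3 carbon with no alpha electron-withdrawing group, N-acylated
#' quaternary ammonium ("quaternary amide") centres, and directly adjacent
#' opposite formal charges outside the legitimate nitro/N-oxide motifs.
#' The library ships as a plain-text file (one `name SMARTS` per line) under
#' `inst/extdata/unstable_patterns.smarts` and can be replaced or extended;
#' it is a declared approximation of the unstable classes named in the
#' screening protocol, not an exhaustive reactivity model. "Extreme acidity
#' or basicity" is likewise handled structurally (these pattern classes),
#' not by pKa prediction.
#'
#' @param path Optional path to an alternative pattern file.
#' @return Named character vector of SMARTS patterns.
#' @export
unstable_patterns <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "unstable_patterns.smarts",
                        package = "ilgen")
    if (path == "") path <- file.path("inst", "extdata",
                                      "unstable_patterns.smarts")
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  stats::setNames(vapply(parts, `[[`, character(1), 2L),
                  vapply(parts, `[[`, character(1), 1L))
}

#' Post-filter configuration
#'
#' @param sascore_max Maximum synthetic-accessibility score (default 4).
#' @param score_min Minimum ion score (default 0.5).
#' @param patterns Unstable-substructure library, from
#'   [unstable_patterns()].
#' @return A list of class `"post_filter_config"`.
#' @export
post_filter_config <- function(sascore_max = 4, score_min = 0.5,
                               patterns = unstable_patterns()) {
  stopifnot(sascore_max >= 1, sascore_max <= 10,
            score_min >= 0, score_min <= 1, length(patterns) >= 1L)
  structure(list(sascore_max = sascore_max, score_min = score_min,
                 patterns = patterns),
            class = "post_filter_config")
}

#' Formal-charge sign check
#'
#' `TRUE` when the net formal charge has the sign the declared ion kind
#' requires: strictly positive for cations, strictly negative for anions
#' (so a neutral species fails either way).
#'
#' @param smiles Character vector of valid SMILES.
#' @param expected_kind `"cation"` or `"anion"`.
#' @return Logical vector.
#' @export
charge_sign_ok <- function(smiles, expected_kind = c("cation", "anion")) {
  expected_kind <- match.arg(expected_kind)
  q <- net_formal_charge(smiles)
  if (expected_kind == "cation") q > 0L else q < 0L
}

#' Match unstable substructures
#'
#' Returns, per molecule, the names of all library patterns with at least
#' one substructure match.
#'
#' @param smiles Character vector of valid SMILES.
#' @param patterns Named SMARTS vector (default [unstable_patterns()]).
#' @return A list (one element per molecule) of matched pattern names;
#'   `character(0)` when clean.
#' @export
matches_unstable_group <- function(smiles, patterns = unstable_patterns()) {
  can <- ob_canonical(smiles)
  if (anyNA(can)) {
    stop("Unparseable SMILES passed to matches_unstable_group().",
         call. = FALSE)
  }
  mols <- ob_mols(can)
  hits <- vapply(patterns, function(p) ob_smarts_count(mols, p) > 0,
                 logical(length(smiles)))
  if (length(smiles) == 1L) hits <- matrix(hits, nrow = 1L)
  lapply(seq_along(smiles), function(i) names(patterns)[hits[i, ]])
}

#' Post-filter generated ions
#'
#' Removes chemically implausible generated ions. A candidate is kept iff,
#' in this order, it (1) parses, (2) has synthetic-accessibility score at
#' most `sascore_max`, (3) carries no unpaired electrons, (4) has the
#' correct formal-charge sign for its kind, (5) receives an ion score of at
#' least `score_min` from the supplied scorer, and (6) matches no unstable
#' substructure pattern. Each rejection is attributed to the first failing
#' rule. The filter is idempotent and invariant to SMILES spelling.
#'
#' @param ions Character vector of candidate SMILES (raw generator output is
#'   fine).
#' @param expected_kind `"cation"` or `"anion"`; must equal the scorer's
#'   kind.
#' @param scorer An `"ion_scorer"` for rule (5).
#' @param config A [post_filter_config()].
#' @return A list with `kept` (tibble: canonical `smiles`, `kind`,
#'   `net_charge`, `score`, `sa_score`, `source = "generated"`) and `report`
#'   (a `rejection_report`).
#' @export
apply_post_filter <- function(ions, expected_kind = c("cation", "anion"),
                              scorer, config = post_filter_config()) {
  expected_kind <- match.arg(expected_kind)
  stopifnot(inherits(scorer, "ion_scorer"),
            inherits(config, "post_filter_config"))
  if (scorer$ion_kind != expected_kind) {
    stop("Scorer kind (", scorer$ion_kind, ") does not match expected_kind (",
         expected_kind, ").", call. = FALSE)
  }
  n <- length(ions)
  rules <- c("parse", "sascore", "unpaired_electrons", "charge_sign",
             "ion_score", "unstable_group")
  rule_of <- rep(NA_character_, n)
  can <- ob_canonical(ions)
  rule_of[is.na(can)] <- "parse"
  ok <- which(is.na(rule_of))

  sa <- rep(NA_real_, n)
  score <- rep(NA_real_, n)
  q <- rep(NA_integer_, n)
  if (length(ok)) {
    graphs <- mol_graphs(can[ok])
    sa[ok] <- sa_score(can[ok])
    unpaired <- has_unpaired_electrons(graphs)
    q[ok] <- vapply(graphs, function(g) sum(g$charge), integer(1))
    sign_ok <- if (expected_kind == "cation") q[ok] > 0L else q[ok] < 0L
    score[ok] <- score_ions(scorer, can[ok])$score
    unstable <- lengths(matches_unstable_group(can[ok], config$patterns)) > 0L

    checks <- list(
      sascore = sa[ok] > config$sascore_max,
      unpaired_electrons = unpaired,
      charge_sign = !sign_ok,
      ion_score = score[ok] < config$score_min,
      unstable_group = unstable
    )
    for (rule in names(checks)) {
      hit <- ok[checks[[rule]] & is.na(rule_of[ok])]
      rule_of[hit] <- rule
    }
  }
  keep <- is.na(rule_of)
  kept <- tibble::tibble(
    smiles = can[keep], kind = expected_kind, net_charge = q[keep],
    score = score[keep], sa_score = sa[keep], source = "generated"
  )
  counts <- vapply(rules, function(r) sum(rule_of == r, na.rm = TRUE),
                   integer(1))
  examples <- tibble::tibble(smiles = ions[!keep], rule = rule_of[!keep])
  list(kept = kept,
       report = .new_report(rules, counts, examples, n, nrow(kept)))
}
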