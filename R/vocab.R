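#' Character vocabulary for SMILES corpora
#'
#' Builds a character-level vocabulary from a corpus: one token per unique
#' character (sorted, so reconstruction is deterministic) plus the three
#' specials `PAD`, `BOS`, `EOS` at fixed reserved ids 1-3. Multi-character
#' element symbols such as `Cl` are deliberately two tokens — the sequence
#' model is character-level.
#'
#' @param corpus Character vector of SMILES strings.
#' @return An object of class `"smiles_vocab"` with `token_to_id`,
#'   `id_to_token` and `specials`.
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(is.character(corpus), length(corpus) >= 1L)
  chars <- sort(unique(unlist(strsplit(corpus, "", fixed = TRUE))))
  id_to_token <- c("<pad>", "<bos>", "<eos>", chars)
  structure(
    list(
      token_to_id = stats::setNames(seq_along(id_to_token), id_to_token),
      id_to_token = id_to_token,
      specials = c(PAD = 1L, BOS = 2L, EOS = 3L)
    ),
    class = "smiles_vocab"
  )
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat("SMILES character vocabulary:", length(x$id_to_token), "tokens (3 special)\n")
  invisible(x)
}

#' Tokenize SMILES to id sequences
#'
#' Converts each string to `BOS, chars..., EOS` integer ids.
#' [detokenize_smiles()] inverts the mapping exactly for any in-vocabulary
#' string (round trip).
#'
#' @param smiles Character vector.
#' @param vocab A [build_vocabulary()] object.
#' @param max_len Maximum sequence length including the two specials; longer
#'   strings are an error.
#' @return A list of integer vectors.
#' @export
tokenize_smiles <- function(smiles, vocab, max_len = 128L) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  lapply(smiles, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    ids <- vocab$token_to_id[chars]
    if (anyNA(ids)) {
      stop("Out-of-vocabulary character(s) in \"", s, "\": ",
           paste(unique(chars[is.na(ids)]), collapse = " "), call. = FALSE)
    }
    if (length(ids) + 2L > max_len) {
      stop("Sequence longer than max_len (", max_len, "): \"", s, "\"",
           call. = FALSE)
    }
    as.integer(c(vocab$specials["BOS"], ids, vocab$specials["EOS"]))
  })
}

#' @rdname tokenize_smiles
#' @param ids Integer vector (one tokenized sequence).
#' @return `detokenize_smiles()`: the decoded string, specials stripped.
#' @export
detokenize_smiles <- function(ids, vocab) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  keep <- !(ids %in% vocab$specials)
  paste(vocab$id_to_token[ids[keep]], collapse = "")
}

## Pad a list of id sequences into a [batch x T] matrix (PAD = 1).
pad_batch <- function(seqs) {
  t_max <- max(lengths(seqs))
  out <- matrix(1L, nrow = length(seqs), ncol = t_max)
  for (i in seq_along(seqs)) out[i, seq_along(seqs[[i]])] <- seqs[[i]]
  out
}
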