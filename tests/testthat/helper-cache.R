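## Shared, lazily built fixtures. Heavy objects (trained models, descriptor
## tables) are built once per test run and reused across files.

.tcache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.tcache[[key]])) .tcache[[key]] <- force(expr)
  .tcache[[key]]
}

## 120 IL-like + 120 decoy cations with descriptors and split
small_ion_ds <- function() {
  cached("ds_small", {
    il <- make_il_like_corpus(120, 7, "cation")
    de <- make_decoy_corpus(120, 7, "cation")
    build_scorer_dataset(il, de, seed = 7)
  })
}

small_scorer <- function() {
  cached("scorer_small", {
    ds <- small_ion_ds()
    feats <- select_features(ds, k = 25, seed = 7)
    train_scorer(ds, feats, alpha = 0.2, ion_kind = "cation", seed = 7)
  })
}

small_mpt <- function() {
  cached("mpt_small", {
    train_mpt(make_synthetic_mpt_dataset(150, 7), seed = 7, num_trees = 200)
  })
}

## compact CVAE trained on a 150-ion mixed corpus (fast, for mechanics tests)
tiny_cvae <- function() {
  cached("cvae_tiny", {
    il <- make_il_like_corpus(75, 7, "cation")
    de <- make_decoy_corpus(75, 7, "cation")
    dat <- tibble::tibble(smiles = c(il$smiles, de$smiles),
                          condition = rep(c(1, 0), each = 75))
    train_cvae(dat, cvae_config(embed_dim = 24, hidden_dim = 32,
                                n_gru_layers = 1, latent_dim = 8,
                                lr = 3e-3, batch_size = 64, epochs = 8,
                                max_len = 64, seed = 7))
  })
}

## CVAE trained on a single repeated string (memorization oracle)
memor_cvae <- function() {
  cached("cvae_memor", {
    dat <- tibble::tibble(smiles = rep("CC[n+]1ccn(C)c1", 64), condition = 1)
    train_cvae(dat, cvae_config(embed_dim = 16, hidden_dim = 24,
                                n_gru_layers = 1, latent_dim = 4,
                                lr = 8e-3, batch_size = 32, epochs = 120,
                                max_len = 32, seed = 3))
  })
}

## The 30-molecule curation fixture: 20 clean ions + one planted violation
## per curation rule, in rule order.
curation_fixture <- function() {
  clean_cat <- c("CC[n+]1ccn(C)c1", "CCCC[n+]1ccn(C)c1", "CCCCCC[n+]1ccn(C)c1",
                 "CCCC[n+]1ccccc1", "CC[n+]1ccc(C)cc1", "CCCC[N+]1(C)CCCC1",
                 "CC[N+]1(C)CCCC1", "C[N+](C)(C)C", "CC[N+](CC)(CC)CC",
                 "CCCC[N+](C)(C)CC", "C[P+](C)(C)C", "CCCC[P+](C)(C)C",
                 "[NH4+]", "CC[NH3+]", "OCC[N+](C)(C)C")
  clean_an <- c("CC(=O)[O-]", "CCCC(=O)[O-]", "[Cl-]", "[B-](F)(F)(F)F",
                "[O-][N+](=O)[O-]")
  plants <- tibble::tribble(
    ~smiles, ~kind, ~rule,
    "not_a_smiles", "cation", "parse",
    "CC(=O)[O-]", "cation", "charge",
    paste0("C[N+](C)(C)C", strrep("OC", 17)), "cation", "mw",
    "c1ccc(cc1)C(c1ccccc1)(c1ccccc1)[P+](c1ccccc1)(CCCC)CCCC", "cation",
    "logp",
    "[NH3+]CCNCCNCCNCCNCCNCCNCCN", "cation", "hbd",
    "[O-]C(=O)COCOCOCOCOCOCOCOCOCOCOC", "anion", "hba",
    "CCOCCOCCOCCOCCOCC[n+]1ccn(C)c1", "cation", "rotatable_bonds",
    "C[S+](C)C", "cation", "elements",
    "C[N+](C)(C)C.C[N+](C)(C)C", "cation", "components",
    "[NH3+]C[CH2]", "cation", "unpaired_electrons"
  )
  list(
    ions = tibble::tibble(
      smiles = c(clean_cat, clean_an, plants$smiles),
      kind = c(rep("cation", length(clean_cat)),
               rep("anion", length(clean_an)), plants$kind)
    ),
    n_clean = length(clean_cat) + length(clean_an),
    plants = plants
  )
}

## A synthetic tabular dataset shaped like a scorer dataset: class signal in
## named informative columns, the rest pure noise.
synthetic_ds <- function(n = 200, informative = c("f1", "f2", "f3"),
                         n_noise = 5, shift = 3, seed = 11) {
  withr::with_seed(seed, {
    label <- rep(c(0, 1), each = n / 2)
    cols <- list()
    for (f in informative) cols[[f]] <- rnorm(n) + shift * label
    for (i in seq_len(n_noise)) cols[[paste0("noise", i)]] <- rnorm(n)
    ds <- tibble::as_tibble(cols)
    ds$smiles <- paste0("mol", seq_len(n))
    ds$label <- label
    ds$split <- rep(c("train", "test"), length.out = n)
    attr(ds, "feature_cols") <- c(informative,
                                  paste0("noise", seq_len(n_noise)))
    ds
  })
}

## Acceptance-scale objects: 400 ions per class, and the toy CVAE trained on
## the 800-ion mixed corpus (hidden 64, latent 16, 20 epochs).
acc_scorer_stack <- function() {
  cached("acc_scorer", {
    il <- make_il_like_corpus(400, 42, "cation")
    de <- make_decoy_corpus(400, 42, "cation")
    ds <- build_scorer_dataset(il, de, seed = 42)
    feats <- select_features(ds, k = 25, seed = 42)
    model <- train_scorer(ds, feats, alpha = 0.2, ion_kind = "cation",
                          seed = 42)
    list(ds = ds, features = feats, model = model)
  })
}

acc_cvae <- function() {
  cached("acc_cvae", {
    il <- make_il_like_corpus(400, 42, "cation")
    de <- make_decoy_corpus(400, 42, "cation")
    dat <- tibble::tibble(smiles = c(il$smiles, de$smiles),
                          condition = rep(c(1, 0), each = 400))
    train_cvae(dat, cvae_config(embed_dim = 48L, hidden_dim = 64L,
                                n_gru_layers = 1L, latent_dim = 16L,
                                lr = 3e-3, batch_size = 128L, epochs = 20L,
                                max_len = 64L, seed = 7L))
  })
}
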