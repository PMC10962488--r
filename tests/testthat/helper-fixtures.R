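# Shared fixtures, memoized across test files so the expensive pieces
# (pretraining the small generator) run once per suite.

.shared <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .shared)) assign(name, build(), envir = .shared)
  get(name, envir = .shared)
}

# The small-scale generator configuration used by the learning and transfer
# tests: 16-dim latent, 64-unit single-layer LSTMs, FPC rescaling on and a
# small annealed KL weight (the configuration rationale is covered in the
# methods vignette).
tiny_gen_config <- function() {
  gen_config(embedding_dim = 32, encoder_rnn_dim = 64, encoder_rnn_layers = 1,
             latent_dim = 16, fpc_hidden_dims = c(16, 16),
             decoder_rnn_dim = 64, decoder_rnn_layers = 1,
             kl_weight = 0.008, kl_anneal_steps = 480, fpc_rescale = TRUE,
             max_len = 80)
}

micro_gen_config <- function() {
  gen_config(embedding_dim = 8, encoder_rnn_dim = 12, encoder_rnn_layers = 1,
             latent_dim = 4, fpc_hidden_dims = c(6, 6), decoder_rnn_dim = 12,
             decoder_rnn_layers = 1, kl_weight = 0.1, max_len = 40)
}

fixture_corpus <- function() memo("corpus", function() {
  generate_smiles_corpus(500, seed = 11)
})

fixture_corpus_qed <- function() memo("corpus_qed", function() {
  compute_qed(canonicalize_smiles(fixture_corpus()))
})

# Pretrained small generator (the expensive shared fixture).
pretrained_model <- function() memo("pretrained", function() {
  vae_train(fixture_corpus(), config = tiny_gen_config(),
            train = train_config(batch_size = 64, base_lr = 3e-3,
                                 max_epochs = 120, seed = 7),
            cond = fixture_corpus_qed())
})

# Marker target domain: every molecule carries a thiophene ring (aromatic S).
marker_domain <- function() memo("marker_domain", function() {
  generate_smiles_corpus(120, seed = 23, required_fragment = "c1ccsc1")
})

marker_prevalence <- function(samples) mean(grepl("s", samples, fixed = TRUE))

fixture_activity <- function() memo("activity", function() {
  generate_activity_dataset(300, seed = 5, noise_sigma = 0.3)
})

# Two linearly separable Gaussian clusters shaped like fingerprint features.
separable_clusters <- function(n = 200, p = 32, shift = 2.5, seed = 42) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(stats::rnorm(n * p), n, p)
  x[y == 1, 1:8] <- x[y == 1, 1:8] + shift
  list(x = x, y = y)
}
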