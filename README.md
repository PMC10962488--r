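# denovomol

Property-conditioned de novo molecular generation with partition transfer
learning, activity prediction and screening — an R toolkit for the
generate-and-screen style of early drug discovery that starts from a
*disease-direct-related activity dataset* (e.g. cell-viability IC50s)
rather than from a protein target.

## What it does

The pipeline has five computational stages:

1. **Corpus preprocessing.** SMILES corpora are parsed, canonicalized and
   filtered (raw length ≤ 120, 5–70 heavy atoms, atoms from
   {*, C, N, O, F, S, Cl, Br}, known actives excluded); drug-likeness is
   scored with QED, and activity datasets are partitioned into four
   sub-domains by QED and IC50:

   * **A** — drug-like, high activity (QED > 0.6, IC50 below the split)
   * **B** — drug-like, low activity
   * **C**, **D** — their non-drug-like counterparts

2. **Conditional generation.** A sequence variational autoencoder encodes a
   molecule into a latent code *z* (`z = μ + e^{log σ} ⊙ ε`); a
   feature–property-correlation (FPC) attention network scores each latent
   dimension's relevance to the condition property (QED),
   `S = softmax(MLP([z; c]))`, and the decoder generates SMILES token by
   token from the conditioned code `Z_c = S ⊙ z` and the condition. The
   loss is masked token cross-entropy plus a weighted KL term; training
   uses Adam with multiplicative learning-rate decay and a two-part early
   stop (epoch cap, or token accuracy above δ = 0.95 for 500 consecutive
   steps).

3. **Partition transfer learning.** The pretrained generator is finetuned
   through sub-domain stages (C → A, or D → B), each stage stopping on an
   epoch-loss plateau and restoring its best parameters. The *recurrent*
   variant (PRTL) then alternates finetuning, sampling (10 × 64 molecules),
   and qualification (valid, unique, QED > 0.6, predicted active, novel),
   feeding qualifiers back into the target domain until no novel molecule
   appears or 50 recurrences elapse.

4. **Activity prediction.** Fingerprints (path-based, Morgan/ECFP4,
   SMARTS-feature) with MI or Lasso feature selection feed SVM / random
   forest / gradient-boosted models, tuned by seeded random search over the
   stated hyperparameter spaces with fivefold cross-validation
   (accuracy/F1 for classification, MRE/MAE/RMSE for regression).

5. **Screening.** Candidates are novelty-filtered against local reference
   sets, ranked by predicted pIC50 (descending) or by externally supplied
   docking scores (ascending), and one synthesis candidate is picked per
   rank window (Top 1–10, Top 11–20) by lowest synthetic-accessibility
   score.

A deterministic fragment-grammar simulator (`generate_smiles_corpus()`,
`generate_activity_dataset()`) makes every stage runnable and testable
offline with known structure–activity signal.

## Worked example

```r
library(denovomol)

# simulate a corpus and pretrain a small conditional generator
corpus <- generate_smiles_corpus(500, seed = 11)
cfg <- gen_config(embedding_dim = 32, encoder_rnn_dim = 64,
                  encoder_rnn_layers = 1, latent_dim = 16,
                  fpc_hidden_dims = c(16, 16), decoder_rnn_dim = 64,
                  decoder_rnn_layers = 1, kl_weight = 0.008,
                  kl_anneal_steps = 480, fpc_rescale = TRUE, max_len = 80)
fit <- vae_train(corpus, config = cfg,
                 train = train_config(batch_size = 64, base_lr = 3e-3,
                                      max_epochs = 120, seed = 7))

# sample at a high drug-likeness condition and evaluate
reps <- lapply(1:10, function(r)
  vae_sample(fit$model, 64, condition = 0.9, seed = 100 + r))
evaluate_generation(reps, training_set = canonicalize_smiles(corpus),
                    activity_model = function(s) rep(TRUE, length(s)))
#> generation report (10 repetitions of 64 samples)
#>   validity     77.66%
#>   uniqueness   98.99%
#>   QED>0.6      49.82%  (n=24.6)
#>   lead        100.00%  (n=24.6)
#>   novelty      94.26%  (n=23.2)
```

Read: ~78% of sampled strings are chemically valid, ~99% of the valid ones
are distinct molecules, ~50% of those clear the QED > 0.6 drug-likeness
bar (≈ 25 molecules per 64-sample batch), and ~94% of the qualifying
molecules are not in the training corpus. The `lead` line is 100% here
because the example plugs in an accept-everything activity predicate; with
a trained model (`train_activity_model()`) it reports the predicted-active
fraction.

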