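# tedi — temporal distribution matching for text encoders

Biomedical corpora drift over time: study populations, co-mentioned
concepts and vocabulary all shift between, say, 2010–2013 and 2016–2018.
An encoder trained by masked language modeling (MLM) over the whole range
averages the periods, and downstream clinical predictions inherit whatever
the training mass favors. `tedi` implements *temporal distribution
matching*: an adversarial training scheme in which a linear discriminator
tries to tell old from new documents from their embeddings while the
encoder is trained to defeat it — without losing its semantics.

For whom: researchers studying diachronic drift in clinical text
representations, and anyone who needs a fully self-contained, CPU-scale
testbed (synthetic corpora, patients, and paired statistics included) for
adversarial distribution matching on text encoders.

## The objective

Three components train together. The generator `M_e` (a small transformer,
2 layers, hidden size `d`) embeds each sentence; the first `m` sentence
embeddings form an `m × d` abstract embedding (zero-padded, default
`m = 20`). The discriminator `M_d` is a linear classifier over the
flattened embedding (`d·m + 1` parameters). A frozen anchor encoder of the
same architecture, trained MLM-only, pins the embeddings down. Per batch,
the discriminator takes a step on its binary cross-entropy `L_adv`; then,
with the discriminator frozen, the generator takes a step on

    (1 − λ_adv − λ_A) · L_MLM + λ_adv · L_adv′ + λ_A · L_A

where `L_adv′` is the adversarial term against flipped period labels and
`L_A` is the Frobenius distance to the anchor's embedding. Default
operating point: `λ_adv = λ_A = 0.3`.

Everything around the loop is included: a drift-corpus generator with
planted concept pairs, temporal probing, held-out MLM evaluation,
future-relatedness ranking against a new-period reference model,
frozen-encoder LSTM heads for group-wise downstream evaluation, and the
paired tests (DeLong, Diebold–Mariano with MAD criterion, bootstrap CIs).

## Worked example

```r
library(tedi)

# a drifted corpus: 400 old + 400 new documents, strong drift
cfg    <- drift_corpus_config(vocab_size = 300, n_docs_old = 400,
                              n_docs_new = 400, drift_strength = 0.8,
                              seed = 7)
pairs  <- generate_concept_pairs(cfg, 10)
corpus <- generate_drift_corpus(cfg, pairs)

tok  <- whitespace_tokenizer(build_vocab(corpus$text))
ecfg <- encoder_config(n_layers = 2, hidden_size = 64, n_heads = 2,
                       ff_size = 128, max_tokens = 32, seed = 1)

# the frozen anchor doubles as the MLM-only baseline
anchor <- train_anchor(corpus, ecfg, epochs = 5, tokenizer = tok,
                       lr = 1e-3, seed = 2)
base   <- anchor$encoder

tcfg   <- tedi_train_config(lambda_adv = 0.3, lambda_anchor = 0.3,
                            epochs = 5, lr_generator = 1e-3,
                            lr_discriminator = 1e-2, seed = 3)
bundle <- train_tedi(corpus, anchor, tcfg)

temporal_probe(base, corpus, split_seed = 9)$accuracy
#> [1] 0.6708333
temporal_probe(bundle$generator, corpus, split_seed = 9)$accuracy
#> [1] 0.4875
heldout_mlm_loss(base, corpus, seed = 4)
#> [1] 4.236358
heldout_mlm_loss(bundle$generator, corpus, seed = 4)
#> [1] 4.177363
```

On this 800-document corpus the probe — a fresh ridge-logistic classifier
on frozen embeddings — reads the period from the baseline's embeddings at
accuracy 0.671, and from the matched encoder's at 0.488: distribution
matching removed most of the linearly recoverable period information,
while the matched encoder's masked-token loss (4.18) actually edges out
the baseline's (4.24).

The same experiment, at the package's canonical sizes and with the
no-anchor ablation, reference model, and downstream cohort, is wrapped as

```r
tedi_synthetic_study(seeds = 1:3)   # one row of metrics per seed
tedi_downstream_study(seed = 1)     # oracle AUC, head AUC, group-wise CIs
```

A command-line interface over the same functions ships in
`inst/cli/tedi` (`synth-corpus`, `label`, `split`, `train-mlm`,
`train-tedi`, `eval-probe`, `eval-relatedness`, `compare-auc`, ...).

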