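# elscore

Automated scoring of child expressive-language subtests from transcripts.

Standardized expressive-language batteries for children — confrontation
naming (Expressive Vocabulary, EV), inflectional morphology (Word
Structure, WS), sentence repetition (Recalling Sentences, RS), and sentence
formulation (Formulated Sentences, FS) — are scored by hand today: an
examiner credits each item response, sums item scores into a raw score per
subtest, converts raw scores to age-normed scaled scores (mean 10, SD 3, on
1–19), and combines the FS + RS + WS scaled scores into an Expressive
Language Index composite (ELI; mean 100, SD 15, on 45–155). `elscore`
implements that scoring pipeline end to end for speech-language researchers
and computational psychometricians:

- **Item scoring.** Trainable classifiers score `(prompt, response)` pairs
  per subtest behind one fit/predict contract: a small self-attention pair
  encoder trained with a 10% validation holdout, L2 regularization, and
  patience-4 early stopping with best-state restore; SVM baselines on mean
  word embeddings (EV/WS) and on edit-distance correctness features (RS);
  an MLP on static sentence embeddings (FS); and a deterministic n-gram
  nearest-profile model. RS items can also be scored by rule: tokenize,
  collapse adjacent repetitions (repetitions are not errors), align against
  the target with unit-cost Levenshtein operations, and map the error count
  to a 0–3 score (default: 0 errors → 3, 1 → 2, 2–3 → 1, ≥4 → 0).
- **Aggregation.** Item scores → raw (with per-subtest discontinuation
  rules: EV stops after 7 consecutive zeros, FS and RS after 5, WS never)
  → age-banded scaled lookup → ELI composite lookup.
- **Synthetic data.** A generator produces clean/verbatim transcript
  corpora with known gold scores (verbatim adds prefatory chatter such as
  "i think that one's a pirate" for the clean "pirate"), RS responses with
  an exact injected error count, and terminal zero runs that exercise
  discontinuation. A norms module builds internally consistent synthetic
  lookup tables by quantile matching, calibrated to the published scaled
  and composite moments.
- **Evaluation.** Repeated k-fold cross-validation (default 5 folds × 20
  reshuffles, folds split by child), reporting accuracy, precision, recall
  (weighted or macro), per-tier MAE, Spearman correlation, and subgroup
  stratification.

## Worked example

```r
library(elscore)

gen     <- generator_config(seed = 42, n_children = 12)
corpora <- generate_corpus(gen)
table   <- build_norm_tables(reference_population(norms_config(), seed = 42))

backends <- list(EV = "ngram", WS = "ngram", FS = "ngram",
                 RS = "svm_edit_features")
report <- cross_validate(corpora$clean, backends, train_config(seed = 42),
                         eval_config(n_folds = 5, n_repetitions = 3, seed = 42),
                         table)
subset(report$summary, metric %in% c("accuracy", "mae") & tier == "item")
```

```
  subtest tier   metric   mean       sd n_reps n_excluded
1      EV item accuracy 0.9321 0.010692      3          0
2      EV item      mae 0.0679 0.010692      3          0
3      FS item accuracy 0.9704 0.000000      3          0
4      FS item      mae 0.0296 0.000000      3          0
5      RS item accuracy 1.0000 0.000000      3          0
6      RS item      mae 0.0000 0.000000      3          0
7      WS item accuracy 0.9835 0.006014      3          0
8      WS item      mae 0.0165 0.006014      3          0
```

Item accuracy is the fraction of test-fold items scored exactly right,
averaged over the three repetitions (±SD); item MAE is the mean absolute
item-score error. The RS edit-feature SVM is perfect here because the
synthetic RS gold scores are a deterministic function of the alignment
features it sees. At the composite tier the same report shows
`ELI eli mae 3.0` and `ELI eli spearman 0.978`: predicted composites land
within about 3 standard-score points of the gold-derived ones.

Aggregating gold item scores directly gives each child's score report:

```r
scored <- corpora$clean
scored$item_score <- scored$gold_score
rep <- score_reports(scored, table)
head(rep$subtest_reports, 4); head(rep$eli_reports, 2)
```

```
  child_id subtest age_months n_items discontinued_at raw scaled
1    c0001      EV         91      27              NA  39      9
2    c0001      FS         91      24              NA  35     12
3    c0001      RS         91      32              NA  61     10
4    c0001      WS         91      32              NA  25     11
  child_id scaled_sum eli
1    c0001         33 109
2    c0002         36 118
```

Child `c0001` sits near the reference mean on every subtest (scaled 9–12),
and the FS+RS+WS scaled sum of 33 maps to an ELI of 109.

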