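{
  "model": "lda",
  "hyperparameter": { "lambda": "auto" },
  "metric": ["accuracy", "auc"],
  "preprocess": ["zscore"],
  "cv": "kfold",
  "k": 5,
  "repeat": 2,
  "stratify": true,
  "seed": 1
}
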