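# cmiphmm

Interface residue prediction for domain–domain interaction (DDI) families,
with contact-matrix feedback.

## The problem

When two proteins interact through a pair of domains, two computational
questions arise at different depths: which residues of each domain are
interaction sites, and which residue pairs across the interface are in
contact (the binary residue–residue **contact matrix**). A correct contact
matrix implies the interaction sites, but not the other way around.
cmiphmm predicts interaction sites by first predicting the contact matrix
and then feeding each residue's predicted matrix row (or column) back into
the site classifier, so a residue's call aggregates evidence from all of
its potential partners. The package is for computational biologists who
work with aligned domain families and per-residue interface annotations.

## The models

1. **Interaction-profile HMM (ipHMM).** A profile HMM per domain whose
   match states are split into interacting and non-interacting flavours,
   `M_i(j)` and `M_ni(j)`. Parameters are maximum-likelihood counts from a
   labeled alignment with add-one pseudocounts; posterior decoding
   (forward–backward) gives each residue an interaction probability
   `p_int = γ(M_i) / (γ(M_i) + γ(M_ni))`, thresholded at 0.5.
2. **Contact-matrix SVM.** Every residue pair (one residue per domain,
   match-state coordinates) is a 414-dimensional example:
   `(20 Fisher scores + 11×17 windowed AAindex properties) × 2`,
   min–max normalised to [0, 1], classified by an RBF-kernel SVM
   (`K(x,y) = exp(−γ‖x−y‖²)`, defaults γ = 1/414, C = 1). Fisher scores
   are the constrained gradient of the sequence log-likelihood with
   respect to the ipHMM's emission parameters — how the likelihood reacts
   to mutating the residue.
3. **Integrated logistic site classifier (CM-ipHMM).** Per domain, a
   residue's features are its predicted contact-matrix row/column plus its
   ipHMM score in the last slot, classified by L2-penalised logistic
   regression (`Pr(Y=1|X) = 1/(1+exp(−(β₀+β'X)))`, C = 1), trained with
   positives oversampled to class balance. Ablations: `cm_only` (no ipHMM
   slot) and `ground_truth_cm` (true matrix instead of predicted).

Evaluation is leave-one-out over a family's sequence pairs with accuracy,
precision, recall, F1 and MCC per sequence, macro-averaged, plus paired
t-tests between methods. A synthetic DDI-family generator with known
ground truth makes the whole pipeline trainable and testable offline.

## Worked example

```r
library(cmiphmm)

fam <- sample_family(family_spec(n_pairs = 10, seed = 42), "demo")
fam
#> <synthetic_family> demo: 10 pairs, domains 12 + 15 match columns, 32 topology contacts

pred   <- loocv_family(fam, seed = 1)           # all four methods, LOOCV
report <- aggregate_report(evaluate_predictions(pred))
report$overall[, c("method", "accuracy", "precision", "recall", "f1", "mcc")]
#>   method          accuracy precision recall    f1   mcc
#> 1 cm_iphmm           0.972     1      0.94  0.963 0.949
#> 2 cm_only            0.965     1      0.926 0.955 0.936
#> 3 ground_truth_cm    0.99      1      0.979 0.988 0.981
#> 4 iphmm              0.849     0.798  0.885 0.835 0.706
```

The rows are mean per-sequence metrics over the 20 held-out sequences.
The plain ipHMM reaches MCC 0.71 on this family — its site annotations are
noisy by construction (`label_noise = 0.3`). Feeding the predicted contact
matrix into the logistic integrator lifts MCC to 0.95 (`cm_iphmm`), close
to the 0.98 ceiling obtained with the ground-truth matrix, and the contact
matrix alone (`cm_only`, 0.94) carries most of that signal. The
improvement is not noise:

```r
per_seq <- evaluate_predictions(pred)
wide <- tidyr::pivot_wider(per_seq[, c("method", "seq_id", "mcc")],
                           names_from = "method", values_from = "mcc")
paired_t_test(wide$cm_iphmm, wide$iphmm)
#>   mean_diff     t    df    p_value degenerate
#> 1     0.243  6.86    19 0.00000152 FALSE
```

`autoplot(report)` draws the per-method metric bars;
`plot_contact_matrix(predict_pair_contacts(fam, "p01")$binary)` shows a
predicted matrix next to `plot_contact_matrix(fam$contacts[["p01"]])`.

A thin command-line front-end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cmiphmm", package = "cmiphmm"))')
Rscript $CLI simulate --out families --n-families 10 --seed 1
Rscript $CLI evaluate --dir families --cv loocv --seed 1
```

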