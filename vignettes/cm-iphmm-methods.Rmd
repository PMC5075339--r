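---
title: "Interface residue prediction with contact-matrix feedback: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface residue prediction with contact-matrix feedback: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two related questions arise when analysing a pair of interacting protein
domains. First, *which residues* of each domain sit in the interface
(interaction-site prediction)? Second, *which residue pairs* across the
interface are actually in contact (contact-matrix prediction)? The second
question is strictly deeper: a correct residue–residue contact matrix
implies the interaction sites, but not vice versa. cmiphmm implements a
three-stage pipeline that exploits this asymmetry — it predicts a contact
matrix and then feeds it *back* into site prediction, so that a residue's
site call can draw on evidence aggregated across all of its potential
partner residues.

All models operate at the level of a domain–domain interaction (DDI)
family: a set of protein pairs that interact through the same two domains,
aligned into one labeled multiple sequence alignment per domain, with one
shared interface topology per family.

## Stage 1: the interaction-profile HMM

A profile HMM represents a domain family with one match state per conserved
alignment column plus insert and delete states. The interaction-profile HMM
(ipHMM) splits every match state $M(j)$ into two flavours: an interacting
match $M_i(j)$ and a non-interacting match $M_{ni}(j)$, each with its own
emission distribution over the 20 amino acids. Connectivity follows the
usual profile-HMM restrictions (Begin→{M\*, D, I}, M\*→{M\*, I, D, End},
I→{I, M\*, D}, D→{D, M\*, End}).

Parameters are maximum-likelihood counts from the labeled alignment — each
residue's match flavour comes from its interaction label, each row's
indel structure from its gap pattern — smoothed with add-one pseudocounts
(`pseudocount = 1`): every amino acid receives one extra count in every
emitting state, and every allowed arc one extra count, so an amino acid
never observed in a state still has positive probability.

Decoding is by forward–backward (posterior decoding), implemented in log
space. For a residue aligned to column $j$ the interaction probability is
the posterior mass ratio

$$p_{\mathrm{int}}(j) = \frac{\gamma(M_i(j))}{\gamma(M_i(j)) + \gamma(M_{ni}(j))},$$

and the site call is *interacting* iff $p_{\mathrm{int}} > 0.5$. The tie at
exactly 0.5 goes to the majority (non-interacting) class, and a match
column deleted by the sequence is non-interacting with
$p_{\mathrm{int}} = 0$. The decision rule beyond "posterior decoding" is a
design choice of this package; the threshold is exposed as a parameter.

**Fisher scores.** Each residue is also summarised by the gradient of the
sequence log-likelihood with respect to the (sum-constrained) emission
parameters of its best-supported match column $j^\*$ (the column with the
largest posterior match mass — an argmax over posteriors, consistent with
posterior decoding used elsewhere):

$$F_i(a) = \sum_{m \in \{M_{ni}, M_i\}} \gamma(i, m(j^\*))\,
  \big(\mathbf{1}[x_i = a] - e_{m(j^\*)}(a)\big).$$

This measures how the likelihood would react to mutating residue $i$ into
each of the 20 amino acids. The constraint projection gives the testable
identity $\sum_a F_i(a) = 0$ for every residue; a residue with no match
mass (pure insert) gets a zero vector and is flagged.

## Stage 2: contact-matrix prediction

Every (match column of A) × (match column of B) cell where both sequences
align a residue becomes one example for an RBF-kernel SVM,
$K(x,y) = \exp(-\gamma\lVert x-y\rVert^2)$. The feature vector concatenates,
for each of the two residues, its 20 Fisher scores and its windowed
physicochemical profile: 17 AAindex property scales evaluated over an
11-residue window centred on the residue ($11 \times 17 = 187$ values,
offset-major), giving $(20 + 187) \times 2 = 414$ features. Window slots
beyond the sequence ends are padded with the per-property mean over the
training residues (neutral under the subsequent scaling; zero-padding would
instead pin those slots to an extreme after min–max normalisation).
Features are min–max normalised to $[0,1]$ on the training set; constant
features map to 0 and test values are clamped.

Defaults follow the common library convention: $\gamma = 1/414$ (one over
the feature count) and $C = 1$, both exposed as configuration. The contact
matrix is indexed by match-state coordinates, not raw sequence positions,
so its dimension is constant across family members; cells involving a
deleted match column are 0 (binary) or the minimum score. The binary
prediction is the sign of the SVM decision value; no per-pair calibration
is applied. No resampling is used at this stage.

## Stage 3: the integrated site classifier

For a residue of domain A aligned to match column $r$, the integrator's
feature vector is row $r$ of the predicted binary contact matrix followed
by the residue's ipHMM score as the **last** component (domain B residues
take columns). The continuous posterior $p_{\mathrm{int}}$ is used rather
than the binary call — it carries strictly more information; the binary
option exists as a flag. Two separate logistic-regression models are
trained per family (one per domain), since the feature length is the
partner domain's match-state count plus one:

$$\Pr(Y = 1 \mid X_1, \dots, X_k) =
  \frac{1}{1 + \exp[-(\beta_0 + \beta_1 X_1 + \dots + \beta_k X_k)]}.$$

The fit is L2-penalised with inverse strength $C = 1$ in the convention of
the common machine-learning libraries (summed log-loss against
$\tfrac12\lVert\beta\rVert^2/C$), mapped onto glmnet's per-observation
objective as ridge with $\lambda = 1/(nC)$ and an unpenalised intercept.
Before fitting, interacting residues are randomly oversampled with
replacement to the negative count (class balance), deterministically under
the run seed, on training folds only — oversampling before the
cross-validation split would leak held-out residues into training.

Two ablations bound the integrator: `cm_only` drops the trailing ipHMM
slot (what does the contact matrix alone achieve?), and `ground_truth_cm`
substitutes the true contact matrix (what would a perfect contact
prediction achieve?). The fitted weight of the last slot, exposed via
`tidy()`, is the standard diagnostic of how much the integrated model
leans on the ipHMM call.

## Evaluation protocol

Evaluation is leave-one-out over the sequence pairs of each family: for
each held-out pair, both ipHMMs are rebuilt without its two alignment rows,
the contact SVM is trained on the remaining pairs, and the site models are
trained on the remaining pairs' residues using each training pair's own
out-of-fold predictions as features (every pair's predicted contact matrix
and site scores come from the fold that held *it* out, mirroring the
two-phase reserve-then-integrate flow). No information from the held-out
pair enters any model applied to it. A k-fold protocol (`cv = "tenfold"`)
is available behind a flag; it errors when folds exceed pairs.

Metrics are accuracy, precision, recall, F1 and Matthews correlation
coefficient (MCC), computed per sequence over its non-deleted match
columns and macro-averaged over all sequences of all families ("average of
results for all the sequences"; per-family averaging is also reported).
Ratios with zero denominators are reported as `NA` and excluded from
means with an exclusion count — never silently zero. Method comparisons
use classical two-sided paired t-tests on per-sequence MCC; zero-variance
differences are reported as degenerate rather than raising.

Ground-truth site labels are derived from the ground-truth contact
matrices (a residue is an interaction site iff its matrix row/column has a
contact): the contact matrices play the role of the structural truth,
while the alignment's label track — which may be noisy — is used only to
train the ipHMMs. This separation matters for the synthetic benchmark
below.

## The synthetic family generator

No curated DDI data ships with the package; `sample_family()` generates
families with known ground truth so that every stage is trainable and
testable offline. The generator emulates the structural features the
pipeline relies on, with these choices:

- **Column emissions.** Every column has a support-2 background
  distribution (a consensus amino acid with mass 0.96–0.99 and one
  alternative). Interface columns additionally have an interacting
  distribution $e_i = (1-w)\,b + w\,d$ with $w = 1 - e^{-\kappa}$, where
  $d$ is an independent support-2 distribution avoiding the background
  consensus and $\kappa$ is `emission_sharpness` (default 6, i.e. nearly
  pure $d$). At $\kappa = 0$ interface residues are emission-indistinguishable
  from background. The strong conservation is a deliberate idealisation:
  it keeps multinomial estimation error at the benchmark's family sizes
  below the package's parameter-recovery tolerance (total variation 0.05
  per column at 200 members), so recovery failures indicate bugs rather
  than sampling noise.
- **Interface topology.** Each domain designates `frac_interface`
  (default 0.45) of its columns as interface; a shared bipartite topology
  connects interface columns with density `contact_density` (default 0.9),
  every interface column keeping at least one edge. The dense, compact
  patch mirrors real interfaces and makes contacts approximately
  "both residues active" — a structure the default near-linear SVM
  ($\gamma = 1/414$, $C = 1$) can learn; sparse random topologies are
  XOR-like in the residue features and defeat any low-capacity kernel.
- **Per-pair variation.** Each pair drops every topology edge independently
  with `pair_dropout` (default 0.15); a residue's ground-truth label is
  "has a contact in this pair's matrix". Deletions (rate `indel_rate`,
  default 0.02) remove residues and zero their contacts; insertions come
  from a flat background.
- **Annotation noise.** The alignment's emitted labels flip with
  probability `label_noise` (default 0.3) relative to the ground truth.
  This models inconsistent interface annotations projected through a
  family alignment and creates the regime the integrator is designed for:
  the ipHMM trains on the noisy labels, while the contact stages train on
  the clean structural matrices. With noiseless labels the ipHMM baseline
  is already near-perfect on synthetic families and no integration could
  be demonstrated.
- **Scale.** Defaults are desk-scale: domains of 12 + 15 match columns and
  10–16 members (14 by default; the benchmark suite jitters 10–14),
  far below the 150-residue cap the containers enforce. The full pipeline
  on the 10-family benchmark completes in minutes on one CPU.

`benchmark_suite()` draws families with jittered lengths, member counts,
interface fractions and sharpness on a fixed seed stream. On this
benchmark the mean-MCC ordering `ground_truth_cm ≥ cm_iphmm ≥
max(cm_only, iphmm)` holds, `ground_truth_cm` exceeds 0.95 (near-perfect
site recovery given a perfect matrix), and the cm_iphmm-vs-iphmm paired
t-test has a positive mean difference — the qualitative structure the
integrated method is designed to show.

What the generator does **not** emulate: real amino-acid composition and
substitution structure, phylogenetic correlation between family members,
structural contact geometry, and domain lengths typical of real families.
A passing benchmark therefore demonstrates the correctness and internal
consistency of the pipeline in its favourable regime, not expected
performance on curated DDI data.

## Numerical choices and degenerate inputs

- Forward–backward runs entirely in log space (`logsumexp`); forward and
  backward totals agree to 1e-8 relative, per-residue posterior sums to
  1e-6, Fisher sums to 1e-6, model stochasticity to 1e-9.
- The sharpness-0 isolation experiment uses high `pair_dropout` (0.5) and
  a sparse topology so that per-pair truth varies: the ipHMM's MCC drops
  substantially while `ground_truth_cm` stays near 1, isolating the
  contact-matrix information channel. The ipHMM cannot be driven fully to
  0 in this design: transition priors retain column-level signal.
- An alignment row whose gap/insert pattern implies the disallowed D→I
  arc contributes emission counts but no count for that arc (the generator
  never emits such rows).
- glmnet requires two or more predictors; one-feature designs are padded
  with a zero column whose ridge coefficient is exactly zero, and a design
  in which every feature is constant (e.g. an all-zero predicted contact
  matrix under `cm_only`) falls back to the closed-form intercept-only
  fit. Logistic convergence uses tolerance 1e-10 with a 1e6-pass cap; a
  capped fit is flagged on the model and warned about.
- SVM decision values are oriented so positive always means contact,
  regardless of libsvm's internal class ordering.
- Ties at probability exactly 0.5 are non-interacting everywhere (the
  majority class); `predict_sites` treats a column as deleted when its
  posterior match mass is below 0.5 unless occupancy is supplied
  explicitly (the pipeline always supplies it from the alignment).
- Parameter recovery checks estimate with `pseudocount = 0.1`: add-one
  smoothing at 200 observations contributes ~0.04 total variation of pure
  bias, which would swamp the quantity being measured.

## Known limitations

- The contact stage's default SVM is effectively near-linear
  ($\gamma = 1/414$ on $[0,1]$ features); families whose contact pattern
  is not approximately additive in the two residues' activities will not
  be predicted well at the defaults (raise `gamma`/`cost` via
  configuration).
- Per-family models only: nothing is shared across families, so families
  with fewer than ~6 pairs give unstable contact SVMs.
- The two-phase protocol reserves each pair's out-of-fold predictions for
  reuse as training features in other folds; training pairs' features are
  therefore derived from models that saw each other (never the held-out
  pair). This mirrors the reserve-then-integrate flow and keeps the
  held-out guarantee, but is not a fully nested cross-validation.
- No hyperparameter search, no alternative classifiers, no HMMER file
  compatibility, and no structure-based contact definition: ground-truth
  contacts are inputs.
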