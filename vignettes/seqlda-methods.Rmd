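---
title: "Topic models for nucleotide sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic models for nucleotide sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqlda)
```

## The model

seqlda applies latent Dirichlet allocation (LDA) to nucleotide sequences by
treating k-mers as words and sequences (or positions in an alignment, or
pools of sequences) as documents. A corpus of $D$ samples over a vocabulary
of $V$ features is modelled as

$$
\theta_d \sim \mathrm{Dirichlet}(\alpha), \qquad
\phi_t \sim \mathrm{Dirichlet}(\eta), \qquad
w \mid d \sim \sum_{t=1}^{K} \theta_{dt}\,\phi_{tw},
$$

where $\theta_d$ is sample $d$'s membership over the $K$ topics and
$\phi_t$ is topic $t$'s distribution over the feature vocabulary. The
appeal for sequence analysis is threefold: samples get *partial*
memberships (a position near a 3' splice site can be part branch site,
part pyrimidine tract); topics are *interpretable* through their driving
k-mers; and the structure plot of memberships gives an immediate picture
of how signals distribute across samples.

### Featurizations

Three featurizations turn sequences into the count matrices the model
consumes:

* **bulk** — `count_bulk_kmers()`: every overlapping k-mer window,
  position-free. Suited to unaligned sequences of variable length.
* **positional** — `count_positional_kmers()`: features couple a k-mer
  with its start position relative to an alignment anchor, rendered
  `KMER_at_POS` (e.g. `CCAG_at_-4`). Suited to aligned windows around
  splice sites. Positions follow the 3' splice-site convention: the anchor
  sits just downstream of the intron, so the terminal AG occupies
  positions $-2/-1$.
* **frame** — `count_frame_kmers()`: the k-mer starting at 0-based offset
  $i$ of a coding sequence is tagged with reading frame $(i \bmod 3) + 1$,
  giving three samples per sequence. Frame numbering is anchored at the
  annotated CDS start, matching the convention that the k-mer starting at
  the first base belongs to frame 1.

`build_position_sample_matrix()` implements the positions-as-samples view:
sample $p$ aggregates the k-mers starting at positions $[p, p+\mathrm{window})$
across all sequences. Rows are labelled by the *window start* (the most
upstream position in the window); the alternative, centre labelling, only
relabels the axis and we prefer start labelling because it keeps the row
index equal to the first k-mer position actually counted.

Throughout the package, any k-mer window containing a non-ACGT base is
skipped entirely — it contributes to neither numerator nor denominator of
any count, fraction or likelihood. This is our own rule for ambiguous
bases (there is no canonical one); it has the property that N's reduce
the effective number of observations rather than distorting frequencies.

### Pooling

Single sequences have zero counts for most features, especially with
positional vocabularies (a 4-mer vocabulary over an 80 nt window has
20 480 features against at most 77 tokens per sequence). `pool_samples()`
groups `pack` same-label sequences into one sample by summing counts:
within each label, samples are shuffled with the given seed, grouped into
consecutive packs, and an incomplete final pack is dropped so every
output sample aggregates exactly `pack` inputs (keeping per-sample token
totals comparable). A rule of thumb that holds up in the frame
experiments below: aim for a mean count per feature above about 0.5 per
sample.

## Inference

`seqlda()` fits the model by batch variational Bayes with fixed-point
updates — the same family of algorithm used by mainstream LDA
implementations (e.g. scikit-learn's batch mode, against which the test
suite cross-checks a small fit). The variational posterior factorizes as
$q(\theta_d) = \mathrm{Dir}(\gamma_d)$ and $q(\phi_t) = \mathrm{Dir}(\lambda_t)$;
the E-step iterates the per-document updates to convergence under fixed
topics, the M-step updates $\lambda$, and the evidence lower bound (ELBO)
is recorded each iteration. Numerical choices:

* **Priors** default to the symmetric $\alpha = \eta = 1/K$, the common
  default of batch variational implementations; both are overridable.
* **Initialization and restarts**: $\lambda \sim \mathrm{Gamma}(100, 100)$
  elementwise, seeded. Batch VB occasionally lands in a degenerate local
  optimum in which one topic goes unused (we observe this in roughly one
  in ten initializations on the frame task, where it is clearly visible
  as a much worse final bound), so `seqlda()` runs `n_init = 3` restarts
  with seeds derived from `seed` and keeps the fit with the best final
  ELBO. Fitting remains fully deterministic given `seed`, and identical
  seeds reproduce serialized models bit-for-bit.
* **Convergence**: stop when the relative ELBO change drops below
  `tol` (default $10^{-3}$) or after `max_iter` (default 100) iterations.
  Per-document updates stop at a mean relative change of $10^{-4}$ in
  $\gamma$ (at most 100 inner iterations), which keeps the recorded ELBO
  monotone to well within $10^{-5}$ relative tolerance.
* **Topic identity**: LDA topics are exchangeable, so after fitting the
  topics are re-ordered by descending token-weighted corpus usage. This
  gives stable identities across runs without changing the model.
* **Degenerate inputs**: an all-zero matrix is an error; $K$ larger than
  the sample count is a warning; an all-zero *sample* transforms to the
  uniform membership $1/K$ (the prior mean).

`predict()` (the transform step) runs document-side inference with topics
fixed at $\log \phi$. Features missing from the input are treated as zero
counts, but features *unknown to the model* are an error: positional
vocabularies are huge, and silently dropping columns is the likeliest way
to misalign two featurizations without noticing.

Models serialize to a single JSON document (`write_seqlda()`) holding the
priors, feature ids, $\phi$ and fit metadata, written with 17 significant
digits so that write–read–write round-trips are bit-identical.

## Interpreting topics: driving k-mers

Raw per-topic probabilities are a poor guide to what distinguishes a
topic, because high-probability k-mers are often shared. Instead each
feature's occurrence under a topic is treated as a Bernoulli variable and
compared across topics with the Kullback–Leibler divergence
(`bernoulli_kl()`, natural log, so distinctiveness is reported in nats):

$$
d(t, w) = \min_{t' \neq t} \mathrm{KL}\!\left(\phi_{tw} \,\|\, \phi_{t'w}\right).
$$

The minimum over other topics is the conservative aggregation — a feature
is only as distinctive as its closest competitor. Each feature is
assigned to the topic maximizing $d(t, w)$, and each topic reports its
assigned features ranked by distinctiveness (`driving_features()`), with
exact ties broken by lexicographic feature id. Probabilities are clamped
at $10^{-12}$ before the logs; $\eta > 0$ already guarantees positivity,
so the clamp only guards round-off in deserialized models.

## Scoring and classification

Two scores connect topics back to sequences:

* `sequence_log_likelihood()` sums $\log \phi_{t,w}$ over **all**
  overlapping windows of a sequence. When the window product is written
  with an upper index of $\mathrm{length} - k$ it misses the final
  window; we treat that as an off-by-one and use all
  $\mathrm{length} - k + 1$ windows, which also makes the log-likelihood
  agree with the brute-force product the tests check against. The value
  is returned in log space only — exponentiating underflows for realistic
  lengths.
* `position_log_likelihood()` is the multinomial log-likelihood
  $\sum_w n_w \log \phi_{tw}$ of a count vector, up to the count-only
  combinatorial constant, which is topic-independent and therefore
  irrelevant to comparisons across topics.

The subtype classifier is deliberately simple. `topic_label_scores()`
associates topics with labels:

$$
\mathrm{Score}(t \mid \ell) = \log_2
\frac{\tfrac{1}{N_\ell}\sum_{d \in \ell} \theta_{dt}}
     {\tfrac{1}{M}\sum_{d} \theta_{dt}},
$$

the log2 enrichment of topic $t$'s average membership in label $\ell$'s
$N_\ell$ samples over its average across all $M$ samples. Prediction
(`predict_label()`) multiplies a membership vector by this matrix and
takes the argmax, with exact ties going to the alphabetically first label.

### Reading frames and frame shifts

`classify_reading_frames()` applies this machinery to the three
frame-tagged count vectors of a CDS, predicting a frame label for each.
A sequence counts as correct only when the triple is $(1,2,3)$ — a much
stricter criterion than any single binary call — and the cyclic triples
$(2,3,1)$ and $(3,1,2)$ are flagged as potential frame shifts, since
deleting one or two leading bases rotates the frame tags exactly this
way. No bespoke frame model exists: the frame classifier is the generic
two-step classifier with labels `frame1..frame3`.

`centered_subsequence()` supports the question of how much sequence the
classifier needs: it cuts $3 n_\mathrm{codons}$ bases around the CDS
midpoint, snapping the start down to a codon boundary so the
subsequence's frame 1 equals the parent's.

### smORFs

`find_smorfs()` scans the three sense-strand frames of a UTR or lncRNA
for ATG–stop pairs with at least 25 codons strictly between them (the
threshold is a parameter; "between" is read literally as excluding both
the start and the stop codon). For each stop, the default pairs it with
the most upstream in-frame ATG after the previous in-frame stop — the
longest-ORF rule; since the enumeration policy is genuinely
underdetermined, `all_starts = TRUE` emits every qualifying ATG instead.
Only ATG starts and TAA/TAG/TGA stops are considered and only the sense
strand is scanned, since the inputs are transcripts. A smORF is called
coding-like (`score_smorf_coding()`) exactly when a CDS-trained
classifier predicts all three of its frames correctly.

## Motif signal curves

`motif_fraction_curve()` provides the model-free baseline the topic
curves are compared against: at each window position the fraction of
k-mers containing an IUPAC pattern (containment semantics — the pattern
may sit at any offset inside the k-mer), then that fraction divided by
$\mathrm{window} \times k$. The second step changes units in a way that
is hard to motivate — it makes curves with different window/k
incomparable on the raw scale — so the package reports *both* the raw
fraction and the normalized value. The branch-site consensus is written
variously (TNAC, CTNA/CUNA in RNA form, CTRAY); the pattern is therefore
always an explicit argument, with TNAC as the documented human default
and TAAC for Drosophila.

## The synthetic generators, and what passing tests show

Every stage is testable offline through three generators whose defaults
define the package's study conditions:

* `simulate_topic_corpus()` draws from the LDA generative process itself
  (topic rows from Dirichlet(0.1): sparse, well-separated topics;
  memberships from Dirichlet(0.5): mixed but not degenerate). It is the
  oracle for parameter recovery: at $K=3$, $V=256$, 200 samples of 2000
  tokens, fitted topics match the truth to within total-variation
  distance 0.1 per topic.
* `simulate_anchored_introns()` emulates the region upstream of a 3'
  splice site: i.i.d. background, a branch-site motif (default TNAC,
  IUPAC instantiated per sequence) planted at a fixed offset with given
  probability, a C/T-rich tract, and a terminal AG. The acceptance
  conditions plant TNAC at $-30$ with probability 0.7 and a pyrimidine
  tract over $[-20, -6)$ — roughly the geometry of real human introns.
* `simulate_cds()` generates ATG…stop ORFs with i.i.d. internal codons
  from a Zipf-skewed table over the 61 sense codons ($1/\mathrm{rank}$ in
  lexicographic order). Natural codon bias is weaker; the skew is chosen
  so that frame signal exists at desk scale (thousands, not hundreds of
  thousands, of sequences).

What the generators do **not** emulate: positional dependence between
codons, splice-site core signals beyond the terminal AG, repeat
structure, GC heterogeneity, and the long-tailed length distributions of
real introns and CDS. Passing the pipeline tests therefore demonstrates
that the algorithms are implemented correctly and recover planted
structure; it does not by itself establish the classification accuracies
achievable on real genomes, which depend on genome-scale training sets
and true codon bias.

### Problem sizes used in the checks

The test suite and the acceptance script run: parameter recovery at
$200 \times 256$ with 2000 tokens per sample; the frame task with 3000
training and 500 held-out CDS of 100–300 codons, hexamer features, packs
of 50, $K = 3$ (the held-out all-three-frames accuracy criterion is
0.95); a pooling sweep over packs $\{1, 5, 25\}$ and three seeds; and
motif recovery on 500 introns of 120 nt. These sizes were chosen so the
whole suite runs comfortably on a laptop while leaving every effect it
measures far from the noise floor.

### Measurement geometry for the planted motif

The motif-recovery check reads its curves with `window = 1` so the curve
is indexed by k-mer start position: a 6-mer contains a TNAC planted at
$-30$ iff it starts at $-32 \ldots -30$, so the peak must land within
that span. With a wider sliding window the curve is indexed by *window*
start, which sits up to $\mathrm{window}-1$ positions further upstream —
that would measure window placement rather than motif placement. The
position-sample LDA check uses `window = 3`, for which the same geometry
puts the unique count-maximizing window start at $-32$.

## Known limitations

* Batch VB only; corpora must fit in memory (the E-step is sparse, so
  the practical limit is the nonzero count, not $D \times V$).
* The ELBO is an approximate bound evaluated per iteration; with capped
  inner iterations it is monotone only to within a small relative
  tolerance.
* Topic *number* selection is out of scope; excess topics show up as
  unused or uniform topics in the structure plot.
* Driving k-mers are reported as k-mers; assembling them into a
  consensus or PWM is left to the analyst (`pwm_from_sequences()` gives
  the logo-ready frequencies for any anchored region).
* No reverse-complement handling anywhere: inputs are transcripts or
  anchored genomic windows on the sense strand.

## A minimal end-to-end example

```{r example, eval = FALSE}
train <- simulate_cds(1000, c(100, 300), seed = 1)
clf <- fit_frame_classifier(train, k = 6, pack = 50, seed = 1)
test <- simulate_cds(200, c(100, 300), seed = 2, prefix = "t")
pred <- predict(clf, test)
mean(pred$all_correct)

introns <- simulate_anchored_introns(
  400, 120,
  classes = list(intron = list(branch_offset = -30, branch_prob = 0.7,
                               pyrimidine_region = c(-20, -6))),
  seed = 3)
m <- build_position_sample_matrix(introns, k = 6, window = 3,
                                  positions = c(-100, -12))
fit <- seqlda(m, n_topics = 4, seed = 3)
summary(fit)
driving_features(fit, top_n = 5)
```
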