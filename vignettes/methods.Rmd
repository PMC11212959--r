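---
title: "Models and methods behind synreco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synreco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synreco)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical and design choices that were genuinely
open, and what the synthetic-data tests do and do not establish about real
data.

## The scientific setting

Experiments on the syntax-dependence of sentence comprehension manipulate
word order and lexical content to tease apart two quantities that normally
covary: a string's *local combinability* — whether nearby words could enter
a semantic dependency, given prior linguistic experience — and its
*incremental parsability* — whether a syntactic structure can be recovered
word by word. The package provides the full computational tool chain for
such studies: the condition generators, the two string-level measures, an
incremental-reordering behavioral paradigm with its analyses, the
counterbalanced experiment design, and functional-ROI statistics for the
imaging side.

## Windowed PPMI: the combinability measure

For a string $w_1 \dots w_n$, all index pairs with $1 \le j - i \le 3$ (the
pairs a sliding four-word window collects: bigrams, 1-skip-grams,
2-skip-grams) are scored

$$\mathrm{PPMI}(w_i, w_j) \;=\; \max\!\Big(0,\; \log \frac{\hat P(w_i, w_j)}
{\hat P(w_i)\,\hat P(w_j)}\Big)$$

and averaged into one score per string. Negative PMI values are clipped:
a negative association is read as "no dependency worth building", and
letting strongly negative pairs cancel positive ones would conflate absence
of association with anti-association.

**Smoothing.** Probabilities are Laplace-smoothed with $\alpha = 0.1$:
$\hat P(w) = (c(w) + \alpha) / (N_1 + \alpha V)$ and
$\hat P(w_i, w_j) = (c(w_i, w_j) + \alpha) / (N_2 + \alpha V^2)$, with $V$
the vocabulary size and $N_1, N_2$ the unigram and pair masses. The
event-space sizes in the denominators ($V$ and $V^2$) are this package's
choice — smoothing conventions differ across implementations — and are the
natural maximum-entropy completion of the count tables. Pairs are unordered
(symmetric PMI); an ordered-pair mode is available for directional variants
but requires a table whose counts were tallied ordered.

**Normalization.** The default divides the summed clipped scores by the
actual number of window pairs, $3n - 6$ for $n \ge 4$, which makes the
score a mean over pairs. A `"printed"` mode divides by the constant
$3n - 2$ instead, reproducing a normalization that appears in the
literature for this statistic; the two modes differ by a constant factor
per length and never change rank orders within a fixed $n$. Both are kept
because neither resolves the other: one is the arithmetic mean, the other
is the published constant.

**Reversal invariance.** The window pair set depends only on unordered
index distance, so reversing a string maps the pair set onto itself and the
score is *exactly* invariant (not approximately — the acceptance suite
checks equality at machine precision over 1,000 sampled sentences). This is
the computational content of using full reversal as a condition that
preserves combinability while destroying word-order cues.

## PCFG prefix probabilities: the parsability measure

Per-word surprisal is $-\log P(w_i \mid w_1 \dots w_{i-1})$, the log ratio
of consecutive *prefix probabilities* $P(w_1 \dots w_m \text{ begins a
sentence})$. Prefix probabilities are computed exactly by a chart
algorithm: the grammar is converted internally to Chomsky normal form
(terminal lifting, binarization, unit-rule elimination by matrix closure),
ordinary inside probabilities give the mass of derivations whose yield *is*
a span, and a left-corner closure matrix $R = (I - Q)^{-1}$ (with
$Q[A,B] = \sum_C p(A \to B\,C)$) resolves the recursion for derivations
whose yield *begins with* a span. Unit chains and left recursion are
handled exactly by the two closures rather than by iteration cutoffs.

The algorithmic subtlety worth recording: in the prefix recurrence, the
"left child covers an exact sub-span, prefix continues in the right child"
term already contains all derivations whose complete yield equals the span
(via the right child's own prefix mass), so adding the full inside mass of
the span would double-count; only the single-token lexical base enters the
recurrence directly. The test suite pins this down by comparing every
prefix of every sentence of every fixture grammar against an independent
oracle that exhaustively enumerates the grammar's language and sums the
probabilities of matching sentences; agreement is required at $10^{-9}$
(observed: $\sim 10^{-17}$).

**Smoothing toward broad coverage.** A bare toy grammar assigns probability
zero to out-of-grammar word orders, so their surprisal is undefined or
infinite — unlike the trained broad-coverage parsers used on real stimuli,
which assign finite surprisal to anything. The scorer therefore accepts an
interpolation weight $\lambda$: $P = (1-\lambda) P_{\text{grammar}} +
\lambda / V$ per conditional, bounding surprisal by $\log(V/\lambda)$.
Defaults: $\lambda = 0$ (exact; used by every oracle and chain-identity
test), $\lambda = 0.01$ in the reconstruction analyses. Natural log is the
internal base; base 2 is available where bits are wanted. External per-word
surprisals (from any LM or parser the user runs) enter through a TSV
backend that validates token alignment and is interchangeable with the
grammar backend downstream.

## Stimulus conditions

*Local scrambles.* `scramble_local(s, k, seed)` samples `k` positions
without replacement and swaps each, in sampled order on the evolving
string, with a uniformly chosen existing immediate neighbor. This is one
concrete reading of "iteratively and randomly choosing k words and swapping
them with a neighbor"; the published description does not fix edge
behavior, whether a word can be displaced twice, or whether swaps may
cancel, so: edge words swap with their only neighbor, later swaps act on
the evolving string, and cancellation is permitted and logged in
provenance. Every output is reachable by exactly `k` adjacent
transpositions (brute-force verified for small lengths).

*Low-combinability scramble.* Only the goal is published — move
originally-proximal content words far apart — so the algorithm is this
package's: the objective counts content-word pairs within window distance
(3) in *both* the original and the permuted string; it is minimized
exhaustively for sentences of up to 8 words and by seeded hill-climbing
with random restarts above that, with the identity permutation always a
candidate (so the returned objective never exceeds the identity's).
Function words are permuted too — whether the original materials moved
them is unstated; permuting the whole string is the simpler and documented
choice. PPMI itself is not the optimization target (it is corpus-dependent);
the window-overlap objective is the corpus-free core of the stated goal,
and the PPMI drop falls out of it (verified as a property).

*Nonsense substitution.* Content words are replaced by words sharing a full
feature key (POS, dependency label, sorted morphological features, verb
valence, noun onset class) drawn from a replacement dictionary built over
the corpus *with duplicates*, so sampling reflects token frequency. Noun
onset (vowel vs. consonant first letter) is an orthographic proxy for the
phonological onset. Where a key has no candidate, matching relaxes in a
fixed order — drop the dependency label, then onset, then morphology
(keeping POS and valence), finally bare POS — erroring only when POS-level
matching fails. This automated ladder replaces the hand-curation a human
experimenter would apply. Self-replacement is allowed (nothing excludes
it), and the degenerate case is well-defined: a single-candidate key
reproduces the original word.

*Jabberwocky substitution.* The nonword generator preserves word length,
the consonant/vowel skeleton, and any detected inflectional suffix (-s,
-ed, -ing, -er, -est), and rejects candidates found in a real-word
blocklist. It deliberately does not model syllable-transition frequencies
— that is the published pseudoword tool's contribution, and this simpler
generator preserves exactly the properties the analyses depend on
(function-word positions, length, functional morphology).

*Lists.* `recombine_lists` redistributes the pooled tokens of a stimulus
set by sampling without replacement; the pooled multiset is conserved
exactly and the pool size must match `n_seqs × seq_len`.

All generators draw from one explicit integer seed per call through a local
RNG stream (the session RNG is saved and restored), so a fixed seed gives
bit-identical outputs and no call perturbs another's stream.

## The reordering paradigm and its analyses

A trial is a pure state machine: `reveal_next` appends the next stimulus
word to the last submitted order; `apply_reorder` replaces the display with
a permutation of the revealed multiset and records the submission with its
step. Duplicate words are handled by multiset identity. Permissible-order
sets are item *data* (authored or simulation-derived), never inferred from
a grammar — matching the practice of validating allowed orders with human
raters. Logs serialize as JSON-lines event streams and are replayed through
the state machine on reading, so malformed logs fail loudly.

The analyses consume only final submitted orders (intermediate submissions
are stored but not analyzed — the published analyses are stated for finals
only): verbatim accuracy (exact match with the original order, averaged by
condition) and reconstruction grammaticality (mean surprisal of finals,
against the unreconstructed stimulus baseline). Inclusion filters: at least
4 of 7 attention checks *and* at least 6 of 12 remaining fillers; rater QC:
full use of the 1–5 scale, mean Sentence grammaticality ≥ 3, mean WordList
grammaticality ≤ 3 (boundary values included, per "at least"/"lower
than"/"higher than").

**The simulated participant** is deliberately minimal: at each reveal, with
probability $\text{skill}^{d}$ (one Bernoulli per step, $d$ = number of
displaced words), the display is restored to the original relative order of
the revealed words; otherwise it is left untouched. This is the weakest
model with the needed limiting behavior — skill 1 yields verbatim
reconstruction everywhere, skill 0 reproduces the stimulus orders exactly,
and accuracy is monotone in skill. Default per-condition skills (0.95,
0.9, 0.8, 0.7, 0.6 for Intact and Scrambled 1–7; 0.1 and 0.05 for the
low-combinability scramble and reversal) encode the one assumption the
paradigm is about — repair gets harder with displacement severity, and
collapses when local order cues are gone — at values chosen once to give
clearly separated but non-degenerate accuracies at the study's scale.
Working-memory limits, incremental garden-pathing, and individual
differences are intentionally out of scope.

## Experiment design

Latin-square lists rotate items through conditions so each list holds every
item exactly once and each (item, condition) pair appears on exactly one
list. Runs are built by splitting a list into equal per-condition subsets,
grouping same-condition triples into 18 s blocks, ordering blocks with a
seeded permutation under the constraint that a condition's two blocks are
never adjacent (block order within runs is not published; the non-adjacency
constraint avoids accidental 36 s same-condition stretches), and
interleaving five 12 s fixation blocks — one at run start, one after every
four experimental blocks, a symmetric placement the source design leaves
unstated. The 6 s trial timeline (12 × 350 ms words, 300 ms blank, 1,000 ms
probe, 500 ms blank) and the 348 s run duration are recomputed from event
timelines, never from closed-form totals. Memory probes match the final
token on exactly half of each condition's trials; mismatch probes are final
tokens of same-condition stimuli from a different block of the *same run*
(the scope of "different block" is ambiguous in the source; same-run is the
most conservative reading that keeps probe statistics homogeneous).

## fROI statistics

Within a mask, the top $\lceil 0.10 \times \text{mask size}\rceil$ voxels
by localizer statistic are selected (only "10%" is published; the ceiling
rule guarantees a non-empty fROI for any mask and ties break
deterministically by voxel id). Condition responses are voxel means over
the selection. The lateralization index is $(LH - RH)/(LH + RH)$ over
significant-voxel counts, right-lateralized at $\le -0.25$; the
significance cutoff on the statistic is a parameter, matching the
fixed-threshold policy such analyses use. Model tables are long-format
(participant × ROI × condition) with dummy coding against a reference
condition (all-zero rows for the reference); mixed-model fitting is
specification-plus-delegation — the package owns the table and coding, the
user's solver (e.g. lme4) owns REML, and recovery tests use ordinary least
squares on the fixed part, which is unbiased for the planted effects under
the simulated noise.

## What the synthetic data does and does not show

The toy world (36-word lexicon, non-recursive grammar with 4–15-word
sentences, grammar-sampled co-occurrence tables, skill-model participants,
Gaussian voxel maps) is built so that every analysis runs end to end with
the statistical structure it assumes: grammar-sampled strings have higher
windowed PPMI than independent word draws, low-combinability scrambles
score below their bases, simulated reconstruction separates locally
scrambled from reversed conditions, and planted voxel contrasts are
recoverable at realistic noise (sign recovery ≥ 95% over replicates at
noise sd 1, signal fraction 0.2, 500-voxel masks). Problem sizes in the
tests mirror the study scales — 35 and 192 items, 72 included participants,
100 voxel-map replicates — which the machinery handles in seconds.

Passing these tests shows the *pipeline* is correct and the *signatures*
are recoverable under the generating assumptions. It does not show that
real corpora have the toy grammar's statistics, that human repair behavior
follows the skill model, or that real BOLD noise is Gaussian and
independent; numeric replication of any published estimate is therefore
not claimed anywhere in the package — the published magnitudes depend on
unreleased participant and scanner data.

## Known limitations

- The PPMI table treats pairs as unordered; the directional mode is an
  inference, not a published definition.
- The chart algorithms require a proper PCFG (per-LHS probabilities summing
  to 1, no epsilon rules); improper or leaky grammars are rejected rather
  than renormalized.
- `enumerate_language` (the oracle) is exponential and intended only for
  fixture-scale grammars; it aborts beyond configurable sentence-count and
  length bounds.
- The exhaustive branch of the low-combinability scramble is limited to
  8-word sentences; beyond that, hill-climbing offers no optimality
  guarantee (only the never-worse-than-identity bound).
- The annotation backend is a lexicon lookup; words with context-dependent
  POS or dependency labels need an external tagger's table, and
  disagreements between annotation sources are the user's to resolve.
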