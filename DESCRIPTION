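Package: synreco
Title: Stimulus Construction, Combinability Scoring, and Incremental
    Syntactic-Reconstruction Analyses for Language Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analyzing word-order manipulation
    experiments on sentence processing. Generates stimulus conditions from
    annotated base sentences (local scrambles, low-combinability scrambles,
    backward reversal, feature-matched nonsense substitution, jabberwocky
    nonword substitution, and word/nonword list recombination); scores local
    word combinability with sliding-window positive pointwise mutual
    information under Laplace smoothing; computes incremental word surprisal
    from probabilistic context-free grammars via chart-based prefix
    probabilities; simulates and analyzes the SynReco incremental
    word-reordering paradigm (verbatim reconstruction accuracy,
    reconstruction grammaticality, participant and rater inclusion filters);
    constructs Latin-square counterbalanced lists, blocked run schedules and
    memory-probe assignments; and performs functional-ROI voxel selection,
    condition-response extraction, lateralization indexing and dummy-coded
    model-table construction. A synthetic-data module (toy lexicon, toy
    grammar, simulated participants, simulated voxel maps) provides a
    self-contained test surface for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
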