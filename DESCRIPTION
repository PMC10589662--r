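Package: semtraj
Title: Semantic Trajectory Analysis of Verbal Fluency Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies semantically and orthographically guided word sampling
    in timed verbal fluency tasks ("name animals", "name words starting with
    p"). Word lists are treated as trajectories through a word-embedding
    space: the package computes global and local path-optimality divergence
    against shortest Hamiltonian paths with participant-specific permutation
    nulls, semantic-community trajectory statistics (Louvain partition,
    community lifetimes and returns, retrieval-time regression), and fits a
    family of generative softmax local-search choice models by maximum
    likelihood with AIC model comparison, yielding the goal-induced semantic
    modulation index (delta-omega). A synthetic-cohort generator with known
    ground truth and a group-level statistical reporting layer support
    end-to-end validation by parameter, model and effect-direction recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
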