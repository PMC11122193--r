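# seeded random normalized patch in [0, 1]
random_patch <- function(p, seed) {
  normalize_minmax(synth_image("random", p, p, seed = seed))
}

# all (size, graph type) cases used by the property tests
graph_cases <- expand.grid(
  p = 2:8,
  type = c("grid2d", "pairwise", "knn"),
  stringsAsFactors = FALSE
)

build_case_graph <- function(patch, type) {
  build_patch_graph(patch, type, k = min(nrow(patch), length(patch) - 1L))
}
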