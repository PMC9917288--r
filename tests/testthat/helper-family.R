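# The default synthetic family pipeline is expensive (alignment + 200
# bootstrap replicates), so it is computed once and shared across test files.

.family_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (is.null(.family_cache$res)) {
    .family_cache$res <- run_pipeline(family_spec(), n_bootstrap = 200L)
  }
  .family_cache$res
}

small_spec <- function(seed = 11L) {
  family_spec(pattern_mix = c("1:1:1" = 2L, "1:2:1" = 1L),
              rcl_variants = c("LRS", "LES", "LRS"),
              lesions = list(), signal_peptides = rep(FALSE, 3L),
              archetypes = c("ubiquitous", "root", "grain"), seed = seed)
}
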