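# Memoised synthetic benchmarks shared by the acceptance tests (building
# the 26 x 10 sets once keeps the suite inside its time budget).

.bench_cache <- new.env(parent = emptyenv())

cached_benchmark_features <- function(difficulty, normalize = TRUE,
                                      n_species = 26L, n_per_species = 10L,
                                      seed = 20260911L) {
  key <- paste(difficulty, normalize, n_species, n_per_species, seed, sep = "_")
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  bkey <- paste("bench", difficulty, n_species, n_per_species, seed, sep = "_")
  if (is.null(.bench_cache[[bkey]]))
    .bench_cache[[bkey]] <- generate_benchmark(n_species, n_per_species,
                                               difficulty, seed = seed)
  bench <- .bench_cache[[bkey]]
  bf <- herbleaf:::benchmark_features(bench, normalize = normalize)
  bf$species_table <- bench$species_table
  .bench_cache[[key]] <- bf
  bf
}
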