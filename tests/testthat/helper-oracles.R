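# Independent oracles used across the suite.

# Monte-Carlo draw of the connectivity process on one virtual process:
# each of n_draws sources drawn uniformly with replacement from N neurons;
# returns per-neuron local target-list lengths for one realization.
mc_list_lengths <- function(N, n_draws) {
  tabulate(sample.int(N, n_draws, replace = TRUE), nbins = N)
}

# Brute-force smallest-offset layout honoring alignment and declaration
# order (the oracle for the sequential layout rule).
brute_layout_total <- function(sizes, aligns) {
  off <- 0
  for (i in seq_along(sizes)) {
    while (off %% aligns[i] != 0) off <- off + 1
    off <- off + sizes[i]
  }
  maxa <- max(aligns)
  while (off %% maxa != 0) off <- off + 1
  off
}

# Naive per-(source, syn_id) multimap against which the adaptive
# containers are compared.
multimap_new <- function() list()
multimap_add <- function(mm, source, record) {
  key <- as.character(source)
  mm[[key]] <- c(mm[[key]], list(record))
  mm
}
multimap_records <- function(mm, source) {
  recs <- mm[[as.character(source)]]
  if (is.null(recs)) list() else recs
}

# Canonical multiset signature of a record list for comparisons.
record_signature <- function(recs) {
  if (!length(recs)) return(character(0))
  sort(vapply(recs, function(r)
    paste(r$target, r$syn_id, r$delay_steps, signif(r$weight, 12), sep = "/"),
    character(1)))
}

# Linear-scan lookup oracle for the sparse node array.
scan_lookup <- function(gids, gid) {
  i <- match(gid, gids)
  list(found = !is.na(i), index = i)
}

expect_rel_equal <- function(actual, expected, rel) {
  expect_lt(abs(actual - expected), rel * abs(expected))
}
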