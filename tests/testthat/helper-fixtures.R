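# Shared fixtures, built in code and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Well-separated 3-component fixture (disjoint dominant-taxon blocks).
fixture_sep3 <- function(n = 150, n_taxa = 30, seed = 401) {
  memo(sprintf("sep3_%d_%d_%d", n, n_taxa, seed), function() {
    al <- separated_alpha_matrix(3, n_taxa, block_mass = 0.7)
    simulate_dmm_counts(al, c(0.4, 0.35, 0.25), n, c(2000, 5000), seed = seed)
  })
}

# Diversity-graded 3-component fixture: component Shannon decreases with
# the component index; the last block is the pathogen block.
fixture_graded3 <- function(n = 150, n_taxa = 30, seed = 402) {
  memo(sprintf("graded3_%d_%d_%d", n, n_taxa, seed), function() {
    al <- separated_alpha_matrix(3, n_taxa, block_mass = c(0.5, 0.7, 0.9))
    simulate_dmm_counts(al, c(0.4, 0.35, 0.25), n, c(2000, 5000), seed = seed)
  })
}

# A tiny deterministic count table for I/O and arithmetic tests.
tiny_table <- function() {
  m <- matrix(c(10L, 1L, 1L, 1L,
                5L,  5L, 0L, 2L,
                0L,  3L, 3L, 6L), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), paste0("t", 1:4)))
  count_table(m, "lung")
}

# Minimal metadata covering a table's samples.
meta_for <- function(table, soiled = TRUE) {
  data.frame(sample_id = rownames(table),
             subject_id = paste0("subj", seq_len(nrow(table))),
             compartment = compartment(table),
             interval = "baseline",
             soiled_flag = soiled)
}

# Plain (unadjusted) Rand index between two partitions.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  agree <- (same_a == same_b)
  (sum(agree) - n) / (n * (n - 1))
}
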