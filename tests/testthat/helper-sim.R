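# shared synthetic fixtures, built once per test run
.fixtures <- new.env()

base_sim <- function() {
  if (is.null(.fixtures$base))
    .fixtures$base <- sim_ancestral_genome(sim_config(seed = 42L))
  .fixtures$base
}

# map event ops to the classifier's status vocabulary
status_of_op <- c(shuffle = "shuffled", local_invert = "local_inversion",
                  translocate = "translocation",
                  remote_invert = "remote_inversion")

# rotate a mito_genome by `by` bp (annotations rotated accordingly)
rotate_genome <- function(g, by) {
  n <- g$length
  f <- g$features
  f$start <- (f$start - by) %% n
  f$end <- f$start + (g$features$end - g$features$start)
  mito_genome(g$id, mitocomp:::rotate_seq(g$sequence, by), f,
              circular = g$circular, completeness = g$completeness)
}

# reverse-complement a mito_genome with annotations flipped
revcomp_genome <- function(g) {
  n <- g$length
  f <- g$features
  len <- f$end - f$start
  new_start <- (n - f$end) %% n
  f$start <- new_start
  f$end <- new_start + len
  f$strand <- ifelse(f$strand == "+", "-", "+")
  mito_genome(g$id, revcomp(g$sequence), f, circular = g$circular,
              completeness = g$completeness)
}

random_codon_string <- function(n, exclude_stops = TRUE) {
  code <- mitocomp:::mito_code()
  sense <- names(code)[code != "*"]
  paste(sample(sense, n, replace = TRUE), collapse = "")
}
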