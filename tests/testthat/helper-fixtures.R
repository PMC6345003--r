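# Shared fixture builders; everything is generated in code.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

rand_aa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# A sequence differing from `base` at exactly `n_diff` positions (evenly
# spread), each changed to a different residue. Gives exact hand-countable
# identity under a gapless alignment.
mutated_at <- function(base, n_diff) {
  L <- nchar(base)
  pos <- unique(round(seq(1, L, length.out = n_diff)))
  stopifnot(length(pos) == n_diff)
  ch <- strsplit(base, "")[[1]]
  ch[pos] <- AA20[match(ch[pos], AA20) %% 20L + 1L]   # rotate the alphabet
  paste(ch, collapse = "")
}

small_sim_config <- function(seed = 11, ...) {
  defaults <- list(seed = seed, n_genera = 4L, strains_per_genus = 4L,
                   populations = c("US", "CN", "HZ"),
                   n_individuals_per_population = 3L,
                   coverage_per_gene = 20)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
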