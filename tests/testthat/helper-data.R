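# Small fixtures built in code.

# A compact two-chromosome map for fast scan tests.
small_map <- function() default_linkage_map(n_chrom = 2, n_markers = 6,
                                            spacing_cM = 10)

# One strong additive QTL on the small map.
small_scenario <- function(a = 3, d = 0, h2 = 0.6, n_env = 2) {
  qtl_scenario(data.frame(id = "Q1", chrom = 1L, pos_cM = 25,
                          a = a, d = d, stringsAsFactors = FALSE),
               n_env = n_env, h2 = h2)
}

small_data <- function(n1 = 60, n2 = 60, seed = 1, ...) {
  simulate_cross(small_scenario(...), small_map(), n1, n2, seed = seed)
}

# A pure-noise dataset on the small map (no QTL signal).
null_data <- function(n1 = 60, n2 = 60, seed = 1, n_env = 2) {
  sc <- qtl_scenario(data.frame(id = "Q1", chrom = 1L, pos_cM = 25,
                                a = 0, d = 0, stringsAsFactors = FALSE),
                     n_env = n_env, h2 = 0.5)
  map <- small_map()
  lines <- simulate_lines(map, n1 + n2, "DH",
                          qtl_positions = sc$qtl[, c("chrom", "pos_cM")],
                          seed = seed)
  prog <- simulate_double_backcross(lines, n1, n2, seed = seed + 1)
  simulate_phenotypes(prog, sc, seed = seed + 2, sigma2_eps = 1)
}
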