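# Shared fixtures and independent oracles, built in code.

# Simulate a 10-chromosome testcross population and call its crossovers.
sim_pop <- function(marey = "flat", nu = 1, n = 100, seed = 1,
                    n_chrom = 10, genetic_length = 1, physical_length = 30e6,
                    spacing = 1.5e6) {
  chroms <- lapply(seq_len(n_chrom), function(i)
    chromosome_model(sprintf("A%02d", i), physical_length, genetic_length,
                     marey = marey))
  cfg <- sim_config(chroms, n, nu = nu, seed = seed)
  sim <- simulate_population(cfg, simulation_marker_map(chroms, spacing))
  list(sim = sim,
       pop = suppressMessages(crossover_population(sim$genotypes, sim$map)))
}

# Independent high-precision KL oracle: terms accumulated with Kahan
# compensated summation over ascending magnitudes, coded without reference
# to the package's own kl_divergence().
kl_oracle <- function(p_counts, q_counts) {
  p <- p_counts / sum(p_counts)
  q <- q_counts / sum(q_counts)
  terms <- numeric(0)
  for (i in seq_along(p)) {
    if (p[i] > 0) {
      stopifnot(q[i] > 0)
      terms <- c(terms, p[i] * (log(p[i]) - log(q[i])))
    }
  }
  terms <- terms[order(abs(terms))]
  s <- 0; comp <- 0
  for (t in terms) {
    y <- t - comp
    tot <- s + y
    comp <- (tot - s) - y
    s <- tot
  }
  s
}

# A tiny hand-checkable map: two chromosomes, three markers each.
toy_map <- function() {
  marker_map(data.frame(
    marker = c("m1", "m2", "m3", "m4", "m5", "m6"),
    chrom = rep(c("c1", "c2"), each = 3),
    pos = c(0, 5e6, 10e6, 0, 4e6, 8e6)),
    chrom_lengths = c(c1 = 10e6, c2 = 8e6))
}

toy_genotypes <- function(rows) {
  g <- do.call(rbind, rows)
  rownames(g) <- sprintf("i%d", seq_len(nrow(g)))
  colnames(g) <- c("m1", "m2", "m3", "m4", "m5", "m6")
  g
}
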