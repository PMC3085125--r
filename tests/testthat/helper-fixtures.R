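# Small builders used across tests; all fixtures are constructed in code.

# Two populations, one locus: {a,a},(a,b)-style toy genotypes.
toy_microsats <- function() {
  microsat_dataset(
    ids = paste0("i", 1:8),
    populations = rep(c("A", "B"), each = 4L),
    genotypes = list(
      L1 = rbind(c(101L, 101L), c(101L, 103L), c(103L, 103L), c(101L, 101L),
                 c(105L, 105L), c(105L, 107L), c(107L, 107L), c(105L, 105L)),
      L2 = rbind(c(11L, 11L), c(11L, 12L), c(12L, 12L), c(11L, 12L),
                 c(11L, 11L), c(11L, 12L), c(12L, 12L), c(11L, 12L))))
}

# The haploid {a,a} | {b,b} toy with known exact permutation p = 1/3.
toy_haploid_2x2 <- function() {
  haploid_dataset(paste0("h", 1:4), c("A", "A", "B", "B"), c(1L, 1L, 2L, 2L))
}

# Two demes fixed for sequences differing at every site.
toy_alignment <- function() {
  seq_alignment(paste0("s", 1:4), rep(c("p1", "p2"), each = 2L),
                c("AAAA", "AAAA", "TTTT", "TTTT"))
}

# Table-1-style per-site microsatellite sample counts for the primary host.
host_sample_counts <- c(IL = 50L, MD = 2L, MI = 3L, NY = 50L, OH = 50L,
                        PA = 33L, VT = 32L, VA = 2L, WV = 50L)

# A dataset with one individual per colony count in `counts`, single locus.
dataset_from_counts <- function(counts) {
  pops <- rep(names(counts), counts)
  n <- length(pops)
  microsat_dataset(paste0("c", seq_len(n)), pops,
                   list(L1 = cbind(rep(101L, n), rep(103L, n))))
}

# Small island-model dataset for property tests.
sim_small <- function(seed, K = 3L, m = 0.05, mu = 0.01, n_loci = 3L,
                      model = "infinite_alleles", N_deme = 30L,
                      sample_n = 10L, burn_in = 600L) {
  p <- island_model_params(K = K, N_deme = N_deme, m = m, mu = mu,
                           marker_model = model, sample_n = sample_n,
                           burn_in = burn_in, seed = seed)
  simulate_microsats(p, n_loci)
}
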