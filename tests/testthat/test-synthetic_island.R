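test_that("island-model parameters are validated", {
  expect_error(island_model_params(K = 0, N_deme = 10, m = 0.1, mu = 0.01),
               "K must be")
  expect_error(island_model_params(K = 2, N_deme = 10, m = 1.5, mu = 0.01),
               "m must be")
  expect_error(island_model_params(K = 2, N_deme = 10, m = 0.1, mu = -1),
               "mu must be")
  expect_error(island_model_params(K = 2, N_deme = 10, m = 0.1, mu = 0.01,
                                   sample_n = 11),
               "sample_n")
  expect_error(island_model_params(K = 2, N_deme = 10, m = 0.1, mu = 0.01,
                                   marker_model = "finite_sites"),
               "L >= 1")
  p <- island_model_params(K = 3, N_deme = 20, m = 0.1, mu = 0.01)
  expect_equal(p$burn_in, 10L * 20L * 3L)
})

test_that("the generator is deterministic and satisfies dataset invariants", {
  p <- island_model_params(K = 3L, N_deme = 25L, m = 0.05, mu = 0.02,
                           marker_model = "stepwise", sample_n = 10L,
                           burn_in = 400L, seed = 101L)
  a <- simulate_microsats(p, 4L)
  b <- simulate_microsats(p, 4L)
  expect_identical(a, b)
  expect_s3_class(a, "microsat_dataset")  # constructor enforces invariants
  expect_equal(length(a$ids), 30L)
  expect_equal(sort(unique(a$populations)), paste0("pop", 1:3))
  expect_true(all(unlist(a$genotypes) > 0L))

  ps <- island_model_params(K = 2L, N_deme = 20L, m = 0.05, mu = 1e-4,
                            marker_model = "finite_sites", L = 200L,
                            sample_n = 6L, burn_in = 300L, seed = 55L)
  s1 <- simulate_sequences(ps)
  s2 <- simulate_sequences(ps)
  expect_identical(s1, s2)
  expect_equal(s1$length, 200L)
  expect_true(all(nchar(s1$seqs) == 200L))
})

test_that("zero mutation from a monomorphic start stays monomorphic", {
  p <- island_model_params(K = 2L, N_deme = 15L, m = 0.1, mu = 0,
                           marker_model = "stepwise", sample_n = 6L,
                           burn_in = 200L, seed = 1L)
  ms <- simulate_microsats(p, 2L)
  expect_true(all(unlist(ms$genotypes) == 1000L))
  row <- locus_differentiation(ms, "L1", "plain")
  expect_equal(row$D, 0)

  ps <- island_model_params(K = 2L, N_deme = 16L, m = 0.1, mu = 0,
                            marker_model = "finite_sites", L = 50L,
                            sample_n = 5L, burn_in = 100L, seed = 2L)
  al <- simulate_sequences(ps)
  expect_equal(length(unique(al$seqs)), 1L)
})

test_that("within-deme diversity rises with mutation rate", {
  mean_ne <- function(mu, marker = "infinite_alleles", seeds = 1:3) {
    mean(vapply(seeds, function(s) {
      ms <- sim_small(seed = 1000L + s, K = 2L, m = 0.1, mu = mu,
                      n_loci = 2L, model = marker, N_deme = 40L,
                      sample_n = 15L, burn_in = 800L)
      mean(diversity_summary(ms)$per$n_e)
    }, numeric(1L)))
  }
  ne <- vapply(c(0.0005, 0.005, 0.05), mean_ne, numeric(1L))
  expect_true(all(diff(ne) > 0))
})

test_that("within-deme nucleotide diversity rises with mutation rate", {
  mean_pi <- function(mu) {
    mean(vapply(1:6, function(s) {
      p <- island_model_params(K = 2L, N_deme = 60L, m = 0.05, mu = mu,
                               marker_model = "finite_sites", L = 1000L,
                               sample_n = 12L, burn_in = 1200L,
                               seed = 2000L + s)
      al <- simulate_sequences(p)
      mean(diversity_summary(al)$per$pi)
    }, numeric(1L)))
  }
  pis <- vapply(c(1e-6, 1e-5, 1e-4), mean_pi, numeric(1L))
  expect_true(all(diff(pis) > 0))
})

test_that("isolation drives sequence differentiation toward private haplotypes", {
  p <- island_model_params(K = 3L, N_deme = 30L, m = 0.0005, mu = 5e-5,
                           marker_model = "finite_sites", L = 600L,
                           sample_n = 10L, burn_in = 2000L, seed = 77L)
  al <- simulate_sequences(p)
  row <- sequence_differentiation(al, "plain")
  expect_gt(row$D, 0.8)
})

test_that("D decreases with migration rate", {
  mean_d <- function(m) {
    mean(vapply(1:4, function(s) {
      ms <- sim_small(seed = 300L + s, K = 4L, m = m, mu = 0.005,
                      n_loci = 3L, model = "infinite_alleles",
                      N_deme = 40L, sample_n = 15L, burn_in = 1200L)
      attr(differentiation_table(ms, "plain"), "mean_D")
    }, numeric(1L)))
  }
  d <- vapply(c(0.001, 0.01, 0.05, 0.2), mean_d, numeric(1L))
  expect_true(all(diff(d) < 0))
})

test_that("null-allele injection degrades heterozygotes as designed", {
  ms <- sim_small(seed = 12L, K = 2L, m = 0.1, mu = 0.05,
                  model = "infinite_alleles", N_deme = 50L,
                  sample_n = 40L, burn_in = 1000L, n_loci = 3L)
  # identity at zero
  expect_identical(inject_null_alleles(ms, 0, seed = 1L), ms)

  inj <- inject_null_alleles(ms, 0.5, seed = 9L)
  div0 <- diversity_summary(ms)$per
  div1 <- diversity_summary(inj)$per
  # observed heterozygosity drops well below the original
  expect_lt(mean(div1$H_o), mean(div0$H_o))
  # and below its own expectation (apparent heterozygote deficit)
  expect_lt(mean(div1$H_o), mean(div1$H_exp))
  # injection is deterministic under a seed
  inj2 <- inject_null_alleles(ms, 0.5, seed = 9L)
  expect_identical(inj, inj2)
})

test_that("species-shaped fixtures have the documented shape", {
  fx <- make_paperlike_fixture("parasite", seed = 5L)
  expect_equal(length(fx$microsats$loci), 6L)  # two markers fail to amplify
  expect_equal(length(unique(fx$microsats$populations)), 6L)
  expect_equal(fx$alignment$length, 1305L)
  expect_s3_class(fx$coords, "population_table")
  expect_true(all(fx$coords$lat > 38 & fx$coords$lat < 45.5))
  expect_true(all(fx$coords$lon < 0))
  expect_equal(as.vector(table(fx$microsats$populations)[
    paste0("pop", 1:6)]), c(50L, 50L, 12L, 49L, 10L, 14L))

  # deterministic: same seed gives byte-identical genotype files
  fx2 <- make_paperlike_fixture("parasite", seed = 5L)
  t1 <- withr::local_tempfile()
  t2 <- withr::local_tempfile()
  write_genotype_table(fx$microsats, t1)
  write_genotype_table(fx2$microsats, t2)
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))

  expect_error(make_paperlike_fixture("mystery", seed = 1L), "unknown")
})
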