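test_that("allele frequencies are counted per population", {
  ds <- microsat_dataset(
    c("i1", "i2"), c("A", "A"),
    list(L1 = rbind(c(7L, 7L), c(7L, 9L))))
  fr <- allele_frequencies(ds, "L1")
  expect_equal(fr$freqs$A[["7"]], 0.75)
  expect_equal(fr$freqs$A[["9"]], 0.25)
  expect_equal(unname(fr$n[["A"]]), 2)
  expect_error(allele_frequencies(ds, "nope"), "unknown locus")

  # a population with all genotypes missing at the locus is excluded
  ds2 <- microsat_dataset(
    c("i1", "i2", "i3"), c("A", "A", "B"),
    list(L1 = rbind(c(7L, 7L), c(7L, 9L), c(NA_integer_, NA_integer_))))
  expect_warning(fr2 <- allele_frequencies(ds2, "L1"), "excluded")
  expect_equal(fr2$excluded, "B")

  # frequencies always sum to 1 per population on simulated data
  ms <- sim_small(seed = 21L)
  for (loc in ms$loci) {
    fr <- allele_frequencies(ms, loc)
    expect_true(all(abs(vapply(fr$freqs, sum, numeric(1L)) - 1) < 1e-9))
  }
})

test_that("effective number of alleles is the reciprocal of homozygosity", {
  expect_equal(effective_alleles(rep(0.25, 4)), 4)
  expect_equal(effective_alleles(1), 1)
  expect_equal(effective_alleles(c(0.5, 0.3, 0.2)), 1 / 0.38)
  expect_error(effective_alleles(numeric(0L)), "empty")
  expect_error(effective_alleles(c(0.5, 0.4)), "sum to 1")

  # k equal alleles: n_e = k and H = 1 - 1/k, jointly
  for (k in c(1, 2, 4, 10)) {
    p <- rep(1 / k, k)
    expect_equal(effective_alleles(p), k)
    expect_equal(heterozygosity_equal_alleles(k), 1 - sum(p^2))
  }
  expect_equal(heterozygosity_equal_alleles(c(4, 2, 1)), c(0.75, 0.5, 0))
  expect_error(heterozygosity_equal_alleles(0), ">= 1")

  # n_e * J = 1 on simulated per-population frequencies
  ms <- sim_small(seed = 4L)
  fr <- allele_frequencies(ms, "L1")
  for (p in fr$freqs) {
    expect_equal(effective_alleles(p) * sum(p^2), 1)
  }
})

test_that("H_S and H_T match hand computation in both modes", {
  # Three populations, two alleles, known frequencies and sample sizes.
  freqs <- structure(list(
    freqs = list(p1 = c("1" = 0.8, "2" = 0.2),
                 p2 = c("1" = 0.5, "2" = 0.5),
                 p3 = c("1" = 0.2, "2" = 0.8)),
    n = c(p1 = 10, p2 = 20, p3 = 5),
    ho = c(p1 = 0.3, p2 = 0.5, p3 = 0.4),
    ploidy = 2L, excluded = character(0L)), class = "allele_freqs")

  # plain: spreadsheet-style arithmetic written out independently
  hs_hand <- mean(c(1 - (0.8^2 + 0.2^2), 1 - 0.5, 1 - (0.2^2 + 0.8^2)))
  pbar <- c(mean(c(0.8, 0.5, 0.2)), mean(c(0.2, 0.5, 0.8)))
  ht_hand <- 1 - sum(pbar^2)
  plain <- hs_ht(freqs, "plain")
  expect_equal(plain$H_S, hs_hand)
  expect_equal(plain$H_T, ht_hand)

  # nei_chesser: harmonic-mean correction, hand-evaluated
  ntil <- 3 / (1 / 10 + 1 / 20 + 1 / 5)
  ho_bar <- mean(c(0.3, 0.5, 0.4))
  hs_nc <- ntil / (ntil - 1) * (hs_hand - ho_bar / (2 * ntil))
  ht_nc <- ht_hand + hs_nc / (ntil * 3) - ho_bar / (2 * ntil * 3)
  nc <- hs_ht(freqs, "nei_chesser")
  expect_equal(nc$H_S, hs_nc)
  expect_equal(nc$H_T, ht_nc)
  expect_equal(nc$n_tilde, ntil)

  # degenerate cases
  same <- structure(list(
    freqs = list(a = c("1" = 0.5, "2" = 0.5), b = c("1" = 0.5, "2" = 0.5)),
    n = c(a = 10, b = 10), ho = c(a = 0.5, b = 0.5),
    ploidy = 2L, excluded = character(0L)), class = "allele_freqs")
  s <- hs_ht(same, "plain")
  expect_equal(s$H_S, s$H_T)  # identical populations: D = 0 downstream

  fixed <- structure(list(
    freqs = list(a = c("1" = 1), b = c("2" = 1)),
    n = c(a = 10, b = 10), ho = c(a = 0, b = 0),
    ploidy = 2L, excluded = character(0L)), class = "allele_freqs")
  f <- hs_ht(fixed, "plain")
  expect_equal(f$H_S, 0)
  expect_equal(f$H_T, 0.5)

  one <- structure(list(
    freqs = list(a = c("1" = 1), b = c("2" = 1)),
    n = c(a = 1, b = 10), ho = c(a = 0, b = 0),
    ploidy = 2L, excluded = character(0L)), class = "allele_freqs")
  expect_error(hs_ht(one, "nei_chesser"), "n = 1")
})

test_that("plain H_T >= H_S on random allele-frequency fixtures", {
  set.seed(99)
  for (rep in 1:25) {
    K <- sample(2:6, 1L)
    A <- sample(2:8, 1L)
    fl <- lapply(seq_len(K), function(i) {
      p <- runif(A)
      setNames(p / sum(p), as.character(seq_len(A)))
    })
    names(fl) <- paste0("p", seq_len(K))
    fr <- structure(list(freqs = fl, n = rep(10, K), ho = NULL,
                         ploidy = 1L, excluded = character(0L)),
                    class = "allele_freqs")
    h <- hs_ht(fr, "plain")
    expect_gte(h$H_T, h$H_S - 1e-12)
  }
})

test_that("sample-size-corrected H_S converges to plain H_S", {
  # Balanced two-allele population in exact Hardy-Weinberg counts,
  # duplicated so K = 2; the correction shrinks monotonically with n.
  make_pop <- function(n) {
    g <- rbind(
      matrix(rep(c(1L, 1L), n / 4), ncol = 2, byrow = TRUE),
      matrix(rep(c(1L, 2L), n / 2), ncol = 2, byrow = TRUE),
      matrix(rep(c(2L, 2L), n / 4), ncol = 2, byrow = TRUE))
    microsat_dataset(paste0("i", seq_len(2 * n)),
                     rep(c("A", "B"), each = n),
                     list(L1 = rbind(g, g)))
  }
  dev <- vapply(c(8L, 52L, 500L), function(n) {
    fr <- allele_frequencies(make_pop(n), "L1")
    nc <- hs_ht(fr, "nei_chesser")
    plain <- hs_ht(fr, "plain")
    abs(nc$H_S - plain$H_S)
  }, numeric(1L))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3L], 0.001)
})

test_that("nucleotide diversity counts comparable sites pairwise", {
  al <- seq_alignment(c("x", "y"), c("p", "p"),
                      c(strrep("A", 100),
                        paste0(strrep("A", 98), "TT")))
  expect_equal(nucleotide_diversity(al, "p"), 0.02)

  # identical sequences
  al2 <- seq_alignment(c("x", "y"), c("p", "p"), c("ACGT", "ACGT"))
  expect_equal(nucleotide_diversity(al2, "p"), 0)

  # an N excludes that site for that pair only: 1 diff over 99 sites
  al3 <- seq_alignment(c("x", "y"), c("p", "p"),
                       c(paste0(strrep("A", 99), "N"),
                         paste0(strrep("A", 98), "TG")))
  expect_equal(nucleotide_diversity(al3, "p"), 1 / 99)

  expect_error(nucleotide_diversity(al2, "q"), ">= 2 sequences")
})

test_that("null-allele proportion follows the heterozygote deficit", {
  expect_equal(null_allele_proportion(0.9, 0.9), 0)
  expect_equal(null_allele_proportion(0.9, 0), 1)
  expect_equal(null_allele_proportion(0.9, 0.3), 0.5)
  expect_true(is.na(null_allele_proportion(0, 0)))
  # floored at zero when H_o exceeds H_exp
  expect_equal(null_allele_proportion(0.3, 0.5), 0)
  expect_error(null_allele_proportion(1.2, 0.5), "\\[0, 1\\]")

  tab <- null_allele_table(toy_microsats())
  expect_equal(nrow(tab$per_population), 4L)  # 2 loci x 2 pops
  expect_equal(nrow(tab$by_locus), 2L)
  expect_true(all(tab$per_population$r >= 0 | is.na(tab$per_population$r)))
})

test_that("expansion sign test reproduces exact binomial probabilities", {
  expect_equal(expansion_sign_test(rep(-1, 8))$p_value, 0.0078125)
  expect_equal(round(expansion_sign_test(rep(-1, 8))$p_value, 3), 0.008)
  expect_equal(round(expansion_sign_test(c(rep(-1, 6), 1, 2))$p_value, 2),
               0.29)
  expect_equal(expansion_sign_test(c(rep(-1, 4), 1, 3))$p_value, 0.6875)
  # perfectly balanced counts give p = 1
  expect_equal(expansion_sign_test(c(rep(-1, 4), rep(1, 4)))$p_value, 1)
  # zeros count as non-negative
  expect_equal(expansion_sign_test(c(-1, -1, 0, 0))$n_negative, 2L)
  expect_error(expansion_sign_test(numeric(0L)), "empty")
  expect_error(expansion_sign_test(c(1, NA)), "finite")
})

test_that("diversity summaries satisfy their invariants", {
  ms <- sim_small(seed = 17L)
  ds <- diversity_summary(ms)
  expect_true(all(ds$per$n_e >= 1))
  expect_true(all(ds$per$n_e <= ds$per$n_alleles + 1e-9))
  expect_true(all(abs(ds$per$J * ds$per$n_e - 1) < 1e-12))
  expect_true(all(ds$per$H_o >= 0 & ds$per$H_o <= 1))
  expect_true(all(ds$per$H_exp >= 0 & ds$per$H_exp <= 1))

  params <- island_model_params(K = 2L, N_deme = 30L, m = 0.02, mu = 1e-4,
                                marker_model = "finite_sites", L = 400L,
                                sample_n = 8L, burn_in = 600L, seed = 3L)
  al <- simulate_sequences(params)
  sa <- diversity_summary(al)
  expect_true(all(sa$per$pi >= 0 & sa$per$pi <= 1))
  expect_true(all(abs(sa$per$J * sa$per$n_e - 1) < 1e-12))
})
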