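test_that("G_ST and D formulas match hand arithmetic", {
  expect_equal(gst(0.5, 0), 1)
  expect_equal(gst(0.3, 0.3), 0)
  expect_equal(gst(0.77, 0.74), 0.03 / 0.77)
  expect_true(is.na(gst(0, 0)))  # undefined marker, not an exception

  expect_equal(jost_d(0.5, 0, 2), 1)
  expect_equal(jost_d(0.4, 0.4, 5), 0)
  expect_equal(jost_d(0.77, 0.74, 8), (8 / 7) * (0.03 / 0.26))
  expect_error(jost_d(0.9, 1, 4), "saturated")
  expect_error(jost_d(0.5, 0.2, 1), "N must be >= 2")

  expect_equal(jost_d_from_ne(1, 6, 6), 6 / 5 * (1 - 1 / 6))
  expect_equal(jost_d_from_ne(3, 3, 4), 0)
})

test_that("the two D formulations are algebraically identical", {
  set.seed(12)
  for (i in 1:100) {
    H_S <- runif(1, 0, 0.98)
    H_T <- runif(1, H_S, 0.99)
    N <- sample(2:12, 1L)
    expect_equal(jost_d(H_T, H_S, N),
                 jost_d_from_ne(1 / (1 - H_S), 1 / (1 - H_T), N),
                 tolerance = 1e-12)
  }
})

test_that("per-locus differentiation matches hand-computed examples", {
  # two identical population samples: D = 0, G_ST = 0
  same <- microsat_dataset(
    paste0("i", 1:8), rep(c("A", "B"), each = 4L),
    list(L1 = rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L), c(1L, 2L),
                    c(1L, 1L), c(1L, 2L), c(2L, 2L), c(1L, 2L))))
  row <- locus_differentiation(same, "L1", "plain")
  expect_equal(row$D, 0)
  expect_equal(row$G_ST, 0)

  # pops {a,a,b,b} and {c,c,d,d}: H_S = 0.5, H_T = 0.75, D = 1
  hd <- haploid_dataset(paste0("h", 1:8),
                        rep(c("A", "B"), each = 4L),
                        c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  srow <- sequence_differentiation(hd, "plain")
  expect_equal(srow$H_S, 0.5)
  expect_equal(srow$H_T, 0.75)
  expect_equal(srow$D, 1)
  expect_equal(srow$N, 2L)

  # fewer than two usable populations is a missing row, not an error
  solo <- microsat_dataset(c("i1", "i2"), c("A", "A"),
                           list(L1 = rbind(c(1L, 2L), c(1L, 1L))))
  miss <- locus_differentiation(solo, "L1", "plain")
  expect_true(is.na(miss$D))
  expect_match(miss$note, "fewer than 2")
})

test_that("mean D over loci reproduces printed summary-table means", {
  host <- c(0.62, 0.23, 0.16, 0.07, 0.32, 0.24, 0.31, 0.02)
  parasite <- c(0.60, 0.67, 0.33, 0.59, 0.55, 0.75)
  expect_equal(multilocus_mean(host), 0.24625)
  expect_equal(round(multilocus_mean(host), 2), 0.25)
  expect_equal(round(multilocus_mean(parasite), 2), 0.58)
  expect_equal(multilocus_mean(c(NA, 0.4)), 0.4)
  expect_equal(multilocus_mean(0.7), 0.7)
  expect_error(multilocus_mean(c(NA_real_, NA_real_)), "missing")
})

test_that("sequence differentiation equals the haplotype-count oracle", {
  params <- island_model_params(K = 3L, N_deme = 40L, m = 0.01, mu = 2e-5,
                                marker_model = "finite_sites", L = 800L,
                                sample_n = 10L, burn_in = 1200L, seed = 8L)
  al <- simulate_sequences(params)
  row <- sequence_differentiation(al, "plain")

  # independent haplotype-collapse: tabulate sequence strings per pop,
  # then plain H_S / H_T from the count table
  tab <- table(al$populations, al$seqs)
  P <- tab / rowSums(tab)
  H_s <- 1 - rowSums(P^2)
  H_S <- mean(H_s)
  H_T <- 1 - sum(colMeans(P)^2)
  K <- nrow(tab)
  expect_equal(row$H_S, H_S, tolerance = 1e-12)
  expect_equal(row$H_T, H_T, tolerance = 1e-12)
  expect_equal(row$D, (K / (K - 1)) * (H_T - H_S) / (1 - H_S),
               tolerance = 1e-12)

  # degenerate alignments
  flat <- seq_alignment(paste0("s", 1:4), rep(c("a", "b"), each = 2L),
                        rep("ACGT", 4L))
  frow <- sequence_differentiation(flat, "plain")
  expect_equal(frow$D, 0)
  expect_true(is.na(frow$G_ST))
  expect_equal(frow$note, "no variation")

  fixed <- seq_alignment(paste0("s", 1:4), rep(c("a", "b"), each = 2L),
                         c("AAAA", "AAAA", "TTTT", "TTTT"))
  expect_equal(sequence_differentiation(fixed, "plain")$D, 1)
})

test_that("gamma_ST averages per-site heterozygosities over all sites", {
  # populations fixed for sequences differing at every site
  expect_equal(gamma_st(toy_alignment())$gamma_ST, 1)

  # identical composition in both populations
  al <- seq_alignment(paste0("s", 1:4), rep(c("a", "b"), each = 2L),
                      c("AT", "TA", "AT", "TA"))
  expect_equal(gamma_st(al)$gamma_ST, 0)

  # pop1 = {AA, AA}, pop2 = {AT, AT}: H_Snuc = 0, H_Tnuc = 0.25
  al2 <- seq_alignment(paste0("s", 1:4), rep(c("a", "b"), each = 2L),
                       c("AA", "AA", "AT", "AT"))
  g <- gamma_st(al2)
  expect_equal(g$H_Snuc, 0)
  expect_equal(g$H_Tnuc, 0.25)
  expect_equal(g$gamma_ST, 1)

  # monomorphic sites dilute the average: same data + 2 invariant sites
  al3 <- seq_alignment(paste0("s", 1:4), rep(c("a", "b"), each = 2L),
                       c("AAGG", "AAGG", "ATGG", "ATGG"))
  g3 <- gamma_st(al3)
  expect_equal(g3$H_Tnuc, 0.125)
  expect_equal(g3$gamma_ST, 1)

  # no variation at all: undefined marker
  expect_true(is.na(gamma_st(seq_alignment(paste0("s", 1:4),
                                           rep(c("a", "b"), each = 2L),
                                           rep("AC", 4L)))$gamma_ST))
})

test_that("pairwise D matrix matches independent two-population runs", {
  ms <- sim_small(seed = 33L, K = 3L)
  pd <- pairwise_d(ms, "plain")
  expect_equal(diag(pd), setNames(rep(0, 3), rownames(pd)))
  expect_equal(pd, t(pd))
  pops <- unique(ms$populations)
  for (i in 1:2) for (j in (i + 1):3) {
    sel <- ms$populations %in% pops[c(i, j)]
    sub <- microsat_dataset(ms$ids[sel], ms$populations[sel],
                            lapply(ms$genotypes,
                                   function(g) g[sel, , drop = FALSE]))
    d_sub <- mean(vapply(sub$loci, function(l)
      locus_differentiation(sub, l, "plain")$D, numeric(1L)), na.rm = TRUE)
    expect_equal(pd[pops[i], pops[j]], d_sub, tolerance = 1e-12)
  }

  # two identical populations: off-diagonal 0 (plain mode)
  same <- microsat_dataset(
    paste0("i", 1:8), rep(c("A", "B"), each = 4L),
    list(L1 = rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L), c(1L, 2L),
                    c(1L, 1L), c(1L, 2L), c(2L, 2L), c(1L, 2L))))
  expect_equal(pairwise_d(same, "plain")["A", "B"], 0)
})

test_that("fragment scan at full length reproduces the full-data D", {
  params <- island_model_params(K = 3L, N_deme = 30L, m = 0.01, mu = 3e-5,
                                marker_model = "finite_sites", L = 300L,
                                sample_n = 8L, burn_in = 900L, seed = 14L)
  al <- simulate_sequences(params)
  full <- sequence_differentiation(al, "nei_chesser")
  fa <- fragment_length_analysis(al, lengths = 300L, n_frag = 3L,
                                 n_perm = 50L, seed = 2L)
  expect_equal(fa$summary$mean_D, full$D, tolerance = 1e-12)
  expect_true(fa$summary$power %in% c(0, 1))
  expect_equal(nrow(fa$records), 3L)

  # alignment without variation: D = 0 everywhere, power 0
  flat <- seq_alignment(paste0("s", 1:8), rep(c("a", "b"), each = 4L),
                        rep(strrep("A", 50L), 8L))
  fz <- fragment_length_analysis(flat, lengths = c(10L, 20L), n_frag = 4L,
                                 n_perm = 20L, seed = 3L)
  expect_true(all(fz$summary$mean_D == 0))
  expect_true(all(fz$summary$power == 0))

  expect_error(fragment_length_analysis(flat, lengths = 60L, n_frag = 2L,
                                        n_perm = 10L, seed = 1L),
               "exceeds")
})
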