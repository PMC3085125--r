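## Finite-island-model data generator: forward-time Wright-Fisher
## simulation of microsatellite and sequence data with known mutation and
## migration rates, plus a null-allele injector and species-shaped fixture
## bundles, so every pipeline stage is testable against known truth.

#' Parameters of the finite-island model
#'
#' `K` demes of equal diploid size `N_deme` exchange migrants at equal
#' rates: each gene copy (individual, for sequences) descends from a
#' parent in another deme with probability `m`, the destination deme being
#' uniform over the `K - 1` others. Mutation is per allele copy
#' (microsatellites) or per site (sequences) per generation.
#'
#' @param K number of demes (`>= 1`).
#' @param N_deme diploid individuals per deme.
#' @param m per-generation emigration probability, in `[0, 1]`.
#' @param mu per-allele (or per-site) per-generation mutation rate.
#' @param marker_model `"stepwise"`, `"infinite_alleles"` or
#'   `"finite_sites"`.
#' @param L sequence length in bp (finite-sites model only).
#' @param sample_n individuals sampled per deme (`<= N_deme`).
#' @param burn_in generations simulated from a monomorphic start; the
#'   default `10 * N_deme * K` reaches mutation-migration-drift
#'   quasi-equilibrium at the parameter ranges used here.
#' @param seed integer seed (optional; `set.seed` is applied when given).
#' @return List of class `island_model_params`.
#' @export
island_model_params <- function(K, N_deme, m, mu,
                                marker_model = c("stepwise",
                                                 "infinite_alleles",
                                                 "finite_sites"),
                                L = NULL, sample_n = N_deme,
                                burn_in = 10 * N_deme * K, seed = NULL) {
  marker_model <- match.arg(marker_model)
  if (K < 1) stop("K must be >= 1")
  if (m < 0 || m > 1) stop("m must be in [0, 1]")
  if (mu < 0) stop("mu must be >= 0")
  if (sample_n > N_deme) stop("sample_n must be <= N_deme")
  if (marker_model == "finite_sites" && (is.null(L) || L < 1))
    stop("finite_sites model needs L >= 1")
  structure(list(K = as.integer(K), N_deme = as.integer(N_deme),
                 m = m, mu = mu, marker_model = marker_model,
                 L = if (is.null(L)) NULL else as.integer(L),
                 sample_n = as.integer(sample_n),
                 burn_in = as.integer(burn_in), seed = seed),
            class = "island_model_params")
}

#' Simulate microsatellite genotypes under the finite-island model
#'
#' Forward-time Wright-Fisher: per generation each deme's `2 * N_deme`
#' allele copies are drawn from parental deme pools after migration;
#' the stepwise model mutates by +/-1 repeat unit with equal probability at
#' rate `mu`, the infinite-alleles model draws a brand-new label. Loci are
#' simulated independently. `sample_n` individuals per deme are returned
#' as a [microsat_dataset] with deme labels `pop1..popK`.
#'
#' @param params an [island_model_params] with marker_model
#'   `"stepwise"` or `"infinite_alleles"`.
#' @param n_loci number of independent loci.
#' @return A [microsat_dataset].
#' @export
simulate_microsats <- function(params, n_loci) {
  stopifnot(inherits(params, "island_model_params"))
  if (!params$marker_model %in% c("stepwise", "infinite_alleles"))
    stop("marker_model must be stepwise or infinite_alleles")
  if (!is.null(params$seed)) set.seed(params$seed)
  init <- if (params$marker_model == "stepwise") 1000L else 1L
  pool <- .wf_microsat_cpp(params$K, params$N_deme, params$m, params$mu,
                           params$burn_in, n_loci,
                           ifelse(params$marker_model == "stepwise", 0L, 1L),
                           init)
  if (any(pool <= 0L))
    stop("stepwise walk left the positive range; increase the start label")
  C <- 2L * params$N_deme
  genotypes <- vector("list", n_loci)
  ids <- character(0L)
  pops <- character(0L)
  pick <- list()
  for (k in seq_len(params$K)) {
    ind <- sample.int(params$N_deme, params$sample_n)  # individuals in deme k
    rows1 <- (k - 1L) * C + 2L * ind - 1L
    pick[[k]] <- cbind(rows1, rows1 + 1L)
    ids <- c(ids, sprintf("pop%d_i%03d", k, seq_len(params$sample_n)))
    pops <- c(pops, rep(paste0("pop", k), params$sample_n))
  }
  sel <- do.call(rbind, pick)
  for (l in seq_len(n_loci)) {
    genotypes[[l]] <- cbind(pool[sel[, 1L], l], pool[sel[, 2L], l])
  }
  names(genotypes) <- paste0("L", seq_len(n_loci))
  microsat_dataset(ids, pops, genotypes)
}

#' Simulate a haploid sequence alignment under the finite-island model
#'
#' Haploid maternal transmission is emulated with `N_deme / 2` copies per
#' deme (at least 2): the effective population size of a mitochondrial
#' locus is 4-fold lower than that of nuclear markers in a diploid,
#' two-sex population. Per site, mutation replaces the base by a uniformly
#' chosen different base at rate `mu`.
#'
#' @param params an [island_model_params] with marker_model
#'   `"finite_sites"` and `L` set.
#' @return A [seq_alignment] with `min(sample_n, N_deme/2)` sequences per
#'   deme.
#' @export
simulate_sequences <- function(params) {
  stopifnot(inherits(params, "island_model_params"))
  if (params$marker_model != "finite_sites")
    stop("marker_model must be finite_sites")
  if (!is.null(params$seed)) set.seed(params$seed)
  Nh <- max(2L, as.integer(round(params$N_deme / 2)))
  pool <- .wf_seq_cpp(params$K, Nh, params$m, params$mu,
                      params$burn_in, params$L)
  bases <- c("A", "C", "G", "T")
  take <- min(params$sample_n, Nh)
  ids <- character(0L)
  pops <- character(0L)
  seqs <- character(0L)
  for (k in seq_len(params$K)) {
    rows <- (k - 1L) * Nh + sample.int(Nh, take)
    for (r in rows) {
      seqs <- c(seqs, paste(bases[pool[r, ]], collapse = ""))
    }
    ids <- c(ids, sprintf("pop%d_s%03d", k, seq_len(take)))
    pops <- c(pops, rep(paste0("pop", k), take))
  }
  seq_alignment(ids, pops, seqs)
}

#' Inject null alleles into a microsatellite dataset
#'
#' Each allele copy independently becomes unamplifiable with probability
#' `null_freq`. A heterozygote (visible, null) becomes an apparent
#' homozygote for the visible allele; (null, null) becomes a missing
#' genotype. Under Hardy-Weinberg proportions this makes the Chakraborty
#' heterozygote-deficit estimator consistent for `null_freq`.
#'
#' @param dataset a [microsat_dataset].
#' @param null_freq probability an allele copy is null, in `[0, 1)`.
#' @param seed integer seed.
#' @return A [microsat_dataset] with degraded genotypes.
#' @export
inject_null_alleles <- function(dataset, null_freq, seed) {
  stopifnot(inherits(dataset, "microsat_dataset"))
  if (null_freq < 0 || null_freq >= 1) stop("null_freq must be in [0, 1)")
  if (null_freq == 0) return(dataset)
  set.seed(seed)
  genotypes <- lapply(dataset$genotypes, function(g) {
    ok <- !is.na(g[, 1L])
    nul <- matrix(runif(2L * nrow(g)) < null_freq, ncol = 2L) & ok
    out <- g
    ## one null copy: apparent homozygote for the visible allele
    out[nul[, 1L] & !nul[, 2L], 1L] <- g[nul[, 1L] & !nul[, 2L], 2L]
    out[!nul[, 1L] & nul[, 2L], 2L] <- g[!nul[, 1L] & nul[, 2L], 1L]
    out[nul[, 1L] & nul[, 2L], ] <- NA_integer_
    out
  })
  microsat_dataset(dataset$ids, dataset$populations, genotypes)
}

## Species-shaped fixture presets: deme count, per-deme sample sizes,
## locus count and per-locus mutation rates chosen so that the per-locus
## effective number of alleles spans roughly 2-22, sample sizes echo the
## 10-50 colonies per site of a field study, and the sequence locus is a
## 1305 bp mtDNA-like fragment.
.fixture_profiles <- list(
  host_primary = list(
    K = 6L, sample_sizes = c(50L, 50L, 50L, 33L, 32L, 50L),
    n_loci = 8L,
    mu = c(0.05, 0.08, 0.02, 0.01, 0.002, 0.06, 0.002, 0.0005),
    m = 0.02, seq_mu = 2e-5, seq_m = 0.02),
  host_secondary = list(
    K = 8L, sample_sizes = c(48L, 42L, 48L, 50L, 46L, 10L, 44L, 50L),
    n_loci = 8L,
    mu = c(0.01, 0.1, 0.02, 0.04, 0.005, 0.06, 0.03, 0.001),
    m = 0.01, seq_mu = 8e-6, seq_m = 0.01),
  parasite = list(
    K = 6L, sample_sizes = c(50L, 50L, 12L, 49L, 10L, 14L),
    n_loci = 6L,
    mu = c(0.05, 0.09, 0.05, 0.07, 0.004, 0.05),
    m = 0.005, seq_mu = 1.2e-5, seq_m = 0.01))

#' Generate a species-shaped synthetic dataset bundle
#'
#' A bundle shaped like one species' field data: `K` demes (6-9), per-site
#' sample sizes of 10-50, 6 or 8 microsatellite loci whose mutation rates
#' are tuned to span per-locus effective allele numbers of roughly 2-22, a
#' 1305 bp haploid alignment, and site coordinates drawn in a
#' northeastern-North-America-like bounding box. The `parasite` profile
#' has 6 loci (emulating two markers that fail to amplify in that
#' species).
#'
#' @param species_profile `"host_primary"`, `"host_secondary"` or
#'   `"parasite"`.
#' @param seed integer master seed.
#' @param N_deme deme size used by the generator (default 100).
#' @return List with `microsats` ([microsat_dataset]), `alignment`
#'   ([seq_alignment]), `coords` ([population_table]) and `params` (echo
#'   of all generation parameters).
#' @export
make_paperlike_fixture <- function(species_profile, seed, N_deme = 100L) {
  if (!species_profile %in% names(.fixture_profiles))
    stop("unknown profile: ", species_profile)
  prof <- .fixture_profiles[[species_profile]]
  K <- prof$K
  ## one locus at a time so each can have its own mutation rate
  loci <- vector("list", prof$n_loci)
  for (l in seq_len(prof$n_loci)) {
    p <- island_model_params(
      K = K, N_deme = N_deme, m = prof$m, mu = prof$mu[l],
      marker_model = "stepwise", sample_n = max(prof$sample_sizes),
      seed = derive_seed(seed, paste0(species_profile, "_locus", l)))
    loci[[l]] <- simulate_microsats(p, 1L)
  }
  ## subsample each deme to its profile sample size
  base <- loci[[1L]]
  keep <- logical(length(base$ids))
  for (k in seq_len(K)) {
    idx <- which(base$populations == paste0("pop", k))
    keep[idx[seq_len(prof$sample_sizes[k])]] <- TRUE
  }
  genotypes <- lapply(seq_len(prof$n_loci), function(l)
    loci[[l]]$genotypes[[1L]][keep, , drop = FALSE])
  names(genotypes) <- paste0("L", seq_len(prof$n_loci))
  ms <- microsat_dataset(base$ids[keep], base$populations[keep], genotypes)

  sp <- island_model_params(
    K = K, N_deme = N_deme, m = prof$seq_m, mu = prof$seq_mu,
    marker_model = "finite_sites", L = 1305L,
    sample_n = min(20L, N_deme %/% 2L),
    seed = derive_seed(seed, paste0(species_profile, "_seq")))
  al <- simulate_sequences(sp)

  set.seed(derive_seed(seed, paste0(species_profile, "_coords")))
  coords <- population_table(
    label = paste0("pop", seq_len(K)),
    lat = runif(K, 38.1, 45.5),
    lon_west = runif(K, 71.2, 88.8))

  list(microsats = ms, alignment = al, coords = coords,
       params = list(profile = species_profile, K = K, N_deme = N_deme,
                     sample_sizes = prof$sample_sizes, m = prof$m,
                     mu = prof$mu, seq_mu = prof$seq_mu,
                     seq_m = prof$seq_m, L = 1305L, seed = seed))
}
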