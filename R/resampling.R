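## Permutation significance machinery, small-sample exact enumeration, and
## the Mantel test for isolation by distance.

#' Permutation test configuration
#'
#' @param n_perm number of randomized datasets (default 1000).
#' @param seed integer seed (required for reproducibility).
#' @param alpha significance level used downstream (default 0.05).
#' @param add_one use the (count + 1)/(n_perm + 1) p-value convention
#'   instead of the default count/n_perm (which can legitimately be 0).
#' @return List of class `permutation_config`. The permutation unit is
#'   always the individual: a full multilocus genotype moves as one block,
#'   the conservative choice when samples deviate from Hardy-Weinberg.
#' @export
permutation_config <- function(n_perm = 1000, seed = NULL, alpha = 0.05,
                               add_one = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(n_perm = as.integer(n_perm), seed = seed,
                 alpha = alpha, add_one = isTRUE(add_one)),
            class = "permutation_config")
}

#' Derive a child seed from a master seed
#'
#' Deterministic per-analysis seed streams: adding an analysis does not
#' shift the random numbers used by earlier ones. Keeps results within
#' 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the analysis.
#' @return A derived integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) *
             (seq_along(utf8ToInt(as.character(tag))) %% 97 + 1))
  as.integer((as.numeric(seed) * 2654435 + h * 40503 + 12345) %% 2147483629)
}

#' Redistribute individuals over populations
#'
#' One randomized dataset: population labels are permuted over
#' individuals, so every individual is used exactly once (no replacement)
#' and the sample size of every population is preserved exactly. An
#' individual's full multilocus genotype moves as one unit; individual
#' order is untouched. Uses the current RNG state.
#'
#' @param dataset a [microsat_dataset], [haploid_dataset] or
#'   [seq_alignment].
#' @return A dataset of the same class with permuted population labels.
#' @export
permute_individuals <- function(dataset) {
  dataset$populations <- sample(dataset$populations)
  dataset
}

#' Permutation test for differentiation statistics
#'
#' The p-value of each statistic is the proportion of randomized datasets
#' whose statistic is `>=` the observed one (so p can be 0). All
#' statistics in the bundle are evaluated on the *same* randomized
#' datasets — for D and G_ST this makes the two p-values comparable (and,
#' for haploid data, identical).
#'
#' @param dataset a [microsat_dataset], [haploid_dataset] or
#'   [seq_alignment].
#' @param statistic function(dataset) returning a named numeric vector
#'   (e.g. [d_gst_statistic()]).
#' @param config a [permutation_config()].
#' @return List of class `permutation_outcome`: `observed`, `p` (named as
#'   the statistics), `null_quantiles` (2.5/50/97.5% of the permutation
#'   distribution), `n_perm`, `seed`.
#' @export
permutation_test <- function(dataset, statistic, config = permutation_config()) {
  stopifnot(inherits(config, "permutation_config"))
  obs <- statistic(dataset)
  if (anyNA(obs))
    stop("statistic undefined on observed data: ",
         paste(names(obs)[is.na(obs)], collapse = ", "))
  if (!is.null(config$seed)) set.seed(config$seed)
  perm <- matrix(NA_real_, config$n_perm, length(obs),
                 dimnames = list(NULL, names(obs)))
  for (b in seq_len(config$n_perm)) {
    perm[b, ] <- statistic(permute_individuals(dataset))
  }
  cnt <- colSums(sweep(perm, 2L, obs, ">="), na.rm = TRUE)
  p <- if (config$add_one) (cnt + 1) / (config$n_perm + 1)
       else cnt / config$n_perm
  structure(list(observed = obs, p = p,
                 null_quantiles = apply(perm, 2L, quantile,
                                        probs = c(0.025, 0.5, 0.975),
                                        na.rm = TRUE),
                 n_perm = config$n_perm, seed = config$seed),
            class = "permutation_outcome")
}

#' @export
print.permutation_outcome <- function(x, ...) {
  cat("Permutation test (", x$n_perm, " randomized datasets)\n", sep = "")
  for (s in names(x$observed))
    cat("  ", s, " = ", format(x$observed[[s]], digits = 4),
        ", P = ", format(x$p[[s]], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Statistic bundle: mean D and G_ST
#'
#' Returns a closure computing `c(D = ..., G_ST = ...)` on a dataset:
#' the across-locus unweighted means for microsatellite data, the single
#' haploid-locus values for haplotype data or alignments.
#'
#' @param mode estimator mode, see [hs_ht()].
#' @return A function usable as the `statistic` of [permutation_test()].
#' @export
d_gst_statistic <- function(mode = c("nei_chesser", "plain")) {
  mode <- match.arg(mode)
  function(x) {
    if (inherits(x, "microsat_dataset")) {
      tab <- differentiation_table(x, mode)
      c(D = attr(tab, "mean_D"), G_ST = attr(tab, "mean_GST"))
    } else {
      row <- sequence_differentiation(x, mode)
      c(D = row$D, G_ST = row$G_ST)
    }
  }
}

#' Statistic bundle: D only
#'
#' @param mode estimator mode, see [hs_ht()].
#' @return A function usable as the `statistic` of [permutation_test()].
#' @export
d_statistic <- function(mode = c("nei_chesser", "plain")) {
  mode <- match.arg(mode)
  function(x) {
    if (inherits(x, "microsat_dataset")) {
      tab <- differentiation_table(x, mode)
      c(D = attr(tab, "mean_D"))
    } else {
      c(D = sequence_differentiation(x, mode)$D)
    }
  }
}

#' gamma_ST permutation test
#'
#' Individual-level permutation test of [gamma_st()], with per-site
#' indicator matrices precomputed once (permutations only relabel
#' populations).
#'
#' @param alignment a [seq_alignment].
#' @param config a [permutation_config()].
#' @return A `permutation_outcome` for `gamma_ST`.
#' @export
gamma_st_test <- function(alignment, config = permutation_config()) {
  pre <- .gamma_precompute(alignment)
  stat <- function(x) {
    c(gamma_ST = .gamma_core(pre, x$populations)[["gamma_ST"]])
  }
  permutation_test(alignment, stat, config)
}

#' Exact permutation p-value by exhaustive enumeration
#'
#' Enumerates every distinct assignment of individuals to populations that
#' preserves the observed sample sizes and returns the exact
#' `P(statistic >= observed)`. A brute-force oracle for small datasets.
#'
#' @param dataset a [microsat_dataset], [haploid_dataset] or
#'   [seq_alignment] with at most 12 individuals.
#' @param statistic function(dataset) returning a single numeric value.
#' @return The exact p-value.
#' @export
exact_permutation_pvalue <- function(dataset, statistic) {
  n <- length(dataset$populations)
  if (n > 12L)
    stop("more than 12 individuals: use the Monte-Carlo permutation test")
  obs <- statistic(dataset)
  if (is.na(obs)) stop("statistic undefined on observed data")
  pops <- dataset$populations
  labels <- unique(pops)
  sizes <- as.integer(table(factor(pops, levels = labels)))
  assigns <- .enumerate_assignments(seq_len(n), sizes)
  tol <- 1e-12
  hits <- 0L
  for (a in assigns) {
    lab <- character(n)
    for (g in seq_along(labels)) lab[a[[g]]] <- labels[g]
    d2 <- dataset
    d2$populations <- lab
    if (statistic(d2) >= obs - tol) hits <- hits + 1L
  }
  hits / length(assigns)
}

## All ways to partition `idx` into ordered groups of the given sizes.
.enumerate_assignments <- function(idx, sizes) {
  if (length(sizes) == 1L) return(list(list(idx)))
  first <- combn(idx, sizes[1L], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- .enumerate_assignments(setdiff(idx, f), sizes[-1L])
    for (r in rest) out[[length(out) + 1L]] <- c(list(f), r)
  }
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation `r` over the strictly-lower-triangle entries, with
#' significance from random row/column-label permutations of the second
#' matrix. Two-sided: `p = count(|r_perm| >= |r_obs|) / n_perm` (the same
#' `>=`-counting convention as [permutation_test()]).
#'
#' @param matrix_a,matrix_b symmetric matrices with identical labels and
#'   zero diagonals, `>= 3` populations.
#' @param n_perm number of permutations (default 1000); ignored when
#'   `exact = TRUE`.
#' @param seed integer seed.
#' @param exact enumerate all label permutations (feasible for `<= 8`
#'   labels) instead of Monte-Carlo sampling.
#' @return List of class `mantel_result`: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(matrix_a, matrix_b, n_perm = 1000, seed = NULL,
                        exact = FALSE) {
  a <- as.matrix(matrix_a)
  b <- as.matrix(matrix_b)
  if (!identical(dim(a), dim(b)))
    stop("dimension mismatch between matrices")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("label mismatch between matrices")
  n <- nrow(a)
  if (n < 3L) stop("need >= 3 populations")
  lower <- lower.tri(a)
  r_obs <- cor(a[lower], b[lower])
  r_perm_of <- function(ord) {
    bp <- b[ord, ord]
    cor(a[lower], bp[lower])
  }
  if (exact) {
    perms <- .all_permutations(n)
    rp <- vapply(perms, r_perm_of, numeric(1L))
    p <- mean(abs(rp) >= abs(r_obs) - 1e-12)
    n_used <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    rp <- vapply(seq_len(n_perm), function(i) r_perm_of(sample.int(n)),
                 numeric(1L))
    p <- sum(abs(rp) >= abs(r_obs) - 1e-12) / n_perm
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = p, n_perm = n_used), class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel test: r = ", format(x$r, digits = 4), ", P = ",
      format(x$p, digits = 4), " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

.all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- list()
  for (s in sub) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(s, n, after = pos)
    }
  }
  out
}

#' Great-circle distance matrix between populations
#'
#' Geographic input for isolation-by-distance Mantel tests, computed from
#' decimal coordinates (WGS84 geodesic, in kilometres).
#'
#' @param tab a [population_table].
#' @return Symmetric distance matrix (km) with population labels.
#' @export
geographic_distances <- function(tab) {
  stopifnot(inherits(tab, "population_table"))
  n <- nrow(tab)
  M <- matrix(0, n, n, dimnames = list(tab$label, tab$label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        d <- geosphere::distGeo(c(tab$lon[i], tab$lat[i]),
                                c(tab$lon[j], tab$lat[j])) / 1000
        M[i, j] <- M[j, i] <- d
      }
    }
  }
  M
}

#' Precomputed D/G_ST statistic for heavy permutation runs
#'
#' Builds a closure equivalent to [d_gst_statistic()] but with allele
#' recoding and missingness masks precomputed from `dataset`, so each
#' evaluation only re-tabulates counts under the new population labels.
#' Intended for permutation streams over label-permutations of `dataset`
#' (the genotypes themselves must not change between calls). Populations
#' left without usable data at a locus under a permutation (none
#' non-missing, or a single individual in `nei_chesser` mode) are dropped
#' from that locus; a locus with fewer than two usable populations
#' contributes `NA`.
#'
#' @param dataset a [microsat_dataset], [haploid_dataset] or
#'   [seq_alignment].
#' @param mode estimator mode, see [hs_ht()].
#' @return A function usable as the `statistic` of [permutation_test()],
#'   returning `c(D = ..., G_ST = ...)` (across-locus unweighted means for
#'   multilocus data).
#' @export
make_d_gst_statistic <- function(dataset, mode = c("nei_chesser", "plain")) {
  mode <- match.arg(mode)
  lev <- unique(dataset$populations)
  K <- length(lev)
  if (inherits(dataset, "seq_alignment"))
    dataset <- as_haplotype_dataset(dataset)
  if (inherits(dataset, "haploid_dataset")) {
    a <- match(dataset$alleles, sort(unique(dataset$alleles)))
    A <- max(a)
    return(function(x) {
      pf <- match(x$populations, lev)
      counts <- matrix(tabulate(pf + K * (a - 1L), K * A), nrow = K)
      n <- tabulate(pf, K)
      use <- if (mode == "plain") n >= 1L else n >= 2L
      if (sum(use) < 2L) return(c(D = NA_real_, G_ST = NA_real_))
      P <- counts[use, , drop = FALSE] / n[use]
      h <- .hs_ht_core(P, n[use], NULL, mode, 1L)
      if (h$H_S >= 1 - 1e-12 || h$H_T >= 1 - 1e-12)
        return(c(D = NA_real_, G_ST = NA_real_))
      c(D = jost_d(h$H_T, h$H_S, sum(use)), G_ST = gst(h$H_T, h$H_S))
    })
  }
  pre <- lapply(dataset$genotypes, function(g) {
    ok <- which(!is.na(g[, 1L]))
    labels <- sort(unique(as.vector(g[ok, ])))
    list(ok = ok,
         a1 = match(g[ok, 1L], labels), a2 = match(g[ok, 2L], labels),
         het = g[ok, 1L] != g[ok, 2L], A = length(labels))
  })
  function(x) {
    pf <- match(x$populations, lev)
    D <- G <- rep(NA_real_, length(pre))
    for (l in seq_along(pre)) {
      p <- pre[[l]]
      pfl <- pf[p$ok]
      n <- tabulate(pfl, K)
      use <- n >= 2L
      if (sum(use) < 2L) next
      counts <- matrix(tabulate(pfl + K * (p$a1 - 1L), K * p$A) +
                         tabulate(pfl + K * (p$a2 - 1L), K * p$A),
                       nrow = K)
      P <- counts[use, , drop = FALSE] / (2 * n[use])
      ho <- (tabulate(pfl[p$het], K) / n)[use]
      h <- .hs_ht_core(P, n[use], ho, mode, 2L)
      if (h$H_S >= 1 - 1e-12 || h$H_T >= 1 - 1e-12) next
      D[l] <- jost_d(h$H_T, h$H_S, sum(use))
      G[l] <- gst(h$H_T, h$H_S)
    }
    if (all(is.na(D))) c(D = NA_real_, G_ST = NA_real_)
    else c(D = mean(D, na.rm = TRUE), G_ST = mean(G, na.rm = TRUE))
  }
}
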