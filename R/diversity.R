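## Within-population diversity: homozygosity, effective number of alleles,
## observed/expected heterozygosity, nucleotide diversity, null-allele
## proportions and the sign-test aggregation of per-locus expansion
## statistics.

#' Per-population allele frequencies at one locus
#'
#' Frequencies are computed from allele counts: two per non-missing diploid
#' individual, one per haploid sequence/haplotype. Populations with zero
#' non-missing individuals at the locus are excluded (with a warning) and
#' listed in the `excluded` field.
#'
#' @param dataset a [microsat_dataset], [haploid_dataset] or
#'   [seq_alignment] (for alignments the single "locus" is the haplotype
#'   identity and `locus` is ignored).
#' @param locus locus name (microsatellite datasets only).
#' @return An object of class `allele_freqs`: list with `freqs` (named list
#'   of per-population frequency vectors, names = allele labels), `n`
#'   (non-missing individuals per population), `ho` (observed
#'   heterozygosity per population; diploid only), `ploidy`, `excluded`.
#' @export
allele_frequencies <- function(dataset, locus = NULL) {
  UseMethod("allele_frequencies")
}

.freqs_from_counts <- function(alleles, pops, ploidy, ho = NULL) {
  ## alleles: vector of allele labels (one per gene copy), pops parallel
  pops_all <- unique(pops)
  freqs <- lapply(pops_all, function(s) {
    a <- alleles[pops == s]
    tab <- table(a)
    p <- as.numeric(tab) / sum(tab)
    names(p) <- names(tab)
    p
  })
  names(freqs) <- pops_all
  structure(list(freqs = freqs,
                 n = vapply(pops_all, function(s) sum(pops == s) / ploidy,
                            numeric(1L)),
                 ho = ho, ploidy = ploidy, excluded = character(0L)),
            class = "allele_freqs")
}

#' @export
allele_frequencies.microsat_dataset <- function(dataset, locus = NULL) {
  if (is.null(locus) || !(locus %in% dataset$loci))
    stop("unknown locus: ", if (is.null(locus)) "<missing>" else locus)
  g <- dataset$genotypes[[locus]]
  ok <- !is.na(g[, 1L])
  pops_all <- unique(dataset$populations)
  excluded <- pops_all[!pops_all %in% dataset$populations[ok]]
  if (length(excluded))
    warning("locus ", locus, ": populations with no non-missing data ",
            "excluded: ", paste(excluded, collapse = ", "))
  if (!any(ok))
    stop("locus ", locus, ": no non-missing individuals")
  pops <- dataset$populations[ok]
  kept <- unique(pops)
  ho <- vapply(kept, function(s) {
    gi <- g[ok & dataset$populations == s, , drop = FALSE]
    mean(gi[, 1L] != gi[, 2L])
  }, numeric(1L))
  ## transposing pairs the two allele columns with rep(pops, each = 2)
  out <- .freqs_from_counts(as.vector(t(g[ok, , drop = FALSE])),
                            rep(pops, each = 2L),
                            ploidy = 2L, ho = ho)
  out$excluded <- excluded
  out
}

#' @export
allele_frequencies.haploid_dataset <- function(dataset, locus = NULL) {
  .freqs_from_counts(as.character(dataset$alleles), dataset$populations,
                     ploidy = 1L)
}

#' @export
allele_frequencies.seq_alignment <- function(dataset, locus = NULL) {
  allele_frequencies(as_haplotype_dataset(dataset))
}

#' Effective number of alleles
#'
#' The reciprocal of homozygosity, `n_e = 1 / sum(p^2)`: the number of
#' equally frequent alleles that would give the observed homozygosity.
#' Unlike heterozygosity it scales linearly with diversity, which makes it
#' the better comparison currency for highly variable markers.
#'
#' @param p numeric vector of allele frequencies (must sum to 1).
#' @return `n_e`, a value `>= 1`.
#' @examples
#' effective_alleles(rep(0.25, 4))  # 4
#' @export
effective_alleles <- function(p) {
  if (length(p) == 0L) stop("empty frequency vector")
  if (abs(sum(p) - 1) > 1e-6) stop("frequencies must sum to 1")
  1 / sum(p^2)
}

#' Expected heterozygosity of k equally frequent alleles
#'
#' Worked-example helper: with `k` alleles at equal frequency,
#' `H = 1 - 1/k` (0.75, 0.5 and 0 for k = 4, 2, 1) while the effective
#' number of alleles is exactly `k`.
#'
#' @param k integer number of alleles, `>= 1`.
#' @return `1 - 1/k`.
#' @export
heterozygosity_equal_alleles <- function(k) {
  if (any(k < 1)) stop("k must be >= 1")
  1 - 1 / k
}

## Shared estimator core. P: K x A matrix of per-population allele
## frequencies; n: per-population sample sizes (individuals for diploid,
## sequences for haploid); ho: per-population observed heterozygosity
## (diploid only).
.hs_ht_core <- function(P, n, ho, mode, ploidy) {
  K <- nrow(P)
  hs_s <- 1 - rowSums(P^2)
  HS_plain <- mean(hs_s)
  pbar <- colMeans(P)               # unweighted across populations
  HT_plain <- 1 - sum(pbar^2)
  if (mode == "plain") {
    return(list(H_S = HS_plain, H_T = HT_plain,
                H_o = if (is.null(ho)) NA_real_ else mean(ho),
                n_tilde = NA_real_))
  }
  if (any(n <= 1))
    stop("sample-size correction undefined: a population has n = 1")
  ntil <- K / sum(1 / n)            # harmonic mean sample size
  if (ploidy == 2L) {
    Ho <- mean(ho)
    HS <- ntil / (ntil - 1) * (HS_plain - Ho / (2 * ntil))
    HT <- HT_plain + HS / (ntil * K) - Ho / (2 * ntil * K)
  } else {
    Ho <- NA_real_
    HS <- ntil / (ntil - 1) * HS_plain
    HT <- HT_plain + HS / (ntil * K)
  }
  list(H_S = HS, H_T = HT, H_o = Ho, n_tilde = ntil)
}

.freqs_to_matrix <- function(freqs) {
  alleles <- sort(unique(unlist(lapply(freqs$freqs, names))))
  P <- matrix(0, nrow = length(freqs$freqs), ncol = length(alleles),
              dimnames = list(names(freqs$freqs), alleles))
  for (s in names(freqs$freqs)) P[s, names(freqs$freqs[[s]])] <- freqs$freqs[[s]]
  P
}

#' Within- and total-sample heterozygosity (H_S, H_T)
#'
#' `H_S` is the mean within-population expected heterozygosity, `H_T` the
#' expected heterozygosity of the total sample with allele frequencies
#' averaged (unweighted) over populations. `"plain"` mode uses the direct
#' frequency formulas; `"nei_chesser"` (default) applies the Nei & Chesser
#' sample-size corrections using the harmonic mean sample size and, for
#' diploid data, the observed heterozygosity.
#'
#' @param freqs an `allele_freqs` object over `K >= 2` populations.
#' @param mode `"nei_chesser"` or `"plain"`.
#' @return List with `H_S`, `H_T`, `H_o` (diploid; `NA` for haploid),
#'   `n_tilde` (harmonic mean sample size; `NA` in plain mode) and `K`.
#' @export
hs_ht <- function(freqs, mode = c("nei_chesser", "plain")) {
  mode <- match.arg(mode)
  stopifnot(inherits(freqs, "allele_freqs"))
  K <- length(freqs$freqs)
  if (K < 2L) stop("need at least 2 populations")
  P <- .freqs_to_matrix(freqs)
  out <- .hs_ht_core(P, freqs$n, freqs$ho, mode, freqs$ploidy)
  out$K <- K
  out$mode <- mode
  out
}

#' Nucleotide diversity within a population
#'
#' Mean over all unordered sequence pairs of (number of differences /
#' number of compared sites), where a site enters the comparison only if
#' both characters are in `{A, C, G, T}`.
#'
#' @param alignment a [seq_alignment].
#' @param population population label.
#' @return pi, the mean pairwise difference per nucleotide, in `[0, 1]`.
#' @export
nucleotide_diversity <- function(alignment, population) {
  stopifnot(inherits(alignment, "seq_alignment"))
  idx <- which(alignment$populations == population)
  if (length(idx) < 2L)
    stop("need >= 2 sequences in population ", population)
  M <- .seq_char_matrix(alignment$seqs[idx])
  ok <- M == "A" | M == "C" | M == "G" | M == "T"
  n <- nrow(M)
  vals <- numeric(0L)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L) next
      vals <- c(vals, sum(M[i, comp] != M[j, comp]) / nc)
    }
  }
  if (!length(vals)) stop("no comparable sites in population ", population)
  mean(vals)
}

.seq_char_matrix <- function(seqs) {
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

#' Chakraborty null-allele proportion from a heterozygote deficit
#'
#' Under the assumption that the whole heterozygote deficit is due to
#' null alleles, the null-allele proportion is
#' `r = (H_exp - H_o) / (H_exp + H_o)`, floored at 0. Returns `NA` where
#' both heterozygosities are 0 (undefined). Vectorised.
#'
#' @param H_exp expected heterozygosity (within-sample, from allele
#'   frequencies).
#' @param H_o observed heterozygosity.
#' @return Estimated null-allele proportion(s) in `[0, 1]`, `NA` where
#'   undefined.
#' @export
null_allele_proportion <- function(H_exp, H_o) {
  if (any(H_exp < 0 | H_exp > 1 | H_o < 0 | H_o > 1, na.rm = TRUE))
    stop("heterozygosities must be in [0, 1]")
  r <- (H_exp - H_o) / (H_exp + H_o)
  r[H_exp == 0 & H_o == 0] <- NA_real_
  pmax(r, 0)
}

#' Null-allele proportions per locus and population
#'
#' Applies [null_allele_proportion()] to every locus x population cell of
#' a dataset (plain within-sample expected heterozygosity vs observed) and
#' also reports the across-population average per locus, which serves as
#' an upper bound on the null-allele proportion for that locus.
#'
#' @param dataset a [microsat_dataset].
#' @return List with `per_population` (data.frame: locus, population, n,
#'   H_exp, H_o, r) and `by_locus` (data.frame: locus, mean_r).
#' @export
null_allele_table <- function(dataset) {
  stopifnot(inherits(dataset, "microsat_dataset"))
  rows <- list()
  for (loc in dataset$loci) {
    fr <- suppressWarnings(allele_frequencies(dataset, loc))
    for (s in names(fr$freqs)) {
      he <- 1 - sum(fr$freqs[[s]]^2)
      ho <- fr$ho[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, population = s, n = fr$n[[s]],
        H_exp = he, H_o = ho,
        r = null_allele_proportion(he, ho),
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  by_locus <- aggregate(r ~ locus, data = per, FUN = mean, na.rm = TRUE,
                        na.action = NULL)
  names(by_locus)[2L] <- "mean_r"
  list(per_population = per, by_locus = by_locus)
}

#' Sign-test aggregation of per-locus expansion statistics
#'
#' A negative per-locus value of the expansion statistic k indicates
#' population growth. Across loci, the number of negative values is tested
#' against Binomial(n_loci, 1/2) with an exact two-sided p-value:
#' `p = min(1, 2 * min(P(X <= n_neg), P(X >= n_neg)))`. Exact zeros count
#' as non-negative (conservative toward the expansion hypothesis). The
#' per-locus statistic itself is pluggable — any real-valued function of a
#' locus's allele sizes can feed this aggregation.
#'
#' @param k_values numeric vector of per-locus statistics (finite).
#' @return List of class `expansion_test` with `k_values`, `n_negative`,
#'   `n_loci`, `p_value`.
#' @examples
#' expansion_sign_test(rep(-1, 8))$p_value  # 0.0078125, prints 0.008
#' @export
expansion_sign_test <- function(k_values) {
  k_values <- as.numeric(k_values)
  if (!length(k_values)) stop("empty input")
  if (any(!is.finite(k_values))) stop("k values must be finite")
  n <- length(k_values)
  neg <- sum(k_values < 0)
  p <- min(1, 2 * min(pbinom(neg, n, 0.5),
                      1 - pbinom(neg - 1L, n, 0.5)))
  structure(list(k_values = k_values, n_negative = neg, n_loci = n,
                 p_value = p),
            class = "expansion_test")
}

#' @export
print.expansion_test <- function(x, ...) {
  cat("Expansion sign test: ", x$n_negative, " negative of ", x$n_loci,
      " loci, exact binomial P = ", format(x$p_value, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' Per-population diversity summary
#'
#' For microsatellite data: per locus x population homozygosity `J`,
#' effective number of alleles `n_e = 1/J`, observed heterozygosity `H_o`
#' and unbiased expected heterozygosity `H_exp`
#' (`2n/(2n-1) * (1 - sum p^2)`), plus per-locus means over populations
#' (the convention for summary tables: compute within each population,
#' then average over populations) and the grand mean. For alignments:
#' haplotype-based `J`, `n_e`, `H_exp` (`n/(n-1)` correction) and
#' nucleotide diversity `pi` per population.
#'
#' @param x a [microsat_dataset] or [seq_alignment].
#' @return List with `per` (per locus x population data.frame), `by_locus`
#'   (means over populations) and `overall` (grand means). For alignments
#'   `per` is per population and `overall` averages over populations.
#' @export
diversity_summary <- function(x) UseMethod("diversity_summary")

#' @export
diversity_summary.microsat_dataset <- function(x) {
  rows <- list()
  for (loc in x$loci) {
    fr <- suppressWarnings(allele_frequencies(x, loc))
    for (s in names(fr$freqs)) {
      p <- fr$freqs[[s]]
      J <- sum(p^2)
      n <- fr$n[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc, population = s, n = n,
        n_alleles = length(p), J = J, n_e = 1 / J,
        H_o = fr$ho[[s]],
        H_exp = if (n > 0.5) 2 * n / (2 * n - 1) * (1 - J) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  by_locus <- aggregate(cbind(n_e, H_o, H_exp) ~ locus, data = per,
                        FUN = mean)
  by_locus <- by_locus[match(x$loci, by_locus$locus), , drop = FALSE]
  rownames(by_locus) <- NULL
  list(per = per, by_locus = by_locus,
       overall = c(n_e = mean(per$n_e), H_o = mean(per$H_o),
                   H_exp = mean(per$H_exp)))
}

#' @export
diversity_summary.seq_alignment <- function(x) {
  hd <- as_haplotype_dataset(x)
  fr <- allele_frequencies(hd)
  rows <- lapply(names(fr$freqs), function(s) {
    p <- fr$freqs[[s]]
    J <- sum(p^2)
    n <- fr$n[[s]]
    data.frame(
      population = s, n = n, n_haplotypes = length(p),
      J = J, n_e = 1 / J,
      H_exp = if (n > 1) n / (n - 1) * (1 - J) else NA_real_,
      pi = if (n >= 2) nucleotide_diversity(x, s) else NA_real_,
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(per = per,
       overall = c(n_e = mean(per$n_e), H_exp = mean(per$H_exp),
                   pi = mean(per$pi, na.rm = TRUE)))
}
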