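## Between-population differentiation: G_ST, Jost's D (both formulations),
## gamma_ST for sequences, per-locus/mean reporting, pairwise-D matrices and
## the fragment-length analysis.

#' G_ST from total and mean within-population heterozygosity
#'
#' `G_ST = (H_T - H_S) / H_T`. When within-population heterozygosity is
#' high, `H_T` is close to `H_S` no matter how differentiated the
#' populations are, so G_ST is automatically pushed toward 0 — the central
#' caveat motivating D for highly variable markers.
#'
#' @param H_T total expected heterozygosity.
#' @param H_S mean within-population expected heterozygosity.
#' @return G_ST, or `NA` (undefined marker) when `H_T = 0`.
#' @export
gst <- function(H_T, H_S) {
  if (any(H_T < 0 | H_T > 1 | H_S < 0 | H_S > 1, na.rm = TRUE))
    stop("heterozygosities must be in [0, 1]")
  out <- (H_T - H_S) / H_T
  out[H_T == 0] <- NA_real_
  out
}

#' Jost's D from heterozygosities
#'
#' `D = (N / (N - 1)) * (H_T - H_S) / (1 - H_S)`, where `N` is the number
#' of sampled subpopulations. D measures the fraction of allelic
#' diversity that is partitioned among populations and, unlike G_ST, is
#' not suppressed by high within-population diversity.
#'
#' @param H_T total expected heterozygosity.
#' @param H_S mean within-population expected heterozygosity (`< 1`).
#' @param N number of sampled subpopulations (`>= 2`).
#' @return D (small negative values can occur as estimator noise).
#' @export
jost_d <- function(H_T, H_S, N) {
  if (any(N < 2)) stop("N must be >= 2")
  if (any(H_S >= 1)) stop("degenerate: within-population diversity saturated")
  (N / (N - 1)) * (H_T - H_S) / (1 - H_S)
}

#' Jost's D from effective numbers of alleles
#'
#' Algebraically identical reformulation,
#' `D = (N / (N - 1)) * (1 - n_eS / n_eT)` with `n_e = 1 / (1 - H)`:
#' D depends only on the ratio of within- to total-sample effective
#' number of alleles.
#'
#' @param n_eS within-population effective number of alleles (`>= 1`).
#' @param n_eT total-sample effective number of alleles (`>= 1`).
#' @param N number of sampled subpopulations (`>= 2`).
#' @return D.
#' @export
jost_d_from_ne <- function(n_eS, n_eT, N) {
  if (any(N < 2)) stop("N must be >= 2")
  if (any(n_eS < 1 | n_eT < 1)) stop("n_e values must be >= 1")
  (N / (N - 1)) * (1 - n_eS / n_eT)
}

.diff_row_from_hsht <- function(h, locus, N) {
  H_S <- h$H_S
  H_T <- h$H_T
  ## sample-size-corrected estimates can reach 1 when (almost) every
  ## individual carries a unique allele; D is then undefined (0/0)
  if (H_S >= 1 - 1e-12 || H_T >= 1 - 1e-12) {
    row <- .missing_diff_row(locus, "within-population diversity saturated")
    row$N <- N
    row$H_S <- H_S
    row$H_T <- H_T
    return(row)
  }
  data.frame(
    locus = locus, N = N,
    H_S = H_S, H_T = H_T,
    n_eS = 1 / (1 - H_S), n_eT = 1 / (1 - H_T),
    D = jost_d(H_T, H_S, N), G_ST = gst(H_T, H_S),
    note = "", stringsAsFactors = FALSE)
}

.missing_diff_row <- function(locus, note) {
  data.frame(locus = locus, N = NA_integer_, H_S = NA_real_,
             H_T = NA_real_, n_eS = NA_real_, n_eT = NA_real_,
             D = NA_real_, G_ST = NA_real_, note = note,
             stringsAsFactors = FALSE)
}

#' Per-locus differentiation (D and G_ST)
#'
#' Computes `H_S` and `H_T` at one locus via [hs_ht()] over the populations
#' with non-missing data, then D and G_ST. `N` is the number of
#' populations actually included at this locus.
#'
#' @param dataset a [microsat_dataset].
#' @param locus locus name.
#' @param mode heterozygosity estimator mode, see [hs_ht()].
#' @return One-row data.frame: `locus`, `N`, `H_S`, `H_T`, `n_eS`, `n_eT`,
#'   `D`, `G_ST`, `note` (reason when marked missing).
#' @export
locus_differentiation <- function(dataset, locus,
                                  mode = c("nei_chesser", "plain")) {
  mode <- match.arg(mode)
  fr <- suppressWarnings(allele_frequencies(dataset, locus))
  N <- length(fr$freqs)
  if (N < 2L)
    return(.missing_diff_row(locus, "fewer than 2 usable populations"))
  h <- hs_ht(fr, mode)
  .diff_row_from_hsht(h, locus, N)
}

#' Differentiation table over all loci
#'
#' @param dataset a [microsat_dataset].
#' @param mode estimator mode, see [hs_ht()].
#' @return Data.frame with one row per locus (see
#'   [locus_differentiation()]); the unweighted across-locus means are in
#'   `attr(., "mean_D")` and `attr(., "mean_GST")`.
#' @export
differentiation_table <- function(dataset,
                                  mode = c("nei_chesser", "plain")) {
  mode <- match.arg(mode)
  rows <- lapply(dataset$loci, function(loc)
    locus_differentiation(dataset, loc, mode))
  out <- do.call(rbind, rows)
  attr(out, "mean_D") <- multilocus_mean(out$D)
  attr(out, "mean_GST") <- multilocus_mean(out$G_ST)
  out
}

#' Unweighted mean over loci
#'
#' Across-locus aggregation is the arithmetic mean of the per-locus
#' statistics (missing loci excluded), not a statistic recomputed from
#' averaged heterozygosities.
#'
#' @param per_locus_values numeric vector of per-locus statistics.
#' @return Their unweighted mean.
#' @export
multilocus_mean <- function(per_locus_values) {
  v <- per_locus_values[!is.na(per_locus_values)]
  if (!length(v)) stop("all per-locus values missing")
  mean(v)
}

#' Differentiation of a sequence alignment treated as one haploid locus
#'
#' Distinct full-length sequences are mapped to allele ids
#' ([as_haplotype_dataset()]) and the allele-based D/G_ST machinery is
#' applied to the resulting single haploid locus.
#'
#' @param alignment a [seq_alignment] (or an already collapsed
#'   [haploid_dataset]).
#' @param mode estimator mode, see [hs_ht()].
#' @return One-row data.frame as in [locus_differentiation()].
#' @export
sequence_differentiation <- function(alignment,
                                     mode = c("nei_chesser", "plain")) {
  mode <- match.arg(mode)
  hd <- if (inherits(alignment, "haploid_dataset")) alignment
        else as_haplotype_dataset(alignment)
  fr <- allele_frequencies(hd)
  N <- length(fr$freqs)
  if (N < 2L)
    return(.missing_diff_row("sequence", "fewer than 2 usable populations"))
  h <- hs_ht(fr, mode)
  row <- .diff_row_from_hsht(h, "sequence", N)
  if (length(unique(hd$alleles)) == 1L) row$note <- "no variation"
  row
}

#' gamma_ST: differentiation from per-nucleotide heterozygosities
#'
#' Per site, plain `H_S` and `H_T` are computed from character frequencies
#' (a sequence with `N` or `-` at a site is excluded at that site only),
#' then averaged over all sites — including monomorphic ones — to give
#' `H_Snuc` and `H_Tnuc`, and
#' `gamma_ST = (H_Tnuc - H_Snuc) / H_Tnuc`. Because per-site
#' heterozygosities stay far from saturation (at most four states), this
#' G_ST-type ratio incorporates genetic distance without the
#' high-diversity suppression that afflicts haplotype-level G_ST.
#'
#' @param alignment a [seq_alignment] with `>= 2` populations of `>= 2`
#'   sequences each.
#' @return List of class `gamma_st_result`: `H_Snuc`, `H_Tnuc`,
#'   `gamma_ST` (`NA` if the alignment has no variation).
#' @export
gamma_st <- function(alignment) {
  stopifnot(inherits(alignment, "seq_alignment"))
  pops <- unique(alignment$populations)
  if (length(pops) < 2L) stop("need >= 2 populations")
  if (any(table(alignment$populations) < 2L))
    stop("need >= 2 sequences per population")
  pre <- .gamma_precompute(alignment)
  res <- .gamma_core(pre, alignment$populations)
  structure(list(H_Snuc = res[["H_Snuc"]], H_Tnuc = res[["H_Tnuc"]],
                 gamma_ST = res[["gamma_ST"]]),
            class = "gamma_st_result")
}

## Precompute per-sequence, per-site base indicators (n x L logical per
## base); permutations only relabel populations, so these are fixed.
.gamma_precompute <- function(alignment) {
  M <- .seq_char_matrix(alignment$seqs)
  list(base_ind = lapply(c("A", "C", "G", "T"), function(b) M == b),
       usable = M == "A" | M == "C" | M == "G" | M == "T",
       L = alignment$length)
}

.gamma_core <- function(pre, populations) {
  pops <- unique(populations)
  K <- length(pops)
  U <- vapply(pops, function(s) as.numeric(populations == s),
              numeric(length(populations)))          # n x K
  tU <- t(U)                                          # K x n
  n_ps <- tU %*% pre$usable                           # K x L usable counts
  use <- n_ps > 0
  sump2 <- matrix(0, K, ncol(n_ps))
  pbar2 <- 0
  nk_site <- colSums(use)                             # pops usable per site
  for (b in 1:4) {
    cnt <- tU %*% pre$base_ind[[b]]                   # K x L
    p <- cnt / ifelse(n_ps > 0, n_ps, 1)
    p[!use] <- 0
    sump2 <- sump2 + p^2
    pb <- colSums(p) / ifelse(nk_site > 0, nk_site, 1)
    pbar2 <- pbar2 + pb^2
  }
  hs_site_pop <- (1 - sump2) * use
  HS_site <- colSums(hs_site_pop) / ifelse(nk_site > 0, nk_site, 1)
  HS_site[nk_site == 0] <- 0
  HT_site <- 1 - pbar2
  HT_site[nk_site == 0] <- 0
  HSn <- mean(HS_site)
  HTn <- mean(HT_site)
  c(H_Snuc = HSn, H_Tnuc = HTn,
    gamma_ST = if (HTn > 0) (HTn - HSn) / HTn else NA_real_)
}

#' Matrix of pairwise Jost's D between populations
#'
#' For each unordered pair of populations, D is computed per locus on the
#' pair (with `N = 2`) and averaged over loci; the diagonal is 0 and the
#' matrix symmetric. Pairs with no usable shared locus get `NA` and are
#' flagged in `attr(., "incomplete_pairs")`.
#'
#' @param dataset a [microsat_dataset] (or [haploid_dataset], treated as
#'   one locus).
#' @param mode estimator mode, see [hs_ht()].
#' @return Symmetric numeric matrix with population labels.
#' @export
pairwise_d <- function(dataset, mode = c("nei_chesser", "plain")) {
  mode <- match.arg(mode)
  pops <- unique(dataset$populations)
  K <- length(pops)
  if (K < 2L) stop("need >= 2 populations")
  M <- matrix(0, K, K, dimnames = list(pops, pops))
  incomplete <- character(0L)
  for (i in 1:(K - 1L)) {
    for (j in (i + 1L):K) {
      sub <- .restrict_pops(dataset, c(pops[i], pops[j]))
      vals <- if (inherits(sub, "haploid_dataset")) {
        row <- tryCatch(sequence_differentiation(sub, mode),
                        error = function(e) NULL)
        if (is.null(row)) NA_real_ else row$D
      } else {
        vapply(sub$loci, function(loc) {
          row <- tryCatch(locus_differentiation(sub, loc, mode),
                          error = function(e) NULL)
          if (is.null(row)) NA_real_ else row$D
        }, numeric(1L))
      }
      if (all(is.na(vals))) {
        M[i, j] <- M[j, i] <- NA_real_
        incomplete <- c(incomplete, paste(pops[i], pops[j], sep = "-"))
      } else {
        M[i, j] <- M[j, i] <- mean(vals, na.rm = TRUE)
      }
    }
  }
  attr(M, "incomplete_pairs") <- incomplete
  M
}

.restrict_pops <- function(x, keep) {
  sel <- x$populations %in% keep
  if (inherits(x, "microsat_dataset")) {
    microsat_dataset(x$ids[sel], x$populations[sel],
                     lapply(x$genotypes, function(g) g[sel, , drop = FALSE]))
  } else if (inherits(x, "haploid_dataset")) {
    haploid_dataset(x$ids[sel], x$populations[sel], x$alleles[sel])
  } else {
    seq_alignment(x$ids[sel], x$populations[sel], x$seqs[sel])
  }
}

#' Mean pairwise sequence divergence between populations
#'
#' Mean number of pairwise differences (per comparable site if
#' `per_site = TRUE`) over all between-population sequence pairs; the
#' genetic-distance input for sequence-based isolation by distance.
#'
#' @param alignment a [seq_alignment].
#' @param per_site divide by the number of compared sites (default TRUE).
#' @return Symmetric matrix with zero diagonal.
#' @export
pairwise_sequence_divergence <- function(alignment, per_site = TRUE) {
  stopifnot(inherits(alignment, "seq_alignment"))
  pops <- unique(alignment$populations)
  K <- length(pops)
  M <- .seq_char_matrix(alignment$seqs)
  ok <- M == "A" | M == "C" | M == "G" | M == "T"
  out <- matrix(0, K, K, dimnames = list(pops, pops))
  for (i in 1:(K - 1L)) {
    for (j in (i + 1L):K) {
      ii <- which(alignment$populations == pops[i])
      jj <- which(alignment$populations == pops[j])
      vals <- numeric(0L)
      for (a in ii) for (b in jj) {
        comp <- ok[a, ] & ok[b, ]
        nc <- sum(comp)
        if (nc == 0L) next
        d <- sum(M[a, comp] != M[b, comp])
        vals <- c(vals, if (per_site) d / nc else d)
      }
      out[i, j] <- out[j, i] <- mean(vals)
    }
  }
  out
}

#' Fragment-length analysis of sequence differentiation
#'
#' Emulates having sequenced only a shorter fragment: for each length `L`,
#' `n_frag` windows are drawn with uniformly random start positions
#' (contiguous, no wrap, sampled with replacement), and on each window the
#' haplotype-based D and G_ST plus a permutation p-value (on D; the
#' permutation stream is shared, and p-values for D and G_ST coincide for
#' haploid data) are computed. Power at a length is the fraction of
#' windows with `p < alpha`.
#'
#' @param alignment a [seq_alignment].
#' @param lengths fragment lengths (bp) to scan.
#' @param n_frag number of random fragments per length (default 20).
#' @param n_perm permutations per fragment (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed (mandatory: the scan is stochastic).
#' @param mode estimator mode, see [hs_ht()].
#' @return List of class `fragment_analysis`: `summary` (per length:
#'   `length`, `mean_D`, `mean_GST`, `power`) and `records` (per fragment:
#'   `length`, `start`, `D`, `G_ST`, `p`).
#' @export
fragment_length_analysis <- function(alignment,
                                     lengths = c(100, 300, 500, 700, 900, 1100),
                                     n_frag = 20, n_perm = 1000,
                                     alpha = 0.05, seed,
                                     mode = c("nei_chesser", "plain")) {
  mode <- match.arg(mode)
  stopifnot(inherits(alignment, "seq_alignment"))
  if (missing(seed)) stop("seed is required")
  if (max(lengths) > alignment$length)
    stop("fragment length ", max(lengths), " exceeds alignment length ",
         alignment$length)
  set.seed(seed)
  recs <- list()
  for (L in lengths) {
    starts <- sample.int(alignment$length - L + 1L, n_frag, replace = TRUE)
    for (f in seq_len(n_frag)) {
      s0 <- starts[f]
      win <- seq_alignment(alignment$ids, alignment$populations,
                           substr(alignment$seqs, s0, s0 + L - 1L))
      hd <- as_haplotype_dataset(win)
      row <- sequence_differentiation(hd, mode)
      if (length(unique(hd$alleles)) == 1L) {
        p <- 1                        # no variation: never significant
      } else if (is.na(row$D)) {
        p <- NA_real_                 # saturated window: untestable
      } else {
        cfg <- permutation_config(n_perm = n_perm,
                                  seed = derive_seed(seed, paste0(L, ":", f)))
        out <- permutation_test(hd, make_d_gst_statistic(hd, mode), cfg)
        p <- out$p[["D"]]
      }
      recs[[length(recs) + 1L]] <- data.frame(
        length = L, start = s0, D = row$D, G_ST = row$G_ST, p = p)
    }
  }
  records <- do.call(rbind, recs)
  summ <- do.call(rbind, lapply(lengths, function(L) {
    r <- records[records$length == L, , drop = FALSE]
    data.frame(length = L,
               mean_D = mean(r$D, na.rm = TRUE),
               mean_GST = mean(r$G_ST, na.rm = TRUE),
               power = mean(!is.na(r$p) & r$p < alpha))
  }))
  structure(list(summary = summ, records = records,
                 n_frag = n_frag, n_perm = n_perm, alpha = alpha),
            class = "fragment_analysis")
}
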