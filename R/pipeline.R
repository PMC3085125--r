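## Report assembly: neighbour-joining trees from pairwise D and the
## end-to-end pipeline (filter -> diversity -> differentiation ->
## permutation tests -> gamma_ST -> pairwise D + NJ -> Mantel -> fragment
## analysis) with a JSON run manifest.

#' Neighbour-joining tree from a pairwise distance matrix
#'
#' Standard neighbour-joining agglomeration (via \pkg{ape}); negative
#' branch lengths, which NJ can produce as estimator noise, are clamped to
#' 0 with the deficit moved to the sister branch so path lengths are
#' preserved. The unrooted tree is serialized as a newick string with
#' branch lengths.
#'
#' @param d complete symmetric matrix (e.g. from [pairwise_d()]) with
#'   labels, `>= 2` taxa.
#' @return A newick string.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (anyNA(d))
    stop("missing cells in distance matrix: imputation is unsupported")
  n <- nrow(d)
  if (n < 2L) stop("need >= 2 taxa")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (n == 2L) {
    h <- d[1L, 2L] / 2
    return(sprintf("(%s:%s,%s:%s);", labs[1L], format(h, digits = 10),
                   labs[2L], format(h, digits = 10)))
  }
  dimnames(d) <- list(labs, labs)
  tree <- ape::nj(stats::as.dist(d))
  tree <- .clamp_negative_edges(tree)
  ape::write.tree(tree)
}

## Zero out negative branch lengths, moving each deficit to a sister
## branch (first sister in edge order as the deterministic tie-break), as
## is conventional after NJ.
.clamp_negative_edges <- function(tree, max_iter = 100L) {
  for (it in seq_len(max_iter)) {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[order(tree$edge.length[neg])][1L]
    parent <- tree$edge[e, 1L]
    sisters <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sisters)) {
      tree$edge.length[sisters[1L]] <-
        tree$edge.length[sisters[1L]] + tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree
}

#' Analysis configuration for [run_pipeline()]
#'
#' @param genotypes path to a wide-TSV genotype table (see
#'   [read_genotype_table()]), or `NULL`.
#' @param fasta,popmap paths to the sequence alignment and its population
#'   map, or `NULL`.
#' @param coords path to a population coordinate table, or `NULL`
#'   (Mantel stage skipped without it).
#' @param mode heterozygosity estimator mode, see [hs_ht()].
#' @param min_n minimum sample size per population (default 5).
#' @param n_perm permutations for significance tests (default 1000).
#' @param fragment_lengths,n_frag fragment-length scan settings.
#' @param alpha significance level (default 0.05).
#' @param seed master integer seed (mandatory: permutation and fragment
#'   stages are stochastic).
#' @param outdir output directory (created if absent).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(genotypes = NULL, fasta = NULL, popmap = NULL,
                            coords = NULL,
                            mode = c("nei_chesser", "plain"),
                            min_n = 5, n_perm = 1000,
                            fragment_lengths = c(100, 300, 500, 700, 900, 1100),
                            n_frag = 20, alpha = 0.05, seed, outdir) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is mandatory")
  if (missing(outdir)) stop("outdir is required")
  for (p in c(genotypes, fasta, popmap, coords)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  if (!is.null(fasta) && is.null(popmap))
    stop("fasta requires a popmap")
  structure(list(genotypes = genotypes, fasta = fasta, popmap = popmap,
                 coords = coords, mode = mode, min_n = min_n,
                 n_perm = as.integer(n_perm),
                 fragment_lengths = fragment_lengths,
                 n_frag = as.integer(n_frag), alpha = alpha,
                 seed = as.integer(seed), outdir = outdir),
            class = "analysis_config")
}

.stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full comparative analysis pipeline
#'
#' Executes, in order: sample-size filter, diversity summaries,
#' per-locus differentiation with permutation p-values, sequence
#' differentiation and gamma_ST (if an alignment is supplied), pairwise D
#' and a neighbour-joining tree, Mantel isolation by distance (if
#' coordinates are supplied) and the fragment-length scan. Writes
#' table-shaped TSVs, a newick file and a JSON run manifest into
#' `config$outdir`. Deterministic under a fixed seed.
#'
#' @param config an [analysis_config()].
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  results <- list()
  note <- function(stage, msg) {
    message("[", stage, "] ", msg)
    log[[length(log) + 1L]] <<- list(stage = stage, message = msg)
  }

  ms <- NULL
  al <- NULL
  coords <- NULL
  .stage("load", log, {
    if (!is.null(config$genotypes)) ms <- read_genotype_table(config$genotypes)
    if (!is.null(config$fasta)) al <- read_alignment(config$fasta, config$popmap)
    if (!is.null(config$coords)) coords <- read_population_table(config$coords)
    note("load", paste0(
      if (!is.null(ms)) paste0(length(ms$ids), " individuals/",
                               length(ms$loci), " loci; ") else "",
      if (!is.null(al)) paste0(length(al$ids), " sequences of ",
                               al$length, " bp") else ""))
  })

  .stage("filter", log, {
    if (!is.null(ms)) {
      ms <- filter_small_samples(ms, config$min_n)
      note("filter", paste0("microsats: removed ",
        length(attr(ms, "removed_populations")), " populations (",
        paste(attr(ms, "removed_populations"), collapse = ", "), "); ",
        length(unique(ms$populations)), " kept"))
    }
    if (!is.null(al)) {
      al <- filter_small_samples(al, config$min_n)
      note("filter", paste0("sequences: removed ",
        length(attr(al, "removed_populations")), " populations; ",
        length(unique(al$populations)), " kept"))
    }
  })

  .stage("diversity", log, {
    if (!is.null(ms)) {
      results$diversity_microsats <- diversity_summary(ms)
      write_results(results$diversity_microsats$per,
                    file.path(config$outdir, "diversity_microsats.tsv"))
      write_results(results$diversity_microsats$by_locus,
                    file.path(config$outdir, "diversity_microsats_by_locus.tsv"))
    }
    if (!is.null(al)) {
      results$diversity_sequences <- diversity_summary(al)
      write_results(results$diversity_sequences$per,
                    file.path(config$outdir, "diversity_sequences.tsv"))
    }
    note("diversity", "summaries written")
  })

  if (!is.null(ms)) .stage("differentiation", log, {
    tab <- differentiation_table(ms, config$mode)
    tab$p_value <- NA_real_
    for (i in seq_len(nrow(tab))) {
      loc <- tab$locus[i]
      if (is.na(tab$D[i])) next
      sub <- microsat_dataset(ms$ids, ms$populations, ms$genotypes[loc])
      cfg <- permutation_config(config$n_perm,
                                derive_seed(config$seed, paste0("diff_", loc)))
      tab$p_value[i] <-
        permutation_test(sub, make_d_gst_statistic(sub, config$mode), cfg)$p[["D"]]
    }
    results$differentiation <- tab
    write_results(tab, file.path(config$outdir, "differentiation_microsats.tsv"))
    note("differentiation",
         sprintf("mean D = %.3f, mean G_ST = %.3f over %d loci",
                 attr(tab, "mean_D"), attr(tab, "mean_GST"), nrow(tab)))
  })

  if (!is.null(al)) .stage("sequence_differentiation", log, {
    hd <- as_haplotype_dataset(al)
    row <- sequence_differentiation(hd, config$mode)
    cfg <- permutation_config(config$n_perm, derive_seed(config$seed, "seqdiff"))
    row$p_value <- if (is.na(row$D) || row$note == "no variation") NA_real_
      else permutation_test(hd, make_d_gst_statistic(hd, config$mode),
                            cfg)$p[["D"]]
    results$sequence_differentiation <- row
    write_results(row, file.path(config$outdir, "differentiation_sequences.tsv"))
    gs <- gamma_st(al)
    gcfg <- permutation_config(config$n_perm, derive_seed(config$seed, "gamma"))
    gp <- if (is.na(gs$gamma_ST)) NA_real_
      else gamma_st_test(al, gcfg)$p[["gamma_ST"]]
    results$gamma_st <- data.frame(H_Snuc = gs$H_Snuc, H_Tnuc = gs$H_Tnuc,
                                   gamma_ST = gs$gamma_ST, p_value = gp)
    write_results(results$gamma_st, file.path(config$outdir, "gamma_st.tsv"))
    note("sequence_differentiation",
         sprintf("D = %.3f, gamma_ST = %.3f", row$D, gs$gamma_ST))
  })

  if (!is.null(ms)) .stage("pairwise_nj", log, {
    pd <- pairwise_d(ms, config$mode)
    results$pairwise_D <- pd
    write_results(cbind(data.frame(population = rownames(pd)),
                        as.data.frame(pd)),
                  file.path(config$outdir, "pairwise_D.tsv"))
    if (!anyNA(pd)) {
      nwk <- nj_tree(pd)
      writeLines(nwk, file.path(config$outdir, "nj_tree.nwk"))
      results$nj <- nwk
    }
    note("pairwise_nj", "pairwise D matrix and NJ tree written")
  })

  if (!is.null(coords)) .stage("mantel", log, {
    rows <- list()
    if (!is.null(results$pairwise_D)) {
      shared <- intersect(rownames(results$pairwise_D), coords$label)
      if (length(shared) >= 3L) {
        geo <- geographic_distances(coords[match(shared, coords$label), ])
        gen <- results$pairwise_D[shared, shared]
        mt <- mantel_test(gen, geo, n_perm = config$n_perm,
                          seed = derive_seed(config$seed, "mantel_ms"))
        rows[[1L]] <- data.frame(data = "microsats_D", r = mt$r, p = mt$p)
      }
    }
    if (!is.null(al)) {
      dv <- pairwise_sequence_divergence(al)
      shared <- intersect(rownames(dv), coords$label)
      if (length(shared) >= 3L) {
        geo <- geographic_distances(coords[match(shared, coords$label), ])
        mt <- mantel_test(dv[shared, shared], geo, n_perm = config$n_perm,
                          seed = derive_seed(config$seed, "mantel_seq"))
        rows[[length(rows) + 1L]] <-
          data.frame(data = "sequence_divergence", r = mt$r, p = mt$p)
      }
    }
    if (length(rows)) {
      results$mantel <- do.call(rbind, rows)
      write_results(results$mantel, file.path(config$outdir, "mantel.tsv"))
    }
    note("mantel", paste(length(rows), "isolation-by-distance tests"))
  })

  if (!is.null(al)) .stage("fragments", log, {
    fl <- config$fragment_lengths[config$fragment_lengths <= al$length]
    fa <- fragment_length_analysis(
      al, lengths = fl, n_frag = config$n_frag, n_perm = config$n_perm,
      alpha = config$alpha, seed = derive_seed(config$seed, "fragments"),
      mode = config$mode)
    results$fragments <- fa
    write_results(fa$summary, file.path(config$outdir, "fragments_summary.tsv"))
    write_results(fa$records, file.path(config$outdir, "fragments_records.tsv"))
    note("fragments", paste("scanned lengths:", paste(fl, collapse = ", ")))
  })

  manifest <- list(
    package = "jostdiv",
    version = as.character(utils::packageVersion("jostdiv")),
    config = config[setdiff(names(config), "outdir")],
    seed = config$seed,
    stages = log,
    outputs = list.files(config$outdir))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(list(results = results, manifest = manifest))
}
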