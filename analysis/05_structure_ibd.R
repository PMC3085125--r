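#!/usr/bin/env Rscript
# Stage 5: spatial structure.
#
# Per species: the matrix of pairwise D between demes (averaged over
# loci, N = 2 per pair), its neighbour-joining tree, and Mantel
# isolation-by-distance tests of pairwise D (microsatellites) and mean
# pairwise sequence divergence (mtDNA) against great-circle distance.
# Under the finite-island model migration is distance-independent, so the
# Mantel correlations should hover around zero.

suppressMessages(library(jostdiv))

SEED <- 42L
profiles <- c("host_primary", "host_secondary", "parasite")

for (prof in profiles) {
  dir <- file.path("results", "fixtures", prof)
  out <- file.path("results", prof)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  ms <- filter_small_samples(read_genotype_table(
    file.path(dir, "genotypes.tsv")), min_n = 5)
  al <- filter_small_samples(read_alignment(
    file.path(dir, "alignment.fasta"), file.path(dir, "popmap.tsv")),
    min_n = 5)
  coords <- read_population_table(file.path(dir, "coords.tsv"))

  pd <- pairwise_d(ms, "nei_chesser")
  write_results(cbind(data.frame(population = rownames(pd)),
                      as.data.frame(pd)),
                file.path(out, "pairwise_D.tsv"))
  nwk <- nj_tree(pd)
  writeLines(nwk, file.path(out, "nj_tree.nwk"))

  geo <- geographic_distances(coords[match(rownames(pd), coords$label), ])
  mt_ms <- mantel_test(pd, geo, n_perm = 1000,
                       seed = derive_seed(SEED, paste0(prof, "ibd_ms")))
  dv <- pairwise_sequence_divergence(al)
  geo2 <- geographic_distances(coords[match(rownames(dv), coords$label), ])
  mt_seq <- mantel_test(dv, geo2, n_perm = 1000,
                        seed = derive_seed(SEED, paste0(prof, "ibd_seq")))
  write_results(data.frame(data = c("microsats_D", "sequence_divergence"),
                           r = c(mt_ms$r, mt_seq$r),
                           p = c(mt_ms$p, mt_seq$p)),
                file.path(out, "mantel_ibd.tsv"))

  cat(sprintf("%-14s NJ: %s\n", prof, nwk))
  cat(sprintf("%-14s IBD microsats r = %5.2f (P = %.2f); mtDNA r = %5.2f (P = %.2f)\n",
              prof, mt_ms$r, mt_ms$p, mt_seq$r, mt_seq$p))
}
cat("structure/IBD outputs written under results/<profile>/\n")
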