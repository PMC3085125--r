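## Data containers and file I/O: genotype tables, sequence alignments,
## population coordinate tables, the minimum-sample filter and result export.

#' Construct a diploid multilocus microsatellite dataset
#'
#' The universal container for the microsatellite side of the pipeline:
#' one record per individual (id, population label) and, per locus, an
#' ordered pair of allele labels. Allele labels are positive integers
#' (binned fragment or repeat lengths). A genotype is missing only as a
#' whole pair — exactly one `NA` allele slot is invalid.
#'
#' @param ids character vector of unique individual identifiers.
#' @param populations character vector of population labels, same length.
#' @param genotypes named list, one element per locus, each an
#'   `n x 2` integer matrix of allele labels (`NA` pairs allowed).
#' @return An object of class `microsat_dataset`.
#' @export
microsat_dataset <- function(ids, populations, genotypes) {
  ids <- as.character(ids)
  populations <- as.character(populations)
  n <- length(ids)
  if (length(populations) != n)
    stop("ids and populations must have the same length")
  if (anyDuplicated(ids))
    stop("duplicate individual id: ", ids[duplicated(ids)][1L])
  if (any(!nzchar(populations)) || anyNA(populations))
    stop("population labels must be non-empty strings")
  if (is.null(names(genotypes)) || any(!nzchar(names(genotypes))))
    stop("genotypes must be a named list (one element per locus)")
  genotypes <- lapply(genotypes, function(g) {
    g <- as.matrix(g)
    storage.mode(g) <- "integer"
    g
  })
  for (loc in names(genotypes)) {
    g <- genotypes[[loc]]
    if (nrow(g) != n || ncol(g) != 2L)
      stop("locus ", loc, ": genotype matrix must be n x 2")
    half <- xor(is.na(g[, 1L]), is.na(g[, 2L]))
    if (any(half))
      stop("half-missing genotype at locus ", loc, ", individual ",
           ids[which(half)[1L]])
    ok <- !is.na(g[, 1L])
    if (any(g[ok, ] <= 0L))
      stop("locus ", loc, ": allele labels must be positive integers")
  }
  structure(
    list(ids = ids, populations = populations,
         loci = names(genotypes), genotypes = genotypes),
    class = "microsat_dataset")
}

#' @export
print.microsat_dataset <- function(x, ...) {
  cat("<microsat_dataset> ", length(x$ids), " individuals, ",
      length(x$loci), " loci, ",
      length(unique(x$populations)), " populations\n", sep = "")
  invisible(x)
}

#' Construct a haploid sequence alignment with population labels
#'
#' Equal-length haploid sequences (e.g. an mtDNA COI/COII alignment) over
#' the alphabet `A, C, G, T, N, -`. Sequences are uppercased on entry.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param populations character vector of population labels.
#' @param seqs character vector of equal-length sequences.
#' @return An object of class `seq_alignment` with a `length` field (bp).
#' @export
seq_alignment <- function(ids, populations, seqs) {
  ids <- as.character(ids)
  populations <- as.character(populations)
  seqs <- toupper(as.character(seqs))
  n <- length(ids)
  if (length(populations) != n || length(seqs) != n)
    stop("ids, populations and seqs must have the same length")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  if (any(!nzchar(populations)) || anyNA(populations))
    stop("population labels must be non-empty strings")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  L <- lens[1L]
  if (L < 1L) stop("alignment length must be >= 1")
  bad <- regexpr("[^ACGTN-]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal character '", substr(seqs[i], bad[i], bad[i]),
         "' in sequence ", ids[i], " at position ", bad[i])
  }
  structure(
    list(ids = ids, populations = populations, seqs = seqs,
         length = as.integer(L)),
    class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("<seq_alignment> ", length(x$ids), " sequences of ", x$length,
      " bp, ", length(unique(x$populations)), " populations\n", sep = "")
  invisible(x)
}

#' Construct a population coordinate table
#'
#' Latitude is decimal degrees North; longitude is given as decimal degrees
#' West (as in field tables for North American sites) and stored internally
#' as negative degrees East, the usual GIS sign convention.
#'
#' @param label unique population labels.
#' @param lat latitude, decimal degrees North.
#' @param lon_west longitude, decimal degrees West (positive numbers).
#' @return A data.frame of class `population_table` with columns
#'   `label`, `lat`, `lon` (degrees East, negative for the western
#'   hemisphere).
#' @export
population_table <- function(label, lat, lon_west) {
  label <- as.character(label)
  if (anyDuplicated(label)) stop("population labels must be unique")
  if (!all(is.finite(lat)) || !all(is.finite(lon_west)))
    stop("coordinates must be finite")
  out <- data.frame(label = label, lat = as.numeric(lat),
                    lon = -as.numeric(lon_west),
                    stringsAsFactors = FALSE)
  class(out) <- c("population_table", "data.frame")
  out
}

#' Read a wide-format genotype table
#'
#' Dialect: tab-separated, header row, columns `id`, `population`, then two
#' columns per locus named `<locus>.1` and `<locus>.2`. Missing genotypes
#' are coded by a configurable token set (default `"0"` or `"NA"`) and are
#' only valid as whole pairs.
#'
#' @param path path to the TSV file.
#' @param missing_tokens character vector of tokens coding a missing allele.
#' @return A [microsat_dataset].
#' @export
read_genotype_table <- function(path, missing_tokens = c("0", "NA")) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 4L)
    stop("format error: need id, population and at least one locus pair")
  if (!identical(colnames(tab)[1:2], c("id", "population")))
    stop("format error: first two columns must be 'id' and 'population'")
  acols <- colnames(tab)[-(1:2)]
  if (length(acols) %% 2L != 0L)
    stop("format error: odd number of allele columns (", length(acols), ")")
  loci <- unique(sub("\\.[12]$", "", acols))
  expected <- as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
  if (!identical(acols, expected))
    stop("format error: allele columns must come in '<locus>.1','<locus>.2' pairs")
  parse_col <- function(col) {
    v <- tab[[col]]
    v[v %in% missing_tokens] <- NA_character_
    num <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & (is.na(num) | num <= 0L |
                                num != suppressWarnings(as.numeric(v))))
    if (length(bad))
      stop("parse error: non-integer allele token '", v[bad[1L]],
           "' in row ", bad[1L], ", column ", col)
    num
  }
  genotypes <- lapply(loci, function(loc) {
    cbind(parse_col(paste0(loc, ".1")), parse_col(paste0(loc, ".2")))
  })
  names(genotypes) <- loci
  microsat_dataset(tab$id, tab$population, genotypes)
}

#' Write a genotype table in the package's wide TSV dialect
#'
#' @param dataset a [microsat_dataset].
#' @param path output path.
#' @param missing_token token used for missing alleles (default `"NA"`).
#' @return Invisibly, `path`.
#' @export
write_genotype_table <- function(dataset, path, missing_token = "NA") {
  stopifnot(inherits(dataset, "microsat_dataset"))
  cols <- list(id = dataset$ids, population = dataset$populations)
  for (loc in dataset$loci) {
    g <- dataset$genotypes[[loc]]
    for (j in 1:2) {
      v <- as.character(g[, j])
      v[is.na(v)] <- missing_token
      cols[[paste0(loc, ".", j)]] <- v
    }
  }
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FASTA alignment plus a population map
#'
#' @param fasta_path FASTA file of aligned equal-length sequences.
#' @param popmap_path two-column TSV (no header): sequence id, population.
#' @return A [seq_alignment].
#' @export
read_alignment <- function(fasta_path, popmap_path) {
  if (!file.exists(fasta_path)) stop("file not found: ", fasta_path)
  if (!file.exists(popmap_path)) stop("file not found: ", popmap_path)
  ss <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate sequence id in FASTA: ", ids[duplicated(ids)][1L])
  pm <- read.table(popmap_path, header = FALSE, sep = "\t",
                   colClasses = "character")
  if (ncol(pm) < 2L) stop("popmap must have two columns: id, population")
  pops <- setNames(pm[[2L]], pm[[1L]])
  missing <- setdiff(ids, names(pops))
  if (length(missing))
    stop("ids missing from popmap: ", paste(missing, collapse = ", "))
  seq_alignment(ids, unname(pops[ids]), as.character(ss))
}

#' Write a FASTA alignment plus a population map
#'
#' @param alignment a [seq_alignment].
#' @param fasta_path output FASTA path.
#' @param popmap_path output popmap TSV path.
#' @return Invisibly, `fasta_path`.
#' @export
write_alignment <- function(alignment, fasta_path, popmap_path) {
  stopifnot(inherits(alignment, "seq_alignment"))
  ss <- Biostrings::BStringSet(setNames(alignment$seqs, alignment$ids))
  Biostrings::writeXStringSet(ss, fasta_path, width = 80L)
  write.table(data.frame(alignment$ids, alignment$populations),
              popmap_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(fasta_path)
}

#' Drop population samples smaller than a minimum size
#'
#' Power to detect differentiation collapses when some samples are very
#' small, so populations with fewer than `min_n` individuals (or sequences)
#' are removed entirely before analysis. The default of 5 is the
#' conventional cutoff for this family of statistics.
#'
#' @param x a [microsat_dataset] or [seq_alignment].
#' @param min_n minimum sample size to keep a population (default 5).
#' @return The filtered object; removed population labels are available in
#'   `attr(., "removed_populations")`. Genotypes/sequences of surviving
#'   individuals are untouched.
#' @export
filter_small_samples <- function(x, min_n = 5) {
  UseMethod("filter_small_samples")
}

.filter_keep <- function(populations, min_n) {
  if (min_n < 1) stop("min_n must be >= 1")
  cnt <- table(populations)
  removed <- names(cnt)[cnt < min_n]
  if (length(removed) == length(cnt))
    stop("no populations survive filter (min_n = ", min_n, ")")
  list(keep = !(populations %in% removed), removed = removed)
}

#' @export
filter_small_samples.microsat_dataset <- function(x, min_n = 5) {
  f <- .filter_keep(x$populations, min_n)
  out <- microsat_dataset(
    x$ids[f$keep], x$populations[f$keep],
    lapply(x$genotypes, function(g) g[f$keep, , drop = FALSE]))
  attr(out, "removed_populations") <- f$removed
  out
}

#' @export
filter_small_samples.seq_alignment <- function(x, min_n = 5) {
  f <- .filter_keep(x$populations, min_n)
  out <- seq_alignment(x$ids[f$keep], x$populations[f$keep], x$seqs[f$keep])
  attr(out, "removed_populations") <- f$removed
  out
}

#' @export
filter_small_samples.haploid_dataset <- function(x, min_n = 5) {
  f <- .filter_keep(x$populations, min_n)
  out <- haploid_dataset(x$ids[f$keep], x$populations[f$keep],
                         x$alleles[f$keep])
  attr(out, "removed_populations") <- f$removed
  out
}

#' Write a result table to TSV or JSON
#'
#' Deterministic column order and float formatting (fixed number of
#' significant digits), so identical results produce byte-identical files.
#'
#' @param result a data.frame (or coercible) of results.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @param digits significant digits for numeric columns (default 6).
#' @return Invisibly, `path`.
#' @export
write_results <- function(result, path, format = c("tsv", "json"),
                          digits = 6) {
  format <- match.arg(format)
  df <- as.data.frame(result, stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  if (format == "tsv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                eol = "\n", na = "NA")
  } else {
    jsonlite::write_json(df, path, dataframe = "columns", digits = NA,
                         na = "null", auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path file path.
#' @param format `"tsv"` or `"json"`.
#' @return A data.frame.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                  stringsAsFactors = FALSE)
  }
}

#' Write a population coordinate table
#'
#' Longitude is written back in the degrees-West convention used on input.
#'
#' @param tab a [population_table].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_population_table <- function(tab, path) {
  stopifnot(inherits(tab, "population_table"))
  out <- data.frame(label = tab$label, lat = tab$lat, lon_west = -tab$lon)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population coordinate table
#'
#' @param path TSV with columns `label`, `lat`, `lon_west`.
#' @return A [population_table].
#' @export
read_population_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  population_table(tab$label, tab$lat, tab$lon_west)
}
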