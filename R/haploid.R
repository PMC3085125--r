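## Haploid one-locus allele data: the common currency between the sequence
## side (haplotypes collapsed to allele ids) and the allele-based statistics.

#' Construct a haploid one-locus dataset
#'
#' One allele label per individual (e.g. an mtDNA haplotype id). Used by the
#' sequence-based differentiation machinery, which collapses identical
#' full-length sequences to allele ids and then treats the alignment as a
#' single haploid locus.
#'
#' @param ids character vector of unique identifiers.
#' @param populations character vector of population labels.
#' @param alleles positive integer allele labels.
#' @return An object of class `haploid_dataset`.
#' @export
haploid_dataset <- function(ids, populations, alleles) {
  ids <- as.character(ids)
  populations <- as.character(populations)
  alleles <- as.integer(alleles)
  n <- length(ids)
  if (length(populations) != n || length(alleles) != n)
    stop("ids, populations and alleles must have the same length")
  if (anyDuplicated(ids)) stop("duplicate id")
  if (anyNA(alleles) || any(alleles <= 0L))
    stop("allele labels must be positive integers")
  structure(list(ids = ids, populations = populations, alleles = alleles),
            class = "haploid_dataset")
}

#' @export
print.haploid_dataset <- function(x, ...) {
  cat("<haploid_dataset> ", length(x$ids), " individuals, ",
      length(unique(x$alleles)), " alleles, ",
      length(unique(x$populations)), " populations\n", sep = "")
  invisible(x)
}

#' Collapse an alignment to haplotype alleles
#'
#' Two sequences carry the same allele iff they are identical over all
#' sites (after uppercasing); `N` and `-` are treated as ordinary,
#' distinct characters for this identity rule. Allele ids are assigned in
#' order of first appearance.
#'
#' @param alignment a [seq_alignment].
#' @return A [haploid_dataset] whose alleles are haplotype ids.
#' @export
as_haplotype_dataset <- function(alignment) {
  stopifnot(inherits(alignment, "seq_alignment"))
  ids <- match(alignment$seqs, unique(alignment$seqs))
  haploid_dataset(alignment$ids, alignment$populations, ids)
}
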