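#' Published F2 segregation counts at the two incompatibility regions
#'
#' Per-marker a/h/b genotype counts observed in the selfed F2 progeny of
#' the Trinitario clone TSH 516 (an ICS 1 x Scavina 6 hybrid), at SSR
#' markers covering the chromosome-1 and chromosome-4 incompatibility
#' regions.  Class \code{a} is homozygous for the ICS 1 (Amelonado-type)
#' allele, \code{b} homozygous for the Scavina 6 allele, \code{h}
#' heterozygous.  The chromosome-1 region shows a complete absence of
#' class \code{a} over six consecutive markers; the chromosome-4 region a
#' complete absence of class \code{b} over twenty markers.  Each marker
#' was genotyped on its own subset of individuals, so totals differ
#' between markers.
#'
#' @param path optional override of the shipped TSV.
#' @return data.frame: marker, chrom, pos, n_a, n_h, n_b.
#' @export
f2_segregation_counts <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "f2_tsh516_counts.tsv",
                        package = "cacaoSI", mustWork = TRUE)
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  out$pos <- strip_pos(out$pos)
  out
}

#' Expand per-marker genotype counts into a marker table
#'
#' Count-preserving expansion: builds an individual-level marker table
#' whose per-marker a/h/b counts reproduce the given counts exactly.  The
#' number of individuals is the largest per-marker total; at each marker
#' the first \code{n_a} individuals are coded \code{a}, the next
#' \code{n_h} are \code{h}, the next \code{n_b} are \code{b} and the rest
#' are missing.  Only per-marker counts are meaningful in the result
#' (which is all the segregation scan uses); the co-genotyping structure
#' across markers is not reconstructed.
#'
#' @param counts data.frame with columns marker, chrom, pos, n_a, n_h,
#'   n_b.
#' @return A marker table (see \code{\link{as_marker_table}}).
#' @export
counts_to_marker_table <- function(counts) {
  need <- c("marker", "chrom", "pos", "n_a", "n_h", "n_b")
  stopifnot(all(need %in% names(counts)))
  n <- max(counts$n_a + counts$n_h + counts$n_b)
  out <- counts[, c("marker", "chrom", "pos")]
  codes <- t(vapply(seq_len(nrow(counts)), function(i) {
    v <- c(rep("a", counts$n_a[i]), rep("h", counts$n_h[i]),
           rep("b", counts$n_b[i]))
    c(v, rep(NA_character_, n - length(v)))
  }, character(n)))
  for (j in seq_len(n)) out[[paste0("ind_", j)]] <- codes[, j]
  as_marker_table(out)
}
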