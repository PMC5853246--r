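#' SSR allele frequencies by genetic group
#'
#' Simple allele-count proportions per (group, marker): each non-missing
#' individual contributes two allele copies, so the frequency of an allele
#' is its copy count divided by twice the number of genotyped individuals.
#' No null-allele or inbreeding correction is applied (the reference
#' groups include fully homozygous varieties, where such corrections are
#' moot).  Frequencies sum to 1 over observed alleles within each
#' (group, marker); a group with zero non-missing calls at a marker is
#' omitted with a warning.
#'
#' @param table grouped SSR table: an SSR genotype table (see
#'   \code{\link{ssr-tables}}) with an additional \code{group} column
#'   giving each individual's genetic group (Amelonado, Criollo, ...).
#' @return data.frame with columns group, marker, allele, count, n_ind,
#'   freq.
#' @export
allele_frequencies <- function(table) {
  stopifnot("group" %in% names(table))
  table <- normalize_ssr_table(table)
  markers <- ssr_marker_cols(table)
  out <- list()
  for (g in sort(unique(table$group))) {
    sub <- table[table$group == g, , drop = FALSE]
    for (m in sort(markers)) {
      cells <- sub[[m]]
      ok <- !is.na(cells)
      if (!any(ok)) {
        warning("group '", g, "' has no genotyped individual at marker '",
                m, "'; frequency row omitted")
        next
      }
      copies <- unlist(strsplit(cells[ok], "/", fixed = TRUE))
      tab <- table(copies)
      out[[length(out) + 1L]] <- data.frame(
        group = g, marker = m, allele = as.numeric(names(tab)),
        count = as.integer(tab), n_ind = sum(ok),
        freq = as.numeric(tab) / (2 * sum(ok)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) stop("no genotyped (group, marker) cell")
  res <- do.call(rbind, out)
  res <- res[order(res$group, res$marker, res$allele), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Variety-specific (private) alleles
#'
#' Flags alleles that characterize one genetic group: frequency at least
#' \code{f_min} in the target group and at most \code{epsilon} in every
#' other group.  An allele entirely absent elsewhere is \code{"strict"};
#' an allele with nonzero frequency up to \code{epsilon} in some other
#' group(s) is \code{"diagnostic-with-leakage"} and the leakage groups are
#' listed (low-frequency leakage typically reflects introgression of the
#' variety into those groups).
#'
#' @param freqs frequency table from \code{\link{allele_frequencies}}.
#' @param target_group group whose private alleles are sought.
#' @param epsilon tolerated leakage frequency in non-target groups
#'   (default 0.05).
#' @param f_min minimum frequency in the target group (default 0.5).
#' @return data.frame: marker, allele, target_group, freq_target,
#'   max_freq_elsewhere, leakage_groups (comma-joined), status.
#' @export
specific_alleles <- function(freqs, target_group, epsilon = 0.05,
                             f_min = 0.5) {
  if (!target_group %in% freqs$group)
    stop("unknown group: ", target_group)
  tgt <- freqs[freqs$group == target_group & freqs$freq >= f_min, ,
               drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tgt))) {
    m <- tgt$marker[i]; al <- tgt$allele[i]
    other <- freqs[freqs$group != target_group & freqs$marker == m &
                     freqs$allele == al, , drop = FALSE]
    max_elsewhere <- if (nrow(other)) max(other$freq) else 0
    if (max_elsewhere > epsilon) next
    leak <- other$group[other$freq > 0]
    out[[length(out) + 1L]] <- data.frame(
      marker = m, allele = al, target_group = target_group,
      freq_target = tgt$freq[i], max_freq_elsewhere = max_elsewhere,
      leakage_groups = paste(sort(leak), collapse = ","),
      status = if (max_elsewhere == 0) "strict" else
        "diagnostic-with-leakage",
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(marker = character(0), allele = numeric(0),
                      target_group = character(0), freq_target = numeric(0),
                      max_freq_elsewhere = numeric(0),
                      leakage_groups = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$marker, res$allele), , drop = FALSE]
}

#' Two-marker haplotype discriminators for a shared allele
#'
#' When two groups share an allele at one marker (so that allele alone
#' cannot resolve a haplotype's origin), this searches the other markers
#' for alleles frequent in one group (>= \code{f_min}) and rare or absent
#' in the other (<= \code{epsilon}); typing such an allele alongside the
#' shared one resolves the origin.
#'
#' @param freqs frequency table from \code{\link{allele_frequencies}}.
#' @param group_a,group_b the two groups sharing the allele.
#' @param shared_allele length-2 vector \code{c(marker, allele)}.
#' @param epsilon,f_min as in \code{\link{specific_alleles}}.
#' @return data.frame: marker, allele, direction (\code{"a_not_b"} or
#'   \code{"b_not_a"}), freq_a, freq_b.
#' @export
haplotype_discriminators <- function(freqs, group_a, group_b, shared_allele,
                                     epsilon = 0.05, f_min = 0.5) {
  sm <- shared_allele[[1]]; sa <- as.numeric(shared_allele[[2]])
  freq_of <- function(g, m, al) {
    r <- freqs[freqs$group == g & freqs$marker == m & freqs$allele == al, ]
    if (nrow(r)) r$freq[1] else 0
  }
  if (freq_of(group_a, sm, sa) == 0 || freq_of(group_b, sm, sa) == 0)
    stop("shared allele absent from one of the groups")
  out <- list()
  markers <- setdiff(unique(freqs$marker), sm)
  for (m in sort(markers)) {
    alleles <- unique(freqs$allele[freqs$marker == m &
                                     freqs$group %in% c(group_a, group_b)])
    for (al in sort(alleles)) {
      fa <- freq_of(group_a, m, al); fb <- freq_of(group_b, m, al)
      dir <- if (fa >= f_min && fb <= epsilon) "a_not_b"
      else if (fb >= f_min && fa <= epsilon) "b_not_a" else NA
      if (is.na(dir)) next
      out[[length(out) + 1L]] <- data.frame(
        marker = m, allele = al, direction = dir, freq_a = fa, freq_b = fb,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(marker = character(0), allele = numeric(0),
                      direction = character(0), freq_a = numeric(0),
                      freq_b = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
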