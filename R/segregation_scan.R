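#' Validate and sort a progeny marker table
#'
#' A marker table has one row per marker with columns \code{marker},
#' \code{chrom}, \code{pos} (bp), followed by one column per individual
#' holding a genotype code: \code{a} (homozygous for the parent-A allele),
#' \code{h} (heterozygous), \code{b} (homozygous for the parent-B allele)
#' or missing (\code{NA}).  Rows are sorted by (chrom, pos); markers with
#' identical printed positions are kept distinct, ties broken by input
#' order.
#'
#' @param table data.frame as above.
#' @return The validated, sorted data.frame.
#' @export
as_marker_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(table)))
    stop("marker table needs columns marker, chrom, pos")
  if (anyDuplicated(table$marker))
    stop("duplicate marker names: ",
         paste(unique(table$marker[duplicated(table$marker)]), collapse = ", "))
  if (!is.numeric(table$pos) || anyNA(table$pos))
    stop("non-numeric marker positions")
  ind_cols <- setdiff(names(table), need)
  for (cc in ind_cols) {
    v <- table[[cc]]
    bad <- !is.na(v) & !(v %in% c("a", "h", "b"))
    if (any(bad))
      stop("invalid genotype code(s) in column '", cc, "' at marker(s) ",
           paste(table$marker[bad], collapse = ", "))
  }
  ord <- order(table$chrom, table$pos)
  out <- table[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

marker_individual_cols <- function(table)
  setdiff(names(table), c("marker", "chrom", "pos"))

#' Genotype counts at a marker
#'
#' @param table a marker table (see \code{\link{as_marker_table}}).
#' @param marker marker name.
#' @return Named integer vector \code{c(a, h, b, missing)}.  Missing calls
#'   are excluded from downstream tests.
#' @export
genotype_counts <- function(table, marker) {
  i <- match(marker, table$marker)
  if (is.na(i)) stop("unknown marker: ", marker)
  v <- unlist(table[i, marker_individual_cols(table)], use.names = FALSE)
  c(a = sum(v == "a", na.rm = TRUE),
    h = sum(v == "h", na.rm = TRUE),
    b = sum(v == "b", na.rm = TRUE),
    missing = sum(is.na(v)))
}

all_genotype_counts <- function(table) {
  cols <- marker_individual_cols(table)
  m <- as.matrix(table[, cols, drop = FALSE])
  data.frame(marker = table$marker, chrom = table$chrom, pos = table$pos,
             n_a = rowSums(m == "a", na.rm = TRUE),
             n_h = rowSums(m == "h", na.rm = TRUE),
             n_b = rowSums(m == "b", na.rm = TRUE),
             n_missing = rowSums(is.na(m)),
             stringsAsFactors = FALSE)
}

parse_ratio <- function(expected_ratio) {
  if (is.character(expected_ratio) && length(expected_ratio) == 1L)
    expected_ratio <- as.numeric(strsplit(expected_ratio, ":",
                                          fixed = TRUE)[[1]])
  if (anyNA(expected_ratio) || any(expected_ratio < 0) ||
      sum(expected_ratio) <= 0)
    stop("invalid expected ratio")
  if (length(expected_ratio) != 3L)
    stop("expected ratio must have three terms (a:h:b)")
  expected_ratio / sum(expected_ratio)
}

# exact multinomial goodness-of-fit tail: sum of probabilities of all
# outcomes no more probable than the observed one
exact_multinomial_p <- function(counts, probs) {
  n <- sum(counts)
  k <- length(counts)
  logp_obs <- stats::dmultinom(counts, prob = probs, log = TRUE)
  tol <- 1e-9
  if (k == 1L) return(1)
  if (k == 2L) {
    x <- 0:n
    lp <- stats::dbinom(x, n, probs[1], log = TRUE)
    return(sum(exp(lp[lp <= logp_obs + tol])))
  }
  # k == 3: vectorized enumeration over (x1, x2)
  x1 <- rep(0:n, each = n + 1L)
  x2 <- rep(0:n, times = n + 1L)
  keep <- x1 + x2 <= n
  x1 <- x1[keep]; x2 <- x2[keep]; x3 <- n - x1 - x2
  lp <- lfactorial(n) - lfactorial(x1) - lfactorial(x2) - lfactorial(x3) +
    x1 * log(probs[1]) + x2 * log(probs[2]) + x3 * log(probs[3])
  sum(exp(lp[lp <= logp_obs + tol]))
}

#' Goodness-of-fit test of a genotype segregation ratio
#'
#' Chi-square goodness of fit of observed a/h/b counts against an expected
#' ratio such as 1:2:1, restricted to the classes with nonzero expectation
#' (df = classes with nonzero expectation minus 1).  When any expected
#' count is below 5 an exact multinomial tail probability is used instead.
#' A nonzero observed count in a class with zero expectation is impossible
#' under the model: statistic \code{Inf}, p = 0.
#'
#' @param counts numeric vector of observed counts \code{c(a, h, b)} (a
#'   \code{missing} element, if present, is ignored).
#' @param expected_ratio ratio as numeric vector or string (\code{"1:2:1"},
#'   \code{"0:2:1"}).
#' @return List with \code{statistic}, \code{p}, \code{df}, \code{method}.
#' @examples
#' segregation_test(c(25, 50, 25), "1:2:1")  # p = 1
#' segregation_test(c(0, 77, 32), "0:2:1")   # X2 ~ 0.774
#' @export
segregation_test <- function(counts, expected_ratio = c(1, 2, 1)) {
  if (!is.null(names(counts)))
    counts <- counts[setdiff(names(counts), "missing")]
  counts <- as.numeric(counts)
  if (length(counts) != 3L) stop("counts must be (a, h, b)")
  ratio <- parse_ratio(expected_ratio)
  n <- sum(counts)
  if (n < 1) stop("zero total count: marker not testable")
  zero_exp <- ratio == 0
  if (any(counts[zero_exp] > 0))
    return(list(statistic = Inf, p = 0, df = sum(!zero_exp) - 1L,
                method = "impossible-class"))
  obs <- counts[!zero_exp]
  pr <- ratio[!zero_exp] / sum(ratio[!zero_exp])
  expd <- n * pr
  stat <- sum((obs - expd)^2 / expd)
  df <- length(obs) - 1L
  if (df == 0L)
    return(list(statistic = 0, p = 1, df = 0L, method = "degenerate"))
  if (any(expd < 5)) {
    p <- exact_multinomial_p(obs, pr)
    method <- "exact-multinomial"
  } else {
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    method <- "chi-square"
  }
  list(statistic = stat, p = min(p, 1), df = df, method = method)
}

#' Scan all markers for segregation distortion
#'
#' Applies \code{\link{segregation_test}} to every testable marker and
#' adjusts p-values for multiple testing with Benjamini-Hochberg
#' \code{\link{bh_qvalues}}; markers are flagged distorted when q <= alpha.
#'
#' @param table a marker table.
#' @param expected_ratio segregation ratio to test (default 1:2:1, a selfed
#'   F2; pass e.g. "0:2:1" to test the model-conditional ratio).
#' @param alpha FDR threshold for the distorted flag (default 0.05).
#' @param min_calls minimum non-missing calls for a marker to be testable
#'   (default 20).
#' @return data.frame with one row per testable marker: counts, statistic,
#'   p, q, distorted.
#' @export
scan_markers <- function(table, expected_ratio = c(1, 2, 1), alpha = 0.05,
                         min_calls = 20L) {
  table <- as_marker_table(table)
  cnt <- all_genotype_counts(table)
  testable <- (cnt$n_a + cnt$n_h + cnt$n_b) >= min_calls
  if (!any(testable)) stop("no testable marker (all below min_calls)")
  cnt <- cnt[testable, , drop = FALSE]
  res <- lapply(seq_len(nrow(cnt)), function(i)
    segregation_test(c(cnt$n_a[i], cnt$n_h[i], cnt$n_b[i]), expected_ratio))
  cnt$statistic <- vapply(res, `[[`, 0, "statistic")
  cnt$p <- vapply(res, `[[`, 0, "p")
  cnt$method <- vapply(res, `[[`, "", "method")
  cnt$q <- bh_qvalues(cnt$p)
  cnt$distorted <- cnt$q <= alpha
  rownames(cnt) <- NULL
  cnt
}

#' Find runs of markers with a genotype class completely absent
#'
#' Reports maximal runs of consecutive markers (within a chromosome, in map
#' order) whose count of the given class is zero, the signature of complete
#' gametic or zygotic selection against that class at a linked locus.
#'
#' @param table a marker table.
#' @param class genotype class, one of \code{"a"}, \code{"h"}, \code{"b"}.
#' @param min_run minimum number of markers in a reported run (default 1).
#' @return data.frame with one row per run: chrom, absent_class,
#'   start_marker, end_marker, start_pos, end_pos, n_markers, markers
#'   (comma-joined).  Zero rows when no run exists.
#' @export
find_absent_runs <- function(table, class = c("a", "h", "b"), min_run = 1L) {
  class <- match.arg(class)
  table <- as_marker_table(table)
  cnt <- all_genotype_counts(table)
  zero <- cnt[[paste0("n_", class)]] == 0
  out <- list()
  for (ch in unique(cnt$chrom)) {
    idx <- which(cnt$chrom == ch)
    z <- zero[idx]
    if (!any(z)) next
    r <- rle(z)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_run)) {
      ii <- idx[starts[j]:ends[j]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, absent_class = class,
        start_marker = cnt$marker[ii[1]],
        end_marker = cnt$marker[ii[length(ii)]],
        start_pos = cnt$pos[ii[1]], end_pos = cnt$pos[ii[length(ii)]],
        n_markers = length(ii),
        markers = paste(cnt$marker[ii], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), absent_class = character(0),
                      start_marker = character(0), end_marker = character(0),
                      start_pos = numeric(0), end_pos = numeric(0),
                      n_markers = integer(0), markers = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Delimit a candidate region from an absent-class run
#'
#' The candidate region is bounded by the nearest \emph{informative}
#' flanking markers: the closest markers outside the run, on the same
#' chromosome, with a nonzero count of the absent class (recombinants
#' exist there).  The span is the plain difference of the flank positions
#' in bp, matching the convention that delimits a region by its flanking
#' recombinant markers.  At a chromosome end with no flank, the span is
#' measured from the outermost run marker and the side is flagged
#' open-ended.
#'
#' @param run a single-row data.frame from \code{\link{find_absent_runs}}.
#' @param table the same marker table the run was computed from.
#' @return List of class \code{"region_report"}: chromosome, absent_class,
#'   run_markers, left/right flank (marker, pos, or NA), span_bp, span_kb,
#'   open_left, open_right.
#' @export
delimit_region <- function(run, table) {
  stopifnot(is.data.frame(run), nrow(run) == 1L)
  table <- as_marker_table(table)
  cnt <- all_genotype_counts(table)
  cls <- run$absent_class
  idx <- which(cnt$chrom == run$chrom)
  run_markers <- strsplit(run$markers, ",", fixed = TRUE)[[1]]
  pos_in <- match(run_markers, cnt$marker)
  if (anyNA(pos_in)) stop("run markers not found in table")
  nz <- cnt[[paste0("n_", cls)]] > 0
  left_cand <- idx[idx < min(pos_in) & nz[idx]]
  right_cand <- idx[idx > max(pos_in) & nz[idx]]
  left <- if (length(left_cand)) max(left_cand) else NA_integer_
  right <- if (length(right_cand)) min(right_cand) else NA_integer_
  lo <- if (is.na(left)) cnt$pos[min(pos_in)] else cnt$pos[left]
  hi <- if (is.na(right)) cnt$pos[max(pos_in)] else cnt$pos[right]
  span <- hi - lo
  structure(list(
    chromosome = run$chrom, absent_class = cls, run_markers = run_markers,
    left_flank = if (is.na(left)) NULL else
      list(marker = cnt$marker[left], pos = cnt$pos[left]),
    right_flank = if (is.na(right)) NULL else
      list(marker = cnt$marker[right], pos = cnt$pos[right]),
    span_bp = span, span_kb = span / 1000,
    open_left = is.na(left), open_right = is.na(right)),
    class = "region_report")
}

#' Scan a marker table and report all candidate regions
#'
#' Convenience wrapper: finds absent-class runs for every class and
#' delimits each.
#'
#' @param table a marker table.
#' @param classes classes to scan (default all three).
#' @param min_run minimum run length.
#' @return List of \code{"region_report"} objects.
#' @export
find_regions <- function(table, classes = c("a", "h", "b"), min_run = 1L) {
  table <- as_marker_table(table)
  out <- list()
  for (cls in classes) {
    runs <- find_absent_runs(table, cls, min_run = min_run)
    for (i in seq_len(nrow(runs)))
      out[[length(out) + 1L]] <- delimit_region(runs[i, , drop = FALSE], table)
  }
  out
}
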