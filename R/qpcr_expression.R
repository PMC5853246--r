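#' Relative expression by the comparative Ct method
#'
#' Quantifies the expression of a target gene in a sample condition
#' relative to a calibrator condition (typically unpollinated ovules),
#' normalized against one or more reference (housekeeping) genes.  Per
#' replicate, delta-Ct = Ct_target - mean(Ct_references); the fold change
#' is 2^-(ddCt) with ddCt = mean dCt_sample - mean dCt_calibrator.  When
#' per-gene amplification efficiencies E are supplied, the
#' efficiency-corrected fold is
#' E_target^-dCt_target / geomean_over_refs(E_ref^-dCt_ref), where
#' dCt_gene = mean Ct in the sample minus mean Ct in the calibrator; at
#' E = 2 for every gene this reduces exactly to 2^-ddCt.
#'
#' @param ct long-format Ct table: columns \code{condition},
#'   \code{time_window}, \code{gene}, \code{replicate}, \code{ct}, and
#'   optionally \code{efficiency} (fold per cycle, in (1, 2.2]).
#' @param target target gene name.
#' @param condition sample condition (e.g. \code{"SC"}, \code{"SI"}).
#' @param calibrator calibrator condition (default \code{"unpollinated"}).
#' @param ref_genes character vector of reference gene names (>= 1).
#' @param time_window restrict to one pooled time window (\code{NULL} uses
#'   all rows as a single condition).
#' @param use_efficiency use the efficiency-corrected formula (requires an
#'   \code{efficiency} column).
#' @return List of class \code{"rel_expr"}: gene, condition, time_window,
#'   \code{fold}, \code{fold_reps} (per-replicate sample folds against the
#'   calibrator mean), \code{spread} (sd of log2 per-replicate folds),
#'   \code{n_reps}.
#' @export
relative_expression <- function(ct, target, condition,
                                calibrator = "unpollinated", ref_genes,
                                time_window = NULL,
                                use_efficiency = FALSE) {
  need <- c("condition", "gene", "replicate", "ct")
  stopifnot(all(need %in% names(ct)))
  if (any(ct$ct <= 0, na.rm = TRUE)) stop("non-positive Ct value")
  if (missing(ref_genes) || length(ref_genes) < 1L)
    stop("at least one reference gene is required")
  if (!is.null(time_window)) {
    stopifnot("time_window" %in% names(ct))
    ct <- ct[ct$time_window == time_window, , drop = FALSE]
  }
  get_ct <- function(cond, gene) {
    v <- ct[ct$condition == cond & ct$gene == gene, , drop = FALSE]
    if (nrow(v) == 0L)
      stop("no Ct rows for gene '", gene, "' in condition '", cond, "'")
    v[order(v$replicate), c("replicate", "ct")]
  }
  dct <- function(cond) {
    tg <- get_ct(cond, target)
    refs <- lapply(ref_genes, function(g) get_ct(cond, g))
    reps <- Reduce(intersect, c(list(tg$replicate),
                                lapply(refs, `[[`, "replicate")))
    if (length(reps) == 0L) stop("no common replicate between target and refs")
    ref_mean <- rowMeans(vapply(refs, function(r)
      r$ct[match(reps, r$replicate)], numeric(length(reps))))
    list(dct = tg$ct[match(reps, tg$replicate)] - ref_mean,
         target_ct = tg$ct[match(reps, tg$replicate)],
         ref_ct = vapply(refs, function(r)
           mean(r$ct[match(reps, r$replicate)]), 0))
  }
  smp <- dct(condition); cal <- dct(calibrator)
  if (use_efficiency) {
    eff_of <- function(gene) {
      if (!"efficiency" %in% names(ct)) stop("no efficiency column")
      e <- unique(stats::na.omit(ct$efficiency[ct$gene == gene]))
      if (length(e) != 1L) stop("gene '", gene,
                                "' needs a single efficiency value")
      if (e <= 1 || e > 2.2) stop("efficiency out of range (1, 2.2]")
      e
    }
    e_t <- eff_of(target)
    d_target <- mean(smp$target_ct) - mean(cal$target_ct)
    ref_fold <- vapply(seq_along(ref_genes), function(j) {
      e_r <- eff_of(ref_genes[j])
      e_r^-(smp$ref_ct[j] - cal$ref_ct[j])
    }, 0)
    fold <- e_t^-d_target / exp(mean(log(ref_fold)))
  } else {
    fold <- 2^-(mean(smp$dct) - mean(cal$dct))
  }
  fold_reps <- 2^-(smp$dct - mean(cal$dct))
  structure(list(gene = target, condition = condition,
                 time_window = time_window, fold = fold,
                 fold_reps = fold_reps,
                 spread = stats::sd(log2(fold_reps)),
                 n_reps = length(smp$dct)),
            class = "rel_expr")
}

#' Differential expression between two replicate sets of fold changes
#'
#' Default: an exact permutation test on the difference of mean log-fold
#' between the two groups, enumerating all assignments of the pooled
#' replicates to groups (exhaustive up to 10 000 assignments, Monte-Carlo
#' beyond); at 3 + 3 replicates the attainable minimum is 2/20 = 0.1.  A
#' categorical mode dichotomizing replicates at fold 1 and applying the
#' two-sided exact test is kept as an option.
#'
#' @param fold_a,fold_b numeric vectors of per-replicate fold changes
#'   (> 0), at least 2 each (>= 3 recommended).
#' @param mode \code{"permutation"} (default) or \code{"categorical"}.
#' @param n_mc Monte-Carlo draws when exhaustive enumeration exceeds
#'   10 000 assignments.
#' @param seed seed for the Monte-Carlo branch only.
#' @return p-value.
#' @export
differential_test <- function(fold_a, fold_b,
                              mode = c("permutation", "categorical"),
                              n_mc = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  if (length(fold_a) < 2L || length(fold_b) < 2L)
    stop("at least 2 replicates per group")
  if (any(c(fold_a, fold_b) <= 0)) stop("fold changes must be positive")
  if (mode == "categorical") {
    up_a <- sum(fold_a > 1); up_b <- sum(fold_b > 1)
    tab <- matrix(c(up_a, length(fold_a) - up_a,
                    up_b, length(fold_b) - up_b), 2, 2, byrow = TRUE)
    return(suppressWarnings(fisher_exact(tab)))
  }
  xa <- log(fold_a); xb <- log(fold_b)
  pooled <- c(xa, xb)
  na <- length(xa); n <- length(pooled)
  obs <- abs(mean(xa) - mean(xb))
  tol <- 1e-12
  if (choose(n, na) <= 10000L) {
    sets <- utils::combn(n, na, simplify = FALSE)
    stats <- vapply(sets, function(i)
      abs(mean(pooled[i]) - mean(pooled[-i])), 0)
    mean(stats >= obs - tol)
  } else {
    set.seed(as.integer(seed))
    hits <- vapply(seq_len(n_mc), function(k) {
      i <- sample.int(n, na)
      abs(mean(pooled[i]) - mean(pooled[-i])) >= obs - tol
    }, logical(1))
    (1 + sum(hits)) / (1 + n_mc)
  }
}
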