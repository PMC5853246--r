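#' @section SSR tables:
#' An SSR genotype table is a data.frame with an \code{individual} column
#' followed by one column per marker; each cell is an unordered pair of
#' allele sizes in bp written \code{"223/225"} (homozygotes as equal pair,
#' \code{"161/161"}), or \code{NA}.  Cells are normalized so the smaller
#' size comes first; a phenotype table has columns \code{individual},
#' \code{sc_status} (0 = self-incompatible, 1 = self-compatible) and
#' optionally \code{fruit_set_pct}.
#' @name ssr-tables
#' @keywords internal
NULL

normalize_ssr_cell <- function(x) {
  if (is.na(x) || x == "" || x == ".") return(NA_character_)
  parts <- strsplit(x, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed SSR cell: '", x, "'")
  sizes <- suppressWarnings(as.numeric(parts))
  if (anyNA(sizes) || any(sizes <= 0))
    stop("malformed SSR cell: '", x, "' (allele sizes must be positive numbers)")
  paste(sort(sizes), collapse = "/")
}

ssr_marker_cols <- function(table)
  setdiff(names(table), c("individual", "group"))

normalize_ssr_table <- function(table) {
  stopifnot(is.data.frame(table), "individual" %in% names(table))
  if (anyDuplicated(table$individual)) stop("duplicate individual ids")
  for (m in ssr_marker_cols(table))
    table[[m]] <- vapply(as.character(table[[m]]), normalize_ssr_cell,
                         "", USE.NAMES = FALSE)
  table
}

ssr_alleles_of_cell <- function(cell) {
  if (is.na(cell)) return(character(0))
  strsplit(cell, "/", fixed = TRUE)[[1]]
}

join_phenotype <- function(table, phenotype) {
  stopifnot(all(c("individual", "sc_status") %in% names(phenotype)))
  if (!all(phenotype$sc_status %in% c(0, 1)))
    stop("sc_status must be 0 (SI) or 1 (SC)")
  missing_ind <- setdiff(phenotype$individual, table$individual)
  if (length(missing_ind))
    warning("phenotyped individuals absent from SSR table, excluded: ",
            paste(utils::head(missing_ind, 5), collapse = ", "))
  keep <- phenotype[phenotype$individual %in% table$individual, , drop = FALSE]
  if (length(unique(keep$sc_status)) < 2L)
    stop("phenotype has a single class; association is undefined")
  merge(table, keep, by = "individual", sort = TRUE)
}

#' Enumerate genotype combinations for the diagnostic screen
#'
#' All combinations of \emph{observed} genotypes at 1 to \code{max_order}
#' distinct markers whose carrier count (individuals matching the exact
#' genotype at every marker of the combo, complete-case over those
#' markers) is at least \code{min_support}.  Ordering is deterministic:
#' markers alphabetically, genotypes by allele size.
#'
#' @param table SSR genotype table (see \code{\link{ssr-tables}}).
#' @param max_order maximum number of loci per combination (1--3).
#' @param min_support minimum carrier count (>= 1; default 3, avoiding
#'   degenerate 2x2 tables downstream).
#' @return data.frame with columns \code{markers}, \code{genotypes}
#'   (comma-joined, aligned), \code{order}, \code{support}.
#' @export
enumerate_combos <- function(table, max_order = 3L, min_support = 3L) {
  if (max_order < 1L || max_order > 3L) stop("max_order must be in 1..3")
  if (min_support < 1L) stop("min_support must be >= 1")
  table <- normalize_ssr_table(table)
  if (nrow(table) == 0L) stop("empty SSR table")
  markers <- sort(ssr_marker_cols(table))
  out <- list()
  for (ord in seq_len(min(max_order, length(markers)))) {
    sets <- utils::combn(markers, ord, simplify = FALSE)
    for (ms in sets) {
      cells <- table[, ms, drop = FALSE]
      cc <- stats::complete.cases(cells)
      if (!any(cc)) next
      joint <- do.call(paste, c(cells[cc, , drop = FALSE], sep = "\t"))
      tab <- table(joint)
      tab <- tab[tab >= min_support]
      if (length(tab) == 0L) next
      keys <- sort(names(tab))
      for (k in keys) {
        gts <- strsplit(k, "\t", fixed = TRUE)[[1]]
        out[[length(out) + 1L]] <- data.frame(
          markers = paste(ms, collapse = ","),
          genotypes = paste(gts, collapse = ","),
          order = ord, support = as.integer(tab[[k]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(markers = character(0), genotypes = character(0),
                      order = integer(0), support = integer(0)))
  do.call(rbind, out)
}

combo_carriers <- function(table, markers, genotypes) {
  cells <- table[, markers, drop = FALSE]
  cc <- stats::complete.cases(cells)
  has <- cc
  for (j in seq_along(markers))
    has <- has & !is.na(cells[[j]]) & cells[[j]] == genotypes[j]
  list(complete = cc, has = has)
}

# Single-indicator logistic fit of status on carrier state.  The MLE of a
# saturated indicator model is the pair of group proportions (a boundary
# value when a group is pure), so the proportions are computed directly;
# separation is flagged when either group is pure.
indicator_probs <- function(has, status) {
  prob_has <- if (any(has)) mean(status[has]) else NA_real_
  prob_not <- if (any(!has)) mean(status[!has]) else NA_real_
  pure <- function(p, n) !is.na(p) && n > 0 && (p == 0 || p == 1)
  list(prob_has = prob_has, prob_not = prob_not,
       separation = pure(prob_has, sum(has)) || pure(prob_not, sum(!has)))
}

#' Diagnostic genotype-combination screen
#'
#' For every genotype combination (1 to \code{max_order} loci) the screen
#' builds the 2x2 carrier-by-phenotype contingency table, tests association
#' with self-compatibility by the two-sided exact test, adjusts for
#' multiple testing (Benjamini-Hochberg), and estimates the conditional
#' probabilities P(SC | carries combo) and P(SC | does not) from a
#' single-indicator logistic fit (equal to the empirical carrier and
#' non-carrier SC proportions whenever the fit is not separated; a
#' bias-reduced fit is substituted and flagged under separation).
#' Individuals missing any marker of a combo are excluded from that
#' combo's table (complete-case).
#'
#' @param table SSR genotype table.
#' @param phenotype phenotype table (\code{individual}, \code{sc_status}).
#' @param max_order maximum combination order (default 3).
#' @param min_support minimum carrier count (default 3).
#' @param alpha FDR threshold used for the \code{significant} flag.
#' @return data.frame sorted by (q, p): combo columns, contingency counts
#'   \code{n_has_sc}, \code{n_has_si}, \code{n_not_sc}, \code{n_not_si},
#'   \code{p}, \code{q}, \code{prob_sc_has}, \code{prob_sc_not},
#'   \code{separation}, \code{significant}.
#' @export
combo_screen <- function(table, phenotype, max_order = 3L, min_support = 3L,
                         alpha = 0.05) {
  table <- normalize_ssr_table(table)
  joined <- join_phenotype(table, phenotype)
  combos <- enumerate_combos(joined[, c("individual", ssr_marker_cols(table)),
                                    drop = FALSE],
                             max_order = max_order,
                             min_support = min_support)
  if (nrow(combos) == 0L) stop("no combination passes min_support")
  res <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    ms <- strsplit(combos$markers[i], ",", fixed = TRUE)[[1]]
    gts <- strsplit(combos$genotypes[i], ",", fixed = TRUE)[[1]]
    cw <- combo_carriers(joined, ms, gts)
    sub <- joined[cw$complete, , drop = FALSE]
    has <- cw$has[cw$complete]
    status <- sub$sc_status
    tab <- matrix(c(sum(has & status == 1), sum(has & status == 0),
                    sum(!has & status == 1), sum(!has & status == 0)),
                  2, 2, byrow = TRUE)
    p <- suppressWarnings(fisher_exact(tab))
    pr <- indicator_probs(has, status)
    res[[i]] <- data.frame(
      markers = combos$markers[i], genotypes = combos$genotypes[i],
      order = combos$order[i], support = combos$support[i],
      n_has_sc = tab[1, 1], n_has_si = tab[1, 2],
      n_not_sc = tab[2, 1], n_not_si = tab[2, 2],
      p = p, prob_sc_has = pr$prob_has, prob_sc_not = pr$prob_not,
      separation = pr$separation, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$q <- bh_qvalues(out$p)
  out$significant <- out$q <= alpha
  out <- out[order(out$q, out$p, out$markers, out$genotypes), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-allele presence/absence screen
#'
#' For each (marker, allele): 2x2 of allele presence (>= 1 copy) versus
#' SC/SI status, two-sided exact test, Benjamini-Hochberg q.
#'
#' @inheritParams combo_screen
#' @return data.frame sorted by (q, p): marker, allele, counts, p, q.
#' @export
allele_presence_screen <- function(table, phenotype, alpha = 0.05) {
  table <- normalize_ssr_table(table)
  joined <- join_phenotype(table, phenotype)
  res <- list()
  for (m in sort(ssr_marker_cols(table))) {
    cells <- joined[[m]]
    ok <- !is.na(cells)
    if (!any(ok)) next
    allele_lists <- strsplit(cells[ok], "/", fixed = TRUE)
    alleles <- sort(unique(unlist(allele_lists)))
    status <- joined$sc_status[ok]
    for (al in alleles) {
      present <- vapply(allele_lists, function(x) al %in% x, logical(1))
      tab <- matrix(c(sum(present & status == 1), sum(present & status == 0),
                      sum(!present & status == 1), sum(!present & status == 0)),
                    2, 2, byrow = TRUE)
      p <- suppressWarnings(fisher_exact(tab))
      res[[length(res) + 1L]] <- data.frame(
        marker = m, allele = as.numeric(al),
        n_present_sc = tab[1, 1], n_present_si = tab[1, 2],
        n_absent_sc = tab[2, 1], n_absent_si = tab[2, 2],
        p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) stop("no genotyped marker")
  out <- do.call(rbind, res)
  out$q <- bh_qvalues(out$p)
  out$significant <- out$q <= alpha
  out <- out[order(out$q, out$p, out$marker, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Allele dose-response fit
#'
#' Logistic regression of SC status on the copy number (0, 1, 2) of a
#' given allele at a given marker, by iterative maximum likelihood; on
#' complete or quasi-complete separation a Firth-type bias-reduced fit is
#' substituted and flagged.  Reports P(SC | dose) for doses 0, 1, 2.
#'
#' @inheritParams combo_screen
#' @param marker marker name.
#' @param allele allele size (bp).
#' @return List of class \code{"allele_dose_fit"}: marker, allele,
#'   dose_counts (2 x 3 matrix SC/SI by dose), coef (intercept, slope),
#'   prob_sc (named, doses 0/1/2), p (exact-test p of presence vs status),
#'   separation, method, converged.
#' @export
allele_dose_fit <- function(table, phenotype, marker, allele) {
  table <- normalize_ssr_table(table)
  joined <- join_phenotype(table, phenotype)
  if (!marker %in% ssr_marker_cols(table)) stop("unknown marker: ", marker)
  cells <- joined[[marker]]
  ok <- !is.na(cells)
  allele <- as.character(as.numeric(allele))
  dose <- vapply(strsplit(cells[ok], "/", fixed = TRUE),
                 function(x) sum(x == allele), integer(1))
  status <- joined$sc_status[ok]
  if (length(unique(dose)) < 2L)
    stop("single dose observed for allele ", allele, " at ", marker,
         "; dose-response is undefined")
  counts <- matrix(0L, 2, 3, dimnames = list(c("SC", "SI"), c("0", "1", "2")))
  for (d in 0:2) {
    counts["SC", d + 1L] <- sum(dose == d & status == 1)
    counts["SI", d + 1L] <- sum(dose == d & status == 0)
  }
  fit <- logistic_irls(dose, status)
  method <- "ml"; converged <- fit$converged
  if (fit$separation) {
    ffit <- logistic_firth(dose, status)
    if (!ffit$converged)
      stop("dose-response fit failed to converge (penalized fit included)")
    fit <- ffit; method <- "firth"; converged <- ffit$converged
  } else if (!fit$converged) {
    stop("dose-response fit failed to converge after 100 iterations")
  }
  eta <- fit$coef["intercept"] + fit$coef["slope"] * (0:2)
  prob <- stats::plogis(eta); names(prob) <- c("0", "1", "2")
  present_tab <- matrix(c(sum(dose > 0 & status == 1),
                          sum(dose > 0 & status == 0),
                          sum(dose == 0 & status == 1),
                          sum(dose == 0 & status == 0)), 2, 2, byrow = TRUE)
  structure(list(marker = marker, allele = as.numeric(allele),
                 dose_counts = counts, coef = fit$coef, prob_sc = prob,
                 p = suppressWarnings(fisher_exact(present_tab)),
                 separation = method == "firth", method = method,
                 converged = converged),
            class = "allele_dose_fit")
}
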