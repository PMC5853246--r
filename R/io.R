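#' @section File dialects:
#' All tabular inputs and outputs are tab-delimited UTF-8 text with a
#' header row (TSV); commas inside fields are not supported.  Genotype
#' codes are \code{a}/\code{h}/\code{b} with missing tokens \code{"."},
#' \code{"NA"} or the empty string.  Positions may contain embedded
#' thousands spaces (\code{"4 021 267"}), which are stripped on read.
#' Readers reject malformed cells (naming the offending cell) rather than
#' silently coercing them.
#' @name file-dialects
#' @keywords internal
NULL

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ".", ""))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

strip_pos <- function(x) as.numeric(gsub("[ , ]", "", as.character(x)))

#' Read a progeny marker table from TSV
#'
#' Expected columns: \code{marker}, \code{chrom}, \code{pos}, then one
#' column per individual with codes a/h/b or a missing token.
#'
#' @param path TSV file path.
#' @return A validated marker table (see \code{\link{as_marker_table}}).
#' @export
read_marker_table <- function(path) {
  raw <- read_tsv_checked(path)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(raw)))
    stop("marker TSV must have columns marker, chrom, pos: ", path)
  raw$pos <- strip_pos(raw$pos)
  if (anyNA(raw$pos))
    stop("non-numeric position(s) at marker(s) ",
         paste(raw$marker[is.na(raw$pos)], collapse = ", "))
  ind_cols <- setdiff(names(raw), need)
  for (cc in ind_cols) {
    v <- as.character(raw[[cc]])
    bad <- which(!is.na(v) & !(v %in% c("a", "h", "b")))
    if (length(bad))
      stop("invalid genotype code '", v[bad[1]], "' in column '", cc,
           "', data line ", bad[1], " (marker ", raw$marker[bad[1]], ")")
    raw[[cc]] <- v
  }
  as_marker_table(raw)
}

#' Write a marker table to TSV
#' @param table marker table.
#' @param path output path.
#' @export
write_marker_table <- function(table, path) {
  table <- as_marker_table(table)
  write_tsv(table, path)
}

#' Read an SSR genotype table from TSV
#'
#' Expected columns: \code{individual}, optionally \code{group}, then one
#' column per SSR marker with cells like \code{"223/225"} (order
#' irrelevant) or a missing token.
#'
#' @param path TSV file path.
#' @return Normalized SSR genotype table.
#' @export
read_ssr_table <- function(path) {
  raw <- read_tsv_checked(path)
  if (!"individual" %in% names(raw))
    stop("SSR TSV must have an 'individual' column: ", path)
  for (m in ssr_marker_cols(raw)) {
    cells <- as.character(raw[[m]])
    for (i in seq_along(cells)) {
      res <- tryCatch(normalize_ssr_cell(cells[i]), error = function(e) e)
      if (inherits(res, "error"))
        stop("marker '", m, "', data line ", i, " (individual ",
             raw$individual[i], "): ", conditionMessage(res))
      cells[i] <- res
    }
    raw[[m]] <- cells
  }
  raw
}

#' Read a phenotype table from TSV
#'
#' Expected columns: \code{individual}, \code{sc_status} (0 = SI,
#' 1 = SC), optional \code{fruit_set_pct} in [0, 100].
#'
#' @param path TSV file path.
#' @return Phenotype data.frame.
#' @export
read_phenotype <- function(path) {
  raw <- read_tsv_checked(path)
  if (!all(c("individual", "sc_status") %in% names(raw)))
    stop("phenotype TSV must have columns individual, sc_status: ", path)
  if (!all(raw$sc_status %in% c(0, 1)))
    stop("sc_status must be 0 (SI) or 1 (SC)")
  if ("fruit_set_pct" %in% names(raw)) {
    v <- raw$fruit_set_pct
    if (any(!is.na(v) & (v < 0 | v > 100)))
      stop("fruit_set_pct must lie in [0, 100]")
  }
  raw
}

#' Read a long-format qPCR Ct table from TSV
#' @param path TSV path with columns condition, time_window, gene,
#'   replicate, ct, optional efficiency.
#' @return Ct data.frame.
#' @export
read_ct_table <- function(path) {
  raw <- read_tsv_checked(path)
  need <- c("condition", "gene", "replicate", "ct")
  if (!all(need %in% names(raw)))
    stop("Ct TSV must have columns condition, gene, replicate, ct: ", path)
  if (any(is.na(raw$ct)) || any(raw$ct <= 0))
    stop("Ct values must be positive numbers")
  raw
}

#' Read an SI model and cross specification from a YAML config
#'
#' Keys: \code{alleles} (list of id/activity/rank), optional
#' \code{ch1_elimination_pairs} (list of activator/target), optional
#' \code{ch4_requires}, \code{ch1_activator_in}, \code{gametic_locus},
#' \code{zygotic_locus}; \code{cross} with \code{mother}/\code{father}
#' (locus -> two allele ids), \code{n}, \code{mentor_fraction},
#' \code{baseline_abortion}; \code{seed}.
#'
#' @param path YAML file path.
#' @return List with \code{model}, \code{cross}, \code{seed}.
#' @export
read_si_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$alleles)) stop("config needs an 'alleles' list")
  al <- do.call(rbind, lapply(cfg$alleles, as.data.frame))
  alleles <- si_alleles(al$id, al$activity, al$rank)
  pairs <- if (!is.null(cfg$ch1_elimination_pairs))
    do.call(rbind, lapply(cfg$ch1_elimination_pairs, as.data.frame))
  else NULL
  model <- si_model(alleles, ch1_pairs = pairs,
                    gametic_locus = cfg$gametic_locus %||% "CH4",
                    zygotic_locus = cfg$zygotic_locus %||% "CH1",
                    ch4_requires = cfg$ch4_requires %||% "both",
                    ch1_activator_in = cfg$ch1_activator_in %||% "either")
  cross <- NULL
  if (!is.null(cfg$cross)) {
    mother <- lapply(cfg$cross$mother, unlist)
    father <- if (!is.null(cfg$cross$father))
      lapply(cfg$cross$father, unlist) else mother
    cross <- cross_spec(mother, father,
                        n_offspring = cfg$cross$n %||% cfg$n %||% 100L,
                        mentor_fraction = cfg$cross$mentor_fraction %||% 0,
                        baseline_abortion =
                          cfg$cross$baseline_abortion %||% 0.10)
  }
  list(model = model, cross = cross, seed = cfg$seed %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a progeny simulation as TSV
#'
#' One row per (individual, locus): individual_id, locus, class,
#' parentage.
#'
#' @param sim a \code{"progeny_sim"} result.
#' @param path output path.
#' @export
write_progeny <- function(sim, path) {
  off <- sim$offspring
  loci <- sub("_class$", "", grep("_class$", names(off), value = TRUE))
  rows <- do.call(rbind, lapply(loci, function(l)
    data.frame(individual_id = off$individual, locus = l,
               class = off[[paste0(l, "_class")]],
               parentage = off$parentage, stringsAsFactors = FALSE)))
  write_tsv(rows[order(rows$individual_id, rows$locus), ], path)
}

region_report_to_list <- function(rr) {
  list(chromosome = rr$chromosome, absent_class = rr$absent_class,
       run_markers = rr$run_markers,
       left_flank = rr$left_flank, right_flank = rr$right_flank,
       span_bp = rr$span_bp, span_kb = rr$span_kb,
       open_left = rr$open_left, open_right = rr$open_right)
}

#' Write region reports as JSON
#' @param regions list of \code{"region_report"} objects.
#' @param path output path.
#' @export
write_region_reports <- function(regions, path) {
  jsonlite::write_json(lapply(regions, region_report_to_list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
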