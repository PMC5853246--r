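#' Simulate a progeny marker table around an SI locus
#'
#' Generates the substrate of the segregation scan: offspring are first
#' simulated at the SI loci under the full selection model, then every
#' marker's genotype code is derived from its locus by recombining each
#' gamete independently at the marker's stated recombination fraction
#' (no marker-marker interference; each marker is coupled to its locus
#' only, which is sufficient to reproduce the small recombinant counts at
#' flanking markers while the core region stays at zero).
#'
#' @param cross a \code{\link{cross_spec}}; \code{cross$n_offspring}
#'   individuals are produced.
#' @param model an \code{\link{si_model}}.
#' @param marker_map data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos}, \code{recomb} (recombination fraction to the SI locus, in
#'   [0, 0.5]), and optionally \code{locus} (defaults to \code{chrom}).
#' @param missingness per-cell missing-call probability in [0, 1).
#' @param seed integer random seed.
#' @return A marker table (see \code{\link{as_marker_table}}).
#' @export
gen_progeny_marker_table <- function(cross, model, marker_map,
                                     missingness = 0, seed) {
  stopifnot(is.data.frame(marker_map),
            all(c("marker", "chrom", "pos", "recomb") %in% names(marker_map)))
  if (any(marker_map$recomb < 0 | marker_map$recomb > 0.5))
    stop("recombination fractions must lie in [0, 0.5]")
  if (missingness < 0 || missingness >= 1)
    stop("missingness must lie in [0, 1)")
  if (missing(seed)) stop("seed is required")
  if (!"locus" %in% names(marker_map)) marker_map$locus <- marker_map$chrom
  unknown <- setdiff(unique(marker_map$locus), names(cross$mother))
  if (length(unknown))
    stop("marker map references loci absent from the cross: ",
         paste(unknown, collapse = ", "))
  sim <- simulate_progeny(cross, model, seed = seed)
  off <- sim$offspring
  n <- nrow(off)
  out <- data.frame(marker = marker_map$marker, chrom = marker_map$chrom,
                    pos = marker_map$pos, stringsAsFactors = FALSE)
  codes <- matrix(NA_character_, nrow(marker_map), n)
  for (i in seq_len(nrow(marker_map))) {
    locus <- marker_map$locus[i]
    r <- marker_map$recomb[i]
    mg <- cross$mother[[locus]]; fg <- cross$father[[locus]]
    aa <- mg[1]
    mat_idx <- match(off[[paste0(locus, "_mat")]], mg)
    pat_idx <- match(off[[paste0(locus, "_pat")]], fg)
    flip_m <- stats::runif(n) < r
    flip_p <- stats::runif(n) < r
    mat_idx <- ifelse(flip_m, 3L - mat_idx, mat_idx)
    pat_idx <- ifelse(flip_p, 3L - pat_idx, pat_idx)
    mal <- mg[mat_idx]; pal <- fg[pat_idx]
    codes[i, ] <- ifelse(mal != pal, "h", ifelse(mal == aa, "a", "b"))
  }
  if (missingness > 0) {
    miss <- matrix(stats::runif(length(codes)) < missingness, nrow(codes))
    codes[miss] <- NA_character_
  }
  for (j in seq_len(n)) out[[off$individual[j]]] <- codes[, j]
  as_marker_table(out)
}

#' Configuration of a synthetic association population
#'
#' Describes a structured population of the kind used for the diagnostic
#' screen: K genetic subgroups with mixture weights, per-group latent
#' S-haplotype frequencies (self-compatibility follows deterministically
#' from the S-genotype through the dominance engine: an individual is SC
#' iff its genotype expresses no active specificity), per-group SSR allele
#' frequency profiles, and a tunable linkage disequilibrium r2 between one
#' designated SSR allele and one S-allele.  For the LD coupling to achieve
#' exactly the requested r2, the linked SSR allele's marginal frequency
#' must equal the linked S-allele's frequency within each group; the
#' default profiles are constructed to satisfy this.
#'
#' @param n number of individuals (default 700, the scale of a diagnostic
#'   screen population).
#' @param model \code{\link{si_model}} providing the dominance engine.
#' @param groups data.frame with columns \code{name}, \code{weight}
#'   (weights sum to 1).
#' @param s_freqs named list: group -> named numeric of S-allele
#'   frequencies (sum to 1).
#' @param profiles named list: group -> marker -> named numeric of SSR
#'   allele frequencies (names are allele sizes in bp).
#' @param ld list with elements \code{marker}, \code{allele},
#'   \code{s_allele}, \code{r2} (r2 in [0, 1]).
#' @param missingness per-cell missing probability.
#' @return List of class \code{"assoc_pop_config"}.
#' @export
assoc_pop_config <- function(n = 700L, model = si_model(),
                             groups = NULL, s_freqs = NULL, profiles = NULL,
                             ld = list(marker = "mSI_460", allele = "161",
                                       s_allele = "Sf", r2 = 0.8),
                             missingness = 0) {
  if (is.null(groups))
    groups <- data.frame(name = c("Amelonado", "Criollo", "Trinitario"),
                         weight = c(0.35, 0.15, 0.50),
                         stringsAsFactors = FALSE)
  if (abs(sum(groups$weight) - 1) > 1e-9) stop("group weights must sum to 1")
  if (is.null(s_freqs))
    s_freqs <- list(
      Amelonado  = c(Sf = 0.90, S4 = 0.10),
      Criollo    = c(Sf = 0.50, S2 = 0.50),
      Trinitario = c(Sf = 0.30, S1 = 0.30, S2 = 0.20, S4 = 0.20))
  if (is.null(profiles))
    profiles <- default_ssr_profiles(groups$name, s_freqs, ld)
  if (ld$r2 < 0 || ld$r2 > 1) stop("r2 must lie in [0, 1]")
  for (g in groups$name) {
    if (abs(sum(s_freqs[[g]]) - 1) > 1e-9)
      stop("S-allele frequencies must sum to 1 in group ", g)
    prof <- profiles[[g]][[ld$marker]]
    s_f <- if (ld$s_allele %in% names(s_freqs[[g]]))
      s_freqs[[g]][[ld$s_allele]] else 0
    p_l <- if (ld$allele %in% names(prof)) prof[[ld$allele]] else 0
    if (ld$r2 > 0 && abs(p_l - s_f) > 1e-9)
      stop("LD coupling needs freq(", ld$allele, ") == freq(", ld$s_allele,
           ") in group ", g, " (got ", p_l, " vs ", s_f, ")")
  }
  structure(list(n = as.integer(n), model = model, groups = groups,
                 s_freqs = s_freqs, profiles = profiles, ld = ld,
                 missingness = missingness),
            class = "assoc_pop_config")
}

# default 11-marker SSR profiles; the LD marker's linked-allele frequency
# is pinned to the linked S-allele's frequency within each group
default_ssr_profiles <- function(group_names, s_freqs, ld) {
  markers <- c("mSI_460", "mSI_103", "mSI_107", "mSI_303", "mSI_458",
               "mSI_7", "mSI_2", "mSI_35", "mSI_309", "mSI_315", "mTcCIR15")
  base_sizes <- list(c(133, 145, 155, 161), c(223, 225, 228, 231),
                     c(233, 239, 241, 245), c(225, 227, 231, 233),
                     c(292, 300, 310, 318), c(188, 194, 197, 203),
                     c(140, 146, 152, 158), c(201, 207, 213, 219),
                     c(166, 172, 178, 184), c(250, 256, 262, 268),
                     c(120, 126, 132, 138))
  shapes <- list(c(0.40, 0.30, 0.20, 0.10), c(0.10, 0.40, 0.30, 0.20),
                 c(0.25, 0.25, 0.25, 0.25))
  out <- list()
  for (gi in seq_along(group_names)) {
    g <- group_names[gi]
    prof <- list()
    for (mi in seq_along(markers)) {
      m <- markers[mi]
      sizes <- base_sizes[[mi]]
      fr <- shapes[[(gi + mi) %% length(shapes) + 1L]]
      names(fr) <- as.character(sizes)
      if (m == ld$marker) {
        s_f <- if (ld$s_allele %in% names(s_freqs[[g]]))
          s_freqs[[g]][[ld$s_allele]] else 0
        others <- setdiff(as.character(sizes), ld$allele)
        rest <- fr[others] / sum(fr[others]) * (1 - s_f)
        fr <- c(stats::setNames(s_f, ld$allele), rest)
      }
      prof[[m]] <- fr
    }
    out[[g]] <- prof
  }
  out
}

#' Generate a synthetic association population
#'
#' Draws group membership, two latent S-haplotypes and SSR genotypes per
#' individual under the configured LD, assigns SC/SI status
#' deterministically from the S-genotype via the dominance engine, and
#' reports the ground truth of the planted diagnostic allele.  The LD
#' coupling works per haplotype: with probability sqrt(r2) the SSR allele
#' at the designated marker is fully determined by whether the haplotype
#' carries the linked S-allele, otherwise it is drawn from the marginal
#' group profile; with matched marginal frequencies this yields a
#' haplotype-level squared correlation of exactly r2.
#'
#' @param config an \code{\link{assoc_pop_config}}.
#' @param seed integer random seed.
#' @return List: \code{ssr} (SSR genotype table), \code{phenotype}
#'   (individual, sc_status, fruit_set_pct), \code{grouped} (SSR table
#'   with group column), \code{truth} (planted marker/allele, linked
#'   S-allele, r2, per-individual S-genotypes).
#' @export
gen_association_population <- function(config, seed) {
  stopifnot(inherits(config, "assoc_pop_config"))
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  n <- config$n
  ld <- config$ld
  rho <- sqrt(ld$r2)
  grp <- sample(config$groups$name, n, replace = TRUE,
                prob = config$groups$weight)
  draw_from <- function(freqs, k = 1L)
    sample(names(freqs), k, replace = TRUE, prob = freqs)
  ids <- sprintf("ind_%03d", seq_len(n))
  s1 <- character(n); s2 <- character(n)
  ssr <- data.frame(individual = ids, stringsAsFactors = FALSE)
  markers <- names(config$profiles[[1]])
  cells <- matrix(NA_character_, n, length(markers),
                  dimnames = list(NULL, markers))
  for (i in seq_len(n)) {
    g <- grp[i]
    sf <- config$s_freqs[[g]]
    haps <- c(draw_from(sf), draw_from(sf))
    s1[i] <- haps[1]; s2[i] <- haps[2]
    for (m in markers) {
      prof <- config$profiles[[g]][[m]]
      two <- vapply(1:2, function(h) {
        if (m == ld$marker && stats::runif(1) < rho) {
          if (haps[h] == ld$s_allele) return(ld$allele)
          others <- prof[setdiff(names(prof), ld$allele)]
          if (sum(others) <= 0) return(ld$allele)
          return(draw_from(others / sum(others)))
        }
        draw_from(prof)
      }, "")
      cells[i, m] <- paste(sort(as.numeric(two)), collapse = "/")
    }
  }
  if (config$missingness > 0) {
    miss <- matrix(stats::runif(length(cells)) < config$missingness,
                   nrow(cells))
    cells[miss] <- NA_character_
  }
  for (m in markers) ssr[[m]] <- cells[, m]
  sc <- vapply(seq_len(n), function(i)
    as.integer(length(expressed_specificities(c(s1[i], s2[i]),
                                              config$model)) == 0L),
    integer(1))
  fruit <- ifelse(sc == 1, stats::runif(n, 20, 80), stats::runif(n, 0, 5))
  phenotype <- data.frame(individual = ids, sc_status = sc,
                          fruit_set_pct = round(fruit, 1),
                          stringsAsFactors = FALSE)
  grouped <- cbind(ssr, group = grp, stringsAsFactors = FALSE)
  list(ssr = ssr, phenotype = phenotype, grouped = grouped,
       truth = list(marker = ld$marker, allele = as.numeric(ld$allele),
                    s_allele = ld$s_allele, r2 = ld$r2,
                    s_genotype = paste(s1, s2, sep = "/"), group = grp))
}

#' Generate a synthetic qPCR Ct table
#'
#' Three replicates per condition and gene with Gaussian Ct noise; the
#' target gene's Ct is lowered by the condition's log2-fold effect
#' (one cycle per doubling), reference genes are unshifted.
#'
#' @param effects named numeric: log2 fold change of the target per
#'   non-calibrator condition (e.g. \code{c(SC = 1, SI = 0)}).
#' @param target target gene name.
#' @param ref_genes reference gene names.
#' @param calibrator calibrator condition name.
#' @param time_window label stored in the table.
#' @param noise_sd Gaussian Ct noise in cycles (>= 0).
#' @param base_ct,ref_ct baseline Ct of target and reference genes.
#' @param n_reps replicates per condition x gene.
#' @param efficiency amplification efficiency stored per gene.
#' @param seed integer random seed.
#' @return Long-format Ct data.frame (condition, time_window, gene,
#'   replicate, ct, efficiency).
#' @export
gen_ct_table <- function(effects = c(SC = 1, SI = 0), target = "target",
                         ref_genes = c("ref1", "ref2"),
                         calibrator = "unpollinated",
                         time_window = "2-8h", noise_sd = 0,
                         base_ct = 25, ref_ct = 20, n_reps = 3L,
                         efficiency = 2.0, seed) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  conds <- c(calibrator, names(effects))
  shift <- c(0, unname(effects))
  rows <- list()
  for (ci in seq_along(conds)) {
    for (g in c(target, ref_genes)) {
      mu <- if (g == target) base_ct - shift[ci] else ref_ct
      rows[[length(rows) + 1L]] <- data.frame(
        condition = conds[ci], time_window = time_window, gene = g,
        replicate = seq_len(n_reps),
        ct = mu + stats::rnorm(n_reps, 0, noise_sd),
        efficiency = efficiency, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
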