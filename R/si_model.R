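#' S-allele definitions for the cacao late-acting self-incompatibility model
#'
#' Builds the allele table underlying the two-locus incompatibility model.
#' Each allele has an activity class (\code{"active"} alleles carry an
#' incompatibility specificity, \code{"amorphous"} alleles such as the
#' Amelonado \emph{Sf} allele carry none) and an integer dominance rank.
#' Lower rank means more dominant; equal ranks are codominant.  The classic
#' cacao dominance series S0=S1 > S2=S3 > Sf > S4 > S5 is encoded as ranks
#' 1,1,2,2,3,4,5.
#'
#' @param id character vector of allele labels (e.g. \code{"S1"},
#'   \code{"Sf"}, \code{"S_sca"}).
#' @param activity character vector, one of \code{"active"} or
#'   \code{"amorphous"} per allele.
#' @param rank integer vector of dominance ranks (lower = more dominant).
#' @param linked_ssr optional named list mapping allele id to a named
#'   numeric vector of linked SSR allele sizes (marker -> bp), used by the
#'   synthetic-data generators.
#' @return A data.frame of class \code{"si_alleles"} with columns
#'   \code{id}, \code{activity}, \code{rank}.
#' @examples
#' si_alleles(c("Sf", "S_sca"), c("amorphous", "active"), c(3L, 1L))
#' @export
si_alleles <- function(id, activity, rank, linked_ssr = NULL) {
  if (length(activity) == 1L) activity <- rep(activity, length(id))
  stopifnot(length(id) == length(activity), length(id) == length(rank))
  if (anyDuplicated(id)) stop("duplicate allele ids")
  if (!all(activity %in% c("active", "amorphous")))
    stop("activity must be 'active' or 'amorphous'")
  rank <- as.integer(rank)
  if (anyNA(rank)) stop("dominance ranks must be integers")
  out <- data.frame(id = as.character(id), activity = activity,
                    rank = rank, stringsAsFactors = FALSE)
  attr(out, "linked_ssr") <- linked_ssr
  class(out) <- c("si_alleles", "data.frame")
  out
}

#' Default S-allele set with the published cacao dominance series
#'
#' Convenience constructor for the S0=S1 > S2=S3 > Sf > S4 > S5 series plus
#' the Scavina-6 allele (\code{"S_sca"}), which behaves as an active allele
#' dominant over the amorphous Amelonado \code{"Sf"} allele.
#'
#' @return An \code{\link{si_alleles}} table.
#' @export
cacao_s_alleles <- function() {
  si_alleles(
    id       = c("S0", "S1", "S2", "S3", "Sf", "S4", "S5", "S_sca"),
    activity = c("active", "active", "active", "active",
                 "amorphous", "active", "active", "active"),
    rank     = c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 2L)
  )
}

#' Two-locus self-incompatibility rule system
#'
#' Packages the allele table together with the two selection-rule families
#' observed in cacao: a gametic fusion-failure rule (the chromosome-4 locus:
#' an ovule's gamete pair fails fusion when female and male gametes carry
#' the same specificity expressed in the parents) and a zygotic pre-fusion
#' elimination rule (the chromosome-1 locus: a homozygous target genotype is
#' eliminated before gamete fusion whenever an activator allele is carried
#' by a parent, so the ovule is still fertilized by a different pollen
#' gamete and no extra ovule abortion arises).
#'
#' @param alleles an \code{\link{si_alleles}} table.
#' @param ch1_pairs data.frame with columns \code{activator} and
#'   \code{target}: zygotes homozygous for \code{target} are eliminated when
#'   \code{activator} is present in the parents.  \code{NULL} disables the
#'   zygotic rule.
#' @param gametic_locus locus name the fusion-failure rule applies to
#'   (default \code{"CH4"}); \code{NA} disables it.
#' @param zygotic_locus locus name the elimination rule applies to (default
#'   \code{"CH1"}).
#' @param ch4_requires whether the shared specificity must be expressed in
#'   \code{"both"} parents (default) or in the \code{"mother"} only.
#' @param ch1_activator_in which parent must carry the activator:
#'   \code{"either"} (default), \code{"mother"}, \code{"father"}, or
#'   \code{"both"}.
#' @return A list of class \code{"si_model"}.
#' @export
si_model <- function(alleles = cacao_s_alleles(), ch1_pairs = NULL,
                     gametic_locus = "CH4", zygotic_locus = "CH1",
                     ch4_requires = c("both", "mother"),
                     ch1_activator_in = c("either", "mother", "father", "both")) {
  stopifnot(inherits(alleles, "si_alleles"))
  ch4_requires <- match.arg(ch4_requires)
  ch1_activator_in <- match.arg(ch1_activator_in)
  if (!is.null(ch1_pairs)) {
    ch1_pairs <- as.data.frame(ch1_pairs)
    stopifnot(all(c("activator", "target") %in% names(ch1_pairs)))
    unknown <- setdiff(unique(c(ch1_pairs$activator, ch1_pairs$target)),
                       alleles$id)
    if (length(unknown))
      stop("ch1_pairs reference unknown alleles: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(alleles = alleles, ch1_pairs = ch1_pairs,
                 gametic_locus = gametic_locus,
                 zygotic_locus = zygotic_locus,
                 ch4_requires = ch4_requires,
                 ch1_activator_in = ch1_activator_in),
            class = "si_model")
}

rank_of <- function(model, ids) {
  i <- match(ids, model$alleles$id)
  if (anyNA(i)) stop("unknown allele id(s): ",
                     paste(ids[is.na(i)], collapse = ", "))
  model$alleles$rank[i]
}

activity_of <- function(model, ids) {
  i <- match(ids, model$alleles$id)
  if (anyNA(i)) stop("unknown allele id(s): ",
                     paste(ids[is.na(i)], collapse = ", "))
  model$alleles$activity[i]
}

#' Expressed incompatibility specificities of a diploid genotype
#'
#' The sporophytic step of the model: from a diploid genotype the dominant
#' allele(s) are those with the minimal dominance rank; of these, only
#' active alleles contribute a specificity.  Codominant active alleles
#' (equal rank) are both expressed; a genotype whose dominant allele is
#' amorphous expresses nothing (this is why \emph{Sf}/\emph{Sf} plants, and
#' \emph{Sf}/S4 plants with S4 recessive to \emph{Sf}, are self-compatible).
#'
#' @param genotype character vector of two allele ids.
#' @param model an \code{\link{si_model}}.
#' @return Character vector of expressed allele ids (possibly empty).
#' @examples
#' m <- si_model()
#' expressed_specificities(c("Sf", "Sf"), m)     # character(0): SC
#' expressed_specificities(c("Sf", "S_sca"), m)  # "S_sca"
#' expressed_specificities(c("S2", "S3"), m)     # both (codominant)
#' @export
expressed_specificities <- function(genotype, model) {
  stopifnot(length(genotype) == 2L)
  r <- rank_of(model, genotype)
  a <- activity_of(model, genotype)
  dominant <- genotype[r == min(r)]
  act <- a[r == min(r)]
  unique(dominant[act == "active"])
}

#' Cross specification
#'
#' @param mother,father named lists mapping locus name (e.g. \code{"CH1"},
#'   \code{"CH4"}) to a character vector of two allele ids.
#' @param n_offspring number of surviving offspring to simulate.
#' @param mentor_fraction proportion of the pollen pool contributed by a
#'   mentor parent (interspecific compatible pollen), in [0, 1].
#' @param baseline_abortion proportion of ovules aborting for reasons
#'   unrelated to incompatibility (intrinsic fertility of the clone);
#'   default 0.10, matching the 9.2--11\% observed in hand-pollination
#'   dissections.
#' @return A list of class \code{"cross_spec"}.
#' @export
cross_spec <- function(mother, father = mother, n_offspring = 100L,
                       mentor_fraction = 0, baseline_abortion = 0.10) {
  check_gt <- function(g, who) {
    if (!is.list(g) || is.null(names(g)) || any(names(g) == ""))
      stop(who, " must be a named list of loci")
    for (loc in names(g))
      if (length(g[[loc]]) != 2L)
        stop(who, " genotype at ", loc, " must have exactly two alleles")
  }
  check_gt(mother, "mother"); check_gt(father, "father")
  if (!setequal(names(mother), names(father)))
    stop("mother and father must be genotyped at the same loci")
  stopifnot(n_offspring >= 1, mentor_fraction >= 0, mentor_fraction <= 1,
            baseline_abortion >= 0, baseline_abortion < 1)
  structure(list(mother = mother, father = father,
                 n_offspring = as.integer(n_offspring),
                 mentor_fraction = mentor_fraction,
                 baseline_abortion = baseline_abortion),
            class = "cross_spec")
}

# gamete pair (female f, male m) fails fusion at the gametic locus iff both
# gametes carry the same specificity s and s is expressed in the required
# parent(s)
ch4_pair_fails <- function(f, m, mother_gt, father_gt, model) {
  if (f != m) return(FALSE)
  exp_m <- expressed_specificities(mother_gt, model)
  if (!(f %in% exp_m)) return(FALSE)
  if (model$ch4_requires == "both") {
    exp_f <- expressed_specificities(father_gt, model)
    if (!(f %in% exp_f)) return(FALSE)
  }
  TRUE
}

# elimination targets active for a given parental pair: character vector of
# target alleles X such that zygote X/X is eliminated pre-fusion
active_ch1_targets <- function(mother_gt, father_gt, model) {
  if (is.null(model$ch1_pairs)) return(character(0))
  present <- switch(model$ch1_activator_in,
    either = function(y) y %in% mother_gt || y %in% father_gt,
    mother = function(y) y %in% mother_gt,
    father = function(y) y %in% father_gt,
    both   = function(y) y %in% mother_gt && y %in% father_gt)
  keep <- vapply(model$ch1_pairs$activator, present, logical(1))
  unique(model$ch1_pairs$target[keep])
}

gt_key <- function(x, y) paste(sort(c(x, y)), collapse = "/")

# per-locus table of gamete pairs: female allele, male allele, probability,
# fails-fusion flag, eliminated flag
locus_pair_table <- function(cross, model, locus) {
  mg <- cross$mother[[locus]]; fg <- cross$father[[locus]]
  pairs <- expand.grid(f = mg, m = fg, stringsAsFactors = FALSE)
  pairs$prob <- 0.25
  gametic <- identical(locus, model$gametic_locus)
  zygotic <- identical(locus, model$zygotic_locus)
  pairs$unfused <- if (gametic)
    mapply(ch4_pair_fails, pairs$f, pairs$m,
           MoreArgs = list(mother_gt = mg, father_gt = fg, model = model))
  else rep(FALSE, nrow(pairs))
  targets <- if (zygotic) active_ch1_targets(mg, fg, model) else character(0)
  pairs$eliminated <- pairs$f == pairs$m & pairs$f %in% targets
  pairs
}

#' Expected genotype distribution among surviving offspring
#'
#' Exact conditional probabilities over offspring genotype classes at each
#' locus: start from Mendelian gamete-pair probabilities, remove pairs
#' failing gamete fusion (gametic rule) and zygotes eliminated pre-fusion
#' (zygotic rule), and renormalize.  Loci are assumed unlinked, so ovule
#' loss at one locus does not distort the conditional distribution at the
#' other.
#'
#' When the parents jointly carry at most two distinct alleles at a locus,
#' the distribution is additionally reported in a/h/b coding: \code{a} =
#' homozygous for the designated A allele (the mother's first allele by
#' default), \code{b} = homozygous for the other allele, \code{h} =
#' heterozygous.
#'
#' @param cross a \code{\link{cross_spec}}.
#' @param model an \code{\link{si_model}}.
#' @param allele_a optional named character vector (locus -> allele id)
#'   fixing which allele maps to class \code{a}.
#' @return Named list per locus, each with \code{classes} (probabilities
#'   over genotype strings) and \code{ahb} (probabilities over a/h/b, or
#'   \code{NULL} when more than two distinct alleles segregate).
#' @examples
#' m <- si_model()
#' cs <- cross_spec(mother = list(CH4 = c("Sf", "S_sca")))
#' expected_genotype_distribution(cs, m)$CH4$ahb  # 1/3, 2/3, 0
#' @export
expected_genotype_distribution <- function(cross, model, allele_a = NULL) {
  out <- list()
  for (locus in names(cross$mother)) {
    pairs <- locus_pair_table(cross, model, locus)
    keep <- !pairs$unfused & !pairs$eliminated
    if (!any(keep) || sum(pairs$prob[keep]) <= 0)
      stop("fully incompatible cross: no surviving genotype at locus ", locus,
           call. = FALSE)
    surv <- pairs[keep, , drop = FALSE]
    key <- mapply(gt_key, surv$f, surv$m)
    probs <- tapply(surv$prob, key, sum)
    probs <- probs / sum(probs)
    classes <- as.numeric(probs); names(classes) <- names(probs)
    out[[locus]] <- list(
      classes = classes,
      ahb = ahb_from_classes(classes, cross, locus, allele_a))
  }
  out
}

ahb_from_classes <- function(classes, cross, locus, allele_a = NULL) {
  alleles <- unique(c(cross$mother[[locus]], cross$father[[locus]]))
  if (length(alleles) > 2L) return(NULL)
  aa <- if (!is.null(allele_a) && locus %in% names(allele_a))
    allele_a[[locus]] else cross$mother[[locus]][1]
  bb <- setdiff(alleles, aa)
  if (length(bb) == 0L) bb <- aa  # fully homozygous cross
  ahb <- c(a = 0, h = 0, b = 0)
  for (k in names(classes)) {
    pr <- classes[[k]]
    parts <- strsplit(k, "/", fixed = TRUE)[[1]]
    cls <- if (parts[1] != parts[2]) "h" else if (parts[1] == aa) "a" else "b"
    ahb[cls] <- ahb[cls] + pr
  }
  ahb
}

#' Expected fraction of ovules with gamete non-fusion
#'
#' Probability that a random ovule's gamete pair fails fusion under the
#' gametic rule, before any renormalization and excluding baseline
#' abortion.  Selfing a genotype expressing one specificity gives 25\%,
#' two codominant specificities give 50\%, and a homozygous active genotype
#' gives 100\%, reproducing the three unfused-ovule classes reported in the
#' cacao cytology literature.
#'
#' @inheritParams expected_genotype_distribution
#' @return A single proportion in [0, 1].
#' @export
expected_unfused_fraction <- function(cross, model) {
  locus <- model$gametic_locus
  if (is.na(locus) || !(locus %in% names(cross$mother))) return(0)
  pairs <- locus_pair_table(cross, model, locus)
  sum(pairs$prob[pairs$unfused])
}

#' Forward simulation of a cross under the two-locus SI model
#'
#' Samples ovules one at a time: each ovule first aborts with the baseline
#' (non-SI) probability; otherwise female and male gametes are drawn at
#' every locus.  A gamete pair producing a zygote eliminated by the
#' pre-fusion rule is redrawn (rejection sampling of the pair), so the
#' ovule is still fertilized -- in line with the observation that the
#' chromosome-1 selection adds no ovule abortion -- and the surviving
#' genotype law equals the renormalized conditional distribution of
#' \code{\link{expected_genotype_distribution}}.  Gamete pairs failing the
#' fusion rule at the gametic locus leave the ovule unfused.  Sampling
#' continues until \code{cross$n_offspring} fertilized offspring exist.
#'
#' @inheritParams expected_genotype_distribution
#' @param seed integer random seed (required; no global state is consulted).
#' @param max_redraws bound on pollen redraws per ovule before declaring the
#'   cross fully incompatible.
#' @return A list of class \code{"progeny_sim"}: \code{offspring} (one row
#'   per individual with maternal/paternal allele and a/h/b class per locus
#'   and a parentage label), \code{ovule_fates} (counts fertilized, unfused,
#'   baseline_aborted), \code{fruit_retained}.
#' @export
simulate_progeny <- function(cross, model, seed, max_redraws = 1000L) {
  stopifnot(inherits(cross, "cross_spec"), inherits(model, "si_model"))
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  # fail fast on fully incompatible crosses (also validates alleles)
  expected_genotype_distribution(cross, model)
  loci <- names(cross$mother)
  n <- cross$n_offspring
  gl <- model$gametic_locus; zl <- model$zygotic_locus
  # specificities whose gamete pairs fail fusion, fixed by the parents
  failset <- character(0)
  if (!is.na(gl) && gl %in% loci) {
    exp_m <- expressed_specificities(cross$mother[[gl]], model)
    failset <- if (model$ch4_requires == "both")
      intersect(exp_m, expressed_specificities(cross$father[[gl]], model))
    else exp_m
  }
  targets <- if (zl %in% loci && !is.null(model$ch1_pairs))
    active_ch1_targets(cross$mother[[zl]], cross$father[[zl]], model)
  else character(0)
  p_succ <- (1 - cross$baseline_abortion) *
    (1 - expected_unfused_fraction(cross, model))
  fem_keep <- mal_keep <- NULL
  got <- 0L; unfused_n <- 0L; aborted_n <- 0L
  while (got < n) {
    B <- as.integer(ceiling((n - got) / max(p_succ, 0.01) * 1.2) + 64L)
    abort <- stats::runif(B) < cross$baseline_abortion
    fem <- mal <- matrix("", B, length(loci), dimnames = list(NULL, loci))
    for (l in loci) {
      fem[, l] <- cross$mother[[l]][sample.int(2L, B, replace = TRUE)]
      mal[, l] <- cross$father[[l]][sample.int(2L, B, replace = TRUE)]
    }
    if (length(targets)) {
      # rejection sampling of the gamete pair: an eliminated zygote is
      # replaced by a fresh pair draw so the surviving-genotype law equals
      # the renormalized conditional distribution, while the ovule is
      # still fertilized (no extra abortion)
      live <- which(!abort)
      elim <- live[fem[live, zl] == mal[live, zl] &
                     fem[live, zl] %in% targets]
      tries <- 0L
      while (length(elim)) {
        tries <- tries + 1L
        if (tries > max_redraws)
          stop("fully incompatible cross: gamete redraw bound exceeded")
        fem[elim, zl] <-
          cross$mother[[zl]][sample.int(2L, length(elim), replace = TRUE)]
        mal[elim, zl] <-
          cross$father[[zl]][sample.int(2L, length(elim), replace = TRUE)]
        elim <- elim[fem[elim, zl] == mal[elim, zl] &
                       fem[elim, zl] %in% targets]
      }
    }
    unf <- !abort & if (length(failset))
      fem[, gl] == mal[, gl] & fem[, gl] %in% failset
    else rep(FALSE, B)
    fert <- !abort & !unf
    idx <- which(fert)
    take <- utils::head(idx, n - got)
    # ovules drawn after the last needed fertilized one never happened
    cutoff <- if (length(take)) take[length(take)] else 0L
    aborted_n <- aborted_n + sum(abort[seq_len(cutoff)])
    unfused_n <- unfused_n + sum(unf[seq_len(cutoff)])
    fem_keep <- rbind(fem_keep, fem[take, , drop = FALSE])
    mal_keep <- rbind(mal_keep, mal[take, , drop = FALSE])
    got <- got + length(take)
  }
  off <- data.frame(individual = paste0("ind_", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (locus in loci) {
    aa <- cross$mother[[locus]][1]
    fm <- fem_keep[, locus]; ml <- mal_keep[, locus]
    off[[paste0(locus, "_mat")]] <- fm
    off[[paste0(locus, "_pat")]] <- ml
    off[[paste0(locus, "_class")]] <-
      ifelse(fm != ml, "h", ifelse(fm == aa, "a", "b"))
  }
  off$parentage <- "self"
  structure(list(offspring = off,
                 ovule_fates = c(fertilized = n, unfused = unfused_n,
                                 baseline_aborted = aborted_n),
                 fruit_retained = TRUE),
            class = "progeny_sim")
}

#' Mixed (mentor) pollination simulation
#'
#' Mentor pollen (compatible, typically heterospecific) is mixed with self
#' pollen so that fruits of self-incompatible genotypes are not dropped and
#' self-fertilized seeds can mature.  Each ovule is pollinated by mentor
#' pollen with probability \code{mentor_fraction}; mentor gametes always
#' fuse but the resulting embryos are flat/nonviable.  Self-pollinated
#' ovules follow the full SI model.  A fruit is retained iff its proportion
#' of fused ovules is at least \code{retention_threshold} (default 0:
#' mentor pollination always rescues the fruit).  Viable offspring are the
#' self-derived fertilized ovules of retained fruits.
#'
#' @inheritParams simulate_progeny
#' @param ovules_per_fruit ovules per simulated fruit (cacao ovaries carry
#'   dozens of ovules; default 40).
#' @param retention_threshold minimum fused-ovule proportion for fruit
#'   retention, in [0, 1].
#' @param n_fruits number of fruits to simulate.
#' @return A \code{"progeny_sim"} list; \code{offspring} carries both
#'   viable self-derived seeds and flat mentor-derived embryos
#'   (\code{parentage}, \code{viable} columns), \code{fruit_retained} is a
#'   logical vector per fruit.
#' @export
simulate_mixed_pollination <- function(cross, model, ovules_per_fruit = 40L,
                                       retention_threshold = 0, seed,
                                       n_fruits = NULL) {
  stopifnot(inherits(cross, "cross_spec"))
  if (ovules_per_fruit < 1L) stop("ovules_per_fruit must be >= 1")
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  if (is.null(n_fruits))
    n_fruits <- max(1L, ceiling(cross$n_offspring / ovules_per_fruit))
  loci <- names(cross$mother)
  gl <- model$gametic_locus; zl <- model$zygotic_locus
  draw_gamete <- function(gt) gt[sample.int(2L, 1L)]
  rows <- list(); fates <- c(fertilized = 0L, unfused = 0L,
                             baseline_aborted = 0L)
  retained <- logical(n_fruits)
  for (fr in seq_len(n_fruits)) {
    fused_in_fruit <- 0L
    fruit_rows <- list()
    for (ov in seq_len(ovules_per_fruit)) {
      if (stats::runif(1) < cross$baseline_abortion) {
        fates["baseline_aborted"] <- fates["baseline_aborted"] + 1L
        next
      }
      mentor <- stats::runif(1) < cross$mentor_fraction
      if (mentor) {
        fates["fertilized"] <- fates["fertilized"] + 1L
        fused_in_fruit <- fused_in_fruit + 1L
        fruit_rows[[length(fruit_rows) + 1L]] <-
          list(fruit = fr, parentage = "mentor", viable = FALSE,
               gt = NULL)
        next
      }
      fem <- vapply(loci, function(l) draw_gamete(cross$mother[[l]]), "")
      mal <- vapply(loci, function(l) draw_gamete(cross$father[[l]]), "")
      if (zl %in% loci && !is.null(model$ch1_pairs)) {
        targets <- active_ch1_targets(cross$mother[[zl]], cross$father[[zl]],
                                      model)
        tries <- 0L
        while (fem[[zl]] == mal[[zl]] && fem[[zl]] %in% targets) {
          tries <- tries + 1L
          if (tries > 10000L) stop("fully incompatible cross at zygotic locus")
          fem[[zl]] <- draw_gamete(cross$mother[[zl]])
          mal[[zl]] <- draw_gamete(cross$father[[zl]])
        }
      }
      if (!is.na(gl) && gl %in% loci &&
          ch4_pair_fails(fem[[gl]], mal[[gl]], cross$mother[[gl]],
                         cross$father[[gl]], model)) {
        fates["unfused"] <- fates["unfused"] + 1L
        next
      }
      fates["fertilized"] <- fates["fertilized"] + 1L
      fused_in_fruit <- fused_in_fruit + 1L
      fruit_rows[[length(fruit_rows) + 1L]] <-
        list(fruit = fr, parentage = "self", viable = TRUE,
             gt = list(fem = fem, mal = mal))
    }
    retained[fr] <- (fused_in_fruit / ovules_per_fruit) >= retention_threshold
    if (retained[fr]) rows <- c(rows, fruit_rows)
  }
  off <- mixed_rows_to_df(rows, cross, loci)
  structure(list(offspring = off, ovule_fates = fates,
                 fruit_retained = retained),
            class = "progeny_sim")
}

mixed_rows_to_df <- function(rows, cross, loci) {
  n <- length(rows)
  base <- data.frame(individual = if (n) paste0("seed_", seq_len(n))
                     else character(0),
                     fruit = if (n) vapply(rows, `[[`, 0, "fruit")
                     else integer(0),
                     parentage = if (n) vapply(rows, `[[`, "", "parentage")
                     else character(0),
                     viable = if (n) vapply(rows, `[[`, TRUE, "viable")
                     else logical(0),
                     stringsAsFactors = FALSE)
  for (locus in loci) {
    aa <- cross$mother[[locus]][1]
    get_allele <- function(r, side)
      if (is.null(r$gt)) NA_character_ else r$gt[[side]][[locus]]
    fm <- if (n) vapply(rows, get_allele, "", side = "fem") else character(0)
    ml <- if (n) vapply(rows, get_allele, "", side = "mal") else character(0)
    base[[paste0(locus, "_mat")]] <- fm
    base[[paste0(locus, "_pat")]] <- ml
    base[[paste0(locus, "_class")]] <-
      ifelse(is.na(fm) | is.na(ml), NA_character_,
             ifelse(fm != ml, "h", ifelse(fm == aa, "a", "b")))
  }
  base
}

#' Classify offspring parentage from SSR profiles
#'
#' Used to separate self- from cross-fertilized seedlings in mixed
#' pollinations: an offspring is \code{"outcross"} if, at any marker, it
#' carries an allele absent from the seed parent and present in the
#' candidate outcross parent; \code{"self"} if all its alleles are
#' derivable from the seed parent and at least one marker excludes the
#' outcross parent (the offspring lacks any allele that an offspring of
#' that parent must carry); otherwise \code{"ambiguous"}.
#'
#' @param offspring,seed_parent,outcross_parent named lists mapping marker
#'   name to a numeric vector of two allele sizes (bp); \code{NA} cells are
#'   treated as missing.
#' @param markers markers to use (default: markers present in all three
#'   profiles).
#' @return One of \code{"self"}, \code{"outcross"}, \code{"ambiguous"}.
#' @export
classify_offspring_parentage <- function(offspring, seed_parent,
                                         outcross_parent, markers = NULL) {
  if (is.null(markers))
    markers <- Reduce(intersect, list(names(offspring), names(seed_parent),
                                      names(outcross_parent)))
  ok <- function(x) !is.null(x) && !all(is.na(x))
  markers <- markers[vapply(markers, function(m)
    ok(offspring[[m]]) && ok(seed_parent[[m]]) && ok(outcross_parent[[m]]),
    logical(1))]
  if (length(markers) == 0L)
    stop("no marker genotyped in all three profiles")
  foreign <- FALSE; excludes_outcross <- FALSE; all_from_seed <- TRUE
  for (m in markers) {
    off <- offspring[[m]]; sp <- seed_parent[[m]]; op <- outcross_parent[[m]]
    novel <- setdiff(off, sp)
    if (length(novel)) {
      all_from_seed <- FALSE
      if (any(novel %in% op)) foreign <- TRUE
    }
    # an offspring sired by the outcross parent must carry one of its two
    # alleles at every marker
    if (!any(off %in% op)) excludes_outcross <- TRUE
  }
  if (foreign) return("outcross")
  if (all_from_seed && excludes_outcross) return("self")
  "ambiguous"
}
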