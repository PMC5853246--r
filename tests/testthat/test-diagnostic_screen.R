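test_that("combo enumeration equals the brute-force count", {
  d <- toy_screen_data()
  # 2 markers x 2 observed genotypes each, min_support 1:
  # table built so every joint genotype pair is observed
  ssr <- data.frame(individual = paste0("x", 1:4),
                    m1 = c("1/1", "1/1", "1/2", "1/2"),
                    m2 = c("3/3", "3/4", "3/3", "3/4"),
                    stringsAsFactors = FALSE)
  combos <- enumerate_combos(ssr, max_order = 2, min_support = 1)
  expect_identical(sum(combos$order == 1), 4L)
  expect_identical(sum(combos$order == 2), 4L)
  # min_support beyond n empties the list
  expect_identical(nrow(enumerate_combos(ssr, 2, min_support = 5L)), 0L)
  expect_error(enumerate_combos(ssr, max_order = 4), "max_order")

  # brute-force combinatorial oracle on a larger synthetic table
  cfg <- assoc_pop_config(n = 60)
  pop <- gen_association_population(cfg, seed = 3)
  combos <- enumerate_combos(pop$ssr, max_order = 2, min_support = 3)
  markers <- sort(setdiff(names(pop$ssr), "individual"))
  brute <- 0L
  for (ord in 1:2) for (ms in utils::combn(markers, ord, simplify = FALSE)) {
    cells <- pop$ssr[, ms, drop = FALSE]
    cc <- stats::complete.cases(cells)
    gts <- lapply(ms, function(m) unique(cells[[m]][!is.na(cells[[m]])]))
    for (combo in split(as.matrix(expand.grid(gts, stringsAsFactors = FALSE)),
                        seq_len(prod(lengths(gts))))) {
      carriers <- cc
      for (j in seq_along(ms))
        carriers <- carriers & !is.na(cells[[j]]) & cells[[j]] == combo[[j]]
      if (sum(carriers) >= 3L) brute <- brute + 1L
    }
  }
  expect_identical(nrow(combos), brute)
})

test_that("combo screen reports exact-test p, q ordering and carrier probabilities", {
  # planted fully predictive genotype: carriers all SC
  set.seed(9)
  n <- 112
  carrier <- c(rep(TRUE, 12), rep(FALSE, 100))
  ssr <- data.frame(individual = sprintf("i%03d", 1:n),
                    mX = ifelse(carrier, "10/12", "10/10"),
                    mY = sample(c("5/5", "5/7"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  phen <- data.frame(individual = ssr$individual,
                     sc_status = ifelse(carrier, 1,
                                        rep(c(1, 0, 0, 0, 0), 20)),
                     stringsAsFactors = FALSE)
  res <- combo_screen(ssr, phen, max_order = 1, min_support = 3)
  top <- res[res$markers == "mX" & res$genotypes == "10/12", ]
  expect_equal(top$prob_sc_has, 1.0)
  expect_equal(top$prob_sc_not, mean(phen$sc_status[!carrier]))
  expect_true(top$separation)
  expect_identical(res$q, sort(res$q))
  # contingency margins sum to the phenotyped complete-case totals
  expect_equal(top$n_has_sc + top$n_has_si + top$n_not_sc + top$n_not_si, n)
  # one-class phenotype errors
  expect_error(combo_screen(ssr, transform(phen, sc_status = 1)),
               "single class")
})

test_that("carrier probabilities equal the indicator-logistic MLE on non-separated data", {
  set.seed(15)
  for (i in 1:5) {
    n <- 150
    has <- stats::runif(n) < 0.35
    y <- stats::rbinom(n, 1, ifelse(has, 0.65, 0.35))
    if (all(y[has] == y[has][1]) || all(y[!has] == y[!has][1])) next
    pr <- cacaoSI:::indicator_probs(has, y)
    ref <- stats::glm(y ~ has, family = stats::binomial())
    expect_equal(pr$prob_has,
                 unname(stats::plogis(sum(stats::coef(ref)))),
                 tolerance = 1e-9)
    expect_equal(pr$prob_not,
                 unname(stats::plogis(stats::coef(ref)[1])),
                 tolerance = 1e-9)
    expect_false(pr$separation)
  }
})

test_that("screens recover a planted diagnostic allele and rank it first", {
  cfg <- assoc_pop_config(n = 400, ld = list(marker = "mSI_460",
                                             allele = "161",
                                             s_allele = "Sf", r2 = 0.9))
  pop <- gen_association_population(cfg, seed = 21)
  res <- allele_presence_screen(pop$ssr, pop$phenotype)
  expect_identical(res$marker[1], "mSI_460")
  expect_identical(res$allele[1], 161)
  # consistency: the top row's p equals fisher_exact of its own table
  tab <- matrix(c(res$n_present_sc[1], res$n_present_si[1],
                  res$n_absent_sc[1], res$n_absent_si[1]), 2, 2, byrow = TRUE)
  expect_equal(res$p[1], fisher_exact(tab))
  # combo screen also surfaces the planted marker's genotypes at the top
  cres <- combo_screen(pop$ssr, pop$phenotype, max_order = 1,
                       min_support = 5)
  expect_match(cres$markers[1], "mSI_460")
})

test_that("allele presence screen handles degenerate margins", {
  ssr <- data.frame(individual = paste0("i", 1:8),
                    m1 = rep("7/7", 8),  # allele 7 in everyone
                    stringsAsFactors = FALSE)
  phen <- data.frame(individual = ssr$individual,
                     sc_status = rep(c(0, 1), 4), stringsAsFactors = FALSE)
  res <- allele_presence_screen(ssr, phen)
  expect_identical(res$p, 1)
})

test_that("screen output is invariant to individual and marker order", {
  d <- toy_screen_data()
  r1 <- combo_screen(d$ssr, d$phen, max_order = 2, min_support = 2)
  shuffled <- d$ssr[sample(nrow(d$ssr)), c("individual", "m2", "m1")]
  r2 <- combo_screen(shuffled, d$phen[sample(nrow(d$phen)), ],
                     max_order = 2, min_support = 2)
  expect_equal(r1, r2)
  a1 <- allele_presence_screen(d$ssr, d$phen)
  a2 <- allele_presence_screen(shuffled, d$phen)
  expect_equal(a1, a2)
})

test_that("label permutation yields uniform p-values and ~alpha rejections", {
  cfg <- assoc_pop_config(n = 250, ld = list(marker = "mSI_460",
                                             allele = "161",
                                             s_allele = "Sf", r2 = 0))
  pop <- gen_association_population(cfg, seed = 5)
  set.seed(99)
  pvals <- unlist(lapply(1:30, function(i) {
    phen <- pop$phenotype
    phen$sc_status <- sample(phen$sc_status)
    allele_presence_screen(pop$ssr, phen)$p
  }))
  # discrete exact-test p-values are stochastically >= uniform under the
  # null; check no excess of small p and no mass concentration
  expect_lt(mean(pvals <= 0.05), 0.07)
  expect_gt(mean(pvals > 0.5), 0.4)
})

test_that("allele dose fit recovers planted dose effects and flags separation", {
  # well-powered recovery at n = 2000 through the SSR plumbing,
  # averaged over simulation replicates of the oracle
  set.seed(55)
  n <- 2000
  dose <- sample(0:2, n, replace = TRUE)
  cell <- c("9/9", "8/9", "8/8")[dose + 1L]
  ssr <- data.frame(individual = sprintf("i%04d", 1:n), mD = cell,
                    stringsAsFactors = FALSE)
  coefs <- vapply(1:5, function(i) {
    y <- stats::rbinom(n, 1, stats::plogis(0.5 - 1.0 * dose))
    phen <- data.frame(individual = ssr$individual, sc_status = y,
                       stringsAsFactors = FALSE)
    fit <- allele_dose_fit(ssr, phen, "mD", 8)
    expect_identical(fit$method, "ml")
    fit$coef
  }, c(intercept = 0, slope = 0))
  expect_lt(abs(mean(coefs["slope", ]) - (-1.0)), 0.15)
  expect_lt(abs(mean(coefs["intercept", ]) - 0.5), 0.15)
  phen <- data.frame(individual = ssr$individual,
                     sc_status = stats::rbinom(n, 1,
                                               stats::plogis(0.5 - dose)),
                     stringsAsFactors = FALSE)
  # dose-ignoring phenotype: flat probabilities
  set.seed(56)
  y0 <- stats::rbinom(n, 1, 0.5)
  fit0 <- allele_dose_fit(ssr, transform(phen, sc_status = y0), "mD", 8)
  expect_lt(max(fit0$prob_sc) - min(fit0$prob_sc), 0.1)
  # complete separation: penalized fallback, flagged, never a crash
  ysep <- as.integer(dose == 0)
  ysep[dose == 0] <- rep(c(1, 0), length.out = sum(dose == 0))
  ysep[dose > 0] <- 0
  fsep <- allele_dose_fit(ssr, transform(phen, sc_status = ysep), "mD", 8)
  expect_true(fsep$separation)
  expect_identical(fsep$method, "firth")
  expect_lt(fsep$prob_sc[["2"]], 0.1)
  # single observed dose errors
  ssr1 <- transform(ssr, mD = "8/8")
  expect_error(allele_dose_fit(ssr1, phen, "mD", 8), "single dose")
})
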