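test_that("expressed specificities follow the dominance series", {
  m <- default_model()
  # amorphous homozygote expresses nothing
  expect_identical(expressed_specificities(c("Sf", "Sf"), m), character(0))
  # active allele dominant over amorphous Sf is expressed
  expect_identical(expressed_specificities(c("Sf", "S_sca"), m), "S_sca")
  # codominant actives (equal rank) are both expressed
  expect_setequal(expressed_specificities(c("S2", "S3"), m), c("S2", "S3"))
  # recessive active under a dominant amorphous allele is silenced
  # (S4 and S5 are recessive to Sf: such plants are self-compatible)
  expect_identical(expressed_specificities(c("Sf", "S4"), m), character(0))
  expect_identical(expressed_specificities(c("Sf", "S5"), m), character(0))
  # dominant active over recessive active
  expect_identical(expressed_specificities(c("S1", "S4"), m), "S1")
  expect_error(expressed_specificities(c("S1", "nope"), m), "unknown allele")
})

test_that("expected genotype distributions reproduce the printed crosses", {
  # no rules: Mendelian 1:2:1 for a selfed heterozygote
  m0 <- si_model(ch1_alleles(), gametic_locus = NA)
  d0 <- expected_genotype_distribution(br59_cross(), m0)$CH1
  expect_equal(unname(d0$ahb), c(0.25, 0.5, 0.25))

  # gametic-locus selfing of Sf/S_sca: b absent, a:h = 1:2
  d1 <- expected_genotype_distribution(tsh516_cross(), default_model())$CH4
  expect_equal(unname(d1$ahb), c(1 / 3, 2 / 3, 0))

  # zygotic elimination: BR59-type selfing -> (0, 2/3, 1/3)
  d2 <- expected_genotype_distribution(br59_cross(), ch1_model())$CH1
  expect_equal(unname(d2$ahb), c(0, 2 / 3, 1 / 3))

  # Criollo allele is not an activator: UF676 x ICS95 stays 1:2:1
  d3 <- expected_genotype_distribution(uf676_ics95_cross(), ch1_model())$CH1
  expect_equal(unname(d3$ahb), c(0.25, 0.5, 0.25))

  # fully incompatible cross errors rather than dividing by zero
  expect_error(
    expected_genotype_distribution(
      cross_spec(mother = list(CH4 = c("S1", "S1"))), default_model()),
    "fully incompatible")
})

test_that("distribution is a probability law for random rule configurations", {
  set.seed(11)
  m <- default_model()
  ids <- m$alleles$id
  for (i in 1:40) {
    mo <- sample(ids, 2, replace = TRUE)
    fa <- sample(ids, 2, replace = TRUE)
    cs <- cross_spec(mother = list(CH4 = mo), father = list(CH4 = fa))
    d <- tryCatch(expected_genotype_distribution(cs, m)$CH4,
                  error = function(e) e)
    if (inherits(d, "error")) {
      expect_match(conditionMessage(d), "fully incompatible")
      next
    }
    expect_true(all(d$classes >= 0))
    expect_equal(sum(d$classes), 1)
    # with rules disabled the same cross is Mendelian
    m_off <- si_model(m$alleles, gametic_locus = NA)
    dm <- expected_genotype_distribution(cs, m_off)$CH4
    mendel <- table(c(outer(mo, fa, Vectorize(cacaoSI:::gt_key)))) / 4
    expect_equal(dm$classes[sort(names(mendel))],
                 c(mendel[sort(names(mendel))]))
  }
})

test_that("unfused-ovule fractions give the 25/50/100% classes", {
  m <- default_model()
  self_of <- function(g) cross_spec(mother = list(CH4 = g))
  expect_equal(expected_unfused_fraction(self_of(c("Sf", "Sf")), m), 0)
  expect_equal(expected_unfused_fraction(self_of(c("Sf", "S_sca")), m), 0.25)
  expect_equal(expected_unfused_fraction(self_of(c("S2", "S3")), m), 0.50)
  expect_equal(expected_unfused_fraction(self_of(c("S1", "S1")), m), 1.00)
  # zygotic-only model never produces unfused ovules
  expect_equal(expected_unfused_fraction(br59_cross(), ch1_model()), 0)
})

test_that("simulated progeny matches the analytic law", {
  # BR59-type selfing: class a absent, h near 2/3
  s <- simulate_progeny(br59_cross(109), ch1_model(), seed = 101)
  cls <- table(factor(s$offspring$CH1_class, levels = c("a", "h", "b")))
  expect_identical(unname(cls[["a"]]), 0L)
  expect_lt(abs(cls[["h"]] - 109 * 2 / 3), 3 * sqrt(109 * 2 / 9))
  # zygotic-only rules add no unfused ovules
  expect_identical(unname(s$ovule_fates[["unfused"]]), 0L)
  # fates partition the ovule total
  expect_identical(sum(s$ovule_fates), s$ovule_fates[["fertilized"]] +
                     s$ovule_fates[["unfused"]] +
                     s$ovule_fates[["baseline_aborted"]])

  # no-rule selfing at n = 10000: 1:2:1 chi-square sanity across seeds
  m0 <- si_model(ch1_alleles(), gametic_locus = NA)
  ok <- vapply(1:25, function(sd) {
    sim <- simulate_progeny(br59_cross(10000, baseline_abortion = 0), m0,
                            seed = sd)
    cnt <- table(factor(sim$offspring$CH1_class, levels = c("a", "h", "b")))
    stats::chisq.test(c(cnt), p = c(1, 2, 1) / 4)$p.value > 0.001
  }, logical(1))
  expect_gte(mean(ok), 0.96)
})

test_that("gametic-rule selfing converges to 25% unfused and 1/3:2/3 classes", {
  s <- simulate_progeny(tsh516_cross(10000, baseline_abortion = 0),
                        default_model(), seed = 7)
  f <- s$ovule_fates
  tot <- f[["fertilized"]] + f[["unfused"]]
  expect_lt(abs(f[["unfused"]] / tot - 0.25), 3 * sqrt(0.25 * 0.75 / tot))
  cls <- table(factor(s$offspring$CH4_class, levels = c("a", "h", "b")))
  expect_identical(unname(cls[["b"]]), 0L)
  expect_lt(abs(cls[["a"]] / 10000 - 1 / 3), 3 * sqrt(2 / 9 / 10000))
})

test_that("baseline abortion is unchanged by zygotic-only selection", {
  # mirrors the dissection result: ~equal abortion after selfing (with
  # elimination segregating) and outcrossing
  for (sd in 1:5) {
    s_self <- simulate_progeny(br59_cross(4000, baseline_abortion = 0.10),
                               ch1_model(), seed = sd)
    f <- s_self$ovule_fates
    frac <- f[["baseline_aborted"]] / sum(f)
    expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / sum(f)))
    expect_identical(unname(f[["unfused"]]), 0L)
  }
})

test_that("mixed pollination rescues fruits and yields self-derived seeds", {
  m <- default_model()
  # fully self-incompatible genotype (cannot arise by selfing; construct an
  # S1/S1 x S1/S1 cross directly)
  si_self <- cross_spec(mother = list(CH4 = c("S1", "S1")), n_offspring = 10,
                        baseline_abortion = 0)
  # mentor_fraction = 0, threshold > 0: everything unfused, no fruit kept
  mp0 <- simulate_mixed_pollination(si_self, m, ovules_per_fruit = 20,
                                    retention_threshold = 0.2, seed = 5,
                                    n_fruits = 8)
  expect_identical(sum(mp0$fruit_retained), 0L)

  # mentor_fraction = 1: all embryos mentor-derived, none viable
  allm <- cross_spec(mother = list(CH4 = c("S1", "S1")), n_offspring = 10,
                     mentor_fraction = 1, baseline_abortion = 0)
  mp1 <- simulate_mixed_pollination(allm, m, ovules_per_fruit = 20,
                                    retention_threshold = 0.2, seed = 5,
                                    n_fruits = 5)
  expect_true(all(mp1$offspring$parentage == "mentor"))
  expect_identical(sum(mp1$offspring$viable), 0L)
  expect_identical(sum(mp1$fruit_retained), 5L)

  # SI genotype with one expressed specificity (Sf/S_sca selfing), 50%
  # mentor: viable seeds are self-derived and follow the analytic law
  half <- cross_spec(mother = list(CH4 = c("Sf", "S_sca")), n_offspring = 10,
                     mentor_fraction = 0.5, baseline_abortion = 0)
  mp <- simulate_mixed_pollination(half, m, ovules_per_fruit = 25,
                                   retention_threshold = 0.5, seed = 11,
                                   n_fruits = 250)
  viable <- mp$offspring[mp$offspring$viable, , drop = FALSE]
  expect_true(all(viable$parentage == "self"))
  cls <- table(factor(viable$CH4_class, levels = c("a", "h", "b")))
  expect_identical(unname(cls[["b"]]), 0L)
  n <- sum(cls)
  expect_gt(n, 1000)
  expect_lt(abs(cls[["a"]] / n - 1 / 3), 3 * sqrt(2 / 9 / n))
})

test_that("offspring parentage classification follows allele derivability", {
  seedp <- list(mA = c(133, 145), mB = c(210, 214))
  outp <- list(mA = c(133, 160), mB = c(220, 224))
  # foreign allele present in the outcross parent -> outcross
  expect_identical(classify_offspring_parentage(
    list(mA = c(133, 160), mB = c(210, 220)), seedp, outp), "outcross")
  # all alleles from the seed parent, outcross parent excluded at mB
  expect_identical(classify_offspring_parentage(
    list(mA = c(133, 145), mB = c(210, 214)), seedp, outp), "self")
  # compatible with both -> ambiguous
  expect_identical(classify_offspring_parentage(
    list(mA = c(133, 133)), list(mA = c(133, 145)), list(mA = c(133, 160))),
    "ambiguous")
  expect_error(classify_offspring_parentage(
    list(mA = NA), seedp["mA"], outp["mA"]), "no marker")
})

test_that("simulation is reproducible given the seed", {
  s1 <- simulate_progeny(tsh516_cross(500), default_model(), seed = 77)
  s2 <- simulate_progeny(tsh516_cross(500), default_model(), seed = 77)
  expect_identical(s1$offspring, s2$offspring)
  expect_identical(s1$ovule_fates, s2$ovule_fates)
})
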