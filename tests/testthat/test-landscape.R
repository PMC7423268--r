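test_that("haplotype fitnesses reproduce the additive-plus-epistasis table", {
  # independent oracle: explicit formula for each of the 8 haplotypes,
  # written out by hand for random coefficients
  set.seed(11)
  for (rep in 1:5) {
    co <- stats::rnorm(7)
    names(co) <- c("a", "b", "g", "eAB", "eAC", "eBC", "eABC")
    ls <- fitness_landscape(co[1:3],
      epistasis = list(list(loci = c(1, 2), value = co["eAB"]),
                       list(loci = c(1, 3), value = co["eAC"]),
                       list(loci = c(2, 3), value = co["eBC"]),
                       list(loci = c(1, 2, 3), value = co["eABC"])))
    expect_equal(haplotype_fitness(ls, "abc"), 0)
    expect_equal(haplotype_fitness(ls, "Abc"), unname(co["a"]))
    expect_equal(haplotype_fitness(ls, "aBc"), unname(co["b"]))
    expect_equal(haplotype_fitness(ls, "abC"), unname(co["g"]))
    expect_equal(haplotype_fitness(ls, "ABc"), unname(co["a"] + co["b"] + co["eAB"]))
    expect_equal(haplotype_fitness(ls, "AbC"), unname(co["a"] + co["g"] + co["eAC"]))
    expect_equal(haplotype_fitness(ls, "aBC"), unname(co["b"] + co["g"] + co["eBC"]))
    expect_equal(haplotype_fitness(ls, "ABC"),
                 unname(sum(co[1:3]) + co["eAB"] + co["eAC"] + co["eBC"] + co["eABC"]))
  }
})

test_that("simple substitution examples evaluate correctly", {
  ls <- dmi2(1, -0.2, -10)
  expect_equal(haplotype_fitness(ls, "ab"), 0)
  expect_equal(haplotype_fitness(ls, "AB"), -9.2)
  expect_error(haplotype_fitness(ls, "ABC"), "length")
})

test_that("landscape constructor validates its inputs", {
  expect_error(fitness_landscape(c(1, 1),
    epistasis = list(list(loci = 1:2, value = 1),
                     list(loci = 2:1, value = 2))), "duplicate")
  expect_error(fitness_landscape(c(1, 1),
    epistasis = list(list(loci = 1L, value = 1))), "size >= 2")
  expect_error(fitness_landscape(c(1, 1), ploidy = 2), "dominance")
  expect_error(fitness_landscape(c(1, 1), dominance = "recessive"),
               "ploidy = 2")
  expect_error(fitness_landscape(rep(1, 5)), "4 loci")
})

test_that("cryptic and derived-allele parameterizations give identical fitnesses", {
  set.seed(5)
  for (rep in 1:5) {
    gp <- stats::rnorm(1); eabC <- -stats::rexp(1, 0.1)
    d <- cryptic_to_derived(gp, eabC)
    ls_cry <- cryptic(1, -0.2, gp, -10, eabC)
    ls_der <- fitness_landscape(c(1, -0.2, d$gamma),
      epistasis = list(list(loci = c(1, 2), value = -10),
                       list(loci = c(1, 3), value = d$eps_AC),
                       list(loci = c(2, 3), value = d$eps_BC),
                       list(loci = c(1, 2, 3), value = d$eps_ABC)))
    expect_equal(ls_cry$w, ls_der$w, tolerance = 1e-12)
    # round trip of the parameter maps themselves
    back <- derived_to_cryptic(d$gamma, d$eps_AC)
    expect_equal(back$gamma_prime, gp)
    expect_equal(back$eps_abC, eabC)
  }
})

test_that("scenario landscape matches its defining substitutions", {
  ls <- cryptic(1, -0.2, 0.1, -10, -20)
  expect_equal(haplotype_fitness(ls, "AbC") - haplotype_fitness(ls, "aBC"),
               1.2)
  # eps_abC = 0 removes the background interaction entirely: C becomes a
  # plain additive locus
  ls0 <- cryptic(1, -0.2, 0.1, -10, 0)
  two <- dmi2(1, -0.2, -10)
  for (h in c("ab", "Ab", "aB", "AB")) {
    expect_equal(haplotype_fitness(ls0, paste0(h, "C")) -
                   haplotype_fitness(ls0, "abC"),
                 haplotype_fitness(two, h))
    expect_equal(haplotype_fitness(ls0, paste0(h, "c")),
                 haplotype_fitness(two, h))
  }
  expect_error(scenario_landscape(0, 1, 1, -1, -1), "alpha")
})

test_that("diploid homozygotes reproduce haploid fitness differences", {
  set.seed(21)
  for (dom in c("codominant", "recessive")) {
    ls <- cryptic(1, stats::rnorm(1), 0.1, -stats::rexp(1, 0.2),
                  -stats::rexp(1, 0.1), ploidy = 2, dominance = dom)
    for (h in names(haplotype_fitnesses(ls))) {
      expect_equal(genotype_fitness(ls, h, h) -
                     genotype_fitness(ls, "abc", "abc"),
                   haplotype_fitness(ls, h),
                   tolerance = 1e-12)
    }
  }
})

test_that("heterozygote epistasis expression follows the dominance scheme", {
  lsc <- dmi2(1, -0.2, -10, ploidy = 2, dominance = "codominant")
  lsr <- dmi2(1, -0.2, -10, ploidy = 2, dominance = "recessive")
  add <- (1 - 0.2) / 2
  # codominant: dosage product (1/2)(1/2) of the interaction
  expect_equal(genotype_fitness(lsc, "Ab", "aB"), add - 10 / 4)
  # recessive: a double heterozygote expresses nothing
  expect_equal(genotype_fitness(lsr, "Ab", "aB"), add)
  # recessive incompatibilities stay silent unless all partners homozygous
  expect_equal(genotype_fitness(lsr, "AB", "Ab"), 1 + (-0.2) / 2)
  expect_equal(genotype_fitness(lsr, "AB", "AB"), 1 - 0.2 - 10)
})

test_that("haplotype strings and indices round-trip", {
  ls <- cryptic()
  for (h in c("abc", "AbC", "ABC", "aBc")) {
    expect_equal(hap_string(ls, hap_index(ls, h)), h)
  }
  expect_equal(hap_index(ls, c(0, 1, 1)), hap_index(ls, "aBC"))
  expect_error(hap_index(ls, "xyz"), "does not match")
})
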