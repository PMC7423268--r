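test_that("per-step local adaptation reproduces the two-locus components", {
  ls <- dmi2(1, -0.2, -10)
  scn <- history_scenario(ls, c("island", "continent"))
  hh <- enumerate_histories(scn)
  expect_length(hh, 2L)  # A first or B first
  orders <- vapply(hh, function(h) paste(h$order, collapse = ""),
                   character(1))
  expect_setequal(orders, c("AB", "BA"))
  a_first <- hh[[which(orders == "AB")]]
  expect_equal(lambda_current(a_first$steps[[1]], ls), 1)        # alpha
  expect_equal(lambda_current(a_first$steps[[2]], ls), 1.2)      # alpha - beta
  b_first <- hh[[which(orders == "BA")]]
  expect_equal(lambda_current(b_first$steps[[1]], ls), 0.2)      # -beta
  expect_equal(lambda_max(scn), 1.2)
})

test_that("the cryptic-epistasis scenario admits exactly three histories", {
  scn <- history_scenario(cryptic(), cryptic_origins)
  hh <- enumerate_histories(scn)
  expect_length(hh, 3L)
  orders <- vapply(hh, function(h) paste(h$order, collapse = ""),
                   character(1))
  # the background allele can only establish on the continent after B
  expect_setequal(orders, c("ABC", "BAC", "BCA"))
})

test_that("a background allele deleterious on every continental background is excluded", {
  # gamma = gamma_prime + eps_abC < 0 on the ancestral background, and the
  # history C-first offers no compensating partner
  scn <- history_scenario(cryptic(), cryptic_origins)
  orders <- vapply(enumerate_histories(scn), function(h)
    paste(h$order, collapse = ""), character(1))
  expect_false(any(substr(orders, 1, 1) == "C"))
  # the exhaustive switch disables the filter
  all6 <- enumerate_histories(scn, exhaustive = TRUE)
  expect_length(all6, 6L)
})

test_that("maximum local adaptation matches its closed form across backgrounds", {
  # Lambda_max^{Ab|C} = max(alpha, -beta, alpha-beta, alpha-beta-gamma',
  #                         -gamma')
  for (gp in c(0.1, 0.5, -0.4, -1.5)) {
    for (beta in c(-0.2, 1.2)) {
      ls <- cryptic(1, beta, gp, -10, -20)
      expect_equal(lambda_max(history_scenario(ls, cryptic_origins)),
                   max(1, -beta, 1 - beta, 1 - beta - gp, -gp),
                   info = sprintf("gp=%g beta=%g", gp, beta))
    }
  }
  # beneficial background allele: the bound of the two-locus DMI persists
  ls <- cryptic(1, -0.2, 0.1, -10, -20)
  expect_equal(lambda_max(history_scenario(ls, cryptic_origins)),
               max(1, 1.2))
})

test_that("local adaptation is additive without epistasis and bounded by its maximum", {
  set.seed(8)
  alphas <- stats::runif(3, 0.2, 1)
  ls <- fitness_landscape(alphas)
  scn <- history_scenario(ls, rep("island", 3))
  expect_equal(lambda_max(scn), sum(alphas), tolerance = 1e-12)
  # Lambda <= Lambda_max at every step of every admissible history
  for (rep in 1:5) {
    rl <- random_landscape(sample(1:4, 1), 3, seed = 900 + rep)
    rscn <- history_scenario(rl, attr(rl, "origins"))
    lm <- lambda_max(rscn)
    for (h in enumerate_histories(rscn))
      for (st in h$steps)
        expect_lte(lambda_current(st, rl), lm + 1e-12)
  }
})

test_that("larger barriers can only increase the local-adaptation bound", {
  # the two-locus DMI embedded in the three-locus scenario
  ls3 <- cryptic(1, -0.2, 0.1, -10, -20)
  ls2 <- dmi2(1, -0.2, -10)
  lm3 <- lambda_max(history_scenario(ls3, cryptic_origins))
  lm2 <- lambda_max(history_scenario(ls2, c("island", "continent")))
  expect_gte(lm3, lm2 - 1e-12)
})

test_that("single-locus barrier strength equals the local-adaptation maximum", {
  ls <- fitness_landscape(0.8)
  lm <- lambda_max(history_scenario(ls, "island"))
  expect_equal(lm, 0.8)
  expect_equal(mmax_of(ls, "A", tol_m = 1e-4), lm, tolerance = 2e-3)
})

test_that("background-allele fixation on the island is verified dynamically", {
  ls <- cryptic()
  scn <- history_scenario(ls, cryptic_origins)
  pp <- model_params(ls, 0.05, "aBC", mode = "loose")
  r1 <- check_background_fixation(scn, pp, after = c("A", "B"))
  expect_true(r1$fixed)
  # no compensating allele present and deleterious next to none
  lsn <- cryptic(1, -0.2, -0.3, -10, -20)
  scn2 <- history_scenario(lsn, cryptic_origins)
  pp2 <- model_params(lsn, 0.05, "aBC", mode = "loose")
  r2 <- check_background_fixation(scn2, pp2, after = character(0))
  expect_false(r2$fixed)
  # without migration, fixation follows from the invasion fitness alone
  pp0 <- model_params(ls, 0, "aBC", mode = "loose")
  expect_true(check_background_fixation(scn, pp0,
                                        after = c("A", "B"))$fixed)
})
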