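test_that("P(h^v) is exactly one when only the suspect is typed", {
  for (id in c("A01", "B01")) {
    sc <- build_scenario(id, mu = 0.1)
    res <- estimate_pv(sc$case, sc$model, n_sims = 10, seed = 1)
    expect_identical(res$estimate, 1)
    expect_true(res$exact)
    expect_equal(res$std_error, 0)
  }
})

test_that("P(h^v) with no untyped members is the exact edge product", {
  ped <- pedigree(c(son = "S", grandson = "son"))
  model <- mutation_model(c(M1 = 0.1))
  case <- case_configuration(ped, "S", list(S = c(M1 = 14L), son = c(M1 = 14L),
                                            grandson = c(M1 = 15L)))
  res <- estimate_pv(case, model, n_sims = 10, seed = 1)
  expect_true(res$exact)
  expect_equal(res$estimate, 0.9 * 0.05)
})

test_that("importance-sampling estimates fall within 5 SE of the oracle", {
  cases <- list(c("C01", 1), c("D02", 1), c("E03", 1), c("H04", 2), c("I01", 2))
  for (cs in cases) {
    id <- cs[[1]]; x <- as.integer(cs[[2]])
    sc <- build_scenario(id, mu = 0.1)
    exact <- exact_distribution_dp(sc$case, sc$model)
    pv <- estimate_pv(sc$case, sc$model, n_sims = 5e4, seed = 11)
    if (!pv$exact)
      expect_lte(abs(pv$estimate - exact$pv), 5 * pv$std_error + 1e-12)
    px <- estimate_px(sc$case, sc$model, x, exact$pv, n_sims = 5e4, seed = 12)
    expect_lte(abs(px$estimate - exact$dist$probs[[as.character(x)]]),
               5 * px$std_error + 1e-12)
    expect_lte(px$n_nonzero, px$n_sims)
  }
})

test_that("structurally impossible match counts estimate to exactly zero", {
  for (id in c("I04", "I08", "I11", "I12")) {
    sc <- build_scenario(id, mu = 0.1)
    pv <- scenario_exact(id, 0.1)$pv
    for (seed in c(2, 97)) {
      res <- estimate_px(sc$case, sc$model, 1, pv, n_sims = 2e4, seed = seed)
      expect_identical(res$estimate, 0)
      expect_identical(res$n_nonzero, 0L)
    }
  }
})

test_that("the full distribution estimate complements p_0 and is seed-reproducible", {
  sc <- build_scenario("A01", mu = 0.1)
  res <- estimate_distribution(sc$case, sc$model, n_sims = 5e4, seed = 5)
  expect_equal(sum(res$dist$probs), 1)
  expect_equal(res$dist$probs[["1"]], 0.9, tolerance = 0.02)
  expect_equal(res$dist$probs[["0"]], 0.1, tolerance = 0.2)

  res2 <- estimate_distribution(sc$case, sc$model, n_sims = 5e4, seed = 5)
  expect_identical(res$dist$probs, res2$dist$probs)

  # a scenario with simulated (not only pinned) members varies with the seed
  b <- build_scenario("B01", mu = 0.1)
  rb1 <- estimate_distribution(b$case, b$model, n_sims = 2e4, seed = 5)
  rb2 <- estimate_distribution(b$case, b$model, n_sims = 2e4, seed = 6)
  expect_false(identical(rb1$dist$probs, rb2$dist$probs))
})

test_that("a fully typed case yields the trivial distribution", {
  ped <- pedigree(c(son = "S"))
  model <- mutation_model(c(M1 = 0.1))
  case <- case_configuration(ped, "S", list(S = c(M1 = 14L), son = c(M1 = 14L)))
  res <- estimate_distribution(case, model, n_sims = 10, seed = 1)
  expect_equal(res$dist$probs, c(`0` = 1))
  expect_true(res$dist$exact)
})

test_that("an impossible typed configuration is rejected as undefined", {
  ped <- pedigree(c(son = "S", grandson = "son"))
  model <- mutation_model(c(M1 = 0.1))
  # typed son two repeats away: every P(h^v) weight is zero
  case <- case_configuration(ped, "S", list(S = c(M1 = 14L), son = c(M1 = 16L)))
  expect_error(estimate_px(case, model, 1, pv = 0, n_sims = 10, seed = 1),
               class = "ystr_undefined_conditional")
  expect_error(suppressWarnings(
    estimate_distribution(case, model, n_sims = 100, seed = 1)),
    class = "ystr_undefined_conditional")
  expect_error(estimate_px(case, model, 9, pv = 1, n_sims = 10, seed = 1),
               class = "ystr_validation_error")
})

test_that("estimators leave the caller's RNG state untouched", {
  sc <- build_scenario("B01", mu = 0.1)
  set.seed(99)
  before <- .Random.seed
  invisible(estimate_distribution(sc$case, sc$model, n_sims = 1000, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("sign-flipped allele assignments leave exact values unchanged", {
  for (id in c("C02", "E03", "H04", "I05")) {
    sc <- build_scenario(id, mu = 0.1)
    fl <- build_scenario_flipped(id, 0.1)
    a <- exact_distribution_dp(sc$case, sc$model)
    b <- exact_distribution_dp(fl$case, fl$model)
    expect_equal(a$pv, b$pv, tolerance = 1e-12)
    expect_equal(a$dist$probs, b$dist$probs, tolerance = 1e-12)
  }
})

test_that("the accuracy experiment reports percentage differences per quantity", {
  sc <- build_scenario("D02", mu = 0.1)
  tab <- suppressWarnings(run_accuracy_experiment(
    sc$case, sc$model, scenario_exact("D02", 0.1),
    repeats = 3, n_sims = 2e4, seed = 42))
  expect_equal(tab$quantity, c("P(h^v)", "p_1"))
  expect_true(all(is.finite(tab$mean_pct)))
  expect_true(all(abs(tab$mean_pct) < 10))

  # exact-zero quantities are reported as all-zero checks, not percentages
  sc0 <- build_scenario("I04", mu = 0.1)
  tab0 <- suppressWarnings(run_accuracy_experiment(
    sc0$case, sc0$model, scenario_exact("I04", 0.1),
    repeats = 2, n_sims = 5e3, seed = 42))
  zero_rows <- tab0[tab0$exact == 0, ]
  expect_true(nrow(zero_rows) >= 1)
  expect_true(all(zero_rows$all_zero))
  expect_true(all(is.na(zero_rows$mean_pct)))
})
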