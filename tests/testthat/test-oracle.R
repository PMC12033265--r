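test_that("enumeration and dynamic program agree on all catalogued scenarios", {
  for (id in ystr_scenarios()) {
    for (mu in c(0.1, 0.02, 0.005)) {
      sc <- build_scenario(id, mu = mu)
      e <- exact_distribution_enum(sc$case, sc$model)
      d <- exact_distribution_dp(sc$case, sc$model)
      expect_equal(d$pv, e$pv, tolerance = 1e-12)
      expect_equal(d$dist$probs, e$dist$probs, tolerance = 1e-12)
      expect_equal(sum(e$dist$probs), 1, tolerance = 1e-12)
      expect_true(e$pv > 0 && e$pv <= 1)
    }
  }
})

test_that("both oracles agree with an independent brute force on random trees", {
  for (seed in 21:24) {
    rc <- random_case(sample(4:6, 1L), seed)
    prep <- ystrmatch:::prepare_case(rc$case)
    bf <- brute_force_exact(prep$pedigree, rc$case$suspect,
                            prep$typed_shifted, mu = 0.1,
                            range = max(prep$depth))
    e <- exact_distribution_enum(rc$case, rc$model)
    d <- exact_distribution_dp(rc$case, rc$model)
    expect_equal(e$pv, bf$pv, tolerance = 1e-12)
    expect_equal(d$pv, bf$pv, tolerance = 1e-12)
    U <- length(prep$order)
    expect_equal(unname(e$dist$probs), unname(bf$probs[as.character(0:U)]),
                 tolerance = 1e-12)
  }
})

test_that("exact results are invariant to the pedigree representation", {
  # MRCA-rooted tree with the suspect two generations down; the brute force
  # multiplies transition factors over the ORIGINAL edge directions, the
  # package oracle re-roots at the suspect first
  ped <- pedigree(c(a = "mrca", suspect = "a", b = "mrca", c = "a"))
  typed <- list(suspect = c(M1 = 10L), b = c(M1 = 11L))
  model <- mutation_model(c(M1 = 0.1))
  case <- case_configuration(ped, "suspect", typed)

  shifted <- lapply(typed, function(h) h - typed$suspect)
  bf <- brute_force_exact(ped, "suspect", shifted, mu = 0.1, range = 4)
  d <- exact_distribution_dp(case, model)
  expect_equal(d$pv, bf$pv, tolerance = 1e-12)
  expect_equal(unname(d$dist$probs), unname(bf$probs[as.character(0:3)]),
               tolerance = 1e-12)
})

test_that("oracle handles degenerate and oversized cases", {
  # fully typed pedigree: distribution concentrates on zero matches
  ped <- pedigree(c(son = "S"))
  model <- mutation_model(c(M1 = 0.1))
  full <- case_configuration(ped, "S", list(S = c(M1 = 14L), son = c(M1 = 15L)))
  res <- exact_distribution_enum(full, model)
  expect_equal(res$pv, 0.05)
  expect_equal(res$dist$probs, c(`0` = 1))

  # typed father-son pair two repeats apart: P(h^v) = 0
  impossible <- case_configuration(ped, "S",
                                   list(S = c(M1 = 14L), son = c(M1 = 16L)))
  expect_error(exact_distribution_enum(impossible, model),
               class = "ystr_undefined_conditional")

  # state-space cap
  big <- build_scenario("F01", 0.1)
  expect_error(exact_distribution_enum(big$case, big$model, cap = 10),
               class = "ystr_cap_exceeded")
  expect_error(exact_distribution_dp(big$case, big$model, cap = 2),
               class = "ystr_cap_exceeded")
})

test_that("p_1 for a single untyped son equals 1 - mu and decreases in mu", {
  p1 <- vapply(c(0.1, 0.02, 0.005), function(mu) {
    sc <- build_scenario("A01", mu = mu)
    exact_distribution_dp(sc$case, sc$model)$dist$probs[["1"]]
  }, numeric(1))
  expect_equal(p1, 1 - c(0.1, 0.02, 0.005))
  expect_true(all(diff(p1) > 0))  # smaller mu, larger match probability
})

test_that("the oracle handles multi-marker panels", {
  ped <- pedigree(c(t = "S", u = "t"))
  model <- mutation_model(c(A = 0.1, B = 0.02))
  case <- case_configuration(
    ped, "S", list(S = c(A = 14L, B = 30L), t = c(A = 15L, B = 30L)))
  e <- exact_distribution_enum(case, model)
  d <- exact_distribution_dp(case, model)
  expect_equal(e$pv, 0.05 * 0.98)
  expect_equal(d$dist$probs, e$dist$probs, tolerance = 1e-12)
  # p_1: the untyped grandson must step back at A and stay at B
  expect_equal(e$dist$probs[["1"]], 0.05 * 0.98)
})
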