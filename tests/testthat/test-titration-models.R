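test_that("one-pKa curve hits its midpoint, limits, and hand-computed values", {
  p <- one_pka_params(28.0, 30.5, 10.6)
  # midpoint symmetry at pH = pKa
  expect_equal(shift_one_pka(10.6, p), (28.0 + 30.5) / 2)
  # fully protonated limit six units below the midpoint
  expect_equal(shift_one_pka(4.6, p), 28.0, tolerance = 1e-5)
  # hand evaluation: f = 10^-0.6 / (1 + 10^-0.6) = 0.20076
  expect_equal(shift_one_pka(10.0, p), 28.502, tolerance = 1e-3)
  # far limits stay finite and pinned to the plateaus
  expect_equal(shift_one_pka(c(-300, 300) + 10.6, p), c(28.0, 30.5))
})

test_that("one-pKa curve is monotone and bounded by the limiting shifts", {
  set.seed(11)
  for (k in 1:25) {
    lo <- runif(1, 10, 60)
    amp <- runif(1, -3, 3)
    p <- one_pka_params(lo, lo + amp, runif(1, 3, 12))
    grid <- seq(0, 14, by = 0.1)
    d <- shift_one_pka(grid, p)
    expect_true(all(d >= min(lo, lo + amp) - 1e-12))
    expect_true(all(d <= max(lo, lo + amp) + 1e-12))
    if (abs(amp) > 0) {
      expect_true(all(sign(diff(d)) == sign(amp) | diff(d) == 0))
    }
  }
})

test_that("two-pKa curve matches its closed form and nested limits", {
  q <- two_pka_params(0, 0.5, 1.0, 7.3, 10.7)
  # doubly protonated limit
  expect_equal(shift_two_pka(2.0, q), 0.0, tolerance = 1e-5)
  # direct evaluation at the first midpoint: Z = 1 + 1 + 10^-3.4
  expect_equal(shift_two_pka(7.3, q), 0.2502, tolerance = 5e-4)
  # pushing the first transition far below the window collapses the model
  # onto the one-pKa curve governed by the second midpoint
  a <- 27.5; b <- 30.1
  q2 <- two_pka_params(a, a, b, 10.7 - 20, 10.7)
  grid <- seq(0, 14, by = 0.25)
  expect_equal(shift_two_pka(grid, q2),
               shift_one_pka(grid, one_pka_params(a, b, 10.7)),
               tolerance = 1e-6)
  expect_error(two_pka_params(0, 1, 2, 10, 7), "pka1")
})

test_that("two-pKa curve is monotone when the plateau sits between the limits", {
  set.seed(12)
  grid <- seq(0, 14, by = 0.1)
  for (k in 1:25) {
    base <- runif(1, 10, 60)
    amp <- runif(1, 0.3, 3)
    mid <- base + runif(1, 0.1, 0.9) * amp
    p1 <- runif(1, 3, 8)
    q <- two_pka_params(base, mid, base + amp, p1, p1 + runif(1, 0.5, 5))
    expect_true(all(diff(shift_two_pka(grid, q)) >= -1e-12))
  }
})

test_that("coupled model enforces cycle closure and can derive the fourth pKa", {
  m <- coupled_site_model(5.8, 10.6, pk_b_given_a = 11.2)
  expect_equal(m$pk_a_given_b, 5.8 + 11.2 - 10.6)
  expect_error(
    coupled_site_model(5.8, 10.6, pk_a_given_b = 6.0, pk_b_given_a = 11.2),
    "cycle closure"
  )
  expect_silent(
    coupled_site_model(5.8, 10.6, pk_a_given_b = 6.4, pk_b_given_a = 11.2)
  )
})

test_that("microstate fractions reproduce the partition-function values", {
  m <- symmetric_coupled_model(7.6, 10.4)
  # low-pH limit: everything doubly protonated
  expect_gt(microstate_fractions(2.0, m)$f_hh, 0.99999)
  # Z = 1 + 2 * 10^1.4 + 1 at pH 9
  f <- microstate_fractions(9.0, m)
  expect_equal(unlist(f[c("f_hh", "f_ah", "f_hb", "f_ab")]),
               c(f_hh = 0.0191, f_ah = 0.4809, f_hb = 0.4809, f_ab = 0.0191),
               tolerance = 1e-3)
})

test_that("microstate fractions are normalized and nonnegative everywhere", {
  set.seed(13)
  for (k in 1:100) {
    m <- random_coupled_model()
    ph <- runif(100, -2, 16)
    f <- microstate_fractions(ph, m)
    sums <- f$f_hh + f$f_ah + f$f_hb + f$f_ab
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(f$f_hh >= 0 & f$f_ah >= 0 & f$f_hb >= 0 & f$f_ab >= 0))
  }
})

test_that("site deprotonation curves behave like coupled titrations", {
  m <- symmetric_coupled_model(7.6, 10.4)
  # two almost equal steps: the first-step amplitude is K_B / (K_A + K_B)
  expect_equal(10^(-m$pk_b_first) /
                 (10^(-m$pk_a_first) + 10^(-m$pk_b_first)), 0.5)
  expect_equal(site_deprotonation_fraction(9.0, m, "B"), 0.500,
               tolerance = 1e-3)
  # monotone nondecreasing in pH
  grid <- seq(0, 14, by = 0.05)
  expect_true(all(diff(site_deprotonation_fraction(grid, m, "B")) >= -1e-13))
  # uncoupled, well-separated sites recover a plain Henderson-Hasselbalch
  ind <- coupled_site_model(5, 9, pk_a_given_b = 5, pk_b_given_a = 9)
  expect_equal(site_deprotonation_fraction(5, ind, "A"), 0.5,
               tolerance = 1e-3)
  expect_error(site_deprotonation_fraction(7, m, "C"))
})

test_that("macroscopic constants follow the statistical-factor closed form", {
  m <- symmetric_coupled_model(7.6, 10.4)
  mac <- macroscopic_from_microscopic(m)
  expect_equal(unname(mac), c(7.6 - log10(2), 10.4 + log10(2)),
               tolerance = 1e-9)
  expect_equal(unname(mac), c(7.299, 10.701), tolerance = 1e-3)
  ind <- coupled_site_model(5, 9, pk_a_given_b = 5, pk_b_given_a = 9)
  expect_equal(unname(macroscopic_from_microscopic(ind)), c(5, 9),
               tolerance = 1e-3)
})

test_that("site curves equal the two-pKa closed form with macroscopic constants", {
  set.seed(14)
  grid <- seq(0, 14, by = 0.05)
  for (k in 1:20) {
    m <- random_coupled_model()
    mac <- macroscopic_from_microscopic(m)
    kb_share <- 10^(-m$pk_b_first) /
      (10^(-m$pk_a_first) + 10^(-m$pk_b_first))
    oracle <- shift_two_pka(
      grid, two_pka_params(0, kb_share, 1, mac[["pka1"]], mac[["pka2"]])
    )
    expect_lt(max(abs(oracle - site_deprotonation_fraction(grid, m, "B"))),
              1e-10)
  }
})

test_that("macroscopic-microscopic conversion round-trips under symmetry", {
  set.seed(15)
  for (k in 1:20) {
    p1 <- runif(1, 4, 9)
    p2 <- p1 + runif(1, 0.8, 4)
    m <- symmetric_coupled_model(p1, p2)
    mac <- macroscopic_from_microscopic(m)
    back <- microscopic_from_macroscopic(mac[["pka1"]], mac[["pka2"]])
    expect_equal(back$pk_a_first, p1, tolerance = 1e-12)
    expect_equal(back$pk_b_given_a, p2, tolerance = 1e-12)
  }
})
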