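test_that("cap_delta33 vanishes on the mass-dependent reference line", {
  for (d34 in c(-200, -47.9, 0, 21.3, 300)) {
    d33 <- ((1 + d34 / 1000)^0.515 - 1) * 1000
    expect_equal(cap_delta33(d33, d34), 0, tolerance = 1e-12)
  }
  expect_equal(cap_delta33(0, 0), 0)
  # seawater sulfate: d33S 10.963, d34S 21.3 gives ~+0.050
  expect_lt(abs(cap_delta33(10.963, 21.3) - 0.050), 5e-4)
})

test_that("epsilon34 reproduces the worked sulfide/sulfate pairs", {
  expect_equal(epsilon34(21.3, 21.3), 0)
  expect_equal(round(epsilon34(-47.95, 21.3), 1), 67.8)
  expect_equal(round(epsilon34(-35.2, 21.3), 1), 55.3)
  expect_error(epsilon34(-1000, 21.3), "-1000")
})

test_that("lambda33 recovers a constructed mass-law exponent", {
  d34_sf <- 21.3
  d33_sf <- 10.963
  for (theta in c(0.514, 0.515, 0.510)) {
    r34 <- 0.94  # arbitrary fractionation of the 34S ratio
    d34 <- (1000 + d34_sf) * r34 - 1000
    d33 <- (1000 + d33_sf) * r34^theta - 1000
    expect_equal(lambda33(d33, d34, d33_sf, d34_sf), theta, tolerance = 1e-12)
  }
  expect_error(lambda33(1, 21.3, 2, 21.3), "degenerate")
})

test_that("msr_forward round-trips through epsilon34 and lambda33", {
  set.seed(31)
  for (i in 1:15) {
    eps <- runif(1, 5, 70); lam <- runif(1, 0.505, 0.520)
    s <- msr_forward(10.963, 21.3, eps, lam)
    expect_equal(epsilon34(s[["delta34S"]], 21.3), eps, tolerance = 1e-9)
    expect_equal(lambda33(s[["delta33S"]], s[["delta34S"]], 10.963, 21.3),
                 lam, tolerance = 1e-9)
  }
  # identity fractionation changes nothing
  s0 <- msr_forward(10.963, 21.3, 0, 0.515)
  expect_equal(unname(s0[c("delta33S", "delta34S")]), c(10.963, 21.3))
  # the largest observed fractionation puts sulfide near -47.9 permil
  s1 <- msr_forward(10.963, 21.3, 67.8, 0.514)
  expect_equal(s1[["delta34S"]], -47.95, tolerance = 0.01)
})

test_that("reference-exponent consistency: lambda 0.515 preserves a zero cap_delta33", {
  d34_sf <- 21.3
  d33_sf <- ((1 + d34_sf / 1000)^0.515 - 1) * 1000  # on the reference line
  s <- msr_forward(d33_sf, d34_sf, 55, 0.515)
  expect_equal(s[["cap_delta33"]], 0, tolerance = 1e-9)
})

test_that("mixing curve reproduces endpoints and the abundance oracle", {
  # brute-force oracle: independent molar-abundance mixing of 32S/33S/34S
  oracle <- function(e1, e2, f, r33 = 0.0078777, r34 = 0.0441626) {
    rat <- function(e) c(r33 * (1 + e[1] / 1000), r34 * (1 + e[2] / 1000))
    x <- function(R) c(1, R) / (1 + sum(R))
    m <- (1 - f) * x(rat(e1)) + f * x(rat(e2))
    d33 <- (m[2] / m[1] / r33 - 1) * 1000
    d34 <- (m[3] / m[1] / r34 - 1) * 1000
    c(d33 = d33, d34 = d34)
  }
  juv <- c(0, 0)
  top <- c(0.16 + ((1 - 30 / 1000)^0.515 - 1) * 1000, -30)  # cap_delta33 +0.16
  curve <- sulfur_mixing_curve(juv, top, c(0, 0.5, 1))
  expect_equal(curve$delta34S[1], 0, tolerance = 1e-9)
  expect_equal(curve$delta33S[1], 0, tolerance = 1e-9)
  expect_equal(curve$delta34S[3], -30, tolerance = 1e-9)
  expect_equal(curve$cap_delta33[3], 0.16, tolerance = 1e-9)
  o <- oracle(juv, top, 0.5)
  expect_equal(curve$delta33S[2], o[["d33"]], tolerance = 1e-10)
  expect_equal(curve$delta34S[2], o[["d34"]], tolerance = 1e-10)
})

test_that("abundance mixing is order-independent and scale-insensitive", {
  a <- c(5, 10); b <- c(-20, -40); c3 <- c(0.05, 21.3)
  # three-component closed form via sequential mixing
  m_ab <- sulfur_mixing_curve(a, b, 0.5)
  seq_mix <- sulfur_mixing_curve(c(m_ab$delta33S, m_ab$delta34S), c3, 1 / 3,
                                 weight2 = 1)
  # direct: equal thirds, built by mixing a-b at 0.5 then adding c at 1/3
  # versus mixing b-c at 0.5 then adding a at 1/3
  m_bc <- sulfur_mixing_curve(b, c3, 0.5)
  seq_mix2 <- sulfur_mixing_curve(c(m_bc$delta33S, m_bc$delta34S), a, 1 / 3)
  expect_equal(seq_mix$delta34S, seq_mix2$delta34S, tolerance = 1e-9)
  expect_equal(seq_mix$delta33S, seq_mix2$delta33S, tolerance = 1e-9)

  # a mixture of two mass-dependent endmembers acquires a small NEGATIVE
  # cap_delta33 (the reference line is concave); at a 21.3 permil
  # separation the excursion is of order 0.01 permil
  end_line <- c(((1 + 21.3 / 1000)^0.515 - 1) * 1000, 21.3)
  mid <- sulfur_mixing_curve(c(0, 0), end_line, 0.5)
  expect_lt(mid$cap_delta33, 0)
  expect_gt(mid$cap_delta33, -0.02)
})

test_that("mixing curvature vanishes as the endmembers approach in delta34S", {
  base <- c(0.1, 0)
  dev <- vapply(c(60, 20, 5), function(gap) {
    e2 <- c(0.1 + ((1 + gap / 1000)^0.515 - 1) * 1000, gap)
    mid <- sulfur_mixing_curve(base, e2, 0.5)
    straight <- (base[1] + e2[1]) / 2
    abs(mid$delta33S - straight)
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
})
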