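test_that("Compton-to-total ratio behaves as a quotient of mixture sums", {
  xs <- make_powerlaw_xs()
  co <- attr(xs, "coef")
  # compton == total forces ratio 1 regardless of composition
  xs1 <- xs
  xs1$compton_mu_rho_cm2_g <- xs1$total_mu_rho_cm2_g
  expect_equal(compton_total_ratio(xs1, "C30H44N6O2", 0.3), 1, tolerance = 1e-12)
  # compton = 0.5 * total forces 0.5
  xs5 <- xs
  xs5$compton_mu_rho_cm2_g <- 0.5 * xs5$total_mu_rho_cm2_g
  expect_equal(compton_total_ratio(xs5, "CH4", 1.7), 0.5, tolerance = 1e-12)
  # hand oracle: quotient of two four-term dot products
  w <- weight_fractions(parse_formula("C30H44N6O2"))
  e <- 0.662
  num <- sum(vapply(names(w), function(el) {
    i <- match(el, co$element)
    w[[el]] * co$fraction[i] * co$alpha[i] * e^(-co$beta[i])
  }, numeric(1)))
  den <- sum(vapply(names(w), function(el) {
    i <- match(el, co$element)
    w[[el]] * co$alpha[i] * e^(-co$beta[i])
  }, numeric(1)))
  expect_equal(compton_total_ratio(xs, "C30H44N6O2", e), num / den,
               tolerance = 1e-12)
})

test_that("Zeq interpolation honors endpoints, midpoints and the closed form", {
  ratios <- make_ratios(Zs = 4:10)
  # endpoint identity
  r4 <- ratios$R[ratios$Z == 4]
  expect_equal(equivalent_atomic_number(r4, ratios)$zeq, 4)
  # geometric-mean R between Z=6 and Z=7 lands at zeq = 6.5
  r6 <- ratios$R[ratios$Z == 6]; r7 <- ratios$R[ratios$Z == 7]
  expect_equal(equivalent_atomic_number(sqrt(r6 * r7), ratios)$zeq, 6.5,
               tolerance = 1e-12)
  # independent scalar evaluation of the interpolation formula
  ratios2 <- tibble::tibble(Z = c(6L, 7L), R = c(0.98, 0.95))
  got <- equivalent_atomic_number(0.96, ratios2)
  expected <- (6 * (log(0.95) - log(0.96)) + 7 * (log(0.96) - log(0.98))) /
    (log(0.95) - log(0.98))
  expect_equal(got$zeq, expected, tolerance = 1e-12)
  expect_equal(c(got$Z1, got$Z2), c(6, 7))
  expect_true(got$zeq >= got$Z1 && got$zeq <= got$Z2)
})

test_that("Zeq rejects out-of-span ratios and non-monotone tables", {
  ratios <- make_ratios()
  expect_error(equivalent_atomic_number(0.999, ratios), "span")
  expect_error(equivalent_atomic_number(0.5, ratios), "span")
  bad <- ratios
  bad$R[3] <- bad$R[1] + 0.01
  expect_error(equivalent_atomic_number(0.9, bad), "monotone")
})

test_that("Zeq is recovered from ratios constructed at a known zeq", {
  set.seed(7)
  for (i in 1:20) {
    ratios <- make_ratios(Zs = 4:12, R0 = runif(1, 0.9, 0.99),
                          step = runif(1, 0.93, 0.98))
    zeq_true <- runif(1, 4.01, 11.99)
    i1 <- findInterval(zeq_true, ratios$Z)
    Z1 <- ratios$Z[i1]; Z2 <- ratios$Z[i1 + 1]
    lR1 <- log(ratios$R[i1]); lR2 <- log(ratios$R[i1 + 1])
    lR <- (zeq_true * (lR2 - lR1) - Z1 * lR2 + Z2 * lR1) / (Z2 - Z1)
    expect_equal(equivalent_atomic_number(exp(lR), ratios)$zeq, zeq_true,
                 tolerance = 1e-9)
  }
})

test_that("G-P parameter interpolation is exact on tabulated and synthetic surfaces", {
  gp <- make_linear_gp()
  surf <- attr(gp, "surface")
  # integer zeq at a grid energy: tabulated quintuple exactly
  row <- gp[gp$Z == 6 & gp$energy_MeV == 1, ]
  got <- interpolate_gp_parameters(gp, 6, 1, "EBF")
  expect_equal(unlist(got), unlist(row[, c("b", "c", "a", "Xk", "d")]),
               tolerance = 1e-12)
  # log-midpoint of Z1, Z2 gives the arithmetic mean of the parameter sets
  zmid <- exp((log(6) + log(8)) / 2)
  got_mid <- interpolate_gp_parameters(gp, zmid, 1, "EBF")
  mean_par <- (gp[gp$Z == 6 & gp$energy_MeV == 1, c("b", "c", "a", "Xk", "d")] +
               gp[gp$Z == 8 & gp$energy_MeV == 1, c("b", "c", "a", "Xk", "d")]) / 2
  expect_equal(unlist(got_mid), unlist(mean_par), tolerance = 1e-12)
  # arbitrary zeq on the linear-in-logZ surface: closed form
  for (zeq in c(4.7, 6.4, 9.9, 12.2)) {
    for (j in 1:3) {
      e <- c(0.1, 1, 10)[j]
      got <- interpolate_gp_parameters(gp, zeq, e, "EBF")
      expect_equal(got$b, surf$b$p0[j] + surf$b$p1[j] * log(zeq), tolerance = 1e-12)
      expect_equal(got$Xk, surf$Xk$p0[j] + surf$Xk$p1[j] * log(zeq), tolerance = 1e-12)
      expect_equal(got$d, surf$d$p0[j] + surf$d$p1[j] * log(zeq), tolerance = 1e-12)
    }
  }
  expect_error(interpolate_gp_parameters(gp, 3, 1, "EBF"), "range")
  expect_error(interpolate_gp_parameters(gp, 6, 100, "EBF"), "grid")
  expect_error(interpolate_gp_parameters(gp, 6, 1, "EABF"), "kind")
})

test_that("the K factor matches direct scalar evaluation", {
  # constant: c=1, a=0, d=0 -> K = 1 for all x
  expect_equal(gp_K(list(b = 1.2, c = 1, a = 0, Xk = 10, d = 0), c(1, 10, 40)),
               rep(1, 3))
  # d = 0 -> pure power law
  p <- list(b = 1.2, c = 0.7, a = 0.15, Xk = 10, d = 0)
  x <- c(0.5, 5, 33)
  expect_equal(gp_K(p, x), 0.7 * x^0.15, tolerance = 1e-12)
  # full form, independently evaluated term by term
  p2 <- list(b = NA, c = 0.8, a = 0.1, Xk = 14, d = 0.05)
  k <- 0.8 * 10^0.1 +
    0.05 * (tanh(10 / 14 - 2) - tanh(-2)) / (1 - tanh(-2))
  expect_equal(gp_K(p2, 10), k, tolerance = 1e-12)
  expect_equal(round(gp_K(p2, 10), 4), 1.0098)
  expect_error(gp_K(p2, 0), "40 mfp")
  expect_error(gp_K(p2, 41), "40 mfp")
})

test_that("the buildup factor follows both branches and their limit", {
  # b = 1 collapses both branches to 1
  expect_equal(buildup_factor(list(b = 1, c = 0.7, a = 0.1, Xk = 10, d = 0.02),
                              c(0, 1, 17, 40)), rep(1, 4))
  # K = 1 linear branch
  expect_equal(buildup_factor(list(b = 2, c = 1, a = 0, Xk = 10, d = 0), 5), 6)
  # geometric branch, independently evaluated
  p <- list(b = 1.5, c = 0.8, a = 0.1, Xk = 14, d = 0.05)
  K <- gp_K(p, 10)
  expect_equal(buildup_factor(p, 10), 1 + 0.5 * (K^10 - 1) / (K - 1),
               tolerance = 1e-12)
  expect_equal(round(buildup_factor(p, 10), 2), 6.23)
  # boundary condition
  expect_equal(buildup_factor(p, 0), 1)
  expect_error(buildup_factor(p, -1), "40 mfp")
})

test_that("B >= 1 over randomized valid parameters; monotone in depth at fixed K", {
  set.seed(11)
  for (i in 1:200) {
    p <- list(b = runif(1, 1, 3), c = runif(1, 0.2, 2), a = runif(1, -0.3, 0.3),
              Xk = runif(1, 5, 40), d = runif(1, -0.2, 0.2))
    x <- sort(runif(6, 1e-3, 40))
    expect_true(all(buildup_factor(p, x) >= 1 - 1e-12))
    # with a = d = 0 the K factor is constant in depth and B must be
    # non-decreasing (for x-dependent K the G-P form need not be monotone)
    pk <- list(b = p$b, c = p$c, a = 0, Xk = p$Xk, d = 0)
    if (p$b > 1) expect_true(all(diff(buildup_factor(pk, x)) >= -1e-9))
  }
})

test_that("the K -> 1 branch boundary is continuous", {
  set.seed(13)
  for (i in 1:50) {
    b <- runif(1, 1, 3); x <- runif(1, 0.5, 40)
    mk <- function(K) list(b = b, c = K, a = 0, Xk = 10, d = 0)  # K == c here
    B1 <- buildup_factor(mk(1), x)
    expect_lt(abs(buildup_factor(mk(1 + 1e-9), x) - B1), 1e-6)
    expect_lt(abs(buildup_factor(mk(1 - 1e-9), x) - B1), 1e-6)
    # just outside the switching band the generic branch agrees to the
    # Taylor bound (b-1) x^2 |K-1| / 2
    expect_lt(abs(buildup_factor(mk(1 + 2e-8), x) - B1),
              (b - 1) * x^2 * 2e-8 + 1e-9)
  }
})

test_that("buildup_curve equals per-energy scalar evaluation", {
  xs <- make_powerlaw_xs(
    elements = data.frame(element = c("Be", "C", "O", "Al"),
                          Z = c(4L, 6L, 8L, 13L),
                          alpha = c(0.14, 0.15, 0.17, 0.19),
                          beta = c(0.33, 0.35, 0.37, 0.40),
                          fraction = c(0.92, 0.85, 0.75, 0.65)),
    energies = c(0.1, 0.5, 1, 5, 10)
  )
  gp <- make_linear_gp(Zs = c(4L, 6L, 8L, 13L), energies = c(0.1, 1, 10))
  cmp <- tibble::tibble(id = "m", formula = "C3O2")
  depths <- c(10, 20, 40)
  curve <- buildup_curve(cmp, xs, gp, energies = c(0.1, 1, 10),
                         depths = depths, kind = "EBF")
  expect_equal(nrow(curve), 9)
  expect_true(all(curve$B >= 1))
  for (e in c(0.1, 1, 10)) {
    R <- compton_total_ratio(xs, "C3O2", e)
    zres <- equivalent_atomic_number(R, elemental_ratios(xs, e))
    pars <- interpolate_gp_parameters(gp, zres$zeq, e, "EBF")
    sub <- curve[curve$energy_MeV == e, ]
    expect_equal(sub$zeq, rep(zres$zeq, 3), tolerance = 1e-12)
    expect_equal(sub$B, vapply(depths, function(x) buildup_factor(pars, x),
                               numeric(1)), tolerance = 1e-12)
  }
  # depth 0 gives an all-ones column
  c0 <- buildup_curve(cmp, xs, gp, energies = 1, depths = 0, kind = "EBF")
  expect_equal(c0$B, 1)
  expect_error(buildup_curve(cmp, xs, gp, energies = 1, depths = 50), "40")
})

test_that("a G-P table constant in Z and E reproduces scalar buildup values", {
  xs <- make_powerlaw_xs()
  p <- list(b = 1.4, c = 0.9, a = -0.05, Xk = 12, d = 0.02)
  gp <- tidyr::expand_grid(kind = "EBF", Z = c(1L, 6L, 7L, 8L),
                           energy_MeV = c(0.1, 1, 10))
  gp <- dplyr::mutate(gp, b = p$b, c = p$c, a = p$a, Xk = p$Xk, d = p$d)
  cmp <- tibble::tibble(id = "x", formula = "C30H44N6O2")
  curve <- buildup_curve(cmp, xs, gp, energies = c(0.1, 1, 10),
                         depths = c(10, 20, 40), kind = "EBF")
  expect_equal(curve$B, rep(buildup_factor(p, c(10, 20, 40)), 3),
               tolerance = 1e-12)
})
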