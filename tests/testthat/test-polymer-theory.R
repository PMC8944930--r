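test_that("tether plateaus match closed forms and Gaussian-chain oracles", {
  expect_equal(plateau_linear(0, 0.25), 0)
  expect_equal(plateau_linear(10, 1), 20)
  expect_equal(plateau_ring(0, 7, 0.25), 0)
  expect_equal(plateau_ring(0, 0, 0.25), 0)
  expect_equal(plateau_ring(9, 9, 0.25), 0.25^2 * 9)
  expect_equal(plateau_ring(12, 6, 0.25), plateau_ring(6, 12, 0.25))
  expect_lte(plateau_ring(12, 6, 0.25), plateau_linear(6, 0.25))

  set.seed(11)
  expect_lt(abs(oracle_plateau_linear(12, 0.25) /
                  plateau_linear(12, 0.25) - 1), 0.02)
  expect_lt(abs(oracle_plateau_ring(12, 6, 0.25) /
                  plateau_ring(12, 6, 0.25) - 1), 0.02)
  ## several parameter points against the oracles
  for (par in list(c(4, 0.25), c(40, 0.25), c(12, 0.1))) {
    expect_lt(abs(oracle_plateau_linear(par[1], par[2]) /
                    plateau_linear(par[1], par[2]) - 1), 0.03)
  }
  for (par in list(c(3, 9), c(20, 20), c(1, 40))) {
    expect_lt(abs(oracle_plateau_ring(par[1], par[2], 0.25) /
                    plateau_ring(par[1], par[2], 0.25) - 1), 0.03)
  }
})

test_that("ring plateau composes harmonically from linear plateaus", {
  b <- 0.25
  for (n1 in c(0.5, 3, 12, 80)) for (n2 in c(0.5, 7, 33)) {
    expect_equal(1 / plateau_ring(n1, n2, b),
                 1 / plateau_linear(n1, b) + 1 / plateau_linear(n2, b))
  }
})

test_that("theory crossover curves have the stated asymptotes", {
  pp <- polymer_params()
  ## exponential form: closed-form value and limits
  t <- c(0, 1e-12, 16, 1e9)
  v <- mscd_theory_curve(2, polymer_params(D0 = 1 / 6), t,
                         form = "exponential")$value
  expect_equal(v[1], 0)
  expect_equal(v[2] / (1 * 1e-12^0.24), 1, tolerance = 1e-3)  # early power law
  expect_equal(v[3], 2 * (1 - exp(-16^0.24 / 2)))
  expect_equal(v[4], 2, tolerance = 1e-6)                     # saturation
  ## mode-sum form: same asymptotes
  tt <- c(0.01, 0.1, 1, 10, 1e9)
  vm <- mscd_theory_curve(1.8, pp, tt)$value
  expect_lt(max(abs(vm[1:4] / (6 * pp$D0 * tt[1:4]^0.24) - 1)), 0.05)
  expect_equal(vm[5], 1.8, tolerance = 1e-6)
  ## both forms monotone nondecreasing; exponential concave in t^(alpha/2)
  grid <- seq(0, 3000, by = 30)
  for (form in c("modesum", "exponential")) {
    vv <- mscd_theory_curve(1.5, pp, grid, form = form)$value
    expect_true(all(diff(vv) >= -1e-12))
  }
  ve <- mscd_theory_curve(1.5, pp, grid[-1], form = "exponential")$value
  s <- grid[-1]^(pp$alpha / 2)
  slopes <- diff(ve) / diff(s)
  expect_true(all(diff(slopes) <= 1e-10))
  ## zero plateau pins the curve at zero
  expect_equal(mscd_theory_curve(0, pp, grid)$value, rep(0, length(grid)))
})

test_that("confined plateau is monotone in the radius and zero when pinned", {
  ch <- lookup_chromosome("URA3")
  seeds <- 1234
  plats <- vapply(c(1.1, 1.59, 2.4), function(a) {
    pp <- polymer_params(sphere_radius_a = a)
    with(list(), {
      set.seed(seeds)
      as.numeric(plateau_confined(ch, pp, "telomeres_only",
                                  n_anchor = 25, n_per = 40))
    })
  }, numeric(1))
  expect_true(all(diff(plats) > 0))
  ## locus at the centromere under Rabl co-anchoring: separation pinned
  ch0 <- chromosome_spec("x", 577000, 116000, 116000)
  expect_equal(as.numeric(plateau_confined(ch0, polymer_params(), "rabl")), 0)
  expect_error(confined_locus_stats(ch, polymer_params(), "bogus"))
})

test_that("per-cell curves obey the minimum-plateau rule", {
  ch <- lookup_chromosome("URA3")
  pp <- polymer_params()
  lt <- seq(0, 600, 30)
  set.seed(3)
  ## unlinked cell: identical to the confined theory curve
  cell <- sample_cell(ch, pp, 0, 0)
  cur <- cell_mscd_curve(cell, ch, pp, lt, confined_plateau = 1.8)
  expect_equal(cur$value, mscd_theory_curve(1.8, pp, lt)$value)
  ## tight ring dominates confinement
  ring <- structure(list(topology = "ring", segments = c(n1 = 1, n2 = 1),
                         rabl = FALSE, pinned = FALSE),
                    class = "cell_realization")
  cr <- cell_mscd_curve(ring, ch, pp, lt, confined_plateau = 1.8)
  expect_equal(attr(cr, "plateau"), plateau_ring(1, 1, 0.25))
  expect_lt(attr(cr, "plateau"), 0.2)
  ## huge linear tether: confinement wins
  lin <- structure(list(topology = "linear", segments = c(nL = 500),
                        rabl = FALSE, pinned = FALSE),
                   class = "cell_realization")
  cl <- cell_mscd_curve(lin, ch, pp, lt, confined_plateau = 1.8)
  expect_equal(attr(cl, "plateau"), 1.8)
})

test_that("ensemble MSCD: censoring raises values, mu lowers the plateau", {
  ch <- lookup_chromosome("URA3")
  pp <- polymer_params()
  lt <- seq(0, 1470, 30)
  conf <- list(telomeres_only = 1.8, rabl = 0.7)
  ## mu = 0, no Rabl: every cell is the unlinked confined curve
  set.seed(5)
  e0 <- ensemble_mscd(ch, pp, 0, 0, 50, lt, confined = conf)
  expect_equal(e0$value, mscd_theory_curve(1.8, pp, lt)$value)
  ## censored >= uncensored pointwise (same realizations via seed)
  set.seed(7)
  ec <- ensemble_mscd(ch, pp, 3, 0, 400, lt, censor = TRUE, confined = conf)
  set.seed(7)
  eu <- ensemble_mscd(ch, pp, 3, 0, 400, lt, censor = FALSE, confined = conf)
  both <- !is.na(ec$value) & !is.na(eu$value)
  expect_true(all(ec$value[both] >= eu$value[both] - 1e-12))
  ## plateau strictly decreasing in mu
  plats <- vapply(c(0, 1, 3), function(mu) {
    set.seed(9)
    e <- ensemble_mscd(ch, pp, mu, 0, 400, lt, confined = conf)
    fit_powerlaw_plateau(e)$C
  }, numeric(1))
  expect_true(all(diff(plats) < 0))
})

test_that("Rabl plateau relaxation evaluates the two-state formula", {
  expect_equal(rabl_decay(0, 1.0, 1.74, 0.605), 1.0)
  expect_equal(rabl_decay(1e6, 1.0, 1.74, 0.605), 1.74)
  expect_equal(rabl_decay(1.6529, 1.0, 1.74, 0.605),
               1.0 * exp(-0.605 * 1.6529) + 1.74 * (1 - exp(-0.605 * 1.6529)))
  expect_equal(round(rabl_decay(1.6529, 1.0, 1.74, 0.605), 4), 1.4678)
  expect_error(rabl_decay(1, 1, 1.74, -0.1), "nonnegative")
})
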