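tab <- load_stopping_table()
cell <- cell_model()

test_that("stopping table invariants: positivity, monotone range, round trip", {
  expect_true(all(tab$grid_sp > 0))
  expect_true(all(diff(tab$grid_range) > 0))
  e <- c(0.5, 1, 2, 4, 5.8695, 7.4503, 9.5)
  back <- residual_energy(e, 0, tab)
  expect_equal(back, e, tolerance = 1e-3)   # energy->range->energy identity
})

test_that("residual energy matches fine-step Euler integration to <0.5%", {
  for (case in list(c(6.0, 3.75), c(5.8695, 10), c(7.4503, 20),
                    c(4.5, 5), c(8.7849, 30))) {
    ours <- residual_energy(case[1], case[2], tab)
    oracle <- euler_residual(case[1], case[2])
    expect_equal(ours, oracle, tolerance = 5e-3)
  }
})

test_that("full-range path deposits everything", {
  r <- csda_range(6, tab)
  expect_equal(residual_energy(6, r, tab), 0, tolerance = 1e-6)
  expect_equal(residual_energy(6, r * 2, tab), 0)
  expect_error(residual_energy(6, -1, tab), "non-negative")
})

test_that("alpha ranges sit in the tens-of-microns regime", {
  # therapeutic alphas: ranges ~40-90 um in water, LET ~60-90 keV/um
  expect_gt(csda_range(5.87, tab), 35)
  expect_lt(csda_range(8.78, tab), 100)
  expect_equal(stopping_power(5.5, tab), 0.0828, tolerance = 0.02)
})

test_that("centre track deposits the stopping-power integral per region", {
  d <- transport_alpha(c(0, 0, 0), c(0, 0, 1), 6.787, cell, tab)
  e_nuc <- d$edep[d$region == "nucleus"]
  oracle <- 6.787 - euler_residual(6.787, 5)
  expect_equal(e_nuc, oracle, tolerance = 5e-3)
  expect_gt(e_nuc, 0.25)  # several hundred keV over the 5 um radius
  expect_lt(e_nuc, 0.55)
  # next 5 um of loss goes to the cytoplasm, and is larger (rising LET)
  e_cyt <- d$edep[d$region == "cytoplasm"]
  expect_gt(e_cyt, e_nuc)
})

test_that("energy is conserved per track to 1e-9 relative", {
  set.seed(8)
  for (i in 1:25) {
    origin <- sample_source_position(1, sample(c("cell_membrane", "cytoplasm",
                                                 "nucleus_volume"), 1), cell)
    dir <- random_directions(1)[1, ]
    E0 <- runif(1, 4.5, 9.5)
    d <- transport_alpha(origin[1, ], dir, E0, cell, tab)
    expect_lt(abs(sum(d$edep) + attr(d, "residual") - E0) / E0, 1e-9)
    expect_true(all(d$edep >= 0))
  }
})

test_that("track aimed away from the cell never touches the nucleus", {
  d <- transport_alpha(c(10.005, 0, 0), c(1, 0, 0), 7.45, cell, tab)
  expect_false(attr(d, "entered_nucleus"))
  expect_equal(sum(d$edep[d$region == "nucleus"]), 0)
})

test_that("transport is deterministic given origin, direction, energy", {
  a <- transport_alpha(c(2, 1, 0.5), c(0, 0.6, 0.8), 7.1, cell, tab)
  b <- transport_alpha(c(2, 1, 0.5), c(0, 0.6, 0.8), 7.1, cell, tab)
  expect_identical(a, b)
})

test_that("interior-source mean nucleus deposit approaches S(E0) * 3R/4", {
  # closed-form limit for energies far above the chord-stopping regime
  set.seed(9)
  n <- 3000
  pos <- sample_source_position(n, "nucleus_volume", cell)
  dirs <- random_directions(n)
  E0 <- 9.0
  edep <- vapply(seq_len(n), function(i) {
    d <- transport_alpha(pos[i, ], dirs[i, ], E0, cell, tab)
    sum(d$edep[d$region == "nucleus"])
  }, 0)
  expect_equal(mean(edep), stopping_power(E0, tab) * 3.75, tolerance = 0.1)
})

test_that("ionization events conserve energy and have Poisson counts", {
  set.seed(10)
  ev <- generate_ionization_events(c(0, 0, -2), c(0, 0, 2), 0.1)
  expect_equal(sum(ev$edep_ev), 0.1e6, tolerance = 1e-9)
  expect_true(all(sqrt(ev$x^2 + ev$y^2 + ev$z^2) <= 5000 + 1e-9))
  expect_equal(nrow(generate_ionization_events(c(0, 0, 0), c(0, 0, 1), 0)), 0)
  # mean count at edep = 375 keV is 1e4 (W = 37.5 eV); 3 sigma over 100 draws
  counts <- vapply(1:100, function(i)
    nrow(generate_ionization_events(c(0, 0, -1), c(0, 0, 1), 0.375)), 0)
  expect_lt(abs(mean(counts) - 1e4), 3 * sqrt(1e4 / 100))
})

test_that("light-particle policy: range cut decides local vs dropped", {
  em <- data.frame(kind = c("electron", "electron", "gamma", "recoil"),
                   energy = c(0.004, 1.0, 0.57, 0.113),
                   parent = "X")
  dep <- deposit_light_particles(em, c(0, 0, 0), cell)
  # 4 keV electron (range ~0.5 um) and the recoil deposit in the nucleus;
  # the 1 MeV conversion electron (range >> box) and the gamma are dropped
  expect_equal(nrow(dep), 2)
  expect_true(all(dep$region == "nucleus"))
  expect_setequal(dep$kind, c("electron", "recoil"))
  expect_equal(sum(dep$edep), 0.004 + 0.113)
  # a 10 keV electron has range ~2.5 um, above the default 1 um cut
  em10 <- data.frame(kind = "electron", energy = 0.010, parent = "X")
  expect_equal(nrow(deposit_light_particles(em10, c(0, 0, 0), cell)), 0)
  expect_gt(electron_range(0.010), 1)
  # policy = ignore drops everything -> alpha-only dose equals total dose
  expect_equal(nrow(deposit_light_particles(em, c(0, 0, 0), cell,
                                            policy = "ignore")), 0)
  # recoil policy "drop" imitates heavy-ion-blind transport
  expect_false("recoil" %in%
    deposit_light_particles(em, c(0, 0, 0), cell,
                            recoil_policy = "drop")$kind)
})
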