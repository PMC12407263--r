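# Capillary design equations: hand-evaluated oracles and scaling laws.

water <- fluid_spec(gamma = 0.072, theta = 0, mu = 1e-3)

test_that("Laplace pressure matches the hand evaluation and its symmetries", {
  geom <- channel_geometry("rectangular", w = 1e-3, h = 1e-3, L = 1e-2)
  expect_equal(laplace_pressure(water, geom), 288, tolerance = 1e-9)
  # theta = 90 deg -> zero driving pressure
  neutral <- fluid_spec(0.072, pi / 2, 1e-3)
  expect_equal(laplace_pressure(neutral, geom), 0, tolerance = 1e-12)
  # symmetric in w <-> h; halving both doubles the pressure
  g1 <- channel_geometry("rectangular", w = 2e-3, h = 0.5e-3, L = 1e-2)
  g2 <- channel_geometry("rectangular", w = 0.5e-3, h = 2e-3, L = 1e-2)
  expect_equal(laplace_pressure(water, g1), laplace_pressure(water, g2))
  gh <- channel_geometry("rectangular", w = 0.5e-3, h = 0.5e-3, L = 1e-2)
  expect_equal(laplace_pressure(water, gh),
               2 * laplace_pressure(water, geom), tolerance = 1e-12)
  cyl <- channel_geometry("cylindrical", r = 1e-4, L = 1e-2)
  expect_error(laplace_pressure(water, cyl), "rectangular")
})

test_that("Hagen-Poiseuille flow matches the hand evaluation and r^4 scaling", {
  cyl <- channel_geometry("cylindrical", r = 1e-4, L = 1e-2)
  expect_equal(poiseuille_flow(water, cyl, 100),
               pi * 1e-16 * 100 / (8 * 1e-3 * 1e-2), tolerance = 1e-9)
  expect_equal(poiseuille_flow(water, cyl, 100), 3.926991e-10,
               tolerance = 1e-6)
  expect_equal(poiseuille_flow(water, cyl, 0), 0)
  big <- channel_geometry("cylindrical", r = 2e-4, L = 1e-2)
  expect_equal(poiseuille_flow(water, big, 100),
               16 * poiseuille_flow(water, cyl, 100), tolerance = 1e-12)
  expect_error(poiseuille_flow(water, cyl, -10), "backflow")
  rect <- channel_geometry("rectangular", w = 1e-3, h = 1e-3, L = 1e-2)
  expect_error(poiseuille_flow(water, rect, 10), "cylindrical")
})

test_that("Washburn filling follows the square-root law and inverts exactly", {
  D <- 2e-4
  expect_equal(washburn_fill(water, D, 0), 0)
  L1 <- washburn_fill(water, D, 1)
  expect_equal(washburn_fill(water, D, 4), 2 * L1, tolerance = 1e-12)
  # hand evaluation: L = sqrt(gamma D cos(theta) t / (4 mu))
  expect_equal(L1, sqrt(0.072 * D / (4e-3)), tolerance = 1e-12)
  # exact inverse round trip
  for (t in c(0.5, 3, 60))
    expect_equal(washburn_time(water, D, washburn_fill(water, D, t)), t,
                 tolerance = 1e-9)
  dry <- fluid_spec(0.072, 1.6, 1e-3)   # theta > 90 deg
  expect_error(washburn_fill(dry, D, 5), "non-wetting")
  # d(L^2)/dt is constant on a grid
  ts <- seq(1, 10, by = 1)
  L2 <- washburn_fill(water, D, ts)^2
  expect_equal(diff(L2), rep(L2[1], 9), tolerance = 1e-9)
})

test_that("reservoir fill times follow volume/flow and the prototype ratios", {
  expect_equal(reservoir_fill_time(ul_to_m3(60), ul_to_m3(1)), 60)
  q <- 3.2e-10
  expect_equal(reservoir_fill_time(ul_to_m3(150), q) /
                 reservoir_fill_time(ul_to_m3(60), q), 2.5,
               tolerance = 1e-12)
  expect_error(reservoir_fill_time(1e-9, 0), "positive")
  vols <- prototype_volumes()
  expect_equal(vols$prototype1_reservoir_ul / vols$prototype2_inlet_ul, 2.5)
})

test_that("the chained design computation matches a single-expression oracle", {
  blood <- fluid_spec(gamma = 0.058, theta = 30 * pi / 180, mu = 3.5e-3)
  rect <- channel_geometry("rectangular", w = 8e-4, h = 4e-4, L = 5e-3)
  cyl <- channel_geometry("cylindrical", r = 1.5e-4, L = 8e-3)
  dp <- laplace_pressure(blood, rect)
  q <- poiseuille_flow(blood, cyl, dp)
  t_chain <- reservoir_fill_time(ul_to_m3(25), q)
  t_oracle <- ul_to_m3(25) /
    (pi * (1.5e-4)^4 *
       (2 * 0.058 * cos(30 * pi / 180) * (1 / 8e-4 + 1 / 4e-4)) /
       (8 * 3.5e-3 * 8e-3))
  expect_equal(t_chain, t_oracle, tolerance = 1e-12)
  # monotone: more viscous is slower, higher surface tension is faster
  thicker <- fluid_spec(0.058, 30 * pi / 180, 7e-3)
  expect_gt(reservoir_fill_time(ul_to_m3(25),
                                poiseuille_flow(thicker, cyl,
                                                laplace_pressure(thicker, rect))),
            t_chain)
  tenser <- fluid_spec(0.08, 30 * pi / 180, 3.5e-3)
  expect_lt(reservoir_fill_time(ul_to_m3(25),
                                poiseuille_flow(tenser, cyl,
                                                laplace_pressure(tenser, rect))),
            t_chain)
})

test_that("unit helpers round-trip exactly", {
  expect_equal(m3_to_ul(ul_to_m3(153.2)), 153.2, tolerance = 1e-12)
  expect_equal(m_to_mm(mm_to_m(0.73)), 0.73, tolerance = 1e-12)
})
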