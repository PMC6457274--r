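test_that("zone partition tiles the cycle into pull and push quadrants", {
  z <- zone_partition()
  expect_equal(z$breaks, seq(0, 2 * pi, length.out = 5L))
  expect_equal(z$phase, c("pull", "push", "push", "pull"))
  th <- seq(0, 2 * pi - 1e-9, length.out = 400L)
  zi <- hbpsim:::.zone_of(th, z)
  expect_setequal(unique(zi), 1:4)
  expect_true(all(diff(zi) >= 0))            # quadrants in crank order
})

test_that("muscle work integrates force times shortening per zone", {
  n <- 241L
  # muscle 1: constant force, constant shortening; muscle 2: isometric
  force <- cbind(rep(40, n), rep(60, n))
  v_mt <- cbind(rep(-0.05, n), rep(0, n))
  tr <- synthetic_trace(force, v_mt)
  mw <- muscle_work(tr)
  period <- tr$period
  # rectangle integral: W = F * v * T, split evenly over four zones
  expect_equal(unname(mw$total[1L]), 40 * 0.05 * period, tolerance = 1e-10)
  expect_equal(unname(mw$work[1L, ]), rep(40 * 0.05 * period / 4, 4L),
               tolerance = 1e-10)
  expect_equal(unname(mw$total[2L]), 0)
  expect_true(all(mw$work[2L, ] == 0))
})

test_that("zone works sum exactly to the whole-cycle integral", {
  set.seed(21)
  n <- 241L
  tt <- seq(0, 1.2, length.out = n)
  force <- matrix(abs(sin(outer(tt, c(3, 5, 7)))) * 100, n, 3L)
  v_mt <- matrix(0.04 * sin(outer(tt, c(2, 4, 6)) + 1), n, 3L)
  tr <- synthetic_trace(force, v_mt)
  mw <- muscle_work(tr)
  whole <- vapply(1:3, function(i)
    pracma::trapz(tr$time, -force[, i] * v_mt[, i]), numeric(1L))
  expect_equal(unname(rowSums(mw$work)), whole, tolerance = 1e-12)
  # positive and negative components recompose the net work
  expect_equal(mw$positive + mw$negative, mw$work, tolerance = 1e-12)
})

test_that("rom summary reports extrema and ergonomic flags", {
  n <- 721L
  tt <- seq(0, 2 * pi, length.out = n)
  q <- cbind(rep(-1.0, n), rep(1.2, n))
  tr <- synthetic_trace(matrix(0, n, 2L), matrix(0, n, 2L), q = q,
                        flexion_deg = 40 + 10 * sin(tt))
  rom <- rom_summary(tr)
  sh <- rom[rom$joint == "shoulder", ]
  expect_equal(sh$min_deg, sh$max_deg)
  el <- rom[rom$joint == "elbow", ]
  expect_equal(c(el$min_deg, el$max_deg), c(30, 50), tolerance = 1e-3)
  expect_false(el$exceeds)
  rom2 <- rom_summary(tr, ergonomic_deg = list(shoulder = c(-40, 20),
                                               elbow = c(0, 45)))
  expect_true(rom2$exceeds[rom2$joint == "elbow"])     # max 50 > 45
  expect_true(rom2$exceeds[rom2$joint == "shoulder"])  # -57.3 < -40
})

test_that("fiber mechanics exposes normalized states and the activity mask", {
  n <- 101L
  a <- cbind(rep(0.1, n), c(rep(0.1, 50L), rep(0.5, 51L)))
  tr <- synthetic_trace(matrix(0, n, 2L), matrix(0, n, 2L), a = a)
  fm <- fiber_mechanics(tr)
  expect_false(any(fm$active[, 1L]))
  expect_equal(sum(fm$active[, 2L]), 51L)
  expect_true(all(fm$vnorm == 0))            # constant musculotendon length
  expect_true(all(abs(fm$lnorm - 1) < 1e-12))
})

test_that("peak forces match the Hill identity and dominate the mean", {
  mus <- muscle_set(as.data.frame(default_muscles())[8L, , drop = FALSE])
  mus$penn_deg <- 0                         # pennation 0: peak = F_iso_max
  n <- 101L
  a <- matrix(seq(0, 1, length.out = n), n, 1L)
  l_iso <- mus$L_slack_m + mus$L_opt_m
  force <- matrix(musculotendon_force(as.list(mus[1L, ]), a[, 1L], l_iso), n, 1L)
  tr <- synthetic_trace(force, matrix(0, n, 1L), a = a, muscles = mus)
  pk <- peak_forces(tr)
  expect_equal(unname(pk), mus$F_iso_max_N)
  expect_gte(unname(pk), mean(force))
})

test_that("report bundles are deterministic and internally consistent", {
  prof <- printed_profile()
  mus <- four_muscle_set()
  set.seed(13)
  exc <- matrix(runif(20L), 4L, 5L)
  tr <- simulate_cycles(prof, exc, mus, arm_config(), mechanism_config(),
                        n_cycles = 2L, n_out = 120L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- propulsion_report(tr, printed_shape(), d1)
  s2 <- propulsion_report(tr, printed_shape(), d2)
  for (f in c("summary.json", "trace.csv", "muscle_work.csv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  back <- jsonlite::fromJSON(file.path(d1, "summary.json"))
  expect_equal(back$net_power_W, net_propulsion_power(tr))
  expect_equal(back$shape$A_m, 0.151)
  expect_equal(s1$circularity, circularity(sample_path(printed_shape())))
})

test_that("whole-system energy bookkeeping closes through the work report", {
  prof <- printed_profile()
  set.seed(3)
  exc <- matrix(runif(150), 15L, 10L)
  tr <- simulate_cycles(prof, exc, default_muscles(), arm_config(),
                        mechanism_config())
  mw <- muscle_work(tr)
  ea <- energy_audit(tr)
  crank_work <- net_propulsion_power(tr) * tr$period
  scale <- max(abs(crank_work), sum(abs(mw$total)))
  expect_lt(abs(sum(mw$total) + ea$limit - crank_work) / scale, 0.01)
})
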