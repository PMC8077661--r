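test_that("Michelson and Weber contrasts follow their definitions", {
  expect_equal(michelson_contrast(255, 0), 1)
  expect_equal(michelson_contrast(80, 80), 0)
  expect_equal(michelson_contrast(100, 80), 1 / 9)
  expect_error(michelson_contrast(0, 0), class = "polardrum_error")

  expect_equal(weber_contrast(0, 255), -1)
  expect_equal(weber_contrast(42, 42), 0)
  expect_equal(weber_contrast(255, 127), 128 / 127)
  expect_equal(weber_contrast(255, 127), 1.0079, tolerance = 1e-4)
  expect_error(weber_contrast(10, 0), class = "polardrum_error")
})

test_that("quantum catch equals the brute-force two-axis absorber", {
  model <- receptor_model(sp = 10)
  set.seed(5)
  n <- 1e4
  st <- stokes_state(i = stats::runif(n, 0.1, 10),
                     dop = stats::runif(n),
                     aop = stats::runif(n, 0, 180))
  axis <- stats::runif(n, 0, 180)
  q <- quantum_catch(st, axis, model)
  q_oracle <- oracle_quantum_catch(st$i, st$dop, st$aop, axis, 10)
  expect_lt(max(abs(q - q_oracle) / q_oracle), 1e-12)
})

test_that("polarization sensitivity sets the parallel:perpendicular catch ratio", {
  model <- receptor_model(sp = 10)
  q_par <- quantum_catch(stokes_state(1, 1, 30), axis = 30, model)
  q_perp <- quantum_catch(stokes_state(1, 1, 120), axis = 30, model)
  expect_equal(q_par / q_perp, 10)
  # unpolarized light is axis-independent
  q <- quantum_catch(stokes_state(1, 0, 77), axis = c(0, 45, 90), model)
  expect_equal(q, rep(q[1], 3))
})

test_that("polarization distance has metric-like properties and the drum value", {
  model <- receptor_model(sp = 10)
  a <- stokes_state(1, 1, 0)
  expect_equal(polarization_distance(a, a, model), 0)
  set.seed(9)
  for (i in 1:20) {
    x <- stokes_state(stats::runif(1, 0.5, 2), stats::runif(1), stats::runif(1, 0, 180))
    y <- stokes_state(stats::runif(1, 0.5, 2), stats::runif(1), stats::runif(1, 0, 180))
    expect_equal(polarization_distance(x, y, model),
                 polarization_distance(y, x, model))
    expect_gte(polarization_distance(x, y, model), 0)
  }
  # the H (DoP 1) vs V (DoP 0.45) grating pair, via the oracle
  obj <- stokes_state(1, 1, 0)
  bkg <- stokes_state(1, 0.45, 90)
  want <- abs(oracle_opponent_signal(1, 1, 0, 10) -
                oracle_opponent_signal(1, 0.45, 90, 10))
  expect_equal(polarization_distance(obj, bkg, model), want)
  expect_equal(polarization_distance(obj, bkg, model), 1.186, tolerance = 1e-3)
})

test_that("polarization distance grows monotonically with the AoP difference", {
  model <- receptor_model(sp = 10)
  d <- vapply(seq(0, 90, by = 5), function(da)
    polarization_distance(stokes_state(1, 1, 0), stokes_state(1, 1, da), model),
    numeric(1))
  expect_true(all(diff(d) >= -1e-12))
  # unpolarized states are indistinguishable whatever their AoP labels
  expect_equal(
    polarization_distance(stokes_state(1, 0, 10), stokes_state(1, 0, 150), model),
    0)
})

test_that("screen calibration decodes endpoint and crossover drives", {
  cal <- screen_calibration()
  h <- decode_drive(0, cal)
  expect_equal(h$dop, 1)
  expect_equal(h$aop, 0)
  v <- decode_drive(255, cal)
  expect_equal(v$dop, 0.45)
  expect_equal(v$aop, 90)
  expect_equal(decode_drive(127, cal)$dop, 0)
  # interior drives interpolate DoP monotonically on each side
  lo <- decode_drive(seq(0, 127, by = 1), cal)$dop
  hi <- decode_drive(seq(127, 255, by = 1), cal)$dop
  expect_true(all(diff(lo) <= 0))
  expect_true(all(diff(hi) >= 0))
  expect_error(decode_drive(256, cal), class = "polardrum_error")
  # intensity is constant across drives: the screens' defining feature
  expect_equal(decode_drive(c(0, 60, 127, 200, 255), cal)$i, rep(1, 5))
})

test_that("Stokes maps recover trivial stacks", {
  m <- matrix(1, 4, 5)
  flat <- stokes_from_stack(m, m, m, m)
  expect_true(all(flat$dop == 0))
  expect_equal(flat$intensity, 2 * m)

  h <- stokes_from_stack(matrix(1, 2, 2), matrix(0.5, 2, 2),
                         matrix(0, 2, 2), matrix(0.5, 2, 2))
  expect_true(all(h$dop == 1))
  expect_true(all(h$aop == 0))
})

test_that("stokes_from_stack inverts the Malus forward model exactly", {
  set.seed(21)
  i <- matrix(stats::runif(300, 0.5, 3), 15, 20)
  d <- matrix(stats::runif(300), 15, 20)
  th <- matrix(stats::runif(300, 0, 180), 15, 20)
  stack <- make_polarimetric_stack(i, d, th)
  maps <- stokes_from_stack(stack$i0, stack$i45, stack$i90, stack$i135)
  expect_equal(maps$intensity, i, tolerance = 1e-12)
  expect_equal(maps$dop, d, tolerance = 1e-12)
  # AoP is defined mod 180; compare on the circle
  diff_aop <- abs(maps$aop - th) %% 180
  diff_aop <- pmin(diff_aop, 180 - diff_aop)
  expect_lt(max(diff_aop), 1e-9)
})

test_that("mismatched or invalid stacks are rejected and S0 = 0 is masked", {
  expect_error(stokes_from_stack(matrix(1, 2, 2), matrix(1, 2, 3),
                                 matrix(1, 2, 2), matrix(1, 2, 2)),
               class = "polardrum_error")
  z <- matrix(0, 2, 2)
  masked <- stokes_from_stack(z, z, z, z)
  expect_true(all(is.na(masked$dop)))
})

test_that("polarimetric stacks round-trip through multi-page TIFF", {
  set.seed(3)
  i <- matrix(stats::runif(100, 0.2, 1), 10, 10)
  d <- matrix(stats::runif(100), 10, 10)
  th <- matrix(stats::runif(100, 0, 180), 10, 10)
  stack <- make_polarimetric_stack(i, d, th)
  tmp <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(stack, identity), tmp, bits.per.sample = 32L)
  rt <- read_polarimetric_stack(tmp)
  expect_equal(rt$i0, stack$i0, tolerance = 1e-6)
  maps <- stokes_from_stack(rt$i0, rt$i45, rt$i90, rt$i135)
  expect_equal(maps$dop, d, tolerance = 1e-5)
  unlink(tmp)
})
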