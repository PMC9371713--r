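test_that("the Hill response satisfies its algebraic identities", {
  for (k in c(0.2, 0.5, 2)) {
    for (n in c(1, 2, 4)) {
      expect_equal(hill(k, k, n, "+"), 0.5)
      expect_equal(hill(0, k, n, "+"), 0)
      expect_equal(hill(0, k, n, "-"), 1)
      x <- seq(0, 3, length.out = 11)
      expect_equal(hill(x, k, n, "+") + hill(x, k, n, "-"), rep(1, 11))
      expect_true(all(diff(hill(x, k, n, "+")) >= 0))
      expect_true(all(diff(hill(x, k, n, "-")) <= 0))
    }
  }
  expect_error(hill(-1, 0.5, 2), "nonnegative")
})

test_that("model construction validates its inputs", {
  expect_error(build_model("X", data.frame(from = "X", to = "Q", sign = "+")),
               "unknown node")
  expect_error(build_model("X", data.frame(from = "X", to = "X", sign = "+",
                                           k = -1, n = 2)), "positive")
  expect_error(build_model("X", data.frame(from = "X", to = "X", sign = "*")),
               "sign")
  m <- circuit_fixture("C1FFL")
  expect_equal(length(m$dynamic), 2) # X is an external input
  expect_equal(nrow(m$edges), 3)
})

test_that("with no production the solution is pure exponential decay", {
  m <- build_model("X", data.frame(from = character(0), to = character(0),
                                   sign = character(0)))
  tr <- simulate_circuit(m, x0 = c(X = 1), t_end = 5)
  expect_equal(tr$states[, "X"], exp(-tr$time), tolerance = 1e-6)
  expect_equal(classify_dynamics(tr, "X"), "monotone-converge")
})

test_that("the self-activating node is bistable", {
  fps <- find_fixed_points(circuit_fixture("SL"))
  expect_length(fps, 3)
  stable <- vapply(fps, `[[`, logical(1), "stable")
  expect_equal(sum(stable), 2)
  states <- vapply(fps, function(fp) fp$state[["X"]], numeric(1))
  expect_equal(min(states), 0, tolerance = 1e-6)
})

test_that("a feedforward Jacobian has purely real negative spectrum", {
  # unit-removal linearization of the feedforward loop: lower triangular
  J <- rbind(c(-1, 0, 0), c(1, -1, 0), c(1, 1, -1))
  ev <- eigen(J, only.values = TRUE)$values
  expect_equal(sort(Re(ev)), c(-1, -1, -1))
  expect_true(all(abs(Im(ev)) == 0))
})

test_that("trajectory classification recognizes canonical shapes", {
  tt <- seq(0, 40, length.out = 1500)
  expect_equal(classify_dynamics(fake_trajectory(tt, x = exp(-tt)), "x"),
               "monotone-converge")
  pulse <- tt * exp(-tt)
  expect_equal(classify_dynamics(fake_trajectory(tt, x = pulse), "x"), "pulse")
  damped <- exp(-0.15 * tt) * cos(2 * tt) + 1.1
  expect_equal(classify_dynamics(fake_trajectory(tt, x = damped), "x"),
               "damped-oscillation")
  sustained <- cos(2 * tt) + 1.1
  expect_equal(classify_dynamics(fake_trajectory(tt, x = sustained), "x"),
               "sustained-oscillation")
  short <- fake_trajectory(seq(0, 1, length.out = 10), x = 1:10)
  expect_equal(classify_dynamics(short, "x"), "inconclusive")
})

test_that("synchronization metrics resolve phase on synthetic sinusoids", {
  tt <- seq(0, 60, length.out = 3000)
  a <- cos(tt) + 1.5
  s_in <- synchronization_metrics(
    fake_trajectory(tt, a = a, b = a), "a", "b")
  expect_equal(s_in$phase, "in-phase")
  s_anti <- synchronization_metrics(
    fake_trajectory(tt, a = a, b = cos(tt + pi) + 1.5), "a", "b")
  expect_equal(s_anti$phase, "anti-phase")
  expect_equal(s_anti$period, 2 * pi, tolerance = 0.05)
  s_none <- synchronization_metrics(
    fake_trajectory(tt, a = a, b = exp(-tt)), "a", "b")
  expect_equal(s_none$phase, "none")
})

test_that("circuit specifications round-trip through the text format", {
  m <- circuit_fixture("I1FFL+SLy")
  tf <- withr::local_tempfile(fileext = ".spec")
  write_circuit(m, tf)
  m2 <- read_circuit(tf)
  expect_equal(m2$edges, m$edges)
  expect_equal(m2$beta, m$beta)
  expect_equal(m2$gate, m$gate)
  expect_equal(m2$inputs, m$inputs)
  tr1 <- simulate_circuit(m, x0 = c(Y = 0.185, Z = 0.19), t_end = 10)
  tr2 <- simulate_circuit(m2, x0 = c(Y = 0.185, Z = 0.19), t_end = 10)
  expect_equal(tr1$states, tr2$states, tolerance = 1e-10)
})

test_that("nonnegativity is preserved along trajectories", {
  for (nm in c("TMFL", "OMFL", "I1FFL", "LOOP3-pair")) {
    tr <- simulate_circuit(circuit_fixture(nm),
                           x0 = setNames(rep(0.2, 4), c("X", "Y", "Z", "W")),
                           t_end = 30)
    expect_true(all(tr$states >= 0))
  }
})

test_that("the Lock-ON circuit gains nothing from added self-loops", {
  plain <- find_fixed_points(circuit_fixture("LMFL"))
  with_sl <- find_fixed_points(circuit_fixture("LMFL+SL"))
  n_stable <- function(fps) sum(vapply(fps, `[[`, logical(1), "stable"))
  expect_equal(n_stable(plain), 2)
  expect_equal(n_stable(with_sl), 2)
  # both retain an ON-ON and an OFF-OFF state
  on_off <- function(fps) {
    st <- vapply(fps[vapply(fps, `[[`, logical(1), "stable")],
                 function(fp) sum(fp$state), numeric(1))
    c(min(st), max(st))
  }
  expect_equal(on_off(plain)[1], 0, tolerance = 1e-6)
  expect_equal(on_off(with_sl)[1], 0, tolerance = 1e-6)
  expect_gt(on_off(plain)[2], 1)
  expect_gt(on_off(with_sl)[2], 1)
})
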