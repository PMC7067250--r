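# Timed transcription: discretization accuracy, conservation, refinement.

test_that("fixed-control trajectories converge to the matrix-exponential solution", {
  m0 <- c(p1 = 0, p2 = 4, p3 = 5)
  want <- cycle_closed_form(c(0, 4, 5), 0.5, 5)
  errs <- vapply(c(0.25, 0.1, 0.05), function(dt) {
    tr <- solve_fixed(0.5, m0, dt, 5)
    expect_equal(tr$status, "optimal")
    got <- unlist(tr$states[nrow(tr$states),
                            c("m[p1]", "m[p2]", "m[p3]")])
    max(abs(got - want) / pmax(abs(want), 1))
  }, 0)
  expect_lt(errs[2], 0.02)            # within 2% at dt = 0.1
  expect_true(all(diff(errs) < 0))    # error shrinks with dt
})

test_that("a one-interval step equals the hand-integrated midpoint update", {
  m0 <- c(p1 = 1, p2 = 4, p3 = 4)
  dt <- 0.1
  u <- 0.4
  tr <- solve_fixed(u, m0, dt, dt)
  got <- unlist(tr$states[2, c("m[p1]", "m[p2]", "m[p3]")])
  M <- matrix(c(-1, 1, 0, 0, -1, 1, 1, 0, -1), 3, 3)
  b <- c(-1, 3, -2) * u
  # (I - dt/2 M) m1 = (I + dt/2 M) m0 + dt b
  want <- solve(diag(3) - dt / 2 * M,
                (diag(3) + dt / 2 * M) %*% c(1, 4, 4) + dt * b)
  expect_equal(unname(got), as.numeric(want), tolerance = 1e-7)
})

test_that("trajectory snapshots satisfy the conservation rows", {
  net <- fn_resource_allocation()
  obj <- fn_objective("max", linear = c("mbar[p2]" = 1, "mbar[p4]" = 0.5,
                                        "mbar[p5]" = 0.25))
  prob <- transcribe(net, seq(0, 1, by = 0.25), objective = obj,
                     forced_exec = attr(net, "forced_exec"))
  tr <- solve_program_fn(prob)
  expect_equal(tr$status, "optimal")
  S <- structure_matrices(net)
  sol <- tr$solution
  n <- length(tr$times) - 1L
  for (k in 0:n) {
    g <- function(stub) sol[[paste0(stub, ".", k)]]
    expect_lt(max(abs(g("sigma") - g("aT") - S$Y_sigma %*% g("aE"))), 1e-6)
    expect_lt(max(abs(g("m") - sol$m.0 - S$Z_m %*% g("dm"))), 1e-6)
  }
  for (i in 1:n) {
    g <- function(stub) sol[[paste0(stub, ".", i)]]
    expect_lt(max(abs(g("mbar") - g("muP") - S$Y_m %*% g("muE"))), 1e-6)
    expect_lt(max(abs(g("lam") - sol$lambda0 -
                        S$Z_lambda %*% g("dlam"))), 1e-6)
    # interval handler rows imply the cumulative rows by summation
  }
  G <- global_blocks(net)
  expect_true(all(G$A %*% sol[[paste0("dm.", n)]] <=
                  G$B %*% sol[[paste0("aE.", n)]] + 1e-6))
})

test_that("nesting the grid never decreases a maximization optimum", {
  net <- fn_resource_allocation()
  obj <- fn_objective("max", linear = c("mbar[p2]" = 1, "mbar[p4]" = 0.5,
                                        "mbar[p5]" = 0.25))
  vals <- vapply(c(0.5, 0.25, 0.125), function(dt) {
    prob <- transcribe(net, seq(0, 2, by = dt), objective = obj,
                       forced_exec = attr(net, "forced_exec"))
    solve_program_fn(prob)$objective
  }, 0)
  expect_true(all(diff(vals) >= -1e-7))
})

test_that("a constant objective yields a feasible conservative point", {
  net <- fn_timed_choice()
  prob <- transcribe(net, c(0, 0.5, 1))
  tr <- solve_program_fn(prob)
  expect_equal(tr$status, "optimal")
  S <- structure_matrices(net)
  sol <- tr$solution
  expect_lt(max(abs(sol$m.2 - sol$m.0 - S$Z_m %*% sol$dm.2)), 1e-6)
})

test_that("steady-state program reproduces the intensity-split invariant", {
  net <- fn_intensity_split()
  terms <- c("lambda[t1]" = 1, "lambda[t2]" = 1, "lambda[t3]" = 1)
  expect_equal(steady_state_program(net, terms, "max")$value, 6,
               tolerance = 1e-7)
  expect_equal(steady_state_program(net, terms, "min")$value, 6,
               tolerance = 1e-7)
})

test_that("steady-state marking of the control loop keeps the token total", {
  net <- fn_control_loop()
  # steadiness is asked for any marking with the conserved token sum,
  # not for the exact start marking (which is not a fixed point)
  init <- fn_initial_conditions(
    net, lambda0 = list(t1 = 0, t2 = 0, t3 = 0, t4 = c(0, 1.5)),
    m0cons = "p1 + p2 + p3 = 9")
  for (sense in c("min", "max")) {
    r <- steady_state_program(
      net, c("m[p1]" = 1, "m[p2]" = 1, "m[p3]" = 1), sense,
      forced_exec = attr(net, "forced_exec"),
      forced_active = attr(net, "forced_active"),
      init = init)
    expect_equal(r$status, "optimal")
    expect_equal(r$value, 9, tolerance = 1e-7)
  }
})

test_that("bad grids and nonconvex objectives are rejected", {
  net <- fn_timed_choice()
  expect_error(transcribe(net, c(0.5, 1)), "starting at 0")
  expect_error(transcribe(net, c(0, 1, 1)), "increasing")
  expect_error(fn_objective("max", quadratic = list(
    list(term = "m[p1]", target = 0))), "convexity")
})

test_that("infeasible forced sets surface as infeasible status", {
  # forcing execution makes the produced tokens land in p3, while forcing
  # p3's (nonexistent) activity pins its marking at zero: no state fits
  net <- fn_timed_choice()
  prob <- transcribe(net, c(0, 1), forced_exec = "t1",
                     forced_active = c("p1", "p3"))
  tr <- solve_program_fn(prob)
  expect_equal(tr$status, "infeasible")
})
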