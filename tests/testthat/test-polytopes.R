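# State-equation systems of event nets, intensity nets and full nets.

test_that("intensity transfer: one active token gives intensities (4, 1)", {
  net <- fn_intensity_transfer()
  cs <- intensity_polytope(net, mu_E = c("{p1,s1}" = 1))
  lo <- optimize_over(cs, c("lambda[t1]" = 1), "min")
  hi <- optimize_over(cs, c("lambda[t1]" = 1), "max")
  expect_equal(lo$value, 4, tolerance = 1e-9)
  expect_equal(hi$value, 4, tolerance = 1e-9)
  expect_equal(lo$solution$lambda[["t2"]], 1, tolerance = 1e-9)
})

test_that("intensity split: total intensity is conserved at 6", {
  net <- fn_intensity_split()
  cs <- intensity_polytope(net)
  terms <- c("lambda[t1]" = 1, "lambda[t2]" = 1, "lambda[t3]" = 1)
  expect_equal(optimize_over(cs, terms, "max")$value, 6, tolerance = 1e-9)
  expect_equal(optimize_over(cs, terms, "min")$value, 6, tolerance = 1e-9)
})

test_that("with no active tokens and equal-transfer handlers, lambda = lambda0", {
  net <- fn_intensity_transfer()
  mu0 <- stats::setNames(numeric(nrow(net$ESP)), net$ESP$id)
  cs <- intensity_polytope(net, mu_E = mu0)
  r <- optimize_over(cs, c("lambda[t1]" = 1), "max")
  expect_equal(r$solution$lambda[["t1"]], 5, tolerance = 1e-9)
  expect_equal(r$solution$lambda[["t2"]], 0, tolerance = 1e-9)
})

test_that("event polytope: integer production values match brute force", {
  net <- fn_event_choice()  # m0 = (2, 0, 0)
  feasible <- oracle_choice_production_values()
  for (v in 0:3) {
    cs <- event_polytope(net, sigma = c(t1 = 1))
    cs_fix(cs, "dm", c("(v2,p3)" = v))
    r <- cs_optimize(cs, c("m[p1]" = 1), sense = "max",
                     integrality = rep(1L, cs$nvar))
    if (v %in% feasible) {
      expect_equal(r$status, "optimal", info = paste("production", v))
    } else {
      expect_equal(r$status, "infeasible", info = paste("production", v))
    }
  }
})

test_that("zero actions only allow the silent token flow", {
  net <- fn_event_choice()
  cs <- event_polytope(net, sigma = c(t1 = 0))
  r <- optimize_over(cs, c("m[p3]" = 1), "max")
  expect_equal(r$value, 0, tolerance = 1e-9)       # no production into p3
  r2 <- optimize_over(cs, c("m[p2]" = 1), "max")
  expect_equal(r2$value, 2, tolerance = 1e-9)      # silent handler still moves
})

test_that("forcing execution or activity never enlarges the feasible set", {
  net <- fn_timed_choice()
  set.seed(42)
  for (i in 1:4) {
    w <- stats::setNames(round(stats::runif(3, -1, 1), 3),
                         c("m[p1]", "m[p2]", "m[p3]"))
    free <- fn_polytope_at(net, tau = 1)
    forc <- fn_polytope_at(net, tau = 1, forced_exec = "t1")
    vf <- optimize_over(free, w, "max")
    vc <- optimize_over(forc, w, "max")
    if (vc$status == "optimal") {
      expect_lte(vc$value, vf$value + 1e-7)
    }
  }
})

test_that("full-net system at time tau bounds executed actions by tokens", {
  net <- fn_timed_choice()  # m0 = (2, 0, 0)
  cs <- fn_polytope_at(net, tau = 1)
  r <- optimize_over(cs, c("a_E[{t1,v2}]" = 1), "max")
  expect_equal(r$value, 2, tolerance = 1e-8)   # at most both tokens of p1
  r2 <- optimize_over(cs, c("m[p3]" = 1), "max")
  expect_equal(r2$value, 4, tolerance = 1e-8)  # b <= 2x with x <= 2
})

test_that("intensity-decrease-only nets are pinned at time zero", {
  net <- fn_net(places = "p1", transitions = "t1",
                shandlers = list(s1 = fn_sh(from = c(x = "t1"),
                                            link = c(u = "p1"))),
                m0 = list(p1 = 1), lambda0 = list(t1 = 2))
  cs <- fn_polytope_at(net, tau = 0)
  r <- optimize_over(cs, c("sigma[t1]" = 1), "max")
  expect_equal(r$value, 0, tolerance = 1e-9)
})

test_that("conservation rows hold in returned solutions", {
  net <- fn_timed_choice()
  S <- structure_matrices(net)
  cs <- fn_polytope_at(net, tau = 1)
  r <- optimize_over(cs, c("m[p3]" = 1), "max")
  s <- r$solution
  expect_lt(max(abs(s$sigma - s$a_T - S$Y_sigma %*% s$a_E)), 1e-6)
  expect_lt(max(abs(s$m - s$m0 - S$Z_m %*% s$dm)), 1e-6)
  expect_lt(max(abs(s$m - s$mu_P - S$Y_m %*% s$mu_E)), 1e-6)
  expect_lt(max(abs(s$lambda - s$lambda0 - S$Z_lambda %*% s$dl)), 1e-6)
})

test_that("negative time and unknown forced identifiers are rejected", {
  net <- fn_timed_choice()
  expect_error(fn_polytope_at(net, tau = -1), "nonnegative")
  expect_error(event_polytope(net, forced = "t99"), "unknown transition")
  expect_error(intensity_polytope(net, forced = "p99"), "unknown place")
})
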