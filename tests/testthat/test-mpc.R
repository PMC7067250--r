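# Receding-horizon driver.

test_that("configuration errors are caught", {
  net <- fn_control_loop()
  obj <- fn_objective("min", quadratic = list(list(term = "m[p1]",
                                                   target = 1)))
  expect_error(run_mpc(net, obj, dt = 0.1, horizon = 0), "horizon")
  expect_error(run_mpc(net, obj, dt = -1), "dt must be positive")
  expect_error(run_mpc(net, obj, dt = 0.1, n_steps = 0), "n_steps")
})

test_that("the control loop converges to a fixed point with conserved tokens", {
  net <- fn_control_loop()
  obj <- fn_objective("min", quadratic = list(
    list(term = "m[p1]", target = 1), list(term = "m[p2]", target = 4)))
  res <- run_mpc(net, obj, dt = 0.1, horizon = 1, n_steps = 200,
                 forced_exec = attr(net, "forced_exec"),
                 forced_active = attr(net, "forced_active"))
  expect_true(res$converged)
  sums <- rowSums(as.matrix(res$states[, c("m[p1]", "m[p2]", "m[p3]")]))
  expect_lt(max(abs(sums - 9)), 1e-6)
  # applied control always respects its static block
  u <- res$controls[["lambda0[t4]"]]
  expect_true(all(u >= -1e-9 & u <= 1.5 + 1e-9))
  # and the dynamic bound u <= mbar[p2] / 2 emerges from lambda[t2] >= 0
  expect_true(all(res$controls[["lambda[t2]"]] >= -1e-7))

  # idempotence: re-solving from the converged state reproduces it
  last <- res$states[nrow(res$states), ]
  m_fix <- stats::setNames(
    as.numeric(last[c("m[p1]", "m[p2]", "m[p3]")]),
    c("p1", "p2", "p3"))
  again <- run_mpc(net, obj, dt = 0.1, horizon = 1, n_steps = 1,
                   forced_exec = attr(net, "forced_exec"),
                   forced_active = attr(net, "forced_active"),
                   m0 = m_fix)
  m_next <- stats::setNames(
    as.numeric(again$states[2, c("m[p1]", "m[p2]", "m[p3]")]),
    c("p1", "p2", "p3"))
  expect_lt(max(abs(m_next - m_fix)), 1e-3)
})

test_that("tidy and glance summarise MPC runs", {
  net <- fn_control_loop()
  obj <- fn_objective("min", quadratic = list(
    list(term = "m[p1]", target = 1), list(term = "m[p2]", target = 4)))
  res <- run_mpc(net, obj, dt = 0.1, horizon = 1, n_steps = 3,
                 forced_exec = attr(net, "forced_exec"),
                 forced_active = attr(net, "forced_active"))
  td <- tidy(res)
  expect_true(all(c("time", "series", "value") %in% names(td)))
  expect_equal(nrow(td), 4L * 3L)  # 4 boundaries x 3 places
  gl <- glance(res)
  expect_equal(gl$steps, 3L)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
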