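# Discrete execution: enabling, firing, reachability graphs and
# observation-consistent marking sets.

test_that("enabling matches the worked choice-net example", {
  net <- fn_event_choice()
  st <- event_state(net, sigma = c(t1 = 1), m = c(p1 = 2, p2 = 0, p3 = 0))
  expect_false(is.null(is_enabled(net, st, "v1")))
  expect_false(is.null(is_enabled(net, st, "v2")))
  empty <- event_state(net, sigma = c(t1 = 0),
                       m = c(p1 = 0, p2 = 0, p3 = 0))
  expect_null(is_enabled(net, empty, "v1"))
  expect_null(is_enabled(net, empty, "v2"))
  # continuous-mode enabling agrees here
  expect_false(is.null(is_enabled(net, st, "v2", integer = FALSE)))
  expect_null(is_enabled(net, empty, "v2", integer = FALSE))
})

test_that("firing applies exactly the witnessed amounts", {
  net <- fn_event_choice()
  st <- event_state(net, sigma = c(t1 = 1), m = c(p1 = 2, p2 = 0, p3 = 0))
  w <- list(a_f = c("{t1,v2}" = 1),
            dm_f = c("(p1,v2)" = 1, "(v2,p3)" = 2))
  st2 <- fire(net, st, "v2", w)
  expect_equal(unname(st2$m), c(1, 0, 2))
  expect_equal(st2$a_T[["t1"]], 0)
  expect_equal(st2$a_E[["{t1,v2}"]], 1)
  expect_equal(st2$dm[["(v2,p3)"]], 2)
  expect_equal(st2$sigma[["t1"]], 1)  # production unchanged by firing
  # token moves p1 -> p2 through the silent handler
  st3 <- fire(net, st, "v1",
              list(a_f = numeric(0), dm_f = c("(p1,v1)" = 1,
                                              "(v1,p2)" = 1)))
  expect_equal(unname(st3$m), c(1, 1, 0))
  # a zero witness leaves the state unchanged
  st4 <- fire(net, st, "v2", list(a_f = c("{t1,v2}" = 0),
                                  dm_f = c("(p1,v2)" = 0, "(v2,p3)" = 0)))
  expect_equal(st4, st)
})

test_that("invalid witnesses are rejected with the violated constraint", {
  net <- fn_event_choice()
  st <- event_state(net, sigma = c(t1 = 1), m = c(p1 = 2, p2 = 0, p3 = 0))
  expect_error(
    fire(net, st, "v2", list(a_f = c("{t1,v2}" = 2),
                             dm_f = c("(p1,v2)" = 2, "(v2,p3)" = 2))),
    "exceeds available actions")
  expect_error(
    fire(net, st, "v2", list(a_f = c("{t1,v2}" = 1),
                             dm_f = c("(p1,v2)" = 1, "(v2,p3)" = 3))),
    "handler row")
  expect_error(
    fire(net, st, "v1", list(a_f = numeric(0),
                             dm_f = c("(p1,v1)" = 3, "(v1,p2)" = 3))),
    "consumption exceeds tokens")
})

test_that("reachability graph equals the exhaustive recursion oracle", {
  net <- fn_event_choice()
  g <- reachability_graph(net, sigma = c(t1 = 1))
  got <- cbind(g$m, aT = g$a_T[, "t1"])
  got <- got[do.call(order, as.data.frame(got)), ]
  want <- oracle_choice_reach(c(2, 0, 0), 1)
  expect_equal(unname(got), unname(want))
  expect_false(g$truncated)
})

test_that("graph nodes satisfy the event state equations (necessity)", {
  net <- fn_event_choice()
  g <- reachability_graph(net, sigma = c(t1 = 1))
  # every reachable (m, a_T) admits an integer state-equation solution
  for (i in seq_len(nrow(g$m))) {
    mk <- enumerate_event_solutions(
      net, sigma = c(t1 = 1),
      a_T = stats::setNames(g$a_T[i, "t1"], "t1"),
      m0 = c(p1 = 2, p2 = 0, p3 = 0))
    keys <- vapply(mk, paste, "", collapse = ",")
    expect_true(paste(g$m[i, ], collapse = ",") %in% keys)
  }
})

test_that("observation-consistent markings reproduce the observer example", {
  net <- fn_observer_net()
  after_all <- consistent_markings(net, sigma = c(t1 = 2, t2 = 1, t3 = 1),
                                   a_T = c(t1 = 1, t2 = 0, t3 = 0))
  expect_equal(unname(sorted_marking_matrix(after_all)),
               matrix(c(0, 0, 0, 0, 0, 1), 1))
  after_two <- consistent_markings(net, sigma = c(t1 = 2, t2 = 1, t3 = 0),
                                   a_T = c(t1 = 1, t2 = 0, t3 = 0))
  expect_equal(unname(sorted_marking_matrix(after_two)),
               rbind(c(0, 0, 0, 0, 1, 0),
                     c(0, 0, 0, 0, 2, 0),
                     c(0, 0, 0, 1, 0, 0)))
  # nothing executed: only the initial marking is consistent
  none <- consistent_markings(net, sigma = c(t1 = 2, t2 = 1, t3 = 1),
                              a_T = c(t1 = 2, t2 = 1, t3 = 1))
  expect_equal(unname(sorted_marking_matrix(none)),
               matrix(c(1, 0, 0, 0, 0, 0), 1))
  # an impossible observation yields the empty set, not an error
  impossible <- consistent_markings(net, sigma = c(t1 = 0, t2 = 1, t3 = 0),
                                    a_T = c(t1 = 0, t2 = 0, t3 = 0))
  expect_equal(nrow(impossible), 0L)
})

test_that("graph-based consistent markings are contained in equation-based", {
  net <- fn_observer_net()
  combos <- list(
    list(sigma = c(t1 = 2, t2 = 1, t3 = 1), a_T = c(t1 = 1, t2 = 0, t3 = 0)),
    list(sigma = c(t1 = 2, t2 = 1, t3 = 0), a_T = c(t1 = 1, t2 = 0, t3 = 0)),
    list(sigma = c(t1 = 1, t2 = 0, t3 = 0), a_T = c(t1 = 0, t2 = 0, t3 = 0))
  )
  for (cb in combos) {
    by_graph <- consistent_markings(net, cb$sigma, cb$a_T, method = "graph")
    by_eq <- consistent_markings(net, cb$sigma, cb$a_T)
    keys_eq <- apply(as.matrix(by_eq), 1, paste, collapse = ",")
    keys_gr <- apply(as.matrix(by_graph), 1, paste, collapse = ",")
    expect_true(all(keys_gr %in% keys_eq))
  }
  # same containment on the choice net
  cm_g <- consistent_markings(fn_event_choice(), c(t1 = 1), c(t1 = 0),
                              method = "graph")
  cm_e <- consistent_markings(fn_event_choice(), c(t1 = 1), c(t1 = 0))
  expect_true(all(apply(as.matrix(cm_g), 1, paste, collapse = ",") %in%
                  apply(as.matrix(cm_e), 1, paste, collapse = ",")))
})

test_that("non-integer mode returns the fixed polytope description", {
  net <- fn_observer_net()
  cs <- consistent_markings(net, sigma = c(t1 = 2, t2 = 1, t3 = 1),
                            a_T = c(t1 = 1, t2 = 0, t3 = 0),
                            integer = FALSE)
  expect_s3_class(cs, "fn_consys")
})

test_that("non-integer inputs to the graph are rejected", {
  net <- fn_event_choice()
  expect_error(reachability_graph(net, sigma = c(t1 = 0.5)), "integer")
})
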