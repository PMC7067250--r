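# Net construction, validation, and global block assembly.

test_that("global A and B of the two-handler choice net match the printed forms", {
  net <- fn_event_choice()
  G <- global_blocks(net)
  A_expected <- rbind(
    c(1, -1, 0, 0), c(-1, 1, 0, 0),
    c(0, 0, 1, 0), c(0, 0, -1, 0), c(0, 0, 0, -1), c(0, 0, 0, 1))
  colnames(A_expected) <- c("(p1,v1)", "(v1,p2)", "(p1,v2)", "(v2,p3)")
  B_expected <- rbind(c(0, 0), c(0, 0), c(0, 1), c(0, -1), c(0, -1),
                      c(0, 2))
  colnames(B_expected) <- c("{.fv1,v1}", "{t1,v2}")
  expect_equal(unname(G$A), unname(A_expected))
  expect_equal(colnames(G$A), colnames(A_expected))
  expect_equal(unname(G$B), unname(B_expected))
  expect_equal(colnames(G$B), colnames(B_expected))
})

test_that("global assembly equals the entry-by-entry oracle on all examples", {
  nets <- list(fn_event_choice(), fn_observer_net(), fn_reaction_chain(),
               fn_intensity_transfer(), fn_intensity_choice(),
               fn_uncertain_linear(), fn_resource_allocation(),
               fn_control_loop(), fn_timed_choice(), fn_intensity_split(),
               fn_intensity_single())
  for (net in nets) {
    G <- global_blocks(net)
    O <- oracle_global_blocks(net)
    expect_equal(G$A, O$A)
    expect_equal(G$B, O$B)
    expect_equal(G$C, O$C)
    expect_equal(G$D, O$D)
  }
})

test_that("two handlers with disjoint labels produce zero off-diagonal blocks", {
  net <- fn_observer_net()
  G <- global_blocks(net)
  for (h in names(net$ehandlers)) {
    rsel <- rep(names(net$ehandlers),
                vapply(net$eblocks, function(b) nrow(b$left), 0L)) == h
    csel <- net$EVP$handler == h
    expect_true(all(G$A[rsel, !csel] == 0))
    esel <- net$EVT$handler == h
    expect_true(all(G$B[rsel, !esel] == 0))
  }
})

test_that("all example nets validate cleanly", {
  for (ctor in list(fn_event_choice, fn_observer_net, fn_reaction_chain,
                    fn_intensity_single, fn_intensity_transfer,
                    fn_intensity_split, fn_intensity_choice,
                    fn_timed_choice, fn_uncertain_linear,
                    fn_resource_allocation, fn_control_loop)) {
    expect_equal(nrow(validate_fn(ctor())), 0L)
  }
})

test_that("structural violations are reported, not raised", {
  # a handler linking a transition where a place is expected models the
  # forbidden direct place-transition connection
  net <- fn_net(places = c("p1", "p2"), transitions = "t1",
                ehandlers = list(v = fn_eh(from = c(a = "t1"),
                                           to = c(b = "p2"),
                                           link = c(x = "t1"))))
  v <- validate_fn(net)
  expect_equal(nrow(v), 1L)
  expect_match(v$detail, "t1")
  # the same edge declared twice
  net2 <- fn_net(places = c("p1", "p2"), transitions = "t1",
                 ehandlers = list(v = fn_eh(from = c(a = "p1"),
                                            to = c(b = "p2"),
                                            link = c(x = "t1", y = "t1"),
                                            rel = "a = x")))
  v2 <- validate_fn(net2)
  expect_equal(nrow(v2), 1L)
  expect_match(v2$rule, "unique-connection")
})

test_that("initial-condition blocks capture points, intervals and relations", {
  net <- fn_net(
    places = c("p1", "p2"), transitions = "t1",
    ehandlers = list(v = fn_eh(from = c(a = "p1"), to = c(b = "p2"),
                               link = c(x = "t1"))),
    m0 = list(p1 = c(1, 3), p2 = c(0, 5)), m0cons = "p1 + p2 = 5")
  blk <- net$init$m0_block
  expect_true(is.na(net$init$m0["p1"]))
  expect_true(is.na(net$init$m0["p2"]))
  # rows: two bounds per place plus the two rows of the equality relation
  expect_equal(nrow(blk$J), 6L)
  m <- c(p1 = 2, p2 = 3)
  expect_true(all(blk$J %*% m <= blk$K + 1e-12))
  m_bad <- c(p1 = 4, p2 = 1)
  expect_false(all(blk$J %*% m_bad <= blk$K + 1e-12))
})

test_that("unknown identifiers are rejected at construction", {
  expect_error(fn_net(places = "p1", transitions = "t1",
                      m0 = list(p9 = 1)), "unknown place")
  expect_error(
    fn_net(places = "p1", transitions = "t1",
           ehandlers = list(v = fn_eh(from = c(a = "p1"), rel = "a = q"))),
    "unknown label 'q'")
})
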