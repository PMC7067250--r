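# Relation-string parsing into constraint rows and handler blocks.

test_that("linear expressions parse coefficients, signs and constants", {
  e <- parse_linear_expr("2x")
  expect_equal(e$coefs, c(x = 2))
  e <- parse_linear_expr("0.9a - b + 3")
  expect_equal(e$coefs, c(a = 0.9, b = -1))
  expect_equal(e$const, 3)
  e <- parse_linear_expr("2*x + x")
  expect_equal(e$coefs, c(x = 3))
  expect_error(parse_linear_expr("(a + b)"), "cannot parse")
  expect_error(parse_linear_expr(""), "empty")
})

test_that("chains split pairwise and equalities become two rows", {
  rr <- relation_rows("x <= b <= 2x", labels = c("b", "x"))
  expect_equal(nrow(rr$M), 2L)
  # x - b <= 0 ; b - 2x <= 0
  expect_equal(unname(rr$M), rbind(c(-1, 1), c(1, -2)))
  rr <- relation_rows("a = b", labels = c("a", "b"))
  expect_equal(unname(rr$M), rbind(c(1, -1), c(-1, 1)))
  expect_error(relation_rows("a = z", labels = c("a", "b")),
               "unknown label 'z'")
  expect_error(relation_rows("a", labels = "a"), "no comparison")
})

test_that("handler blocks match the worked two-handler example", {
  net <- fn_event_choice()
  b1 <- net$eblocks$v1
  expect_equal(unname(b1$left), rbind(c(1, -1), c(-1, 1)))
  expect_equal(unname(b1$right), cbind(c(0, 0)))  # fake transition column
  b2 <- net$eblocks$v2
  expect_equal(unname(b2$left),
               rbind(c(1, 0), c(-1, 0), c(0, -1), c(0, 1)))
  expect_equal(unname(b2$right), cbind(c(1, -1, -1, 2)))
  expect_equal(b2$left_index, c("(p1,v2)", "(v2,p3)"))
  expect_equal(b2$right_index, "{t1,v2}")
})

test_that("an empty relation set yields the all-labels-equal block", {
  net <- fn_net(
    places = c("p1", "p2"), transitions = "t1",
    ehandlers = list(v = fn_eh(from = c(a = "p1"), to = c(b = "p2"),
                               link = c(x = "t1"))))
  blk <- net$eblocks$v
  # chain a = b = x: every row pairs adjacent labels
  expect_equal(nrow(blk$left), 4L)
  dm <- c(1, 1)
  expect_true(all(blk$left %*% dm <= blk$right %*% 1))
  expect_false(all(blk$left %*% c(2, 1) <= blk$right %*% 1))
})

test_that("constant terms are rejected in handler relations", {
  expect_error(
    fn_net(places = c("p1", "p2"), transitions = "t1",
           ehandlers = list(v = fn_eh(from = c(a = "p1"), to = c(b = "p2"),
                                      link = c(x = "t1"),
                                      rel = "a = b + 1"))),
    "constant")
})

test_that("each handler row only references its own connections", {
  for (net in list(fn_observer_net(), fn_resource_allocation(),
                   fn_uncertain_linear(), fn_control_loop())) {
    G <- global_blocks(net)
    r0 <- 0L
    for (h in names(net$eblocks)) {
      blk <- net$eblocks[[h]]
      rows <- r0 + seq_len(nrow(blk$left))
      own <- net$EVP$id[net$EVP$handler == h]
      other <- setdiff(colnames(G$A), own)
      if (length(other) && length(rows)) {
        expect_true(all(G$A[rows, other] == 0))
      }
      r0 <- r0 + nrow(blk$left)
    }
  }
})
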