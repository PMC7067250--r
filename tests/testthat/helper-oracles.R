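# Independent oracles used by the tests.  These deliberately avoid the
# package's own assembly/enumeration code paths: blocks are rebuilt by
# per-entry loops, reachable state sets by purpose-written recursions over
# the semantics of one concrete net.

# Entry-by-entry reconstruction of the global block-diagonal matrices.
oracle_global_blocks <- function(net) {
  build <- function(blocks, index_df, side_cols) {
    nr <- 0L
    for (b in blocks) nr <- nr + nrow(b$left)
    M <- matrix(0, nr, length(side_cols), dimnames = list(NULL, side_cols))
    r0 <- 0L
    for (h in names(blocks)) {
      b <- blocks[[h]]
      loc <- if (identical(side_cols, colnames(M))) NULL else NULL
      for (i in seq_len(nrow(b$left))) {
        for (j in seq_along(b$left_index)) {
          M[r0 + i, b$left_index[j]] <- b$left[i, j]
        }
      }
      r0 <- r0 + nrow(b$left)
    }
    M
  }
  build_right <- function(blocks, side_cols) {
    nr <- 0L
    for (b in blocks) nr <- nr + nrow(b$right)
    M <- matrix(0, nr, length(side_cols), dimnames = list(NULL, side_cols))
    r0 <- 0L
    for (h in names(blocks)) {
      b <- blocks[[h]]
      for (i in seq_len(nrow(b$right))) {
        for (j in seq_along(b$right_index)) {
          M[r0 + i, b$right_index[j]] <- b$right[i, j]
        }
      }
      r0 <- r0 + nrow(b$right)
    }
    M
  }
  list(
    A = build(net$eblocks, net$EVP, net$EVP$id),
    B = build_right(net$eblocks, net$EVT$id),
    C = build(net$sblocks, net$EST, net$EST$id),
    D = build_right(net$sblocks, net$ESP$id)
  )
}

# Exhaustive recursive enumeration (with memoization) of the states of the
# three-place choice net reachable by unit firings.  Semantics hard-coded
# from first principles: the silent handler moves one token p1 -> p2; the
# action handler consumes one action and one token of p1 and produces one
# OR two tokens in p3.
oracle_choice_reach <- function(m0, actions) {
  seen <- new.env(parent = emptyenv())
  key <- function(s) paste(s, collapse = ",")
  rec <- function(m1, m2, m3, a) {
    k <- key(c(m1, m2, m3, a))
    if (!is.null(seen[[k]])) return(invisible())
    seen[[k]] <- c(m1, m2, m3, a)
    if (m1 >= 1) rec(m1 - 1, m2 + 1, m3, a)            # silent move
    if (m1 >= 1 && a >= 1) {
      rec(m1 - 1, m2, m3 + 1, a - 1)                   # produce one
      rec(m1 - 1, m2, m3 + 2, a - 1)                   # produce two
    }
  }
  rec(m0[1], m0[2], m0[3], actions)
  out <- do.call(rbind, as.list(seen))
  rownames(out) <- NULL
  out[order(out[, 1], out[, 2], out[, 3], out[, 4]), , drop = FALSE]
}

# Brute-force feasibility of the printed event block of the choice net:
# which integer values of the production dm[(v2,p3)] admit an integer
# solution with sigma[t1] = 1 executed and m0 = (2,0,0)?
oracle_choice_production_values <- function() {
  feas <- integer(0)
  for (aE in 0:1) {          # at most sigma = 1 action executed
    for (dmv1 in 0:2) {      # silent handler moves dmv1 tokens (a = b)
      for (dmv2in in 0:2) {  # tokens consumed by the action handler
        for (dmv2out in 0:4) {
          ok <- dmv2in == aE &&               # a = x
            dmv2out >= aE && dmv2out <= 2 * aE &&  # x <= b <= 2x
            dmv1 + dmv2in <= 2                # p1 availability
          if (ok) feas <- c(feas, dmv2out)
        }
      }
    }
  }
  sort(unique(feas))
}

sorted_marking_matrix <- function(tb) {
  m <- as.matrix(as.data.frame(tb))
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

# Fix the control input of the control-loop net to a constant and return a
# copy whose default-intensity block pins every transition.
fixed_control_net <- function(u) {
  net <- fn_control_loop()
  ids <- colnames(net$init$lambda0_block$J)
  rows <- list()
  K <- numeric(0)
  for (tt in ids) {
    val <- if (tt == "t4") u else 0
    r <- stats::setNames(numeric(length(ids)), ids)
    r[tt] <- 1
    rows[[length(rows) + 1L]] <- r
    K <- c(K, val)
    r[tt] <- -1
    rows[[length(rows) + 1L]] <- r
    K <- c(K, -val)
  }
  net$init$lambda0_block <- list(J = do.call(rbind, rows), K = K)
  net
}

# Closed-form solution of the cycle's linear dynamics dm/dt = M m + b u.
cycle_closed_form <- function(m0, u, t_end) {
  M <- matrix(c(-1, 1, 0, 0, -1, 1, 1, 0, -1), 3, 3)
  b <- c(-1, 3, -2) * u
  Aug <- rbind(cbind(M, diag(3)), matrix(0, 3, 6))
  ex <- as.matrix(Matrix::expm(Aug * t_end))
  as.numeric(ex[1:3, 1:3] %*% m0 + ex[1:3, 4:6] %*% b)
}

solve_fixed <- function(u, m0, dt, t_end) {
  net <- fixed_control_net(u)
  prob <- transcribe(net, seq(0, t_end, by = dt), m0 = m0,
                     forced_exec = attr(fn_control_loop(), "forced_exec"),
                     forced_active = attr(fn_control_loop(),
                                          "forced_active"))
  solve_program_fn(prob)
}

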