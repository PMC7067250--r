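# Discrete execution of event nets: enabling checks and firings of event
# handlers, breadth-first reachability graphs under unit-amount integer
# firings, and observation-consistent marking sets.

#' Construct an event-net state
#'
#' @param net an `fn_net`.
#' @param sigma named vector of produced actions per (real) transition.
#' @param m named marking vector (defaults to the net's exact `m0`).
#' @param a_T available actions (defaults to `sigma`: nothing executed yet).
#' @param a_E executed actions per event edge (defaults to 0).
#' @param dm cumulative token changes per event arc (defaults to 0).
#' @return An object of class `fn_event_state`.
#' @export
event_state <- function(net, sigma, m = NULL, a_T = NULL, a_E = NULL,
                        dm = NULL) {
  full <- function(x, ids, default = 0) {
    y <- stats::setNames(rep(default, length(ids)), ids)
    if (!is.null(x)) {
      bad <- setdiff(names(x), ids)
      if (length(bad)) stop("unknown identifier: ", bad[1], call. = FALSE)
      y[names(x)] <- as.numeric(x)
    }
    y
  }
  if (is.null(m)) {
    m <- net$init$m0
    if (anyNA(m)) stop("net has interval m0; supply m explicitly",
                       call. = FALSE)
  }
  st <- list(
    sigma = full(sigma, net$all_transitions),
    a_T = full(if (is.null(a_T)) sigma else a_T, net$all_transitions),
    a_E = full(a_E, net$EVT$id),
    dm = full(dm, net$EVP$id),
    m = full(m, net$places)
  )
  structure(st, class = "fn_event_state")
}

# Interval propagation of upper bounds for x >= 0 subject to M x <= rhs.
# Returns per-variable upper bounds (possibly Inf when the rows do not
# bound a variable).
propagate_bounds <- function(M, rhs, ub = rep(Inf, ncol(M)),
                             passes = 25L) {
  if (nrow(M) == 0L) return(ub)
  for (pass in seq_len(passes)) {
    changed <- FALSE
    for (r in seq_len(nrow(M))) {
      row <- M[r, ]
      pos <- which(row > 0)
      neg <- which(row < 0)
      for (e in pos) {
        slack <- rhs[r] - sum(row[neg] * ub[neg])
        if (!is.finite(slack)) next
        cand <- slack / row[e]
        if (cand < ub[e] - 1e-12) {
          ub[e] <- max(cand, 0)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  ub
}

# Enumerate nonnegative integer vectors x (length n) with componentwise
# bounds ub, satisfying M x <= rhs; DFS with final row check.
enum_integer_box <- function(M, rhs, ub) {
  n <- length(ub)
  if (any(!is.finite(ub))) {
    stop("cannot bound integer search; net admits unbounded token changes",
         call. = FALSE)
  }
  ub <- floor(ub + 1e-9)
  sols <- list()
  x <- integer(n)
  rec <- function(i) {
    if (i > n) {
      if (nrow(M) == 0L || all(M %*% x <= rhs + 1e-9)) {
        sols[[length(sols) + 1L]] <<- x
      }
      return(invisible())
    }
    for (v in 0:ub[i]) {
      x[i] <<- v
      rec(i + 1L)
    }
    x[i] <<- 0L
  }
  rec(1L)
  sols
}

# All integer firing witnesses of one handler at a state.
# unit = TRUE restricts to the graph-generation convention: a_f in {0,1}
# with at least one 1, or (for silent handlers) total consumption 1.
handler_witnesses <- function(net, handler, a_T, m, unit = FALSE) {
  blk <- net$eblocks[[handler]]
  if (is.null(blk)) stop("unknown handler: ", handler, call. = FALSE)
  arcs <- net$EVP[net$EVP$handler == handler, , drop = FALSE]
  edges <- net$EVT[net$EVT$handler == handler, , drop = FALSE]
  silent <- all(edges$fake)
  # action ranges per edge
  amax <- ifelse(edges$fake, 0, floor(pmax(a_T[edges$transition], 0) + 1e-9))
  if (unit) amax <- pmin(amax, 1)
  agrid <- do.call(expand.grid, lapply(amax, function(u) 0:u))
  out <- list()
  for (g in seq_len(nrow(agrid))) {
    a_f <- as.numeric(agrid[g, ])
    names(a_f) <- edges$id
    if (unit && !silent && sum(a_f) == 0) next
    # bound dm_f: handler rows plus token availability on input arcs
    ubs <- rep(Inf, nrow(arcs))
    inn <- arcs$dir == "in"
    ubs[inn] <- floor(pmax(m[arcs$place[inn]], 0) + 1e-9)
    rhs <- as.numeric(blk$right %*% a_f)
    ubs <- propagate_bounds(blk$left, rhs, ubs)
    if (unit && silent) ubs[inn] <- pmin(ubs[inn], 1)
    dms <- enum_integer_box(blk$left, rhs, ubs)
    for (dm_f in dms) {
      names(dm_f) <- arcs$id
      if (sum(a_f) + sum(dm_f) == 0) next
      if (unit && silent && sum(dm_f[inn]) != 1) next
      out[[length(out) + 1L]] <- list(a_f = a_f, dm_f = dm_f)
    }
  }
  out
}

#' Enabling check for an event handler
#'
#' A handler is enabled when a firing witness exists: executed amounts
#' bounded by the available actions of the linked transitions, token
#' changes satisfying the handler block and bounded by the tokens present
#' in the input places, with a strictly positive total change.
#'
#' @param net an `fn_net`.
#' @param state an `fn_event_state`.
#' @param handler handler identifier.
#' @param integer when `TRUE` (default) the witness components must be
#'   integers (witnesses are enumerated); otherwise a linear program decides
#'   enabling with strictness threshold `eps`.
#' @param eps strictness for the continuous mode (default `1e-9`).
#' @return A witness `list(a_f, dm_f)` or `NULL` when not enabled.
#' @export
is_enabled <- function(net, state, handler, integer = TRUE, eps = 1e-9) {
  stopifnot(inherits(state, "fn_event_state"))
  if (integer) {
    w <- handler_witnesses(net, handler, state$a_T, state$m)
    return(if (length(w)) w[[1]] else NULL)
  }
  blk <- net$eblocks[[handler]]
  if (is.null(blk)) stop("unknown handler: ", handler, call. = FALSE)
  arcs <- net$EVP[net$EVP$handler == handler, , drop = FALSE]
  edges <- net$EVT[net$EVT$handler == handler, , drop = FALSE]
  na <- nrow(arcs)
  ne <- nrow(edges)
  cs <- new_consys()
  cs_add_var(cs, "a_f", edges$id)
  cs_add_var(cs, "dm_f", arcs$id)
  amax <- ifelse(edges$fake, 0, pmax(state$a_T[edges$transition], 0))
  cs_add_rows(cs, list(a_f = diag(ne)), "<=", amax)
  if (nrow(blk$left)) {
    cs_add_rows(cs, list(dm_f = blk$left, a_f = -blk$right), "<=",
                numeric(nrow(blk$left)))
  }
  inn <- which(arcs$dir == "in")
  if (length(inn)) {
    cs_add_rows(cs, list(dm_f = diag(na)[inn, , drop = FALSE]), "<=",
                pmax(state$m[arcs$place[inn]], 0))
  }
  # cap to keep the LP bounded; enabling only needs some positive witness
  cs_add_rows(cs, list(dm_f = matrix(1, 1, na), a_f = matrix(1, 1, ne)),
              "<=", 1e6)
  r <- cs_optimize(cs, c(a_f = 1, dm_f = 1), sense = "max")
  if (r$status != "optimal" || r$value < eps) return(NULL)
  list(a_f = r$solution$a_f, dm_f = r$solution$dm_f)
}

#' Fire an event handler
#'
#' Applies one firing with the given witness: available actions decrease,
#' executed actions and cumulative token changes increase, input places
#' lose and output places gain the witnessed amounts.  All other state
#' components are unchanged.
#'
#' @param net an `fn_net`.
#' @param state an `fn_event_state`.
#' @param handler handler identifier.
#' @param witness list with `a_f` (named by the handler's edges) and `dm_f`
#'   (named by the handler's arcs); e.g. from [is_enabled()].
#' @return The new `fn_event_state`.
#' @export
fire <- function(net, state, handler, witness) {
  stopifnot(inherits(state, "fn_event_state"))
  blk <- net$eblocks[[handler]]
  if (is.null(blk)) stop("unknown handler: ", handler, call. = FALSE)
  arcs <- net$EVP[net$EVP$handler == handler, , drop = FALSE]
  edges <- net$EVT[net$EVT$handler == handler, , drop = FALSE]
  a_f <- stats::setNames(rep(0, nrow(edges)), edges$id)
  a_f[names(witness$a_f)] <- witness$a_f
  dm_f <- stats::setNames(rep(0, nrow(arcs)), arcs$id)
  dm_f[names(witness$dm_f)] <- witness$dm_f
  if (any(a_f < -1e-9) || any(dm_f < -1e-9)) {
    stop("invalid witness: negative component", call. = FALSE)
  }
  for (i in seq_len(nrow(edges))) {
    if (!edges$fake[i] &&
        a_f[i] > state$a_T[edges$transition[i]] + 1e-9) {
      stop(sprintf(
        "invalid witness: executed amount on %s exceeds available actions of %s",
        edges$id[i], edges$transition[i]), call. = FALSE)
    }
    if (edges$fake[i] && a_f[i] > 1e-9) {
      stop("invalid witness: silent handlers execute no actions",
           call. = FALSE)
    }
  }
  lhs <- blk$left %*% dm_f
  rhs <- blk$right %*% a_f
  if (any(lhs > rhs + 1e-9)) {
    bad <- which(lhs > rhs + 1e-9)[1]
    stop(sprintf("invalid witness: handler row %d of '%s' violated (%g > %g)",
                 bad, handler, lhs[bad], rhs[bad]), call. = FALSE)
  }
  inn <- arcs$dir == "in"
  if (any(dm_f[inn] > state$m[arcs$place[inn]] + 1e-9)) {
    stop("invalid witness: consumption exceeds tokens present",
         call. = FALSE)
  }
  st <- state
  for (i in which(!edges$fake)) {
    tj <- edges$transition[i]
    st$a_T[tj] <- st$a_T[tj] - a_f[i]
    st$a_E[edges$id[i]] <- st$a_E[edges$id[i]] + a_f[i]
  }
  for (i in seq_len(nrow(arcs))) {
    st$dm[arcs$id[i]] <- st$dm[arcs$id[i]] + dm_f[i]
    pi <- arcs$place[i]
    st$m[pi] <- st$m[pi] + if (arcs$dir[i] == "in") -dm_f[i] else dm_f[i]
  }
  st
}

#' Reachability graph under unit-amount integer firings
#'
#' Breadth-first closure of the `(marking, available-actions)` state under
#' firings in which each edge executes 0 or 1 action (at least one action
#' for handlers linked to transitions) and silent handlers consume exactly
#' one token.  Nondeterministic production is enumerated over the integer
#' solutions of each handler block.
#'
#' @param net an `fn_net`.
#' @param sigma named integer vector of initially available actions.
#' @param m0 named integer marking (defaults to the net's exact `m0`).
#' @param max_nodes truncation bound on the number of distinct states.
#' @return A list of class `fn_reach_graph`: `m` and `a_T` matrices (one row
#'   per node), `edges` tibble (`from`, `to`, `handler`) and a `truncated`
#'   flag.
#' @export
reachability_graph <- function(net, sigma, m0 = NULL, max_nodes = 1000L) {
  if (is.null(m0)) {
    m0 <- net$init$m0
    if (anyNA(m0)) stop("net has interval m0; supply m0 explicitly",
                        call. = FALSE)
  }
  st0 <- event_state(net, sigma = sigma, m = m0)
  if (any(abs(st0$m - round(st0$m)) > 1e-9) ||
      any(abs(st0$sigma - round(st0$sigma)) > 1e-9)) {
    stop("reachability_graph requires integer sigma and m0", call. = FALSE)
  }
  key <- function(m, a) paste(c(round(m), round(a)), collapse = ",")
  nodes_m <- list(st0$m)
  nodes_a <- list(st0$a_T)
  seen <- stats::setNames(1L, key(st0$m, st0$a_T))
  edges <- list()
  queue <- 1L
  truncated <- FALSE
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    m <- nodes_m[[i]]
    aT <- nodes_a[[i]]
    for (h in names(net$ehandlers)) {
      for (w in handler_witnesses(net, h, aT, m, unit = TRUE)) {
        arcs <- net$EVP[net$EVP$handler == h, , drop = FALSE]
        edgesh <- net$EVT[net$EVT$handler == h, , drop = FALSE]
        m2 <- m
        for (k in seq_len(nrow(arcs))) {
          pi <- arcs$place[k]
          m2[pi] <- m2[pi] +
            if (arcs$dir[k] == "in") -w$dm_f[k] else w$dm_f[k]
        }
        a2 <- aT
        for (k in which(!edgesh$fake)) {
          a2[edgesh$transition[k]] <- a2[edgesh$transition[k]] - w$a_f[k]
        }
        if (any(m2 < -1e-9)) next
        kk <- key(m2, a2)
        j <- seen[kk]
        if (is.na(j)) {
          if (length(nodes_m) >= max_nodes) {
            truncated <- TRUE
            next
          }
          nodes_m[[length(nodes_m) + 1L]] <- m2
          nodes_a[[length(nodes_a) + 1L]] <- a2
          j <- length(nodes_m)
          seen[kk] <- j
          queue <- c(queue, j)
        }
        edges[[length(edges) + 1L]] <-
          data.frame(from = i, to = j, handler = h,
                     stringsAsFactors = FALSE)
      }
    }
  }
  ed <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(from = integer(0), to = integer(0), handler = character(0))
  structure(list(
    m = do.call(rbind, nodes_m),
    a_T = do.call(rbind, nodes_a),
    edges = tibble::as_tibble(ed),
    truncated = truncated
  ), class = "fn_reach_graph")
}

#' @export
print.fn_reach_graph <- function(x, ...) {
  cat(sprintf("Reachability graph: %d nodes, %d arcs%s\n", nrow(x$m),
              nrow(x$edges), if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Export a reachability graph in DOT format
#'
#' @param graph an `fn_reach_graph`.
#' @param file optional path; when `NULL` the DOT text is returned.
#' @return The DOT source, invisibly when written to a file.
#' @export
reach_graph_dot <- function(graph, file = NULL) {
  lab <- apply(graph$m, 1, function(r) paste(round(r), collapse = " "))
  lines <- c(
    "digraph reachability {",
    sprintf('  n%d [label="(%s)"];', seq_along(lab), lab),
    sprintf('  n%d -> n%d [label="%s"];', graph$edges$from, graph$edges$to,
            graph$edges$handler),
    "}"
  )
  txt <- paste(lines, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Enumerate all integer solutions (a_E, dm, m) of the event state equations
# with sigma and a_T fixed.  Returns a list of named marking vectors.
enumerate_event_solutions <- function(net, sigma, a_T, m0) {
  st <- event_state(net, sigma = sigma, m = m0, a_T = a_T)
  executed <- st$sigma - st$a_T
  if (any(executed < -1e-9)) return(list())
  executed <- round(executed)
  # distribute executed actions of each transition over its edges
  per_trans <- lapply(net$all_transitions, function(tj) {
    eids <- net$EVT$id[net$EVT$transition == tj]
    if (length(eids) == 0L) {
      if (executed[tj] > 0) return(NULL)  # infeasible
      return(list(stats::setNames(numeric(0), character(0))))
    }
    combos <- compositions(executed[tj], length(eids))
    lapply(combos, function(cc) stats::setNames(cc, eids))
  })
  if (any(vapply(per_trans, is.null, TRUE))) return(list())
  S <- structure_matrices(net)
  G <- global_blocks(net)
  markings <- list()
  rec_aE <- function(ti, acc) {
    if (ti > length(per_trans)) {
      a_E <- stats::setNames(numeric(nrow(net$EVT)), net$EVT$id)
      a_E[names(acc)] <- acc
      # bound and enumerate dm per handler, then combine subject to m >= 0
      per_handler <- list()
      M_all <- rbind(G$A, -S$Z_m)
      rhs_all <- c(as.numeric(G$B %*% a_E), st$m)
      ub <- propagate_bounds(M_all, rhs_all, rep(Inf, nrow(net$EVP)))
      for (h in names(net$ehandlers)) {
        sel <- net$EVP$handler == h
        blk <- net$eblocks[[h]]
        rhs <- as.numeric(blk$right %*%
                            a_E[net$EVT$id[net$EVT$handler == h]])
        sols <- enum_integer_box(blk$left, rhs, ub[sel])
        if (length(sols) == 0L) return(invisible())
        per_handler[[h]] <- sols
      }
      combine <- function(hi, dm) {
        if (hi > length(per_handler)) {
          m <- st$m + as.numeric(S$Z_m %*% dm)
          if (all(m >= -1e-9)) {
            markings[[length(markings) + 1L]] <<- round(m)
          }
          return(invisible())
        }
        h <- names(net$ehandlers)[hi]
        sel <- which(net$EVP$handler == h)
        for (s in per_handler[[h]]) {
          dm[sel] <- s
          combine(hi + 1L, dm)
        }
      }
      combine(1L, numeric(nrow(net$EVP)))
      return(invisible())
    }
    for (cc in per_trans[[ti]]) rec_aE(ti + 1L, c(acc, cc))
  }
  rec_aE(1L, stats::setNames(numeric(0), character(0)))
  markings <- lapply(markings, function(m) {
    names(m) <- net$places
    m
  })
  markings[!duplicated(vapply(markings, paste, "", collapse = ","))]
}

compositions <- function(total, k) {
  if (k == 1L) return(list(total))
  out <- list()
  for (first in 0:total) {
    for (rest in compositions(total - first, k - 1L)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

#' Observation-consistent markings
#'
#' Computes the set of markings consistent with an observation: `sigma`
#' actions were produced per transition and `a_T` of them are still
#' unexecuted.  Under integrality the integer solutions of the event
#' state equations are enumerated exactly (`method = "equations"`), or the
#' unit-firing reachability graph is filtered for nodes with the observed
#' leftover actions (`method = "graph"`).  Without integrality the fixed
#' polytope itself is returned as the (projection) description.
#'
#' @param net an `fn_net`.
#' @param sigma named vector of produced actions per transition.
#' @param a_T named vector of leftover (unexecuted) actions.
#' @param m0 named initial marking (defaults to the net's exact `m0`).
#' @param integer enumerate integer solutions (default `TRUE`).
#' @param method `"equations"` (state-equation enumeration) or `"graph"`
#'   (reachability-graph filter).
#' @return A tibble with one row per consistent marking (columns are
#'   places), or an `fn_consys` when `integer = FALSE`.
#' @export
consistent_markings <- function(net, sigma, a_T, m0 = NULL,
                                integer = TRUE,
                                method = c("equations", "graph")) {
  method <- match.arg(method)
  if (is.null(m0)) {
    m0 <- net$init$m0
    if (anyNA(m0)) stop("net has interval m0; supply m0 explicitly",
                        call. = FALSE)
  }
  if (!integer) {
    return(event_polytope(net, sigma = sigma, a_T = a_T))
  }
  if (method == "equations") {
    ms <- enumerate_event_solutions(net, sigma, a_T, m0)
  } else {
    g <- reachability_graph(net, sigma = sigma, m0 = m0)
    st <- event_state(net, sigma = sigma, m = m0, a_T = a_T)
    keep <- apply(g$a_T, 1, function(r) all(abs(r - st$a_T) < 1e-9))
    ms <- lapply(which(keep), function(i) {
      stats::setNames(g$m[i, ], net$places)
    })
    ms <- ms[!duplicated(vapply(ms, paste, "", collapse = ","))]
  }
  if (length(ms) == 0L) {
    out <- matrix(numeric(0), 0, length(net$places),
                  dimnames = list(NULL, net$places))
    return(tibble::as_tibble(as.data.frame(out)))
  }
  tibble::as_tibble(as.data.frame(do.call(rbind, ms)))
}
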