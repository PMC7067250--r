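# Flexible Net model: tripartite structure (places, transitions, handlers)
# plus per-handler linear constraint blocks.
#
# An event handler v links transitions to places.  Its block (A_k, B_k)
# relates token changes on its place arcs (columns of A_k) to executed
# actions on its transition edges (columns of B_k) by A_k dm <= B_k a.
# An intensity handler s links places to transitions.  Its block (C_l, D_l)
# relates intensity changes on its transition arcs to active tokens on its
# place edges by C_l dl <= D_l mu.

#' Declare an event handler
#'
#' Event handlers turn executed actions into token consumption and
#' production.  Arcs from places carry consumed tokens, arcs to places carry
#' produced tokens, and undirected edges to transitions carry executed
#' actions.  Every connection is given a single-letter (or longer) label that
#' the relation strings refer to.
#'
#' @param from named character vector: labels -> places whose tokens the
#'   handler consumes (arcs place -> handler).
#' @param to named character vector: labels -> places in which the handler
#'   produces tokens (arcs handler -> place).
#' @param link named character vector: labels -> transitions whose actions
#'   the handler executes (undirected edges).
#' @param rel character vector of linear relation strings over the labels,
#'   e.g. `c("a = x", "x <= b <= 2x")`.  When empty, all labels are chained
#'   as equalities (the usual 1:1 stoichiometry shorthand).
#' @return An object of class `fn_eh`.
#' @seealso [fn_sh()], [fn_net()]
#' @export
fn_eh <- function(from = character(0), to = character(0),
                  link = character(0), rel = character(0)) {
  structure(list(from = from, to = to, link = link, rel = rel),
            class = "fn_eh")
}

#' Declare an intensity handler
#'
#' Intensity handlers turn active tokens into transition speed-ups and
#' slow-downs.  Arcs from transitions carry intensity taken away from the
#' transition, arcs to transitions carry intensity added, and undirected
#' edges to places carry the active tokens the handler is using.
#'
#' @param from named character vector: labels -> transitions whose intensity
#'   the handler decreases (arcs transition -> handler).
#' @param to named character vector: labels -> transitions whose intensity
#'   the handler increases (arcs handler -> transition).
#' @param link named character vector: labels -> places whose tokens the
#'   handler can activate (undirected edges).
#' @param rel character vector of linear relation strings over the labels.
#'   When empty, all labels are chained as equalities.
#' @return An object of class `fn_sh`.
#' @seealso [fn_eh()], [fn_net()]
#' @export
fn_sh <- function(from = character(0), to = character(0),
                  link = character(0), rel = character(0)) {
  structure(list(from = from, to = to, link = link, rel = rel),
            class = "fn_sh")
}

arc_id <- function(a, b) sprintf("(%s,%s)", a, b)
edge_id <- function(a, b) sprintf("{%s,%s}", a, b)

#' Build a Flexible Net
#'
#' Assembles the tripartite structure, parses every handler's relation
#' strings into its constraint block, and attaches initial conditions
#' (point values or interval/linear constraint blocks) for the marking and
#' the default intensities.
#'
#' Event handlers without a transition edge are silent: a fake transition
#' (named `".f<handler>"`, zero default intensity, zero action production)
#' is inserted so that the matrix forms stay rectangular; the corresponding
#' column of the global B matrix is zero.  Intensity handlers without a
#' place edge get an analogous zero column in D.
#'
#' @param places character vector of place identifiers (declaration order is
#'   the canonical index order).
#' @param transitions character vector of transition identifiers.
#' @param ehandlers named list of [fn_eh()] objects.
#' @param shandlers named list of [fn_sh()] objects.
#' @param m0 named list/vector of initial markings: a single number for an
#'   exact value or a length-2 numeric `c(lo, hi)` for an interval.
#'   Omitted places default to 0.
#' @param lambda0 named list/vector of default intensities, same
#'   conventions as `m0`.  Omitted transitions default to 0.
#' @param m0cons character vector of extra linear relations over place
#'   identifiers constraining the initial marking, e.g. `"p1 + p2 = 5"`.
#' @param l0cons character vector of extra linear relations over transition
#'   identifiers constraining the default intensities.
#' @return An object of class `fn_net`.
#' @examples
#' net <- fn_net(
#'   places = c("p1", "p2", "p3"),
#'   transitions = "t1",
#'   ehandlers = list(
#'     v1 = fn_eh(from = c(a = "p1"), to = c(b = "p2"), rel = "a = b"),
#'     v2 = fn_eh(from = c(a = "p1"), to = c(b = "p3"), link = c(x = "t1"),
#'                rel = c("a = x", "x <= b <= 2x"))
#'   ),
#'   m0 = list(p1 = 2)
#' )
#' global_blocks(net)$A
#' @export
fn_net <- function(places, transitions = character(0),
                   ehandlers = list(), shandlers = list(),
                   m0 = list(), lambda0 = list(),
                   m0cons = character(0), l0cons = character(0)) {
  stopifnot(is.character(places))
  if (length(places) + length(transitions) == 0L) {
    stop("a net needs at least one place or transition", call. = FALSE)
  }
  if (anyDuplicated(c(places, transitions))) {
    stop("duplicate place/transition identifiers", call. = FALSE)
  }
  net <- list(
    places = places,
    transitions = transitions,
    fake_transitions = character(0),
    ehandlers = ehandlers,
    shandlers = shandlers
  )

  # --- canonical index tables (row order = global column order) ----------
  EVP <- EVT <- EST <- ESP <- NULL
  for (h in names(ehandlers)) {
    eh <- ehandlers[[h]]
    for (i in seq_along(eh$from)) {
      EVP <- rbind(EVP, data.frame(
        id = arc_id(eh$from[[i]], h), handler = h, place = eh$from[[i]],
        dir = "in", label = names(eh$from)[i], stringsAsFactors = FALSE))
    }
    for (i in seq_along(eh$to)) {
      EVP <- rbind(EVP, data.frame(
        id = arc_id(h, eh$to[[i]]), handler = h, place = eh$to[[i]],
        dir = "out", label = names(eh$to)[i], stringsAsFactors = FALSE))
    }
    if (length(eh$link) == 0L) {
      tf <- paste0(".f", h)
      net$fake_transitions <- c(net$fake_transitions, tf)
      EVT <- rbind(EVT, data.frame(
        id = edge_id(tf, h), handler = h, transition = tf,
        label = NA_character_, fake = TRUE, stringsAsFactors = FALSE))
    } else {
      for (i in seq_along(eh$link)) {
        EVT <- rbind(EVT, data.frame(
          id = edge_id(eh$link[[i]], h), handler = h,
          transition = eh$link[[i]], label = names(eh$link)[i],
          fake = FALSE, stringsAsFactors = FALSE))
      }
    }
  }
  for (h in names(shandlers)) {
    sh <- shandlers[[h]]
    for (i in seq_along(sh$from)) {
      EST <- rbind(EST, data.frame(
        id = arc_id(sh$from[[i]], h), handler = h,
        transition = sh$from[[i]], dir = "in", label = names(sh$from)[i],
        stringsAsFactors = FALSE))
    }
    for (i in seq_along(sh$to)) {
      EST <- rbind(EST, data.frame(
        id = arc_id(h, sh$to[[i]]), handler = h, transition = sh$to[[i]],
        dir = "out", label = names(sh$to)[i], stringsAsFactors = FALSE))
    }
    if (length(sh$link) == 0L) {
      ESP <- rbind(ESP, data.frame(
        id = edge_id(paste0(".f", h), h), handler = h,
        place = NA_character_, label = NA_character_, fake = TRUE,
        stringsAsFactors = FALSE))
    } else {
      for (i in seq_along(sh$link)) {
        ESP <- rbind(ESP, data.frame(
          id = edge_id(sh$link[[i]], h), handler = h, place = sh$link[[i]],
          label = names(sh$link)[i], fake = FALSE,
          stringsAsFactors = FALSE))
      }
    }
  }
  empty_df <- function(...) {
    d <- data.frame(..., stringsAsFactors = FALSE)
    d[0L, , drop = FALSE]
  }
  net$EVP <- if (is.null(EVP))
    empty_df(id = "", handler = "", place = "", dir = "", label = "") else EVP
  net$EVT <- if (is.null(EVT))
    empty_df(id = "", handler = "", transition = "", label = "",
             fake = TRUE) else EVT
  net$EST <- if (is.null(EST))
    empty_df(id = "", handler = "", transition = "", dir = "",
             label = "") else EST
  net$ESP <- if (is.null(ESP))
    empty_df(id = "", handler = "", place = "", label = "",
             fake = TRUE) else ESP
  net$all_transitions <- c(transitions, net$fake_transitions)

  # --- per-handler constraint blocks -------------------------------------
  net$eblocks <- lapply(names(ehandlers), function(h) {
    parse_handler_constraints(net, h, kind = "event")
  })
  names(net$eblocks) <- names(ehandlers)
  net$sblocks <- lapply(names(shandlers), function(h) {
    parse_handler_constraints(net, h, kind = "intensity")
  })
  names(net$sblocks) <- names(shandlers)

  # --- initial conditions -------------------------------------------------
  net$init <- build_initial_conditions(places, net$all_transitions,
                                       m0, lambda0, m0cons, l0cons,
                                       net$fake_transitions)
  net$m0cons <- m0cons
  net$l0cons <- l0cons
  net$m0_input <- if (is.numeric(m0)) as.list(m0) else m0
  net$lambda0_input <- if (is.numeric(lambda0)) as.list(lambda0) else
    lambda0
  class(net) <- "fn_net"
  net
}

#' Parse the relation strings of one handler into its constraint block
#'
#' For an event handler the left matrix columns are its place arcs (token
#' changes) and the right matrix columns are its transition edges (executed
#' actions); the block encodes `left %*% dm <= right %*% a`.  For an
#' intensity handler the left columns are its transition arcs (intensity
#' changes) and the right columns its place edges (active tokens).  An empty
#' relation set yields the all-labels-equal block.  Handlers lacking a
#' right-side connection get a single zero column on the right.
#'
#' @param net an `fn_net` (may be mid-construction; only index tables used).
#' @param handler handler identifier.
#' @param kind `"event"` or `"intensity"`.
#' @return list with `left`, `right` matrices and `left_index`,
#'   `right_index` identifier vectors.
#' @export
parse_handler_constraints <- function(net, handler,
                                      kind = c("event", "intensity")) {
  kind <- match.arg(kind)
  if (kind == "event") {
    arcs <- net$EVP[net$EVP$handler == handler, , drop = FALSE]
    edges <- net$EVT[net$EVT$handler == handler, , drop = FALSE]
    spec <- net$ehandlers[[handler]]
  } else {
    arcs <- net$EST[net$EST$handler == handler, , drop = FALSE]
    edges <- net$ESP[net$ESP$handler == handler, , drop = FALSE]
    spec <- net$shandlers[[handler]]
  }
  if (is.null(spec)) stop(sprintf("unknown handler '%s'", handler),
                          call. = FALSE)
  real_edges <- edges[!edges$fake, , drop = FALSE]
  arc_labels <- arcs$label
  edge_labels <- real_edges$label
  labels <- c(arc_labels, edge_labels)
  if (anyDuplicated(labels)) {
    stop(sprintf("handler '%s': duplicate label", handler), call. = FALSE)
  }
  specs <- spec$rel
  if (length(specs) == 0L) specs <- all_equal_specs(labels)
  rr <- relation_rows(specs, labels,
                      where = sprintf(" (handler '%s')", handler))
  if (any(rr$const != 0)) {
    stop(sprintf("handler '%s': constant terms are not allowed in handler relations",
                 handler), call. = FALSE)
  }
  left <- rr$M[, arc_labels, drop = FALSE]
  right <- -rr$M[, edge_labels, drop = FALSE]
  if (ncol(right) == 0L) {
    # fake connection: single zero column
    right <- matrix(0, nrow(left), 1L)
  }
  colnames(left) <- arcs$id
  colnames(right) <- edges$id
  list(left = left, right = right,
       left_index = arcs$id, right_index = edges$id)
}

build_initial_conditions <- function(places, all_transitions, m0, lambda0,
                                     m0cons, l0cons, fake_transitions) {
  pointify <- function(ids, vals, defaults0, cons, what) {
    point <- rep(NA_real_, length(ids))
    names(point) <- ids
    rows <- list()
    rhs <- numeric(0)
    add <- function(co, k) {
      rows[[length(rows) + 1L]] <<- co
      rhs[length(rhs) + 1L] <<- k
    }
    unit <- function(id, s = 1) {
      co <- numeric(length(ids))
      names(co) <- ids
      co[id] <- s
      co
    }
    for (id in ids) {
      v <- vals[[id]]
      if (is.null(v)) {
        if (defaults0) point[id] <- 0
      } else if (length(v) == 1L) {
        point[id] <- as.numeric(v)
      } else if (length(v) == 2L) {
        if (is.finite(min(v))) add(unit(id, -1), -min(v))  # x >= lo
        if (is.finite(max(v))) add(unit(id, 1), max(v))    # x <= hi
      } else {
        stop(sprintf("%s['%s'] must be a value or c(lo, hi)", what, id),
             call. = FALSE)
      }
    }
    # exact values become equality rows in the block as well
    for (id in ids[!is.na(point)]) {
      add(unit(id, 1), point[[id]])
      add(unit(id, -1), -point[[id]])
    }
    if (length(cons)) {
      rr <- relation_rows(cons, ids, where = sprintf(" (%s constraints)", what))
      for (i in seq_len(nrow(rr$M))) add(rr$M[i, ], -rr$const[i])
    }
    J <- if (length(rows)) do.call(rbind, rows) else
      matrix(0, 0, length(ids), dimnames = list(NULL, ids))
    colnames(J) <- ids
    list(point = point, J = J, K = rhs)
  }
  if (is.numeric(m0) && !is.null(names(m0))) m0 <- as.list(m0)
  if (is.numeric(lambda0) && !is.null(names(lambda0))) {
    lambda0 <- as.list(lambda0)
  }
  bad <- setdiff(names(m0), places)
  if (length(bad)) stop(sprintf("m0 given for unknown place '%s'", bad[1]),
                        call. = FALSE)
  bad <- setdiff(names(lambda0), all_transitions)
  if (length(bad)) stop(sprintf("lambda0 given for unknown transition '%s'",
                                bad[1]), call. = FALSE)
  for (tf in fake_transitions) lambda0[[tf]] <- 0
  mb <- pointify(places, m0, defaults0 = TRUE, m0cons, "m0")
  lb <- pointify(all_transitions, lambda0, defaults0 = TRUE, l0cons,
                 "lambda0")
  list(
    m0 = mb$point, m0_block = list(J = mb$J, K = mb$K),
    lambda0 = lb$point, lambda0_block = list(J = lb$J, K = lb$K)
  )
}

#' Construct alternative initial conditions for a net
#'
#' Unlike the conditions built by [fn_net()] (where omitted entries default
#' to zero), entries omitted here are left unconstrained, which is the
#' natural reading for steady-state and what-if analyses.
#'
#' @param net an `fn_net`.
#' @param m0 named list/vector: value or `c(lo, hi)` per constrained place.
#' @param lambda0 named list/vector per constrained transition.
#' @param m0cons,l0cons extra linear relation strings over place /
#'   transition identifiers.
#' @return An initial-conditions list usable as the `init` argument of the
#'   polytope, transcription and steady-state functions.
#' @export
fn_initial_conditions <- function(net, m0 = list(), lambda0 = list(),
                                  m0cons = character(0),
                                  l0cons = character(0)) {
  stopifnot(inherits(net, "fn_net"))
  init <- build_initial_conditions(net$places, net$all_transitions,
                                   m0, lambda0, m0cons, l0cons,
                                   net$fake_transitions)
  # leave unmentioned entries free instead of pinned at zero
  free_m <- setdiff(net$places, names(m0))
  free_l <- setdiff(net$all_transitions,
                    c(names(lambda0), net$fake_transitions))
  init$m0[free_m] <- NA_real_
  init$lambda0[free_l] <- NA_real_
  drop_rows <- function(blk, ids) {
    if (!length(ids) || !nrow(blk$J)) return(blk)
    pin <- vapply(seq_len(nrow(blk$J)), function(r) {
      nz <- which(blk$J[r, ] != 0)
      length(nz) == 1L && colnames(blk$J)[nz] %in% ids &&
        abs(blk$K[r]) < 1e-12
    }, TRUE)
    list(J = blk$J[!pin, , drop = FALSE], K = blk$K[!pin])
  }
  init$m0_block <- drop_rows(init$m0_block, free_m)
  init$lambda0_block <- drop_rows(init$lambda0_block, free_l)
  init
}

#' Validate the structure of a Flexible Net
#'
#' Checks the tripartite-connection rules: no direct place-transition
#' connections, at most one connection per vertex pair, event handlers touch
#' only place arcs and transition edges (and the symmetric rule for
#' intensity handlers), and every relation label maps to exactly one
#' incident connection.
#'
#' @param net an `fn_net`.
#' @return A tibble of violations (empty when the net is valid) with columns
#'   `rule` and `detail`.
#' @export
validate_fn <- function(net) {
  stopifnot(inherits(net, "fn_net"))
  viol <- list()
  note <- function(rule, detail) {
    viol[[length(viol) + 1L]] <<- tibble::tibble(rule = rule, detail = detail)
  }
  all_ids <- c(net$EVP$id, net$EVT$id, net$EST$id, net$ESP$id)
  if (anyDuplicated(all_ids)) {
    for (d in unique(all_ids[duplicated(all_ids)])) {
      note("unique-connection", sprintf("connection %s declared twice", d))
    }
  }
  vertices <- c(net$places, net$all_transitions,
                names(net$ehandlers), names(net$shandlers))
  if (anyDuplicated(vertices)) {
    note("unique-vertex", sprintf(
      "identifier used for more than one vertex: %s",
      paste(unique(vertices[duplicated(vertices)]), collapse = ", ")))
  }
  chk_member <- function(x, set, what, ctx) {
    for (v in setdiff(x, set)) {
      note("membership", sprintf("%s '%s' (%s) is not declared", what, v, ctx))
    }
  }
  for (h in names(net$ehandlers)) {
    eh <- net$ehandlers[[h]]
    chk_member(unlist(c(eh$from, eh$to)), net$places, "place",
               sprintf("event handler %s", h))
    chk_member(unlist(eh$link), net$transitions, "transition",
               sprintf("event handler %s", h))
    # a place<->transition direct link is unrepresentable by construction;
    # the corresponding rule is violated when a handler id collides with a
    # place or transition id (caught above)
  }
  for (h in names(net$shandlers)) {
    sh <- net$shandlers[[h]]
    chk_member(unlist(c(sh$from, sh$to)), net$transitions, "transition",
               sprintf("intensity handler %s", h))
    chk_member(unlist(sh$link), net$places, "place",
               sprintf("intensity handler %s", h))
  }
  if (length(viol)) do.call(rbind, viol) else
    tibble::tibble(rule = character(0), detail = character(0))
}

#' Assemble the global constraint blocks of a net
#'
#' The per-handler blocks are arranged block-diagonally: `A` and `B` collect
#' the event-handler blocks (rows grouped by handler; columns of `A` are the
#' place arcs in canonical order, columns of `B` the transition edges), `C`
#' and `D` collect the intensity-handler blocks likewise.  The global system
#' reads `A %*% dm <= B %*% a_E` and `C %*% dl <= D %*% mu_E`.
#'
#' @param net an `fn_net`.
#' @return list with matrices `A`, `B`, `C`, `D` (dimnames carry the
#'   canonical arc/edge identifiers).
#' @export
global_blocks <- function(net) {
  diag_cat <- function(blocks, side, cols) {
    rows <- sum(vapply(blocks, function(b) nrow(b[[side]]), 0L))
    M <- matrix(0, rows, length(cols), dimnames = list(NULL, cols))
    r <- 0L
    for (b in blocks) {
      m <- b[[side]]
      if (nrow(m)) {
        M[r + seq_len(nrow(m)), colnames(m)] <- m
      }
      r <- r + nrow(m)
    }
    M
  }
  list(
    A = diag_cat(net$eblocks, "left", net$EVP$id),
    B = diag_cat(net$eblocks, "right", net$EVT$id),
    C = diag_cat(net$sblocks, "left", net$EST$id),
    D = diag_cat(net$sblocks, "right", net$ESP$id)
  )
}

#' @export
print.fn_net <- function(x, ...) {
  cat(sprintf(
    "Flexible net: %d places, %d transitions (+%d silent), %d event handler(s), %d intensity handler(s)\n",
    length(x$places), length(x$transitions), length(x$fake_transitions),
    length(x$ehandlers), length(x$shandlers)))
  cat("  places:      ", paste(x$places, collapse = ", "), "\n")
  if (length(x$transitions)) {
    cat("  transitions: ", paste(x$transitions, collapse = ", "), "\n")
  }
  invisible(x)
}
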