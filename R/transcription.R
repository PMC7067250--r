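# Transcription of Flexible-Net dynamics over a time grid into a single
# linear (or convex-quadratic) program.
#
# Intensities, active tokens and idle tokens are interval-constant decision
# variables; action production integrates them exactly under that
# assumption; the intensity-handler rows are coupled to the interval-average
# marking (midpoint rule), which makes the fixed-intensity limit a
# second-order accurate discretization of the underlying ODE.  Uncertain
# parameters (default intensities within their block, handler slack within
# the inequality blocks) are decision variables resolved by the optimizer.

#' Build an objective for transcription or MPC
#'
#' Objective terms reference trajectory quantities by name:
#' `"m[p]"` marking at the final boundary, `"m0[p]"` initial marking,
#' `"mbar[p]"` time-averaged marking over the horizon (interval averages
#' weighted by interval length), `"lbar[t]"` time-averaged intensity,
#' `"lambda0[t]"` default intensity, `"sigma[t]"` produced actions at the
#' final boundary.
#'
#' @param sense `"min"` or `"max"` (quadratic objectives must be `"min"`;
#'   they are sums of squares, so maximisation would be nonconvex).
#' @param linear named numeric vector of linear coefficients.
#' @param quadratic list of `list(term =, target =, weight = 1)` entries,
#'   each contributing `weight * (term - target)^2`.
#' @return An object of class `fn_objective`.
#' @examples
#' fn_objective("max", linear = c("mbar[p2]" = 1, "mbar[p4]" = 0.5))
#' fn_objective("min", quadratic = list(
#'   list(term = "m[p1]", target = 1), list(term = "m[p2]", target = 4)))
#' @export
fn_objective <- function(sense = c("min", "max"), linear = NULL,
                         quadratic = NULL) {
  sense <- match.arg(sense)
  if (!is.null(quadratic) && sense == "max") {
    stop("quadratic objectives must be minimised (convexity)", call. = FALSE)
  }
  structure(list(sense = sense, linear = linear, quadratic = quadratic),
            class = "fn_objective")
}

#' Transcribe a Flexible Net over a time grid
#'
#' Builds the mathematical program whose feasible points are the
#' grid-discretized necessary reachability conditions: per interval the
#' handler blocks couple interval-constant intensity changes to active
#' tokens at the interval-average marking, and per-interval nonnegative
#' increments of executed actions and token changes satisfy the event
#' blocks; boundary states chain the conservation rows of the state
#' equations.
#'
#' @param net an `fn_net`.
#' @param times increasing numeric vector of boundary times starting at 0.
#' @param objective an [fn_objective()] or `NULL` (feasibility).
#' @param forced_exec transitions whose actions must always all be executed.
#' @param forced_active places whose tokens must always all be active.
#' @param m0 optional exact named initial marking overriding the net's
#'   initial-conditions block (used by the MPC driver).
#' @param a_T0 optional named vector of actions already available at time 0.
#' @param init initial conditions; defaults to the net's own.
#' @param integer when `TRUE` all variables are integer (MILP).
#' @return An object of class `fn_program`.
#' @export
transcribe <- function(net, times, objective = NULL,
                       forced_exec = character(0),
                       forced_active = character(0),
                       m0 = NULL, a_T0 = NULL, init = net$init,
                       integer = FALSE) {
  stopifnot(inherits(net, "fn_net"))
  times <- as.numeric(times)
  if (length(times) < 2L || times[1] != 0 || any(diff(times) <= 0)) {
    stop("times must be an increasing grid starting at 0", call. = FALSE)
  }
  bad <- setdiff(forced_exec, net$all_transitions)
  if (length(bad)) stop("unknown transition in forced_exec: ", bad[1],
                        call. = FALSE)
  bad <- setdiff(forced_active, net$places)
  if (length(bad)) stop("unknown place in forced_active: ", bad[1],
                        call. = FALSE)
  n <- length(times) - 1L
  dts <- diff(times)
  S <- structure_matrices(net)
  G <- global_blocks(net)
  P <- net$places
  Tt <- net$all_transitions
  nP <- length(P)
  nT <- length(Tt)
  nEVT <- nrow(net$EVT)
  nEVP <- nrow(net$EVP)
  nEST <- nrow(net$EST)
  nESP <- nrow(net$ESP)
  aT0 <- stats::setNames(numeric(nT), Tt)
  if (!is.null(a_T0)) aT0[names(a_T0)] <- as.numeric(a_T0)

  cs <- new_consys()
  cs_add_var(cs, "lambda0", Tt)
  for (k in 0:n) {
    cs_add_var(cs, paste0("m.", k), P)
    cs_add_var(cs, paste0("sigma.", k), Tt)
    cs_add_var(cs, paste0("aT.", k), Tt)
    cs_add_var(cs, paste0("aE.", k), net$EVT$id)
    cs_add_var(cs, paste0("dm.", k), net$EVP$id)
    cs_add_var(cs, paste0("dsig.", k), net$EST$id)
  }
  for (i in seq_len(n)) {
    cs_add_var(cs, paste0("dlam.", i), net$EST$id)
    cs_add_var(cs, paste0("muE.", i), net$ESP$id)
    cs_add_var(cs, paste0("muP.", i), P)
    cs_add_var(cs, paste0("lam.", i), Tt)
    cs_add_var(cs, paste0("mbar.", i), P)
    cs_add_var(cs, paste0("daE.", i), net$EVT$id)
    cs_add_var(cs, paste0("ddm.", i), net$EVP$id)
  }
  v <- function(stub, k) paste0(stub, ".", k)
  IP <- diag(nP)
  IT <- diag(nT)

  # --- initial boundary ---------------------------------------------------
  cs_fix(cs, "aT.0", aT0)
  for (nm in c("aE.0", "dm.0", "dsig.0")) {
    nv <- cs$vars[[nm]]$n
    if (nv) cs_fix(cs, nm, stats::setNames(numeric(nv), cs$vars[[nm]]$ids))
  }
  if (!is.null(m0)) {
    st <- stats::setNames(numeric(nP), P)
    st[names(m0)] <- as.numeric(m0)
    cs_fix(cs, "m.0", st)
  } else {
    blk <- init$m0_block
    if (nrow(blk$J)) {
      tl <- list(blk$J)
      names(tl) <- "m.0"
      cs_add_rows(cs, tl, "<=", blk$K)
    }
  }
  lblk <- init$lambda0_block
  if (nrow(lblk$J)) cs_add_rows(cs, list(lambda0 = lblk$J), "<=", lblk$K)

  # --- boundary equations (k = 0..n) -------------------------------------
  for (k in 0:n) {
    tl <- list(IT, -IT * times[k + 1], -S$Z_lambda)
    names(tl) <- c(v("sigma", k), "lambda0", v("dsig", k))
    cs_add_rows(cs, tl, "=", aT0)
    tl <- list(IT, -IT, -S$Y_sigma)
    names(tl) <- c(v("sigma", k), v("aT", k), v("aE", k))
    cs_add_rows(cs, tl, "=", numeric(nT))
    if (k > 0 && nP) {  # at k = 0 the row is m.0 = m.0 (dm.0 = 0)
      tl <- list(IP, -IP, -S$Z_m)
      names(tl) <- c(v("m", k), "m.0", v("dm", k))
      cs_add_rows(cs, tl, "=", numeric(nP))
    }
    if (k > 0 && length(forced_exec)) {
      cs_fix(cs, v("aT", k),
             stats::setNames(numeric(length(forced_exec)), forced_exec))
    }
  }

  # --- interval equations (i = 1..n) -------------------------------------
  for (i in seq_len(n)) {
    k0 <- i - 1L
    k1 <- i
    # cumulative increments
    tl <- list(diag(nEVT), -diag(nEVT), -diag(nEVT))
    names(tl) <- c(v("aE", k1), v("aE", k0), v("daE", i))
    cs_add_rows(cs, tl, "=", numeric(nEVT))
    tl <- list(diag(nEVP), -diag(nEVP), -diag(nEVP))
    names(tl) <- c(v("dm", k1), v("dm", k0), v("ddm", i))
    cs_add_rows(cs, tl, "=", numeric(nEVP))
    if (nrow(G$A)) {
      tl <- list(G$A, -G$B)
      names(tl) <- c(v("ddm", i), v("daE", i))
      cs_add_rows(cs, tl, "<=", numeric(nrow(G$A)))
    }
    # average marking and intensity coupling
    tl <- list(IP, -IP / 2, -IP / 2)
    names(tl) <- c(v("mbar", i), v("m", k0), v("m", k1))
    cs_add_rows(cs, tl, "=", numeric(nP))
    tl <- list(IP, -IP, -S$Y_m)
    names(tl) <- c(v("mbar", i), v("muP", i), v("muE", i))
    cs_add_rows(cs, tl, "=", numeric(nP))
    if (nrow(G$C)) {
      tl <- list(G$C, -G$D)
      names(tl) <- c(v("dlam", i), v("muE", i))
      cs_add_rows(cs, tl, "<=", numeric(nrow(G$C)))
    }
    tl <- list(IT, -IT, -S$Z_lambda)
    names(tl) <- c(v("lam", i), "lambda0", v("dlam", i))
    cs_add_rows(cs, tl, "=", numeric(nT))
    # action production: dsig integrates dlam exactly (interval-constant)
    tl <- list(diag(nEST), -diag(nEST), -diag(nEST) * dts[i])
    names(tl) <- c(v("dsig", k1), v("dsig", k0), v("dlam", i))
    cs_add_rows(cs, tl, "=", numeric(nEST))
    if (any(net$ESP$fake)) {
      cs_fix(cs, v("muE", i),
             stats::setNames(numeric(sum(net$ESP$fake)),
                             net$ESP$id[net$ESP$fake]))
    }
    if (length(forced_active)) {
      cs_fix(cs, v("muP", i),
             stats::setNames(numeric(length(forced_active)), forced_active))
    }
  }

  structure(list(
    cs = cs, net = net, times = times, objective = objective,
    forced_exec = forced_exec, forced_active = forced_active,
    integer = integer
  ), class = "fn_program")
}

#' @export
print.fn_program <- function(x, ...) {
  cat(sprintf(
    "Transcribed program: %d intervals over [0, %g], %d variables, %d rows\n",
    length(x$times) - 1L, max(x$times), x$cs$nvar, x$cs$nrow))
  invisible(x)
}

# Column vector for one objective term over the program's variables.
program_term_vector <- function(prob, term) {
  cs <- prob$cs
  n <- length(prob$times) - 1L
  dts <- diff(prob$times)
  w <- dts / sum(dts)
  m <- regmatches(term, regexec("^([A-Za-z0-9_]+)\\[(.+)\\]$", term))[[1]]
  if (length(m) == 0L) stop("cannot parse objective term: ", term,
                            call. = FALSE)
  what <- m[2]
  idx <- m[3]
  vec <- numeric(cs$nvar)
  switch(what,
    m = { vec[cs_cols(cs, paste0("m.", n), idx)] <- 1 },
    m0 = { vec[cs_cols(cs, "m.0", idx)] <- 1 },
    sigma = { vec[cs_cols(cs, paste0("sigma.", n), idx)] <- 1 },
    lambda0 = { vec[cs_cols(cs, "lambda0", idx)] <- 1 },
    mbar = {
      for (i in seq_len(n)) {
        vec[cs_cols(cs, paste0("mbar.", i), idx)] <- w[i]
      }
    },
    lbar = {
      for (i in seq_len(n)) {
        vec[cs_cols(cs, paste0("lam.", i), idx)] <- w[i]
      }
    },
    stop("unknown objective term kind: ", what, call. = FALSE)
  )
  vec
}

program_objective <- function(prob) {
  cs <- prob$cs
  obj <- prob$objective
  cvec <- numeric(cs$nvar)
  Q <- NULL
  const <- 0
  if (!is.null(obj)) {
    for (i in seq_along(obj$linear)) {
      cvec <- cvec +
        obj$linear[[i]] * program_term_vector(prob, names(obj$linear)[i])
    }
    if (!is.null(obj$quadratic)) {
      Q <- matrix(0, cs$nvar, cs$nvar)
      for (q in obj$quadratic) {
        wgt <- q$weight %||% 1
        vv <- program_term_vector(prob, q$term)
        Q <- Q + 2 * wgt * tcrossprod(vv)
        cvec <- cvec - 2 * wgt * (q$target %||% 0) * vv
        const <- const + wgt * (q$target %||% 0)^2
      }
    }
    if (obj$sense == "max") cvec <- -cvec
  }
  list(c = cvec, Q = Q, const = const)
}

#' Solve a transcribed program
#'
#' Linear programs are solved with HiGHS, quadratic ones with a dual
#' active-set method; the solution is unpacked into a trajectory.
#'
#' @param prob an `fn_program` from [transcribe()].
#' @return An object of class `fn_trajectory`: `states` tibble (one row per
#'   boundary: time, markings, produced/available actions), `intervals`
#'   tibble (one row per interval: interval-constant intensities, average
#'   markings, active tokens), `lambda0` (resolved default intensities),
#'   `objective` value, `status`, and the raw `solution`.
#' @export
solve_program_fn <- function(prob) {
  stopifnot(inherits(prob, "fn_program"))
  mats <- cs_matrices(prob$cs)
  ob <- program_objective(prob)
  p <- c(list(c = ob$c, Q = ob$Q), mats)
  if (isTRUE(prob$integer)) p$integrality <- rep(1L, prob$cs$nvar)
  res <- solve_program(p)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, states = NULL,
                          intervals = NULL, lambda0 = NULL,
                          objective = NA_real_, solution = NULL,
                          times = prob$times), class = "fn_trajectory"))
  }
  sol <- cs_unpack(prob$cs, res$x)
  n <- length(prob$times) - 1L
  net <- prob$net
  raw <- sum(ob$c * res$x) +
    if (is.null(ob$Q)) 0 else 0.5 * as.numeric(t(res$x) %*% ob$Q %*% res$x)
  obj_val <- if (!is.null(prob$objective) && prob$objective$sense == "max")
    -raw else raw + ob$const
  grab <- function(stub, k) sol[[paste0(stub, ".", k)]]
  states <- do.call(rbind, lapply(0:n, function(k) {
    data.frame(time = prob$times[k + 1],
               t(grab("m", k)), t(grab("sigma", k)), t(grab("aT", k)),
               check.names = FALSE)
  }))
  names(states) <- c("time", paste0("m[", net$places, "]"),
                     paste0("sigma[", net$all_transitions, "]"),
                     paste0("aT[", net$all_transitions, "]"))
  intervals <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(t_start = prob$times[i], t_end = prob$times[i + 1],
               t(grab("lam", i)), t(grab("mbar", i)), t(grab("muE", i)),
               check.names = FALSE)
  }))
  names(intervals) <- c("t_start", "t_end",
                        paste0("lambda[", net$all_transitions, "]"),
                        paste0("mbar[", net$places, "]"),
                        paste0("muE", net$ESP$id))
  structure(list(
    status = "optimal",
    states = tibble::as_tibble(states),
    intervals = tibble::as_tibble(intervals),
    lambda0 = sol$lambda0,
    objective = obj_val,
    solution = sol,
    times = prob$times
  ), class = "fn_trajectory")
}

#' @export
print.fn_trajectory <- function(x, ...) {
  cat(sprintf("Flexible-net trajectory: status %s", x$status))
  if (x$status == "optimal") {
    cat(sprintf(", %d boundaries over [0, %g], objective %.6g",
                nrow(x$states), max(x$times), x$objective))
  }
  cat("\n")
  invisible(x)
}

#' Steady-state program
#'
#' Convenience wrapper: a one-interval transcription with the additional
#' requirement that the boundary markings coincide (zero net token flow),
#' optimised for a linear objective over the steady marking, intensities
#' and default intensities.  A net is usually not steady at its own exact
#' initial marking, so steady-state questions are asked with relaxed
#' initial conditions from [fn_initial_conditions()] (e.g. only a
#' token-sum row).
#'
#' @param net an `fn_net`.
#' @param terms named numeric objective coefficients over `"m[p]"` (steady
#'   marking), `"lambda[t]"` (steady intensity) and `"lambda0[t]"` terms.
#' @param sense `"min"` or `"max"`.
#' @param forced_exec,forced_active forced sets as in [transcribe()].
#' @param init initial conditions; defaults to the net's own.
#' @return list with `status`, `value` and the unpacked `solution`.
#' @export
steady_state_program <- function(net, terms, sense = c("min", "max"),
                                 forced_exec = character(0),
                                 forced_active = character(0),
                                 init = net$init) {
  sense <- match.arg(sense)
  prob <- transcribe(net, c(0, 1), forced_exec = forced_exec,
                     forced_active = forced_active, init = init)
  cs <- prob$cs
  nP <- length(net$places)
  if (nP) {
    tl <- list(diag(nP), -diag(nP))
    names(tl) <- c("m.1", "m.0")
    cs_add_rows(cs, tl, "=", numeric(nP))
  }
  cvec <- numeric(cs$nvar)
  for (i in seq_along(terms)) {
    nm <- names(terms)[i]
    mm <- regmatches(nm, regexec("^([A-Za-z0-9_]+)\\[(.+)\\]$", nm))[[1]]
    if (length(mm) == 0L) stop("cannot parse term: ", nm, call. = FALSE)
    cols <- switch(mm[2],
      m = cs_cols(cs, "m.1", mm[3]),
      lambda = cs_cols(cs, "lam.1", mm[3]),
      lbar = cs_cols(cs, "lam.1", mm[3]),
      lambda0 = cs_cols(cs, "lambda0", mm[3]),
      stop("unknown steady-state term kind: ", mm[2], call. = FALSE))
    cvec[cols] <- cvec[cols] + terms[[i]]
  }
  mats <- cs_matrices(cs)
  res <- solve_program(c(
    list(c = if (sense == "max") -cvec else cvec), mats))
  if (res$status != "optimal") {
    return(list(status = res$status, value = NA_real_, solution = NULL))
  }
  list(status = "optimal",
       value = if (sense == "max") -res$fun else res$fun,
       solution = cs_unpack(cs, res$x))
}
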