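# State-equation constraint systems.  These encode the *necessary*
# reachability conditions of event nets, intensity nets and full Flexible
# Nets: every reachable state satisfies them, but the converse can fail
# (cumulative equations admit spurious solutions), so no operation here
# claims sufficiency.

#' Event-net state-equation system
#'
#' Builds the linear system satisfied by every state reachable from the
#' initial state in which `sigma` actions are available and nothing has
#' fired: `sigma = a_T + Y_sigma a_E`, `A dm <= B a_E`,
#' `m = m0 + Z_m dm`, `J_m m0 <= K_m`, all variables nonnegative.  Silent
#' (fake) transitions carry `sigma = 0`.
#'
#' @param net an `fn_net`.
#' @param sigma optional named vector fixing produced actions per (real)
#'   transition; `NULL` leaves them free.
#' @param a_T optional named vector fixing leftover (available) actions.
#' @param forced character vector of transitions whose actions must all
#'   have been executed (`a_T = 0` rows).
#' @param init initial conditions; defaults to the net's own.
#' @return An `fn_consys` with variables `sigma`, `a_T`, `a_E`, `dm`, `m`,
#'   `m0`.
#' @export
event_polytope <- function(net, sigma = NULL, a_T = NULL,
                           forced = character(0), init = net$init) {
  stopifnot(inherits(net, "fn_net"))
  bad <- setdiff(forced, net$all_transitions)
  if (length(bad)) stop("forced set contains unknown transition: ", bad[1],
                        call. = FALSE)
  S <- structure_matrices(net)
  G <- global_blocks(net)
  Tt <- net$all_transitions
  cs <- new_consys()
  cs_add_var(cs, "sigma", Tt)
  cs_add_var(cs, "a_T", Tt)
  cs_add_var(cs, "a_E", net$EVT$id)
  cs_add_var(cs, "dm", net$EVP$id)
  cs_add_var(cs, "m", net$places)
  cs_add_var(cs, "m0", net$places)
  nT <- length(Tt)
  # sigma = a_T + Y_sigma a_E
  cs_add_rows(cs, list(sigma = diag(nT), a_T = -diag(nT), a_E = -S$Y_sigma),
              "=", numeric(nT))
  # A dm <= B a_E
  if (nrow(G$A)) {
    cs_add_rows(cs, list(dm = G$A, a_E = -G$B), "<=", numeric(nrow(G$A)))
  }
  # m = m0 + Z_m dm
  nP <- length(net$places)
  cs_add_rows(cs, list(m = diag(nP), m0 = -diag(nP), dm = -S$Z_m),
              "=", numeric(nP))
  # J_m m0 <= K_m (includes point values recorded as equality pairs)
  blk <- init$m0_block
  if (nrow(blk$J)) cs_add_rows(cs, list(m0 = blk$J), "<=", blk$K)
  # silent transitions produce no actions
  if (length(net$fake_transitions)) {
    cs_fix(cs, "sigma", stats::setNames(
      numeric(length(net$fake_transitions)), net$fake_transitions))
  }
  if (!is.null(sigma)) cs_fix(cs, "sigma", sigma)
  if (!is.null(a_T)) cs_fix(cs, "a_T", a_T)
  if (length(forced)) {
    cs_fix(cs, "a_T", stats::setNames(numeric(length(forced)), forced))
  }
  cs
}

#' Intensity-net state-equation system
#'
#' Builds the linear system satisfied by every intensity-net state reachable
#' from `m` idle tokens and default intensities: `m = mu_P + Y_m mu_E`,
#' `C dl <= D mu_E`, `lambda = lambda0 + Z_lambda dl`,
#' `J_lambda lambda0 <= K_lambda`, all nonnegative.
#'
#' @param net an `fn_net`.
#' @param m optional named marking vector to fix; `NULL` leaves it free
#'   (still subject to the initial-marking block if `tie_m0` is `TRUE`).
#' @param mu_E optional named vector fixing active tokens per intensity
#'   edge.
#' @param forced character vector of places whose tokens must all be active
#'   (`mu_P = 0` rows).
#' @param init initial conditions; defaults to the net's own.
#' @param tie_m0 when `TRUE` (default) and `m` is not given, the marking is
#'   constrained by the initial-marking block (the marking at time zero).
#' @return An `fn_consys` with variables `m`, `mu_P`, `mu_E`, `dl`,
#'   `lambda`, `lambda0`.
#' @export
intensity_polytope <- function(net, m = NULL, mu_E = NULL,
                               forced = character(0), init = net$init,
                               tie_m0 = TRUE) {
  stopifnot(inherits(net, "fn_net"))
  bad <- setdiff(forced, net$places)
  if (length(bad)) stop("forced set contains unknown place: ", bad[1],
                        call. = FALSE)
  S <- structure_matrices(net)
  G <- global_blocks(net)
  Tt <- net$all_transitions
  nP <- length(net$places)
  nT <- length(Tt)
  cs <- new_consys()
  cs_add_var(cs, "m", net$places)
  cs_add_var(cs, "mu_P", net$places)
  cs_add_var(cs, "mu_E", net$ESP$id)
  cs_add_var(cs, "dl", net$EST$id)
  cs_add_var(cs, "lambda", Tt)
  cs_add_var(cs, "lambda0", Tt)
  # m = mu_P + Y_m mu_E
  cs_add_rows(cs, list(m = diag(nP), mu_P = -diag(nP), mu_E = -S$Y_m),
              "=", numeric(nP))
  # C dl <= D mu_E
  if (nrow(G$C)) {
    cs_add_rows(cs, list(dl = G$C, mu_E = -G$D), "<=", numeric(nrow(G$C)))
  }
  # lambda = lambda0 + Z_lambda dl
  cs_add_rows(cs, list(lambda = diag(nT), lambda0 = -diag(nT),
                       dl = -S$Z_lambda), "=", numeric(nT))
  blk <- init$lambda0_block
  if (nrow(blk$J)) cs_add_rows(cs, list(lambda0 = blk$J), "<=", blk$K)
  # fake place edges never hold tokens
  if (any(net$ESP$fake)) {
    cs_fix(cs, "mu_E", stats::setNames(numeric(sum(net$ESP$fake)),
                                       net$ESP$id[net$ESP$fake]))
  }
  if (!is.null(m)) {
    cs_fix(cs, "m", m)
  } else if (tie_m0) {
    mb <- init$m0_block
    if (nrow(mb$J)) cs_add_rows(cs, list(m = mb$J), "<=", mb$K)
  }
  if (!is.null(mu_E)) cs_fix(cs, "mu_E", mu_E)
  if (length(forced)) {
    cs_fix(cs, "mu_P", stats::setNames(numeric(length(forced)), forced))
  }
  cs
}

#' Flexible-net state-equation system at a single time
#'
#' Union of the event-net and intensity-net systems plus the action
#' production rows `sigma = lambda0 * tau + Z_lambda dsigma`, `dsigma >= 0`.
#' The integral linkage between `dsigma` and the intensity trajectory over
#' `[0, tau]` is deliberately not imposed here (single-time relaxation);
#' the time-linked version lives in [transcribe()].
#'
#' @param net an `fn_net`.
#' @param tau nonnegative time.
#' @param forced_exec transitions with forced execution (`a_T = 0`).
#' @param forced_active places with forced activity (`mu_P = 0`).
#' @param init initial conditions; defaults to the net's own.
#' @return An `fn_consys` over the full ten-component state tuple.
#' @export
fn_polytope_at <- function(net, tau, forced_exec = character(0),
                           forced_active = character(0), init = net$init) {
  stopifnot(inherits(net, "fn_net"))
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) {
    stop("tau must be a nonnegative number", call. = FALSE)
  }
  S <- structure_matrices(net)
  G <- global_blocks(net)
  Tt <- net$all_transitions
  nP <- length(net$places)
  nT <- length(Tt)
  cs <- new_consys()
  for (v in c("m", "mu_P")) cs_add_var(cs, v, net$places)
  cs_add_var(cs, "mu_E", net$ESP$id)
  cs_add_var(cs, "dl", net$EST$id)
  for (v in c("lambda", "lambda0")) cs_add_var(cs, v, Tt)
  cs_add_var(cs, "dsigma", net$EST$id)
  for (v in c("sigma", "a_T")) cs_add_var(cs, v, Tt)
  cs_add_var(cs, "a_E", net$EVT$id)
  cs_add_var(cs, "dm", net$EVP$id)
  cs_add_var(cs, "m0", net$places)
  # intensity side
  cs_add_rows(cs, list(m = diag(nP), mu_P = -diag(nP), mu_E = -S$Y_m),
              "=", numeric(nP))
  if (nrow(G$C)) {
    cs_add_rows(cs, list(dl = G$C, mu_E = -G$D), "<=", numeric(nrow(G$C)))
  }
  cs_add_rows(cs, list(lambda = diag(nT), lambda0 = -diag(nT),
                       dl = -S$Z_lambda), "=", numeric(nT))
  lblk <- init$lambda0_block
  if (nrow(lblk$J)) cs_add_rows(cs, list(lambda0 = lblk$J), "<=", lblk$K)
  # action production
  cs_add_rows(cs, list(sigma = diag(nT), lambda0 = -diag(nT) * tau,
                       dsigma = -S$Z_lambda), "=", numeric(nT))
  # event side
  cs_add_rows(cs, list(sigma = diag(nT), a_T = -diag(nT), a_E = -S$Y_sigma),
              "=", numeric(nT))
  if (nrow(G$A)) {
    cs_add_rows(cs, list(dm = G$A, a_E = -G$B), "<=", numeric(nrow(G$A)))
  }
  cs_add_rows(cs, list(m = diag(nP), m0 = -diag(nP), dm = -S$Z_m),
              "=", numeric(nP))
  mblk <- init$m0_block
  if (nrow(mblk$J)) cs_add_rows(cs, list(m0 = mblk$J), "<=", mblk$K)
  if (any(net$ESP$fake)) {
    cs_fix(cs, "mu_E", stats::setNames(numeric(sum(net$ESP$fake)),
                                       net$ESP$id[net$ESP$fake]))
  }
  if (length(forced_exec)) {
    cs_fix(cs, "a_T",
           stats::setNames(numeric(length(forced_exec)), forced_exec))
  }
  if (length(forced_active)) {
    cs_fix(cs, "mu_P",
           stats::setNames(numeric(length(forced_active)), forced_active))
  }
  cs
}

#' Optimize a linear objective over a constraint system
#'
#' @param cs an `fn_consys` (from [event_polytope()],
#'   [intensity_polytope()], [fn_polytope_at()] or [transcribe()]).
#' @param terms named numeric vector of objective coefficients; names are
#'   `"var[index]"` references, e.g. `c("lambda[t1]" = 1, "lambda[t2]" = 1)`.
#' @param sense `"min"` or `"max"`.
#' @return list with `status`, `value` and `solution` (named per-variable
#'   vectors).
#' @export
optimize_over <- function(cs, terms, sense = c("min", "max")) {
  cs_optimize(cs, terms, sense = match.arg(sense))
}
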