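# Receding-horizon (model predictive control) driver on top of the
# transcription: at every step the program is built over the prediction
# horizon from the current state, solved, and only the first interval is
# applied; uncertain default intensities and handler slack are re-resolved
# at every step.

#' Run model predictive control on a Flexible Net
#'
#' @param net an `fn_net`.
#' @param objective an [fn_objective()]; evaluated at the end of the
#'   horizon (final-boundary terms) or over the horizon (average terms).
#' @param dt sample time (length of each interval), must be positive.
#' @param horizon number of intervals per solve (prediction horizon), >= 1.
#' @param n_steps maximum number of applied steps, >= 1.
#' @param forced_exec,forced_active forced sets as in [transcribe()].
#' @param m0 named exact initial marking; defaults to the net's point `m0`.
#' @param tol convergence tolerance: the run stops early when the boundary
#'   marking changes by less than `tol` (infinity norm) over `patience`
#'   consecutive steps.
#' @param patience number of consecutive quiet steps declaring convergence.
#' @return An object of class `fn_mpc`: `states` tibble (time, markings),
#'   `controls` tibble (per step: resolved default intensities and applied
#'   interval intensities), `converged` flag and `steps` count.
#' @export
run_mpc <- function(net, objective, dt, horizon = 1L, n_steps = 100L,
                    forced_exec = character(0),
                    forced_active = character(0), m0 = NULL,
                    tol = 1e-4, patience = 10L) {
  stopifnot(inherits(net, "fn_net"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (horizon < 1L) stop("horizon must be at least 1 interval",
                         call. = FALSE)
  if (n_steps < 1L) stop("n_steps must be at least 1", call. = FALSE)
  if (is.null(m0)) {
    m0 <- net$init$m0
    if (anyNA(m0)) {
      stop("net has interval m0; supply an exact m0 for MPC", call. = FALSE)
    }
  }
  m_cur <- stats::setNames(numeric(length(net$places)), net$places)
  m_cur[names(m0)] <- as.numeric(m0)
  aT_cur <- stats::setNames(numeric(length(net$all_transitions)),
                            net$all_transitions)
  times <- dt * (0:horizon)
  states <- list(data.frame(step = 0L, time = 0, t(m_cur),
                            check.names = FALSE))
  controls <- list()
  quiet <- 0L
  converged <- FALSE
  steps_done <- 0L
  for (s in seq_len(n_steps)) {
    prob <- transcribe(net, times, objective = objective,
                       forced_exec = forced_exec,
                       forced_active = forced_active,
                       m0 = m_cur, a_T0 = aT_cur)
    traj <- solve_program_fn(prob)
    if (traj$status != "optimal") {
      stop(sprintf(
        "MPC step %d: %s program (time %.4g); the forced sets or blocks admit no state here",
        s, traj$status, dt * (s - 1)), call. = FALSE)
    }
    sol <- traj$solution
    m_new <- sol[["m.1"]]
    aT_new <- sol[["aT.1"]]
    controls[[s]] <- data.frame(
      step = s, t_start = dt * (s - 1), t_end = dt * s,
      t(stats::setNames(sol$lambda0,
                        paste0("lambda0[", net$all_transitions, "]"))),
      t(stats::setNames(sol[["lam.1"]],
                        paste0("lambda[", net$all_transitions, "]"))),
      objective = traj$objective,
      check.names = FALSE)
    states[[s + 1L]] <- data.frame(step = s, time = dt * s, t(m_new),
                                   check.names = FALSE)
    delta <- max(abs(m_new - m_cur))
    m_cur <- m_new
    aT_cur <- aT_new
    steps_done <- s
    quiet <- if (delta < tol) quiet + 1L else 0L
    if (quiet >= patience) {
      converged <- TRUE
      break
    }
  }
  st <- do.call(rbind, states)
  names(st) <- c("step", "time", paste0("m[", net$places, "]"))
  structure(list(
    states = tibble::as_tibble(st),
    controls = tibble::as_tibble(do.call(rbind, controls)),
    converged = converged,
    steps = steps_done,
    dt = dt, horizon = horizon
  ), class = "fn_mpc")
}

#' @export
print.fn_mpc <- function(x, ...) {
  cat(sprintf("MPC run: %d applied steps of dt = %g (horizon %d)%s\n",
              x$steps, x$dt, x$horizon,
              if (x$converged) ", converged" else ""))
  invisible(x)
}
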