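# Broom-style accessors and ggplot2 methods for solved objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a solved trajectory
#'
#' @param x an `fn_trajectory`.
#' @param ... unused.
#' @return A long tibble with columns `time`, `series` (e.g. `"m[p1]"`)
#'   and `value`, one row per boundary and state component.
#' @method tidy fn_trajectory
#' @export
tidy.fn_trajectory <- function(x, ...) {
  if (x$status != "optimal") {
    return(tibble::tibble(time = numeric(0), series = character(0),
                          value = numeric(0)))
  }
  st <- as.data.frame(x$states)
  cols <- setdiff(names(st), "time")
  tibble::tibble(
    time = rep(st$time, times = length(cols)),
    series = rep(cols, each = nrow(st)),
    value = unlist(st[cols], use.names = FALSE)
  )
}

#' @method glance fn_trajectory
#' @export
glance.fn_trajectory <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    objective = x$objective,
    n_boundaries = if (is.null(x$states)) 0L else nrow(x$states),
    t_end = max(x$times)
  )
}

#' Tidy an MPC run
#'
#' @param x an `fn_mpc`.
#' @param ... unused.
#' @return A long tibble of the applied markings over time.
#' @method tidy fn_mpc
#' @export
tidy.fn_mpc <- function(x, ...) {
  st <- as.data.frame(x$states)
  cols <- setdiff(names(st), c("step", "time"))
  tibble::tibble(
    time = rep(st$time, times = length(cols)),
    series = rep(cols, each = nrow(st)),
    value = unlist(st[cols], use.names = FALSE)
  )
}

#' @method glance fn_mpc
#' @export
glance.fn_mpc <- function(x, ...) {
  tibble::tibble(
    steps = x$steps,
    converged = x$converged,
    dt = x$dt,
    horizon = x$horizon,
    t_end = max(x$states$time)
  )
}

#' Plot a trajectory's markings over time
#'
#' @param object an `fn_trajectory`.
#' @param what prefix of the series to show (default markings, `"m["`).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fn_trajectory
#' @export
autoplot.fn_trajectory <- function(object, what = "m[", ...) {
  d <- tidy(object)
  d <- d[startsWith(d$series, what), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the applied markings of an MPC run
#'
#' @param object an `fn_mpc`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fn_mpc
#' @export
autoplot.fn_mpc <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "marking", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
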