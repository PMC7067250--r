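# Catalogue of small example nets covering the formalism's modeling
# features: uncertain stoichiometry, silent handlers and partial
# observability, intensity transfer and splitting, resource allocation and
# a controlled cycle.  Each constructor returns a ready-validated fn_net
# with its canonical initial conditions, and (where meaningful) the forced
# sets used in the timed analyses.

#' Reaction network with uncertain stoichiometry
#'
#' Two reactions: a source reaction producing compound A at an uncertain
#' rate in `[4.5, 5.5]`, and a decomposition `A -> n B + 4n C` with
#' `n` uncertain in `[20, 22]`, rate proportional to `[A]` within 10%.
#' The initial concentration of A is interval-valued.
#'
#' @param m0_A length-2 interval for the initial concentration of A.  The
#'   default `c(0.9, 1.1)` is a consistent reading; set it explicitly if a
#'   different range is wanted.
#' @return An `fn_net`.
#' @export
fn_reaction_chain <- function(m0_A = c(0.9, 1.1)) {
  fn_net(
    places = c("A", "B", "C"),
    transitions = c("t1", "t2"),
    ehandlers = list(
      v1 = fn_eh(to = c(a = "A"), link = c(v = "t1")),
      v2 = fn_eh(from = c(a = "A"), to = c(b = "B", c = "C"),
                 link = c(v = "t2"),
                 rel = c("a = v", "20v <= b <= 22v", "c = 4b"))
    ),
    shandlers = list(
      s1 = fn_sh(to = c(r = "t2"), link = c(u = "A"),
                 rel = "0.9u <= r <= 1.1u")
    ),
    m0 = list(A = m0_A),
    lambda0 = list(t1 = c(4.5, 5.5))
  )
}

#' Event net with a choice on one place
#'
#' Three places, one transition and two event handlers competing for the
#' tokens of the first place: a silent handler moving tokens 1:1 and an
#' action-driven handler producing a nondeterministic amount in `[x, 2x]`.
#'
#' @param m0_p1 initial tokens in the first place (default 2).
#' @return An `fn_net`.
#' @export
fn_event_choice <- function(m0_p1 = 2) {
  fn_net(
    places = c("p1", "p2", "p3"),
    transitions = "t1",
    ehandlers = list(
      v1 = fn_eh(from = c(a = "p1"), to = c(b = "p2"), rel = "a = b"),
      v2 = fn_eh(from = c(a = "p1"), to = c(b = "p3"), link = c(x = "t1"),
                 rel = c("a = x", "x <= b <= 2x"))
    ),
    m0 = list(p1 = m0_p1)
  )
}

#' Partially observable event net
#'
#' Six places, three observable transitions and five handlers; the second
#' handler is silent (no transition edge), two handlers share the actions
#' of the second transition, and the last handler needs two tokens per
#' action.  Used for observation-consistent marking sets.
#'
#' @return An `fn_net` with `m0 = (1, 0, 0, 0, 0, 0)`.
#' @export
fn_observer_net <- function() {
  fn_net(
    places = paste0("p", 1:6),
    transitions = c("t1", "t2", "t3"),
    ehandlers = list(
      v1 = fn_eh(from = c(a = "p1"), to = c(b = "p2"), link = c(x = "t1")),
      v2 = fn_eh(from = c(a = "p2"), to = c(b = "p3")),
      v3 = fn_eh(from = c(a = "p3"), to = c(b = "p4"), link = c(x = "t2")),
      v4 = fn_eh(from = c(a = "p2"), to = c(b = "p5"), link = c(x = "t2"),
                 rel = c("a = x", "x <= b <= 2x")),
      v5 = fn_eh(from = c(a = "p5"), to = c(b = "p6"), link = c(x = "t3"),
                 rel = c("a = 2x", "b = x"))
    ),
    m0 = list(p1 = 1)
  )
}

#' Intensity net: tokens produce an interval-valued intensity
#'
#' One place with two tokens; each active token contributes an intensity
#' in `[2, 3]` to the single transition.
#'
#' @return An `fn_net`.
#' @export
fn_intensity_single <- function() {
  fn_net(
    places = "p1", transitions = "t1",
    shandlers = list(
      s1 = fn_sh(to = c(y = "t1"), link = c(u = "p1"),
                 rel = "2u <= y <= 3u")
    ),
    m0 = list(p1 = 2)
  )
}

#' Intensity net: intensity transfer between two transitions
#'
#' Each active token of the place moves one intensity unit from the first
#' transition (default intensity 5) to the second (default 0).
#'
#' @return An `fn_net`.
#' @export
fn_intensity_transfer <- function() {
  fn_net(
    places = "p1", transitions = c("t1", "t2"),
    shandlers = list(
      s1 = fn_sh(from = c(x = "t1"), to = c(y = "t2"), link = c(u = "p1"))
    ),
    m0 = list(p1 = 2),
    lambda0 = list(t1 = 5)
  )
}

#' Intensity net: splitting one intensity over two transitions
#'
#' The first transition (default intensity 6) feeds two transfer handlers
#' with no place edges, so any split is possible: every feasible state has
#' total intensity 6 across the three transitions.
#'
#' @return An `fn_net` (no places).
#' @export
fn_intensity_split <- function() {
  fn_net(
    places = character(0),
    transitions = c("t1", "t2", "t3"),
    shandlers = list(
      s1 = fn_sh(from = c(x = "t1"), to = c(y = "t2")),
      s2 = fn_sh(from = c(x = "t1"), to = c(y = "t3"))
    ),
    lambda0 = list(t1 = 6)
  )
}

#' Intensity net: choice between activating alone or synchronising
#'
#' Tokens of the first place either produce an intensity in `[1, 2]` on
#' their own, or synchronise 1:1 with tokens of the second place to produce
#' an intensity in `[3, 5]` on another transition.
#'
#' @return An `fn_net`.
#' @export
fn_intensity_choice <- function() {
  fn_net(
    places = c("p1", "p2"), transitions = c("t1", "t2"),
    shandlers = list(
      s1 = fn_sh(to = c(y = "t1"), link = c(u = "p1"),
                 rel = "u <= y <= 2u"),
      s2 = fn_sh(to = c(y = "t2"), link = c(u = "p1", w = "p2"),
                 rel = c("u = w", "3u <= y <= 5u"))
    ),
    m0 = list(p1 = 2, p2 = 1)
  )
}

#' Timed net combining the event choice with a token-driven intensity
#'
#' The event net of [fn_event_choice()] with the intensity net of
#' [fn_intensity_single()]: tokens of the first place drive the transition
#' whose actions feed the nondeterministic handler.
#'
#' @return An `fn_net`.
#' @export
fn_timed_choice <- function() {
  fn_net(
    places = c("p1", "p2", "p3"),
    transitions = "t1",
    ehandlers = list(
      v1 = fn_eh(from = c(a = "p1"), to = c(b = "p2"), rel = "a = b"),
      v2 = fn_eh(from = c(a = "p1"), to = c(b = "p3"), link = c(x = "t1"),
                 rel = c("a = x", "x <= b <= 2x"))
    ),
    shandlers = list(
      s1 = fn_sh(to = c(y = "t1"), link = c(u = "p1"),
                 rel = "2u <= y <= 3u")
    ),
    m0 = list(p1 = 2)
  )
}

#' Linear system with two uncertain parameters
#'
#' A three-place cycle whose fluid dynamics are
#' `dm1/dt = -q - h m1 + m2 + 2`, `dm2/dt = q - m2`,
#' `dm3/dt = h m1 - 2`, with the production rate `q` uncertain in
#' `[1.0, 1.5]` (default intensity of the first transition) and the decay
#' gain `h` uncertain in `[0.9, 1.1]` (slack of the third intensity
#' handler).  All tokens of the regulated places are forced active and all
#' actions are forced executed in the timed analyses; the forced sets are
#' attached as attributes `forced_exec` and `forced_active`.
#'
#' @return An `fn_net` with `m0 = (4, 0, 0)`.
#' @export
fn_uncertain_linear <- function() {
  net <- fn_net(
    places = c("p1", "p2", "p3"),
    transitions = c("t1", "t2", "t3", "t4"),
    ehandlers = list(
      v1 = fn_eh(from = c(a = "p1"), to = c(b = "p2"), link = c(x = "t1")),
      v2 = fn_eh(from = c(a = "p2"), to = c(b = "p1"), link = c(x = "t2")),
      v3 = fn_eh(from = c(a = "p1"), to = c(b = "p3"), link = c(x = "t3")),
      v4 = fn_eh(from = c(a = "p3"), to = c(b = "p1"), link = c(x = "t4"))
    ),
    shandlers = list(
      s2 = fn_sh(to = c(y = "t2"), link = c(u = "p2")),
      s3 = fn_sh(to = c(r = "t3"), link = c(a = "p1"),
                 rel = "0.9a <= r <= 1.1a")
    ),
    m0 = list(p1 = 4),
    lambda0 = list(t1 = c(1.0, 1.5), t4 = 2)
  )
  attr(net, "forced_exec") <- c("t1", "t2", "t3", "t4")
  attr(net, "forced_active") <- c("p1", "p2")
  net
}

#' Resource-allocation system with three production lines
#'
#' Two resource pools (`pa` with two copies, `pb` with one) drive three
#' production lines: line 1 consumes `p1` into `p2` at the speed of the
#' `pa` tokens allocated to it, line 2 consumes `p3` into `p4` and needs
#' one `pa` and one `pb` token in equal amounts, line 3 produces `p5` at
#' the speed of the `pb` tokens allocated to it.  All actions are forced
#' executed; resources may idle.
#'
#' @return An `fn_net` with `m0 = (3, 0, 2, 0, 0, 2, 1)`.
#' @export
fn_resource_allocation <- function() {
  net <- fn_net(
    places = c("p1", "p2", "p3", "p4", "p5", "pa", "pb"),
    transitions = c("t1", "t2", "t3"),
    ehandlers = list(
      v1 = fn_eh(from = c(a = "p1"), to = c(b = "p2"), link = c(x = "t1")),
      v2 = fn_eh(from = c(a = "p3"), to = c(b = "p4"), link = c(x = "t2")),
      v3 = fn_eh(to = c(b = "p5"), link = c(x = "t3"))
    ),
    shandlers = list(
      s1 = fn_sh(to = c(y = "t1"), link = c(u = "pa")),
      s2 = fn_sh(to = c(y = "t2"), link = c(u = "pa", w = "pb")),
      s3 = fn_sh(to = c(y = "t3"), link = c(u = "pb"))
    ),
    m0 = list(p1 = 3, p3 = 2, pa = 2, pb = 1)
  )
  attr(net, "forced_exec") <- c("t1", "t2", "t3")
  attr(net, "forced_active") <- character(0)
  net
}

#' Controlled cycle with a dynamically constrained input
#'
#' Three places in a cycle, each driving its outgoing transition at the
#' speed of its own marking, plus a control transition whose default
#' intensity `u` in `[0, 1.5]` is the only input: through the fourth
#' intensity handler (`y = x`, `z = 2x`) each unit of `u` adds one unit of
#' intensity to the first transition and removes two from the second, so
#' `lambda[t1] = m1 + u`, `lambda[t2] = m2 - 2u`, `lambda[t3] = m3`.
#' Nonnegativity of `lambda[t2]` imposes the dynamic bound `u <= m2 / 2`
#' without an explicit rule.
#'
#' @return An `fn_net` with `m0 = (0, 0, 9)`.
#' @export
fn_control_loop <- function() {
  net <- fn_net(
    places = c("p1", "p2", "p3"),
    transitions = c("t1", "t2", "t3", "t4"),
    ehandlers = list(
      v1 = fn_eh(from = c(a = "p1"), to = c(b = "p2"), link = c(x = "t1")),
      v2 = fn_eh(from = c(a = "p2"), to = c(b = "p3"), link = c(x = "t2")),
      v3 = fn_eh(from = c(a = "p3"), to = c(b = "p1"), link = c(x = "t3"))
    ),
    shandlers = list(
      s1 = fn_sh(to = c(y = "t1"), link = c(u = "p1")),
      s2 = fn_sh(to = c(y = "t2"), link = c(u = "p2")),
      s3 = fn_sh(to = c(y = "t3"), link = c(u = "p3")),
      s4 = fn_sh(from = c(x = "t4", z = "t2"), to = c(y = "t1"),
                 rel = c("y = x", "z = 2x"))
    ),
    m0 = list(p3 = 9),
    lambda0 = list(t4 = c(0, 1.5))
  )
  attr(net, "forced_exec") <- c("t1", "t2", "t3", "t4")
  attr(net, "forced_active") <- c("p1", "p2", "p3")
  net
}
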