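# Reading and writing net description files (YAML).
#
# Schema:
#   places:       map place -> m0 value or [lo, hi]
#   transitions:  map transition -> lambda0 value or [lo, hi]
#   ehandlers:    map handler -> {from: {label: place}, to: {label: place},
#                                 link: {label: transition}, rel: [strings]}
#   shandlers:    map handler -> {from: {label: transition}, to: {...},
#                                 link: {label: place}, rel: [strings]}
#   m0cons:       [relation strings over place ids]
#   l0cons:       [relation strings over transition ids]

#' Read a Flexible Net from a YAML description file
#'
#' @param path file path.
#' @return A validated `fn_net`.
#' @export
read_fn <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop(sprintf("cannot parse '%s' as YAML: %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.list(doc) || is.null(doc$places)) {
    stop(sprintf("'%s': schema error: a net file needs a 'places' section",
                 path), call. = FALSE)
  }
  as_handler <- function(x, ctor, h) {
    for (f in setdiff(names(x), c("from", "to", "link", "rel"))) {
      stop(sprintf("handler '%s': unknown field '%s'", h, f), call. = FALSE)
    }
    cv <- function(v) {
      if (is.null(v)) return(character(0))
      stats::setNames(as.character(unlist(v)), names(v))
    }
    ctor(from = cv(x$from), to = cv(x$to), link = cv(x$link),
         rel = as.character(unlist(x$rel)))
  }
  vals <- function(x) {
    lapply(x, function(v) as.numeric(unlist(v)))
  }
  net <- fn_net(
    places = names(doc$places) %||% character(0),
    transitions = names(doc$transitions) %||% character(0),
    ehandlers = stats::setNames(
      lapply(names(doc$ehandlers),
             function(h) as_handler(doc$ehandlers[[h]], fn_eh, h)),
      names(doc$ehandlers)),
    shandlers = stats::setNames(
      lapply(names(doc$shandlers),
             function(h) as_handler(doc$shandlers[[h]], fn_sh, h)),
      names(doc$shandlers)),
    m0 = vals(doc$places),
    lambda0 = vals(doc$transitions),
    m0cons = as.character(unlist(doc$m0cons)),
    l0cons = as.character(unlist(doc$l0cons))
  )
  bad <- validate_fn(net)
  if (nrow(bad)) {
    stop(sprintf("'%s': invalid net: %s", path,
                 paste(bad$detail, collapse = "; ")), call. = FALSE)
  }
  net
}

#' Write a Flexible Net to a YAML description file
#'
#' The written file round-trips through [read_fn()] to a net with
#' identical constraint matrices and index orders.
#'
#' @param net an `fn_net`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fn <- function(net, path) {
  stopifnot(inherits(net, "fn_net"))
  hmap <- function(handlers) {
    lapply(handlers, function(h) {
      out <- list()
      if (length(h$from)) out$from <- as.list(h$from)
      if (length(h$to)) out$to <- as.list(h$to)
      if (length(h$link)) out$link <- as.list(h$link)
      if (length(h$rel)) out$rel <- as.list(h$rel)
      out
    })
  }
  icv <- function(inputs, id) {
    v <- inputs[[id]]
    if (is.null(v)) 0 else as.numeric(v)
  }
  doc <- list(
    places = stats::setNames(
      lapply(net$places, function(p) icv(net$m0_input, p)), net$places),
    transitions = stats::setNames(
      lapply(net$transitions, function(tt) icv(net$lambda0_input, tt)),
      net$transitions)
  )
  if (length(net$ehandlers)) doc$ehandlers <- hmap(net$ehandlers)
  if (length(net$shandlers)) doc$shandlers <- hmap(net$shandlers)
  if (length(net$m0cons)) doc$m0cons <- as.list(net$m0cons)
  if (length(net$l0cons)) doc$l0cons <- as.list(net$l0cons)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Write a trajectory as CSV
#'
#' One row per boundary with the marking, produced and available actions;
#' interval quantities (average markings, intensities, active tokens) go to
#' a companion file when `intervals_path` is given.
#'
#' @param traj an `fn_trajectory`.
#' @param path CSV path for the boundary states.
#' @param intervals_path optional CSV path for per-interval rows.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, intervals_path = NULL) {
  stopifnot(inherits(traj, "fn_trajectory"))
  if (traj$status != "optimal") {
    stop("trajectory has status ", traj$status, call. = FALSE)
  }
  utils::write.csv(as.data.frame(traj$states), path, row.names = FALSE)
  if (!is.null(intervals_path)) {
    utils::write.csv(as.data.frame(traj$intervals), intervals_path,
                     row.names = FALSE)
  }
  invisible(path)
}
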