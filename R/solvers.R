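# Numerical back ends.  Linear programs (and the few integer programs) are
# handed to the HiGHS solver through scipy's optimize interface, driven as a
# batch subprocess with JSON interchange; convex quadratic programs are
# solved in-process with quadprog (Goldfarb-Idnani dual method).  Both
# back ends are deterministic.

the_python <- function() {
  p <- getOption("flexnets.python", "")
  if (nzchar(p)) return(p)
  for (cand in c("python", "python3")) {
    w <- Sys.which(cand)
    if (nzchar(w)) return(unname(w))
  }
  stop("no python interpreter found on PATH (needed for the LP back end)",
       call. = FALSE)
}

sparse_json <- function(M) {
  if (is.null(M) || nrow(M) == 0L) {
    return(list(i = integer(0), j = integer(0), x = numeric(0),
                m = 0L, n = if (is.null(M)) 0L else ncol(M)))
  }
  M <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
  list(i = M@i, j = M@j, x = M@x, m = nrow(M), n = ncol(M))
}

# Solve a batch of LPs/MILPs.  Each problem is a list with c, Aeq, beq,
# Aub, bub, lb, ub and optional integrality.  Returns list of results
# (status, x, fun).
solve_lp_batch <- function(problems) {
  script <- system.file("python", "lp_solve.py", package = "flexnets")
  if (!nzchar(script)) {
    # during development (pkgload) fall back to the source tree
    script <- file.path("inst", "python", "lp_solve.py")
  }
  payload <- lapply(problems, function(p) {
    n <- length(p$c)
    list(
      c = as.numeric(p$c),
      Aeq = sparse_json(p$Aeq), beq = as.numeric(p$beq),
      Aub = sparse_json(p$Aub), bub = as.numeric(p$bub),
      lb = lapply(as.numeric(p$lb %||% numeric(n)),
                  function(v) if (is.finite(v)) v else NULL),
      ub = lapply(as.numeric(p$ub %||% rep(Inf, n)),
                  function(v) if (is.finite(v)) v else NULL),
      integrality = if (is.null(p$integrality)) NULL else
        as.integer(p$integrality)
    )
  })
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(the_python(), c(script, fin, fout),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("LP back end failed: ", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  lapply(res, function(r) {
    list(status = r$status,
         x = if (is.null(r$x)) NULL else as.numeric(unlist(r$x)),
         fun = if (is.null(r$fun)) NA_real_ else as.numeric(r$fun))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Solve one program: LP via HiGHS, QP (Q non-null) via quadprog.
# prob: list(c, Q (optional sparse/dense), Aeq, beq, Aub, bub, lb, ub,
#            integrality (optional))
solve_program <- function(prob) {
  if (is.null(prob$Q)) {
    res <- solve_lp_batch(list(prob))[[1]]
    return(res)
  }
  solve_qp_quadprog(prob)
}

# Convex QP by null-space reduction: the (typically many, partly redundant)
# equality rows are eliminated with an SVD, leaving a small dense QP over
# the remaining degrees of freedom that the dual active-set method of
# quadprog handles robustly.  Flat objective directions are lifted by a
# tiny ridge in the reduced space (tie-break toward the minimum-norm
# particular solution; objective distortion is O(1e-7)).
solve_qp_quadprog <- function(prob) {
  n <- length(prob$c)
  if (n > 5000) {
    stop("quadratic objectives are supported for moderate problem sizes;",
         " reduce the horizon or use a linear objective", call. = FALSE)
  }
  Q <- as.matrix(prob$Q)
  cvec <- as.numeric(prob$c)
  Aeq <- as.matrix(prob$Aeq %||% matrix(0, 0, n))
  beq <- prob$beq %||% numeric(0)
  Aub <- as.matrix(prob$Aub %||% matrix(0, 0, n))
  bub <- prob$bub %||% numeric(0)
  lb <- prob$lb %||% numeric(n)
  ub <- prob$ub %||% rep(Inf, n)
  fin <- which(is.finite(lb))
  finu <- which(is.finite(ub))
  G <- rbind(Aub, -diag(n)[fin, , drop = FALSE],
             diag(n)[finu, , drop = FALSE])
  h <- c(bub, -lb[fin], ub[finu])
  if (nrow(Aeq)) {
    sv <- svd(Aeq, nu = min(dim(Aeq)), nv = n)
    tolr <- max(dim(Aeq)) * max(sv$d, 0) * 1e-12
    r <- sum(sv$d > tolr)
    Ur <- sv$u[, seq_len(r), drop = FALSE]
    Vr <- sv$v[, seq_len(r), drop = FALSE]
    x0 <- as.numeric(Vr %*% ((t(Ur) %*% beq) / sv$d[seq_len(r)]))
    if (max(abs(Aeq %*% x0 - beq)) > 1e-7 * max(1, max(abs(beq)))) {
      return(list(status = "infeasible", x = NULL, fun = NA_real_))
    }
    N <- sv$v[, setdiff(seq_len(n), seq_len(r)), drop = FALSE]
  } else {
    x0 <- numeric(n)
    N <- diag(n)
  }
  qval <- function(x) {
    as.numeric(0.5 * t(x) %*% Q %*% x + sum(cvec * x))
  }
  if (ncol(N) == 0L) {
    if (length(h) && any(G %*% x0 > h + 1e-8)) {
      return(list(status = "infeasible", x = NULL, fun = NA_real_))
    }
    return(list(status = "optimal", x = x0, fun = qval(x0)))
  }
  Hr <- t(N) %*% Q %*% N
  Hr <- (Hr + t(Hr)) / 2
  ridge <- 1e-7 * max(1, max(abs(Hr)))
  Dr <- Hr + diag(ridge, ncol(N))
  dr <- -as.numeric(t(N) %*% (cvec + Q %*% x0))
  Gr <- G %*% N
  hr <- as.numeric(h - G %*% x0)
  # clean the reduced system: rows that vanish in the null space are either
  # vacuous or witness infeasibility; the rest are normalized and
  # deduplicated to keep the active-set method out of degenerate corners
  rn <- sqrt(rowSums(Gr^2))
  zero <- rn < 1e-10
  if (any(zero & hr < -1e-8)) {
    return(list(status = "infeasible", x = NULL, fun = NA_real_))
  }
  Gr <- Gr[!zero, , drop = FALSE]
  hr <- hr[!zero] / rn[!zero]
  Gr <- Gr / rn[!zero]
  key <- apply(round(cbind(Gr, hr), 10), 1, paste, collapse = ",")
  dup <- duplicated(key)
  Gr <- Gr[!dup, , drop = FALSE]
  hr <- hr[!dup]
  # feasible sets produced by forced-execution/activity rows often have an
  # empty interior; a vanishing uniform relaxation restores one without
  # materially moving the optimum (violations stay below LP tolerances)
  res <- NULL
  for (eps in c(0, 1e-9, 1e-8, 1e-7)) {
    res <- tryCatch(
      quadprog::solve.QP(Dr, dr, t(-Gr), -(hr + eps), meq = 0),
      error = function(e) e
    )
    if (!inherits(res, "error")) break
  }
  if (inherits(res, "error")) {
    msg <- conditionMessage(res)
    status <- if (grepl("inconsistent|no solution", msg))
      "infeasible" else "error"
    return(list(status = status, x = NULL, fun = NA_real_, message = msg))
  }
  x <- x0 + as.numeric(N %*% res$solution)
  list(status = "optimal", x = x, fun = qval(x))
}

# Optimize a linear objective over a constraint system.
# terms: named numeric, names "var" or "var[idx]"; sense "max"/"min".
cs_optimize <- function(cs, terms, sense = c("min", "max"),
                        integrality = NULL) {
  sense <- match.arg(sense)
  mats <- cs_matrices(cs)
  cvec <- cs_term_vector(cs, terms)
  prob <- c(list(c = if (sense == "max") -cvec else cvec), mats)
  if (!is.null(integrality)) prob$integrality <- integrality
  res <- solve_program(prob)
  if (res$status != "optimal") {
    return(list(status = res$status, value = NA_real_, solution = NULL))
  }
  list(status = "optimal",
       value = if (sense == "max") -res$fun else res$fun,
       solution = cs_unpack(cs, res$x))
}

# Feasibility check / feasible point of a constraint system.
cs_feasible_point <- function(cs) {
  cs_optimize(cs, stats::setNames(numeric(0), character(0)))
}
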