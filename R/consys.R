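# A light constraint-system container: named variable vectors with index
# labels, plus linear equality/inequality rows accumulated as sparse
# triplets.  All variables are nonnegative unless a variable is registered
# as free.  Systems are solved by solve_cs() / cs_optimize().

new_consys <- function() {
  e <- new.env(parent = emptyenv())
  e$vars <- list()     # name -> list(ids, offset, free)
  e$nvar <- 0L
  e$ti <- integer(0)   # triplets
  e$tj <- integer(0)
  e$tx <- numeric(0)
  e$sense <- character(0)  # "=" or "<="
  e$rhs <- numeric(0)
  e$nrow <- 0L
  class(e) <- "fn_consys"
  e
}

cs_add_var <- function(cs, name, ids, free = FALSE) {
  if (!is.null(cs$vars[[name]])) stop("variable exists: ", name)
  ids <- as.character(ids)
  cs$vars[[name]] <- list(ids = ids, offset = cs$nvar, free = free,
                          n = length(ids))
  cs$nvar <- cs$nvar + length(ids)
  invisible(cs)
}

cs_cols <- function(cs, name, ids = NULL) {
  v <- cs$vars[[name]]
  if (is.null(v)) stop("unknown variable: ", name)
  if (is.null(ids)) return(v$offset + seq_len(v$n))
  idx <- match(as.character(ids), v$ids)
  if (anyNA(idx)) {
    stop(sprintf("unknown index '%s' for variable '%s'",
                 ids[which(is.na(idx))[1]], name))
  }
  v$offset + idx
}

# Add nrow(rows of each matrix) rows: sum_v M_v x_v  (sense)  rhs.
# terms: named list var -> matrix (columns must match the variable's ids,
# or a numeric vector for single-row constraints).
cs_add_rows <- function(cs, terms, sense, rhs) {
  nr <- length(rhs)
  for (nm in names(terms)) {
    M <- terms[[nm]]
    if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
    stopifnot(nrow(M) == nr)
    cols <- cs_cols(cs, nm)
    if (ncol(M) != length(cols)) {
      stop(sprintf("term '%s': %d columns but variable has %d entries",
                   nm, ncol(M), length(cols)))
    }
    nz <- which(M != 0, arr.ind = TRUE)
    if (nrow(nz)) {
      cs$ti <- c(cs$ti, cs$nrow + nz[, 1L])
      cs$tj <- c(cs$tj, cols[nz[, 2L]])
      cs$tx <- c(cs$tx, M[nz])
    }
  }
  cs$sense <- c(cs$sense, rep(sense, length.out = nr))
  cs$rhs <- c(cs$rhs, rhs)
  cs$nrow <- cs$nrow + nr
  invisible(cs)
}

# Fix a subset of a variable to given values (equality rows).
cs_fix <- function(cs, name, values, ids = NULL) {
  v <- cs$vars[[name]]
  if (is.null(ids)) {
    ids <- if (!is.null(names(values))) names(values) else v$ids
  }
  cols <- cs_cols(cs, name, ids)
  nr <- length(cols)
  cs$ti <- c(cs$ti, cs$nrow + seq_len(nr))
  cs$tj <- c(cs$tj, cols)
  cs$tx <- c(cs$tx, rep(1, nr))
  cs$sense <- c(cs$sense, rep("=", nr))
  cs$rhs <- c(cs$rhs, unname(as.numeric(values)))
  cs$nrow <- cs$nrow + nr
  invisible(cs)
}

cs_matrices <- function(cs) {
  A <- Matrix::sparseMatrix(i = cs$ti, j = cs$tj, x = cs$tx,
                            dims = c(cs$nrow, cs$nvar))
  eq <- cs$sense == "="
  lb <- numeric(cs$nvar)
  for (v in cs$vars) if (isTRUE(v$free)) lb[v$offset + seq_len(v$n)] <- -Inf
  list(Aeq = A[eq, , drop = FALSE], beq = cs$rhs[eq],
       Aub = A[!eq, , drop = FALSE], bub = cs$rhs[!eq],
       lb = lb, ub = rep(Inf, cs$nvar))
}

# Expand a solution vector into named per-variable vectors.
cs_unpack <- function(cs, x) {
  out <- lapply(cs$vars, function(v) {
    y <- x[v$offset + seq_len(v$n)]
    names(y) <- v$ids
    y
  })
  out
}

# Parse objective terms written as "var[idx]" or "var" into a column vector.
cs_term_vector <- function(cs, terms) {
  c0 <- numeric(cs$nvar)
  for (i in seq_along(terms)) {
    nm <- names(terms)[i]
    m <- regmatches(nm, regexec("^([^\\[]+)(\\[(.+)\\])?$", nm))[[1]]
    var <- m[2]
    idx <- if (nzchar(m[4])) m[4] else NULL
    cols <- cs_cols(cs, var, idx)
    c0[cols] <- c0[cols] + terms[[i]]
  }
  c0
}

#' @export
print.fn_consys <- function(x, ...) {
  cat(sprintf("Constraint system: %d variables, %d rows (%d equalities)\n",
              x$nvar, x$nrow, sum(x$sense == "=")))
  for (nm in names(x$vars)) {
    cat(sprintf("  %s [%d]\n", nm, x$vars[[nm]]$n))
  }
  invisible(x)
}
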