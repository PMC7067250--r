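# Parsing of linear relation strings such as "a = b", "x <= b <= 2x" or
# "0.9a <= r <= 1.1a".  A relation string is a chain of linear expressions
# over declared labels joined by "=", "<=" or ">=".  Chains are split into
# pairwise relations; equalities become two inequality rows.  The canonical
# row form is  coef . x + const <= 0.

# Parse one linear expression into a named coefficient vector plus constant.
# Supported terms: "2x", "0.9a", "x", "-x", "+3", "2*x".  No parentheses.
parse_linear_expr <- function(s, where = "") {
  s0 <- s
  s <- gsub("\\s+", "", s)
  s <- gsub("\\*", "", s)
  if (!nzchar(s)) {
    stop(sprintf("empty expression in relation%s", where), call. = FALSE)
  }
  # split into signed terms
  matches <- gregexpr("[+-]?[^+-]+", s)[[1]]
  terms <- regmatches(s, gregexpr("[+-]?[^+-]+", s))[[1]]
  if (sum(nchar(terms)) != nchar(s)) {
    stop(sprintf("cannot parse expression '%s'%s", s0, where), call. = FALSE)
  }
  coefs <- numeric(0)
  const <- 0
  for (term in terms) {
    m <- regmatches(
      term,
      regexec("^([+-]?)((?:[0-9]*\\.)?[0-9]+)?([A-Za-z_][A-Za-z0-9_]*)?$", term)
    )[[1]]
    if (length(m) == 0L || (!nzchar(m[3]) && !nzchar(m[4]))) {
      stop(sprintf("cannot parse term '%s' in '%s'%s", term, s0, where),
           call. = FALSE)
    }
    sign <- if (identical(m[2], "-")) -1 else 1
    num <- if (nzchar(m[3])) as.numeric(m[3]) else 1
    label <- m[4]
    if (nzchar(label)) {
      coefs[label] <- (if (label %in% names(coefs)) coefs[[label]] else 0) +
        sign * num
    } else {
      const <- const + sign * num
    }
  }
  list(coefs = coefs, const = const)
}

# Parse a full chain "e1 REL e2 REL e3" -> list of expressions and relations.
parse_relation_chain <- function(s, where = "") {
  s1 <- gsub("\\s+", "", s)
  ops <- regmatches(s1, gregexpr("<=|>=|==|=", s1))[[1]]
  exprs <- strsplit(s1, "<=|>=|==|=")[[1]]
  if (length(ops) == 0L) {
    stop(sprintf("relation '%s' has no comparison operator%s", s, where),
         call. = FALSE)
  }
  if (length(exprs) != length(ops) + 1L || any(!nzchar(exprs))) {
    stop(sprintf("malformed relation chain '%s'%s", s, where), call. = FALSE)
  }
  list(
    exprs = lapply(exprs, parse_linear_expr, where = where),
    ops = sub("^==$", "=", ops)
  )
}

# Turn a set of relation strings into canonical inequality rows
# M x + const <= 0 over the given label universe.
relation_rows <- function(specs, labels, where = "") {
  rows <- list()
  consts <- numeric(0)
  add_row <- function(lhs, rhs, flip = FALSE) {
    # lhs - rhs <= 0 (or >= 0 when flip, i.e. rhs - lhs <= 0)
    co <- numeric(length(labels))
    names(co) <- labels
    for (nm in names(lhs$coefs)) {
      if (!nm %in% labels) {
        stop(sprintf("unknown label '%s'%s", nm, where), call. = FALSE)
      }
      co[nm] <- co[nm] + lhs$coefs[[nm]]
    }
    for (nm in names(rhs$coefs)) {
      if (!nm %in% labels) {
        stop(sprintf("unknown label '%s'%s", nm, where), call. = FALSE)
      }
      co[nm] <- co[nm] - rhs$coefs[[nm]]
    }
    cc <- lhs$const - rhs$const
    if (flip) {
      co <- -co
      cc <- -cc
    }
    rows[[length(rows) + 1L]] <<- co
    consts[length(consts) + 1L] <<- cc
  }
  for (s in specs) {
    ch <- parse_relation_chain(s, where = where)
    for (i in seq_along(ch$ops)) {
      lhs <- ch$exprs[[i]]
      rhs <- ch$exprs[[i + 1L]]
      op <- ch$ops[[i]]
      if (op == "=") {
        add_row(lhs, rhs)
        add_row(lhs, rhs, flip = TRUE)
      } else if (op == "<=") {
        add_row(lhs, rhs)
      } else {
        add_row(lhs, rhs, flip = TRUE)
      }
    }
  }
  M <- if (length(rows)) do.call(rbind, rows) else
    matrix(0, 0, length(labels), dimnames = list(NULL, labels))
  colnames(M) <- labels
  list(M = M, const = consts)
}

# Relation strings that chain every label of a handler as equalities; used
# when a handler declares no relations (the equal-transfer convention).
all_equal_specs <- function(labels) {
  if (length(labels) < 2L) return(character(0))
  paste(labels, collapse = " = ")
}
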