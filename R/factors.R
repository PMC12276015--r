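# Internal factor algebra for exact inference. A factor is a
# nonnegative table over a set of discrete variables, stored as a flat
# numeric vector in column-major order (first variable fastest).

new_factor <- function(vars, card, val) {
  stopifnot(length(val) == prod(card), length(vars) == length(card))
  list(vars = vars, card = setNames(as.integer(card), vars),
       val = as.numeric(val))
}

# CPT array (child dimension first, then parents) -> factor.
cpt_as_factor <- function(node, cpt) {
  dn <- dimnames(cpt)
  vars <- names(dn)
  new_factor(vars, vapply(dn, length, integer(1)), as.numeric(cpt))
}

# For each cell of the enumeration over `uvars` (column-major, first
# fastest), the linear index into a factor over `fvars` (subset of
# `uvars`, any order).
union_index <- function(uvars, ucard, fvars, fcard) {
  n <- prod(ucard)
  t0 <- 0:(n - 1)
  idx <- rep(0L, n)
  stride <- 1
  for (v in fvars) {
    j <- match(v, uvars)
    before <- if (j == 1L) 1 else prod(ucard[seq_len(j - 1L)])
    coord <- (t0 %/% before) %% ucard[[j]]
    idx <- idx + coord * stride
    stride <- stride * fcard[[v]]
  }
  idx + 1L
}

factor_product <- function(f1, f2) {
  uvars <- union(f1$vars, f2$vars)
  ucard <- c(f1$card, f2$card)[uvars]
  i1 <- union_index(uvars, ucard, f1$vars, f1$card)
  i2 <- union_index(uvars, ucard, f2$vars, f2$card)
  new_factor(uvars, ucard, f1$val[i1] * f2$val[i2])
}

factor_sum_out <- function(f, var) {
  j <- match(var, f$vars)
  if (is.na(j)) return(f)
  a <- array(f$val, dim = f$card)
  perm <- c(seq_along(f$card)[-j], j)
  m <- matrix(aperm(a, perm), ncol = f$card[[j]])
  new_factor(f$vars[-j], f$card[-j], rowSums(m))
}

# Hard evidence: slice the factor at the observed state, dropping the
# variable from its scope.
factor_reduce <- function(f, var, state_idx) {
  j <- match(var, f$vars)
  if (is.na(j)) return(f)
  a <- array(f$val, dim = f$card)
  args <- rep(list(quote(expr = )), length(f$card))
  args[[j]] <- state_idx
  sliced <- do.call(`[`, c(list(a), args, list(drop = FALSE)))
  new_factor(f$vars[-j], f$card[-j], as.numeric(sliced))
}

# Soft evidence: multiply a per-state likelihood into the factor along
# `var`, keeping the variable in scope.
factor_scale <- function(f, var, weights) {
  j <- match(var, f$vars)
  if (is.na(j)) return(f)
  i <- union_index(f$vars, f$card, var, f$card[j])
  new_factor(f$vars, f$card, f$val * weights[i])
}
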