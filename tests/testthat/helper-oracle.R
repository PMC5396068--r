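# Independent brute-force oracles.  These recompute pipeline quantities
# by direct enumeration (per-element loops, no shared code with the
# implementation) so that vectorized results can be checked against them.

oracle_window <- function(chars, values, i, w = 7L) {
  v <- values[chars[i:(i + w - 1L)]]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  sum(v) / length(v)
}

# fragments x properties thermo-minus-meso difference matrix by loops
oracle_D <- function(set, table, w = 7L) {
  accs <- names(table$entries)
  m <- set$s - w + 1L
  D <- matrix(NA_real_, m, length(accs))
  for (k in seq_along(accs)) {
    vals <- table$entries[[accs[k]]]
    for (i in seq_len(m)) {
      gmean <- function(grp) {
        rows <- which(set$group == grp)
        xs <- numeric(0)
        for (r in rows) {
          x <- oracle_window(set$mat[r, ], vals, i, w)
          if (!is.na(x)) xs <- c(xs, x)
        }
        if (length(xs) == 0L) NA_real_ else mean(xs)
      }
      D[i, k] <- gmean("thermophilic") - gmean("mesophilic")
    }
  }
  D
}

oracle_missing <- function(set) {
  rows <- which(set$group != "reference")
  out <- integer(set$s)
  for (j in seq_len(set$s)) {
    out[j] <- sum(set$mat[rows, j] == "-")
  }
  out
}

oracle_rates <- function(set, grp) {
  rows <- which(set$group == grp)
  out <- numeric(set$s)
  for (j in seq_len(set$s)) out[j] <- mean(set$mat[rows, j] == "-")
  out
}

oracle_composition <- function(set, column, grp) {
  rows <- which(set$group == grp)
  ch <- set$mat[rows, column]
  ch <- ch[ch != "-"]
  if (length(ch) == 0L) return(numeric(0))
  tab <- table(ch)
  stats::setNames(as.numeric(tab) / length(ch) * 100, names(tab))
}

# PCA by direct eigendecomposition of the correlation matrix, independent
# of prcomp's SVD route
oracle_pca <- function(Z) {
  C <- crossprod(Z) / (nrow(Z) - 1)
  e <- eigen(C, symmetric = TRUE)
  list(sdev = sqrt(pmax(e$values, 0)), loadings = e$vectors)
}

# align the sign of each loading column of x to the reference y
sign_align <- function(x, y) {
  for (j in seq_len(ncol(x))) {
    if (sum(x[, j] * y[, j]) < 0) x[, j] <- -x[, j]
  }
  x
}

# varimax simplicity criterion: variance of squared loadings per column,
# evaluated on Kaiser (row-) normalized loadings, the objective the
# rotation maximizes; orthogonal rotation preserves the row norms, so the
# same normalization applies before and after
varimax_criterion <- function(L) {
  L <- L / sqrt(rowSums(L^2))
  sum(apply(L^2, 2L, function(x) mean(x^2) - mean(x)^2))
}
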