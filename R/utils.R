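# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators behave as pure functions of their arguments.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Lower-triangle (off-diagonal) values of a square matrix.
lower_tri <- function(m) m[lower.tri(m)]

# Mean of the off-diagonal entries of a square matrix.
mean_offdiag <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(NA_real_)
  (sum(m) - sum(diag(m))) / (n * (n - 1L))
}

# Connected components of an undirected adjacency given as a logical matrix.
# Small n (module merge graphs), so a simple label-propagation suffices.
connected_components <- function(link) {
  n <- nrow(link)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(link[i, ])
      if (length(nb)) {
        m <- min(comp[i], comp[nb])
        if (any(c(comp[i], comp[nb]) != m)) {
          comp[c(i, nb)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Two-sided p-value for a Pearson correlation from the t distribution.
cor_pvalue <- function(r, n) {
  if (n < 3L || !is.finite(r)) return(NA_real_)
  r <- max(min(r, 1), -1)
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tval), df = n - 2)
}
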