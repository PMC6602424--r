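# Exact rational arithmetic on small matrices (conservation / link-matrix
# decomposition must be exact, so structural computations never touch
# floating point) plus the Trajectory container shared by all engines.

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

# double -> exact small rational (num, den); stoichiometries and conserved
# coefficients are ratios of small integers by construction
.to_rational <- function(x, max_den = 1e6) {
  num <- den <- numeric(length(x))
  for (i in seq_along(x)) {
    v <- x[[i]]
    if (v == round(v)) { num[i] <- v; den[i] <- 1; next }
    # continued-fraction expansion
    p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- abs(v)
    repeat {
      a <- floor(r)
      p2 <- a * p1 + p0; q2 <- a * q1 + q0
      if (q2 > max_den) break
      p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
      frac <- r - a
      if (frac < 1e-12) break
      r <- 1 / frac
    }
    if (abs(p1 / q1 - abs(v)) > 1e-9)
      stop("value ", v, " is not a small rational")
    num[i] <- sign(v) * p1; den[i] <- q1
  }
  list(num = num, den = den)
}

.rat_simplify <- function(num, den) {
  g <- mapply(.gcd2, num, den)
  g[g == 0] <- 1
  num <- num / g; den <- den / g
  neg <- den < 0
  num[neg] <- -num[neg]; den[neg] <- -den[neg]
  list(num = num, den = den)
}

# a/b + c/d and (a/b)*(c/d), vectorized, kept reduced
.rat_add <- function(a, b, c, d) .rat_simplify(a * d + c * b, b * d)
.rat_mul <- function(a, b, c, d) .rat_simplify(a * c, b * d)

# Exact Gauss-Jordan elimination of a rational matrix, tracking the row
# transform T with T %*% A = R.  Returns reduced matrix, transform, pivot
# rows (rows of A that carry pivots, in elimination order) and pivot cols.
#' @keywords internal
rat_eliminate <- function(A) {
  m <- nrow(A); n <- ncol(A)
  r <- .to_rational(as.numeric(A))
  Rn <- matrix(r$num, m, n); Rd <- matrix(r$den, m, n)
  Tn <- diag(1, m); Td <- matrix(1, m, m)
  pivot_rows <- integer(0); pivot_cols <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    piv <- which(Rn[row:m, col] != 0)
    if (!length(piv)) next
    piv <- piv[1L] + row - 1L
    if (piv != row) {
      Rn[c(row, piv), ] <- Rn[c(piv, row), ]; Rd[c(row, piv), ] <- Rd[c(piv, row), ]
      Tn[c(row, piv), ] <- Tn[c(piv, row), ]; Td[c(row, piv), ] <- Td[c(piv, row), ]
    }
    # scale pivot row to 1
    pn <- Rn[row, col]; pd <- Rd[row, col]
    s <- .rat_mul(Rn[row, ], Rd[row, ], pd, pn)
    Rn[row, ] <- s$num; Rd[row, ] <- s$den
    s <- .rat_mul(Tn[row, ], Td[row, ], pd, pn)
    Tn[row, ] <- s$num; Td[row, ] <- s$den
    for (i in seq_len(m)) {
      if (i == row || Rn[i, col] == 0) next
      fn <- -Rn[i, col]; fd <- Rd[i, col]
      s1 <- .rat_mul(Rn[row, ], Rd[row, ], fn, fd)
      s2 <- .rat_add(Rn[i, ], Rd[i, ], s1$num, s1$den)
      Rn[i, ] <- s2$num; Rd[i, ] <- s2$den
      s1 <- .rat_mul(Tn[row, ], Td[row, ], fn, fd)
      s2 <- .rat_add(Tn[i, ], Td[i, ], s1$num, s1$den)
      Tn[i, ] <- s2$num; Td[i, ] <- s2$den
    }
    pivot_rows <- c(pivot_rows, row)
    pivot_cols <- c(pivot_cols, col)
    row <- row + 1L
  }
  list(Rnum = Rn, Rden = Rd, Tnum = Tn, Tden = Td,
       rank = length(pivot_cols), pivot_cols = pivot_cols)
}

# Exact solve A x = b for full-column-rank A (used to build the link matrix);
# returns rational solution as a plain numeric vector (exact ratio values).
#' @keywords internal
rat_solve <- function(A, b) {
  aug <- cbind(A, b)
  el <- rat_eliminate(aug)
  n <- ncol(A)
  if (any(el$pivot_cols > n)) stop("inconsistent linear system")
  x <- numeric(n)
  for (k in seq_along(el$pivot_cols)) {
    j <- el$pivot_cols[k]
    x[j] <- el$Rnum[k, n + 1L] / el$Rden[k, n + 1L]
  }
  x
}

# integer-scale a rational vector: multiply by lcm of denominators, divide by
# gcd of numerators, make the first nonzero entry positive
#' @keywords internal
integer_scale <- function(num, den) {
  nz <- which(num != 0)
  if (!length(nz)) return(num)
  l <- 1
  for (d in den[nz]) l <- l * d / .gcd2(l, d)
  v <- num * (l / den)
  g <- 0
  for (a in v[nz]) g <- .gcd2(g, a)
  v <- v / g
  if (v[nz[1L]] < 0) v <- -v
  v
}

## ---- Trajectory ----

#' Trajectory of a simulation
#'
#' @param times Strictly ascending numeric vector.
#' @param states Matrix, one row per time, named columns per variable.
#' @param events Data frame of fired events (`time`, `id`).
#' @param halt `NULL`, or `list(time=, message=)` when a halting event
#'   (typically a violated constraint) truncated the run.
#' @export
trajectory <- function(times, states, events = NULL, halt = NULL) {
  if (is.null(events))
    events <- data.frame(time = numeric(0), id = character(0),
                         stringsAsFactors = FALSE)
  structure(list(times = times, states = states, events = events, halt = halt),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$times), "time points,",
      ncol(x$states), "variables")
  if (nrow(x$events)) cat(",", nrow(x$events), "events fired")
  if (!is.null(x$halt))
    cat("; halted at t =", format(x$halt$time), "(", x$halt$message, ")")
  cat("\n")
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' Writes a `time` column followed by one column per variable.
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate a trajectory at given times (linear)
#' @keywords internal
traj_interp <- function(traj, times) {
  out <- matrix(NA_real_, length(times), ncol(traj$states),
                dimnames = list(NULL, colnames(traj$states)))
  for (j in seq_len(ncol(out)))
    out[, j] <- stats::approx(traj$times, traj$states[, j], xout = times,
                              rule = 2)$y
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
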