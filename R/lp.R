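# Dense two-phase simplex used by the DEA envelopment and slack programs.
# The LPs solved here are tiny (at most a few dozen columns), so a full
# tableau with Bland's anti-cycling rule is both robust and fast; no
# sparse machinery is warranted.

#' Solve a small linear program
#'
#' Minimises (or maximises) \code{c'x} subject to \code{A x (dir) b} and
#' \code{x >= 0}, using a full-tableau two-phase simplex with Bland's rule.
#' Intended for the small, dense envelopment programs arising in DEA;
#' problem sizes beyond a few hundred columns are out of scope.
#'
#' @param objective numeric objective coefficients, length \code{ncol(A)}.
#' @param A constraint coefficient matrix.
#' @param b right-hand side vector, length \code{nrow(A)}.
#' @param dir character vector of constraint directions, each one of
#'   \code{"<="}, \code{">="}, \code{"=="}.
#' @param maximize maximise instead of minimise?
#' @param tol pivot tolerance.
#' @return list with \code{status} (0 optimal, 1 infeasible, 2 unbounded),
#'   and for status 0 the primal solution \code{x} and objective
#'   \code{value}.
#' @keywords internal
lp_simplex <- function(objective, A, b, dir, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(objective) == n, length(b) == m, length(dir) == m,
            all(dir %in% c("<=", ">=", "==")))
  obj <- if (maximize) -objective else objective

  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[neg]]
  }

  nslack <- sum(dir != "==")
  S <- matrix(0, m, nslack)
  slack_of_row <- rep(NA_integer_, m)
  k <- 0L
  for (i in seq_len(m)) {
    if (dir[i] != "==") {
      k <- k + 1L
      S[i, k] <- if (dir[i] == "<=") 1 else -1
      slack_of_row[i] <- n + k
    }
  }
  need_art <- dir != "<="
  nart <- sum(need_art)
  Aa <- matrix(0, m, nart)
  art_of_row <- rep(NA_integer_, m)
  k <- 0L
  for (i in seq_len(m)) {
    if (need_art[i]) {
      k <- k + 1L
      Aa[i, k] <- 1
      art_of_row[i] <- n + nslack + k
    }
  }
  Tb <- cbind(A, S, Aa, b)
  ntot <- n + nslack + nart
  basis <- ifelse(need_art, art_of_row, slack_of_row)

  pivot <- function(Tb, r, cl) {
    Tb[r, ] <- Tb[r, ] / Tb[r, cl]
    other <- which(Tb[, cl] != 0)
    other <- other[other != r]
    if (length(other))
      Tb[other, ] <- Tb[other, ] - outer(Tb[other, cl], Tb[r, ])
    Tb
  }
  run <- function(Tb, basis, cost, ncols) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > 5000L) stop("simplex iteration limit reached")
      rc <- cost - as.numeric(cost[basis] %*% Tb[, seq_len(ncols), drop = FALSE])
      rc[basis] <- 0
      cand <- which(rc < -tol)
      if (!length(cand)) return(list(Tb = Tb, basis = basis, status = 0L))
      e <- min(cand)                       # Bland: lowest-index entering
      col <- Tb[, e]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tb = Tb, basis = basis, status = 2L))
      ratio <- Tb[pos, ncol(Tb)] / col[pos]
      rmin <- min(ratio)
      lv <- pos[ratio <= rmin + tol]
      r <- lv[which.min(basis[lv])]        # Bland: lowest-index leaving
      Tb <- pivot(Tb, r, e)
      basis[r] <- e
    }
  }

  if (nart > 0) {
    c1 <- c(rep(0, n + nslack), rep(1, nart))
    res <- run(Tb, basis, c1, ntot)
    if (res$status != 0L) return(list(status = 1L))
    Tb <- res$Tb; basis <- res$basis
    if (sum(c1[basis] * Tb[, ncol(Tb)]) > 1e-7) return(list(status = 1L))
    # drive zero-level artificials out of the basis; redundant rows dropped
    drop_rows <- integer(0)
    for (r in which(basis > n + nslack)) {
      nonbasic <- setdiff(seq_len(n + nslack), basis)
      piv <- nonbasic[abs(Tb[r, nonbasic]) > tol]
      if (length(piv)) {
        Tb <- pivot(Tb, r, piv[1])
        basis[r] <- piv[1]
      } else {
        drop_rows <- c(drop_rows, r)
      }
    }
    if (length(drop_rows)) {
      Tb <- Tb[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
    }
    Tb <- Tb[, c(seq_len(n + nslack), ntot + 1L), drop = FALSE]
    ntot <- n + nslack
  }

  c2 <- c(obj, rep(0, nslack))
  res <- run(Tb, basis, c2, ntot)
  if (res$status != 0L) return(list(status = res$status))
  x <- numeric(ntot)
  x[res$basis] <- res$Tb[, ncol(res$Tb)]
  val <- sum(obj * x[seq_len(n)])
  list(status = 0L, x = x[seq_len(n)], value = if (maximize) -val else val)
}
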