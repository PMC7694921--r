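# Input-oriented data envelopment analysis: CCR (constant returns) and
# BCC (variable returns) envelopment programs, two-phase slack
# maximisation, the TE = PTE x SE decomposition and slack-based
# input/output adjustment targets.

#' Specify a DEA model
#'
#' Names the panel fields entering the input and output matrices.  Fields
#' with a \code{"_per1000"} suffix are computed as densities per 1000
#' persons via \code{\link{derive_density}}; all other fields are taken
#' as-is.  The default model uses five inputs (institutions, beds and
#' health workers per 1000 persons; government subsidies and total
#' expenditures in billions) and three outputs (outpatient volume in ten
#' thousands, annual hospitalization rate in percent, general income in
#' billions).
#'
#' @param inputs character vector of input field names.
#' @param outputs character vector of output field names.
#' @return object of class \code{dea_model}.
#' @export
dea_model <- function(inputs = c("institutions_per1000", "beds_per1000",
                                 "health_workers_per1000", "gov_subsidy_bn",
                                 "total_expenditure_bn"),
                      outputs = c("outpatient_10k", "hosp_rate_pct",
                                  "general_income_bn")) {
  stopifnot(length(inputs) >= 1, length(outputs) >= 1)
  known <- c(resource_fields(),
             paste0(c("institutions", "beds", "health_workers"), "_per1000"))
  bad <- setdiff(c(inputs, outputs), known)
  if (length(bad))
    stop_hera("hera_schema_error",
              paste0("unknown model field(s): ", paste(bad, collapse = ", ")))
  structure(list(inputs = inputs, outputs = outputs, orientation = "input"),
            class = "dea_model")
}

#' Extract DEA input/output matrices for one year
#'
#' @param panel a \code{\link{resource_panel}}.
#' @param year year present in the panel.
#' @param model a \code{\link{dea_model}}.
#' @return list with matrices \code{X} (n x m inputs) and \code{Y}
#'   (n x s outputs), rows named by city.
#' @export
dea_matrices <- function(panel, year, model = dea_model()) {
  if (!year %in% panel$year)
    stop_hera("hera_lookup_error", paste0("year not in panel: ", year))
  sl <- panel[panel$year == year, ]
  col <- function(f) {
    if (grepl("_per1000$", f)) {
      base <- sub("_per1000$", "", f)
      sl[[base]] / sl$population_thousand
    } else sl[[f]]
  }
  X <- sapply(model$inputs, col)
  Y <- sapply(model$outputs, col)
  X <- matrix(X, nrow = nrow(sl), dimnames = list(sl$city, model$inputs))
  Y <- matrix(Y, nrow = nrow(sl), dimnames = list(sl$city, model$outputs))
  if (any(X <= 0))
    stop_hera("hera_validation_error",
              "DEA requires strictly positive inputs")
  if (any(apply(Y, 1, max) <= 0))
    stop_hera("hera_validation_error",
              "every DMU needs at least one positive output")
  list(X = X, Y = Y)
}

# rescale columns to unit mean for LP conditioning; theta is invariant
scale_unit_mean <- function(M) sweep(M, 2, colMeans(M), "/")

#' Solve one input-oriented envelopment program
#'
#' Minimises the radial contraction \eqn{\theta} subject to
#' \eqn{\sum_j \lambda_j x_j \le \theta x_0},
#' \eqn{\sum_j \lambda_j y_j \ge y_0}, \eqn{\lambda \ge 0}, plus
#' \eqn{\sum_j \lambda_j = 1} under variable returns to scale.  The
#' evaluated point defaults to a row of the frontier data but may be any
#' external point (used for cross-period Malmquist distances, where
#' \eqn{\theta} can exceed 1).
#'
#' @param dmu index of the evaluated DMU in \code{X}/\code{Y}, or
#'   \code{NULL} when \code{x0}/\code{y0} are given.
#' @param X n x m input matrix of the frontier-defining DMUs (positive).
#' @param Y n x s output matrix (non-negative, each DMU with at least one
#'   positive output).
#' @param rts \code{"crs"} or \code{"vrs"}.
#' @param x0,y0 input/output vectors of the evaluated point (default: row
#'   \code{dmu}).
#' @return list with \code{theta} and the intensity vector
#'   \code{lambda}.
#' @export
#' @examples
#' X <- matrix(c(2, 4, 1), 3, 1); Y <- matrix(c(4, 4, 1), 3, 1)
#' solve_envelopment(2, X, Y, "crs")$theta   # 0.5
solve_envelopment <- function(dmu = NULL, X, Y, rts = c("crs", "vrs"),
                              x0 = NULL, y0 = NULL) {
  rts <- match.arg(rts)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  if (is.null(x0)) x0 <- X[dmu, ]
  if (is.null(y0)) y0 <- Y[dmu, ]
  cx <- colMeans(X); cy <- colMeans(Y)
  Xs <- scale_unit_mean(X); Ys <- scale_unit_mean(Y)
  x0s <- x0 / cx; y0s <- y0 / cy
  A <- rbind(cbind(-x0s, t(Xs)), cbind(rep(0, s), t(Ys)))
  b <- c(rep(0, m), y0s)
  dir <- c(rep("<=", m), rep(">=", s))
  if (rts == "vrs") {
    A <- rbind(A, c(0, rep(1, n)))
    b <- c(b, 1)
    dir <- c(dir, "==")
  }
  r <- lp_simplex(c(1, rep(0, n)), A, b, dir, maximize = FALSE)
  if (r$status != 0L)
    stop_hera("hera_solver_error",
              paste0("envelopment LP not solvable (status ", r$status,
                     ") for DMU ",
                     if (!is.null(dmu)) rownames(X)[dmu] %||% dmu else "<external>"))
  list(theta = r$value, lambda = stats::setNames(r$x[-1], rownames(X)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phase-2 slack maximisation
#'
#' With the radial score \eqn{\theta} fixed, maximises the sum of input
#' and output slacks subject to
#' \eqn{\sum_j \lambda_j x_j + s^- = \theta x_0} and
#' \eqn{\sum_j \lambda_j y_j - s^+ = y_0}, so the projected point
#' \eqn{(\theta x_0 - s^-, y_0 + s^+)} is frontier-dominating.  Slacks
#' are maximised on unit-mean-scaled columns (making the phase-2
#' objective units-invariant) and reported in original units.
#'
#' @inheritParams solve_envelopment
#' @param theta radial score from \code{\link{solve_envelopment}}.
#' @return list with \code{input_slacks}, \code{output_slacks} (original
#'   units, \code{>= 0}) and \code{lambda}.
#' @export
max_slacks <- function(dmu = NULL, theta, X, Y, rts = c("crs", "vrs"),
                       x0 = NULL, y0 = NULL) {
  rts <- match.arg(rts)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  if (is.null(x0)) x0 <- X[dmu, ]
  if (is.null(y0)) y0 <- Y[dmu, ]
  cx <- colMeans(X); cy <- colMeans(Y)
  Xs <- scale_unit_mean(X); Ys <- scale_unit_mean(Y)
  A <- rbind(cbind(t(Xs), diag(m), matrix(0, m, s)),
             cbind(t(Ys), matrix(0, s, m), -diag(s)))
  b <- c(theta * x0 / cx, y0 / cy)
  dir <- rep("==", m + s)
  if (rts == "vrs") {
    A <- rbind(A, c(rep(1, n), rep(0, m + s)))
    b <- c(b, 1)
    dir <- c(dir, "==")
  }
  r <- lp_simplex(c(rep(0, n), rep(1, m + s)), A, b, dir, maximize = TRUE)
  if (r$status != 0L)
    stop_hera("hera_solver_error",
              paste0("slack LP not solvable (status ", r$status, ")"))
  sin <- pmax(r$x[n + seq_len(m)], 0) * cx
  sout <- pmax(r$x[n + m + seq_len(s)], 0) * cy
  list(input_slacks = stats::setNames(sin, colnames(X)),
       output_slacks = stats::setNames(sout, colnames(Y)),
       lambda = stats::setNames(r$x[seq_len(n)], rownames(X)))
}

#' Yearly DEA efficiency table
#'
#' Runs the CCR (CRS) and BCC (VRS) input-oriented envelopment programs
#' for every city against that year's own frontier and decomposes overall
#' technical efficiency as TE = PTE x SE.  Slacks and peers come from the
#' phase-2 VRS solution.
#'
#' @inheritParams dea_matrices
#' @param efficient_tol scores within this distance of 1 are classified
#'   as efficient in printing (raw scores are kept in the data).
#' @return object of class \code{dea_efficiency}: list with \code{scores}
#'   (data frame: city, te, pte, se, peers), \code{input_slacks},
#'   \code{output_slacks} (matrices), \code{summary} (mean/max/min of
#'   te, pte, se), \code{year}, \code{model}, and the matrices used.
#' @export
dea_efficiency <- function(panel, year, model = dea_model(),
                           efficient_tol = 1e-6) {
  mats <- dea_matrices(panel, year, model)
  X <- mats$X; Y <- mats$Y
  n <- nrow(X)
  te <- pte <- numeric(n)
  Sin <- matrix(0, n, ncol(X), dimnames = dimnames(X))
  Sout <- matrix(0, n, ncol(Y), dimnames = dimnames(Y))
  peers <- character(n)
  lambdas <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (j in seq_len(n)) {
    te[j] <- min(solve_envelopment(j, X, Y, "crs")$theta, 1)
    vr <- solve_envelopment(j, X, Y, "vrs")
    pte[j] <- min(vr$theta, 1)
    sl <- max_slacks(j, pte[j], X, Y, "vrs")
    Sin[j, ] <- sl$input_slacks
    Sout[j, ] <- sl$output_slacks
    lambdas[j, ] <- sl$lambda
    pk <- which(sl$lambda > 1e-7)
    peers[j] <- paste(rownames(X)[pk], collapse = ";")
  }
  scores <- data.frame(city = rownames(X), te = te, pte = pte,
                       se = te / pte, peers = peers, row.names = NULL,
                       stringsAsFactors = FALSE)
  summ <- data.frame(
    stat = c("mean", "max", "min"),
    te = c(mean(te), max(te), min(te)),
    pte = c(mean(pte), max(pte), min(pte)),
    se = c(mean(scores$se), max(scores$se), min(scores$se)))
  structure(list(scores = scores, input_slacks = Sin, output_slacks = Sout,
                 lambdas = lambdas, summary = summ, year = year,
                 model = model, X = X, Y = Y,
                 efficient_tol = efficient_tol),
            class = "dea_efficiency")
}

#' @export
print.dea_efficiency <- function(x, ...) {
  cat("Input-oriented DEA, year ", x$year, " (", nrow(x$scores),
      " DMUs, ", ncol(x$X), " inputs, ", ncol(x$Y), " outputs)\n", sep = "")
  df <- x$scores
  df$te <- round(df$te, 3); df$pte <- round(df$pte, 3); df$se <- round(df$se, 3)
  print(df)
  cat("summary:\n")
  s <- x$summary; s[2:4] <- round(s[2:4], 3)
  print(s)
  invisible(x)
}

#' Slack-based adjustment targets
#'
#' For every city, the signed change needed to reach the BCC (VRS)
#' frontier: input variation \eqn{(\theta_{VRS} - 1) x_i - s^-_i \le 0}
#' (radial contraction plus residual slack) and output variation
#' \eqn{+s^+_r \ge 0}.  Cities that are VRS-efficient with zero slacks
#' emit all-zero rows.
#'
#' @param eff a \code{\link{dea_efficiency}} result.
#' @return data frame with one row per city: the input variation columns
#'   (named \code{d_<input>}, all \code{<= 0}) and output variation
#'   columns (named \code{d_<output>}, all \code{>= 0}).
#' @export
dea_adjustments <- function(eff) {
  stopifnot(inherits(eff, "dea_efficiency"))
  X <- eff$X; Y <- eff$Y
  dv_in <- sweep(X, 1, eff$scores$pte - 1, "*") - eff$input_slacks
  dv_in[abs(dv_in) < 1e-9] <- 0
  dv_out <- eff$output_slacks
  dv_out[abs(dv_out) < 1e-9] <- 0
  out <- data.frame(city = eff$scores$city, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(X))) out[[paste0("d_", colnames(X)[i])]] <- dv_in[, i]
  for (r in seq_len(ncol(Y))) out[[paste0("d_", colnames(Y)[r])]] <- dv_out[, r]
  out
}
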