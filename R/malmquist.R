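# Adjacent-period Malmquist productivity indices in the geometric-mean
# (Fare-Grosskopf-Lindgren-Roos) form, with the decompositions
# TFPC = TEC x TC and TEC = PTEC x SEC.

#' Distance of a point to a period's frontier
#'
#' Input-oriented radial distance of the point \code{(x0, y0)} to the
#' frontier spanned by \code{frontier_X}/\code{frontier_Y}.  Same-period
#' evaluation of an observed DMU returns \eqn{\theta \in (0, 1]};
#' cross-period evaluation may exceed 1 (the point lies beyond the other
#' period's frontier).  CRS cross-period evaluation is always feasible on
#' positive data; an infeasible program raises a solver error.
#'
#' @param x0,y0 input and output vectors of the evaluated point.
#' @param frontier_X,frontier_Y matrices of the frontier-defining DMUs.
#' @param rts \code{"crs"} or \code{"vrs"}.
#' @return the radial distance (a positive scalar).
#' @export
#' @examples
#' cross_distance(1, 2, matrix(1), matrix(1))   # 2
cross_distance <- function(x0, y0, frontier_X, frontier_Y,
                           rts = c("crs", "vrs")) {
  rts <- match.arg(rts)
  solve_envelopment(NULL, frontier_X, frontier_Y, rts,
                    x0 = x0, y0 = y0)$theta
}

#' Malmquist indices for one adjacent year pair
#'
#' For every city, with \eqn{D^a(b)} the CRS input-oriented distance of
#' the city's period-\eqn{b} point to the period-\eqn{a} frontier:
#' \deqn{TEC = D^{t+1}(t+1) / D^{t}(t)}
#' \deqn{TC = \sqrt{\frac{D^{t}(t+1)}{D^{t+1}(t+1)} \cdot
#'                  \frac{D^{t}(t)}{D^{t+1}(t)}}}
#' \deqn{TFPC = TEC \times TC}
#' PTEC is the same ratio under VRS (same-period evaluations only, so the
#' cross-period VRS infeasibility pathology never arises) and
#' \eqn{SEC = TEC / PTEC}.  Both decomposition identities hold to
#' construction precision.
#'
#' @param panel a \code{\link{resource_panel}} containing years \code{t}
#'   and \code{t + 1}.
#' @param t first year of the pair.
#' @param model a \code{\link{dea_model}}.
#' @return data frame with columns city, t, tec, tc, ptec, sec, tfpc.
#' @export
malmquist_pair <- function(panel, t, model = dea_model()) {
  yrs <- panel_years(panel)
  if (!(t %in% yrs) || !((t + 1) %in% yrs))
    stop_hera("hera_lookup_error",
              paste0("years ", t, " and ", t + 1, " must both be in the panel"))
  m1 <- dea_matrices(panel, t, model)
  m2 <- dea_matrices(panel, t + 1, model)
  stopifnot(identical(rownames(m1$X), rownames(m2$X)))
  n <- nrow(m1$X)
  out <- data.frame(city = rownames(m1$X), t = t, tec = NA_real_,
                    tc = NA_real_, ptec = NA_real_, sec = NA_real_,
                    tfpc = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    d_t_t   <- solve_envelopment(j, m1$X, m1$Y, "crs")$theta
    d_s_s   <- solve_envelopment(j, m2$X, m2$Y, "crs")$theta
    d_t_s   <- cross_distance(m2$X[j, ], m2$Y[j, ], m1$X, m1$Y, "crs")
    d_s_t   <- cross_distance(m1$X[j, ], m1$Y[j, ], m2$X, m2$Y, "crs")
    v_t_t   <- solve_envelopment(j, m1$X, m1$Y, "vrs")$theta
    v_s_s   <- solve_envelopment(j, m2$X, m2$Y, "vrs")$theta
    tec <- d_s_s / d_t_t
    tc <- sqrt((d_t_s / d_s_s) * (d_t_t / d_s_t))
    ptec <- v_s_s / v_t_t
    out$tec[j] <- tec
    out$tc[j] <- tc
    out$ptec[j] <- ptec
    out$sec[j] <- tec / ptec
    out$tfpc[j] <- tec * tc
  }
  out
}

#' Malmquist indices over all adjacent year pairs
#'
#' @inheritParams malmquist_pair
#' @param years years to use (default: all panel years); consecutive
#'   entries form the evaluated pairs.
#' @return object of class \code{malmquist_result}: data frame of
#'   \code{\link{malmquist_pair}} rows over all adjacent pairs.
#' @export
malmquist <- function(panel, model = dea_model(), years = NULL) {
  if (is.null(years)) years <- panel_years(panel)
  years <- sort(years)
  if (length(years) < 2)
    stop_hera("hera_lookup_error", "need at least two years")
  recs <- do.call(rbind, lapply(years[-length(years)], function(t)
    malmquist_pair(panel, t, model)))
  structure(recs, class = c("malmquist_result", "data.frame"),
            model = model)
}

#' Summarise Malmquist records
#'
#' Geometric means of every component by year pair or by city (the
#' convention for reporting Malmquist tables; arithmetic means available
#' for sensitivity), plus per-component frequency counts of records
#' \code{> 1}, \code{= 1} (within 1e-9) and \code{< 1}.
#'
#' @param records data frame from \code{\link{malmquist}} or
#'   \code{\link{malmquist_pair}}.
#' @param by \code{"year"} (one row per adjacent pair, aggregated over
#'   cities) or \code{"city"} (one row per city, aggregated over pairs).
#' @param mean_type \code{"geometric"} (default) or \code{"arithmetic"}.
#' @return data frame with columns key, tec, tc, ptec, sec, tfpc, n, and
#'   frequency columns \code{<component>_gt1/_eq1/_lt1} for every
#'   component.
#' @export
malmquist_summary <- function(records, by = c("year", "city"),
                              mean_type = c("geometric", "arithmetic")) {
  by <- match.arg(by)
  mean_type <- match.arg(mean_type)
  stopifnot(nrow(records) >= 1)
  comp <- c("tec", "tc", "ptec", "sec", "tfpc")
  keyv <- if (by == "year") paste0(records$t, "-", records$t + 1)
          else records$city
  mfun <- if (mean_type == "geometric") function(v) exp(mean(log(v)))
          else mean
  keys <- unique(keyv)
  out <- NULL
  for (k in keys) {
    sel <- records[keyv == k, ]
    row <- data.frame(key = k, n = nrow(sel), stringsAsFactors = FALSE)
    for (cc in comp) {
      v <- sel[[cc]]
      row[[cc]] <- mfun(v)
      row[[paste0(cc, "_gt1")]] <- sum(v > 1 + 1e-9)
      row[[paste0(cc, "_eq1")]] <- sum(abs(v - 1) <= 1e-9)
      row[[paste0(cc, "_lt1")]] <- sum(v < 1 - 1e-9)
    }
    out <- rbind(out, row)
  }
  out[c("key", "n", comp, as.vector(t(outer(comp, c("_gt1", "_eq1", "_lt1"),
                                            paste0))))]
}
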