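# Equity measures: weighted Lorenz curve and Gini coefficient, Theil index
# with intra/inter-group decomposition and contribution rates, and the
# health resource density index (HRDI).

#' Weighted Lorenz curve
#'
#' Orders units by resource-per-basis ratio (ascending; ties broken by
#' unit identifier so the curve is deterministic) and accumulates shares.
#' The x axis carries the cumulative basis share (population or area), the
#' y axis the cumulative resource share, with the origin prepended, so an
#' allocation proportional to the basis lies on the 45-degree diagonal.
#'
#' @param resource per-unit resource amounts, all \code{>= 0} with a
#'   positive total.
#' @param basis per-unit basis amounts (population or area), all
#'   \code{> 0}.
#' @param ids optional unit identifiers used for deterministic
#'   tie-breaking; defaults to position.
#' @return object of class \code{lorenz_curve}: data frame with columns
#'   \code{x}, \code{y} (both in [0, 1], starting at (0, 0) and ending at
#'   (1, 1)) plus the ordering attribute \code{order}.
#' @export
#' @examples
#' lorenz_curve(c(0, 1), c(1, 1))
lorenz_curve <- function(resource, basis, ids = NULL) {
  stopifnot(length(resource) == length(basis), all(is.finite(resource)),
            all(is.finite(basis)))
  if (any(resource < 0))
    stop_hera("hera_validation_error", "resource values must be >= 0")
  if (any(basis <= 0))
    stop_hera("hera_validation_error", "basis values must be > 0")
  if (sum(resource) <= 0)
    stop_hera("hera_degenerate_error", "total resource is zero")
  if (is.null(ids)) ids <- seq_along(resource)
  ord <- order(resource / basis, ids)
  x <- c(0, cumsum(basis[ord]) / sum(basis))
  y <- c(0, cumsum(resource[ord]) / sum(resource))
  structure(data.frame(x = x, y = y),
            order = ids[ord], class = c("lorenz_curve", "data.frame"))
}

#' Weighted Gini coefficient
#'
#' Trapezoid-rule Gini on the weighted Lorenz curve:
#' \deqn{G = 1 - \sum_i (x_{i+1} - x_i)(y_{i+1} + y_i)}
#' with units sorted ascending by resource-per-basis ratio.  Equals twice
#' the area between the curve and the equality diagonal; 0 means the
#' resource is allocated exactly proportionally to the basis.
#'
#' @inheritParams lorenz_curve
#' @return Gini coefficient in [0, 1).
#' @export
#' @examples
#' gini(c(0, 1), c(1, 1))   # 0.5
gini <- function(resource, basis, ids = NULL) {
  lc <- lorenz_curve(resource, basis, ids)
  n <- nrow(lc)
  dx <- diff(lc$x)
  sy <- lc$y[-1] + lc$y[-n]
  g <- 1 - sum(dx * sy)
  if (g < -1e-12) stop("internal error: negative Gini")
  min(max(g, 0), 1 - .Machine$double.eps)
}

#' Total Theil index
#'
#' \deqn{T = \sum_i P_i \log(P_i / E_i)} where \eqn{P_i} are basis
#' (population or geography) shares and \eqn{E_i} resource shares.  Zero
#' iff the allocation is proportional to the basis; always \code{>= 0} by
#' Gibbs' inequality.  Natural logarithm by default; base-10 optionally
#' (the index scales by \code{1/log(10)}, all decomposition identities are
#' base-invariant).
#'
#' @param p basis shares, all \code{> 0}, summing to 1 (tolerance 1e-9).
#' @param e resource shares, all \code{> 0}, summing to 1.
#' @param log_base \code{"natural"} or \code{"base10"}.
#' @return the Theil index (non-negative scalar).
#' @export
theil_total <- function(p, e, log_base = c("natural", "base10")) {
  log_base <- match.arg(log_base)
  stopifnot(length(p) == length(e))
  if (any(e <= 0 & p > 0))
    stop_hera("hera_divergence_error",
              "zero resource share with positive basis share: Theil diverges; merge or drop such units explicitly")
  if (any(p <= 0))
    stop_hera("hera_validation_error", "basis shares must be > 0")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(e) - 1) > 1e-9)
    stop_hera("hera_validation_error", "shares must each sum to 1")
  lg <- if (log_base == "natural") log else log10
  sum(p * lg(p / e))
}

#' Theil index decomposition by region
#'
#' Splits the total Theil index into an intra-regional part
#' \eqn{T_{intra} = \sum_g P_g T_g} (with \eqn{T_g} the Theil index of the
#' within-group shares, renormalised to sum to 1 inside the group) and an
#' inter-regional part \eqn{T_{inter} = \sum_g P_g \log(P_g / E_g)}.  The
#' identity \eqn{T = T_{intra} + T_{inter}} is exact; it is recomputed
#' directly and checked to 1e-10.  Contribution rates are
#' \code{intra/total} and \code{inter/total}.
#'
#' @inheritParams theil_total
#' @param group group label per unit.
#' @return object of class \code{theil_decomposition}: list with
#'   \code{total}, \code{intra}, \code{inter}, \code{contribution_intra},
#'   \code{contribution_inter}, \code{log_base}, and \code{per_group}
#'   (data frame: group, p, e, theil, share_of_intra).
#' @export
theil_decompose <- function(p, e, group, log_base = c("natural", "base10")) {
  log_base <- match.arg(log_base)
  stopifnot(length(p) == length(e), length(group) == length(p))
  total <- theil_total(p, e, log_base)
  lg <- if (log_base == "natural") log else log10
  group <- as.character(group)
  gl <- sort(unique(group))
  pg <- vapply(gl, function(g) sum(p[group == g]), 0)
  eg <- vapply(gl, function(g) sum(e[group == g]), 0)
  if (any(eg <= 0))
    stop_hera("hera_divergence_error", "group with zero total resource")
  tg <- vapply(gl, function(g) {
    sel <- group == g
    theil_total(p[sel] / sum(p[sel]), e[sel] / sum(e[sel]), log_base)
  }, 0)
  intra <- sum(pg * tg)
  inter <- sum(pg * lg(pg / eg))
  if (abs(total - (intra + inter)) > 1e-10)
    stop("internal error: Theil decomposition identity violated")
  ci <- if (total > 0) intra / total else NA_real_
  structure(list(
    total = total, intra = intra, inter = inter,
    contribution_intra = ci,
    contribution_inter = if (total > 0) 1 - ci else NA_real_,
    log_base = log_base,
    per_group = data.frame(group = gl, p = pg, e = eg, theil = tg,
                           share_of_intra = if (intra > 0) pg * tg / intra
                                            else rep(NA_real_, length(gl)),
                           row.names = NULL)),
    class = "theil_decomposition")
}

#' @export
print.theil_decomposition <- function(x, ...) {
  cat(sprintf("Theil decomposition (%s log): total %.6f = intra %.6f + inter %.6f\n",
              x$log_base, x$total, x$intra, x$inter))
  if (!is.na(x$contribution_intra))
    cat(sprintf("  contribution: intra %.2f%%, inter %.2f%%\n",
                100 * x$contribution_intra, 100 * x$contribution_inter))
  print(x$per_group)
  invisible(x)
}

#' Health resource density index
#'
#' \deqn{HRDI = HR / \sqrt{A \cdot P}} -- the resource amount divided by
#' the geometric mean of land area (km2) and population (thousand
#' persons).  Balances the population-only and geography-only views of
#' resource agglomeration.  Vectorised; a merged region's HRDI must be
#' computed from summed resource, area and population (it is not the mean
#' of member HRDIs).
#'
#' @param resource resource amounts, \code{>= 0}.
#' @param area land areas in km2, \code{> 0}.
#' @param population populations in thousand persons, \code{> 0}.
#' @return numeric vector of HRDI values.
#' @export
#' @examples
#' hrdi(10, 4, 9)   # 10/6
hrdi <- function(resource, area, population) {
  if (any(!is.finite(area)) || any(area <= 0) ||
      any(!is.finite(population)) || any(population <= 0))
    stop_hera("hera_validation_error", "area and population must be > 0")
  if (any(resource < 0))
    stop_hera("hera_validation_error", "resource must be >= 0")
  resource / sqrt(area * population)
}

# ---- panel-level tables ----------------------------------------------------

panel_basis <- function(sl, basis) {
  if (basis == "population") sl$population_thousand else sl$area_km2
}

#' Gini coefficients per year, resource and basis
#'
#' @param panel a \code{\link{resource_panel}}.
#' @param resources indicator fields to assess.
#' @param bases one or both of \code{"population"}, \code{"area"}.
#' @return data frame with columns year, resource, basis, gini.
#' @export
gini_table <- function(panel, resources = resource_fields(),
                       bases = c("population", "area")) {
  out <- expand.grid(year = panel_years(panel), resource = resources,
                     basis = bases, stringsAsFactors = FALSE)
  out$gini <- mapply(function(y, r, b) {
    sl <- panel[panel$year == y, ]
    gini(sl[[r]], panel_basis(sl, b), sl$city)
  }, out$year, out$resource, out$basis)
  out[order(out$resource, out$basis, out$year), ]
}

#' Theil decomposition per year and resource
#'
#' Mirrors the layout of the published provincial tables: the total index
#' with intra-/inter-regional contribution rates (in percent), per-region
#' Theil indices and each region's share of the intra-regional part.
#'
#' @inheritParams gini_table
#' @param basis \code{"population"} or \code{"area"} shares for
#'   \eqn{P_i}.
#' @param log_base passed to \code{\link{theil_decompose}}.
#' @return list of two data frames: \code{totals} (year, resource, theil,
#'   contrib_intra_pct, contrib_inter_pct) and \code{regions} (year,
#'   resource, region, theil_g, share_of_intra_pct).
#' @export
theil_table <- function(panel, resources = resource_fields(),
                        basis = c("population", "area"),
                        log_base = c("natural", "base10")) {
  basis <- match.arg(basis)
  log_base <- match.arg(log_base)
  totals <- NULL; regions <- NULL
  for (y in panel_years(panel)) {
    sl <- panel[panel$year == y, ]
    b <- panel_basis(sl, basis)
    for (r in resources) {
      td <- theil_decompose(b / sum(b), sl[[r]] / sum(sl[[r]]),
                            sl$region, log_base)
      totals <- rbind(totals, data.frame(
        year = y, resource = r, theil = td$total,
        contrib_intra_pct = 100 * td$contribution_intra,
        contrib_inter_pct = 100 * td$contribution_inter))
      pg <- td$per_group
      regions <- rbind(regions, data.frame(
        year = y, resource = r, region = pg$group, theil_g = pg$theil,
        share_of_intra_pct = 100 * pg$share_of_intra))
    }
  }
  list(totals = totals, regions = regions)
}

#' HRDI per city or per region
#'
#' @inheritParams gini_table
#' @param by \code{"city"} or \code{"region"}; regional values use summed
#'   resource, area and population.
#' @return data frame with columns year, resource, unit, hrdi.
#' @export
hrdi_table <- function(panel, resources = resource_fields(),
                       by = c("city", "region")) {
  by <- match.arg(by)
  out <- NULL
  for (y in panel_years(panel)) {
    sl <- panel[panel$year == y, ]
    if (by == "region") {
      agg <- function(v) tapply(v, sl$region, sum)
      units <- sort(unique(sl$region))
      a <- agg(sl$area_km2)[units]; p <- agg(sl$population_thousand)[units]
      for (r in resources)
        out <- rbind(out, data.frame(year = y, resource = r, unit = units,
                                     hrdi = as.numeric(hrdi(agg(sl[[r]])[units], a, p))))
    } else {
      for (r in resources)
        out <- rbind(out, data.frame(year = y, resource = r, unit = sl$city,
                                     hrdi = hrdi(sl[[r]], sl$area_km2,
                                                 sl$population_thousand)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Plot a Lorenz curve
#'
#' Draws the curve against the 45-degree equality diagonal.
#'
#' @param x a \code{lorenz_curve}.
#' @param main plot title.
#' @param ... passed to \code{plot}.
#' @export
plot.lorenz_curve <- function(x, main = "Lorenz curve", ...) {
  graphics::plot(x$x, x$y, type = "l", lwd = 2, col = "steelblue",
                 xlab = "cumulative basis share",
                 ylab = "cumulative resource share", main = main,
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  invisible(x)
}
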