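# Seeded synthetic city-year panels with controllable regional inequality,
# and a known (Cobb-Douglas) production technology for DEA/Malmquist
# ground truth.  The generator emulates the qualitative regime of a
# 13-city, 3-zone, 5-year provincial panel -- inter-regional differences
# dominating for beds, health workers and finance, near-proportional
# allocation of institutions, monotone resource growth -- but its values
# are synthetic stand-ins, not any province's ground truth.

#' Configuration for the synthetic panel generator
#'
#' Defaults describe a 13-city, 3-region, 2014-2018 panel.  City sizes are
#' log-normal per region (population in thousand persons, area in km2,
#' totalling roughly 80 million persons and 107,000 km2).  Each resource
#' has a per-capita scale, regional multipliers (which control how much of
#' the Theil index is inter-regional), a within-region log-normal
#' dispersion (coefficient of variation), and an annual growth rate.
#' With the default multipliers, beds/health-worker/financial inequality
#' is predominantly inter-regional (southern cities systematically better
#' endowed per capita) while institutions are allocated nearly
#' proportionally to population.
#'
#' @param n_cities named integer vector: cities per region.
#' @param years calendar years of the balanced panel.
#' @param pop_meanlog,pop_sdlog,area_meanlog,area_sdlog log-normal size
#'   parameters (meanlogs per region, in log thousand-persons / log km2).
#' @param percap named per-capita scale of each resource (units per
#'   thousand persons).
#' @param multipliers named list: per resource, the per-region relative
#'   per-capita endowment (all \code{> 0}).
#' @param cv named within-region coefficient of variation per resource
#'   (\code{>= 0}).
#' @param growth named annual growth rate per resource.
#' @param year_jitter_sd log-scale sd of the idiosyncratic year-on-year
#'   wobble around the deterministic growth path.
#' @param hosp_rate_base,hosp_rate_sd mean and sd (percentage points) of
#'   the annual hospitalization rate.
#' @param city_names optional city names; defaults to the
#'   \code{\link{jiangsu_scheme}} cities when the region layout matches,
#'   synthetic labels otherwise.
#' @param seed integer seed; the generator is deterministic given it.
#' @return object of class \code{panel_gen_config}.
#' @export
panel_gen_config <- function(
    n_cities = c(south = 5, middle = 3, north = 5),
    years = 2014:2018,
    pop_meanlog = c(south = 8.9, middle = 8.5, north = 8.6),
    pop_sdlog = 0.35,
    area_meanlog = c(south = 8.85, middle = 8.95, north = 9.15),
    area_sdlog = 0.25,
    percap = c(institutions = 0.41, beds = 5.5, health_workers = 8.2,
               gov_subsidy_bn = 3.5e-4, total_expenditure_bn = 2.75e-3,
               outpatient_10k = 0.66, general_income_bn = 2.4e-3),
    multipliers = list(
      institutions         = c(south = 0.95, middle = 1.00, north = 1.10),
      beds                 = c(south = 1.35, middle = 1.00, north = 0.75),
      health_workers       = c(south = 1.40, middle = 1.00, north = 0.72),
      gov_subsidy_bn       = c(south = 1.90, middle = 1.00, north = 0.55),
      total_expenditure_bn = c(south = 1.70, middle = 1.00, north = 0.65),
      outpatient_10k       = c(south = 1.30, middle = 1.00, north = 0.80),
      general_income_bn    = c(south = 1.60, middle = 1.00, north = 0.70)),
    cv = c(institutions = 0.08, beds = 0.12, health_workers = 0.12,
           gov_subsidy_bn = 0.25, total_expenditure_bn = 0.20,
           outpatient_10k = 0.12, general_income_bn = 0.15),
    growth = c(institutions = 0.005, beds = 0.055, health_workers = 0.058,
               gov_subsidy_bn = 0.165, total_expenditure_bn = 0.12,
               outpatient_10k = 0.05, general_income_bn = 0.11),
    year_jitter_sd = 0.02,
    hosp_rate_base = 16, hosp_rate_sd = 1.5,
    city_names = NULL,
    seed = 1234L) {
  regions <- names(n_cities)
  res <- names(percap)
  stopifnot(length(regions) >= 1, all(n_cities >= 1),
            length(years) >= 1,
            setequal(names(multipliers), res),
            setequal(names(cv), res), setequal(names(growth), res))
  if (any(unlist(multipliers) <= 0))
    stop_hera("hera_validation_error", "multipliers must be > 0")
  if (any(cv < 0) || year_jitter_sd < 0 || hosp_rate_sd < 0)
    stop_hera("hera_validation_error", "dispersion parameters must be >= 0")
  if (any(growth <= -1))
    stop_hera("hera_validation_error", "growth rates must exceed -1")
  for (r in res)
    if (!setequal(names(multipliers[[r]]), regions))
      stop_hera("hera_validation_error",
                paste0("multipliers for ", r, " must name every region"))
  structure(list(n_cities = n_cities, years = as.integer(years),
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 area_meanlog = area_meanlog, area_sdlog = area_sdlog,
                 percap = percap, multipliers = multipliers, cv = cv,
                 growth = growth, year_jitter_sd = year_jitter_sd,
                 hosp_rate_base = hosp_rate_base, hosp_rate_sd = hosp_rate_sd,
                 city_names = city_names, seed = as.integer(seed)),
            class = "panel_gen_config")
}

default_city_names <- function(config) {
  if (!is.null(config$city_names)) return(config$city_names)
  js <- jiangsu_scheme()
  if (identical(names(config$n_cities), names(js$groups)) &&
      all(config$n_cities == lengths(js$groups)))
    return(unlist(js$groups, use.names = FALSE))
  unlist(lapply(names(config$n_cities), function(r)
    paste0(r, "_", seq_len(config$n_cities[[r]]))))
}

# deterministic sub-stream: each draw family gets seed + fixed offset, so
# adding a resource does not perturb the draws of the others
substream <- function(seed, offset, expr) {
  withr::with_seed(seed + offset, expr)
}

#' Generate a synthetic balanced resource panel
#'
#' Deterministic given \code{config$seed}.  City populations and areas are
#' drawn once and held fixed over years; each resource value is
#' \code{percap * regional multiplier * population * exp(city effect) *
#' (1 + growth)^(year - first year) * exp(year jitter)}.  Each resource
#' uses its own sub-stream of the seed.
#'
#' @param config a \code{\link{panel_gen_config}}.
#' @return a validated \code{\link{resource_panel}}.
#' @export
#' @examples
#' p <- generate_panel(panel_gen_config(seed = 42))
#' gini(p$beds[p$year == 2014], p$population_thousand[p$year == 2014])
generate_panel <- function(config = panel_gen_config()) {
  stopifnot(inherits(config, "panel_gen_config"))
  regions <- names(config$n_cities)
  region_of_city <- rep(regions, config$n_cities)
  cities <- default_city_names(config)
  stopifnot(length(cities) == length(region_of_city))
  n <- length(cities)
  yrs <- config$years
  y0 <- min(yrs)
  seed <- config$seed

  pop <- substream(seed, 1L,
    stats::rlnorm(n, config$pop_meanlog[region_of_city], config$pop_sdlog))
  area <- substream(seed, 2L,
    stats::rlnorm(n, config$area_meanlog[region_of_city], config$area_sdlog))

  grid <- expand.grid(city = cities, year = yrs, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$region <- region_of_city[match(grid$city, cities)]
  grid$population_thousand <- pop[match(grid$city, cities)]
  grid$area_km2 <- area[match(grid$city, cities)]

  res <- names(config$percap)
  for (k in seq_along(res)) {
    r <- res[k]
    draws <- substream(seed, 10L + k, list(
      eff = stats::rnorm(n, 0, config$cv[[r]]),
      jit = matrix(stats::rnorm(n * length(yrs), 0, config$year_jitter_sd),
                   n, length(yrs))))
    base <- config$percap[[r]] *
      config$multipliers[[r]][region_of_city] * pop * exp(draws$eff)
    vals <- outer(base, (1 + config$growth[[r]])^(yrs - y0)) *
      exp(draws$jit)
    grid[[r]] <- vals[cbind(match(grid$city, cities),
                            match(grid$year, yrs))]
  }
  hr <- substream(seed, 100L, {
    base <- stats::rnorm(n, config$hosp_rate_base, config$hosp_rate_sd)
    jit <- matrix(stats::rnorm(n * length(yrs), 0, 0.3), n, length(yrs))
    pmin(pmax(outer(base, rep(1, length(yrs))) + jit, 1), 95)
  })
  grid$hosp_rate_pct <- hr[cbind(match(grid$city, cities),
                                 match(grid$year, yrs))]

  scheme <- region_scheme("synthetic", split(cities, region_of_city))
  resource_panel(grid, scheme = scheme)
}

#' Configuration for the production-frontier generator
#'
#' A log-linear (Cobb-Douglas) technology over chosen DEA input fields:
#' \deqn{y^*_{jt} = e^{a_0} \prod_k x_{kjt}^{\alpha_k} \cdot g^{t - t_0}}
#' with Hicks-neutral annual technology growth \code{g}, half-normal
#' technical inefficiency (outputs observed as
#' \eqn{y = y^* e^{-u}}, \eqn{u \sim |N(0, \sigma_u)|}, i.i.d. per
#' city-year) and optional log-normal measurement noise \eqn{\sigma_v}.
#' An elasticity sum of 1 gives constant returns to scale.  The aggregate
#' output is spread over \code{output_fields} in fixed proportions
#' \code{output_mix} (proportional outputs, so the multi-output frontier
#' is equivalent to a single-output one).
#'
#' @param input_fields DEA input field names (see \code{\link{dea_model}}).
#' @param elasticities non-negative Cobb-Douglas exponents, one per input.
#' @param log_a0 log of the technology intercept.
#' @param g annual Hicks-neutral technology growth factor (\code{> 0}).
#' @param sigma_u half-normal inefficiency scale (\code{>= 0}).
#' @param sigma_v log-normal noise sd (\code{>= 0}; 0 = deterministic
#'   frontier).
#' @param output_fields panel output fields receiving the produced
#'   output.
#' @param output_mix positive weights, one per output field (normalised
#'   to sum to 1).
#' @param seed integer seed for the inefficiency/noise draws.
#' @return object of class \code{frontier_gen_config}.
#' @export
frontier_gen_config <- function(
    input_fields = c("beds_per1000", "total_expenditure_bn"),
    elasticities = c(0.4, 0.6),
    log_a0 = 3,
    g = 1.05,
    sigma_u = 0.15,
    sigma_v = 0,
    output_fields = c("outpatient_10k", "general_income_bn"),
    output_mix = c(0.8, 0.2),
    seed = 4321L) {
  stopifnot(length(elasticities) == length(input_fields),
            length(output_mix) == length(output_fields))
  if (any(elasticities < 0))
    stop_hera("hera_validation_error", "elasticities must be >= 0")
  if (g <= 0 || sigma_u < 0 || sigma_v < 0)
    stop_hera("hera_validation_error",
              "need g > 0, sigma_u >= 0, sigma_v >= 0")
  if (any(output_mix <= 0))
    stop_hera("hera_validation_error", "output mix weights must be > 0")
  structure(list(input_fields = input_fields,
                 elasticities = elasticities, log_a0 = log_a0, g = g,
                 sigma_u = sigma_u, sigma_v = sigma_v,
                 output_fields = output_fields,
                 output_mix = output_mix / sum(output_mix),
                 seed = as.integer(seed)),
            class = "frontier_gen_config")
}

#' Generate a panel with a known production technology
#'
#' Draws a base panel with \code{\link{generate_panel}}, then overwrites
#' the configured output fields with frontier output x technology level x
#' drawn efficiency (x optional noise).  The returned truth table stores
#' every draw, so DEA and Malmquist estimates can be validated against
#' known efficiencies and the known technology path.
#'
#' @param config a \code{\link{frontier_gen_config}}.
#' @param base a \code{\link{panel_gen_config}} for the input side.
#' @return list with \code{panel} (a \code{\link{resource_panel}}),
#'   \code{truth} (data frame: city, year, true_efficiency, tech_level,
#'   frontier_output), and \code{model} (the matching
#'   \code{\link{dea_model}}).
#' @export
generate_frontier_panel <- function(config = frontier_gen_config(),
                                    base = panel_gen_config()) {
  stopifnot(inherits(config, "frontier_gen_config"),
            inherits(base, "panel_gen_config"))
  panel <- generate_panel(base)
  df <- as.data.frame(panel)
  yrs <- panel_years(panel)
  y0 <- min(yrs)
  n <- length(panel_cities(panel))
  draws <- substream(config$seed, 0L, list(
    u = matrix(abs(stats::rnorm(n * length(yrs), 0, config$sigma_u)),
               n, length(yrs)),
    v = matrix(stats::rnorm(n * length(yrs), 0, config$sigma_v),
               n, length(yrs))))
  truth <- NULL
  model <- dea_model(inputs = config$input_fields,
                     outputs = config$output_fields)
  for (iy in seq_along(yrs)) {
    y <- yrs[iy]
    sl <- df[df$year == y, ]
    Xc <- sapply(config$input_fields, function(f) {
      if (grepl("_per1000$", f))
        sl[[sub("_per1000$", "", f)]] / sl$population_thousand
      else sl[[f]]
    })
    Xc <- matrix(Xc, nrow = nrow(sl))
    ystar <- exp(config$log_a0 +
                   as.numeric(log(Xc) %*% config$elasticities)) *
      config$g^(y - y0)
    eff <- exp(-draws$u[, iy])
    yobs <- ystar * eff * exp(draws$v[, iy])
    for (r in seq_along(config$output_fields))
      df[df$year == y, config$output_fields[r]] <-
        config$output_mix[r] * yobs
    truth <- rbind(truth, data.frame(
      city = sl$city, year = y, true_efficiency = eff,
      tech_level = config$g^(y - y0), frontier_output = ystar))
  }
  list(panel = resource_panel(df, scheme = attr(panel, "region_scheme")),
       truth = truth, model = model)
}
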