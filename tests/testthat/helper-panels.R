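# Small panel builders used across the suite.

# balanced panel from per-city vectors; resources default to
# population-proportional values so equity indices are zero unless a
# field is overridden
toy_panel <- function(cities = c("A", "B", "C", "D"),
                      regions = c("s", "s", "n", "n"),
                      years = 2014:2015,
                      population = c(10, 20, 30, 40),
                      area = c(100, 200, 300, 400),
                      ...) {
  over <- list(...)
  rows <- expand.grid(city = cities, year = years,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  idx <- match(rows$city, cities)
  rows$region <- regions[idx]
  rows$population_thousand <- population[idx]
  rows$area_km2 <- area[idx]
  defaults <- list(institutions = 0.4, beds = 6, health_workers = 9,
                   gov_subsidy_bn = 3e-4, total_expenditure_bn = 3e-3,
                   outpatient_10k = 0.7, general_income_bn = 2e-3)
  for (f in names(defaults)) rows[[f]] <- defaults[[f]] * rows$population_thousand
  rows$hosp_rate_pct <- 15
  for (f in names(over)) rows[[f]] <- rep_len(over[[f]], nrow(rows))
  resource_panel(rows)
}

# brute-force O(n^2) weighted Gini: sum_ij w_i w_j |r_i - r_j| / (2 mu)
gini_pairwise <- function(resource, basis) {
  w <- basis / sum(basis)
  r <- resource / basis
  mu <- sum(w * r)
  sum(outer(w, w) * abs(outer(r, r, "-"))) / (2 * mu)
}

# closed-form CRS input-oriented efficiency for 1-input/1-output data
crs_ratio_oracle <- function(x, y) (y / x) / max(y / x)
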