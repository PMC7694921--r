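# Panel data model: city-year records of health resources, with a region
# grouping scheme, CSV exchange format and validation.

#' Canonical panel columns
#'
#' Column names of the CSV exchange dialect for city-year resource panels.
#' Population is stored in thousands of persons (so a count divided by
#' `population_thousand` is a rate per 1000 persons); area in km2;
#' financial fields in billions of currency units; outpatient volume in
#' units of ten thousand visits; hospitalization rate in percent.
#'
#' @return character vector of column names.
#' @export
panel_columns <- function() {
  c("city", "year", "region", "population_thousand", "area_km2",
    "institutions", "beds", "health_workers", "gov_subsidy_bn",
    "total_expenditure_bn", "outpatient_10k", "hosp_rate_pct",
    "general_income_bn")
}

# indicator fields (everything except the keys and the bases)
resource_fields <- function() {
  setdiff(panel_columns(),
          c("city", "year", "region", "population_thousand", "area_km2"))
}

stop_hera <- function(class, message, ...) {
  stop(structure(class = c(class, "hera_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

#' Define a region grouping scheme
#'
#' @param name scheme label.
#' @param groups named list mapping group label to a character vector of
#'   city identifiers.  Groups must be disjoint.
#' @return an object of class \code{region_scheme}.
#' @export
#' @examples
#' region_scheme("toy", list(a = c("X", "Y"), b = "Z"))
region_scheme <- function(name, groups) {
  stopifnot(is.character(name), length(name) == 1, is.list(groups),
            !is.null(names(groups)))
  cities <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(cities))
    stop_hera("hera_validation_error",
              "region scheme groups must be disjoint")
  structure(list(name = name, groups = lapply(groups, as.character)),
            class = "region_scheme")
}

#' @export
print.region_scheme <- function(x, ...) {
  cat("Region scheme '", x$name, "': ", length(x$groups), " groups, ",
      length(unlist(x$groups)), " cities\n", sep = "")
  for (g in names(x$groups))
    cat("  ", g, ": ", paste(x$groups[[g]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default three-zone scheme for the 13 Jiangsu prefecture cities
#'
#' Southern, middle and northern economic zones used throughout the
#' equity decompositions.  Any other scheme can be supplied in its place.
#'
#' @return a \code{region_scheme}.
#' @export
jiangsu_scheme <- function() {
  region_scheme("jiangsu3", list(
    south  = c("Nanjing", "Zhenjiang", "Suzhou", "Wuxi", "Changzhou"),
    middle = c("Yangzhou", "Taizhou", "Nantong"),
    north  = c("Xuzhou", "Lianyungang", "Suqian", "Huaian", "Yancheng")))
}

region_of <- function(scheme, cities) {
  map <- rep(names(scheme$groups), lengths(scheme$groups))
  names(map) <- unlist(scheme$groups, use.names = FALSE)
  unname(map[cities])
}

#' Construct a validated resource panel
#'
#' A resource panel is a balanced city-year table: every city appears in
#' every year exactly once, and every city belongs to exactly one region
#' of the grouping scheme.  Balance is enforced because both the yearly
#' DEA frontiers and the adjacent-period Malmquist pairs assume a constant
#' set of decision-making units; silently dropping cities would corrupt
#' the frontier comparisons.
#'
#' @param records data frame with the columns of \code{\link{panel_columns}}
#'   (the \code{region} column may be omitted when \code{scheme} is given).
#' @param scheme a \code{\link{region_scheme}}; when \code{NULL}, regions
#'   are taken from the \code{region} column.
#' @return object of class \code{resource_panel}: a data frame in canonical
#'   column order with the scheme attached as an attribute.
#' @export
resource_panel <- function(records, scheme = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- setdiff(panel_columns(), "region")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop_hera("hera_schema_error",
              paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  if (is.null(scheme)) {
    if (!"region" %in% names(records))
      stop_hera("hera_schema_error",
                "missing column(s): region (or supply a region scheme)")
    grp <- split(records$city, records$region)
    scheme <- region_scheme("from-data", lapply(grp, function(x) sort(unique(x))))
  }
  records$city <- as.character(records$city)
  records$year <- as.integer(records$year)

  reg <- region_of(scheme, records$city)
  if (anyNA(reg)) {
    bad <- unique(records$city[is.na(reg)])
    stop_hera("hera_validation_error",
              paste0("cities not covered by region scheme: ",
                     paste(bad, collapse = ", ")))
  }
  if ("region" %in% names(records) &&
      !all(is.na(records$region)) &&
      !identical(as.character(records$region), reg))
    stop_hera("hera_validation_error",
              "region column disagrees with the region scheme")
  records$region <- reg

  key <- paste(records$city, records$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop_hera("hera_duplicate_error",
              paste0("duplicate (city, year) pair(s): ",
                     paste(gsub("\r", ", ", dup), collapse = "; ")))
  }
  cities <- sort(unique(records$city))
  years <- sort(unique(records$year))
  full <- as.vector(outer(cities, years, paste, sep = "\r"))
  absent <- setdiff(full, key)
  if (length(absent))
    stop_hera("hera_balance_error",
              paste0("unbalanced panel; missing (city, year) pair(s): ",
                     paste(gsub("\r", ", ", absent), collapse = "; ")))

  num <- setdiff(panel_columns(), c("city", "year", "region"))
  for (f in num) records[[f]] <- as.numeric(records[[f]])
  check_pos <- c("population_thousand", "area_km2")
  for (f in check_pos) {
    bad <- which(!is.finite(records[[f]]) | records[[f]] <= 0)
    if (length(bad))
      stop_hera("hera_validation_error",
                sprintf("%s must be > 0 (city %s, year %d)", f,
                        records$city[bad[1]], records$year[bad[1]]))
  }
  for (f in resource_fields()) {
    bad <- which(!is.finite(records[[f]]) | records[[f]] < 0)
    if (length(bad))
      stop_hera("hera_validation_error",
                sprintf("%s must be >= 0 (city %s, year %d)", f,
                        records$city[bad[1]], records$year[bad[1]]))
  }
  bad <- which(records$hosp_rate_pct > 100)
  if (length(bad))
    stop_hera("hera_validation_error",
              sprintf("hosp_rate_pct must be in [0, 100] (city %s, year %d)",
                      records$city[bad[1]], records$year[bad[1]]))

  records <- records[order(records$year, records$city), panel_columns()]
  rownames(records) <- NULL
  structure(records, class = c("resource_panel", "data.frame"),
            region_scheme = scheme)
}

#' @export
print.resource_panel <- function(x, ...) {
  sc <- attr(x, "region_scheme")
  cat("Resource panel: ", length(panel_cities(x)), " cities x ",
      length(panel_years(x)), " years (", min(x$year), "-", max(x$year),
      "), scheme '", sc$name, "'\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' @rdname resource_panel
#' @param panel a \code{resource_panel}.
#' @export
panel_years <- function(panel) sort(unique(panel$year))

#' @rdname resource_panel
#' @export
panel_cities <- function(panel) sort(unique(panel$city))

#' Read a resource panel from CSV
#'
#' Reads the canonical CSV dialect (see \code{\link{panel_columns}};
#' header matching is case-insensitive, thousands separators such as
#' \code{"491,522"} are tolerated in numeric fields) and returns a
#' validated balanced panel.
#'
#' @param path CSV file path.
#' @param scheme optional \code{\link{region_scheme}}; defaults to the
#'   \code{region} column of the file.
#' @return a \code{\link{resource_panel}}.
#' @export
read_panel <- function(path, scheme = NULL) {
  if (!file.exists(path))
    stop_hera("hera_io_error", paste0("file not found: ", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  have <- names(raw)
  keep <- intersect(panel_columns(), have)
  raw <- raw[keep]
  num <- setdiff(keep, c("city", "region"))
  for (f in num) raw[[f]] <- as.numeric(gsub(",", "", raw[[f]], fixed = TRUE))
  resource_panel(raw, scheme = scheme)
}

#' Write a resource panel to CSV
#'
#' Inverse of \code{\link{read_panel}} on canonical files: writes the
#' canonical columns, UTF-8, no thousands separators.
#'
#' @param panel a \code{resource_panel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "resource_panel"))
  utils::write.csv(as.data.frame(panel)[panel_columns()], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Resource density per population or per area
#'
#' Computes resource density for one year: per 1000 persons
#' (\code{resource / population_thousand}) or per km2
#' (\code{resource / area_km2}).  At \code{level = "province"} the density
#' is the ratio of totals -- resource summed over cities divided by the
#' summed basis -- which in general differs from the mean of city
#' densities.
#'
#' @param panel a \code{\link{resource_panel}}.
#' @param resource indicator field name (see \code{\link{panel_columns}}).
#' @param basis \code{"population"} or \code{"area"}.
#' @param year calendar year present in the panel.
#' @param level \code{"city"} (default) for per-city densities or
#'   \code{"province"} for the single aggregate density.
#' @return for \code{level = "city"} a named numeric vector (city ->
#'   density); for \code{level = "province"} a single number.
#' @export
#' @examples
#' p <- generate_panel(panel_gen_config(seed = 1))
#' derive_density(p, "beds", "population", 2014)
derive_density <- function(panel, resource, basis = c("population", "area"),
                           year, level = c("city", "province")) {
  basis <- match.arg(basis)
  level <- match.arg(level)
  if (!resource %in% resource_fields())
    stop_hera("hera_lookup_error", paste0("unknown resource field: ", resource))
  if (!year %in% panel$year)
    stop_hera("hera_lookup_error", paste0("year not in panel: ", year))
  sl <- panel[panel$year == year, ]
  bvals <- if (basis == "population") sl$population_thousand else sl$area_km2
  if (level == "province") return(sum(sl[[resource]]) / sum(bvals))
  stats::setNames(sl[[resource]] / bvals, sl$city)
}
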