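# Cohort exclusion rules with flowchart-style accounting.
#
# Rule order (attribution only; the surviving set is order-invariant):
#   home delivery -> maternal age outside range -> gestational age below
#   24 completed weeks -> municipality outside the geographic domain ->
#   missing critical information -> low-volume municipality.
# A record failing several rules is counted once, at the first matching
# rule. The low-volume rule removes a municipality wholesale when its
# mean annual birth count, among records passing all other rules, is
# at or below the threshold (49 by default, i.e. "49 or less per year");
# evaluating it on the other-rule survivors makes the filter idempotent.

FILTER_RULES <- c("home_delivery", "age_outside_range", "ga_below_minimum",
                  "outside_domain", "missing_values", "low_volume")

FILTERABLE_COLUMNS <- c("municipality_id", "maternal_age_years", "ga_days",
                        "sex", "birthweight_g", "unit_volume", "presentation")

#' Apply the cohort exclusion rules
#'
#' @param records birth-record data frame; must contain
#'   `home_delivery`, `maternal_age_years`, `ga_days` and the critical
#'   columns `municipality_id`, `sex`, `birthweight_g`, `unit_volume`,
#'   `presentation`.
#' @param geo municipality table; records whose (non-missing)
#'   municipality is absent from it count as outside the domain.
#' @param min_births_per_year municipalities whose mean annual births
#'   are `<= min_births_per_year - 1` are excluded wholesale; the
#'   default 50 implements "49 births or less per year".
#' @param age_range inclusive maternal age bounds (years).
#' @param min_ga_days minimum gestational age in completed days
#'   (default 168 = 24 weeks; half-open, 168 survives).
#' @return list with `records` (survivors, input order preserved) and
#'   `report` (class `cs_filter_report`): `n_input`, `n_output` and the
#'   per-rule removal counts.
#' @export
filter_cohort <- function(records, geo, min_births_per_year = 50,
                          age_range = c(15, 45), min_ga_days = 168) {
  need <- c("home_delivery", FILTERABLE_COLUMNS)
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop2("records table is missing filterable column(s): ",
          paste(miss, collapse = ", "))
  n_in <- nrow(records)
  if (n_in == 0L) {
    rep0 <- setNames(integer(length(FILTER_RULES)), FILTER_RULES)
    return(list(records = records,
                report = structure(list(n_input = 0L, removed = rep0,
                                        n_output = 0L),
                                   class = "cs_filter_report")))
  }

  home <- !is_missing_val(records$home_delivery) & records$home_delivery == 1
  age <- records$maternal_age_years
  bad_age <- !is.na(age) & (age < age_range[1] | age > age_range[2])
  ga <- records$ga_days
  bad_ga <- !is.na(ga) & ga < min_ga_days
  muni <- records$municipality_id
  outside <- !is_missing_val(muni) & !(muni %in% geo$municipality_id)
  missing_any <- Reduce(`|`, lapply(FILTERABLE_COLUMNS, function(cl)
    is_missing_val(records[[cl]])))

  # first matching rule wins for attribution
  fails <- cbind(home_delivery = home, age_outside_range = bad_age,
                 ga_below_minimum = bad_ga, outside_domain = outside,
                 missing_values = missing_any)
  first <- apply(fails, 1L, function(z) {
    w <- which(z)
    if (length(w) == 0L) 0L else w[1L]
  })

  pass_other <- first == 0L
  # low-volume: mean annual births among other-rule survivors
  n_years <- length(unique(records$year[pass_other]))
  low_munis <- character(0)
  if (n_years > 0L) {
    cnt <- table(muni[pass_other])
    low_munis <- names(cnt)[cnt / n_years <= (min_births_per_year - 1)]
  }
  low <- pass_other & muni %in% low_munis
  first[low] <- length(FILTER_RULES)

  removed <- vapply(seq_along(FILTER_RULES),
                    function(r) sum(first == r), integer(1))
  names(removed) <- FILTER_RULES
  keep <- first == 0L
  report <- structure(list(n_input = n_in, removed = removed,
                           n_output = sum(keep)),
                      class = "cs_filter_report")
  list(records = records[keep, , drop = FALSE], report = report)
}

#' @export
print.cs_filter_report <- function(x, ...) {
  cat("Cohort filter:", x$n_input, "records in,", x$n_output, "out\n")
  for (r in names(x$removed))
    cat(sprintf("  - %-18s %d removed\n", r, x$removed[[r]]))
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report a `cs_filter_report`.
#' @param path output file.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(
    list(n_input = report$n_input, removed = as.list(report$removed),
         n_output = report$n_output),
    path, auto_unbox = TRUE)
  invisible(path)
}
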