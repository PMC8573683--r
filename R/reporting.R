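# Output surfaces: parameter tables, odds-ratio tables, rate
# trajectories and GeoJSON map export. Exports store raw rates; colour
# binning is left to the consumer.

#' Spatial and temporal parameter table
#'
#' Rows in the conventional order: spatial standard deviation
#' (sigma_eps), correlation distance (rho, km), temporal correlation
#' (alpha), linear time trend (omega); estimates with standard errors.
#' Values are kept numeric; `format = TRUE` renders to the conventional
#' precision (3 decimals, rho to 1).
#'
#' @param fit a `cs_fit`.
#' @param format render to character at table precision.
#' @return data frame with `parameter`, `estimate`, `se` (and a
#'   `converged` attribute).
#' @export
parameter_table <- function(fit, format = FALSE) {
  stopifnot(inherits(fit, "cs_fit"))
  est <- fit$estimates
  se <- fit$se %||% list(sigma_eps = NA_real_, rho = NA_real_,
                         alpha = NA_real_, omega = NA_real_)
  tab <- data.frame(
    parameter = c("sigma_eps", "rho_km", "alpha", "omega"),
    estimate = c(est$sigma_eps, est$rho, est$alpha, est$omega),
    se = c(se$sigma_eps, se$rho, se$alpha, se$omega))
  attr(tab, "converged") <- fit$converged
  if (format) {
    dig <- c(3L, 1L, 3L, 3L)
    tab$estimate <- sprintf("%.*f", dig, tab$estimate)
    tab$se <- ifelse(is.na(tab$se), "NA", sprintf("%.*f", dig, tab$se))
  }
  tab
}

#' Odds-ratio table for the fixed effects
#'
#' One row per design column (reference levels of categorical
#' covariates carry no coefficient and are rendered as `"Ref"` rows
#' when labels are supplied). Standard errors of the OR follow by the
#' delta method, `exp(beta) * se(beta)`.
#'
#' @param fit a `cs_fit`.
#' @param labels optional named character vector mapping design-column
#'   names to display labels; must cover every non-intercept
#'   coefficient.
#' @param include_ref insert `"Ref"` rows after each categorical
#'   covariate's non-reference levels (only with default labels).
#' @return data frame with `covariate`, `or`, `se` (`NA` on Ref rows).
#' @export
or_table <- function(fit, labels = NULL, include_ref = FALSE) {
  stopifnot(inherits(fit, "cs_fit"))
  beta <- fit$estimates$beta
  nm <- setdiff(names(beta), "(Intercept)")
  if (!is.null(labels)) {
    missing_lab <- setdiff(nm, names(labels))
    if (length(missing_lab) > 0L)
      stop2("labels missing for coefficient(s): ",
            paste(missing_lab, collapse = ", "))
  }
  se_b <- if (is.null(fit$se)) rep(NA_real_, length(beta)) else fit$se$beta
  tab <- data.frame(
    covariate = if (is.null(labels)) nm else unname(labels[nm]),
    or = odds_ratio(unname(beta[nm])),
    se = unname(odds_ratio(beta[nm]) * se_b[nm]))
  if (include_ref) {
    refs <- c(age_class = "age 20-34 (Ref)",
              parity_class = "multiparous, no previous CS (Ref)",
              ga_class = "GA 37-41+6 weeks (Ref)",
              unit_volume = "medium unit (Ref)")
    present <- intersect(names(refs), fit$covariates)
    if (length(present) > 0L)
      tab <- rbind(tab, data.frame(covariate = unname(refs[present]),
                                   or = NA_real_, se = NA_real_))
  }
  rownames(tab) <- NULL
  tab
}

#' Long-format rate trajectories
#'
#' @param surface a [predict_rates()] surface.
#' @param highlight optional municipality ids flagged for plotting
#'   (e.g. the largest cities).
#' @return the surface ordered by municipality then year, with a
#'   logical `highlight` column when requested.
#' @export
rate_trajectories <- function(surface, highlight = NULL) {
  stopifnot(inherits(surface, "cs_surface"))
  out <- surface[order(surface$municipality_id, surface$year), ,
                 drop = FALSE]
  if (!is.null(highlight))
    out$highlight <- out$municipality_id %in% highlight
  rownames(out) <- NULL
  out
}

#' Export a rate surface as GeoJSON
#'
#' One feature per municipality, with one `rate_<year>` property per
#' year; each polygon carries the constant rate of its municipality
#' centre. Municipalities without a polygon are skipped with a warning.
#'
#' @param surface a [predict_rates()] surface.
#' @param polygons either a GeoJSON FeatureCollection (parsed list or
#'   file path) whose features carry a `municipality_id` property, or a
#'   named list mapping municipality id to a polygon coordinate array.
#' @param path optional output file; when given, the GeoJSON is written
#'   there.
#' @return the FeatureCollection as a list (invisibly when `path` is
#'   given).
#' @export
map_export <- function(surface, polygons, path = NULL) {
  stopifnot(inherits(surface, "cs_surface"))
  if (is.character(polygons) && length(polygons) == 1L)
    polygons <- jsonlite::read_json(polygons)
  geom_of <- list()
  if (is.list(polygons) && identical(polygons$type, "FeatureCollection")) {
    for (f in polygons$features)
      geom_of[[as.character(f$properties$municipality_id)]] <- f$geometry
  } else {
    for (id in names(polygons))
      geom_of[[id]] <- list(type = "Polygon", coordinates = polygons[[id]])
  }
  years <- sort(unique(surface$year))
  feats <- list()
  for (id in unique(surface$municipality_id)) {
    g <- geom_of[[as.character(id)]]
    if (is.null(g)) {
      warning("no polygon for municipality ", id, "; feature skipped",
              call. = FALSE)
      next
    }
    rows <- surface[surface$municipality_id == id, , drop = FALSE]
    props <- list(municipality_id = id)
    for (y in years) {
      r <- rows$rate[rows$year == y]
      if (length(r) == 1L) props[[paste0("rate_", y)]] <- r
    }
    feats[[length(feats) + 1L]] <-
      list(type = "Feature", properties = props, geometry = g)
  }
  fc <- list(type = "FeatureCollection", features = feats)
  if (!is.null(path)) {
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
    return(invisible(fc))
  }
  fc
}

#' Serialize a fit to JSON
#'
#' Estimates, standard errors, marginal NLL and convergence
#' diagnostics; the empirical-Bayes field mode goes to a separate CSV
#' (`vertex`, `year`, `value`) when `field_path` is given.
#'
#' @param fit a `cs_fit`.
#' @param path output JSON file.
#' @param field_path optional CSV path for the field mode.
#' @export
write_fit <- function(fit, path, field_path = NULL) {
  est <- fit$estimates
  jsonlite::write_json(
    list(estimates = list(beta = as.list(est$beta), omega = est$omega,
                          sigma_eps = est$sigma_eps, rho = est$rho,
                          alpha = est$alpha),
         se = if (is.null(fit$se)) NULL else
           list(beta = as.list(fit$se$beta), omega = fit$se$omega,
                sigma_eps = fit$se$sigma_eps, rho = fit$se$rho,
                alpha = fit$se$alpha),
         marginal_nll = fit$marginal_nll, converged = fit$converged,
         n_outer_iterations = fit$n_outer_iterations,
         reference_year = fit$reference_year, years = fit$years),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(field_path)) {
    fm <- fit$field_mode
    write.csv(data.frame(vertex = rep(seq_len(nrow(fm)), ncol(fm)),
                         year = rep(fit$years, each = nrow(fm)),
                         value = as.vector(fm)),
              field_path, row.names = FALSE)
  }
  invisible(path)
}
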