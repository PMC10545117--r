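# Population-level metric table and regressions against expansion
# covariates (distance to the southernmost site, distance to the ocean,
# tree root distance): the correlation layer behind the expansion-load
# figures.

#' Assemble the population-level metric table
#'
#' Joins the outputs of upstream stages on population id. Any metric tibble
#' with a `population` column can be supplied; remaining columns are taken
#' as metrics, and their provenance (the stage that produced them) is
#' recorded in the `provenance` attribute. Populations missing from a stage
#' keep `NA` cells with a warning.
#'
#' @param covariates tibble with `population` and covariate columns
#'   (distance_south, distance_ocean, ...), typically the distinct
#'   population rows of a popmap.
#' @param ... named metric tibbles, each with a `population` column.
#' @return Tibble, one row per population.
#' @export
assemble_metric_table <- function(covariates, ...) {
  stages <- list(...)
  out <- covariates |> distinct(.data$population, .keep_all = TRUE)
  if ("sample" %in% names(out)) out$sample <- NULL
  prov <- tibble(column = setdiff(names(out), "population"),
                 stage = "covariates")
  for (nm in names(stages)) {
    st <- stages[[nm]]
    if (!"population" %in% names(st)) {
      abort(sprintf("stage %s lacks a population column", nm))
    }
    missing_pop <- setdiff(out$population, st$population)
    if (length(missing_pop)) {
      warn(sprintf("stage %s missing population(s) %s; cells left NA",
                   nm, paste(missing_pop, collapse = ", ")))
    }
    dup <- intersect(setdiff(names(st), "population"), names(out))
    if (length(dup)) {
      st <- rename_with(st, ~ paste(nm, .x, sep = "_"), dplyr::all_of(dup))
    }
    prov <- bind_rows(prov, tibble(column = setdiff(names(st), "population"),
                                   stage = nm))
    out <- left_join(out, st, by = "population")
  }
  attr(out, "provenance") <- prov
  out
}

#' Ordinary least squares of one metric on one covariate
#'
#' Simple linear regression across populations with an optional
#' population-exclusion list (the outlier-river sensitivity analysis), a
#' two-sided slope test, and both plain and adjusted R-squared.
#'
#' @param table metric table from [assemble_metric_table()] (or any tibble
#'   with a `population` column).
#' @param response,predictor column names (strings).
#' @param exclude optional character vector of populations to drop.
#' @return One-row tibble of class `surf_regression`: `slope`, `intercept`,
#'   `r_squared`, `adj_r_squared`, `p_value`, `n`, plus the underlying `lm`
#'   fit as attribute `fit`.
#' @export
fit_linear <- function(table, response, predictor, exclude = NULL) {
  df <- table
  if (!is.null(exclude)) df <- filter(df, !.data$population %in% exclude)
  df <- df[, c("population", response, predictor)]
  names(df) <- c("population", "y", "x")
  df <- filter(df, is.finite(.data$y), is.finite(.data$x))
  if (nrow(df) < 3) abort("need at least 3 complete pairs")
  if (var(df$x) == 0) abort("predictor has zero variance")
  fit <- lm(y ~ x, data = df)
  sm <- summary(fit)
  r2 <- sm$r.squared; ar2 <- sm$adj.r.squared
  pv <- sm$coefficients[2, 4]
  if (var(df$y) == 0) { r2 <- 0; ar2 <- 0; pv <- NA_real_ }
  out <- tibble(
    response = response, predictor = predictor,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2, adj_r_squared = ar2,
    p_value = pv, n = nrow(df)
  )
  attr(out, "fit") <- fit
  class(out) <- c("surf_regression", class(out))
  out
}

#' Regress every metric against every covariate
#'
#' Convenience sweep of [fit_linear()] over metric/covariate pairs,
#' returning the regression table behind the distance-correlation panels.
#'
#' @param table metric table from [assemble_metric_table()].
#' @param responses metric column names.
#' @param predictors covariate column names.
#' @param exclude optional populations to drop from every fit.
#' @return Tibble with one row per (response, predictor) pair.
#' @export
regression_sweep <- function(table, responses, predictors, exclude = NULL) {
  purrr::map_dfr(responses, function(rs) {
    purrr::map_dfr(predictors, function(pd) {
      tryCatch(
        as_tibble(fit_linear(table, rs, pd, exclude = exclude)),
        error = function(e) tibble()
      )
    })
  })
}
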