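#' Rescale a per-SD effect to a concentration increment
#'
#' Effect estimates on normalized (per-SD) exposures are converted to a
#' fixed concentration increment — conventionally 10 ug/m^3 so studies with
#' different exposure distributions can be compared — by
#' \deqn{\beta_{incr} = \beta \cdot \frac{increment}{sd}.}
#' The same arithmetic converts literature effect sizes reported per SD of
#' a different cohort's exposure: e.g. an estimate of -0.16 per SD with
#' SD 1.99 ug/m^3 becomes (10/1.99) * (-0.16) = -0.8 per 10 ug/m^3.
#'
#' @param beta effect estimate per SD of exposure (or per raw unit, with
#'   `sd = 1`).
#' @param sd standard deviation of the exposure (ug/m^3), > 0.
#' @param increment target increment (ug/m^3), default 10.
#' @return effect per `increment` ug/m^3; linear in both `beta` and
#'   `increment`, and the identity when `sd == increment`.
#' @examples
#' rescale_per_increment(-0.16, 1.99)  # about -0.8
#' rescale_per_increment(-0.3, 3.0)    # -1.0
#' @export
rescale_per_increment <- function(beta, sd, increment = 10) {
  if (any(sd <= 0)) stop("sd must be > 0")
  if (any(increment <= 0)) stop("increment must be > 0")
  beta * (increment / sd)
}

#' Assemble the standard result tables
#'
#' Formats the outputs of the analysis pipeline into the conventional
#' deliverables of a PM/FMD association study:
#' \describe{
#'   \item{main_effects}{per pollutant and stratum (all/men/women), the
#'     normalized 12-month moving-average association with the outcome.}
#'   \item{shear_effects}{the same layout for response to shear stress
#'     (when supplied).}
#'   \item{posteriors}{PDL order posterior probabilities per pollutant.}
#'   \item{age_sex_strata}{sex-by-age stratified associations.}
#'   \item{per_increment}{main associations rescaled to a 10 ug/m^3
#'     increment using each window's exposure SD.}
#'   \item{lag_profiles}{model-averaged monthly lag coefficients plus the
#'     cumulative effect.}
#' }
#' Full numeric precision is kept in the tables; a `display` copy rounded
#' to 2 decimals (the conventional printed precision for these effect
#' sizes) is included for each.
#'
#' @param main named list (by pollutant) of `stratified_fits()` outputs for
#'   the primary outcome.
#' @param scans named list (by pollutant) of [window_scan()] results.
#' @param bmas named list (by pollutant) of [bma_average()] results.
#' @param shear optional named list like `main` for the shear-response
#'   outcome.
#' @param increment rescaling increment, ug/m^3.
#' @return named list of data frames (class `report_bundle`).
#' @export
assemble_results_tables <- function(main, scans, bmas, shear = NULL,
                                    increment = 10) {
  stopifnot(length(main) >= 1, identical(names(main), names(scans)))

  stack_strata <- function(lst, which_strata = NULL) {
    rows <- lapply(names(lst), function(pol) {
      tb <- lst[[pol]]$table
      if (is.null(tb)) return(NULL)
      if (!is.null(which_strata))
        tb <- tb[tb$stratum %in% which_strata, , drop = FALSE]
      if (!nrow(tb)) return(NULL)
      cbind(pollutant = pol, tb)
    })
    out <- do.call(rbind, rows)
    if (!is.null(out)) rownames(out) <- NULL
    out
  }

  main_tab <- stack_strata(main, c("all", "men", "women"))
  shear_tab <- if (!is.null(shear)) stack_strata(shear, c("all", "men", "women"))
  agesex_tab <- stack_strata(main)

  post_tab <- do.call(rbind, lapply(names(bmas), function(pol)
    cbind(pollutant = pol, bmas[[pol]]$posterior)))
  rownames(post_tab) <- NULL

  lag_tab <- do.call(rbind, lapply(names(bmas), function(pol)
    cbind(pollutant = pol, lag_profile(bmas[[pol]]))))
  rownames(lag_tab) <- NULL

  incr_tab <- do.call(rbind, lapply(names(scans), function(pol) {
    tb <- scans[[pol]]$table
    data.frame(pollutant = pol, window = tb$window,
               exposure_sd = tb$exposure_sd,
               estimate_per_sd = tb$estimate,
               estimate_per_increment =
                 rescale_per_increment(tb$estimate, tb$exposure_sd, increment),
               se_per_increment =
                 rescale_per_increment(tb$se, tb$exposure_sd, increment),
               increment = increment, stringsAsFactors = FALSE)
  }))
  rownames(incr_tab) <- NULL

  tabs <- list(main_effects = main_tab, shear_effects = shear_tab,
               posteriors = post_tab, age_sex_strata = agesex_tab,
               per_increment = incr_tab, lag_profiles = lag_tab)
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  tabs$display <- lapply(tabs, round_numeric, digits = 2)
  class(tabs) <- c("report_bundle", "list")
  tabs
}

round_numeric <- function(df, digits = 2) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Write a report bundle to CSV files
#'
#' One CSV per table (full precision) plus `<name>_display.csv` rounded
#' copies.  Files regenerate byte-identically from the same inputs.
#'
#' @param bundle an [assemble_results_tables()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in setdiff(names(bundle), "display")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(bundle[[nm]], p, row.names = FALSE)
    pd <- file.path(dir, paste0(nm, "_display.csv"))
    utils::write.csv(bundle$display[[nm]], pd, row.names = FALSE)
    paths <- c(paths, p, pd)
  }
  invisible(paths)
}
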