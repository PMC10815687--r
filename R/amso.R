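#' Exclude confounded GBA1 carriers from onset analysis
#'
#' Removes severe-class GBA1 mutation carriers, compound heterozygotes and
#' N370S homozygotes, whose onset is shifted by the mutation itself and
#' would confound a haplotype effect. Samples matching several reasons are
#' excluded (and counted in the total) once.
#'
#' @param meta Per-sample tibble with `gba1_class`
#'   (`severe`/`mild`/`risk`/`none`), `compound_het` and `n370s_hom` flags.
#' @return A list: `meta` (retained samples) and `report` (tibble of
#'   per-reason counts plus a `total_excluded` row counting unique samples).
#' @examples
#' ch <- simulate_cohort(cohort_config(n_samples = 200, seed = 4))
#' amso_exclusion_filter(ch$meta)$report
#' @export
amso_exclusion_filter <- function(meta) {
  needed <- c("gba1_class", "compound_het", "n370s_hom")
  if (!all(needed %in% names(meta))) {
    abort(paste0("meta must have columns: ", paste(needed, collapse = ", ")))
  }
  severe <- meta$gba1_class == "severe"
  chet <- meta$compound_het %in% TRUE
  hom <- meta$n370s_hom %in% TRUE
  drop <- severe | chet | hom
  report <- tibble(
    reason = c("severe_gba1", "compound_het", "n370s_hom", "total_excluded"),
    n = c(sum(severe), sum(chet), sum(hom), sum(drop))
  )
  list(meta = meta[!drop, , drop = FALSE], report = report)
}

#' Linear regression of onset age on dominant H2 carrier status
#'
#' Ordinary least squares of AMSO on an H2 carrier indicator (dosage >= 1,
#' the dominant coding) and a female indicator, within one stratum.
#' Inference is t-based (coefficients, 95% confidence intervals, two-sided
#' p-values).
#'
#' @param meta Per-sample tibble with `amso`, `h2_dosage` (or `h2_carrier`),
#'   `sex`, and `subgroup` when a stratum is requested.
#' @param stratum Subgroup to restrict to, or `"all"`.
#' @param ci_level Confidence level for the intervals.
#' @return An object of class `amso_fit` wrapping the `lm` fit; use
#'   [tidy()] for the coefficient table and [glance()] for fit summaries.
#' @examples
#' ch <- simulate_cohort(cohort_config(n_samples = 300, seed = 6))
#' fit <- fit_amso_regression(ch$meta, stratum = "all")
#' tidy(fit)
#' @export
fit_amso_regression <- function(meta, stratum = "all", ci_level = 0.95) {
  if (!"h2_carrier" %in% names(meta)) {
    if (!"h2_dosage" %in% names(meta)) {
      abort("meta must have `h2_carrier` or `h2_dosage`")
    }
    meta$h2_carrier <- meta$h2_dosage >= 1L
  }
  needed <- c("amso", "sex", "h2_carrier")
  if (!all(needed %in% names(meta))) {
    abort(paste0("meta must have columns: ", paste(needed, collapse = ", ")))
  }
  sub <- if (stratum == "all") meta else {
    if (!"subgroup" %in% names(meta)) abort("stratified fit needs a `subgroup` column")
    meta |> filter(.data$subgroup == stratum)
  }
  usable <- !is.na(sub$amso) & !is.na(sub$h2_carrier) & !is.na(sub$sex)
  n_dropped <- sum(!usable)
  if (n_dropped > 0) {
    message(sprintf("dropping %d sample(s) with missing onset or genotype", n_dropped))
  }
  sub <- sub[usable, , drop = FALSE]
  if (nrow(sub) < 3) {
    abort(sprintf("stratum '%s' has %d usable samples; at least 3 required",
                  stratum, nrow(sub)))
  }
  df <- tibble(amso = sub$amso,
               h2_carrier = as.numeric(sub$h2_carrier),
               female = as.numeric(sub$sex == "female"))
  for (col in c("h2_carrier", "female")) {
    if (stats::var(df[[col]]) == 0) {
      abort(sprintf("degenerate design: column '%s' is constant in stratum '%s'",
                    col, stratum))
    }
  }
  X <- cbind(1, df$h2_carrier, df$female)
  if (qr(X)$rank < 3) {
    abort("degenerate design: 'h2_carrier' and 'female' are collinear")
  }
  fit <- lm(amso ~ h2_carrier + female, data = df)
  structure(list(fit = fit, stratum = stratum, n_used = nrow(df),
                 n_dropped = n_dropped, ci_level = ci_level),
            class = "amso_fit")
}

#' @export
print.amso_fit <- function(x, ...) {
  cat(sprintf("<amso_fit> stratum '%s', n = %d\n", x$stratum, x$n_used))
  print(tidy(x))
  invisible(x)
}

#' Tidy an onset regression
#'
#' @param x An `amso_fit`.
#' @param ... Unused.
#' @return Tibble with `stratum`, `term`, `estimate` (years), `std_error`,
#'   `ci_low`, `ci_high`, `p_value`, `n_used`.
#' @export
tidy.amso_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- confint(x$fit, level = x$ci_level)
  tibble(
    stratum = x$stratum,
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    ci_low = unname(ci[, 1]),
    ci_high = unname(ci[, 2]),
    p_value = unname(sm[, "Pr(>|t|)"]),
    n_used = x$n_used
  )
}

#' One-row summary of an onset regression
#'
#' @param x An `amso_fit`.
#' @param ... Unused.
#' @return Tibble with `stratum`, `n_used`, `n_dropped`, `r_squared`,
#'   `sigma`, `df_residual`.
#' @export
glance.amso_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(stratum = x$stratum, n_used = x$n_used, n_dropped = x$n_dropped,
         r_squared = sm$r.squared, sigma = sm$sigma,
         df_residual = x$fit$df.residual)
}
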