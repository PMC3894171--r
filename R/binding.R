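# Hill-equation quantification of protein-RNA titrations and conversion of
# dissociation constants to standard binding free energies.
#
# Model: response = B + A * [P]^n / (Kd^n + [P]^n), with [P] the protein
# concentration (nM). F-EMSA fraction-bound data fixes B = 0, A = 1;
# fluorescence polarization (raw mP) leaves both free.

GAS_CONSTANT_KCAL <- 1.987e-3  # kcal mol^-1 K^-1

#' Fraction bound from band intensities
#'
#' @param bound_intensity,free_intensity non-negative fluorescence
#'   intensities of the bound and free species.
#' @return bound / (bound + free); `NA` with a warning when both are zero
#'   (the point should be dropped).
#' @export
normalize_fraction_bound <- function(bound_intensity, free_intensity) {
  stopifnot(all(bound_intensity >= 0, na.rm = TRUE),
            all(free_intensity >= 0, na.rm = TRUE))
  tot <- bound_intensity + free_intensity
  bad <- !is.na(tot) & tot == 0
  if (any(bad)) {
    warning(sum(bad), " point(s) with zero total intensity set to NA")
  }
  out <- bound_intensity / tot
  out[bad] <- NA_real_
  out
}

#' Construct a titration series
#'
#' @param concentration_nM protein concentrations in nM, strictly
#'   increasing, >= 0; at least 5 points.
#' @param response fraction bound (F-EMSA) or raw polarization in mP (FP).
#' @param assay `"femsa"` or `"fp"`.
#' @param rna,protein labels.
#' @return class `titration_series`.
#' @export
titration_series <- function(concentration_nM, response,
                             assay = c("femsa", "fp"),
                             rna = NA_character_, protein = NA_character_) {
  assay <- match.arg(assay)
  ok <- is.finite(concentration_nM) & is.finite(response)
  concentration_nM <- concentration_nM[ok]
  response <- response[ok]
  if (length(concentration_nM) < 5L) stop("at least 5 finite points required")
  if (any(concentration_nM < 0) || any(diff(concentration_nM) <= 0)) {
    stop("concentrations must be >= 0 and strictly increasing")
  }
  structure(list(concentration_nM = concentration_nM, response = response,
                 assay = assay, rna = rna, protein = protein),
            class = "titration_series")
}

#' Fit a Hill binding curve by Levenberg-Marquardt least squares
#'
#' For F-EMSA series the baseline is fixed at 0 and the amplitude at 1
#' (fraction-bound scale) unless `fix_baseline`/`fix_amplitude` say
#' otherwise; FP series fit baseline and amplitude freely on the raw mP
#' scale. The Hill coefficient is free by default and can be fixed at 1.
#'
#' @param series a [titration_series()].
#' @param fix_n fix the Hill coefficient at this value (e.g. 1), or `NULL`
#'   (free, the default).
#' @param fix_baseline,fix_amplitude override the assay defaults: numeric
#'   value to fix, `NA` to free the parameter.
#' @param init optional named list of starting values (`kd`, `n`, `A`, `B`).
#' @return class `hill_fit`: list with `kd`, `n`, `A`, `B`, `se` (named
#'   standard errors from the fit covariance; fixed parameters get 0),
#'   `converged`, `rss`, `censored_hint` (">max[P]" when the fitted Kd
#'   exceeds the titrated range, else `NA`), and the input `series`.
#' @export
fit_hill <- function(series, fix_n = NULL, fix_baseline = NULL,
                     fix_amplitude = NULL, init = NULL) {
  stopifnot(inherits(series, "titration_series"))
  conc <- series$concentration_nM
  y <- series$response
  if (is.null(fix_baseline)) {
    fix_baseline <- if (series$assay == "femsa") 0 else NA_real_
  }
  if (is.null(fix_amplitude)) {
    fix_amplitude <- if (series$assay == "femsa") 1 else NA_real_
  }

  rng <- range(y)
  start <- list(
    kd = if (!is.null(init$kd)) init$kd else {
      half <- rng[1L] + 0.5 * diff(rng)
      max(conc[which.min(abs(y - half))], min(conc[conc > 0], 1))
    },
    n = if (!is.null(init$n)) init$n else 1,
    B = if (!is.null(init$B)) init$B else rng[1L],
    A = if (!is.null(init$A)) init$A else max(diff(rng), 1e-6))

  free <- c(kd = TRUE, n = is.null(fix_n),
            A = is.na(fix_amplitude), B = is.na(fix_baseline))
  fixed <- list(n = fix_n, A = fix_amplitude, B = fix_baseline)
  form_terms <- c(kd = "kd", n = if (free[["n"]]) "n" else
                    sprintf("%.17g", fixed$n),
                  A = if (free[["A"]]) "A" else sprintf("%.17g", fixed$A),
                  B = if (free[["B"]]) "B" else sprintf("%.17g", fixed$B))
  form <- stats::as.formula(sprintf(
    "y ~ %s + %s * conc^%s / (kd^%s + conc^%s)",
    form_terms[["B"]], form_terms[["A"]], form_terms[["n"]],
    form_terms[["n"]], form_terms[["n"]]))
  lower <- c(kd = 1e-9, n = 0.05, A = -Inf, B = -Inf)

  fit <- tryCatch(
    minpack.lm::nlsLM(form,
                      data = data.frame(conc = conc, y = y),
                      start = start[names(free)[free]],
                      lower = unname(lower[names(free)[free]]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  out <- list(kd = NA_real_, n = if (free[["n"]]) NA_real_ else fixed$n,
              A = if (free[["A"]]) NA_real_ else fixed$A,
              B = if (free[["B"]]) NA_real_ else fixed$B,
              se = c(kd = NA_real_, n = 0, A = 0, B = 0),
              converged = FALSE, rss = NA_real_,
              censored_hint = NA_character_, series = series,
              message = NULL)
  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    class(out) <- "hill_fit"
    return(out)
  }
  cf <- coef(fit)
  se <- rep(NA_real_, length(cf))
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  if (!is.null(sm)) se <- sm$coefficients[, "Std. Error"]
  names(se) <- names(cf)
  for (p in names(cf)) {
    out[[p]] <- unname(cf[[p]])
    out$se[[p]] <- unname(se[[p]])
  }
  out$converged <- fit$convInfo$isConv %||% TRUE
  out$rss <- sum(stats::residuals(fit)^2)
  if (is.finite(out$kd) && out$kd > max(conc)) {
    out$censored_hint <- sprintf(">%g", max(conc))
  }
  class(out) <- "hill_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Hill fit: NOT converged", if (!is.null(x$message))
      paste0("(", x$message, ")"), "\n")
  } else {
    cat(sprintf("Hill fit (%s): Kd = %.3g +/- %.2g nM, n = %.3g, rss = %.3g%s\n",
                x$series$assay, x$kd, x$se[["kd"]], x$n, x$rss,
                if (!is.na(x$censored_hint))
                  paste0(" [suggest censoring ", x$censored_hint, "]") else ""))
  }
  invisible(x)
}

#' Construct an affinity estimate (one affinity-table row)
#'
#' @param mean_kd_nM mean Kd in nM (NA for censored estimates).
#' @param sd_nM standard deviation across replicates (or fit standard error
#'   for a single replicate).
#' @param n replicate count.
#' @param assay `"femsa"` or `"fp"`.
#' @param censored logical; censored estimates carry `bound_nM` (a lower
#'   bound such as 2000 for ">2000") instead of a mean.
#' @param bound_nM lower bound in nM for censored estimates.
#' @param protein,rna labels.
#' @return class `affinity_estimate`.
#' @export
affinity_estimate <- function(mean_kd_nM, sd_nM, n = 1L,
                              assay = c("femsa", "fp"),
                              censored = FALSE, bound_nM = NA_real_,
                              protein = NA_character_, rna = NA_character_) {
  assay <- match.arg(assay)
  if (censored) {
    if (!is.finite(bound_nM) || bound_nM <= 0) {
      stop("censored estimates need a positive bound_nM")
    }
    mean_kd_nM <- NA_real_
    sd_nM <- NA_real_
  } else {
    stopifnot(is.finite(mean_kd_nM), mean_kd_nM > 0, sd_nM >= 0, n >= 1L)
  }
  structure(list(mean_kd_nM = mean_kd_nM, sd_nM = sd_nM, n = as.integer(n),
                 assay = assay, censored = censored, bound_nM = bound_nM,
                 protein = protein, rna = rna),
            class = "affinity_estimate")
}

#' @export
print.affinity_estimate <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$protein, x$rna)), collapse = " / ")
  if (x$censored) {
    cat(sprintf("Affinity (%s%s): Kd > %g nM (censored, n = %d)\n",
                x$assay, if (nzchar(lab)) paste0(", ", lab) else "",
                x$bound_nM, x$n))
  } else {
    cat(sprintf("Affinity (%s%s): Kd = %g +/- %g nM (n = %d)\n",
                x$assay, if (nzchar(lab)) paste0(", ", lab) else "",
                x$mean_kd_nM, x$sd_nM, x$n))
  }
  invisible(x)
}

#' Aggregate replicate Hill fits into one affinity estimate
#'
#' Unweighted mean and sample standard deviation of the replicate Kds; for a
#' single replicate the fit's own standard error stands in for the s.d.
#' Censored inputs (numeric lower bounds of class `censored_kd`, e.g. from
#' `censored_kd(2000)`) yield a censored estimate whose bound is the
#' smallest input bound; mixing censored and converged fits is an error.
#'
#' @param fits list of converged `hill_fit` objects, or of `censored_kd`
#'   bounds.
#' @param assay,protein,rna labels for the estimate (assay defaults to the
#'   first fit's).
#' @return an [affinity_estimate()].
#' @export
aggregate_replicates <- function(fits, assay = NULL,
                                 protein = NA_character_,
                                 rna = NA_character_) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  cens <- vapply(fits, inherits, logical(1L), what = "censored_kd")
  if (all(cens)) {
    bounds <- vapply(fits, as.numeric, numeric(1L))
    return(affinity_estimate(NA, NA, n = length(fits),
                             assay = assay %||% "femsa",
                             censored = TRUE, bound_nM = min(bounds),
                             protein = protein, rna = rna))
  }
  if (any(cens)) stop("cannot mix censored bounds with converged fits")
  ok <- vapply(fits, function(f) inherits(f, "hill_fit") && f$converged,
               logical(1L))
  if (!any(ok)) stop("no converged fits to aggregate")
  fits <- fits[ok]
  kds <- vapply(fits, `[[`, numeric(1L), "kd")
  assay <- assay %||% fits[[1L]]$series$assay
  if (length(kds) == 1L) {
    affinity_estimate(kds, fits[[1L]]$se[["kd"]], n = 1L, assay = assay,
                      protein = protein, rna = rna)
  } else {
    affinity_estimate(mean(kds), sd(kds), n = length(kds), assay = assay,
                      protein = protein, rna = rna)
  }
}

#' Mark a dissociation constant as censored (">bound")
#'
#' @param bound_nM lower bound in nM.
#' @export
censored_kd <- function(bound_nM) {
  structure(as.numeric(bound_nM), class = "censored_kd")
}

#' Standard binding free energy from an affinity estimate
#'
#' dG0 = -R T ln(Kd in molar), R = 1.987e-3 kcal mol^-1 K^-1, with
#' first-order (delta-method) uncertainty R T sd(Kd) / Kd.
#'
#' @param est an [affinity_estimate()] (not censored).
#' @param temperature_K absolute temperature, default 298 K.
#' @return class `free_energy`: list with `kcal_per_mol`, `sd`,
#'   `temperature_K`, `kind = "dG"` and the labels of the estimate.
#' @export
delta_g <- function(est, temperature_K = 298) {
  stopifnot(inherits(est, "affinity_estimate"))
  if (est$censored) {
    stop("censored estimate: only a free-energy bound is defined (Kd > ",
         est$bound_nM, " nM)")
  }
  rt <- GAS_CONSTANT_KCAL * temperature_K
  kd_molar <- est$mean_kd_nM * 1e-9
  structure(list(kcal_per_mol = -rt * log(kd_molar),
                 sd = rt * est$sd_nM / est$mean_kd_nM,
                 temperature_K = temperature_K, kind = "dG",
                 labels = paste(stats::na.omit(c(est$protein, est$rna)),
                                collapse = "/")),
            class = "free_energy")
}

#' Binding free-energy difference between two affinity estimates
#'
#' ddG0 = dG0(A) - dG0(B) = -R T ln(Kd_A / Kd_B); the nM-to-M conversion
#' cancels. Uncertainties combine in quadrature from the two delta-method
#' terms, and the result is antisymmetric in its arguments.
#'
#' @param est_a,est_b [affinity_estimate()] objects (neither censored).
#' @param temperature_K absolute temperature, default 298 K.
#' @return class `free_energy` with `kind = "ddG"`.
#' @export
delta_delta_g <- function(est_a, est_b, temperature_K = 298) {
  stopifnot(inherits(est_a, "affinity_estimate"),
            inherits(est_b, "affinity_estimate"))
  for (e in list(est_a, est_b)) {
    if (e$censored) {
      stop("censored estimate (Kd > ", e$bound_nM,
           " nM): ddG has only a directional bound")
    }
  }
  rt <- GAS_CONSTANT_KCAL * temperature_K
  # difference of logs rather than log of the ratio: exact antisymmetry
  val <- -rt * (log(est_a$mean_kd_nM) - log(est_b$mean_kd_nM))
  sdv <- rt * sqrt((est_a$sd_nM / est_a$mean_kd_nM)^2 +
                     (est_b$sd_nM / est_b$mean_kd_nM)^2)
  structure(list(kcal_per_mol = val, sd = sdv,
                 temperature_K = temperature_K, kind = "ddG",
                 labels = paste(c(paste(stats::na.omit(c(est_a$protein, est_a$rna)),
                                        collapse = "/"),
                                  paste(stats::na.omit(c(est_b$protein, est_b$rna)),
                                        collapse = "/")),
                                collapse = " vs ")),
            class = "free_energy")
}

#' @export
print.free_energy <- function(x, ...) {
  cat(sprintf("%s%s = %.3f +/- %.3f kcal/mol (T = %g K)\n",
              if (x$kind == "ddG") "ddG0" else "dG0",
              if (nzchar(x$labels)) paste0(" [", x$labels, "]") else "",
              x$kcal_per_mol, x$sd, x$temperature_K))
  invisible(x)
}
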