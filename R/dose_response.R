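#' Default 12-point, 3-fold ELISA dilution series
#'
#' The campaign's plate design: 12 three-fold dilutions starting at
#' 80 ug/mL of nanobody (~5714 nM at the default 14 kDa), i.e. down to
#' ~4.5e-4 ug/mL.
#'
#' @param top_ug_ml top concentration in ug/mL
#' @param n number of dilution points
#' @param fold dilution factor between points
#' @param mass_kda nanobody molecular mass used to convert to molar
#' @return concentrations in nM, descending
#' @export
default_dose_grid <- function(top_ug_ml = 80, n = 12, fold = 3, mass_kda = 14) {
  ug_ml <- top_ug_ml / fold^(seq_len(n) - 1)
  conc_to_nm(ug_ml, "ug_per_ml", mass_kda)
}

#' Convert concentrations to nanomolar
#'
#' @param x concentrations
#' @param unit one of `"nM"`, `"uM"`, `"M"`, `"ug_per_ml"`, `"ng_per_ul"`,
#'   `"pg_per_ul"`
#' @param mass_kda molecular mass (kDa) for mass/volume units (default
#'   14 kDa, a typical nanobody)
#' @return concentrations in nM
#' @export
conc_to_nm <- function(x, unit, mass_kda = 14) {
  switch(unit,
    nM = x,
    uM = x * 1e3,
    M = x * 1e9,
    ug_per_ml = x * 1000 / mass_kda,
    ng_per_ul = x * 1000 / mass_kda,   # ng/uL == ug/mL
    pg_per_ul = x / mass_kda,
    stop("unknown concentration unit: ", unit))
}

#' Assemble a dose-response curve
#'
#' @param clone_id,antigen_id identifiers
#' @param concentration concentrations (converted to nM internally)
#' @param a450 absorbance readings
#' @param conc_unit unit of `concentration`
#' @param blank plate blank absorbance (scalar)
#' @param replicate replicate index per point
#' @param mass_kda molecular mass for unit conversion
#' @return object of class `dose_response_curve`: data.frame of points plus
#'   attributes
#' @export
dose_response_curve <- function(clone_id, antigen_id, concentration, a450,
                                conc_unit = "nM", blank = 0, replicate = 1,
                                mass_kda = 14) {
  conc <- conc_to_nm(concentration, conc_unit, mass_kda)
  if (any(conc <= 0)) stop("concentrations must be strictly positive")
  df <- data.frame(concentration = conc, a450 = a450,
                   replicate = rep_len(replicate, length(conc)))
  for (rep_i in split(df, df$replicate)) {
    if (anyDuplicated(rep_i$concentration)) {
      stop("concentrations must be distinct within a replicate")
    }
  }
  structure(df, class = c("dose_response_curve", "data.frame"),
            clone_id = clone_id, antigen_id = antigen_id, blank = blank)
}

fourpl <- function(x, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / x)^hill)
}

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (ec50/x)^hill)`
#' to the blank-subtracted absorbances, pooling replicates. Optimization is
#' a quasi-Newton search over (bottom, top, log10 ec50, log hill) from the
#' deterministic start: bottom = min y, top = max y, ec50 = concentration
#' nearest the half-range crossing, hill = 1. Degenerate flat data (signal
#' span below `min_span`) is flagged `no_response` rather than fitted;
#' non-convergence yields a flagged fit, not an error.
#'
#' @param curve a [dose_response_curve()]
#' @param min_span minimum blank-subtracted signal span (absorbance) for a
#'   fit to be attempted
#' @return list of class `fourpl_fit`: `bottom`, `top`, `ec50` (nM),
#'   `hill`, `converged`, `no_response`, `extrapolated` (EC50 outside
#'   [min conc/10, max conc*10]), `residual_sse`, `n`
#' @export
fit_4pl <- function(curve, min_span = 0.05) {
  x <- curve$concentration
  y <- curve$a450 - attr(curve, "blank")
  out <- list(clone_id = attr(curve, "clone_id"),
              antigen_id = attr(curve, "antigen_id"),
              bottom = NA_real_, top = NA_real_, ec50 = NA_real_,
              hill = NA_real_, converged = FALSE, no_response = FALSE,
              extrapolated = FALSE, residual_sse = NA_real_, n = length(x))
  class(out) <- "fourpl_fit"
  if (length(unique(x)) < 4) stop("need >= 4 distinct concentrations")
  if (!all(is.finite(y))) stop("non-finite absorbance")
  if (diff(range(y)) < min_span) {
    out$no_response <- TRUE
    return(out)
  }
  half <- (min(y) + max(y)) / 2
  x0 <- x[which.min(abs(y - half))]
  theta0 <- c(min(y), max(y), log10(x0), 0)   # log(hill) = 0 -> hill 1
  sse <- function(th) {
    mu <- fourpl(x, th[1], th[2], 10^th[3], exp(th[4]))
    sum((y - mu)^2)
  }
  opt <- stats::optim(theta0, sse, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  # polish with Nelder-Mead in case BFGS stalls on a flat valley
  opt2 <- stats::optim(opt$par, sse, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-15))
  if (opt2$value < opt$value) opt <- opt2
  th <- opt$par
  out$bottom <- min(th[1], th[2]); out$top <- max(th[1], th[2])
  out$ec50 <- 10^th[3]; out$hill <- exp(th[4])
  out$residual_sse <- opt$value
  out$converged <- is.finite(opt$value)
  out$extrapolated <- out$ec50 < min(x) / 10 || out$ec50 > max(x) * 10
  out
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (x$no_response) {
    cat("fourpl_fit:", x$clone_id, "- no response\n")
  } else {
    cat(sprintf("fourpl_fit: %s vs %s  EC50 %.3g nM  hill %.2f  [%.3f, %.3f]%s\n",
                x$clone_id, x$antigen_id, x$ec50, x$hill, x$bottom, x$top,
                if (x$extrapolated) " (extrapolated)" else ""))
  }
  invisible(x)
}

#' Area under a dose-response curve on the log10-dose axis
#'
#' Trapezoid rule over log10(concentration) of the blank-subtracted
#' absorbance, with negative values clamped to zero first (the AUC feeds a
#' ratio statistic and must be non-negative). Computed per replicate and
#' averaged.
#'
#' @param curve a [dose_response_curve()]
#' @return scalar area (absorbance x log10-concentration units)
#' @export
auc_logdose <- function(curve) {
  per_rep <- vapply(split(as.data.frame(curve), curve$replicate), function(d) {
    if (nrow(d) < 2) stop("AUC needs >= 2 points per replicate")
    o <- order(d$concentration)
    lx <- log10(d$concentration[o])
    yy <- pmax(d$a450[o] - attr(curve, "blank"), 0)
    sum(diff(lx) * (utils::head(yy, -1) + yy[-1]) / 2)
  }, numeric(1))
  mean(per_rep)
}

#' Compare apo-antigen and RNP affinities
#'
#' @param fit_apo,fit_rnp converged [fit_4pl()] fits for the same clone
#' @param fold_threshold EC50 fold-difference below which the two
#'   affinities are called "similar"
#' @return list with `fold` (larger/smaller EC50 ratio) and `similar`
#' @export
compare_apo_vs_rnp <- function(fit_apo, fit_rnp, fold_threshold = 3) {
  if (!fit_apo$converged || !fit_rnp$converged ||
      fit_apo$no_response || fit_rnp$no_response) {
    stop("both fits must have converged")
  }
  fold <- max(fit_apo$ec50, fit_rnp$ec50) / min(fit_apo$ec50, fit_rnp$ec50)
  list(fold = fold, similar = fold <= fold_threshold,
       ec50_apo = fit_apo$ec50, ec50_rnp = fit_rnp$ec50)
}

#' Cross-reactivity screen of one clone against several antigens
#'
#' A clone is called reactive against an antigen when its maximum
#' blank-subtracted signal clears `k` times the blank noise AND the 4PL fit
#' converges with an EC50 inside the tested concentration range.
#'
#' @param curves named list of [dose_response_curve()]s (name = antigen)
#' @param blank_sd standard deviation of blank wells
#' @param k signal threshold multiplier
#' @return data.frame with columns `antigen`, `max_signal`, `reactive`
#' @export
cross_reactivity <- function(curves, blank_sd = 0.02, k = 3) {
  rows <- lapply(names(curves), function(ag) {
    cu <- curves[[ag]]
    maxsig <- max(cu$a450 - attr(cu, "blank"))
    fit <- fit_4pl(cu)
    reactive <- maxsig >= k * blank_sd && fit$converged &&
      !fit$no_response && !fit$extrapolated
    data.frame(antigen = ag, max_signal = maxsig, reactive = reactive,
               ec50 = fit$ec50, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate a list of 4PL fits
#'
#' @param fits list of [fit_4pl()] results
#' @return data.frame (clone, antigen, bottom, top, ec50_nM, hill,
#'   converged, no_response, sse)
#' @export
fit_table <- function(fits) {
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(clone = f$clone_id, antigen = f$antigen_id,
               bottom = f$bottom, top = f$top, ec50_nM = f$ec50,
               hill = f$hill, converged = f$converged,
               no_response = f$no_response, sse = f$residual_sse,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
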