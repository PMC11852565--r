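#' Calibrate contrast to mass
#'
#' Ordinary least-squares line through (contrast, known mass) pairs from a
#' protein standard, as used to convert single-molecule landing contrasts
#' into kDa.
#'
#' @param contrast measured contrasts of the standards
#' @param standard_mass known masses (kDa)
#' @return list of class `mp_calibration`: `slope`, `intercept`,
#'   `r_squared`, `n_standards`
#' @export
mp_calibrate <- function(contrast, standard_mass) {
  if (length(contrast) < 2 || length(standard_mass) != length(contrast)) {
    stop("need >= 2 (contrast, mass) standard pairs")
  }
  fit <- stats::lm(standard_mass ~ contrast)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) stop("calibration slope must be positive")
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 # collinear standards trip summary.lm's perfect-fit warning
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_standards = length(contrast)),
            class = "mp_calibration")
}

#' Apply a calibration to raw contrasts
#'
#' @param calibration an [mp_calibrate()] fit
#' @param contrast raw contrast values
#' @return masses in kDa
#' @export
mp_apply_calibration <- function(calibration, contrast) {
  calibration$intercept + calibration$slope * contrast
}

# one EM run for a k-component univariate Gaussian mixture;
# deterministic quantile-spaced initialization
.em_gaussian <- function(x, k, max_iter = 1000, tol = 1e-8, sd_floor = 0.5) {
  n <- length(x)
  mu <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  sg <- rep(stats::sd(x) / max(1, k - 1) + sd_floor, k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sg[j]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    if (any(tot <= 0)) return(NULL)
    ll <- sum(log(tot))
    r <- dens / tot
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sg <- sqrt(vapply(seq_len(k), function(j) sum(r[, j] * (x - mu[j])^2) / nk[j],
                      numeric(1)))
    if (any(sg < sd_floor)) return(NULL)   # degenerate spike -> disqualify k
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  o <- order(mu)
  counts <- as.integer(table(factor(max.col(r), levels = seq_len(k))))
  list(mean = mu[o], sd = sg[o], weight = w[o], count = counts[o],
       loglik = ll, k = k, bic = -2 * ll + (3 * k - 1) * log(n))
}

#' Fit Gaussian mass populations to landing events
#'
#' Expectation-maximization fit of a univariate Gaussian mixture to the
#' event masses, after discarding events below the instrument noise floor
#' (`min_mass`, default 40 kDa — free 12-14 kDa nanobodies are invisible to
#' the instrument). With `k = NULL` the component count is chosen over
#' `1..max_k` by BIC, disqualifying solutions with a component weight below
#' `min_weight` or a collapsed (near-zero sd) component. Initialization is
#' deterministic (quantile-spaced means), so results are reproducible
#' without a seed.
#'
#' @param events numeric masses in kDa (>= 100 events after filtering)
#' @param k fixed component count, or NULL to select by BIC
#' @param max_k largest component count tried
#' @param min_mass noise floor (kDa); events below are dropped
#' @param min_weight minimum mixture weight for an admissible component
#' @return data.frame of class `mp_components` with columns `mean`, `sd`,
#'   `weight`, `count` (events hard-assigned to each component), ordered by
#'   mean; attributes `loglik`, `bic`, `k`, `n_events`
#' @export
fit_mass_components <- function(events, k = NULL, max_k = 4, min_mass = 40,
                                min_weight = 0.05) {
  if (length(events) == 0) stop("no events")
  x <- events[events >= min_mass]
  if (length(x) < 100) stop("need >= 100 events above the mass floor")
  ks <- if (is.null(k)) seq_len(max_k) else k
  best <- NULL
  for (kk in ks) {
    fit <- if (kk == 1) {
      list(mean = mean(x), sd = stats::sd(x), weight = 1, count = length(x),
           loglik = sum(stats::dnorm(x, mean(x), stats::sd(x), log = TRUE)),
           k = 1L, bic = -2 * sum(stats::dnorm(x, mean(x), stats::sd(x), log = TRUE)) +
             2 * log(length(x)))
    } else {
      .em_gaussian(x, kk)
    }
    if (is.null(fit)) next
    if (any(fit$weight < min_weight)) next
    if (is.null(best) || fit$bic < best$bic) best <- fit
  }
  if (is.null(best)) stop("no admissible mixture fit (all k degenerate)")
  out <- data.frame(mean = best$mean, sd = best$sd, weight = best$weight,
                    count = best$count)
  attr(out, "loglik") <- best$loglik
  attr(out, "bic") <- best$bic
  attr(out, "k") <- best$k
  attr(out, "n_events") <- length(x)
  class(out) <- c("mp_components", "data.frame")
  out
}

#' Assign nanobody-bound complexes to fitted mass peaks
#'
#' For each fitted peak, finds the subset of nanobodies whose summed mass,
#' added to the antigen, best matches the observed peak mean; the
#' assignment is flagged when the residual exceeds `tolerance`. The default
#' tolerance (8 kDa) sits below a single-nanobody step (10-20 kDa), so
#' successive occupancy states are not merged.
#'
#' @param components an [fit_mass_components()] table (or data.frame with a
#'   `mean` column)
#' @param antigen_mass antigen mass in kDa
#' @param nanobody_masses named numeric vector of nanobody masses (kDa,
#'   including any tags)
#' @param tolerance maximum |expected - observed| for an assignment (kDa)
#' @return data.frame: `peak_mass`, `composition` ("antigen" or
#'   "antigen+<names>", NA when unassigned), `n_nanobodies`,
#'   `expected_mass`, `delta`, `within_tolerance`
#' @export
assign_complexes <- function(components, antigen_mass, nanobody_masses,
                             tolerance = 8) {
  stopifnot(antigen_mass > 0, all(nanobody_masses > 0), tolerance > 0)
  nb <- sort(nanobody_masses)   # permutation-invariant in input order
  n <- length(nb)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  expected <- antigen_mass + as.matrix(subsets) %*% nb
  rows <- lapply(components$mean, function(m) {
    i <- which.min(abs(expected - m))
    delta <- m - expected[i]
    ok <- abs(delta) <= tolerance
    members <- names(nb)[unlist(subsets[i, ])]
    data.frame(
      peak_mass = m,
      composition = if (!ok) NA_character_ else if (length(members) == 0) "antigen"
                    else paste(c("antigen", members), collapse = "+"),
      n_nanobodies = if (ok) length(members) else NA_integer_,
      expected_mass = if (ok) unname(expected[i]) else NA_real_,
      delta = if (ok) unname(delta) else NA_real_,
      within_tolerance = ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stepwise mass-shift report
#'
#' Orders peak masses and reports each successive shift and whether it
#' falls inside the window expected for one additional bound nanobody.
#'
#' @param peak_masses numeric peak means (kDa), any order
#' @param window length-2 numeric: acceptable per-addition shift (kDa)
#' @return data.frame: `from`, `to`, `delta`, `in_window`
#' @export
stepwise_shifts <- function(peak_masses, window = c(10, 20)) {
  m <- sort(peak_masses)
  if (length(m) < 2) stop("need >= 2 peaks for shifts")
  d <- diff(m)
  data.frame(from = utils::head(m, -1), to = m[-1], delta = d,
             in_window = d >= window[1] & d <= window[2])
}
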