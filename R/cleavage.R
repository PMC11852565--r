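#' Percent cleavage from gel band intensities
#'
#' `100 * sum(products) / (uncut + sum(products))`, the densitometric
#' fraction of substrate converted to product. Band intensities are assumed
#' proportional to DNA mass (stain scales with mass), so product bands are
#' summed without mass-weighting by default; `weights` allows per-band
#' weighting if desired.
#'
#' @param uncut intensity of the uncut band
#' @param products intensities of the product bands
#' @param weights optional per-band weights for `products`
#' @return percent cleaved, in [0, 100]
#' @export
percent_cleavage <- function(uncut, products, weights = NULL) {
  if (any(c(uncut, products) < 0)) stop("intensities must be >= 0")
  w <- if (is.null(weights)) rep(1, length(products)) else weights
  prod_sum <- sum(w * products)
  total <- uncut + prod_sum
  if (total <= 0) stop("all-zero lane")
  100 * prod_sum / total
}

#' Build a cleavage time course from gel lanes
#'
#' Computes percent cleavage per lane, then the mean and standard deviation
#' across replicates at each time point (error bars are the SD of the
#' replicate measurements).
#'
#' @param lanes data.frame with columns `condition`, `replicate`,
#'   `time_min`, `band_role` (`"uncut"` or `"product"`), `intensity`
#' @return data.frame of class `cleavage_time_course`: `condition`,
#'   `time_min`, `mean_percent`, `sd_percent`, `n_replicates`, ordered by
#'   condition then time
#' @export
build_time_course <- function(lanes) {
  req <- c("condition", "replicate", "time_min", "band_role", "intensity")
  if (!all(req %in% names(lanes))) stop("lanes must have columns: ", paste(req, collapse = ", "))
  key <- interaction(lanes$condition, lanes$replicate, lanes$time_min, drop = TRUE)
  per_lane <- lapply(split(lanes, key), function(d) {
    uncut <- d$intensity[d$band_role == "uncut"]
    if (length(uncut) != 1) {
      stop("each (condition, replicate, time) lane needs exactly one uncut band; ",
           "got ", length(uncut), " for ", d$condition[1], " t=", d$time_min[1])
    }
    data.frame(condition = d$condition[1], replicate = d$replicate[1],
               time_min = d$time_min[1],
               percent = percent_cleavage(uncut, d$intensity[d$band_role == "product"]))
  })
  per_lane <- do.call(rbind, per_lane)
  agg_key <- interaction(per_lane$condition, per_lane$time_min, drop = TRUE)
  out <- do.call(rbind, lapply(split(per_lane, agg_key), function(d) {
    data.frame(condition = d$condition[1], time_min = d$time_min[1],
               mean_percent = mean(d$percent),
               sd_percent = if (nrow(d) > 1) stats::sd(d$percent) else NA_real_,
               n_replicates = nrow(d))
  }))
  for (cond in unique(out$condition)) {
    tt <- out$time_min[out$condition == cond]
    if (length(tt) < 2) stop("need >= 2 time points per condition (", cond, ")")
  }
  out <- out[order(out$condition, out$time_min), ]
  rownames(out) <- NULL
  class(out) <- c("cleavage_time_course", "data.frame")
  out
}

#' Decide inhibition from control and treated time courses
#'
#' Compares percent-cleavage trajectories on their shared time range
#' (linear interpolation where grids differ). The treated condition is
#' called non-inhibitory when the absolute difference stays within
#' `threshold` percentage points at every shared time; the assay's claim is
#' qualitative, so the default threshold (15 points) is deliberately loose
#' and configurable.
#'
#' @param control,treated [build_time_course()] outputs (single condition
#'   each)
#' @param threshold maximum tolerated |difference| in percentage points
#' @return list: `verdict` ("non-inhibitory"/"inhibitory"), `max_delta`,
#'   `time_of_max`, `deltas` (data.frame time_min, delta)
#' @export
compare_inhibition <- function(control, treated, threshold = 15) {
  lo <- max(min(control$time_min), min(treated$time_min))
  hi <- min(max(control$time_min), max(treated$time_min))
  if (lo > hi) stop("disjoint time ranges")
  times <- sort(unique(c(control$time_min, treated$time_min)))
  times <- times[times >= lo & times <= hi]
  c_i <- stats::approx(control$time_min, control$mean_percent, xout = times)$y
  t_i <- stats::approx(treated$time_min, treated$mean_percent, xout = times)$y
  delta <- t_i - c_i
  i_max <- which.max(abs(delta))
  list(verdict = if (max(abs(delta)) <= threshold) "non-inhibitory" else "inhibitory",
       max_delta = abs(delta[i_max]), time_of_max = times[i_max],
       deltas = data.frame(time_min = times, delta = delta))
}
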