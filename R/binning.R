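#' Classification thresholds for the competition statistic
#'
#' Percent-binding below `same_max` means the analyte was blocked by the
#' capture clone (same epitope); above `diff_min` it bound freely
#' (different epitope); values in between are left indeterminate rather
#' than forced.
#'
#' @param same_max upper bound (percent) for a same-epitope call
#' @param diff_min lower bound (percent) for a different-epitope call
#' @return list of class `binning_thresholds`
#' @export
binning_thresholds <- function(same_max = 25, diff_min = 60) {
  stopifnot(0 <= same_max, same_max < diff_min, diff_min <= 100)
  structure(list(same_max = same_max, diff_min = diff_min),
            class = "binning_thresholds")
}

#' Assemble a sandwich-ELISA competition experiment
#'
#' One experiment = one unlabeled capture clone immobilizing the antigen,
#' with dose-response curves for every biotinylated analyte clone
#' (including the capture clone's own biotinylated version).
#'
#' @param capture_clone clone id of the unlabeled capture nanobody
#' @param analyte_curves named list of [dose_response_curve()]s, one per
#'   biotinylated analyte; must include `capture_clone`
#' @return list of class `competition_experiment`
#' @export
competition_experiment <- function(capture_clone, analyte_curves) {
  if (!capture_clone %in% names(analyte_curves)) {
    stop("capture clone must be among the analytes (self competition)")
  }
  grids <- lapply(analyte_curves, function(cu) sort(unique(cu$concentration)))
  if (length(unique(vapply(grids, paste, character(1), collapse = ","))) != 1) {
    stop("all analyte curves must share the dilution design")
  }
  structure(list(capture = capture_clone, curves = analyte_curves),
            class = "competition_experiment")
}

#' Score a competition experiment
#'
#' The campaign's binning statistic: from each analyte's log-dose AUC,
#' subtract the AUC of the capture clone's own biotinylated curve (the
#' residual signal a fully blocked analyte would give), then express the
#' corrected AUC as a percentage of the largest corrected AUC — by default
#' the tightest binder within the same experiment. Percentages are clamped
#' to [0, 100]; negative corrected areas are noise below the self-blocked
#' baseline.
#'
#' @param exp a [competition_experiment()]
#' @param thresholds a [binning_thresholds()]
#' @param reference_auc optional externally supplied denominator (e.g. the
#'   tightest binder's corrected AUC from a direct ELISA) replacing the
#'   per-experiment maximum
#' @return data.frame with one row per analyte: `capture`, `analyte`,
#'   `auc`, `corrected_auc`, `percent_binding`, `classification`
#'   (same_epitope / different_epitope / indeterminate), `usable`
#' @export
score_competition <- function(exp, thresholds = binning_thresholds(),
                              reference_auc = NULL) {
  aucs <- vapply(exp$curves, auc_logdose, numeric(1))
  corrected <- aucs - aucs[[exp$capture]]
  denom <- if (is.null(reference_auc)) max(corrected) else reference_auc
  usable <- denom > 0
  percent <- if (usable) clamp(100 * corrected / denom, 0, 100) else rep(NA_real_, length(corrected))
  percent[names(corrected) == exp$capture] <- 0   # self is 0 by construction
  cls <- rep("indeterminate", length(corrected))
  if (usable) {
    cls[percent <= thresholds$same_max] <- "same_epitope"
    cls[percent > thresholds$diff_min] <- "different_epitope"
  }
  cls[names(corrected) == exp$capture] <- "same_epitope"
  out <- data.frame(capture = exp$capture, analyte = names(corrected),
                    auc = unname(aucs), corrected_auc = unname(corrected),
                    percent_binding = unname(percent), classification = cls,
                    usable = usable, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Infer epitope bins from competition scores
#'
#' Builds an undirected graph over the clone universe with an edge for
#' every pair called same-epitope in any experiment (either direction);
#' bins are the connected components, i.e. the transitive closure of the
#' pairwise calls. Pairs called both same and different across experiments
#' are kept connected but reported as conflicts; intra-bin pairs never
#' directly assayed as same are flagged `inferred_by_transitivity`.
#'
#' @param scores one data.frame from [score_competition()], or a list of
#'   them (one per capture experiment), or a data.frame with at least
#'   `capture`, `analyte`, `classification` columns (e.g. a hand-encoded
#'   qualitative pattern)
#' @param clones optional explicit clone universe
#' @return list of class `bin_assignment`: `bins` (named character vector
#'   clone -> bin label, bins numbered by decreasing size then
#'   alphabetically by first member), `graph` (igraph), `conflicts`,
#'   `indeterminate` and `transitive_pairs` data.frames
#' @export
infer_bins <- function(scores, clones = NULL) {
  if (is.data.frame(scores)) scores <- list(scores)
  calls <- do.call(rbind, lapply(scores, function(s) {
    s[, c("capture", "analyte", "classification")]
  }))
  if (is.null(clones)) clones <- sort(unique(c(calls$capture, calls$analyte)))
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  nonself <- calls[calls$capture != calls$analyte, ]
  keys <- pair_key(nonself$capture, nonself$analyte)
  same_pairs <- unique(keys[nonself$classification == "same_epitope"])
  diff_pairs <- unique(keys[nonself$classification == "different_epitope"])
  indet_pairs <- unique(keys[nonself$classification == "indeterminate"])
  conflicts <- intersect(same_pairs, diff_pairs)

  g <- igraph::make_empty_graph(n = length(clones), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = clones)
  if (length(same_pairs) > 0) {
    ends <- do.call(rbind, strsplit(same_pairs, "|", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(ends)))
  }
  comp <- igraph::components(g)
  member <- split(clones, comp$membership)
  # stable bin labels: by decreasing size, ties by first member
  ord <- order(-vapply(member, length, integer(1)),
               vapply(member, function(m) sort(m)[1], character(1)))
  bins <- character(0)
  for (i in seq_along(ord)) {
    bins[member[[ord[i]]]] <- paste0("bin", i)
  }
  bins <- bins[clones]

  split_key <- function(k) {
    if (length(k) == 0) {
      return(data.frame(clone_a = character(0), clone_b = character(0)))
    }
    ends <- do.call(rbind, strsplit(k, "|", fixed = TRUE))
    data.frame(clone_a = ends[, 1], clone_b = ends[, 2], stringsAsFactors = FALSE)
  }
  # intra-bin pairs with no direct same-epitope call
  trans <- list()
  for (b in unique(bins)) {
    mem <- sort(names(bins)[bins == b])
    if (length(mem) < 2) next
    prs <- utils::combn(mem, 2)
    for (i in seq_len(ncol(prs))) {
      k <- pair_key(prs[1, i], prs[2, i])
      if (!k %in% same_pairs) trans[[length(trans) + 1]] <- k
    }
  }
  structure(list(bins = bins, graph = g,
                 conflicts = split_key(conflicts),
                 indeterminate = split_key(setdiff(indet_pairs,
                                                   c(same_pairs, diff_pairs))),
                 transitive_pairs = split_key(unlist(trans))),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  for (b in sort(unique(x$bins))) {
    cat(b, ": ", paste(sort(names(x$bins)[x$bins == b]), collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$conflicts) > 0) {
    cat("WARNING:", nrow(x$conflicts), "conflicting same/different pair(s)\n")
  }
  invisible(x)
}

#' Capture-by-analyte percent-binding matrix with bin table
#'
#' @param scores list of [score_competition()] data.frames
#' @param assignment a [infer_bins()] result (computed from `scores` when
#'   omitted)
#' @return list with `matrix` (rows = captures, columns = analytes,
#'   entries percent binding; self cells 0) and `bin_table` (clone, bin)
#' @export
binning_report <- function(scores, assignment = NULL) {
  if (is.data.frame(scores)) scores <- list(scores)
  if (is.null(assignment)) assignment <- infer_bins(scores)
  captures <- vapply(scores, function(s) s$capture[1], character(1))
  analytes <- sort(unique(unlist(lapply(scores, function(s) s$analyte))))
  m <- matrix(NA_real_, length(captures), length(analytes),
              dimnames = list(captures, analytes))
  for (s in scores) {
    m[s$capture[1], s$analyte] <- round_half_up(s$percent_binding, 1)
  }
  bin_table <- data.frame(clone = names(assignment$bins),
                          bin = unname(assignment$bins),
                          stringsAsFactors = FALSE)
  bin_table <- bin_table[order(bin_table$bin, bin_table$clone), ]
  rownames(bin_table) <- NULL
  list(matrix = m, bin_table = bin_table)
}
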