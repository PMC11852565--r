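#' Published germline gene-usage census of the anti-Cas9 library
#'
#' Gene usage of the 51-clone anti-SpCas9 library as printed in the
#' campaign report: counts (and percent) of clones per inferred germline V,
#' D and J gene. D percentages are over the 12 clones with an identifiable
#' D segment.
#'
#' @return data.frame with columns `segment`, `gene`, `count`, `percent`
#' @export
campaign_gene_usage <- function() {
  data.frame(
    segment = c(rep("V", 5), rep("D", 5), rep("J", 3)),
    gene = c("IGHV3S66", "IGHV3S53", "IGHV3S65", "IGHV3S1", "IGHV3S61",
             "IGHD3", "IGHD5", "IGHD6", "IGHD2", "IGHD1",
             "IGHJ4", "IGHJ6", "IGHJ7"),
    count = c(26L, 12L, 11L, 1L, 1L, 7L, 2L, 1L, 1L, 1L, 39L, 8L, 4L),
    percent = c(51, 23.5, 21.6, 2, 2, 58.3, 16.7, 8.3, 8.3, 8.3,
                76.5, 15.7, 7.8),
    stringsAsFactors = FALSE)
}

#' Published mutation/lysine census of the fifteen selected clones
#'
#' The selected biotinylation candidates with their V-gene nucleotide
#' mutation counts, amino-acid changes from the inferred unmutated common
#' ancestor, and lysines outside CDR3 (all selected clones have none inside
#' CDR3).
#'
#' @return data.frame with columns `clone`, `v_nt_mutations`, `aa_changes`,
#'   `non_cdr3_lysines`
#' @export
campaign_selected_clones <- function() {
  data.frame(
    clone = c("C1", "C7", "F9", "D9", "G7", "E6", "F8", "F1", "G10", "D5",
              "F6", "A6", "G5", "D8", "E4"),
    v_nt_mutations = c(33L, 37L, 35L, 14L, 10L, 8L, 10L, 7L, 10L, 41L,
                       10L, 44L, 32L, 12L, 9L),
    aa_changes = c(20L, 21L, 20L, 7L, 6L, 5L, 6L, 3L, 6L, 20L,
                   5L, 23L, 17L, 6L, 4L),
    non_cdr3_lysines = c(3L, rep(5L, 14)),
    stringsAsFactors = FALSE)
}

#' Published EC50 estimates of the five tightest binders
#'
#' Half-maximal effective concentrations (nM) against apo SpCas9 for the
#' clones whose values were reported individually; the remaining four
#' binders' EC50s were reported only as a range (18.5-63.4 nM).
#'
#' @return named numeric vector (nM)
#' @export
campaign_ec50 <- function() {
  c(C1 = 2, D9 = 4.5, F9 = 6.6, C7 = 7.1, G7 = 9.1)
}

#' Published qualitative competition outcomes for the nine binders
#'
#' The sandwich-ELISA outcomes as reported: three capture experiments (E6,
#' F9, C1) over nine biotinylated analytes, each pair called same-epitope
#' (blocked, <25% binding) or different-epitope (>60%). The two cells with
#' printed percentages carry them (4.1% for C7 on F9 capture; 90.6% for C1
#' on F9 capture); self cells are 0 by construction.
#'
#' @return data.frame with columns `capture`, `analyte`, `classification`,
#'   `percent_binding` (NA where only the qualitative call was printed)
#' @export
campaign_competition_calls <- function() {
  clones <- c("C1", "C7", "D9", "E6", "F1", "F8", "F9", "G10", "G7")
  same_by_capture <- list(
    E6 = c("F1", "F8", "G10", "G7", "D9"),
    F9 = c("C7"),
    C1 = character(0))
  rows <- list()
  for (cap in names(same_by_capture)) {
    for (ana in clones) {
      cls <- if (ana == cap || ana %in% same_by_capture[[cap]]) {
        "same_epitope"
      } else "different_epitope"
      pct <- NA_real_
      if (ana == cap) pct <- 0
      if (cap == "F9" && ana == "C7") pct <- 4.1
      if (cap == "F9" && ana == "C1") pct <- 90.6
      rows[[length(rows) + 1]] <- data.frame(
        capture = cap, analyte = ana, classification = cls,
        percent_binding = pct, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Published mass-photometry peak series
#'
#' Average complex masses (kDa) observed as the three bin representatives
#' were added stepwise to SpCas9: antigen alone, +C1, +C1+D9, +C1+D9+F9.
#'
#' @return data.frame with columns `condition`, `peak_kda`,
#'   `nanobodies` (list column of bound clones)
#' @export
campaign_mp_peaks <- function() {
  out <- data.frame(
    condition = c("Cas9", "Cas9+C1", "Cas9+C1+D9", "Cas9+C1+D9+F9"),
    peak_kda = c(160, 180, 190, 209), stringsAsFactors = FALSE)
  out$nanobodies <- list(character(0), "C1", c("C1", "D9"), c("C1", "D9", "F9"))
  out
}

#' Full simulation scenario mirroring the campaign's headline layout
#'
#' One configuration bundle reproducing the campaign's stated world: the
#' nine binders partitioned into three epitope bins ({C1}, {F9, C7},
#' {E6, F1, F8, G10, G7, D9}); EC50s at the five printed values with the
#' remaining four spread over the printed 18.5-63.4 nM range (F8 = 18.5 and
#' E6 = 37, a 2-fold pair; F1 = 21 and G10 = 63.4, a ~3-fold pair, as
#' described for those clone pairs); the fifteen selected clones' planted
#' V-gene mutation counts; the stepwise mass-photometry series; and equal
#' cleavage rate constants for the inhibition assay (the nanobodies do not
#' inhibit).
#'
#' @return named list of scenario parameters consumed by the generators
#' @export
campaign_scenario <- function() {
  epitope_map <- c(
    C1 = "ep1", F9 = "ep2", C7 = "ep2",
    E6 = "ep3", F1 = "ep3", F8 = "ep3", G10 = "ep3", G7 = "ep3", D9 = "ep3")
  affinities <- c(campaign_ec50(), F8 = 18.5, F1 = 21, E6 = 37, G10 = 63.4)
  sel <- campaign_selected_clones()
  mp <- campaign_mp_peaks()
  list(
    epitope_map = epitope_map,
    affinities = affinities[names(epitope_map)],
    planted_mutations = stats::setNames(sel$v_nt_mutations, sel$clone),
    mp_conditions = mp,
    antigen_mass = 160,
    nanobody_masses = c(C1 = 17, D9 = 14, F9 = 16),
    mp_sd = 12,
    cleavage_k = c(`RNP alone` = 0.45, `RNP+C1` = 0.45,
                   `RNP+D9` = 0.45, `RNP+F9` = 0.45),
    cleavage_times = c(1, 5, 10, 60))
}
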