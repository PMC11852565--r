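#' Simulate a somatically mutated nanobody repertoire
#'
#' Builds each clone as a V (+ optional D) + J germline concatenation and
#' plants point substitutions in the V region (substitution-only model, so
#' mutation-count oracles are exact; indels are not simulated). Each
#' mutation is targeted silent with probability `silent_fraction` when a
#' synonymous substitution exists at the sampled position. The returned
#' truth records every planted change, so downstream mutation counting can
#' be checked position-by-position.
#'
#' @param germline_set a [germline_set()]
#' @param n number of clones
#' @param mutation_rate per-base V-region substitution rate in [0, 0.2]
#'   (ignored for clones with an entry in `planted_counts`)
#' @param silent_fraction target fraction of silent substitutions
#' @param seed RNG seed
#' @param planted_counts optional integer vector (length `n`) of exact
#'   mutation counts per clone
#' @param clone_ids optional clone names (default NB001..)
#' @param gene_probs optional named probabilities for V-gene draws
#' @param d_prob probability a clone includes a D segment
#' @return list with `records` (list of [nanobody_record()]) and `truth`
#'   (per-clone list: genes, n_mutations, n_nonsilent, mutation table)
#' @export
gen_repertoire <- function(germline_set, n, mutation_rate = 0.05,
                           silent_fraction = 0.3, seed = 1,
                           planted_counts = NULL, clone_ids = NULL,
                           gene_probs = NULL, d_prob = 0.8) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 0.2)
  gs <- germline_set
  if (is.null(clone_ids)) clone_ids <- sprintf("NB%03d", seq_len(n))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    records <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      vp <- if (is.null(gene_probs)) NULL else gene_probs[names(gs$v)]
      v_gene <- sample(names(gs$v), 1, prob = vp)
      has_d <- length(gs$d) > 0 && stats::runif(1) < d_prob
      d_gene <- if (has_d) sample(names(gs$d), 1) else NA_character_
      j_gene <- sample(names(gs$j), 1)
      v_nt <- strsplit(gs$v[[v_gene]], "")[[1]]
      n_mut <- if (!is.null(planted_counts)) planted_counts[i] else {
        stats::rbinom(1, length(v_nt), mutation_rate)
      }
      pos <- sample(length(v_nt), min(n_mut, length(v_nt)))
      muts <- NULL
      for (p in pos) {
        codon_i <- (p - 1) %/% 3
        codon <- v_nt[(3 * codon_i + 1):(3 * codon_i + 3)]
        within <- (p - 1) %% 3 + 1
        ref_aa <- .translate_inframe(paste(codon, collapse = ""))
        alts <- setdiff(bases, v_nt[p])
        alt_aa <- vapply(alts, function(b) {
          cd <- codon; cd[within] <- b
          .translate_inframe(paste(cd, collapse = ""))
        }, character(1))
        viable <- alt_aa != "*"
        if (!any(viable)) next
        alts <- alts[viable]; alt_aa <- alt_aa[viable]
        want_silent <- stats::runif(1) < silent_fraction
        pool <- if (want_silent && any(alt_aa == ref_aa)) {
          alts[alt_aa == ref_aa]
        } else if (!want_silent && any(alt_aa != ref_aa)) {
          alts[alt_aa != ref_aa]
        } else alts
        alt <- pool[sample.int(length(pool), 1)]
        silent <- alt_aa[match(alt, alts)] == ref_aa
        muts <- rbind(muts, data.frame(pos0 = p - 1L, ref = v_nt[p], alt = alt,
                                       silent = silent, stringsAsFactors = FALSE))
        v_nt[p] <- alt
      }
      nt <- paste0(paste(v_nt, collapse = ""),
                   if (has_d) gs$d[[d_gene]] else "", gs$j[[j_gene]])
      records[[i]] <- nanobody_record(clone_ids[i], nt)
      # position-wise translation comparison: the exact aa-change oracle
      # (multi-hit codons can make this differ from the non-silent tally)
      germ_aa <- strsplit(.translate_inframe(gs$v[[v_gene]]), "")[[1]]
      mut_aa <- strsplit(.translate_inframe(paste(v_nt, collapse = "")), "")[[1]]
      truth[[i]] <- list(clone_id = clone_ids[i], v_gene = v_gene,
                         d_gene = d_gene, j_gene = j_gene,
                         n_mutations = if (is.null(muts)) 0L else nrow(muts),
                         n_nonsilent = if (is.null(muts)) 0L else sum(!muts$silent),
                         n_aa_changes = sum(germ_aa != mut_aa),
                         mutations = muts)
    }
    names(truth) <- clone_ids
    list(records = records, truth = truth)
  })
}

#' Simulate ELISA dose-response plates
#'
#' Generates long-format plate data: for each (clone, antigen) parameter
#' row, `a450 = max(4PL(dose) + noise, 0) + blank` over the dose grid, per
#' replicate.
#'
#' @param params data.frame with columns `clone_id`, `antigen_id`,
#'   `bottom`, `top`, `ec50`, `hill` (EC50 in nM)
#' @param doses dose grid in nM
#' @param noise_sd additive Gaussian absorbance noise
#' @param replicates replicates per curve
#' @param blank blank absorbance level
#' @param seed RNG seed
#' @return list with `plate` (data.frame clone_id, antigen_id, replicate,
#'   concentration, conc_unit, a450, blank) and `truth` (= `params`)
#' @export
gen_dose_response <- function(params, doses = default_dose_grid(),
                              noise_sd = 0.02, replicates = 1, blank = 0.05,
                              seed = 1) {
  stopifnot(all(doses > 0))
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(params))) {
      p <- params[i, ]
      for (r in seq_len(replicates)) {
        sig <- fourpl(doses, p$bottom, p$top, p$ec50, p$hill) +
          stats::rnorm(length(doses), 0, noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          clone_id = p$clone_id, antigen_id = p$antigen_id, replicate = r,
          concentration = doses, conc_unit = "nM",
          a450 = pmax(sig, 0) + blank, blank = blank,
          stringsAsFactors = FALSE)
      }
    }
    list(plate = do.call(rbind, rows), truth = params)
  })
}

#' Simulate sandwich-ELISA competition plates
#'
#' Occupancy model: a biotinylated analyte's signal follows its own 4PL
#' curve, multiplied by a blocking factor `eps_block` (<< 1) when the
#' analyte targets the same epitope as the capture clone (the captured
#' antigen's epitope is already occupied). The capture clone's biotinylated
#' self is always blocked.
#'
#' @param epitope_map named character vector clone -> epitope label
#' @param affinities named numeric vector clone -> EC50 (nM)
#' @param capture_set clones used as capture (default: all)
#' @param doses dose grid (nM)
#' @param noise_sd additive absorbance noise
#' @param eps_block residual occupancy for a blocked analyte, in [0, 0.25)
#' @param top,bottom,hill shared 4PL shape parameters
#' @param blank blank absorbance
#' @param seed RNG seed
#' @return list with `plates` (data.frame capture_clone, analyte_clone,
#'   replicate, concentration, conc_unit, a450, blank) and `truth`
#'   (epitope_map)
#' @export
gen_competition <- function(epitope_map, affinities,
                            capture_set = names(epitope_map),
                            doses = default_dose_grid(), noise_sd = 0.02,
                            eps_block = 0.05, top = 1.8, bottom = 0,
                            hill = 1, blank = 0.05, seed = 1) {
  stopifnot(eps_block >= 0, eps_block < 0.25 || eps_block == 1)
  clones <- names(epitope_map)
  stopifnot(all(capture_set %in% clones), all(clones %in% names(affinities)))
  with_seed(seed, {
    rows <- list()
    for (cap in capture_set) {
      for (ana in clones) {
        blocked <- epitope_map[[ana]] == epitope_map[[cap]]
        fac <- if (blocked) eps_block else 1
        sig <- fac * fourpl(doses, bottom, top, affinities[[ana]], hill) +
          stats::rnorm(length(doses), 0, noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          capture_clone = cap, analyte_clone = ana, replicate = 1,
          concentration = doses, conc_unit = "nM",
          a450 = pmax(sig, 0) + blank, blank = blank,
          stringsAsFactors = FALSE)
      }
    }
    list(plates = do.call(rbind, rows), truth = epitope_map)
  })
}

#' Build competition experiments from a simulated (or read) plate table
#'
#' @param plates data.frame as produced by [gen_competition()] (columns
#'   capture_clone, analyte_clone, replicate, concentration, conc_unit,
#'   a450, blank)
#' @return list of [competition_experiment()]s, one per capture clone
#' @export
plates_to_experiments <- function(plates) {
  lapply(split(plates, plates$capture_clone), function(p) {
    curves <- lapply(split(p, p$analyte_clone), function(d) {
      dose_response_curve(d$analyte_clone[1], paste0("captured_by_", d$capture_clone[1]),
                          d$concentration, d$a450, conc_unit = d$conc_unit[1],
                          blank = d$blank[1], replicate = d$replicate)
    })
    competition_experiment(p$capture_clone[1], curves)
  })
}

#' Simulate mass-photometry landing events
#'
#' @param means component mean masses (kDa)
#' @param weights mixture weights (sum to 1)
#' @param sd common component standard deviation (kDa)
#' @param n number of events
#' @param seed RNG seed
#' @return list with `events` (numeric masses) and `truth` (means, weights,
#'   sd, component index per event)
#' @export
gen_mp_events <- function(means, weights, sd, n, seed = 1) {
  stopifnot(abs(sum(weights) - 1) < 1e-8, length(means) == length(weights))
  with_seed(seed, {
    comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
    events <- stats::rnorm(n, means[comp], sd)
    list(events = events,
         truth = list(means = means, weights = weights, sd = sd, component = comp))
  })
}

#' Simulate gel lanes for a first-order cleavage time course
#'
#' Cleaved fraction follows `1 - exp(-k t)`; each lane's uncut band carries
#' the remaining substrate and two product bands split the cleaved fraction
#' equally (a linearized substrate cut once gives two fragments).
#' Intensities get multiplicative log-normal noise.
#'
#' @param k_per_condition named numeric vector condition -> rate constant
#'   (per minute, >= 0)
#' @param times sampling times in minutes
#' @param noise_sd sd of the log-normal intensity noise (0 = noiseless)
#' @param replicates lanes per (condition, time)
#' @param i0 total lane intensity before noise
#' @param seed RNG seed
#' @return list with `lanes` (data.frame condition, replicate, time_min,
#'   band_role, intensity) and `truth` (k per condition, expected fraction
#'   table)
#' @export
gen_gel <- function(k_per_condition, times = c(1, 5, 10, 60), noise_sd = 0.05,
                    replicates = 3, i0 = 1000, seed = 1) {
  stopifnot(all(k_per_condition >= 0))
  with_seed(seed, {
    rows <- list()
    for (cond in names(k_per_condition)) {
      k <- k_per_condition[[cond]]
      for (r in seq_len(replicates)) {
        for (t in times) {
          frac <- 1 - exp(-k * t)
          noise <- function() if (noise_sd > 0) exp(stats::rnorm(1, 0, noise_sd)) else 1
          rows[[length(rows) + 1]] <- data.frame(
            condition = cond, replicate = r, time_min = t,
            band_role = c("uncut", "product", "product"),
            intensity = c(i0 * (1 - frac) * noise(),
                          i0 * frac / 2 * noise(), i0 * frac / 2 * noise()),
            stringsAsFactors = FALSE)
        }
      }
    }
    expected <- expand.grid(condition = names(k_per_condition), time_min = times,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    expected$fraction <- 1 - exp(-k_per_condition[expected$condition] * expected$time_min)
    list(lanes = do.call(rbind, rows),
         truth = list(k = k_per_condition, expected = expected))
  })
}
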