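#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume, with the
# ground truth serialized alongside. The scenario mirrors the campaign's
# stated world: a 51-clone library dominated by one V gene, nine binders in
# three epitope bins, EC50s spanning 2-63.4 nM, a stepwise mass-photometry
# series and non-inhibitory cleavage kinetics.

library(nbscreen)

seed <- 1
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sc <- campaign_scenario()
gs <- synthetic_germline_set()
write_germline_set(gs, file.path(out, "germline.fasta"),
                   file.path(out, "germline_anchors.tsv"))

# --- repertoire: 51 clones, V usage skewed like the published library ----
usage <- campaign_gene_usage()
v_probs <- with(usage[usage$segment == "V", ],
                stats::setNames(count / sum(count), gene))
rep_lib <- gen_repertoire(gs, 51, mutation_rate = 0.05, seed = seed,
                          gene_probs = v_probs,
                          clone_ids = sprintf("LIB%03d", 1:51))
Biostrings::writeXStringSet(Biostrings::DNAStringSet(
  stats::setNames(vapply(rep_lib$records, function(r) r$nt_seq, character(1)),
                  vapply(rep_lib$records, function(r) r$clone_id, character(1)))),
  file.path(out, "library.fasta"))

# a 15-clone panel carrying the published selected-clone mutation loads
sel <- campaign_selected_clones()
rep_sel <- gen_repertoire(gs, 15, seed = seed + 1,
                          planted_counts = sel$v_nt_mutations,
                          clone_ids = sel$clone)
Biostrings::writeXStringSet(Biostrings::DNAStringSet(
  stats::setNames(vapply(rep_sel$records, function(r) r$nt_seq, character(1)),
                  sel$clone)),
  file.path(out, "selected_panel.fasta"))

# --- direct ELISA plates: nine binders vs apo Cas9 and RNP --------------
params_apo <- data.frame(clone_id = names(sc$affinities), antigen_id = "Cas9",
                         bottom = 0, top = 1.8,
                         ec50 = unname(sc$affinities), hill = 1)
params_rnp <- transform(params_apo, antigen_id = "RNP")
plate <- rbind(gen_dose_response(params_apo, noise_sd = 0.02, replicates = 2,
                                 seed = seed + 2)$plate,
               gen_dose_response(params_rnp, noise_sd = 0.02, replicates = 2,
                                 seed = seed + 3)$plate)
utils::write.csv(plate, file.path(out, "elisa_direct.csv"), row.names = FALSE)

# cross-reactivity: flat plates for the non-cognate nucleases
flat <- data.frame(clone_id = rep(c("C1", "D9", "F9"), each = 3),
                   antigen_id = rep(c("Cas3", "Cas12", "Cas14"), 3),
                   bottom = 0, top = 0, ec50 = 1, hill = 1)
plate_x <- gen_dose_response(flat, noise_sd = 0.01, seed = seed + 4)$plate
utils::write.csv(plate_x, file.path(out, "elisa_crossreact.csv"), row.names = FALSE)

# --- competition plates: all nine clones as capture ---------------------
comp <- gen_competition(sc$epitope_map, sc$affinities, noise_sd = 0.02,
                        seed = seed + 5)
utils::write.csv(comp$plates, file.path(out, "competition.csv"), row.names = FALSE)

# --- mass photometry: four stepwise acquisitions ------------------------
mp <- sc$mp_conditions
for (i in seq_len(nrow(mp))) {
  ev <- gen_mp_events(mp$peak_kda[i], 1, sc$mp_sd, 10000, seed = seed + 10 + i)
  utils::write.csv(data.frame(mass_kda = round(ev$events, 3)),
                   file.path(out, sprintf("mp_%d_%s.csv", i,
                                          gsub("[^A-Za-z0-9]", "_", mp$condition[i]))),
                   row.names = FALSE)
}

# --- cleavage gels ------------------------------------------------------
gel <- gen_gel(sc$cleavage_k, times = sc$cleavage_times, noise_sd = 0.06,
               replicates = 3, seed = seed + 20)
utils::write.csv(gel$lanes, file.path(out, "gel_lanes.csv"), row.names = FALSE)

# --- ground truth sidecar ----------------------------------------------
truth <- list(
  seed = seed,
  epitope_map = as.list(sc$epitope_map),
  ec50_nM = as.list(sc$affinities),
  library_genes = lapply(rep_lib$truth, function(t) {
    t[c("v_gene", "d_gene", "j_gene", "n_mutations", "n_aa_changes")]
  }),
  selected_planted_mutations = as.list(stats::setNames(sel$v_nt_mutations, sel$clone)),
  mp_peaks_kda = mp$peak_kda,
  cleavage_k_per_min = as.list(sc$cleavage_k))
jsonlite::write_json(truth, file.path(out, "truth.json"), auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

message("wrote synthetic campaign inputs to ", out,
        " (51-clone library, 15-clone panel, ELISA/competition/MP/gel data)")
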