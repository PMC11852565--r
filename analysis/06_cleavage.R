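#!/usr/bin/env Rscript
# Cleavage inhibition: gel band intensities to percent-cleavage time
# courses, then an inhibition verdict for each nanobody-treated reaction
# against the RNP-alone control.

library(nbscreen)

sim <- "results/sim"
out <- "results/cleavage"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

lanes <- read_lanes_csv(file.path(sim, "gel_lanes.csv"))
tc <- build_time_course(lanes)
write_report_tsv(tc, file.path(out, "time_courses.tsv"), seed = seed)

ctrl <- tc[tc$condition == "RNP alone", ]
verdicts <- lapply(setdiff(unique(tc$condition), "RNP alone"), function(cond) {
  v <- compare_inhibition(ctrl, tc[tc$condition == cond, ])
  message(cond, ": ", v$verdict, " (max |delta| ", round(v$max_delta, 1),
          " points at t=", v$time_of_max, " min)")
  list(condition = cond, verdict = v$verdict, max_delta = v$max_delta,
       time_of_max = v$time_of_max)
})
jsonlite::write_json(list(seed = seed, control = "RNP alone",
                          verdicts = verdicts),
                     file.path(out, "inhibition_verdicts.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("all treated reactions compared against the RNP-alone control")
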