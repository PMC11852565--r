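# Shared fixtures: everything is generated in code, nothing is downloaded.

gs_fix <- synthetic_germline_set()

# a germline V+J concatenation (no D, no mutations) for a given gene pair
germline_concat <- function(v_gene, j_gene, gs = gs_fix) {
  paste0(gs$v[[v_gene]], gs$j[[j_gene]])
}

# fabricate an annotated record carrying a given germline call, for tests
# of census arithmetic that do not need real alignments
fake_called_record <- function(clone_id, v_gene, d_gene = NA_character_,
                               j_gene = "IGHJ4",
                               v_nt_mutations = 0L, aa_changes = 0L) {
  r <- nanobody_record(clone_id, germline_concat("IGHV3S66", "IGHJ4"))
  r$germline <- list(v_gene = v_gene, d_gene = d_gene, j_gene = j_gene,
                     v_identity = 100, v_nt_mutations = as.integer(v_nt_mutations),
                     aa_changes = as.integer(aa_changes))
  r
}

# canonical-form partition comparison (order-free)
partition_of <- function(labels) {
  unname(sort(vapply(split(names(labels), labels),
                     function(m) paste(sort(m), collapse = ","), character(1))))
}

# all set partitions of a small clone set, as epitope maps
all_epitope_maps <- function(clones) {
  n <- length(clones)
  maps <- list()
  # assign each clone a block index; keep canonical (restricted growth) codes
  grow <- function(code) {
    if (length(code) == n) {
      maps[[length(maps) + 1]] <<- stats::setNames(paste0("ep", code), clones)
      return(invisible())
    }
    for (b in seq_len(max(code) + 1)) grow(c(code, b))
  }
  grow(1L)
  maps
}
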