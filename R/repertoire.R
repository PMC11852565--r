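#' Translate a nanobody coding sequence, choosing the reading frame
#'
#' Scans the three forward frames and returns the translation with the
#' longest stop-free run from the start of the frame, which for a cloned
#' VHH coding sequence is the full-length domain. Ambiguous codons
#' (containing N) translate to X.
#'
#' @param nt_seq DNA string (alphabet ACGTN), length >= 90
#' @param min_len minimum acceptable stop-free translation length (aa)
#' @return list with `aa_seq` and 0-based `frame_offset`
#' @export
translate_and_frame <- function(nt_seq, min_len = 30) {
  nt_seq <- toupper(nt_seq)
  if (nchar(nt_seq) < 90) stop("nt_seq shorter than 90 bases")
  if (grepl("[^ACGTN]", nt_seq)) stop("nt_seq alphabet must be ACGTN")
  best <- list(len = -1L, aa = NULL, off = NA_integer_)
  for (off in 0:2) {
    n_codons <- (nchar(nt_seq) - off) %/% 3
    if (n_codons < 1) next
    aa <- .translate_inframe(substr(nt_seq, off + 1, off + 3 * n_codons))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    run <- if (stop_at > 0) stop_at - 1L else nchar(aa)
    if (run > best$len) best <- list(len = run, aa = substr(aa, 1, run), off = off)
  }
  if (best$len < min_len) {
    stop("untranslatable: no stop-free frame of >= ", min_len, " aa")
  }
  list(aa_seq = best$aa, frame_offset = best$off)
}

#' Create a nanobody clone record
#'
#' Translates the nucleotide sequence (frame chosen by
#' [translate_and_frame()]) and wraps it with empty annotation slots.
#' Region annotation and the germline call are filled in by
#' [assign_germline()].
#'
#' @param clone_id clone identifier
#' @param nt_seq nucleotide sequence
#' @return object of class `nanobody_record` with fields `clone_id`,
#'   `nt_seq`, `aa_seq`, `frame_offset`, `regions` (data.frame of 0-based
#'   half-open aa intervals, or NULL), `germline` (list, or NULL)
#' @export
nanobody_record <- function(clone_id, nt_seq) {
  tr <- translate_and_frame(nt_seq)
  structure(list(clone_id = clone_id, nt_seq = toupper(nt_seq),
                 aa_seq = tr$aa_seq, frame_offset = tr$frame_offset,
                 regions = NULL, germline = NULL),
            class = "nanobody_record")
}

#' @export
print.nanobody_record <- function(x, ...) {
  cat("nanobody_record", x$clone_id, "-", nchar(x$aa_seq), "aa",
      if (!is.null(x$germline)) paste0("[", x$germline$v_gene, "]") else "[unannotated]",
      "\n")
  invisible(x)
}

#' Group identical sequences
#'
#' Partitions clone records into groups of identical sequences at the
#' nucleotide or protein level; the group count is the library's
#' unique-sequence census.
#'
#' @param records list of [nanobody_record()]s
#' @param level `"nt"` or `"aa"`
#' @return list with `n_groups`, `level` and `groups` (named list of clone
#'   id vectors, named after each group's first member)
#' @export
deduplicate <- function(records, level = c("aa", "nt")) {
  level <- match.arg(level)
  if (length(records) < 1) stop("need at least one record")
  keys <- vapply(records, function(r) if (level == "nt") r$nt_seq else r$aa_seq,
                 character(1))
  ids <- vapply(records, function(r) r$clone_id, character(1))
  groups <- split(ids, factor(keys, levels = unique(keys)))
  names(groups) <- vapply(groups, `[`, character(1), 1)
  list(n_groups = length(groups), level = level, groups = groups)
}

# scoring conventions shared by all alignments: match 1 / mismatch 0,
# affine gaps (open 10, extend 1); identity = matches / alignment columns
.nt_submat <- function() Biostrings::nucleotideSubstitutionMatrix(1, 0)

.aa_submat <- function() {
  letters <- c(Biostrings::AA_STANDARD, "X", "*")
  m <- matrix(0, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m
}

.aln_stats <- function(pa) {
  p <- as.character(Biostrings::alignedPattern(pa))
  s <- as.character(Biostrings::alignedSubject(pa))
  ncols <- nchar(p)
  indel_cols <- sum(strsplit(p, "")[[1]] == "-") + sum(strsplit(s, "")[[1]] == "-")
  list(p = p, s = s, ncols = ncols,
       nmatch = Biostrings::nmatch(pa), nmismatch = Biostrings::nmismatch(pa),
       indel_cols = indel_cols,
       identity = 100 * Biostrings::nmatch(pa) / ncols,
       subj_start = Biostrings::start(Biostrings::subject(pa)),
       subj_end = Biostrings::end(Biostrings::subject(pa)))
}

# map a 1-based position on the (ungapped) pattern to the corresponding
# 1-based subject position, walking the alignment columns
.map_pat_pos <- function(p_aligned, s_aligned, pat_pos, subj_start) {
  pc <- strsplit(p_aligned, "")[[1]]
  sc <- strsplit(s_aligned, "")[[1]]
  pi <- 0L; si <- subj_start - 1L
  for (i in seq_along(pc)) {
    if (sc[i] != "-") si <- si + 1L
    if (pc[i] != "-") {
      pi <- pi + 1L
      if (pi == pat_pos) return(si)
    }
  }
  si
}

# fast frame-0 translation via a plain codon-table lookup (ambiguous
# codons, e.g. containing N, give X); Biostrings::translate rebuilds its
# fuzzy genetic code on every call, which is far too slow for per-codon use
.translate_inframe <- function(nt) {
  n_codons <- nchar(nt) %/% 3
  if (n_codons == 0) return("")
  codons <- substring(nt, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Assign the germline origin of a clone and annotate its regions
#'
#' Aligns the clone's nucleotide sequence against every germline V and J
#' gene (and the intervening stretch against every D gene) and keeps the
#' highest-identity hit per segment class, mimicking unmutated-common-
#' ancestor mapping. Somatic mutations are counted on the V alignment:
#' `v_nt_mutations` is mismatches plus indel columns; `aa_changes` is the
#' number of residue differences in the codon-aligned V translation. FR/CDR
#' boundaries are transferred from the winning V gene's anchors (CDR3 end
#' from the winning J gene's FR4 anchor).
#'
#' @param record a [nanobody_record()]
#' @param germline_set a [germline_set()]
#' @param min_v_identity percent identity floor below which the record is
#'   unassignable
#' @param d_min_match minimum matched bases for a D call
#' @param d_min_identity percent identity floor for a D call
#' @return the record, with `$germline` (fields `v_gene`, `d_gene` possibly
#'   NA, `j_gene`, `v_identity`, `v_nt_mutations`, `aa_changes`) and
#'   `$regions` filled in
#' @export
assign_germline <- function(record, germline_set, min_v_identity = 60,
                            d_min_match = 7, d_min_identity = 80) {
  gs <- germline_set
  subj <- Biostrings::DNAString(record$nt_seq)
  mat <- .nt_submat()

  align_seg <- function(genes, subject) {
    best <- NULL
    for (g in sort(names(genes))) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(genes[[g]]), subject,
        type = "global-local", substitutionMatrix = mat,
        gapOpening = 10, gapExtension = 1)
      st <- .aln_stats(pa)
      if (is.null(best) || st$identity > best$identity + 1e-9) {
        best <- c(st, list(gene = g))
      }
    }
    best
  }

  v <- align_seg(gs$v, subj)
  if (v$identity < min_v_identity) {
    stop("unassignable: best V identity ", round(v$identity, 1),
         "% below floor for clone ", record$clone_id)
  }
  v_nt_mutations <- v$nmismatch + v$indel_cols

  # J search is restricted to the sequence after the V alignment
  j_region_start <- v$subj_end + 1L
  if (j_region_start > nchar(record$nt_seq) - 10L) {
    stop("unassignable: no sequence left for a J segment in clone ", record$clone_id)
  }
  jsub <- Biostrings::subseq(subj, j_region_start)
  jb <- align_seg(gs$j, jsub)
  j_start_nt <- j_region_start + jb$subj_start - 1L

  # D: local alignment within the V-J junction, with length/identity floors
  d_gene <- NA_character_
  if (length(gs$d) > 0) {
    junc_start <- v$subj_end + 1L
    junc_end <- j_start_nt - 1L
    if (junc_end - junc_start + 1 >= d_min_match) {
      junc <- Biostrings::subseq(subj, junc_start, junc_end)
      best_d <- NULL
      for (g in sort(names(gs$d))) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(gs$d[[g]]), junc, type = "local",
          substitutionMatrix = mat, gapOpening = 10, gapExtension = 1)
        st <- .aln_stats(pa)
        if (st$nmatch >= d_min_match && st$identity >= d_min_identity &&
            (is.null(best_d) || st$nmatch > best_d$nmatch)) {
          best_d <- c(st, list(gene = g))
        }
      }
      if (!is.null(best_d)) d_gene <- best_d$gene
    }
  }

  # amino-acid changes in the codon-aligned V translation
  germ_v_nt <- gs$v[[v$gene]]
  germ_v_aa <- .translate_inframe(germ_v_nt)
  off <- record$frame_offset
  codon_aligned <- v$indel_cols == 0 && (v$subj_start - 1 - off) %% 3 == 0
  if (codon_aligned) {
    rec_sub <- substr(record$nt_seq, v$subj_start, v$subj_end)
    rec_aa <- .translate_inframe(rec_sub)
    n <- min(nchar(rec_aa), nchar(germ_v_aa))
    aa_changes <- sum(strsplit(substr(rec_aa, 1, n), "")[[1]] !=
                        strsplit(substr(germ_v_aa, 1, n), "")[[1]])
  } else {
    # indels or frame-broken span: fall back to a protein-level alignment
    aa_lo <- max(0L, (v$subj_start - 1L - off) %/% 3L)
    aa_hi <- min(nchar(record$aa_seq), ceiling((v$subj_end - off) / 3))
    rec_aa <- substr(record$aa_seq, aa_lo + 1L, aa_hi)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(germ_v_aa), Biostrings::AAString(rec_aa),
      type = "global", substitutionMatrix = .aa_submat(),
      gapOpening = 10, gapExtension = 1)
    st <- .aln_stats(pa)
    aa_changes <- st$nmismatch + st$indel_cols
  }

  # transfer anchors: germline aa position -> germline nt -> record nt -> record aa
  anch <- gs$v_anchors[gs$v_anchors$gene == v$gene, ]
  v_anchor_to_rec_aa <- function(aa_pos0) {
    nt_pos <- 3L * aa_pos0 + 1L
    rec_nt <- .map_pat_pos(v$p, v$s, nt_pos, v$subj_start)
    as.integer((rec_nt - 1L - off) %/% 3L)
  }
  fr4_nt_in_j <- 3L * gs$j_fr4[[jb$gene]] + 1L
  fr4_rec_nt <- .map_pat_pos(jb$p, jb$s, fr4_nt_in_j, j_start_nt)
  fr4_aa <- as.integer((fr4_rec_nt - 1L - off) %/% 3L)

  b <- c(0L,
         v_anchor_to_rec_aa(anch$cdr1_start), v_anchor_to_rec_aa(anch$cdr1_end),
         v_anchor_to_rec_aa(anch$cdr2_start), v_anchor_to_rec_aa(anch$cdr2_end),
         v_anchor_to_rec_aa(anch$cdr3_start), fr4_aa, nchar(record$aa_seq))
  if (any(diff(b) <= 0)) {
    stop("region anchors map to a non-ascending layout for clone ", record$clone_id)
  }
  record$regions <- data.frame(
    region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
    start = b[1:7], end = b[2:8], stringsAsFactors = FALSE)

  record$germline <- list(
    v_gene = v$gene, d_gene = d_gene, j_gene = jb$gene,
    v_identity = v$identity, v_nt_mutations = as.integer(v_nt_mutations),
    aa_changes = as.integer(aa_changes))
  record
}

#' Count lysines inside and outside CDR3
#'
#' Chemical biotinylation with NHS esters targets lysine side chains;
#' candidates for labeling should have no lysine in the antigen-contacting
#' CDR3 loop and enough lysines elsewhere to label efficiently.
#'
#' @param record an annotated [nanobody_record()]
#' @return list with `cdr3_lysines` and `non_cdr3_lysines`
#' @export
count_lysines <- function(record) {
  if (is.null(record$regions)) stop("record has no region annotation")
  cdr3 <- record$regions[record$regions$region == "CDR3", ]
  if (nrow(cdr3) != 1) stop("missing CDR3 annotation")
  aa <- strsplit(record$aa_seq, "")[[1]]
  in_cdr3 <- seq_along(aa) > cdr3$start & seq_along(aa) <= cdr3$end
  list(cdr3_lysines = sum(aa[in_cdr3] == "K"),
       non_cdr3_lysines = sum(aa[!in_cdr3] == "K"))
}

#' Candidate-selection criteria for biotinylation
#'
#' @param max_cdr3_lysines maximum lysines tolerated inside CDR3
#' @param min_non_cdr3_lysines required lysines outside CDR3
#' @param comparator `"at_least"` (>= min) or `"strict_greater"` (> min).
#'   The default is `at_least`, matching the published selected set (one
#'   selected clone carries exactly 3 non-CDR3 lysines).
#' @return list of class `selection_criteria`
#' @export
selection_criteria <- function(max_cdr3_lysines = 0, min_non_cdr3_lysines = 3,
                               comparator = c("at_least", "strict_greater")) {
  comparator <- match.arg(comparator)
  stopifnot(max_cdr3_lysines >= 0, min_non_cdr3_lysines >= 0)
  structure(list(max_cdr3_lysines = max_cdr3_lysines,
                 min_non_cdr3_lysines = min_non_cdr3_lysines,
                 comparator = comparator),
            class = "selection_criteria")
}

#' Select biotinylation-suitable candidates
#'
#' @param records annotated records
#' @param criteria a [selection_criteria()]
#' @return the subset of records satisfying the criteria (deterministic,
#'   input order preserved)
#' @export
select_candidates <- function(records, criteria = selection_criteria()) {
  keep <- vapply(records, function(r) {
    lys <- count_lysines(r)
    ok_cdr3 <- lys$cdr3_lysines <= criteria$max_cdr3_lysines
    ok_out <- if (criteria$comparator == "at_least") {
      lys$non_cdr3_lysines >= criteria$min_non_cdr3_lysines
    } else {
      lys$non_cdr3_lysines > criteria$min_non_cdr3_lysines
    }
    ok_cdr3 && ok_out
  }, logical(1))
  records[keep]
}

#' Germline gene-usage table
#'
#' Tallies V, D and J gene usage across a repertoire. Percentages are per
#' segment class; the D denominator counts only records with an assigned D
#' (short or heavily mutated D segments are often unidentifiable).
#'
#' @param records annotated records
#' @return data.frame with columns `segment`, `gene`, `count`, `percent`
#'   (one decimal, half-up), sorted by descending count within class
#' @export
gene_usage <- function(records) {
  calls <- lapply(records, function(r) {
    if (is.null(r$germline)) stop("record ", r$clone_id, " has no germline call")
    r$germline
  })
  one_class <- function(seg, genes) {
    genes <- genes[!is.na(genes)]
    if (length(genes) == 0) return(NULL)
    tab <- sort(table(genes), decreasing = TRUE)
    data.frame(segment = seg, gene = names(tab), count = as.integer(tab),
               percent = round_half_up(100 * as.integer(tab) / length(genes), 1),
               stringsAsFactors = FALSE)
  }
  get_gene <- function(field) {
    vapply(calls, function(cl) as.character(cl[[field]]), character(1))
  }
  out <- rbind(
    one_class("V", get_gene("v_gene")),
    one_class("D", get_gene("d_gene")),
    one_class("J", get_gene("j_gene")))
  rownames(out) <- NULL
  out
}

#' Somatic-mutation summary
#'
#' @param records annotated records
#' @return data.frame with rows `v_nt_mutations` and `aa_changes` and
#'   columns `mean` (one decimal), `min`, `max`
#' @export
mutation_summary <- function(records) {
  if (length(records) == 0) stop("no records")
  nt <- vapply(records, function(r) r$germline$v_nt_mutations, integer(1))
  aa <- vapply(records, function(r) r$germline$aa_changes, integer(1))
  data.frame(
    metric = c("v_nt_mutations", "aa_changes"),
    mean = c(round_half_up(mean(nt), 1), round_half_up(mean(aa), 1)),
    min = c(min(nt), min(aa)), max = c(max(nt), max(aa)),
    stringsAsFactors = FALSE)
}

#' Pairwise percent-identity matrix
#'
#' Global pairwise alignment (match 1 / mismatch 0, affine gaps) of every
#' clone pair; identity is matches over alignment columns, in percent.
#'
#' @param records list of records (>= 2)
#' @param level `"aa"` (default, as for an MSA of protein sequences) or `"nt"`
#' @return symmetric numeric matrix, diagonal exactly 100, dimnames clone ids
#' @export
identity_matrix <- function(records, level = c("aa", "nt")) {
  level <- match.arg(level)
  if (length(records) < 2) stop("need >= 2 records")
  ids <- vapply(records, function(r) r$clone_id, character(1))
  seqs <- vapply(records, function(r) if (level == "aa") r$aa_seq else r$nt_seq,
                 character(1))
  mat <- if (level == "aa") .aa_submat() else .nt_submat()
  as_x <- if (level == "aa") Biostrings::AAString else Biostrings::DNAString
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      pa <- Biostrings::pairwiseAlignment(
        as_x(seqs[i]), as_x(seqs[k]), type = "global",
        substitutionMatrix = mat, gapOpening = 10, gapExtension = 1)
      st <- .aln_stats(pa)
      m[i, k] <- m[k, i] <- st$identity
    }
  }
  m
}

#' Neighbor-joining cladogram from an identity matrix
#'
#' Builds an unrooted tree from the distance 100 - identity by
#' neighbor-joining; tiny negative branch lengths produced by NJ are
#' clamped at zero.
#'
#' @param identity a matrix from [identity_matrix()], >= 3 clones
#' @return an [ape::nj()] `phylo` tree
#' @export
build_cladogram <- function(identity) {
  if (nrow(identity) < 3) stop("cladogram needs >= 3 clones")
  tree <- ape::nj(stats::as.dist(100 - identity))
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Repertoire census table
#'
#' One row per clone: germline call, mutation counts, lysine census and
#' selection flag — the table the campaign's candidate triage is read from.
#'
#' @param records annotated records
#' @param criteria a [selection_criteria()]
#' @return data.frame (clone, v_gene, d_gene, j_gene, v_identity,
#'   v_nt_mutations, aa_changes, cdr3_lysines, non_cdr3_lysines, selected)
#' @export
census_table <- function(records, criteria = selection_criteria()) {
  sel_ids <- vapply(select_candidates(records, criteria),
                    function(r) r$clone_id, character(1))
  rows <- lapply(records, function(r) {
    lys <- count_lysines(r)
    data.frame(clone = r$clone_id, v_gene = r$germline$v_gene,
               d_gene = r$germline$d_gene, j_gene = r$germline$j_gene,
               v_identity = round_half_up(r$germline$v_identity, 1),
               v_nt_mutations = r$germline$v_nt_mutations,
               aa_changes = r$germline$aa_changes,
               cdr3_lysines = lys$cdr3_lysines,
               non_cdr3_lysines = lys$non_cdr3_lysines,
               selected = r$clone_id %in% sel_ids,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
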