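#' Construct a germline V/D/J reference set
#'
#' A `germline_set` bundles named nucleotide sequences for the V, D and J
#' gene segments of a heavy-chain-only (VHH) locus together with
#' fixed-anchor coordinates that delimit the framework (FR) and
#' complementarity-determining (CDR) regions on each V gene's translation.
#' All coordinates are 0-based half-open on the amino-acid sequence, the
#' convention used throughout the package's sequence interfaces.
#'
#' @param v,d,j named character vectors of DNA sequences. V and J sequences
#'   must be in-frame (length a multiple of 3, stop-free); D segments are
#'   short junctional fragments.
#' @param v_anchors data.frame with columns `gene`, `cdr1_start`,
#'   `cdr1_end`, `cdr2_start`, `cdr2_end`, `cdr3_start`: amino-acid
#'   positions on the V translation delimiting CDR1, CDR2 and the start of
#'   CDR3 (0-based half-open).
#' @param j_fr4 named integer vector: for each J gene, the amino-acid
#'   position within the J translation where framework 4 begins (the
#'   W of the W-G-x-G motif).
#' @return an object of class `germline_set`
#' @export
germline_set <- function(v, d, j, v_anchors, j_fr4) {
  stopifnot(length(v) >= 1, length(j) >= 1)
  for (seg in list(v, d, j)) {
    if (anyDuplicated(names(seg))) stop("gene names must be unique within a segment class")
  }
  if (!all(names(v) %in% v_anchors$gene)) stop("every V gene needs an anchor row")
  if (!all(names(j) %in% names(j_fr4))) stop("every J gene needs an fr4 anchor")
  for (i in seq_len(nrow(v_anchors))) {
    a <- v_anchors[i, ]
    b <- c(a$cdr1_start, a$cdr1_end, a$cdr2_start, a$cdr2_end, a$cdr3_start)
    if (any(diff(b) <= 0) || b[1] <= 0) {
      stop("CDR anchors must be ascending and non-overlapping for gene ", a$gene)
    }
  }
  structure(list(v = v, d = d, j = j, v_anchors = v_anchors, j_fr4 = j_fr4),
            class = "germline_set")
}

#' @export
print.germline_set <- function(x, ...) {
  cat("germline_set:", length(x$v), "V,", length(x$d), "D,", length(x$j), "J genes\n")
  invisible(x)
}

# one fixed codon per amino acid, used to back-translate the synthetic
# germline proteins deterministically
.codon_table <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAG",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCG", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAT", V = "GTG"
)

back_translate <- function(aa) {
  paste(.codon_table[strsplit(aa, "")[[1]]], collapse = "")
}

#' Synthetic germline reference for tests and simulation
#'
#' A deterministic, fully synthetic stand-in for an alpaca heavy-chain
#' germline database: five V genes, five D genes and three J genes carrying
#' the gene names seen in camelid repertoires (IGHV3S66 etc.). The
#' sequences are invented VHH-like scaffolds (99-aa V with IMGT-like CDR
#' anchors at 25-33, 50-58 and CDR3 from 96), NOT real IMGT alleles; real
#' analyses should load a user-supplied reference with
#' [read_germline_set()].
#'
#' @return a [germline_set()]
#' @export
synthetic_germline_set <- function() {
  fr1  <- "QVQLVESGGGLVQAGGSLRLSCAAS"           # 25 aa
  fr2  <- "MGWFRQAPGKEREFVAA"                   # 17 aa
  fr3  <- "YYADSVKGRFTISRDNAKNTVYLQMNSLKPEDTAVYYC" # 38 aa
  mk_v <- function(cdr1, cdr2, cdr3h) paste0(fr1, cdr1, fr2, cdr2, fr3, cdr3h)
  v_aa <- c(
    IGHV3S66 = mk_v("GRTFSSYA", "ISWSGGST", "AAD"),
    IGHV3S53 = mk_v("GFTFSSYW", "ISTGGGST", "ARD"),
    IGHV3S65 = mk_v("GSIFSINA", "ITSGGSTN", "NAD"),
    IGHV3S1  = mk_v("GRTFSRYV", "ISWNDGRT", "AKD"),
    IGHV3S61 = mk_v("GLTFSNYD", "ISGSDGTT", "ATD")
  )
  d_aa <- c(IGHD1 = "GYSS", IGHD2 = "RLRY", IGHD3 = "DSGSY",
            IGHD5 = "GWEL", IGHD6 = "VLPA")
  j_aa <- c(IGHJ4 = "ADYWGQGTQVTVSS", IGHJ6 = "AEYWGQGTLVTVSS",
            IGHJ7 = "GNYWGKGTLVTVSS")
  v <- vapply(v_aa, back_translate, character(1))
  d <- vapply(d_aa, back_translate, character(1))
  j <- vapply(j_aa, back_translate, character(1))
  anchors <- data.frame(
    gene = names(v), cdr1_start = 25L, cdr1_end = 33L,
    cdr2_start = 50L, cdr2_end = 58L, cdr3_start = 96L,
    stringsAsFactors = FALSE
  )
  j_fr4 <- c(IGHJ4 = 3L, IGHJ6 = 3L, IGHJ7 = 3L)
  germline_set(v, d, j, anchors, j_fr4)
}

#' Write / read a germline set as FASTA plus anchor sidecar
#'
#' The FASTA holds every segment's nucleotide sequence; the sidecar TSV has
#' one row per gene with columns `gene`, `segment` (V/D/J) and the 0-based
#' half-open amino-acid anchors (`cdr1_start`..`cdr3_start` for V genes,
#' `fr4_start` for J genes; NA elsewhere).
#'
#' @param gs a [germline_set()]
#' @param fasta_path,anchors_path output (or input) file paths
#' @return `read_germline_set` returns a [germline_set()];
#'   `write_germline_set` returns the paths invisibly.
#' @export
write_germline_set <- function(gs, fasta_path, anchors_path) {
  seqs <- c(gs$v, gs$d, gs$j)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)
  rows <- rbind(
    data.frame(gene = names(gs$v), segment = "V",
               gs$v_anchors[match(names(gs$v), gs$v_anchors$gene), -1],
               fr4_start = NA_integer_),
    data.frame(gene = names(gs$d), segment = "D", cdr1_start = NA, cdr1_end = NA,
               cdr2_start = NA, cdr2_end = NA, cdr3_start = NA, fr4_start = NA),
    data.frame(gene = names(gs$j), segment = "J", cdr1_start = NA, cdr1_end = NA,
               cdr2_start = NA, cdr2_end = NA, cdr3_start = NA,
               fr4_start = gs$j_fr4[names(gs$j)])
  )
  utils::write.table(rows, anchors_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, anchors_path))
}

#' @rdname write_germline_set
#' @export
read_germline_set <- function(fasta_path, anchors_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  seqs <- stats::setNames(as.character(seqs), names(seqs))
  tab <- utils::read.delim(anchors_path, stringsAsFactors = FALSE)
  pick <- function(seg) seqs[tab$gene[tab$segment == seg]]
  v_anchors <- tab[tab$segment == "V",
                   c("gene", "cdr1_start", "cdr1_end", "cdr2_start",
                     "cdr2_end", "cdr3_start")]
  jrows <- tab[tab$segment == "J", ]
  germline_set(pick("V"), pick("D"), pick("J"), v_anchors,
               stats::setNames(as.integer(jrows$fr4_start), jrows$gene))
}
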