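#' Find candidate open reading frames in a transcript contig
#'
#' Scans all six frames for maximal Met-to-stop spans (one ORF per stop: from
#' the first Met after the previous in-frame stop). ORFs running off the
#' contig end without a stop are kept and flagged `partial3`. Coordinates are
#' 0-based half-open on the forward strand; the span includes the stop codon
#' when present. ORFs are retained when they cover at least `min_coverage`
#' of the contig, and returned sorted by protein length, longest first.
#'
#' @param contig a nucleotide string (A/C/G/T/N) or `DNAString`.
#' @param contig_id label carried into the output.
#' @param min_coverage minimum ORF-span / contig-length fraction, in (0, 1].
#' @return a data.frame with columns `orf_id`, `contig_id`, `strand`,
#'   `frame`, `start`, `end`, `protein`, `coverage`, `partial3`.
#' @export
find_orfs <- function(contig, contig_id = "contig", min_coverage = 0.20) {
  stopifnot(min_coverage > 0, min_coverage <= 1)
  if (is(contig, "DNAString")) contig <- as.character(contig)
  stopifnot(is.character(contig), length(contig) == 1, nchar(contig) >= 1)
  contig <- toupper(contig)
  L <- nchar(contig)
  gc <- Biostrings::GENETIC_CODE
  revcomp <- function(x) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }

  strand_v <- frame_v <- start_v <- end_v <- prot_v <- partial_v <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else revcomp(contig)
    for (frame in 0:2) {
      naa <- (L - frame) %/% 3
      if (naa < 1) next
      at <- frame + 1L + 3L * (seq_len(naa) - 1L)
      aa <- unname(gc[substring(s, at, at + 2L)])
      aa[is.na(aa)] <- "X"                       # fuzzy codons (N)
      stops <- which(aa == "*")
      mets <- which(aa == "M")
      if (!length(mets)) next
      # maximal ORF per stop: first Met after the previous in-frame stop
      grp <- findInterval(mets, stops) + 1L      # index of following stop
      first_met <- vapply(split(mets, grp), min, 1L)
      grp_id <- as.integer(names(first_met))
      for (k in seq_along(first_met)) {
        m <- first_met[k]
        has_stop <- grp_id[k] <= length(stops)
        b <- if (has_stop) stops[grp_id[k]] else naa + 1L
        aa_end <- if (has_stop) b else b - 1L    # include stop codon
        if (aa_end < m) next
        nt_start <- frame + 3L * (m - 1L)        # 0-based on this strand
        nt_end <- frame + 3L * aa_end
        if (strand == "-") {
          tmp <- L - nt_end
          nt_end <- L - nt_start
          nt_start <- tmp
        }
        strand_v <- c(strand_v, strand); frame_v <- c(frame_v, frame)
        start_v <- c(start_v, nt_start); end_v <- c(end_v, nt_end)
        prot_v <- c(prot_v, paste(aa[m:(b - 1L)], collapse = ""))
        partial_v <- c(partial_v, !has_stop)
      }
    }
  }
  out <- data.frame(
    contig_id = rep(contig_id, length(strand_v)),
    strand = as.character(strand_v), frame = as.integer(frame_v),
    start = as.integer(start_v), end = as.integer(end_v),
    protein = as.character(prot_v),
    coverage = if (length(start_v)) (end_v - start_v) / L else numeric(),
    partial3 = as.logical(partial_v), stringsAsFactors = FALSE)
  out <- out[out$coverage >= min_coverage, , drop = FALSE]
  if (nrow(out)) {
    out <- out[order(-nchar(out$protein), out$strand, out$start), , drop = FALSE]
    out$orf_id <- sprintf("%s_orf%02d", contig_id, seq_len(nrow(out)))
    rownames(out) <- NULL
    out <- out[, c("orf_id", "contig_id", "strand", "frame", "start", "end",
                   "protein", "coverage", "partial3")]
  } else {
    out$orf_id <- character()
    out <- out[, c("orf_id", "contig_id", "strand", "frame", "start", "end",
                   "protein", "coverage", "partial3")]
  }
  out
}

#' Find ORFs across a set of contigs
#'
#' @param contigs a named character vector or `DNAStringSet`.
#' @inheritParams find_orfs
#' @return row-bound [find_orfs()] output for every contig.
#' @export
find_orfs_set <- function(contigs, min_coverage = 0.20) {
  if (is(contigs, "DNAStringSet")) {
    contigs <- setNames(as.character(contigs), names(contigs))
  }
  if (is.null(names(contigs))) {
    names(contigs) <- sprintf("contig%04d", seq_along(contigs))
  }
  do.call(rbind, lapply(names(contigs), function(nm) {
    find_orfs(contigs[[nm]], contig_id = nm, min_coverage = min_coverage)
  }))
}

#' Retain ORFs homologous to reference C1 peptidases
#'
#' Smith-Waterman local alignment (BLOSUM62, gap open 11 / extend 1) of each
#' predicted protein against a reference protein set. An ORF is retained when
#' its best hit reaches `min_identity` over at least `min_aln_len` aligned
#' residue pairs, or over at least half the shorter sequence when that
#' sequence is shorter than `min_aln_len`. Identity is matches over aligned
#' residue pairs (gap columns excluded).
#'
#' @param orfs data.frame from [find_orfs_set()] (needs `orf_id`, `protein`).
#' @param references named character vector or `AAStringSet` of reference
#'   proteins, e.g. `vapply(reference_panel(), function(e) e$mature, "")`.
#' @param min_identity minimum identity of the best local alignment.
#' @param min_aln_len minimum aligned residues for full-length sequences.
#' @return `orfs` with columns `best_hit`, `hit_identity`, `hit_aln_len`,
#'   `retained`, filtered to retained rows.
#' @export
homology_filter <- function(orfs, references, min_identity = 0.30,
                            min_aln_len = 100L) {
  if (is(references, "AAStringSet")) {
    references <- setNames(as.character(references), names(references))
  }
  stopifnot(length(references) > 0, !is.null(names(references)))
  out <- orfs
  out$best_hit <- NA_character_
  out$hit_identity <- NA_real_
  out$hit_aln_len <- NA_integer_
  out$retained <- FALSE
  if (nrow(out) == 0) return(out)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  # score every ORF against every reference in one vectorized pass, then
  # compute the full alignment only against each ORF's best reference
  scores <- vapply(names(references), function(rn) {
    Biostrings::pairwiseAlignment(
      out$protein, references[[rn]], type = "local",
      substitutionMatrix = B62, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
  }, numeric(nrow(out)))
  scores <- matrix(scores, nrow = nrow(out),
                   dimnames = list(NULL, names(references)))
  best_ref <- names(references)[max.col(scores, ties.method = "first")]
  for (rn in unique(best_ref)) {
    idx <- which(best_ref == rn)
    aln <- Biostrings::pairwiseAlignment(
      out$protein[idx], references[[rn]], type = "local",
      substitutionMatrix = B62, gapOpening = 11, gapExtension = 1)
    nm <- Biostrings::nmatch(aln)
    nmm <- Biostrings::nmismatch(aln)
    pairs <- nm + nmm
    ident <- ifelse(pairs > 0, nm / pairs, 0)
    short <- pmin(nchar(out$protein[idx]), nchar(references[[rn]]))
    need <- ifelse(short < min_aln_len, ceiling(0.5 * short), min_aln_len)
    out$best_hit[idx] <- rn
    out$hit_identity[idx] <- ident
    out$hit_aln_len[idx] <- pairs
    out$retained[idx] <- ident >= min_identity & pairs >= need
  }
  out[out$retained, , drop = FALSE]
}
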