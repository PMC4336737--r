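#' Assign contigs to peptidase mRNAs for expression counting
#'
#' A contig is assigned to a peptidase when its alignment identity to the
#' consensus mRNA is at least `min_identity` (default 97%). Full-length
#' alignments contribute with weight 1; a partially aligned contig
#' contributes proportionally to its aligned fraction when that fraction
#' exceeds 50% of the contig length, and not at all otherwise. A contig may
#' be assigned to several peptidases (multi-assignment is preserved).
#'
#' @param alignments data.frame with columns `contig_id`, `peptidase_id`,
#'   `identity` and `aligned_fraction` (both in `[0,1]`).
#' @param min_identity identity threshold (default 0.97).
#' @param full_fraction aligned fraction at or above which a contig counts
#'   as full-length (default 0.99).
#' @return the assigned rows with a `contribution_weight` column.
#' @export
assign_contigs <- function(alignments, min_identity = 0.97,
                           full_fraction = 0.99) {
  need <- c("contig_id", "peptidase_id", "identity", "aligned_fraction")
  stopifnot(all(need %in% names(alignments)))
  if (any(alignments$identity < 0 | alignments$identity > 1,
          alignments$aligned_fraction < 0 | alignments$aligned_fraction > 1)) {
    stop("identity and aligned_fraction must lie in [0, 1]")
  }
  out <- alignments[alignments$identity >= min_identity, , drop = FALSE]
  out$contribution_weight <- ifelse(
    out$aligned_fraction >= full_fraction, 1,
    ifelse(out$aligned_fraction > 0.5, out$aligned_fraction, 0))
  out <- out[out$contribution_weight > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param read_count reads attributed to the transcript (may be fractional).
#' @param transcript_length_nt transcript length in nucleotides (> 0).
#' @param total_mapped_reads total mapped reads in the library (> 0).
#' @return RPKM value(s): `read_count / (length/1e3) / (total/1e6)`.
#' @export
rpkm <- function(read_count, transcript_length_nt, total_mapped_reads) {
  if (any(transcript_length_nt <= 0)) stop("transcript length must be > 0")
  if (any(total_mapped_reads <= 0)) stop("total mapped reads must be > 0")
  read_count / (transcript_length_nt / 1e3) / (total_mapped_reads / 1e6)
}

# per-contig read counts; multiread policy "per_site_full" counts a read as
# one full unit at every contig it maps to (the estimator traditionally criticised as
# inflated), "once_best" counts it once, at its alphabetically first contig
contig_counts_naive <- function(read_aln,
                                multiread = c("per_site_full", "once_best")) {
  multiread <- match.arg(multiread)
  read_aln <- unique(read_aln[, c("read_id", "contig_id")])
  if (multiread == "once_best" && nrow(read_aln)) {
    read_aln <- read_aln[order(read_aln$read_id, read_aln$contig_id), ]
    read_aln <- read_aln[!duplicated(read_aln$read_id), , drop = FALSE]
  }
  tab <- table(read_aln$contig_id)
  setNames(as.numeric(tab), names(tab))
}

# fractional per-contig counts under the rescue rule: unique reads first,
# then each multiread split across its contigs proportionally to the
# unique-read expression density (unique count / contig length); equal split
# when every candidate density is zero
contig_counts_rescue <- function(read_aln, contig_lengths, iterations = 1L) {
  read_aln <- unique(read_aln[, c("read_id", "contig_id")])
  per_read <- split(read_aln$contig_id, read_aln$read_id)
  uniq <- per_read[lengths(per_read) == 1L]
  multi <- per_read[lengths(per_read) > 1L]
  counts <- setNames(rep(0, length(contig_lengths)), names(contig_lengths))
  ut <- table(unlist(uniq))
  counts[names(ut)] <- as.numeric(ut)
  dens <- counts / contig_lengths
  for (it in seq_len(max(1L, iterations))) {
    alloc <- setNames(rep(0, length(contig_lengths)), names(contig_lengths))
    alloc[names(ut)] <- as.numeric(ut)
    for (cs in multi) {
      d <- dens[cs]
      f <- if (sum(d) > 0) d / sum(d) else rep(1 / length(cs), length(cs))
      alloc[cs] <- alloc[cs] + f
    }
    dens <- alloc / contig_lengths
    counts <- alloc
  }
  counts
}

#' Per-peptidase read counts, multiread counted as one unit at each site
#'
#' Each read contributes one full unit to every contig it maps to; contig
#' counts roll up to peptidases through the contig assignment weights. This
#' is the naive estimator; it inflates paralog expression when multireads
#' are present.
#'
#' @param read_aln data.frame `read_id`, `contig_id` (one row per mapping).
#' @param assignments [assign_contigs()] output.
#' @param multiread `"per_site_full"` (default) or `"once_best"`.
#' @return named numeric vector of per-peptidase counts.
#' @export
count_naive <- function(read_aln, assignments,
                        multiread = c("per_site_full", "once_best")) {
  cc <- contig_counts_naive(read_aln, match.arg(multiread))
  rollup_counts(cc, assignments)
}

#' Per-peptidase read counts under the rescue rule
#'
#' Unique reads are counted per contig; each multiread is then split across
#' its contigs proportionally to the unique-read expression density
#' (unique count / contig length), or equally when all densities are zero.
#' Every multiread contributes exactly one unit in total. Contig counts roll
#' up to peptidases through the assignment weights.
#'
#' @inheritParams count_naive
#' @param contig_lengths named contig lengths (nt) for the density term.
#' @param iterations re-estimation passes for the allocation densities
#'   (default 1, the one-pass allocation).
#' @return named numeric vector of per-peptidase counts.
#' @export
count_rescue <- function(read_aln, assignments, contig_lengths,
                         iterations = 1L) {
  stopifnot(!is.null(names(contig_lengths)))
  missing <- setdiff(unique(read_aln$contig_id), names(contig_lengths))
  if (length(missing)) stop("no length for contig(s): ",
                            paste(missing, collapse = ", "))
  cc <- contig_counts_rescue(read_aln, contig_lengths, iterations)
  rollup_counts(cc, assignments)
}

rollup_counts <- function(contig_counts, assignments) {
  peps <- sort(unique(assignments$peptidase_id))
  out <- setNames(rep(0, length(peps)), peps)
  for (i in seq_len(nrow(assignments))) {
    cid <- assignments$contig_id[i]
    if (cid %in% names(contig_counts)) {
      out[assignments$peptidase_id[i]] <- out[assignments$peptidase_id[i]] +
        assignments$contribution_weight[i] * contig_counts[[cid]]
    }
  }
  out
}

#' Fill relative expression percentages
#'
#' Per estimator, each peptidase's RPKM divided by the summed RPKM of all
#' peptidases, times 100.
#'
#' @param records expression data.frame with `rpkm_naive` and/or
#'   `rpkm_rescue` columns.
#' @return `records` with `relative_pct_naive` / `relative_pct_rescue` added.
#' @export
relative_expression <- function(records) {
  for (est in c("naive", "rescue")) {
    col <- paste0("rpkm_", est)
    if (col %in% names(records)) {
      tot <- sum(records[[col]])
      if (tot <= 0) stop("all ", col, " values are zero")
      records[[paste0("relative_pct_", est)]] <- records[[col]] / tot * 100
    }
  }
  records
}

#' Quantify per-peptidase expression with both estimators
#'
#' @inheritParams count_rescue
#' @param peptidase_lengths named consensus mRNA lengths (nt).
#' @param total_mapped_reads library size used in the RPKM denominator;
#'   default is the number of distinct mapped reads in `read_aln`.
#' @return data.frame (class `papcat_expression`) with per-peptidase raw and
#'   rescue counts, RPKM values and relative percentages.
#' @export
quantify_expression <- function(read_aln, assignments, contig_lengths,
                                peptidase_lengths,
                                total_mapped_reads = NULL) {
  if (is.null(total_mapped_reads)) {
    total_mapped_reads <- length(unique(read_aln$read_id))
  }
  cn <- count_naive(read_aln, assignments)
  cr <- count_rescue(read_aln, assignments, contig_lengths)
  peps <- names(cn)
  stopifnot(all(peps %in% names(peptidase_lengths)))
  rec <- data.frame(
    peptidase_id = peps,
    count_naive = as.numeric(cn), count_rescue = as.numeric(cr[peps]),
    rpkm_naive = rpkm(as.numeric(cn), peptidase_lengths[peps],
                      total_mapped_reads),
    rpkm_rescue = rpkm(as.numeric(cr[peps]), peptidase_lengths[peps],
                       total_mapped_reads),
    stringsAsFactors = FALSE)
  rec <- relative_expression(rec)
  class(rec) <- c("papcat_expression", "data.frame")
  rec
}

#' Map reads to contigs by exact substring match
#'
#' A minimal built-in mapper for synthetic data: a read maps to every contig
#' containing it as an exact substring on either strand. Reads must share a
#' common length. Real read mapping is out of scope; alignment tables from an
#' external mapper can be supplied wherever this function's output is used.
#'
#' @param reads named character vector or `DNAStringSet` of reads.
#' @param contigs named character vector or `DNAStringSet` of contigs.
#' @return data.frame `read_id`, `contig_id`, one row per mapping.
#' @export
map_reads_exact <- function(reads, contigs) {
  if (!is(reads, "DNAStringSet")) reads <- Biostrings::DNAStringSet(reads)
  if (!is(contigs, "DNAStringSet")) contigs <- Biostrings::DNAStringSet(contigs)
  if (length(reads) == 0) {
    return(data.frame(read_id = character(), contig_id = character(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(!is.null(names(reads)), !is.null(names(contigs)))
  hits <- list()
  for (rs in list(reads, Biostrings::reverseComplement(reads))) {
    pd <- Biostrings::PDict(rs)
    m <- Biostrings::vwhichPDict(pd, contigs)
    for (ci in seq_along(contigs)) {
      if (length(m[[ci]])) {
        hits[[length(hits) + 1L]] <- data.frame(
          read_id = names(reads)[m[[ci]]],
          contig_id = names(contigs)[ci], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(read_id = character(), contig_id = character(),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, hits))
}
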