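#' Collapse redundant ORFs into unique peptidases
#'
#' Two proteins refer to the same peptidase when their Wagner-Fischer global
#' alignment reaches `min_identity` over the overlap columns and the overlap
#' spans at least `min_overlap` residues. Clusters are the single-linkage
#' transitive closure of that relation, so partial fragments of one gene
#' chain together through shared overlaps. The partition is independent of
#' input order: clusters are reported sorted by their lexicographically
#' smallest member.
#'
#' @param proteins named character vector of ORF protein sequences.
#' @param min_identity identity threshold over overlap columns (default 0.95).
#' @param min_overlap minimum overlap columns (default 10 residues).
#' @return object of class `papcat_clusters`: list with `membership`
#'   (data.frame `orf_id`, `peptidase_id`) and `clusters` (named list of
#'   member id vectors).
#' @export
cluster_orfs <- function(proteins, min_identity = 0.95, min_overlap = 10L) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  n <- length(proteins)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    pw <- .wf_pairs_cpp(unname(proteins), 0L, 1L, 1L)
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        if (pw$identity[i, j] >= min_identity && pw$overlap[i, j] >= min_overlap) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  groups <- split(names(proteins), root)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, "", 1))]
  ids <- sprintf("pep%03d", seq_along(groups))
  names(groups) <- ids
  membership <- data.frame(
    orf_id = unlist(groups, use.names = FALSE),
    peptidase_id = rep(ids, lengths(groups)),
    stringsAsFactors = FALSE)
  structure(list(membership = membership, clusters = groups),
            class = "papcat_clusters")
}

#' @export
print.papcat_clusters <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat("Redundancy clustering:", nrow(x$membership), "ORFs in",
      length(x$clusters), "unique peptidases\n")
  cat("  cluster sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

# majority residue per column (gaps ignored; "-" for all-gap columns);
# unanimous gap-free columns take a vectorized fast path
msa_majority <- function(aln) {
  cons <- aln[1, ]
  easy <- !colSums(aln != rep(aln[1, ], each = nrow(aln)))
  easy <- easy & aln[1, ] != "-"
  for (col in which(!easy)) {
    obs <- aln[, col]
    obs <- obs[obs != "-"]
    if (!length(obs)) { cons[col] <- "-"; next }
    r <- rle(sort(obs))
    cons[col] <- r$values[which.max(r$lengths)]
  }
  cons
}

# Progressive multiple alignment over the Wagner-Fischer core. Sequences are
# added in descending length order (the longest member anchors coordinates);
# each new sequence is aligned against the running majority consensus and the
# existing rows are padded at insertion columns.
progressive_msa <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  aln <- matrix(strsplit(seqs[[1]], "")[[1]], nrow = 1)
  rownames(aln) <- names(seqs)[1]
  if (length(seqs) > 1) {
    for (k in 2:length(seqs)) {
      cons <- msa_majority(aln)
      r <- .wf_align_cpp(paste(cons, collapse = ""), seqs[[k]], 0L, 1L, 1L)
      ac <- strsplit(r$aligned_a, "")[[1]]  # consensus with insertions
      as_ <- strsplit(r$aligned_b, "")[[1]]
      newaln <- matrix("-", nrow = nrow(aln) + 1, ncol = length(ac))
      rownames(newaln) <- c(rownames(aln), names(seqs)[k])
      ci <- 0L
      for (col in seq_along(ac)) {
        if (ac[col] != "-") {
          ci <- ci + 1L
          newaln[seq_len(nrow(aln)), col] <- aln[, ci]
        }
        newaln[nrow(newaln), col] <- as_[col]
      }
      aln <- newaln
    }
  }
  aln
}

#' Build the consensus sequence of a redundancy cluster
#'
#' Members are multiple-aligned progressively (longest first) over the
#' Wagner-Fischer core. Per column, the consensus residue is the most
#' frequent residue among non-gap observations when its frequency exceeds
#' 50% of them; otherwise the column is flagged as an unresolved SNP and
#' written as `X`. Every polymorphic column is recorded in the SNP table.
#'
#' @param members named character vector of member sequences (protein or
#'   nucleotide).
#' @param ambiguity character emitted for unresolved columns (default "X";
#'   use "N" for nucleotide consensus).
#' @return list with `consensus` (string), `snps` (data.frame `column`,
#'   `residues` ("A:3,V:1"), `chosen`, `resolved`), and `alignment` (the
#'   character matrix).
#' @export
build_consensus <- function(members, ambiguity = "X") {
  stopifnot(length(members) >= 1)
  if (is.null(names(members))) names(members) <- sprintf("m%02d", seq_along(members))
  aln <- progressive_msa(members)
  cons <- character(ncol(aln))
  snp <- list()
  unanimous <- !colSums(aln != rep(aln[1, ], each = nrow(aln)))
  unanimous <- unanimous & aln[1, ] != "-"
  cons[unanimous] <- aln[1, unanimous]
  for (col in which(!unanimous)) {
    obs <- aln[, col]
    obs <- obs[obs != "-"]
    r <- rle(sort(obs))
    ord <- order(r$lengths, decreasing = TRUE)
    vals <- r$values[ord]; cnts <- r$lengths[ord]
    if (length(vals) == 1) {
      cons[col] <- vals[1]
      next
    }
    resolved <- cnts[1] > 0.5 * sum(cnts) && sum(cnts == cnts[1]) == 1
    cons[col] <- if (resolved) vals[1] else ambiguity
    snp[[length(snp) + 1L]] <- data.frame(
      column = col,
      residues = paste(sprintf("%s:%d", vals, cnts), collapse = ","),
      chosen = cons[col], resolved = resolved, stringsAsFactors = FALSE)
  }
  snps <- if (length(snp)) do.call(rbind, snp) else
    data.frame(column = integer(), residues = character(),
               chosen = character(), resolved = logical(),
               stringsAsFactors = FALSE)
  list(consensus = paste(cons, collapse = ""), snps = snps, alignment = aln)
}

#' Map the mature-enzyme start of a consensus protein by homology
#'
#' Globally aligns the consensus against the mature human cathepsin L and
#' cathepsin B references (the better-scoring one is used) and returns the
#' 1-based consensus position aligned to the reference mature N-terminus, or
#' `NA` when that column is a gap in the consensus.
#'
#' @param protein consensus protein string.
#' @param panel reference panel from [reference_panel()].
#' @return 1-based integer position, or `NA_integer_` if unresolved.
#' @export
map_mature_start <- function(protein, panel = reference_panel()) {
  stopifnot(is.character(protein), length(protein) == 1, nchar(protein) > 0)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  refs <- list(L = ref_by_family(panel, "L"), B = ref_by_family(panel, "B"))
  best <- NULL
  for (r in refs) {
    aln <- Biostrings::pairwiseAlignment(
      protein, r$mature, type = "global", substitutionMatrix = B62,
      gapOpening = 10, gapExtension = 2)
    if (is.null(best) || Biostrings::score(aln) > best$score) {
      best <- list(score = Biostrings::score(aln), aln = aln)
    }
  }
  qa <- strsplit(as.character(Biostrings::alignedPattern(best$aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(best$aln)), "")[[1]]
  qpos <- 0L
  for (col in seq_along(qa)) {
    if (qa[col] != "-") qpos <- qpos + 1L
    if (sa[col] != "-") {               # reference mature position 1
      return(if (qa[col] == "-") NA_integer_ else qpos)
    }
  }
  NA_integer_
}

#' Assemble unique peptidases from retained ORFs
#'
#' Runs [cluster_orfs()], then per cluster builds the protein consensus (and
#' the nucleotide consensus of the ORF spans when contig sequences are
#' supplied) and maps the mature start by homology.
#'
#' @param orfs retained ORF data.frame ([homology_filter()] output).
#' @param contigs optional named contig sequences for nucleotide consensus.
#' @param panel reference panel.
#' @inheritParams cluster_orfs
#' @return list of `unique_peptidase` objects: `peptidase_id`, `members`,
#'   `consensus_protein`, `consensus_mrna` (or NA), `snps`, `mature_start`.
#' @export
unique_peptidases <- function(orfs, contigs = NULL, panel = reference_panel(),
                              min_identity = 0.95, min_overlap = 10L) {
  prot <- setNames(orfs$protein, orfs$orf_id)
  cl <- cluster_orfs(prot, min_identity = min_identity,
                     min_overlap = min_overlap)
  if (!is.null(contigs) && is(contigs, "DNAStringSet")) {
    contigs <- setNames(as.character(contigs), names(contigs))
  }
  lapply(names(cl$clusters), function(pid) {
    members <- cl$clusters[[pid]]
    cp <- build_consensus(prot[members], ambiguity = "X")
    cmrna <- NA_character_
    if (!is.null(contigs)) {
      idx <- match(members, orfs$orf_id)
      nt <- vapply(idx, function(i) {
        s <- substring(contigs[[orfs$contig_id[i]]],
                       orfs$start[i] + 1L, orfs$end[i])
        if (orfs$strand[i] == "-") {
          s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
        }
        s
      }, "")
      names(nt) <- members
      cmrna <- build_consensus(nt, ambiguity = "N")$consensus
    }
    structure(list(
      peptidase_id = pid, members = members,
      consensus_protein = cp$consensus, consensus_mrna = cmrna,
      snps = cp$snps,
      mature_start = map_mature_start(cp$consensus, panel)
    ), class = "unique_peptidase")
  })
}

#' @export
print.unique_peptidase <- function(x, ...) {
  cat(sprintf("Unique peptidase %s: %d member(s), consensus %d aa, %d SNP column(s), mature start %s\n",
              x$peptidase_id, length(x$members), nchar(x$consensus_protein),
              nrow(x$snps), ifelse(is.na(x$mature_start), "unknown",
                                   x$mature_start)))
  invisible(x)
}
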