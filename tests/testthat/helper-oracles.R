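# Independent oracles used to validate the implementation on small inputs.
# These deliberately use naive algorithms (exhaustive recursion, brute-force
# enumeration) and never share code with the package internals they check.

# exhaustive-recursion edit distance (memoised), for strings up to ~12 chars
oracle_edit_distance <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == 0) j else if (j == 0) i else {
      min(rec(i - 1, j - 1) + (substring(a, i, i) != substring(b, j, j)),
          rec(i - 1, j) + 1,
          rec(i, j - 1) + 1)
    }
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

# brute-force ORF scanner: every ATG in every frame/strand, extended to the
# first in-frame stop (or contig end); nested same-stop ORFs reduced to the
# maximal (first-Met) one; coverage filter applied at the end
oracle_orfs <- function(contig, min_coverage = 0.2) {
  revcomp <- function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  L <- nchar(contig)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(contig) else revcomp(toupper(contig))
    codons <- function(from) {
      n <- (L - from + 1) %/% 3
      if (n < 1) return(character())
      vapply(seq_len(n), function(k) substring(s, from + 3 * (k - 1),
                                               from + 3 * k - 1), "")
    }
    gc <- Biostrings::GENETIC_CODE
    for (start in seq_len(L)) {
      if (substring(s, start, start + 2) != "ATG") next
      cs <- codons(start)
      aa <- ifelse(is.na(gc[cs]), "X", gc[cs])
      stop_at <- which(aa == "*")
      if (length(stop_at)) {
        span_end <- start + 3 * stop_at[1] - 1
        prot <- paste(aa[seq_len(stop_at[1] - 1)], collapse = "")
        partial <- FALSE
      } else {
        span_end <- start + 3 * length(aa) - 1
        prot <- paste(aa, collapse = "")
        partial <- TRUE
      }
      if (nchar(prot) == 0) next
      a <- start - 1L; b <- span_end        # 0-based half-open on strand
      if (strand == "-") { tmp <- L - b; b <- L - a; a <- tmp }
      out[[length(out) + 1L]] <- data.frame(
        strand = strand, start = a, end = b, protein = prot,
        coverage = (b - a) / L, partial3 = partial,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(strand = character(), start = integer(),
                      end = integer(), protein = character(),
                      coverage = numeric(), partial3 = logical()))
  }
  df <- do.call(rbind, out)
  # keep the maximal ORF per (strand, stop end): the longest protein
  key <- paste(df$strand, ifelse(df$strand == "+", df$end, df$start))
  df <- df[order(key, -nchar(df$protein)), ]
  df <- df[!duplicated(paste(df$strand, ifelse(df$strand == "+", df$end,
                                               df$start))), ]
  df <- df[df$coverage >= min_coverage, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# brute-force all-pairs + union-find clustering oracle
oracle_cluster <- function(proteins, min_identity = 0.95, min_overlap = 10) {
  n <- length(proteins)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        a <- wagner_fischer_align(proteins[[i]], proteins[[j]])
        if (a$identity >= min_identity && a$overlap_len >= min_overlap) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  # canonical partition signature: sorted member-name groups
  sig <- lapply(split(names(proteins), root), sort)
  unname(sig[order(vapply(sig, `[`, "", 1))])
}

# least-squares fit of an additive 5-taxon matrix to each of the 15 unrooted
# topologies, used as the exhaustive NJ oracle
oracle_best_topology <- function(d) {
  taxa <- rownames(d)
  stopifnot(length(taxa) == 5)
  splits <- list()
  # every unrooted 5-taxon topology is determined by its two non-trivial
  # bipartitions {2|3}; enumerate all pairs of compatible 2-vs-3 splits
  pairs2 <- combn(taxa, 2, simplify = FALSE)
  topos <- list()
  for (i in seq_along(pairs2)) {
    for (j in seq_along(pairs2)) {
      if (i >= j) next
      a <- pairs2[[i]]; b <- pairs2[[j]]
      if (length(intersect(a, b)) == 0) {
        topos[[length(topos) + 1L]] <- list(a, b)
      }
    }
  }
  best <- NULL
  for (tp in topos) {
    nwk <- sprintf("((%s,%s),(%s,%s),%s);", tp[[1]][1], tp[[1]][2],
                   tp[[2]][1], tp[[2]][2], setdiff(taxa, c(tp[[1]], tp[[2]])))
    tr <- ape::read.tree(text = nwk)
    fit <- try(phangorn::nnls.tree(as.dist(d), tr, method = "unrooted"),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    dd <- as.matrix(ape::cophenetic.phylo(fit))[taxa, taxa]
    rss <- sum((dd - d)^2)
    if (is.null(best) || rss < best$rss) best <- list(tree = tr, rss = rss)
  }
  best$tree
}

# random additive distance matrix from a random 5-taxon tree; returns both
random_additive_5taxa <- function() {
  tr <- ape::rtree(5, tip.label = paste0("t", 1:5))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  d <- as.matrix(ape::cophenetic.phylo(tr))
  d <- d[paste0("t", 1:5), paste0("t", 1:5)]
  list(tree = ape::unroot(tr), d = d)
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1] == 0
}
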