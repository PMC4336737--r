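# Distance trees and clade-rule orthology calls. Neighbor-joining, rooting
# and bipartition counting are delegated to ape; the distance definitions,
# the seeded column-resampling bootstrap and the cherry-first orthology
# rules are implemented here.

#' Pairwise distance matrix from aligned proteins
#'
#' Distance is the fraction of differing columns among columns where both
#' sequences carry a residue (p-distance), optionally transformed by the
#' Dayhoff/PAM correction `d = -ln(1 - p - 0.2 p^2)`.
#'
#' @param aln named character vector of aligned (equal-length) sequences, or
#'   a character matrix with one row per taxon.
#' @param correction `"none"` (p-distance) or `"dayhoff"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(aln, correction = c("none", "dayhoff")) {
  correction <- match.arg(correction)
  m <- as_aln_matrix(aln)
  pc <- pairwise_column_stats(m)
  n <- nrow(m)
  shared <- pc$shared; diff <- pc$diff
  sh <- rowSums(shared); df <- rowSums(diff)
  if (any(sh == 0)) stop("taxon pair with zero shared non-gap columns")
  p <- df / sh
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  k <- 1L
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d[i, j] <- d[j, i] <- p[k]
      k <- k + 1L
    }
  }
  if (correction == "dayhoff") {
    arg <- 1 - d - 0.2 * d^2
    if (any(arg <= 0)) stop("Dayhoff correction undefined for a distance this large")
    d[] <- -log(arg)
    diag(d) <- 0
  }
  d
}

as_aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  stopifnot(is.character(aln), !is.null(names(aln)))
  L <- unique(nchar(aln))
  if (length(L) != 1) stop("aligned sequences must share one length")
  m <- do.call(rbind, strsplit(aln, ""))
  rownames(m) <- names(aln)
  m
}

# per-pair, per-column shared/differing indicator matrices (rows = pairs in
# combn order), reused across bootstrap replicates
pairwise_column_stats <- function(m) {
  n <- nrow(m); L <- ncol(m)
  np <- n * (n - 1) / 2
  shared <- matrix(FALSE, np, L)
  diff <- matrix(FALSE, np, L)
  gap <- m == "-" | m == "X"
  k <- 1L
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      s <- !gap[i, ] & !gap[j, ]
      shared[k, ] <- s
      diff[k, ] <- s & (m[i, ] != m[j, ])
      k <- k + 1L
    }
  }
  list(shared = shared, diff = diff)
}

dist_from_stats <- function(pc, cols, taxa, correction = "none") {
  sh <- rowSums(pc$shared[, cols, drop = FALSE])
  df <- rowSums(pc$diff[, cols, drop = FALSE])
  p <- ifelse(sh > 0, df / sh, 0)
  if (correction == "dayhoff") {
    arg <- pmax(1 - p - 0.2 * p^2, 1e-6)
    p <- -log(arg)
  }
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  k <- 1L
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d[i, j] <- d[j, i] <- p[k]; k <- k + 1L
    }
  }
  d
}

#' Neighbor-joining tree, optionally rooted on an outgroup
#'
#' @param d symmetric distance matrix with taxon dimnames.
#' @param outgroup optional taxon id to root on.
#' @return an `ape::phylo` tree (rooted when `outgroup` is given).
#' @export
nj_tree <- function(d, outgroup = NULL) {
  stopifnot(nrow(d) >= 3)
  tr <- ape::nj(as.dist(d))
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) {
      stop("outgroup '", outgroup, "' is not among the taxa")
    }
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

#' Bootstrapped neighbor-joining tree with clade support
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' NJ tree per replicate, and reports, for each internal node of the full
#' tree, the percentage of replicates containing the same bipartition.
#' Seeded and reproducible.
#'
#' @param aln named aligned sequences (or character matrix).
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed (default 111).
#' @param outgroup optional rooting taxon.
#' @param correction distance correction passed through.
#' @return the NJ tree with `node.label` set to support percentages and a
#'   `boot_support` attribute (numeric vector per internal node).
#' @export
bootstrap_nj <- function(aln, n_reps = 1000L, seed = 111L, outgroup = NULL,
                         correction = c("none", "dayhoff")) {
  correction <- match.arg(correction)
  stopifnot(n_reps >= 1)
  m <- as_aln_matrix(aln)
  pc <- pairwise_column_stats(m)
  taxa <- rownames(m)
  base <- nj_tree(dist_from_stats(pc, seq_len(ncol(m)), taxa, correction))
  set.seed(seed)
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boots[[r]] <- nj_tree(dist_from_stats(pc, cols, taxa, correction))
  }
  counts <- ape::prop.clades(base, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / n_reps * 100
  base$node.label <- format(round(support, 1), trim = TRUE)
  out <- if (is.null(outgroup)) base else
    ape::root(base, outgroup = outgroup, resolve.root = TRUE)
  attr(out, "boot_support") <- support
  out
}

#' Call ortholog pairs and groups from a species-tagged tree
#'
#' Leaves are tagged by species through `species_of` (default: leading
#' `Tm`/`Tc` in the label; other leaves are neutral references). Cherries
#' with exactly one leaf of each species become ortholog pairs. Remaining
#' leaves are swept root-ward: each minimal clade containing at least one
#' unclaimed leaf of each species and no already-called leaf becomes an
#' ortholog group. Leaves never inside a mixed clade stay unpaired.
#'
#' @param tree rooted `phylo` tree.
#' @param species_of function mapping tip labels to species tags (`NA` for
#'   neutral leaves).
#' @return list with `calls` (list of `type`/`members`), `pairs`
#'   (two-column matrix Tm/Tc), `unpaired` (character vector).
#' @export
call_orthologs <- function(tree,
                           species_of = function(x) {
                             ifelse(grepl("^Tm", x), "Tm",
                                    ifelse(grepl("^Tc", x), "Tc", NA))
                           }) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("call_orthologs() needs a rooted tree")
  ntip <- length(tree$tip.label)
  sp <- species_of(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc_tips <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(kids[[as.character(node)]], desc_tips))
  }
  claimed <- rep(FALSE, ntip)
  calls <- list()
  # pass 1: cherries
  for (node in sort(unique(tree$edge[, 1]))) {
    ch <- kids[[as.character(node)]]
    if (length(ch) == 2 && all(ch <= ntip)) {
      s <- sp[ch]
      if (!anyNA(s) && length(unique(s)) == 2) {
        claimed[ch] <- TRUE
        calls[[length(calls) + 1L]] <- list(
          type = "pair", members = tree$tip.label[ch][order(s[order(ch)])])
        # store Tm first
        mem <- tree$tip.label[ch]
        calls[[length(calls)]]$members <- c(mem[s == "Tm"], mem[s == "Tc"])
      }
    }
  }
  # pass 2: minimal mixed clades over unclaimed leaves (post-order = by
  # increasing clade size)
  internal <- sort(unique(tree$edge[, 1]))
  sizes <- vapply(internal, function(n) length(desc_tips(n)), 1L)
  for (node in internal[order(sizes)]) {
    tips <- desc_tips(node)
    s <- sp[tips]
    if (any(claimed[tips])) next
    real <- !is.na(s)
    if (sum(s[real] == "Tm") >= 1 && sum(s[real] == "Tc") >= 1) {
      claimed[tips[real]] <- TRUE
      calls[[length(calls) + 1L]] <- list(
        type = "group", members = tree$tip.label[tips[real]])
    }
  }
  pairs <- do.call(rbind, lapply(Filter(function(x) x$type == "pair", calls),
                                 function(x) x$members))
  unpaired <- tree$tip.label[!claimed & !is.na(sp)]
  list(calls = calls, pairs = pairs, unpaired = unpaired)
}
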