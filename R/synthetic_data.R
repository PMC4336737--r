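# Synthetic peptidase gene families, reads and contigs with ground truth.
# The generator emulates the structure the catalogue analysis assumes:
# clusters of tandem-duplicated paralogs derived from a common ancestor,
# inactivating substitutions at catalytic positions, shortened cathepsin-B
# occluding loops, cross-species ortholog copies, per-gene expression
# levels, within-gene SNP haplotypes and multi-mapping reads.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Specification for a synthetic peptidase gene-family simulation
#'
#' @param n_clusters number of paralog clusters.
#' @param genes_per_cluster integer range (length-2) or single count of
#'   genes per cluster.
#' @param substitution_rate expected amino-acid substitutions per site
#'   between a paralog and its cluster ancestor; ortholog copies of a gene
#'   diverge at half this rate each.
#' @param homolog_fraction probability a gene receives an inactivating
#'   catalytic substitution (drawn from C25S, C25A, Q19E, H159T).
#' @param shortloop_fraction probability a cathepsin-B-derived gene has its
#'   occluding loop deleted to <= 18 aligned residues (both loop histidines
#'   removed).
#' @param ortholog_fraction probability a gene has a counterpart in the
#'   second species.
#' @param expression_profile optional named per-gene expected TPM; drawn
#'   log-uniformly in `[10, 1e4]` when `NULL`.
#' @param snp_rate within-gene polymorphism probability per nucleotide site
#'   (a second haplotype carries the variants).
#' @param read_length,read_error_rate read simulation defaults.
#' @param seed integer fixing all randomness.
#' @return validated list of class `gene_family_spec`.
#' @export
gene_family_spec <- function(n_clusters = 4L, genes_per_cluster = c(3L, 7L),
                             substitution_rate = 0.2,
                             homolog_fraction = 0.15,
                             shortloop_fraction = 0.7,
                             ortholog_fraction = 0.8,
                             expression_profile = NULL,
                             snp_rate = 0.002, read_length = 75L,
                             read_error_rate = 0.001, seed = 1L) {
  rates <- c(substitution_rate = substitution_rate,
             homolog_fraction = homolog_fraction,
             shortloop_fraction = shortloop_fraction,
             ortholog_fraction = ortholog_fraction,
             snp_rate = snp_rate, read_error_rate = read_error_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  }
  if (!is.null(expression_profile)) {
    s <- sum(expression_profile)
    if (!is.finite(s) || s <= 0) stop("expression_profile must sum to a positive finite value")
  }
  stopifnot(n_clusters >= 1, read_length >= 20)
  structure(list(
    n_clusters = as.integer(n_clusters),
    genes_per_cluster = as.integer(rep_len(genes_per_cluster, 2)),
    substitution_rate = substitution_rate,
    homolog_fraction = homolog_fraction,
    shortloop_fraction = shortloop_fraction,
    ortholog_fraction = ortholog_fraction,
    expression_profile = expression_profile,
    snp_rate = snp_rate, read_length = as.integer(read_length),
    read_error_rate = read_error_rate, seed = as.integer(seed)
  ), class = "gene_family_spec")
}

mutate_protein <- function(aa, rate, protect = integer()) {
  hit <- setdiff(which(runif(length(aa)) < rate), protect)
  for (i in hit) aa[i] <- sample(setdiff(AA20, aa[i]), 1)
  aa
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

back_translate <- function(aa, codons = codon_table()) {
  paste(vapply(aa, function(a) {
    cs <- codons[[a]]
    cs[sample.int(length(cs), 1L)]
  }, ""), collapse = "")
}

inactivating_subs <- function() {
  # substitutions observed among natural inactive homologs
  list(list(pos = 25L, to = "S"), list(pos = 25L, to = "A"),
       list(pos = 19L, to = "E"), list(pos = 159L, to = "T"))
}

#' Generate synthetic peptidase gene families with a truth table
#'
#' Each cluster descends from the cathepsin L or cathepsin B reference
#' scaffold (alternating): an ancestor diverged at `substitution_rate`, then
#' one paralog per gene diverged again at `substitution_rate`, then a
#' species copy for Tm (and, with probability `ortholog_fraction`, an
#' ortholog copy for Tc) each diverged at half that rate. Catalytic-tetrad
#' positions and, on the B branch, the occluding-loop histidines are
#' protected from random substitution (purifying selection); inactivating
#' substitutions and loop shortening are injected deliberately, before the
#' species split, and recorded in the truth table. Proteins are
#' back-translated with uniform synonymous codon choice, prefixed with Met
#' and closed with a stop codon.
#'
#' @param spec a [gene_family_spec()].
#' @param panel reference panel with annotated catalytic positions.
#' @return object of class `papcat_genefamilies`: list with `genes` (named
#'   nucleotide strings), `proteins` (translations incl. leading Met),
#'   `truth` (one row per gene: `gene_id`, `species`, `cluster`,
#'   `family_truth`, `active_truth`, `loop_truth`, `true_tpm`,
#'   `ortholog_partner`), `protected` (per gene, protein positions excluded
#'   from SNP perturbation) and `log` (injection counts).
#' @export
generate_gene_families <- function(spec, panel = reference_panel()) {
  stopifnot(inherits(spec, "gene_family_spec"))
  for (fam in c("L", "B")) {
    e <- ref_by_family(panel, fam)
    if (is.null(e$scheme)) stop("reference for family ", fam,
                                " lacks annotated catalytic positions")
  }
  set.seed(spec$seed)
  refL <- ref_by_family(panel, "L")
  refB <- ref_by_family(panel, "B")
  genes <- character(); proteins <- character()
  truth <- list(); protected <- list()
  n_homolog_injected <- 0L; n_shortloop_injected <- 0L
  codons <- codon_table()

  for (k in seq_len(spec$n_clusters)) {
    family <- if (k %% 2 == 1) "L" else "B"
    ref <- if (family == "L") refL else refB
    scaffold <- strsplit(ref$mature, "")[[1]]
    protect <- canonical_to_index(ref$scheme, PAPAIN_TETRAD)
    if (family == "B") protect <- c(protect, ref$loop$his)
    ancestor <- mutate_protein(scaffold, spec$substitution_rate, protect)
    ng <- if (spec$genes_per_cluster[1] == spec$genes_per_cluster[2]) {
      spec$genes_per_cluster[1]
    } else {
      sample(seq(spec$genes_per_cluster[1], spec$genes_per_cluster[2]), 1L)
    }
    for (g in seq_len(ng)) {
      para <- mutate_protein(ancestor, spec$substitution_rate, protect)
      is_homolog <- runif(1) < spec$homolog_fraction
      is_short <- family == "B" && runif(1) < spec$shortloop_fraction
      sub_txt <- NA_character_
      if (is_homolog) {
        n_homolog_injected <- n_homolog_injected + 1L
        s <- inactivating_subs()[[sample.int(4L, 1L)]]
        idx <- canonical_to_index(ref$scheme, s$pos)
        sub_txt <- sprintf("%s%d%s", para[idx], s$pos, s$to)
        para[idx] <- s$to
      }
      del <- integer()
      if (is_short) {
        n_shortloop_injected <- n_shortloop_injected + 1L
        del <- seq.int(ref$loop$start + 3L, ref$loop$end - 7L)  # 107..119
      }
      has_ortholog <- runif(1) < spec$ortholog_fraction
      base_id <- sprintf("c%02dg%02d", k, g)
      for (sp in c("Tm", if (has_ortholog) "Tc")) {
        copy <- mutate_protein(para, spec$substitution_rate / 2, protect)
        if (length(del)) copy <- copy[-del]
        aa <- c("M", copy)
        nt <- paste0(back_translate(aa, codons),
                     sample(c("TAA", "TGA", "TAG"), 1L))
        gid <- paste0(sp, "_", base_id)
        genes[gid] <- nt
        proteins[gid] <- paste(aa, collapse = "")
        prot_idx <- if (length(del)) {
          keep <- setdiff(seq_along(para), del)
          match(intersect(protect, keep), keep)
        } else protect
        protected[[gid]] <- prot_idx + 1L  # account for leading Met
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gid, species = sp, cluster = k,
          family_truth = if (family == "B" && is_short) "B-like" else family,
          active_truth = if (is_homolog) "homolog" else "active",
          loop_truth = if (family != "B") "not-B" else
            if (is_short) "short" else "typical",
          injected_sub = sub_txt,
          true_tpm = NA_real_,
          ortholog_partner = if (has_ortholog) {
            paste0(if (sp == "Tm") "Tc" else "Tm", "_", base_id)
          } else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, truth)
  if (is.null(spec$expression_profile)) {
    truth$true_tpm <- 10^runif(nrow(truth), 1, 4)
  } else {
    m <- match(truth$gene_id, names(spec$expression_profile))
    if (anyNA(m)) stop("expression_profile must name every generated gene")
    truth$true_tpm <- as.numeric(spec$expression_profile[m])
  }
  structure(list(genes = genes, proteins = proteins, truth = truth,
                 protected = protected,
                 log = list(homologs_injected = n_homolog_injected,
                            shortloops_injected = n_shortloop_injected)),
            class = "papcat_genefamilies")
}

#' @export
print.papcat_genefamilies <- function(x, ...) {
  cat("Synthetic gene families:", length(x$genes), "genes,",
      length(unique(x$truth$cluster)), "clusters\n")
  cat("  families:", paste(sprintf("%s=%d", names(table(x$truth$family_truth)),
                                   as.integer(table(x$truth$family_truth))),
                           collapse = " "), "\n")
  cat("  injected homologs:", x$log$homologs_injected,
      " shortened loops:", x$log$shortloops_injected, "\n")
  invisible(x)
}

#' Simulate reads from synthetic genes
#'
#' Reads are drawn with per-gene probability proportional to TPM times gene
#' length, uniform start positions, random strand, and per-base substitution
#' errors at `error_rate`. Genes shorter than the read length are skipped
#' with a warning.
#'
#' @param genes named nucleotide strings.
#' @param tpm named per-gene expected TPM.
#' @param n_reads number of reads to draw.
#' @param read_length,error_rate,seed simulation parameters.
#' @return list `reads` (named character), `quality` (constant string),
#'   `origin` (data.frame `read_id`, `gene_id`, `start`, `strand`).
#' @export
simulate_reads <- function(genes, tpm, n_reads, read_length = 75L,
                           error_rate = 0.001, seed = 1L) {
  stopifnot(n_reads >= 0, all(names(genes) %in% names(tpm)))
  set.seed(seed)
  len <- nchar(genes)
  ok <- len >= read_length
  if (any(!ok)) {
    warning("skipping gene(s) shorter than read length: ",
            paste(names(genes)[!ok], collapse = ", "))
  }
  genes <- genes[ok]; len <- len[ok]
  empty <- list(reads = setNames(character(), character()),
                quality = character(),
                origin = data.frame(read_id = character(),
                                    gene_id = character(), start = integer(),
                                    strand = character(),
                                    stringsAsFactors = FALSE))
  if (n_reads == 0 || length(genes) == 0) return(empty)
  w <- tpm[names(genes)] * len
  src <- sample(names(genes), n_reads, replace = TRUE, prob = w / sum(w))
  starts <- vapply(src, function(g) sample.int(nchar(genes[[g]]) - read_length + 1L, 1L), 1L)
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    s <- substring(genes[[src[i]]], starts[i], starts[i] + read_length - 1L)
    v <- strsplit(s, "")[[1]]
    err <- which(runif(read_length) < error_rate)
    for (e in err) v[e] <- sample(setdiff(bases, v[e]), 1)
    s <- paste(v, collapse = "")
    if (strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    reads[i] <- s
  }
  ids <- sprintf("read%06d", seq_len(n_reads))
  list(reads = setNames(reads, ids),
       quality = strrep("I", read_length),
       origin = data.frame(read_id = ids, gene_id = src, start = starts,
                           strand = strand, stringsAsFactors = FALSE))
}

#' Fragment genes into redundant, SNP-perturbed contigs
#'
#' Emulates the redundant and partial contigs of a de novo assembly. Each
#' gene yields `n_fragments` contigs. In the default `"anchored"` mode the
#' first fragment is the full gene and the others are 5'-anchored
#' truncations (3'-incomplete assemblies), so all fragments share the ORF
#' start and overlap; in `"staggered"` mode fragments tile the gene with
#' overlaps. Within-gene polymorphism is modelled as a second haplotype
#' carrying SNPs at `snp_rate` per site (codons of catalytic/loop-His
#' residues excluded, via `protected`); each fragment after the first is
#' drawn from either haplotype.
#'
#' @param genes named nucleotide strings.
#' @param fragmentation list: `n_fragments`, `min_frac`, `max_frac`, `mode`.
#' @param snp_rate per-site polymorphism probability.
#' @param protected optional per-gene protein positions whose codons are
#'   excluded from SNPs (as produced by [generate_gene_families()]).
#' @param seed integer seed.
#' @return list `contigs` (named nucleotide strings) and `provenance`
#'   (data.frame `contig_id`, `gene_id`, `start`, `end`, `haplotype`).
#' @export
fragment_into_contigs <- function(genes,
                                  fragmentation = list(n_fragments = 3L,
                                                       min_frac = 0.6,
                                                       max_frac = 0.9,
                                                       mode = "anchored"),
                                  snp_rate = 0, protected = NULL, seed = 1L) {
  set.seed(seed)
  fr <- utils::modifyList(list(n_fragments = 3L, min_frac = 0.6,
                               max_frac = 0.9, mode = "anchored"),
                          fragmentation)
  bases <- c("A", "C", "G", "T")
  contigs <- character(); prov <- list()
  for (g in names(genes)) {
    nt <- strsplit(genes[[g]], "")[[1]]
    L <- length(nt)
    hap2 <- nt
    if (snp_rate > 0) {
      excl <- integer()
      if (!is.null(protected[[g]])) {
        excl <- as.vector(vapply(protected[[g]],
                                 function(p) (3L * (p - 1L) + 1L):(3L * p),
                                 integer(3)))
      }
      snp_at <- setdiff(which(runif(L) < snp_rate), excl)
      for (s in snp_at) hap2[s] <- sample(setdiff(bases, hap2[s]), 1)
    }
    for (f in seq_len(fr$n_fragments)) {
      if (fr$mode == "anchored") {
        if (f == 1L) { a <- 1L; b <- L }
        else {
          b <- max(ceiling(runif(1, fr$min_frac, fr$max_frac) * L), 60L)
          a <- 1L
        }
      } else {
        w <- max(ceiling(runif(1, fr$min_frac, fr$max_frac) * L), 60L)
        step <- if (fr$n_fragments > 1) (L - w) / (fr$n_fragments - 1) else 0
        a <- max(1L, as.integer(round((f - 1) * step)) + 1L)
        b <- min(L, a + w - 1L)
      }
      hap <- if (f == 1L || snp_rate == 0) 1L else sample(1:2, 1L)
      src <- if (hap == 1L) nt else hap2
      cid <- sprintf("ctg_%s_%d", g, f)
      contigs[cid] <- paste(src[a:b], collapse = "")
      prov[[length(prov) + 1L]] <- data.frame(
        contig_id = cid, gene_id = g, start = a, end = b, haplotype = hap,
        stringsAsFactors = FALSE)
    }
  }
  list(contigs = contigs, provenance = do.call(rbind, prov))
}

#' Write generator output to FASTA/FASTQ/TSV files
#'
#' @param sim output of [generate_gene_families()].
#' @param contigs,reads optional [fragment_into_contigs()] /
#'   [simulate_reads()] outputs.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_simulation <- function(sim, contigs = NULL, reads = NULL, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genes = file.path(dir, "genes.fasta"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genes),
                              paths["genes"])
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(contigs)) {
    paths["contigs"] <- file.path(dir, "contigs.fasta")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs$contigs),
                                paths["contigs"])
    paths["provenance"] <- file.path(dir, "provenance.tsv")
    write.table(contigs$provenance, paths["provenance"], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(reads) && length(reads$reads)) {
    paths["reads"] <- file.path(dir, "reads.fastq")
    rs <- Biostrings::DNAStringSet(reads$reads)
    q <- Biostrings::BStringSet(rep(reads$quality, length(rs)))
    Biostrings::writeQualityScaledXStringSet(
      Biostrings::QualityScaledDNAStringSet(
        rs, Biostrings::PhredQuality(q)), paths["reads"])
  }
  invisible(paths)
}
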