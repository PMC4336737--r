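# End-to-end orchestration: configuration object, YAML round-trip, staged
# execution with a plain-text log and TSV/Newick/JSON outputs.

#' Pipeline configuration with the catalogue defaults
#'
#' Thresholds default to the values used throughout the analysis: ORF
#' coverage 0.20, clustering 95% identity / 10-residue overlap, contig
#' assignment 97% identity with the 50% partial-alignment rule, bootstrap
#' 1000 with seed 111, catalytic distance 4.0 Angstrom.
#'
#' @param out_dir output directory.
#' @param simulate `NULL`, or a list of [gene_family_spec()] arguments; when
#'   set, inputs are generated rather than read.
#' @param contigs,reads optional input FASTA/FASTQ paths (files mode).
#' @param n_reads reads to simulate (simulate mode).
#' @param min_coverage,min_identity,min_overlap,assign_identity,full_fraction
#'   stage thresholds.
#' @param min_orf_aa minimum retained ORF protein length (default 100
#'   residues, the length below which the homology filter's alignment-length
#'   requirement is no longer meaningful).
#' @param bootstrap,tree_seed bootstrap replicates and seed.
#' @param outgroup outgroup taxon for rooting (default the cathepsin K
#'   panel reference).
#' @param max_dist pose-filter catalytic distance threshold.
#' @return validated list of class `papcat_config`.
#' @export
papcat_config <- function(out_dir = tempfile("papcat_"), simulate = NULL,
                          contigs = NULL, reads = NULL, n_reads = 20000L,
                          min_orf_aa = 100L,
                          min_coverage = 0.20, min_identity = 0.95,
                          min_overlap = 10L, assign_identity = 0.97,
                          full_fraction = 0.99, bootstrap = 1000L,
                          tree_seed = 111L,
                          outgroup = "cathepsinK_ref_synth",
                          max_dist = 4.0) {
  stopifnot(min_coverage > 0, min_coverage <= 1,
            min_identity > 0, min_identity <= 1,
            min_overlap >= 1, assign_identity > 0, assign_identity <= 1,
            bootstrap >= 1, max_dist > 0)
  structure(list(out_dir = out_dir, simulate = simulate, contigs = contigs,
                 reads = reads, n_reads = as.integer(n_reads),
                 min_orf_aa = as.integer(min_orf_aa),
                 min_coverage = min_coverage, min_identity = min_identity,
                 min_overlap = as.integer(min_overlap),
                 assign_identity = assign_identity,
                 full_fraction = full_fraction,
                 bootstrap = as.integer(bootstrap),
                 tree_seed = as.integer(tree_seed), outgroup = outgroup,
                 max_dist = max_dist),
            class = "papcat_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a `papcat_config`.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   reloaded `papcat_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "papcat_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(papcat_config, v)
}

#' Run the catalogue pipeline end to end
#'
#' Stages: obtain contigs and reads (simulated under the config's generator
#' spec, or read from files), ORF discovery, homology filtering, redundancy
#' clustering with consensus building, contig-to-peptidase assignment,
#' read mapping and expression quantification (naive and rescue), per-
#' peptidase annotation, catalogue assembly, and a bootstrapped NJ tree
#' with orthology calls over the consensus proteins plus the reference
#' panel. Writes `catalogue.tsv`, `tree.nwk`, `orthologs.tsv`,
#' `summary.json` and `pipeline.log` under `config$out_dir`.
#'
#' @param config a [papcat_config()].
#' @return invisibly, a list with the stage results (`sim`, `orfs`,
#'   `peptidases`, `expression`, `catalogue`, `tree`, `orthologs`,
#'   `summary`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "papcat_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "pipeline.log")
  cat("", file = logf)
  logline <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, paste0(...)), file = logf, append = TRUE)
  }
  panel <- reference_panel()

  # stage: inputs
  sim <- NULL
  if (!is.null(config$simulate)) {
    spec <- do.call(gene_family_spec, config$simulate)
    sim <- generate_gene_families(spec, panel)
    frag <- fragment_into_contigs(sim$genes, snp_rate = spec$snp_rate,
                                  protected = sim$protected,
                                  seed = spec$seed + 1L)
    contigs <- frag$contigs
    tm <- sim$truth$gene_id[sim$truth$species == "Tm"]
    rd <- simulate_reads(sim$genes[tm],
                         setNames(sim$truth$true_tpm, sim$truth$gene_id),
                         config$n_reads, spec$read_length,
                         spec$read_error_rate, seed = spec$seed + 2L)
    reads <- rd$reads
    logline("input", length(sim$genes), " genes simulated, ",
            length(contigs), " contigs, ", length(reads), " reads")
  } else {
    contigs <- setNames(as.character(Biostrings::readDNAStringSet(config$contigs)),
                        names(Biostrings::readDNAStringSet(config$contigs)))
    reads <- NULL
    if (!is.null(config$reads)) {
      rs <- Biostrings::readDNAStringSet(config$reads, format = "fastq")
      reads <- setNames(as.character(rs), names(rs))
    }
    logline("input", length(contigs), " contigs read")
  }

  # stage: ORF discovery + homology filter
  orfs <- find_orfs_set(contigs, min_coverage = config$min_coverage)
  orfs <- orfs[nchar(orfs$protein) >= config$min_orf_aa, , drop = FALSE]
  refs <- vapply(panel, function(e) e$mature, "")
  orfs <- homology_filter(orfs, refs)
  logline("orfs", nrow(orfs), " peptidase-homologous ORFs")

  # stage: redundancy clustering + consensus
  peps <- unique_peptidases(orfs, contigs = contigs, panel = panel,
                            min_identity = config$min_identity,
                            min_overlap = config$min_overlap)
  logline("cluster", length(peps), " unique peptidases")

  # stage: expression
  expression <- NULL
  if (!is.null(reads) && length(reads)) {
    aln_rows <- lapply(peps, function(p) {
      members <- p$members
      idx <- match(members, orfs$orf_id)
      cids <- unique(orfs$contig_id[idx])
      do.call(rbind, lapply(cids, function(cid) {
        st <- wf_stats(contigs[[cid]], p$consensus_mrna)
        data.frame(contig_id = cid, peptidase_id = p$peptidase_id,
                   identity = st[["identity"]],
                   aligned_fraction = st[["overlap"]] / nchar(contigs[[cid]]),
                   stringsAsFactors = FALSE)
      }))
    })
    assignments <- assign_contigs(do.call(rbind, aln_rows),
                                  min_identity = config$assign_identity,
                                  full_fraction = config$full_fraction)
    read_aln <- map_reads_exact(reads, contigs[unique(assignments$contig_id)])
    expression <- quantify_expression(
      read_aln, assignments,
      contig_lengths = nchar(contigs),
      peptidase_lengths = setNames(
        vapply(peps, function(p) nchar(p$consensus_mrna), 1),
        vapply(peps, function(p) p$peptidase_id, "")))
    logline("quant", nrow(expression), " expression records from ",
            length(unique(read_aln$read_id)), " mapped reads")
  }

  # stage: annotation + catalogue
  ann <- do.call(rbind, lapply(peps, function(p) {
    annotate_peptidase(p$consensus_protein, p$peptidase_id, panel)
  }))
  cat_tab <- catalogue(ann, expression)
  write.table(cat_tab, file.path(config$out_dir, "catalogue.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  logline("annotate", nrow(cat_tab), " catalogue rows")

  # stage: phylogeny + orthology over consensus proteins + panel
  tree <- NULL; orth <- NULL
  prot <- setNames(vapply(peps, function(p) p$consensus_protein, ""),
                   vapply(peps, function(p) p$peptidase_id, ""))
  # keep species tags when simulating: name by dominant member gene
  if (!is.null(sim)) {
    names(prot) <- vapply(peps, function(p) {
      cid <- orfs$contig_id[match(p$members[1], orfs$orf_id)]
      sub("^ctg_", "", sub("_[0-9]+$", "", cid))
    }, "")
  }
  taxa <- c(prot, refs)
  if (length(taxa) >= 4) {
    aln <- progressive_msa(taxa)
    aseq <- setNames(apply(aln, 1, paste, collapse = ""), rownames(aln))
    tree <- bootstrap_nj(aseq, n_reps = config$bootstrap,
                         seed = config$tree_seed,
                         outgroup = config$outgroup)
    ape::write.tree(tree, file.path(config$out_dir, "tree.nwk"))
    orth <- call_orthologs(tree)
    pairs <- orth$pairs
    ot <- data.frame(
      type = vapply(orth$calls, `[[`, "", "type"),
      members = vapply(orth$calls, function(x) paste(x$members, collapse = ","), ""))
    write.table(ot, file.path(config$out_dir, "orthologs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    logline("tree", length(tree$tip.label), " taxa, ",
            if (is.null(pairs)) 0 else nrow(pairs), " ortholog pairs")
  }

  # stage: summary
  s <- attr(cat_tab, "summary")
  top <- NULL
  if (!is.null(expression)) {
    sp <- split(seq_len(nrow(cat_tab)), cat_tab$family)
    top <- lapply(sp, function(ix) {
      i <- ix[which.max(cat_tab$rpkm_rescue[ix])]
      list(peptidase = cat_tab$peptidase_id[i],
           rpkm_rescue = cat_tab$rpkm_rescue[i])
    })
  }
  summary <- list(
    n_peptidases = s$n,
    families = as.list(setNames(as.integer(s$by_family), names(s$by_family))),
    homologs = s$homologs, typical_loops = s$typical_loops,
    short_loops = s$short_loops,
    top_expressed = top,
    ortholog_pairs = if (!is.null(orth) && !is.null(orth$pairs))
      nrow(orth$pairs) else 0L)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logline("summary", "written")

  invisible(list(sim = sim, orfs = orfs, peptidases = peps,
                 expression = expression, catalogue = cat_tab, tree = tree,
                 orthologs = orth, summary = summary,
                 paths = list(out_dir = config$out_dir, log = logf)))
}
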