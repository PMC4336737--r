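#' Load the packaged reference peptidase panel
#'
#' The panel is a constructed synthetic stand-in for the classical C1-family
#' reference set (papain, human cathepsins L1/L2/B plus F/O/K exemplars): a
#' 212-residue papain-like scaffold carrying the canonical papain-numbering
#' residues (Gln19, Gly23, Cys25, Gly65, His159, Asn175), and a
#' cathepsin-B-like scaffold with a 23-residue occluding loop (cathepsin-B
#' numbering 104-126, His110/His111). Each entry is annotated with its family,
#' numbering scheme, mature-domain start and, for the B branch, the loop
#' region, so that every downstream classification step is exercised without
#' network access.
#'
#' @param fasta,annotation optional paths overriding the packaged files.
#' @return an object of class `papcat_refpanel`: a named list of reference
#'   entries with fields `name`, `seq` (full sequence), `mature` (mature
#'   domain), `family`, `scheme` (`"papain"` or `"cathB"`), `mature_start`,
#'   and `loop` (B branch only: `start`, `end`, `his`, mature-domain indices).
#' @export
reference_panel <- function(fasta = NULL, annotation = NULL) {
  if (is.null(fasta) && is.null(annotation) &&
      !is.null(.papcat_env$refpanel)) {
    return(.papcat_env$refpanel)
  }
  if (is.null(fasta)) {
    fasta <- system.file("extdata", "reference_panel_synthetic.fasta",
                         package = "papcat", mustWork = TRUE)
  }
  if (is.null(annotation)) {
    annotation <- system.file("extdata", "reference_panel_synthetic.yaml",
                              package = "papcat", mustWork = TRUE)
  }
  seqs <- Biostrings::readAAStringSet(fasta)
  ann <- yaml::read_yaml(annotation)
  panel <- lapply(names(seqs), function(nm) {
    a <- ann[[nm]]
    if (is.null(a)) {
      stop("reference '", nm, "' lacks an annotation entry", call. = FALSE)
    }
    s <- as.character(seqs[[nm]])
    entry <- list(
      name = nm,
      seq = s,
      family = a$family,
      scheme = a$scheme,
      mature_start = as.integer(a$mature_start),
      mature = substring(s, a$mature_start, nchar(s)),
      loop = if (!is.null(a$loop)) {
        list(start = as.integer(a$loop$start), end = as.integer(a$loop$end),
             his = as.integer(a$loop$his))
      }
    )
    entry
  })
  names(panel) <- names(seqs)
  structure(panel, class = "papcat_refpanel")
}

#' @export
print.papcat_refpanel <- function(x, ...) {
  cat("Reference peptidase panel (synthetic):", length(x), "entries\n")
  for (e in x) {
    cat(sprintf("  %-24s family %s  scheme %-6s  mature %d aa\n",
                e$name, e$family, e$scheme, nchar(e$mature)))
  }
  invisible(x)
}

# map a canonical position to a mature-domain sequence index under the
# reference's numbering scheme; the cathepsin-B scaffold carries a 23-residue
# occluding-loop insertion after core position 103
canonical_to_index <- function(scheme, pos) {
  switch(scheme,
    papain = pos,
    cathB = ifelse(pos <= 103L, pos, pos + 23L),
    stop("unknown numbering scheme: ", scheme)
  )
}

ref_by_family <- function(panel, family) {
  hit <- Filter(function(e) identical(e$family, family), panel)
  if (length(hit) == 0) stop("no panel reference for family ", family)
  hit[[1]]
}

# default classification reference for a family branch (L-branch families
# are numbered against the papain scheme via the cathepsin L1 exemplar)
branch_reference <- function(panel, family) {
  if (family %in% c("B")) ref_by_family(panel, "B") else
    ref_by_family(panel, family)
}
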