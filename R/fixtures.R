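# Packaged catalogue fixtures transcribing the published T. castaneum and
# T. molitor cysteine-cathepsin tables (ids, accessions, family branch,
# printed active-site strings, S1/S2 fingerprints, RPKM/rescue columns).
# Cells whose typesetting in the source table is ambiguous are flagged
# (rpkm_ambiguous / fingerprint_ambiguous) and excluded from assertions.

#' Read a packaged catalogue fixture table
#'
#' @param species `"tm"` (T. molitor) or `"tc"` (T. castaneum), or a path to
#'   a fixture TSV with the same columns.
#' @return data.frame of class `papcat_fixture`.
#' @export
read_catalogue_fixture <- function(species = c("tm", "tc")) {
  path <- if (file.exists(species[1])) species[1] else {
    species <- match.arg(species)
    system.file("extdata",
                sprintf("%s_catalogue_fixture.tsv",
                        c(tm = "tmol", tc = "tcas")[species]),
                package = "papcat", mustWork = TRUE)
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$tetrad <- sub(" HH$", "", df$active_site)
  df$hh <- grepl(" HH$", df$active_site)
  class(df) <- c("papcat_fixture", "data.frame")
  df
}

#' Apply the catalogue classification rules to a fixture table
#'
#' Derives the headline counts from the fixture's printed strings using the
#' package's rules: a gene is counted when it is not the pseudogene; a
#' peptidase is an inactive homolog when its tetrad differs from `QCHN`;
#' a B-branch peptidase is `typical B` when its active-site string carries
#' the occluding-loop `HH` mark, a `homolog` when inactive, and `B-like`
#' (short loop) otherwise; short-loop counts are B-branch rows without the
#' `HH` mark (homologs included).
#'
#' @param fixture a [read_catalogue_fixture()] table.
#' @return named list of counts: `genes`, `l_branch`, `b_branch`,
#'   `l_homologs`, `b_homologs`, `typical_b`, `b_like`, `short_loop`,
#'   `families` (table over family_branch).
#' @export
fixture_counts <- function(fixture) {
  f <- fixture[fixture$pseudogene == 0, , drop = FALSE]
  homolog <- f$tetrad != "QCHN"
  isB <- f$family_branch == "B"
  list(
    genes = nrow(f),
    l_branch = sum(f$family_branch == "L"),
    b_branch = sum(isB),
    l_homologs = sum(homolog & f$family_branch == "L"),
    b_homologs = sum(homolog & isB & !f$hh),
    typical_b = sum(isB & f$hh),
    b_like = sum(isB & !f$hh & !homolog),
    short_loop = sum(isB & !f$hh),
    families = table(f$family_branch)
  )
}

#' Reconstruct synthetic proteins carrying a fixture row's printed residues
#'
#' For every non-pseudogene row with unambiguous fingerprints, builds a
#' synthetic protein on the family's reference scaffold with the printed
#' tetrad residues written at papain-numbering positions 19/25/159/175 and
#' the printed S1/S2 residues at 23/65 and 67/68/133/157/205. B-branch rows
#' without the `HH` mark additionally have the occluding loop deleted to a
#' short loop (both histidines removed). These sequences are synthetic
#' stand-ins for the accessioned transcripts (which are not packaged); they
#' exercise the numbering and extraction machinery round-trip.
#'
#' @param fixture a [read_catalogue_fixture()] table.
#' @param panel reference panel.
#' @return list with `proteins` (named character) and `expected`
#'   (data.frame `id`, `tetrad`, `s1`, `s2`, `hh`, `family_branch`).
#' @export
synth_catalogue_proteins <- function(fixture, panel = reference_panel()) {
  keep <- fixture$pseudogene == 0 & fixture$fingerprint_ambiguous == 0 &
    !is.na(fixture$s1) & !is.na(fixture$s2) & nchar(fixture$tetrad) == 4
  rows <- fixture[keep, , drop = FALSE]
  proteins <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    fam <- rows$family_branch[i]
    ref <- branch_reference(panel, fam)
    aa <- strsplit(ref$mature, "")[[1]]
    pos <- canonical_to_index(ref$scheme,
                              c(PAPAIN_TETRAD, PAPAIN_S1, PAPAIN_S2))
    res <- strsplit(paste0(rows$tetrad[i], rows$s1[i], rows$s2[i]), "")[[1]]
    aa[pos] <- res
    if (fam == "B" && !rows$hh[i]) {
      del <- seq.int(ref$loop$start + 3L, ref$loop$end - 7L)
      aa <- aa[-del]
    }
    proteins[i] <- paste(aa, collapse = "")
  }
  names(proteins) <- rows$id
  list(proteins = proteins,
       expected = data.frame(id = rows$id, tetrad = rows$tetrad,
                             s1 = rows$s1, s2 = rows$s2, hh = rows$hh,
                             family_branch = rows$family_branch,
                             stringsAsFactors = FALSE))
}
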