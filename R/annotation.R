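#' Project a peptidase onto a reference's canonical residue numbering
#'
#' Globally aligns the peptidase (mature domain, when `mature_start` is
#' given) against the reference's mature domain (BLOSUM62, gap open 10 /
#' extend 2) and records, for every reference position, the aligned
#' peptidase residue and position. Canonical positions (papain numbering,
#' or cathepsin-B numbering for the B branch) are resolved through the
#' reference's numbering scheme. When overlap identity falls below
#' `min_identity` the map is refused (`status = "refused"`) because the
#' numbering would be unreliable.
#'
#' @param protein peptidase protein string.
#' @param reference a reference entry from [reference_panel()].
#' @param peptidase_id label carried in the result.
#' @param mature_start optional 1-based mature start of `protein`; when
#'   given, numbering is computed on the mature domain.
#' @param min_identity refusal threshold on overlap identity (default 0.15).
#' @return object of class `numbering_map`: `peptidase_id`, `reference`,
#'   `scheme`, `status` ("ok"/"refused"), `score`, `identity`, `columns`
#'   (data.frame `col`, `ref_index`, `pep_index`, `pep_residue`; `NA`
#'   ref_index marks an insertion, `NA` pep_index a deletion), and `offset`
#'   (0-based offset of the mature domain within `protein`).
#' @export
build_numbering_map <- function(protein, reference, peptidase_id = "pep",
                                mature_start = NULL, min_identity = 0.15) {
  stopifnot(is.list(reference), !is.null(reference$mature))
  offset <- 0L
  pep <- protein
  if (!is.null(mature_start) && !is.na(mature_start) && mature_start > 1) {
    offset <- as.integer(mature_start) - 1L
    pep <- substring(protein, mature_start, nchar(protein))
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    pep, reference$mature, type = "global", substitutionMatrix = B62,
    gapOpening = 10, gapExtension = 2)
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qi <- si <- 0L
  n <- length(qa)
  cols <- data.frame(col = seq_len(n), ref_index = NA_integer_,
                     pep_index = NA_integer_, pep_residue = NA_character_)
  matches <- overlap <- 0L
  for (col in seq_len(n)) {
    if (qa[col] != "-") qi <- qi + 1L
    if (sa[col] != "-") si <- si + 1L
    cols$ref_index[col] <- if (sa[col] != "-") si else NA_integer_
    cols$pep_index[col] <- if (qa[col] != "-") qi + offset else NA_integer_
    cols$pep_residue[col] <- if (qa[col] != "-") qa[col] else NA_character_
    if (qa[col] != "-" && sa[col] != "-") {
      overlap <- overlap + 1L
      if (qa[col] == sa[col]) matches <- matches + 1L
    }
  }
  identity <- if (overlap > 0) matches / overlap else 0
  structure(list(
    peptidase_id = peptidase_id, reference = reference$name,
    scheme = reference$scheme, family = reference$family,
    loop = reference$loop, status = if (identity < min_identity) "refused" else "ok",
    score = Biostrings::score(aln), identity = identity,
    columns = cols, offset = offset
  ), class = "numbering_map")
}

#' @export
print.numbering_map <- function(x, ...) {
  cat(sprintf("Numbering map: %s vs %s (%s scheme), status %s, identity %.2f\n",
              x$peptidase_id, x$reference, x$scheme, x$status, x$identity))
  invisible(x)
}

# residue aligned at a canonical position; "-" for a deletion
residue_at <- function(map, canonical_pos) {
  idx <- canonical_to_index(map$scheme, canonical_pos)
  vapply(idx, function(i) {
    row <- map$columns[!is.na(map$columns$ref_index) &
                         map$columns$ref_index == i, , drop = FALSE]
    if (nrow(row) == 0 || is.na(row$pep_residue[1])) "-" else row$pep_residue[1]
  }, "")
}

#' Extract the catalytic tetrad and call activity
#'
#' Concatenates the residues aligned at papain-numbering positions
#' 19/25/159/175 (`-` for deletions). A peptidase is called `active` only
#' when the tetrad is exactly `QCHN`; any substitution or deletion makes it
#' an (inactive) `homolog`.
#'
#' @param map a [build_numbering_map()] result with `status == "ok"`.
#' @return list `tetrad` (4-character string) and `activity`
#'   (`"active"`/`"homolog"`).
#' @export
extract_tetrad <- function(map) {
  stopifnot(inherits(map, "numbering_map"))
  if (map$status != "ok") stop("numbering map was refused; no tetrad")
  tetrad <- paste(residue_at(map, PAPAIN_TETRAD), collapse = "")
  list(tetrad = tetrad,
       activity = if (identical(tetrad, "QCHN")) "active" else "homolog")
}

#' Type the cathepsin-B occluding loop
#'
#' Counts peptidase residues aligned within the reference occluding-loop
#' region (cathepsin-B numbering 104-126, insertions inside the region
#' included) and checks for histidines at positions 110 and 111. Loops of
#' at least `typical_min` residues carrying both histidines are `typical`;
#' loops of at most `short_max` residues, or lacking either histidine, are
#' `short`.
#'
#' @param map a numbering map against the cathepsin-B reference.
#' @param typical_min,short_max loop-length thresholds (defaults 20 / 18).
#' @return list `loop_type` (`"typical"`/`"short"`/`"ambiguous"`),
#'   `loop_length`, `loop_HH`.
#' @export
type_occluding_loop <- function(map, typical_min = 20L, short_max = 18L) {
  stopifnot(inherits(map, "numbering_map"))
  if (map$scheme != "cathB" || is.null(map$loop)) {
    stop("occluding-loop typing requires a cathepsin-B-branch numbering map")
  }
  cols <- map$columns
  lo <- map$loop$start; hi <- map$loop$end
  incl <- which(!is.na(cols$ref_index) & cols$ref_index >= lo &
                  cols$ref_index <= hi)
  if (length(incl)) {
    span <- seq.int(min(incl), max(incl))   # insertions inside the region
  } else {
    span <- integer()
  }
  loop_length <- sum(!is.na(cols$pep_index[span]))
  # loop$his are stored in reference (mature-domain) indices, not canonical
  # positions, so look them up directly rather than via the scheme mapping
  his <- vapply(map$loop$his, function(i) {
    row <- cols[!is.na(cols$ref_index) & cols$ref_index == i, , drop = FALSE]
    if (nrow(row) == 0 || is.na(row$pep_residue[1])) "-" else row$pep_residue[1]
  }, "")
  loop_HH <- all(his == "H")
  loop_type <- if (loop_length <= short_max || !loop_HH) "short"
  else if (loop_length >= typical_min) "typical"
  else "ambiguous"
  list(loop_type = loop_type, loop_length = loop_length, loop_HH = loop_HH)
}

#' Extract the S1 and S2 subsite fingerprints
#'
#' @param map a valid numbering map.
#' @return list `s1` (residues at papain positions 23, 65) and `s2`
#'   (positions 67, 68, 133, 157, 205), `-` for deletions.
#' @export
extract_subsites <- function(map) {
  stopifnot(inherits(map, "numbering_map"))
  if (map$status != "ok") stop("numbering map was refused; no subsites")
  list(s1 = paste(residue_at(map, PAPAIN_S1), collapse = ""),
       s2 = paste(residue_at(map, PAPAIN_S2), collapse = ""))
}

#' Assign the peptidase family by best-scoring panel reference
#'
#' @param protein peptidase protein string.
#' @param panel reference panel.
#' @return list `family` (panel family of the best global alignment score),
#'   `reference` (the entry), `score`.
#' @export
assign_family <- function(protein, panel = reference_panel()) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  best <- NULL
  for (e in panel) {
    sc <- Biostrings::pairwiseAlignment(
      protein, e$mature, type = "global", substitutionMatrix = B62,
      gapOpening = 10, gapExtension = 2, scoreOnly = TRUE)
    if (is.null(best) || sc > best$score) {
      best <- list(family = e$family, reference = e, score = sc)
    }
  }
  best
}

#' Annotate one peptidase: family, tetrad, loop type, subsite fingerprints
#'
#' Runs [assign_family()], numbers the sequence against the chosen family's
#' reference, and extracts the catalytic tetrad, occluding-loop type (B
#' branch only) and S1/S2 fingerprints. A B-branch peptidase with a short
#' loop is reported as family `B-like`.
#'
#' @param protein peptidase protein string.
#' @param peptidase_id label.
#' @param panel reference panel.
#' @param mature_start optional mature start (1-based) of `protein`.
#' @return one-row data.frame with columns `peptidase_id`, `family`,
#'   `tetrad`, `activity`, `loop_type`, `loop_length`, `loop_HH`, `s1`, `s2`,
#'   `reference`, `identity`.
#' @export
annotate_peptidase <- function(protein, peptidase_id = "pep",
                               panel = reference_panel(),
                               mature_start = NULL) {
  fam <- assign_family(protein, panel)
  map <- build_numbering_map(protein, fam$reference,
                             peptidase_id = peptidase_id,
                             mature_start = mature_start)
  if (map$status != "ok") {
    return(data.frame(peptidase_id = peptidase_id, family = "unknown",
                      tetrad = NA_character_, activity = NA_character_,
                      loop_type = NA_character_, loop_length = NA_integer_,
                      loop_HH = NA, s1 = NA_character_, s2 = NA_character_,
                      reference = fam$reference$name, identity = map$identity,
                      stringsAsFactors = FALSE))
  }
  tet <- extract_tetrad(map)
  sub <- extract_subsites(map)
  loop <- list(loop_type = "n/a", loop_length = NA_integer_, loop_HH = NA)
  family <- fam$family
  if (identical(fam$family, "B")) {
    loop <- type_occluding_loop(map)
    if (identical(loop$loop_type, "short")) family <- "B-like"
  }
  data.frame(peptidase_id = peptidase_id, family = family,
             tetrad = tet$tetrad, activity = tet$activity,
             loop_type = loop$loop_type, loop_length = loop$loop_length,
             loop_HH = loop$loop_HH, s1 = sub$s1, s2 = sub$s2,
             reference = fam$reference$name, identity = map$identity,
             stringsAsFactors = FALSE)
}

#' Join annotations and expression into the peptidase catalogue
#'
#' One row per peptidase with the classification, the Table-style active-site
#' string (tetrad plus an `HH` suffix for typical occluding loops) and the
#' expression estimates; summary counts (per family, activity, loop type)
#' are attached as the `summary` attribute and printed.
#'
#' @param annotations row-bound [annotate_peptidase()] output.
#' @param expression optional [quantify_expression()] records.
#' @return data.frame of class `papcat_catalogue`.
#' @export
catalogue <- function(annotations, expression = NULL) {
  out <- annotations
  out$active_site <- ifelse(!is.na(out$loop_HH) & out$loop_HH,
                            paste(out$tetrad, "HH"), out$tetrad)
  if (!is.null(expression)) {
    m <- match(out$peptidase_id, expression$peptidase_id)
    if (anyNA(m)) {
      warning("no expression record for: ",
              paste(out$peptidase_id[is.na(m)], collapse = ", "))
    }
    for (cl in setdiff(names(expression), "peptidase_id")) {
      out[[cl]] <- expression[[cl]][m]
    }
  }
  summary <- list(
    n = nrow(out),
    by_family = table(out$family),
    homologs = sum(out$activity == "homolog", na.rm = TRUE),
    typical_loops = sum(out$loop_type == "typical", na.rm = TRUE),
    short_loops = sum(out$loop_type == "short", na.rm = TRUE))
  attr(out, "summary") <- summary
  class(out) <- c("papcat_catalogue", "data.frame")
  out
}

#' @export
print.papcat_catalogue <- function(x, ...) {
  fam <- table(x$family)
  cat("Peptidase catalogue:", nrow(x), "entries\n")
  cat("  families:", paste(sprintf("%s=%d", names(fam), as.integer(fam)),
                           collapse = " "), "\n")
  cat("  inactive homologs:", sum(x$activity == "homolog", na.rm = TRUE),
      " typical loops:", sum(x$loop_type == "typical", na.rm = TRUE),
      " short loops:", sum(x$loop_type == "short", na.rm = TRUE), "\n")
  NextMethod()
}
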