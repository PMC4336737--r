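# Geometric validation of enzyme-substrate docking poses. No docking is
# performed; poses arrive as coordinates (constructed, or read from PDB via
# bio3d) and are screened against three criteria for productive binding of a
# P2-P1-P1' tripeptide in a C1 peptidase cleft.

#' Construct an enzyme-substrate pose
#'
#' @param enzyme data.frame of enzyme atoms: `resno`, `resid` (3-letter
#'   residue name), `elety` (atom name), `x`, `y`, `z` (Angstrom).
#' @param substrate data.frame of substrate atoms with the same columns plus
#'   `plabel` in `P2`/`P1`/`P1p`.
#' @param catalytic_cys residue number of the catalytic Cys (must have an SG
#'   atom).
#' @param s2_residues,s1p_residues enzyme residue numbers forming the S2
#'   subsite and the S1' region.
#' @param p1_atom substrate atom name holding the scissile carbonyl carbon
#'   of P1 (default `"C"`; the bond hydrolysed is P1-P1').
#' @return object of class `papcat_pose`.
#' @export
make_pose <- function(enzyme, substrate, catalytic_cys, s2_residues,
                      s1p_residues, p1_atom = "C") {
  need <- c("resno", "resid", "elety", "x", "y", "z")
  stopifnot(all(need %in% names(enzyme)),
            all(c(need, "plabel") %in% names(substrate)))
  xyz <- as.matrix(rbind(enzyme[, c("x", "y", "z")],
                         substrate[, c("x", "y", "z")]))
  if (!all(is.finite(xyz))) stop("pose coordinates must be finite")
  structure(list(enzyme = enzyme, substrate = substrate,
                 catalytic_cys = catalytic_cys,
                 s2_residues = s2_residues, s1p_residues = s1p_residues,
                 p1_atom = p1_atom),
            class = "papcat_pose")
}

#' Read an enzyme-substrate pose from a PDB file
#'
#' The enzyme is taken from ATOM records of `enzyme_chain`, the substrate
#' tripeptide from `substrate_chain` (its three residues, in residue-number
#' order, are labelled P2, P1, P1').
#'
#' @param path PDB file.
#' @param annotation list with `catalytic_cys`, `s2_residues`,
#'   `s1p_residues` (residue numbers), optionally `p1_atom`; or a YAML file
#'   path with those fields.
#' @param enzyme_chain,substrate_chain chain identifiers (defaults A and B).
#' @return a `papcat_pose`.
#' @export
read_pose_pdb <- function(path, annotation, enzyme_chain = "A",
                          substrate_chain = "B") {
  if (is.character(annotation)) annotation <- yaml::read_yaml(annotation)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  enz <- at[at$chain == enzyme_chain, c("resno", "resid", "elety", "x", "y", "z")]
  sub <- at[at$chain == substrate_chain, c("resno", "resid", "elety", "x", "y", "z")]
  if (nrow(sub) == 0) stop("no substrate atoms in chain ", substrate_chain)
  resnos <- sort(unique(sub$resno))
  if (length(resnos) != 3) stop("substrate must be a tripeptide (3 residues)")
  sub$plabel <- c("P2", "P1", "P1p")[match(sub$resno, resnos)]
  make_pose(enz, sub, annotation$catalytic_cys,
            annotation$s2_residues, annotation$s1p_residues,
            p1_atom = annotation$p1_atom %||% "C")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.dist <- function(a, b) sqrt(sum((a - b)^2))

atom_xyz <- function(df, sel) {
  as.matrix(df[sel, c("x", "y", "z"), drop = FALSE])
}

#' Criterion 1: catalytic distance
#'
#' Euclidean distance between the scissile carbonyl carbon of P1 and the SG
#' atom of the catalytic cysteine; passes when it does not exceed
#' `max_dist` (boundary inclusive).
#'
#' @param pose a `papcat_pose`.
#' @param max_dist threshold in Angstrom (default 4.0).
#' @return list `distance`, `pass`, `status` (`"ok"`/`"unevaluable"`).
#' @export
check_catalytic_distance <- function(pose, max_dist = 4.0) {
  sg <- pose$enzyme$resno == pose$catalytic_cys & pose$enzyme$elety == "SG"
  p1 <- pose$substrate$plabel == "P1" & pose$substrate$elety == pose$p1_atom
  if (sum(sg) != 1 || sum(p1) != 1) {
    return(list(distance = NA_real_, pass = NA, status = "unevaluable"))
  }
  d <- .dist(atom_xyz(pose$enzyme, sg)[1, ], atom_xyz(pose$substrate, p1)[1, ])
  list(distance = d, pass = d <= max_dist, status = "ok")
}

#' Criterion 2: substrate orientation
#'
#' The P2 side chain must sit in the S2 subsite and the P1' residue toward
#' the S1' region: the minimum heavy-atom distance from the P2 side-chain
#' to the S2 residue set must be smaller than to the S1' set (and vice
#' versa for P1'), and both contact distances must not exceed `max_dist`.
#'
#' @param pose a `papcat_pose`.
#' @param max_dist contact threshold in Angstrom (default 6.0).
#' @return list with the four minimum distances, `pass`, `status`.
#' @export
check_orientation <- function(pose, max_dist = 6.0) {
  if (length(pose$s2_residues) == 0 || length(pose$s1p_residues) == 0) {
    return(list(pass = NA, status = "unevaluable"))
  }
  backbone <- c("N", "CA", "C", "O", "OXT")
  p2 <- pose$substrate$plabel == "P2" & !(pose$substrate$elety %in% backbone)
  if (!any(p2)) p2 <- pose$substrate$plabel == "P2"   # Gly-like P2
  p1p <- pose$substrate$plabel == "P1p"
  s2 <- pose$enzyme$resno %in% pose$s2_residues
  s1p <- pose$enzyme$resno %in% pose$s1p_residues
  if (!any(p2) || !any(p1p) || !any(s2) || !any(s1p)) {
    return(list(pass = NA, status = "unevaluable"))
  }
  mind <- function(A, B) {
    min(apply(A, 1, function(a) min(sqrt(colSums((t(B) - a)^2)))))
  }
  d_p2_s2 <- mind(atom_xyz(pose$substrate, p2), atom_xyz(pose$enzyme, s2))
  d_p2_s1p <- mind(atom_xyz(pose$substrate, p2), atom_xyz(pose$enzyme, s1p))
  d_p1p_s1p <- mind(atom_xyz(pose$substrate, p1p), atom_xyz(pose$enzyme, s1p))
  d_p1p_s2 <- mind(atom_xyz(pose$substrate, p1p), atom_xyz(pose$enzyme, s2))
  pass <- d_p2_s2 < d_p2_s1p && d_p1p_s1p < d_p1p_s2 &&
    d_p2_s2 <= max_dist && d_p1p_s1p <= max_dist
  list(d_p2_s2 = d_p2_s2, d_p2_s1p = d_p2_s1p, d_p1p_s1p = d_p1p_s1p,
       d_p1p_s2 = d_p1p_s2, pass = pass, status = "ok")
}

#' Criterion 3: terminal accessibility
#'
#' The substrate's free amino and carboxyl termini must not be buried in the
#' enzyme: for each terminal group atom, the number of enzyme heavy atoms
#' within `radius` must not exceed `burial_max` (boundary inclusive).
#'
#' @param pose a `papcat_pose`.
#' @param radius neighbourhood radius in Angstrom (default 5.0).
#' @param burial_max maximum enzyme heavy-atom count (default 12).
#' @return list `n_count`, `c_count`, `pass`, `status`.
#' @export
check_terminal_accessibility <- function(pose, radius = 5.0,
                                         burial_max = 12L) {
  nter <- pose$substrate$plabel == "P2" & pose$substrate$elety == "N"
  cter <- pose$substrate$plabel == "P1p" & pose$substrate$elety == "C"
  if (sum(nter) != 1 || sum(cter) != 1) {
    return(list(n_count = NA_integer_, c_count = NA_integer_, pass = NA,
                status = "unevaluable"))
  }
  enz <- atom_xyz(pose$enzyme, rep(TRUE, nrow(pose$enzyme)))
  cnt <- function(p) sum(sqrt(colSums((t(enz) - p)^2)) <= radius)
  n_count <- cnt(atom_xyz(pose$substrate, nter)[1, ])
  c_count <- cnt(atom_xyz(pose$substrate, cter)[1, ])
  list(n_count = n_count, c_count = c_count,
       pass = n_count <= burial_max && c_count <= burial_max, status = "ok")
}

#' Full verdict for one pose
#'
#' @param pose a `papcat_pose`.
#' @param max_dist,orient_dist,radius,burial_max criterion parameters.
#' @return one-row data.frame: `criterion1_distance`, `criterion1_pass`,
#'   `criterion2_pass`, `criterion3_pass`, `overall_pass`, `status`
#'   (`"ok"` or `"unevaluable"`).
#' @export
pose_verdict <- function(pose, max_dist = 4.0, orient_dist = 6.0,
                         radius = 5.0, burial_max = 12L) {
  c1 <- check_catalytic_distance(pose, max_dist)
  c2 <- check_orientation(pose, orient_dist)
  c3 <- check_terminal_accessibility(pose, radius, burial_max)
  status <- if (any(c(c1$status, c2$status, c3$status) == "unevaluable"))
    "unevaluable" else "ok"
  overall <- if (status == "ok") c1$pass && c2$pass && c3$pass else NA
  data.frame(criterion1_distance = c1$distance, criterion1_pass = c1$pass,
             criterion2_pass = c2$pass, criterion3_pass = c3$pass,
             overall_pass = overall, status = status,
             stringsAsFactors = FALSE)
}

#' Filter a pose set against the three geometric criteria
#'
#' @param poses list of `papcat_pose` objects (named or not).
#' @param ... parameters passed to [pose_verdict()].
#' @return list with `verdicts` (data.frame, one row per pose), `survivors`
#'   (indices of poses passing all criteria) and `status`: `"ok"` when at
#'   least one pose was evaluable, `"no_evaluable"` otherwise.
#' @export
filter_poses <- function(poses, ...) {
  stopifnot(length(poses) >= 1)
  v <- do.call(rbind, lapply(poses, pose_verdict, ...))
  v$pose <- if (!is.null(names(poses))) names(poses) else seq_along(poses)
  rownames(v) <- NULL
  survivors <- which(!is.na(v$overall_pass) & v$overall_pass)
  status <- if (all(v$status == "unevaluable")) "no_evaluable" else "ok"
  list(verdicts = v, survivors = survivors, status = status)
}
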