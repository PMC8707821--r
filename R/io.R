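#' Default atom-role assignment rules
#'
#' Role labeling drives every downstream selection: protein alpha-carbons
#' (`PROTEIN_CA`), the four porphyrin nitrogens of the heme (`PORPHYRIN_N`),
#' the lipid C1 carbons that define the leaflet reference plane (`LIPID_C1`),
#' and ligand heavy atoms (`LIGAND_HEAVY`). Anything unmatched becomes
#' `OTHER`. Rules are matched in the order given; the first match wins, so
#' roles always form a partition of the atoms.
#'
#' @param ligand_resid residue names treated as ligand molecules.
#' @param lipid_resid residue names treated as membrane lipids.
#' @param heme_resid residue names treated as the heme group.
#' @return A named list of rules, one per role, each a list with character
#'   vectors `resid` and/or `elety` (atom-name patterns) to match.
#' @export
default_role_rules <- function(ligand_resid = c("LIG", "UNK", "MOL", "DRG"),
                               lipid_resid = c("POP", "POPC", "PC"),
                               heme_resid = c("HEM", "HEC", "HEA", "HEB")) {
  list(
    PORPHYRIN_N = list(resid = heme_resid, elety = c("NA", "NB", "NC", "ND")),
    LIPID_C1 = list(resid = lipid_resid, elety = "C1"),
    LIGAND_HEAVY = list(resid = ligand_resid, heavy_only = TRUE),
    PROTEIN_CA = list(resid = .standard_aa3, elety = "CA")
  )
}

.standard_aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                   "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                   "THR", "TRP", "TYR", "VAL")

#' Assign roles to the atoms of a parsed structure
#'
#' @param atom data frame with columns `elety`, `resid`, `elesy` (element).
#' @param rules role rules as produced by [default_role_rules()].
#' @return Character vector of roles, one per atom.
#' @keywords internal
assign_roles <- function(atom, rules = default_role_rules()) {
  role <- rep("OTHER", nrow(atom))
  elem <- atom$elesy
  for (r in names(rules)) {
    rule <- rules[[r]]
    hit <- rep(TRUE, nrow(atom))
    if (!is.null(rule$resid)) hit <- hit & atom$resid %in% rule$resid
    if (!is.null(rule$elety)) hit <- hit & atom$elety %in% rule$elety
    if (isTRUE(rule$heavy_only)) hit <- hit & toupper(elem) != "H"
    role[hit & role == "OTHER"] <- r
  }
  role
}

#' Read a PDB structure and label atom roles
#'
#' Parses a PDB file (via bio3d) and assigns each atom exactly one role used
#' by the analysis modules. Atoms that match no rule are labeled `OTHER`, so
#' the role counts always sum to the total atom count.
#'
#' @param path path to a PDB file.
#' @param rules role-assignment rules, see [default_role_rules()].
#' @param require_protein error when no `PROTEIN_CA` atom is found (default
#'   `TRUE`; a structure without a single alpha-carbon is not a protein
#'   system).
#' @return A `labeled_system`: data frame with columns `atom_id`, `atom_name`,
#'   `residue_number`, `residue_name`, `chain`, `element`, `role`, plus an
#'   `xyz` attribute holding the structure's coordinates (flat vector, Å).
#' @export
read_structure <- function(path, rules = default_role_rules(),
                           require_protein = TRUE) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("malformed PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  labeled_system_from_pdb(pdb, rules = rules, require_protein = require_protein)
}

#' @keywords internal
labeled_system_from_pdb <- function(pdb, rules = default_role_rules(),
                                    require_protein = TRUE) {
  at <- pdb$atom
  elem <- at$elesy
  # fall back to first alphabetic character of the atom name when the
  # element column is blank (common in minimal or generated PDB files)
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", at$elety[blank])), 1, 1)
  at$elesy <- trimws(elem)
  role <- assign_roles(at, rules)
  if (require_protein && !any(role == "PROTEIN_CA")) {
    stop("role labeling found no PROTEIN_CA atoms; check the role rules ",
         "against the structure's residue and atom names", call. = FALSE)
  }
  sys <- data.frame(
    atom_id = seq_len(nrow(at)),
    atom_name = at$elety,
    residue_number = at$resno,
    residue_name = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    element = at$elesy,
    role = role,
    stringsAsFactors = FALSE
  )
  class(sys) <- c("labeled_system", "data.frame")
  attr(sys, "xyz") <- as.numeric(pdb$xyz[1, , drop = TRUE])
  sys
}

#' Indices of atoms with a given role
#'
#' @param system a `labeled_system`.
#' @param role one of `PROTEIN_CA`, `PORPHYRIN_N`, `LIPID_C1`,
#'   `LIGAND_HEAVY`, `OTHER`.
#' @return Integer atom indices.
#' @export
role_indices <- function(system, role) {
  which(system$role == role)
}

#' @export
print.labeled_system <- function(x, ...) {
  cat("Labeled system:", nrow(x), "atoms\n")
  print(table(x$role))
  invisible(x)
}

#' Read a trajectory against a labeled system
#'
#' Accepts a multi-model PDB or a DCD file. Coordinates are returned in Å in
#' the bio3d layout (one row per frame, columns x1,y1,z1,x2,...). The atom
#' count of every frame must match the system; a truncated or inconsistent
#' file raises an error rather than returning a silently short read.
#'
#' @param path trajectory file (multi-model PDB or DCD).
#' @param system the `labeled_system` describing the topology.
#' @param frame_interval_ps time between stored frames, picoseconds.
#' @param format `"auto"` (by extension), `"pdb"` or `"dcd"`.
#' @return A `labeled_trajectory`: list with `system`, `xyz` (frames x 3N
#'   matrix), `frame_interval_ps`.
#' @export
read_trajectory <- function(path, system, frame_interval_ps = 50,
                            format = c("auto", "pdb", "dcd")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  }
  natom <- nrow(system)
  if (format == "dcd") {
    xyz <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                    error = function(e) stop("failed to read DCD '", path,
                                             "': ", conditionMessage(e),
                                             call. = FALSE))
  } else {
    n_model <- length(grep("^MODEL", readLines(path)))
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                    error = function(e) stop("failed to read multi-model PDB '",
                                             path, "': ", conditionMessage(e),
                                             call. = FALSE))
    xyz <- pdb$xyz
    if (n_model > 0 && nrow(xyz) != n_model) {
      stop("trajectory '", path, "' is truncated: ", n_model,
           " MODEL records but ", nrow(xyz), " complete frames", call. = FALSE)
    }
  }
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * natom) {
    stop("atom-count mismatch: trajectory has ", ncol(xyz) / 3,
         " atoms per frame, system has ", natom, call. = FALSE)
  }
  labeled_trajectory(system, xyz, frame_interval_ps)
}

#' Construct a labeled trajectory
#'
#' @param system a `labeled_system`.
#' @param xyz numeric matrix, one row per frame, 3N columns (Å).
#' @param frame_interval_ps time between frames (ps), must be positive.
#' @return A `labeled_trajectory` object.
#' @export
labeled_trajectory <- function(system, xyz, frame_interval_ps = 50) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  stopifnot(ncol(xyz) == 3 * nrow(system))
  if (!is.numeric(frame_interval_ps) || frame_interval_ps <= 0) {
    stop("frame_interval_ps must be positive", call. = FALSE)
  }
  structure(list(system = system, xyz = xyz,
                 frame_interval_ps = frame_interval_ps),
            class = "labeled_trajectory")
}

#' @export
print.labeled_trajectory <- function(x, ...) {
  cat("Labeled trajectory:", nrow(x$xyz), "frames,",
      ncol(x$xyz) / 3, "atoms,", x$frame_interval_ps, "ps/frame\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `labeled_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame as an N x 3 matrix
#'
#' @param traj a `labeled_trajectory`.
#' @param frame frame index (1-based).
#' @param indices optional atom indices to extract.
#' @return Numeric matrix with one row per atom, columns x, y, z (Å).
#' @export
frame_coords <- function(traj, frame, indices = NULL) {
  v <- traj$xyz[frame, ]
  m <- matrix(v, ncol = 3, byrow = TRUE)
  if (!is.null(indices)) m <- m[indices, , drop = FALSE]
  m
}

#' Frame times in picoseconds
#'
#' Frame `i` is at time `(i - 1) * frame_interval_ps`, i.e. the first stored
#' frame is time zero.
#' @param traj a `labeled_trajectory`.
#' @return Numeric vector of times (ps).
#' @export
frame_times <- function(traj) {
  (seq_len(n_frames(traj)) - 1) * traj$frame_interval_ps
}

#' Write a labeled trajectory as a multi-model PDB
#'
#' @param traj a `labeled_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  sys <- traj$system
  bio3d::write.pdb(file = path, xyz = traj$xyz,
                   resno = sys$residue_number, resid = sys$residue_name,
                   eleno = sys$atom_id, elety = sys$atom_name,
                   chain = sys$chain)
  invisible(path)
}

#' Read a metadynamics hills file
#'
#' Reads a whitespace-delimited table of deposited Gaussians with columns
#' time (ps), center (Å), width (Å) and height (kcal/mol); any further
#' columns are ignored, and lines starting with `#` are comments. Rows are
#' returned sorted by time. Non-positive widths or heights are rejected with
#' the offending row number.
#'
#' @param path hills text file.
#' @return A `hills_table` (see [hills_table()]).
#' @export
read_hills <- function(path) {
  raw <- readLines(path)
  if (!any(nzchar(trimws(raw)) & !startsWith(trimws(raw), "#"))) {
    return(hills_table())   # empty (or comment-only) file: empty table
  }
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = paste0("V", 1:20), fill = TRUE)
  tab <- tab[, colSums(!is.na(tab)) > 0, drop = FALSE]
  if (ncol(tab) < 4) {
    stop("hills file '", path, "' needs at least 4 columns ",
         "(time, center, width, height); found ", ncol(tab), call. = FALSE)
  }
  h <- tab[, 1:4]
  names(h) <- c("time", "center", "width", "height")
  bad <- which(h$width <= 0 | h$height <= 0)
  if (length(bad) > 0) {
    stop("non-positive hill width/height at data row ", bad[1],
         " of '", path, "'", call. = FALSE)
  }
  hills_table(h$time, h$center, h$width, h$height)
}

#' Write a hills table to a whitespace-delimited text file
#'
#' @param hills a `hills_table` or data frame with columns time, center,
#'   width, height.
#' @param path output file.
#' @param header write a `#`-prefixed column header line.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path, header = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("# time center width height", con)
  if (nrow(hills) > 0) {
    utils::write.table(as.data.frame(hills)[, c("time", "center", "width", "height")],
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
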