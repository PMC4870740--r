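#' Generate a synthetic protein-ligand complex with exact C-X...A geometry
#'
#' Builds a minimal geometric probe: a ligand (HETATM records) carrying
#' one carbon-halogen bond, and a receptor (ATOM records) carrying one
#' acceptor atom placed so that the X...A distance and the C-X...A angle
#' equal the request to machine precision (1e-3 A / deg after PDB
#' coordinate rounding). Optional decoy atoms - extra ligand carbons and
#' receptor backbone carbons at least 6 A from the contact - exercise
#' pair enumeration without creating additional donors or acceptors.
#' These fixtures are geometric probes, not chemically realistic
#' molecules.
#'
#' Construction: the halogen sits at the origin with the carbon at
#' `(-cx_bond_length, 0, 0)`; the acceptor is placed in the xy-plane at
#' the requested distance and angle, then the whole complex can be
#' rigidly moved without changing any score.
#'
#' @param halogen `"Cl"`, `"Br"` or `"I"`.
#' @param acceptor `"O"`, `"N"` or `"S"`.
#' @param distance X...A distance, Angstroms.
#' @param theta C-X...A angle, degrees, in [0, 180].
#' @param cx_bond_length C-X bond length, Angstroms; default typical
#'   bond length per halogen (Cl 1.79, Br 1.94, I 2.13).
#' @param decoy_atoms number of decoy carbons added to each of ligand
#'   and receptor (default 3).
#' @param seed seed for decoy placement.
#' @return A list with elements `protein` and `ligand`, both
#'   [xbsf_structure]s.
#' @export
#' @examples
#' cx <- make_complex(halogen = "I", acceptor = "O",
#'                    distance = 3.354, theta = 177.8)
#' score_complex(cx$protein, cx$ligand)
make_complex <- function(halogen = "I", acceptor = "O",
                         distance = 3.354, theta = 177.8,
                         cx_bond_length = NULL, decoy_atoms = 3,
                         seed = 1) {
  stopifnot(halogen %in% c("Cl", "Br", "I"),
            acceptor %in% c("O", "N", "S"),
            distance > 0, decoy_atoms >= 0)
  if (!is.finite(theta) || theta < 0 || theta > 180)
    stop("infeasible geometry: theta must lie in [0, 180] degrees")
  if (is.null(cx_bond_length))
    cx_bond_length <- c(Cl = 1.79, Br = 1.94, I = 2.13)[[halogen]]

  X <- c(0, 0, 0)
  C <- c(-cx_bond_length, 0, 0)
  # angle between X->C = (-1,0,0) and X->A equals theta
  th <- theta * pi / 180
  A <- distance * c(-cos(th), sin(th), 0)

  decoys <- if (decoy_atoms > 0) {
    with_local_seed(seed, {
      pts <- matrix(NA_real_, 0, 3)
      while (nrow(pts) < 2 * decoy_atoms) {
        p <- random_unit_vector() * stats::runif(1, 8, 12)
        if (min(vec_norm(p - X), vec_norm(p - C), vec_norm(p - A)) >= 6)
          pts <- rbind(pts, p)
      }
      pts
    })
  } else matrix(NA_real_, 0, 3)

  lig_xyz <- rbind(C, X)
  lig_names <- c("C1", paste0(toupper(halogen), "1"))
  lig_el <- c("C", halogen)
  if (decoy_atoms > 0) {
    lig_xyz <- rbind(lig_xyz, decoys[seq_len(decoy_atoms), , drop = FALSE])
    lig_names <- c(lig_names, paste0("C", 1 + seq_len(decoy_atoms)))
    lig_el <- c(lig_el, rep("C", decoy_atoms))
  }
  ligand <- new_structure(lig_xyz, lig_names, lig_el, record = "HETATM",
                          resname = "LIG", chain = "L", resno = 1)

  acc_name <- c(O = "O", N = "N", S = "SG")[[acceptor]]
  prot_xyz <- matrix(A, 1, 3)
  prot_names <- acc_name
  prot_el <- acceptor
  if (decoy_atoms > 0) {
    prot_xyz <- rbind(prot_xyz,
                      decoys[decoy_atoms + seq_len(decoy_atoms), ,
                             drop = FALSE])
    prot_names <- c(prot_names, rep("CA", decoy_atoms))
    prot_el <- c(prot_el, rep("C", decoy_atoms))
  }
  protein <- new_structure(prot_xyz, prot_names, prot_el, record = "ATOM",
                           resname = "GLY", chain = "A",
                           resno = seq_len(nrow(prot_xyz)))
  list(protein = protein, ligand = ligand)
}

new_structure <- function(xyz, names, elements, record, resname, chain,
                          resno) {
  n <- nrow(xyz)
  atoms <- data.frame(
    serial = seq_len(n), name = names, altloc = " ",
    resname = rep_len(resname, n), chain = rep_len(chain, n),
    resno = rep_len(resno, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b = 0, record = rep_len(record, n),
    element = elements, stringsAsFactors = FALSE)
  atoms$is_water <- atoms$resname %in% WATER_RESNAMES
  structure(list(atoms = atoms, model_id = 1L, resolution = NA_real_),
            class = "xbsf_structure")
}

#' Generate a rigidly perturbed pose set from a fixture geometry
#'
#' Pose 1 is the exact requested geometry (identical to the
#' [make_complex()] ligand); each subsequent pose is a rigid copy,
#' rotated by a small random angle about its centroid and translated by
#' exactly `perturbation` Angstroms in a uniformly random direction.
#' Deterministic under `seed`.
#'
#' @param n_poses number of poses (>= 1).
#' @param perturbation rigid displacement magnitude, Angstroms.
#' @param seed RNG seed for the perturbations.
#' @param max_rotation maximum rotation angle about the centroid,
#'   degrees.
#' @param ... geometry arguments passed to [make_complex()].
#' @return A list with `protein` (as in [make_complex()]) and `poses`, a
#'   list of ligand [xbsf_structure]s with `model_id` 1..n.
#' @export
make_pose_set <- function(n_poses, perturbation = 1, seed = 1,
                          max_rotation = 15, ...) {
  stopifnot(n_poses >= 1, perturbation >= 0)
  cx <- make_complex(...)
  base <- cx$ligand
  xyz0 <- as.matrix(base$atoms[, c("x", "y", "z")])
  centroid <- colMeans(xyz0)
  poses <- with_local_seed(seed, lapply(seq_len(n_poses), function(i) {
    s <- base
    s$model_id <- i
    if (i > 1 && (perturbation > 0 || max_rotation > 0)) {
      R <- rotation_matrix(random_unit_vector(),
                           stats::runif(1, 0, max_rotation))
      shift <- random_unit_vector() * perturbation
      xyz <- t(R %*% t(sweep(xyz0, 2, centroid))) +
        matrix(centroid + shift, nrow(xyz0), 3, byrow = TRUE)
      s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
    }
    s
  }))
  list(protein = cx$protein, poses = poses)
}

#' Rigidly transform a structure
#'
#' Applies `x -> R x + t` to every atom. Used for invariance checks and
#' pose manipulation.
#'
#' @param structure an [xbsf_structure].
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation length-3 translation vector, Angstroms.
#' @return The transformed structure.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- t(rotation %*% t(xyz)) + matrix(translation, nrow(xyz), 3,
                                         byrow = TRUE)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Measure the C-X...A geometry of a complex
#'
#' Re-measures the X...A distance and C-X...A angle of the first
#' halogen site against the nearest acceptor; the inverse of
#' [make_complex()], used for round-trip checks.
#'
#' @param protein,ligand [xbsf_structure]s.
#' @param params an [xbsf_params()] set.
#' @return A list with `distance` (A) and `theta` (degrees), or `NULL`
#'   when there is no halogen site or acceptor.
#' @export
measure_geometry <- function(protein, ligand, params = xbsf_params()) {
  sites <- find_halogen_sites(ligand, params)
  acc <- find_acceptors(protein, include_waters = TRUE)
  if (nrow(sites) == 0 || nrow(acc) == 0) return(NULL)
  X <- as.numeric(ligand$atoms[sites$hal_idx[1], c("x", "y", "z")])
  C <- as.numeric(ligand$atoms[sites$carbon_idx[1], c("x", "y", "z")])
  axyz <- as.matrix(acc[, c("x", "y", "z")])
  d <- sqrt(colSums((t(axyz) - X)^2))
  j <- which.min(d)
  list(distance = d[j], theta = point_angle(C, X, axyz[j, ]))
}
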