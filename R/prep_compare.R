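#' Compute a docking grid box around a ligand
#'
#' The box size per axis is the ligand's coordinate extent
#' (max - min) plus a total padding (default 15 A per axis); the center
#' is the midpoint of the extent. When a seed is given, the center is
#' additionally shifted per axis by an independently drawn value from
#' {-s, 0, +s} (default s = 2.5 A, equal probability), so repeated runs
#' with the same seed give a bitwise-identical box; `seed = NULL` applies
#' no shift. The randomized shift de-biases comparisons that would
#' otherwise depend on perfect box centering.
#'
#' @param ligand an [xbsf_structure] with at least one atom.
#' @param padding_total total padding added per axis, Angstroms.
#' @param shift_magnitude per-axis shift step, Angstroms.
#' @param seed integer seed for the shift draw, or `NULL` for no shift.
#' @return An object of class `xbsf_gridbox`: list with `center`, `size`,
#'   `shift_applied` (each a named xyz vector, Angstroms) and `seed`.
#' @export
#' @examples
#' cx <- make_complex()
#' compute_grid_box(cx$ligand)             # centered, no shift
#' compute_grid_box(cx$ligand, seed = 42)  # reproducible shifted box
compute_grid_box <- function(ligand, padding_total = 15,
                             shift_magnitude = 2.5, seed = NULL) {
  atoms <- ligand$atoms
  if (is.null(atoms) || nrow(atoms) == 0)
    stop("ligand structure has no atoms")
  stopifnot(padding_total >= 0, shift_magnitude >= 0)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  mins <- apply(xyz, 2, min)
  maxs <- apply(xyz, 2, max)
  size <- (maxs - mins) + padding_total
  center <- (maxs + mins) / 2
  shift <- c(x = 0, y = 0, z = 0)
  if (!is.null(seed)) {
    steps <- with_local_seed(seed,
      sample(c(-1, 0, 1), 3, replace = TRUE))
    shift <- stats::setNames(steps * shift_magnitude, c("x", "y", "z"))
  }
  structure(list(center = center + shift, size = size,
                 shift_applied = shift,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "xbsf_gridbox")
}

#' @export
print.xbsf_gridbox <- function(x, ...) {
  cat(sprintf("grid box: center (%.3f, %.3f, %.3f), size (%.3f, %.3f, %.3f) A\n",
              x$center[1], x$center[2], x$center[3],
              x$size[1], x$size[2], x$size[3]))
  if (any(x$shift_applied != 0))
    cat(sprintf("  shift applied: (%.1f, %.1f, %.1f) A [seed %d]\n",
                x$shift_applied[1], x$shift_applied[2], x$shift_applied[3],
                x$seed))
  invisible(x)
}

#' Write a docking config file for a grid box
#'
#' Emits the conventional key = value docking configuration (receptor,
#' ligand, seed, center_x/y/z, size_x/y/z).
#'
#' @param box an `xbsf_gridbox`.
#' @param path output path.
#' @param receptor,ligand file names recorded in the config.
#' @param seed search seed recorded in the config (defaults to the box
#'   seed when available).
#' @return `path`, invisibly.
#' @export
write_vina_config <- function(box, path, receptor = "receptor.pdbqt",
                              ligand = "ligand.pdbqt", seed = box$seed) {
  stopifnot(inherits(box, "xbsf_gridbox"))
  lines <- c(
    paste0("receptor = ", receptor),
    paste0("ligand = ", ligand),
    if (!is.na(seed)) paste0("seed = ", seed),
    sprintf("center_x = %.3f", box$center[1]),
    sprintf("center_y = %.3f", box$center[2]),
    sprintf("center_z = %.3f", box$center[3]),
    sprintf("size_x = %.3f", box$size[1]),
    sprintf("size_y = %.3f", box$size[2]),
    sprintf("size_z = %.3f", box$size[3]))
  writeLines(lines, path)
  invisible(path)
}

# Shortest-augmenting-path solution of the square assignment problem
# (minimize sum of cost[i, perm[i]]); returns the column permutation.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cur <- cost[i0, j - 1] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) perm[p[j]] <- j - 1L
  perm
}

heavy_atoms <- function(structure) {
  structure$atoms[structure$atoms$element != "H", , drop = FALSE]
}

#' In-place heavy-atom RMSD between two poses
#'
#' Root-mean-square deviation over heavy atoms without superposition
#' (docking-pose convention: poses live in the receptor frame, so
#' alignment would hide real displacement) and without symmetry
#' correction. By default atoms are matched by order, with a name check;
#' `match = "element"` instead solves, within each element, the optimal
#' (minimum-RMSD) assignment, for pose files whose writers reorder
#' atoms.
#'
#' @param reference,pose two [xbsf_structure]s with the same heavy-atom
#'   composition.
#' @param match `"order"` (name-checked positional matching, default) or
#'   `"element"` (optimal per-element assignment).
#' @return RMSD in Angstroms (0 for identical coordinates).
#' @export
#' @examples
#' cx <- make_complex()
#' pose_rmsd(cx$ligand, cx$ligand)  # 0
pose_rmsd <- function(reference, pose, match = c("order", "element")) {
  match <- match.arg(match)
  a <- heavy_atoms(reference)
  b <- heavy_atoms(pose)
  if (nrow(a) != nrow(b))
    stop("heavy-atom count mismatch: reference has ", nrow(a),
         ", pose has ", nrow(b))
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  if (match == "order") {
    bad <- which(a$name != b$name)
    if (length(bad) > 0)
      stop("atom name mismatch at position ", bad[1], ": reference '",
           a$name[bad[1]], "' vs pose '", b$name[bad[1]], "'")
    return(sqrt(mean(rowSums((A - B)^2))))
  }
  # element-wise optimal assignment on squared distances
  if (!identical(sort(a$element), sort(b$element)))
    stop("element composition mismatch between reference and pose")
  ss <- 0
  for (el in unique(a$element)) {
    ia <- which(a$element == el)
    ib <- which(b$element == el)
    cost <- outer(ia, ib, function(i, j)
      rowSums((A[i, , drop = FALSE] - B[j, , drop = FALSE])^2))
    cost <- matrix(cost, length(ia), length(ib))
    perm <- solve_assignment(cost)
    ss <- ss + sum(cost[cbind(seq_along(ia), perm)])
  }
  sqrt(ss / nrow(a))
}

#' Rescore a set of docked poses against a receptor
#'
#' For each pose: the halogen-bond energy and nonzero-contact count from
#' [score_complex()], plus the in-place heavy-atom RMSD to a reference
#' (native) ligand when one is given. This supports the
#' best-pose-vs-native comparison workflow used to judge docking
#' accuracy.
#'
#' @param protein receptor [xbsf_structure].
#' @param poses list of ligand [xbsf_structure]s (e.g. from a
#'   multi-MODEL pose file parsed with [parse_structure()]).
#' @param reference native ligand [xbsf_structure], or `NULL`.
#' @param include_waters passed to [score_complex()].
#' @param params an [xbsf_params()] set.
#' @return A data frame ordered by pose index: `pose_index`,
#'   `rmsd_to_reference` (NA when no reference), `xb_energy`,
#'   `n_xb_contacts`.
#' @export
rescore_poses <- function(protein, poses, reference = NULL,
                          include_waters = FALSE, params = xbsf_params()) {
  if (inherits(poses, "xbsf_structure")) poses <- list(poses)
  stopifnot(length(poses) >= 1)
  rows <- lapply(seq_along(poses), function(i) {
    sc <- score_complex(protein, poses[[i]],
                        include_waters = include_waters, params = params)
    data.frame(
      pose_index = i,
      rmsd_to_reference = if (is.null(reference)) NA_real_ else
        pose_rmsd(reference, poses[[i]]),
      xb_energy = sc$total,
      n_xb_contacts = nrow(sc$interactions))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
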