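#' Sigma-hole angle factor
#'
#' The positive sigma-hole charge on a carbon-bonded halogen is strongest
#' when the C-X...A angle \eqn{\Theta} is 180 degrees and decays as the
#' acceptor moves off-axis, crossing zero at the halogen-specific
#' electroneutral angle \eqn{\Theta_0} (Cl 146, Br 126, I 122 degrees).
#' The effective charge is \eqn{Z = A cos(\nu\alpha) + B} with
#' \eqn{\alpha = 180 - \Theta}, and the angle factor is the normalized
#' charge
#' \deqn{\Phi = Z_\Theta / Z_{180} \quad for \; \Theta_0 \le \Theta \le 180,
#'   \qquad \Phi = 0 \; otherwise.}
#' With the default coefficients this is
#' \eqn{(\cos\alpha - \cos\alpha_0) / (1 - \cos\alpha_0)}, which is 1 at
#' 180 degrees, exactly 0 at \eqn{\Theta_0}, and monotone in between.
#'
#' @param theta C-X...A angle(s), degrees, in [0, 180]. Vectorized.
#' @param halogen `"Cl"`, `"Br"` or `"I"`.
#' @param params an [xbsf_params()] set.
#' @return \eqn{\Phi} in [0, 1], same length as `theta`.
#' @export
#' @examples
#' angle_factor(177.8, "I")   # 0.998 to three decimals
#' angle_factor(180, "Cl")    # exactly 1
#' angle_factor(146, "Cl")    # exactly 0 (electroneutral angle)
angle_factor <- function(theta, halogen, params = xbsf_params()) {
  h <- halogen_params(halogen, params)
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 180))
    stop("theta must lie in [0, 180] degrees")
  ch <- h$charge
  z <- function(th) ch$A * cospi(ch$nu * (180 - th) / 180) + ch$B
  z180 <- z(180)
  if (z180 <= 0) stop("charge model gives non-positive Z at 180 degrees")
  phi <- z(theta) / z180
  phi[theta < h$theta0] <- 0
  pmin(1, pmax(0, phi))
}

halogen_params <- function(halogen, params) {
  validate_params(params)
  if (length(halogen) != 1 || !halogen %in% names(params$halogens))
    stop("halogen must be one of ", paste(names(params$halogens),
                                          collapse = ", "),
         " (got ", paste(halogen, collapse = ","), ")")
  params$halogens[[halogen]]
}

# delta (A) for one halogen at a vector of angles, honouring the
# extension policy for angles below the lowest tabulated range.
delta_lookup <- function(theta, halogen, params) {
  h <- halogen_params(halogen, params)
  tab <- h$delta
  out <- rep(NA_real_, length(theta))
  for (i in seq_len(nrow(tab))) {
    inbin <- theta >= tab$low[i] & (theta < tab$high[i] | tab$high[i] == 180)
    out[inbin] <- tab$delta[i]
  }
  below <- is.na(out) & theta < min(tab$low)
  out[below] <- if (params$delta_extension == "extend")
    tab$delta[nrow(tab)] else 0
  out
}

#' Polar-flattening distance factor
#'
#' The signed van der Waals overlap is
#' \eqn{d = |X...A| - (r_X + r_A)}; negative d means interpenetrating
#' radii. The distance factor D is 1 when \eqn{d \le -\delta}, 0 when
#' \eqn{d \ge 0}, and linearly interpolated in between. The saturation
#' depth \eqn{\delta} depends on both the halogen and the C-X...A angle
#' (three 15-degree ranges, 165-180 / 150-165 / 135-150), shrinking as
#' the acceptor approaches the flattened sigma-hole axis: this encodes
#' the aspherical (polar-flattened) halogen shape seen in surveyed
#' crystal-structure contact distances.
#'
#' @param distance X...A internuclear distance(s), Angstroms. Vectorized
#'   (recycled against `theta`).
#' @param theta C-X...A angle(s), degrees.
#' @param halogen `"Cl"`, `"Br"` or `"I"`.
#' @param acceptor acceptor element, `"O"`, `"N"` or `"S"`.
#' @param params an [xbsf_params()] set.
#' @return D in [0, 1].
#' @export
#' @examples
#' distance_factor(3.354, 177.8, "I", "O")  # 0.993 to three decimals
#' distance_factor(3.90, 175, "I", "O")     # 0: zero overlap (r_I + r_O)
distance_factor <- function(distance, theta, halogen, acceptor,
                            params = xbsf_params()) {
  h <- halogen_params(halogen, params)
  if (length(acceptor) != 1 || !acceptor %in% names(params$acceptors))
    stop("acceptor must be one of ", paste(names(params$acceptors),
                                           collapse = ", "))
  if (any(distance <= 0)) stop("distance must be positive")
  if (any(theta < 0) || any(theta > 180))
    stop("theta must lie in [0, 180] degrees")
  d <- distance - (h$vdw + params$acceptors[[acceptor]])
  d[abs(d) < 1e-9] <- 0  # snap the zero-overlap boundary (FP-safe)
  delta <- delta_lookup(rep_len(theta, length(d)), halogen, params)
  dfac <- ifelse(delta > 0, -d / delta, 0)
  dfac[d <= -delta & delta > 0] <- 1
  dfac[d >= 0] <- 0
  pmin(1, pmax(0, dfac))
}

#' Per-halogen energy weight
#'
#' The depth of the halogen-bond energy well per halogen: Cl -0.265,
#' Br -0.32, I -0.4 (dimensionless scoring-function units). Fluorine is
#' not a halogen-bond donor and is rejected.
#'
#' @inheritParams angle_factor
#' @return W (negative scalar).
#' @export
halogen_weight <- function(halogen, params = xbsf_params()) {
  halogen_params(halogen, params)$weight
}

#' Score one C-X...A interaction
#'
#' Evaluates the halogen-bond energy \eqn{E = W \Phi D} for a single
#' candidate interaction given its internuclear distance and C-X...A
#' angle, returning the individual terms alongside.
#'
#' @param halogen donor halogen element.
#' @param acceptor acceptor element.
#' @param distance X...A distance, Angstroms.
#' @param theta C-X...A angle, degrees.
#' @param params an [xbsf_params()] set.
#' @return A one-row data frame: `halogen`, `acceptor`, `distance`,
#'   `theta`, `phi`, `dfac`, `weight`, `pre_weight` (\eqn{\Phi D}) and
#'   `energy`.
#' @export
#' @examples
#' score_interaction("I", "O", 3.354, 177.8)
score_interaction <- function(halogen, acceptor, distance, theta,
                              params = xbsf_params()) {
  phi <- angle_factor(theta, halogen, params)
  dfac <- distance_factor(distance, theta, halogen, acceptor, params)
  w <- halogen_weight(halogen, params)
  data.frame(halogen = halogen, acceptor = acceptor,
             distance = distance, theta = theta,
             phi = phi, dfac = dfac, weight = w,
             pre_weight = phi * dfac, energy = w * phi * dfac,
             stringsAsFactors = FALSE)
}

#' Score all halogen bonds of a protein-ligand complex
#'
#' Enumerates every (C-X donor site, acceptor) pair between the ligand's
#' halogens and the receptor's O/N/S atoms, measures the X...A distance
#' and C-X...A angle, and evaluates \eqn{E = W \Phi D} for each. Pairs
#' with zero energy (acceptor outside the radii-overlap window or below
#' the electroneutral angle) are dropped from the table but the total is
#' an exact sum of the retained terms. Non-halogenated ligands score
#' exactly zero.
#'
#' @param protein receptor [xbsf_structure].
#' @param ligand ligand [xbsf_structure] (one pose).
#' @param include_waters pass water oxygens as acceptors?
#' @param include_hetatm pass receptor HETATM O/N/S as acceptors?
#' @param params an [xbsf_params()] set.
#' @return An object of class `xbsf_score`: list with `interactions` (one
#'   row per nonzero pair, ordered by halogen serial then acceptor
#'   serial, with residue/atom context columns) and `total` (sum of
#'   energies).
#' @export
score_complex <- function(protein, ligand, include_waters = FALSE,
                          include_hetatm = TRUE, params = xbsf_params()) {
  sites <- find_halogen_sites(ligand, params)
  acc <- find_acceptors(protein, include_waters, include_hetatm)
  cols <- c("hal_serial", "hal_name", "hal_element", "carbon_serial",
            "acc_serial", "acc_name", "acc_element", "acc_resname",
            "acc_resno", "acc_chain", "distance", "theta",
            "phi", "dfac", "weight", "pre_weight", "energy")
  empty <- as.data.frame(stats::setNames(
    lapply(cols, function(nm)
      if (nm %in% c("hal_name", "hal_element", "acc_name", "acc_element",
                    "acc_resname", "acc_chain")) character() else numeric()),
    cols))
  if (nrow(sites) == 0 || nrow(acc) == 0)
    return(structure(list(interactions = empty, total = 0),
                     class = "xbsf_score"))

  lat <- ligand$atoms
  axyz <- as.matrix(acc[, c("x", "y", "z")])
  rows <- vector("list", nrow(sites) * nrow(acc))
  k <- 0L
  for (i in seq_len(nrow(sites))) {
    X <- as.numeric(lat[sites$hal_idx[i], c("x", "y", "z")])
    C <- as.numeric(lat[sites$carbon_idx[i], c("x", "y", "z")])
    el <- sites$element[i]
    w <- halogen_weight(el, params)
    dist <- sqrt(colSums((t(axyz) - X)^2))
    for (j in seq_len(nrow(acc))) {
      theta <- point_angle(C, X, axyz[j, ])
      phi <- angle_factor(theta, el, params)
      if (phi == 0) next
      dfac <- distance_factor(dist[j], theta, el, acc$element[j], params)
      if (dfac == 0) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        hal_serial = sites$hal_serial[i],
        hal_name = lat$name[sites$hal_idx[i]],
        hal_element = el,
        carbon_serial = sites$carbon_serial[i],
        acc_serial = acc$serial[j], acc_name = acc$name[j],
        acc_element = acc$element[j], acc_resname = acc$resname[j],
        acc_resno = acc$resno[j], acc_chain = acc$chain[j],
        distance = dist[j], theta = theta, phi = phi, dfac = dfac,
        weight = w, pre_weight = phi * dfac, energy = w * phi * dfac,
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(structure(list(interactions = empty, total = 0),
                     class = "xbsf_score"))
  tab <- do.call(rbind, rows[seq_len(k)])
  tab <- tab[order(tab$hal_serial, tab$acc_serial), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(interactions = tab, total = sum(tab$energy)),
            class = "xbsf_score")
}

#' @export
print.xbsf_score <- function(x, digits = 3, ...) {
  n <- nrow(x$interactions)
  cat(sprintf("XBSF halogen-bond score: %d interaction%s, total energy %.4f\n",
              n, if (n == 1) "" else "s", x$total))
  if (n > 0) {
    t2 <- x$interactions
    t2$distance <- round(t2$distance, digits)
    t2$theta <- round(t2$theta, 1)
    for (cc in c("phi", "dfac", "pre_weight", "energy"))
      t2[[cc]] <- round(t2[[cc]], digits)
    print(t2[, c("hal_element", "hal_serial", "acc_resname", "acc_resno",
                 "acc_name", "distance", "theta", "phi", "dfac",
                 "pre_weight", "energy")], row.names = FALSE)
  }
  invisible(x)
}
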