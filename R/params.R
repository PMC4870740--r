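#' XBSF parameter set
#'
#' Returns the shipped parameter set of the halogen-bond scoring function:
#' per-halogen energy weights W, electroneutral angles \eqn{\Theta_0}, van
#' der Waals radii, the angle-ranged polar-flattening overlap table
#' (\eqn{\delta}), acceptor radii, C--X covalent-bond cutoffs used for
#' donor detection, and the sigma-hole effective-charge model behind the
#' angle factor.
#'
#' The defaults are, per halogen:
#' \itemize{
#'   \item Cl: W = -0.265, \eqn{\Theta_0} = 146 deg, r = 1.8 A,
#'     \eqn{\delta} = 0.25 A (165--180 deg), 0.15 A (150--165 deg)
#'   \item Br: W = -0.32, \eqn{\Theta_0} = 126 deg, r = 2.02 A,
#'     \eqn{\delta} = 0.45 / 0.35 / 0.25 A for the 165--180 / 150--165 /
#'     135--150 deg ranges
#'   \item I: W = -0.4, \eqn{\Theta_0} = 122 deg, r = 2.2 A,
#'     \eqn{\delta} = 0.55 / 0.45 / 0.35 A for the same ranges
#' }
#' Acceptor radii: O 1.7 A, N 1.8 A, S 2.0 A (sulfur uses the conventional
#' value; it is not part of the published radii table and can be edited in
#' the config). All acceptors are equally weighted.
#'
#' The effective surface charge on the halogen at C--X...A angle
#' \eqn{\Theta} is modelled as \eqn{Z = A cos(\nu\alpha) + B} with
#' \eqn{\alpha = 180 - \Theta}. By default \eqn{A = 1}, \eqn{\nu = 1} and
#' \eqn{B = -cos(180 - \Theta_0)}, i.e. the cosine is shifted so that the
#' charge crosses zero exactly at the electroneutral angle; the angle
#' factor \eqn{\Phi = Z_\Theta / Z_{180}} is then a normalized cosine.
#' Users holding calibrated \eqn{(A, B, \nu)} coefficients can override
#' them per halogen via `charge` or in a YAML config file.
#'
#' @param delta_extension how the distance factor picks \eqn{\delta} for
#'   angles below the lowest tabulated range of a halogen (e.g. chlorine
#'   between its electroneutral angle 146 deg and the 150 deg bin edge):
#'   `"extend"` (default) reuses the halogen's lowest tabulated
#'   \eqn{\delta}; `"zero"` forces D = 0 there.
#' @param sulfur_radius van der Waals radius assigned to sulfur acceptors, A.
#' @param charge optional named list of per-halogen effective-charge
#'   coefficient overrides, e.g. `list(I = list(A = 1.2, B = -0.5, nu = 1))`.
#'
#' @return An object of class `xbsf_params`.
#' @seealso [read_xbsf_params()], [write_xbsf_params()]
#' @export
#' @examples
#' p <- xbsf_params()
#' p$halogens$I$weight     # -0.4
#' p$halogens$Cl$theta0    # 146
xbsf_params <- function(delta_extension = c("extend", "zero"),
                        sulfur_radius = 2.0,
                        charge = NULL) {
  delta_extension <- match.arg(delta_extension)
  stopifnot(is.numeric(sulfur_radius), length(sulfur_radius) == 1L,
            sulfur_radius > 0)
  halogens <- list(
    Cl = list(
      weight = -0.265, theta0 = 146, vdw = 1.8,
      delta = data.frame(low = c(165, 150), high = c(180, 165),
                         delta = c(0.25, 0.15))
    ),
    Br = list(
      weight = -0.32, theta0 = 126, vdw = 2.02,
      delta = data.frame(low = c(165, 150, 135), high = c(180, 165, 150),
                         delta = c(0.45, 0.35, 0.25))
    ),
    I = list(
      weight = -0.4, theta0 = 122, vdw = 2.2,
      delta = data.frame(low = c(165, 150, 135), high = c(180, 165, 150),
                         delta = c(0.55, 0.45, 0.35))
    )
  )
  for (el in names(halogens)) {
    halogens[[el]]$charge <- list(A = 1, nu = 1,
                                  B = -cospi((180 - halogens[[el]]$theta0) / 180))
    if (!is.null(charge[[el]])) {
      ov <- charge[[el]]
      stopifnot(all(names(ov) %in% c("A", "B", "nu")))
      halogens[[el]]$charge[names(ov)] <- ov
    }
  }
  structure(list(
    halogens = halogens,
    acceptors = c(O = 1.7, N = 1.8, S = sulfur_radius),
    covalent_cutoff = c(Cl = 2.1, Br = 2.2, I = 2.4),
    delta_extension = delta_extension
  ), class = "xbsf_params")
}

#' @export
print.xbsf_params <- function(x, ...) {
  cat("XBSF parameter set\n")
  for (el in names(x$halogens)) {
    h <- x$halogens[[el]]
    cat(sprintf("  %-2s  W = %+.3f  theta0 = %g deg  r = %g A  delta(A): %s\n",
                el, h$weight, h$theta0, h$vdw,
                paste(sprintf("[%g,%g)=%g", h$delta$low, h$delta$high,
                              h$delta$delta), collapse = " ")))
  }
  cat("  acceptor radii (A):",
      paste(names(x$acceptors), x$acceptors, sep = "=", collapse = " "), "\n")
  cat("  delta extension below lowest bin:", x$delta_extension, "\n")
  invisible(x)
}

validate_params <- function(params) {
  stopifnot(inherits(params, "xbsf_params"))
  for (el in names(params$halogens)) {
    h <- params$halogens[[el]]
    stopifnot(h$weight < 0, h$theta0 > 90, h$theta0 < 180,
              h$vdw > 0, all(diff(h$delta$delta) < 0))
  }
  stopifnot(all(params$acceptors > 0))
  invisible(params)
}

#' Write an XBSF parameter set to a YAML config file
#'
#' Serializes the full parameter set (weights, electroneutral angles,
#' radii, delta table, charge-model coefficients, covalent cutoffs) as
#' human-editable YAML. [read_xbsf_params()] restores it exactly.
#'
#' @param params an `xbsf_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xbsf_params <- function(params, path) {
  validate_params(params)
  out <- list(
    halogens = lapply(params$halogens, function(h) list(
      weight = h$weight, theta0 = h$theta0, vdw = h$vdw,
      delta = lapply(seq_len(nrow(h$delta)), function(i)
        list(low = h$delta$low[i], high = h$delta$high[i],
             delta = h$delta$delta[i])),
      charge = h$charge
    )),
    acceptors = as.list(params$acceptors),
    covalent_cutoff = as.list(params$covalent_cutoff),
    delta_extension = params$delta_extension
  )
  yaml::write_yaml(out, path, precision = 12L)
  invisible(path)
}

#' Read an XBSF parameter set from a YAML config file
#'
#' @param path a YAML file written by [write_xbsf_params()] (or edited by
#'   hand in the same layout).
#' @return An `xbsf_params` object.
#' @export
read_xbsf_params <- function(path) {
  raw <- yaml::read_yaml(path)
  halogens <- lapply(raw$halogens, function(h) {
    d <- do.call(rbind, lapply(h$delta, as.data.frame))
    list(weight = h$weight, theta0 = h$theta0, vdw = h$vdw,
         delta = d[, c("low", "high", "delta")],
         charge = h$charge)
  })
  params <- structure(list(
    halogens = halogens,
    acceptors = unlist(raw$acceptors),
    covalent_cutoff = unlist(raw$covalent_cutoff),
    delta_extension = raw$delta_extension
  ), class = "xbsf_params")
  validate_params(params)
}
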