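#' Mine C-X...A contact geometries from structures
#'
#' Enumerates every (halogen site, acceptor) pair within a distance
#' cutoff and above a minimum C-X...A angle, one record per pair. Input
#' is either a list of `list(protein = , ligand = )` pairs or a single
#' mixed structure, in which case HETATM records (excluding waters) are
#' treated as the ligand and ATOM records as the receptor. Structures
#' whose recorded crystallographic resolution exceeds
#' `resolution_cutoff` contribute nothing (structures with unknown
#' resolution are kept).
#'
#' @param x a list of `list(protein, ligand)` pairs (optionally named by
#'   source id), a single such pair, or one mixed [xbsf_structure].
#' @param max_distance maximum X...A distance, Angstroms (default 4.5).
#' @param min_theta minimum C-X...A angle, degrees (default 120).
#' @param resolution_cutoff keep only structures at this resolution (A)
#'   or better; `NULL` disables the filter.
#' @param include_waters count water oxygens as acceptors?
#' @param params an [xbsf_params()] set (for donor-site detection).
#' @return A data frame of contact records: `source_id`,
#'   `halogen_element`, `acceptor_element`, `distance_XA`, `theta`,
#'   `acceptor_context` (residue name + atom name, e.g. `"VAL O"`).
#' @export
mine_contacts <- function(x, max_distance = 4.5, min_theta = 120,
                          resolution_cutoff = NULL,
                          include_waters = FALSE,
                          params = xbsf_params()) {
  stopifnot(max_distance > 0, min_theta >= 0, min_theta <= 180)
  pairs <- as_complex_list(x)
  empty <- data.frame(source_id = character(),
                      halogen_element = character(),
                      acceptor_element = character(),
                      distance_XA = numeric(), theta = numeric(),
                      acceptor_context = character(),
                      stringsAsFactors = FALSE)
  out <- lapply(names(pairs), function(id) {
    pr <- pairs[[id]]$protein
    lg <- pairs[[id]]$ligand
    if (!is.null(resolution_cutoff)) {
      res <- pr$resolution
      if (is.finite(res) && res > resolution_cutoff) return(NULL)
    }
    sites <- find_halogen_sites(lg, params)
    acc <- find_acceptors(pr, include_waters = include_waters)
    if (nrow(sites) == 0 || nrow(acc) == 0) return(NULL)
    axyz <- as.matrix(acc[, c("x", "y", "z")])
    recs <- lapply(seq_len(nrow(sites)), function(i) {
      X <- as.numeric(lg$atoms[sites$hal_idx[i], c("x", "y", "z")])
      C <- as.numeric(lg$atoms[sites$carbon_idx[i], c("x", "y", "z")])
      d <- sqrt(colSums((t(axyz) - X)^2))
      keep <- which(d <= max_distance)
      if (length(keep) == 0) return(NULL)
      th <- vapply(keep, function(j) point_angle(C, X, axyz[j, ]),
                   numeric(1))
      ok <- th >= min_theta
      if (!any(ok)) return(NULL)
      keep <- keep[ok]
      data.frame(source_id = id,
                 halogen_element = sites$element[i],
                 acceptor_element = acc$element[keep],
                 distance_XA = d[keep], theta = th[ok],
                 acceptor_context = paste(acc$resname[keep],
                                          acc$name[keep]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

# Normalize mine_contacts() input to a named list of protein/ligand pairs.
as_complex_list <- function(x) {
  if (inherits(x, "xbsf_structure")) {
    at <- x$atoms
    lig_rows <- at$record == "HETATM" & !at$is_water
    pairs <- list(structure_1 = list(
      protein = structure(list(atoms = at[!lig_rows, , drop = FALSE],
                               model_id = x$model_id,
                               resolution = x$resolution),
                          class = "xbsf_structure"),
      ligand = structure(list(atoms = at[lig_rows, , drop = FALSE],
                              model_id = x$model_id,
                              resolution = x$resolution),
                         class = "xbsf_structure")))
    return(pairs)
  }
  if (is.list(x) && !is.null(x$protein) && !is.null(x$ligand))
    x <- list(x)
  stopifnot(is.list(x), length(x) > 0)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- paste0("structure_", seq_along(x))
  x
}

#' Bin mined contacts into an angle/distance histogram
#'
#' Tallies contact records for one halogen/acceptor element pair over the
#' three 15-degree angle ranges (135-150, 150-165, 165-180; bins
#' half-open below, the top bin closed at 180) crossed with half-open
#' distance bins of the given width. Records outside [135, 180] degrees
#' or outside the distance range are excluded. This is the summary used
#' to read off how the preferred contact distance shifts with angle, i.e.
#' the polar-flattening signal behind the delta table.
#'
#' @param records a contact table from [mine_contacts()].
#' @param halogen,acceptor element pair to tally.
#' @param distance_bin_width bin width, Angstroms (default 0.1).
#' @param distance_range two-vector, Angstroms, outer edges of the
#'   distance axis (default `c(2.5, 4.5)`); widened outward to whole
#'   bins.
#' @return An object of class `xbsf_histogram`: data frame with columns
#'   `angle_bin` (factor, `"135-150"`, `"150-165"`, `"165-180"`),
#'   `distance_low`, `distance_high`, `count`.
#' @export
bin_contacts <- function(records, halogen, acceptor,
                         distance_bin_width = 0.1,
                         distance_range = c(2.5, 4.5)) {
  stopifnot(distance_bin_width > 0, length(distance_range) == 2,
            distance_range[2] > distance_range[1])
  w <- distance_bin_width
  lo <- floor(distance_range[1] / w) * w
  hi <- ceiling(distance_range[2] / w) * w
  edges <- seq(lo, hi, by = w)
  angle_lows <- c(135, 150, 165)
  labels <- c("135-150", "150-165", "165-180")

  grid <- expand.grid(bin = seq_len(length(edges) - 1),
                      angle = seq_along(angle_lows))
  hist <- data.frame(
    angle_bin = factor(labels[grid$angle], levels = labels),
    distance_low = edges[grid$bin],
    distance_high = edges[grid$bin + 1],
    count = 0L)

  sel <- records$halogen_element == halogen &
    records$acceptor_element == acceptor &
    records$theta >= 135 & records$theta <= 180 &
    records$distance_XA >= lo & records$distance_XA < hi
  r <- records[sel, , drop = FALSE]
  if (nrow(r) > 0) {
    ai <- findInterval(r$theta, c(angle_lows, 180), rightmost.closed = TRUE)
    di <- findInterval(r$distance_XA, edges, rightmost.closed = FALSE)
    for (k in seq_len(nrow(r))) {
      row <- which(hist$angle_bin == labels[ai[k]] &
                     abs(hist$distance_low - edges[di[k]]) < 1e-9)
      hist$count[row] <- hist$count[row] + 1L
    }
  }
  structure(hist, class = c("xbsf_histogram", "data.frame"))
}

#' @export
print.xbsf_histogram <- function(x, ...) {
  cat("C-X...A geometry histogram:", sum(x$count), "contacts\n")
  nonzero <- x[x$count > 0, , drop = FALSE]
  if (nrow(nonzero) > 0) print.data.frame(nonzero, row.names = FALSE)
  invisible(x)
}

#' Write contact records or a histogram as CSV
#'
#' @param x a contact table from [mine_contacts()] or an
#'   `xbsf_histogram`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contacts_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Plot a contact-geometry histogram
#'
#' One distance-distribution panel per 15-degree angle range, drawn with
#' base graphics.
#'
#' @param x an `xbsf_histogram`.
#' @param main plot title.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.xbsf_histogram <- function(x, main = "C-X...A contact geometry", ...) {
  bins <- levels(x$angle_bin)
  op <- graphics::par(mfrow = c(1, length(bins)))
  on.exit(graphics::par(op))
  for (b in bins) {
    sub <- x[x$angle_bin == b, , drop = FALSE]
    graphics::barplot(sub$count, names.arg = sprintf("%.1f", sub$distance_low),
                      xlab = "X...A distance (A)", ylab = "contacts",
                      main = paste0(main, "\n", b, " deg"), las = 2, ...)
  }
  invisible(x)
}
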