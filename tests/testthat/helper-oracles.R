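# Independent brute-force oracles. These recompute everything from raw
# coordinates with their own hard-coded constant tables and naive loops,
# sharing no code path with the package internals they check.

oracle_constants <- list(
  W = c(Cl = -0.265, Br = -0.32, I = -0.4),
  theta0 = c(Cl = 146, Br = 126, I = 122),
  rx = c(Cl = 1.8, Br = 2.02, I = 2.2),
  ra = c(O = 1.7, N = 1.8, S = 2.0),
  cutoff = c(Cl = 2.1, Br = 2.2, I = 2.4)
)

oracle_delta <- function(halogen, theta) {
  if (halogen == "Cl") {
    if (theta >= 165) 0.25 else 0.15
  } else if (halogen == "Br") {
    if (theta >= 165) 0.45 else if (theta >= 150) 0.35 else 0.25
  } else {
    if (theta >= 165) 0.55 else if (theta >= 150) 0.45 else 0.35
  }
}

oracle_phi <- function(theta, halogen) {
  t0 <- oracle_constants$theta0[[halogen]]
  if (theta < t0) return(0)
  a <- (180 - theta) * pi / 180
  a0 <- (180 - t0) * pi / 180
  (cos(a) - cos(a0)) / (1 - cos(a0))
}

oracle_angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) /
                     sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# Total halogen-bond energy of a complex by exhaustive double loop.
oracle_total_energy <- function(protein, ligand) {
  K <- oracle_constants
  lat <- ligand$atoms
  pat <- protein$atoms
  acc <- pat[pat$element %in% c("O", "N", "S") & !pat$is_water, ,
             drop = FALSE]
  total <- 0
  for (i in seq_len(nrow(lat))) {
    el <- lat$element[i]
    if (!el %in% c("Cl", "Br", "I")) next
    X <- as.numeric(lat[i, c("x", "y", "z")])
    best_d <- Inf; Cpos <- NULL
    for (j in seq_len(nrow(lat))) {
      if (lat$element[j] != "C") next
      Cj <- as.numeric(lat[j, c("x", "y", "z")])
      dj <- sqrt(sum((X - Cj)^2))
      if (dj <= K$cutoff[[el]] && dj < best_d) { best_d <- dj; Cpos <- Cj }
    }
    if (is.null(Cpos)) next
    for (j in seq_len(nrow(acc))) {
      A <- as.numeric(acc[j, c("x", "y", "z")])
      dist <- sqrt(sum((X - A)^2))
      theta <- oracle_angle_deg(Cpos, X, A)
      phi <- oracle_phi(theta, el)
      d <- dist - (K$rx[[el]] + K$ra[[acc$element[j]]])
      delta <- oracle_delta(el, theta)
      D <- if (d >= 0) 0 else if (d <= -delta) 1 else -d / delta
      total <- total + K$W[[el]] * phi * D
    }
  }
  total
}

# Histogram tally by direct loop over records.
oracle_histogram_count <- function(records, halogen, acceptor,
                                   angle_low, dist_low, width) {
  n <- 0L
  for (k in seq_len(nrow(records))) {
    r <- records[k, ]
    if (r$halogen_element != halogen || r$acceptor_element != acceptor) next
    in_angle <- r$theta >= angle_low &
      (r$theta < angle_low + 15 | (angle_low == 165 & r$theta <= 180))
    in_dist <- r$distance_XA >= dist_low & r$distance_XA < dist_low + width
    if (in_angle && in_dist) n <- n + 1L
  }
  n
}

# Minimum assignment cost by permutation enumeration (small n only).
oracle_min_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  min(vapply(perms(seq_len(n)), function(p)
    sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

random_geometry_spec <- function() {
  list(halogen = sample(c("Cl", "Br", "I"), 1),
       acceptor = sample(c("O", "N", "S"), 1),
       distance = stats::runif(1, 2.8, 4.4),
       theta = stats::runif(1, 100, 180))
}
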