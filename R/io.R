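#' Read an extended-XYZ coordinate file
#'
#' Minimal extended-XYZ reader: the comment line carries the (cubic) lattice
#' as `Lattice="L 0 0 0 L 0 0 0 L"`; columns are species, x, y, z and
#' (optionally) charge.
#'
#' @param path file path
#' @return a [particle_system()]
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  m <- regmatches(lines[2], regexec('Lattice="([^"]+)"', lines[2]))[[1]]
  if (length(m) < 2) stop("missing Lattice=\"...\" in the comment line")
  lat <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
  if (length(lat) != 9) stop("Lattice must contain 9 numbers")
  Lm <- matrix(lat, 3, 3, byrow = TRUE)
  if (any(abs(Lm - diag(diag(Lm))) > 0) || length(unique(diag(Lm))) != 1)
    stop("only cubic boxes are supported")
  L <- Lm[1, 1]
  body <- lines[3:(2 + n)]
  fields <- strsplit(trimws(body), "\\s+")
  pos <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  q <- vapply(fields, function(f)
    if (length(f) >= 5) as.numeric(f[5]) else 0, 0)
  particle_system(pos, q, L)
}

#' Write an extended-XYZ coordinate file
#' @param system a [particle_system()]
#' @param path output path
#' @param species species labels (default "X")
#' @export
write_extxyz <- function(system, path, species = "X") {
  n <- nrow(system$positions)
  species <- rep_len(species, n)
  L <- system$box_edge
  header <- c(sprintf("%d", n),
              sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3:charge:R:1',
                      L, L, L))
  body <- sprintf("%s %.12g %.12g %.12g %.12g", species,
                  system$positions[, 1], system$positions[, 2],
                  system$positions[, 3], system$charges)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a site-topology JSON file
#'
#' Format: `{"sites": [{"particles": [0-based indices], "forms":
#' [[charges of form 0], [charges of form 1], ...]}]}`. Indices refer to the
#' coordinate-file order and are converted to 1-based internally.
#'
#' @param path file path
#' @return a [site_topology()]
#' @export
read_site_topology <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sites <- lapply(js$sites, function(s) {
    forms <- do.call(rbind, lapply(s$forms, as.numeric))
    list(particles = as.integer(unlist(s$particles)) + 1L, forms = forms)
  })
  site_topology(sites)
}

#' Write a site-topology JSON file (0-based indices)
#' @param topology a [site_topology()]
#' @param path output path
#' @export
write_site_topology <- function(topology, path) {
  js <- list(sites = lapply(topology$sites, function(s)
    list(particles = as.integer(s$particles) - 1L,
         forms = lapply(seq_len(nrow(s$forms)), function(r)
           as.numeric(s$forms[r, ])))))
  jsonlite::write_json(js, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Write a per-site lambda-force decomposition to CSV
#' @param report a `lambda_force_report`
#' @param path output path
#' @export
write_lambda_report <- function(report, path) {
  rows <- list()
  for (s in seq_along(report$sites)) {
    st <- report$sites[[s]]
    for (r in seq_len(nrow(st$decomposition)))
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, form = r - 1L,
        F_weight = st$F_weights[r],
        baseline = st$decomposition[r, "baseline"],
        corr_boxbox = st$decomposition[r, "boxbox"],
        corr_lattice = st$decomposition[r, "lattice"],
        corr_dipole = st$decomposition[r, "dipole"])
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a lambda trajectory to CSV
#' @param traj a `lambda_trajectory`
#' @param path output path
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time_ps = traj$time)
  for (j in seq_len(ncol(traj$lambda))) {
    df[[sprintf("lambda%d", j)]] <- traj$lambda[, j]
    df[[sprintf("vel%d", j)]] <- traj$velocity[, j]
  }
  df$energy <- traj$energy
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Cumulative-transition table for plotting
#' @param traj a `lambda_trajectory`
#' @param lo,hi hysteresis thresholds
#' @return data frame with time (ps) and cumulative transition count
#' @export
cumulative_transitions <- function(traj, lo = 0.2, hi = 0.8) {
  tr <- count_transitions(traj, lo, hi)
  data.frame(time_ps = c(0, tr$events$time),
             cumulative = seq(0, nrow(tr$events)))
}
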