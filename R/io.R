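# CSV readers/writers with schema validation.  Dialect: comma, ".",
# UTF-8, header mandatory; errors name the offending column and lines.

events_cols <- c("cell_id", "index", "kind", "side", "alpha_deg",
                 "x_start", "y_start", "t_start", "x_end", "y_end", "t_end")
trajectory_cols <- c("cell_id", "step", "x", "y")
outline_cols <- c("cell_id", "node_index", "x", "y")
msd_cols <- c("lag", "msd", "n_traj")
strain_cols <- c("strain", "lambda_p", "s", "a", "phi", "sigma_phi")

read_schema_csv <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_domain(what, " file '", path, "' is missing column(s): ",
                paste(missing, collapse = ", "))
  }
  for (cl in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "NA")
    if (length(bad)) {
      stop_domain(what, " file '", path, "': non-numeric value in column '",
                  cl, "' at data line(s) ",
                  paste(utils::head(bad, 5), collapse = ", "))
    }
    df[[cl]] <- v
  }
  df
}

write_schema_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write pseudopod event tables
#'
#' Events CSV schema: `cell_id, index, kind, side, alpha_deg, x_start,
#' y_start, t_start, x_end, y_end, t_end` (extra columns such as the
#' synthetic tangent decomposition are preserved).
#'
#' @param path CSV file path.
#' @param events Event data frame (from [make_event_table()] or
#'   [simulate_trajectory()]).
#' @return The data frame (readers) or the path, invisibly (writers).
#' @export
read_events <- function(path) {
  read_schema_csv(path, events_cols,
                  setdiff(events_cols, c("cell_id", "kind", "side")),
                  "events")
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  missing <- setdiff(events_cols, names(events))
  if (length(missing)) stop_domain("events are missing column(s): ",
                                   paste(missing, collapse = ", "))
  write_schema_csv(events, path)
}

#' Read and write trajectory tables
#'
#' Trajectory CSV schema: `cell_id, step, x, y`.
#'
#' @param path CSV file path.
#' @param walk A `pseudopod_walk` or a data frame already in the schema.
#' @export
read_trajectories <- function(path) {
  read_schema_csv(path, trajectory_cols, c("step", "x", "y"), "trajectory")
}

#' @rdname read_trajectories
#' @export
write_trajectories <- function(walk, path) {
  if (inherits(walk, "pseudopod_walk")) {
    walk <- data.frame(
      cell_id = sprintf("cell_%03d", rep(seq_len(walk$nsim),
                                         each = walk$n_steps + 1L)),
      step = rep(0:walk$n_steps, walk$nsim),
      x = as.vector(walk$x), y = as.vector(walk$y))
  }
  missing <- setdiff(trajectory_cols, names(walk))
  if (length(missing)) stop_domain("trajectories are missing column(s): ",
                                   paste(missing, collapse = ", "))
  write_schema_csv(walk, path)
}

#' Read and write outline tables
#'
#' Outline CSV schema: `cell_id, node_index, x, y`; polygons are closed
#' implicitly.
#'
#' @param path CSV file path.
#' @param outlines Named list of [cell_outline()] objects.
#' @return `read_outlines` returns a named list of `cell_outline`s.
#' @export
read_outlines <- function(path) {
  df <- read_schema_csv(path, outline_cols, c("node_index", "x", "y"),
                        "outline")
  out <- lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$node_index), ]
    cell_outline(d$x, d$y)
  })
  out
}

#' @rdname read_outlines
#' @export
write_outlines <- function(outlines, path) {
  if (inherits(outlines, "cell_outline")) outlines <- list(cell_001 = outlines)
  if (is.null(names(outlines))) {
    names(outlines) <- sprintf("cell_%03d", seq_along(outlines))
  }
  df <- do.call(rbind, lapply(names(outlines), function(id) {
    o <- outlines[[id]]
    data.frame(cell_id = id, node_index = seq_len(o$n), x = o$x, y = o$y,
               stringsAsFactors = FALSE)
  }))
  write_schema_csv(df, path)
}

#' Read and write MSD curves
#'
#' MSD CSV schema: `lag, msd, n_traj`.
#'
#' @param path CSV file path.
#' @param curve An `msd_curve` data frame.
#' @export
read_msd <- function(path) {
  df <- read_schema_csv(path, msd_cols, msd_cols, "MSD")
  structure(df, class = c("msd_curve", "data.frame"))
}

#' @rdname read_msd
#' @export
write_msd <- function(curve, path) {
  missing <- setdiff(msd_cols, names(curve))
  if (length(missing)) stop_domain("MSD curve is missing column(s): ",
                                   paste(missing, collapse = ", "))
  write_schema_csv(as.data.frame(curve), path)
}

#' Read and write strain parameter tables
#'
#' Strain CSV schema: `strain, lambda_p, s, a, phi, sigma_phi`, with
#' optional reference columns (`gamma_obs`, `gamma_mc_ref`,
#' `gamma_step_ref`).  Parameter bounds are validated and strain names
#' must be unique.
#'
#' @param path CSV file path.
#' @param strains Strain data frame (e.g. [table1_strains()]).
#' @export
read_strains <- function(path) {
  df <- read_schema_csv(path, strain_cols,
                        c(setdiff(strain_cols, "strain"),
                          "gamma_obs", "gamma_mc_ref", "gamma_step_ref"),
                        "strain")
  if (anyDuplicated(df$strain)) stop_domain("duplicate strain names in ", path)
  for (i in seq_len(nrow(df))) {
    pseudopod_model(df$lambda_p[i], df$s[i], df$a[i], df$phi[i],
                    df$sigma_phi[i])
  }
  df
}

#' @rdname read_strains
#' @export
write_strains <- function(strains, path) {
  missing <- setdiff(strain_cols, names(strains))
  if (length(missing)) stop_domain("strain table is missing column(s): ",
                                   paste(missing, collapse = ", "))
  write_schema_csv(strains, path)
}

#' Read a single-column angle file
#'
#' Angles CSV schema: one column `angle_deg`, header required.
#'
#' @param path CSV file path.
#' @param angles Numeric vector of angles in degrees.
#' @export
read_angles <- function(path) {
  df <- read_schema_csv(path, "angle_deg", "angle_deg", "angles")
  df$angle_deg
}

#' @rdname read_angles
#' @export
write_angles <- function(angles, path) {
  write_schema_csv(data.frame(angle_deg = angles), path)
}
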