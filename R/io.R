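# Trajectory and configuration I/O: extended-XYZ text frames and YAML run
# configuration.

format_xyz_frame <- function(state, time = 0, digits = 8) {
  n <- n_beads(state)
  lat <- sprintf("Lattice=\"%g 0 0 0 %g 0 0 0 %g\"",
                 state$box[1], state$box[2], state$box[3])
  props <- "Properties=species:S:1:pos:R:3:mol:I:1:frozen:I:1:molname:S:1"
  comment <- paste(lat, props,
                   sprintf("Boundary=%s Time=%g", state$boundary, time))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f %d %d %s")
  rows <- sprintf(fmt, state$species, state$positions[, 1],
                  state$positions[, 2], state$positions[, 3],
                  state$molecule_id, as.integer(state$frozen),
                  state$molecule_name)
  c(as.character(n), comment, rows)
}

#' Write a trajectory (or single state) as extended XYZ
#'
#' One frame per snapshot: bead species, position, molecule id, frozen flag
#' and template name, with the box and boundary mode in the comment line.
#' Round-trips losslessly to the stored precision via
#' [read_xyz_trajectory()].
#'
#' @param x a `dpd_trajectory` or a single `dpd_state`.
#' @param path output file path.
#' @param digits decimal digits for coordinates (default 8).
#' @export
write_xyz_trajectory <- function(x, path, digits = 8) {
  if (inherits(x, "dpd_state")) {
    lines <- format_xyz_frame(x, 0, digits)
  } else if (inherits(x, "dpd_trajectory")) {
    lines <- unlist(lapply(seq_len(n_snapshots(x)), function(i)
      format_xyz_frame(get_snapshot(x, i), x$times[i], digits)))
  } else stop("x must be a dpd_state or dpd_trajectory")
  writeLines(lines, path)
  invisible(path)
}

parse_xyz_frame <- function(lines, start) {
  n <- suppressWarnings(as.integer(lines[start]))
  if (is.na(n) || n < 0)
    stop("parse error at line ", start, ": expected bead count, got '",
         lines[start], "'")
  if (start + 1 + n > length(lines))
    stop("parse error: truncated frame starting at line ", start,
         " (expected ", n, " beads)")
  comment <- lines[start + 1]
  latm <- regmatches(comment,
                     regexec("Lattice=\"([-0-9.eE+ ]+)\"", comment))[[1]]
  if (length(latm) < 2)
    stop("parse error at line ", start + 1, ": no Lattice entry")
  lat <- as.numeric(strsplit(trimws(latm[2]), "[ ]+")[[1]])
  box <- lat[c(1, 5, 9)]
  boundary <- if (grepl("Boundary=walled_x", comment)) "walled_x" else "periodic"
  time <- 0
  tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]]
  if (length(tm) == 2) time <- as.numeric(tm[2])
  body <- lines[start + 1 + seq_len(n)]
  fields <- strsplit(trimws(body), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("parse error in frame at line ", start, ": record ",
         which(nf < 4)[1], " has fewer than 4 fields")
  species <- vapply(fields, `[`, "", 1)
  pos <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  if (any(!is.finite(pos)))
    stop("parse error in frame at line ", start, ": non-numeric coordinate")
  has_mol <- all(nf >= 5)
  if (has_mol) {
    mol <- as.integer(vapply(fields, `[`, "", 5))
  } else {
    warning("no molecule ids in frame; reading beads as singleton molecules")
    mol <- seq_len(n)
  }
  frozen <- if (all(nf >= 6)) as.integer(vapply(fields, `[`, "", 6)) == 1L
            else rep(FALSE, n)
  molname <- if (all(nf >= 7)) vapply(fields, `[`, "", 7) else species
  list(state = dpd_state(pos, species, box, molecule_id = mol,
                         molecule_name = molname, frozen = frozen,
                         boundary = boundary),
       time = time, next_line = start + 2 + n)
}

#' Read an extended-XYZ trajectory
#'
#' Accepts the frames written by [write_xyz_trajectory()] as well as foreign
#' extended-XYZ without molecule ids (beads are then read as singleton
#' molecules, with a warning).  Bond topology is not stored in XYZ; reattach
#' it from templates if dynamics are to be continued.
#'
#' @param path input file path.
#' @return A list with `states` (list of `dpd_state`) and `times`.
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  states <- list(); times <- numeric(0)
  at <- 1
  while (at <= length(lines)) {
    if (trimws(lines[at]) == "") { at <- at + 1; next }
    fr <- parse_xyz_frame(lines, at)
    states[[length(states) + 1]] <- fr$state
    times <- c(times, fr$time)
    at <- fr$next_line
  }
  if (length(states) == 0) stop("parse error: no frames in ", path)
  list(states = states, times = times)
}

#' Read a run configuration
#'
#' YAML with (at least) sections `composition` (molecule name -> volume
#' fraction), `box` (3 numbers), and optional `parameters` (overrides for
#' [dpd_params()] fields), `schedule` (`equilibrate_steps`, `relax_steps`,
#' `dissolve_steps`, `stride`, `n_layers`, `end_conc`) and `interaction`
#' (named pair overrides like `A-O: 106.5`).
#'
#' @param path YAML file path.
#' @return The validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$composition) || is.null(cfg$box))
    stop("configuration error: 'composition' and 'box' are required")
  if (abs(sum(unlist(cfg$composition)) - 1) > 1e-9)
    stop("configuration error: composition fractions must sum to 1")
  if (length(cfg$box) != 3)
    stop("configuration error: box must have 3 entries")
  cfg
}

# polynomial rolling hash of the deparsed configuration; a fingerprint for
# manifests (not cryptographic)
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write an analysis table with a provenance header
#'
#' Tab-separated values preceded by comment lines naming the producing stage
#' and the configuration fingerprint.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param stage producing stage name.
#' @param hash configuration fingerprint string.
#' @export
write_stage_table <- function(df, path, stage, hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# stage: %s", stage),
               sprintf("# config: %s", hash)), con)
  suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}
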