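#' Read and write tracheidogram CSV files
#'
#' The on-disk format is a plain comma-separated table (UTF-8, `.` decimal
#' mark, mandatory header) with the columns `index`, `rel_position`,
#' `LA_um2`, `LRD_um`, `WT_um` and optionally `latewood` (0/1; recomputed
#' from Mork's formula when absent).  Lines starting with `#` hold
#' `key: value` metadata (species, n_cells, source, curve).  Values are
#' written with 6 significant digits, so a write/read round trip is lossless
#' at that precision.
#'
#' @param path File path.
#' @return `read_tracheidogram()` returns a validated `tracheidogram`
#'   tibble; malformed files fail with a named error (missing column,
#'   non-monotone positions, negative traits).
#' @seealso [as_tracheidogram()], [simulate_ring()]
#' @export
read_tracheidogram <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- parse_meta_lines(lines)
  df <- readr::read_csv(
    I(paste(lines[!grepl("^\\s*#", lines)], collapse = "\n")),
    show_col_types = FALSE, progress = FALSE
  )
  required <- c("index", "rel_position", "LA_um2", "LRD_um", "WT_um")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(
      paste0(
        "Tracheidogram file ", path, " lacks column(s): ",
        paste(missing, collapse = ", "), "."
      ),
      class = "tracheidr_error_missing_column"
    )
  }
  out <- tibble(
    cell = as.integer(df$index),
    rel_position = df$rel_position,
    LA = df$LA_um2,
    LRD = df$LRD_um,
    WT = df$WT_um
  )
  if (!is.null(df[["latewood"]])) out$latewood <- as.logical(df[["latewood"]])
  source <- meta$source %||% "observed"
  if (!source %in% c("observed", "simulated", "synthetic")) source <- "observed"
  as_tracheidogram(
    out,
    species = meta$species %||% NA_character_,
    source = source,
    curve = parse_curve_meta(meta$curve)
  )
}

#' @rdname read_tracheidogram
#' @param tr A `tracheidogram`.
#' @return `write_tracheidogram()` invisibly returns `path`.
#' @export
write_tracheidogram <- function(tr, path) {
  stopifnot(is.data.frame(tr))
  meta <- c(
    sprintf("# species: %s", attr(tr, "species") %||% NA),
    sprintf("# n_cells: %d", nrow(tr)),
    sprintf("# source: %s", attr(tr, "source") %||% "observed"),
    format_curve_meta(attr(tr, "curve"))
  )
  lw <- tr[["latewood"]] %||% mork_latewood(tr$LRD, tr$WT)
  body <- data.frame(
    index = tr[["cell"]] %||% seq_len(nrow(tr)),
    rel_position = fmt6(tr$rel_position),
    LA_um2 = fmt6(tr$LA),
    LRD_um = fmt6(tr$LRD),
    WT_um = fmt6(tr$WT),
    latewood = as.integer(lw)
  )
  writeLines(
    c(meta, readr::format_csv(body)),
    path
  )
  invisible(path)
}

#' Write a single-cell trajectory to CSV
#'
#' Columns: `time_d`, `CA_um2`, `WA_um2`, `LWA_um2`, `WT_um`, `LA_um2`,
#' `LRD_um`, `phase` (enlarging / thickening / dead), with the run settings
#' as `#` metadata lines.
#'
#' @param traj A `tracheid_trajectory` from [simulate_cell()].
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "tracheid_trajectory"))
  meta <- c(
    sprintf("# species: %s", attr(traj, "species") %||% NA),
    sprintf("# S: %g", attr(traj, "S")),
    sprintf("# dt: %g", attr(traj, "dt")),
    sprintf("# saturation: %s", attr(traj, "saturation"))
  )
  body <- data.frame(
    time_d = fmt6(traj$time),
    CA_um2 = fmt6(traj$CA),
    WA_um2 = fmt6(traj$WA),
    LWA_um2 = fmt6(traj$LWA),
    WT_um = fmt6(traj$WT),
    LA_um2 = fmt6(traj$LA),
    LRD_um = fmt6(traj$LRD),
    phase = traj$phase
  )
  writeLines(c(meta, readr::format_csv(body)), path)
  invisible(path)
}

#' Read and write species parameter files
#'
#' Parameter files are YAML with the Table-style field names (`CA0`, `WA0`,
#' `CTD`, `WT0`, `vc`, `CAmax`, `WTstar`, `vw`, `WAmax`, `mw`, `sw`, `vl`,
#' `ml`, `sl`) plus an optional `curve` block (`family`, `a`, `b`, `c`).
#' Reading validates every invariant and reports violations by name.
#'
#' @param path File path.
#' @return `read_species_params()` returns a list with elements `params`
#'   (a [species_params()]) and `curve` (a [sugar_curve()] or `NULL`).
#' @examples
#' f <- system.file("extdata", "species", "larix_decidua.yml",
#'   package = "tracheidr"
#' )
#' read_species_params(f)$params
#' @export
read_species_params <- function(path) {
  y <- yaml::read_yaml(path)
  fields <- c(
    "CA0", "CTD", "WT0", "vc", "CAmax", "WTstar", "vw", "WAmax",
    "mw", "sw", "vl", "ml", "sl"
  )
  missing <- setdiff(fields, names(y))
  if (length(missing)) {
    abort(
      paste0(
        "Parameter file ", path, " lacks field(s): ",
        paste(missing, collapse = ", "), "."
      ),
      class = "tracheidr_error_missing_column"
    )
  }
  args <- c(list(name = y$name %||% basename(path)), y[fields])
  if (!is.null(y$WA0)) args$WA0 <- y$WA0
  params <- do.call(species_params, args)
  curve <- NULL
  if (!is.null(y$curve)) {
    curve <- sugar_curve(y$curve$family, y$curve$a, y$curve$b, y$curve$c)
  }
  list(params = params, curve = curve)
}

#' @rdname read_species_params
#' @param params A [species_params()] object.
#' @param curve Optional [sugar_curve()] to store alongside.
#' @return `write_species_params()` invisibly returns `path`.
#' @export
write_species_params <- function(params, path, curve = NULL) {
  validate_species_params(params)
  y <- unclass(params)
  if (!is.null(curve)) {
    stopifnot(inherits(curve, "sugar_curve"))
    y$curve <- list(family = curve$family, a = curve$a, b = curve$b, c = curve$c)
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

# Resolve a --species argument: bundled fixture name or parameter file path.
resolve_species <- function(spec) {
  if (file.exists(spec)) {
    return(read_species_params(spec))
  }
  tracheid_species(spec)
}

fmt6 <- function(x) as.numeric(formatC(x, digits = 6, format = "g"))

parse_meta_lines <- function(lines) {
  m <- grep("^\\s*#", lines, value = TRUE)
  out <- list()
  for (line in m) {
    hit <- regmatches(line, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_ ]*):\\s*(.*)$", line))[[1]]
    if (length(hit) == 3) out[[trimws(hit[2])]] <- trimws(hit[3])
  }
  out
}

format_curve_meta <- function(curve) {
  if (is.null(curve)) {
    return(character(0))
  }
  sprintf(
    "# curve: %s a=%g b=%g c=%g",
    curve$family, curve$a, curve$b, curve$c
  )
}

parse_curve_meta <- function(txt) {
  if (is.null(txt)) {
    return(NULL)
  }
  hit <- regmatches(
    txt,
    regexec("^(quadratic|exponential)\\s+a=([-0-9.eE+]+)\\s+b=([-0-9.eE+]+)\\s+c=([-0-9.eE+]+)$", txt)
  )[[1]]
  if (length(hit) != 5) {
    return(NULL)
  }
  sugar_curve(hit[2], as.numeric(hit[3]), as.numeric(hit[4]), as.numeric(hit[5]))
}
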