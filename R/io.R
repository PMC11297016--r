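#' Read and write shape files
#'
#' Plain-text `.grid` format: one `"x y"` axial integer pair per line,
#' `#` comments allowed.  Axial coordinates keep all grid arithmetic
#' exact; Cartesian conversion is confined to rendering.
#'
#' @param path file path.
#' @return `read_shape()` returns a [tm_shape()].
#' @export
read_shape <- function(path) {
  if (!file.exists(path)) stop("ParseError: no such file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  if (!any(keep)) stop("ParseError: no points in shape file")
  pts <- matrix(NA_integer_, sum(keep), 2L)
  rowi <- 0L
  for (ln in which(keep)) {
    toks <- strsplit(lines[ln], "[[:space:]]+")[[1L]]
    val <- suppressWarnings(as.integer(toks))
    if (length(val) != 2L || anyNA(val))
      stop(sprintf("ParseError at line %d: expected 'x y' integers", ln))
    rowi <- rowi + 1L
    pts[rowi, ] <- val
  }
  if (anyDuplicated(point_keys(pts)))
    stop("ParseError: duplicate point in shape file")
  tm_shape(pts)
}

#' @rdname read_shape
#' @param shape a [tm_shape()].
#' @export
write_shape <- function(shape, path) {
  stopifnot(inherits(shape, "tm_shape"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# triangular-grid shape: axial x y per line", con)
  writeLines(sprintf("%d %d", shape$points[, 1L], shape$points[, 2L]), con)
  invisible(path)
}

#' Read and write program files
#'
#' Structured-text `.tmprog` format:
#' \preformatted{
#' name: L(7,6)
#' states: 6 6 6 6 6 6 0
#' positions:        # optional; default is the east line
#' 0 0
#' 1 0
#' ...
#' }
#'
#' @param path file path.
#' @return `read_program()` returns a [tm_program()].
#' @export
read_program <- function(path) {
  if (!file.exists(path)) stop("ParseError: no such file: ", path)
  lines <- readLines(path)
  stripped <- trimws(sub("#.*$", "", lines))
  name <- "program"
  states <- NULL
  positions <- NULL
  in_pos <- FALSE
  for (ln in seq_along(stripped)) {
    s <- stripped[ln]
    if (!nzchar(s)) next
    if (in_pos) {
      toks <- suppressWarnings(as.integer(strsplit(s, "[[:space:]]+")[[1L]]))
      if (length(toks) != 2L || anyNA(toks))
        stop(sprintf("ParseError at line %d: expected 'x y'", ln))
      positions <- rbind(positions, toks)
    } else if (grepl("^name:", s)) {
      name <- trimws(sub("^name:", "", s))
    } else if (grepl("^states:", s)) {
      toks <- strsplit(trimws(sub("^states:", "", s)),
                      "[[:space:]]+")[[1L]]
      states <- suppressWarnings(as.integer(toks))
      if (anyNA(states))
        stop(sprintf("ParseError at line %d: non-integer state", ln))
    } else if (grepl("^positions:", s)) {
      in_pos <- TRUE
    } else {
      stop(sprintf("ParseError at line %d: unrecognised field", ln))
    }
  }
  if (is.null(states)) stop("ParseError: missing 'states:' field")
  tm_program(states, positions = positions, name = name)
}

#' @rdname read_program
#' @param program a [tm_program()].
#' @export
write_program <- function(program, path) {
  stopifnot(inherits(program, "tm_program"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("name: %s", program$name), con)
  writeLines(paste("states:", paste(program$states0, collapse = " ")), con)
  pos <- program$positions0
  default_line <- all(pos[, 2L] == 0L) &&
    all(pos[, 1L] == seq_len(nrow(pos)) - 1L)
  if (!default_line) {
    writeLines("positions:", con)
    writeLines(sprintf("%d %d", pos[, 1L], pos[, 2L]), con)
  }
  invisible(path)
}

#' Render a configuration
#'
#' `svg` mode draws the chain with one disk per monomer at its Cartesian
#' projection, bonds between successive monomers, state labels, and a red
#' highlight on monomers whose nonzero state is currently blocked.
#' `ascii` mode gives a lossy text sketch (one character per monomer on a
#' sheared grid; digits are states mod 10, `*` marks blocked monomers).
#' Output is deterministic.
#'
#' @param config a [tm_configuration()].
#' @param mode `"svg"` or `"ascii"`.
#' @return a single string (the SVG document or the ASCII sketch).
#' @export
render_configuration <- function(config, mode = c("svg", "ascii")) {
  stopifnot(inherits(config, "tm_configuration"))
  mode <- match.arg(mode)
  pos <- config$positions
  n <- nrow(pos)
  blocked <- config$states != 0L
  blocked[applicable_moves(config)] <- FALSE
  if (mode == "ascii") {
    col <- 2L * pos[, 1L] + pos[, 2L]
    row <- -pos[, 2L]
    col <- col - min(col)
    row <- row - min(row)
    grid <- matrix(" ", max(row) + 1L, max(col) + 1L)
    for (i in seq_len(n)) {
      ch <- if (blocked[i]) "*" else
        as.character(abs(config$states[i]) %% 10L)
      grid[row[i] + 1L, col[i] + 1L] <- ch
    }
    return(paste(apply(grid, 1L, paste, collapse = ""), collapse = "\n"))
  }
  xy <- axial_to_cartesian(pos)
  scale <- 24
  x <- xy[, 1L] * scale
  y <- -xy[, 2L] * scale
  pad <- 30
  x0 <- min(x) - pad; y0 <- min(y) - pad
  x <- x - x0; y <- y - y0
  w <- ceiling(max(x) + pad); h <- ceiling(max(y) + pad)
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%d" height="%d">'), w, h))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      stroke <- if (blocked[i]) "#cc0000" else "#555555"
      out <- c(out, sprintf(paste0('<line x1="%.1f" y1="%.1f" x2="%.1f" ',
                                   'y2="%.1f" stroke="%s" stroke-width="2"/>'),
                            x[i], y[i], x[i + 1L], y[i + 1L], stroke))
    }
  }
  for (i in seq_len(n)) {
    fill <- if (blocked[i]) "#cc0000" else
      if (config$states[i] == 0L) "#ffd24d" else "#4477cc"
    out <- c(out, sprintf(paste0('<circle class="monomer" cx="%.1f" ',
                                 'cy="%.1f" r="8" fill="%s"/>'),
                          x[i], y[i], fill),
             sprintf(paste0('<text x="%.1f" y="%.1f" font-size="8" ',
                            'text-anchor="middle">%d</text>'),
                     x[i], y[i] + 3, config$states[i]))
  }
  paste(c(out, "</svg>"), collapse = "\n")
}
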