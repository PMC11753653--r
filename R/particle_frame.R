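#' Construct a particle frame
#'
#' A particle frame is one configuration of a particle system: positions in
#' an orthorhombic periodic box, per-particle charges (elementary charge
#' units) and species labels (e.g. `"HEAD+"`, `"HEAD-"`, `"TAIL"`,
#' `"WATER"`). Coordinates are wrapped into `[0, L)` per axis on
#' construction; a particle exactly at `L` wraps to 0.
#'
#' @param positions N x 3 numeric matrix of coordinates (nm).
#' @param charges Numeric vector of length N (e).
#' @param labels Character vector of length N.
#' @param box Length-3 positive numeric: box edges (Lx, Ly, Lz) in nm.
#' @param time Optional frame timestamp (ns).
#' @return An object of class `particle_frame`.
#' @export
particle_frame <- function(positions, charges, labels, box,
                           time = NA_real_) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be N x 3", call. = FALSE)
  n <- nrow(positions)
  if (length(charges) != n || length(labels) != n) {
    stop("positions, charges and labels must agree in length", call. = FALSE)
  }
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be 3 positive edge lengths", call. = FALSE)
  }
  if (anyNA(positions) || anyNA(charges)) {
    stop("missing values in positions or charges", call. = FALSE)
  }
  for (ax in 1:3) {
    positions[, ax] <- positions[, ax] %% box[ax]
    # %% can return L itself for tiny negative arguments; force [0, L)
    positions[positions[, ax] >= box[ax], ax] <- 0
  }
  colnames(positions) <- c("x", "y", "z")
  structure(list(positions = positions, charges = as.numeric(charges),
                 labels = as.character(labels), box = box,
                 time = as.numeric(time)),
            class = "particle_frame")
}

#' @export
print.particle_frame <- function(x, ...) {
  cat(sprintf("particle_frame: %d particles, box %.3f x %.3f x %.3f nm",
              nrow(x$positions), x$box[1], x$box[2], x$box[3]))
  if (!is.na(x$time)) cat(sprintf(", t = %g ns", x$time))
  cat("\n")
  tab <- table(x$labels)
  cat("  species:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Write a particle frame in the native columnar text format
#'
#' The native format is plain text: a comment line, a `box Lx Ly Lz` line,
#' an optional `time t` line, a header `x y z charge label`, then one row
#' per particle. Numbers are written with 17 significant digits, so
#' [read_particle_frame()] round-trips a frame bit-exactly.
#'
#' @param frame A `particle_frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_particle_frame <- function(frame, path) {
  stopifnot(inherits(frame, "particle_frame"))
  num <- function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    "# pefpore particle frame v1",
    paste("box", paste(num(frame$box), collapse = " "))
  )
  if (!is.na(frame$time)) lines <- c(lines, paste("time", num(frame$time)))
  lines <- c(lines, "x y z charge label",
             paste(num(frame$positions[, 1]), num(frame$positions[, 2]),
                   num(frame$positions[, 3]), num(frame$charges),
                   frame$labels))
  writeLines(lines, path)
  invisible(path)
}

#' Read a particle frame from the native columnar text format
#'
#' @param path Path written by [write_particle_frame()].
#' @return A `particle_frame`.
#' @export
read_particle_frame <- function(path) {
  if (!file.exists(path)) stop("frame file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  box_line <- grep("^box\\s", lines)
  if (length(box_line) != 1L) stop("native frame needs one 'box' line",
                                   call. = FALSE)
  box <- as.numeric(strsplit(trimws(lines[box_line]), "\\s+")[[1]][-1])
  time <- NA_real_
  time_line <- grep("^time\\s", lines)
  if (length(time_line)) {
    time <- as.numeric(strsplit(trimws(lines[time_line[1]]), "\\s+")[[1]][2])
  }
  hdr <- grep("^x\\s+y\\s+z\\s+charge\\s+label$", lines)
  if (length(hdr) != 1L) {
    stop("native frame needs the header line 'x y z charge label'",
         call. = FALSE)
  }
  body <- lines[(hdr + 1L):length(lines)]
  df <- utils::read.table(text = body, col.names = c("x", "y", "z",
                                                     "charge", "label"),
                          colClasses = c("numeric", "numeric", "numeric",
                                         "numeric", "character"))
  particle_frame(as.matrix(df[, c("x", "y", "z")]), df$charge, df$label,
                 box = box, time = time)
}

.apply_charge_map <- function(labels, charge_map) {
  unmapped <- setdiff(unique(labels), names(charge_map))
  if (length(unmapped)) {
    stop("charge map does not cover label(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  unname(unlist(charge_map)[labels])
}

#' Read a particle frame from a GRO structure file
#'
#' Positions are taken from the fixed-column GRO records (already in nm) and
#' the box from the final box-vector line. GRO files carry no charges, so a
#' named charge map from atom-name label to charge (e) must be supplied.
#'
#' @param path GRO file path.
#' @param charge_map Named list/vector mapping every atom-name label in the
#'   file to a charge in e.
#' @return A `particle_frame` labeled by atom name.
#' @export
read_gro_frame <- function(path, charge_map) {
  if (!file.exists(path)) stop("frame file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 4L) stop("truncated GRO file", call. = FALSE)
  n <- as.integer(trimws(lines[2]))
  atom_lines <- lines[3:(2 + n)]
  labels <- trimws(substr(atom_lines, 11L, 15L))
  x <- as.numeric(substr(atom_lines, 21L, 28L))
  y <- as.numeric(substr(atom_lines, 29L, 36L))
  z <- as.numeric(substr(atom_lines, 37L, 44L))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  charges <- .apply_charge_map(labels, charge_map)
  particle_frame(cbind(x, y, z), charges, labels, box = box)
}

#' Read a particle frame from a PDB structure file
#'
#' Uses \pkg{bio3d} to parse ATOM/HETATM records; coordinates are converted
#' from Angstrom to nm and the box is taken from the CRYST1 record. PDB
#' files carry no charges, so a named charge map from atom-name label to
#' charge (e) must be supplied.
#'
#' @param path PDB file path.
#' @param charge_map Named list/vector mapping atom-name labels to charges.
#' @return A `particle_frame` labeled by atom name.
#' @export
read_pdb_frame <- function(path, charge_map) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB frames requires the 'bio3d' package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  labels <- trimws(pdb$atom$elety)
  pos <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z) / 10  # Angstrom -> nm
  cryst <- grep("^CRYST1", readLines(path), value = TRUE)
  if (!length(cryst)) {
    stop("PDB file lacks a CRYST1 box record", call. = FALSE)
  }
  box <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                      substr(cryst[1], 25, 33))) / 10
  if (anyNA(box)) stop("unparseable CRYST1 record", call. = FALSE)
  charges <- .apply_charge_map(labels, charge_map)
  particle_frame(pos, charges, labels, box = box)
}

#' Write a particle frame as a minimal PDB file
#'
#' Emits HETATM records (labels as atom names, coordinates in Angstrom) and
#' a CRYST1 box record. Charges are not representable in PDB and are
#' dropped; use the native format for lossless round trips.
#'
#' @param frame A `particle_frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_frame <- function(frame, path) {
  stopifnot(inherits(frame, "particle_frame"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     frame$box[1] * 10, frame$box[2] * 10, frame$box[3] * 10),
             con)
  nm <- substr(gsub("[^A-Za-z0-9]", "", frame$labels), 1L, 4L)
  writeLines(sprintf("HETATM%5d %-4s MOL A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                     seq_len(nrow(frame$positions)) %% 100000L, nm,
                     1L, frame$positions[, 1] * 10, frame$positions[, 2] * 10,
                     frame$positions[, 3] * 10),
             con)
  writeLines("END", con)
  invisible(path)
}
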