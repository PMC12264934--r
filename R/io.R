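# Standard-format I/O. PDB and DCD parsing is delegated to bio3d; the plain
# XYZ chemical format has no installed reader so it is parsed here.

#' Read a molecular structure from PDB or XYZ
#'
#' @param file Path to a `.pdb` or `.xyz` file (format from extension unless
#'   `format` is given).
#' @param format "pdb" or "xyz".
#' @param ... Passed to [structure3d()] (e.g. `solvent_cfg`).
#' @return A `structure3d`. For a multi-model PDB only the first model's
#'   coordinates are used (see [read_trajectory()] for all models).
#' @export
read_structure <- function(file, format = guess_format(file), ...) {
  switch(format,
         pdb = pdb_to_structure(read_pdb_checked(file), model = 1L, ...),
         xyz = read_xyz_file(file, ...)$structure,
         stop("unsupported structure format: ", format))
}

#' Write a molecular structure to PDB or XYZ
#'
#' @param x A `structure3d`.
#' @param file Output path.
#' @param format "pdb" or "xyz".
#' @param o,b Optional occupancy / B-factor columns (PDB only).
#' @return Invisibly, `file`.
#' @export
write_structure <- function(x, file, format = guess_format(file),
                            o = NULL, b = NULL) {
  stopifnot(inherits(x, "structure3d"))
  switch(format,
         pdb = write_pdb_frames(x, list(x$coords), file, o = o, b = b),
         xyz = write_xyz_file(list(x$coords), x$atoms$element, file),
         stop("unsupported structure format: ", format))
  invisible(file)
}

#' Read a trajectory (multi-model PDB, XYZ with repeated blocks, or DCD)
#'
#' @param file Coordinate file; `.dcd` requires `topology`.
#' @param topology Optional `structure3d` (required for DCD, optional
#'   otherwise; when given, its atom table is used).
#' @param dt Frame interval in ps.
#' @param format "pdb", "xyz" or "dcd".
#' @param ... Passed to [structure3d()].
#' @return A `trajectory3d` with one frame per model/block.
#' @export
read_trajectory <- function(file, topology = NULL, dt = 1,
                            format = guess_format(file), ...) {
  if (format == "pdb") {
    pdb <- read_pdb_checked(file, multi = TRUE)
    topo <- if (is.null(topology)) pdb_to_structure(pdb, model = 1L, ...) else topology
    nf <- nrow(pdb$xyz)
    frames <- array(0, dim = c(nrow(topo$atoms), 3L, nf))
    for (i in seq_len(nf)) frames[, , i] <- matrix(pdb$xyz[i, ], ncol = 3L, byrow = TRUE)
    trajectory3d(topo, frames, dt = dt)
  } else if (format == "xyz") {
    parsed <- read_xyz_file(file, ...)
    topo <- if (is.null(topology)) parsed$structure else topology
    trajectory3d(topo, parsed$frames, dt = dt)
  } else if (format == "dcd") {
    if (is.null(topology)) stop("DCD trajectories need an explicit topology")
    xyz <- bio3d::read.dcd(file, verbose = FALSE)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    nf <- nrow(xyz)
    frames <- array(0, dim = c(nrow(topology$atoms), 3L, nf))
    for (i in seq_len(nf)) frames[, , i] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
    trajectory3d(topology, frames, dt = dt)
  } else stop("unsupported trajectory format: ", format)
}

#' Write a trajectory as multi-model PDB or multi-block XYZ
#'
#' @param traj A `trajectory3d`.
#' @param file Output path.
#' @param format "pdb" or "xyz".
#' @return Invisibly, `file`.
#' @export
write_trajectory <- function(traj, file, format = guess_format(file)) {
  stopifnot(inherits(traj, "trajectory3d"))
  frames <- lapply(seq_len(n_frames(traj)), function(i) get_frame(traj, i))
  switch(format,
         pdb = write_pdb_frames(traj$topology, frames, file),
         xyz = write_xyz_file(frames, traj$topology$atoms$element, file),
         stop("unsupported trajectory format: ", format))
  invisible(file)
}

guess_format <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("pdb", "ent")) "pdb"
  else if (ext == "xyz") "xyz"
  else if (ext == "dcd") "dcd"
  else stop("cannot guess format from extension: ", file)
}

read_pdb_checked <- function(file, multi = FALSE) {
  pdb <- tryCatch(bio3d::read.pdb(file, multi = multi, verbose = FALSE),
                  error = function(e) stop("malformed PDB '", file, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L) {
    stop("malformed PDB '", file, "': no ATOM records")
  }
  pdb
}

pdb_to_structure <- function(pdb, model = 1L, ...) {
  at <- pdb$atom
  coords <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- toupper(substr(trimws(at$elety), 1L, 1L))
  }
  elem[is.na(elem) | elem == ""] <- toupper(substr(trimws(at$elety), 1L, 1L))[is.na(elem) | elem == ""]
  structure3d(coords, name = trimws(at$elety), resid = at$resno,
              resname = trimws(at$resid), chain = ifelse(is.na(at$chain), "A", at$chain),
              element = trimws(elem), ...)
}

# Minimal fixed-width PDB writer used for both structures and path files so
# occupancy/B-factor weight columns are under our control.
write_pdb_frames <- function(topo, frames, file, o = NULL, b = NULL) {
  at <- topo$atoms
  n <- nrow(at)
  if (is.null(o)) o <- rep(1, n)
  if (is.null(b)) b <- rep(0, n)
  con <- file(file, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (m in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frames[[m]]
    rec <- ifelse(at$is_solvent | at$is_ion | at$is_ligand, "HETATM", "ATOM  ")
    lines <- sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, seq_len(n), formatC(substr(at$name, 1L, 4L), width = -4),
                     substr(at$resname, 1L, 4L), substr(at$chain, 1L, 1L),
                     at$resid, xyz[, 1L], xyz[, 2L], xyz[, 3L], o, b,
                     substr(at$element, 1L, 2L))
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con) else writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(file)
}

# XYZ chemical format: "natoms\ncomment\nelem x y z ..." blocks, one per frame.
read_xyz_file <- function(file, ...) {
  lines <- readLines(file)
  frames <- list()
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0L) {
      stop("malformed XYZ '", file, "' at line ", i, ": expected atom count")
    }
    if (i + 1L + nat > length(lines)) {
      stop("malformed XYZ '", file, "' at line ", i, ": truncated block")
    }
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad)) {
      stop("malformed XYZ '", file, "' at line ", i + 1L + bad[1L],
           ": expected 'element x y z'")
    }
    elem <- vapply(toks, `[`, character(1), 1L)
    xyz <- t(vapply(toks, function(tk) {
      suppressWarnings(as.numeric(tk[2:4]))
    }, numeric(3)))
    if (any(!is.finite(xyz))) {
      stop("malformed XYZ '", file, "' at line ", i, ": non-numeric coordinate")
    }
    if (is.null(elements)) elements <- elem
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("malformed XYZ '", file, "': no frames")
  topo <- structure3d(frames[[1L]], name = elements, element = elements, ...)
  list(structure = topo, frames = frames)
}

write_xyz_file <- function(frames, elements, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    xyz <- frames[[m]]
    writeLines(as.character(nrow(xyz)), con)
    writeLines(sprintf("frame %d", m), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", elements,
                       xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
  }
  invisible(file)
}
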