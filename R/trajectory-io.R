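#' @include trajectory-class.R geometry.R
NULL

# ---- GRO ------------------------------------------------------------------

.readGro <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  boxes <- list()
  times <- numeric()
  top <- NULL
  nat0 <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat))
      stop("malformed trajectory: bad atom-count line at line ", i + 1L)
    if (is.na(nat0)) nat0 <- nat
    if (nat != nat0)
      stop("malformed trajectory: frame atom count ", nat,
           " differs from first frame (", nat0, ")")
    if (i + 1L + nat + 1L > length(lines))
      stop("malformed trajectory: truncated GRO frame")
    al <- lines[(i + 2L):(i + 1L + nat)]
    resid <- as.integer(substr(al, 1, 5))
    resname <- trimws(substr(al, 6, 10))
    name <- trimws(substr(al, 11, 15))
    x <- as.numeric(substr(al, 21, 28))
    y <- as.numeric(substr(al, 29, 36))
    z <- as.numeric(substr(al, 37, 44))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop("malformed trajectory: unparsable GRO coordinates")
    boxv <- suppressWarnings(as.numeric(strsplit(trimws(
      lines[i + 2L + nat]), "\\s+")[[1]]))
    if (length(boxv) < 3 || anyNA(boxv[1:3]))
      stop("malformed trajectory: bad GRO box line")
    if (length(boxv) > 3 && any(abs(boxv[4:length(boxv)]) > 1e-9))
      stop("triclinic boxes are not supported; orthorhombic input only")
    if (is.null(top))
      top <- data.frame(name = name, resname = resname, resid = resid,
                        stringsAsFactors = FALSE)
    # frame time from a "t= <ps>" tag in the title, if present
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(tm)) as.numeric(sub("t=\\s*", "", tm))
               else NA_real_)
    frames[[length(frames) + 1L]] <- cbind(x, y, z) * 10  # nm -> Angstrom
    boxes[[length(boxes) + 1L]] <- boxv[1:3] * 10
    i <- i + nat + 3L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) stop("malformed trajectory: no frames found")
  if (anyNA(times)) times <- as.numeric(seq_along(frames) - 1L)
  co <- array(0, c(nat0, 3L, length(frames)))
  for (f in seq_along(frames)) co[, , f] <- frames[[f]]
  newTrajectory(top, co, do.call(rbind, boxes), times)
}

.writeGro <- function(traj, path) {
  top <- atoms(traj)
  con <- file(path, "w")
  on.exit(close(con))
  atnum <- (seq_len(nrow(top)) - 1L) %% 100000L + 1L
  for (f in seq_len(nFrames(traj))) {
    xyz <- coords(traj, f) / 10  # Angstrom -> nm
    writeLines(sprintf("generated by xanmem t= %.3f", frameTimes(traj)[f]), con)
    writeLines(sprintf("%d", nrow(top)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       top$resid %% 100000L, top$resname, top$name, atnum,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    b <- boxLengths(traj, f) / 10
    writeLines(sprintf("%10.5f%10.5f%10.5f", b[1], b[2], b[3]), con)
  }
  invisible(path)
}

# ---- PDB ------------------------------------------------------------------

.readPdb <- function(path) {
  # box from CRYST1 (bio3d does not retain it)
  hdr <- readLines(path, n = 2000L)
  cl <- grep("^CRYST1", hdr, value = TRUE)
  if (!length(cl)) {
    all <- readLines(path)
    cl <- grep("^CRYST1", all, value = TRUE)
  }
  if (!length(cl))
    stop("PDB file has no CRYST1 record; a periodic box is required")
  cv <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                     substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                     substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
  if (any(abs(cv[4:6] - 90) > 1e-3))
    stop("triclinic boxes are not supported; orthorhombic input only")
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- p$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  nat <- nrow(p$atom)
  nf <- nrow(xyz)
  co <- array(0, c(nat, 3L, nf))
  for (f in seq_len(nf))
    co[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  top <- data.frame(name = p$atom$elety, resname = p$atom$resid,
                    resid = as.integer(p$atom$resno), stringsAsFactors = FALSE)
  newTrajectory(top, co, matrix(cv[1:3], nf, 3, byrow = TRUE),
                as.numeric(seq_len(nf) - 1L))
}

.writePdb <- function(traj, path) {
  top <- atoms(traj)
  con <- file(path, "w")
  on.exit(close(con))
  b <- boxLengths(traj, 1)
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    b[1], b[2], b[3], 90, 90, 90), con)
  atnum <- (seq_len(nrow(top)) - 1L) %% 100000L + 1L
  # atom names of <4 chars start in column 14, PDB convention
  nm <- ifelse(nchar(top$name) < 4, paste0(" ", top$name), top$name)
  for (f in seq_len(nFrames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- coords(traj, f)
    writeLines(sprintf("ATOM  %5d %-4s %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       atnum, nm, top$resname, top$resid %% 10000L,
                       xyz[, 1], xyz[, 2], xyz[, 3], top$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- public API -----------------------------------------------------------

#' Read a multi-frame GRO or PDB trajectory
#'
#' GRO coordinates (nm) are converted to Angstrom on read; PDB is read as
#' Angstrom.  Frame times are taken from `t=` tags in GRO title lines when
#' present, otherwise default to frame index x 1 ps.  Only orthorhombic
#' boxes are accepted.
#'
#' @param path input file.
#' @param format `"gro"` or `"pdb"`; inferred from the file extension when
#'   missing.
#' @return a [Trajectory].
#' @export
readTrajectory <- function(path, format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("gro", "pdb"))
      stop("unknown trajectory format: '", ext, "' (use gro or pdb)")
    format <- ext
  }
  switch(format, gro = .readGro(path), pdb = .readPdb(path))
}

#' Write a trajectory to GRO or PDB
#'
#' GRO is written in nm at the format's 0.001 nm precision; PDB as
#' multi-MODEL records with a CRYST1 box.
#'
#' @param traj a [Trajectory] with at least one frame.
#' @param path destination file.
#' @param format `"gro"` or `"pdb"`; inferred from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path, format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (nFrames(traj) < 1) stop("refusing to write an empty trajectory")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("gro", "pdb"))
      stop("unknown trajectory format: '", ext, "' (use gro or pdb)")
    format <- ext
  }
  switch(format, gro = .writeGro(traj, path), pdb = .writePdb(traj, path))
  invisible(path)
}
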