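# File formats: NIfTI volumes (via RNifti), TCK tractograms, CSV connectomes
# and manifests, JSON fit reports, YAML run configuration.

# ---------------------------------------------------------------------------
# Tractograms (TCK)
# ---------------------------------------------------------------------------

#' Read a tractogram
#'
#' Reads an MRtrix TCK file (text header, Float32 little/big-endian point
#' triplets separated by NaN triplets and terminated by an Inf triplet).
#' Streamline points are returned in world millimetres; the streamline count
#' is preserved. TRK files are not supported; convert them to TCK first.
#'
#' @param path file path ending in `.tck`.
#' @return a [Tractogram-class].
#' @export
readTractogram <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "trk")
    stop("TRK reading is not supported; convert the tractogram to TCK")
  if (ext != "tck")
    stop("unknown tractogram extension '", ext, "' (expected .tck)")
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  endPat <- as.raw(c(0x0a, 0x45, 0x4e, 0x44, 0x0a))   # "\nEND\n"
  headEnd <- NA_integer_
  limit <- min(length(raw), 65536L)
  for (i in seq_len(limit - 4L)) {
    if (raw[i] == endPat[1L] && all(raw[i + 1:4] == endPat[2:5])) {
      headEnd <- i + 4L
      break
    }
  }
  if (is.na(headEnd)) stop("malformed TCK header: no END marker")
  header <- strsplit(rawToChar(raw[seq_len(headEnd)]), "\n", fixed = TRUE)[[1]]
  if (!identical(header[1L], "mrtrix tracks"))
    stop("malformed TCK header: missing 'mrtrix tracks' magic line")
  field <- function(name) {
    hit <- grep(paste0("^", name, ": "), header, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^", name, ": "), "", hit[1L])
  }
  datatype <- field("datatype")
  if (is.na(datatype) || !datatype %in% c("Float32LE", "Float32BE"))
    stop("malformed TCK header: unsupported or missing field 'datatype'")
  endian <- if (datatype == "Float32LE") "little" else "big"
  fileField <- field("file")
  if (is.na(fileField)) stop("malformed TCK header: missing field 'file'")
  offset <- as.integer(sub("^\\. ", "", fileField))
  if (is.na(offset)) stop("malformed TCK header: unparsable field 'file'")

  nFloats <- (length(raw) - offset) %/% 4L
  vals <- readBin(raw[(offset + 1L):length(raw)], what = "numeric",
                  n = nFloats, size = 4L, endian = endian)
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  streamlines <- list()
  start <- 1L
  for (r in seq_len(nrow(pts))) {
    if (all(is.infinite(pts[r, ]))) break
    if (all(is.nan(pts[r, ]))) {
      if (r > start)
        streamlines[[length(streamlines) + 1L]] <-
          pts[start:(r - 1L), , drop = FALSE]
      start <- r + 1L
    }
  }
  declared <- suppressWarnings(as.integer(field("count")))
  if (!is.na(declared) && declared != length(streamlines))
    stop("malformed TCK header: field 'count' (", declared,
         ") does not match the ", length(streamlines), " streamlines read")
  Tractogram(streamlines)
}

#' Write a tractogram to TCK
#'
#' @param tractogram a [Tractogram-class].
#' @param path output path ending in `.tck`.
#' @return `path`, invisibly.
#' @export
writeTractogram <- function(tractogram, path) {
  stopifnot(is(tractogram, "Tractogram"))
  if (tolower(tools::file_ext(path)) != "tck")
    stop("unknown tractogram extension (expected .tck)")
  sl <- streamlines(tractogram)
  makeHeader <- function(offset)
    paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", length(sl),
           "\nfile: . ", offset, "\nEND\n")
  offset <- nchar(makeHeader(0L), type = "bytes")
  while (nchar(makeHeader(offset), type = "bytes") != offset)
    offset <- nchar(makeHeader(offset), type = "bytes")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(makeHeader(offset), con, eos = NULL)
  for (s in sl) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}

# ---------------------------------------------------------------------------
# NIfTI volumes
# ---------------------------------------------------------------------------

#' Write a 3D volume to NIfTI
#'
#' @param data 3D numeric or integer array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxelSize isotropic voxel edge length in mm (default 1).
#' @param datatype passed to [RNifti::writeNifti()] (e.g. `"int32"` for
#'   parcellations; default `"auto"`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(data, path, voxelSize = 1, datatype = "auto") {
  img <- RNifti::asNifti(array(as.vector(data), dim = dim(data)))
  RNifti::pixdim(img) <- rep(voxelSize, 3L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a 3D volume from NIfTI
#'
#' @param path NIfTI file path.
#' @return plain 3D array with attribute `voxelSize` (first spatial pixdim).
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L && all(d[-(1:3)] == 1L)) d <- d[1:3]
  if (length(d) < 3L) d <- c(d, rep(1L, 3L - length(d)))  # singleton planes
  arr <- array(as.vector(img), dim = d)
  attr(arr, "voxelSize") <- RNifti::pixdim(img)[1L]
  arr
}

# ---------------------------------------------------------------------------
# Connectomes (CSV + JSON sidecar)
# ---------------------------------------------------------------------------

#' Write a connectome matrix to CSV
#'
#' Writes the symmetric matrix with node labels as header row and first
#' column, plus a JSON sidecar (`<path>.json`) recording the variant and node
#' count. Read-back equals the original to full double precision.
#'
#' @param connectome a [Connectome-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeConnectome <- function(connectome, path) {
  stopifnot(is(connectome, "Connectome"))
  m <- connectome@matrix
  labels <- paste0("node_", seq_len(nrow(m)))
  dimnames(m) <- list(labels, labels)
  old <- options(digits = 17)
  on.exit(options(old))
  write.csv(m, path, quote = FALSE)
  jsonlite::write_json(
    list(variant = connectome@variant, nNodes = nrow(m)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a connectome matrix from CSV
#'
#' Restores the matrix and variant written by [writeConnectome()].
#' Asymmetric input is rejected.
#'
#' @param path CSV path.
#' @param tolerance symmetry tolerance (default `1e-8` relative).
#' @return a [Connectome-class].
#' @export
readConnectome <- function(path, tolerance = 1e-8) {
  df <- read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  scale <- max(abs(m), 1)
  if (max(abs(m - t(m))) > tolerance * scale)
    stop("connectome matrix is not symmetric")
  m <- (m + t(m)) / 2
  variant <- "standard"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$variant)) variant <- meta$variant
  }
  new("Connectome", matrix = m, variant = variant)
}

# ---------------------------------------------------------------------------
# Phantom export and cohort manifest
# ---------------------------------------------------------------------------

#' Write a phantom dataset to a directory
#'
#' Writes the signal map, WM mask, lesion mask and parcellation as NIfTI,
#' the bundle streamlines as TCK, and the true weights as CSV.
#'
#' @param phantomData list as returned by [makeCrossingPhantom()] (elements
#'   `phantom`, `signal`, `lesionMask`, `trueWeights`).
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
writePhantom <- function(phantomData, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- phantomData$phantom
  vs <- ph@voxelSize
  paths <- c(
    signal = file.path(dir, "signal.nii.gz"),
    wmMask = file.path(dir, "wm_mask.nii.gz"),
    lesionMask = file.path(dir, "lesion_mask.nii.gz"),
    parcellation = file.path(dir, "parcellation.nii.gz"),
    tractogram = file.path(dir, "tracts.tck"),
    trueWeights = file.path(dir, "true_weights.csv"))
  writeVolume(phantomData$signal, paths[["signal"]], vs)
  writeVolume(ph@wmMask + 0L, paths[["wmMask"]], vs, datatype = "int32")
  writeVolume(phantomData$lesionMask + 0L, paths[["lesionMask"]], vs,
              datatype = "int32")
  writeVolume(ph@parcellation, paths[["parcellation"]], vs,
              datatype = "int32")
  writeTractogram(tractogram(ph), paths[["tractogram"]])
  write.csv(data.frame(bundle = seq_along(phantomData$trueWeights),
                       trueWeight = phantomData$trueWeights),
            paths[["trueWeights"]], row.names = FALSE)
  invisible(paths)
}

#' Write a synthesized cohort to disk with a manifest
#'
#' One subdirectory per subject (signal per damage level, lesion mask) plus a
#' `manifest.csv` listing subject ids, damage levels and file paths, and the
#' shared tractogram/parcellation of the base phantom.
#'
#' @param cohort list as returned by [synthesizeCohort()].
#' @param dir output directory.
#' @return path of the manifest CSV, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- cohort$phantom
  vs <- ph@voxelSize
  writeTractogram(cohort$tractogram, file.path(dir, "tracts.tck"))
  writeVolume(ph@parcellation, file.path(dir, "parcellation.nii.gz"), vs,
              datatype = "int32")
  writeVolume(ph@wmMask + 0L, file.path(dir, "wm_mask.nii.gz"), vs,
              datatype = "int32")
  rows <- list()
  for (s in seq_along(cohort$subjects)) {
    sd <- file.path(dir, sprintf("sub-%03d", s))
    dir.create(sd, showWarnings = FALSE)
    subj <- cohort$subjects[[s]]
    maskPath <- file.path(sd, "lesion_mask.nii.gz")
    writeVolume(subj$lesionMask + 0L, maskPath, vs, datatype = "int32")
    for (li in seq_along(cohort$damageLevels)) {
      d <- cohort$damageLevels[li]
      sigPath <- file.path(sd, sprintf("signal_damage%03d.nii.gz",
                                       round(100 * d)))
      writeVolume(subj$signals[[li]], sigPath, vs)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, damageLevel = d, signal = sigPath,
        lesionMask = maskPath)
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

# ---------------------------------------------------------------------------
# Run configuration (YAML)
# ---------------------------------------------------------------------------

#' Read and validate a YAML run configuration
#'
#' Required fields: `signal`, `tractogram`, `parcellation` (paths that must
#' exist); optional: `lesionMask` (path), `tolerance` (positive), `density`
#' (in (0, 1]), `metrics`, `iterations`, `innerResamples`, `seed`
#' (nonnegative integer).
#'
#' @param path YAML file path.
#' @return validated named list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("signal", "tractogram", "parcellation")) {
    if (is.null(cfg[[f]])) stop("run config is missing field '", f, "'")
    if (!file.exists(cfg[[f]]))
      stop("run config field '", f, "' points to a missing file: ", cfg[[f]])
  }
  if (!is.null(cfg$lesionMask) && !file.exists(cfg$lesionMask))
    stop("run config field 'lesionMask' points to a missing file")
  if (is.null(cfg$tolerance)) cfg$tolerance <- 1e-10
  if (cfg$tolerance <= 0) stop("'tolerance' must be positive")
  if (!is.null(cfg$density) && (cfg$density <= 0 || cfg$density > 1))
    stop("'density' must lie in (0, 1]")
  if (is.null(cfg$seed)) cfg$seed <- 0L
  if (cfg$seed < 0 || cfg$seed != round(cfg$seed))
    stop("'seed' must be a nonnegative integer")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
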