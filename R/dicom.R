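# Minimal DICOM support: uncompressed, little-endian, single-frame axial CT
# series (explicit or implicit VR). This covers the format CT scanners
# export as "uncompressed DICOM"; compressed transfer syntaxes are
# rejected with an error.

.UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.UID_IMPLICIT_LE <- "1.2.840.10008.1.2"

.u16 <- function(raw, i) {
  readBin(raw[i:(i + 1L)], "integer", size = 2L, endian = "little",
          signed = FALSE)
}

.u32 <- function(raw, i) {
  readBin(raw[i:(i + 3L)], "integer", size = 4L, endian = "little")
}

.longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one DICOM file into a named list of raw element values
# (keys "GGGGEEEE" in upper-case hex).
.parseDicomFile <- function(path) {
  n <- file.size(path)
  raw <- readBin(path, "raw", n)
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L
  store <- list()
  explicit <- TRUE     # file meta group is always explicit
  metaDone <- FALSE
  while (pos + 7L <= length(raw)) {
    group <- .u16(raw, pos)
    elem <- .u16(raw, pos + 2L)
    if (!metaDone && group > 2L) {
      metaDone <- TRUE
      ts <- .dcmString(store, "00020010")
      if (is.null(ts)) ts <- .UID_EXPLICIT_LE
      if (ts == .UID_EXPLICIT_LE) explicit <- TRUE
      else if (ts == .UID_IMPLICIT_LE) explicit <- FALSE
      else stop("unsupported DICOM transfer syntax: ", ts)
    }
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .longVRs) {
        len <- .u32(raw, pos + 8L)
        dataPos <- pos + 12L
      } else {
        len <- .u16(raw, pos + 6L)
        dataPos <- pos + 8L
      }
    } else {
      len <- .u32(raw, pos + 4L)
      dataPos <- pos + 8L
    }
    if (len < 0L)
      stop("undefined-length DICOM element (sequences unsupported): ", path)
    key <- sprintf("%04X%04X", group, elem)
    store[[key]] <- if (len > 0L) raw[dataPos:(dataPos + len - 1L)] else raw(0)
    pos <- dataPos + len
  }
  store
}

.dcmString <- function(store, key) {
  v <- store[[key]]
  if (is.null(v)) return(NULL)
  s <- rawToChar(v[v != as.raw(0)])
  trimws(s)
}

.dcmNumeric <- function(store, key) {
  s <- .dcmString(store, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dcmU16 <- function(store, key) {
  v <- store[[key]]
  if (is.null(v)) return(NULL)
  .u16(v, 1L)
}

#' Read a DICOM series as a CT volume
#'
#' Reads all files of a single uncompressed little-endian DICOM series from
#' a directory, sorts the slices by spatial position, converts stored
#' values to Hounsfield units via each slice's rescale slope/intercept, and
#' assembles a [CTVolume-class]. The result is independent of file
#' ordering on disk.
#'
#' @param directory directory containing exactly one axial CT series.
#' @param gapTolerance maximum allowed deviation (mm) between inter-slice
#'   gaps before the series is rejected as corrupt.
#' @return A [CTVolume-class] in HU.
#' @seealso [writeDicomSeries()], [readVolume()]
#' @export
readDicomSeries <- function(directory, gapTolerance = 1e-3) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in DICOM directory: ", directory)
  slices <- lapply(files, .parseDicomFile)

  uids <- vapply(slices, function(s) {
    u <- .dcmString(s, "0020000E")
    if (is.null(u)) "" else u
  }, "")
  if (length(unique(uids)) != 1L)
    stop("mixed DICOM series in directory: found series identifiers ",
         paste(unique(uids), collapse = ", "))

  ipp <- vapply(slices, function(s) {
    p <- .dcmNumeric(s, "00200032")
    if (is.null(p) || length(p) != 3L)
      stop("missing ImagePositionPatient in series")
    p
  }, numeric(3))
  for (s in slices) {
    iop <- .dcmNumeric(s, "00200037")
    if (!is.null(iop) && max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-4)
      stop("non-axial slice orientation is not supported")
  }

  ord <- order(ipp[3, ])
  slices <- slices[ord]
  zs <- ipp[3, ord]
  nz <- length(slices)
  if (nz > 1L) {
    gaps <- diff(zs)
    if (any(gaps <= 0))
      stop("duplicate slice positions in series")
    if (max(gaps) - min(gaps) > gapTolerance)
      stop(sprintf(
        "non-uniform slice spacing (gaps %.4f..%.4f mm exceed tolerance %g)",
        min(gaps), max(gaps), gapTolerance))
    dz <- mean(gaps)
  } else {
    th <- .dcmNumeric(slices[[1]], "00180050")
    dz <- if (is.null(th)) 1 else th[1]
  }

  first <- slices[[1]]
  rows <- .dcmU16(first, "00280010")
  cols <- .dcmU16(first, "00280011")
  ps <- .dcmNumeric(first, "00280030")  # (row, col) spacing
  if (is.null(rows) || is.null(cols) || is.null(ps))
    stop("missing Rows/Columns/PixelSpacing in series")
  pid <- .dcmString(first, "00100020")
  if (is.null(pid)) pid <- ""

  vox <- array(0, c(nz, rows, cols))
  for (i in seq_len(nz)) {
    s <- slices[[i]]
    slope <- .dcmNumeric(s, "00281053")
    icept <- .dcmNumeric(s, "00281052")
    if (is.null(slope) || is.null(icept))
      stop("missing rescale slope/intercept; cannot convert to HU")
    bits <- .dcmU16(s, "00280100")
    if (is.null(bits) || bits != 16L)
      stop("only 16-bit DICOM pixel data is supported")
    signed <- identical(.dcmU16(s, "00280103"), 1L)
    px <- s[["7FE00010"]]
    if (is.null(px)) stop("missing pixel data in series")
    v <- readBin(px, "integer", n = rows * cols, size = 2L,
                 endian = "little", signed = signed)
    if (!signed) v[v < 0] <- v[v < 0] + 65536L
    vox[i, , ] <- slope * t(matrix(v, nrow = cols)) + icept
  }
  ctVolume(vox, spacing = c(dz, ps[1], ps[2]),
           origin = c(zs[1], ipp[2, ord[1]], ipp[1, ord[1]]),
           patientId = pid)
}

# ---- writing (round-trip fixture generation and NIfTI conversion tests) ----

.dcmPad <- function(s, uid = FALSE) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, if (uid) as.raw(0) else charToRaw(" "))
  r
}

.dcmElt <- function(group, elem, vr, value) {
  hdr <- writeBin(as.integer(c(group, elem)), raw(), size = 2L,
                  endian = "little")
  if (vr %in% .longVRs) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value), raw(), size = 4L, endian = "little"), value)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(length(value), raw(), size = 2L, endian = "little"), value)
  }
}

.dcmUS <- function(v) writeBin(as.integer(v), raw(), size = 2L,
                               endian = "little")

#' Write a CT volume as a DICOM series
#'
#' Writes one explicit-VR little-endian file per axial slice (stored
#' values = HU + 1024 with rescale intercept -1024), primarily to exercise
#' and validate the DICOM reading path.
#'
#' @param vol a [CTVolume-class]; HU values are rounded to integers.
#' @param directory output directory (created if needed).
#' @param seriesUID optional series instance UID.
#' @return The directory path, invisibly.
#' @export
writeDicomSeries <- function(vol, directory,
                             seriesUID = "1.2.826.0.1.3680043.2.1143.1") {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol)
  sp <- spacing(vol)
  orig <- origin(vol)
  vox <- round(voxels(vol))
  if (any(vox < -1024 | vox > 30000))
    stop("HU values outside the writable range [-1024, 30000]")
  for (i in seq_len(d[1])) {
    sopUID <- sprintf("%s.%d", seriesUID, i)
    meta <- c(
      .dcmElt(0x0002, 0x0010, "UI", .dcmPad(.UID_EXPLICIT_LE, uid = TRUE)))
    ipp <- sprintf("%.6f\\%.6f\\%.6f", orig[3], orig[2],
                   orig[1] + (i - 1) * sp[1])
    stored <- as.integer(t(vox[i, , ]) ) + 1024L  # col-fastest = DICOM order
    body <- c(
      .dcmElt(0x0008, 0x0018, "UI", .dcmPad(sopUID, uid = TRUE)),
      .dcmElt(0x0010, 0x0020, "LO", .dcmPad(patientId(vol))),
      .dcmElt(0x0018, 0x0050, "DS", .dcmPad(sprintf("%.6f", sp[1]))),
      .dcmElt(0x0020, 0x000E, "UI", .dcmPad(seriesUID, uid = TRUE)),
      .dcmElt(0x0020, 0x0013, "IS", .dcmPad(sprintf("%d", i))),
      .dcmElt(0x0020, 0x0032, "DS", .dcmPad(ipp)),
      .dcmElt(0x0020, 0x0037, "DS", .dcmPad("1\\0\\0\\0\\1\\0")),
      .dcmElt(0x0028, 0x0002, "US", .dcmUS(1)),
      .dcmElt(0x0028, 0x0004, "CS", .dcmPad("MONOCHROME2")),
      .dcmElt(0x0028, 0x0010, "US", .dcmUS(d[2])),
      .dcmElt(0x0028, 0x0011, "US", .dcmUS(d[3])),
      .dcmElt(0x0028, 0x0030, "DS",
              .dcmPad(sprintf("%.6f\\%.6f", sp[2], sp[3]))),
      .dcmElt(0x0028, 0x0100, "US", .dcmUS(16)),
      .dcmElt(0x0028, 0x0101, "US", .dcmUS(16)),
      .dcmElt(0x0028, 0x0102, "US", .dcmUS(15)),
      .dcmElt(0x0028, 0x0103, "US", .dcmUS(0)),
      .dcmElt(0x0028, 0x1052, "DS", .dcmPad("-1024")),
      .dcmElt(0x0028, 0x1053, "DS", .dcmPad("1")),
      .dcmElt(0x7FE0, 0x0010, "OW", .dcmUS(stored)))
    con <- file(file.path(directory, sprintf("slice_%04d.dcm", i)), "wb")
    writeBin(rep(as.raw(0), 128L), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, body), con)
    close(con)
  }
  invisible(directory)
}
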