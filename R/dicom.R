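# Minimal DICOM codec: explicit VR little endian only.
#
# Covers exactly the dialect this package emits: CT image slices
# (MONOCHROME2, 16-bit signed, rescale slope/intercept) and an RT
# Structure Set-style contour file (StructureSetROISequence +
# ROIContourSequence with CLOSED_PLANAR / POINT contours, sequences written
# with undefined lengths and item delimiters). Files written here are
# readable by standard DICOM tooling; the reader accepts both defined- and
# undefined-length sequences.
#
# Coordinate note: ContourData and ImagePositionPatient are stored in DICOM
# patient coordinates where +y points posterior (down for a supine
# patient); the package's volume frame uses y up, so y is negated on
# export and again on import.

UID_ROOT <- "1.2.826.0.1.3680043.9.7291"   # generated instance UIDs
UID_CT <- "1.2.840.10008.5.1.4.1.1.2"
UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_uid <- function(...) paste(UID_ROOT, ..., sep = ".")

.rtclear_env <- new.env(parent = emptyenv())
next_instance_number <- function() {
  n <- (.rtclear_env$instance %||% 0L) + 1L
  .rtclear_env$instance <- n
  n
}

pad_even <- function(raw_, pad = as.raw(0)) {
  if (length(raw_) %% 2L == 1L) c(raw_, pad) else raw_
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) {
  # unsigned 32-bit little endian
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

dcm_element <- function(group, elem, vr, value) {
  if (vr %in% c("UI")) {
    bytes <- pad_even(charToRaw(value), as.raw(0))
  } else if (vr %in% c("CS", "DS", "IS", "LO", "SH", "DA", "TM", "PN")) {
    bytes <- pad_even(charToRaw(value), charToRaw(" "))
  } else if (vr == "US") {
    bytes <- u16(value)
  } else if (vr %in% c("OW", "OB")) {
    bytes <- value
  } else stop("unsupported VR for writing: ", vr)
  head <- c(u16(group), u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), u32(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65535) stop("element too long for short VR")
    c(head, u16(length(bytes)), bytes)
  }
}

# sequence with undefined length; items = list of raw vectors (item bodies)
dcm_sequence <- function(group, elem, items) {
  body <- raw(0)
  for (it in items) {
    body <- c(body, u16(0xFFFE), u16(0xE000), u32(4294967295), it,
              u16(0xFFFE), u16(0xE00D), u32(0))
  }
  c(u16(group), u16(elem), charToRaw("SQ"), as.raw(c(0, 0)),
    u32(4294967295), body, u16(0xFFFE), u16(0xE0DD), u32(0))
}

# (0002,0000) group length needs the UL writer.
dcm_ul <- function(group, elem, value) {
  c(u16(group), u16(elem), charToRaw("UL"), u16(4L), u32(value))
}

write_dicom <- function(path, sop_class, sop_instance, body) {
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", sop_class),
    dcm_element(0x0002, 0x0003, "UI", sop_instance),
    dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_element(0x0002, 0x0012, "UI", dcm_uid("1"))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcm_ul(0x0002, 0x0000, length(meta)), con)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(path)
}

ds_fmt <- function(x) {
  s <- sub("0+$", "", sprintf("%.6f", x))
  sub("\\.$", "", s)
}

# ---------------------------------------------------------------------------
# CT series
# ---------------------------------------------------------------------------

#' Write a CT volume as a DICOM series
#'
#' One explicit-VR little-endian CT file per slice; pixel data is 16-bit
#' signed HU (rescale slope 1, intercept 0). Slice files carry
#' ImagePositionPatient in DICOM patient coordinates (y posterior); the
#' package volume frame (y up) is converted on the way out and back in.
#'
#' @param vol a [ct_volume()].
#' @param dir output directory (created if needed).
#' @param series_tag short string mixed into the generated series UID so
#'   distinct phantoms produce distinct series.
#' @return character vector of files written, invisibly.
#' @export
write_ct_series <- function(vol, dir, series_tag = "1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$voxels)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  series_uid <- dcm_uid("2", series_tag)
  study_uid <- dcm_uid("3", series_tag)
  xs <- ct_x_coords(vol)
  ys <- ct_y_coords(vol)
  # DICOM position of pixel (row 1, col 1) = (min x, most-anterior y): row
  # index runs down in DICOM (+y posterior), our j index runs up; row r maps
  # to j = ny + 1 - r, so row 1 is the top of the image (max y_up).
  pos_y_dicom <- -ys[ny]
  files <- character(nz)
  for (k in seq_len(nz)) {
    sop <- dcm_uid("4", series_tag, k)
    sl <- vol$voxels[, , k]
    # DICOM pixel order is row-major, rows top-to-bottom (j = ny..1)
    pix <- round(t(sl[, ny:1, drop = FALSE]))   # rows x cols matrix
    pix[pix < -32768] <- -32768
    pix[pix > 32767] <- 32767
    pixel_bytes <- writeBin(as.integer(t(pix)), raw(), size = 2,
                            endian = "little")  # t() back: walk row by row
    body <- c(
      dcm_element(0x0008, 0x0016, "UI", UID_CT),
      dcm_element(0x0008, 0x0018, "UI", sop),
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      dcm_element(0x0018, 0x0050, "DS",
                  ds_fmt(if (nz > 1) diff(vol$slice_positions[1:2]) else 1)),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", as.character(k)),
      dcm_element(0x0020, 0x0032, "DS",
                  paste(ds_fmt(xs[1]), ds_fmt(pos_y_dicom),
                        ds_fmt(vol$slice_positions[k]), sep = "\\")),
      dcm_element(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", ny),   # Rows
      dcm_element(0x0028, 0x0011, "US", nx),   # Columns
      dcm_element(0x0028, 0x0030, "DS",
                  paste(ds_fmt(vol$pixel_spacing[2]),
                        ds_fmt(vol$pixel_spacing[1]), sep = "\\")),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 1L),
      dcm_element(0x0028, 0x1052, "DS", "0"),
      dcm_element(0x0028, 0x1053, "DS", "1"),
      dcm_element(0x7FE0, 0x0010, "OW", pixel_bytes)
    )
    files[k] <- file.path(dir, sprintf("ct_%04d.dcm", k))
    write_dicom(files[k], UID_CT, sop, body)
  }
  invisible(files)
}

# ---------------------------------------------------------------------------
# Parser
# ---------------------------------------------------------------------------

rd_u16 <- function(raw_, at) as.integer(raw_[at]) + 256L * as.integer(raw_[at + 1L])
rd_u32 <- function(raw_, at) {
  as.numeric(raw_[at]) + 256 * as.numeric(raw_[at + 1L]) +
    65536 * as.numeric(raw_[at + 2L]) + 16777216 * as.numeric(raw_[at + 3L])
}

# Parse an explicit-VR-LE element stream into a flat list keyed
# "gggg,eeee"; SQ values become lists of nested keyed lists. Repeated tags
# within one level keep the last occurrence except inside sequence items.
parse_elements <- function(raw_, from, to) {
  out <- list()
  i <- from
  while (i <= to - 7L) {
    group <- rd_u16(raw_, i)
    elem <- rd_u16(raw_, i + 2L)
    if (group == 0xFFFE) {  # delimiter at this level: caller handles
      break
    }
    vr <- rawToChar(raw_[(i + 4L):(i + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- rd_u32(raw_, i + 8L)
      body_at <- i + 12L
    } else {
      len <- rd_u16(raw_, i + 6L)
      body_at <- i + 8L
    }
    key <- sprintf("%04X,%04X", group, elem)
    if (vr == "SQ") {
      items <- list()
      if (len == 4294967295) {       # undefined length
        j <- body_at
        repeat {
          g2 <- rd_u16(raw_, j); e2 <- rd_u16(raw_, j + 2L)
          il <- rd_u32(raw_, j + 4L)
          if (g2 == 0xFFFE && e2 == 0xE0DD) { j <- j + 8L; break }
          if (!(g2 == 0xFFFE && e2 == 0xE000)) stop("malformed sequence")
          if (il == 4294967295) {
            parsed <- parse_item_undef(raw_, j + 8L)
          } else {
            parsed <- list(value = parse_elements(raw_, j + 8L, j + 7L + il),
                           end = j + 8L + il)
          }
          items[[length(items) + 1L]] <- parsed$value
          j <- parsed$end
        }
        i <- j
      } else {
        j <- body_at
        stop_at <- body_at + len - 1L
        while (j <= stop_at) {
          g2 <- rd_u16(raw_, j); e2 <- rd_u16(raw_, j + 2L)
          il <- rd_u32(raw_, j + 4L)
          if (!(g2 == 0xFFFE && e2 == 0xE000)) stop("malformed sequence")
          if (il == 4294967295) {
            parsed <- parse_item_undef(raw_, j + 8L)
          } else {
            parsed <- list(value = parse_elements(raw_, j + 8L, j + 7L + il),
                           end = j + 8L + il)
          }
          items[[length(items) + 1L]] <- parsed$value
          j <- parsed$end
        }
        i <- stop_at + 1L
      }
      out[[key]] <- items
      next
    }
    body <- if (len > 0) raw_[body_at:(body_at + len - 1L)] else raw(0)
    out[[key]] <- parse_value(vr, body)
    i <- body_at + len
  }
  out
}

parse_item_undef <- function(raw_, from) {
  # item with undefined length: scan nested elements until item delimiter
  val <- parse_elements(raw_, from, length(raw_))
  # parse_elements stops at the first 0xFFFE tag at this level; find it
  j <- from
  depth <- 0L
  repeat {
    g <- rd_u16(raw_, j); e <- rd_u16(raw_, j + 2L)
    if (g == 0xFFFE) {
      if (e == 0xE00D) return(list(value = val, end = j + 8L))
      stop("malformed item")
    }
    vr <- rawToChar(raw_[(j + 4L):(j + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- rd_u32(raw_, j + 8L)
      if (vr == "SQ" && len == 4294967295) {
        j <- skip_sq_undef(raw_, j + 12L)
      } else j <- j + 12L + len
    } else {
      j <- j + 8L + rd_u16(raw_, j + 6L)
    }
  }
}

skip_sq_undef <- function(raw_, from) {
  j <- from
  repeat {
    g <- rd_u16(raw_, j); e <- rd_u16(raw_, j + 2L)
    il <- rd_u32(raw_, j + 4L)
    if (g == 0xFFFE && e == 0xE0DD) return(j + 8L)
    if (!(g == 0xFFFE && e == 0xE000)) stop("malformed sequence")
    if (il == 4294967295) {
      j <- parse_item_undef(raw_, j + 8L)$end
    } else j <- j + 8L + il
  }
}

strip_pad <- function(body) {
  while (length(body) > 0L &&
         (body[length(body)] == as.raw(0) || body[length(body)] == as.raw(32)))
    body <- body[-length(body)]
  body
}

parse_value <- function(vr, body) {
  if (vr %in% c("UI", "CS", "LO", "SH", "PN", "DA", "TM")) {
    rawToChar(strip_pad(body))
  } else if (vr == "DS") {
    as.numeric(strsplit(rawToChar(strip_pad(body)), "\\\\")[[1]])
  } else if (vr == "IS") {
    as.integer(strsplit(rawToChar(strip_pad(body)), "\\\\")[[1]])
  } else if (vr == "US") {
    readBin(body, "integer", n = length(body) / 2L, size = 2,
            endian = "little", signed = FALSE)
  } else if (vr == "UL") {
    rd_u32(body, 1L)
  } else if (vr %in% c("OW", "OB")) {
    body
  } else {
    body  # opaque
  }
}

read_dicom <- function(path) {
  raw_ <- readBin(path, "raw", n = file.size(path))
  if (length(raw_) < 160 ||
      rawToChar(raw_[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  # meta group: (0002,0000) UL group length right after the magic
  if (rd_u16(raw_, 133L) != 2L) stop("missing file meta group: ", path)
  meta_len <- rd_u32(raw_, 141L)
  meta <- parse_elements(raw_, 133L, 144L + meta_len)
  ts <- meta[["0002,0010"]]
  if (!is.null(ts) && ts != UID_EXPLICIT_LE)
    stop("unsupported transfer syntax: ", ts)
  body <- parse_elements(raw_, 145L + meta_len, length(raw_))
  list(meta = meta, data = body)
}

#' Load a DICOM CT series from a directory
#'
#' Reads every `.dcm` file, checks that all slices belong to one series,
#' sorts them by ImagePositionPatient (filename order is ignored), applies
#' the rescale slope/intercept, and validates uniform slice spacing.
#'
#' @param directory directory containing exactly one CT series.
#' @return a [ct_volume()] (isocenter and plate height unset; see
#'   [set_reference_geometry()]).
#' @export
load_ct_series <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) stop("no .dcm files in ", directory)
  slices <- lapply(files, read_dicom)
  series <- vapply(slices, function(s) s$data[["0020,000E"]] %||% "", "")
  if (length(unique(series)) != 1L)
    stop("directory contains mixed series")
  zs <- vapply(slices, function(s) s$data[["0020,0032"]][3], 0)
  ord <- order(zs)
  slices <- slices[ord]
  zs <- zs[ord]
  if (length(zs) > 1L) {
    gaps <- diff(zs)
    if (diff(range(gaps)) > 1e-3)
      stop("non-uniform slice gap (missing slice?): spread ",
           format(diff(range(gaps))), " mm")
  }
  s1 <- slices[[1L]]$data
  rows <- s1[["0028,0010"]]
  cols <- s1[["0028,0011"]]
  spacing <- s1[["0028,0030"]]  # row spacing, col spacing
  slope <- s1[["0028,1053"]]
  inter <- s1[["0028,1052"]]
  if (is.null(slope) || is.null(inter)) stop("missing rescale tags")
  pos <- s1[["0020,0032"]]
  nx <- cols; ny <- rows
  vox <- array(0, dim = c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    body <- slices[[k]]$data[["7FE0,0010"]]
    pix <- readBin(body, "integer", n = rows * cols, size = 2,
                   endian = "little", signed = TRUE)
    m <- matrix(pix, nrow = cols, ncol = rows)  # column of m = one DICOM row
    vox[, , k] <- m[, rows:1] * slope + inter   # flip rows: DICOM y down -> y up
  }
  origin_x <- pos[1]
  origin_y <- -(pos[2]) - (ny - 1) * spacing[1]  # y_up of j = 1
  ct_volume(vox, pixel_spacing = c(spacing[2], spacing[1]),
            slice_positions = zs, origin = c(origin_x, origin_y))
}

# ---------------------------------------------------------------------------
# RT structure export / import
# ---------------------------------------------------------------------------

#' Export a contour stack as an RT-structure-style DICOM file
#'
#' Writes one CLOSED_PLANAR ROI per collider, one POINT ROI named
#' `ISOCENTER`, and one CLOSED_PLANAR ROI named `PLATE_HEIGHT` (a reference
#' rectangle whose vertical coordinate is the plate top). Round-trips
#' through [import_contours()] within 1e-3 mm.
#'
#' @param stack a `contour_stack` with isocenter and plate height set.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_contours <- function(stack, path) {
  if (is.null(stack$isocenter_mm)) stop("contour stack has no isocenter")
  if (is.null(stack$plate_height_mm)) stop("contour stack has no plate height")
  labels <- unique(vapply(stack$contours, function(cc) cc$label, ""))
  roi_names <- c(labels, "ISOCENTER", "PLATE_HEIGHT")
  sop <- dcm_uid("5", next_instance_number())
  roi_items <- lapply(seq_along(roi_names), function(i) {
    c(dcm_element(0x3006, 0x0022, "IS", as.character(i)),
      dcm_element(0x3006, 0x0026, "LO", roi_names[i]))
  })
  to_dicom_xyz <- function(points3) {
    # volume (x, y_up, z) -> DICOM (x, -y, z)
    paste(apply(points3, 1, function(p)
      paste(ds_fmt(p[1]), ds_fmt(-p[2]), ds_fmt(p[3]), sep = "\\")),
      collapse = "\\")
  }
  contour_item <- function(points3, type) {
    c(dcm_element(0x3006, 0x0042, "CS", type),
      dcm_element(0x3006, 0x0046, "IS", as.character(nrow(points3))),
      dcm_element(0x3006, 0x0050, "DS", to_dicom_xyz(points3)))
  }
  rc_items <- list()
  for (i in seq_along(labels)) {
    cs <- contour_stack_label(stack, labels[i])
    items <- lapply(cs, function(cc)
      contour_item(cbind(cc$points, cc$z_mm), "CLOSED_PLANAR"))
    rc_items[[i]] <- c(dcm_element(0x3006, 0x0084, "IS", as.character(i)),
                       dcm_sequence(0x3006, 0x0040, items))
  }
  iso <- matrix(stack$isocenter_mm, 1)
  rc_items[[length(labels) + 1L]] <-
    c(dcm_element(0x3006, 0x0084, "IS", as.character(length(labels) + 1L)),
      dcm_sequence(0x3006, 0x0040, list(contour_item(iso, "POINT"))))
  h <- stack$plate_height_mm
  z0 <- stack$contours[[1L]]$z_mm
  plate_rect <- cbind(c(-100, 100, 100, -100), h, z0)
  rc_items[[length(labels) + 2L]] <-
    c(dcm_element(0x3006, 0x0084, "IS", as.character(length(labels) + 2L)),
      dcm_sequence(0x3006, 0x0040, list(contour_item(plate_rect, "CLOSED_PLANAR"))))
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", UID_RTSTRUCT),
    dcm_element(0x0008, 0x0018, "UI", sop),
    dcm_element(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_element(0x3006, 0x0002, "SH", "rtclear"),
    dcm_sequence(0x3006, 0x0020, roi_items),
    dcm_sequence(0x3006, 0x0039, rc_items)
  )
  write_dicom(path, UID_RTSTRUCT, sop, body)
  invisible(path)
}

#' Import a contour stack from an RT-structure-style file
#'
#' Inverse of [export_contours()]; fails when the isocenter or plate-height
#' structure is missing.
#'
#' @param path file written by [export_contours()] (or following the same
#'   tag layout).
#' @return a `contour_stack`.
#' @export
import_contours <- function(path) {
  d <- read_dicom(path)$data
  rois <- d[["3006,0020"]]
  rcs <- d[["3006,0039"]]
  if (is.null(rois) || is.null(rcs)) stop("malformed structure file: ", path)
  names_by_num <- character(0)
  for (it in rois)
    names_by_num[as.character(it[["3006,0022"]])] <- it[["3006,0026"]]
  contours <- list()
  isocenter <- NULL
  plate_height <- NULL
  for (it in rcs) {
    num <- as.character(it[["3006,0084"]])
    nm <- names_by_num[[num]]
    for (ci in it[["3006,0040"]]) {
      pts <- matrix(ci[["3006,0050"]], ncol = 3, byrow = TRUE)
      pts[, 2] <- -pts[, 2]   # DICOM y posterior -> y up
      if (identical(nm, "ISOCENTER")) {
        isocenter <- pts[1, ]
      } else if (identical(nm, "PLATE_HEIGHT")) {
        plate_height <- pts[1, 2]
      } else {
        contours[[length(contours) + 1L]] <-
          slice_contour(pts[, 1:2, drop = FALSE], z_mm = pts[1, 3], label = nm)
      }
    }
  }
  if (is.null(isocenter)) stop("structure file lacks an ISOCENTER structure")
  if (is.null(plate_height)) stop("structure file lacks a PLATE_HEIGHT structure")
  if (length(contours) == 0L) stop("structure file has no collider contours")
  structure(list(contours = contours, isocenter_mm = isocenter,
                 plate_height_mm = plate_height),
            class = "contour_stack")
}
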