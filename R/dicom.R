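# Minimal DICOM reader for RTSTRUCT contour data.
#
# No installed R package parses DICOM, so this file implements the narrow
# subset needed here: explicit- or implicit-VR little-endian datasets, with
# recursive sequence (SQ) handling for the structure-set ROI and ROI-contour
# sequences. It deliberately ignores everything else (pixel data, CT, RTPLAN).

.TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length.
.LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

readUint16 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}

readUint32 <- function(bytes, pos) {
  # as double: lengths can exceed .Machine$integer.max (0xFFFFFFFF = undefined)
  as.numeric(bytes[pos]) + 256 * as.numeric(bytes[pos + 1L]) +
    65536 * as.numeric(bytes[pos + 2L]) + 16777216 * as.numeric(bytes[pos + 3L])
}

readAscii <- function(bytes, pos, len) {
  if (len <= 0) {
    return("")
  }
  b <- bytes[pos:(pos + len - 1L)]
  b <- b[b != as.raw(0)] # UI values are NUL-padded
  gsub(" +$", "", rawToChar(b))
}

# Parse one element header. Returns list(group, element, vr, length, dataPos, nextPos).
parseElementHeader <- function(bytes, pos, explicit) {
  group <- readUint16(bytes, pos)
  element <- readUint16(bytes, pos + 2L)
  if (group == 0xFFFE) { # item / delimiter tags: always implicit-style
    len <- readUint32(bytes, pos + 4L)
    return(list(
      group = group, element = element, vr = NA_character_,
      length = len, dataPos = pos + 8L
    ))
  }
  if (explicit) {
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- readUint32(bytes, pos + 8L)
      list(group = group, element = element, vr = vr, length = len, dataPos = pos + 12L)
    } else {
      len <- as.numeric(readUint16(bytes, pos + 6L))
      list(group = group, element = element, vr = vr, length = len, dataPos = pos + 8L)
    }
  } else {
    len <- readUint32(bytes, pos + 4L)
    list(group = group, element = element, vr = NA_character_, length = len, dataPos = pos + 8L)
  }
}

.UNDEFINED <- 4294967295 # 0xFFFFFFFF

# Tags we descend into / read. Key = group*65536 + element.
.tagKey <- function(group, element) group * 65536 + element

.SEQ_TAGS <- c(
  .tagKey(0x3006, 0x0020), # StructureSetROISequence
  .tagKey(0x3006, 0x0039), # ROIContourSequence
  .tagKey(0x3006, 0x0040) # ContourSequence
)
.VALUE_TAGS <- c(
  .tagKey(0x3006, 0x0022), # ROINumber
  .tagKey(0x3006, 0x0026), # ROIName
  .tagKey(0x3006, 0x0084), # ReferencedROINumber
  .tagKey(0x3006, 0x0050) # ContourData
)

# Find the end of an undefined-length sequence/item by walking its content.
# Returns position just past the delimiter.
skipUndefined <- function(bytes, pos, explicit, itemLevel) {
  repeat {
    if (pos + 7L > length(bytes)) stop("truncated DICOM stream inside undefined-length region")
    group <- readUint16(bytes, pos)
    element <- readUint16(bytes, pos + 2L)
    if (group == 0xFFFE && element == (if (itemLevel) 0xE00D else 0xE0DD)) {
      return(pos + 8L)
    }
    h <- parseElementHeader(bytes, pos, explicit)
    if (h$length == .UNDEFINED) {
      inner <- h$group == 0xFFFE && h$element == 0xE000
      pos <- skipUndefined(bytes, h$dataPos, explicit, itemLevel = inner)
    } else {
      pos <- h$dataPos + h$length
    }
  }
}

# Parse a sequence of items between pos and end (or until sequence delimiter
# when end is NA). Each item is parsed as a dataset (list of wanted elements).
parseSequence <- function(bytes, pos, end, explicit) {
  items <- list()
  repeat {
    if (is.na(end)) {
      if (pos + 7L > length(bytes)) stop("truncated sequence")
      g <- readUint16(bytes, pos)
      e <- readUint16(bytes, pos + 2L)
      if (g == 0xFFFE && e == 0xE0DD) {
        pos <- pos + 8L
        break
      }
    } else if (pos >= end) {
      break
    }
    h <- parseElementHeader(bytes, pos, explicit)
    if (!(h$group == 0xFFFE && h$element == 0xE000)) {
      stop(sprintf("expected sequence item, found tag (%04x,%04x)", h$group, h$element))
    }
    if (h$length == .UNDEFINED) {
      itemEnd <- skipUndefined(bytes, h$dataPos, explicit, itemLevel = TRUE)
      parsed <- parseDataset(bytes, h$dataPos, itemEnd - 8L, explicit)
      pos <- itemEnd
    } else {
      parsed <- parseDataset(bytes, h$dataPos, h$dataPos + h$length, explicit)
      pos <- h$dataPos + h$length
    }
    items[[length(items) + 1L]] <- parsed
  }
  list(items = items, nextPos = pos)
}

# Parse a dataset span, returning a list keyed by tag key with either string
# values (for the value tags above) or item lists (for the sequence tags).
parseDataset <- function(bytes, pos, end, explicit) {
  out <- list()
  while (pos < end) {
    h <- parseElementHeader(bytes, pos, explicit)
    key <- .tagKey(h$group, h$element)
    isSeq <- key %in% .SEQ_TAGS || identical(h$vr, "SQ")
    if (isSeq) {
      seqEnd <- if (h$length == .UNDEFINED) NA else h$dataPos + h$length
      sq <- parseSequence(bytes, h$dataPos, seqEnd, explicit)
      if (key %in% .SEQ_TAGS) out[[as.character(key)]] <- sq$items
      pos <- sq$nextPos
    } else if (h$length == .UNDEFINED) {
      pos <- skipUndefined(bytes, h$dataPos, explicit, itemLevel = FALSE)
    } else {
      if (key %in% .VALUE_TAGS) {
        out[[as.character(key)]] <- readAscii(bytes, h$dataPos, h$length)
      }
      pos <- h$dataPos + h$length
    }
  }
  out
}

# Read the ROI name -> point-cloud map from an RTSTRUCT file.
readRTStructContours <- function(path) {
  bytes <- readBin(path, what = "raw", n = file.info(path)$size)
  pos <- 1L
  transferSyntax <- .TS_IMPLICIT_LE
  if (length(bytes) > 132 && rawToChar(bytes[129:132]) == "DICM") {
    pos <- 133L
    # file meta group (0002): always explicit VR little endian
    while (pos + 7L <= length(bytes) && readUint16(bytes, pos) == 0x0002) {
      h <- parseElementHeader(bytes, pos, explicit = TRUE)
      if (h$group == 0x0002 && h$element == 0x0010) {
        transferSyntax <- readAscii(bytes, h$dataPos, h$length)
      }
      pos <- h$dataPos + h$length
    }
  }
  explicit <- if (transferSyntax == .TS_EXPLICIT_LE) {
    TRUE
  } else if (transferSyntax == .TS_IMPLICIT_LE) {
    FALSE
  } else {
    stop("unsupported DICOM transfer syntax: ", transferSyntax)
  }
  ds <- parseDataset(bytes, pos, length(bytes) + 1L, explicit)

  ssroi <- ds[[as.character(.tagKey(0x3006, 0x0020))]]
  rcont <- ds[[as.character(.tagKey(0x3006, 0x0039))]]
  if (is.null(ssroi)) stop("not an RTSTRUCT: StructureSetROISequence (3006,0020) absent")
  roiNames <- character(0)
  for (item in ssroi) {
    num <- trimws(item[[as.character(.tagKey(0x3006, 0x0022))]])
    nm <- item[[as.character(.tagKey(0x3006, 0x0026))]]
    roiNames[[num]] <- nm
  }
  clouds <- stats::setNames(vector("list", length(roiNames)), unname(roiNames))
  for (nm in names(clouds)) clouds[[nm]] <- matrix(numeric(0), ncol = 3)
  if (!is.null(rcont)) {
    for (item in rcont) {
      refRaw <- item[[as.character(.tagKey(0x3006, 0x0084))]]
      if (is.null(refRaw)) next
      ref <- trimws(refRaw)
      nm <- roiNames[[ref]]
      if (is.null(nm)) next
      contours <- item[[as.character(.tagKey(0x3006, 0x0040))]]
      pts <- list()
      for (ct in contours) {
        dataStr <- ct[[as.character(.tagKey(0x3006, 0x0050))]]
        if (is.null(dataStr)) next
        vals <- as.numeric(strsplit(dataStr, "\\\\")[[1]])
        if (length(vals) %% 3 != 0) stop("ContourData length not a multiple of 3 for ROI ", nm)
        pts[[length(pts) + 1L]] <- matrix(vals, ncol = 3, byrow = TRUE)
      }
      if (length(pts) > 0) clouds[[nm]] <- do.call(rbind, pts)
    }
  }
  lapply(clouds, function(m) {
    colnames(m) <- c("x", "y", "z")
    m
  })
}
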