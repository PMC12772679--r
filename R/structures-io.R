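#' Default role-resolution patterns
#'
#' Maps each canonical structure role to a case-insensitive regular expression
#' used to resolve clinic-specific ROI names. Shipped as an editable JSON
#' config in `inst/extdata/role_map.json`; this function loads it (or a user
#' supplied file of the same shape).
#'
#' @param path Optional path to a JSON file `{role: pattern, ...}`.
#' @return Named character vector, one pattern per canonical role.
#' @export
defaultRoleMap <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "role_map.json", package = "autofif")
  }
  rm <- jsonlite::read_json(path, simplifyVector = TRUE)
  rm <- unlist(rm)
  missing <- setdiff(structureRoles(), names(rm))
  if (length(missing) > 0) {
    stop("role map lacks pattern(s) for: ", paste(missing, collapse = ", "))
  }
  rm[structureRoles()]
}

# Resolve ROI names against a role map. Returns named character vector
# role -> ROI name; errors on missing or ambiguous roles.
resolveRoles <- function(roiNames, roleMap) {
  out <- character(0)
  for (role in structureRoles()) {
    pat <- roleMap[[role]]
    if (is.null(pat) || is.na(pat)) stop("role map has no pattern for role ", role)
    hits <- roiNames[grepl(pat, roiNames, ignore.case = TRUE, perl = TRUE)]
    if (length(hits) == 0) {
      stop("no ROI matches role ", role, " (pattern '", pat, "')")
    }
    if (length(hits) > 1) {
      stop(
        "ambiguous match for role ", role, ": candidates ",
        paste(sQuote(hits), collapse = ", ")
      )
    }
    out[[role]] <- hits
  }
  out
}

#' Load a DICOM RTSTRUCT structure set
#'
#' Reads the structure-set ROI and contour sequences of an RTSTRUCT file and
#' assembles the five canonical roles into a [StructureSet-class]. Contour
#' vertices are concatenated per ROI into point clouds in native LPS
#' millimetre coordinates. RTSTRUCT files carry no isocenter; unless one is
#' supplied, the brain centroid is used with a warning.
#'
#' @param path Path to an RTSTRUCT DICOM file (explicit or implicit VR,
#'   little endian).
#' @param roleMap Named character vector of case-insensitive regex patterns,
#'   one per canonical role (default [defaultRoleMap()]). Each role must
#'   resolve to exactly one ROI; ambiguous matches raise an error listing the
#'   candidates.
#' @param isocenter Optional length-3 isocenter (mm, LPS).
#' @param caseId Case identifier; defaults to the file name.
#' @return A [StructureSet-class].
#' @export
loadRTStruct <- function(path, roleMap = defaultRoleMap(), isocenter = NULL,
                         caseId = sub("\\.dcm$", "", basename(path))) {
  rt <- readRTStructContours(path)
  resolved <- resolveRoles(names(rt), roleMap)
  structures <- lapply(resolved, function(nm) rt[[nm]])
  names(structures) <- names(resolved)
  empty <- names(structures)[vapply(structures, nrow, integer(1)) == 0]
  if (length(empty) > 0) {
    stop("ROI(s) resolved but contain no contour data: ", paste(empty, collapse = ", "))
  }
  structureSet(structures, isocenter = isocenter, caseId = caseId)
}

#' Load a plain-text structure fixture
#'
#' The fixture format is line oriented: a `case <id>` line, then one block per
#' structure starting with `structure <ROLE>` followed by one `x y z` point
#' per line (mm, LPS), and an optional `isocenter` block with a single point.
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path Fixture file path.
#' @return A [StructureSet-class]; when the isocenter block is absent the
#'   brain centroid is used with a warning.
#' @export
loadFixture <- function(path) {
  lines <- readLines(path, warn = FALSE)
  structuresList <- list()
  iso <- NULL
  caseIdVal <- sub("\\.[^.]*$", "", basename(path))
  current <- NULL # NULL, "isocenter", or role name
  buf <- list()
  flush <- function() {
    if (is.null(current) || length(buf) == 0) {
      return()
    }
    m <- do.call(rbind, buf)
    if (identical(current, "isocenter")) {
      if (nrow(m) != 1) stop("isocenter block must contain exactly one point")
      iso <<- as.numeric(m[1, ])
    } else {
      structuresList[[current]] <<- m
    }
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    if (grepl("^case\\s+", ln)) {
      caseIdVal <- sub("^case\\s+", "", ln)
      next
    }
    if (grepl("^structure\\s+", ln)) {
      flush()
      buf <- list()
      current <- sub("^structure\\s+", "", ln)
      next
    }
    if (grepl("^isocenter\\b", ln)) {
      flush()
      buf <- list()
      current <- "isocenter"
      next
    }
    parts <- strsplit(ln, "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 3 || any(is.na(vals))) {
      stop("malformed fixture line ", i, ": '", lines[[i]], "'")
    }
    if (is.null(current)) stop("coordinate line ", i, " appears before any block header")
    buf[[length(buf) + 1]] <- vals
  }
  flush()
  structureSet(structuresList, isocenter = iso, caseId = caseIdVal)
}

#' Write a StructureSet as a plain-text fixture
#'
#' Inverse of [loadFixture()]: `loadFixture(saveFixture(s, f))` reproduces `s`
#' exactly for finite inputs (coordinates are written in full precision).
#'
#' @param s A [StructureSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
saveFixture <- function(s, path) {
  stopifnot(is(s, "StructureSet"))
  validObject(s)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste("case", s@caseId), con)
  for (nm in names(s@structures)) {
    writeLines(paste("structure", nm), con)
    m <- s@structures[[nm]]
    writeLines(paste(formatCoord(m[, 1]), formatCoord(m[, 2]), formatCoord(m[, 3])), con)
  }
  writeLines("isocenter", con)
  writeLines(paste(
    formatCoord(s@isocenter[1]), formatCoord(s@isocenter[2]),
    formatCoord(s@isocenter[3])
  ), con)
  invisible(path)
}
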