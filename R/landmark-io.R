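## Stream serialisation. Two equivalent on-disk forms are supported:
## a long-form CSV (frame_index, landmark_id, x, y, z, valid) with the
## video/section metadata in '#key=value' header lines, and a nested JSON
## document. Coordinates survive a round trip to >= 12 significant digits.

.streamError <- function(msg, class) {
  stop(structure(class = c(class, "tasteFaceError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.fmtNum <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Read a landmark stream from CSV or JSON
#'
#' Frames are returned sorted by frame index; estimator-failure frames are
#' preserved with \code{valid = FALSE} and empty coordinates. Section
#' annotations (SI/SII bounds) are read from the file's metadata and
#' validated against the frame range.
#'
#' @param path input file.
#' @param format "csv" or "json"; guessed from the file extension by
#'   default.
#' @return A \linkS4class{LandmarkStream}.
#' @seealso \code{\link{writeLandmarkStream}}
#' @export
readLandmarkStream <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  if (!file.exists(path))
    .streamError(paste0("file not found: ", path), "ioError")
  if (format == "json") .readStreamJSON(path) else .readStreamCSV(path)
}

.parseMeta <- function(lines) {
  kv <- sub("^#", "", lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

.metaInt <- function(meta, key) {
  v <- meta[[key]]
  if (is.null(v) || identical(v, "NA") || !nzchar(v)) NA_integer_
  else as.integer(v)
}

.readStreamCSV <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  n.meta <- match(FALSE, hdr) - 1L
  meta <- .parseMeta(lines[seq_len(n.meta)])
  body <- lines[!hdr]
  tab <- tryCatch(
    utils::read.csv(text = body, stringsAsFactors = FALSE,
                    colClasses = c(frame_index = "integer",
                                   landmark_id = "integer",
                                   x = "numeric", y = "numeric",
                                   z = "numeric", valid = "logical")),
    error = function(e) .streamError(
      paste0("malformed landmark CSV at ", path, ": ",
             conditionMessage(e)), "parseError"))
  need <- c("frame_index", "landmark_id", "x", "y", "z", "valid")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    .streamError(paste0("landmark CSV ", path, " lacks columns: ",
                        paste(miss, collapse = ", ")), "parseError")
  bad <- which(is.na(tab$frame_index) | is.na(tab$valid))
  if (length(bad))
    .streamError(sprintf(
      "malformed row in %s: data line %d has missing frame_index or valid",
      path, bad[1]), "parseError")
  bad <- which(tab$valid & (is.na(tab$landmark_id) |
                              is.na(tab$x) | is.na(tab$y) | is.na(tab$z)))
  if (length(bad))
    .streamError(sprintf(
      "malformed row in %s: data line %d is valid but has missing values",
      path, bad[1]), "parseError")
  frameList <- lapply(split(seq_len(nrow(tab)), tab$frame_index),
    function(i) {
      vl <- tab$valid[i[1]]
      if (!vl)
        return(LandmarkFrame(tab$frame_index[i[1]], valid = FALSE))
      LandmarkFrame(tab$frame_index[i[1]], tab$landmark_id[i],
                    cbind(x = tab$x[i], y = tab$y[i], z = tab$z[i]),
                    valid = TRUE)
    })
  names(frameList) <- NULL
  sec <- tryCatch(
    SectionAnnotation(.metaInt(meta, "si_start"), .metaInt(meta, "si_end"),
                      .metaInt(meta, "sii_start"), .metaInt(meta, "sii_end")),
    error = function(e) .streamError(
      paste0("invalid section annotation in ", path, ": ",
             conditionMessage(e)), "validationError"))
  fps <- meta[["fps"]]
  fps <- if (is.null(fps) || identical(fps, "NA")) NA_real_
         else as.numeric(fps)
  tryCatch(
    LandmarkStream(videoId = meta[["video_id"]] %||% "",
                   subjectId = meta[["subject_id"]] %||% "",
                   frames = frameList, sections = sec, fps = fps),
    error = function(e) .streamError(
      paste0("invalid stream in ", path, ": ", conditionMessage(e)),
      "validationError"))
}

.readStreamJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  frameList <- lapply(doc$frames, function(f) {
    lm <- f$landmarks
    if (!isTRUE(f$valid) || length(lm) == 0L)
      return(LandmarkFrame(f$frame_index, valid = isTRUE(f$valid)))
    ids <- vapply(lm, function(l) as.integer(l$id), integer(1))
    m <- cbind(x = vapply(lm, function(l) as.numeric(l$x), numeric(1)),
               y = vapply(lm, function(l) as.numeric(l$y), numeric(1)),
               z = vapply(lm, function(l) as.numeric(l$z), numeric(1)))
    LandmarkFrame(f$frame_index, ids, m, valid = TRUE)
  })
  s <- doc$sections
  toInt <- function(v) if (is.null(v)) NA_integer_ else as.integer(v)
  sec <- tryCatch(
    SectionAnnotation(toInt(s$si_start), toInt(s$si_end),
                      toInt(s$sii_start), toInt(s$sii_end)),
    error = function(e) .streamError(
      paste0("invalid section annotation in ", path, ": ",
             conditionMessage(e)), "validationError"))
  tryCatch(
    LandmarkStream(videoId = doc$video_id %||% "",
                   subjectId = doc$subject_id %||% "",
                   frames = frameList, sections = sec,
                   fps = if (is.null(doc$fps)) NA_real_
                         else as.numeric(doc$fps)),
    error = function(e) .streamError(
      paste0("invalid stream in ", path, ": ", conditionMessage(e)),
      "validationError"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a landmark stream to CSV or JSON
#'
#' The output is re-readable by \code{\link{readLandmarkStream}} with
#' bitwise-equal indices and validity flags and coordinates equal to at
#' least 12 significant digits.
#'
#' @param stream a \linkS4class{LandmarkStream}.
#' @param path output file.
#' @param format "csv" or "json"; guessed from the extension by default.
#' @export
writeLandmarkStream <- function(stream, path,
                                format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  validObject(stream)
  if (format == "json") .writeStreamJSON(stream, path)
  else .writeStreamCSV(stream, path)
  invisible(path)
}

.secField <- function(v) if (is.na(v)) "NA" else as.character(v)

.writeStreamCSV <- function(stream, path) {
  s <- stream@sections
  meta <- c(
    "#tasteface_stream=v1",
    paste0("#video_id=", stream@videoId),
    paste0("#subject_id=", stream@subjectId),
    paste0("#fps=", .secField(stream@fps)),
    paste0("#si_start=", .secField(s@siStart)),
    paste0("#si_end=", .secField(s@siEnd)),
    paste0("#sii_start=", .secField(s@siiStart)),
    paste0("#sii_end=", .secField(s@siiEnd)))
  rows <- lapply(stream@frames, function(f) {
    if (!f@valid || length(f@landmarkId) == 0L)
      return(paste(f@frameIndex, "NA", "NA", "NA", "NA",
                   tolower(f@valid), sep = ","))
    paste(f@frameIndex, f@landmarkId, .fmtNum(f@coords[, 1]),
          .fmtNum(f@coords[, 2]), .fmtNum(f@coords[, 3]),
          tolower(f@valid), sep = ",")
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(meta, "frame_index,landmark_id,x,y,z,valid",
               unlist(rows)), con)
}

.writeStreamJSON <- function(stream, path) {
  s <- stream@sections
  naNull <- function(v) if (is.na(v)) NULL else v
  doc <- list(
    format = "tasteface_stream",
    video_id = stream@videoId,
    subject_id = stream@subjectId,
    fps = naNull(stream@fps),
    sections = list(si_start = s@siStart, si_end = s@siEnd,
                    sii_start = naNull(s@siiStart),
                    sii_end = naNull(s@siiEnd)),
    frames = lapply(stream@frames, function(f) {
      list(frame_index = f@frameIndex, valid = f@valid,
           landmarks = if (f@valid && length(f@landmarkId))
             lapply(seq_along(f@landmarkId), function(i)
               list(id = f@landmarkId[i], x = f@coords[i, 1],
                    y = f@coords[i, 2], z = f@coords[i, 3]))
           else list())
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
}

#' Read and validate a session-metadata table
#'
#' One row per (subject, taste) session: demographics, strip order,
#' hedonic score (5-point smiley scale) and, when a video was recorded and
#' analysable, its id and SI/SII section bounds. Categorical fields are
#' validated against the study's allowed values and per-subject taste
#' uniqueness is enforced.
#'
#' @param path CSV with headers subject_id, age, sex, taste,
#'   order_sequence, hedonic_score, video_id, si_start, si_end, sii_start,
#'   sii_end (the last five may be empty when no video exists).
#' @return data.frame of validated session records (factor taste with the
#'   canonical level order).
#' @export
readSessionTable <- function(path) {
  if (!file.exists(path))
    .streamError(paste0("file not found: ", path), "ioError")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- c("subject_id", "age", "sex", "taste", "order_sequence",
            "hedonic_score")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    .streamError(paste0("session table lacks columns: ",
                        paste(miss, collapse = ", ")), "parseError")
  for (col in c("video_id", "si_start", "si_end", "sii_start", "sii_end"))
    if (is.null(tab[[col]])) tab[[col]] <- NA
  validateSessionRecords(tab)
}

#' Validate a data.frame of session records
#'
#' @param tab data.frame with the session-table columns.
#' @return The validated data.frame, taste as a factor with canonical
#'   levels.
#' @export
validateSessionRecords <- function(tab) {
  bad <- which(!tab$taste %in% tasteLevels())
  if (length(bad))
    .streamError(sprintf("row %d: unknown taste '%s'", bad[1],
                         tab$taste[bad[1]]), "validationError")
  bad <- which(!tab$sex %in% c("male", "female"))
  if (length(bad))
    .streamError(sprintf("row %d: sex must be male or female", bad[1]),
                 "validationError")
  bad <- which(!is.na(tab$hedonic_score) &
                 (tab$hedonic_score < 1 | tab$hedonic_score > 5 |
                    tab$hedonic_score != round(tab$hedonic_score)))
  if (length(bad))
    .streamError(sprintf("row %d: hedonic_score must be an integer in 1..5",
                         bad[1]), "validationError")
  bad <- which(!is.na(tab$age) & (tab$age < 4 | tab$age > 11))
  if (length(bad))
    .streamError(sprintf("row %d: age must be in 4..11 years", bad[1]),
                 "validationError")
  bad <- which(!tab$order_sequence %in% orderSequences())
  if (length(bad))
    .streamError(sprintf("row %d: unknown order_sequence '%s'", bad[1],
                         tab$order_sequence[bad[1]]), "validationError")
  dup <- duplicated(tab[, c("subject_id", "taste")])
  if (any(dup))
    .streamError(sprintf("duplicate (subject, taste) pair: %s / %s",
                         tab$subject_id[which(dup)[1]],
                         tab$taste[which(dup)[1]]), "validationError")
  tab$taste <- factor(tab$taste, levels = tasteLevels())
  tab$hedonic_score <- as.integer(tab$hedonic_score)
  tab$age <- as.integer(tab$age)
  tab
}

#' Write a session-metadata table
#'
#' @param records validated session data.frame.
#' @param path output CSV path.
#' @export
writeSessionTable <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Select analysis frames of a task section
#'
#' Returns, in order, the frames with \code{valid = TRUE} whose index lies
#' inside the requested section's inclusive bounds. Requesting SII on a
#' stream without an annotated post-tasting section is an explicit error
#' (condition class \code{absentSectionError}), never a silent empty
#' result.
#'
#' @param stream a \linkS4class{LandmarkStream}.
#' @param section "SI", "SII" or "SI+SII".
#' @return list of valid \linkS4class{LandmarkFrame}s.
#' @export
selectFrames <- function(stream, section = c("SI+SII", "SI", "SII")) {
  section <- match.arg(section)
  s <- stream@sections
  wantSII <- section %in% c("SII", "SI+SII")
  if (section == "SII" && is.na(s@siiStart))
    .streamError(paste0("stream ", stream@videoId,
                        " has no annotated SII section"),
                 "absentSectionError")
  idx <- vapply(stream@frames, slot, integer(1), name = "frameIndex")
  valid <- vapply(stream@frames, slot, logical(1), name = "valid")
  inSI <- idx >= s@siStart & idx <= s@siEnd
  inSII <- if (!is.na(s@siiStart)) idx >= s@siiStart & idx <= s@siiEnd
           else rep(FALSE, length(idx))
  keep <- switch(section,
                 "SI" = inSI,
                 "SII" = inSII,
                 "SI+SII" = inSI | inSII)
  stream@frames[keep & valid]
}

#' Subset a frame to the landmarks of a map
#'
#' @param frame a valid \linkS4class{LandmarkFrame}.
#' @param map a \linkS4class{LandmarkMap}; every map id must be present in
#'   the frame, otherwise the error names the missing id and its region.
#' @return A \linkS4class{LandmarkFrame} containing exactly the map's ids.
#' @export
subsetLandmarks <- function(frame, map) {
  ids <- landmarkIds(map)
  missIdx <- which(!ids %in% frame@landmarkId)
  if (length(missIdx)) {
    id <- ids[missIdx[1]]
    region <- names(Filter(function(v) id %in% v, map@regions))[1]
    .streamError(sprintf(
      "frame %d lacks landmark id %d (region %s)",
      frame@frameIndex, id, region), "missingLandmarkError")
  }
  pos <- match(ids, frame@landmarkId)
  LandmarkFrame(frame@frameIndex, ids, frame@coords[pos, , drop = FALSE],
                valid = frame@valid)
}
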