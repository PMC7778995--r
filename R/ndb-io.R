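#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## The .ndb dialect implemented here
##
## Header keywords (one per line, keyword in columns 1-6):
##   HEADER <title>          TITLE of the deposition (may be empty)
##   AUTHOR <name>           repeatable, one author per line
##   GENOME <assembly>       genome assembly label
##   UNITS  <unit>           unit of length for fields 7-9
##   TIMESR <0|1>            1 when the models form a time series
##   NUMMDL <k>              number of models in the file
##   SEQCHR <chain> <i> ...  compartment-annotation sequence per chain,
##                           wrapped; <i> is the 1-based serial of the first
##                           code on the line
## Body records are fixed-width (widths mirror PDB conventions: 8.3f-style
## coordinate fields, left-justified codes); a whitespace-delimited 12-token
## fallback is accepted on read. Missing values are a single dash.
##   cols  1-6   field 1  element type    CHROM | DNAELE
##   cols  7-14  field 2  element index   %8d
##   cols 16-19  field 3  epigenetic code %-4s (two-letter code)
##   cols 21-32  field 4  genetic info    %-12s (e.g. CTCF motif+orientation)
##   cols 34-37  field 5  chain id        %-4s (e.g. 1M, 1P)
##   cols 38-45  field 6  within-chain index %8d
##   cols 46-75  fields 7-9  x, y, z      %10.3f each
##   cols 76-99  fields 10-11 genomic start/end (bp, 1-based inclusive) %12d
##   cols 100-109 field 12 spatial spread %10.3f
## Loop records:   LOOPS <anchor_a %8d><anchor_b %8d> <class>
## Model blocks:   MODEL <n> ... ENDMDL ; file ends with END.
## ---------------------------------------------------------------------------

.NDB_RECORD_FMT <- "%-6s%8d %-4s %-12s %-4s%8d%10.3f%10.3f%10.3f%12s%12s%10s"

.fmtOrDash <- function(x, fmt, width) {
  ifelse(is.na(x), sprintf(paste0("%", width, "s"), "-"), sprintf(fmt, x))
}

.formatNdbRecord <- function(rec, xyz) {
  gi <- rec$genetic_info
  gi[is.na(gi) | gi == ""] <- "-"
  sprintf(.NDB_RECORD_FMT,
          rec$element_type, rec$element_index, rec$code, gi, rec$chain_id,
          rec$within_chain_index, xyz[, 1L], xyz[, 2L], xyz[, 3L],
          .fmtOrDash(rec$genomic_start, "%12d", 12L),
          .fmtOrDash(rec$genomic_end, "%12d", 12L),
          .fmtOrDash(rec$spread, "%10.3f", 10L))
}

#' Write a structural ensemble to an .ndb file
#'
#' Serialises a [ChromEnsemble-class] to the human-readable `.ndb` text
#' format: a PDB-style header (title, authors, assembly, length unit,
#' per-chain compartment-annotation sequence), one fixed-width 12-field
#' record per nuclear element per model, loop records, and `MODEL`/`ENDMDL`
#' delimiters between frames. The output is byte-stable: writing, reading
#' and re-writing yields an identical file.
#'
#' @param ensemble a valid [ChromEnsemble-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readNdb()]
#' @export
writeNdb <- function(ensemble, path) {
  if (length(ensemble@models) == 0L)
    stop("refusing to write an ensemble with an empty model list")
  validObject(ensemble)
  rec <- ensemble@records
  if (any(grepl("[[:space:]]", rec$genetic_info)))
    stop("genetic_info must not contain whitespace (use e.g. 'CTCF+')")
  if (any(nchar(rec$genetic_info) > 12L))
    stop("genetic_info exceeds the 12-character field width")
  if (any(nchar(rec$code) > 4L))
    stop("epigenetic code exceeds the 4-character field width")
  hdr <- ensemble@header
  lines <- c(
    sub(" +$", "", sprintf("HEADER %s", hdr$title)),
    sprintf("AUTHOR %s", hdr$authors),
    if (nzchar(hdr$assembly)) sprintf("GENOME %s", hdr$assembly),
    sprintf("UNITS  %s", hdr$length_unit),
    sprintf("TIMESR %d", as.integer(ensemble@isTimeSeries)),
    sprintf("NUMMDL %d", length(ensemble@models))
  )
  for (ch in names(hdr$compartment_sequence)) {
    codes <- hdr$compartment_sequence[[ch]]
    starts <- seq(1L, length(codes), by = 13L)
    lines <- c(lines, vapply(starts, function(s) {
      e <- min(s + 12L, length(codes))
      sprintf("SEQCHR %-4s%6d  %s", ch, s, paste(codes[s:e], collapse = " "))
    }, character(1)))
  }
  body <- character()
  for (m in seq_along(ensemble@models)) {
    body <- c(body,
              sprintf("MODEL %8d", m),
              .formatNdbRecord(rec, round(ensemble@models[[m]], 3L)),
              "ENDMDL")
  }
  lp <- ensemble@loops
  looplines <- if (nrow(lp))
    sprintf("LOOPS %8d%8d %-8s", lp$anchor_a, lp$anchor_b, lp$loop_class)
  else character()
  writeLines(c(lines, body, looplines, "END"), path)
  invisible(path)
}

.parseIntOrNA <- function(s) {
  s <- trimws(s)
  ifelse(s == "-" | s == "", NA_integer_, suppressWarnings(as.integer(s)))
}
.parseNumOrNA <- function(s) {
  s <- trimws(s)
  ifelse(s == "-" | s == "", NA_real_, suppressWarnings(as.numeric(s)))
}

.parseNdbRecordLine <- function(line, lineno) {
  if (nchar(line) >= 100L) {
    f <- list(
      element_type = trimws(substr(line, 1L, 6L)),
      element_index = .parseIntOrNA(substr(line, 7L, 14L)),
      code = trimws(substr(line, 16L, 19L)),
      genetic_info = trimws(substr(line, 21L, 32L)),
      chain_id = trimws(substr(line, 34L, 37L)),
      within_chain_index = .parseIntOrNA(substr(line, 38L, 45L)),
      x = .parseNumOrNA(substr(line, 46L, 55L)),
      y = .parseNumOrNA(substr(line, 56L, 65L)),
      z = .parseNumOrNA(substr(line, 66L, 75L)),
      genomic_start = .parseIntOrNA(substr(line, 76L, 87L)),
      genomic_end = .parseIntOrNA(substr(line, 88L, 99L)),
      spread = .parseNumOrNA(substr(line, 100L, 109L))
    )
  } else {
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
    if (length(tok) != 12L)
      stop(sprintf("malformed record at line %d: expected 12 fields, found %d",
                   lineno, length(tok)))
    f <- list(
      element_type = tok[1L], element_index = .parseIntOrNA(tok[2L]),
      code = tok[3L], genetic_info = tok[4L], chain_id = tok[5L],
      within_chain_index = .parseIntOrNA(tok[6L]),
      x = .parseNumOrNA(tok[7L]), y = .parseNumOrNA(tok[8L]),
      z = .parseNumOrNA(tok[9L]),
      genomic_start = .parseIntOrNA(tok[10L]),
      genomic_end = .parseIntOrNA(tok[11L]),
      spread = .parseNumOrNA(tok[12L])
    )
  }
  if (is.na(f$element_index) || is.na(f$within_chain_index) ||
      is.na(f$x) || is.na(f$y) || is.na(f$z))
    stop(sprintf("malformed record at line %d: unparseable index or coordinate", lineno))
  if (f$genetic_info == "-") f$genetic_info <- ""
  f
}

#' Read an .ndb file into a structural ensemble
#'
#' Parses the 12-field `.ndb` text format (see [writeNdb()] for the layout
#' implemented here). All models are returned, in file order, sharing one
#' per-element metadata table; loop records are attached. Both the
#' fixed-width layout and a whitespace-delimited 12-token fallback are
#' accepted; malformed lines raise an error naming the line number, and an
#' inconsistent record count across models raises a structure error.
#'
#' @param path path to an `.ndb` file.
#' @return A [ChromEnsemble-class].
#' @examples
#' e <- makeRandomEnsemble(nBeads = 4, nModels = 2, seed = 1)
#' f <- tempfile(fileext = ".ndb")
#' writeNdb(e, f)
#' identical(readNdb(f), e)
#' @export
readNdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list(title = "", authors = character(), assembly = "",
              length_unit = "reduced")
  timesr <- FALSE
  nummdl <- NA_integer_
  seqchr <- list()
  loops <- list()
  model_recs <- list()   # list of per-model lists of parsed records
  cur <- NULL
  in_model <- FALSE
  saw_model_kw <- FALSE
  flat <- list()         # records outside MODEL blocks (single-model file)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    kw <- trimws(substr(line, 1L, 6L))
    rest <- if (nchar(line) > 7L) substr(line, 8L, nchar(line)) else ""
    if (kw == "HEADER") { hdr$title <- trimws(rest) }
    else if (kw == "AUTHOR") { hdr$authors <- c(hdr$authors, trimws(rest)) }
    else if (kw == "GENOME") { hdr$assembly <- trimws(rest) }
    else if (kw == "UNITS") { hdr$length_unit <- trimws(rest) }
    else if (kw == "TIMESR") { timesr <- trimws(rest) == "1" }
    else if (kw == "NUMMDL") { nummdl <- as.integer(trimws(rest)) }
    else if (kw == "SEQCHR") {
      ch <- trimws(substr(line, 8L, 11L))
      codes <- strsplit(trimws(substr(line, 18L, nchar(line))), "[[:space:]]+")[[1L]]
      seqchr[[ch]] <- c(seqchr[[ch]], codes)
    }
    else if (kw == "MODEL") {
      saw_model_kw <- TRUE; in_model <- TRUE; cur <- list()
    }
    else if (kw == "ENDMDL") {
      in_model <- FALSE
      model_recs[[length(model_recs) + 1L]] <- cur
      cur <- NULL
    }
    else if (kw == "LOOPS") {
      tok <- strsplit(trimws(rest), "[[:space:]]+")[[1L]]
      if (length(tok) < 2L)
        stop(sprintf("malformed LOOPS record at line %d", i))
      loops[[length(loops) + 1L]] <- data.frame(
        anchor_a = as.integer(tok[1L]), anchor_b = as.integer(tok[2L]),
        loop_class = if (length(tok) >= 3L) tok[3L] else "UNKNOWN",
        stringsAsFactors = FALSE)
    }
    else if (kw == "END") { break }
    else if (kw %in% c("CHROM", "DNAELE")) {
      f <- .parseNdbRecordLine(line, i)
      if (in_model) cur[[length(cur) + 1L]] <- f
      else flat[[length(flat) + 1L]] <- f
    }
    else stop(sprintf("unrecognised record '%s' at line %d", kw, i))
  }
  if (!saw_model_kw) {
    if (!length(flat)) stop("no records found in ", path)
    model_recs <- list(flat)
  } else if (length(flat)) {
    stop("records found outside MODEL/ENDMDL blocks in a multi-model file")
  }
  nrec <- vapply(model_recs, length, integer(1))
  if (length(unique(nrec)) != 1L)
    stop(sprintf("inconsistent record count across models: %s",
                 paste(unique(nrec), collapse = " vs ")))
  first <- model_recs[[1L]]
  toRow <- function(f) data.frame(
    element_type = f$element_type, element_index = f$element_index,
    code = f$code, genetic_info = f$genetic_info, chain_id = f$chain_id,
    within_chain_index = f$within_chain_index,
    genomic_start = f$genomic_start, genomic_end = f$genomic_end,
    spread = f$spread, stringsAsFactors = FALSE)
  records <- do.call(rbind, lapply(first, toRow))
  models <- lapply(model_recs, function(recs)
    matrix(unlist(lapply(recs, function(f) c(f$x, f$y, f$z))),
           ncol = 3L, byrow = TRUE))
  loops <- if (length(loops)) do.call(rbind, loops) else NULL
  e <- chromEnsemble(records, models, loops = loops, header = hdr,
                     isTimeSeries = timesr)
  if (!is.na(nummdl) && nummdl != length(models))
    stop(sprintf("structure error: NUMMDL says %d models but %d were read",
                 nummdl, length(models)))
  if (length(seqchr)) {
    derived <- e@header$compartment_sequence
    for (ch in names(seqchr)) {
      if (!identical(unname(seqchr[[ch]]), unname(derived[[ch]])))
        stop(sprintf(
          "structure error: SEQCHR for chain %s disagrees with the body records", ch))
    }
  }
  e
}

#' Validate an .ndb file or ensemble
#'
#' Runs the full invariant set (monotone within-chain indices,
#' genomic_end >= genomic_start, single-record DNAELE chains, loop anchors
#' resolving to existing CHROM indices, model consistency) and returns the
#' issues found rather than throwing.
#'
#' @param x a file path or a [ChromEnsemble-class].
#' @return `TRUE` if valid, otherwise a character vector of issues.
#' @export
validateNdb <- function(x) {
  if (is.character(x)) {
    e <- tryCatch(readNdb(x), error = function(err) conditionMessage(err))
    if (is.character(e)) return(e)
    x <- e
  }
  .validChromEnsemble(x)
}

## .spw ------------------------------------------------------------------------

#' Project an ensemble to the .spw (spacewalk-style) format
#'
#' The `.spw` format is the 6-column projection of `.ndb` fields
#' 1, 10, 11, 7, 8, 9: element type, genomic start, genomic end, x, y, z,
#' in record order. Multi-model ensembles emit one `MODEL`/`ENDMDL` block
#' per frame.
#'
#' @param ensemble a [ChromEnsemble-class]; every `CHROM` record must carry
#'   genomic coordinates.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readSpw()]
#' @export
toSpw <- function(ensemble, path) {
  validObject(ensemble)
  rec <- ensemble@records
  chrom <- rec$element_type == "CHROM"
  if (any(chrom & (is.na(rec$genomic_start) | is.na(rec$genomic_end))))
    stop("cannot project to .spw: a CHROM record lacks genomic coordinates")
  lines <- character()
  for (m in seq_along(ensemble@models)) {
    xyz <- round(ensemble@models[[m]], 3L)
    rows <- sprintf("%-6s %11s %11s %10.3f %10.3f %10.3f",
                    rec$element_type,
                    ifelse(is.na(rec$genomic_start), "-", rec$genomic_start),
                    ifelse(is.na(rec$genomic_end), "-", rec$genomic_end),
                    xyz[, 1L], xyz[, 2L], xyz[, 3L])
    lines <- c(lines, sprintf("MODEL %d", m), rows, "ENDMDL")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an .spw file, re-inflating to a structural ensemble
#'
#' Only fields 1, 10, 11, 7, 8, 9 are stored in `.spw`; the remaining
#' `.ndb` fields take documented defaults on re-inflation: element index
#' and within-chain index are assigned in row order, the epigenetic code is
#' `"UN"` (unknown, preserved-verbatim extensible code), genetic info is
#' empty, all records join chain `"1"`, and spread is absent.
#'
#' @param path path to an `.spw` file.
#' @return A [ChromEnsemble-class].
#' @export
readSpw <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- trimws(lines[keep])
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  # headerless files are a single frame
  frame_id <- if (any(is_model)) cumsum(is_model) else rep(1L, length(lines))
  body <- !is_model & !is_end
  if (!any(body)) stop("no rows found in ", path)
  parseRows <- function(rows) {
    tok <- strsplit(rows, "[[:space:]]+")
    bad <- which(lengths(tok) != 6L)
    if (length(bad))
      stop(sprintf("malformed .spw row: expected 6 fields, got %d",
                   lengths(tok)[bad[1L]]))
    m <- do.call(rbind, tok)
    list(element_type = m[, 1L],
         genomic_start = .parseIntOrNA(m[, 2L]),
         genomic_end = .parseIntOrNA(m[, 3L]),
         xyz = matrix(as.numeric(m[, 4:6]), ncol = 3L))
  }
  frames <- lapply(split(lines[body], frame_id[body]), parseRows)
  first <- frames[[1L]]
  n <- length(first$element_type)
  records <- data.frame(
    element_type = first$element_type,
    element_index = seq_len(n),
    code = "UN", genetic_info = "", chain_id = "1",
    within_chain_index = seq_len(n),
    genomic_start = first$genomic_start,
    genomic_end = first$genomic_end,
    spread = NA_real_, stringsAsFactors = FALSE)
  chromEnsemble(records, lapply(frames, `[[`, "xyz"))
}

## .cndb -----------------------------------------------------------------------

.CNDB_MAGIC <- charToRaw("CNDB")
.CNDB_VERSION <- 1L

#' Write / read the binary .cndb container
#'
#' `.cndb` is the lossless binary sibling of `.ndb` (in the same way a
#' binary macromolecular format relates to `.pdb`): a little-endian
#' container holding a 4-byte magic, a format version, a JSON metadata
#' block (header, per-element records, loops, time-series flag) and one
#' float64 coordinate array per frame. Coordinates are stored at full
#' double precision, so `fromCndb(toCndb(e))` is exactly `e`; frame arrays
#' are fixed-size, so single frames can be read by offset without loading
#' the whole file.
#'
#' @param ensemble a valid [ChromEnsemble-class].
#' @param path output (input) file path.
#' @return `toCndb()`: `path`, invisibly. `fromCndb()`: a
#'   [ChromEnsemble-class].
#' @export
toCndb <- function(ensemble, path) {
  validObject(ensemble)
  meta <- list(
    header = ensemble@header[setdiff(names(ensemble@header),
                                     c("model_count", "compartment_sequence"))],
    records = ensemble@records,
    loops = ensemble@loops,
    is_time_series = ensemble@isTimeSeries
  )
  raw_meta <- charToRaw(as.character(jsonlite::toJSON(
    meta, dataframe = "columns", digits = NA, na = "null", null = "null",
    auto_unbox = FALSE)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.CNDB_MAGIC, con)
  writeBin(.CNDB_VERSION, con, size = 4L, endian = "little")
  writeBin(length(raw_meta), con, size = 4L, endian = "little")
  writeBin(raw_meta, con)
  writeBin(length(ensemble@models), con, size = 4L, endian = "little")
  writeBin(nrow(ensemble@records), con, size = 4L, endian = "little")
  for (m in ensemble@models)
    writeBin(as.vector(m), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname toCndb
#' @param frames optional integer vector of frame numbers to read (1-based);
#'   default all.
#' @export
fromCndb <- function(path, frames = NULL) {
  sz <- file.info(path)$size
  if (is.na(sz)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, .CNDB_MAGIC))
    stop("integrity error: not a .cndb container (bad magic)")
  ver <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!identical(ver, .CNDB_VERSION))
    stop("integrity error: unsupported .cndb version ", ver)
  mlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  raw_meta <- readBin(con, "raw", mlen)
  if (length(raw_meta) < mlen) stop("integrity error: truncated metadata block")
  meta <- jsonlite::fromJSON(rawToChar(raw_meta), simplifyVector = TRUE)
  n_models <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  n_rec <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  data_start <- 4L + 4L + 4L + mlen + 4L + 4L
  expected <- data_start + as.numeric(n_models) * n_rec * 3 * 8
  if (sz != expected)
    stop(sprintf("integrity error: file has %d bytes, expected %d", sz, expected))
  if (is.null(frames)) frames <- seq_len(n_models)
  stopifnot(all(frames >= 1L), all(frames <= n_models))
  models <- lapply(frames, function(k) {
    seek(con, data_start + (k - 1) * n_rec * 3 * 8)
    v <- readBin(con, "double", n_rec * 3L, size = 8L, endian = "little")
    matrix(v, ncol = 3L)
  })
  records <- as.data.frame(meta$records, stringsAsFactors = FALSE)
  records$genetic_info <- as.character(records$genetic_info)
  records$genetic_info[is.na(records$genetic_info)] <- ""
  loops <- if (!is.null(meta$loops) && length(meta$loops) &&
               length(meta$loops$anchor_a))
    as.data.frame(meta$loops, stringsAsFactors = FALSE) else NULL
  hdr <- meta$header
  hdr$authors <- as.character(unlist(hdr$authors))
  chromEnsemble(records, models, loops = loops, header = hdr,
                isTimeSeries = isTRUE(as.logical(meta$is_time_series)))
}

## .pdb ------------------------------------------------------------------------

#' Export an ensemble as a fixed-column PDB file
#'
#' Writes one `MODEL`/`ENDMDL` block per frame with one `ATOM` row per
#' nuclear element, for use with standard 3D structure viewers. An optional
#' per-bead scalar track (e.g. an integrated ChIP-seq signal) is linearly
#' rescaled to `[0, 99.99]` and written into the B-factor column so viewers
#' can colour by signal intensity. In the PDB dialect, atom serials above
#' 99999 and residue numbers above 9999 wrap around modulo the field
#' capacity (documented index-wrapping behaviour).
#'
#' @param ensemble a [ChromEnsemble-class] with finite coordinates.
#' @param path output file path.
#' @param scalarTrack optional numeric vector, one value per element,
#'   written (rescaled) into the B-factor column.
#' @return `path`, invisibly.
#' @export
toPdb <- function(ensemble, path, scalarTrack = NULL) {
  validObject(ensemble)
  rec <- ensemble@records
  n <- nrow(rec)
  if (!all(vapply(ensemble@models, function(m) all(is.finite(m)), logical(1))))
    stop("coordinates must be finite for PDB export")
  if (!is.null(scalarTrack)) {
    if (length(scalarTrack) != n)
      stop("scalarTrack length must equal the element count")
    rng <- range(scalarTrack)
    bfac <- if (diff(rng) == 0) rep(0, n)
            else (scalarTrack - rng[1L]) / diff(rng) * 99.99
  } else bfac <- rep(0, n)
  serial <- ((seq_len(n) - 1L) %% 99999L) + 1L
  resseq <- ((rec$within_chain_index - 1L) %% 9999L) + 1L
  chain <- substr(rec$chain_id, 1L, 1L)
  resname <- substr(ifelse(rec$code == "", "UNK", rec$code), 1L, 3L)
  lines <- c(sprintf("TITLE     %s", ensemble@header$title),
             sprintf("REMARK    LENGTH UNIT %s", ensemble@header$length_unit))
  for (m in seq_along(ensemble@models)) {
    xyz <- ensemble@models[[m]]
    rows <- sprintf("ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                    serial, resname, chain, resseq,
                    xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, bfac)
    lines <- c(lines, sprintf("MODEL %8d", m), rows, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

## .gro ------------------------------------------------------------------------

#' Export an ensemble (first frame) as a .gro coordinate file
#'
#' The `.gro` file carries the initial polymer position in 3D space, one
#' row per bead, with the compartment annotation of each segment encoded
#' in the residue and atom name columns (`A1`..`B4`; neutral/centromeric
#' loci as `NA`).
#'
#' @param ensemble a [ChromEnsemble-class].
#' @param path output file path.
#' @param annotations optional [AnnotationSequence-class] or character
#'   vector overriding the record codes.
#' @param model frame to export (default first).
#' @return `path`, invisibly.
#' @export
toGro <- function(ensemble, path, annotations = NULL, model = 1L) {
  validObject(ensemble)
  labels <- if (is.null(annotations)) ensemble@records$code
            else if (is(annotations, "AnnotationSequence")) annotations@labels
            else as.character(annotations)
  if (length(labels) != nrow(ensemble@records))
    stop("annotation length must equal the element count")
  writeGro(ensemble@models[[model]], labels, path,
           title = ensemble@header$title)
}

#' @rdname toGro
#' @param positions n-by-3 coordinate matrix.
#' @param labels per-bead annotation labels.
#' @param title title line.
#' @export
writeGro <- function(positions, labels, path, title = "chromosome") {
  n <- nrow(positions)
  stopifnot(length(labels) == n)
  resid <- ((seq_len(n) - 1L) %% 99999L) + 1L
  lines <- c(
    if (nzchar(title)) title else "chromosome",
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            resid, labels, labels, resid,
            positions[, 1L], positions[, 2L], positions[, 3L]),
    sprintf("%10.5f%10.5f%10.5f", 0, 0, 0)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read back a .gro file written by this package
#'
#' @param path path to a `.gro` file.
#' @return list with `positions` (n-by-3 matrix) and `labels` (residue
#'   names).
#' @export
readGro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2L]))
  rows <- lines[2L + seq_len(n)]
  labels <- trimws(substr(rows, 6L, 10L))
  xyz <- matrix(c(as.numeric(substr(rows, 21L, 28L)),
                  as.numeric(substr(rows, 29L, 36L)),
                  as.numeric(substr(rows, 37L, 44L))), ncol = 3L)
  list(positions = xyz, labels = labels)
}
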