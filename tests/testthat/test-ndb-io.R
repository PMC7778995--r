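# Format ecosystem: .ndb / .spw / .cndb / .pdb / .gro

test_that("ndb round trip is identity across chain layouts and a second rewrite is byte-stable", {
  cases <- list(
    list(nBeads = 3, nModels = 2, nChains = 1, nDnaele = 0, withLoops = FALSE, withSpread = FALSE),
    list(nBeads = 6, nModels = 1, nChains = 2, nDnaele = 1, withLoops = TRUE, withSpread = TRUE),
    list(nBeads = 10, nModels = 5, nChains = 2, nDnaele = 2, withLoops = TRUE, withSpread = FALSE)
  )
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    e <- makeRandomEnsemble(cs$nBeads, cs$nModels, seed = 100 + k,
                            nChains = cs$nChains, nDnaele = cs$nDnaele,
                            withLoops = cs$withLoops, withSpread = cs$withSpread)
    f1 <- withr::local_tempfile(fileext = ".ndb")
    writeNdb(e, f1)
    e2 <- readNdb(f1)
    expect_identical(e2, e)
    f2 <- withr::local_tempfile(fileext = ".ndb")
    writeNdb(e2, f2)
    expect_identical(readLines(f2), readLines(f1))
  }
})

test_that("maternal and paternal chain labels yield distinct chains", {
  e <- makeRandomEnsemble(4, 1, seed = 7, nChains = 2)
  rec <- records(e)
  expect_setequal(unique(rec$chain_id), c("1M", "1P"))
  cs <- ndbHeader(e)$compartment_sequence
  expect_named(cs, c("1M", "1P"), ignore.order = TRUE)
  expect_length(cs[["1M"]], 4L)
})

test_that("unbound DNAELE rows carry dashes for the genomic fields and re-read as absent", {
  e <- makeRandomEnsemble(3, 1, seed = 9, nDnaele = 1)
  f <- withr::local_tempfile(fileext = ".ndb")
  writeNdb(e, f)
  line <- grep("^DNAELE", readLines(f), value = TRUE)[1]
  expect_match(line, " - ")
  rec <- records(readNdb(f))
  ele <- rec[rec$element_type == "DNAELE", ]
  expect_true(is.na(ele$genomic_start) && is.na(ele$genomic_end))
  expect_true(ele$code %in% c("TF", "CH"))
})

test_that("loop records survive the round trip with their class labels", {
  e <- makeRandomEnsemble(8, 2, seed = 21, withLoops = TRUE)
  f <- withr::local_tempfile(fileext = ".ndb")
  writeNdb(e, f)
  expect_true(any(grepl("^LOOPS", readLines(f))))
  lp <- loops(readNdb(f))
  expect_identical(lp, loops(e))
  expect_true(all(lp$loop_class %in% c("COHESIN", "POLYCOMB", "UNKNOWN")))
})

test_that("writeNdb refuses an empty model list and invalid ensembles", {
  e <- makeRandomEnsemble(3, 1, seed = 1)
  broken <- e
  broken@models <- list()
  expect_error(writeNdb(broken, tempfile()), "empty model")
})

test_that("malformed and structurally inconsistent files raise located errors", {
  e <- makeRandomEnsemble(3, 2, seed = 5)
  f <- withr::local_tempfile(fileext = ".ndb")
  writeNdb(e, f)
  lines <- readLines(f)
  rec_at <- grep("^CHROM", lines)[1]
  bad <- lines
  bad[rec_at] <- "CHROM broken line"
  fb <- withr::local_tempfile(); writeLines(bad, fb)
  expect_error(readNdb(fb), sprintf("line %d", rec_at))
  # drop one record from the second model -> record count mismatch
  bad2 <- lines[-grep("^CHROM", lines)[4]]
  fb2 <- withr::local_tempfile(); writeLines(bad2, fb2)
  expect_error(readNdb(fb2), "inconsistent record count|SEQCHR")
})

test_that("validation rejects the documented invariant violations", {
  e <- makeRandomEnsemble(5, 1, seed = 2)
  # non-monotone within-chain index
  b <- e; b@records$within_chain_index <- rev(b@records$within_chain_index)
  expect_match(paste(validateNdb(b), collapse = " "), "strictly increasing")
  # genomic_end < genomic_start
  b <- e; b@records$genomic_end[2] <- b@records$genomic_start[2] - 10L
  expect_match(paste(validateNdb(b), collapse = " "), "genomic_end")
  # multi-record DNAELE chain
  b <- makeRandomEnsemble(3, 1, seed = 3, nDnaele = 1)
  b@records$element_type[2] <- "DNAELE"
  b@records$chain_id[2] <- b@records$chain_id[4]
  expect_false(isTRUE(validateNdb(b)))
  # loop anchors referencing absent indices
  b <- e
  b@loops <- data.frame(anchor_a = 1L, anchor_b = 99L, loop_class = "COHESIN")
  expect_match(paste(validateNdb(b), collapse = " "), "anchor")
})

test_that("spw projection emits exactly fields 1,10,11,7,8,9 in record order", {
  e <- makeRandomEnsemble(3, 2, seed = 31)
  f <- withr::local_tempfile(fileext = ".spw")
  toSpw(e, f)
  lines <- readLines(f)
  expect_length(grep("^MODEL", lines), 2L)   # one block per frame
  rows <- grep("^CHROM", lines, value = TRUE)
  expect_length(rows, 6L)
  rec <- records(e)
  for (m in 1:2) {
    xyz <- round(coords(e, m), 3)
    for (i in 1:3) {
      tok <- strsplit(trimws(rows[(m - 1) * 3 + i]), "[[:space:]]+")[[1]]
      expect_length(tok, 6L)
      expect_identical(tok[1], rec$element_type[i])
      expect_equal(as.integer(tok[2:3]),
                   c(rec$genomic_start[i], rec$genomic_end[i]))
      expect_equal(as.numeric(tok[4:6]), unname(xyz[i, ]))
    }
  }
})

test_that("spw re-inflation recovers the projected fields and applies documented defaults", {
  e <- makeRandomEnsemble(4, 2, seed = 33)
  f <- withr::local_tempfile(fileext = ".spw")
  toSpw(e, f)
  e2 <- readSpw(f)
  expect_identical(nModels(e2), 2L)
  rec <- records(e); rec2 <- records(e2)
  expect_identical(rec2$element_type, rec$element_type)
  expect_identical(rec2$genomic_start, rec$genomic_start)
  expect_identical(rec2$genomic_end, rec$genomic_end)
  for (m in 1:2) expect_equal(coords(e2, m), round(coords(e, m), 3))
  # documented defaults for the non-projected fields
  expect_identical(rec2$code, rep("UN", 4))
  expect_identical(rec2$chain_id, rep("1", 4))
  expect_identical(rec2$element_index, 1:4)
  expect_true(all(is.na(rec2$spread)))
})

test_that("spw projection refuses CHROM records without genomic coordinates", {
  e <- makeRandomEnsemble(3, 1, seed = 35)
  e@records$genomic_start[2] <- NA_integer_
  expect_error(toSpw(e, tempfile()), "genomic coordinates")
})

test_that("cndb round trip is lossless at full float precision", {
  e <- makeRandomEnsemble(6, 100, seed = 41, withLoops = TRUE, withSpread = TRUE)
  # full-precision coordinates (not representable at 3 decimals)
  e@models <- lapply(e@models, function(m) m + pi * 1e-5)
  f <- withr::local_tempfile(fileext = ".cndb")
  toCndb(e, f)
  e2 <- fromCndb(f)
  expect_identical(e2@models, e@models)
  expect_equal(e2, e)
  expect_identical(max(abs(e2@models[[50]] - e@models[[50]])), 0)
})

test_that("cndb supports partial-frame reads and detects corruption", {
  e <- makeRandomEnsemble(5, 20, seed = 43)
  f <- withr::local_tempfile(fileext = ".cndb")
  toCndb(e, f)
  part <- fromCndb(f, frames = c(3L, 17L))
  expect_identical(nModels(part), 2L)
  expect_identical(coords(part, 1), coords(e, 3))
  expect_identical(coords(part, 2), coords(e, 17))
  # truncated container
  raw <- readBin(f, "raw", file.info(f)$size)
  fb <- withr::local_tempfile(); writeBin(raw[1:(length(raw) - 13)], fb)
  expect_error(fromCndb(fb), "integrity")
  # wrong magic
  raw2 <- raw; raw2[1:4] <- as.raw(0)
  fb2 <- withr::local_tempfile(); writeBin(raw2, fb2)
  expect_error(fromCndb(fb2), "integrity")
})

test_that("binary encoding is smaller than text for many-frame ensembles", {
  e <- makeRandomEnsemble(10, 1000, seed = 45)
  ft <- withr::local_tempfile(fileext = ".ndb")
  fb <- withr::local_tempfile(fileext = ".cndb")
  writeNdb(e, ft); toCndb(e, fb)
  expect_gt(file.info(ft)$size / file.info(fb)$size, 1)
})

test_that("pdb export has one MODEL block per frame, one ATOM row per bead, and a rescaled colour column", {
  e <- makeRandomEnsemble(5, 1, seed = 51)
  f <- withr::local_tempfile(fileext = ".pdb")
  track <- c(0, 1, 2, 3, 4)
  toPdb(e, f, scalarTrack = track)
  lines <- readLines(f)
  expect_length(grep("^MODEL", lines), 1L)
  expect_length(grep("^ENDMDL", lines), 1L)
  atoms <- grep("^ATOM", lines, value = TRUE)
  expect_length(atoms, 5L)
  bfac <- as.numeric(substr(atoms, 61, 66))
  expect_equal(bfac, track / 4 * 99.99, tolerance = 1e-2)
  # fixed-column coordinates match the model
  xyz <- cbind(as.numeric(substr(atoms, 31, 38)),
               as.numeric(substr(atoms, 39, 46)),
               as.numeric(substr(atoms, 47, 54)))
  expect_equal(xyz, unname(round(coords(e, 1), 3)))
})

test_that("pdb export cross-checks against an independent PDB reader", {
  skip_if_not_installed("bio3d")
  e <- makeRandomEnsemble(7, 1, seed = 53)
  f <- withr::local_tempfile(fileext = ".pdb")
  toPdb(e, f)
  pdb <- suppressWarnings(bio3d::read.pdb(f, verbose = FALSE))
  expect_equal(unname(matrix(pdb$atom$x, ncol = 1))[, 1],
               unname(round(coords(e, 1), 3))[, 1])
  expect_identical(nrow(pdb$atom), 7L)
})

test_that("gro export encodes compartment annotations in the bead names", {
  e <- makeRandomEnsemble(6, 1, seed = 55)
  f <- withr::local_tempfile(fileext = ".gro")
  toGro(e, f)
  g <- readGro(f)
  expect_identical(g$labels, records(e)$code)
  expect_equal(g$positions, unname(round(coords(e, 1), 3)))
  expect_identical(as.integer(trimws(readLines(f)[2])), 6L)
})
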