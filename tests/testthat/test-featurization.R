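test_that("log rate-ratio target behaves as defined", {
  expect_identical(computeTarget(1.0e7, 1.0e7), 0)
  expect_equal(computeTarget(exp(1) * 3e8, 3e8), 1)
  expect_equal(computeTarget(2.3e9, 2.3e7), log(100), tolerance = 1e-12)
  expect_identical(targetFromSoac(1), 0)
  expect_error(targetFromSoac(0), "soac")
  expect_error(computeTarget(-1, 2), "kQ")
  expect_error(computeTarget(2, 0), "kRef")
  ## definitional consistency and monotonicity over random rate pairs
  set.seed(1)
  for (i in 1:25) {
    kq <- runif(1, 1e5, 1e10); kref <- runif(1, 1e5, 1e10)
    expect_equal(targetFromSoac(kq / kref), computeTarget(kq, kref),
                 tolerance = 1e-12)
    expect_gt(computeTarget(kq * 1.5, kref), computeTarget(kq, kref))
    expect_lt(computeTarget(kq, kref * 1.5), computeTarget(kq, kref))
  }
})

test_that("compound ingestion is robust and soac takes precedence", {
  path <- write_compound_csv(withr::local_tempfile(fileext = ".csv"), c(
    "c1,ethanol,CCO,0.5", "c2,phenol,c1ccccc1O,2.0", "c3,prenol,CC(C)=CCO,1.2"))
  res <- readCompounds(path)
  expect_length(res$records, 3)
  expect_equal(vapply(res$records, function(r) r@y, numeric(1)),
               log(c(0.5, 2.0, 1.2)))
  expect_equal(nrow(res$rejected), 0)

  ## malformed rows rejected, rest kept
  bad <- write_compound_csv(withr::local_tempfile(fileext = ".csv"), c(
    "c1,ethanol,CCO,abc", "c2,phenol,c1ccccc1O,2.0", "c3,neg,CCO,-4",
    "c4,nosmiles,,1.0"))
  res2 <- readCompounds(bad)
  expect_length(res2$records, 1)
  expect_setequal(res2$rejected$id, c("c1", "c3", "c4"))

  ## soac wins over k_q when both are present
  both <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,soac,k_q", "c1,CCO,4.0,1e9"), both)
  res3 <- readCompounds(both, kRef = 1e7)
  expect_equal(res3$records[[1]]@y, log(4.0))

  ## schema errors
  nosmiles <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,soac", "c1,1.0"), nosmiles)
  expect_error(readCompounds(nosmiles), "smiles")
  notarget <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "c1,CCO"), notarget)
  expect_error(readCompounds(notarget), "soac|k_q")
  kqonly <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,k_q", "c1,CCO,1e9"), kqonly)
  expect_error(readCompounds(kqonly), "kRef")
  expect_equal(readCompounds(kqonly, kRef = 1e9)$records[[1]]@y, 0)
})

test_that("stub backend is a pure function of the SMILES string", {
  stub <- descriptorBackend("stub")
  rec <- compoundRecord("a", "c1ccccc1O", soac = 2)
  d1 <- computeDescriptors(rec, stub)
  d2 <- computeDescriptors(rec, stub)
  expect_identical(descriptorVector(d1), descriptorVector(d2))
  expect_equal(d1@gap, d1@lumo - d1@homo, tolerance = 1e-12)
  d3 <- computeDescriptors(compoundRecord("b", "CCO", soac = 1), stub)
  expect_false(identical(descriptorVector(d1), descriptorVector(d3)))
  expect_true(all(is.finite(descriptorVector(d1))))
})

test_that("toolkit backend canonicalizes equivalent SMILES spellings", {
  tk <- descriptorBackend("toolkit")
  spellings <- c("CCO", "OCC", "C(O)C")
  vecs <- lapply(spellings, function(s)
    descriptorVector(computeDescriptors(compoundRecord(s, s, soac = 1), tk)))
  expect_equal(vecs[[1]], vecs[[2]], tolerance = 1e-12)
  expect_equal(vecs[[1]], vecs[[3]], tolerance = 1e-12)
  ## a few ground-truth 2-D values for ethanol
  expect_equal(unname(vecs[[1]]["nAtoms"]), 3)
  expect_equal(unname(vecs[[1]]["nO"]), 1)
  expect_equal(unname(vecs[[1]]["MW"]), 46.07, tolerance = 1e-3)
  expect_equal(vecs[[1]][["gap"]], vecs[[1]][["lumo"]] - vecs[[1]][["homo"]],
               tolerance = 1e-9)
})

test_that("semiempirical engine backend fails loudly when unavailable", {
  qb <- descriptorBackend("quantum", executable = "no_such_engine_xyz")
  expect_error(computeDescriptors(compoundRecord("a", "CCO", soac = 1), qb),
               class = "soacqspr_capability_error")
})

test_that("engine output listing parser extracts the quantum fields", {
  listing <- c(
    " *  PM7 PRECISE",
    "          FINAL HEAT OF FORMATION =        -56.33204 KCAL/MOL =    -235.69345 KJ/MOL",
    "          HOMO LUMO ENERGIES (EV) =        -10.719  2.899",
    "           DIPOLE           X         Y         Z       TOTAL",
    " SUM            1.550    -0.662     0.546     1.772")
  q <- soacqspr:::.parse_engine_output(listing)
  expect_equal(unname(q["homo"]), -10.719)
  expect_equal(unname(q["lumo"]), 2.899)
  expect_equal(unname(q["heat_of_formation"]), -56.33204)
  expect_equal(unname(q["dipole"]), 1.772)
  expect_error(soacqspr:::.parse_engine_output("garbage"),
               class = "soacqspr_capability_error")
})

test_that("Morgan fingerprints are deterministic, non-degenerate and nested", {
  f1 <- computeFingerprint("c1ccccc1O", radius = 2L, nBits = 2048L)
  f2 <- computeFingerprint("c1ccccc1O", radius = 2L, nBits = 2048L)
  expect_identical(f1, f2)
  expect_true(all(f1 %in% c(0L, 1L)))
  expect_gt(sum(f1), 0)
  expect_length(f1, 2048L)
  expect_error(computeFingerprint("xx$$", 2L, 64L), "smiles")
  ## radius-0 environments are a subset of the radius-2 environments
  for (smi in c("C", "CCO", "c1ccccc1O")) {
    b0 <- which(computeFingerprint(smi, radius = 0L, nBits = 4096L) == 1)
    b2 <- which(computeFingerprint(smi, radius = 2L, nBits = 4096L) == 1)
    expect_true(all(b0 %in% b2))
  }
})

test_that("feature tables align rows and drop failing compounds consistently", {
  recs <- stub_records()
  ft <- buildFeatureTables(recs, descriptorBackend("stub"),
                           radius = 2L, nBits = 128L)
  expect_identical(sampleIds(ft$descriptors), sampleIds(ft$fingerprints))
  expect_identical(sampleIds(ft$descriptors), names(ft$y))
  expect_equal(ncol(ft$descriptors), 5)
  expect_equal(nrow(ft$fingerprints), 128)
  expect_true(all(featureKind(ft$descriptors) == "descriptor"))
  expect_true(all(featureKind(ft$fingerprints) == "fingerprint_bit"))

  ## a compound with an unparsable SMILES drops from both tables, logged
  broken <- methods::new("CompoundRecord", id = "cX", name = "broken",
                         smiles = "xx$$bad", kQ = NA_real_, soac = 3,
                         y = log(3))
  ft2 <- buildFeatureTables(c(recs, broken), descriptorBackend("stub"),
                            radius = 2L, nBits = 64L)
  expect_equal(ncol(ft2$descriptors), 5)
  expect_identical(sampleIds(ft2$descriptors), sampleIds(ft2$fingerprints))
  expect_equal(ft2$rejected$id, "cX")

  expect_error(buildFeatureTables(recs[1:2]), "at least 3")

  ## featurization is a pure function: repeated runs identical
  ft3 <- buildFeatureTables(recs, descriptorBackend("stub"),
                            radius = 2L, nBits = 128L)
  expect_identical(featureMatrix(ft$descriptors), featureMatrix(ft3$descriptors))
  expect_identical(featureMatrix(ft$fingerprints), featureMatrix(ft3$fingerprints))
})
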