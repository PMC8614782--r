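#' @include AllClasses.R utils.R
NULL

## Names of the 2-D descriptor panel shared by all backends so tables have
## the same shape whichever backend produced them. The toolkit backend
## computes these for real; the stub draws pseudo-values from seeded ranges.
.DESC_2D_NAMES <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF",
                    "nAtoms", "nC", "nN", "nO", "nAromAtoms", "nRingAtoms")
.QUANTUM_NAMES <- c("homo", "lumo", "gap", "heat_of_formation", "dipole")

#' Create a descriptor backend
#'
#' @param name \code{"stub"}, \code{"toolkit"} or \code{"quantum"}; see
#'   \linkS4class{DescriptorBackend} for what each computes.
#' @param quantumSource for the toolkit backend: \code{"stub"} (default) or
#'   \code{"engine"} to take HOMO/LUMO/heat of formation/dipole from the
#'   external semiempirical engine.
#' @param executable path to the semiempirical engine executable (quantum
#'   backend, or toolkit backend with \code{quantumSource = "engine"}).
#' @param keywords keyword line written at the top of the engine input deck.
#' @return A \linkS4class{DescriptorBackend} object.
#' @examples
#' b <- descriptorBackend("stub")
#' @export
descriptorBackend <- function(name = c("stub", "toolkit", "quantum"),
                              quantumSource = c("stub", "engine"),
                              executable = "", keywords = "PM7 PRECISE") {
  name <- match.arg(name)
  switch(name,
    stub = methods::new("StubBackend", id = "stub"),
    toolkit = methods::new("ToolkitBackend", id = "toolkit",
                           quantumSource = match.arg(quantumSource),
                           executable = executable),
    quantum = methods::new("QuantumBackend", id = "quantum",
                           executable = executable, keywords = keywords))
}

.new_descriptor_set <- function(quantum, d2d) {
  methods::new("DescriptorSet", homo = unname(quantum[["homo"]]),
               lumo = unname(quantum[["lumo"]]),
               gap = unname(quantum[["lumo"]] - quantum[["homo"]]),
               heatOfFormation = unname(quantum[["heat_of_formation"]]),
               dipole = unname(quantum[["dipole"]]),
               descriptors2d = d2d)
}

#' Flatten a DescriptorSet to a named vector
#'
#' @param x A \linkS4class{DescriptorSet}.
#' @return Named numeric: quantum fields then 2-D descriptors.
#' @export
descriptorVector <- function(x) {
  c(homo = x@homo, lumo = x@lumo, gap = x@gap,
    heat_of_formation = x@heatOfFormation, dipole = x@dipole,
    x@descriptors2d)
}

setMethod("show", "DescriptorSet", function(object) {
  cat(sprintf("DescriptorSet: homo %.3f eV, lumo %.3f eV, gap %.3f eV, %d 2-D descriptors\n",
              object@homo, object@lumo, object@gap, length(object@descriptors2d)))
})

## -- stub -------------------------------------------------------------------

## Pseudo-descriptors: a deterministic hash of the SMILES string seeds a
## local RNG stream, from which loosely realistic ranges are drawn. Purely
## syntactic — two SMILES spellings of one molecule hash differently.
.stub_quantum <- function(smiles) {
  .with_op_seed(.hash32(smiles), "stub-quantum", {
    homo <- stats::runif(1, -10, -6)
    gap <- stats::runif(1, 0.5, 10)
    c(homo = homo, lumo = homo + gap,
      heat_of_formation = stats::runif(1, -150, 150),
      dipole = stats::runif(1, 0, 12))
  })
}

.stub_2d <- function(smiles) {
  lo <- c(50, -3, 0, 10, 0, 0, 0, 0, 3, 1, 0, 0, 0, 0)
  hi <- c(600, 8, 180, 160, 12, 12, 8, 6, 45, 40, 6, 10, 6, 4)
  .with_op_seed(.hash32(smiles), "stub-2d", {
    v <- stats::runif(length(.DESC_2D_NAMES), lo, hi)
    names(v) <- .DESC_2D_NAMES
    v
  })
}

#' Compute molecular descriptors for one compound
#'
#' @param record A \linkS4class{CompoundRecord}.
#' @param backend A \linkS4class{DescriptorBackend}.
#' @param ... unused.
#' @return A \linkS4class{DescriptorSet}. Deterministic for a fixed backend
#'   and input; backend unavailability raises a capability error naming the
#'   backend, never silent zeros.
#' @rdname computeDescriptors
#' @export
setMethod("computeDescriptors", signature("CompoundRecord", "StubBackend"),
  function(record, backend, ...) {
    if (!nzchar(record@smiles))
      .validation_error("smiles: empty SMILES", field = "smiles")
    .new_descriptor_set(.stub_quantum(record@smiles), .stub_2d(record@smiles))
  })

## -- toolkit ----------------------------------------------------------------

.require_toolkit <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    .capability_error(
      "cheminformatics toolkit backend unavailable: package 'ChemmineOB' not installed",
      backend = "toolkit")
}

## Apply f to the parsed molecule of one SMILES; invalid input -> error.
.with_mol <- function(smiles, f) {
  .require_toolkit()
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles)))
    .validation_error("smiles: a single non-empty SMILES string is required",
                      field = "smiles")
  res <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(mol) f(list(mol))),
    error = function(e) .validation_error(
      sprintf("smiles: cannot parse '%s' (%s)", smiles,
              trimws(conditionMessage(e))), field = "smiles"))
  res[[1]]
}

## element counts parsed from a Hill-system molecular formula, e.g. "C2H6O"
.formula_counts <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  el <- sub("[0-9]+$", "", parts)
  n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", parts)))
  n[is.na(n)] <- 1L
  stats::setNames(n, el)
}

.toolkit_2d <- function(smiles) {
  .with_mol(smiles, function(mol) {
    pr <- ChemmineOB::prop_OB(mol)
    cnt <- .formula_counts(pr$formula)
    heavy <- sum(cnt[names(cnt) != "H"])
    v <- c(MW = pr$MW, logP = pr$logP, TPSA = pr$TPSA, MR = pr$MR,
           HBA1 = pr$HBA1, HBA2 = pr$HBA2, HBD = pr$HBD, nF = pr$nF,
           nAtoms = heavy, nC = sum(cnt[names(cnt) == "C"]),
           nN = sum(cnt[names(cnt) == "N"]),
           nO = sum(cnt[names(cnt) == "O"]),
           nAromAtoms = ChemmineOB::smartsSearch_OB(mol, "[a]",
                                                    uniqueMatches = FALSE),
           nRingAtoms = ChemmineOB::smartsSearch_OB(mol, "[R]",
                                                    uniqueMatches = FALSE))
    v <- vapply(v, as.numeric, numeric(1))
    ## canonical SMILES keys the quantum stub so that equivalent spellings
    ## of a molecule featurize identically under the toolkit backend
    attr(v, "cansmi") <- pr$cansmiNS
    v
  })
}

#' @rdname computeDescriptors
#' @export
setMethod("computeDescriptors", signature("CompoundRecord", "ToolkitBackend"),
  function(record, backend, ...) {
    d2d <- .toolkit_2d(record@smiles)
    cansmi <- attr(d2d, "cansmi")
    attr(d2d, "cansmi") <- NULL
    quantum <- if (backend@quantumSource == "engine")
      .run_quantum_engine(record@smiles, backend@executable)
    else .stub_quantum(cansmi)
    .new_descriptor_set(quantum, d2d)
  })

## -- external semiempirical engine (subprocess adapter) ---------------------

#' @rdname computeDescriptors
#' @export
setMethod("computeDescriptors", signature("CompoundRecord", "QuantumBackend"),
  function(record, backend, ...) {
    d2d <- .toolkit_2d(record@smiles)
    attr(d2d, "cansmi") <- NULL
    quantum <- .run_quantum_engine(record@smiles, backend@executable,
                                   backend@keywords)
    .new_descriptor_set(quantum, d2d)
  })

## Writes an input deck (3-D structure from OpenBabel's coordinate
## generation), runs the engine, parses the output listing.
.run_quantum_engine <- function(smiles, executable, keywords = "PM7 PRECISE") {
  if (!nzchar(executable) || !nzchar(Sys.which(executable)))
    .capability_error(sprintf(
      "semiempirical engine backend unavailable: executable '%s' not found",
      executable), backend = "quantum")
  obabel <- Sys.which("obabel")
  if (!nzchar(obabel))
    .capability_error("semiempirical engine backend unavailable: 'obabel' not found (needed to build the input deck)",
                      backend = "quantum")
  wd <- tempfile("qm_")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  deck <- file.path(wd, "job.mop")
  status <- system2(obabel, c(paste0("-:", shQuote(smiles)), "-omopin",
                              "-O", deck, "--gen3d"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(deck))
    .validation_error(sprintf("smiles: deck generation failed for '%s'", smiles),
                      field = "smiles")
  lines <- readLines(deck)
  lines[1] <- keywords
  writeLines(lines, deck)
  status <- system2(executable, deck, stdout = FALSE, stderr = FALSE)
  out <- file.path(wd, "job.out")
  if (status != 0 || !file.exists(out))
    .capability_error(sprintf("semiempirical engine run failed (exit %d)", status),
                      backend = "quantum")
  .parse_engine_output(readLines(out))
}

## Parses HOMO/LUMO energies (eV), final heat of formation (kcal/mol) and
## total dipole (Debye) from a MOPAC-style output listing.
.parse_engine_output <- function(lines) {
  num <- "[-+]?[0-9]*\\.?[0-9]+"
  grab <- function(pattern, k = 1L) {
    hit <- grep(pattern, lines, value = TRUE)
    if (!length(hit)) return(NULL)
    m <- regmatches(hit[length(hit)], gregexpr(num, hit[length(hit)]))[[1]]
    as.numeric(m)
  }
  hl <- grab("HOMO LUMO ENERGIES")
  hof <- grab("FINAL HEAT OF FORMATION")
  dip <- grab("^ *SUM")  # dipole table: SUM row, last column is the total
  if (is.null(hl) || length(hl) < 2 || is.null(hof))
    .capability_error("could not parse engine output listing (HOMO/LUMO or heat of formation missing)",
                      backend = "quantum")
  c(homo = hl[1], lumo = hl[2], heat_of_formation = hof[1],
    dipole = if (is.null(dip)) 0 else dip[length(dip)])
}
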