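# Subprocess bridge to the RDKit-based chemistry engine.
#
# kinprof delegates standard cheminformatics primitives (SMILES parsing and
# canonicalisation, descriptor evaluation, fingerprints, distance-geometry
# conformer embedding, SMARTS matching) to RDKit through a small batch
# worker shipped in inst/python/.  Everything scientific that the package
# contributes -- the signature space, the ensemble averaging, the model,
# the profiling statistics -- is implemented in R on top of it.

.kinprof_cache <- new.env(parent = emptyenv())

#' Locate the python interpreter used by the chemistry engine
#'
#' The interpreter must have RDKit importable.  Override with
#' `options(kinprof.python = "/path/to/python")`.
#'
#' @return Path to the python executable.
#' @keywords internal
chem_python <- function() {
  opt <- getOption("kinprof.python", "")
  if (nzchar(opt)) return(opt)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("no python interpreter on PATH; set options(kinprof.python = ...)")
}

#' Run one batched operation of the chemistry engine
#'
#' @param op Operation name understood by `chem_bridge.py`.
#' @param payload List serialised to JSON for the worker.
#' @return Parsed JSON result (lists, not simplified).
#' @keywords internal
chem_bridge <- function(op, payload = list()) {
  script <- system.file("python", "chem_bridge.py", package = "kinprof",
                        mustWork = TRUE)
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  log <- suppressWarnings(
    system2(chem_python(), c(shQuote(script), op, shQuote(fin), shQuote(fout)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(log, "status")
  if ((!is.null(status) && status != 0L) || !file.exists(fout)) {
    stop("chemistry engine failed (op = ", op, "):\n",
         paste(log, collapse = "\n"))
  }
  jsonlite::read_json(fout, simplifyVector = FALSE)
}

# per-session memoisation keyed by operation and input SMILES
.cache_get <- function(key) {
  if (exists(key, envir = .kinprof_cache, inherits = FALSE)) {
    get(key, envir = .kinprof_cache, inherits = FALSE)
  } else {
    NULL
  }
}

.cache_set <- function(key, value) {
  assign(key, value, envir = .kinprof_cache)
  invisible(value)
}
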