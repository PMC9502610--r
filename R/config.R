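#' Load a phenotype configuration
#'
#' Reads the YAML configuration that drives all code-based and threshold-based
#' logic: named code sets (prefix-matched, per coding system), the
#' stage-implying code maps used by the administrative-code comparator, the
#' clinical thresholds (KDIGO G/A boundaries, persistence windows, HbA1c and
#' blood-pressure cut-offs, the maintenance-dialysis guard), and the CKD-EPI
#' coefficient block.
#'
#' The package ships a documented default configuration
#' (`system.file("extdata/config/default_config.yaml", package = "ckdphen")`)
#' whose code sets are standard chapter-prefix stand-ins; deployments are
#' expected to override them with curated local lists. Entries given in
#' `overrides` (a nested list mirroring the YAML structure) replace the
#' corresponding defaults.
#'
#' @param path path to a YAML configuration; `NULL` loads the shipped default.
#' @param overrides optional nested list merged over the loaded configuration.
#' @return an object of class `phen_config`: a list with elements
#'   `code_sets`, `stage_codes`, `thresholds`, `ckd_epi`, `version`.
#' @export
#' @examples
#' cfg <- load_config()
#' names(cfg$code_sets)
load_config <- function(path = NULL, overrides = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "config", "default_config.yaml",
                        package = "ckdphen")
  }
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (!is.null(overrides)) {
    cfg <- utils::modifyList(cfg, overrides)
  }
  for (block in c("code_sets", "stage_codes", "thresholds", "ckd_epi")) {
    if (is.null(cfg[[block]])) {
      stop("configuration is missing the '", block, "' block", call. = FALSE)
    }
  }
  cfg$code_sets <- lapply(cfg$code_sets, function(by_system) {
    lapply(by_system, function(prefixes) {
      pfx <- normalise_code(as.character(unlist(prefixes)))
      if (anyDuplicated(pfx)) {
        stop("duplicate code prefixes within a concept/system", call. = FALSE)
      }
      pfx
    })
  })
  structure(cfg, class = "phen_config")
}

#' @export
print.phen_config <- function(x, ...) {
  cat("<phen_config> version", x$version, "\n")
  cat("  concepts:", paste(names(x$code_sets), collapse = ", "), "\n")
  invisible(x)
}

# Canonical form used everywhere codes are compared:
# uppercase, dots stripped, surrounding whitespace removed.
normalise_code <- function(code) {
  gsub(".", "", toupper(trimws(as.character(code))), fixed = TRUE)
}

# Map an entity-table system label onto the code-set key.
.system_key <- function(system) {
  key <- c(ICD10AM = "icd10am", ICPC2 = "icpc2", ATC = "atc",
           ICD10AM_procedure = "icd10am_procedure", MBS = "mbs")
  out <- unname(key[system])
  if (anyNA(out)) {
    stop("unknown coding system: ",
         paste(unique(system[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Match codes against a configured concept
#'
#' Prefix-match semantics over the hierarchical coding systems (ICD-10-AM,
#' ICPC-2, ATC, procedure codes): a code matches a concept when, after
#' normalisation (uppercase, dots removed), it begins with any prefix
#' configured for that concept under the code's own system. Systems are never
#' mixed: an ICPC code is only compared with ICPC prefixes.
#'
#' @param code character vector of codes.
#' @param system character vector (recycled) of coding systems, one of
#'   `"ICD10AM"`, `"ICPC2"`, `"ATC"`, `"ICD10AM_procedure"`, `"MBS"`.
#' @param concept name of a concept present in `config$code_sets`.
#' @param config a [load_config()] object.
#' @return logical vector, one element per code.
#' @export
#' @examples
#' cfg <- load_config()
#' match_code(c("N18.3", "E11.9"), "ICD10AM", "ckd_related", cfg)
match_code <- function(code, system, concept, config) {
  stopifnot(inherits(config, "phen_config"))
  if (!concept %in% names(config$code_sets)) {
    stop("unknown concept: '", concept, "'", call. = FALSE)
  }
  if (length(code) == 0L) return(logical(0))
  system <- rep_len(as.character(system), length(code))
  keys <- .system_key(system)
  norm <- normalise_code(code)
  sets <- config$code_sets[[concept]]
  vapply(seq_along(norm), function(i) {
    pfx <- sets[[keys[i]]]
    if (is.null(pfx) || length(pfx) == 0L) return(FALSE)
    any(startsWith(norm[i], pfx))
  }, logical(1))
}

# Stage (1..5) implied by a single diagnosis code, NA when none.
# Prefix-matched against the configured stage_codes maps.
code_implied_stage <- function(code, system, config) {
  if (length(code) == 0L) return(integer(0))
  system <- rep_len(as.character(system), length(code))
  keys <- .system_key(system)
  norm <- normalise_code(code)
  vapply(seq_along(norm), function(i) {
    map <- config$stage_codes[[keys[i]]]
    if (is.null(map)) return(NA_integer_)
    pfx <- normalise_code(names(map))
    hit <- which(startsWith(norm[i], pfx))
    if (length(hit) == 0L) return(NA_integer_)
    # most specific (longest) matching prefix wins
    as.integer(map[[hit[which.max(nchar(pfx[hit]))]]])
  }, integer(1))
}
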