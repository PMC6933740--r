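COHORT_COLUMNS <- c("subject_id", "genotype", "pet_positive", "abeta40",
                    "abeta42", "tau", "suvr", "age", "sex", "education",
                    "mmse", "cdr")

#' Write a cohort to the canonical CSV dialect
#'
#' One fixed schema:
#' `subject_id,genotype,pet_positive,abeta40,abeta42,tau,suvr,age,sex,education,mmse,cdr`
#' with genotypes spelled `e2e2..e4e4`, `pet_positive` as 0/1, missing
#' optional fields empty, decimal point, UTF-8 and LF line endings. Writing
#' the same cohort twice produces byte-identical files.
#'
#' @param cohort an `ab_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(COHORT_COLUMNS %in% names(cohort)))
  fmt <- function(x) {
    if (is.logical(x)) return(ifelse(is.na(x), "", as.character(as.integer(x))))
    if (is.numeric(x)) {
      out <- vapply(x, function(v) {
        if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
      }, character(1))
      return(out)
    }
    ifelse(is.na(x), "", as.character(x))
  }
  cols <- lapply(COHORT_COLUMNS, function(nm) fmt(cohort[[nm]]))
  lines <- c(paste(COHORT_COLUMNS, collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a cohort from the canonical CSV dialect
#'
#' Validates the header, genotype labels, marker numerics and subject-id
#' uniqueness; rows missing a required field (id, genotype, PET status, any
#' plasma marker) are rejected with their row numbers. Optional fields may
#' be empty and come back as `NA`.
#'
#' @param path CSV path (see [write_cohort()] for the schema).
#' @return an `ab_cohort` with provenance `"external file"`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(df), COHORT_COLUMNS)) {
    stop("cohort header must be exactly: ",
         paste(COHORT_COLUMNS, collapse = ","), call. = FALSE)
  }
  rows <- seq_len(nrow(df)) + 1L  # file line numbers
  required <- c("subject_id", "genotype", "pet_positive", "abeta40",
                "abeta42", "tau")
  for (nm in required) {
    miss <- which(is.na(df[[nm]]) | df[[nm]] == "")
    if (length(miss) > 0L) {
      stop("missing required field '", nm, "' on row(s): ",
           paste(rows[miss], collapse = ", "), call. = FALSE)
    }
  }
  bad_gt <- which(!(df$genotype %in% GENOTYPES))
  if (length(bad_gt) > 0L) {
    stop("unknown genotype label(s) ",
         paste(unique(df$genotype[bad_gt]), collapse = ", "),
         " on row(s): ", paste(rows[bad_gt], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!all(df$pet_positive %in% c("0", "1"))) {
    stop("pet_positive must be 0 or 1", call. = FALSE)
  }
  num <- function(nm, required_field = FALSE) {
    raw <- df[[nm]]
    out <- suppressWarnings(as.numeric(ifelse(raw == "", NA, raw)))
    bad <- which(raw != "" & is.na(out))
    if (length(bad) > 0L) {
      stop("non-numeric ", nm, " on row(s): ",
           paste(rows[bad], collapse = ", "), call. = FALSE)
    }
    out
  }
  cohort <- data.frame(
    subject_id = df$subject_id,
    genotype = df$genotype,
    pet_positive = df$pet_positive == "1",
    abeta40 = num("abeta40"),
    abeta42 = num("abeta42"),
    tau = num("tau"),
    suvr = num("suvr"),
    age = num("age"),
    sex = ifelse(df$sex == "", NA_character_, df$sex),
    education = num("education"),
    mmse = as.integer(num("mmse")),
    cdr = num("cdr"),
    stringsAsFactors = FALSE
  )
  as_ab_cohort(cohort, provenance = list(source = "external file",
                                         path = path))
}

#' Write / read a flat key=value configuration file
#'
#' The canonicalised flat form also underlies [config_digest()].
#'
#' @param config an `ab_sim_config`.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_config <- function(config, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(config_flatten(config), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Run manifest for a reproducible analysis
#'
#' Collects everything needed to re-run an analysis: the input source (file
#' path or simulation config digest), the seed, which cut-offs each pathway
#' used (reference vs derived, with their values), the output artifact paths
#' and the package version.
#'
#' @param input_source character description of the cohort source.
#' @param seed integer seed in force.
#' @param cutoff_provenance named list describing cut-off origin and values.
#' @param outputs character vector of artifact paths.
#' @return object of class `ab_manifest` (a named list).
#' @export
run_manifest <- function(input_source, seed, cutoff_provenance = list(),
                         outputs = character(0)) {
  structure(list(
    input_source = input_source,
    seed = as.integer(seed),
    cutoff_provenance = cutoff_provenance,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("abetascreen")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "ab_manifest")
}
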