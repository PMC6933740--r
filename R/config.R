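#' Genotype labels and genotype classes
#'
#' Six APOE genotypes are modelled. A subject is an e4 carrier when the
#' genotype contains at least one e4 allele (e2e4, e3e4, e4e4); "e2-only"
#' subjects carry an e2 allele and no e4 allele (e2e2, e2e3). The remaining
#' class is e3e3. The e2e4 genotype counts as an e4 carrier throughout.
#'
#' @param genotype character vector of genotype labels
#'   (`"e2e2"`, `"e2e3"`, `"e2e4"`, `"e3e3"`, `"e3e4"`, `"e4e4"`).
#' @return logical vector.
#' @export
is_e4_carrier <- function(genotype) {
  check_genotype(genotype)
  genotype %in% c("e2e4", "e3e4", "e4e4")
}

#' @rdname is_e4_carrier
#' @export
is_e2_only <- function(genotype) {
  check_genotype(genotype)
  genotype %in% c("e2e2", "e2e3")
}

GENOTYPES <- c("e2e2", "e2e3", "e2e4", "e3e3", "e3e4", "e4e4")
GENOTYPE_CLASSES <- c("e4_carrier", "e2_only", "e3e3")
MARKERS <- c("abeta40", "abeta42", "tau")

check_genotype <- function(genotype) {
  bad <- !is.na(genotype) & !(genotype %in% GENOTYPES)
  if (any(bad)) {
    stop("unknown genotype label(s): ",
         paste(unique(genotype[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(genotype)
}

#' Map genotypes to their screening class
#'
#' @inheritParams is_e4_carrier
#' @return factor with levels `e4_carrier`, `e2_only`, `e3e3`.
#' @export
genotype_class <- function(genotype) {
  cls <- ifelse(is_e4_carrier(genotype), "e4_carrier",
                ifelse(is_e2_only(genotype), "e2_only", "e3e3"))
  factor(cls, levels = GENOTYPE_CLASSES)
}

#' Default simulation configuration
#'
#' Builds the calibrated configuration of the synthetic cohort generator.
#' Class-level probabilities follow the reference clinical cohort of 52
#' suspected early-stage AD patients that the package's screening rules were
#' developed on: P(e4 carrier) = 14/52, P(e2-only | non-carrier) = 7/38, and
#' genotype-class PET+ rates 12/14 (carriers), 0 (e2-only), 10/31 (e3e3).
#' Marker moments are the PET-status-conditional means/SDs of that cohort
#' (pg/ml): Abeta42 16.3 (2.3) in PET+ vs 17.6 (3.3) in PET-, Abeta40
#' 50.9 (7.7) vs 49.1 (7.3), tau 18.4 (8.5) vs 22.5 (10.4). SUVR marginals
#' (PET- mean 1.00, SD 0.10; PET+ mean 1.35, SD 0.15) are nominal values on
#' the usual whole-cerebellum-normalised scale; the within-group Pearson
#' correlations between Abeta42 and SUVR (0.387 in PET-, -0.068 in PET+) are
#' the calibration targets.
#'
#' Within-class genotype splits are not identified by class totals; the
#' defaults use (e3e4 : e4e4 : e2e4) = (12 : 1 : 1) among the 14 carriers and
#' (e2e3 : e2e2) = (7 : 0) among e2-only subjects. They are recorded in the
#' configuration, overridable, and irrelevant to every class-level statistic.
#'
#' Genotype-conditional marker shifts are off by default: PET status fully
#' mediates the markers, so the PET-conditional moments above are reproduced
#' exactly in the marginal. Supply `genotype_marker_offsets` (e.g. from
#' [genotype_offsets_calibrated()]) to emulate carrier/non-carrier marker
#' differences instead.
#'
#' @param n_subjects integer, cohort size.
#' @param seed integer seed recorded in the configuration.
#' @param genotype_marker_offsets optional named list
#'   `list(<class> = c(<marker> = shift_pg_ml, ...), ...)` of additive mean
#'   shifts per genotype class; classes are `e4_carrier`, `e2_only`, `e3e3`.
#' @return an object of class `ab_sim_config`.
#' @seealso [simulate_cohort()], [cohort_moments()]
#' @export
default_config <- function(n_subjects = 52L, seed = 1L,
                           genotype_marker_offsets = NULL) {
  carriers <- 14 / 52
  e2_only_given_noncarrier <- 7 / 38
  genotype_probs <- c(
    e2e2 = 0,
    e2e3 = (1 - carriers) * e2_only_given_noncarrier,
    e2e4 = carriers * (1 / 14),
    e3e3 = (1 - carriers) * (1 - e2_only_given_noncarrier),
    e3e4 = carriers * (12 / 14),
    e4e4 = carriers * (1 / 14)
  )
  marker_params <- data.frame(
    marker = rep(MARKERS, each = 2L),
    pet = rep(c("pos", "neg"), times = 3L),
    mean = c(50.9, 49.1, 16.3, 17.6, 18.4, 22.5),
    sd   = c(7.7, 7.3, 2.3, 3.3, 8.5, 10.4),
    stringsAsFactors = FALSE
  )
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects),
    genotype_probs = genotype_probs,
    pet_rate_by_class = c(e4_carrier = 12 / 14, e2_only = 0, e3e3 = 10 / 31),
    marker_params = marker_params,
    marker_floor = 1,
    suvr_params = list(
      pos = c(mean = 1.35, sd = 0.15, rho = -0.068),
      neg = c(mean = 1.00, sd = 0.10, rho = 0.387)
    ),
    genotype_marker_offsets = genotype_marker_offsets,
    covariates = list(
      age = c(mean = 72.0, sd = 8.8, min = 55, max = 90),
      education = c(mean = 11.4, sd = 3.9, min = 6),
      p_female = 22 / 52,
      mmse = c(mean = 25.8, sd = 2.8, min = 20, max = 30)
    ),
    seed = as.integer(seed)
  ), class = "ab_sim_config")
  validate_config(cfg)
  cfg
}

#' Genotype marker offsets calibrated to published class means
#'
#' The generator's default leaves genotype and markers conditionally
#' independent given PET status, which reproduces the PET-conditional
#' marker moments but not the published carrier/non-carrier marker
#' differences (carriers show higher Abeta42 and tau despite being mostly
#' PET+). This helper solves the class-mixture identities for the additive
#' per-class shifts that reproduce the published class means (pg/ml):
#' Abeta40 47.1 / 50.9 / 50.0, Abeta42 17.9 / 16.7 / 16.5 and tau
#' 24.7 / 19.3 / 18.8 for carriers / all non-carriers / e2-only subjects.
#' The shifts are derived algebraically from `config`'s own PET rates and
#' PET-conditional means, so they stay consistent if those are overridden.
#'
#' The resulting joint distribution is an approximation: only class means
#' shift, class SDs are not matched.
#'
#' @param config an `ab_sim_config`.
#' @param class_means named list of published class means per marker; the
#'   default carries the reference cohort's values.
#' @return named list suitable for the `genotype_marker_offsets` field.
#' @export
genotype_offsets_calibrated <- function(config = default_config(),
                                        class_means = list(
                                          abeta40 = c(e4_carrier = 47.1, non_carrier = 50.9, e2_only = 50.0),
                                          abeta42 = c(e4_carrier = 17.9, non_carrier = 16.7, e2_only = 16.5),
                                          tau     = c(e4_carrier = 24.7, non_carrier = 19.3, e2_only = 18.8)
                                        )) {
  stopifnot(inherits(config, "ab_sim_config"))
  p_class <- class_probabilities(config)
  rate <- config$pet_rate_by_class
  base_mean <- function(marker, class) {
    m <- config$marker_params
    mu_pos <- m$mean[m$marker == marker & m$pet == "pos"]
    mu_neg <- m$mean[m$marker == marker & m$pet == "neg"]
    rate[[class]] * mu_pos + (1 - rate[[class]]) * mu_neg
  }
  out <- list(e4_carrier = numeric(0), e2_only = numeric(0), e3e3 = numeric(0))
  p_e2_given_nc <- p_class[["e2_only"]] / (p_class[["e2_only"]] + p_class[["e3e3"]])
  for (marker in MARKERS) {
    tgt <- class_means[[marker]]
    d_car <- tgt[["e4_carrier"]] - base_mean(marker, "e4_carrier")
    d_e2 <- tgt[["e2_only"]] - base_mean(marker, "e2_only")
    # all-non-carrier mean is the e2-only / e3e3 mixture; solve for the e3e3 shift
    d_e3 <- (tgt[["non_carrier"]] -
               p_e2_given_nc * tgt[["e2_only"]] -
               (1 - p_e2_given_nc) * base_mean(marker, "e3e3")) / (1 - p_e2_given_nc)
    out$e4_carrier[marker] <- d_car
    out$e2_only[marker] <- d_e2
    out$e3e3[marker] <- d_e3
  }
  out
}

class_probabilities <- function(config) {
  gp <- config$genotype_probs
  tapply(gp, genotype_class(names(gp)), sum)[GENOTYPE_CLASSES]
}

#' Validate a simulation configuration
#'
#' @param config an `ab_sim_config`.
#' @return `config`, invisibly, or an error describing the violation.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "ab_sim_config"))
  if (length(config$n_subjects) != 1L || is.na(config$n_subjects) ||
      config$n_subjects < 1L) {
    stop("n_subjects must be a positive integer", call. = FALSE)
  }
  gp <- config$genotype_probs
  if (!setequal(names(gp), GENOTYPES)) {
    stop("genotype_probs must cover exactly the six genotypes", call. = FALSE)
  }
  if (any(gp < 0) || abs(sum(gp) - 1) > 1e-12) {
    stop("genotype_probs must be non-negative and sum to 1 (within 1e-12)",
         call. = FALSE)
  }
  rate <- config$pet_rate_by_class
  if (!setequal(names(rate), GENOTYPE_CLASSES) ||
      any(rate < 0 | rate > 1)) {
    stop("pet_rate_by_class must give a probability in [0, 1] per class",
         call. = FALSE)
  }
  m <- config$marker_params
  if (!all(m$sd > 0)) stop("all marker SDs must be > 0", call. = FALSE)
  if (!(config$marker_floor > 0)) stop("marker_floor must be > 0", call. = FALSE)
  for (s in config$suvr_params) {
    if (s[["sd"]] <= 0) stop("SUVR SDs must be > 0", call. = FALSE)
    if (abs(s[["rho"]]) >= 1) {
      stop("correlation targets must lie in (-1, 1)", call. = FALSE)
    }
  }
  invisible(config)
}

#' Canonical digest of a simulation configuration
#'
#' Serialises the configuration to a canonical flat key=value text (sorted
#' keys, full precision) and returns its MD5, so cohort provenance can record
#' exactly which configuration produced it.
#'
#' @param config an `ab_sim_config`.
#' @return character MD5 digest.
#' @export
config_digest <- function(config) {
  txt <- config_flatten(config)
  tf <- tempfile(fileext = ".cfg")
  on.exit(unlink(tf), add = TRUE)
  con <- file(tf, open = "wb")
  writeLines(txt, con, sep = "\n")
  close(con)
  unname(tools::md5sum(tf))
}

config_flatten <- function(config) {
  out <- character(0)
  flat <- function(prefix, x) {
    if (is.data.frame(x)) {
      for (i in seq_len(nrow(x))) flat(paste0(prefix, ".", i), as.list(x[i, ]))
    } else if (is.list(x)) {
      for (nm in names(x)) flat(paste0(prefix, ".", nm), x[[nm]])
    } else if (is.null(x)) {
      out[[length(out) + 1L]] <<- paste0(prefix, "=")
    } else {
      vals <- if (is.numeric(x)) format(x, digits = 17, trim = TRUE) else as.character(x)
      if (!is.null(names(x))) {
        for (nm in names(x)) {
          out[[length(out) + 1L]] <<- paste0(prefix, ".", nm, "=",
                                             vals[[which(names(x) == nm)[1]]])
        }
      } else {
        out[[length(out) + 1L]] <<- paste0(prefix, "=",
                                           paste(vals, collapse = ","))
      }
    }
  }
  for (nm in names(config)) flat(nm, config[[nm]])
  sort(out)
}
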