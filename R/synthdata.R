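#' Configuration for the synthetic-data generators
#'
#' Encodes the cultivation design (conditions C / O2 / O3, sampled weeks,
#' extract fractions), the planted feature classes, and the noise model:
#' multiplicative Gaussian mass error on the ppm scale (how Q-TOF accuracy is
#' specified), Gaussian retention-time jitter, and per-cell detection
#' dropout. Assay-style outputs default to the sampled weeks 1,3,5,7,9,11;
#' sequence series use weeks 1-12.
#'
#' @param seed Integer seed; fixes all randomness of a generator call.
#' @param strain Strain label.
#' @param conditions,weeks,fractions The sampling design.
#' @param n_constitutive,n_experimental_only,n_induced,n_control_only Number
#'   of planted features per presence class. `constitutive` features occur in
#'   every sample; `experimental_only` in every experimental sample and no
#'   control sample; `induced` in every experimental sample plus a single
#'   control week; `control_only` in control samples only.
#' @param mass_error_sd_ppm Mass error standard deviation in ppm (default 2,
#'   comfortably inside the 10 ppm dereplication gate).
#' @param rt_jitter_sd_min Retention-time jitter SD in minutes (default
#'   0.05).
#' @param dropout_prob Per-cell probability that a detection in an
#'   experimental sample is missed (default 0).
#' @param control_dropout_prob Same for control samples (default 0, so that
#'   control-arm evidence is never silently lost; see the methods vignette).
#' @param gc_content GC fraction of generated 16S-like sequences (default
#'   0.70, the high-GC actinobacterial range).
#' @param seq_length Length of generated 16S-like sequences (default 1450
#'   nt, covering the V1-V9 map).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, strain = "synthetic_strain",
                       conditions = c("C", "O2", "O3"),
                       weeks = c(1, 3, 5, 7, 9, 11),
                       fractions = "cultural_liquid",
                       n_constitutive = 10, n_experimental_only = 5,
                       n_induced = 5, n_control_only = 3,
                       mass_error_sd_ppm = 2, rt_jitter_sd_min = 0.05,
                       dropout_prob = 0, control_dropout_prob = 0,
                       gc_content = 0.70, seq_length = 1450) {
  stopifnot(dropout_prob >= 0, dropout_prob <= 1,
            control_dropout_prob >= 0, control_dropout_prob <= 1,
            gc_content > 0, gc_content < 1,
            mass_error_sd_ppm >= 0, rt_jitter_sd_min >= 0)
  if (!length(conditions) || !length(weeks) || !length(fractions)) {
    stop("design must be non-empty")
  }
  structure(as.list(environment()), class = "sim_config")
}

design_grid <- function(config) {
  g <- expand.grid(strain = config$strain, condition = config$conditions,
                   week = config$weeks, fraction = config$fractions,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g[order(match(g$condition, CONDITIONS), g$fraction, g$week), , drop = FALSE]
}

#' Generate a synthetic feature table with planted ground truth
#'
#' Plants features of four presence classes over the configured design, then
#' observes them with ppm-scale multiplicative mass error, RT jitter and
#' optional dropout. True masses are drawn uniformly over 160-900 Da (kept
#' at least 0.05 Da apart) and true RTs uniformly over 0.5-17.5 min.
#'
#' @param config A [sim_config()].
#' @return A list with `features` (a [feature_table()]) and `truth`: the
#'   per-feature class and true (mass, RT), plus the realized intended
#'   presence per sample after dropout (`presence`, logical matrix).
#' @export
gen_feature_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  design <- design_grid(config)
  ids <- sample_id(design$strain, design$condition, design$week,
                   design$fraction)
  classes <- rep(c("constitutive", "experimental_only", "induced",
                   "control_only"),
                 c(config$n_constitutive, config$n_experimental_only,
                   config$n_induced, config$n_control_only))
  nf <- length(classes)
  if (!nf) stop("no features configured")

  # well-separated true masses so the planted clustering is unambiguous
  repeat {
    true_mass <- sort(stats::runif(nf, 160, 900))
    if (nf == 1 || min(diff(true_mass)) > 0.05) break
  }
  true_rt <- stats::runif(nf, 0.5, 17.5)
  feature_id <- sprintf("feat%03d", seq_len(nf))

  is_ctrl <- design$condition == "C"
  intended <- matrix(FALSE, nf, nrow(design),
                     dimnames = list(feature_id, ids))
  for (f in seq_len(nf)) {
    intended[f, ] <- switch(classes[f],
      constitutive = TRUE,
      experimental_only = !is_ctrl,
      induced = !is_ctrl |
        (is_ctrl & design$week == sample(config$weeks, 1)),
      control_only = is_ctrl)
  }

  drop_p <- ifelse(is_ctrl, config$control_dropout_prob, config$dropout_prob)
  dropped <- matrix(stats::rbinom(nf * nrow(design), 1,
                                  rep(drop_p, each = nf)) == 1,
                    nf, nrow(design))
  realized <- intended & !dropped

  obs <- which(realized, arr.ind = TRUE)
  features <- data.frame(
    feature_id = feature_id[obs[, 1]],
    rt_min = pmin(pmax(true_rt[obs[, 1]] +
                         stats::rnorm(nrow(obs), 0, config$rt_jitter_sd_min),
                       0), 18),
    neutral_mass = true_mass[obs[, 1]] *
      (1 + stats::rnorm(nrow(obs), 0, config$mass_error_sd_ppm * 1e-6)),
    intensity = stats::rlnorm(nrow(obs), log(1e6), 0.5),
    strain = design$strain[obs[, 2]],
    condition = design$condition[obs[, 2]],
    week = design$week[obs[, 2]],
    fraction = design$fraction[obs[, 2]]
  )
  features <- features[order(features$feature_id, features$condition,
                             features$week, features$fraction), , drop = FALSE]
  rownames(features) <- NULL
  list(
    features = feature_table(features),
    truth = list(
      feature_id = feature_id, class = classes, true_mass = true_mass,
      true_rt = true_rt, intended = intended, presence = realized,
      design = design)
  )
}

#' Load the bundled study presence fixture as a feature table
#'
#' Expands the bundled presence/absence fixture for the Streptomyces
#' cultivation study (named metabolites with their neutral masses and
#' retention times, conditions C/O2/O3, weeks 1,3,5,7,9,11, cultural-liquid
#' fraction) into one feature row per detection, with unit intensities.
#'
#' @param strain Strain label to attach.
#' @return A list with `features` (a [feature_table()]), `design` (the full
#'   sample grid) and `feature_names` (named by neutral mass).
#' @export
streptomyces_presence_fixture <- function(strain = "Streptomyces_M1") {
  path <- system.file("extdata", "streptomyces_presence_fixture.csv",
                      package = "oxyderep")
  fix <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  sample_cols <- grep("^(C|O2|O3)_[0-9]+$", names(fix), value = TRUE)
  parts <- strsplit(sample_cols, "_", fixed = TRUE)
  design <- data.frame(
    strain = strain,
    condition = vapply(parts, `[`, character(1), 1),
    week = as.integer(vapply(parts, `[`, character(1), 2)),
    fraction = "cultural_liquid"
  )
  rows <- lapply(seq_along(sample_cols), function(k) {
    present <- fix[[sample_cols[k]]] == 1
    if (!any(present)) return(NULL)
    data.frame(feature_name = fix$name[present],
               rt_min = fix$rt_min[present],
               neutral_mass = fix$neutral_mass[present],
               intensity = 1e6,
               strain = strain,
               condition = design$condition[k],
               week = design$week[k],
               fraction = design$fraction[k])
  })
  features <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(features) <- NULL
  list(features = feature_table(features), design = design,
       feature_names = stats::setNames(fix$name, fix$neutral_mass))
}

random_16s_sequence <- function(length, gc_content) {
  probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
             G = gc_content / 2, T = (1 - gc_content) / 2)
  paste(sample(names(probs), length, replace = TRUE, prob = probs),
        collapse = "")
}

#' Generate a weekly 16S sequence series with planted substitutions
#'
#' Produces one consensus sequence per week: the week-1 base sequence (random
#' with the configured GC content) with the scenario's substitutions planted
#' in the designated weeks. Presets encode the two study scenarios: a
#' Rhodococcus-style series under oxygen + ozone carrying a T-to-G
#' substitution in week 10 (inside V2) and a C-to-T substitution in week 12
#' (inside V9), and a Streptomyces-style series with no substitutions at all.
#'
#' @param config A [sim_config()] (supplies seed, GC content, length).
#' @param preset `"rhodococcus_o3"`, `"streptomyces"`, or `"custom"`.
#' @param scenario For `preset = "custom"`: a data.frame with columns `week`,
#'   `position`, `ref`, `alt` (`ref != alt`, positions within the sequence).
#' @param n_weeks Number of weekly sequences (default 12).
#' @return A list with `sequences` (named character vector `week01`..) and
#'   `truth` (the scenario data.frame, possibly empty).
#' @export
gen_16s_series <- function(config, preset = c("custom", "rhodococcus_o3",
                                              "streptomyces"),
                           scenario = NULL, n_weeks = 12) {
  stopifnot(inherits(config, "sim_config"))
  preset <- match.arg(preset)
  if (preset == "rhodococcus_o3") {
    scenario <- data.frame(week = c(10L, 12L), position = c(180L, 1350L),
                           ref = c("T", "C"), alt = c("G", "T"))
  } else if (preset == "streptomyces") {
    scenario <- data.frame(week = integer(0), position = integer(0),
                           ref = character(0), alt = character(0))
  } else if (is.null(scenario)) {
    scenario <- data.frame(week = integer(0), position = integer(0),
                           ref = character(0), alt = character(0))
  }
  if (nrow(scenario)) {
    if (any(scenario$ref == scenario$alt)) {
      stop("scenario alt base must differ from ref base")
    }
    if (any(scenario$position < 1 | scenario$position > config$seq_length)) {
      stop("scenario position outside the sequence")
    }
    if (any(scenario$week < 1 | scenario$week > n_weeks)) {
      stop("scenario week outside the series")
    }
  }

  set.seed(config$seed)
  base <- strsplit(random_16s_sequence(config$seq_length, config$gc_content),
                   "", fixed = TRUE)[[1]]
  base[scenario$position] <- scenario$ref  # force the planted reference bases

  sequences <- vapply(seq_len(n_weeks), function(w) {
    s <- base
    hit <- scenario$week == w
    s[scenario$position[hit]] <- scenario$alt[hit]
    paste(s, collapse = "")
  }, character(1))
  names(sequences) <- sprintf("week%02d", seq_len(n_weeks))
  list(sequences = sequences, truth = scenario)
}

#' Generate DPPH plate absorbances realizing a target activity grid
#'
#' Draws per-well absorbances such that [call_dpph()] at the default 20%
#' scavenging threshold reproduces the requested grid exactly: positive
#' cells scavenge 35-75% of the control absorbance, negative cells 0-8%.
#'
#' @param pattern A call list (`condition`, `week`, `fraction`, `call`) or a
#'   grid in [activity_table()] layout.
#' @param config A [sim_config()] (supplies the seed).
#' @param control_absorbance Negative-control absorbance at 517 nm.
#' @return A data.frame plate: the pattern columns plus `absorbance_517` and
#'   `negative_control_absorbance`.
#' @export
gen_dpph_plates <- function(pattern, config = sim_config(),
                            control_absorbance = 0.8) {
  stopifnot(inherits(config, "sim_config"))
  if (!"call" %in% names(pattern)) pattern <- parse_activity_table(pattern)
  if (!all(pattern$call %in% c("+", "-"))) {
    stop("pattern calls must be '+' or '-'")
  }
  set.seed(config$seed)
  s <- ifelse(pattern$call == "+",
              stats::runif(nrow(pattern), 0.35, 0.75),
              stats::runif(nrow(pattern), 0.00, 0.08))
  out <- pattern[c("condition", "week", "fraction")]
  out$absorbance_517 <- control_absorbance * (1 - s)
  out$negative_control_absorbance <- control_absorbance
  out
}

#' Generate disk-diffusion zone diameters realizing a target activity grid
#'
#' Positive cells get integer zones of 8-20 mm (zones are read to the
#' nearest millimetre), negative cells the bare 6 mm disk diameter.
#'
#' @inheritParams gen_dpph_plates
#' @param disk_mm Disk diameter in mm.
#' @param test_organism Label for the assay organism.
#' @return A data.frame with the pattern columns plus `test_organism` and
#'   `zone_mm`.
#' @export
gen_zone_table <- function(pattern, config = sim_config(), disk_mm = 6,
                           test_organism = "Bacillus subtilis") {
  stopifnot(inherits(config, "sim_config"))
  if (!"call" %in% names(pattern)) pattern <- parse_activity_table(pattern)
  if (!all(pattern$call %in% c("+", "-"))) {
    stop("pattern calls must be '+' or '-'")
  }
  set.seed(config$seed)
  out <- pattern[c("condition", "week", "fraction")]
  out$test_organism <- test_organism
  out$zone_mm <- ifelse(pattern$call == "+",
                        sample(8:20, nrow(pattern), replace = TRUE),
                        disk_mm)
  out
}
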