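#' Kidney-dominant peptide kinetic preset
#'
#' Default per-organ kinetic parameters for the generator: a radiolabelled
#' peptide cleared by glomerular filtration, so the kidneys take the largest
#' fractional uptake, with secondary accumulation in the urinary bladder and
#' liver and only transient blood-pool signal in heart, lungs and brain.
#' `f` is the peak fractional uptake (dimensionless), `k_up`/`k_out` the
#' uptake and washout rates in 1/min.
#'
#' @return Data frame with columns `organ`, `f`, `k_up`, `k_out`.
#' @export
peptide_kinetics <- function() {
  data.frame(
    organ = c("kidneys", "urinary bladder", "liver", "heart", "lungs",
              "brain", "intestine"),
    f     = c(0.25, 0.10, 0.06, 0.02, 0.02, 0.005, 0.04),
    k_up  = c(0.15, 0.05, 0.20, 0.50, 0.50, 0.30, 0.10),
    k_out = c(0.002, 0.0005, 0.005, 0.010, 0.010, 0.008, 0.003))
}

#' Kinetic specification for the scan generator
#'
#' Describes each organ's sum-of-exponentials time course, the
#' reconstruction-method bias and the noise level of a simulated subject.
#' The organ shape is `(exp(-k_out t) - exp(-k_up t))`, peak-normalised,
#' scaled by the fractional uptake `f` and the physical-decay envelope.
#'
#' @param organs Data frame with columns `organ`, `f`, `k_up`, `k_out`
#'   (rates 1/min); default [peptide_kinetics()].
#' @param rho Iterative/FBP residence-time scale (reconstruction bias),
#'   default 1.6.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   frame noise, default 0.1.
#' @param excreted_fraction Fraction of activity voided from the body during
#'   the scan. Default 0: anaesthetised rats do not void, so the whole-body
#'   curve is the pure physical-decay envelope.
#' @param excretion_rate Rate (1/min) at which the excreted fraction leaves,
#'   used only when `excreted_fraction > 0`.
#' @param seed Integer seed; identical specs generate identical scans.
#' @return Object of class `kinetic_spec`.
#' @export
kinetic_spec <- function(organs = peptide_kinetics(), rho = 1.6,
                         noise_cv = 0.1, excreted_fraction = 0,
                         excretion_rate = 0.01, seed = 1L) {
  organs <- as.data.frame(organs)
  stopifnot(all(c("organ", "f", "k_up", "k_out") %in% names(organs)))
  if (sum(organs$f) > 1)
    stop("organ fractional uptakes must sum to at most 1", call. = FALSE)
  if (any(organs$f < 0) || any(organs$k_out < 0) || any(organs$k_up <= 0))
    stop("rates must be non-negative and k_up positive", call. = FALSE)
  if (any(organs$k_up <= organs$k_out))
    stop("uptake rate k_up must exceed washout rate k_out", call. = FALSE)
  if (rho <= 0) stop("rho must be positive", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  if (excreted_fraction < 0 || excreted_fraction > 1)
    stop("excreted_fraction must be in [0, 1]", call. = FALSE)
  structure(list(organs = organs, rho = rho, noise_cv = noise_cv,
                 excreted_fraction = excreted_fraction,
                 excretion_rate = excretion_rate, seed = as.integer(seed)),
            class = "kinetic_spec")
}

## peak-normalised biexponential uptake/washout shape, sup = 1
organ_shape <- function(t_min, k_up, k_out) {
  if (is.infinite(k_up)) {
    s <- exp(-k_out * t_min)
    s[t_min == 0] <- 0          # bolus not yet arrived
    return(s)
  }
  raw <- exp(-k_out * t_min) - exp(-k_up * t_min)
  peak <- if (k_out == 0) 1 else {
    t_pk <- log(k_up / k_out) / (k_up - k_out)
    exp(-k_out * t_pk) - exp(-k_up * t_pk)
  }
  raw / peak
}

## noiseless organ activity (%ID) at times t_min, physical decay included
organ_activity <- function(t_min, f, k_up, k_out, decay) {
  100 * f * organ_shape(t_min, k_up, k_out) * exp(-decay$lambda * t_min)
}

## mean-1 multiplicative lognormal noise with coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate a matched FBP/iterative scan pair
#'
#' Simulates one subject's whole-body scan under both reconstruction
#' methods. Organ activities follow the kinetic spec's peak-normalised
#' uptake/washout shapes under the physical-decay envelope, sampled at the
#' frame midpoints with multiplicative lognormal noise. The whole-body curve
#' is the (noiseless) physical-decay envelope minus any excreted fraction.
#' The iterative scan's organ activities are scaled by `rho`, reproducing
#' the systematic residence-time inflation of iterative reconstruction; the
#' whole-body curve is shared. All randomness flows through the spec's seed,
#' so identical specs give bit-identical scans.
#'
#' @param spec A [kinetic_spec()].
#' @param schedule Frame schedule data frame; default
#'   [default_frame_schedule()].
#' @param decay A [decay_constants()].
#' @param subject_id Subject label.
#' @param radiotracer Radiotracer label.
#' @param body_mass_g Animal body mass in grams (metadata).
#' @return List with elements `fbp` and `iterative`, each a
#'   [subject_scan()].
#' @export
generate_scan <- function(spec, schedule = default_frame_schedule(),
                          decay = decay_constants(), subject_id = "S1",
                          radiotracer = "synthetic-peptide",
                          body_mass_g = 443.09) {
  stopifnot(inherits(spec, "kinetic_spec"))
  mids <- frame_midpoints(schedule)
  nfr <- nrow(schedule)

  wb_act <- 100 * exp(-decay$lambda * mids)
  if (spec$excreted_fraction > 0)
    wb_act <- wb_act * (1 - spec$excreted_fraction *
                          (1 - exp(-spec$excretion_rate * mids)))

  withr::with_seed(spec$seed, {
    build <- function(scale, recon) {
      tacs <- lapply(seq_len(nrow(spec$organs)), function(i) {
        p <- spec$organs[i, ]
        act <- scale * organ_activity(mids, p$f, p$k_up, p$k_out, decay) *
          lognormal_noise(nfr, spec$noise_cv)
        tac(p$organ, data.frame(t_start = schedule$t_start,
                                t_end = schedule$t_end, activity = act))
      })
      names(tacs) <- spec$organs$organ
      subject_scan(
        subject_id = subject_id, radiotracer = radiotracer,
        body_mass = body_mass_g, tacs = tacs,
        whole_body = tac("whole_body",
                         data.frame(t_start = schedule$t_start,
                                    t_end = schedule$t_end,
                                    activity = wb_act)),
        reconstruction = recon)
    }
    list(fbp = build(1, "FBP"), iterative = build(spec$rho, "iterative"))
  })
}

#' Standard clinical target-organ labels
#'
#' @param n How many labels to return (max 20).
#' @return Character vector of organ names, always starting with the main
#'   dosimetry targets and including `"LLI wall"`.
#' @export
clinical_organ_labels <- function(n = 12) {
  labs <- c("urinary bladder", "LLI wall", "kidneys", "liver", "lungs",
            "heart", "brain", "red marrow", "spleen", "pancreas",
            "thyroid", "stomach", "small intestine", "bone surfaces",
            "adrenals", "muscle", "skin", "thymus", "uterus", "testes")
  if (n > length(labs)) stop("at most ", length(labs), " organ labels",
                             call. = FALSE)
  labs[seq_len(n)]
}

#' Generate matched predicted/true clinical dose tables
#'
#' Draws true organ doses uniformly in `true_dose_range` and produces
#' predictions as `slope * true` under multiplicative lognormal noise —
#' the generating process assumed by the bias regression, so the fitted
#' slope should recover `slope` up to noise.
#'
#' @param n_organs Number of organ pairs (>= 3).
#' @param true_dose_range Range of true doses, mGy/MBq.
#' @param slope Generating slope (multiplicative model bias).
#' @param noise_cv Lognormal noise CV on the predictions.
#' @param seed Integer seed.
#' @return List with named vectors `predicted` and `true` (mGy/MBq),
#'   labelled with standard organ names including `"LLI wall"`.
#' @export
generate_dose_pairs <- function(n_organs = 12,
                                true_dose_range = c(0.005, 0.06),
                                slope = 0.6, noise_cv = 0.2, seed = 1L) {
  if (n_organs < 3) stop("n_organs must be at least 3", call. = FALSE)
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  stopifnot(length(true_dose_range) == 2L,
            all(true_dose_range > 0),
            true_dose_range[1] < true_dose_range[2])
  organs <- clinical_organ_labels(n_organs)
  withr::with_seed(as.integer(seed), {
    tru <- stats::runif(n_organs, true_dose_range[1], true_dose_range[2])
    pred <- slope * tru * lognormal_noise(n_organs, noise_cv)
  })
  list(predicted = stats::setNames(pred, organs),
       true = stats::setNames(tru, organs))
}

#' Reference organ-mass fixtures
#'
#' Editable default mass tables. The rat and phantom body masses are the
#' study constants (332.67 g rat; 73,000 g adult male, 60,000 g adult
#' female); the individual organ masses are plausible reference values
#' shipped as synthetic fixtures, to be replaced with measured masses for
#' real analyses.
#'
#' @param species `"rat"`, `"adult male"` or `"adult female"`.
#' @return An [organ_mass_table()].
#' @export
default_organ_masses <- function(species = c("rat", "adult male",
                                             "adult female")) {
  species <- match.arg(species)
  organs <- c("brain", "heart", "intestine", "kidneys", "liver", "lungs",
              "urinary bladder", "spleen")
  masses <- switch(species,
    "rat" = c(1.9, 1.2, 8.0, 2.66, 12.0, 1.7, 0.35, 0.75),
    "adult male" = c(1420, 316, 1000, 299, 1910, 1000, 47.6, 183),
    "adult female" = c(1200, 240, 880, 275, 1400, 800, 35.9, 150))
  body <- switch(species, "rat" = 332.67, "adult male" = 73000,
                 "adult female" = 60000)
  organ_mass_table(species, body, stats::setNames(masses, organs))
}

#' Synthetic phantom S-value matrix
#'
#' Builds a diagonally dominant, physically plausible S-value matrix for a
#' phantom: self-dose inversely proportional to target mass, small
#' symmetric cross-organ terms, a weak uniform contribution from the
#' remainder, and an `other tissues` target collecting the unassigned body
#' mass. These are synthetic fixtures — real phantom S-values must be
#' supplied to reproduce reference dosimetry numerics — but they preserve
#' the structure the dose engine assumes (kidney self-dose dominates for a
#' kidney-retained tracer). Tissue weighting factors follow the ICRP-60
#' style scheme over the modelled targets, with `other tissues` absorbing
#' the balance so the weights sum to exactly 1.
#'
#' @param phantom `"adult male"` or `"adult female"`.
#' @return An [svalue_matrix()].
#' @export
synthetic_svalue_matrix <- function(phantom = c("adult male",
                                                "adult female")) {
  phantom <- match.arg(phantom)
  masses <- default_organ_masses(phantom)
  m <- masses$organ_masses
  m["LLI wall"] <- if (phantom == "adult male") 167 else 160
  m["other tissues"] <- masses$body_mass - sum(m)
  sources <- c(names(masses$organ_masses), "remainder")
  targets <- names(m)

  k_self <- 45     # g * mGy / (MBq h): self-dose scale
  k_cross <- 0.015 # relative strength of cross-organ photon dose
  self_s <- k_self / m
  S <- outer(self_s[targets], self_s[c(names(masses$organ_masses))],
             function(a, b) k_cross * sqrt(a * b))
  dimnames(S) <- list(targets, names(masses$organ_masses))
  for (org in names(masses$organ_masses)) S[org, org] <- self_s[org]
  ## gut proximity: intestine irradiates the LLI wall strongly
  S["LLI wall", "intestine"] <- 0.5 * self_s["LLI wall"]
  S <- cbind(S, remainder = k_self / masses$body_mass * rep(1, length(targets)))

  w <- c(brain = 0.025, heart = 0.03, intestine = 0.12, kidneys = 0.025,
         liver = 0.05, lungs = 0.12, "urinary bladder" = 0.05,
         spleen = 0.0, "LLI wall" = 0.12)
  w["other tissues"] <- 1 - sum(w)
  svalue_matrix(phantom, S, w)
}

#' Synthetic clinical reference dose table
#'
#' Plausible adult absorbed organ doses (mGy/MBq) for a glucose-analogue
#' tracer, shipped as a synthetic stand-in for published clinical dosimetry
#' tables.
#'
#' @return Named numeric vector, mGy/MBq.
#' @export
synthetic_clinical_doses <- function() {
  c(brain = 0.038, heart = 0.067, intestine = 0.013, kidneys = 0.017,
    liver = 0.021, lungs = 0.020, "urinary bladder" = 0.16,
    spleen = 0.015, "LLI wall" = 0.016, "other tissues" = 0.012)
}

#' Write a complete synthetic fixture bundle
#'
#' Generates a worked dataset on which the whole pipeline runs end to end:
#' three subjects x two reconstructions of TAC files, rat and human
#' organ-mass tables, synthetic phantom S-value matrices with tissue
#' weights, and a synthetic clinical reference dose table. Every file
#' records the generating seed in a header comment. Regeneration with the
#' same seed reproduces the files byte-identically.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; per-subject seeds are derived from it.
#' @param n_subjects Number of subjects (default 3).
#' @param spec Base [kinetic_spec()]; its seed field is overridden per
#'   subject.
#' @return Invisibly, a named list of written file paths.
#' @export
generate_fixture_bundle <- function(out_dir, seed = 1L, n_subjects = 3,
                                    spec = kinetic_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  tag <- paste0("synthetic fixture; seed: ", seed)
  paths <- list()

  for (i in seq_len(n_subjects)) {
    sspec <- spec
    sspec$seed <- (seed * 131L + i) %% .Machine$integer.max
    pair <- generate_scan(sspec, subject_id = sprintf("S%02d", i))
    for (recon in names(pair)) {
      p <- file.path(out_dir, sprintf("tac_S%02d_%s.csv", i, recon))
      write_tac_file(pair[[recon]], p, comment = tag)
      paths[[sprintf("tac_S%02d_%s", i, recon)]] <- p
    }
  }

  for (sp in c("rat", "adult male", "adult female")) {
    p <- file.path(out_dir,
                   paste0(gsub(" ", "_", sp), "_organ_masses.csv"))
    write_organ_masses(default_organ_masses(sp), p, comment = tag)
    paths[[paste0("masses_", gsub(" ", "_", sp))]] <- p
  }

  wpath <- file.path(out_dir, "tissue_weights_synthetic.csv")
  for (sp in c("adult male", "adult female")) {
    sv <- synthetic_svalue_matrix(sp)
    p <- file.path(out_dir,
                   paste0("svalues_", gsub(" ", "_", sp), "_synthetic.csv"))
    write_svalue_matrix(sv, p, wpath, comment = tag)
    paths[[paste0("svalues_", gsub(" ", "_", sp))]] <- p
  }
  paths$tissue_weights <- wpath

  cpath <- file.path(out_dir, "clinical_reference_doses_synthetic.csv")
  write_dose_table(synthetic_clinical_doses(), cpath, comment = tag)
  paths$clinical_doses <- cpath

  invisible(paths)
}
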