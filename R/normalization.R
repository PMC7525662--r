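#' Rat-to-human organ-mass scaling factor
#'
#' The interspecies normalisation factor for one organ is
#' `(b_r / o_r) * (o_h / b_h)`: the ratio of the human organ's body-mass
#' fraction to the rat organ's body-mass fraction. Residence times scaled by
#' it carry the rat kinetics onto human anatomy. The factor is exactly 1
#' when the organ occupies the same fraction of body mass in both species.
#'
#' @param b_r Rat body mass (g).
#' @param o_r Rat organ mass (g).
#' @param b_h Human body mass (g); 73,000 g for the adult male phantom,
#'   60,000 g for the adult female.
#' @param o_h Human organ mass (g).
#' @return Dimensionless scaling factor.
#' @export
scaling_factor <- function(b_r, o_r, b_h, o_h) {
  if (any(c(b_r, o_r, b_h, o_h) <= 0))
    stop("non-positive mass", call. = FALSE)
  (b_r / o_r) * (o_h / b_h)
}

#' Per-organ scaling-factor table for a phantom
#'
#' @param rat_masses [organ_mass_table()] for the rat.
#' @param human_masses [organ_mass_table()] for the human phantom.
#' @param organs Organs to include; default the intersection check is strict:
#'   every requested organ must be in both tables.
#' @return Object of class `scaling_factor_table`: named `factors` vector
#'   plus the provenance masses used.
#' @export
scaling_factor_table <- function(rat_masses, human_masses,
                                 organs = names(rat_masses$organ_masses)) {
  stopifnot(inherits(rat_masses, "organ_mass_table"),
            inherits(human_masses, "organ_mass_table"))
  miss_r <- setdiff(organs, names(rat_masses$organ_masses))
  miss_h <- setdiff(organs, names(human_masses$organ_masses))
  if (length(miss_r) || length(miss_h))
    stop("organ missing from mass table: ",
         paste(unique(c(miss_r, miss_h)), collapse = ", "), call. = FALSE)
  f <- vapply(organs, function(org) {
    scaling_factor(rat_masses$body_mass, rat_masses$organ_masses[[org]],
                   human_masses$body_mass, human_masses$organ_masses[[org]])
  }, numeric(1))
  structure(list(phantom = human_masses$species,
                 factors = stats::setNames(f, organs),
                 b_r = rat_masses$body_mass, b_h = human_masses$body_mass,
                 o_r = rat_masses$organ_masses[organs],
                 o_h = human_masses$organ_masses[organs]),
            class = "scaling_factor_table")
}

#' Normalise residence times to human organ masses
#'
#' Multiplies every source-organ residence time by its organ scaling factor.
#' The whole-body residence time is left untouched (total-body cumulated
#' activity is fixed by the decay physics and the factor is defined per
#' organ); the remainder is then recomputed as whole-body tau minus the sum
#' of the scaled organ taus, under the same clamping rule as
#' [residence_times()]. Applying normalisation twice is an error.
#'
#' @param rts A non-normalised [residence_time_set()].
#' @param rat_masses,human_masses [organ_mass_table()]s, or a prebuilt
#'   [scaling_factor_table()] passed as `rat_masses` (then `human_masses`
#'   may be missing).
#' @param remainder_tol Clamp tolerance for the recomputed remainder.
#' @return A normalised `residence_time_set`.
#' @export
normalise_residence_times <- function(rts, rat_masses, human_masses = NULL,
                                      remainder_tol = 0.02) {
  stopifnot(inherits(rts, "residence_time_set"))
  if (rts$normalised)
    stop("residence times are already normalised", call. = FALSE)
  sft <- if (inherits(rat_masses, "scaling_factor_table")) rat_masses
         else scaling_factor_table(rat_masses, human_masses,
                                   organs = names(rts$tau))
  miss <- setdiff(names(rts$tau), names(sft$factors))
  if (length(miss))
    stop("organ missing from mass table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tau2 <- rts$tau * sft$factors[names(rts$tau)]
  residence_time_set(tau2, rts$whole_body,
                     reconstruction = rts$reconstruction,
                     normalised = TRUE, remainder_tol = remainder_tol)
}
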