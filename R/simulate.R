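#' Parameters of the synthetic high-light cohort generator
#'
#' The generator emulates a germplasm screen: `n_genotypes` accessions grown
#' under control and high-light stress with `n_replicates` biological
#' replicates, scored on the nine canonical traits. Defaults are calibrated to
#' the descriptive statistics of a 48-accession oat seedling screen: control
#' grand means and inter-genotype SDs match the screen's control column, and
#' each trait's stress factor is the stress/control grand-mean ratio (all
#' traits decline under stress except proline, which rises; dry weight is
#' nearly unchanged).
#'
#' Trait-trait correlation between genotype effects is induced by a
#' single-factor model: each trait loads on a latent "vigor" factor with the
#' structural traits, SPAD, Rubisco and biomass loading positively and proline
#' negatively, so the correlation matrix `L L' + diag(1 - L^2)` is positive
#' semidefinite by construction, with a positive block among growth traits and
#' negative coupling of that block with proline.
#'
#' Genotypic tolerance heterogeneity -- the signal the TOPSIS screen must
#' recover -- is a latent per-genotype scalar `tol ~ N(0, 1)` that multiplies
#' the stress factor by `exp(tolerance_effect * tol)` for every trait except
#' proline, where the sign is flipped (tolerant genotypes accumulate less
#' proline under stress).
#'
#' @param n_genotypes number of accessions (default 48).
#' @param n_replicates biological replicates per genotype x treatment
#'   (default 3).
#' @param control_mean,control_sd named numeric vectors over [hl_traits()]:
#'   control grand mean and inter-genotype SD per trait.
#' @param stress_factor named numeric vector: expected stress/control mean
#'   ratio per trait (> 0).
#' @param loadings named numeric vector in (-1, 1): latent-factor loadings
#'   inducing the trait-trait correlation of genotype effects.
#' @param tolerance_effect scale of the latent tolerance scalar's effect on
#'   the per-genotype stress factor (log scale; default 0.1).
#' @param residual_cv replicate-level residual SD as a fraction of the
#'   genotype x treatment expected value (default 0.10; the screen reports no
#'   replicate-level variance, so this is a free choice).
#' @param log_scale traits drawn lognormally (strictly positive, CV up to
#'   ~63% in the calibration data); the rest are natural-scale normal.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_genotypes = 48L,
                          n_replicates = 3L,
                          control_mean = c(plant_height = 35.82,
                                           stem_diameter = 1.81,
                                           spad = 30.19,
                                           leaf_thickness = 0.52,
                                           afw = 0.54, adw = 0.07,
                                           pn = 6.98, proline = 422.41,
                                           rubisco = 210.43),
                          control_sd = c(plant_height = 4.95,
                                         stem_diameter = 0.30,
                                         spad = 6.98,
                                         leaf_thickness = 0.11,
                                         afw = 0.21, adw = 0.03,
                                         pn = 2.63, proline = 266.55,
                                         rubisco = 69.05),
                          stress_factor = c(plant_height = 31.51 / 35.82,
                                            stem_diameter = 1.55 / 1.81,
                                            spad = 24.37 / 30.19,
                                            leaf_thickness = 0.46 / 0.52,
                                            afw = 0.42 / 0.54,
                                            adw = 0.06 / 0.07,
                                            pn = 4.13 / 6.98,
                                            proline = 571.95 / 422.41,
                                            rubisco = 168.22 / 210.43),
                          loadings = c(plant_height = 0.70,
                                       stem_diameter = 0.80,
                                       spad = 0.80,
                                       leaf_thickness = 0.60,
                                       afw = 0.85, adw = 0.60,
                                       pn = 0.60, proline = -0.60,
                                       rubisco = 0.60),
                          tolerance_effect = 0.1,
                          residual_cv = 0.10,
                          log_scale = c("afw", "adw", "proline", "rubisco")) {
  traits <- hl_traits()
  for (v in list(control_mean, control_sd, stress_factor, loadings)) {
    if (!all(traits %in% names(v))) {
      stop("per-trait parameter vectors must cover all nine canonical traits")
    }
  }
  if (any(control_sd[traits] < 0)) stop("control SDs must be >= 0")
  if (any(stress_factor[traits] <= 0)) stop("stress factors must be > 0")
  if (any(abs(loadings[traits]) >= 1)) stop("loadings must lie in (-1, 1)")
  if (residual_cv < 0) stop("residual_cv must be >= 0")
  L <- loadings[traits]
  R <- outer(L, L) + diag(1 - L^2)
  dimnames(R) <- list(traits, traits)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("trait correlation matrix is not positive semidefinite")
  out <- list(n_genotypes = as.integer(n_genotypes),
              n_replicates = as.integer(n_replicates),
              control_mean = control_mean[traits],
              control_sd = control_sd[traits],
              stress_factor = stress_factor[traits],
              loadings = L, correlation = R,
              tolerance_effect = tolerance_effect,
              residual_cv = residual_cv,
              log_scale = intersect(log_scale, traits),
              # floors keep every genotype mean strictly positive so the
              # stress/control ratio downstream is always defined
              floor = 0.02 * control_mean[traits])
  class(out) <- "cohort_params"
  out
}

#' Simulate a replicate-level high-light cohort
#'
#' Draws one latent tolerance scalar and one correlated genotype-effect vector
#' per genotype, forms control genotype means (lognormal for strictly positive
#' traits, normal otherwise), multiplies by the tolerance-modulated stress
#' factor for stress means, and adds independent replicate noise. Values are
#' truncated at trait-specific positive floors; truncation events are counted.
#' Each genotype consumes its own random sub-stream derived from `seed`, so
#' genotype g's data are reproducible regardless of `n_genotypes`.
#'
#' @param params a [cohort_params()] object.
#' @param seed master integer seed; the run is deterministic given it.
#' @return A [trait_table()] with attributes `latent_tolerance` (named vector,
#'   the generator's ground-truth tolerance scalar per genotype) and
#'   `n_truncated` (count of floor-truncation events).
#' @export
simulate_cohort <- function(params = cohort_params(), seed) {
  stopifnot(inherits(params, "cohort_params"))
  if (missing(seed)) stop("simulate_cohort requires an explicit seed")
  traits <- hl_traits()
  p <- params
  chol_R <- chol(p$correlation)
  # lognormal reparameterisation matching mean and SD on the natural scale
  sdlog <- sqrt(log(1 + (p$control_sd / p$control_mean)^2))
  meanlog <- log(p$control_mean) - sdlog^2 / 2
  gids <- sprintf("G%03d", seq_len(p$n_genotypes))
  # per-genotype sub-streams: genotype g's seed is the g-th draw from the
  # master stream, so g's data do not depend on n_genotypes
  set.seed(as.integer(seed))
  gseeds <- sample.int(2147483647L, p$n_genotypes)
  tol <- numeric(p$n_genotypes)
  names(tol) <- gids
  n_trunc <- 0L
  rows <- vector("list", p$n_genotypes)
  for (g in seq_len(p$n_genotypes)) {
    set.seed(gseeds[g])
    tol[g] <- stats::rnorm(1)
    z <- drop(crossprod(chol_R, stats::rnorm(length(traits))))
    ctrl <- ifelse(traits %in% p$log_scale,
                   exp(meanlog + sdlog * z),
                   p$control_mean + p$control_sd * z)
    names(ctrl) <- traits
    # tolerant genotypes hold growth traits up under stress and accumulate
    # less proline; the proline loading of the latent scalar is inverted
    sgn <- ifelse(traits == "proline", -1, 1)
    strs <- ctrl * p$stress_factor * exp(p$tolerance_effect * sgn * tol[g])
    n_trunc <- n_trunc + sum(ctrl < p$floor) + sum(strs < p$floor)
    ctrl <- pmax(ctrl, p$floor)
    strs <- pmax(strs, p$floor)
    mk <- function(mu, trt) {
      noise <- stats::rnorm(length(traits) * p$n_replicates,
                            sd = rep(p$residual_cv * mu, each = p$n_replicates))
      val <- rep(mu, each = p$n_replicates) + noise
      low <- val < rep(p$floor, each = p$n_replicates)
      n_trunc <<- n_trunc + sum(low)
      val[low] <- rep(p$floor, each = p$n_replicates)[low]
      data.frame(genotype = gids[g], treatment = trt,
                 replicate = rep(seq_len(p$n_replicates), times = length(traits)),
                 trait = rep(traits, each = p$n_replicates),
                 value = val, stringsAsFactors = FALSE)
    }
    rows[[g]] <- rbind(mk(ctrl, "control"), mk(strs, "stress"))
  }
  out <- trait_table(do.call(rbind, rows))
  attr(out, "latent_tolerance") <- tol
  attr(out, "n_truncated") <- n_trunc
  out
}
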