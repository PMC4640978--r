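# Cohort generator presets.

# Deterministic per-stage child seeds from one root seed.
childSeed <- function(seed, stage) {
    ((as.numeric(seed) %% 99991) * 21001 + stage * 101) %% 2147483629
}

#' Generator presets for synthetic femur cohorts
#'
#' A preset bundles everything the synthetic-data generator needs: cohort
#' size, demographic moments and ranges (mean, SD, range for age in years,
#' weight in kg, height in cm), site labels, per-mode shape variance
#' fractions, the planted focal-patch effect (percent CMSD change per SD of
#' the size coefficient S0), target covariate correlations, field baselines
#' and noise, and the imaging model (Gaussian blur SD in mm, additive noise
#' SD in mg/cm^3, profile spacing and half-extent in mm).
#'
#' \code{malePreset} and \code{femalePreset} encode the two study cohorts
#' (n = 308 and n = 125): demographics 73.5 +/- 5.7 (65-91) years,
#' 84.3 +/- 14.0 (56-125) kg, 174.3 +/- 7.2 (147-198) cm for the males and
#' 76.8 +/- 7.4 (53-98), 66.4 +/- 11.1 (40-96), 158.1 +/- 6.7 (141-175) for
#' the females; mode variance fractions starting 58/15/6 percent (59/14/6
#' for females); planted patch effects of -6.87 and -6.74 percent per SD;
#' and height-size / weight-size correlations 0.64 / 0.42 with age-size
#' correlation 0.  \code{nullPreset} plants no effect.
#'
#' @param n cohort size override.
#' @param ... named overrides of any preset field.
#' @return A list of class \code{"GeneratorPreset"}.
#' @examples
#' p <- malePreset()
#' p$n; p$patchEffect
#' @export
malePreset <- function(n = 308L, ...) {
    makePreset(list(
        name = "male", n = n,
        age = c(mean = 73.5, sd = 5.7, lo = 65, hi = 91),
        weight = c(mean = 84.3, sd = 14.0, lo = 56, hi = 125),
        height = c(mean = 174.3, sd = 7.2, lo = 147, hi = 198),
        sites = c("Birmingham", "Minneapolis", "PaloAlto", "Pittsburgh",
                  "Portland", "SanDiego"),
        modeVariances = c(0.58, 0.15, 0.06, 0.055, 0.045, 0.035,
                          0.028, 0.022, 0.015, 0.010),
        patchEffect = -6.87,
        corr = c(height = 0.64, weight = 0.42, age = 0,
                 heightWeight = 0.5)),
        ...)
}

#' @rdname malePreset
#' @export
femalePreset <- function(n = 125L, ...) {
    makePreset(list(
        name = "female", n = n,
        age = c(mean = 76.8, sd = 7.4, lo = 53, hi = 98),
        weight = c(mean = 66.4, sd = 11.1, lo = 40, hi = 96),
        height = c(mean = 158.1, sd = 6.7, lo = 141, hi = 175),
        sites = c("Cambridge", "Prague"),
        modeVariances = c(0.59, 0.14, 0.06, 0.055, 0.045, 0.035,
                          0.028, 0.022, 0.015, 0.007),
        patchEffect = -6.74,
        corr = c(height = 0.64, weight = 0.42, age = 0,
                 heightWeight = 0.5)),
        ...)
}

#' @rdname malePreset
#' @export
nullPreset <- function(n = 308L, ...) {
    malePreset(n = n, name = "null", patchEffect = 0, ...)
}

makePreset <- function(defaults, ...) {
    base <- defaults
    base$n <- as.integer(base$n)
    p <- c(base, list(
        # field model: baselines, covariate slopes, per-vertex noise
        field = list(
            trabecularDensity = 150, outsideDensity = 30,
            ageSlopePerYear = -0.002,       # fractional CTh change per year
            siteOffsets = NULL,             # built per site label, first = 0
            noiseSdLogCth = 0.05, noiseSdLogCbmd = 0.02,
            effectOn = "cth", cthFloor = 0.02),
        # imaging model for profile synthesis
        imaging = list(sigma = 0.75, noiseSD = 25,
                       spacing = 0.5, extent = 15),
        # scanner pose perturbation applied to each subject mesh
        pose = list(rotationSD = 4, translationSD = 5)
    ))
    ov <- list(...)
    for (nm in names(ov)) {
        if (nm %in% c("field", "imaging", "pose")) {
            p[[nm]][names(ov[[nm]])] <- ov[[nm]]
        } else p[[nm]] <- ov[[nm]]
    }
    if (is.null(p$field$siteOffsets)) {
        k <- length(p$sites)
        off <- if (k > 1) c(0, seq(-0.015, 0.015,
                                   length.out = k - 1L)) else 0
        p$field$siteOffsets <- setNames(off, sort(p$sites))
    }
    validatePreset(p)
    p
}

validatePreset <- function(p) {
    stopifnot(p$n >= 1L, all(p$modeVariances >= 0))
    if (sum(p$modeVariances) > 1 + 1e-8)
        stop("mode variance fractions must sum to at most 1")
    if (p$n < length(p$modeVariances) + 8L + 2L)
        stop("cohort size too small for the number of retained modes ",
             "plus covariates")
    if (p$imaging$sigma <= 0 || p$imaging$spacing <= 0)
        stop("imaging sigma and spacing must be positive")
    invisible(p)
}

# Truncated-normal helpers ---------------------------------------------------

# mean and sd of N(mu, sig) truncated to (lo, hi)
tnormMoments <- function(mu, sig, lo, hi) {
    a <- (lo - mu) / sig; b <- (hi - mu) / sig
    Z <- pnorm(b) - pnorm(a)
    da <- dnorm(a); db <- dnorm(b)
    m <- mu + sig * (da - db) / Z
    v <- sig^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
    c(mean = m, sd = sqrt(pmax(v, 0)))
}

# underlying (mu, sig) so that the truncated distribution has the target
# mean and sd -- the printed cohort moments are moments of the observed
# (range-limited) sample, so the generator must invert the truncation
tnormSolve <- function(mean, sd, lo, hi) {
    obj <- function(par) {
        mm <- tnormMoments(par[1], exp(par[2]), lo, hi)
        (mm[1] - mean)^2 / sd^2 + (mm[2] - sd)^2 / sd^2
    }
    fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))
    c(mu = fit$par[1], sig = exp(fit$par[2]))
}

# quantile transform: latent standard normal -> truncated normal
tnormFromLatent <- function(z, mu, sig, lo, hi) {
    a <- pnorm((lo - mu) / sig); b <- pnorm((hi - mu) / sig)
    u <- a + pnorm(z) * (b - a)
    mu + sig * qnorm(u)
}
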