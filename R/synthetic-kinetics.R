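#' Synthetic kinetics specification
#'
#' Ground-truth parameters and assay designs for [genKinetics()]. The
#' default designs mirror the packaged assay layouts: a 0-12.5 mM
#' substrate titration (two-fold dilutions), competitive inhibition at a
#' fixed 1 mM substrate, a 0-3 uM co-factor titration, and 10-minute
#' linear progress curves read in the first 5 minutes. Default parameter
#' magnitudes are representative of published amidolytic measurements on
#' free FVIIa (KM in the several-mM range, sub-s^-1 turnover, sub-uM
#' co-factor affinity).
#'
#' @param KM Michaelis constant, mM.
#' @param kcat turnover number, 1/s.
#' @param Ki competitive inhibition constant, mM.
#' @param Kd co-factor dissociation constant, uM.
#' @param enzymeConc enzyme concentration (arbitrary molar unit; rates
#'   scale as \code{kcat * enzymeConc}).
#' @param activation fold activity increase at co-factor saturation.
#' @param substrate,inhibitor,titrant,time assay design grids (mM, mM,
#'   uM, minutes).
#' @param noiseSigma multiplicative Gaussian noise SD.
#' @param replicates replicate series per assay.
#' @param seed RNG seed.
#' @return A list of class \code{syntheticKineticsSpec}.
#' @export
syntheticKineticsSpec <- function(KM = 7.2, kcat = 0.3, Ki = 2.0, Kd = 0.09,
                                  enzymeConc = 10, activation = 20,
                                  substrate = c(0, 12.5 / 2^(6:0)),
                                  inhibitor = c(0, 20 / 2^(6:0)),
                                  titrant = c(0, 3 / 2^(6:0)),
                                  time = 0:10,
                                  noiseSigma = 0.02, replicates = 2,
                                  seed = 1) {
  stopifnot(KM > 0, kcat > 0, Ki > 0, Kd > 0, noiseSigma >= 0)
  structure(list(KM = KM, kcat = kcat, Ki = Ki, Kd = Kd,
                 enzymeConc = enzymeConc, activation = activation,
                 substrate = substrate, inhibitor = inhibitor,
                 titrant = titrant, time = time, noiseSigma = noiseSigma,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "syntheticKineticsSpec")
}

.noisy <- function(v, sigma, n) v * (1 + rnorm(n, 0, sigma))

#' Generate synthetic kinetic datasets with known ground truth
#'
#' Draws rates from the four assay models (Michaelis-Menten substrate
#' titration, competitive inhibition at fixed substrate, hyperbolic
#' co-factor binding, linear progress curve) with multiplicative Gaussian
#' noise. Fully deterministic in the seed; the generating spec is embedded
#' as the truth record.
#'
#' @param spec a \code{syntheticKineticsSpec}.
#' @param seed RNG seed (defaults to the one in \code{spec}).
#' @return List of data.frames \code{mm}, \code{ki}, \code{kd},
#'   \code{progress} (each with replicate ids) plus \code{truth}.
#' @examples
#' k <- genKinetics(syntheticKineticsSpec(noiseSigma = 0), seed = 1)
#' fitMichaelisMenten(k$mm$conc, k$mm$rate)$KM   # recovers the true KM
#' @export
genKinetics <- function(spec, seed = spec$seed) {
  set.seed(seed)
  Vmax <- spec$kcat * spec$enzymeConc
  rep1 <- function(x, model) {
    do.call(rbind, lapply(seq_len(spec$replicates), function(r) {
      v <- model(x)
      data.frame(conc = x, rate = .noisy(v, spec$noiseSigma, length(v)),
                 replicate = r)
    }))
  }
  mm <- rep1(spec$substrate, function(S) Vmax * S / (spec$KM + S))
  v1 <- Vmax * 1 / (spec$KM + 1)   # uninhibited rate at the fixed 1 mM S
  ki <- rep1(spec$inhibitor, function(I)
    Vmax * 1 / (spec$KM * (1 + I / spec$Ki) + 1))
  kd <- rep1(spec$titrant, function(Tt)
    v1 + (spec$activation * v1 - v1) * Tt / (spec$Kd + Tt))
  progress <- do.call(rbind, lapply(seq_len(spec$replicates), function(r) {
    s <- v1 * spec$time
    data.frame(time = spec$time,
               signal = s * (1 + rnorm(length(s), 0, spec$noiseSigma)),
               replicate = r)
  }))
  list(mm = mm, ki = ki, kd = kd, progress = progress,
       truth = c(spec, list(Vmax = Vmax, v1 = v1, seedUsed = seed)))
}

#' Average replicate series before fitting
#'
#' @param df data.frame with an x column, a value column and
#'   \code{replicate}.
#' @param xcol,vcol column names (defaults \code{conc}, \code{rate}).
#' @return data.frame of per-x means.
#' @export
averageReplicates <- function(df, xcol = "conc", vcol = "rate") {
  agg <- aggregate(df[[vcol]], by = list(x = df[[xcol]]), FUN = mean)
  setNames(agg, c(xcol, vcol))
}
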