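## Enzyme-kinetics fitting: unweighted nonlinear least squares with
## positivity enforced by log-parameterisation, starting values from
## linearisations (Hanes-Woolf for the Michaelis-Menten model). Standard
## errors for log-parameterised constants are delta-method transforms of
## the asymptotic errors.

.checkSeries <- function(x, v, minPoints = 4L, what = "series") {
  if (length(x) != length(v)) stop(what, ": x and v lengths differ")
  if (any(x < 0)) stop(what, ": concentrations must be non-negative")
  if (length(x) < minPoints)
    stop(what, ": at least ", minPoints, " points required")
}

.nlsFit <- function(formula, data, start, what) {
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(what, " fit did not converge (starting values: ",
           paste(sprintf("%s=%.4g", names(start), unlist(start)),
                 collapse = ", "), "): ", conditionMessage(e)))
  fit
}

.logParamSE <- function(fit, name, value) {
  se <- tryCatch(summary(fit)$coefficients[name, "Std. Error"],
                 error = function(e) NA_real_)
  value * se     # delta method for exp(l)
}

#' Initial rate from a linear progress window
#'
#' Ordinary least-squares slope of signal against time over the early
#' linear window of a progress curve (default: the first 5 minutes).
#'
#' @param time time points (minutes).
#' @param signal observed signal.
#' @param window only points with \code{time <= window} are used.
#' @return List with \code{slope}, its standard error \code{se},
#'   \code{intercept} and \code{n} points used.
#' @examples
#' initialRate(0:10, 3 * (0:10) + 1)$slope   # 3
#' @export
initialRate <- function(time, signal, window = 5) {
  keep <- time <= window
  if (sum(keep) < 3L)
    stop("fewer than 3 points inside the ", window, "-minute window")
  fit <- lm(signal[keep] ~ time[keep])
  co <- summary(fit)$coefficients
  list(slope = unname(co[2, 1]), se = unname(co[2, 2]),
       intercept = unname(co[1, 1]), n = sum(keep))
}

#' Fit the Michaelis-Menten model
#'
#' Nonlinear least squares of \code{v = Vmax * S / (KM + S)} with KM and
#' Vmax log-parameterised (positivity by construction) and Hanes-Woolf
#' starting values. The turnover number is derived as
#' \code{kcat = Vmax / enzymeConc} when the enzyme concentration is given.
#'
#' @param conc substrate concentrations (mM), at least 5 levels spanning
#'   the expected KM.
#' @param rate observed rates.
#' @param enzymeConc optional enzyme concentration (same rate units per
#'   second convention as \code{rate}).
#' @return List of class \code{"MMFit"}: \code{KM} (mM), \code{Vmax},
#'   \code{kcat}, standard errors, \code{residuals} and the underlying
#'   \code{fit}.
#' @examples
#' S <- c(0.2, 0.5, 1, 2, 4, 8, 12.5)
#' v <- 10 * S / (7.2 + S)
#' fitMichaelisMenten(S, v)$KM    # 7.2
#' @export
fitMichaelisMenten <- function(conc, rate, enzymeConc = NULL) {
  .checkSeries(conc, rate, 5L, "Michaelis-Menten")
  pos <- conc > 0
  if (sum(pos) < 3L) stop("need at least 3 non-zero substrate levels")
  ## Hanes-Woolf: S/v = S/Vmax + KM/Vmax
  hw <- lm(I(conc[pos] / rate[pos]) ~ conc[pos])
  v0 <- 1 / max(coef(hw)[2], 1e-9)
  k0 <- max(coef(hw)[1] * v0, 1e-6)
  d <- data.frame(S = conc, v = rate)
  fit <- .nlsFit(v ~ exp(lV) * S / (exp(lK) + S), d,
                 list(lV = log(v0), lK = log(k0)), "Michaelis-Menten")
  KM <- unname(exp(coef(fit)["lK"]))
  Vmax <- unname(exp(coef(fit)["lV"]))
  out <- list(KM = KM, Vmax = Vmax,
              kcat = if (!is.null(enzymeConc)) Vmax / enzymeConc else NA_real_,
              seKM = .logParamSE(fit, "lK", KM),
              seVmax = .logParamSE(fit, "lV", Vmax),
              residuals = unname(residuals(fit)), fit = fit)
  class(out) <- "MMFit"
  out
}

#' @export
print.MMFit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: KM = %.4g mM (SE %.2g), Vmax = %.4g",
              x$KM, x$seKM, x$Vmax))
  if (!is.na(x$kcat)) cat(sprintf(", kcat = %.4g /s", x$kcat))
  cat("\n"); invisible(x)
}

#' Fit a competitive-inhibition constant
#'
#' Nonlinear least squares of
#' \code{v(I) = V * S / (KM * (1 + I/Ki) + S)} at fixed substrate
#' concentration, with the Michaelis constant supplied from an independent
#' fit; V and Ki are free (Ki log-parameterised). A flat series (no
#' inhibition signal) is rejected.
#'
#' @param inhib inhibitor concentrations, at least 5 levels including 0.
#' @param rate observed rates.
#' @param S fixed substrate concentration (mM; default 1).
#' @param KM Michaelis constant (mM) from a substrate-titration fit.
#' @return List of class \code{"KiFit"}: \code{Ki}, \code{seKi}, \code{V},
#'   \code{fit}.
#' @export
fitCompetitiveKi <- function(inhib, rate, S = 1, KM) {
  .checkSeries(inhib, rate, 5L, "inhibition")
  if (!any(inhib == 0)) stop("inhibition series must include I = 0")
  v0 <- mean(rate[inhib == 0])
  vMax <- mean(rate[inhib == max(inhib)])
  if (vMax > 0.9 * v0)
    stop("no inhibition signal: rate at the highest inhibitor level is ",
         "within 10% of the uninhibited rate")
  ## IC50-style start: I at half-inhibition, corrected for competition
  iHalf <- inhib[which.min(abs(rate - v0 / 2))]
  ki0 <- max(iHalf / (1 + S / KM), max(inhib) / 20, 1e-6)
  d <- data.frame(I = inhib, v = rate)
  fit <- .nlsFit(v ~ exp(lV) * S / (KM * (1 + I / exp(lKi)) + S), d,
                 list(lV = log(max(v0, 1e-9)), lKi = log(ki0)),
                 "competitive inhibition")
  Ki <- unname(exp(coef(fit)["lKi"]))
  out <- list(Ki = Ki, seKi = .logParamSE(fit, "lKi", Ki),
              V = unname(exp(coef(fit)["lV"])), S = S, KM = KM, fit = fit)
  class(out) <- "KiFit"
  out
}

#' @export
print.KiFit <- function(x, ...) {
  cat(sprintf("Competitive inhibition fit: Ki = %.4g (SE %.2g) at S = %g, KM = %g\n",
              x$Ki, x$seKi, x$S, x$KM))
  invisible(x)
}

#' Fit a hyperbolic binding constant from an activity titration
#'
#' Nonlinear least squares of
#' \code{v(T) = v0 + (vInf - v0) * T / (Kd + T)} for co-factor titrations
#' read out through activity (e.g. soluble tissue factor titrated against
#' amidolytic activity). The default hyperbolic model assumes titrant far
#' in excess of enzyme; a tight-binding quadratic variant is available
#' when that fails.
#'
#' @param titrant titrant concentrations, at least 5 levels including 0.
#' @param rate observed rates.
#' @param tightBinding use the quadratic (ligand-depletion) model.
#' @param enzymeConc enzyme concentration, required for the quadratic
#'   model (same units as \code{titrant}).
#' @return List of class \code{"KdFit"}: \code{Kd}, \code{seKd},
#'   \code{v0}, \code{vInf}, \code{fit}; a warning is attached when the
#'   titration does not approach saturation (max titrant below the
#'   fitted Kd).
#' @export
fitBindingKd <- function(titrant, rate, tightBinding = FALSE,
                         enzymeConc = NULL) {
  .checkSeries(titrant, rate, 5L, "binding")
  if (!any(titrant == 0)) stop("titration must include T = 0")
  v00 <- mean(rate[titrant == 0])
  vi0 <- mean(rate[titrant == max(titrant)])
  kd0 <- max(median(titrant[titrant > 0]), 1e-6)
  d <- data.frame(Tt = titrant, v = rate)
  if (tightBinding) {
    if (is.null(enzymeConc))
      stop("tight-binding model requires enzymeConc")
    E <- enzymeConc
    fit <- .nlsFit(
      v ~ v0 + (vI - v0) *
        ((E + Tt + exp(lK)) - sqrt((E + Tt + exp(lK))^2 - 4 * E * Tt)) /
        (2 * E),
      d, list(v0 = v00, vI = vi0, lK = log(kd0)), "tight binding")
  } else {
    fit <- .nlsFit(v ~ v0 + (vI - v0) * Tt / (exp(lK) + Tt), d,
                   list(v0 = v00, vI = vi0, lK = log(kd0)), "binding")
  }
  Kd <- unname(exp(coef(fit)["lK"]))
  if (max(titrant) < Kd)
    warning("saturation not approached: max titrant (", max(titrant),
            ") is below the fitted Kd (", signif(Kd, 3), ")")
  out <- list(Kd = Kd, seKd = .logParamSE(fit, "lK", Kd),
              v0 = unname(coef(fit)["v0"]), vInf = unname(coef(fit)["vI"]),
              fit = fit)
  class(out) <- "KdFit"
  out
}

#' @export
print.KdFit <- function(x, ...) {
  cat(sprintf("Binding fit: Kd = %.4g (SE %.2g), v0 = %.4g, vInf = %.4g\n",
              x$Kd, x$seKd, x$v0, x$vInf))
  invisible(x)
}

#' Normalise a per-variant activity table to a reference
#'
#' Adds the percentage columns of the variant characterisation heatmap:
#' catalytic efficiency \code{pct_kcat_over_KM = 100 * (kcat/KM) /
#' (kcat/KM)_ref}, inhibition \code{pct_Ki = 100 * Ki / Ki_ref} (the
#' "percentage Ki of the reference" convention; the inverse direction is
#' emitted alongside as \code{pct_Ki_inv}) and, when present, proteolytic
#' activation \code{pct_fx = 100 * fx_rate / fx_rate_ref}. The reference
#' row carries 100 in every percentage column. Percentages are invariant
#' to rescaling all rates by a common factor.
#'
#' @param table data.frame with a \code{variant} column and metric columns
#'   among \code{kcat}, \code{KM}, \code{Ki}, \code{Kd}, \code{fx_rate}.
#' @param reference value of \code{variant} identifying the reference row
#'   (default \code{"WT"}).
#' @return The table with percentage columns appended.
#' @export
normalizeToReference <- function(table, reference = "WT") {
  i <- which(table$variant == reference)
  if (length(i) != 1L)
    stop("reference '", reference, "' absent (or duplicated) in table")
  out <- table
  if (all(c("kcat", "KM") %in% names(table))) {
    eff <- table$kcat / table$KM
    if (!is.finite(eff[i]) || eff[i] == 0)
      stop("reference catalytic efficiency is zero or undefined")
    out$pct_kcat_over_KM <- 100 * eff / eff[i]
  }
  if ("Ki" %in% names(table)) {
    out$pct_Ki <- 100 * table$Ki / table$Ki[i]
    out$pct_Ki_inv <- 100 * table$Ki[i] / table$Ki
  }
  if ("fx_rate" %in% names(table))
    out$pct_fx <- 100 * table$fx_rate / table$fx_rate[i]
  out
}

#' Assemble the variant characterisation table (heatmap layout)
#'
#' Joins per-variant kinetic fits with the deletion library, sorts rows by
#' remaining loop length then deletion position (the heatmap layout; the
#' canonical variant-number ordering is kept in \code{index}), and
#' optionally renders a diverging heatmap of the percentage columns.
#'
#' @param activity data.frame from [normalizeToReference()] whose
#'   \code{variant} column holds library indices (plus the reference row).
#' @param library A [VariantLibrary-class].
#' @param file optional path for a PNG heatmap of the percentage columns.
#' @param reference reference row label.
#' @return data.frame sorted by loop length and deletion position, with
#'   library metadata columns joined in; missing variants yield NA rows
#'   with a message.
#' @export
buildHeatmapTable <- function(activity, library, file = NULL,
                              reference = "WT") {
  v <- variants(library)
  ref <- activity[activity$variant == reference, , drop = FALSE]
  act <- activity[activity$variant != reference, , drop = FALSE]
  idx <- suppressWarnings(as.integer(act$variant))
  if (anyNA(idx)) stop("non-reference variant labels must be library indices")
  m <- match(v$index, idx)
  if (anyNA(m))
    message(sum(is.na(m)), " library variant(s) missing from the activity ",
            "table; blank cells emitted")
  joined <- cbind(v[, c("index", "size", "start", "end", "deleted_sequence",
                        "loop_length")],
                  act[m, setdiff(names(act), "variant"), drop = FALSE])
  joined <- joined[order(-joined$loop_length, joined$start), ]
  rownames(joined) <- NULL
  out <- list(table = joined, reference = ref)
  if (!is.null(file)) {
    pct <- joined[, grep("^pct_", names(joined)), drop = FALSE]
    if (ncol(pct) && nrow(pct) > 1) {
      mat <- log2(as.matrix(pct) / 100)       # diverging around the reference
      rownames(mat) <- sprintf("no.%02d (len %d)", joined$index,
                               joined$loop_length)
      grDevices::png(file, width = 720, height = 160 + 16 * nrow(mat))
      pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                         main = "log2 fold change vs reference")
      grDevices::dev.off()
    }
  }
  out
}
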