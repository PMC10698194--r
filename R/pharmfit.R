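# Quantitative pharmacology: constrained 3-parameter logistic fits,
# Cheng-Prusoff inhibition constants, Schild regression and fold selectivity.

#' Constrained three-parameter logistic fit
#'
#' Fits `y = Emax / (1 + 10^(logEC50 - x))` with `x = log10(concentration)`,
#' bottom fixed at 0 and Hill slope fixed at 1, by least squares. The fit is
#' deterministic: a grid over logEC50 (with the conditionally optimal Emax in
#' closed form) seeds a Nelder-Mead refinement.
#'
#' @param concentrations numeric, same unit throughout (e.g. molar or nM);
#'   `logEC50` is reported in log10 of that unit.
#' @param responses numeric, normalized percent scale.
#' @return object of class `conc_response_fit`: `emax`, `log_ec50`, `ec50`,
#'   `rss`, `n`.
#' @export
fit_logistic3 <- function(concentrations, responses) {
  if (any(!is.finite(concentrations)) || any(!is.finite(responses)))
    stop("non-finite inputs")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (length(unique(concentrations)) < 3)
    stop("need at least 3 distinct concentrations")
  if (all(responses == 0)) stop("degenerate fit: all responses are zero")
  x <- log10(concentrations)
  y <- responses
  rss_of <- function(le) {
    f <- 1 / (1 + 10^(le - x))
    emax <- sum(y * f) / sum(f * f)
    c(rss = sum((y - emax * f)^2), emax = emax)
  }
  grid <- seq(min(x) - 3, max(x) + 3, by = 0.05)
  g <- vapply(grid, function(le) rss_of(le)["rss"], 0)
  le0 <- grid[which.min(g)]
  em0 <- rss_of(le0)["emax"]
  obj <- function(p) sum((y - p[1] / (1 + 10^(p[2] - x)))^2)
  op <- stats::optim(c(em0, le0), obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 5000))
  op <- stats::optim(op$par, obj, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 5000))
  structure(list(emax = unname(op$par[1]), log_ec50 = unname(op$par[2]),
                 ec50 = unname(10^op$par[2]), rss = op$value,
                 n = length(y)),
            class = "conc_response_fit")
}

#' @export
print.conc_response_fit <- function(x, ...) {
  cat(sprintf("conc_response_fit: Emax = %.2f%%, logEC50 = %.4f (EC50 = %.3g), RSS = %.3g, n = %d\n",
              x$emax, x$log_ec50, x$ec50, x$rss, x$n))
  invisible(x)
}

#' Cheng-Prusoff inhibition constant
#'
#' `Ki = IC50 / (1 + L / Kd)` for competitive displacement of a radioligand
#' at concentration `L` with dissociation constant `Kd`. Units of `ic50`
#' carry through; `L` and `Kd` must share a unit.
#'
#' @param ic50 displacement IC50 (> 0).
#' @param L radioligand concentration (> 0).
#' @param Kd radioligand dissociation constant (> 0).
#' @return Ki in the units of `ic50`.
#' @export
cheng_prusoff <- function(ic50, L, Kd) {
  if (any(c(ic50, L, Kd) <= 0)) stop("all inputs must be > 0")
  ic50 / (1 + L / Kd)
}

#' Schild regression
#'
#' Ordinary least squares of `log10(DR - 1)` on `log10(B)` for antagonist
#' concentrations `B` (molar) and dose ratios `DR` (agonist EC50 with
#' antagonist over EC50 alone). `pA2` is the x-intercept of the unconstrained
#' fit, `-intercept / slope`; the functional affinity is `Kb = 10^(-pA2)`
#' molar. Points with `DR <= 1` carry no antagonism information and are
#' rejected with a warning.
#'
#' @param B antagonist concentrations, molar.
#' @param DR dose ratios (> 1 required per usable point).
#' @return object of class `schild_fit`: `slope`, `pA2`, `kb_M`, `kb_nM`,
#'   `n_points`.
#' @export
schild_fit <- function(B, DR) {
  if (length(B) != length(DR)) stop("B and DR must have equal length")
  bad <- DR <= 1
  if (any(bad)) {
    warning(sum(bad), " point(s) with DR <= 1 rejected")
    B <- B[!bad]; DR <- DR[!bad]
  }
  if (length(B) < 2) stop("need at least 2 points with DR > 1")
  fit <- stats::lm(log10(DR - 1) ~ log10(B))
  cf <- stats::coef(fit)
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  if (!is.finite(slope) || abs(slope) < 1e-12)
    stop("Schild slope is not finite")
  # x-intercept of the regression is -intercept/slope (a log10 molar
  # concentration); pA2 is its negative
  pA2 <- intercept / slope
  structure(list(slope = slope, intercept = intercept, pA2 = pA2,
                 kb_M = 10^(-pA2), kb_nM = 10^(-pA2) * 1e9,
                 n_points = length(B)),
            class = "schild_fit")
}

#' @export
print.schild_fit <- function(x, ...) {
  cat(sprintf("schild_fit: slope = %.3f, pA2 = %.3f, Kb = %.3g nM (n = %d)\n",
              x$slope, x$pA2, x$kb_nM, x$n_points))
  invisible(x)
}

#' Functional affinity from a pA2 value
#'
#' `Kb = 10^(-pA2)` molar, reported in nM.
#'
#' @param pA2 negative log10 of the antagonist concentration doubling the
#'   agonist EC50.
#' @return Kb in nM.
#' @export
kb_from_pa2 <- function(pA2) 10^(-pA2) * 1e9

#' Fold selectivity between two binding affinities
#'
#' `fold = ki_other / ki_reference`; the reported form rounds to the nearest
#' ten with a "~" prefix (affinities themselves are conventionally reported
#' to 2 significant figures).
#'
#' @param ki_reference Ki at the reference (target) receptor.
#' @param ki_other Ki at the off-target receptor, same unit.
#' @param unit_reference,unit_other optional unit labels; a mismatch is an
#'   error.
#' @return list with `fold` (numeric) and `reported` (string like "~80").
#' @export
fold_selectivity <- function(ki_reference, ki_other,
                             unit_reference = NULL, unit_other = NULL) {
  if (!is.null(unit_reference) && !is.null(unit_other) &&
      unit_reference != unit_other)
    stop("unit mismatch: ", unit_reference, " vs ", unit_other)
  if (ki_reference <= 0 || ki_other <= 0) stop("affinities must be > 0")
  fold <- ki_other / ki_reference
  list(fold = fold, reported = paste0("~", round(fold / 10) * 10))
}

#' Simulate a noiseless or noisy concentration-response curve
#'
#' Fixture generator for the logistic machinery: responses from the
#' constrained three-parameter model with optional Gaussian noise.
#'
#' @param concentrations numeric (> 0).
#' @param emax true maximal response, percent.
#' @param ec50 true EC50, same unit as `concentrations`.
#' @param sd Gaussian noise standard deviation, percent (0 = noiseless).
#' @param seed RNG seed (used when `sd > 0`).
#' @return data.frame with `concentration`, `response`.
#' @export
simulate_conc_response <- function(concentrations, emax = 100, ec50 = 2,
                                   sd = 0, seed = 1L) {
  x <- log10(concentrations)
  y <- emax / (1 + 10^(log10(ec50) - x))
  if (sd > 0) y <- .with_seed(seed, y + stats::rnorm(length(y), 0, sd))
  data.frame(concentration = concentrations, response = y)
}

#' Simulate Schild dose-ratio data for a competitive antagonist
#'
#' Gaddum relation: `DR = 1 + B / Kb`.
#'
#' @param B antagonist concentrations, molar.
#' @param kb_M antagonist equilibrium constant, molar.
#' @return data.frame with `B`, `DR`.
#' @export
simulate_schild_points <- function(B, kb_M) {
  data.frame(B = B, DR = 1 + B / kb_M)
}
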