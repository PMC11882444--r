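# Small quantitative assay models used alongside the screens: the
# exact two-component ("quadratic") binding isotherm and a K_D fitter
# built on it, the four-parameter logistic dose-response, per-well
# TR-FRET ratios, the geometric-mean fluorescence reporter score, and
# a constrained single-phase exponential decay.

#' Equilibrium complex concentration from the quadratic binding model
#'
#' Exact mass-action solution for A + B <-> AB without the free-ligand
#' approximation: the smaller root of
#' `AB^2 - (A_T + B_T + K_D) AB + A_T B_T = 0`,
#' computed in the numerically stable form
#' `AB = 2 A_T B_T / (S + sqrt(S^2 - 4 A_T B_T))` with
#' `S = A_T + B_T + K_D`, which remains accurate as `K_D -> 0`.
#'
#' @param A_T,B_T Total concentrations of the two partners (same
#'   units, e.g. nM). Vectorized.
#' @param K_D Dissociation constant (same units).
#' @return Complex concentration `AB`, bounded by `min(A_T, B_T)`.
#' @examples
#' bound_complex(1, 1, 1)  # (3 - sqrt(5)) / 2
#' @export
bound_complex <- function(A_T, B_T, K_D) {
  if (any(A_T < 0) || any(B_T < 0) || any(K_D < 0)) {
    abort("concentrations and K_D must be non-negative")
  }
  s <- A_T + B_T + K_D
  prod <- A_T * B_T
  disc <- sqrt(pmax(s^2 - 4 * prod, 0))
  out <- ifelse(s + disc > 0, 2 * prod / (s + disc), 0)
  pmin(out, pmin(A_T, B_T))
}

new_assay_fit <- function(fit, model, data, extra = list()) {
  structure(c(list(fit = fit, model = model, data = data), extra),
            class = c(paste0(model, "_fit"), "assay_fit"))
}

#' @export
print.assay_fit <- function(x, ...) {
  cat(sprintf("<%s fit> converged: %s\n", x$model, x$converged))
  print(coef(x$fit))
  invisible(x)
}

assay_fit_tidy <- function(x) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = unname(s[, "Estimate"]),
         std.error = unname(s[, "Std. Error"]),
         statistic = unname(s[, "t value"]),
         p.value = unname(s[, "Pr(>|t|)"]))
}

assay_fit_glance <- function(x) {
  r <- stats::resid(x$fit)
  tibble(sigma = summary(x$fit)$sigma,
         rss = sum(r^2), nobs = length(r),
         converged = x$converged, degenerate = isTRUE(x$degenerate))
}

#' @rdname bound_complex
#' @param data Tibble with columns `dose` (the titrated total
#'   concentration `B_T`) and `response`.
#' @param A_T Fixed total concentration of the non-titrated partner.
#' @param float_baseline,float_amplitude Whether the signal model
#'   `response = s0 + amp * AB` floats an offset and amplitude
#'   (both default `TRUE`; with both fixed the response is `AB`
#'   itself).
#' @param start Optional named list of starting values
#'   (`K_D`, `s0`, `amp`).
#' @return `fit_kd()` returns a `kd_fit` object; access estimates via
#'   [tidy()] and fit diagnostics via [glance()].
#' @export
fit_kd <- function(data, A_T, float_baseline = TRUE,
                   float_amplitude = TRUE, start = NULL) {
  stopifnot(all(c("dose", "response") %in% names(data)))
  if (nrow(data) < 6L) abort("K_D fitting needs at least 6 doses")
  rng <- diff(range(data$response))
  if (rng < .Machine$double.eps^0.5 * max(1, abs(mean(data$response)))) {
    abort("responses are constant: amplitude ~ 0, K_D unidentifiable")
  }
  s0_0 <- min(data$response)
  amp_0 <- (max(data$response) - s0_0) / max(bound_complex(
    A_T, max(data$dose), stats::median(data$dose)), .Machine$double.eps)
  init <- list(K_D = stats::median(data$dose), s0 = s0_0, amp = amp_0)
  init[names(start)] <- start
  form <- if (float_baseline && float_amplitude) {
    response ~ s0 + amp * bound_complex(A_T, dose, K_D)
  } else if (float_amplitude) {
    init$s0 <- NULL
    response ~ amp * bound_complex(A_T, dose, K_D)
  } else {
    init$s0 <- NULL; init$amp <- NULL
    response ~ bound_complex(A_T, dose, K_D)
  }
  lower <- setNames(rep(-Inf, length(init)), names(init))
  lower["K_D"] <- 0
  fit <- minpack.lm::nlsLM(
    form, data = data, start = init, lower = lower,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  new_assay_fit(fit, "kd", data, list(
    A_T = A_T,
    K_D = unname(coef(fit)["K_D"]),
    converged = fit$convInfo$isConv
  ))
}

#' @export
tidy.assay_fit <- function(x, ...) assay_fit_tidy(x)

#' @export
glance.assay_fit <- function(x, ...) assay_fit_glance(x)

#' @export
augment.assay_fit <- function(x, ...) {
  mutate(as_tibble(x$data),
         .fitted = as.numeric(stats::fitted(x$fit)),
         .resid = as.numeric(stats::resid(x$fit)))
}

#' Four-parameter logistic dose-response fit
#'
#' Fits `y = bottom + (top - bottom) / (1 + (ec50 / x)^hill)` by
#' Levenberg-Marquardt least squares, with `ec50 > 0`. Initial values
#' come from the response quantiles and the mid-response dose.
#'
#' @param data Tibble with `dose` (strictly positive) and `response`,
#'   or two vectors via `dose`/`response` arguments.
#' @param dose,response Alternative vector interface.
#' @return A `pl4_fit` object (see [tidy()], [glance()], [augment()]).
#' @export
fit_4pl <- function(data = NULL, dose = NULL, response = NULL) {
  if (is.null(data)) data <- tibble(dose = dose, response = response)
  stopifnot(all(c("dose", "response") %in% names(data)))
  if (nrow(data) < 5L) abort("4PL fitting needs at least 5 doses")
  if (any(data$dose <= 0)) abort("doses must be strictly positive")
  lo <- min(data$response); hi <- max(data$response)
  increasing <- stats::cor(log(data$dose), data$response) >= 0
  mid <- (lo + hi) / 2
  ec50_0 <- data$dose[which.min(abs(data$response - mid))]
  init <- list(bottom = if (increasing) lo else hi,
               top = if (increasing) hi else lo,
               ec50 = ec50_0, hill = 1)
  fit <- minpack.lm::nlsLM(
    response ~ bottom + (top - bottom) / (1 + (ec50 / dose)^hill),
    data = data, start = init,
    lower = c(bottom = -Inf, top = -Inf, ec50 = .Machine$double.xmin,
              hill = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  new_assay_fit(fit, "pl4", data,
                list(converged = fit$convInfo$isConv))
}

#' Background-corrected TR-FRET ratio
#'
#' The per-well 520/490 nm intensity ratio after subtracting the mean
#' background intensities of wells containing no ligand.
#'
#' @param data Tibble with per-well columns `I520` and `I490`.
#' @param background Tibble (or length-2 numeric `c(I520, I490)`) of
#'   background wells.
#' @return `data` with added columns `I520_corr`, `I490_corr`,
#'   `tr_fret_ratio`.
#' @examples
#' trfret_ratio(tibble::tibble(I520 = 200, I490 = 100),
#'              background = c(50, 25))  # ratio 2
#' @export
trfret_ratio <- function(data, background = c(0, 0)) {
  stopifnot(all(c("I520", "I490") %in% names(data)))
  bg <- if (is.data.frame(background)) {
    c(mean(background$I520), mean(background$I490))
  } else {
    as.numeric(background)
  }
  out <- mutate(data,
                I520_corr = .data$I520 - bg[1],
                I490_corr = .data$I490 - bg[2])
  if (any(out$I490_corr <= 0)) {
    abort("nonpositive 490 nm intensity after background correction")
  }
  mutate(out, tr_fret_ratio = .data$I520_corr / .data$I490_corr)
}

#' Geometric-mean reporter stability score
#'
#' Per-sample geometric mean of the per-event GFP/mCherry fluorescence
#' ratio, normalized to a reference (vehicle-treated) score.
#' Non-positive events carry no information on a log scale and are
#' excluded; their count is reported as an attribute.
#'
#' @param gfp_events,mcherry_events Paired per-event fluorescence
#'   values.
#' @param reference_score Score of the reference sample (default 1:
#'   unnormalized).
#' @return Normalized stability score (scalar) with attribute
#'   `"n_excluded"`.
#' @export
reporter_score <- function(gfp_events, mcherry_events,
                           reference_score = 1) {
  stopifnot(length(gfp_events) == length(mcherry_events))
  ok <- gfp_events > 0 & mcherry_events > 0
  if (!any(ok)) abort("no positive GFP/mCherry event pairs")
  ratio <- gfp_events[ok] / mcherry_events[ok]
  score <- exp(mean(log(ratio))) / reference_score
  structure(score, n_excluded = sum(!ok))
}

#' Constrained single-phase exponential decay fit
#'
#' Fits `y = exp(-k t)` with the intercept constrained to 1 and the
#' plateau to 0, `k >= 0`. When substrate and enzyme concentrations
#' are supplied the derived first-order rate `V/[E] = k * S0 / E0`
#' (per min) is attached.
#'
#' @param times Time points (min), including t = 0.
#' @param intensities Intensities normalized to the t = 0 value.
#' @param S0,E0 Optional substrate and enzyme concentrations for the
#'   `v_over_E` convention.
#' @return A `decay_fit` object with elements `k` and (optionally)
#'   `v_over_E`.
#' @export
fit_decay <- function(times, intensities, S0 = NULL, E0 = NULL) {
  stopifnot(length(times) == length(intensities))
  if (length(times) < 3L) abort("decay fitting needs >= 3 timepoints")
  data <- tibble(t = times, y = intensities)
  k0 <- {
    pos <- data$y > 0 & data$t > 0
    if (any(pos)) max(mean(-log(data$y[pos]) / data$t[pos]), 1e-6) else 0.1
  }
  fit <- minpack.lm::nlsLM(
    y ~ exp(-k * t), data = data, start = list(k = k0),
    lower = c(k = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  k <- unname(coef(fit)["k"])
  new_assay_fit(fit, "decay", data, list(
    k = k,
    v_over_E = if (!is.null(S0) && !is.null(E0)) k * S0 / E0,
    converged = fit$convInfo$isConv
  ))
}
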