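#' Bounded Levenberg-Marquardt least squares on a residual function
#'
#' Thin wrapper around [minpack.lm::nls.lm()]; the parameter covariance is
#' estimated from the Jacobian cross-product at the optimum scaled by the
#' residual variance.
#' @return list with `par`, `residual_norm`, `vcov` (NULL if the
#'   information matrix is singular), or NULL on optimizer failure.
#' @noRd
.lm_fit <- function(start, lower, upper, resid_fn, n_obs) {
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, maxfev = 10000)),
    error = function(e) NULL)
  if (is.null(out) || !out$info %in% 1:4) return(NULL)
  rss <- sum(out$fvec^2)
  dof <- max(1L, n_obs - length(start))
  vc <- tryCatch(solve(out$hessian) * rss / dof, error = function(e) NULL)
  if (!is.null(vc)) dimnames(vc) <- list(names(start), names(start))
  list(par = out$par, residual_norm = sqrt(rss), vcov = vc)
}

#' Anisotropy decay trace
#'
#' A fluorescence-anisotropy time course: as a labelled RNA probe is
#' degraded by the 5'-3' exonuclease, its anisotropy decays towards the
#' free-dye value, so the decay rate is a proxy for the degradation rate.
#'
#' @param time seconds, strictly increasing, length >= 5.
#' @param anisotropy raw anisotropy readings.
#' @param label optional trace label.
#' @return data.frame of class `decay_trace`.
#' @export
decay_trace <- function(time, anisotropy, label = "") {
  stopifnot(length(time) == length(anisotropy), length(time) >= 5L)
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing", call. = FALSE)
  structure(data.frame(time = as.numeric(time),
                       anisotropy = as.numeric(anisotropy)),
            label = as.character(label),
            class = c("decay_trace", "data.frame"))
}

#' Rescale a trace to the unit interval
#'
#' Affine map of the anisotropy values onto `[0, 1]`
#' (`(y - min) / (max - min)`), the standard preprocessing before fitting
#' the decay model. Idempotent on already-rescaled traces.
#'
#' @param trace a [decay_trace()].
#' @return The rescaled trace.
#' @export
rescale_unit_interval <- function(trace) {
  y <- trace$anisotropy
  rng <- range(y)
  if (rng[1] == rng[2])
    stop("constant trace cannot be rescaled", call. = FALSE)
  decay_trace(trace$time, (y - rng[1]) / (rng[2] - rng[1]),
              attr(trace, "label"))
}

#' Fit an exponential decay with plateau
#'
#' Least-squares fit of `y(t) = (1 - c) * exp(-k t) + c` to a rescaled
#' trace, with rate `k > 0` and plateau `-1 < c < 1`. The plateau absorbs
#' the residual anisotropy of the degradation end products; it is allowed
#' to go mildly negative because unit-interval rescaling of a trace that
#' has not finished decaying maps the true asymptote below zero, and
#' clamping it would bias the rate. The half-life is parametric,
#' `ln(2) / k`. The rate is initialised from a log-linear regression on
#' the upper half of the decay and refined by Levenberg-Marquardt.
#'
#' @param trace a [decay_trace()], rescaled to `[0, 1]` (see
#'   [rescale_unit_interval()]).
#' @return An object of class `fa_decay_fit` with elements `ok`, `k`,
#'   `plateau`, `half_life`, `residual_norm`, `vcov`, `fitted` and the
#'   input trace. Non-decaying data yield `ok = FALSE` rather than an
#'   error.
#' @examples
#' tr <- decay_trace(seq(0, 600, by = 20), exp(-0.00693 * seq(0, 600, by = 20)))
#' fit <- fit_exponential(tr)
#' fit$half_life
#' @export
fit_exponential <- function(trace) {
  t <- trace$time; y <- trace$anisotropy
  fail <- function(reason) structure(
    list(ok = FALSE, reason = reason, k = NA_real_, plateau = NA_real_,
         half_life = NA_real_, residual_norm = NA_real_, vcov = NULL,
         fitted = rep(NA_real_, length(t)), trace = trace),
    class = "fa_decay_fit")
  if (stats::sd(y) == 0 || stats::coef(stats::lm(y ~ t))[2L] >= 0)
    return(fail("trace does not decay"))
  c0 <- max(0, min(y) - 1e-6)
  upper <- y >= (min(y) + max(y)) / 2
  if (sum(upper) >= 3L) {
    ylog <- log(pmax(y[upper] - c0, 1e-8))
    k0 <- -unname(stats::coef(stats::lm(ylog ~ t[upper]))[2L])
  } else k0 <- NA_real_
  if (!is.finite(k0) || k0 <= 0) k0 <- log(2) / (max(t) / 2)
  model <- function(p) (1 - p[2L]) * exp(-p[1L] * t) + p[2L]
  fit <- .lm_fit(start = c(k = k0, cc = min(0.9, c0)),
                 lower = c(1e-12, -1), upper = c(Inf, 0.9999),
                 resid_fn = function(p) y - model(p), n_obs = length(y))
  if (is.null(fit)) return(fail("optimizer failed"))
  p <- fit$par
  if (!is.finite(p[["k"]]) || p[["k"]] <= 1e-12)
    return(fail("best-fit rate not positive"))
  structure(
    list(ok = TRUE, reason = NULL, k = unname(p[["k"]]),
         plateau = unname(p[["cc"]]),
         half_life = log(2) / unname(p[["k"]]),
         residual_norm = fit$residual_norm,
         vcov = fit$vcov, fitted = model(p), trace = trace),
    class = "fa_decay_fit")
}

#' @export
print.fa_decay_fit <- function(x, ...) {
  if (!x$ok) {
    cat("fa_decay_fit: FAILED (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "fa_decay_fit: k = %.5g /s, plateau = %.4f, half-life = %.4g s (rnorm %.3g)\n",
    x$k, x$plateau, x$half_life, x$residual_norm))
  invisible(x)
}

#' @export
coef.fa_decay_fit <- function(object, ...) {
  c(k = object$k, plateau = object$plateau, half_life = object$half_life)
}

#' @export
predict.fa_decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$trace$time else
    if (is.data.frame(newdata)) newdata$time else as.numeric(newdata)
  (1 - object$plateau) * exp(-object$k * t) + object$plateau
}

#' @export
residuals.fa_decay_fit <- function(object, ...) {
  object$trace$anisotropy - object$fitted
}

#' Half-life fold change between two traces
#'
#' `half_life(a) / half_life(b)`; values above 1 mean `a` decays more
#' slowly. Accepts traces (fitted internally after unit-interval
#' rescaling) or fitted `fa_decay_fit` objects. A failed fit propagates as
#' `NA` with a `"reason"` attribute.
#'
#' @param a,b [decay_trace()] or `fa_decay_fit` objects.
#' @return The half-life ratio.
#' @export
halflife_fold <- function(a, b) {
  as_fit <- function(x)
    if (inherits(x, "fa_decay_fit")) x else
      fit_exponential(rescale_unit_interval(x))
  fa <- as_fit(a); fb <- as_fit(b)
  if (!fa$ok || !fb$ok) {
    out <- NA_real_
    attr(out, "reason") <- paste(c(if (!fa$ok) paste("a:", fa$reason),
                                   if (!fb$ok) paste("b:", fb$reason)),
                                 collapse = "; ")
    return(out)
  }
  fa$half_life / fb$half_life
}

#' Titration series
#'
#' @param protein_conc molar protein concentrations, strictly increasing,
#'   nonnegative, length >= 5.
#' @param anisotropy readings.
#' @param probe_conc labelled-probe concentration in molar (default 50 nM).
#' @return data.frame of class `titration`.
#' @export
titration <- function(protein_conc, anisotropy, probe_conc = 50e-9) {
  stopifnot(length(protein_conc) == length(anisotropy),
            length(protein_conc) >= 5L, probe_conc > 0,
            all(protein_conc >= 0))
  if (is.unsorted(protein_conc, strictly = TRUE))
    stop("protein_conc must be strictly increasing", call. = FALSE)
  structure(data.frame(protein_conc = as.numeric(protein_conc),
                       anisotropy = as.numeric(anisotropy)),
            probe_conc = as.numeric(probe_conc),
            class = c("titration", "data.frame"))
}

#' Bound fraction under the 1:1 depletion-aware isotherm
#'
#' Closed form for the fraction of probe bound at total protein `P`, total
#' probe `L` and dissociation constant `Kd`:
#' `f = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / (2 L)`.
#' Unlike the hyperbolic approximation `P / (P + Kd)`, this remains exact
#' when the probe concentration is comparable to `Kd`.
#'
#' @param P total protein concentration (molar, vectorised).
#' @param L total probe concentration (molar).
#' @param Kd dissociation constant (molar).
#' @return Bound fraction in `[0, 1]`.
#' @export
binding_fraction <- function(P, L, Kd) {
  s <- P + L + Kd
  (s - sqrt(pmax(s^2 - 4 * P * L, 0))) / (2 * L)
}

#' Fit a binding isotherm to a titration
#'
#' Least-squares fit of
#' `anisotropy = a_free + (a_bound - a_free) * f(P; L, Kd)` with the
#' depletion-aware bound fraction of [binding_fraction()].
#'
#' @param t a [titration()]; concentrations should span at least a 10-fold
#'   range.
#' @return An object of class `binding_fit` with `ok`, `Kd`, `a_free`,
#'   `a_bound`, `residual_norm`, `vcov`, `fitted`. Non-informative data
#'   yield `ok = FALSE`.
#' @export
fit_binding <- function(t) {
  P <- t$protein_conc; y <- t$anisotropy
  L <- attr(t, "probe_conc")
  pos <- P[P > 0]
  if (length(pos) && max(pos) / min(pos) < 10)
    warning("titration spans less than a 10-fold concentration range",
            call. = FALSE)
  fail <- function(reason) structure(
    list(ok = FALSE, reason = reason, Kd = NA_real_, a_free = NA_real_,
         a_bound = NA_real_, residual_norm = NA_real_, vcov = NULL,
         fitted = rep(NA_real_, length(P)), titration = t),
    class = "binding_fit")
  if (stats::sd(y) == 0) return(fail("constant anisotropy"))
  af0 <- min(y); ab0 <- max(y)
  mid <- (af0 + ab0) / 2
  kd0 <- tryCatch(stats::approx(y, P, xout = mid, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(P[P > 0])
  model <- function(p) p[2L] + (p[3L] - p[2L]) *
    binding_fraction(P, L, p[1L])
  fit <- .lm_fit(start = c(Kd = kd0, af = af0, ab = ab0),
                 lower = c(1e-15, -Inf, -Inf), upper = rep(Inf, 3),
                 resid_fn = function(p) y - model(p), n_obs = length(y))
  if (is.null(fit)) return(fail("optimizer failed"))
  p <- fit$par
  if (p[["ab"]] <= p[["af"]]) return(fail("no binding signal"))
  structure(
    list(ok = TRUE, reason = NULL, Kd = unname(p[["Kd"]]),
         a_free = unname(p[["af"]]), a_bound = unname(p[["ab"]]),
         residual_norm = fit$residual_norm, vcov = fit$vcov,
         fitted = model(p), titration = t),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$ok) {
    cat("binding_fit: FAILED (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "binding_fit: Kd = %.4g M, anisotropy %.4g (free) -> %.4g (bound)\n",
    x$Kd, x$a_free, x$a_bound))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(Kd = object$Kd, a_free = object$a_free, a_bound = object$a_bound)
}

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  P <- if (is.null(newdata)) object$titration$protein_conc else
    if (is.data.frame(newdata)) newdata$protein_conc else as.numeric(newdata)
  L <- attr(object$titration, "probe_conc")
  object$a_free + (object$a_bound - object$a_free) *
    binding_fraction(P, L, object$Kd)
}

#' Normalised reporter activity
#'
#' Phosphatase reporter readings are blank-corrected, normalised to culture
#' density (`(a400 - blank) / od`), and optionally scaled so the mean
#' control activity is exactly 1.
#'
#' @param readings data.frame with columns `a400`, `od`, `blank`,
#'   `condition` (`"control"` rows define the scaling reference).
#' @param scale_to_control divide every activity by the mean control
#'   activity.
#' @return The input with `activity` (and, if requested, `scaled_activity`)
#'   columns appended. Negative blank-corrected values are clipped to 0
#'   with a warning; nonpositive `od` is an error.
#' @export
reporter_activity <- function(readings, scale_to_control = TRUE) {
  stopifnot(all(c("a400", "od", "blank", "condition") %in% names(readings)))
  if (any(readings$od <= 0))
    stop("culture density (od) must be positive", call. = FALSE)
  net <- readings$a400 - readings$blank
  if (any(net < 0)) {
    warning("negative blank-corrected absorbance clipped to 0",
            call. = FALSE)
    net <- pmax(net, 0)
  }
  readings$activity <- net / readings$od
  if (scale_to_control) {
    ctrl <- mean(readings$activity[readings$condition == "control"])
    if (!is.finite(ctrl) || ctrl <= 0)
      stop("no usable control readings to scale to", call. = FALSE)
    readings$scaled_activity <- readings$activity / ctrl
  }
  readings
}

#' Read kinetics tables
#'
#' `read_decay_tsv` expects columns `time` and `anisotropy` (optional
#' `label`); `read_titration_tsv` expects `protein_conc` and `anisotropy`
#' (optional `probe_conc`, first value used).
#'
#' @param path TSV file.
#' @return A [decay_trace()] or [titration()].
#' @export
read_decay_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  decay_trace(d$time, d$anisotropy,
              label = if ("label" %in% names(d)) d$label[1L] else "")
}

#' @rdname read_decay_tsv
#' @export
read_titration_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  titration(d$protein_conc, d$anisotropy,
            probe_conc = if ("probe_conc" %in% names(d)) d$probe_conc[1L]
            else 50e-9)
}

#' JSON fit report
#'
#' Serialises a decay or binding fit (parameters, standard errors from the
#' residual covariance when available, diagnostics) to JSON.
#' @param fit an `fa_decay_fit` or `binding_fit`.
#' @param path output JSON file.
#' @export
write_fit_report <- function(fit, path) {
  se <- if (!is.null(fit$vcov)) sqrt(diag(fit$vcov)) else NULL
  rep <- list(class = class(fit)[1L], ok = fit$ok, reason = fit$reason,
              coefficients = as.list(stats::coef(fit)),
              standard_errors = if (is.null(se)) NULL else as.list(se),
              residual_norm = fit$residual_norm)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
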