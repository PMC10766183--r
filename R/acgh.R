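# Forward model of the array-CGH "waterfall" at palindromic junctions.
#
# When genomic DNA is sheared AFTER random-primed labeling, fragments that
# span a palindromic (inverted) junction snap back into intramolecular
# duplexes on denaturation: the region of the fragment within
# min(distance to either end) of the junction re-anneals with its own
# reverse complement and is unavailable for priming. Under fixed fragment
# length L with uniform junction phase, the probability that a position at
# distance d from the junction is excluded is max(0, 1 - 2d/L), giving a
# linear copy-number ramp that completes at d = L/2. Shearing BEFORE
# labeling replaces L by the (much smaller) shear size, collapsing the
# ramp to an abrupt step.

#' Labeling model for aCGH of a palindromic junction
#'
#' @param fragment_len genomic fragment length L in bp (default 20000).
#' @param protocol `"shear_after_labeling"` (waterfall) or
#'   `"shear_before_labeling"` (abrupt step).
#' @param shear_size fragment size after sonication when shearing before
#'   labeling (default 500 bp).
#' @param c_near copy number on the unamplified side of the junction.
#' @param c_far copy number on the amplified side.
#' @param k number of junction-adjacent palindromic copies among the
#'   `c_far` copies (default 2: at a 1-to-3 inverted triplication junction
#'   two of the three copies meet at the palindrome).
#' @return an object of class `odira_labeling_model`.
#' @export
labeling_model <- function(fragment_len = 20000,
                           protocol = c("shear_after_labeling",
                                        "shear_before_labeling"),
                           shear_size = 500, c_near = 1, c_far = 3, k = 2) {
  protocol <- match.arg(protocol)
  stopifnot(fragment_len > 0, shear_size > 0, c_far >= c_near,
            c_near >= 0, k >= 0, k <= c_far)
  structure(list(fragment_len = fragment_len, protocol = protocol,
                 shear_size = shear_size, c_near = c_near, c_far = c_far,
                 k = k),
            class = "odira_labeling_model")
}

.effective_L <- function(model) {
  if (model$protocol == "shear_before_labeling") model$shear_size
  else model$fragment_len
}

#' Expected copy-number signal at distances from a palindromic junction
#'
#' Closed form `c(d) = c_far - k * max(0, 1 - 2d/L)` with L the effective
#' fragment length of the protocol; `c(0) = c_far - k` and the ramp
#' completes (`c = c_far`) at `d = L/2`.
#'
#' @param model a [labeling_model()].
#' @param distances numeric vector of distances (bp, >= 0) from the
#'   junction into the amplified side.
#' @return numeric vector of expected copy numbers.
#' @export
expected_profile <- function(model, distances) {
  stopifnot(inherits(model, "odira_labeling_model"))
  if (any(distances < 0)) stop("distances must be non-negative")
  L <- .effective_L(model)
  model$c_far - model$k * pmax(0, 1 - 2 * distances / L)
}

#' Monte-Carlo simulation of labeled coverage around a palindromic
#' junction
#'
#' For each probe, `n_fragments` fragments of the effective length L are
#' drawn with uniform phase; on each of the `k` palindromic copies the
#' probe is unlabeled when its fragment spans the junction and the probe
#' lies within min(distance to either fragment end) of it (equivalently,
#' phase u >= 2d). Non-palindromic copies are always labeled. The signal
#' is labeled coverage on the copy-number scale (normalized so single-copy
#' regions average 1).
#'
#' @param model a [labeling_model()].
#' @param probes numeric vector of probe positions (bp).
#' @param junction_pos junction position (bp); the amplified side is at
#'   higher coordinates.
#' @param n_fragments Monte-Carlo fragments per probe and palindromic copy
#'   (default 1e5).
#' @param noise_sd optional Gaussian measurement noise added to the signal
#'   (default 0).
#' @param seed optional integer seed.
#' @return data frame of class `odira_acgh_profile` with columns
#'   `position`, `distance` (signed, negative on the unamplified side),
#'   `signal` and `se` (Monte-Carlo standard error, 0 where the model is
#'   deterministic).
#' @export
simulate_labeling <- function(model, probes, junction_pos = 0,
                              n_fragments = 1e5, noise_sd = 0,
                              seed = NULL) {
  stopifnot(inherits(model, "odira_labeling_model"))
  if (n_fragments <= 0) stop("n_fragments must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.unsorted(probes, strictly = TRUE))
    stop("probe positions must be strictly increasing")
  L <- .effective_L(model)
  d <- probes - junction_pos
  signal <- numeric(length(probes))
  se <- numeric(length(probes))
  for (i in seq_along(probes)) {
    if (d[i] < 0) {              # unamplified side: no palindromic copy
      signal[i] <- model$c_near
      se[i] <- 0
    } else if (d[i] >= L / 2) {  # beyond the ramp: never excluded
      signal[i] <- model$c_far
      se[i] <- 0
    } else {
      u <- runif(n_fragments, 0, L)
      labeled <- u < 2 * d[i]
      p <- mean(labeled)
      signal[i] <- (model$c_far - model$k) + model$k * p
      se[i] <- model$k * sqrt(p * (1 - p) / n_fragments)
    }
  }
  if (noise_sd > 0) signal <- signal + rnorm(length(signal), 0, noise_sd)
  out <- data.frame(position = probes, distance = d, signal = signal,
                    se = se)
  class(out) <- c("odira_acgh_profile", "data.frame")
  out
}

#' Locate a palindromic junction from a copy-number profile
#'
#' Least-squares fit of the piecewise-linear waterfall family
#' `f(x) = c_near + (c_far - c_near) * clamp((x - x0)/W, 0, 1)` over a
#' grid of junction positions x0 (probe positions) and ramp widths W,
#' polished with Nelder-Mead. A profile whose fitted copy-number step is
#' smaller than `min_step` is reported as having no junction rather than
#' raising an error.
#'
#' @param profile data frame with `position` and `signal` columns.
#' @param widths candidate ramp widths in bp.
#' @param min_step minimum fitted `c_far - c_near` to accept a junction
#'   (default 0.5 copies).
#' @return list with `found` (logical) and, when found, `junction_pos`,
#'   `ramp_width`, `c_near`, `c_far`, `sse`.
#' @export
detect_waterfall <- function(profile,
                             widths = c(100, 250, 500, 1000, 2000, 4000,
                                        6000, 8000, 10000, 15000, 20000),
                             min_step = 0.5) {
  x <- profile$position
  y <- profile$signal
  stopifnot(length(x) >= 4L)

  fit_one <- function(x0, W) {
    r <- pmin(pmax((x - x0) / W, 0), 1)
    # closed-form LS for intercept + slope on the ramp regressor
    vr <- stats::var(r)
    if (is.na(vr) || vr == 0) {
      b <- 0; a <- mean(y)
    } else {
      b <- stats::cov(r, y) / vr
      a <- mean(y) - b * mean(r)
    }
    sse <- sum((y - (a + b * r))^2)
    c(sse = sse, c_near = a, step = b)
  }

  best <- NULL
  for (x0 in x) {
    for (W in widths) {
      f <- fit_one(x0, W)
      if (is.null(best) || f["sse"] < best$sse)
        best <- list(sse = f[["sse"]], x0 = x0, W = W,
                     c_near = f[["c_near"]], step = f[["step"]])
    }
  }
  # polish junction position and width
  polish <- optim(c(best$x0, best$W), function(p) {
    if (p[2] <= 0) return(Inf)
    fit_one(p[1], p[2])[["sse"]]
  }, method = "Nelder-Mead")
  f <- fit_one(polish$par[1], polish$par[2])
  if (f[["sse"]] <= best$sse) {
    best <- list(sse = f[["sse"]], x0 = polish$par[1], W = polish$par[2],
                 c_near = f[["c_near"]], step = f[["step"]])
  }

  if (best$step < min_step)
    return(list(found = FALSE))
  list(found = TRUE, junction_pos = best$x0, ramp_width = best$W,
       c_near = best$c_near, c_far = best$c_near + best$step,
       sse = best$sse)
}

#' Convert a copy-number signal to log2 ratio
#'
#' Convenience transform for comparison with conventional aCGH plots.
#'
#' @param signal copy-number scale signal.
#' @param reference reference copy number (default 1).
#' @return log2(signal / reference).
#' @export
as_log2_ratio <- function(signal, reference = 1) log2(signal / reference)
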