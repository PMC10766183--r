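# Replication-fork constraints on template switching.
#
# Two mechanistic filters determine which interrupted inverted repeats can
# seed a junction: (1) the spacer must fit the transient single-stranded
# gap on the lagging strand (bounded by the Okazaki fragment length,
# 165 bp in yeast) while exceeding the self-hairpin threshold below which
# the displaced leading strand folds on itself; (2) the fork crossing the
# repeat must run in the direction that produces the required junction
# orientation (a centromere-proximal junction needs a fork moving toward
# the centromere, i.e. leftward under the convention that the centromere
# is at lower coordinates).

#' Replication fork parameters
#'
#' @param okazaki_len Okazaki fragment length in bp (default 165); the
#'   lagging-strand gap ranges over [0, okazaki_len].
#' @param gap_model `"uniform"` (gap ~ U[0, okazaki_len]) or `"fixed"`.
#' @param gap fixed gap size in bp (required when `gap_model = "fixed"`).
#' @param hairpin_threshold spacer below which the displaced repeats
#'   self-hybridize into a leading-strand hairpin (bp, default 40).
#' @return an object of class `odira_fork_params`.
#' @export
fork_params <- function(okazaki_len = 165L,
                        gap_model = c("uniform", "fixed"), gap = NULL,
                        hairpin_threshold = 40L) {
  gap_model <- match.arg(gap_model)
  stopifnot(okazaki_len > 0L, hairpin_threshold >= 0L)
  if (gap_model == "fixed" && is.null(gap))
    stop("fixed gap model requires a gap size")
  structure(list(okazaki_len = okazaki_len, gap_model = gap_model,
                 gap = gap, hairpin_threshold = hairpin_threshold),
            class = "odira_fork_params")
}

#' Classify a template-switch attempt by spacer and gap size
#'
#' A spacer below the hairpin threshold leads the displaced repeats to
#' self-hybridize (`SELF_HAIRPIN`); a spacer exceeding the current
#' lagging-strand gap finds its complement already covered by an Okazaki
#' fragment (`NO_TEMPLATE`); otherwise the switch is `PRODUCTIVE`.
#' Boundaries: a spacer exactly at the threshold is productive when it
#' fits the gap, and a spacer exactly equal to the gap is productive.
#'
#' @param spacer spacer size(s) in bp.
#' @param gap lagging-strand gap size(s) in bp.
#' @param params a [fork_params()].
#' @return character vector in {SELF_HAIRPIN, NO_TEMPLATE, PRODUCTIVE}.
#' @export
classify_switch <- function(spacer, gap, params = fork_params()) {
  stopifnot(all(spacer >= 0), all(gap >= 0))
  ifelse(spacer < params$hairpin_threshold, "SELF_HAIRPIN",
         ifelse(spacer > gap, "NO_TEMPLATE", "PRODUCTIVE"))
}

#' Relative template-switch productivity as a function of spacer size
#'
#' Integrates [classify_switch()] over the uniform gap distribution:
#' `density(s) = 1[s >= t_h] * max(0, 1 - s/okazaki_len)`. The support is
#' [hairpin threshold, Okazaki length] and the density is non-increasing
#' on it, with its mode at the threshold.
#'
#' @param spacers numeric vector of spacer sizes (bp).
#' @param params a [fork_params()] with uniform gap model.
#' @return numeric vector of relative productivities.
#' @export
productive_spacer_density <- function(spacers, params = fork_params()) {
  if (params$gap_model != "uniform")
    stop("the closed form assumes the uniform gap model")
  ifelse(spacers >= params$hairpin_threshold,
         pmax(0, 1 - spacers / params$okazaki_len), 0)
}

#' Direction of the replication fork crossing a position
#'
#' Under equal fork speed and simultaneous firing of all active origins, a
#' position is replicated by the fork from the nearest active origin:
#' RIGHTWARD when that origin lies to the left (or at the position
#' itself), LEFTWARD when it lies to the right; exact inter-origin
#' midpoints resolve LEFTWARD.
#'
#' @param position genomic position(s) in bp (any consistent unit).
#' @param origins data frame with columns `position` and `active`.
#' @return character vector in {LEFTWARD, RIGHTWARD}.
#' @export
fork_direction <- function(position, origins) {
  act <- sort(origins$position[origins$active])
  if (length(act) == 0L) stop("no active origin")
  vapply(position, function(p) {
    d <- abs(act - p)
    m <- min(d)
    nearest <- act[d == m]
    if (any(nearest == p)) return("RIGHTWARD")      # at an origin
    if (length(nearest) > 1L) return("LEFTWARD")    # midpoint tie
    if (nearest < p) "RIGHTWARD" else "LEFTWARD"
  }, character(1))
}

#' Is a junction orientation compatible with the local fork direction?
#'
#' A centromere-proximal junction (CJ) requires the position to be
#' replicated by a LEFTWARD (centromere-bound) fork; a telomere-proximal
#' junction (TJ) requires a RIGHTWARD fork.
#'
#' @param orientation character vector of `"CJ"` / `"TJ"`.
#' @param position junction position(s).
#' @param origins origin table as in [fork_direction()].
#' @return logical vector.
#' @export
junction_fork_compatibility <- function(orientation, position, origins) {
  if (any(!orientation %in% c("CJ", "TJ")))
    stop("orientation must be CJ or TJ")
  dir <- fork_direction(position, origins)
  ifelse(orientation == "CJ", dir == "LEFTWARD", dir == "RIGHTWARD")
}
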