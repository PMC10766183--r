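#' Pipeline run configuration
#'
#' Collects the tunable parameters of the pipeline in one validated object.
#' Defaults are the study conditions: repeat arms of 2-14 bp with spacers
#' within 250 bp, 150 bp reads at ~125-fold coverage, 165 bp Okazaki
#' fragments, a 40 bp self-hairpin threshold, 20 kb labeling fragments and a
#' two-fragment junction support threshold.
#'
#' @param seed integer random seed recorded with the run.
#' @param min_arm,max_arm inverted-repeat arm length bounds (bp).
#' @param max_spacer maximum spacer between arms (bp).
#' @param read_len read length (bp).
#' @param depth fold coverage of read simulation.
#' @param error_rate per-base substitution error probability.
#' @param okazaki_len Okazaki fragment length (bp); bounds the lagging-strand
#'   gap.
#' @param hairpin_threshold spacers below this self-hybridize into a hairpin
#'   on the leading strand instead of switching template (bp).
#' @param fragment_len genomic fragment length in the labeling model (bp).
#' @param min_support minimum number of unique fragments supporting a
#'   junction.
#' @param k anchor k-mer length for split-read mapping (bp).
#' @return an object of class `odira_config` (a named list).
#' @export
run_config <- function(seed = 1L,
                       min_arm = 2L, max_arm = 14L, max_spacer = 250L,
                       read_len = 150L, depth = 125, error_rate = 0.001,
                       okazaki_len = 165L, hairpin_threshold = 40L,
                       fragment_len = 20000L, min_support = 2L, k = 20L) {
  stopifnot(min_arm >= 1L, min_arm <= max_arm, max_spacer >= 0L,
            error_rate >= 0, error_rate < 1, min_support >= 1L,
            read_len > 0L, depth > 0, okazaki_len > 0L,
            hairpin_threshold >= 0L, fragment_len > 0L, k > 0L)
  cfg <- list(seed = as.integer(seed),
              min_arm = as.integer(min_arm), max_arm = as.integer(max_arm),
              max_spacer = as.integer(max_spacer),
              read_len = as.integer(read_len), depth = depth,
              error_rate = error_rate, okazaki_len = as.integer(okazaki_len),
              hairpin_threshold = as.integer(hairpin_threshold),
              fragment_len = as.integer(fragment_len),
              min_support = as.integer(min_support), k = as.integer(k))
  class(cfg) <- "odira_config"
  cfg
}

#' @export
print.odira_config <- function(x, ...) {
  cat("odira run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Log the configuration of a pipeline stage
#'
#' Emits one message with the stage name, seed and full parameter string so
#' that stochastic runs can be reproduced from the log alone.
#'
#' @param config an [run_config()] object.
#' @param stage character label of the pipeline stage.
#' @return the config, invisibly.
#' @export
log_config <- function(config, stage = "run") {
  stopifnot(inherits(config, "odira_config"))
  message(sprintf("[odira:%s] %s", stage,
                  paste(names(config), unlist(config), sep = "=",
                        collapse = " ")))
  invisible(config)
}
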