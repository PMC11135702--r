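#' Pipeline parameters
#'
#' Bundles every tunable threshold of the atlas pipeline in one validated
#' object that is serialized into all result manifests.
#'
#' @param min_green_species Minimum number of distinct Chloroplastida species
#'   an orthogroup must occur in to qualify as a green orthogroup (GOG).
#' @param max_nongreen_species Exclusive upper bound on non-green species:
#'   a GOG must occur in strictly fewer than this many non-green species.
#' @param core_fraction Strict lower bound on the fraction of green species a
#'   GOG must occur in to count as a core GOG.
#' @param gain_threshold Posterior probability tau above which an orthogroup is
#'   called present at an ancestor when calling gains.
#' @param tau_sweep Additional thresholds swept alongside \code{gain_threshold}.
#' @param domain_fraction_threshold Fraction of member proteins that must carry
#'   a screen domain for an orthogroup to be flagged as RNA-metabolism.
#' @param domain_comparator \code{"gt"} (strict, default) or \code{"ge"};
#'   the Methods and Results of the source workflow phrase the 60\% rule both
#'   ways, so both are exposed.
#' @param nterm_window Number of N-terminal residues over which net charge is
#'   computed.
#' @param rate_bounds Two positive numbers: search interval for the ML gain/loss
#'   rate of the ER model, per unit branch length.
#' @param copy_number_display_cap Display-only clamp for copy-number heat maps.
#' @param gain_parent_rule \code{"confident"}: an orthogroup is gained at node A
#'   only if the parent posterior is below \code{1 - tau} (confident absence);
#'   \code{"lax"}: parent posterior below \code{tau} suffices.
#' @return An object of class \code{atlas_params} (a named list).
#' @export
atlas_params <- function(min_green_species = 3L,
                         max_nongreen_species = 3L,
                         core_fraction = 0.90,
                         gain_threshold = 0.75,
                         tau_sweep = c(0.65, 0.85),
                         domain_fraction_threshold = 0.60,
                         domain_comparator = c("gt", "ge"),
                         nterm_window = 20L,
                         rate_bounds = c(1e-6, 100),
                         copy_number_display_cap = 50L,
                         gain_parent_rule = c("confident", "lax")) {
  domain_comparator <- match.arg(domain_comparator)
  gain_parent_rule <- match.arg(gain_parent_rule)
  stopifnot(
    min_green_species >= 0, max_nongreen_species >= 0,
    core_fraction > 0, core_fraction < 1,
    gain_threshold > 0, gain_threshold < 1,
    all(tau_sweep > 0 & tau_sweep < 1),
    domain_fraction_threshold > 0, domain_fraction_threshold < 1,
    nterm_window >= 1,
    length(rate_bounds) == 2, rate_bounds[1] > 0,
    rate_bounds[2] > rate_bounds[1]
  )
  structure(list(
    min_green_species = as.integer(min_green_species),
    max_nongreen_species = as.integer(max_nongreen_species),
    core_fraction = core_fraction,
    gain_threshold = gain_threshold,
    tau_sweep = sort(unique(c(gain_threshold, tau_sweep))),
    domain_fraction_threshold = domain_fraction_threshold,
    domain_comparator = domain_comparator,
    nterm_window = as.integer(nterm_window),
    rate_bounds = rate_bounds,
    copy_number_display_cap = as.integer(copy_number_display_cap),
    gain_parent_rule = gain_parent_rule
  ), class = "atlas_params")
}

#' @export
print.atlas_params <- function(x, ...) {
  cat("atlas_params:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
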