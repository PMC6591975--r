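#' Scan parameters for the structural Helitron search
#'
#' Bundles the tunable parameters of the terminus scan. The defaults encode
#' the canonical Helitron 3' signature: a GC-rich palindromic hairpin whose
#' right arm ends 2--10 nt before a CTAG-family terminal motif, with 5' TC
#' ends searched up to 20 kb upstream.
#'
#' @param fuzzy_level Integer 0--3, stringency of the 3' terminal motif.
#'   Level 0 requires `CTAG` followed by the target-site `T`, level 1 (the
#'   default) `CTAG`, level 2 `CTRR` (R = A or G), level 3 `CT..` (any two
#'   bases). Levels are nested: every candidate at a stricter level is also
#'   found at looser levels.
#' @param arm_min,arm_max Minimum / maximum hairpin arm length in bases.
#' @param loop_max Maximum loop length between the two arms, bases.
#' @param spacer_min,spacer_max Bases allowed between the hairpin right arm
#'   and the first base of the terminal motif.
#' @param upstream_window Bases upstream of the 3' end searched for 5' TC
#'   starts.
#' @param gc_min Minimum fraction of G/C bases in a hairpin arm (the arm must
#'   also begin and end with G or C, and the right arm must be the exact
#'   reverse complement of the left arm).
#' @param target_site_filter If `TRUE`, only candidates whose flanking bases
#'   match the AT target-site duplication (A before the 5' TC, T after the 3'
#'   motif) are retained. Off by default: the AT preference is biology, not a
#'   hard constraint, so the flag is reported rather than filtered on.
#' @param worker_count Number of parallel workers used by [scan_genome()].
#'   Results are identical for any worker count.
#'
#' @return An object of class `helitron_params` (a validated list).
#' @examples
#' helitron_params(fuzzy_level = 2)
#' @export
helitron_params <- function(fuzzy_level = 1, arm_min = 6, arm_max = 20,
                            loop_max = 10, spacer_min = 2, spacer_max = 10,
                            upstream_window = 20000, gc_min = 0.8,
                            target_site_filter = FALSE, worker_count = 1) {
  p <- list(fuzzy_level = as.integer(fuzzy_level),
            arm_min = as.integer(arm_min), arm_max = as.integer(arm_max),
            loop_max = as.integer(loop_max),
            spacer_min = as.integer(spacer_min),
            spacer_max = as.integer(spacer_max),
            upstream_window = as.integer(upstream_window),
            gc_min = as.numeric(gc_min),
            target_site_filter = isTRUE(target_site_filter),
            worker_count = as.integer(worker_count))
  if (!p$fuzzy_level %in% 0:3) stop("fuzzy_level must be 0, 1, 2 or 3")
  if (p$arm_min < 1 || p$arm_max < p$arm_min)
    stop("need 1 <= arm_min <= arm_max")
  if (p$loop_max < 0) stop("loop_max must be non-negative")
  if (p$spacer_min < 0 || p$spacer_max < p$spacer_min)
    stop("need 0 <= spacer_min <= spacer_max")
  if (p$upstream_window < 1) stop("upstream_window must be positive")
  if (p$gc_min < 0 || p$gc_min > 1) stop("gc_min must be in [0, 1]")
  if (p$worker_count < 1) stop("worker_count must be a positive integer")
  class(p) <- "helitron_params"
  p
}

#' @export
print.helitron_params <- function(x, ...) {
  cat("Helitron scan parameters\n")
  cat(sprintf("  3' motif fuzzy level : %d (%s)\n", x$fuzzy_level,
              c("CTAGT", "CTAG", "CTRR", "CT..")[x$fuzzy_level + 1]))
  cat(sprintf("  hairpin arm          : %d-%d nt, >= %.0f%% G/C\n",
              x$arm_min, x$arm_max, 100 * x$gc_min))
  cat(sprintf("  loop <= %d nt, spacer %d-%d nt\n",
              x$loop_max, x$spacer_min, x$spacer_max))
  cat(sprintf("  5' TC search window  : %d nt\n", x$upstream_window))
  cat(sprintf("  target-site filter   : %s, workers: %d\n",
              if (x$target_site_filter) "on" else "off", x$worker_count))
  invisible(x)
}

as_helitron_params <- function(p) {
  if (inherits(p, "helitron_params")) return(p)
  if (is.list(p)) return(do.call(helitron_params, p))
  stop("expected a 'helitron_params' object (see helitron_params())")
}
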