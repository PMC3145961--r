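#' Construct a chromatin fiber
#'
#' A chromatin fiber is a one-dimensional lattice of nucleosomes, each
#' carrying (\code{TRUE}) or lacking (\code{FALSE}) a repressive histone
#' mark, with a fixed internucleosome spacing in base pairs. New fibers
#' start fully marked: the simulation follows a repressed chromatin domain
#' losing marks through replication.
#'
#' @param n Number of nucleosomes (integer, >= 1).
#' @param spacing_bp Base pairs per nucleosome (integer, >= 1; default 200).
#' @return An object of class \code{chromatin_fiber}: a logical vector of
#'   mark states with a \code{spacing_bp} attribute.
#' @examples
#' f <- new_fiber(5, 200)
#' fraction_marked(f)
#' @export
new_fiber <- function(n, spacing_bp = 200L) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != as.integer(n))
    stop("'n' must be a single integer >= 1", call. = FALSE)
  if (length(spacing_bp) != 1L || !is.finite(spacing_bp) || spacing_bp < 1 ||
      spacing_bp != as.integer(spacing_bp))
    stop("'spacing_bp' must be a single integer >= 1", call. = FALSE)
  structure(rep(TRUE, as.integer(n)),
            spacing_bp = as.integer(spacing_bp),
            class = "chromatin_fiber")
}

as_fiber <- function(states, spacing_bp = 200L) {
  stopifnot(is.logical(states), length(states) >= 1L, !anyNA(states))
  structure(states, spacing_bp = as.integer(spacing_bp),
            class = "chromatin_fiber")
}

#' @export
print.chromatin_fiber <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<chromatin_fiber> %d nucleosomes x %d bp (%.1f kb), %.1f%% marked\n",
              n, attr(x, "spacing_bp"),
              n * attr(x, "spacing_bp") / 1000, 100 * mean(x)))
  invisible(x)
}

#' Fraction of nucleosomes carrying the mark
#'
#' @param f A \code{chromatin_fiber} (or plain logical vector of mark states).
#' @return A value in \code{[0, 1]}: marked count over fiber length. Fibers
#'   start fully marked, so the percentage of marks lost is
#'   \code{1 - fraction_marked(f)}.
#' @export
fraction_marked <- function(f) {
  mean(as.logical(f))
}

#' Length of the unmarked tract containing a site
#'
#' Computes the length of the maximal contiguous run of unmarked nucleosomes
#' containing \code{site}, the tract statistic used when a fixed stall site
#' models a replication impediment such as a G-quadruplex. Returns 0 when
#' the site itself is marked.
#'
#' @param f A \code{chromatin_fiber} (or logical vector of mark states).
#' @param site Nucleosome index, 1-based, within the fiber.
#' @return Integer tract length in nucleosomes.
#' @export
max_unmarked_run <- function(f, site) {
  states <- as.logical(f)
  n <- length(states)
  if (length(site) != 1L || !is.finite(site) || site < 1 || site > n ||
      site != as.integer(site))
    stop(sprintf("'site' must be an integer in [1, %d]", n), call. = FALSE)
  site <- as.integer(site)
  if (states[site]) return(0L)
  a <- site
  while (a > 1L && !states[a - 1L]) a <- a - 1L
  b <- site
  while (b < n && !states[b + 1L]) b <- b + 1L
  b - a + 1L
}

#' Postreplicative gap-length distribution
#'
#' Gap lengths are drawn as a rounded normal with the given mean and
#' variance, clamped to at least one nucleosome; with variance 0 every gap
#' has length \code{round(mean_len)} deterministically.
#'
#' @param mean_len Mean gap length in nucleosomes (>= 1).
#' @param variance Variance of the gap length in nucleosomes squared (>= 0).
#' @return A \code{gap_spec} list.
#' @export
gap_spec <- function(mean_len, variance = 0) {
  if (length(mean_len) != 1L || !is.finite(mean_len) || mean_len < 1)
    stop("'mean_len' must be a single number >= 1", call. = FALSE)
  if (length(variance) != 1L || !is.finite(variance) || variance < 0)
    stop("'variance' must be a single number >= 0", call. = FALSE)
  structure(list(mean_len = as.numeric(mean_len),
                 variance = as.numeric(variance)),
            class = "gap_spec")
}

draw_gap_length <- function(gap) {
  if (gap$variance == 0) {
    max(1L, as.integer(round(gap$mean_len)))
  } else {
    max(1L, as.integer(round(stats::rnorm(1L, gap$mean_len, sqrt(gap$variance)))))
  }
}

#' Simulation parameter set
#'
#' Bundles every knob of the inheritance model. Defaults follow the model
#' description: internucleosome distance 200 bp, 30 generations averaged
#' over 30 replicates, random segregation of parental histones
#' (\code{p_retain = 0.5}), one-place copy probability 1.0 and two-place
#' copy probability 0.25.
#'
#' @param n_nucleosomes Fiber length in nucleosomes (default 500, a 100 kb
#'   domain at 200 bp spacing).
#' @param spacing_bp Base pairs per nucleosome (default 200).
#' @param generations Number of cell divisions to simulate (default 30).
#' @param replicates Number of independent lineages (default 30).
#' @param p_retain Probability that a parental histone is retained on the
#'   tracked daughter at each position (default 0.5).
#' @param p_copy1 Probability that an unmarked nucleosome with a marked
#'   neighbour at distance 1 acquires the mark in the restore pass
#'   (default 1.0).
#' @param p_copy2 Two-place copy probability: acquisition from a marked
#'   neighbour at distance 2 when no distance-1 marked neighbour exists
#'   (default 0.25).
#' @param p_stall_random Per-nucleosome probability of a replication-fork
#'   stall per division (default 0).
#' @param fixed_site Optional nucleosome index stalling recurrently
#'   (models a site-specific impediment); \code{NA} for none.
#' @param p_stall_fixed Per-division stall probability at \code{fixed_site}.
#' @param gap A \code{\link{gap_spec}} for postreplicative gap lengths
#'   (default mean 5, variance 0).
#' @param copy_source Template for the restore pass: \code{"parental"}
#'   (default) copies marks from the parental fiber with gap intervals
#'   masked out (no parental template exists where chromatinization was
#'   uncoupled from the fork); \code{"daughter"} copies from the
#'   post-segregation daughter state.
#' @param gap_anchor Placement of a gap of length L relative to its stall
#'   site: \code{"center"} (default), \code{"downstream"} (increasing
#'   index) or \code{"upstream"}.
#' @param seed Integer RNG seed for \code{\link{run_trajectory}}.
#' @return A \code{sim_params} list.
#' @export
sim_params <- function(n_nucleosomes = 500L,
                       spacing_bp = 200L,
                       generations = 30L,
                       replicates = 30L,
                       p_retain = 0.5,
                       p_copy1 = 1.0,
                       p_copy2 = 0.25,
                       p_stall_random = 0,
                       fixed_site = NA_integer_,
                       p_stall_fixed = 0,
                       gap = gap_spec(5, 0),
                       copy_source = c("parental", "daughter"),
                       gap_anchor = c("center", "downstream", "upstream"),
                       seed = 1L) {
  copy_source <- match.arg(copy_source)
  gap_anchor <- match.arg(gap_anchor)
  for (p in c(p_retain, p_copy1, p_copy2, p_stall_random, p_stall_fixed))
    if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
      stop("all probabilities must be single values in [0, 1]", call. = FALSE)
  if (generations < 1L || replicates < 1L)
    stop("'generations' and 'replicates' must be >= 1", call. = FALSE)
  if (n_nucleosomes < 1L)
    stop("'n_nucleosomes' must be >= 1", call. = FALSE)
  if (!is.na(fixed_site) &&
      (fixed_site < 1L || fixed_site > n_nucleosomes))
    stop("'fixed_site' must lie inside the fiber", call. = FALSE)
  if (!inherits(gap, "gap_spec")) stop("'gap' must be a gap_spec", call. = FALSE)
  structure(list(n_nucleosomes = as.integer(n_nucleosomes),
                 spacing_bp = as.integer(spacing_bp),
                 generations = as.integer(generations),
                 replicates = as.integer(replicates),
                 p_retain = p_retain,
                 p_copy1 = p_copy1,
                 p_copy2 = p_copy2,
                 p_stall_random = p_stall_random,
                 fixed_site = as.integer(fixed_site),
                 p_stall_fixed = p_stall_fixed,
                 gap = gap,
                 copy_source = copy_source,
                 gap_anchor = gap_anchor,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> %d nucleosomes x %d bp, %d generations x %d replicates\n",
    x$n_nucleosomes, x$spacing_bp, x$generations, x$replicates))
  cat(sprintf("  p_retain=%.3g p_copy1=%.3g p_copy2=%.3g\n",
              x$p_retain, x$p_copy1, x$p_copy2))
  cat(sprintf("  p_stall_random=%.4g fixed_site=%s p_stall_fixed=%.3g\n",
              x$p_stall_random,
              ifelse(is.na(x$fixed_site), "none", x$fixed_site),
              x$p_stall_fixed))
  cat(sprintf("  gap: mean %.3g, variance %.3g (%s anchor); copy source %s; seed %d\n",
              x$gap$mean_len, x$gap$variance, x$gap_anchor, x$copy_source,
              x$seed))
  invisible(x)
}
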