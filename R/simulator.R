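#' Segregate parental histones to the tracked daughter
#'
#' Each nucleosome position independently keeps its parental histone (and
#' hence its mark state) with probability \code{p_retain}; otherwise it is
#' occupied by a newly synthesized, unmarked histone. Models random
#' distribution of parental histones between the two daughter strands, with
#' one daughter lineage tracked.
#'
#' Uses R's global random number stream; seed control belongs to
#' \code{\link{run_trajectory}}.
#'
#' @param f A \code{chromatin_fiber}.
#' @param p_retain Retention probability in \code{[0, 1]}.
#' @return A list with \code{fiber} (the daughter fiber) and
#'   \code{retained} (logical mask of positions keeping a parental histone).
#' @export
segregate <- function(f, p_retain) {
  states <- as.logical(f)
  retained <- stats::runif(length(states)) < p_retain
  list(fiber = as_fiber(states & retained, attr(f, "spacing_bp")),
       retained = retained)
}

#' Draw this division's replication-fork stall sites
#'
#' Every nucleosome position stalls independently with probability
#' \code{p_stall_random}; additionally, \code{fixed_site} (when set) stalls
#' with probability \code{p_stall_fixed}. Duplicates are removed.
#'
#' @param params A \code{\link{sim_params}}.
#' @return Sorted integer vector of stall positions (possibly empty).
#' @export
draw_stalls <- function(params) {
  n <- params$n_nucleosomes
  stalls <- which(stats::runif(n) < params$p_stall_random)
  if (!is.na(params$fixed_site) &&
      stats::runif(1L) < params$p_stall_fixed) {
    stalls <- union(stalls, params$fixed_site)
  }
  sort(as.integer(stalls))
}

gap_bounds <- function(site, len, n, anchor) {
  a <- switch(anchor,
              downstream = site,
              upstream   = site - len + 1L,
              center     = site - (len - 1L) %/% 2L)
  c(max(1L, a), min(n, a + len - 1L))
}

#' Apply postreplicative gaps
#'
#' For each stall site a gap length is drawn from \code{gap} (variance 0
#' gives the rounded mean deterministically) and the covered positions are
#' set unmarked regardless of retention: gap-filling DNA synthesis is
#' uncoupled from the fork and chromatinized entirely with new histones.
#' Gaps are truncated at the fiber ends; overlapping gaps in one generation
#' are unioned.
#'
#' @param f A \code{chromatin_fiber}.
#' @param stall_sites Integer vector of stall positions within the fiber.
#' @param gap A \code{\link{gap_spec}}.
#' @param anchor Gap placement relative to the stall site: \code{"center"}
#'   (default), \code{"downstream"} or \code{"upstream"}.
#' @return A list with \code{fiber} and \code{gap_intervals}, a two-column
#'   matrix of closed 1-based \code{[start, end]} nucleosome intervals.
#' @export
apply_gaps <- function(f, stall_sites, gap,
                       anchor = c("center", "downstream", "upstream")) {
  anchor <- match.arg(anchor)
  states <- as.logical(f)
  n <- length(states)
  if (length(stall_sites) && (min(stall_sites) < 1 || max(stall_sites) > n))
    stop("stall sites must lie within the fiber", call. = FALSE)
  ivs <- matrix(integer(0), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  for (s in stall_sites) {
    len <- draw_gap_length(gap)
    b <- gap_bounds(as.integer(s), len, n, anchor)
    states[b[1L]:b[2L]] <- FALSE
    ivs <- rbind(ivs, b)
  }
  list(fiber = as_fiber(states, attr(f, "spacing_bp")), gap_intervals = ivs)
}

#' Restore marks by copying from neighbouring nucleosomes
#'
#' One synchronous pass: every unmarked nucleosome independently acquires
#' the mark with probability \code{p_copy1} if the template has at least one
#' marked neighbour at distance 1, otherwise with probability \code{p_copy2}
#' if there is a marked neighbour at distance 2 ("two-place copy"). Marked
#' nucleosomes never lose marks in this pass, and updates are computed from
#' the template state only -- marks gained within the pass do not cascade.
#' Fiber ends do not wrap: boundaries behave as insulators.
#'
#' @param f A \code{chromatin_fiber} to update.
#' @param p_copy1 Distance-1 copy probability.
#' @param p_copy2 Distance-2 copy probability.
#' @param template Mark states serving as the copy source; defaults to
#'   \code{f} itself. \code{\link{step_generation}} passes the parental
#'   fiber masked by this generation's gap intervals when
#'   \code{copy_source = "parental"}.
#' @return The updated \code{chromatin_fiber}.
#' @export
restore_marks <- function(f, p_copy1, p_copy2, template = f) {
  states <- as.logical(f)
  src <- as.logical(template)
  n <- length(states)
  stopifnot(length(src) == n)
  if (n == 1L) return(f)
  d1 <- c(FALSE, src[-n]) | c(src[-1L], FALSE)
  d2 <- if (n > 2L) {
    c(FALSE, FALSE, src[seq_len(n - 2L)]) | c(src[3:n], FALSE, FALSE)
  } else rep(FALSE, n)
  r <- stats::runif(n)
  gain <- !states & ((d1 & r < p_copy1) | (!d1 & d2 & r < p_copy2))
  as_fiber(states | gain, attr(f, "spacing_bp"))
}

#' Advance the fiber through one cell division
#'
#' Composition of \code{\link{segregate}}, \code{\link{draw_stalls}},
#' \code{\link{apply_gaps}} and \code{\link{restore_marks}}, in that order.
#' With the default \code{copy_source = "parental"}, the restore pass is
#' templated by the start-of-generation (parental) fiber with this
#' division's gap intervals masked out: marks are copied across at the fork
#' while parental histones are in register, but postreplicative gaps carry
#' no parental template. \code{copy_source = "daughter"} templates the pass
#' on the post-segregation daughter state instead.
#'
#' @param f The parental \code{chromatin_fiber}.
#' @param params A \code{\link{sim_params}}.
#' @return A list with \code{fiber} (the daughter) and \code{events}
#'   (retained mask, stall sites, gap intervals).
#' @export
step_generation <- function(f, params) {
  parental <- as.logical(f)
  seg <- segregate(f, params$p_retain)
  stalls <- draw_stalls(params)
  gp <- apply_gaps(seg$fiber, stalls, params$gap, params$gap_anchor)
  template <- if (params$copy_source == "parental") {
    masked <- parental
    if (nrow(gp$gap_intervals)) {
      for (i in seq_len(nrow(gp$gap_intervals)))
        masked[gp$gap_intervals[i, 1L]:gp$gap_intervals[i, 2L]] <- FALSE
    }
    masked
  } else {
    as.logical(gp$fiber)
  }
  daughter <- restore_marks(gp$fiber, params$p_copy1, params$p_copy2,
                            template = template)
  list(fiber = daughter,
       events = list(retained_mask = seg$retained,
                     stall_sites = stalls,
                     gap_intervals = gp$gap_intervals))
}

replicate_seeds <- function(seed, replicates) {
  # fixed derivation scheme: replicate r is reproducible in isolation from
  # the root seed alone
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, replicates)
}

#' Run a multi-replicate, multi-generation trajectory
#'
#' Runs \code{replicates} independent lineages for \code{generations}
#' divisions, each from a fresh all-marked fiber, and records the fraction
#' of nucleosomes marked and -- when a fixed stall site is set -- the length
#' of the unmarked tract containing that site, per generation.
#' Replicate r runs under a seed derived deterministically from
#' \code{params$seed}, so identical parameters give bit-identical results.
#'
#' @param params A \code{\link{sim_params}}.
#' @return A \code{trajectory_result} list: \code{frac_marked} and
#'   \code{lost_tract} are \code{replicates x generations} matrices and
#'   \code{params_echo} the input parameters.
#' @export
run_trajectory <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  reps <- params$replicates
  gens <- params$generations
  seeds <- replicate_seeds(params$seed, reps)
  frac <- matrix(NA_real_, reps, gens)
  tract <- matrix(0, reps, gens)
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    f <- new_fiber(params$n_nucleosomes, params$spacing_bp)
    for (g in seq_len(gens)) {
      f <- step_generation(f, params)$fiber
      frac[r, g] <- fraction_marked(f)
      if (!is.na(params$fixed_site))
        tract[r, g] <- max_unmarked_run(f, params$fixed_site)
    }
  }
  structure(list(frac_marked = frac, lost_tract = tract,
                 params_echo = params),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  g <- ncol(x$frac_marked)
  cat(sprintf(
    "<trajectory_result> %d replicates x %d generations; mean final loss %.1f%%\n",
    nrow(x$frac_marked), g, 100 * (1 - mean(x$frac_marked[, g]))))
  invisible(x)
}

#' Tidy per-replicate, per-generation table of a trajectory
#'
#' @param x A \code{trajectory_result}.
#' @return A data frame with columns replicate, generation, frac_marked,
#'   frac_lost and lost_tract.
#' @export
trajectory_table <- function(x) {
  stopifnot(inherits(x, "trajectory_result"))
  reps <- nrow(x$frac_marked); gens <- ncol(x$frac_marked)
  data.frame(replicate = rep(seq_len(reps), times = gens),
             generation = rep(seq_len(gens), each = reps),
             frac_marked = as.vector(x$frac_marked),
             frac_lost = 1 - as.vector(x$frac_marked),
             lost_tract = as.vector(x$lost_tract))
}

#' Convert a per-nucleosome stall probability to a stall interval
#'
#' With spacing 200 bp, a stall probability of 0.025 per nucleosome
#' corresponds to one stall every 8 kb.
#'
#' @param p_per_nucleosome Stall probability per nucleosome per division,
#'   in \code{(0, 1]}.
#' @param spacing_bp Base pairs per nucleosome.
#' @return Mean distance between stalls, in kb.
#' @export
stall_interval_kb <- function(p_per_nucleosome, spacing_bp = 200L) {
  if (length(p_per_nucleosome) != 1L || !is.finite(p_per_nucleosome) ||
      p_per_nucleosome <= 0 || p_per_nucleosome > 1)
    stop("'p_per_nucleosome' must be in (0, 1]", call. = FALSE)
  spacing_bp / p_per_nucleosome / 1000
}

#' Minimal mean gap length producing a target mark loss
#'
#' Converts a stall interval in kb to a per-nucleosome stall probability
#' (\code{spacing_bp / (interval_kb * 1000)}), then sweeps integer mean gap
#' lengths upward and returns the smallest mean gap whose mean fraction of
#' marks lost at the final generation (over the replicates) reaches
#' \code{loss_target}. Gap variance is taken from \code{base$gap}.
#'
#' @param stall_interval_kb Mean distance between random stalls, kb.
#' @param loss_target Target fraction of marks lost, in \code{(0, 1)}.
#' @param base A \code{\link{sim_params}} supplying all other settings.
#' @param gap_cap Largest mean gap tried before the target is declared
#'   unattained (default 100 nucleosomes).
#' @return A list: \code{min_gap} (NA when unattained), \code{attained},
#'   \code{p_stall}, and \code{losses}, the mean final-generation loss per
#'   gap length tried.
#' @export
sweep_gap_for_loss <- function(stall_interval_kb, loss_target, base,
                               gap_cap = 100L) {
  stopifnot(inherits(base, "sim_params"))
  if (loss_target <= 0 || loss_target >= 1)
    stop("'loss_target' must be in (0, 1)", call. = FALSE)
  p <- base$spacing_bp / (stall_interval_kb * 1000)
  losses <- numeric(0)
  for (g in seq_len(gap_cap)) {
    pars <- base
    pars$p_stall_random <- p
    pars$gap <- gap_spec(g, base$gap$variance)
    pars$seed <- derive_seed(base$seed, g)
    tr <- run_trajectory(pars)
    losses[g] <- 1 - mean(tr$frac_marked[, pars$generations])
    if (losses[g] >= loss_target) {
      return(list(min_gap = g, attained = TRUE, p_stall = p, losses = losses))
    }
  }
  list(min_gap = NA_integer_, attained = FALSE, p_stall = p, losses = losses)
}

derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483646) + 1L
}

#' Mean lost-tract length across a fixed-site stall-probability grid
#'
#' For each combination of gap length and fixed-site stall probability,
#' runs the model with a single recurrent stall site at the fiber midpoint
#' (or \code{base$fixed_site} when set) and records the mean length, over
#' replicates, of the unmarked tract containing the site at the final
#' generation. Gap variance is forced to 0.
#'
#' @param prob_grid Vector of stall probabilities in \code{[0, 1]}.
#' @param gap_lengths Integer vector of gap lengths (nucleosomes).
#' @param base A \code{\link{sim_params}}.
#' @return A \code{gap_lengths x prob_grid} matrix of mean tract lengths.
#' @export
sweep_fixed_stall <- function(prob_grid, gap_lengths, base) {
  stopifnot(inherits(base, "sim_params"))
  if (any(prob_grid < 0 | prob_grid > 1))
    stop("probabilities must be in [0, 1]", call. = FALSE)
  site <- if (is.na(base$fixed_site)) base$n_nucleosomes %/% 2L else base$fixed_site
  out <- matrix(NA_real_, length(gap_lengths), length(prob_grid),
                dimnames = list(paste0("gap", gap_lengths),
                                paste0("p", prob_grid)))
  for (i in seq_along(gap_lengths)) {
    for (j in seq_along(prob_grid)) {
      pars <- base
      pars$fixed_site <- site
      pars$p_stall_fixed <- prob_grid[j]
      pars$gap <- gap_spec(gap_lengths[i], 0)
      pars$seed <- derive_seed(base$seed, i * 1000L + j)
      tr <- run_trajectory(pars)
      out[i, j] <- mean(tr$lost_tract[, pars$generations])
    }
  }
  out
}

#' Smallest fixed-site stall probability sustaining a full-gap tract
#'
#' Sweeps the fixed-site stall probability over a grid and returns the
#' smallest probability at which the mean unmarked tract containing the
#' site has reached at least the gap length by generation
#' \code{base$generations} and does not decline when the simulation is
#' extended by \code{stability_generations} further divisions. Returns
#' \code{NA} when no grid probability qualifies.
#'
#' @param base A \code{\link{sim_params}}; \code{base$gap$mean_len} is the
#'   gap length tested (variance forced to 0).
#' @param prob_grid Probability grid (default 0 to 1 in steps of 0.05).
#' @param stability_generations Extra divisions for the stability check
#'   (default 15).
#' @param decline_tol Allowed Monte-Carlo decline between the two time
#'   points, in nucleosomes (default 0.5).
#' @return A list: \code{p_min} (NA if unattained), and \code{table} with
#'   one row per grid probability giving the mean tract at the final and
#'   extended generations.
#' @export
fixed_stall_threshold <- function(base,
                                  prob_grid = seq(0, 1, by = 0.05),
                                  stability_generations = 15L,
                                  decline_tol = 0.5) {
  stopifnot(inherits(base, "sim_params"))
  gap_len <- round(base$gap$mean_len)
  site <- if (is.na(base$fixed_site)) base$n_nucleosomes %/% 2L else base$fixed_site
  tab <- data.frame(p = prob_grid, tract_final = NA_real_,
                    tract_extended = NA_real_)
  p_min <- NA_real_
  for (j in seq_along(prob_grid)) {
    pars <- base
    pars$fixed_site <- site
    pars$p_stall_fixed <- prob_grid[j]
    pars$gap <- gap_spec(gap_len, 0)
    pars$generations <- base$generations + as.integer(stability_generations)
    pars$seed <- derive_seed(base$seed, 5000L + j)
    tr <- run_trajectory(pars)
    tab$tract_final[j] <- mean(tr$lost_tract[, base$generations])
    tab$tract_extended[j] <- mean(tr$lost_tract[, pars$generations])
    if (is.na(p_min) && tab$tract_final[j] >= gap_len &&
        tab$tract_extended[j] >= tab$tract_final[j] - decline_tol) {
      p_min <- prob_grid[j]
    }
  }
  list(p_min = p_min, table = tab)
}
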