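#' Specification for a synthetic sequence with planted quadruplex motifs
#'
#' @param seq_length Sequence length in bp.
#' @param gc_background Background GC fraction in \code{[0, 1]}
#'   (default 0.4).
#' @param plants Data frame with columns \code{position} (0-based start),
#'   \code{strand} (\code{"+"} or \code{"-"}) and \code{template}, a
#'   consensus-conforming quadruplex string planted at that position (the
#'   reverse complement is inserted for minus-strand plants). May have
#'   zero rows.
#' @param seed Integer seed; generator output is a pure function of
#'   seed and spec.
#' @return A \code{plant_spec} list.
#' @export
plant_spec <- function(seq_length, gc_background = 0.4,
                       plants = data.frame(position = integer(0),
                                           strand = character(0),
                                           template = character(0)),
                       seed = 1L) {
  stopifnot(seq_length >= 1, gc_background >= 0, gc_background <= 1,
            all(c("position", "strand", "template") %in% names(plants)))
  if (nrow(plants)) {
    if (!all(plants$strand %in% c("+", "-")))
      stop("plant strand must be '+' or '-'", call. = FALSE)
    for (i in seq_len(nrow(plants))) {
      tm <- plants$template[i]
      hit <- find_g4(tm, strands = "+")
      if (nrow(hit) != 1L || hit$start != 0L || hit$end != nchar(tm))
        stop(sprintf("plant %d template is not a single full-span consensus motif", i),
             call. = FALSE)
      if (plants$position[i] < 0 ||
          plants$position[i] + nchar(tm) > seq_length)
        stop(sprintf("plant %d does not fit in the sequence", i), call. = FALSE)
    }
    ends <- plants$position + nchar(plants$template)
    o <- order(plants$position)
    if (nrow(plants) > 1L &&
        any(plants$position[o][-1L] < ends[o][-nrow(plants)]))
      stop("planted motifs must not overlap", call. = FALSE)
  }
  structure(list(seq_length = as.integer(seq_length),
                 gc_background = gc_background,
                 plants = plants, seed = as.integer(seed)),
            class = "plant_spec")
}

sample_background <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic sequence with motifs planted at known coordinates
#'
#' Draws an i.i.d. background at the requested GC content, overwrites it
#' with the planted motifs (reverse-complemented for minus-strand plants),
#' and then rejection-scrubs the background: as long as the scanner's
#' output differs from the planted truth, the offending background
#' positions (never positions inside a plant) are locally resampled. The
#' returned truth table therefore lists exactly the motifs the scanner
#' finds.
#'
#' @param spec A \code{\link{plant_spec}}.
#' @param seq_id Sequence name used in the truth table (default "chrS").
#' @param max_iter Scrub iteration cap (default 200).
#' @return A list: \code{seq} (character string), \code{truth} (BED-like
#'   data frame: seq_id, start, end, name, score = motif width, strand).
#' @export
make_sequence <- function(spec, seq_id = "chrS", max_iter = 200L) {
  stopifnot(inherits(spec, "plant_spec"))
  set.seed(spec$seed)
  n <- spec$seq_length
  chars <- sample_background(n, spec$gc_background)
  plants <- spec$plants
  in_plant <- rep(FALSE, n)
  truth <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0))
  if (nrow(plants)) {
    for (i in seq_len(nrow(plants))) {
      tm <- plants$template[i]
      if (plants$strand[i] == "-") tm <- reverse_complement(tm)
      idx <- (plants$position[i] + 1L):(plants$position[i] + nchar(tm))
      chars[idx] <- strsplit(tm, "")[[1L]]
      in_plant[idx] <- TRUE
      truth <- rbind(truth, data.frame(
        seq_id = seq_id, start = plants$position[i],
        end = plants$position[i] + nchar(tm),
        name = sprintf("plant%d", i), score = nchar(tm),
        strand = plants$strand[i]))
    }
    truth <- truth[order(truth$start, match(truth$strand, c("+", "-"))), ,
                   drop = FALSE]
    rownames(truth) <- NULL
  }
  key <- function(df) sprintf("%d:%d:%s", df$start, df$end, df$strand)
  want <- key(truth)
  for (it in seq_len(max_iter)) {
    found <- find_g4(paste(chars, collapse = ""), seq_id = seq_id)
    if (identical(sort(key(found)), sort(want))) {
      return(list(seq = paste(chars, collapse = ""), truth = truth))
    }
    # resample background under every unexpected motif, and around every
    # planted motif that went missing (a flanking base may have extended
    # or shadowed a G-run)
    bad <- rep(FALSE, n)
    spurious <- found[!key(found) %in% want, , drop = FALSE]
    if (nrow(spurious)) {
      for (j in seq_len(nrow(spurious)))
        bad[(spurious$start[j] + 1L):spurious$end[j]] <- TRUE
    }
    missing <- truth[!want %in% key(found), , drop = FALSE]
    if (nrow(missing)) {
      for (j in seq_len(nrow(missing))) {
        lo <- max(1L, missing$start[j] - 7L)
        hi <- min(n, missing$end[j] + 7L)
        bad[lo:hi] <- TRUE
      }
    }
    bad <- bad & !in_plant
    if (!any(bad))
      stop("scrubbing cannot separate interacting plants", call. = FALSE)
    chars[bad] <- sample_background(sum(bad), spec$gc_background)
  }
  stop("background scrubbing did not converge", call. = FALSE)
}

random_g4_template <- function(gmin = 3L, gmax = 5L, lmin = 1L, lmax = 7L) {
  # loops drawn from A/C/T so the template carries exactly one motif
  runs <- vapply(sample(gmin:gmax, 4L, replace = TRUE),
                 function(k) strrep("G", k), character(1L))
  loops <- vapply(sample(lmin:lmax, 3L, replace = TRUE),
                  function(k) paste(sample(c("A", "C", "T"), k,
                                           replace = TRUE), collapse = ""),
                  character(1L))
  paste0(runs[1L], loops[1L], runs[2L], loops[2L], runs[3L], loops[3L],
         runs[4L])
}

#' Generate synthetic test/control gene sets with controlled motif prevalence
#'
#' Emulates a promoter-window prevalence comparison: each gene gets its own
#' sequence spanning one window around its transcription start site, and a
#' set-specific fraction of genes carries exactly one planted quadruplex
#' motif (random consensus instance, random strand, random position fully
#' inside the window); the remaining genes carry none. Defaults plant
#' motifs in 71\% of the test set and 38\% of controls, the effect size at
#' which upregulated gene sets have been reported to differ from controls.
#'
#' @param n_test,n_control Set sizes (default 100 each).
#' @param prevalence_test,prevalence_control Fractions of genes carrying a
#'   motif (defaults 0.71 and 0.38).
#' @param halfwidth Window half-width in bp (default 1500).
#' @param gc_background Background GC fraction (default 0.4).
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return A list: \code{sequences} (named character vector, one per
#'   gene), \code{genes} (gene_id, seq_id, tss, set), \code{truth}
#'   (gene_id, set, has_motif).
#' @export
make_gene_sets <- function(n_test = 100L, n_control = 100L,
                           prevalence_test = 0.71,
                           prevalence_control = 0.38,
                           halfwidth = 1500L, gc_background = 0.4,
                           seed = 1L) {
  stopifnot(n_test >= 1, n_control >= 1,
            prevalence_test >= 0, prevalence_test <= 1,
            prevalence_control >= 0, prevalence_control <= 1)
  set.seed(seed)
  sets <- rep(c("test", "control"), c(n_test, n_control))
  carrier <- c(stats::runif(n_test) < prevalence_test,
               stats::runif(n_control) < prevalence_control)
  ids <- sprintf("%s_g%03d", sets, c(seq_len(n_test), seq_len(n_control)))
  len <- 2L * as.integer(halfwidth)
  seqs <- character(length(ids))
  names(seqs) <- ids
  for (i in seq_along(ids)) {
    plants <- if (carrier[i]) {
      tm <- random_g4_template()
      data.frame(position = sample.int(len - nchar(tm) + 1L, 1L) - 1L,
                 strand = sample(c("+", "-"), 1L),
                 template = tm)
    } else {
      data.frame(position = integer(0), strand = character(0),
                 template = character(0))
    }
    sp <- plant_spec(len, gc_background, plants,
                     seed = derive_seed(seed, i))
    seqs[i] <- make_sequence(sp, seq_id = ids[i])$seq
  }
  list(sequences = seqs,
       genes = data.frame(gene_id = ids, seq_id = ids,
                          tss = as.integer(halfwidth), set = sets),
       truth = data.frame(gene_id = ids, set = sets, has_motif = carrier))
}
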