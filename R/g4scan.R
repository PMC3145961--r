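check_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq))
    stop(sprintf("'%s' must be a single character string", what), call. = FALSE)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' in %s at position %d (alphabet ACGTN)",
                 substr(seq, bad, bad), what, bad), call. = FALSE)
  seq
}

#' Reverse complement of a nucleotide sequence
#'
#' Standard complement over the alphabet \{A, C, G, T, N\}, reversed.
#' An involution: \code{reverse_complement(reverse_complement(x)) == x}.
#'
#' @param seq A single upper-case string over A/C/G/T/N.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  check_dna(seq)
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

g4_pattern <- function(gmin, gmax, lmin, lmax) {
  run <- sprintf("(G{%d,%d})", gmin, gmax)
  loop <- sprintf("([ACGT]{%d,%d}?)", lmin, lmax)
  paste0(run, loop, run, loop, run, loop, run)
}

# leftmost, non-overlapping matches on one strand; returns 0-based
# half-open motif and capture spans
scan_strand <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(list())
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  lapply(seq_along(m), function(i) {
    spans <- cbind(start = unname(cs[i, ]) - 1L,
                   end = unname(cs[i, ]) - 1L + unname(cl[i, ]))
    list(start = m[i] - 1L,
         end = m[i] - 1L + attr(m, "match.length")[i],
         run_spans = spans[c(1L, 3L, 5L, 7L), , drop = FALSE],
         loop_spans = spans[c(2L, 4L, 6L), , drop = FALSE])
  })
}

#' Find G-quadruplex consensus motifs on both strands
#'
#' Matches the quadruplex consensus G(gmin-gmax) L(lmin-lmax) repeated to
#' four G-runs against the forward strand, and against the reverse
#' complement for the minus strand, reporting all motifs on forward
#' coordinates (0-based, half-open). Scanning is left-to-right and
#' non-overlapping per strand: after a match, scanning resumes at its end.
#' G-runs are greedy (a tract of more than \code{gmax} Gs contributes its
#' first \code{gmax}); loops are matched lazily and may contain any of
#' A/C/G/T. N never matches and so breaks both runs and loops.
#'
#' @param seq A single sequence string over A/C/G/T/N (upper case).
#' @param gmin,gmax G-run length bounds (defaults 3 and 5).
#' @param lmin,lmax Loop length bounds (defaults 1 and 7).
#' @param strands Strands to scan: \code{"both"} (default), \code{"+"} or
#'   \code{"-"}.
#' @param seq_id Sequence name recorded in the output.
#' @return A data frame with one row per motif: \code{seq_id},
#'   \code{start}, \code{end} (0-based half-open, forward coordinates),
#'   \code{strand}, \code{width}, and list-columns \code{run_spans} and
#'   \code{loop_spans} holding the per-motif G-run and loop coordinates.
#'   Rows are ordered by start, then strand (+ before -).
#' @examples
#' find_g4("GGGAGGGAGGGAGGG")
#' @export
find_g4 <- function(seq, gmin = 3L, gmax = 5L, lmin = 1L, lmax = 7L,
                    strands = c("both", "+", "-"), seq_id = "seq") {
  strands <- match.arg(strands)
  check_dna(seq)
  stopifnot(gmin >= 1, gmax >= gmin, lmin >= 1, lmax >= lmin)
  pattern <- g4_pattern(gmin, gmax, lmin, lmax)
  n <- nchar(seq)
  hits <- list()
  if (strands %in% c("both", "+")) {
    for (h in scan_strand(seq, pattern)) {
      h$strand <- "+"
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (strands %in% c("both", "-") && n > 0L) {
    rc <- reverse_complement(seq)
    for (h in scan_strand(rc, pattern)) {
      # map [s, e) on the reverse complement to forward coordinates
      map <- function(sp) {
        out <- cbind(start = n - sp[, "end"], end = n - sp[, "start"])
        out[rev(seq_len(nrow(out))), , drop = FALSE]
      }
      hits[[length(hits) + 1L]] <- list(start = n - h$end, end = n - h$start,
                                        run_spans = map(h$run_spans),
                                        loop_spans = map(h$loop_spans),
                                        strand = "-")
    }
  }
  if (!length(hits)) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      width = integer(0),
                      run_spans = I(list()), loop_spans = I(list())))
  }
  out <- data.frame(
    seq_id = seq_id,
    start = vapply(hits, `[[`, integer(1L), "start"),
    end = vapply(hits, `[[`, integer(1L), "end"),
    strand = vapply(hits, `[[`, character(1L), "strand"),
    run_spans = I(lapply(hits, `[[`, "run_spans")),
    loop_spans = I(lapply(hits, `[[`, "loop_spans")))
  out$width <- out$end - out$start
  out <- out[order(out$start, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("seq_id", "start", "end", "strand", "width",
          "run_spans", "loop_spans")]
}

#' Count quadruplex motifs in windows around transcription start sites
#'
#' For each gene, motifs are counted inside the window
#' \code{[tss - halfwidth, tss + halfwidth)} clamped to the sequence
#' bounds. By default a motif counts if at least one base of its span lies
#' inside the window, so motifs straddling a window edge are included;
#' \code{full_containment = TRUE} requires the whole motif inside.
#' A gene whose \code{seq_id} is missing from \code{sequences} receives an
#' error record and the scan continues.
#'
#' @param sequences Named character vector of sequences (upper-case
#'   A/C/G/T/N), e.g. from \code{\link{read_fasta}}.
#' @param genes Data frame with columns \code{gene_id}, \code{seq_id} and
#'   \code{tss} (0-based coordinate).
#' @param halfwidth Window half-width in bp (default 1500).
#' @param full_containment Require motifs fully inside the window
#'   (default FALSE).
#' @param ... Passed to \code{\link{find_g4}} (consensus bounds, strands).
#' @return Data frame with one row per gene: window bounds, \code{n_motifs},
#'   \code{has_motif}, and \code{error} (NA on success).
#' @export
scan_windows <- function(sequences, genes, halfwidth = 1500L,
                         full_containment = FALSE, ...) {
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            all(c("gene_id", "seq_id", "tss") %in% names(genes)))
  motifs <- lapply(sequences, find_g4, ...)
  out <- data.frame(gene_id = genes$gene_id, seq_id = genes$seq_id,
                    window_start = NA_integer_, window_end = NA_integer_,
                    n_motifs = NA_integer_, has_motif = NA,
                    error = NA_character_)
  for (i in seq_len(nrow(genes))) {
    sid <- genes$seq_id[i]
    if (!sid %in% names(sequences)) {
      out$error[i] <- sprintf("sequence '%s' not found", sid)
      next
    }
    len <- nchar(sequences[[sid]])
    ws <- max(0L, as.integer(genes$tss[i]) - as.integer(halfwidth))
    we <- min(len, as.integer(genes$tss[i]) + as.integer(halfwidth))
    mt <- motifs[[sid]]
    inside <- if (full_containment) {
      mt$start >= ws & mt$end <= we
    } else {
      mt$start < we & mt$end > ws
    }
    out$window_start[i] <- ws
    out$window_end[i] <- we
    out$n_motifs[i] <- sum(inside)
    out$has_motif[i] <- any(inside)
  }
  out
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over
#' all tables with the observed margins, that do not exceed the observed
#' table's probability (ties resolved at relative tolerance 1e-7, as in
#' \code{\link[stats]{fisher.test}}, which computes the p-value here).
#' The odds ratio reported is the sample estimate \code{(a*d)/(b*c)}
#' (infinite when \code{b*c == 0} and \code{a*d > 0}), not the conditional
#' maximum-likelihood estimate.
#'
#' @param a,b,c,d Non-negative integer counts; rows are with/without at
#'   least one motif, columns test/control set.
#' @return An \code{enrichment_result} list with the counts,
#'   \code{odds_ratio} and \code{p_two_sided}.
#' @examples
#' fisher_exact_2x2(10, 0, 0, 10)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  counts <- stats::setNames(as.integer(round(counts)),
                            c("a", "b", "c", "d"))
  p <- stats::fisher.test(matrix(counts, 2L, 2L, byrow = TRUE))$p.value
  ad <- as.double(counts[["a"]]) * counts[["d"]]
  bc <- as.double(counts[["b"]]) * counts[["c"]]
  or <- if (bc == 0) {
    if (ad > 0) Inf else NaN
  } else ad / bc
  structure(list(a = counts[["a"]], b = counts[["b"]],
                 c = counts[["c"]], d = counts[["d"]],
                 odds_ratio = or, p_two_sided = min(1, p)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> 2x2 table (rows: motif yes/no; cols: test/control)\n")
  print(matrix(c(x$a, x$b, x$c, x$d), 2L, 2L, byrow = TRUE,
               dimnames = list(c("motif", "no motif"),
                               c("test", "control"))))
  cat(sprintf("odds ratio %.4g, two-sided p %.4g\n",
              x$odds_ratio, x$p_two_sided))
  if (!is.null(x$prevalence_test))
    cat(sprintf("prevalence: test %.1f%%, control %.1f%%\n",
                100 * x$prevalence_test, 100 * x$prevalence_control))
  invisible(x)
}

#' Compare motif prevalence between a test and a control gene set
#'
#' Builds the 2x2 table of genes with/without at least one motif in the
#' test and control sets and runs \code{\link{fisher_exact_2x2}}.
#'
#' @param test_flags,control_flags Logical vectors of per-gene
#'   \code{has_motif} flags; both must be non-empty and NA-free.
#' @return An \code{enrichment_result} with \code{prevalence_test} and
#'   \code{prevalence_control} added.
#' @export
prevalence_enrichment <- function(test_flags, control_flags) {
  test_flags <- as.logical(test_flags)
  control_flags <- as.logical(control_flags)
  if (!length(test_flags) || !length(control_flags))
    stop("both gene sets must be non-empty", call. = FALSE)
  if (anyNA(test_flags) || anyNA(control_flags))
    stop("has_motif flags must not contain NA", call. = FALSE)
  res <- fisher_exact_2x2(sum(test_flags), sum(!test_flags),
                          sum(control_flags), sum(!control_flags))
  res$prevalence_test <- mean(test_flags)
  res$prevalence_control <- mean(control_flags)
  res
}
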