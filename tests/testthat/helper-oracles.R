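# Independent oracles used across the suite. Each is a deliberately naive,
# straight-line implementation kept free of the package's code paths.

# One replication generation, written as per-position loops.
naive_step <- function(states, params) {
  n <- length(states)
  parental <- states
  # segregation
  for (i in seq_len(n)) {
    if (stats::runif(1) >= params$p_retain) states[i] <- FALSE
  }
  # stalls
  stalls <- integer(0)
  for (i in seq_len(n)) {
    if (stats::runif(1) < params$p_stall_random) stalls <- c(stalls, i)
  }
  if (!is.na(params$fixed_site) && stats::runif(1) < params$p_stall_fixed)
    stalls <- sort(unique(c(stalls, params$fixed_site)))
  # gaps
  gapmask <- rep(FALSE, n)
  for (s in stalls) {
    len <- if (params$gap$variance == 0) {
      max(1, round(params$gap$mean_len))
    } else {
      max(1, round(stats::rnorm(1, params$gap$mean_len,
                                sqrt(params$gap$variance))))
    }
    a <- switch(params$gap_anchor,
                downstream = s, upstream = s - len + 1,
                center = s - (len - 1) %/% 2)
    for (j in max(1, a):min(n, a + len - 1)) {
      states[j] <- FALSE
      gapmask[j] <- TRUE
    }
  }
  # restore, synchronous, templated per copy_source
  src <- if (params$copy_source == "parental") parental & !gapmask else states
  out <- states
  for (i in seq_len(n)) {
    if (states[i]) next
    has1 <- (i > 1 && src[i - 1]) || (i < n && src[i + 1])
    has2 <- (i > 2 && src[i - 2]) || (i < n - 1 && src[i + 2])
    r <- stats::runif(1)
    if (has1) {
      if (r < params$p_copy1) out[i] <- TRUE
    } else if (has2) {
      if (r < params$p_copy2) out[i] <- TRUE
    }
  }
  out
}

naive_final_loss <- function(params, replicates, gens, n, seed) {
  set.seed(seed)
  losses <- numeric(replicates)
  for (r in seq_len(replicates)) {
    st <- rep(TRUE, n)
    for (g in seq_len(gens)) st <- naive_step(st, params)
    losses[r] <- 1 - mean(st)
  }
  losses
}

# Exhaustive quadruplex enumerator: leftmost start; at each start a
# depth-first search trying G-run lengths longest-first and loop lengths
# shortest-first; after a match, scanning resumes at its end.
enum_g4_strand <- function(seq, gmin = 3, gmax = 5, lmin = 1, lmax = 7) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  g_run_at <- function(pos, len) {
    if (pos + len - 1 > n) return(FALSE)
    all(chars[pos:(pos + len - 1)] == "G")
  }
  loop_at <- function(pos, len) {
    if (pos + len - 1 > n) return(FALSE)
    all(chars[pos:(pos + len - 1)] %in% c("A", "C", "G", "T"))
  }
  match_from <- function(pos, part) {
    # part 1..7 alternates run, loop, run, ...; returns end (exclusive) or NA
    if (part == 8) return(pos)
    if (part %% 2 == 1) {
      for (len in gmax:gmin) {
        if (g_run_at(pos, len)) {
          e <- match_from(pos + len, part + 1)
          if (!is.na(e)) return(e)
        }
      }
    } else {
      for (len in lmin:lmax) {
        if (loop_at(pos, len)) {
          e <- match_from(pos + len, part + 1)
          if (!is.na(e)) return(e)
        }
      }
    }
    NA_integer_
  }
  hits <- list()
  pos <- 1
  while (pos <= n - 4 * gmin - 3 * lmin + 1) {
    e <- match_from(pos, 1)
    if (!is.na(e)) {
      hits[[length(hits) + 1]] <- c(start = pos - 1, end = e - 1)
      pos <- e
    } else {
      pos <- pos + 1
    }
  }
  hits
}

naive_rc <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

enum_g4 <- function(seq, ...) {
  fwd <- enum_g4_strand(seq, ...)
  n <- nchar(seq)
  rev <- lapply(enum_g4_strand(naive_rc(seq), ...), function(h)
    c(start = n - h[["end"]], end = n - h[["start"]]))
  out <- data.frame(
    start = c(vapply(fwd, `[[`, numeric(1), "start"),
              vapply(rev, `[[`, numeric(1), "start")),
    end = c(vapply(fwd, `[[`, numeric(1), "end"),
            vapply(rev, `[[`, numeric(1), "end")),
    strand = rep(c("+", "-"), c(length(fwd), length(rev))))
  out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
}

motif_key <- function(df) {
  sort(sprintf("%d:%d:%s", df$start, df$end, df$strand))
}

# Two-sided Fisher p by explicit enumeration of all tables with the
# observed margins (tie rule: relative tolerance 1e-7).
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  k <- a + c          # column 1 total
  nn <- a + b + c + d
  xs <- max(0, k - (nn - m)):min(k, m)
  probs <- stats::dhyper(xs, m, nn - m, k)
  obs <- stats::dhyper(a, m, nn - m, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
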