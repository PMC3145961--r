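#' Read a (multi-record) FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

bed_cols <- c("seq_id", "start", "end", "name", "score", "strand")

#' Read a BED6 file
#'
#' BED is 0-based, half-open; coordinates are returned unchanged.
#' Malformed lines fail fast with their line number.
#'
#' @param path BED file path.
#' @return Data frame with columns seq_id, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(stats::setNames(data.frame(character(0), integer(0), integer(0),
                                      character(0), numeric(0), character(0)),
                           bed_cols))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6L))
    stop(sprintf("BED line %d has %d fields; BED6 requires 6",
                 which(nf < 6L)[1L], min(nf)), call. = FALSE)
  out <- data.frame(
    seq_id = vapply(parts, `[[`, character(1L), 1L),
    start = as.integer(vapply(parts, `[[`, character(1L), 2L)),
    end = as.integer(vapply(parts, `[[`, character(1L), 3L)),
    name = vapply(parts, `[[`, character(1L), 4L),
    score = as.numeric(vapply(parts, `[[`, character(1L), 5L)),
    strand = vapply(parts, `[[`, character(1L), 6L))
  bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0 |
                 out$end < out$start | !out$strand %in% c("+", "-", "."))
  if (length(bad))
    stop(sprintf("malformed BED record at line %d", bad[1L]), call. = FALSE)
  out
}

#' Write a BED6 file
#'
#' @param bed Data frame with columns seq_id, start, end, name, score,
#'   strand (0-based half-open coordinates).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(bed, path) {
  stopifnot(all(bed_cols %in% names(bed)))
  out <- bed[, bed_cols]
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(out))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                       out$seq_id, as.integer(out$start),
                       as.integer(out$end), out$name,
                       as.character(out$score), out$strand),
               con)
  invisible(path)
}

#' Convert a motif table to BED6
#'
#' @param motifs Output of \code{\link{find_g4}}.
#' @return BED6 data frame: name is a running motif index, score the motif
#'   width in bp.
#' @export
motifs_to_bed <- function(motifs) {
  data.frame(seq_id = motifs$seq_id, start = motifs$start,
             end = motifs$end,
             name = if (nrow(motifs)) sprintf("g4_%d", seq_len(nrow(motifs)))
                    else character(0),
             score = motifs$width, strand = motifs$strand)
}

#' Read a gene/TSS table
#'
#' Accepts BED6 (the TSS is the start for + genes, end - 1 for - genes)
#' or a TSV with header columns gene_id, seq_id, tss and optionally
#' strand. TSV coordinates are 0-based unless the file carries a
#' \code{# coords=1based} comment, in which case they are shifted down
#' by one on input.
#'
#' @param path Input path; format chosen by extension (.bed vs anything
#'   else).
#' @return Data frame with gene_id, seq_id, tss (0-based), strand.
#' @export
read_gene_table <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- read_bed(path)
    tss <- ifelse(bed$strand == "-", bed$end - 1L, bed$start)
    return(data.frame(gene_id = bed$name, seq_id = bed$seq_id,
                      tss = as.integer(tss), strand = bed$strand))
  }
  header <- readLines(path, n = 5L)
  one_based <- any(grepl("coords\\s*=\\s*1based", header))
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "seq_id", "tss") %in% names(tab)))
    stop("gene table needs columns gene_id, seq_id, tss", call. = FALSE)
  if (one_based) tab$tss <- tab$tss - 1L
  if (is.null(tab$strand)) tab$strand <- "+"
  tab[, c("gene_id", "seq_id", "tss", "strand")]
}

#' Read a plain-text simulation config
#'
#' Key/value lines (\code{key = value}; '#' comments allowed) mirroring
#' \code{\link{sim_params}} argument names, plus \code{gap_mean} and
#' \code{gap_variance} for the gap distribution. Unknown keys fail fast.
#'
#' @param path Config file path.
#' @return A \code{\link{sim_params}}.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_0-9]+)\\s*=\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L))
    stop(sprintf("malformed config line: '%s'",
                 lines[which(lengths(kv) != 3L)[1L]]), call. = FALSE)
  keys <- vapply(kv, `[[`, character(1L), 2L)
  vals <- vapply(kv, `[[`, character(1L), 3L)
  num_keys <- c("n_nucleosomes", "spacing_bp", "generations", "replicates",
                "p_retain", "p_copy1", "p_copy2", "p_stall_random",
                "fixed_site", "p_stall_fixed", "gap_mean", "gap_variance",
                "seed")
  chr_keys <- c("copy_source", "gap_anchor")
  unknown <- setdiff(keys, c(num_keys, chr_keys))
  if (length(unknown))
    stop(sprintf("unknown config key '%s'", unknown[1L]), call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicated config key", call. = FALSE)
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    args[[k]] <- if (k %in% num_keys) {
      if (vals[i] %in% c("NA", "none")) NA_real_ else as.numeric(vals[i])
    } else vals[i]
  }
  gap_mean <- if (!is.null(args$gap_mean)) args$gap_mean else 5
  gap_var <- if (!is.null(args$gap_variance)) args$gap_variance else 0
  args$gap_mean <- NULL
  args$gap_variance <- NULL
  args$gap <- gap_spec(gap_mean, gap_var)
  do.call(sim_params, args)
}

#' Write a simulation config file
#'
#' @param params A \code{\link{sim_params}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sim_config <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  flat <- params
  flat$gap <- NULL
  lines <- c(
    vapply(names(flat), function(k)
      sprintf("%s = %s", k, format(flat[[k]], scientific = FALSE)),
      character(1L)),
    sprintf("gap_mean = %s", format(params$gap$mean_len)),
    sprintf("gap_variance = %s", format(params$gap$variance)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Every CLI run writes one manifest sufficient to reproduce it: the
#' subcommand, the full parameter echo including the seed, input/output
#' paths, the package version and a wall-clock stamp.
#'
#' @param subcommand Subcommand name.
#' @param params Named list echoing all parameters (seed included).
#' @param paths Named list of input/output paths.
#' @param path Manifest output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(subcommand, params, paths, path) {
  manifest <- list(
    tool = "quadmark",
    version = as.character(utils::packageVersion("quadmark")),
    subcommand = subcommand,
    parameters = params,
    paths = paths,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path) {
  drop <- vapply(x, is.list, logical(1L))
  utils::write.table(x[, !drop, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
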