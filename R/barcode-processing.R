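#' Barcode census: per-sample barcode counts with metadata
#'
#' A census maps barcode sequences to read (or cell) counts for one sample,
#' together with the sample's condition (POT / DMSO / GEF / TRM), timepoint
#' and compartment (attached cells harvested at the end, or floating dead
#' cells collected from spent media).
#'
#' @param counts Named non-negative numeric vector (names are barcode
#'   sequences).
#' @param sample_id Sample identifier, e.g. `"GEF1"`.
#' @param condition One of `"POT"`, `"DMSO"`, `"GEF"`, `"TRM"`.
#' @param timepoint Week index, or `NA` for final harvest.
#' @param compartment `"attached"` or `"floating"`.
#' @return A list of class `barcode_census` with elements `sample_id`,
#'   `condition`, `timepoint`, `compartment`, `counts` and `frequencies`
#'   (counts normalised to sum to 1; `NULL` when all counts are zero).
#' @export
barcode_census <- function(counts, sample_id,
                           condition = c("POT", "DMSO", "GEF", "TRM"),
                           timepoint = NA, compartment = "attached") {
  condition <- match.arg(condition)
  if (is.null(names(counts)) && length(counts) > 0)
    stop("'counts' must be named by barcode sequence")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!compartment %in% c("attached", "floating"))
    stop("'compartment' must be 'attached' or 'floating'")
  total <- sum(counts)
  freqs <- if (total > 0) counts / total else NULL
  structure(list(sample_id = sample_id, condition = condition,
                 timepoint = timepoint, compartment = compartment,
                 counts = counts, frequencies = freqs),
            class = "barcode_census")
}

#' @export
print.barcode_census <- function(x, ...) {
  cat(sprintf("barcode_census %s [%s, %s, t=%s]: %d barcodes, %s reads\n",
              x$sample_id, x$condition, x$compartment,
              as.character(x$timepoint), length(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Normalise census counts to frequencies
#'
#' @param census A [barcode_census()] (or a bare named count vector).
#' @return The census with `frequencies = counts / sum(counts)`.
#' @export
census_to_frequencies <- function(census) {
  counts <- if (inherits(census, "barcode_census")) census$counts else census
  total <- sum(counts)
  if (total <= 0) stop("census is empty: total count is zero")
  freqs <- counts / total
  if (inherits(census, "barcode_census")) {
    census$frequencies <- freqs
    census
  } else {
    freqs
  }
}

#' Does a sequence match a weak/strong base pattern?
#'
#' ClonTracer-style barcodes alternate weak (W = A/T) and strong (S = G/C)
#' bases; error reads usually break the pattern, so pattern conformity
#' distinguishes genuine barcodes from sequencing artefacts.
#'
#' @param seq Character vector of sequences.
#' @param pattern Pattern string of `W`/`S` symbols; default `(WS) x 15`.
#' @return Logical vector: `TRUE` where the sequence length matches the
#'   pattern and every W position holds A/T and every S position G/C.
#' @export
matches_ws_pattern <- function(seq, pattern = strrep("WS", 15)) {
  if (!grepl("^[WS]+$", pattern)) stop("'pattern' must use only W/S symbols")
  pat <- strsplit(pattern, "")[[1]]
  allowed <- list(W = c("A", "T"), S = c("G", "C"))
  vapply(seq, function(s) {
    if (is.na(s) || nchar(s) != length(pat)) return(FALSE)
    ch <- strsplit(s, "")[[1]]
    all(vapply(seq_along(pat),
               function(i) ch[i] %in% allowed[[pat[i]]], logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Read a FASTQ file, quality-filter, and extract flank-anchored barcodes
#'
#' Keeps only reads whose every base quality is strictly greater than
#' `min_q`, then extracts the `barcode_length`-base segment found between an
#' exact match of the 12-base forward flank and an exact match of the
#' 12-base reverse flank, and tallies occurrences of each extracted barcode.
#'
#' @param path Path to a FASTQ file (Phred+33 qualities).
#' @param min_q Quality threshold; bases must exceed it strictly.
#' @param flank_fwd,flank_rev Fixed primer-derived flanks (12 bases each).
#' @param barcode_length Barcode length between the flanks.
#' @return Named integer vector of raw barcode counts (may be empty, with a
#'   warning, when no read passes filtering and extraction).
#' @export
read_and_filter_fastq <- function(path, min_q = 20,
                                  flank_fwd = default_flanks()$fwd,
                                  flank_rev = default_flanks()$rev,
                                  barcode_length = 30) {
  if (nchar(flank_fwd) != 12 || nchar(flank_rev) != 12)
    stop("flanks must be 12 bases each")
  reads <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) stop("malformed FASTQ in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(reads) == 0) {
    warning("no reads in ", path)
    return(setNames(integer(0), character(0)))
  }
  qmat <- as(Biostrings::quality(reads), "matrix")
  rmin <- qmat[, 1]
  if (ncol(qmat) > 1) {
    for (j in 2:ncol(qmat)) rmin <- pmin(rmin, qmat[, j], na.rm = TRUE)
  }
  pass <- !is.na(rmin) & rmin > min_q
  if (!any(pass)) {
    warning("no reads passed the quality filter in ", path)
    return(setNames(integer(0), character(0)))
  }
  seqs <- suppressWarnings(as.character(reads[pass]))
  rx <- paste0(flank_fwd, "([ACGTN]{", barcode_length, "})", flank_rev)
  m <- regexpr(rx, seqs, perl = TRUE)
  hit <- m > 0
  if (!any(hit)) {
    warning("no reads matched the flank pattern in ", path)
    return(setNames(integer(0), character(0)))
  }
  full <- regmatches(seqs, m)
  bc <- substr(full, 13, 12 + barcode_length)
  tab <- table(bc)
  setNames(as.integer(tab), names(tab))
}

#' Merge error barcodes into weak/strong-conforming representatives
#'
#' Sequencing and PCR errors create low-count barcodes near true ones.
#' Each barcode is assigned to the nearest pattern-conforming
#' representative within `max_hamming` mismatches: barcodes violating the
#' weak/strong pattern merge into any representative in range, while
#' pattern-conforming barcodes (errors can preserve the weak/strong class
#' of a base) merge only into a strictly more abundant representative.
#' Candidate representatives are ranked by descending count (ties
#' lexicographic), so an equidistant error barcode merges into the more
#' abundant representative. Counts are conserved. Non-conforming barcodes
#' with no representative in range are kept as singletons and flagged.
#'
#' @param counts Named count vector of raw barcodes (equal-length
#'   sequences).
#' @param max_hamming Maximum Hamming distance for a merge (default 2).
#' @param pattern Weak/strong pattern (see [matches_ws_pattern()]).
#' @return Named count vector of merged barcodes (sorted by sequence),
#'   with attribute `"unmerged"` listing flagged non-conforming
#'   singletons.
#' @export
merge_barcodes <- function(counts, max_hamming = 2,
                           pattern = strrep("WS", 15)) {
  if (!length(counts)) {
    return(structure(counts, unmerged = character(0)))
  }
  if (length(unique(nchar(names(counts)))) != 1)
    stop("all barcode sequences must have the same length")
  conforming <- matches_ws_pattern(names(counts), pattern)
  reps <- counts[conforming]
  bad <- counts[!conforming]
  if (!length(reps)) {
    return(structure(counts[order(names(counts))], unmerged = names(bad)))
  }
  # priority order for ties: most abundant first, then lexicographic
  reps <- reps[order(-reps, names(reps))]
  # queries: all non-conforming barcodes (searched against every
  # representative) plus conforming ones (searched only against strictly
  # more abundant representatives); descending count order throughout
  bad <- bad[order(-bad, names(bad))]
  q_seq <- c(names(bad), names(reps))
  q_cnt <- c(bad, reps)
  limit <- c(rep.int(length(reps), length(bad)),
             vapply(reps, function(x) sum(reps > x), integer(1)))
  nn <- hamming_nearest_cpp(q_seq, names(reps), as.integer(max_hamming),
                            as.integer(limit))
  nbad <- length(bad)
  # where each representative's counts end up (self, or an absorber);
  # pointers always move to strictly larger counts, so chains terminate
  target <- seq_along(reps)
  conf_hit <- nn$index[nbad + seq_along(reps)]
  target[conf_hit > 0L] <- conf_hit[conf_hit > 0L]
  repeat {
    nxt <- target[target]
    if (identical(nxt, target)) break
    target <- nxt
  }
  alloc <- numeric(length(reps))
  ag <- tapply(as.numeric(reps), target, sum)
  alloc[as.integer(names(ag))] <- ag
  bad_idx <- if (nbad) nn$index[seq_len(nbad)] else integer(0)
  bhit <- bad_idx > 0L
  if (any(bhit)) {
    ag2 <- tapply(as.numeric(bad[bhit]), target[bad_idx[bhit]], sum)
    ix <- as.integer(names(ag2))
    alloc[ix] <- alloc[ix] + ag2
  }
  merged <- setNames(alloc, names(reps))
  merged <- merged[merged > 0]
  unmerged <- bad[!bhit]
  out <- c(merged, unmerged)
  structure(out[order(names(out))], unmerged = names(unmerged))
}

#' Write / read a census as a TSV table
#'
#' Columns: `sample_id`, `barcode`, `count`, `frequency`.
#'
#' @param census A [barcode_census()].
#' @param path Output path.
#' @return `write_census_tsv` returns `path` invisibly; `read_census_tsv`
#'   returns a `barcode_census`.
#' @export
write_census_tsv <- function(census, path) {
  stopifnot(inherits(census, "barcode_census"))
  df <- data.frame(sample_id = census$sample_id,
                   barcode = names(census$counts),
                   count = as.numeric(census$counts),
                   frequency = if (is.null(census$frequencies)) NA_real_
                               else as.numeric(census$frequencies))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_census_tsv
#' @param condition,timepoint,compartment Metadata for the census read back
#'   (a TSV stores counts only).
#' @export
read_census_tsv <- function(path, condition = "POT", timepoint = NA,
                            compartment = "attached") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  barcode_census(setNames(df$count, df$barcode),
                 sample_id = df$sample_id[1], condition = condition,
                 timepoint = timepoint, compartment = compartment)
}
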