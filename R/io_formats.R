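#' @importFrom stats quantile rnorm rpois runif setNames kmeans approx
#' @importFrom utils read.table write.table modifyList
NULL

# Internal coordinate convention: 0-based, half-open [start, end), the BED
# convention. rtracklayer/GRanges are 1-based closed; conversion happens at
# the I/O boundary and nowhere else.

format_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("tfoccupancy_format_error", "error")))
}

#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames with 0-based half-open coordinates
#' (`start` inclusive, `end` exclusive), the convention used throughout the
#' package.
#'
#' @param seqname character vector of sequence names.
#' @param start,end integer vectors, 0-based half-open; `0 <= start < end`.
#' @param score optional numeric vector.
#' @param strand optional character vector in `+`, `-`, `.`.
#' @return A `data.frame` with columns `seqname`, `start`, `end`, `score`,
#'   `strand`.
#' @export
genomic_intervals <- function(seqname, start, end, score = NA_real_,
                              strand = ".") {
  if (length(seqname) == 0) {
    return(data.frame(seqname = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  x <- data.frame(seqname = as.character(seqname),
                  start = as.integer(start), end = as.integer(end),
                  score = as.numeric(score), strand = as.character(strand),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  if (!all(c("seqname", "start", "end") %in% names(x)))
    format_error("intervals need seqname/start/end columns")
  if (any(is.na(x$seqname)) || any(!nzchar(x$seqname)))
    format_error("empty seqname in intervals")
  if (any(x$start < 0)) format_error("negative interval coordinates")
  if (any(x$start >= x$end)) format_error("interval start >= end")
  invisible(x)
}

# IRanges view of 0-based half-open intervals (for overlap machinery only)
intervals_to_iranges <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

#' Read a FASTA file into a sequence dictionary
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase DNA sequences (A/C/G/T/N only).
#' @export
read_fasta <- function(path) {
  # readDNAStringSet silently drops invalid letters with a warning;
  # promote that to the format error the alphabet contract requires
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) format_error("malformed FASTA: ",
                                                    conditionMessage(e)),
                   warning = function(w) format_error("malformed FASTA: ",
                                                      conditionMessage(w)))
  if (length(seqs) == 0) format_error("empty FASTA file: ", path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (any(grepl("[^ACGTN]", out)))
    format_error("sequence contains letters outside A,C,G,T,N")
  out
}

#' Write a sequence dictionary as FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Read genomic intervals from BED or narrowPeak
#'
#' narrowPeak `signalValue` is mapped to the `score` column (the BED score
#' column is discarded for that dialect, following ENCODE usage).
#'
#' @param path input file.
#' @param dialect `"bed"` or `"narrowPeak"`.
#' @return Interval data frame (see [genomic_intervals()]).
#' @export
read_intervals <- function(path, dialect = c("bed", "narrowPeak")) {
  dialect <- match.arg(dialect)
  gr <- tryCatch({
    if (dialect == "narrowPeak") {
      rtracklayer::import(path, format = "BED",
        extraCols = c(signalValue = "numeric", pValue = "numeric",
                      qValue = "numeric", peak = "integer"))
    } else {
      rtracklayer::import(path, format = "BED")
    }
  }, error = function(e) format_error("malformed ", dialect, " file: ",
                                      conditionMessage(e)))
  score <- if (dialect == "narrowPeak") gr$signalValue
           else if (!is.null(gr$score)) as.numeric(gr$score)
           else NA_real_
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  x <- data.frame(seqname = as.character(GenomicRanges::seqnames(gr)),
                  start = BiocGenerics::start(gr) - 1L,
                  end = BiocGenerics::end(gr),
                  score = if (length(score)) score else NA_real_,
                  strand = strand, stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

#' Write intervals as BED
#'
#' Writes BED6 when scores or strands are informative, BED3 otherwise.
#'
#' @param x interval data frame.
#' @param path output file.
#' @export
write_intervals <- function(x, path) {
  validate_intervals(x)
  has_extra <- (!is.null(x$score) && any(!is.na(x$score))) ||
    (!is.null(x$strand) && any(x$strand != "."))
  if (has_extra) {
    out <- data.frame(x$seqname, x$start, x$end, ".",
                      ifelse(is.na(x$score), 0, x$score),
                      if (is.null(x$strand)) "." else x$strand)
  } else {
    out <- data.frame(x$seqname, x$start, x$end)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Construct a per-base signal track
#'
#' A `SignalTrack` is a named list of numeric vectors, one value per base
#' pair per sequence. bedGraph/wiggle gaps are zero-filled on read: the
#' model treats bases without assay signal as inaccessible, so zero and
#' "no data" are deliberately not distinguished.
#'
#' @param values named list of finite numeric vectors.
#' @return A `SignalTrack` object.
#' @export
signal_track <- function(values) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("signal track sequences must be named")
  values <- lapply(values, as.numeric)
  if (any(vapply(values, function(v) any(!is.finite(v)), logical(1))))
    stop("signal track values must be finite")
  structure(values, class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat("SignalTrack:", length(x), "sequence(s),",
      sum(lengths(x)), "bp total\n")
  invisible(x)
}

track_lengths <- function(track) vapply(track, length, integer(1))

#' Read a signal track (wiggle, bedGraph or bigWig)
#'
#' The declared sequence lengths define the dense per-bp representation;
#' positions not covered by any record are filled with 0.
#'
#' @param path input file.
#' @param dialect `"bedGraph"`, `"wiggle"` or `"bigwig"`.
#' @param seq_lengths named integer vector of sequence lengths (bp).
#' @return A [signal_track()].
#' @export
read_signal <- function(path, dialect = c("bedGraph", "wiggle", "bigwig"),
                        seq_lengths) {
  dialect <- match.arg(dialect)
  fmt <- switch(dialect, bedGraph = "bedGraph", wiggle = "WIG",
                bigwig = "BigWig")
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) format_error("malformed ", dialect,
                                                  " file: ",
                                                  conditionMessage(e)))
  vals <- lapply(seq_lengths, function(L) numeric(L))
  if (length(gr)) {
    sq <- as.character(GenomicRanges::seqnames(gr))
    unknown <- setdiff(unique(sq), names(seq_lengths))
    if (length(unknown))
      format_error("signal on undeclared sequence(s): ",
                   paste(unknown, collapse = ", "))
    st <- BiocGenerics::start(gr); en <- BiocGenerics::end(gr)
    sc <- as.numeric(gr$score)
    if (dialect == "bedGraph") {
      for (s in unique(sq)) {
        i <- which(sq == s)
        o <- i[order(st[i])]
        if (length(o) > 1 && any(st[o][-1] <= en[o][-length(o)]))
          format_error("overlapping bedGraph segments on ", s)
      }
    }
    for (i in seq_along(gr)) {
      s <- sq[i]
      if (en[i] > seq_lengths[[s]] || st[i] < 1)
        format_error("signal segment outside declared sequence length")
      vals[[s]][st[i]:en[i]] <- sc[i]
    }
  }
  signal_track(vals)
}

#' Write a signal track
#'
#' Constant runs are collapsed to one record; zero runs are omitted
#' (re-reading restores them by the zero-fill contract).
#'
#' @param track a [signal_track()].
#' @param path output file.
#' @param dialect `"bedGraph"`, `"wiggle"` or `"bigwig"`.
#' @export
write_signal <- function(track, path,
                         dialect = c("bedGraph", "wiggle", "bigwig")) {
  dialect <- match.arg(dialect)
  grl <- lapply(names(track), function(s) {
    r <- rle(track[[s]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    GenomicRanges::GRanges(s, IRanges::IRanges(starts[keep], ends[keep]),
                           score = r$values[keep])
  })
  gr <- suppressWarnings(do.call(c, grl))
  GenomeInfoDb::seqlengths(gr) <- track_lengths(track)[
    GenomeInfoDb::seqlevels(gr)]
  fmt <- switch(dialect, bedGraph = "bedGraph", wiggle = "WIG",
                bigwig = "BigWig")
  rtracklayer::export(gr, path, format = fmt)
  invisible(path)
}

#' Read a JASPAR position frequency matrix
#'
#' Accepts the JASPAR text format with or without `A [ ... ]` row labels
#' and with an optional `>ID name` header. Rows are reordered to A,C,G,T
#' regardless of label order in the file.
#'
#' @param path input file.
#' @return A `PFM` object: list with `matrix` (4 x m, rows A,C,G,T),
#'   `id`, `name`.
#' @examples
#' pfm <- read_jaspar_pfm(system.file("extdata", "synthetic_motif.jaspar",
#'                                    package = "tfoccupancy"))
#' pfm
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  id <- NA_character_; name <- NA_character_
  if (length(lines) && startsWith(lines[1], ">")) {
    hdr <- strsplit(sub("^>", "", lines[1]), "\\s+")[[1]]
    id <- hdr[1]
    if (length(hdr) > 1) name <- paste(hdr[-1], collapse = " ")
    lines <- lines[-1]
  }
  if (length(lines) != 4)
    format_error("JASPAR PFM must have exactly 4 matrix rows, found ",
                 length(lines))
  labels <- character(4)
  rows <- vector("list", 4)
  for (i in 1:4) {
    ln <- lines[i]
    m <- regmatches(ln, regexec("^([ACGTacgt])\\s*\\[?\\s*(.*?)\\s*\\]?$", ln))[[1]]
    if (length(m) == 3 && nzchar(m[2])) {
      labels[i] <- toupper(m[2])
      num_part <- m[3]
    } else {
      labels[i] <- c("A", "C", "G", "T")[i]
      num_part <- gsub("[\\[\\]]", "", ln)
    }
    vals <- suppressWarnings(as.numeric(strsplit(trimws(num_part), "\\s+")[[1]]))
    if (any(is.na(vals))) format_error("non-numeric PFM entries in row ", i)
    rows[[i]] <- vals
  }
  if (length(unique(lengths(rows))) != 1)
    format_error("PFM rows have unequal lengths")
  if (!setequal(labels, c("A", "C", "G", "T")))
    format_error("PFM row labels must be A,C,G,T; found ",
                 paste(labels, collapse = ","))
  mat <- do.call(rbind, rows)[match(c("A", "C", "G", "T"), labels), ,
                              drop = FALSE]
  rownames(mat) <- c("A", "C", "G", "T")
  if (any(mat < 0)) format_error("negative PFM counts")
  if (any(colSums(mat) == 0)) format_error("PFM column with all-zero counts")
  structure(list(matrix = mat, id = id, name = name), class = "PFM")
}

#' Write a PFM in JASPAR text format
#'
#' @param pfm a `PFM` object.
#' @param path output file.
#' @export
write_jaspar_pfm <- function(pfm, path) {
  hdr <- sprintf(">%s %s",
                 ifelse(is.na(pfm$id), "MOTIF", pfm$id),
                 ifelse(is.na(pfm$name), "synthetic", pfm$name))
  rows <- vapply(1:4, function(i) {
    sprintf("%s [ %s ]", rownames(pfm$matrix)[i],
            paste(format(pfm$matrix[i, ], trim = TRUE), collapse = " "))
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @export
print.PFM <- function(x, ...) {
  cat("PFM", ifelse(is.na(x$id), "", x$id), "-", ncol(x$matrix),
      "columns\n")
  print(x$matrix)
  invisible(x)
}
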