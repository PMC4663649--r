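# Readers for alignments and partition schemes, and coverage extraction.
#
# Column intervals are 1-based inclusive (RAxML convention) at the interface;
# all conversion is confined to this file.

#' Read a multiple sequence alignment
#'
#' FASTA is read with \pkg{Biostrings} (which preserves `'?'` and any other
#' missing-data character); relaxed PHYLIP (sequential, whitespace-separated
#' names of any length, sequences possibly wrapped over lines) is read by
#' the package.  All sequences must have equal length.
#'
#' @param path File path.
#' @param format `"auto"` (default; FASTA if the first character is `>`),
#'   `"fasta"` or `"phylip"`.
#' @return An object of class `"msa"`: list with `taxa`, `seqs` (named
#'   character vector, upper case preserved as read) and `n_sites`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    head1 <- readChar(path, 2048L)
    first <- sub("^[\r\n[:space:]]*", "", head1)
    format <- if (startsWith(first, ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- as.character(ss)
    names(seqs) <- vapply(strsplit(names(ss), "[ \t]"), `[[`, "", 1L)
  } else {
    seqs <- read_relaxed_phylip(path)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(lens, collapse = ", "))
  }
  structure(list(taxa = names(seqs), seqs = seqs, n_sites = lens),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("Alignment:", length(x$taxa), "sequences x", x$n_sites, "sites\n")
  invisible(x)
}

read_relaxed_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("malformed PHYLIP header: ", lines[1L])
  }
  ntax <- as.integer(hdr[1L]); nsites <- as.integer(hdr[2L])
  toks <- unlist(strsplit(trimws(lines[-1L]), "\\s+"))
  seqs <- character(ntax); nms <- character(ntax)
  i <- 1L
  for (s in seq_len(ntax)) {
    if (i > length(toks)) stop("truncated PHYLIP file")
    nms[s] <- toks[i]; i <- i + 1L
    acc <- ""
    while (nchar(acc) < nsites) {
      if (i > length(toks)) {
        stop("sequence for '", nms[s], "' shorter than header length ",
             "(interleaved PHYLIP is not supported)")
      }
      acc <- paste0(acc, toks[i]); i <- i + 1L
    }
    if (nchar(acc) != nsites) stop("sequence for '", nms[s],
                                   "' does not match header length")
    seqs[s] <- acc
  }
  if (i <= length(toks)) stop("trailing content after ", ntax, " sequences")
  names(seqs) <- nms
  seqs
}

#' Read a RAxML-style partition file
#'
#' Lines of the form `TYPE, name = start-end[, start-end]*` with 1-based
#' inclusive column ranges.  Partitions need not cover all columns, but
#' overlapping intervals are rejected, as is the codon-interleaving syntax
#' (`1-100\3`).
#'
#' @param path File path.
#' @return An object of class `"partition_scheme"`: list with `names` and
#'   `ranges` (per partition, a 2-column start/end matrix).
#' @export
read_partitions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty partition file")
  nms <- character(0)
  ranges <- list()
  for (ln in lines) {
    if (grepl("\\\\", ln)) {
      stop("codon-interleaved partition syntax (e.g. '1-100\\3') is not ",
           "supported: ", ln)
    }
    m <- regexec("^[A-Za-z0-9+]+\\s*,\\s*([^=]+?)\\s*=\\s*(.+)$", ln)
    hit <- regmatches(ln, m)[[1L]]
    if (!length(hit)) stop("malformed partition line: ", ln)
    nm <- hit[2L]
    iv <- strsplit(hit[3L], ",")[[1L]]
    rows <- lapply(trimws(iv), function(r) {
      h <- regmatches(r, regexec("^([0-9]+)\\s*-\\s*([0-9]+)$", r))[[1L]]
      if (length(h)) return(as.integer(h[2:3]))
      if (grepl("^[0-9]+$", r)) return(as.integer(c(r, r)))
      stop("malformed range '", r, "' in partition line: ", ln)
    })
    rng <- do.call(rbind, rows)
    colnames(rng) <- c("start", "end")
    if (any(rng[, 1L] > rng[, 2L]) || any(rng < 1L)) {
      stop("invalid interval in partition line: ", ln)
    }
    nms <- c(nms, nm)
    ranges[[length(ranges) + 1L]] <- rng
  }
  if (anyDuplicated(nms)) stop("duplicate partition names")
  cols <- unlist(lapply(ranges, function(r) {
    unlist(lapply(seq_len(nrow(r)), function(i) r[i, 1L]:r[i, 2L]))
  }))
  if (anyDuplicated(cols)) stop("partitions have overlapping column ranges")
  structure(list(names = nms, ranges = ranges), class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat("Partition scheme with", length(x$names), "partitions\n")
  for (i in seq_along(x$names)) {
    cat(" ", x$names[i], "=",
        paste(apply(x$ranges[[i]], 1L, paste, collapse = "-"),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default missing-data characters
#'
#' The characters treated as "no data" when deciding presence: unknown
#' (`?`), gap (`-`), ambiguous (`N`/`X`, either case) and `.`.
#' @return Character vector.
#' @export
default_missing_chars <- function() c("?", "-", "N", "n", "X", "x", ".")

#' Extract a coverage matrix from an alignment and a partition scheme
#'
#' A taxon is present in a partition when its block contains at least
#' `min_sites` characters outside `missing_chars`; a block consisting
#' entirely of unknown characters is missing data for that partition.
#'
#' @param aln An alignment from [read_alignment()].
#' @param scheme A `partition_scheme`.
#' @param missing_chars Characters counting as missing.
#' @param min_sites Presence threshold (default 1 non-missing site).
#' @return A `coverage_matrix`.
#' @export
extract_coverage <- function(aln, scheme,
                             missing_chars = default_missing_chars(),
                             min_sites = 1L) {
  stopifnot(inherits(aln, "msa"), inherits(scheme, "partition_scheme"))
  maxcol <- max(vapply(scheme$ranges, max, 0L))
  if (maxcol > aln$n_sites) {
    stop("partition scheme addresses column ", maxcol,
         " but the alignment has only ", aln$n_sites, " sites")
  }
  chars <- strsplit(aln$seqs, "", fixed = TRUE)
  P <- length(scheme$names)
  m <- matrix(FALSE, nrow = length(aln$taxa), ncol = P,
              dimnames = list(aln$taxa, scheme$names))
  for (j in seq_len(P)) {
    rng <- scheme$ranges[[j]]
    cols <- unlist(lapply(seq_len(nrow(rng)),
                          function(i) rng[i, 1L]:rng[i, 2L]))
    for (i in seq_along(chars)) {
      m[i, j] <- sum(!(chars[[i]][cols] %in% missing_chars)) >= min_sites
    }
  }
  coverage_matrix(m)
}
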