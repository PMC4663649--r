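#' Create a taxon index
#'
#' A taxon index is the fixed, ordered universe of taxon labels for one
#' analysis.  Every split in the analysis is stored as a set of integer ranks
#' into this index, so all trees, moves and coverage matrices that are
#' compared with each other must share the same index.
#'
#' @param labels Character vector of unique, non-empty taxon labels.  The
#'   given order is kept and defines the integer rank of each taxon
#'   (rank 1 = first label).
#' @return A character vector of class `"taxon_index"`.
#' @examples
#' taxon_index(c("t1", "t2", "t3"))
#' @export
taxon_index <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("taxon index must contain at least one label")
  if (anyNA(labels) || any(!nzchar(labels))) {
    stop("taxon labels must be non-empty strings")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate taxon labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(labels, class = "taxon_index")
}

#' @export
print.taxon_index <- function(x, ...) {
  cat("Taxon index with", length(x), "taxa\n")
  utils::str(unclass(x))
  invisible(x)
}

# Rank lookup: labels -> integer positions in the index, with validation.
taxon_ranks <- function(taxa, labels) {
  r <- match(labels, taxa)
  if (anyNA(r)) {
    stop("unknown taxon label(s): ",
         paste(labels[is.na(r)], collapse = ", "))
  }
  r
}

# Accept a taxon subset given as labels, integer ranks or a logical mask and
# return sorted integer ranks.
as_rank_set <- function(taxa, y) {
  if (is.character(y)) {
    r <- taxon_ranks(taxa, unique(y))
  } else if (is.logical(y)) {
    if (length(y) != length(taxa)) stop("logical taxon mask has wrong length")
    r <- which(y)
  } else if (is.numeric(y)) {
    r <- as.integer(unique(y))
    if (any(r < 1L | r > length(taxa))) stop("taxon rank out of range")
  } else {
    stop("taxon subset must be labels, ranks or a logical mask")
  }
  sort(r)
}
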