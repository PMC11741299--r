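#' Genome sequence container
#'
#' A `cutnet_genome` holds one uppercase DNA string per chromosome and the
#' chromosome lengths. Coordinates throughout the package are 0-based,
#' half-open (BED convention).
#'
#' @param x named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return an object of class `cutnet_genome`.
#' @export
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(x))
    x <- stats::setNames(toupper(as.character(x)), nm)
  }
  if (!is.character(x) || is.null(names(x)) || anyNA(names(x)) ||
      any(names(x) == ""))
    stop("genome must be a named character vector or DNAStringSet")
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop("non-ACGTN characters in chromosome(s): ",
         paste(names(x)[bad], collapse = ", "))
  structure(list(seq = x, lengths = stats::setNames(nchar(x), names(x))),
            class = "cutnet_genome")
}

#' Read a genome FASTA
#'
#' @param path path to a FASTA file.
#' @return a `cutnet_genome`.
#' @export
read_genome <- function(path) {
  as_genome(Biostrings::readDNAStringSet(path))
}

#' Write a genome FASTA
#'
#' @param genome a `cutnet_genome`.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "cutnet_genome"))
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' @export
print.cutnet_genome <- function(x, ...) {
  cat("cutnet_genome:", length(x$seq), "chromosome(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Chromosome lengths
#' @param genome a `cutnet_genome`.
#' @return named integer vector of lengths in bp.
#' @export
seq_lengths <- function(genome) genome$lengths

#' Extract a subsequence
#'
#' Half-open 0-based interval `[start, end)`; positions outside the
#' chromosome are rejected.
#'
#' @param genome a `cutnet_genome`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return uppercase character string of length `end - start`.
#' @export
get_seq <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "cutnet_genome"))
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom)
  len <- genome$lengths[[chrom]]
  if (!(start >= 0 && start < end && end <= len))
    stop(sprintf("interval [%d,%d) outside %s (length %d)",
                 start, end, chrom, len))
  substr(genome$seq[[chrom]], start + 1L, end)
}

.BASES <- c("A", "C", "G", "T")

#' One-hot encode a DNA sequence
#'
#' A = (1,0,0,0), C = (0,1,0,0), G = (0,0,1,0), T = (0,0,0,1); any other
#' character (e.g. N) becomes an all-zero column.
#'
#' @param seq character string.
#' @return numeric matrix with 4 rows (A, C, G, T) and `nchar(seq)` columns.
#' @export
one_hot <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(ch, .BASES)
  m <- matrix(0, nrow = 4L, ncol = length(ch),
              dimnames = list(.BASES, NULL))
  keep <- which(!is.na(idx))
  m[cbind(idx[keep], keep)] <- 1
  m
}

#' Reverse complement of a DNA string
#' @param seq character string (ACGTN).
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Run code with a temporarily fixed RNG state; NULL seed leaves the session
# RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
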