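#' @keywords internal
"_PACKAGE"

#' @useDynLib periodscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm median phyper p.adjust setNames dist hclust
#'   cutree
#' @importFrom utils write.table head packageVersion
#' @importFrom graphics plot lines abline
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All randomized operations in the package funnel through this, so a
# (input, seed) pair always yields the same result.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Integer codes for the 5-letter alphabet used throughout: A=0 C=1 G=2 T=3 N=4.
.BASES <- c("A", "C", "G", "T", "N")

encode_seq <- function(seq) {
  if (length(seq) == 1L && nchar(seq) != 1L)
    seq <- strsplit(seq, "", fixed = TRUE)[[1L]]
  codes <- match(seq, .BASES) - 1L
  codes[is.na(codes)] <- 4L
  codes
}

decode_seq <- function(codes) {
  paste(.BASES[codes + 1L], collapse = "")
}

# Normalise a sequence argument (GenomeSequence, character scalar, or
# character vector of single letters) to an uppercase character scalar.
as_seq_string <- function(seq) {
  if (inherits(seq, "GenomeSequence")) return(seq$seq)
  if (is.character(seq) && length(seq) > 1L) seq <- paste(seq, collapse = "")
  stopifnot(is.character(seq), length(seq) == 1L)
  clean_seq(seq)
}

# Uppercase and mask everything outside A/C/G/T as N.
clean_seq <- function(seq) {
  s <- toupper(seq)
  gsub("[^ACGT]", "N", s)
}

# Header comment written at the top of every tabular/BED output.
output_header <- function(params = list()) {
  ver <- as.character(utils::packageVersion("periodscan"))
  p <- if (length(params))
    paste(names(params), vapply(params, function(x) paste(x, collapse = ","),
                                character(1)), sep = "=", collapse = " ")
  else ""
  sprintf("# periodscan %s %s", ver, p)
}
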