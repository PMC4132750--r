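#' Dinucleotide motif sets
#'
#' A `MotifSet` is a named collection of dinucleotides defining the binary
#' indicator track on which all periodicity statistics are computed. The
#' built-in sets are the 16 single dinucleotides, `WW` (all A/T combinations,
#' \{AA, AT, TA, TT\}) and `AT2` (WW without the TpA step, \{AA, AT, TT\} —
#' the minimal AT-tract unit; runs of A/T lacking TpA bend the DNA axis into
#' the minor groove, and phasing such tracts at the helical pitch produces
#' intrinsic curvature).
#'
#' @param x a motif name (`"AT2"`, `"WW"`, or any dinucleotide such as
#'   `"AA"`), a character vector of dinucleotides, or a `MotifSet`.
#' @param name optional display name when `x` is a plain vector.
#' @return an object of class `MotifSet` with elements `name` and `members`.
#' @examples
#' motif_set("AT2")
#' motif_set(c("GG", "GC", "CC"), name = "Srich")
#' @export
motif_set <- function(x, name = NULL) {
  if (inherits(x, "MotifSet")) return(x)
  stopifnot(is.character(x), length(x) >= 1L)
  dinucs <- as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0))
  if (length(x) == 1L && x %in% names(.BUILTIN_MOTIFS)) {
    members <- .BUILTIN_MOTIFS[[x]]
    if (is.null(name)) name <- x
  } else {
    members <- toupper(x)
    bad <- setdiff(members, dinucs)
    if (length(bad))
      stop("not dinucleotides over {A,C,G,T}: ", paste(bad, collapse = ", "),
           call. = FALSE)
    members <- sort(unique(members))
    if (is.null(name)) name <- paste(members, collapse = "+")
  }
  structure(list(name = name, members = members), class = "MotifSet")
}

.BUILTIN_MOTIFS <- local({
  dinucs <- as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0))
  b <- as.list(dinucs)
  names(b) <- dinucs
  b$WW <- c("AA", "AT", "TA", "TT")
  b$AT2 <- c("AA", "AT", "TT")
  b
})

#' Names of all built-in motif sets
#'
#' The 16 dinucleotides plus `WW` and `AT2`, the column set of the per-genome
#' signal-to-noise report.
#' @return character vector of length 18.
#' @export
builtin_motifs <- function() names(.BUILTIN_MOTIFS)

#' @export
print.MotifSet <- function(x, ...) {
  cat(sprintf("MotifSet '%s': {%s}\n", x$name, paste(x$members, collapse = ", ")))
  invisible(x)
}

# 5x5 logical membership matrix over codes A,C,G,T,N; any pair involving N
# is a non-match by construction (row/col 5 all FALSE).
motif_matrix <- function(motif) {
  motif <- motif_set(motif)
  m <- matrix(FALSE, 5L, 5L, dimnames = list(.BASES, .BASES))
  for (d in motif$members) {
    a <- substr(d, 1L, 1L); b <- substr(d, 2L, 2L)
    m[a, b] <- TRUE
  }
  m
}
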