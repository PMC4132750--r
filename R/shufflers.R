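#' Dinucleotide-preserving sequence shuffle
#'
#' Random permutation of a sequence that preserves the exact count of every
#' dinucleotide (and hence the mononucleotide composition and the first and
#' last characters): an Euler-path shuffle over the order-2 de Bruijn
#' multigraph, following the Altschul–Erickson construction (a random
#' arborescence of last edges toward the end vertex, then random edge
#' orderings). This is the null model for the windowed periodicity scan: it
#' conditions on composition, so surviving spectral structure reflects the
#' ordering of the sequence, not its dinucleotide content.
#'
#' @param seq character sequence (or `GenomeSequence`).
#' @param seed integer seed; the shuffle is a pure function of (seq, seed).
#' @return shuffled character scalar.
#' @examples
#' dinucleotide_shuffle("ACGCGTACGT", seed = 1)
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  s <- as_seq_string(seq)
  if (nchar(s) < 2L) stop("sequence must have length >= 2", call. = FALSE)
  with_seed(seed, decode_seq(dinuc_shuffle_cpp(encode_seq(s))))
}

#' Codon-order shuffle of a coding sequence
#'
#' Uniformly permutes whole codons, destroying the amino-acid sequence and
#' any inter-codon phasing while preserving the codon multiset (and hence
#' codon usage bias and base composition).
#'
#' @param cds a [cds_record()] or nucleotide string of length divisible by 3.
#' @param seed integer seed.
#' @return object of the same type as the input.
#' @export
codon_order_shuffle <- function(cds, seed = NULL) {
  co <- split_codons(cds)
  out <- with_seed(seed, paste(co$codons[sample.int(length(co$codons))],
                               collapse = ""))
  rewrap_cds(cds, out)
}

#' Synonymous codon replacement
#'
#' Replaces each codon by one drawn uniformly from its synonym class under
#' the standard genetic code (stop codons are resampled within the stop
#' class), so the translated protein is unchanged but codon usage is
#' randomized ("without any codon usage bias"). An internal stop codon
#' triggers a warning but is still replaced within the stop class.
#'
#' @inheritParams codon_order_shuffle
#' @export
synonymous_replace <- function(cds, seed = NULL) {
  co <- split_codons(cds)
  syn <- synonym_classes()
  aa <- syn$aa_of[co$codons]
  if (any(is.na(aa)))
    stop("untranslatable codon(s): ",
         paste(unique(co$codons[is.na(aa)]), collapse = ", "), call. = FALSE)
  n <- length(co$codons)
  if (any(aa[-n] == "*"))
    warning("internal stop codon(s) present; resampling within the stop class",
            call. = FALSE)
  out <- with_seed(seed, {
    vapply(aa, function(a) {
      cl <- syn$class_of[[a]]
      cl[sample.int(length(cl), 1L)]
    }, character(1), USE.NAMES = FALSE)
  })
  rewrap_cds(cds, paste(out, collapse = ""))
}

#' Permute one codon position across a coding sequence
#'
#' Uniformly permutes the bases at a single codon position (I, II or III)
#' across all codons of the CDS, leaving the other two positions untouched.
#' The base composition at the permuted position is exactly preserved; only
#' its phase along the gene is destroyed.
#'
#' @inheritParams codon_order_shuffle
#' @param position `"I"`, `"II"` or `"III"` (or 1, 2, 3).
#' @export
codon_position_permute <- function(cds, position, seed = NULL) {
  pos <- if (is.character(position))
    match(toupper(position), c("I", "II", "III")) else as.integer(position)
  if (is.na(pos) || pos < 1L || pos > 3L)
    stop("position must be I, II or III", call. = FALSE)
  s <- cds_string(cds)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  idx <- seq(pos, length(chars), by = 3L)
  chars[idx] <- with_seed(seed, chars[idx][sample.int(length(idx))])
  rewrap_cds(cds, paste(chars, collapse = ""))
}

#' Apply a named permutation scheme to a coding sequence
#'
#' Dispatch helper used by the Q' analysis: `"identity"`, `"codon_order"`,
#' `"synonymous"`, `"position_I"`, `"position_II"`, `"position_III"`.
#'
#' @inheritParams codon_order_shuffle
#' @param scheme scheme name.
#' @export
apply_scheme <- function(cds, scheme, seed = NULL) {
  switch(scheme,
         identity = cds,
         codon_order = codon_order_shuffle(cds, seed),
         synonymous = synonymous_replace(cds, seed),
         position_I = codon_position_permute(cds, "I", seed),
         position_II = codon_position_permute(cds, "II", seed),
         position_III = codon_position_permute(cds, "III", seed),
         stop("unknown permutation scheme: ", scheme, call. = FALSE))
}

#' @rdname apply_scheme
#' @export
permutation_schemes <- function()
  c("codon_order", "synonymous", "position_I", "position_II", "position_III")

# ---- helpers ----------------------------------------------------------------

cds_string <- function(cds) {
  s <- if (inherits(cds, "CdsRecord")) cds$seq else as_seq_string(cds)
  if (nchar(s) %% 3L != 0L)
    stop("CDS length not divisible by 3", call. = FALSE)
  s
}

split_codons <- function(cds) {
  s <- cds_string(cds)
  starts <- seq(1L, nchar(s), by = 3L)
  list(seq = s, codons = substring(s, starts, starts + 2L))
}

rewrap_cds <- function(cds, seq) {
  if (inherits(cds, "CdsRecord")) cds_record(cds$gene_id, seq) else seq
}

#' Translate a coding sequence (standard genetic code)
#' @param cds a [cds_record()] or nucleotide string; length divisible by 3.
#' @return amino-acid string, `*` for stops, `X` for codons containing N.
#' @export
translate_cds <- function(cds) {
  co <- split_codons(cds)
  aa <- synonym_classes()$aa_of[co$codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# synonym classes from the standard genetic code (stops form their own class)
synonym_classes <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- Biostrings::GENETIC_CODE
    aa_of <- as.character(gc)
    names(aa_of) <- names(gc)
    class_of <- split(names(gc), as.character(gc))
    cache <<- list(aa_of = aa_of, class_of = class_of)
    cache
  }
})
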