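# shared fixture builders; everything is generated in code at test time

random_seq <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  periodscan:::with_seed(seed,
    paste(sample(alphabet, n, replace = TRUE), collapse = ""))
}

dinuc_counts <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(chars) < 2L) return(table(character()))
  table(paste0(chars[-length(chars)], chars[-1L]))
}

base_counts <- function(seq) table(strsplit(seq, "", fixed = TRUE)[[1L]])

codon_multiset <- function(seq) {
  starts <- seq(1L, nchar(seq), by = 3L)
  sort(substring(seq, starts, starts + 2L))
}

random_cds <- function(n_codons, seed = NULL) {
  periodscan:::with_seed(seed, {
    non_stop <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))
    paste0("ATG", paste(sample(non_stop, n_codons - 2L, replace = TRUE),
                        collapse = ""), "TAA")
  })
}

# all distinct orderings of the letters of `seq` sharing its dinucleotide
# count vector and endpoints (brute force; for short sequences only)
enumerate_dinuc_shuffles <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  stopifnot(n <= 8L)
  ref <- dinuc_counts(seq)
  perms <- unique(apply(gtools_permutations(chars), 1L, paste, collapse = ""))
  keep <- vapply(perms, function(p) {
    identical(as.vector(dinuc_counts(p)[names(ref)]), as.vector(ref)) &&
      length(dinuc_counts(p)) == length(ref) &&
      startsWith(p, chars[1L]) && endsWith(p, chars[n])
  }, logical(1))
  perms[keep]
}

# all permutations of a character vector (recursive, small n)
gtools_permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L, 1L))
  out <- NULL
  for (i in seq_len(n))
    out <- rbind(out, cbind(x[i], gtools_permutations(x[-i])))
  out
}

tiny_gff3 <- function(path, lines) {
  writeLines(c("##gff-version 3", lines), path)
  path
}
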