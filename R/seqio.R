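#' Genome sequence object
#'
#' A minimal container for one uppercase nucleotide sequence over
#' \{A,C,G,T,N\}; every character outside A/C/G/T (ambiguity codes,
#' lowercase leftovers) is masked to N at construction.
#'
#' @param id sequence identifier.
#' @param seq nucleotide string.
#' @return an object of class `GenomeSequence`: list with `id`, `seq`,
#'   `length`.
#' @export
genome_sequence <- function(id, seq) {
  s <- clean_seq(seq)
  structure(list(id = as.character(id), seq = s, length = nchar(s)),
            class = "GenomeSequence")
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat(sprintf("GenomeSequence %s: %d bp\n", x$id, x$length))
  invisible(x)
}

#' Strand-resolved coding sequence
#'
#' @param gene_id gene identifier.
#' @param seq coding-strand nucleotide string; length must be divisible by 3.
#' @return an object of class `CdsRecord`.
#' @export
cds_record <- function(gene_id, seq) {
  s <- clean_seq(seq)
  if (nchar(s) %% 3L != 0L)
    stop("CDS length not divisible by 3: ", gene_id, call. = FALSE)
  structure(list(gene_id = as.character(gene_id), seq = s, length = nchar(s)),
            class = "CdsRecord")
}

#' Reverse complement of a nucleotide string
#' @param seq character scalar over \{A,C,G,T,N\}.
#' @return the reverse complement, with N self-complementary.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
}

#' Read a FASTA file
#'
#' Records are uppercased and characters outside A/C/G/T masked to N; file
#' order is preserved.
#'
#' @param path FASTA file.
#' @param min_len sequences shorter than this are skipped with a warning
#'   (default 0; genome-scale workflows typically set 1000 or more to drop
#'   small plasmids and fragments).
#' @return named list of [genome_sequence()] objects.
#' @export
read_fasta <- function(path, min_len = 0L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    stop("FASTA format error at line 1: empty file", call. = FALSE)
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop("FASTA format error at line ", nonblank[1L],
         ": expected '>' header", call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- list()
  for (i in seq_along(set)) {
    g <- genome_sequence(ids[i], as.character(set[[i]]))
    if (g$length < min_len) {
      warning("skipping ", g$id, ": ", g$length, " bp < min_len ", min_len,
              call. = FALSE)
      next
    }
    out[[g$id]] <- g
  }
  out
}

#' Write sequences to FASTA
#' @param seqs list of `GenomeSequence` or `CdsRecord` objects.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    id <- if (inherits(s, "CdsRecord")) s$gene_id else s$id
    writeLines(paste0(">", id), con)
    n <- nchar(s$seq)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s$seq, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

# ---- feature intervals ------------------------------------------------------

# internal canonical form: data.frame with 0-based half-open coordinates
feature_frame <- function(seq_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          kind = character(), id = character()) {
  data.frame(seq_id = as.character(seq_id), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             kind = as.character(kind), id = as.character(id),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, genome = NULL) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(features)))
  bad <- features$start < 0L | features$end <= features$start
  if (!is.null(genome)) {
    len <- vapply(genome, function(g) g$length, numeric(1))
    known <- features$seq_id %in% names(len)
    bad <- bad | (known & features$end > len[features$seq_id])
  }
  if (any(bad))
    stop("feature coordinates out of bounds: ",
         paste(utils::head(features$id[bad], 5L), collapse = ", "),
         call. = FALSE)
  invisible(features)
}

#' Read genome annotation and extract coding sequences
#'
#' Converts GFF3 (1-based inclusive) or GenBank flat-file feature coordinates
#' to the package-wide 0-based half-open convention, splices compound
#' (`join`) CDS locations in annotation order, reverse-complements minus
#' strand CDS onto the coding strand, and drops (with a warning) CDS whose
#' spliced length is not divisible by 3.
#'
#' @param path annotation file.
#' @param fmt `"gff3"` or `"genbank"`.
#' @param genome for GFF3, the genome as returned by [read_fasta()] (needed
#'   to slice CDS sequences and check bounds); ignored for GenBank, whose
#'   ORIGIN block carries the sequence.
#' @return list with `features` (data.frame: seq_id, start, end, strand,
#'   kind, id; 0-based half-open), `cds` (list of [cds_record()]), and for
#'   GenBank also `genome`.
#' @export
read_annotation <- function(path, fmt = c("gff3", "genbank"), genome = NULL) {
  fmt <- match.arg(fmt)
  if (fmt == "gff3") read_gff3_annotation(path, genome)
  else read_genbank_annotation(path)
}

read_gff3_annotation <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  ids <- if (!is.null(md$ID)) as.character(md$ID) else rep(NA_character_, length(gr))
  if (!is.null(md$locus_tag))
    ids <- ifelse(is.na(ids), as.character(md$locus_tag), ids)
  ids[is.na(ids)] <- paste0("feat", seq_along(gr))[is.na(ids)]
  features <- feature_frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = ifelse(as.character(md$type) == "CDS", "CDS", "other"),
    id = ids)
  features$strand[features$strand == "*"] <- "."
  validate_features(features, genome)
  cds <- extract_cds(features, genome)
  list(features = features, cds = cds)
}

# Splice the (possibly multi-part) CDS of each gene id and strand-resolve.
extract_cds <- function(features, genome) {
  if (is.null(genome)) return(list())
  cdsf <- features[features$kind == "CDS", , drop = FALSE]
  out <- list()
  for (gid in unique(cdsf$id)) {
    parts <- cdsf[cdsf$id == gid, , drop = FALSE]
    g <- genome[[parts$seq_id[1L]]]
    if (is.null(g)) {
      warning("CDS ", gid, " references unknown sequence ", parts$seq_id[1L],
              call. = FALSE)
      next
    }
    spliced <- paste(substring(g$seq, parts$start + 1L, parts$end),
                     collapse = "")
    if (parts$strand[1L] == "-") spliced <- revcomp(spliced)
    if (nchar(spliced) %% 3L != 0L) {
      warning("excluding CDS ", gid, ": length ", nchar(spliced),
              " not divisible by 3", call. = FALSE)
      next
    }
    out[[gid]] <- cds_record(gid, spliced)
  }
  out
}

#' Intergenic complement of an annotated interval set
#'
#' The strand-agnostic complement of the union of the given intervals over
#' `[0, genome_length)`: the "intergenic" (non-annotated) part of the
#' genome. Result intervals are disjoint, sorted, `kind = "intergenic"`.
#'
#' @param features feature data.frame (one seq_id) or NULL/empty.
#' @param genome_length length of the parent sequence in bp.
#' @param seq_id identifier for the output intervals.
#' @return feature data.frame of intergenic intervals.
#' @export
intergenic_complement <- function(features, genome_length,
                                  seq_id = if (NROW(features)) features$seq_id[1L] else "seq") {
  if (NROW(features)) {
    stopifnot(length(unique(features$seq_id)) == 1L)
    ir <- IRanges::reduce(IRanges::IRanges(features$start + 1L, features$end))
    gap <- IRanges::gaps(ir, start = 1L, end = genome_length)
  } else {
    gap <- IRanges::IRanges(1L, genome_length)
  }
  feature_frame(seq_id = rep(seq_id, length(gap)),
                start = IRanges::start(gap) - 1L, end = IRanges::end(gap),
                strand = rep(".", length(gap)),
                kind = rep("intergenic", length(gap)),
                id = if (length(gap)) paste0("intergenic", seq_along(gap)) else character())
}

#' Write intervals as BED 3+
#'
#' 0-based half-open, native BED coordinates; a `#` header line records the
#' tool version and any parameters.
#'
#' @param features feature data.frame.
#' @param path output file.
#' @param params named list recorded in the header comment.
#' @export
write_bed <- function(features, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(params), con)
  if (NROW(features)) {
    name <- if (!is.null(features$id)) features$id else rep(".", nrow(features))
    write.table(data.frame(features$seq_id, features$start, features$end, name),
                con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a BED 3+ file
#' @param path BED file; `#` lines ignored.
#' @param kind kind label to assign.
#' @return feature data.frame (0-based half-open, as in the file).
#' @export
read_bed <- function(path, kind = "other") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) return(feature_frame())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  feature_frame(
    seq_id = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L)),
    strand = rep(".", length(parts)),
    kind = rep(kind, length(parts)),
    id = vapply(parts, function(p) if (length(p) >= 4L) p[4L] else ".", ""))
}

#' Write features as GFF3
#'
#' Converts the internal 0-based half-open coordinates back to GFF3's
#' 1-based inclusive convention at the boundary.
#'
#' @param features feature data.frame.
#' @param seq_lengths named integer vector of sequence lengths (for the
#'   `##sequence-region` pragmas).
#' @param path output file.
#' @export
write_gff3 <- function(features, seq_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (sid in names(seq_lengths))
    writeLines(sprintf("##sequence-region %s 1 %d", sid,
                       as.integer(seq_lengths[[sid]])), con)
  if (NROW(features)) {
    type <- ifelse(features$kind == "CDS", "CDS", features$kind)
    phase <- ifelse(features$kind == "CDS", "0", ".")
    writeLines(sprintf("%s\tperiodscan\t%s\t%d\t%d\t.\t%s\t%s\tID=%s",
                       features$seq_id, type, features$start + 1L,
                       features$end, features$strand, phase, features$id),
               con)
  }
  invisible(path)
}

# ---- GenBank flat file ------------------------------------------------------

# Minimal GenBank flat-file reader: LOCUS name, FEATURES (CDS + other keys),
# ORIGIN sequence. Handles join()/complement() locations; join parts are
# spliced in annotation order, then the whole spliced sequence is
# reverse-complemented if the location is complemented.
read_genbank_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  seq_id <- if (length(locus)) strsplit(trimws(locus[1L]), "\\s+")[[1L]][2L] else "genbank"

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank format error: no ORIGIN block", call. = FALSE)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1L]][1L] else length(lines) + 1L
  seq <- toupper(gsub("[^A-Za-z]", "", paste(lines[(ori[1L] + 1L):(endrec - 1L)],
                                             collapse = "")))
  genome <- genome_sequence(seq_id, seq)

  feat_start <- grep("^FEATURES", lines)
  features <- feature_frame()
  if (length(feat_start)) {
    block <- lines[(feat_start[1L] + 1L):(ori[1L] - 1L)]
    keys <- grepl("^ {5}\\S", block)
    idx <- which(keys)
    n_auto <- 0L
    for (j in seq_along(idx)) {
      first <- block[idx[j]]
      key <- sub("^ {5}(\\S+).*$", "\\1", first)
      if (key == "source") next
      to <- if (j < length(idx)) idx[j + 1L] - 1L else length(block)
      body <- block[idx[j]:to]
      # location may continue over lines until the first qualifier
      qual <- grep("^\\s+/", body)
      locend <- if (length(qual)) qual[1L] - 1L else length(body)
      loc <- paste(trimws(c(sub("^ {5}\\S+\\s*", "", first),
                            body[seq_len(locend)[-1L]])), collapse = "")
      p <- parse_gb_location(loc)
      if (is.null(p)) next
      tag <- sub('.*/locus_tag="([^"]+)".*', "\\1", paste(body, collapse = " "))
      if (identical(tag, paste(body, collapse = " ")))
        tag <- sub('.*/gene="([^"]+)".*', "\\1", paste(body, collapse = " "))
      if (identical(tag, paste(body, collapse = " "))) {
        n_auto <- n_auto + 1L
        tag <- sprintf("%s_%d", key, n_auto)
      }
      features <- rbind(features, feature_frame(
        seq_id = rep(seq_id, nrow(p$parts)),
        start = p$parts$start, end = p$parts$end,
        strand = rep(if (p$complement) "-" else "+", nrow(p$parts)),
        kind = rep(if (key == "CDS") "CDS" else "other", nrow(p$parts)),
        id = rep(tag, nrow(p$parts))))
    }
  }
  validate_features(features, setNames(list(genome), seq_id))
  cds <- extract_cds(features, setNames(list(genome), seq_id))
  list(features = features, cds = cds, genome = setNames(list(genome), seq_id))
}

# "complement(join(a..b,c..d))" etc. -> 0-based half-open parts + strand flag
parse_gb_location <- function(loc) {
  comp <- FALSE
  loc <- gsub("\\s", "", loc)
  while (grepl("^(complement|join|order)\\(", loc)) {
    op <- sub("^([a-z]+)\\(.*", "\\1", loc)
    if (op == "complement") comp <- !comp
    loc <- sub("^[a-z]+\\((.*)\\)$", "\\1", loc)
  }
  spans <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  spans <- gsub("[<>]", "", spans)
  ok <- grepl("^[0-9]+(\\.\\.[0-9]+)?$", spans)
  if (!all(ok) || !length(spans)) return(NULL)
  a <- as.integer(sub("\\.\\..*$", "", spans))
  b <- as.integer(sub("^[0-9]+(\\.\\.)?", "", sub("^([0-9]+)$", "\\1..\\1", spans)))
  list(parts = data.frame(start = a - 1L, end = b), complement = comp)
}
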