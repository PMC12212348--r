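#' Read a (multi-)FASTA file
#'
#' @param path FASTA file, plain or gzipped.
#' @return Named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("no sequences in FASTA file: ", path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(seqs))) stop("duplicate contig names in ", path)
  if (any(nchar(seqs) == 0)) stop("empty sequence in ", path)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (sequences and qualities)
#'
#' @param path FASTQ file, plain or gzipped.
#' @return A data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns on FASTQ input
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = sub("\\s.*$", "", names(x)),
             seq = unname(as.character(x)),
             qual = unname(as.character(Biostrings::quality(x))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq` and optionally `qual`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- if (is.null(reads$qual)) strrep("I", nchar(reads$seq)) else reads$qual
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), con)
  invisible(path)
}

#' Read phased genotypes from a VCF file
#'
#' Thin wrapper around `VariantAnnotation::readVcf` that extracts the fields
#' the pangenome builder needs.  Symbolic alleles (`<DEL>`, `<INS>`, ...) are
#' rejected.
#'
#' @param path VCF file (v4.x) with a GT FORMAT field.
#' @return A list: `variants` (data.frame with `chrom`, `pos`, `ref` and a
#'   list column `alts`), `gt` (character matrix, variants x samples, e.g.
#'   `"0|1"`), `samples`.
#' @export
read_vcf_gt <- function(path) {
  v <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  rr <- SummarizedExperiment::rowRanges(v)
  alts <- as.list(VariantAnnotation::alt(v))
  alts <- lapply(alts, as.character)
  if (any(vapply(alts, function(a) any(grepl("[<>\\[\\]]", a)), logical(1))))
    stop("symbolic or breakend ALT alleles are not supported")
  gt <- VariantAnnotation::geno(v)$GT
  if (is.null(gt)) stop("VCF has no GT FORMAT field: ", path)
  gt <- matrix(as.character(gt), nrow = nrow(gt), dimnames = dimnames(gt))
  variants <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    stringsAsFactors = FALSE)
  variants$alts <- alts
  list(variants = variants, gt = gt, samples = colnames(gt))
}

#' Write variant records to a VCF file
#'
#' Emits a minimal VCF v4.2 with phased GT fields, used by the synthetic
#' pangenome generator.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, list column `alts`.
#' @param gt character matrix (variants x samples) of phased genotypes.
#' @param contig_lens named integer vector of contig lengths for the header.
#' @param path output path.
#' @export
write_vcf <- function(variants, gt, contig_lens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(contig_lens),
                       as.integer(contig_lens)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(gt)), collapse = "\t")), con)
  if (nrow(variants) > 0) {
    alt_str <- vapply(variants$alts, paste, character(1), collapse = ",")
    body <- paste(variants$chrom, variants$pos, ".", variants$ref, alt_str,
                  ".", "PASS", ".", "GT", sep = "\t")
    for (j in seq_len(ncol(gt))) body <- paste(body, gt[, j], sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Parse a SAM text file
#'
#' Minimal reader for the SAM files this package emits (used by the
#' evaluation module and tests).
#'
#' @param path SAM file.
#' @return list(header = character lines, records = data.frame with the 11
#'   mandatory columns plus a `tags` column).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0) {
    rec <- data.frame(qname = character(), flag = integer(), rname = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      rnext = character(), pnext = integer(), tlen = integer(),
                      seq = character(), qual = character(), tags = character(),
                      stringsAsFactors = FALSE)
    return(list(header = hdr, records = rec))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(parts, `[[`, character(1), i)
  tags <- vapply(parts, function(p)
    if (length(p) > 11) paste(p[12:length(p)], collapse = "\t") else "",
    character(1))
  rec <- data.frame(qname = get(1), flag = as.integer(get(2)),
                    rname = get(3), pos = as.integer(get(4)),
                    mapq = as.integer(get(5)), cigar = get(6),
                    rnext = get(7), pnext = as.integer(get(8)),
                    tlen = as.integer(get(9)), seq = get(10), qual = get(11),
                    tags = tags, stringsAsFactors = FALSE)
  list(header = hdr, records = rec)
}
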