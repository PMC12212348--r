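#' Build an alignment index
#'
#' With a reference FASTA plus a phased VCF, every sample haplotype is
#' materialised, concatenated into the pangenome text together with the
#' reference (optional) and indexed; lift maps to the linear reference are
#' stored so alignments can be lifted back.  With FASTA input alone, each
#' record is indexed as its own document/genome and alignments are reported
#' in the coordinates of the indexed sequences (no liftover).
#'
#' @param fasta path to the reference FASTA (or multi-FASTA of haplotypes).
#' @param vcf optional path to a phased VCF with GT fields.
#' @param out_dir optional directory to persist the index into
#'   (see [save_index()]).
#' @param include_reference index the reference contigs as documents too
#'   (VCF mode only; default TRUE).
#' @param w,p prefix-free parsing parameters recorded in the metadata.
#' @return A `pm_index` object.
#' @export
pm_build_index <- function(fasta, vcf = NULL, out_dir = NULL,
                           include_reference = TRUE, w = 10L, p = 100L) {
  ref <- read_fasta(fasta)
  if (!is.null(vcf)) {
    vc <- read_vcf_gt(vcf)
    missing_ctg <- setdiff(unique(vc$variants$chrom), names(ref))
    if (length(missing_ctg))
      stop("VCF contigs absent from FASTA: ", paste(missing_ctg, collapse = ", "))
    haps <- list()
    for (s in vc$samples)
      for (ph in 1:2)
        haps[[length(haps) + 1L]] <- apply_variants(ref, vc, s, ph)
    pt <- build_pangenome_text(haps, include_reference = include_reference,
                               ref = ref)
    mode <- "vcf"
  } else {
    haps <- lapply(names(ref), function(nm) {
      structure(list(id = nm, contigs = setNames(ref[nm], nm),
                     liftmaps = setNames(list(identity_liftmap(nchar(ref[[nm]]), nm)), nm)),
                class = "pm_haplotype")
    })
    pt <- build_pangenome_text(haps, include_reference = FALSE, ref = NULL)
    # in FASTA mode each record is its own genome
    pt$genome_of_doc <- pt$doc_names
    mode <- "fasta"
  }
  ridx <- build_rindex(pt)
  idx <- structure(list(rindex = ridx, pt = pt, ref = ref, mode = mode,
                        meta = list(format_version = 1L, w = as.integer(w),
                                    p = as.integer(p),
                                    built = "panmem 0.1.0")),
                   class = "pm_index")
  if (!is.null(out_dir)) save_index(idx, out_dir)
  idx
}

#' @export
print.pm_index <- function(x, ...) {
  cat("panmem index (", x$mode, " mode): ", length(x$pt$doc_start),
      " documents, n = ", x$rindex$text_len, ", r = ", x$rindex$r, "\n", sep = "")
  invisible(x)
}

#' Persist an index to a directory
#'
#' The directory holds `meta.json` (format version, mode, contig and
#' document tables) and `index.rds` with the run-length BWT components,
#' samples, thresholds and lift maps.
#'
#' @param idx a `pm_index`.
#' @param dir output directory (created if needed).
#' @export
save_index <- function(idx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format_version = idx$meta$format_version, mode = idx$mode,
               w = idx$meta$w, p = idx$meta$p,
               contigs = names(idx$ref), contig_len = unname(nchar(idx$ref)),
               docs = idx$pt$doc_names, n = idx$rindex$text_len,
               r = idx$rindex$r)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  saveRDS(idx, file.path(dir, "index.rds"))
  invisible(dir)
}

#' Load a persisted index
#'
#' @param dir directory written by [save_index()].
#' @return A `pm_index`.
#' @export
load_index <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  if (is.null(meta$format_version) || meta$format_version != 1L)
    stop("unsupported index format in ", dir)
  idx <- readRDS(file.path(dir, "index.rds"))
  stopifnot(inherits(idx, "pm_index"))
  idx
}

# Flatten the per-document lift maps and reference sequences into the
# parallel arrays the C++ pipeline consumes.
index_bundles <- function(idx) {
  pt <- idx$pt
  nseg <- vapply(pt$doc_lifts, nrow, integer(1))
  lifts <- do.call(rbind, lapply(pt$doc_lifts, function(l)
    data.frame(hs = l$hs, rs = l$rs, len = l$len, kind = l$kind)))
  contigs <- names(idx$ref)
  list(
    pg = list(doc_start = pt$doc_start, doc_len = pt$doc_len,
              genome_of_doc = match(pt$genome_of_doc, unique(pt$genome_of_doc)) - 1L),
    lift = list(seg_off = c(0L, cumsum(nseg)),
                hs = as.integer(lifts$hs), rs = as.integer(lifts$rs),
                len = as.integer(lifts$len), kind = as.integer(lifts$kind),
                doc_contig = match(pt$doc_contig, contigs) - 1L),
    ref = list(contig_off = c(0L, cumsum(nchar(idx$ref))),
               seq = charToRaw(paste(idx$ref, collapse = ""))),
    contigs = contigs,
    contig_len = as.integer(nchar(idx$ref)))
}

#' Align reads and write SAM
#'
#' Runs the full pipeline: MEM seeding via matching statistics, occurrence
#' location with the per-genome cap, frequency/orientation filters, colinear
#' chaining with the uniqueness heuristic, gap-filling extension, liftover
#' with same-position deduplication, insert-size estimation (Welford, from
#' the first uniquely-aligning pairs), mate pairing within mean +/- 4 sd,
#' orphan recovery, and BWA-style mapping qualities.
#'
#' @param idx a `pm_index`.
#' @param fastq1 path to the first (or only) FASTQ file.
#' @param fastq2 optional path to the second mate FASTQ.
#' @param out_sam optional output SAM path.
#' @param cfg an [align_config()].
#' @return Invisibly, list(records = SAM record data.frame, header,
#'   insert = list(count, mean, sd)).  With `out_sam` set, the SAM text is
#'   written there (deterministic: identical inputs give identical bytes).
#' @export
pm_align <- function(idx, fastq1, fastq2 = NULL, out_sam = NULL,
                     cfg = align_config()) {
  stopifnot(inherits(idx, "pm_index"))
  rd1 <- read_fastq(fastq1)
  rd2 <- if (!is.null(fastq2)) read_fastq(fastq2) else NULL
  paired <- !is.null(rd2)
  if (paired && nrow(rd1) != nrow(rd2))
    stop("paired FASTQ files contain different read counts")
  bun <- index_bundles(idx)
  res <- cpp_align_batch(idx$rindex$cpp, bun$pg, bun$lift, bun$ref,
                         rd1$seq, if (paired) rd2$seq else NULL,
                         unclass(cfg))
  if (paired && res$insert_count < 2)
    warning("fewer than 2 uniquely aligning pairs; ",
            "falling back to single-end scoring")
  nrec <- length(res$flag)
  qn <- res$qname
  if (paired) {
    mate2 <- bitwAnd(res$flag, 0x80L) > 0L
    seq0 <- ifelse(mate2, rd2$seq[qn], rd1$seq[qn])
    qual0 <- ifelse(mate2, rd2$qual[qn], rd1$qual[qn])
    ids <- ifelse(mate2, rd2$id[qn], rd1$id[qn])
  } else {
    seq0 <- rd1$seq[qn]
    qual0 <- rd1$qual[qn]
    ids <- rd1$id[qn]
  }
  rev <- res$rev
  seq_out <- seq0
  qual_out <- qual0
  if (any(rev)) {
    seq_out[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq0[rev])))
    qual_out[rev] <- as.character(Biostrings::reverse(
      Biostrings::BStringSet(qual0[rev])))
  }
  records <- data.frame(
    qname = ids, flag = res$flag,
    rname = ifelse(res$rname >= 0, bun$contigs[res$rname + 1L], "*"),
    pos = ifelse(res$pos >= 0, res$pos + 1L, 0L),
    mapq = res$mapq, cigar = res$cigar,
    rnext = ifelse(res$rnext == -2L, "=",
                   ifelse(res$rnext >= 0, bun$contigs[res$rnext + 1L], "*")),
    pnext = ifelse(res$pnext >= 0, res$pnext + 1L, 0L),
    tlen = res$tlen, seq = seq_out, qual = qual_out,
    stringsAsFactors = FALSE)
  records$AS <- res$as
  records$XS <- res$xs
  records$NM <- res$nm
  header <- sam_header(bun$contigs, bun$contig_len,
                       cl = paste("panmem align", fastq1,
                                  if (paired) fastq2 else ""))
  if (!is.null(out_sam)) write_sam(records, header, out_sam)
  invisible(list(records = records, header = header,
                 insert = list(count = res$insert_count,
                               mean = res$insert_mean, sd = res$insert_sd)))
}

sam_header <- function(contigs, lens, cl = "panmem") {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", contigs, as.integer(lens)),
    paste0("@PG\tID:panmem\tPN:panmem\tVN:0.1.0\tCL:", trimws(cl)))
}

#' Write SAM records to a file
#'
#' @param records data.frame as produced by [pm_align()] (11 mandatory
#'   columns plus optional `AS`, `XS`, `NM` tag columns).
#' @param header character vector of header lines.
#' @param path output path.
#' @export
write_sam <- function(records, header, path) {
  lines <- header
  if (nrow(records) > 0) {
    tags <- rep("", nrow(records))
    if (!is.null(records$AS))
      tags <- ifelse(is.na(records$AS), tags,
                     paste0(tags, "\tAS:i:", as.integer(round(records$AS))))
    if (!is.null(records$XS))
      tags <- ifelse(is.na(records$XS), tags,
                     paste0(tags, "\tXS:i:", as.integer(round(records$XS))))
    if (!is.null(records$NM))
      tags <- ifelse(is.na(records$NM), tags,
                     paste0(tags, "\tNM:i:", records$NM))
    body <- paste0(records$qname, "\t", records$flag, "\t", records$rname,
                   "\t", records$pos, "\t", records$mapq, "\t", records$cigar,
                   "\t", records$rnext, "\t", records$pnext, "\t",
                   records$tlen, "\t", records$seq, "\t", records$qual, tags)
    lines <- c(lines, body)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
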