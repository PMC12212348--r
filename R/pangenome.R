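#' Apply phased variants to a reference, producing a haplotype and lift maps
#'
#' Builds one haplotype of a sample by substituting the alleles its phased
#' genotype selects into the reference, and records a lift map back to
#' reference coordinates.  Only indels break lift-map segments; SNPs do not
#' change coordinates.  Overlapping records on the same haplotype keep the
#' first and skip later ones with a warning; a REF allele that does not match
#' the reference is an error.  Unphased genotypes are rejected.
#'
#' @param ref named character vector of reference contig sequences.
#' @param vcf result of [read_vcf_gt()].
#' @param sample sample name present in the VCF.
#' @param phase 1 or 2, which haplotype of the sample to build.
#' @return A `pm_haplotype`: list(id, contigs = named character vector of
#'   haplotype sequences, liftmaps = named list of `pm_liftmap`).
#' @export
apply_variants <- function(ref, vcf, sample, phase) {
  stopifnot(phase %in% c(1L, 2L))
  if (!sample %in% vcf$samples) stop("sample not in VCF: ", sample)
  gt <- vcf$gt[, sample]
  if (length(gt) != nrow(vcf$variants)) stop("genotype/variant length mismatch")
  if (nrow(vcf$variants) > 0 && any(!grepl("|", gt, fixed = TRUE) & gt != "."))
    stop("unphased genotypes; haplotype-resolved input is required")
  allele <- vapply(strsplit(gt, "|", fixed = TRUE), function(g) {
    a <- suppressWarnings(as.integer(g[min(phase, length(g))]))
    if (is.na(a)) 0L else a
  }, integer(1))
  id <- paste0(sample, "#", phase)
  contigs <- character(0)
  liftmaps <- list()
  for (ctg in names(ref)) {
    sel <- which(vcf$variants$chrom == ctg & allele > 0L)
    sel <- sel[order(vcf$variants$pos[sel])]
    res <- apply_variants_contig(ref[[ctg]], vcf$variants[sel, , drop = FALSE],
                                 allele[sel], ctg, id)
    contigs[[ctg]] <- res$seq
    liftmaps[[ctg]] <- res$lift
  }
  structure(list(id = id, contigs = contigs, liftmaps = liftmaps),
            class = "pm_haplotype")
}

# One contig: substitute the chosen alleles and build the segment map.
apply_variants_contig <- function(refseq, vars, allele, contig, hap_id) {
  rlen <- nchar(refseq)
  pieces <- character(0)
  hs <- rs <- ln <- kd <- integer(0)   # emitted indel segments (0-based)
  ref_c <- 0L; hap_c <- 0L             # cursors, 0-based
  mh <- 0L; mr <- 0L                   # current match-run start (hap, ref)
  m_hs <- m_rs <- m_ln <- integer(0)   # match segments
  close_match <- function(hap_break, ref_break) {
    if (hap_break > mh) {
      m_hs <<- c(m_hs, mh); m_rs <<- c(m_rs, mr); m_ln <<- c(m_ln, hap_break - mh)
    }
  }
  prev_end <- -1L  # 0-based exclusive end of the previous variant's ref span
  for (k in seq_len(nrow(vars))) {
    p0 <- vars$pos[k] - 1L
    aref <- vars$ref[k]
    ai <- allele[k]
    alts <- vars$alts[[k]]
    if (ai > length(alts)) stop("genotype allele index out of range at ",
                                contig, ":", vars$pos[k])
    aalt <- alts[[ai]]
    if (substr(refseq, p0 + 1L, p0 + nchar(aref)) != aref)
      stop("REF allele mismatch at ", contig, ":", vars$pos[k])
    if (p0 < prev_end) {
      warning("overlapping variant at ", contig, ":", vars$pos[k],
              " skipped for haplotype ", hap_id)
      next
    }
    # unchanged stretch, then the anchored common part of the allele
    pieces <- c(pieces, substr(refseq, ref_c + 1L, p0))
    hap_c <- hap_c + (p0 - ref_c)
    L <- min(nchar(aref), nchar(aalt))
    pieces <- c(pieces, aalt)
    if (nchar(aalt) > nchar(aref)) {        # insertion in the haplotype
      close_match(hap_c + L, p0 + L)
      ins <- nchar(aalt) - L
      hs <- c(hs, hap_c + L); rs <- c(rs, p0 + L); ln <- c(ln, ins); kd <- c(kd, 1L)
      mh <- hap_c + L + ins; mr <- p0 + L
    } else if (nchar(aalt) < nchar(aref)) { # deletion in the haplotype
      close_match(hap_c + L, p0 + L)
      del <- nchar(aref) - L
      hs <- c(hs, hap_c + L); rs <- c(rs, p0 + L); ln <- c(ln, del); kd <- c(kd, 2L)
      mh <- hap_c + L; mr <- p0 + L + del
    }
    hap_c <- hap_c + nchar(aalt)
    ref_c <- p0 + nchar(aref)
    prev_end <- ref_c
  }
  pieces <- c(pieces, substr(refseq, ref_c + 1L, rlen))
  hap_c <- hap_c + (rlen - ref_c)
  close_match(hap_c, rlen)
  seq <- paste(pieces, collapse = "")
  stopifnot(nchar(seq) == hap_c)
  segs <- data.frame(hs = c(m_hs, hs), rs = c(m_rs, rs), len = c(m_ln, ln),
                     kind = c(rep(0L, length(m_hs)), kd))
  segs <- segs[order(segs$hs, -segs$kind), , drop = FALSE]
  rownames(segs) <- NULL
  lift <- structure(segs, class = c("pm_liftmap", "data.frame"))
  attr(lift, "hap_len") <- hap_c
  attr(lift, "ref_len") <- rlen
  attr(lift, "contig") <- contig
  list(seq = seq, lift = lift)
}

#' Identity lift map for a sequence aligned to itself
#'
#' @param len sequence length.
#' @param contig contig name.
#' @return A `pm_liftmap` with a single match segment.
#' @export
identity_liftmap <- function(len, contig) {
  lift <- structure(data.frame(hs = 0L, rs = 0L, len = as.integer(len),
                               kind = 0L),
                    class = c("pm_liftmap", "data.frame"))
  attr(lift, "hap_len") <- as.integer(len)
  attr(lift, "ref_len") <- as.integer(len)
  attr(lift, "contig") <- contig
  lift
}

#' Concatenate haplotypes into the index text
#'
#' Documents (haplotype/contig sequences) are joined by a separator byte and
#' the text ends with a terminator byte; both are reserved non-IUPAC bytes
#' strictly below every sequence character, so matches can never cross
#' document boundaries.
#'
#' @param haplotypes list of `pm_haplotype` objects (see [apply_variants()]).
#' @param include_reference also index the reference contigs as documents.
#' @param ref named character vector of reference contigs (required when
#'   `include_reference` is TRUE, or when lift maps should target it).
#' @return A `pm_pangenome_text`: list(text (raw), doc_start, doc_len,
#'   doc_names, genome_of_doc, doc_contig, doc_lifts).
#' @export
build_pangenome_text <- function(haplotypes, include_reference = TRUE,
                                 ref = NULL) {
  docs <- character(0); doc_names <- character(0)
  genome <- character(0); doc_contig <- character(0)
  doc_lifts <- list()
  if (isTRUE(include_reference)) {
    if (is.null(ref)) stop("include_reference = TRUE requires `ref`")
    for (ctg in names(ref)) {
      docs <- c(docs, ref[[ctg]])
      doc_names <- c(doc_names, ctg)
      genome <- c(genome, "__reference__")
      doc_contig <- c(doc_contig, ctg)
      doc_lifts <- c(doc_lifts, list(identity_liftmap(nchar(ref[[ctg]]), ctg)))
    }
  }
  for (h in haplotypes) {
    for (ctg in names(h$contigs)) {
      docs <- c(docs, h$contigs[[ctg]])
      nm <- if (length(h$contigs) > 1L) paste0(h$id, "#", ctg) else h$id
      doc_names <- c(doc_names, nm)
      genome <- c(genome, sub("#[12]$", "", h$id))
      doc_contig <- c(doc_contig, ctg)
      doc_lifts <- c(doc_lifts, list(h$liftmaps[[ctg]]))
    }
  }
  if (length(docs) == 0) stop("no haplotypes to index")
  if (any(grepl("[\x01\x02]", docs)))
    stop("sequences contain reserved separator bytes")
  text <- charToRaw(paste0(paste(docs, collapse = "\x02"), "\x01"))
  lens <- nchar(docs)
  starts <- c(0L, cumsum(lens[-length(lens)] + 1L))
  structure(list(text = text, doc_start = as.integer(starts),
                 doc_len = as.integer(lens), doc_names = doc_names,
                 genome_of_doc = genome, doc_contig = doc_contig,
                 doc_lifts = doc_lifts),
            class = "pm_pangenome_text")
}

#' Convert a global text offset to (document, local) coordinates
#'
#' @param pt a `pm_pangenome_text`.
#' @param gpos 0-based global offset.
#' @return list(doc = document index (1-based), local = 0-based offset), or
#'   an error if the offset falls on a separator/terminator byte.
#' @export
global_to_local <- function(pt, gpos) {
  d <- findInterval(gpos, pt$doc_start)
  if (d < 1) stop("offset before the first document")
  local <- gpos - pt$doc_start[d]
  if (local >= pt$doc_len[d])
    stop("global offset ", gpos, " is not a sequence position")
  list(doc = d, local = local)
}

#' Convert (document, local) coordinates to a global text offset
#'
#' @param pt a `pm_pangenome_text`.
#' @param doc 1-based document index.
#' @param local 0-based offset within the document.
#' @return 0-based global offset.
#' @export
local_to_global <- function(pt, doc, local) {
  stopifnot(doc >= 1, doc <= length(pt$doc_start))
  if (local < 0 || local >= pt$doc_len[doc])
    stop("local offset out of range")
  pt$doc_start[doc] + local
}

#' @export
print.pm_pangenome_text <- function(x, ...) {
  cat("pangenome text:", length(x$doc_start), "documents,",
      length(x$text), "bytes\n")
  invisible(x)
}

#' @export
print.pm_haplotype <- function(x, ...) {
  cat("haplotype", x$id, "-", length(x$contigs), "contig(s),",
      sum(nchar(x$contigs)), "bp\n")
  invisible(x)
}
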