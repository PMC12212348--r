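# Shared fixtures, built in code at test time.

# terminator-suffixed raw text for direct index construction over DNA
dna_text_raw <- function(s) charToRaw(paste0(s, "\x01"))

index_of <- function(s) build_rindex(dna_text_raw(s))

# a small deterministic pangenome simulation (cheap enough for many tests)
small_sim <- function(seed = 11L) {
  cfg <- sim_config(ref_length = 8000L, n_haplotypes = 4L, n_pairs = 150L,
                    insert_mean = 300, insert_sd = 30, seed = seed,
                    repeat_fraction = 0)
  sim <- simulate_pangenome(cfg)
  list(cfg = cfg, sim = sim)
}

# materialise a simulation to FASTA/VCF/FASTQ files under a tempdir
write_sim_files <- function(sim, reads = NULL, dir = tempfile("simfix")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(ref = file.path(dir, "ref.fa"),
                vcf = file.path(dir, "vars.vcf"),
                r1 = file.path(dir, "r1.fq"), r2 = file.path(dir, "r2.fq"),
                dir = dir)
  write_fasta(sim$ref, paths$ref)
  write_vcf(sim$variants, sim$gt, nchar(sim$ref), paths$vcf)
  if (!is.null(reads)) {
    write_fastq(reads$reads1, paths$r1)
    write_fastq(reads$reads2, paths$r2)
  }
  paths
}

# reference scoring scheme used throughout the tests
test_scheme <- function() scoring_scheme(match = 2, mismatch = 4,
                                         gap_open = 4, gap_extend = 2)
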