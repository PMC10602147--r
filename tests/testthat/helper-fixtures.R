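# Shared small fixtures, built in code.

suppressPackageStartupMessages(library(SummarizedExperiment))

smallDesign <- function(nGenes = 12L, guidesPerGene = 4L, nNTC = 60L)
  makeLibraryDesign(nGenes, guidesPerGene, nNTC)

smallScreen <- function(design = smallDesign(), seed = 7L, ...)
  normalizeCounts(simulateScreen(design, seed = seed, ...))

# 96 x K random signature matrix with unit column sums
randomSignatures <- function(K, seed = 1L, names = paste("Sig", seq_len(K)))
  withr::with_seed(seed, {
    m <- matrix(stats::rgamma(96 * K, shape = 0.5), 96, K,
                dimnames = list(contextLabels96(), names))
    SignatureSet(sweep(m, 2, colSums(m), "/"))
  })

# one valid SNV variant row, overridable field by field
variantRow <- function(...) {
  v <- data.frame(clone_id = "c1", chrom = "chr1", pos = 100L, ref = "C",
                  alt = "A", variant_type = "SNV", maf = 0.5,
                  depth_tumor = 60L, depth_normal = 55L, alt_reads = 30L,
                  context = "ACG", known_polymorphism = FALSE,
                  in_exome_interval = TRUE)
  mods <- list(...)
  for (nm in names(mods)) v[[nm]] <- mods[[nm]]
  v
}

# random variant record set mixing SNVs and indels around filter boundaries
randomVariants <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    labs <- contextLabels96()
    lab <- sample(labs, n, replace = TRUE)
    ref <- substr(lab, 3, 3)
    alt <- substr(lab, 5, 5)
    ctx <- paste0(substr(lab, 1, 1), ref, substr(lab, 7, 7))
    isIndel <- runif(n) < 0.2
    len <- sample(1:15, n, replace = TRUE)
    ref[isIndel] <- vapply(len[isIndel] + 1L, function(k)
      paste(rep("A", k), collapse = ""), character(1))
    alt[isIndel] <- "A"
    ctx[isIndel] <- "AAA"
    data.frame(clone_id = sample(c("c1", "c2", "c3"), n, replace = TRUE),
               chrom = "chr1", pos = seq_len(n) * 10L, ref = ref, alt = alt,
               variant_type = ifelse(isIndel, "deletion", "SNV"),
               maf = round(runif(n, 0, 0.4), 3),
               depth_tumor = sample(5:40, n, replace = TRUE),
               depth_normal = sample(5:40, n, replace = TRUE),
               alt_reads = sample(0:10, n, replace = TRUE),
               context = ctx,
               known_polymorphism = runif(n) < 0.1,
               in_exome_interval = runif(n) > 0.1)
  })
}

# minimal two-sample VCF text used by the VCF ingestion tests
toyVcfLines <- function(records = TRUE) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Trinucleotide context\">",
    "##INFO=<ID=KP,Number=0,Type=Flag,Description=\"Known polymorphism\">",
    "##INFO=<ID=EXON,Number=0,Type=Flag,Description=\"In exome interval\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##contig=<ID=chr1,length=248956422>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", "NORMAL", sep = "\t"))
  if (!records) return(hdr)
  c(hdr,
    paste("chr1", "101", ".", "C", "T", ".", "PASS", "CTX=ACG",
          "AF:DP:AD", "0.41:52:30,22", "0.0:48:48,0", sep = "\t"),
    paste("chr1", "205", ".", "G", "A", ".", "PASS", "CTX=TGA;KP",
          "AF:DP:AD", "0.22:61:47,14", "0.0:50:50,0", sep = "\t"),
    paste("chr1", "309", ".", "TACGT", "T", ".", "PASS", "CTX=TTA",
          "AF:DP:AD", "0.35:40:26,14", "0.0:44:44,0", sep = "\t"))
}
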