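# In-code fixtures: hand-built panels and random test pangenomes.

make_panel <- function(reference, variants, haps,
                       haplotype_names = NULL) {
    N <- ncol(haps)
    if (is.null(haplotype_names))
        haplotype_names <- as.vector(t(outer(sprintf("S%d", seq_len(N / 2)),
                                             1:2, paste, sep = ".")))
    cls <- classify_variant(variants$ref, variants$alt)
    variants$type <- cls$type
    variants$size <- cls$size
    variants$size_class <- cls$size_class
    variants$src_id <- sprintf("%s:%d:%s>%s", variants$chrom, variants$pos,
                               variants$ref, variants$alt)
    structure(list(variants = variants, haps = haps,
                   haplotype_names = haplotype_names, reference = reference),
              class = "panel")
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_seq_fixed <- function(n, seed) {
    set.seed(seed)
    rand_seq(n)
}

# Random small panel with controllable variant spacing; spacing >= 2k keeps
# bubble flanks disjoint so the reference-flank and path-window definitions
# of bubble-local k-mers coincide.
random_test_panel <- function(seed, n_var = 8, N = 4, len = 4000,
                              min_gap = 70, p_indel = 0.3) {
    set.seed(seed)
    ref <- rand_seq(len)
    pos <- sort(sample(seq(80, len - 80), n_var * 3))
    keep <- c(TRUE, diff(pos) >= min_gap)
    pos <- head(pos[keep], n_var)
    vars <- do.call(rbind, lapply(pos, function(p) {
        rb <- substr(ref, p, p)
        if (runif(1) < p_indel) {
            if (runif(1) < 0.5) {
                sz <- sample(1:8, 1)
                data.frame(chrom = "chrT", pos = p,
                           ref = substr(ref, p, p + sz), alt = rb)
            } else {
                data.frame(chrom = "chrT", pos = p, ref = rb,
                           alt = paste0(rb, rand_seq(sample(1:8, 1))))
            }
        } else {
            data.frame(chrom = "chrT", pos = p, ref = rb,
                       alt = sample(setdiff(c("A", "C", "G", "T"), rb), 1))
        }
    }))
    haps <- matrix(0L, nrow(vars), N)
    for (i in seq_len(nrow(vars)))
        haps[i, sample.int(N, sample.int(N - 1, 1))] <- 1L
    make_panel(c(chrT = ref), vars, haps)
}

# Two phased samples, three records, on a short reference; returned as
# written VCF + FASTA paths inside a temp dir.
write_tiny_vcf_fixture <- function(dir, gts = c("0|1", "1|1", "0|0"),
                                   gts2 = c("0|0", "0|1", "1|0")) {
    ref <- paste0(strrep("ACGTTGCA", 30))
    fa <- file.path(dir, "ref.fa")
    writeLines(c(">chr1", ref), fa)
    vcf <- file.path(dir, "panel.vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=chr1,length=240>",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                "FORMAT", "SA", "SB"), collapse = "\t"),
        sprintf("chr1\t41\t.\t%s\tT\t.\tPASS\t.\tGT\t%s\t%s",
                substr(ref, 41, 41), gts[1], gts2[1]),
        sprintf("chr1\t121\t.\t%s\tC\t.\tPASS\t.\tGT\t%s\t%s",
                substr(ref, 121, 121), gts[2], gts2[2]),
        sprintf("chr1\t201\t.\t%s\t%sAAAT\t.\tPASS\t.\tGT\t%s\t%s",
                substr(ref, 201, 201), substr(ref, 201, 201), gts[3], gts2[3])),
        vcf)
    list(fasta = fa, vcf = vcf, ref = ref)
}

# Deterministic small dataset used by CLI / golden-file tests.
golden_sim_config <- function() {
    sim_config(seed = 5, ref_length = 12000, n_haplotypes = 4,
               coverage = 20, repeat_fraction = 0.1,
               snp_rate = 2e-3, indel_rate = 4e-4, sv_rate = 1e-4)
}
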